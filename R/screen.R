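#' Run the full M-factor candidate screen
#'
#' Composes the two gates and the annotation exclusion: (1) the
#' chromosome-quotient male-specificity filter on genomic alignment counts;
#' (2) the staged presence/absence expression filter on (TMM-scale)
#' abundances; (3) exclusion of transposase/reverse-transcriptase-like
#' contigs flagged in the annotation. A reference is a final candidate iff
#' it passes both gates and is not excluded.
#'
#' References present in the count table but absent from the expression
#' matrix are treated as all-zero expression (they fail the `gt_zero`
#' rules) with a warning, mirroring quantifiers that drop unexpressed
#' contigs.
#'
#' @param counts count table (see [read_count_table()]); totals are taken
#'   from its attributes unless given.
#' @param expr expression table (raw or normalized; the filter depends only
#'   on the zero pattern).
#' @param samples sample sheet; defaults to the one attached to `expr`.
#' @param annotation optional annotation tibble with `id` and `te_like`.
#' @param params CQ thresholds from [cq_params()].
#' @param rules stage rules from [stage_rules()].
#' @param male_total,female_total library totals for depth normalization.
#' @param normalize depth-normalize the CQ statistic (default TRUE).
#' @param aggregation replicate aggregation for the expression filter.
#' @return a `screen_report`: per-reference tibble with the full filter
#'   trail (`cq`, `cq_pass`, `expr_pass`, `te_excluded`, `final_candidate`,
#'   `fail_reasons`), final candidates first, sorted by ascending `cq` then
#'   id. Gate counts are available via [glance()].
#' @examples
#' sim <- sim_params(n_m_linked = 2, n_autosomal = 20, seed = 1)
#' sc <- simulate_scenario(sim)
#' screen_candidates(sc$counts, sc$expression)
#' @export
screen_candidates <- function(counts, expr, samples = sample_sheet(expr),
                              annotation = NULL,
                              params = cq_params(), rules = stage_rules(),
                              male_total = attr(counts, "male_total"),
                              female_total = attr(counts, "female_total"),
                              normalize = TRUE,
                              aggregation = c("mean", "all_replicates")) {
  aggregation <- match.arg(aggregation)
  if (nrow(counts) == 0L) {
    return(new_screen_report(tibble(
      id = character(), male_count = numeric(), female_count = numeric(),
      cq = numeric(), cq_pass = logical(), expr_pass = logical(),
      te_excluded = logical(), final_candidate = logical(),
      fail_reasons = character())))
  }

  cq <- compute_cq(counts, male_total = male_total,
                   female_total = female_total, normalize = normalize) |>
    apply_cq_filter(params)

  missing_expr <- setdiff(counts$id, expr$ref_id)
  if (length(missing_expr) > 0L) {
    warn(sprintf(
      "%d reference(s) absent from the expression matrix treated as unexpressed (e.g. %s)",
      length(missing_expr), missing_expr[1]))
  }
  ev <- apply_expression_filter(expr, rules = rules, samples = samples,
                                aggregation = aggregation)
  # unexpressed refs fail every gt_zero rule and satisfy every eq_zero rule
  has_gt <- any(stage_rules_of(rules)$condition == "gt_zero")
  expr_pass <- setNames(ev$pass, ev$ref_id)

  ann_flag <- if (is.null(annotation)) {
    setNames(logical(0), character(0))
  } else {
    assert_columns(annotation, c("id", "te_like"), "annotation table")
    setNames(as.logical(annotation$te_like), annotation$id)
  }

  report <- cq |>
    as_tibble() |>
    rename(cq_pass = "pass", cq_fail_reason = "fail_reason") |>
    mutate(
      expr_pass = dplyr::coalesce(unname(expr_pass[.data$id]), !has_gt),
      te_excluded = dplyr::coalesce(unname(ann_flag[.data$id]), FALSE),
      final_candidate = .data$cq_pass & .data$expr_pass & !.data$te_excluded,
      fail_reasons = purrr::pmap_chr(
        list(.data$cq_pass, .data$cq_fail_reason, .data$expr_pass, .data$te_excluded),
        function(cqp, cqr, exp, te) {
          reasons <- c(if (!cqp) paste0("cq_filter:", cqr),
                       if (!exp) "expression_filter",
                       if (te) "transposase/RT-like")
          if (length(reasons) == 0L) NA_character_ else paste(reasons, collapse = ";")
        })
    ) |>
    select(-"cq_fail_reason") |>
    arrange(dplyr::desc(.data$final_candidate), .data$cq, .data$id)

  new_screen_report(report)
}

stage_rules_of <- function(rules) {
  assert_columns(rules, c("stage", "condition"), "stage rules")
  rules
}

new_screen_report <- function(report) {
  summary <- tibble(
    n_references = nrow(report),
    n_cq_pass = sum(report$cq_pass),
    n_expr_pass = sum(report$expr_pass),
    n_both_gates = sum(report$cq_pass & report$expr_pass),
    n_te_excluded = sum(report$cq_pass & report$expr_pass & report$te_excluded),
    n_final = sum(report$final_candidate)
  )
  structure(report, summary = summary,
            class = c("screen_report", class(report)))
}

#' @export
print.screen_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "M-factor candidate screen: %d references; CQ gate %d; both gates %d; TE-excluded %d; final candidates %d\n",
    s$n_references, s$n_cq_pass, s$n_both_gates, s$n_te_excluded, s$n_final))
  NextMethod()
}

#' Tidy a screen report
#' @param x a `screen_report`.
#' @param ... unused.
#' @return the per-reference filter trail as a plain tibble.
#' @method tidy screen_report
#' @export
tidy.screen_report <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "summary") <- NULL
  out
}

#' One-row gate summary of a screen report
#' @param x a `screen_report`.
#' @param ... unused.
#' @return tibble with columns `n_references`, `n_cq_pass`, `n_expr_pass`,
#'   `n_both_gates`, `n_te_excluded`, `n_final`.
#' @method glance screen_report
#' @export
glance.screen_report <- function(x, ...) {
  attr(x, "summary")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Write a screen report to TSV with a summary header
#'
#' The gate-count summary is written as `#`-prefixed comment lines followed
#' by one TSV row per reference, so the file re-reads cleanly with any
#' comment-aware TSV reader. Output is byte-stable across runs on identical
#' input.
#'
#' @param report a `screen_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  s <- glance(report)
  header <- c(
    "# M-factor candidate screen report",
    sprintf("# references: %d", s$n_references),
    sprintf("# cq_pass: %d", s$n_cq_pass),
    sprintf("# expr_pass: %d", s$n_expr_pass),
    sprintf("# both_gates: %d", s$n_both_gates),
    sprintf("# te_excluded: %d", s$n_te_excluded),
    sprintf("# final_candidates: %d", s$n_final)
  )
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    abort(sprintf("cannot write report to %s: %s", path, conditionMessage(e)))
  })
  on.exit(close(con), add = TRUE)
  writeLines(header, con)
  body <- tidy(report) |>
    mutate(cq = ifelse(is.na(.data$cq), "NA", formatC(.data$cq, digits = 10, format = "g")))
  writeLines(paste(names(body), collapse = "\t"), con)
  if (nrow(body) > 0L) {
    rows <- do.call(paste, c(lapply(body, as.character), sep = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}
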