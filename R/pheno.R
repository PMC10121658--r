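#' Per-tissue feminization summary of a phenotype group
#'
#' Tallies normal / feminized / malformed scores per sexually-dimorphic
#' tissue over all individuals of a group and formats the feminization
#' percentage over the whole group the way screen reports print it, e.g.
#' `"92% (36/39)"` (integer percentage, half-up).
#'
#' @param table per-individual phenotype tibble (see [read_phenotypes()]).
#' @param group which group to summarise (default `"mosaic"`).
#' @return tibble with one row per tissue: `tissue`, `n_feminized`,
#'   `n_malformed`, `n_normal`, `n_scored`, `pct_feminized` (integer,
#'   half-up, denominator = group size) and the formatted `label`; the
#'   group size is in attribute `total`.
#' @export
summarize_phenotypes <- function(table, group = "mosaic") {
  assert_columns(table, c("individual_id", "group", TISSUE_LEVELS),
                 "phenotype table")
  rows <- filter(table, .data$group == !!group)
  total <- nrow(rows)
  if (total == 0L) abort(sprintf("empty group '%s'", group))

  out <- purrr::map_dfr(TISSUE_LEVELS, function(tissue) {
    score <- rows[[tissue]]
    tibble(
      tissue = tissue,
      n_feminized = sum(score == "feminized"),
      n_malformed = sum(score == "malformed"),
      n_normal = sum(score == "normal"),
      n_scored = sum(score != "not_scored")
    )
  }) |>
    mutate(
      pct_feminized = round_half_up(100 * .data$n_feminized / total),
      label = purrr::map2_chr(.data$n_feminized, total, format_pct_fraction)
    )
  structure(out, total = total)
}

#' Injection / hatch / sex-ratio summary of knockout experiments
#'
#' Per replicate and pooled over replicates: hatch rate as a one-decimal
#' percentage of injected embryos, and adult sex shares as two-decimal
#' percentages of all adults, all rounded half-up — the conventions used in
#' published ablation-efficiency tables. The pooled row sums the raw counts
#' and recomputes the percentages.
#'
#' @param counts tibble with one row per replicate and columns `injected`,
#'   `hatched`, `adult_female`, `adult_male`,
#'   `feminized_or_deformed`; optional `group`/`pupae` columns are carried
#'   through.
#' @return the per-replicate rows plus a pooled row (`group = "pooled"`),
#'   with `hatch_pct`, `female_pct`, `male_pct` columns. `female_pct` and
#'   `male_pct` are `NA` when a row has no adults.
#' @export
summarize_injection <- function(counts) {
  need <- c("injected", "hatched", "adult_female", "adult_male",
            "feminized_or_deformed")
  assert_columns(counts, need, "injection table")
  counts <- as_tibble(counts)
  for (col in need) {
    x <- counts[[col]]
    if (any(x < 0 | x != trunc(x))) {
      abort(sprintf("`%s` must contain non-negative integers", col))
    }
  }
  if (any(counts$injected == 0)) abort("`injected` must be positive")
  if (any(counts$hatched > counts$injected)) {
    abort("`hatched` cannot exceed `injected`")
  }
  if (!"group" %in% names(counts)) {
    counts$group <- paste0("rep", seq_len(nrow(counts)))
  }

  pooled <- counts |>
    summarise(across(all_of(intersect(c(need, "pupae"), names(counts))), sum)) |>
    mutate(group = "pooled")
  all_rows <- bind_rows(counts, pooled)

  all_rows |>
    mutate(
      hatch_pct = round_half_up(100 * .data$hatched / .data$injected, 1),
      adults = .data$adult_female + .data$adult_male,
      female_pct = ifelse(.data$adults > 0,
                          round_half_up(100 * .data$adult_female / .data$adults, 2),
                          NA_real_),
      male_pct = ifelse(.data$adults > 0,
                        round_half_up(100 * .data$adult_male / .data$adults, 2),
                        NA_real_)
    ) |>
    select(-"adults") |>
    dplyr::relocate("group")
}

#' Total mosaic individuals across replicates
#'
#' @param feminized_or_deformed vector of per-replicate counts.
#' @return their sum (0 for an empty vector).
#' @examples
#' mosaic_total(c(20, 6, 13))  # 39
#' @export
mosaic_total <- function(feminized_or_deformed) {
  if (length(feminized_or_deformed) == 0L) return(0L)
  if (any(feminized_or_deformed < 0 |
          feminized_or_deformed != trunc(feminized_or_deformed))) {
    abort("counts must be non-negative integers")
  }
  as.integer(sum(feminized_or_deformed))
}

#' Relative expression fold change by the 2^-ddCt method
#'
#' `dCt_case = ct_target_case - ct_reference_case`, likewise for the
#' control; the fold change is `2^-(dCt_case - dCt_control)`. All arguments
#' are vectorised; a data frame with these four columns may be passed as
#' the single first argument.
#'
#' @param ct_target_case,ct_reference_case Ct cycles of the target and the
#'   internal-reference gene in the case (e.g. knockout) sample.
#' @param ct_target_control,ct_reference_control the same in the control.
#' @return numeric fold change(s).
#' @examples
#' fold_change_ddct(24, 20, 26.5, 20)  # 2^2.5
#' @export
fold_change_ddct <- function(ct_target_case, ct_reference_case = NULL,
                             ct_target_control = NULL,
                             ct_reference_control = NULL) {
  if (is.data.frame(ct_target_case)) {
    df <- ct_target_case
    need <- c("ct_target_case", "ct_reference_case",
              "ct_target_control", "ct_reference_control")
    assert_columns(df, need, "Ct table")
    return(fold_change_ddct(df$ct_target_case, df$ct_reference_case,
                            df$ct_target_control, df$ct_reference_control))
  }
  cts <- list(ct_target_case, ct_reference_case,
              ct_target_control, ct_reference_control)
  if (any(vapply(cts, function(x) is.null(x) || anyNA(x) || any(!is.finite(x)),
                 logical(1)))) {
    abort("all four Ct values must be finite and non-missing")
  }
  dct_case <- ct_target_case - ct_reference_case
  dct_control <- ct_target_control - ct_reference_control
  2^(-(dct_case - dct_control))
}
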