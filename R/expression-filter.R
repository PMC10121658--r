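#' Stage rules of the M-factor expression filter
#'
#' The screen's second gate demands the presence/absence signature of a
#' zygotically activated, male-limited transcript: expressed in 4–8 h and
#' 8–12 h embryos (after zygotic genome activation), silent in 0–1 h
#' embryos (no maternal deposition) and silent in adult females. These are
#' the default rules; pass any other set to change the signature.
#'
#' @param ... named conditions, one per stage: `stage = "gt_zero"` or
#'   `stage = "eq_zero"`. With no arguments the default four rules are
#'   returned (`E4_8h` > 0, `E8_12h` > 0, `E0_1h` = 0, `adult_female` = 0).
#' @return tibble with columns `stage` and `condition`.
#' @examples
#' stage_rules()
#' stage_rules(E4_8h = "gt_zero", adult_female = "eq_zero")
#' @export
stage_rules <- function(...) {
  rules <- list(...)
  if (length(rules) == 0L) {
    rules <- list(E4_8h = "gt_zero", E8_12h = "gt_zero",
                  E0_1h = "eq_zero", adult_female = "eq_zero")
  }
  stages <- names(rules)
  if (is.null(stages) || any(!nzchar(stages))) {
    abort("every rule must be named by its stage")
  }
  if (anyDuplicated(stages)) abort("at most one rule per stage")
  bad <- setdiff(stages, STAGE_LEVELS)
  if (length(bad) > 0L) {
    abort(sprintf("unknown stage(s) in rules: %s", paste(bad, collapse = ", ")))
  }
  cond <- unlist(rules, use.names = FALSE)
  if (!all(cond %in% c("eq_zero", "gt_zero"))) {
    abort("conditions must be 'eq_zero' or 'gt_zero'")
  }
  tibble(stage = stages, condition = cond)
}

#' Apply the staged expression filter
#'
#' A reference passes when every stage rule holds over that stage's
#' replicate columns. Under `aggregation = "mean"` an `eq_zero` rule
#' requires the replicate mean to be 0 (equivalently, all replicates 0,
#' since values are non-negative) and a `gt_zero` rule requires the mean to
#' be strictly positive (equivalently, any replicate positive). Under
#' `"all_replicates"` the condition must hold in every replicate
#' individually. Because the conditions are zero/nonzero, verdicts are
#' identical on raw and TMM-normalized values (normalization preserves
#' zeros exactly).
#'
#' @param expr expression table (`ref_id` + sample columns).
#' @param rules tibble from [stage_rules()].
#' @param samples sample sheet; defaults to the one attached to `expr`.
#' @param aggregation `"mean"` (default) or `"all_replicates"`.
#' @return tibble with `ref_id`, one logical verdict column per rule
#'   (named `<stage>_<condition>`), and overall `pass`.
#' @export
apply_expression_filter <- function(expr, rules = stage_rules(),
                                    samples = sample_sheet(expr),
                                    aggregation = c("mean", "all_replicates")) {
  aggregation <- match.arg(aggregation)
  samples <- validate_sample_sheet(samples)
  assert_columns(rules, c("stage", "condition"), "stage rules")
  absent <- setdiff(rules$stage, unique(samples$stage))
  if (length(absent) > 0L) {
    abort(sprintf("rule stage(s) absent from the sample sheet: %s",
                  paste(absent, collapse = ", ")))
  }
  x <- as_expr_matrix(expr)
  miss <- setdiff(samples$sample_id, colnames(x))
  if (length(miss) > 0L) {
    abort(sprintf("sample(s) missing from the matrix: %s",
                  paste(miss, collapse = ", ")))
  }

  out <- tibble(ref_id = expr$ref_id)
  for (i in seq_len(nrow(rules))) {
    cols <- samples$sample_id[samples$stage == rules$stage[i]]
    block <- x[, cols, drop = FALSE]
    verdict <- if (rules$condition[i] == "eq_zero") {
      if (aggregation == "mean") rowMeans(block) == 0 else rowSums(block > 0) == 0L
    } else {
      if (aggregation == "mean") rowMeans(block) > 0 else rowSums(block > 0) == ncol(block)
    }
    out[[paste(rules$stage[i], rules$condition[i], sep = "_")]] <- unname(verdict)
  }
  verdict_cols <- setdiff(names(out), "ref_id")
  out$pass <- rowSums(!as.matrix(out[verdict_cols])) == 0L
  out
}
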