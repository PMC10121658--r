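#' All screen parameters in one auditable object
#'
#' Collects every tunable of the candidate screen — CQ thresholds, stage
#' rules, TMM trim fractions, replicate aggregation, depth normalization —
#' with the screen's published defaults, so a run is fully described by one
#' object. Unknown arguments are rejected.
#'
#' @param cq CQ thresholds, see [cq_params()].
#' @param rules stage rules, see [stage_rules()].
#' @param logratio_trim,abs_trim TMM trim fractions, see [tmm_factors()].
#' @param aggregation replicate aggregation of the expression filter.
#' @param normalize depth-normalize the CQ statistic.
#' @return a `screen_config` list.
#' @export
screen_config <- function(cq = cq_params(), rules = stage_rules(),
                          logratio_trim = 0.30, abs_trim = 0.05,
                          aggregation = c("mean", "all_replicates"),
                          normalize = TRUE) {
  structure(list(cq = cq, rules = stage_rules_of(rules),
                 logratio_trim = logratio_trim, abs_trim = abs_trim,
                 aggregation = match.arg(aggregation),
                 normalize = isTRUE(normalize)),
            class = "screen_config")
}

#' Run the complete screen on a scenario bundle
#'
#' Convenience wrapper: TMM-normalizes the raw expression matrix, runs
#' [screen_candidates()] under a [screen_config()], and (when the bundle
#' carries a truth table) appends the planted linkage class for immediate
#' comparison.
#'
#' @param scenario a list as returned by [simulate_scenario()] or
#'   [read_scenario()], or a directory written by [make_scenario()].
#' @param config a [screen_config()].
#' @param annotation optional annotation tibble (`id`, `te_like`).
#' @return a `screen_report`; when truth is available it gains a `class`
#'   column with the planted linkage class.
#' @export
run_screen <- function(scenario, config = screen_config(), annotation = NULL) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  factors <- tmm_factors(scenario$expression,
                         logratio_trim = config$logratio_trim,
                         abs_trim = config$abs_trim)
  norm <- normalize_tmm(scenario$expression, factors)
  report <- screen_candidates(
    scenario$counts, norm,
    annotation = annotation,
    params = config$cq, rules = config$rules,
    normalize = config$normalize, aggregation = config$aggregation)
  if (!is.null(scenario$truth)) {
    joined <- left_join(tidy(report),
                        select(scenario$truth, all_of(c("id", "class"))),
                        by = "id")
    report <- new_screen_report(joined)
  }
  report
}
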