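#' Compute chromosome quotients
#'
#' The chromosome quotient (CQ) of a reference sequence is the ratio of
#' female to male genomic alignment counts, optionally after scaling each
#' count by its library total. Sequences carried only by males (hemizygous,
#' M-linked) attract essentially no female alignments and score near 0;
#' autosomal sequences score near 1; sequences with higher female copy
#' number score near 2.
#'
#' @param counts a data frame with columns `id`, `male_count`,
#'   `female_count` — typically a [read_count_table()] result or the
#'   simulator's output.
#' @param male_total,female_total library totals. Default to the totals
#'   attached to a `count_table`; required when `normalize = TRUE`.
#' @param normalize scale counts by library totals before taking the ratio
#'   (default TRUE). With near-equal library sizes this changes little, but
#'   it makes the statistic invariant to sequencing depth.
#' @return A `cq_tbl` tibble with columns `id`, `male_count`,
#'   `female_count`, `cq`. `cq` is `NA` (undefined) exactly when
#'   `male_count == 0`; such records can never pass the male-specificity
#'   filter. With `female_count == 0` and `male_count > 0`, `cq` is exactly
#'   0. The `normalize` choice is recorded in attribute `depth_normalized`.
#' @examples
#' counts <- tibble::tibble(id = c("m1", "a1"),
#'                          male_count = c(50, 100), female_count = c(0, 95))
#' compute_cq(counts, male_total = 1e6, female_total = 1e6)
#' @export
compute_cq <- function(counts, male_total = attr(counts, "male_total"),
                       female_total = attr(counts, "female_total"),
                       normalize = TRUE) {
  assert_columns(counts, c("id", "male_count", "female_count"), "count table")
  if (any(counts$male_count < 0) || any(counts$female_count < 0)) {
    abort("alignment counts must be non-negative")
  }
  if (normalize) {
    if (is.null(male_total) || is.null(female_total)) {
      abort("`male_total` and `female_total` are required when normalize = TRUE")
    }
    stopifnot_scalar_number(male_total, "male_total", min = 1)
    stopifnot_scalar_number(female_total, "female_total", min = 1)
    scale <- male_total / female_total
  } else {
    scale <- 1
  }
  out <- counts |>
    as_tibble() |>
    select(all_of(c("id", "male_count", "female_count"))) |>
    mutate(cq = dplyr::if_else(.data$male_count > 0,
                               scale * .data$female_count / .data$male_count,
                               NA_real_))
  structure(out, depth_normalized = isTRUE(normalize),
            class = c("cq_tbl", class(out)))
}

#' Default thresholds of the male-specificity CQ filter
#'
#' All three comparisons are strict, exactly as the screen defines them:
#' a record passes only with CQ strictly below `cq_max`, male count strictly
#' above `male_min` and female count strictly below `female_max`; boundary
#' values fail.
#'
#' @param cq_max upper CQ bound (exclusive), default 0.2.
#' @param male_min lower male-count bound (exclusive), default 20.
#' @param female_max upper female-count bound (exclusive), default 20.
#' @return named list of validated thresholds.
#' @export
cq_params <- function(cq_max = 0.2, male_min = 20, female_max = 20) {
  stopifnot_scalar_number(cq_max, "cq_max")
  if (cq_max <= 0) abort("`cq_max` must be > 0")
  stopifnot_scalar_number(male_min, "male_min", min = 0)
  stopifnot_scalar_number(female_max, "female_max", min = 0)
  list(cq_max = cq_max, male_min = male_min, female_max = female_max)
}

#' Apply the male-specificity CQ filter
#'
#' @param cq_records a `cq_tbl` from [compute_cq()] (any data frame with
#'   `id`, `male_count`, `female_count`, `cq` works).
#' @param params thresholds from [cq_params()].
#' @return the records with logical `pass` and a `fail_reason` column
#'   naming the first failed clause (`no male coverage`, `cq_max`,
#'   `male_min`, `female_max`; `NA` for passing records). Records with
#'   undefined CQ (no male coverage) never pass.
#' @export
apply_cq_filter <- function(cq_records, params = cq_params()) {
  assert_columns(cq_records, c("id", "male_count", "female_count", "cq"),
                 "CQ records")
  out <- cq_records |>
    as_tibble() |>
    mutate(
      pass = !is.na(.data$cq) &
        .data$cq < params$cq_max &
        .data$male_count > params$male_min &
        .data$female_count < params$female_max,
      fail_reason = dplyr::case_when(
        is.na(.data$cq) ~ "no male coverage",
        !(.data$cq < params$cq_max) ~ "cq_max",
        !(.data$male_count > params$male_min) ~ "male_min",
        !(.data$female_count < params$female_max) ~ "female_max",
        .default = NA_character_
      )
    )
  structure(out, depth_normalized = attr(cq_records, "depth_normalized"),
            class = unique(c("cq_tbl", class(out))))
}
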