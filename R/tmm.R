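#' TMM scaling factors from a raw abundance matrix
#'
#' Implements trimmed-mean-of-M-values (TMM) between-library normalization
#' from its definition. For each library j against a reference library r,
#' with counts y and library sizes N, every gene expressed in both gives a
#' log-ratio `M_g = log2((y_gj/N_j)/(y_gr/N_r))` and an average abundance
#' `A_g = (log2(y_gj/N_j) + log2(y_gr/N_r))/2`. The most extreme
#' `logratio_trim` fraction of M values on each side and `abs_trim`
#' fraction of A values on each side are discarded, and the scaling factor
#' is 2 to the power of the inverse-variance-weighted mean of the surviving
#' M values, with weights from the binomial (delta-method) variance
#' approximation `var(M_g) ~ (N_j - y_gj)/(N_j y_gj) + (N_r - y_gr)/(N_r y_gr)`.
#' Factors are rescaled so their geometric mean is 1.
#'
#' The reference library is auto-selected as the one whose 75th percentile
#' of `y/N` (over genes expressed in at least one library) is closest to
#' the across-library mean of those percentiles.
#'
#' @param expr an expression table (`ref_id` column plus one column per
#'   sample, e.g. from [read_expression()]) or a numeric matrix with
#'   samples in columns.
#' @param logratio_trim two-sided trim fraction on M values, default 0.30.
#' @param abs_trim two-sided trim fraction on A values, default 0.05.
#' @param reference_sample optional sample id (or column index) to use as
#'   the reference library instead of auto-selection.
#' @return tibble with columns `sample_id`, `lib_size` (column total) and
#'   `factor`. A library sharing no co-expressed gene with the reference
#'   gets factor 1 with a warning.
#' @examples
#' m <- matrix(rpois(200, 50), ncol = 4,
#'             dimnames = list(NULL, paste0("s", 1:4)))
#' tmm_factors(m)
#' @export
tmm_factors <- function(expr, logratio_trim = 0.30, abs_trim = 0.05,
                        reference_sample = NULL) {
  if (logratio_trim < 0 || logratio_trim >= 0.5 ||
      abs_trim < 0 || abs_trim >= 0.5) {
    abort("trim fractions must lie in [0, 0.5)")
  }
  x <- as_expr_matrix(expr)
  if (ncol(x) < 2L) abort("TMM needs at least 2 samples")
  lib_size <- colSums(x)
  if (any(lib_size <= 0)) abort("every library total must be > 0")

  keep <- rowSums(x > 0) > 0L
  xk <- x[keep, , drop = FALSE]

  if (is.null(reference_sample)) {
    q75 <- apply(xk, 2, stats::quantile, probs = 0.75, names = FALSE) / lib_size
    ref <- if (median(q75) < 1e-20) {
      which.max(colSums(sqrt(xk)))
    } else {
      which.min(abs(q75 - mean(q75)))
    }
  } else if (is.character(reference_sample)) {
    ref <- match(reference_sample, colnames(x))
    if (is.na(ref)) abort(sprintf("reference sample '%s' not found", reference_sample))
  } else {
    ref <- as.integer(reference_sample)
  }

  f <- vapply(seq_len(ncol(xk)), function(j) {
    tmm_pair_factor(xk[, j], xk[, ref], lib_size[j], lib_size[ref],
                    logratio_trim, abs_trim,
                    sample_id = colnames(x)[j])
  }, numeric(1))
  f <- f / exp(mean(log(f)))

  tibble(sample_id = colnames(x) %||% paste0("V", seq_len(ncol(x))),
         lib_size = unname(lib_size), factor = unname(f))
}

# doubly trimmed, inverse-variance-weighted mean of per-gene log-ratios for
# one library against the reference
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim,
                            sample_id = NULL) {
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  # binomial asymptotic variance of M_g; its reciprocal is the weight
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (length(m) == 0L) {
    warn(sprintf("library %s shares no expressed gene with the reference; factor set to 1",
                 sample_id %||% "?"))
    return(1)
  }
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abs_trim) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
  f <- sum(m[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

as_expr_matrix <- function(expr) {
  if (is.matrix(expr)) {
    if (is.null(colnames(expr))) {
      colnames(expr) <- paste0("V", seq_len(ncol(expr)))
    }
    return(expr)
  }
  assert_columns(expr, "ref_id", "expression table")
  m <- as.matrix(expr[setdiff(names(expr), "ref_id")])
  rownames(m) <- expr$ref_id
  m
}

#' Normalize an expression table with TMM factors
#'
#' Entries are rescaled to counts-per-million of the effective library size:
#' `raw / (lib_size * factor) * 1e6`. Zeros map to zeros exactly, so the
#' presence/absence pattern the expression filter relies on is preserved by
#' construction.
#'
#' @param expr raw expression table (`ref_id` + sample columns).
#' @param factors result of [tmm_factors()] (columns `sample_id`,
#'   `lib_size`, `factor`), aligned by sample id.
#' @return the normalized expression table (attribute `normalized = TRUE`).
#' @export
normalize_tmm <- function(expr, factors = tmm_factors(expr)) {
  assert_columns(factors, c("sample_id", "lib_size", "factor"), "factor table")
  if (any(factors$factor <= 0)) abort("scaling factors must be > 0")
  x <- as_expr_matrix(expr)
  miss <- setdiff(colnames(x), factors$sample_id)
  if (length(miss) > 0L) {
    abort(sprintf("no scaling factor for sample(s): %s",
                  paste(miss, collapse = ", ")))
  }
  idx <- match(colnames(x), factors$sample_id)
  eff <- factors$lib_size[idx] * factors$factor[idx]
  norm <- sweep(x, 2, eff, "/") * 1e6

  out <- bind_cols(tibble(ref_id = rownames(norm) %||% expr$ref_id),
                   as_tibble(norm))
  sheet <- attr(expr, "samples")
  if (!is.null(sheet)) {
    structure(out, samples = sheet, normalized = TRUE,
              class = c("expression_tbl", class(out)))
  } else {
    structure(out, normalized = TRUE, class = c("expression_tbl", class(out)))
  }
}
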