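#' Round half away from zero
#'
#' Decimal rounding with the "round half up" convention used throughout the
#' reported percentages (base R's `round()` rounds half to even). For the
#' non-negative percentages handled here, halves always round up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(0.5)        # 1
#' round_half_up(56.525, 2)  # 56.53
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# "P% (n/total)" with half-up integer percentage, as printed in phenotype
# summaries
format_pct_fraction <- function(n, total, digits = 0) {
  pct <- round_half_up(100 * n / total, digits)
  sprintf("%s%% (%d/%d)", format(pct, trim = TRUE), n, total)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number", name))
  }
  if (x < min) {
    abort(sprintf("`%s` must be >= %s (got %s)", name, format(min), format(x)))
  }
  if (integerish && x != trunc(x)) {
    abort(sprintf("`%s` must be a whole number (got %s)", name, format(x)))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# draws a reproducible sub-seed stream without disturbing the caller's RNG
# state; offsets keep the per-component streams independent so adding contigs
# to one class does not perturb draws in another
with_substream <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
  force(code)
}
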