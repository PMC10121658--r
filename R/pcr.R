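#' Reverse complement of a DNA string
#' @param dna DNA string (IUPAC alphabet).
#' @return reverse-complemented string, uppercase.
#' @export
reverse_complement <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(dna))))
}

#' In-silico PCR by exact primer matching
#'
#' Predicts amplicons from a primer pair on a template: the forward primer
#' is matched exactly on the forward strand and the reverse primer —
#' given 5'→3' on the opposite strand, as primers are ordered — is matched
#' as its reverse complement downstream of the forward site. Every
#' non-overlapping forward/reverse site pair with a product no longer than
#' `max_product` is reported. Degenerate-base expansion is not performed.
#'
#' @param template DNA string.
#' @param forward,reverse primer sequences, each at least 10 nt.
#' @param max_product maximum product length in nt (default 3000).
#' @return tibble with 0-based half-open `start`/`end` of the product
#'   (both primer footprints included) and `product_length = end - start`;
#'   zero rows when either site is absent or no pair satisfies the
#'   constraints. Sorted by `start`, then `end`.
#' @examples
#' tpl <- paste0("AAAA", "ACGTACGTACGT", strrep("T", 20),
#'               reverse_complement("GGCCGGCCGGCC"), "AAAA")
#' insilico_pcr(tpl, "ACGTACGTACGT", "GGCCGGCCGGCC")
#' @export
insilico_pcr <- function(template, forward, reverse, max_product = 3000) {
  if (nchar(forward) < 10L || nchar(reverse) < 10L) {
    abort("primers must be at least 10 nt long")
  }
  stopifnot_scalar_number(max_product, "max_product", min = 1)
  template <- toupper(template)
  fwd <- toupper(forward)
  rev_site <- reverse_complement(reverse)

  f_starts <- match_all_fixed(template, fwd)          # 0-based starts
  r_starts <- match_all_fixed(template, rev_site)
  empty <- tibble(start = integer(), end = integer(), product_length = integer())
  if (length(f_starts) == 0L || length(r_starts) == 0L) return(empty)

  pairs <- tidyr::expand_grid(f = f_starts, r = r_starts) |>
    mutate(start = .data$f,
           end = .data$r + nchar(rev_site),
           product_length = .data$end - .data$start) |>
    filter(.data$r >= .data$f + nchar(fwd),            # reverse site downstream
           .data$product_length <= max_product) |>
    select(all_of(c("start", "end", "product_length"))) |>
    arrange(.data$start, .data$end)
  pairs
}

# all (possibly overlapping) exact occurrences, 0-based starts
match_all_fixed <- function(subject, pattern) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                   Biostrings::DNAString(subject))
  Biostrings::start(hits) - 1L
}
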