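#' Translate DNA with the standard genetic code
#'
#' @param dna DNA string (IUPAC alphabet; case-insensitive).
#' @param frame reading-frame offset 0, 1 or 2.
#' @return amino-acid string; stop codons render as `*`, any codon
#'   containing an ambiguity code (N or another IUPAC degenerate base)
#'   renders as `X`, and a trailing partial codon is dropped.
#' @examples
#' translate_dna("ATGTTTTAA")      # "MF*"
#' translate_dna("ATGNNT")         # "MX"
#' @export
translate_dna <- function(dna, frame = 0) {
  if (!frame %in% 0:2) abort("`frame` must be 0, 1 or 2")
  dna <- toupper(dna)
  if (grepl("[^ACGTURYSWKMBDHVN]", dna)) {
    abort("non-IUPAC character in DNA sequence")
  }
  dna <- chartr("U", "T", dna)
  body <- substr(dna, frame + 1L, nchar(dna))
  n_codons <- nchar(body) %/% 3L
  if (n_codons == 0L) return("")
  starts <- seq(1L, by = 3L, length.out = n_codons)
  codons <- substring(body, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"   # any ambiguity code in the codon
  paste(aa, collapse = "")
}

#' Find the longest ATG-initiated ORF on the forward strand
#'
#' Scans all three forward frames for open reading frames that start at ATG
#' and terminate at an in-frame stop codon within the sequence (ORFs
#' without a stop are not reported — a transcript whose reading frame runs
#' off the end encodes no complete protein here). The longest ORF wins;
#' ties break to the 5'-most start. Inputs are mRNA-oriented, so the
#' reverse strand is not searched.
#'
#' @param sequence DNA string.
#' @return one-row tibble with 0-based half-open `start`/`end` (the stop
#'   codon included in the span), `frame` (0–2), `peptide_length`
#'   (`(end - start)/3 - 1`, excluding the stop) and `peptide`; a zero-row
#'   tibble when no ORF exists.
#' @examples
#' find_longest_orf("ATGAAATAG")  # peptide "MK"
#' @export
find_longest_orf <- function(sequence) {
  sequence <- toupper(sequence)
  none <- tibble(start = integer(), end = integer(), frame = integer(),
                 peptide_length = integer(), peptide = character())
  n <- nchar(sequence)
  if (n < 6L) return(none)

  best <- NULL
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3L
    if (n_codons < 2L) next
    starts_nt <- frame + seq(0L, by = 3L, length.out = n_codons)  # 0-based
    codons <- substring(sequence, starts_nt + 1L, starts_nt + 3L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    if (!any(is_start) || !any(is_stop)) next

    # for each stop, the eligible start is the first ATG after the previous
    # stop: that start gives the longest ORF ending at this stop
    prev_stop <- 0L
    for (k in which(is_stop)) {
      win <- which(is_start[seq.int(prev_stop + 1L, k)]) + prev_stop
      if (length(win) > 0L) {
        s <- win[1]
        len_nt <- (k - s + 1L) * 3L
        cand <- list(start = starts_nt[s], end = starts_nt[k] + 3L,
                     frame = frame, len = len_nt)
        if (is.null(best) || cand$len > best$len ||
            (cand$len == best$len && cand$start < best$start)) {
          best <- cand
        }
      }
      prev_stop <- k
    }
  }
  if (is.null(best)) return(none)
  orf_seq <- substr(sequence, best$start + 1L, best$end)
  peptide <- sub("\\*$", "", translate_dna(orf_seq))
  tibble(start = best$start, end = best$end, frame = best$frame,
         peptide_length = (best$end - best$start) %/% 3L - 1L,
         peptide = peptide)
}

#' Longest ORFs for every record of a reference set
#'
#' @param refs tibble with `id` and `sequence` columns (e.g. from
#'   [read_fasta()]).
#' @return tibble with one row per record that has an ORF: `id` plus the
#'   [find_longest_orf()] columns.
#' @export
orf_table <- function(refs) {
  assert_columns(refs, c("id", "sequence"), "reference set")
  purrr::map2_dfr(refs$id, refs$sequence, function(id, seq) {
    hit <- find_longest_orf(seq)
    if (nrow(hit) == 0L) return(NULL)
    bind_cols(tibble(id = id), hit)
  })
}
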