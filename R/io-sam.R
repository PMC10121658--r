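#' Tally alignments per reference from SAM text
#'
#' Counts alignment lines per reference for one sex's genomic library, the
#' raw material of the chromosome-quotient statistic. One SAM alignment line
#' contributes one count (read pairs are not collapsed); this convention is
#' deliberate and documented rather than inferred from the aligner.
#'
#' @param path path to a SAM text file with a header (`@SQ` lines declare
#'   the references; every reference named on an alignment line must be
#'   declared, otherwise a hard error).
#' @param mapq_min minimum MAPQ; alignment lines below it are skipped
#'   (default 0, i.e. keep everything mapped).
#' @param primary_only skip secondary (flag 0x100) and supplementary
#'   (0x800) alignment lines (default TRUE). Unmapped lines (0x4) are always
#'   skipped.
#' @return tibble with columns `id` and `count`, one row per `@SQ`
#'   reference (references with no surviving alignments count 0), in header
#'   order.
#' @export
count_alignments_from_sam <- function(path, mapq_min = 0, primary_only = TRUE) {
  stopifnot_scalar_number(mapq_min, "mapq_min", min = 0)
  lines <- readr::read_lines(path)
  is_header <- startsWith(lines, "@")

  sq <- lines[is_header & startsWith(lines, "@SQ")]
  refs <- stringr::str_match(sq, "\\tSN:([^\\t]+)")[, 2]
  refs <- refs[!is.na(refs)]
  if (length(refs) == 0L) abort("SAM header declares no @SQ references")

  aln <- lines[!is_header & nzchar(lines)]
  counts <- setNames(integer(length(refs)), refs)
  if (length(aln) > 0L) {
    fields <- stringr::str_split(aln, "\\t", n = 6L, simplify = TRUE)
    flag <- as.integer(fields[, 2])
    rname <- fields[, 3]
    mapq <- suppressWarnings(as.integer(fields[, 5]))
    if (anyNA(flag)) abort("malformed SAM: non-integer FLAG field")

    keep <- bitwAnd(flag, 0x4L) == 0L
    if (primary_only) {
      keep <- keep & bitwAnd(flag, 0x900L) == 0L
    }
    keep <- keep & !is.na(mapq) & mapq >= mapq_min
    rname <- rname[keep]

    unknown <- setdiff(unique(rname), c(refs, "*"))
    if (length(unknown) > 0L) {
      abort(sprintf("alignment to reference absent from @SQ header: %s",
                    unknown[1]))
    }
    tallied <- table(factor(rname, levels = refs))
    counts[] <- as.integer(tallied)
  }
  tibble(id = refs, count = unname(counts))
}
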