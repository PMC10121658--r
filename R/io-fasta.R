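#' Read a reference transcript set from FASTA
#'
#' Strict FASTA reader for reference transcript sets. Sequences are
#' uppercased, record order is preserved, and the file is validated as it is
#' read: duplicate record ids and characters outside the DNA alphabet
#' (A, C, G, T, N, case-insensitive) are hard errors that name the offending
#' id or line.
#'
#' @param path path to a FASTA file.
#' @return A tibble with one row per record and columns `id`, `description`
#'   (text after the first whitespace in the header, `NA` if none),
#'   `sequence` (uppercase) and `length` (nucleotides). An empty file yields
#'   a zero-row tibble.
#' @seealso [write_fasta()]
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 demo", "ACGTACGT", ">t2", "GGGTTT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  lines <- readr::read_lines(path)
  empty <- tibble(id = character(), description = character(),
                  sequence = character(), length = integer())
  if (length(lines) == 0L) return(empty)

  is_header <- startsWith(lines, ">")
  first_content <- which(nzchar(trimws(lines)))[1]
  if (is.na(first_content)) return(empty)
  if (!is_header[first_content]) {
    abort(sprintf("line %d: sequence data before the first '>' header",
                  first_content))
  }

  bad <- which(!is_header & grepl("[^ACGTNacgtn[:space:]]", lines))
  if (length(bad) > 0L) {
    abort(sprintf("line %d: illegal character in sequence (allowed: A,C,G,T,N)",
                  bad[1]))
  }

  header_idx <- which(is_header)
  header_txt <- sub("^>", "", lines[header_idx])
  id <- sub("[[:space:]].*$", "", header_txt)
  description <- ifelse(grepl("[[:space:]]", header_txt),
                        sub("^[^[:space:]]+[[:space:]]+", "", header_txt),
                        NA_character_)
  if (anyDuplicated(id)) {
    abort(sprintf("duplicate id %s", id[duplicated(id)][1]))
  }

  block <- findInterval(seq_along(lines), header_idx)
  seq_lines <- split(lines[!is_header], block[!is_header])
  sequence <- character(length(header_idx))
  names(sequence) <- as.character(seq_along(header_idx))
  collapsed <- vapply(seq_lines, function(x) gsub("[[:space:]]", "", paste(x, collapse = "")),
                      character(1))
  sequence[names(collapsed)] <- collapsed
  sequence <- toupper(unname(sequence))

  tibble(id = id, description = description,
         sequence = sequence, length = nchar(sequence))
}

#' Write a reference set to FASTA
#'
#' @param refs tibble with columns `id` and `sequence` (and optionally
#'   `description`, appended to the header after a space).
#' @param path output path.
#' @param width line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(refs, path, width = 70L) {
  assert_columns(refs, c("id", "sequence"), "reference set")
  set <- Biostrings::DNAStringSet(refs$sequence)
  nm <- refs$id
  if ("description" %in% names(refs)) {
    has_desc <- !is.na(refs$description) & nzchar(refs$description)
    nm[has_desc] <- paste(refs$id[has_desc], refs$description[has_desc])
  }
  names(set) <- nm
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
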