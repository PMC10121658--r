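#' Read a per-reference male/female alignment count table
#'
#' The count table carries the inputs of the chromosome-quotient statistic:
#' per reference, the number of male and of female genomic alignments, plus
#' the two library totals. Tab-separated with a header row; lines starting
#' with `#` are ignored.
#'
#' @param path TSV with columns `id`, `male_count`, `female_count`.
#' @param male_total,female_total positive library totals (reads) for the
#'   male and female libraries.
#' @return A `count_table`: a tibble with columns `id`, `male_count`,
#'   `female_count` and attributes `male_total` / `female_total`.
#' @details Counts must be non-negative integers no larger than their
#'   library total; ids must be unique. Violations are hard errors.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tmale_count\tfemale_count", "t1\t50\t0", "t2\t40\t38"), tsv)
#' read_count_table(tsv, male_total = 1e6, female_total = 1e6)
#' @export
read_count_table <- function(path, male_total, female_total) {
  stopifnot_scalar_number(male_total, "male_total", min = 1)
  stopifnot_scalar_number(female_total, "female_total", min = 1)
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  assert_columns(tab, c("id", "male_count", "female_count"), "count table")
  tab <- select(tab, all_of(c("id", "male_count", "female_count")))
  new_count_table(tab, male_total = male_total, female_total = female_total)
}

# constructor + validator shared by the reader and the simulator
new_count_table <- function(tab, male_total, female_total) {
  tab <- as_tibble(tab)
  if (anyDuplicated(tab$id)) {
    abort(sprintf("duplicate id in count table: %s",
                  tab$id[duplicated(tab$id)][1]))
  }
  for (col in c("male_count", "female_count")) {
    x <- tab[[col]]
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != trunc(x))) {
      abort(sprintf("`%s` must contain non-negative integers", col))
    }
  }
  if (any(tab$male_count > male_total)) {
    abort("male_count exceeds male_total")
  }
  if (any(tab$female_count > female_total)) {
    abort("female_count exceeds female_total")
  }
  structure(tab,
            male_total = as.numeric(male_total),
            female_total = as.numeric(female_total),
            class = c("count_table", class(tab)))
}

#' Library totals stored on a count table
#' @param x a `count_table`.
#' @return a named numeric vector `c(male, female)`.
#' @export
library_totals <- function(x) {
  c(male = attr(x, "male_total"), female = attr(x, "female_total"))
}

#' Read a stage-labelled sample sheet
#'
#' @param path TSV with columns `sample_id`, `stage`, `replicate`.
#' @return tibble with validated, unique `sample_id` and `stage` drawn from
#'   the recognised stage set (`E0_1h`, `E2_4h`, `E4_8h`, `E8_12h`, `pupae`,
#'   `adult_male`, `adult_female`).
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  validate_sample_sheet(sheet)
}

validate_sample_sheet <- function(sheet) {
  assert_columns(sheet, c("sample_id", "stage", "replicate"), "sample sheet")
  sheet <- as_tibble(sheet)
  if (anyDuplicated(sheet$sample_id)) {
    abort(sprintf("duplicate sample_id in sheet: %s",
                  sheet$sample_id[duplicated(sheet$sample_id)][1]))
  }
  bad <- setdiff(unique(sheet$stage), STAGE_LEVELS)
  if (length(bad) > 0L) {
    abort(sprintf("unknown stage(s) in sample sheet: %s (allowed: %s)",
                  paste(bad, collapse = ", "),
                  paste(STAGE_LEVELS, collapse = ", ")))
  }
  if (any(sheet$replicate < 1 | sheet$replicate != trunc(sheet$replicate))) {
    abort("`replicate` must be a positive integer")
  }
  sheet
}

#' Read an expression matrix with its sample sheet
#'
#' @param path_matrix TSV whose first column is the reference id (any name)
#'   and remaining columns are samples; values are non-negative abundances
#'   (raw estimated counts unless `normalized = TRUE`).
#' @param path_samplesheet TSV sample sheet, see [read_sample_sheet()].
#' @param normalized declare the matrix already normalized (default FALSE).
#' @return tibble with column `ref_id` plus one column per sample, carrying
#'   attributes `samples` (the sheet) and `normalized`. Matrix columns must
#'   match the sheet's `sample_id` set exactly; mismatches are an error
#'   listing the symmetric difference.
#' @export
read_expression <- function(path_matrix, path_samplesheet, normalized = FALSE) {
  mat <- readr::read_tsv(path_matrix, comment = "#", show_col_types = FALSE)
  names(mat)[1] <- "ref_id"
  sheet <- read_sample_sheet(path_samplesheet)
  new_expression(mat, sheet, normalized = normalized)
}

new_expression <- function(mat, sheet, normalized = FALSE) {
  mat <- as_tibble(mat)
  sheet <- validate_sample_sheet(sheet)
  sample_cols <- setdiff(names(mat), "ref_id")
  only_matrix <- setdiff(sample_cols, sheet$sample_id)
  only_sheet <- setdiff(sheet$sample_id, sample_cols)
  if (length(only_matrix) + length(only_sheet) > 0L) {
    abort(sprintf(
      "matrix columns and sample sheet disagree; only in matrix: {%s}; only in sheet: {%s}",
      paste(only_matrix, collapse = ", "), paste(only_sheet, collapse = ", ")))
  }
  if (anyDuplicated(mat$ref_id)) {
    abort(sprintf("duplicate ref_id in expression matrix: %s",
                  mat$ref_id[duplicated(mat$ref_id)][1]))
  }
  vals <- as.matrix(mat[sheet$sample_id])
  if (anyNA(vals) || any(vals < 0)) {
    abort("expression matrix must contain non-negative, non-missing values")
  }
  mat <- mat[c("ref_id", sheet$sample_id)]
  structure(mat, samples = sheet, normalized = isTRUE(normalized),
            class = c("expression_tbl", class(mat)))
}

#' Sample sheet attached to an expression table
#' @param x an expression table from [read_expression()] or the simulator.
#' @return the sample-sheet tibble.
#' @export
sample_sheet <- function(x) {
  sheet <- attr(x, "samples")
  if (is.null(sheet)) abort("no sample sheet attached to this table")
  sheet
}

#' Is an expression table normalized?
#' @param x an expression table.
#' @return logical flag.
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' Read an annotation table of product descriptions
#'
#' @param path TSV with columns `id`, `product`, and optionally a logical
#'   `te_like` column flagging transposase/reverse-transcriptase-derived
#'   sequences. When absent, the flag is derived from the product string via
#'   [flag_te_like()].
#' @return tibble with columns `id`, `product`, `te_like`.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  assert_columns(ann, c("id", "product"), "annotation table")
  if (!"te_like" %in% names(ann)) {
    ann <- flag_te_like(ann)
  }
  if (!is.logical(ann$te_like) || anyNA(ann$te_like)) {
    abort("`te_like` must be TRUE/FALSE with no missing values")
  }
  as_tibble(ann)
}

#' Flag transposase / reverse-transcriptase-like products
#'
#' Adds a logical `te_like` column by case-insensitive keyword match of the
#' `product` description ("transposase", "reverse transcriptase", and the
#' common shorthand "transposon" / "retrotransposon").
#'
#' @param annotation tibble with a `product` column.
#' @return the tibble with a `te_like` logical column.
#' @export
flag_te_like <- function(annotation) {
  assert_columns(annotation, "product", "annotation table")
  pat <- "transposase|reverse[ _-]?transcriptase|retrotransposon|transposon"
  mutate(annotation,
         te_like = stringr::str_detect(
           stringr::str_to_lower(tidyr::replace_na(.data$product, "")), pat))
}

#' Read a per-individual phenotype table
#'
#' @param path CSV with columns `individual_id`, `group` (one of `mosaic`,
#'   `control`, `wild_type_male`, `wild_type_female`) and one column per
#'   scored tissue (`antennae`, `maxillary_palps`, `external_genitalia`,
#'   `gonads`), each entry one of `normal`, `feminized`, `malformed`,
#'   `not_scored`.
#' @return validated tibble.
#' @export
read_phenotypes <- function(path) {
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  assert_columns(tab, c("individual_id", "group", TISSUE_LEVELS),
                 "phenotype table")
  if (anyDuplicated(tab$individual_id)) {
    abort(sprintf("duplicate individual_id: %s",
                  tab$individual_id[duplicated(tab$individual_id)][1]))
  }
  bad_group <- setdiff(unique(tab$group), GROUP_LEVELS)
  if (length(bad_group) > 0L) {
    abort(sprintf("unknown group(s): %s", paste(bad_group, collapse = ", ")))
  }
  for (tissue in TISSUE_LEVELS) {
    bad <- setdiff(unique(tab[[tissue]]), SCORE_LEVELS)
    if (length(bad) > 0L) {
      abort(sprintf("unknown score(s) in `%s`: %s",
                    tissue, paste(bad, collapse = ", ")))
    }
  }
  as_tibble(tab)
}
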