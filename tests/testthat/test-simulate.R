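test_that("reference simulation is seed-deterministic with declared classes", {
  p <- sim_params(n_m_linked = 3, n_autosomal = 5, n_female_biased = 2, seed = 7)
  a <- simulate_reference_set(p)
  b <- simulate_reference_set(p)
  expect_identical(a, b)
  expect_equal(sum(a$truth$class == "M_linked"), 3L)
  expect_equal(sum(a$truth$class == "autosomal"), 5L)
  expect_equal(sum(a$truth$class == "female_biased"), 2L)
  expect_true(all(a$references$length >= 1500 & a$references$length <= 2000))
  expect_identical(a$references$length, nchar(a$references$sequence))
  # hemizygous copy numbers: M (1,0), autosomal (2,2), female-biased (1,2)
  m <- a$truth[a$truth$class == "M_linked", ]
  expect_true(all(m$copy_male == 1 & m$copy_female == 0))
  fb <- a$truth[a$truth$class == "female_biased", ]
  expect_true(all(fb$copy_male == 1 & fb$copy_female == 2))
})

test_that("zero leakage gives exact female zeros on M-linked contigs", {
  p <- sim_params(seed = 3)
  truth <- simulate_reference_set(p)$truth
  counts <- simulate_dna_counts(truth, p)
  m <- counts[counts$id %in% truth$id[truth$class == "M_linked"], ]
  expect_true(all(m$female_count == 0))
  expect_identical(simulate_dna_counts(truth, p), counts)
  totals <- library_totals(counts)
  expect_gt(totals[["male"]], sum(counts$male_count))
  expect_gt(totals[["female"]], sum(counts$female_count))
})

test_that("autosomal coverage matches the Poisson depth model", {
  p <- sim_params(n_m_linked = 0, n_autosomal = 500, n_female_biased = 0,
                  length_range = c(1000, 1000), depth = 100, seed = 5)
  truth <- simulate_reference_set(p)$truth
  counts <- simulate_dna_counts(truth, p)
  se <- sqrt(100 / 500)
  expect_lt(abs(mean(counts$male_count) - 100), 3 * se)
  expect_lt(abs(mean(counts$female_count) - 100), 3 * se)
})

test_that("expression matrices encode the planted stage signature", {
  p <- sim_params(seed = 11)
  truth <- simulate_reference_set(p)$truth
  expr <- simulate_expression_matrix(truth, p)
  sheet <- sample_sheet(expr)
  mat <- as.matrix(expr[sheet$sample_id])
  rownames(mat) <- expr$ref_id
  m_rows <- truth$id[truth$class == "M_linked"]
  pre <- sheet$sample_id[sheet$stage %in% c("E0_1h", "E2_4h")]
  female <- sheet$sample_id[sheet$stage == "adult_female"]
  post_male <- sheet$sample_id[sheet$stage %in%
                                 c("E4_8h", "E8_12h", "pupae", "adult_male")]
  expect_true(all(mat[m_rows, c(pre, female)] == 0))
  expect_true(all(mat[m_rows, post_male] > 0))
  auto_rows <- truth$id[truth$class == "autosomal"]
  expect_true(all(mat[auto_rows, ] > 0))
  # female-biased contigs are elevated in adult females
  fb <- truth$id[truth$class == "female_biased"]
  expect_gt(mean(mat[fb, female]) / mean(mat[fb, setdiff(colnames(mat), female)]), 2)

  expr2 <- simulate_expression_matrix(truth, sim_params(seed = 12))
  expect_false(identical(as.matrix(expr2[sheet$sample_id]), mat))
})

test_that("an activation hour is honoured relative to collection windows", {
  p <- sim_params(activation_hour = 11, seed = 13)  # only E8_12h spans it
  truth <- simulate_reference_set(p)$truth
  expr <- simulate_expression_matrix(truth, p)
  sheet <- sample_sheet(expr)
  mat <- as.matrix(expr[sheet$sample_id])
  rownames(mat) <- expr$ref_id
  m_rows <- truth$id[truth$class == "M_linked"]
  e48 <- sheet$sample_id[sheet$stage == "E4_8h"]
  e812 <- sheet$sample_id[sheet$stage == "E8_12h"]
  expect_true(all(mat[m_rows, e48] == 0))
  expect_true(all(mat[m_rows, e812] > 0))
})

test_that("scenario bundles round-trip through their plain-text files", {
  dir <- withr::local_tempdir()
  p <- sim_params(n_m_linked = 2, n_autosomal = 10, n_female_biased = 2,
                  seed = 19)
  paths <- make_scenario(file.path(dir, "sc"), p)
  expect_true(all(file.exists(paths)))
  expect_error(make_scenario(file.path(dir, "sc"), p), "force")

  back <- read_scenario(file.path(dir, "sc"))
  direct <- simulate_scenario(p)
  expect_identical(back$references$sequence, direct$references$sequence)
  expect_equal(tibble::as_tibble(back$counts), tibble::as_tibble(direct$counts))
  expect_equal(unname(library_totals(back$counts)),
               unname(library_totals(direct$counts)))
  expect_equal(back$params$seed, 19)
  expect_equal(back$params$depth, p$depth)
  # regenerating under the manifest seed reproduces the FASTA byte-for-byte
  paths2 <- make_scenario(file.path(dir, "sc2"), p)
  expect_identical(readLines(paths[["fasta"]]), readLines(paths2[["fasta"]]))
})

test_that("leakage at shallow depth erodes recovery relative to clean data", {
  candidate_set <- function(leak, s) {
    p <- sim_params(depth = 50, leakage = leak, seed = s)
    r <- tidy(run_screen(simulate_scenario(p)))
    r$id[r$final_candidate]
  }
  seeds <- 1:5
  clean <- lapply(seeds, candidate_set, leak = 0)
  leaky <- lapply(seeds, candidate_set, leak = 0.05)
  # leaked female reads can only hurt: per-seed subset, strictly fewer overall
  for (i in seq_along(seeds)) expect_true(all(leaky[[i]] %in% clean[[i]]))
  expect_lt(sum(lengths(leaky)), sum(lengths(clean)))
})

test_that("simulated bundles re-validate through the package readers", {
  dir <- withr::local_tempdir()
  p <- sim_params(n_m_linked = 2, n_autosomal = 8, n_female_biased = 2,
                  seed = 23)
  paths <- make_scenario(file.path(dir, "sc"), p)
  refs <- read_fasta(paths[["fasta"]])
  expect_equal(nrow(refs), 12L)
  sc <- read_scenario(file.path(dir, "sc"))
  expect_s3_class(sc$counts, "count_table")
  expect_equal(nrow(sample_sheet(sc$expression)), 21L)
})
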