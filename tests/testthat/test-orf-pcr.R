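test_that("translation follows the standard code with ambiguity handling", {
  expect_equal(translate_dna("ATGTTTTAA"), "MF*")
  expect_equal(translate_dna("ATGNNT"), "MX")
  expect_equal(translate_dna("ATGAAAC"), "MK")      # trailing partial dropped
  expect_equal(translate_dna("GATGAAA", frame = 1), "MK")
  expect_error(translate_dna("ATG!"), "non-IUPAC")
  set.seed(41)
  for (i in 1:20) {
    s <- random_dna(300)
    for (fr in 0:2) expect_equal(translate_dna(s, fr), oracle_translate(s, fr))
  }
})

test_that("longest-ORF finding matches construction and brute force", {
  hit <- find_longest_orf("ATGAAATAG")
  expect_equal(hit$start, 0L)
  expect_equal(hit$end, 9L)
  expect_equal(hit$peptide, "MK")
  expect_equal(hit$peptide_length, 2L)

  expect_equal(nrow(find_longest_orf("CCCCCC")), 0L)       # no ATG
  expect_equal(nrow(find_longest_orf("ATGAAAAAA")), 0L)    # no in-frame stop

  set.seed(42)
  n_with_orf <- 0
  for (i in 1:150) {
    s <- random_dna(sample(60:400, 1))
    got <- find_longest_orf(s)
    want <- oracle_longest_orf(s)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      n_with_orf <- n_with_orf + 1
      expect_equal(got$start, want$start1 - 1L)
      expect_equal(got$end, want$end1)
      expect_equal((got$end - got$start) %% 3L, 0L)
    }
  }
  expect_gt(n_with_orf, 50)   # the comparison actually exercised ORFs
})

test_that("ORF calls are invariant to UTR padding without longer ORFs", {
  core <- paste0("ATG", strrep("GCA", 40), "TAA")   # M + 40 alanines
  padded <- paste0("CCTCCTCC", core, "CCTCCGG")
  a <- find_longest_orf(core)
  b <- find_longest_orf(padded)
  expect_equal(b$start, a$start + 8L)
  expect_equal(b$peptide, a$peptide)
  expect_equal(b$peptide_length, 41L)
})

test_that("orf_table maps over a reference set", {
  refs <- tibble::tibble(
    id = c("with", "without"),
    sequence = c("ATGAAATAG", "CCCCCCCCC"))
  tab <- orf_table(refs)
  expect_equal(tab$id, "with")
  expect_equal(tab$peptide, "MK")
})

test_that("in-silico PCR reproduces a constructed male-specific amplicon", {
  fwd <- "ACGGTTACGGTTACGGTTAC"    # 20 nt
  rev <- "TTGGCCAATTGGCCAATTGG"    # 20 nt
  set.seed(43)
  left <- random_dna(100)
  right <- random_dna(500 - 100 - 286)
  middle <- random_dna(286 - nchar(fwd) - nchar(rev))
  template <- paste0(left, fwd, middle, reverse_complement(rev), right)
  expect_equal(nchar(template), 500L)
  hit <- insilico_pcr(template, fwd, rev)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$product_length, 286L)
  expect_equal(hit$start, 100L)

  expect_equal(nrow(insilico_pcr(template, "GGGGGGGGGGGG", rev)), 0L)
  expect_equal(nrow(insilico_pcr(template, fwd, rev, max_product = 200)), 0L)
})

test_that("multiple primer sites yield every admissible product", {
  fwd <- "ACGGTTACGGTTACGGTTAC"
  rev <- "TTGGCCAATTGGCCAATTGG"
  tpl <- paste0("TTTT", fwd, strrep("A", 30), fwd, strrep("C", 30),
                reverse_complement(rev), "TTTT")
  hits <- insilico_pcr(tpl, fwd, rev)
  expect_equal(nrow(hits), 2L)
  expect_equal(sort(hits$product_length), oracle_pcr_products(tpl, fwd, rev))
})

test_that("product sets match a brute-force scan on random templates", {
  set.seed(44)
  fwd <- "ACGGTTACGG"; rev <- "TTGGCCAATT"
  for (i in 1:200) {
    # short alphabet-poor templates make chance primer sites likely
    tpl <- paste(sample(c("A", "C", "G", "T", fwd, reverse_complement(rev)),
                        30, replace = TRUE, prob = c(rep(0.22, 4), 0.06, 0.06)),
                 collapse = "")
    got <- insilico_pcr(tpl, fwd, rev, max_product = 200)
    expect_equal(sort(got$product_length),
                 oracle_pcr_products(tpl, fwd, rev, max_product = 200))
  }
})

test_that("primers shorter than 10 nt are rejected", {
  expect_error(insilico_pcr("ACGTACGTACGT", "ACGT", "ACGTACGTAC"), "at least 10")
})
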