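pheno_fixture <- function() {
  read_phenotypes(system.file("extdata", "mosaic_phenotypes_synthetic.csv",
                              package = "mfscreen"))
}

test_that("mosaic feminization percentages match the per-tissue tallies", {
  s <- summarize_phenotypes(pheno_fixture(), group = "mosaic")
  lab <- setNames(s$label, s$tissue)
  expect_equal(lab[["external_genitalia"]], "92% (36/39)")
  expect_equal(lab[["antennae"]], "54% (21/39)")
  expect_equal(lab[["maxillary_palps"]], "90% (35/39)")
  expect_equal(attr(s, "total"), 39L)
  # formatted labels always agree with the recomputed counts
  recomputed <- sprintf("%s%% (%d/%d)",
                        round_half_up(100 * s$n_feminized / attr(s, "total")),
                        s$n_feminized, attr(s, "total"))
  expect_equal(s$label, recomputed)
  expect_true(all(s$n_feminized + s$n_malformed + s$n_normal == s$n_scored))
})

test_that("an all-normal group scores zero percent everywhere", {
  s <- summarize_phenotypes(pheno_fixture(), group = "control")
  expect_true(all(s$pct_feminized == 0))
  expect_error(summarize_phenotypes(pheno_fixture(), group = "wild_type_male"),
               "empty group")
})

test_that("small-group percentages follow the half-up convention", {
  tab <- tibble::tibble(
    individual_id = paste0("i", 1:4), group = "mosaic",
    antennae = c("feminized", "normal", "normal", "normal"),
    maxillary_palps = "normal", external_genitalia = "normal",
    gonads = c("feminized", "feminized", "normal", "not_scored"))
  s <- summarize_phenotypes(tab)
  expect_equal(s$pct_feminized[s$tissue == "antennae"], 25)
  expect_equal(s$n_scored[s$tissue == "gonads"], 3L)
  expect_equal(s$pct_feminized[s$tissue == "gonads"], 50)
})

test_that("injection summaries reproduce the published table arithmetic", {
  counts <- readr::read_csv(system.file("extdata", "injection_counts.csv",
                                        package = "mfscreen"),
                            comment = "#", show_col_types = FALSE)
  s <- summarize_injection(counts)
  rep1 <- s[s$group == "rep1", ]
  expect_equal(rep1$hatch_pct, 37.2)       # 119/320
  expect_equal(rep1$female_pct, 56.52)     # 52/92
  expect_equal(rep1$male_pct, 43.48)
  rep2 <- s[s$group == "rep2", ]
  expect_equal(rep2$hatch_pct, 15.0)       # 28/187
  expect_equal(rep2$female_pct, 52.38)     # 11/21
  rep3 <- s[s$group == "rep3", ]
  expect_equal(rep3$hatch_pct, 21.4)       # 45/210
  expect_equal(rep3$female_pct, 50.00)

  pooled <- s[s$group == "pooled", ]
  expect_equal(pooled$injected, sum(counts$injected))
  expect_equal(pooled$hatch_pct,
               round_half_up(100 * sum(counts$hatched) / sum(counts$injected), 1))
  # adult shares always sum to 100.00 at two decimals
  expect_true(all(abs(s$female_pct + s$male_pct - 100) <= 0.01))
})

test_that("degenerate injection inputs behave as specified", {
  zero_hatch <- tibble::tibble(injected = 10, hatched = 0, adult_female = 0,
                               adult_male = 0, feminized_or_deformed = 0)
  s <- summarize_injection(zero_hatch)
  expect_equal(s$hatch_pct, c(0, 0))
  expect_true(all(is.na(s$female_pct)))

  expect_error(summarize_injection(dplyr::mutate(zero_hatch, injected = 0)),
               "positive")
  expect_error(summarize_injection(dplyr::mutate(zero_hatch, hatched = 20)),
               "cannot exceed")
})

test_that("mosaic totals are plain sums over replicates", {
  expect_identical(mosaic_total(c(20, 6, 13)), 39L)
  expect_identical(mosaic_total(integer(0)), 0L)
  expect_identical(mosaic_total(5), 5L)
  expect_error(mosaic_total(c(3, -1)), "non-negative")
})

test_that("ddCt fold changes follow the 2^-ddCt definition", {
  expect_equal(fold_change_ddct(20, 20, 20, 20), 1)
  expect_equal(fold_change_ddct(19, 20, 20, 20), 2)    # ddCt = -1 doubles
  expect_equal(fold_change_ddct(24, 20, 26.5, 20), 2^2.5)
  # case/control inversion is exactly reciprocal
  set.seed(51)
  for (i in 1:20) {
    ct <- runif(4, 15, 35)
    expect_lt(abs(fold_change_ddct(ct[1], ct[2], ct[3], ct[4]) *
                    fold_change_ddct(ct[3], ct[4], ct[1], ct[2]) - 1), 1e-12)
  }
  df <- tibble::tibble(ct_target_case = 24, ct_reference_case = 20,
                       ct_target_control = 26.5, ct_reference_control = 20)
  expect_equal(fold_change_ddct(df), 2^2.5)
  expect_error(fold_change_ddct(24, NA, 20, 20), "finite")
})

test_that("round_half_up rounds halves away from zero at every scale", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(2.5), 3)          # base round() would give 2
  expect_equal(round_half_up(37.1875, 1), 37.2)
  expect_equal(round_half_up(56.5217, 2), 56.52)
  expect_equal(round_half_up(52.375, 2), 52.38)
})
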