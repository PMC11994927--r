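test_that("fold error: identity, display rounding, input checks", {
  expect_equal(fold_error(5, 5), 1)
  expect_equal(fold_error(397.62, 602.00, display = TRUE), 0.66)
  expect_equal(fold_error(23123.26, 17375.00, display = TRUE), 1.33)
  expect_error(fold_error(1, 0), class = "sgltsim_validation_error")
})

test_that("round_half_up follows the tabular convention, not round-half-even", {
  expect_equal(sgltsim:::round_half_up(0.125, 2), 0.13)
  expect_equal(sgltsim:::round_half_up(2.375, 2), 2.38)
  expect_equal(sgltsim:::round_half_up(-0.125, 2), -0.13)
  expect_equal(sgltsim:::round_half_up(76.75, 1), 76.8)
})

test_that("MPE oracle and asymmetry", {
  pairs <- data.frame(observed = c(1, 2), predicted = c(2, 1))
  expect_equal(mpe(pairs), 0.25)
  # brute-force elementwise oracle on random pairs
  set.seed(11)
  rp <- data.frame(observed = runif(200, 0.5, 5),
                   predicted = runif(200, 0.5, 5))
  expect_equal(mpe(rp), mean((rp$predicted - rp$observed) / rp$observed),
               tolerance = 1e-14)
  swapped <- data.frame(observed = rp$predicted, predicted = rp$observed)
  expect_false(isTRUE(all.equal(mpe(rp), mpe(swapped))))
})

test_that("AFE: constant ratio, geometric cancellation, inversion", {
  expect_equal(afe(data.frame(observed = 1:5, predicted = 2 * (1:5))), 2)
  expect_equal(afe(data.frame(observed = c(1, 2), predicted = c(2, 1))), 1)
  set.seed(12)
  rp <- data.frame(observed = rlnorm(100), predicted = rlnorm(100))
  swapped <- data.frame(observed = rp$predicted, predicted = rp$observed)
  expect_equal(afe(swapped), 1 / afe(rp), tolerance = 1e-12)
})

test_that("AAFE: identity, |log| symmetry, dominance, swap invariance", {
  expect_equal(aafe(data.frame(observed = 1:4, predicted = 1:4)), 1)
  expect_equal(aafe(data.frame(observed = c(1, 2), predicted = c(2, 1))), 2)
  set.seed(13)
  rp <- data.frame(observed = rlnorm(1e4), predicted = rlnorm(1e4))
  a <- afe(rp); aa <- aafe(rp)
  expect_gte(aa, 1)
  expect_gte(aa, max(a, 1 / a))
  swapped <- data.frame(observed = rp$predicted, predicted = rp$observed)
  expect_equal(aafe(swapped), aafe(rp), tolerance = 1e-12)
})

test_that("band_fraction counts inclusively on unrounded ratios", {
  pairs <- data.frame(observed = c(1, 1, 1), predicted = c(0.8, 1.3, 1.31))
  expect_equal(band_fraction(pairs), sgltsim:::round_half_up(200 / 3, 1))
  expect_equal(band_fraction(pairs, 0, Inf), 100)
  expect_error(band_fraction(pairs[0, ]), class = "sgltsim_validation_error")
})

test_that("shipped paired tables have the documented shapes", {
  t2 <- pk_pairs_table("healthy_normal")
  t3 <- pk_pairs_table("renal_impairment")
  expect_equal(nrow(t2), 56)
  expect_equal(nrow(t3), 42)
  expect_equal(nrow(pk_pairs_table("pooled")), 98)
  expect_true(all(t2$observed > 0) && all(t2$predicted > 0))
  expect_setequal(unique(t2$quantity), c("AUC", "Cmax"))
})

test_that("banding uses unrounded ratios (regression of the rounding decision)", {
  t2 <- pk_pairs_table("healthy_normal")
  unrounded_n <- sum(t2$predicted / t2$observed >= 0.8 &
                       t2$predicted / t2$observed <= 1.3)
  expect_equal(unrounded_n, 43)
  expect_equal(sgltsim:::round_half_up(100 * unrounded_n / nrow(t2), 1),
               band_fraction(t2))
  # a ratio of 0.796 displays as 0.80 but must stay outside the band
  pair <- data.frame(observed = 1, predicted = 0.796)
  expect_equal(fold_error(1, 1 / 0.796, display = TRUE), 0.80)
  expect_equal(band_fraction(pair), 0)
})

test_that("validate_predictions aggregates per group and overall", {
  rep_ <- validate_predictions(pk_pairs_table("pooled"), by = "drug")
  td <- tidy(rep_)
  expect_equal(sort(unique(td$drug)), sort(sglt_drugs()))
  expect_equal(sum(td$n), 98)
  g <- glance(rep_)
  expect_equal(g$n, 98)
  expect_true(g$aafe >= max(g$afe, 1 / g$afe))
})

test_that("malformed paired CSVs raise parse errors", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("drug,observed\nx,1", bad)
  expect_error(read_paired_observations(bad), class = "sgltsim_parse_error")
  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines("drug,regimen,quantity,observed,predicted\nx,a,AUC,-1,2", neg)
  expect_error(read_paired_observations(neg),
               class = "sgltsim_validation_error")
})
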