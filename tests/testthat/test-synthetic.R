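test_that("CV = 0 reproduces the truth exactly and closes the metric loop", {
  pop <- generate_population(population_spec(2, "normal"), seed = 1)
  ds <- synth_observed_pk(sglt_drug("dapagliflozin"), dose_regimen(10), pop,
                          cv = 0, seed = 1)
  expect_equal(ds$observations$observed_ng_ml, ds$observations$truth_ng_ml)
  pairs <- data.frame(observed = ds$observations$observed_ng_ml,
                      predicted = ds$observations$truth_ng_ml)
  expect_equal(mpe(pairs), 0)
  expect_equal(afe(pairs), 1)
  expect_equal(aafe(pairs), 1)
})

test_that("noise grows the metrics monotonically in CV", {
  pop <- generate_population(population_spec(2, "normal"), seed = 1)
  aafes <- purrr::map_dbl(c(0, 0.1, 0.2), function(cv) {
    ds <- synth_observed_pk(sglt_drug("dapagliflozin"), dose_regimen(10), pop,
                            cv = cv, seed = 5)
    aafe(data.frame(observed = ds$observations$observed_ng_ml,
                    predicted = ds$observations$truth_ng_ml))
  })
  expect_true(all(diff(aafes) > 0))
})

test_that("synthetic datasets are seed-deterministic", {
  pop <- generate_population(population_spec(2, "normal"), seed = 1)
  a <- synth_observed_pk(sglt_drug("empagliflozin"), dose_regimen(25), pop,
                         cv = 0.2, seed = 9)
  b <- synth_observed_pk(sglt_drug("empagliflozin"), dose_regimen(25), pop,
                         cv = 0.2, seed = 9)
  expect_equal(a$observations, b$observations)
  c_ <- synth_observed_pk(sglt_drug("empagliflozin"), dose_regimen(25), pop,
                          cv = 0.2, seed = 10)
  expect_false(isTRUE(all.equal(a$observations$observed_ng_ml,
                                c_$observations$observed_ng_ml)))
})

test_that("lognormal noise matches its closed-form AAFE and is symmetric", {
  # AAFE(truth vs observed) = exp(E|ln r|) with ln r ~ N(0, cv):
  # folded-normal mean cv * sqrt(2/pi)
  pop <- generate_population(population_spec(2, "normal"), seed = 1)
  cv <- 0.2
  dense_times <- seq(0.25, 24, length.out = 5000)   # 2 subjects -> 1e4 points
  ds <- synth_observed_pk(sglt_drug("dapagliflozin"), dose_regimen(10), pop,
                          cv = cv, sampling_times_h = dense_times, seed = 3)
  obs_aafe <- aafe(data.frame(observed = ds$observations$observed_ng_ml,
                              predicted = ds$observations$truth_ng_ml))
  expect_equal(obs_aafe, exp(cv * sqrt(2 / pi)), tolerance = 0.02)
  # log-residual normality sanity: skewness near zero at n = 1e4
  lr <- log(ds$observations$observed_ng_ml / ds$observations$truth_ng_ml)
  skew <- mean((lr - mean(lr))^3) / sd(lr)^3
  expect_lt(abs(skew), 0.1)
})

test_that("UGE datasets inherit the model's stage ordering", {
  spec_n <- population_spec(3, "normal"); spec_s <- population_spec(3, "severe")
  dn <- synth_observed_uge(sglt_drug("dapagliflozin"), dose_regimen(10),
                           generate_population(spec_n, 2), cv = 0, seed = 2)
  dsv <- synth_observed_uge(sglt_drug("dapagliflozin"), dose_regimen(10),
                            generate_population(spec_s, 2), cv = 0, seed = 2)
  expect_equal(dn$observations$observed_g, dn$observations$truth_g)
  expect_gt(mean(dn$observations$observed_g), mean(dsv$observations$observed_g))
})

test_that("negative CV is rejected", {
  pop <- generate_population(population_spec(1, "normal"), seed = 1)
  expect_error(synth_observed_pk(sglt_drug("dapagliflozin"), dose_regimen(10),
                                 pop, cv = -0.1),
               class = "sgltsim_validation_error")
  expect_error(synth_observed_uge(sglt_drug("dapagliflozin"), dose_regimen(10),
                                  pop, cv = -0.1),
               class = "sgltsim_validation_error")
})

test_that("noiseless recovery of one free parameter is exact to 0.1%", {
  pop <- generate_population(population_spec(3, "normal"), seed = 4)
  ds <- synth_observed_pk(sglt_drug("dapagliflozin"), dose_regimen(10), pop,
                          cv = 0, sampling_times_h = c(1, 2, 4, 8, 24),
                          seed = 4)
  fit <- recover_parameters(ds,
                            free = list(hepatic_clearance_scalar = c(0.25, 4)))
  expect_equal(fit$estimate, 1, tolerance = 1e-3)
  expect_false(fit$at_bound)
})

test_that("bounds excluding the truth pin the estimate with a flag", {
  pop <- generate_population(population_spec(2, "normal"), seed = 4)
  ds <- synth_observed_pk(sglt_drug("dapagliflozin"), dose_regimen(10), pop,
                          cv = 0, sampling_times_h = c(1, 4, 12), seed = 4)
  fit <- recover_parameters(ds,
                            free = list(hepatic_clearance_scalar = c(2, 4)))
  expect_true(fit$at_bound)
  expect_equal(fit$estimate, 2, tolerance = 1e-2)
})

test_that("non-identifiable requests fail loudly", {
  pop1 <- generate_population(population_spec(1, "normal"), seed = 1)
  ds1 <- synth_observed_uge(sglt_drug("dapagliflozin"), dose_regimen(10),
                            pop1, cv = 0, seed = 1)
  expect_error(
    recover_parameters(ds1, free = list(
      hepatic_clearance_scalar = c(0.5, 2),
      intestinal_permeability_scalar = c(0.5, 2),
      sglt2_kd_umol_l = c(1e-4, 1e-1),
      transporter_capacity_scale = c(0.2, 1))),
    class = "sgltsim_diagnostic_failure")
  expect_error(recover_parameters(ds1, free = list(nonsense = c(0, 1))),
               class = "sgltsim_validation_error")
})
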