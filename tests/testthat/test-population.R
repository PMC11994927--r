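test_that("stage lookup tables", {
  expect_equal(ckd_stage_gfr("normal"), 105)
  expect_equal(ckd_stage_gfr("mild"), 75)
  expect_equal(ckd_stage_gfr("moderate"), 45)
  expect_equal(ckd_stage_gfr("severe"), 15)
  expect_error(ckd_stage_gfr("end-stage"), class = "sgltsim_validation_error")
  expect_equal(transporter_scaling("normal"), c(SGLT1 = 1, SGLT2 = 1))
  expect_equal(transporter_scaling("mild"), c(SGLT1 = 1, SGLT2 = 1))
  expect_equal(transporter_scaling("moderate"), c(SGLT1 = 0.85, SGLT2 = 0.40))
  expect_equal(transporter_scaling("severe"), c(SGLT1 = 0.50, SGLT2 = 0.10))
})

test_that("population generation is deterministic and respects the spec", {
  spec <- population_spec(100, "normal", fraction_male = 0.5)
  a <- generate_population(spec, seed = 42)
  b <- generate_population(spec, seed = 42)
  expect_equal(a, b)
  expect_equal(nrow(a), 100)
  expect_equal(sum(a$sex == "male"), 50)
  expect_s3_class(a, "sglt_population")
  c_ <- generate_population(spec, seed = 43)
  expect_false(isTRUE(all.equal(a$gfr_ml_min, c_$gfr_ml_min)))
})

test_that("sex counts follow fraction_male with rounding", {
  p <- generate_population(population_spec(11, "normal", fraction_male = 0.3),
                           seed = 1)
  expect_equal(sum(p$sex == "male"), round(11 * 0.3))
})

test_that("stage GFR distribution: mean and degenerate CV", {
  p <- generate_population(population_spec(1000, "moderate"), seed = 7)
  expect_lt(abs(mean(p$gfr_ml_min) - 45), 2)
  p0 <- generate_population(population_spec(25, "moderate", gfr_cv = 0),
                            seed = 7)
  expect_equal(p0$gfr_ml_min, rep(45, 25))
})

test_that("per-subject flow variability preserves the cardiac-output invariant", {
  p <- generate_population(population_spec(5, "normal"), seed = 3)
  for (i in 1:5) {
    phys <- p$physiology[[i]]
    expect_equal(sum(phys$organs$flow_l_h, na.rm = TRUE),
                 phys$cardiac_output_l_h, tolerance = 1e-9)
  }
})

test_that("population bands: degenerate, envelope, and coverage", {
  # identical subjects give zero-width bands
  prof1 <- tidyr::crossing(id = 1:5, time_h = 0:3) |>
    dplyr::mutate(value = time_h^2)
  b1 <- population_bands(prof1)
  expect_equal(b1$lower, b1$upper)
  expect_equal(b1$median, b1$lower)
  # (0, 1) quantiles give the min/max envelope
  set.seed(1)
  prof2 <- tidyr::crossing(id = 1:20, time_h = 0:2) |>
    dplyr::mutate(value = rnorm(dplyr::n()))
  b2 <- population_bands(prof2, quantiles = c(0, 1))
  env <- prof2 |> dplyr::group_by(time_h) |>
    dplyr::summarise(lo = min(value), hi = max(value))
  expect_equal(b2$lower, env$lo)
  expect_equal(b2$upper, env$hi)
  # 90% band covers ~90% of held-out draws from the same distribution
  set.seed(2)
  train <- tidyr::crossing(id = 1:1000, time_h = 0:4) |>
    dplyr::mutate(value = rnorm(dplyr::n()))
  held <- rnorm(5000)
  b3 <- population_bands(train)
  cover <- mean(purrr::map_dbl(seq_len(nrow(b3)), function(i)
    mean(held >= b3$lower[i] & held <= b3$upper[i])))
  expect_lt(abs(cover - 0.9), 0.03)
  expect_error(population_bands(prof1[prof1$id == 1, ]),
               class = "sgltsim_validation_error")
})

test_that("population CSV export has the documented columns", {
  p <- generate_population(population_spec(4, "severe"), seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  export_population(p, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back),
               c("id", "age", "sex", "weight_kg", "bmi", "gfr_ml_min",
                 "sglt1_scale", "sglt2_scale"))
  expect_equal(nrow(back), 4)
  expect_equal(back$sglt2_scale, rep(0.10, 4))
})

test_that("simulate_subject couples a subject's PK to their glucodynamics", {
  p <- generate_population(population_spec(2, "moderate"), seed = 5)
  res <- simulate_subject(p, sglt_drug("empagliflozin"), dose_regimen(10),
                          i = 2)
  expect_s3_class(res$pk, "pk_sim")
  expect_s3_class(res$uge, "uge_sim")
  expect_equal(res$uge$gfr_ml_min, p$gfr_ml_min[2])
  expect_equal(unname(res$uge$capacity_scaling),
               unname(c(p$sglt1_scale[2], p$sglt2_scale[2])))
})
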