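test_that("default cohort specs carry the published calibration", {
  er <- default_cohort_spec("erect")
  pe <- default_cohort_spec("pendent")
  expect_equal(er$n_varieties, 56L)
  expect_equal(pe$n_varieties, 49L)
  expect_equal(nrow(er$params), 21L)
  expect_equal(er$params$code, default_registry()$code)
  plr <- er$params[er$params$code == "PLR", ]
  expect_equal(c(plr$mean, plr$sd, plr$min, plr$max), c(0.61, 0.57, 0.00, 2.23))
  ssdr_row <- pe$params[pe$params$code == "SSDR", ]
  expect_equal(c(ssdr_row$mean, ssdr_row$sd), c(0.19, 0.14))
})

test_that("cohort_spec validates its parameter and correlation invariants", {
  pars <- data.frame(code = c("PH", "PSD"), min = c(0, 1), max = c(10, 5),
                     mean = c(5, 3), sd = c(1, 0.5))
  expect_s3_class(cohort_spec(pars, 10, "erect"), "cohort_spec")
  bad <- pars; bad$min[1] <- 11
  expect_error(cohort_spec(bad, 10, "erect"), "min < max")
  bad <- pars; bad$mean[2] <- 9
  expect_error(cohort_spec(bad, 10, "erect"), "mean")
  bad <- pars; bad$sd[1] <- 0
  expect_error(cohort_spec(bad, 10, "erect"), "sd")
  notpsd <- matrix(c(1, 2, 2, 1), 2)
  expect_error(cohort_spec(pars, 10, "erect", correlation = notpsd),
               "\\[-1, 1\\]")
  nonsym <- matrix(c(1, 0.2, 0.5, 1), 2)
  expect_error(cohort_spec(pars, 10, "erect", correlation = nonsym), "symmetric")
})

test_that("generation is deterministic under a fixed seed and respects bounds", {
  spec <- default_cohort_spec("erect", seed = 77)
  a <- generate_trait_matrix(spec)
  b <- generate_trait_matrix(spec)
  expect_identical(unclass(a), unclass(b))
  expect_equal(dim(a), c(56L, 21L))
  expect_true(startsWith(rownames(a)[1], "C"))
  pars <- spec$params
  for (j in seq_len(21)) {
    expect_true(all(a[, pars$code[j]] >= pars$min[j]))
    expect_true(all(a[, pars$code[j]] <= pars$max[j]))
  }
  # a different seed moves the draw
  expect_false(identical(unclass(a),
                         unclass(generate_trait_matrix(
                           default_cohort_spec("erect", seed = 78)))))
})

test_that("marginal moments converge to the truncated-normal quadrature oracle", {
  spec <- default_cohort_spec("erect", n_varieties = 5000, seed = 99)
  x <- generate_trait_matrix(spec)
  pars <- spec$params
  # Bonferroni-adjusted per-column bound: 21 columns checked at once at the
  # family-wise level of a single 3 SE test
  z_star <- qnorm(1 - 0.0027 / (2 * nrow(pars)))
  for (j in seq_len(nrow(pars))) {
    mom <- truncnorm_moments(pars$mean[j], pars$sd[j], pars$min[j], pars$max[j])
    se <- mom["sd"] / sqrt(5000)
    expect_lt(abs(mean(x[, pars$code[j]]) - mom["mean"]), z_star * se)
    expect_lt(abs(sd(x[, pars$code[j]]) - mom["sd"]), (z_star + 1) * se)
  }
})

test_that("a latent copula correlation induces the requested association", {
  reg_codes <- default_registry()$code
  r <- preset_correlation(reg_codes)
  expect_equal(unname(r["SPH", "SSD"]), 0.5)
  spec <- default_cohort_spec("erect", n_varieties = 2000, correlation = r,
                              seed = 13)
  x <- generate_trait_matrix(spec)
  # latent coupling at 0.5 survives the marginal transform approximately
  expect_gt(cor(x[, "SPH"], x[, "SSD"]), 0.3)
  expect_gt(cor(x[, "SSDR"], x[, "SHL"]), 0.3)
  # uncoupled pair stays near zero
  expect_lt(abs(cor(x[, "PH"], x[, "FH"])), 0.1)
})

test_that("measurement records score back to the configured marginals", {
  # drop test: ssdr() means match the truncated-normal oracle on the percent scale
  spec <- default_cohort_spec("erect", n_varieties = 400, seed = 21)
  drops <- generate_measurement_records(spec, "drop_test")  # 5 per variety = 2000
  expect_equal(nrow(drops), 2000L)
  scores <- ssdr(drops$w1, drops$w2)
  pr <- spec$params[spec$params$code == "SSDR", ]
  mom <- truncnorm_moments(pr$mean, pr$sd, pr$min, pr$max)
  se <- 100 * mom["sd"] / sqrt(2000)
  expect_lt(abs(mean(scores) - 100 * mom["mean"]), 3 * se)

  # lodging: randomized rounding preserves the PLR mean
  lodg <- generate_measurement_records(spec, "lodging")
  grades <- plr_grade(lodg$alpha)
  prl <- spec$params[spec$params$code == "PLR", ]
  moml <- truncnorm_moments(prl$mean, prl$sd, prl$min, prl$max)
  expect_lt(abs(mean(grades) - moml["mean"]),
            3 * (moml["sd"] + 0.5) / sqrt(nrow(lodg)))

  # fruit set: a forced single occupied region scores exactly that region
  fs <- generate_measurement_records(spec, "fruit_set", concentration = 1)
  cols <- c("inner_upper", "outer_upper", "inner_middle",
            "outer_middle", "inner_lower", "outer_lower")
  for (i in sample(nrow(fs), 25)) {
    counts <- as.numeric(fs[i, cols])
    expect_equal(sum(counts > 0), 1L)
    expect_identical(fruit_setting_position(counts), which(counts > 0))
  }

  # replicate blocks of 9 support trimmed aggregation per variety
  reps <- generate_measurement_records(spec, "replicate_block", indicator = "SSH")
  expect_equal(unname(table(reps$variety)[1]), 9L)
  agg <- tapply(reps$value, reps$variety, trimmed_aggregate)
  prh <- spec$params[spec$params$code == "SSH", ]
  expect_true(all(agg >= prh$min & agg <= prh$max))

  expect_error(generate_measurement_records(spec, "vibration"))
})

test_that("record tables are reproducible independently of generation order", {
  spec <- default_cohort_spec("pendent", seed = 5)
  a <- generate_measurement_records(spec, "lodging")
  invisible(generate_trait_matrix(spec))  # interleave another draw
  b <- generate_measurement_records(spec, "lodging")
  expect_identical(a, b)
})
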