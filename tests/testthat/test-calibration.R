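published_k <- 0.7218
published_Y0 <- 0.02733
published_span <- 99.50267  # YM - Y0
published_YM <- 99.53

test_that("logit_percent matches its closed form and round-trips with its inverse", {
  expect_equal(logit_percent(50), 0)
  expect_equal(logit_percent(90), log(9))
  expect_equal(logit_percent(0, eps = 1e-4), log(1e-4 / (1 - 1e-4)))
  expect_equal(logit_percent(100, eps = 1e-4), log((1 - 1e-4) / 1e-4))
  p <- c(0.1, 5, 37.5, 50, 82, 99.9)
  expect_equal(inv_logit_percent(logit_percent(p)), p)
  expect_error(logit_percent(101), "\\[0, 100\\]")
  expect_error(logit_percent(-2), "\\[0, 100\\]")
  expect_error(logit_percent(50, eps = 0.7), "eps")
})

test_that("linear families recover generating coefficients on noiseless data", {
  rec <- linear_surface_records(n = 10, b = c(10, 2, -1))
  m <- fit_linear_calibration(rec, "A")
  expect_equal(unname(m$coefficients), c(10, 2, -1), tolerance = 1e-9)
  expect_equal(m$residual_sd, 0, tolerance = 1e-8)

  recC <- logit_surface_records(n = 12, b = c(4, 0.3, -0.45))
  mC <- fit_linear_calibration(recC, "C")
  expect_equal(unname(mC$coefficients), c(4, 0.3, -0.45), tolerance = 1e-8)
  # back-transformed predictions reproduce the generating surface
  pred <- predict(mC, recC)
  expect_equal(pred, recC$observed_percent_microbial, tolerance = 1e-8)
})

test_that("linear fitting rejects underdetermined and degenerate designs", {
  rec <- linear_surface_records(n = 10)
  expect_error(fit_linear_calibration(rec[1:2, ], "B"), "rank")
  rec_const <- rec
  rec_const$ct_16s <- 25
  expect_error(fit_linear_calibration(rec_const, "A"), "collinearity")
  rec_na <- rec
  rec_na$ct_actb[3] <- NA
  expect_error(fit_linear_calibration(rec_na, "A"), "lin03")
  expect_error(fit_linear_calibration(rec, "E"), "nonlinear")
})

test_that("OLS coefficients match a brute-force normal-equations oracle", {
  for (seed in c(11, 12, 13)) {
    rec <- withr::with_seed(seed, {
      n <- sample(6:12, 1)
      data.frame(sample_id = paste0("s", 1:n), sample_type = "stool",
                 ct_16s = runif(n, 15, 35), ct_actb = runif(n, 15, 35),
                 ct_18s = runif(n, 25, 35), delta_ct = 0,
                 observed_percent_microbial = runif(n, 1, 99), flags = "",
                 stringsAsFactors = FALSE)
    })
    rec$delta_ct <- rec$ct_actb - rec$ct_16s
    for (fam in c("A", "B", "C", "D")) {
      m <- fit_linear_calibration(rec, fam)
      preds <- model_spec(fam)$predictors
      X <- cbind(1, as.matrix(rec[, preds]))
      y <- if (model_spec(fam)$transform == "logit") {
        logit_percent(rec$observed_percent_microbial)
      } else {
        rec$observed_percent_microbial
      }
      beta <- solve(t(X) %*% X, t(X) %*% y)
      expect_equal(unname(m$coefficients), unname(drop(beta)), tolerance = 1e-8)
    }
  }
})

test_that("the published curve equals the printed equation and honors its bounds", {
  # independent evaluation of the printed equation
  printed <- function(d) 2.7201549 / (99.50267 * exp(-0.7218 * d) + 0.02733)
  expect_equal(published_model_e(0), published_Y0, tolerance = 1e-12)
  expect_equal(published_model_e(10), printed(10), tolerance = 1e-12)
  expect_equal(published_model_e(10), 27.12233, tolerance = 1e-6)
  # asymptote equals the long division of numerator by baseline
  expect_equal(published_model_e(500), 2.7201549 / 0.02733, tolerance = 1e-9)
  # strictly increasing over (and beyond) the calibration range; at extreme
  # delta the asymptotes saturate double precision, so the wide check is weak
  core <- published_model_e(seq(-20, 40, by = 0.25))
  expect_true(all(diff(core) > 0))
  wide <- published_model_e(seq(-60, 60, by = 0.25))
  expect_true(all(diff(wide) >= 0))
  expect_true(all(wide > 0 & wide < published_YM))
  # Y0 is the value at delta = 0, and a lower bound only for delta > 0
  expect_true(all(published_model_e(seq(0.25, 40, 0.25)) > published_Y0))
  expect_lt(published_model_e(-8.16), published_Y0)
  expect_error(published_model_e(Inf), "finite")
  # reparametrization identity of the printed constants
  expect_equal((published_span + published_Y0) * published_Y0, 2.7201549,
               tolerance = 1e-12)
})

test_that("logistic-growth fitting recovers the generating curve from noiseless data", {
  rec <- simulate_calibration_records(100, noise_sd_logit = 0, seed = 3)
  m <- fit_logistic_growth(rec)
  expect_lt(abs(m$params[["k"]] - published_k) / published_k, 1e-3)
  expect_lt(abs((m$params[["YM"]] - m$params[["Y0"]]) - published_span) /
              published_span, 1e-3)
  expect_gt(m$r_squared, 1 - 1e-9)
  # invariants on the fitted triple
  expect_true(m$params[["Y0"]] > 0)
  expect_true(m$params[["Y0"]] < m$params[["YM"]])
  expect_true(m$params[["YM"]] <= 100)
})

test_that("logistic-growth fitting rejects unidentifiable inputs", {
  rec <- simulate_calibration_records(10, noise_sd_logit = 0, seed = 1)
  rec$delta_ct <- 5
  expect_error(fit_logistic_growth(rec), "identifiability")
  expect_error(fit_logistic_growth(
    simulate_calibration_records(10, seed = 1)[1:3, ]), "rank")
})

test_that("parameter estimates tighten as the sample grows", {
  err <- vapply(c(50, 500), function(n) {
    rec <- simulate_calibration_records(n, noise_sd_logit = 0.3, seed = 99)
    m <- fit_logistic_growth(rec)
    abs(m$params[["k"]] - published_k) / published_k
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("prediction applies validity and extrapolation flags", {
  m <- published_model()
  res <- predict_percent_microbial(m, delta_records(10))
  expect_equal(res$percent_microbial, published_model_e(10), tolerance = 1e-12)
  expect_true(res$in_validity_range)
  expect_false(res$extrapolated)

  expect_true(predict_percent_microbial(m, delta_records(40))$extrapolated)
  expect_true(predict_percent_microbial(m, delta_records(-9))$extrapolated)

  low <- predict_percent_microbial(m, delta_records(6.3))  # ~2% microbial
  expect_lt(low$percent_microbial, 4)
  expect_false(low$in_validity_range)

  rec <- delta_records(10)
  rec$flags <- "censored_ct"
  expect_error(predict_percent_microbial(m, rec), "censored")
  rec2 <- delta_records(10)
  rec2$delta_ct <- NA
  expect_error(predict_percent_microbial(m, rec2), "delta_ct")
})

test_that("out-of-range linear predictions are clamped and noted", {
  rec <- linear_surface_records(n = 10, b = c(10, 2, -1))
  m <- fit_linear_calibration(rec, "A")
  far <- rec[1, , drop = FALSE]
  far$ct_16s <- 80  # pushes the linear response far above 100
  res <- predict_percent_microbial(m, far, level = NULL)
  expect_lt(res$percent_microbial, 100)
  expect_match(res$flags, "clamped")
})

test_that("diagnostics follow their closed forms on the percent scale", {
  m <- published_model()
  rec <- delta_records(c(5, 10, 15))
  rec$observed_percent_microbial <- published_model_e(c(5, 10, 15)) + c(-2, 0, 2)
  d <- diagnostics(m, rec)
  expect_equal(d$residuals, c(-2, 0, 2))
  expect_equal(d$residual_mean, 0)
  expect_equal(d$residual_range, 4)
  expect_equal(d$residual_sd, 2)  # n-1 denominator

  perfect <- rec
  perfect$observed_percent_microbial <- published_model_e(c(5, 10, 15))
  dp <- diagnostics(m, perfect)
  expect_equal(dp$r_squared, 1)
  expect_equal(dp$residual_range, 0)

  flat <- rec
  flat$observed_percent_microbial <- rep(50, 3)
  expect_warning(df <- diagnostics(m, flat), "zero variance")
  expect_true(is.na(df$r_squared))
  expect_error(diagnostics(m, rec[0, ]), "no records")
})

test_that("a refit on realistic noise keeps high explanatory power", {
  rec <- simulate_calibration_records(89, seed = 21)
  m <- fit_logistic_growth(rec)
  expect_gt(m$r_squared, 0.95)
  expect_lt(abs(m$params[["k"]] - published_k) / published_k, 0.25)
})

test_that("shifting zeroes the mean residual, preserves spread, and is idempotent", {
  rec <- simulate_calibration_records(60, seed = 8)
  m <- fit_linear_calibration(rec, "C")
  biased <- m
  biased$shift_offset <- biased$shift_offset - 3  # induce a +3 mean residual
  d0 <- diagnostics(biased, rec)
  shifted <- shift_to_zero_mean_residual(biased, rec)
  expect_equal(shifted$shift_offset - biased$shift_offset, d0$residual_mean)
  d1 <- diagnostics(shifted, rec)
  expect_lt(abs(d1$residual_mean), 1e-10)
  expect_lt(abs(d1$residual_sd - d0$residual_sd), 1e-10)
  twice <- shift_to_zero_mean_residual(shifted, rec)
  expect_equal(twice$shift_offset, shifted$shift_offset, tolerance = 1e-10)
})

test_that("the one-tailed bound matches normal theory and a Monte-Carlo oracle", {
  m <- published_model()  # residual_sd 4.35, n_train 89
  b <- one_tailed_prediction_bound(m, 50, level = 0.95)
  expect_equal(as.numeric(b),
               50 - qnorm(0.95) * 4.35 * sqrt(1 + 1 / 89), tolerance = 1e-12)
  # Monte-Carlo 5th percentile of point + predictive residual draws
  mc <- withr::with_seed(123, {
    quantile(50 + rnorm(4e5, 0, 4.35 * sqrt(1 + 1 / 89)), 0.05, names = FALSE)
  })
  expect_equal(as.numeric(b), mc, tolerance = 0.05)
  expect_equal(attr(b, "method"), "normal")

  degenerate <- m
  degenerate$residual_sd <- 0
  expect_equal(as.numeric(one_tailed_prediction_bound(degenerate, 50)), 50)
  expect_equal(as.numeric(one_tailed_prediction_bound(m, 1)), 0)  # clamped
  expect_error(one_tailed_prediction_bound(m, 50, level = 0.4), "level")
  emp <- one_tailed_prediction_bound(m, 50, method = "empirical",
                                     residuals = c(-5, -1, 0, 1, 5))
  expect_lt(as.numeric(emp), 50)
})

test_that("models survive a JSON serialization round trip", {
  rec <- simulate_calibration_records(40, seed = 5)
  for (maker in list(function() fit_logistic_growth(rec),
                     function() fit_linear_calibration(rec, "D"))) {
    m <- maker()
    path <- tempfile(fileext = ".json")
    write_model(m, path)
    back <- read_model(path)
    expect_equal(back$family, m$family)
    expect_equal(back$coefficients, m$coefficients)
    expect_equal(back$params, m$params)
    expect_equal(predict(back, rec), predict(m, rec))
  }
})
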