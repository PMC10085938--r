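test_that("noise-free single-marker data is interpolated exactly", {
  g <- generate_dataset(one_marker_config(n = 60, cutoff = 20, noise_sd = 0))
  m <- fit_age_model(g$dataset, cutoff = 20)
  # x = 0.3 + 0.1 * f(age)  =>  f(age) = -3 + 10 * x
  expect_equal(unname(m$coefficients["M1"]), 10, tolerance = 1e-8)
  expect_equal(m$intercept, -3, tolerance = 1e-8)
  expect_equal(m$residual_standard_error, 0, tolerance = 1e-8)
})

test_that("cutoff 0 reproduces plain linear regression on raw age", {
  g <- generate_dataset(generator_config(
    n = 120, seed = 21,
    markers = default_marker_panel(noise_sd = 0.05, sst_missing_fraction = 0)))
  d <- g$dataset
  m <- fit_age_model(d, cutoff = 0)
  oracle <- stats::lm(stats::reformulate(dataset_markers(d), "age"),
                      data = as.data.frame(d))
  expect_equal(unname(c(m$intercept, m$coefficients)),
               unname(stats::coef(oracle)), tolerance = 1e-8)
  # predictions agree wherever the plain fit is non-negative (negatives
  # go through the log branch of the backtransform instead)
  pred <- predict_age(m, as.data.frame(d)[dataset_markers(d)])
  ok <- stats::fitted(oracle) >= 0
  expect_equal(unname(pred[ok]), unname(stats::fitted(oracle))[ok],
               tolerance = 1e-8)
  expect_equal(m$residual_standard_error, summary(oracle)$sigma,
               tolerance = 1e-8)
})

test_that("coefficients are recovered within 3 SE under the model's own noise", {
  truth <- make_model(intercept = 0.5,
                      coefficients = c(a = 1.2, b = -0.6, c = 2.0),
                      sigma = 0.29, cutoff = 20)
  g <- generate_from_model(truth, n = 2000, seed = 17, noise_sd = 0.29)
  m <- fit_age_model(g$dataset, cutoff = 20)
  se <- m$residual_standard_error * sqrt(diag(m$xtx_inv))
  est <- c(m$intercept, m$coefficients)
  expect_true(all(abs(est - c(0.5, 1.2, -0.6, 2.0)) <= 3 * se))
})

test_that("fit errors are informative", {
  # constant column is named in the rank-deficiency error
  df <- as.data.frame(generate_dataset(one_marker_config(n = 30))$dataset)
  df$flat <- 0.5
  d2 <- meth_dataset(df)
  expect_error(fit_age_model(d2, cutoff = 20), "flat")
  # too few complete samples: 4 rows, one NA, two markers -> 3 < 4 needed
  small <- meth_dataset(as.data.frame(tiny_dataset())[1:4, ])
  expect_error(fit_age_model(small, markers = c("mkA", "mkB")), "Too few")
})

test_that("in-sample residuals on the epigenetic scale average to zero", {
  g <- generate_dataset(generator_config(n = 100, seed = 9))
  d <- filter_markers_by_missingness(g$dataset)$dataset
  m <- fit_age_model(d, cutoff = 20)
  y <- horvath_transform(d$age, 20)
  resid <- y - predict_epigenetic(m, as.data.frame(d)[dataset_markers(d)])
  expect_lt(abs(mean(resid)), 1e-10)
})

test_that("published model evaluates the printed equation", {
  pm <- published_model()
  expect_length(pm$coefficients, 7)
  expect_equal(pm$cutoff, 20)
  expect_equal(pm$residual_standard_error, 0.2905)
  expect_equal(pm$df_residual, 153L)
  zero <- stats::setNames(rep(0, 7), names(pm$coefficients))
  expect_equal(predict_epigenetic(pm, zero), -1.5880)
  trim <- zero; trim["TRIM59"] <- 1
  expect_equal(predict_epigenetic(pm, trim), -1.5880 + 3.5634)
  # backtransforms: frozen high-precision value for the log branch,
  # closed-form linear branch
  expect_equal(predict_age(pm, zero), 3.29101129269979, tolerance = 1e-9)
  expect_equal(predict_age(pm, trim), 1.9754 * 21 + 20, tolerance = 1e-9)
})

test_that("prediction errors name the offending marker", {
  pm <- published_model()
  expect_error(predict_epigenetic(pm, c(TRIM59 = 0.5)), "PDE4C")
  bad <- stats::setNames(rep(0, 7), names(pm$coefficients))
  bad["FHL2"] <- 1.4
  expect_error(predict_epigenetic(pm, bad), "\\[0,1\\]")
})

test_that("an intercept-only profile lands exactly on the cutoff when y_e = 0", {
  m <- make_model(0, c(x = 0), sigma = 0.1, cutoff = 24.3)
  expect_equal(predict_age(m, c(x = 0.5)), 24.3)
})

test_that("residual-only interval has the closed-form width on the linear branch", {
  pm <- published_model()
  prof <- stats::setNames(rep(0, 7), names(pm$coefficients))
  prof["KLF14"] <- 0.9  # y_e = -1.588 + 4.514 = 2.926; interval all positive
  pi <- prediction_interval(pm, prof, level = 0.95, method = "residual_only")
  width_expected <- 2 * stats::qnorm(0.975) * 0.2905 * 21
  expect_equal(pi$upper - pi$lower, width_expected, tolerance = 1e-9)
  expect_lt(pi$lower, pi$fit); expect_gt(pi$upper, pi$fit)
})

test_that("a zero residual SE collapses the interval to the point estimate", {
  m <- make_model(1, c(x = 0.5), sigma = 0, cutoff = 20)
  pi <- prediction_interval(m, c(x = 0.4))
  expect_equal(pi$lower, pi$fit)
  expect_equal(pi$upper, pi$fit)
})

test_that("chronological interval width is non-decreasing in the estimate", {
  pm <- published_model()
  # sweep y_e from deep log branch into the linear branch via KLF14; width
  # grows strictly until the whole interval is linear, then is constant
  xs <- seq(0, 1, by = 0.05)
  widths <- vapply(xs, function(x) {
    prof <- stats::setNames(rep(0, 7), names(pm$coefficients))
    prof["KLF14"] <- x
    pi <- prediction_interval(pm, prof)
    pi$upper - pi$lower
  }, numeric(1))
  expect_true(all(diff(widths) >= -1e-9))
  expect_true(all(diff(widths[1:8]) > 0))  # strictly, while log branch active
  # constant once entirely linear: 2 * z * s * (cutoff + 1)
  expect_equal(widths[length(widths)],
               2 * stats::qnorm(0.975) * 0.2905 * 21, tolerance = 1e-9)
})

test_that("leverage_t intervals contain the residual-only interval near the data", {
  g <- generate_dataset(generator_config(n = 150, seed = 12))
  d <- filter_markers_by_missingness(g$dataset)$dataset
  m <- fit_age_model(d, cutoff = 20)
  prof <- as.data.frame(d)[3, dataset_markers(d)]
  ro <- prediction_interval(m, prof, method = "residual_only")
  lt <- prediction_interval(m, prof, method = "leverage_t")
  expect_lt(lt$lower, ro$lower)
  expect_gt(lt$upper, ro$upper)
  # the published fixture carries no design information
  expect_error(prediction_interval(published_model(),
                                   stats::setNames(rep(0.3, 7),
                                                   names(published_model()$coefficients)),
                                   method = "leverage_t"),
               "design")
  expect_error(prediction_interval(m, prof, level = 1.2), "level")
})

test_that("models survive a JSON round trip and match the shipped fixture", {
  g <- generate_dataset(generator_config(n = 90, seed = 13))
  d <- filter_markers_by_missingness(g$dataset)$dataset
  m <- fit_age_model(d, cutoff = 24.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$cutoff, m$cutoff)
  expect_equal(m2$residual_standard_error, m$residual_standard_error)
  shipped <- read_model(system.file("extdata", "published_7cpg_model.json",
                                    package = "epiage"))
  pm <- published_model()
  expect_equal(shipped$coefficients, pm$coefficients)
  expect_equal(shipped$intercept, pm$intercept)
})
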