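test_that("MAD and RMSE follow their definitions", {
  expect_equal(mad_error(c(0, 0, 0)), 0)
  expect_equal(rmse_error(c(0, 0, 0)), 0)
  expect_equal(mad_error(c(3, -4)), 3.5)
  expect_equal(rmse_error(c(3, -4)), sqrt(12.5))
  expect_error(mad_error(numeric(0)), "Empty")
  # power-mean inequality on random error sets
  set.seed(77)
  for (i in 1:20) {
    e <- rnorm(sample(2:50, 1), sd = runif(1, 0.1, 10))
    expect_lte(mad_error(e), rmse_error(e))
  }
})

test_that("adjusted R2 matches the reported training and validation values", {
  expect_equal(round(adjusted_r2(0.888, 161, 7), 3), 0.883)
  expect_equal(round(adjusted_r2(0.878, 69, 7), 3), 0.864)
  expect_equal(adjusted_r2(1, 30, 5), 1)
  expect_lte(adjusted_r2(0.7, 50, 6), 0.7)
  expect_error(adjusted_r2(0.5, 8, 7), "n > k")
  expect_error(adjusted_r2(1.4, 100, 3), "\\[0,1\\]")
})

test_that("Bland-Altman reproduces the reported limits of agreement", {
  # differences constructed to have exactly the printed mean and SD
  d <- scaled_differences(-1.718, 6.417, 69)
  ba <- bland_altman(rep(0, 69), d)
  expect_equal(ba$mean_diff, -1.718, tolerance = 1e-12)
  expect_equal(ba$sd_diff, 6.417, tolerance = 1e-12)
  expect_equal(round(ba$loa_upper, 2), 10.86)
  expect_equal(round(ba$loa_lower, 3), -14.295)
})

test_that("Bland-Altman degenerate cases and the 1.96 identity hold", {
  x <- c(10, 20, 35)
  ba <- bland_altman(x, x)
  expect_equal(ba$mean_diff, 0); expect_equal(ba$sd_diff, 0)
  expect_equal(ba$loa_upper, 0); expect_equal(ba$loa_lower, 0)
  off <- bland_altman(x, x + 2.5)
  expect_equal(off$mean_diff, 2.5); expect_equal(off$sd_diff, 0)
  expect_equal(off$loa_upper, 2.5); expect_equal(off$loa_lower, 2.5)
  set.seed(5)
  for (i in 1:10) {
    a <- runif(20, 0, 90); b <- a + rnorm(20, 0, 5)
    ba <- bland_altman(a, b)
    expect_equal(ba$loa_upper, ba$mean_diff + 1.96 * ba$sd_diff)
    expect_equal(ba$loa_lower, ba$mean_diff - 1.96 * ba$sd_diff)
  }
  expect_error(bland_altman(1:3, 1:4), "equal length")
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("the pooled row of the binned table is the weighted subgroup mean", {
  # per-bin constant absolute errors equal to the reported subgroup MADs
  mads <- c(2.64, 3.59, 5.74, 8.68)
  ns <- c(11, 30, 19, 9)
  mids <- c(10, 30, 50, 75)
  chron <- rep(mids, ns)
  est <- chron + rep(mads, ns)
  tab <- binned_accuracy_report(chron, est)
  expect_equal(tab$mad[1:4], mads)
  expect_equal(tab$n[5], 69)
  expect_equal(tab$mad[5], sum(mads * ns) / 69)  # 4.6945
  expect_equal(round(tab$mad[5], 2), 4.69)
})

test_that("binned percentages use an inclusive boundary and pool consistently", {
  chron <- c(10, 10, 10)
  est <- chron + c(1, -2, 3)   # all |e| <= 3
  tab <- binned_accuracy_report(chron, est, bin_edges = c(0, 20))
  expect_true(all(tab$pct_within_3 == 100))
  expect_true(all(tab$pct_within_6 == 100))
  # |e| exactly 3.0 counts as within +/-3
  tab2 <- binned_accuracy_report(10, 13, bin_edges = c(0, 20))
  expect_equal(tab2$pct_within_3[1], 100)
  # pooled counts equal summed per-bin counts
  set.seed(8)
  chron <- runif(80, 0, 90)
  est <- chron + rnorm(80, 0, 5)
  tab3 <- binned_accuracy_report(chron, est)
  k <- nrow(tab3)
  for (cl in grep("^pct_within_", names(tab3), value = TRUE)) {
    per_bin_hits <- sum(tab3[[cl]][-k] * tab3$n[-k] / 100)
    expect_equal(per_bin_hits, tab3[[cl]][k] * tab3$n[k] / 100,
                 tolerance = 1e-9)
  }
  expect_error(binned_accuracy_report(95, 90, bin_edges = c(0, 90)),
               "outside")
})

test_that("correlation screen matches exact and hand-computed cases", {
  n <- 10
  ages <- seq(5, 85, length.out = n)
  d <- meth_dataset(data.frame(
    sample_id = paste0("c", 1:n), age = ages, sex = rep_len(c("M", "F"), n),
    up = 0.1 + 0.008 * ages,
    down = 0.9 - 0.008 * ages))
  sc <- cpg_correlation_screen(d)
  expect_equal(sc$r[sc$marker == "up"], 1, tolerance = 1e-12)
  expect_equal(sc$r[sc$marker == "down"], -1, tolerance = 1e-12)
})

test_that("four-point screen gives r = 0.8 and p = 0.2", {
  # hand computation: cov = 1.5/ (sd 1.2910^2) -> r = 0.8;
  # t = 0.8 * sqrt(2 / 0.36) = 1.8856, two-sided p on 2 df = 0.2
  d <- meth_dataset(data.frame(
    sample_id = paste0("p", 1:4), age = c(1, 3, 2, 4),
    sex = c("M", "F", "M", "F"), mk = c(0.1, 0.2, 0.3, 0.4)))
  sc <- cpg_correlation_screen(d)
  expect_equal(sc$r, 0.8, tolerance = 1e-12)
  expect_equal(sc$p_value, 0.2, tolerance = 1e-9)
  expect_equal(sc$n_used, 4L)
})

test_that("screen agrees with a brute-force covariance formula", {
  set.seed(25)
  n <- 50
  df <- data.frame(sample_id = paste0("r", 1:n),
                   age = runif(n, 1, 88), sex = rep_len(c("M", "F"), n))
  for (j in 1:4) df[[paste0("m", j)]] <- runif(n)
  df$m2[sample(n, 12)] <- NA   # exercise pairwise-complete handling
  d <- meth_dataset(df)
  sc <- cpg_correlation_screen(d)
  for (j in 1:4) {
    m <- paste0("m", j)
    x <- d[[m]]; ok <- !is.na(x)
    xs <- x[ok]; ys <- d$age[ok]; nn <- sum(ok)
    r_oracle <- (sum(xs * ys) / nn - mean(xs) * mean(ys)) /
      sqrt((sum(xs^2) / nn - mean(xs)^2) * (sum(ys^2) / nn - mean(ys)^2))
    expect_equal(sc$r[sc$marker == m], r_oracle, tolerance = 1e-10)
    expect_equal(sc$n_used[sc$marker == m], nn)
  }
})

test_that("constant markers are reported as unavailable, not as errors", {
  d <- meth_dataset(data.frame(
    sample_id = paste0("k", 1:6), age = c(4, 9, 20, 33, 50, 70),
    sex = rep_len(c("M", "F"), 6), flat = rep(0.5, 6),
    sparse = c(0.2, NA, NA, NA, NA, 0.4)))
  sc <- cpg_correlation_screen(d)
  expect_true(is.na(sc$r[sc$marker == "flat"]))
  expect_true(is.na(sc$r[sc$marker == "sparse"]))  # < 3 complete pairs
  expect_equal(sc$n_used[sc$marker == "sparse"], 2L)
})

test_that("evaluating a model on its own noise-free data is perfect", {
  truth <- make_model(0.4, c(a = 1.5, b = -0.8), sigma = 0, cutoff = 20)
  g <- generate_from_model(truth, n = 120, seed = 26, noise_sd = 0)
  rep <- evaluate_model(truth, g$dataset)
  expect_equal(rep$mad, 0, tolerance = 1e-9)
  expect_equal(rep$rmse, 0, tolerance = 1e-9)
  expect_equal(rep$pearson_r, 1, tolerance = 1e-9)
  expect_equal(rep$r_squared_sse, 1, tolerance = 1e-9)
})

test_that("report R2 is exactly the squared Pearson correlation", {
  g <- generate_dataset(generator_config(n = 150, seed = 27))
  d <- filter_markers_by_missingness(g$dataset)$dataset
  sp <- split_train_validation(d, 100, seed = 1)
  m <- fit_age_model(sp$train, cutoff = 20)
  rep <- evaluate_model(m, sp$validation)
  expect_equal(rep$r_squared, rep$pearson_r^2, tolerance = 1e-12)
  expect_lte(rep$adjusted_r_squared, rep$r_squared)
  expect_lte(rep$mad, rep$rmse)
  expect_equal(rep$n + rep$n_dropped, nrow(sp$validation))
  # missing-marker rows are dropped and counted
  df <- as.data.frame(sp$validation)
  df$TRIM59[1:5] <- NA
  rep2 <- evaluate_model(m, meth_dataset(df))
  expect_equal(rep2$n_dropped, 5)
})

test_that("evaluation reports serialise to JSON and tables", {
  g <- generate_dataset(generator_config(n = 100, seed = 28))
  d <- filter_markers_by_missingness(g$dataset)$dataset
  sp <- split_train_validation(d, 70, seed = 2)
  m <- fit_age_model(sp$train, cutoff = 20)
  rep <- evaluate_model(m, sp$validation)
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".csv")
  sp2 <- withr::local_tempfile(fileext = ".csv")
  write_evaluation_report(rep, jp, tp, sp2)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$rmse, rep$rmse)
  expect_equal(back$bland_altman$sd_diff, rep$bland_altman$sd_diff)
  expect_equal(nrow(utils::read.csv(sp2)), rep$n)
})
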