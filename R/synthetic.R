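#' Default synthetic CpG marker panel
#'
#' Eight markers emulating the study panel: slopes are per unit of the
#' transformed (epigenetic-scale) age, signed so that EDARADD and C1orf132
#' correlate negatively with age and the rest positively; the SST-like
#' marker drops out in two thirds of samples. Baselines and slopes are
#' chosen so that methylation stays inside \[0, 1\] over ages 1-88 at
#' cut-offs up to ~35 with little clipping.
#'
#' @param noise_sd Per-marker Gaussian assay noise on the proportion scale.
#'   Default 0.03, a typical minisequencing replicate spread.
#' @param sst_missing_fraction Missing fraction for the SST-like marker.
#'   Default 2/3.
#' @return Data frame with columns `name`, `baseline`, `slope`, `noise_sd`,
#'   `missing_fraction`.
#' @export
default_marker_panel <- function(noise_sd = 0.03, sst_missing_fraction = 2 / 3) {
  data.frame(
    name = c("PDE4C", "EDARADD", "SST", "KLF14", "ELOVL2",
             "FHL2", "C1orf132", "TRIM59"),
    baseline = c(0.50, 0.55, 0.45, 0.20, 0.32, 0.40, 0.60, 0.35),
    slope = c(0.03, -0.08, 0.08, 0.05, 0.13, 0.10, -0.05, 0.12),
    noise_sd = noise_sd,
    missing_fraction = c(0, 0, sst_missing_fraction, 0, 0, 0, 0, 0)
  )
}

#' Configuration for the synthetic methylation-age generator
#'
#' Defaults emulate the study design: 230 donors (102 male, 128 female),
#' ages 1-88 years, the eight-marker panel of [default_marker_panel()] with
#' one marker missing in two thirds of samples, and methylation linear in
#' the transformed age at a generative cut-off of 20 years. Ages are drawn
#' uniformly on 1-88 by default; the `"study"` distribution skews them
#' toward the reported cohort mean of 38 years (scaled Beta(1.7, 2.3)).
#'
#' @param n Number of samples. Default 230.
#' @param age_range Minimum and maximum age in whole years. Default
#'   `c(1, 88)`.
#' @param age_distribution `"uniform"` or `"study"` (right-skewed, mean
#'   ~38 years).
#' @param sex_fractions Named fractions `c(male = , female = )` summing
#'   to 1. Counts are fixed at `round(n * male_fraction)` males so the
#'   default reproduces 102/128 exactly.
#' @param markers Marker panel data frame as in [default_marker_panel()].
#' @param generative_cutoff Adult cut-off (years) used to generate the
#'   methylation-age relation. Default 20.
#' @param sex_cutoff_offsets Named years added to the cut-off per sex,
#'   `c(male = 0, female = 0)` by default; set e.g. `female = 12` to emulate
#'   sex-specific epigenetic aging.
#' @param seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n = 230,
                             age_range = c(1, 88),
                             age_distribution = c("uniform", "study"),
                             sex_fractions = c(male = 102 / 230, female = 128 / 230),
                             markers = default_marker_panel(),
                             generative_cutoff = 20,
                             sex_cutoff_offsets = c(male = 0, female = 0),
                             seed = 1L) {
  age_distribution <- match.arg(age_distribution)
  stopifnot(is.numeric(n), n >= 2, length(age_range) == 2L,
            age_range[1] >= 0, age_range[2] > age_range[1],
            abs(sum(sex_fractions) - 1) < 1e-8,
            all(c("male", "female") %in% names(sex_fractions)),
            is.data.frame(markers),
            all(c("name", "baseline", "slope", "noise_sd",
                  "missing_fraction") %in% names(markers)),
            all(markers$noise_sd >= 0),
            all(markers$missing_fraction >= 0 & markers$missing_fraction <= 1),
            all(markers$baseline >= 0 & markers$baseline <= 1),
            is.numeric(generative_cutoff), generative_cutoff >= 0,
            all(c("male", "female") %in% names(sex_cutoff_offsets)))
  structure(list(n = as.integer(n), age_range = age_range,
                 age_distribution = age_distribution,
                 sex_fractions = sex_fractions, markers = markers,
                 generative_cutoff = generative_cutoff,
                 sex_cutoff_offsets = sex_cutoff_offsets,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic methylation-age dataset
#'
#' For sample \eqn{i} with sex-specific cut-off \eqn{c_i} and marker \eqn{j},
#' methylation is
#' \eqn{x_{ij} = \mathrm{clip}(b_j + s_j f(a_i; c_i) + \epsilon_{ij},\ 0,\ 1)}
#' with \eqn{f} the log/linear transform, \eqn{\epsilon_{ij}} independent
#' Gaussian noise, and per-marker missingness imposed on
#' `round(missing_fraction * n)` randomly chosen samples. This inverts the
#' model's direction of inference (it puts the age signal into the markers),
#' so every downstream stage — screening, cut-off tuning, fitting,
#' evaluation — sees data with the structure the analysis assumes.
#'
#' @param config A [generator_config()].
#' @return List with `dataset` (a [meth_dataset()]) and `ground_truth`
#'   (list: the config, per-sample cut-offs, the transformed ages, and the
#'   pre-clip, pre-missingness methylation matrix).
#' @examples
#' g <- generate_dataset(generator_config(n = 50, seed = 42))
#' g$dataset
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  local_seed(config$seed, {
    n <- config$n
    lo <- config$age_range[1]; hi <- config$age_range[2]
    ages <- if (config$age_distribution == "uniform") {
      sample(seq(lo, hi), n, replace = TRUE)
    } else {
      round(lo + (hi - lo) * stats::rbeta(n, 1.7, 2.3))
    }
    n_male <- round(n * config$sex_fractions[["male"]])
    sex <- sample(rep(c("male", "female"), c(n_male, n - n_male)))
    cutoffs <- config$generative_cutoff +
      unname(config$sex_cutoff_offsets[sex])
    if (any(cutoffs < 0)) stop("Negative sex-specific cutoff.", call. = FALSE)
    # transform each sample's age at its own sex-specific cutoff
    y_e <- vapply(seq_len(n), function(i)
      horvath_transform(ages[i], cutoffs[i]), numeric(1))
    mk <- config$markers
    pre_clip <- matrix(NA_real_, n, nrow(mk), dimnames = list(NULL, mk$name))
    x <- pre_clip
    for (j in seq_len(nrow(mk))) {
      pre_clip[, j] <- mk$baseline[j] + mk$slope[j] * y_e +
        stats::rnorm(n, 0, mk$noise_sd[j])
      x[, j] <- pmin(pmax(pre_clip[, j], 0), 1)
      n_miss <- round(mk$missing_fraction[j] * n)
      if (n_miss > 0) x[sample(n, n_miss), j] <- NA_real_
    }
    d <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                    age = as.numeric(ages), sex = sex,
                    stringsAsFactors = FALSE)
    d <- cbind(d, as.data.frame(x))
    list(dataset = meth_dataset(d, markers = mk$name),
         ground_truth = list(config = config, cutoffs = cutoffs,
                             transformed_age = y_e, pre_clip = pre_clip))
  })
}

#' Generate data from a fitted model's own equation
#'
#' Draws methylation profiles uniformly within per-marker ranges, computes
#' the epigenetic-scale response
#' \eqn{y_e = \beta_0 + \sum_j \beta_j x_j + \varepsilon} with Gaussian
#' noise, and backtransforms to chronological age. This is the forward
#' direction of the model equation, so OLS on the result is correctly
#' specified — the setup for coefficient-recovery and interval-coverage
#' checks. Marker ranges must be chosen so that realised ages are
#' non-negative (an error is raised otherwise).
#'
#' @param model An `age_model`.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param noise_sd Residual noise SD on the epigenetic scale; defaults to
#'   the model's residual standard error.
#' @param marker_ranges Optional named list of `c(min, max)` per marker;
#'   default `c(0, 1)` for all.
#' @return List with `dataset` (sexes assigned alternately; they carry no
#'   signal here) and `ground_truth` (`epigenetic_true` = noiseless linear
#'   predictor, `epigenetic` = with noise, `age`).
#' @export
generate_from_model <- function(model, n, seed = 1L,
                                noise_sd = model$residual_standard_error,
                                marker_ranges = NULL) {
  stopifnot(inherits(model, "age_model"), is.numeric(n), n >= 2)
  mk <- names(model$coefficients)
  local_seed(seed, {
    X <- vapply(mk, function(m) {
      rg <- if (!is.null(marker_ranges[[m]])) marker_ranges[[m]] else c(0, 1)
      stats::runif(n, rg[1], rg[2])
    }, numeric(n))
    y0 <- drop(model$intercept + X %*% model$coefficients)
    y <- y0 + stats::rnorm(n, 0, noise_sd)
    age <- horvath_inverse(y, model$cutoff)
    if (any(age < 0)) {
      stop("Generated negative ages; tighten `marker_ranges` or reduce noise.",
           call. = FALSE)
    }
    d <- data.frame(sample_id = sprintf("M%04d", seq_len(n)),
                    age = age,
                    sex = rep_len(c("male", "female"), n),
                    stringsAsFactors = FALSE)
    d <- cbind(d, as.data.frame(X))
    list(dataset = meth_dataset(d, markers = mk),
         ground_truth = list(epigenetic_true = y0, epigenetic = y, age = age))
  })
}

#' Emit a minisequencing-style peak-height table for a dataset
#'
#' For every present methylation value `m` writes one row with peak heights
#' `(m * S, (1 - m) * S)` where the total signal `S` is drawn uniformly in
#' \[0.5, 1.5\] times `total_signal_scale` — so [methylation_from_peaks()]
#' recovers `m` exactly regardless of signal intensity. Missing values are
#' omitted (drop-out leaves no peaks).
#'
#' @param dataset A [meth_dataset()].
#' @param total_signal_scale Typical total fluorescence per marker
#'   (arbitrary units). Default 2000.
#' @param seed Integer seed for the signal intensities.
#' @return Data frame with columns `sample_id`, `marker`,
#'   `methylated_signal`, `unmethylated_signal`.
#' @export
generate_peak_table <- function(dataset, total_signal_scale = 2000, seed = 1L) {
  stopifnot(inherits(dataset, "meth_dataset"))
  mk <- dataset_markers(dataset)
  long <- expand.grid(row = seq_len(nrow(dataset)), marker = mk,
                      stringsAsFactors = FALSE)
  meth <- mapply(function(r, m) dataset[[m]][r], long$row, long$marker)
  present <- !is.na(meth)
  long <- long[present, , drop = FALSE]
  meth <- meth[present]
  local_seed(seed, {
    S <- stats::runif(nrow(long), 0.5, 1.5) * total_signal_scale
    data.frame(sample_id = dataset$sample_id[long$row],
               marker = long$marker,
               methylated_signal = meth * S,
               unmethylated_signal = (1 - meth) * S,
               stringsAsFactors = FALSE)
  })
}
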