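# Shared fixtures, built in code.

# A tiny deterministic dataset: 6 donors, 2 markers, one missing value.
tiny_dataset <- function() {
  meth_dataset(data.frame(
    sample_id = paste0("t", 1:6),
    age = c(3, 12, 25, 40, 61, 80),
    sex = c("F", "M", "F", "M", "F", "M"),
    mkA = c(0.10, 0.20, 0.35, 0.45, 0.60, 0.72),
    mkB = c(0.80, 0.70, NA, 0.50, 0.42, 0.30)
  ))
}

# Hand-built model object for tests that need full control of the
# coefficients (same shape as fit_age_model()/published_model() output).
make_model <- function(intercept, coefficients, sigma = 0.29, cutoff = 20,
                       n_train = 100L) {
  structure(list(
    intercept = intercept,
    coefficients = coefficients,
    residual_standard_error = sigma,
    cutoff = cutoff,
    sex_scope = "unisex",
    n_train = as.integer(n_train),
    df_residual = as.integer(n_train - length(coefficients) - 1L),
    xtx_inv = NULL
  ), class = "age_model")
}

# Single-marker noise-free generator config: methylation = b + s * f(age).
one_marker_config <- function(n = 60, cutoff = 20, noise_sd = 0, seed = 5,
                              baseline = 0.3, slope = 0.1) {
  generator_config(
    n = n,
    markers = data.frame(name = "M1", baseline = baseline, slope = slope,
                         noise_sd = noise_sd, missing_fraction = 0),
    generative_cutoff = cutoff, seed = seed
  )
}

# Vector of differences with exact sample mean m and sample SD s (n >= 3).
scaled_differences <- function(m, s, n) {
  z <- seq_len(n)
  z <- (z - mean(z)) / stats::sd(z)
  m + s * z
}
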