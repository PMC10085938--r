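#' Fit an OLS age model on the transformed scale
#'
#' Regresses the transformed chronological age
#' \eqn{y_e = f(y_c; y_{c,adult})} on the methylation proportions of the
#' chosen markers by ordinary least squares:
#' \eqn{y_e = \beta_0 + \beta_1 x_1 + \dots + \beta_k x_k + \varepsilon}.
#' Samples outside the requested sex scope, and samples with any missing
#' value among the modelled markers, are dropped before fitting
#' (complete-case analysis; no imputation).
#'
#' @param train A [meth_dataset()] of training samples.
#' @param markers Character vector of marker names to use as predictors.
#'   Default: every marker in the dataset.
#' @param cutoff Adult cut-off in years for [horvath_transform()]; 0 fits the
#'   standard linear model on raw age. Default 20.
#' @param sex_scope One of `"unisex"`, `"male_only"`, `"female_only"`.
#' @return An `age_model` object: list with `intercept`, `coefficients`
#'   (named by marker), `residual_standard_error`, `cutoff`, `sex_scope`,
#'   `n_train`, `df_residual`, and `xtx_inv` (for leverage-based intervals).
#' @examples
#' cfg <- generator_config(n = 80, seed = 7)
#' d <- generate_dataset(cfg)$dataset
#' d <- filter_markers_by_missingness(d)$dataset
#' fit_age_model(d, cutoff = 20)
#' @export
fit_age_model <- function(train, markers = NULL, cutoff = 20,
                          sex_scope = c("unisex", "male_only", "female_only")) {
  stopifnot(inherits(train, "meth_dataset"))
  sex_scope <- match.arg(sex_scope)
  if (is.null(markers)) markers <- dataset_markers(train)
  missing_mk <- setdiff(markers, dataset_markers(train))
  if (length(missing_mk)) {
    stop("Marker(s) not in dataset: ", paste(missing_mk, collapse = ", "),
         call. = FALSE)
  }
  d <- restrict_sex(train, sex_scope)
  X_raw <- as.matrix(as.data.frame(d)[markers])
  complete <- stats::complete.cases(X_raw)
  d <- subset_dataset(d, which(complete))
  X_raw <- X_raw[complete, , drop = FALSE]
  n <- nrow(d)
  if (n < length(markers) + 2L) {
    stop(sprintf("Too few complete samples to fit: %d with %d markers (need >= %d).",
                 n, length(markers), length(markers) + 2L), call. = FALSE)
  }
  y <- horvath_transform(d$age, cutoff)
  X <- cbind("(Intercept)" = 1, X_raw)
  fit <- ols_fit(X, y)
  structure(list(
    intercept = unname(fit$coefficients[1L]),
    coefficients = fit$coefficients[-1L],
    residual_standard_error = fit$sigma,
    cutoff = cutoff,
    sex_scope = sex_scope,
    n_train = n,
    df_residual = fit$df_residual,
    xtx_inv = fit$xtx_inv
  ), class = "age_model")
}

restrict_sex <- function(dataset, sex_scope) {
  switch(sex_scope,
         unisex = dataset,
         male_only = subset_dataset(dataset, which(dataset$sex == "male")),
         female_only = subset_dataset(dataset, which(dataset$sex == "female")))
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("<age_model> %s, cutoff %.4g years, n_train %d, df %d\n",
              x$sex_scope, x$cutoff, x$n_train, x$df_residual))
  cat(sprintf("  intercept %.4f, residual SE %.4f\n",
              x$intercept, x$residual_standard_error))
  print(round(x$coefficients, 4))
  invisible(x)
}

# Build the prediction matrix (rows of marker values) from a named vector,
# list, data frame or meth_dataset; errors on missing/out-of-range markers.
methylation_matrix <- function(model, methylation) {
  mk <- names(model$coefficients)
  if (is.numeric(methylation) && !is.matrix(methylation)) {
    methylation <- as.data.frame(as.list(methylation))
  }
  methylation <- as.data.frame(methylation)
  absent <- setdiff(mk, names(methylation))
  if (length(absent)) {
    stop("Missing marker value(s) for prediction: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(methylation[mk])
  if (anyNA(X)) {
    bad <- mk[colSums(is.na(X)) > 0]
    stop("Missing (NA) marker value(s) for prediction: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(X < 0 | X > 1)) {
    stop("Methylation values must be in [0,1].", call. = FALSE)
  }
  X
}

#' Predict epigenetic age (transformed scale)
#'
#' Evaluates the linear predictor \eqn{\hat y_e = \beta_0 + \sum_j \beta_j x_j}
#' for one or more methylation profiles.
#'
#' @param model An `age_model` (e.g. from [fit_age_model()] or
#'   [published_model()]).
#' @param methylation A named numeric vector, list, data frame or
#'   [meth_dataset()] providing a value in \[0, 1\] for every model marker.
#' @return Numeric vector of epigenetic-scale predictions.
#' @export
predict_epigenetic <- function(model, methylation) {
  stopifnot(inherits(model, "age_model"))
  X <- methylation_matrix(model, methylation)
  drop(model$intercept + X %*% model$coefficients)
}

#' Predict chronological age in years
#'
#' Backtransforms the epigenetic-scale prediction through
#' [horvath_inverse()] at the model's cut-off. Estimates below 0 (possible
#' for extreme methylation profiles) are returned unclamped.
#'
#' @inheritParams predict_epigenetic
#' @return Numeric vector of estimated chronological ages in years.
#' @examples
#' m <- published_model()
#' predict_age(m, c(PDE4C = 0.5, EDARADD = 0.6, KLF14 = 0.1, ELOVL2 = 0.5,
#'                  FHL2 = 0.3, C1orf132 = 0.5, TRIM59 = 0.4))
#' @export
predict_age <- function(model, methylation) {
  horvath_inverse(predict_epigenetic(model, methylation), model$cutoff)
}

#' Prediction interval for chronological age
#'
#' Computes a prediction interval on the epigenetic scale and maps both
#' endpoints through the monotone backtransformation, so the chronological
#' interval is always ordered. Two methods:
#' \describe{
#'   \item{`residual_only`}{\eqn{\hat y_e \pm z_{1-\alpha/2}\, s} with the
#'     standard-normal quantile and the model's residual standard error
#'     \eqn{s} — the procedure described with the published model.}
#'   \item{`leverage_t`}{full OLS prediction interval
#'     \eqn{\hat y_e \pm t_{df} \, s \sqrt{1 + x^\top (X^\top X)^{-1} x}}
#'     with a Student-t quantile; requires a model fitted in-session (the
#'     published fixture carries no design matrix).}
#' }
#' Because the backtransform is flat for negative epigenetic values and steep
#' for positive ones, subjects estimated to be young get shorter
#' chronological-scale intervals.
#'
#' @inheritParams predict_epigenetic
#' @param level Coverage probability in (0, 1). Default 0.95.
#' @param method `"residual_only"` (default) or `"leverage_t"`.
#' @return Data frame with columns `fit` (years), `lower`, `upper`.
#' @export
prediction_interval <- function(model, methylation, level = 0.95,
                                method = c("residual_only", "leverage_t")) {
  stopifnot(inherits(model, "age_model"))
  method <- match.arg(method)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`level` must be a single probability strictly between 0 and 1.",
         call. = FALSE)
  }
  X <- methylation_matrix(model, methylation)
  yhat_e <- drop(model$intercept + X %*% model$coefficients)
  s <- model$residual_standard_error
  if (method == "residual_only") {
    half <- stats::qnorm(1 - (1 - level) / 2) * s
  } else {
    if (is.null(model$xtx_inv)) {
      stop("leverage_t intervals need the fitted design information; ",
           "this model carries none.", call. = FALSE)
    }
    Xfull <- cbind(1, X)
    lev <- rowSums((Xfull %*% model$xtx_inv) * Xfull)
    half <- stats::qt(1 - (1 - level) / 2, df = model$df_residual) *
      s * sqrt(1 + lev)
  }
  data.frame(
    fit = horvath_inverse(yhat_e, model$cutoff),
    lower = horvath_inverse(yhat_e - half, model$cutoff),
    upper = horvath_inverse(yhat_e + half, model$cutoff)
  )
}

#' The published seven-CpG buccal-swab age model
#'
#' Returns the reported unisex model as a ready-to-use fixture: intercept
#' \eqn{-1.5880}; coefficients PDE4C \eqn{-0.0400}, EDARADD \eqn{-1.9120},
#' KLF14 \eqn{+5.0157}, ELOVL2 \eqn{+0.5961}, FHL2 \eqn{+1.7463}, C1orf132
#' \eqn{-0.0108}, TRIM59 \eqn{+3.5634}; residual standard error 0.2905;
#' cut-off 20 years; fitted on 161 training samples. Supports
#' [predict_age()] and `residual_only` prediction intervals (the original
#' design matrix is not available, so `leverage_t` is not).
#'
#' @return An `age_model`.
#' @examples
#' published_model()
#' @export
published_model <- function() {
  structure(list(
    intercept = -1.5880,
    coefficients = c(PDE4C = -0.0400, EDARADD = -1.9120, KLF14 = 5.0157,
                     ELOVL2 = 0.5961, FHL2 = 1.7463, C1orf132 = -0.0108,
                     TRIM59 = 3.5634),
    residual_standard_error = 0.2905,
    cutoff = 20,
    sex_scope = "unisex",
    n_train = 161L,
    df_residual = 153L,   # 161 - 7 - 1
    xtx_inv = NULL
  ), class = "age_model")
}

#' Serialise / deserialise an age model as JSON
#'
#' The JSON document carries `intercept`, `coefficients`,
#' `residual_standard_error`, `cutoff`, `sex_scope`, `n_train` and
#' `df_residual`. The design information used by `leverage_t` intervals is
#' not serialised.
#'
#' @param model An `age_model`.
#' @param path File path.
#' @return `read_model` returns an `age_model`; `write_model` returns `path`
#'   invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "age_model"))
  obj <- list(
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    residual_standard_error = model$residual_standard_error,
    cutoff = model$cutoff,
    sex_scope = model$sex_scope,
    n_train = model$n_train,
    df_residual = model$df_residual
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    intercept = as.numeric(obj$intercept),
    coefficients = unlist(obj$coefficients),
    residual_standard_error = as.numeric(obj$residual_standard_error),
    cutoff = as.numeric(obj$cutoff),
    sex_scope = obj$sex_scope,
    n_train = as.integer(obj$n_train),
    df_residual = as.integer(obj$df_residual),
    xtx_inv = NULL
  ), class = "age_model")
}
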