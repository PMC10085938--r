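#' Configuration for repeated k-fold cut-off cross-validation
#'
#' Bundles the settings of the hyperparameter search that treats the adult
#' cut-off of the age transformation as tunable. Defaults reproduce the
#' study design: 10-fold cross-validation repeated 100 times over a cut-off
#' grid from 0 to 60 years in steps of 0.1 (optima are reported to one
#' decimal). Cut-off 0 — the standard linear model — is always included as
#' the baseline.
#'
#' @param k_folds Number of folds, at least 2. Default 10.
#' @param repeats Number of independent fold randomisations, at least 1.
#'   Default 100.
#' @param grid Strictly increasing non-negative candidate cut-offs in years.
#'   Default `seq(0, 60, by = 0.1)`. A 0 is prepended if absent.
#' @param seed Integer seed for the fold randomisations.
#' @param sex_scope Which samples to tune on: `"unisex"`, `"male_only"`,
#'   `"female_only"`.
#' @return A `cv_config` list.
#' @export
cv_config <- function(k_folds = 10, repeats = 100, grid = seq(0, 60, by = 0.1),
                      seed = 1L,
                      sex_scope = c("unisex", "male_only", "female_only")) {
  sex_scope <- match.arg(sex_scope)
  stopifnot(is.numeric(k_folds), length(k_folds) == 1L, k_folds >= 2,
            is.numeric(repeats), length(repeats) == 1L, repeats >= 1,
            is.numeric(grid), length(grid) >= 1L,
            is.numeric(seed), length(seed) == 1L)
  if (any(grid < 0) || is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be non-negative and strictly increasing.", call. = FALSE)
  }
  if (grid[1L] != 0) grid <- c(0, grid)
  structure(list(k_folds = as.integer(k_folds), repeats = as.integer(repeats),
                 grid = grid, seed = as.integer(seed), sex_scope = sex_scope),
            class = "cv_config")
}

# Fold id per sample: seeded shuffle then contiguous chunks, remainder
# samples distributed one per leading fold. Uses the current RNG state.
make_fold_ids <- function(n, k) {
  if (k > n) stop("More folds than samples.", call. = FALSE)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  ids <- integer(n)
  ids[perm] <- rep.int(seq_len(k), times = sizes)
  ids
}

# Per-repeat pooled RMSE and MAD (chronological scale) for one cutoff.
# X: design matrix with intercept column; ages: chronological ages;
# folds: list of fold-id vectors, one per repeat.
cv_errors_for_cutoff <- function(X, ages, cutoff, folds) {
  y <- horvath_transform(ages, cutoff)
  p <- ncol(X)
  rmse_r <- mad_r <- numeric(length(folds))
  for (r in seq_along(folds)) {
    ids <- folds[[r]]
    errs <- numeric(length(ages))
    for (f in unique(ids)) {
      test <- ids == f
      if (sum(!test) < p + 1L) {
        stop("Fold too small to fit the model.", call. = FALSE)
      }
      fit <- stats::lm.fit(X[!test, , drop = FALSE], y[!test])
      if (fit$rank < p) {
        stop("Rank-deficient design within a cross-validation fold.",
             call. = FALSE)
      }
      pred_e <- drop(X[test, , drop = FALSE] %*% fit$coefficients)
      errs[test] <- horvath_inverse(pred_e, cutoff) - ages[test]
    }
    rmse_r[r] <- sqrt(mean(errs^2))
    mad_r[r] <- mean(abs(errs))
  }
  list(rmse = rmse_r, mad = mad_r)
}

# Complete-case design matrix + ages for CV; shared by cv_rmse/tune_cutoff.
cv_design <- function(dataset, markers) {
  if (is.null(markers)) markers <- dataset_markers(dataset)
  X_raw <- as.matrix(as.data.frame(dataset)[markers])
  keep <- stats::complete.cases(X_raw)
  X_keep <- X_raw[keep, , drop = FALSE]
  list(X = cbind("(Intercept)" = rep(1, nrow(X_keep)), X_keep),
       ages = dataset$age[keep], markers = markers)
}

#' Cross-validated prediction error at one cut-off
#'
#' Repeated k-fold cross-validation of the transformed-scale OLS model at a
#' fixed cut-off. For each repeat the samples are partitioned into `k_folds`
#' folds by a fresh seeded shuffle; each fold is predicted by a model fitted
#' on the remaining folds; errors are taken on the chronological scale after
#' backtransformation, pooled over all held-out predictions within the
#' repeat, and then averaged over repeats. Samples with missing values among
#' the modelled markers are excluded up front (complete-case).
#'
#' @param train A [meth_dataset()].
#' @param cutoff Adult cut-off in years to evaluate.
#' @param config A [cv_config()]; its `grid` is ignored here.
#' @param markers Markers to use; default all in `train`.
#' @param folds Optional list of precomputed fold-id vectors (one per
#'   repeat), as used by [tune_cutoff()] to share partitions across the grid.
#' @return List with `mean_rmse`, `mean_mad` (years) and `per_repeat`,
#'   `per_repeat_mad` (numeric vectors of per-repeat pooled values).
#' @export
cv_rmse <- function(train, cutoff, config = cv_config(), markers = NULL,
                    folds = NULL) {
  stopifnot(inherits(train, "meth_dataset"), inherits(config, "cv_config"))
  des <- cv_design(train, markers)
  if (is.null(folds)) {
    folds <- local_seed(config$seed, lapply(seq_len(config$repeats), function(r)
      make_fold_ids(length(des$ages), config$k_folds)))
  }
  res <- cv_errors_for_cutoff(des$X, des$ages, cutoff, folds)
  list(mean_rmse = mean(res$rmse), mean_mad = mean(res$mad),
       per_repeat = res$rmse, per_repeat_mad = res$mad)
}

#' Tune the adult cut-off by repeated cross-validation
#'
#' Evaluates [cv_rmse()] at every grid cut-off using the same fold
#' partitions for every candidate (common random numbers, which removes
#' fold-assignment noise from the comparison), and selects the cut-off with
#' the smallest mean cross-validated RMSE; ties break toward the smaller
#' cut-off. The dataset is first restricted to `config$sex_scope`.
#'
#' @inheritParams cv_rmse
#' @param config A [cv_config()].
#' @return A `cv_result`: list with `per_cutoff_rmse` (named numeric, mean
#'   over repeats), `per_cutoff_mad`, `best_cutoff`, `best_rmse`, `cv_mad`
#'   (mean MAD at the best cut-off), `per_repeat_rmse` (repeats x grid
#'   matrix), `n_used`, and the `config`.
#' @examples
#' d <- generate_dataset(generator_config(n = 60, seed = 3))$dataset
#' d <- filter_markers_by_missingness(d)$dataset
#' tune_cutoff(d, cv_config(k_folds = 5, repeats = 2, grid = c(0, 10, 20)))
#' @export
tune_cutoff <- function(train, config = cv_config(), markers = NULL) {
  stopifnot(inherits(train, "meth_dataset"), inherits(config, "cv_config"))
  d <- restrict_sex(train, config$sex_scope)
  des <- cv_design(d, markers)
  n <- length(des$ages)
  if (n < ncol(des$X) + 2L) {
    stop("Too few complete samples in scope '", config$sex_scope,
         "' to cross-validate.", call. = FALSE)
  }
  folds <- local_seed(config$seed, lapply(seq_len(config$repeats), function(r)
    make_fold_ids(n, config$k_folds)))
  grid <- config$grid
  per_repeat_rmse <- matrix(NA_real_, nrow = config$repeats, ncol = length(grid),
                            dimnames = list(NULL, as.character(grid)))
  per_repeat_mad <- per_repeat_rmse
  for (j in seq_along(grid)) {
    res <- cv_errors_for_cutoff(des$X, des$ages, grid[j], folds)
    per_repeat_rmse[, j] <- res$rmse
    per_repeat_mad[, j] <- res$mad
  }
  per_cutoff_rmse <- colMeans(per_repeat_rmse)
  per_cutoff_mad <- colMeans(per_repeat_mad)
  best <- which.min(per_cutoff_rmse)  # first minimum = smallest cutoff on ties
  structure(list(
    per_cutoff_rmse = stats::setNames(per_cutoff_rmse, as.character(grid)),
    per_cutoff_mad = stats::setNames(per_cutoff_mad, as.character(grid)),
    grid = grid,
    best_cutoff = grid[best],
    best_rmse = unname(per_cutoff_rmse[best]),
    cv_mad = unname(per_cutoff_mad[best]),
    per_repeat_rmse = per_repeat_rmse,
    n_used = n,
    config = config
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: best cutoff %.4g years (CV RMSE %.4f, MAD %.4f) over %d grid points, %d x %d-fold CV, n = %d\n",
              x$config$sex_scope, x$best_cutoff, x$best_rmse, x$cv_mad,
              length(x$grid), x$config$repeats, x$config$k_folds, x$n_used))
  invisible(x)
}

#' Tune and fit unisex and sex-specific models
#'
#' Runs [tune_cutoff()] on the full training set and on each single-sex
#' subset, then refits the final model on the corresponding (sub)set at its
#' selected cut-off. A scope whose subset is too small to cross-validate is
#' reported as unavailable (`NULL` with a message) without failing the
#' others.
#'
#' @inheritParams tune_cutoff
#' @return Named list with elements `unisex`, `male_only`, `female_only`;
#'   each is `list(cv = <cv_result>, model = <age_model>)` or `NULL` if that
#'   scope was unavailable.
#' @export
fit_sexwise <- function(train, config = cv_config(), markers = NULL) {
  stopifnot(inherits(train, "meth_dataset"))
  scopes <- c("unisex", "male_only", "female_only")
  out <- stats::setNames(vector("list", length(scopes)), scopes)
  for (sc in scopes) {
    cfg <- config
    cfg$sex_scope <- sc
    res <- tryCatch({
      cv <- tune_cutoff(train, cfg, markers)
      model <- fit_age_model(restrict_sex(train, sc), markers = markers,
                             cutoff = cv$best_cutoff, sex_scope = sc)
      list(cv = cv, model = model)
    }, error = function(e) {
      message("Scope '", sc, "' unavailable: ", conditionMessage(e))
      NULL
    })
    out[[sc]] <- res
  }
  out
}

#' Write a cross-validation result to disk
#'
#' Serialises a `cv_result` as a JSON summary plus a delimited-text curve
#' table (`cutoff`, `mean_rmse`, `sd_over_repeats`, `mean_mad`) suitable for
#' plotting RMSE-vs-cut-off curves.
#'
#' @param result A `cv_result` from [tune_cutoff()].
#' @param json_path,curve_path Output file paths; either may be `NULL` to
#'   skip that file.
#' @return Invisibly, the curve table data frame.
#' @export
write_cv_result <- function(result, json_path = NULL, curve_path = NULL) {
  stopifnot(inherits(result, "cv_result"))
  curve <- data.frame(
    cutoff = result$grid,
    mean_rmse = unname(result$per_cutoff_rmse),
    sd_over_repeats = apply(result$per_repeat_rmse, 2, stats::sd),
    mean_mad = unname(result$per_cutoff_mad)
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      sex_scope = result$config$sex_scope,
      best_cutoff = result$best_cutoff,
      best_rmse = result$best_rmse,
      cv_mad = result$cv_mad,
      n_used = result$n_used,
      k_folds = result$config$k_folds,
      repeats = result$config$repeats,
      seed = result$config$seed,
      per_cutoff_rmse = as.list(result$per_cutoff_rmse)
    ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(curve_path)) {
    utils::write.table(curve, curve_path, sep = ",", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(curve)
}
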