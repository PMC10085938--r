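#' Error summary statistics
#'
#' `mad_error()` is the mean of absolute errors ("mean average deviation");
#' `rmse_error()` the root of the mean squared error. Both in years when the
#' errors are. By the power-mean inequality MAD <= RMSE always.
#'
#' @param errors Non-empty numeric vector of prediction errors
#'   (estimated minus chronological age).
#' @return Single numeric value.
#' @export
mad_error <- function(errors) {
  stopifnot(is.numeric(errors))
  if (length(errors) == 0L) stop("Empty error vector.", call. = FALSE)
  mean(abs(errors))
}

#' @rdname mad_error
#' @export
rmse_error <- function(errors) {
  stopifnot(is.numeric(errors))
  if (length(errors) == 0L) stop("Empty error vector.", call. = FALSE)
  sqrt(mean(errors^2))
}

#' Adjusted coefficient of determination
#'
#' \eqn{1 - (1 - R^2)(n - 1)/(n - k - 1)} for a model with `k` predictors
#' fitted on `n` samples.
#'
#' @param r2 Unadjusted R-squared in \[0, 1\].
#' @param n Sample count, must exceed `k + 1`.
#' @param k Number of predictors.
#' @return Adjusted R-squared (can be negative for weak models).
#' @examples
#' adjusted_r2(0.888, 161, 7)
#' @export
adjusted_r2 <- function(r2, n, k) {
  stopifnot(is.numeric(r2), is.numeric(n), is.numeric(k))
  if (any(r2 < 0 | r2 > 1)) stop("`r2` must be in [0,1].", call. = FALSE)
  if (n <= k + 1) stop("Need n > k + 1.", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Bland-Altman agreement statistics
#'
#' Differences are estimated minus chronological age, so a negative mean
#' difference is an average underestimation. Limits of agreement are the
#' mean difference plus/minus 1.96 times the sample standard deviation
#' (n - 1 denominator) of the differences; about 95% of estimation errors
#' are expected inside them.
#'
#' @param chronological,estimated Equal-length numeric vectors of ages in
#'   years, at least 2 pairs.
#' @return List with `n`, `mean_diff`, `sd_diff`, `loa_lower`, `loa_upper`
#'   (all in years).
#' @export
bland_altman <- function(chronological, estimated) {
  stopifnot(is.numeric(chronological), is.numeric(estimated))
  if (length(chronological) != length(estimated)) {
    stop("Vectors must have equal length.", call. = FALSE)
  }
  if (length(chronological) < 2L) stop("Need at least 2 pairs.", call. = FALSE)
  d <- estimated - chronological
  m <- mean(d)
  s <- stats::sd(d)
  list(n = length(d), mean_diff = m, sd_diff = s,
       loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s)
}

#' Age-binned accuracy table
#'
#' Splits samples into age categories and reports, per bin and pooled
#' ("All"), the sample count, the MAD, and the percentage of estimates
#' within each absolute-error threshold (inclusive: an error of exactly 3.0
#' years counts as within +/-3). Default bins \[0,20), \[20,40), \[40,60),
#' \[60,90\] and thresholds 3, 4, 5, 6 years.
#'
#' @param chronological,estimated Equal-length vectors of ages in years.
#' @param bin_edges Increasing age boundaries; bins are left-closed,
#'   right-open except the last, which is closed. Every sample must fall in
#'   a bin.
#' @param thresholds Increasing positive error thresholds in years.
#' @return Data frame with one row per bin plus an `"All"` row; columns
#'   `age_range`, `n`, `mad` and `pct_within_<t>` per threshold.
#' @export
binned_accuracy_report <- function(chronological, estimated,
                                   bin_edges = c(0, 20, 40, 60, 90),
                                   thresholds = c(3, 4, 5, 6)) {
  stopifnot(is.numeric(chronological), is.numeric(estimated),
            length(chronological) == length(estimated),
            length(bin_edges) >= 2L, !is.unsorted(bin_edges, strictly = TRUE),
            all(thresholds > 0), !is.unsorted(thresholds, strictly = TRUE))
  if (any(chronological < bin_edges[1L]) ||
      any(chronological > bin_edges[length(bin_edges)])) {
    stop("Sample age outside every bin.", call. = FALSE)
  }
  abs_err <- abs(estimated - chronological)
  bin <- findInterval(chronological, bin_edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  n_bins <- length(bin_edges) - 1L
  labels <- paste0(bin_edges[-length(bin_edges)], "-", bin_edges[-1L])
  row_for <- function(idx, label) {
    r <- data.frame(age_range = label, n = length(idx),
                    mad = if (length(idx)) mean(abs_err[idx]) else NA_real_)
    for (t in thresholds) {
      r[[paste0("pct_within_", t)]] <-
        if (length(idx)) 100 * mean(abs_err[idx] <= t) else NA_real_
    }
    r
  }
  rows <- lapply(seq_len(n_bins), function(b) row_for(which(bin == b), labels[b]))
  rows <- c(rows, list(row_for(seq_along(abs_err), "All")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-CpG correlation screen against chronological age
#'
#' Pearson correlation of each marker's methylation with age, using
#' pairwise-complete observations, with a two-sided p-value from the
#' t-distribution on `n_used - 2` degrees of freedom. Markers with fewer
#' than 3 complete pairs, or with constant methylation (or age) among them,
#' get `NA` correlation and p-value.
#'
#' @param dataset A [meth_dataset()].
#' @return Data frame with columns `marker`, `r`, `p_value`, `n_used`.
#' @export
cpg_correlation_screen <- function(dataset) {
  stopifnot(inherits(dataset, "meth_dataset"))
  mk <- dataset_markers(dataset)
  rows <- lapply(mk, function(m) {
    x <- dataset[[m]]
    ok <- !is.na(x)
    n_used <- sum(ok)
    if (n_used < 3L || stats::sd(x[ok]) == 0 || stats::sd(dataset$age[ok]) == 0) {
      return(data.frame(marker = m, r = NA_real_, p_value = NA_real_,
                        n_used = n_used))
    }
    ct <- stats::cor.test(x[ok], dataset$age[ok], method = "pearson")
    data.frame(marker = m, r = unname(ct$estimate), p_value = ct$p.value,
               n_used = n_used)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate an age model on a dataset
#'
#' Predicts every sample with complete methylation for the model's markers
#' (incomplete samples are dropped and counted) and assembles the full
#' performance report: MAD, RMSE, Pearson correlation between predicted and
#' chronological age, R-squared as the square of that correlation (with
#' 1 - SSE/SST as a secondary field `r_squared_sse`), adjusted R-squared,
#' Bland-Altman agreement, and the age-binned accuracy table.
#'
#' @param model An `age_model`.
#' @param dataset A [meth_dataset()] with all model markers.
#' @param bin_edges,thresholds Passed to [binned_accuracy_report()]. Bins
#'   are widened automatically if any age falls outside the default range.
#' @return An `evaluation_report` list.
#' @export
evaluate_model <- function(model, dataset, bin_edges = c(0, 20, 40, 60, 90),
                           thresholds = c(3, 4, 5, 6)) {
  stopifnot(inherits(model, "age_model"), inherits(dataset, "meth_dataset"))
  mk <- names(model$coefficients)
  absent <- setdiff(mk, dataset_markers(dataset))
  if (length(absent)) {
    stop("Dataset lacks model marker(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(as.data.frame(dataset)[mk])
  keep <- stats::complete.cases(X)
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("No usable samples (all have missing markers).",
                       call. = FALSE)
  d <- subset_dataset(dataset, which(keep))
  est <- predict_age(model, as.data.frame(d)[mk])
  chron <- d$age
  errs <- est - chron
  r <- stats::cor(est, chron)
  r2 <- r^2
  r2_sse <- 1 - sum(errs^2) / sum((chron - mean(chron))^2)
  k <- length(model$coefficients)
  if (max(chron) > max(bin_edges)) bin_edges[length(bin_edges)] <- max(chron)
  structure(list(
    n = length(chron),
    n_dropped = n_dropped,
    mad = mad_error(errs),
    rmse = rmse_error(errs),
    pearson_r = r,
    r_squared = r2,
    r_squared_sse = r2_sse,
    adjusted_r_squared = adjusted_r2(r2, length(chron), k),
    bland_altman = bland_altman(chron, est),
    binned_table = binned_accuracy_report(chron, est, bin_edges, thresholds),
    predictions = data.frame(sample_id = d$sample_id, age = chron,
                             estimated_age = est)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d (%d dropped for missing markers)\n",
              x$n, x$n_dropped))
  cat(sprintf("  MAD %.3f  RMSE %.3f  r %.3f  R2 %.3f  adj R2 %.3f\n",
              x$mad, x$rmse, x$pearson_r, x$r_squared, x$adjusted_r_squared))
  ba <- x$bland_altman
  cat(sprintf("  Bland-Altman: mean diff %.3f (SD %.3f), LoA [%.3f, %.3f]\n",
              ba$mean_diff, ba$sd_diff, ba$loa_lower, ba$loa_upper))
  tab <- x$binned_table
  tab$mad <- round(tab$mad, 3)
  pct_cols <- grep("^pct_within_", names(tab))
  tab[pct_cols] <- lapply(tab[pct_cols], round, 1)
  print(tab)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' JSON summary plus a delimited-text accuracy table and an optional
#' per-sample prediction/Bland-Altman table for plotting.
#'
#' @param report An `evaluation_report` from [evaluate_model()].
#' @param json_path,table_path,scatter_path Output paths; `NULL` skips.
#' @return Invisibly `report`.
#' @export
write_evaluation_report <- function(report, json_path = NULL,
                                    table_path = NULL, scatter_path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      n = report$n, n_dropped = report$n_dropped,
      mad = report$mad, rmse = report$rmse,
      pearson_r = report$pearson_r, r_squared = report$r_squared,
      r_squared_sse = report$r_squared_sse,
      adjusted_r_squared = report$adjusted_r_squared,
      bland_altman = report$bland_altman,
      binned_table = report$binned_table
    ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
    dataframe = "rows")
  }
  if (!is.null(table_path)) {
    utils::write.table(report$binned_table, table_path, sep = ",",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(scatter_path)) {
    scatter <- report$predictions
    scatter$diff <- scatter$estimated_age - scatter$age
    utils::write.table(scatter, scatter_path, sep = ",", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(report)
}
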