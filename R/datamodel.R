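#' Construct a methylation dataset
#'
#' A `meth_dataset` is a data frame holding one row per donor with columns
#' `sample_id` (unique character), `age` (chronological age in years,
#' non-negative), `sex` (factor with levels `male`, `female`), and one numeric
#' column per CpG marker with methylation proportions in \[0, 1\]. Missing
#' methylation values (assay drop-out) are `NA` — never 0, which is a valid
#' proportion. The marker panel is kept in the `markers` attribute in a fixed
#' order.
#'
#' @param data A data frame with columns `sample_id`, `age`, `sex` and the
#'   marker columns. `sex` may be given as `"M"`/`"F"` (case-insensitive),
#'   `"male"`/`"female"`, or the numeric coding 0 = male, 1 = female used at
#'   model interfaces.
#' @param markers Character vector naming the marker columns, in panel order.
#'   Defaults to every column other than `sample_id`, `age`, `sex`.
#' @return A `meth_dataset` object.
#' @examples
#' d <- meth_dataset(data.frame(
#'   sample_id = c("s1", "s2"), age = c(4, 61), sex = c("F", "M"),
#'   TRIM59 = c(0.12, 0.55), EDARADD = c(0.71, NA)))
#' dataset_markers(d)
#' @export
meth_dataset <- function(data, markers = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  required <- c("sample_id", "age", "sex")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("Required column(s) missing: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(markers)) markers <- setdiff(names(data), required)
  if (!all(markers %in% names(data))) {
    stop("Marker column(s) not in data: ",
         paste(setdiff(markers, names(data)), collapse = ", "), call. = FALSE)
  }
  data$sample_id <- as.character(data$sample_id)
  if (anyDuplicated(data$sample_id)) {
    stop("sample_id values must be unique.", call. = FALSE)
  }
  data$age <- as.numeric(data$age)
  if (anyNA(data$age)) stop("All ages must be numeric and non-missing.", call. = FALSE)
  if (any(data$age < 0)) stop("Ages must be non-negative.", call. = FALSE)
  data$sex <- parse_sex(data$sex)
  for (m in markers) {
    v <- as.numeric(data[[m]])
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad)) {
      stop(sprintf("Methylation value out of [0,1] at row %d, column '%s': %s",
                   bad[1L], m, format(v[bad[1L]])), call. = FALSE)
    }
    data[[m]] <- v
  }
  data <- data[c(required, markers)]
  rownames(data) <- NULL
  structure(data, markers = markers, class = c("meth_dataset", "data.frame"))
}

parse_sex <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) {
      stop("Numeric sex coding must be 0 (male) / 1 (female).", call. = FALSE)
    }
    return(factor(ifelse(x == 0, "male", "female"), levels = c("male", "female")))
  }
  key <- tolower(trimws(as.character(x)))
  map <- c(m = "male", male = "male", "0" = "male",
           f = "female", female = "female", "1" = "female")
  out <- map[key]
  if (anyNA(out)) {
    stop("Unrecognised sex value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  factor(unname(out), levels = c("male", "female"))
}

#' @rdname meth_dataset
#' @param dataset A `meth_dataset`.
#' @export
dataset_markers <- function(dataset) {
  stopifnot(inherits(dataset, "meth_dataset"))
  attr(dataset, "markers")
}

#' Numeric sex coding used at model interfaces
#'
#' Returns 0 for male and 1 for female, the coding used by the sex-specific
#' models.
#' @param sex A factor or character vector of sexes.
#' @return Integer vector of 0/1.
#' @export
sex_code <- function(sex) {
  s <- parse_sex(sex)
  ifelse(s == "male", 0L, 1L)
}

#' @export
print.meth_dataset <- function(x, ...) {
  mk <- attr(x, "markers")
  n_missing <- sum(is.na(as.matrix(x[mk])))
  cat(sprintf("<meth_dataset> %d samples (%d male, %d female), %d markers, %d missing values\n",
              nrow(x), sum(x$sex == "male"), sum(x$sex == "female"),
              length(mk), n_missing))
  cat("markers:", paste(mk, collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

subset_dataset <- function(dataset, idx) {
  mk <- attr(dataset, "markers")
  out <- as.data.frame(dataset)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, markers = mk, class = c("meth_dataset", "data.frame"))
}

#' Read a methylation table from delimited text
#'
#' Expects a header row and columns `sample_id`, `age`, `sex` plus one column
#' per marker. Comma- and tab-delimited files are both accepted (the delimiter
#' is sniffed from the header unless given). Empty cells and the sentinel
#' `"NA"` are read as missing methylation values. Values outside \[0, 1\] and
#' unparseable ages are rejected with an error naming the offending row and
#' column.
#'
#' @param path Path to the delimited text file.
#' @param sep Field delimiter; `NULL` (default) sniffs `,` vs tab from the
#'   header line.
#' @param na_strings Cell contents treated as missing. Default `""` and `"NA"`.
#' @return A [meth_dataset()].
#' @export
read_methylation_table <- function(path, sep = NULL, na_strings = c("", "NA")) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- sniff_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  required <- c("sample_id", "age", "sex")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("File ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  age <- suppressWarnings(as.numeric(raw$age))
  if (anyNA(age)) {
    r <- which(is.na(age))[1L]
    stop(sprintf("Unparseable age at row %d: '%s'", r, raw$age[r]), call. = FALSE)
  }
  markers <- setdiff(names(raw), required)
  for (m in markers) {
    cell <- raw[[m]]
    is_na <- cell %in% na_strings | is.na(cell)
    v <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_na & (is.na(v) | v < 0 | v > 1))
    if (length(bad)) {
      stop(sprintf("Invalid methylation value at row %d, column '%s': '%s' (must be in [0,1])",
                   bad[1L], m, cell[bad[1L]]), call. = FALSE)
    }
    v[is_na] <- NA_real_
    raw[[m]] <- v
  }
  raw$age <- age
  meth_dataset(raw, markers = markers)
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Write a methylation table as delimited text
#'
#' Serialises a [meth_dataset()] so that [read_methylation_table()] recovers
#' an equal dataset. Methylation proportions are written with 8 significant
#' digits; missing values as empty cells.
#'
#' @param dataset A `meth_dataset`.
#' @param path Output file path.
#' @param sep Field delimiter, default comma.
#' @export
write_methylation_table <- function(dataset, path, sep = ",") {
  stopifnot(inherits(dataset, "meth_dataset"))
  mk <- attr(dataset, "markers")
  out <- as.data.frame(dataset)
  out$sex <- ifelse(out$sex == "male", "M", "F")
  for (m in mk) {
    out[[m]] <- ifelse(is.na(out[[m]]), "", sprintf("%.8g", out[[m]]))
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Methylation proportion from minisequencing peak heights
#'
#' Single-base-extension (SNaPshot) assays report one fluorescent peak for the
#' methylated allele (C or G channel) and one for the unmethylated allele
#' (T or A channel). The methylation proportion is the relative peak height
#' `methylated / (methylated + unmethylated)`, which is invariant to overall
#' signal intensity. A pair with both signals zero is a dropped-out marker and
#' raises an error; callers converting whole tables should record such pairs
#' as missing instead (see [peak_table_to_methylation()]).
#'
#' @param methylated,unmethylated Non-negative peak heights (arbitrary
#'   fluorescence units); vectors are processed elementwise.
#' @return Methylation proportions in \[0, 1\].
#' @examples
#' methylation_from_peaks(300, 100)  # 0.75
#' @export
methylation_from_peaks <- function(methylated, unmethylated) {
  stopifnot(is.numeric(methylated), is.numeric(unmethylated),
            length(methylated) == length(unmethylated))
  if (any(methylated < 0, na.rm = TRUE) || any(unmethylated < 0, na.rm = TRUE)) {
    stop("Peak heights must be non-negative.", call. = FALSE)
  }
  total <- methylated + unmethylated
  if (any(total == 0, na.rm = TRUE)) {
    stop("Undefined proportion: both peak signals are zero (marker drop-out); ",
         "record as missing upstream.", call. = FALSE)
  }
  methylated / total
}

#' Convert a long peak-height table to methylation proportions
#'
#' Takes a table with columns `sample_id`, `marker`, `methylated_signal`,
#' `unmethylated_signal` (as read from delimited text) and returns the same
#' table with a `methylation` column. Pairs with both signals zero become
#' `NA` (drop-out), matching the missing-value convention of
#' [meth_dataset()].
#'
#' @param peaks Data frame with the four peak-table columns.
#' @return The input with an added `methylation` column.
#' @export
peak_table_to_methylation <- function(peaks) {
  needed <- c("sample_id", "marker", "methylated_signal", "unmethylated_signal")
  if (!all(needed %in% names(peaks))) {
    stop("Peak table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  total <- peaks$methylated_signal + peaks$unmethylated_signal
  meth <- rep(NA_real_, nrow(peaks))
  ok <- total > 0
  meth[ok] <- peaks$methylated_signal[ok] / total[ok]
  peaks$methylation <- meth
  peaks
}

#' Drop markers with excessive missingness
#'
#' Markers whose fraction of missing values strictly exceeds
#' `max_missing_fraction` are removed from the panel and from every sample;
#' all retained values are untouched. The default threshold 0.5 removes a
#' marker missing in two thirds of samples while keeping anything missing in
#' at most half.
#'
#' @param dataset A [meth_dataset()].
#' @param max_missing_fraction Highest tolerated missing fraction, in
#'   \[0, 1\]. Default 0.5.
#' @return A list with elements `dataset` (filtered) and `excluded`
#'   (character vector of removed marker names).
#' @export
filter_markers_by_missingness <- function(dataset, max_missing_fraction = 0.5) {
  stopifnot(inherits(dataset, "meth_dataset"),
            is.numeric(max_missing_fraction), length(max_missing_fraction) == 1L,
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  mk <- attr(dataset, "markers")
  frac <- vapply(mk, function(m) mean(is.na(dataset[[m]])), numeric(1))
  excluded <- mk[frac > max_missing_fraction]
  keep <- setdiff(mk, excluded)
  out <- as.data.frame(dataset)[c("sample_id", "age", "sex", keep)]
  list(dataset = structure(out, markers = keep,
                           class = c("meth_dataset", "data.frame")),
       excluded = excluded)
}

#' Split a dataset into training and validation sets
#'
#' Seeded random partition into `n_train` training samples and the remainder
#' for validation. With `stratify_by_age_decade = TRUE` the draw is stratified
#' on age decade (0-9, 10-19, ...) so each stratum contributes training
#' samples proportionally (within one sample).
#'
#' @param dataset A [meth_dataset()].
#' @param n_train Number of training samples, strictly between 0 and the
#'   dataset size.
#' @param seed Integer seed making the split reproducible.
#' @param stratify_by_age_decade Stratify on age decade? Default `FALSE`
#'   (simple random split).
#' @return List with `train` and `validation` datasets.
#' @export
split_train_validation <- function(dataset, n_train, seed,
                                   stratify_by_age_decade = FALSE) {
  stopifnot(inherits(dataset, "meth_dataset"))
  n <- nrow(dataset)
  if (!is.numeric(n_train) || n_train <= 0 || n_train >= n) {
    stop("`n_train` must satisfy 0 < n_train < ", n, ".", call. = FALSE)
  }
  n_train <- as.integer(n_train)
  idx <- local_seed(seed, {
    if (stratify_by_age_decade) {
      strata <- split(seq_len(n), floor(dataset$age / 10))
      # largest-remainder apportionment of n_train across strata
      quota <- n_train * lengths(strata) / n
      take <- floor(quota)
      rem <- n_train - sum(take)
      if (rem > 0) {
        order_rem <- order(quota - take, decreasing = TRUE)
        take[order_rem[seq_len(rem)]] <- take[order_rem[seq_len(rem)]] + 1L
      }
      unlist(mapply(function(ix, k) if (k > 0) sample(ix, k) else integer(0),
                    strata, take, SIMPLIFY = FALSE), use.names = FALSE)
    } else {
      sample(n, n_train)
    }
  })
  idx <- sort(idx)
  list(train = subset_dataset(dataset, idx),
       validation = subset_dataset(dataset, setdiff(seq_len(n), idx)))
}
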