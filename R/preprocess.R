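#' @title Fold-aware preprocessing of the asymmetry-metric table
#' @name preprocessing
#'
#' @description
#' Cleaning of the per-patient metric matrix in three fixed stages:
#' 1-nearest-neighbour imputation of missing metrics, winsorization of
#' outliers beyond mean +/- 2 SD, and either range normalization (the
#' descriptive path) or zero-mean/unit-variance standardization (the
#' classifier path). All statistics are *fitted* on a training set only
#' ([fit_preprocess()]) and then *applied* to held-out rows
#' ([apply_preprocess()]); under leave-one-out cross-validation the model is
#' refitted on each fold's n-1 training patients, so no information from a
#' held-out patient ever reaches its fold's model.
#'
#' Transformed matrices carry a `vest_stages` attribute recording which
#' stages have been applied; re-applying an already-applied stage is a
#' no-op, making every stage idempotent.
NULL

stage_done <- function(x, stage) stage %in% attr(x, "vest_stages")
stage_mark <- function(x, stage) {
  attr(x, "vest_stages") <- union(attr(x, "vest_stages"), stage)
  x
}

# Neighbour distance: Euclidean over mutually observed columns, rescaled as
# sqrt(sum(diff^2) * p / m) with p total and m shared columns; Inf when no
# column is shared.

# 1-NN fill of `queries` against raw `donors`; donors are scanned in
# (distance, row index) order and the first donor observing the needed
# column supplies the value. `exclude` gives, per query row, a donor row
# index to skip (used when imputing training rows against themselves).
impute_against <- function(queries, donors, exclude = NULL) {
  p <- ncol(queries)
  for (i in seq_len(nrow(queries))) {
    q <- queries[i, ]
    miss <- which(is.na(q))
    if (length(miss) == 0L) next
    if (all(is.na(q)))
      stop("imputation error: row ", rownames(queries)[i] %||% i,
           " has no observed value", call. = FALSE)
    sq <- sweep(donors, 2, q)^2
    m <- rowSums(!is.na(sq))
    d <- sqrt(rowSums(sq, na.rm = TRUE) * p / m)
    d[m == 0L] <- Inf
    if (!is.null(exclude)) d[exclude[i]] <- Inf
    if (all(is.infinite(d)))
      stop("imputation error: no training row shares an observed column ",
           "with row ", rownames(queries)[i] %||% i, call. = FALSE)
    ord <- order(d, seq_along(d))          # ties -> smallest row index
    for (j in miss) {
      for (t in ord) {
        if (is.infinite(d[t])) break
        if (!is.na(donors[t, j])) { queries[i, j] <- donors[t, j]; break }
      }
      if (is.na(queries[i, j]))
        stop("imputation error: no usable donor for column ",
             colnames(queries)[j], call. = FALSE)
    }
  }
  queries
}

`%||%` <- function(a, b) if (is.null(a)) b else a

winsorize_values <- function(x, lower, upper, train_col) {
  hi <- which(!is.na(x) & x > upper)
  lo <- which(!is.na(x) & x < lower)
  if (length(hi)) {
    cand <- train_col[!is.na(train_col) & train_col <= upper]
    if (length(cand)) x[hi] <- max(cand)
    else {
      warning("no in-range training value below the upper winsor bound; ",
              "using the bound", call. = FALSE)
      x[hi] <- upper
    }
  }
  if (length(lo)) {
    cand <- train_col[!is.na(train_col) & train_col >= lower]
    if (length(cand)) x[lo] <- min(cand)
    else {
      warning("no in-range training value above the lower winsor bound; ",
              "using the bound", call. = FALSE)
      x[lo] <- lower
    }
  }
  x
}

#' Fit a preprocessing model on training rows
#'
#' Fits, in pipeline order, (1) the 1-NN imputation snapshot (the raw
#' training rows; training rows with missing entries are imputed from the
#' *other* training rows), (2) per-column winsor bounds, training mean
#' +/- 2 * sample SD of the imputed training values, (3) the per-column
#' range (max - min) of the winsorized training values, and (4) the
#' standardization mean/SD of the winsorized training values.
#'
#' The fitted object also stores the fully transformed training matrix for
#' both downstream paths (`$train_normalized`, `$train_standardized`), since
#' training rows are transformed during the fit itself.
#'
#' @param train numeric matrix (rows = patients, columns = metrics); may
#'   contain `NA`, but every row needs at least one observed value.
#' @param fold optional fold identifier stored in the model.
#' @return An object of class `preprocess_model`.
#' @export
fit_preprocess <- function(train, fold = NA) {
  train <- as.matrix(train)
  if (is.null(colnames(train)))
    colnames(train) <- paste0("V", seq_len(ncol(train)))
  if (nrow(train) < 2L)
    stop("preprocessing needs >= 2 training rows", call. = FALSE)
  imp <- impute_against(train, train, exclude = seq_len(nrow(train)))
  mu <- colMeans(imp)
  sdv <- apply(imp, 2, stats::sd)
  lower <- mu - 2 * sdv
  upper <- mu + 2 * sdv
  wins <- imp
  for (j in seq_len(ncol(imp)))
    wins[, j] <- winsorize_values(imp[, j], lower[j], upper[j], imp[, j])
  rng_min <- apply(wins, 2, min)
  rng_max <- apply(wins, 2, max)
  std_mean <- colMeans(wins)
  std_sd <- apply(wins, 2, stats::sd)
  model <- structure(list(
    columns = colnames(train), snapshot = train, train_imputed = imp,
    winsor_lower = lower, winsor_upper = upper,
    range_min = rng_min, range_max = rng_max,
    std_mean = std_mean, std_sd = std_sd, fold = fold),
    class = "preprocess_model")
  model$train_winsorized <- stage_mark(stage_mark(wins, "impute"),
                                       "winsorize")
  model$train_normalized <- normalize_range(model$train_winsorized, model)
  model$train_standardized <- standardize(model$train_winsorized, model)
  model
}

#' @export
print.preprocess_model <- function(x, ...) {
  cat(sprintf("Preprocessing model: %d training rows, %d metrics\n",
              nrow(x$snapshot), length(x$columns)))
  cat("  pipeline: impute (1-NN) -> winsorize (mean +/- 2 SD) -> ",
      "normalize | standardize\n", sep = "")
  invisible(x)
}

check_model_cols <- function(matrix, model) {
  matrix <- as.matrix(matrix)
  if (is.null(colnames(matrix))) colnames(matrix) <- model$columns
  if (!identical(colnames(matrix), model$columns))
    stop("matrix columns do not match the fitted model", call. = FALSE)
  matrix
}

#' Impute missing entries by the nearest training row
#'
#' Each missing entry of a row is replaced by the corresponding value of the
#' single nearest training row, using Euclidean distance over mutually
#' observed columns rescaled by `sqrt(n_columns / n_shared)`; ties are
#' broken toward the smallest training-row index. If the nearest row does
#' not observe the needed column, donors are scanned outward in distance
#' order until one does.
#'
#' @param matrix numeric matrix to impute.
#' @param model a [fit_preprocess()] model supplying the training snapshot.
#' @return The matrix with missing entries filled.
#' @export
impute_1nn <- function(matrix, model) {
  stopifnot(inherits(model, "preprocess_model"))
  if (stage_done(matrix, "impute")) return(matrix)
  matrix <- check_model_cols(matrix, model)
  stage_mark(impute_against(matrix, model$snapshot), "impute")
}

#' Winsorize outliers against training bounds
#'
#' Entries beyond the training mean +/- 2 SD are replaced by the most
#' extreme *training* value still inside the bound in the same direction
#' (the largest training value at or below the upper bound, or the smallest
#' at or above the lower bound). If no in-range training value exists in the
#' needed direction the bound itself is used, with a warning.
#'
#' @inheritParams impute_1nn
#' @return The winsorized matrix; all values satisfy
#'   `lower <= x <= upper` per column.
#' @export
winsorize <- function(matrix, model) {
  stopifnot(inherits(model, "preprocess_model"))
  if (stage_done(matrix, "winsorize")) return(matrix)
  matrix <- check_model_cols(matrix, model)
  out <- matrix
  for (j in seq_len(ncol(matrix)))
    out[, j] <- winsorize_values(matrix[, j], model$winsor_lower[j],
                                 model$winsor_upper[j],
                                 model$train_imputed[, j])
  stage_mark(out, "winsorize")
}

#' Range normalization
#'
#' Divides each entry by its column's training range (max - min of the
#' winsorized training values), preserving sign. Columns with zero training
#' range are dropped with a warning.
#'
#' @inheritParams impute_1nn
#' @return The normalized matrix (possibly with columns dropped).
#' @export
normalize_range <- function(matrix, model) {
  stopifnot(inherits(model, "preprocess_model"))
  if (stage_done(matrix, "normalize")) return(matrix)
  matrix <- check_model_cols(matrix, model)
  rng <- model$range_max - model$range_min
  keep <- rng > 0
  if (!all(keep))
    warning("dropping zero-range column(s): ",
            paste(model$columns[!keep], collapse = ", "), call. = FALSE)
  out <- sweep(matrix[, keep, drop = FALSE], 2, rng[keep], `/`)
  stage_mark(stage_mark(out, "normalize"),
             attr(matrix, "vest_stages") %||% character())
}

#' Zero-mean/unit-variance standardization
#'
#' `(x - training mean) / training SD` per column, the classifier-path
#' scaling. Columns with zero training SD are dropped with a warning.
#'
#' @inheritParams impute_1nn
#' @return The standardized matrix (possibly with columns dropped).
#' @export
standardize <- function(matrix, model) {
  stopifnot(inherits(model, "preprocess_model"))
  if (stage_done(matrix, "standardize")) return(matrix)
  matrix <- check_model_cols(matrix, model)
  keep <- model$std_sd > 0
  if (!all(keep))
    warning("dropping zero-variance column(s): ",
            paste(model$columns[!keep], collapse = ", "), call. = FALSE)
  out <- sweep(matrix[, keep, drop = FALSE], 2, model$std_mean[keep], `-`)
  out <- sweep(out, 2, model$std_sd[keep], `/`)
  stage_mark(stage_mark(out, "standardize"),
             attr(matrix, "vest_stages") %||% character())
}

#' Apply a fitted preprocessing pipeline to held-out rows
#'
#' Runs the fixed stage order impute -> winsorize -> (standardize for the
#' classifier path | normalize for the descriptive path) using statistics
#' fitted on the training rows only.
#'
#' @inheritParams impute_1nn
#' @param path `"classifier"` (standardize) or `"descriptive"` (range
#'   normalize).
#' @return The transformed matrix.
#' @export
apply_preprocess <- function(matrix, model,
                             path = c("classifier", "descriptive")) {
  path <- match.arg(path)
  x <- winsorize(impute_1nn(matrix, model), model)
  if (path == "classifier") standardize(x, model) else normalize_range(x, model)
}
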