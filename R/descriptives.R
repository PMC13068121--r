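#' @title Descriptive side-correspondence statistics
#' @name descriptives
#'
#' @description
#' The descriptive layer relates each metric's mean asymmetry magnitude to
#' how often its *direction* agrees with the imaging-given affected side:
#' per-patient side scores (the sign of the canonical asymmetry), the
#' percentage of side correspondence, whole-group versus concordant-subset
#' mean asymmetries, and the Pearson correlation between mean asymmetry and
#' correspondence across metrics. The concordant "subset" is purely
#' descriptive and never enters classification.
NULL

#' Side score of a canonical asymmetry value
#'
#' The sign of the canonical value: +1 means the right side is implicated,
#' -1 the left. An exact zero (or a missing value) gives an undefined score
#' (`NA`), conservatively counted as a non-correspondence downstream.
#'
#' @param values canonical asymmetry values (percent or degrees).
#' @return Integer vector of +1 / -1 / `NA`.
#' @export
side_score <- function(values) {
  s <- sign(values)
  s[!is.na(s) & s == 0] <- NA
  as.integer(s)
}

#' Percentage of side correspondence
#'
#' `100 * #(score == truth) / #patients`; undefined scores count as
#' mismatches.
#'
#' @param scores side scores from [side_score()].
#' @param truth true affected-side labels (+1 / -1).
#' @return Percentage in \[0, 100\].
#' @export
correspondence_percent <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  if (length(truth) == 0L) stop("empty cohort", call. = FALSE)
  if (anyNA(truth)) stop("truth labels must be complete", call. = FALSE)
  100 * sum(!is.na(scores) & scores == truth) / length(truth)
}

#' Whole-group and concordant-subset summary for one metric
#'
#' The "subset" comprises the patients whose asymmetry direction matches
#' the true label. Both the whole-group and the subset mean asymmetry are
#' reported as means of absolute values (signed means are included for
#' completeness); no ordering between the two is assumed.
#'
#' @param values canonical asymmetry values for one metric.
#' @param truth true side labels (+1 / -1).
#' @param metric metric name carried into the output.
#' @return A one-row `data.frame` with columns `metric`, `mean_abs_all`,
#'   `mean_abs_subset`, `mean_signed_all`, `correspondence`, `n`,
#'   `n_subset`.
#' @export
subset_summary <- function(values, truth, metric = NA_character_) {
  stopifnot(length(values) == length(truth))
  scores <- side_score(values)
  concordant <- !is.na(scores) & scores == truth
  data.frame(
    metric = metric,
    mean_abs_all = mean(abs(values), na.rm = TRUE),
    mean_abs_subset = if (any(concordant))
      mean(abs(values[concordant])) else NA_real_,
    mean_signed_all = mean(values, na.rm = TRUE),
    correspondence = correspondence_percent(scores, truth),
    n = length(values),
    n_subset = sum(concordant))
}

#' Descriptive table over all metrics
#'
#' Applies [subset_summary()] to every column of a canonical profile.
#'
#' @param profile canonical metric matrix (see [canonicalize_signs()]);
#'   preprocessed values may be supplied instead (descriptive path).
#' @param truth true side labels (+1 / -1), one per row.
#' @return A `data.frame`, one row per metric.
#' @export
descriptives_table <- function(profile, truth) {
  if (identical(attr(profile, "orientation"), "as_printed"))
    stop("profile must be canonicalized before side scoring", call. = FALSE)
  out <- do.call(rbind, lapply(colnames(profile), function(m)
    subset_summary(profile[, m], truth, metric = m)))
  rownames(out) <- NULL
  out
}

#' Correlation between mean asymmetry and side correspondence
#'
#' Pearson correlation (with the classical two-sided t-based p-value)
#' between the whole-group mean absolute asymmetry and the correspondence
#' percentage, across metrics.
#'
#' @param summaries a [descriptives_table()] result (>= 3 rows).
#' @return A list with elements `r` and `p` (both `NA`, with a warning, if
#'   either vector has zero variance).
#' @export
metric_correlation <- function(summaries) {
  x <- summaries$mean_abs_all
  y <- summaries$correspondence
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L)
    stop("metric correlation needs >= 3 metrics with defined summaries",
         call. = FALSE)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
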