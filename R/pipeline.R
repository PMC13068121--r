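#' @title Cohort I/O and pipeline orchestration
#' @name pipeline
#'
#' @description
#' CSV readers/writers for the cohort column contract, run configuration,
#' and the end-to-end analysis: simulate (or read) cohorts, estimate and
#' remove the monocular vHIT gain bias, compute canonical asymmetry
#' profiles, descriptive side-correspondence statistics, and the full
#' cross-validated prediction layer (univariate ROCs, SVM ranking, stepwise
#' trace, grouped proxies, classifier comparison).
NULL

#' Read a cohort CSV
#'
#' Validates the exact column contract (`subject_id`, the 20 measurement
#' columns, `true_side`; empty cells are missing) and reports parse errors
#' with row/column coordinates.
#'
#' @param path CSV file path.
#' @return A validated cohort `data.frame`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols))
    stop("parse error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), COHORT_COLUMNS)
  if (length(extra))
    stop("parse error: unknown column(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("parse error: duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "), call. = FALSE)
  for (col in c(MEASUREMENT_COLUMNS, "true_side")) {
    raw <- df[[col]]
    raw[raw == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop("parse error: non-numeric value in column `", col, "`, row ",
           bad[1], ": \"", raw[bad[1]], "\"", call. = FALSE)
    df[[col]] <- num
  }
  df[COHORT_COLUMNS]
}

#' Write a cohort CSV
#'
#' @param records cohort `data.frame`.
#' @param path output path; missing values become empty cells.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records[COHORT_COLUMNS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

# stable non-cryptographic FNV-1a hash of the resolved configuration
config_hash <- function(config) {
  s <- paste(deparse(config, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 4294967296
  sprintf("%08x", h)
}

#' Run configuration for the full pipeline
#'
#' Either a simulation configuration or paths to patient/control CSVs,
#' plus analysis settings. All defaults are resolved here so that the
#' effective configuration can be stored next to the results.
#'
#' @param simulate a [synth_config()] (ignored when paths are given).
#' @param patients_csv,controls_csv optional input CSV paths.
#' @param spec a [classifier_spec()] for the main analyses.
#' @param n_boot bootstrap resamples for CIs.
#' @param seed analysis seed (bootstraps).
#' @param bias_correction apply the monocular vHIT offset correction
#'   (requires controls).
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulate = synth_config(), patients_csv = NULL,
                       controls_csv = NULL,
                       spec = classifier_spec("logistic"),
                       n_boot = 2000, seed = 1L, bias_correction = TRUE) {
  structure(list(simulate = simulate, patients_csv = patients_csv,
                 controls_csv = controls_csv, spec = spec,
                 n_boot = n_boot, seed = as.integer(seed),
                 bias_correction = bias_correction),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort acquisition (simulation or CSV), gain-bias
#' estimation from the comparison group and correction of patient gains,
#' asymmetry-profile computation and canonicalization, descriptive
#' statistics on the descriptive preprocessing path (impute, winsorize,
#' range-normalize, fitted on the whole patient cohort), and the
#' cross-validated prediction layer: per-metric univariate LOOCV ROCs with
#' bootstrap CIs and operating points, SVM-weight ranking, the stepwise
#' multivariate AUC trace, the grouped canal-proxy/otolith-proxy models and
#' the three-family classifier comparison.
#'
#' @param config a [run_config()].
#' @return An object of class `vest_report` (a list; see the elements in
#'   the examples), carrying the resolved configuration, its hash and the
#'   seed.
#' @examples
#' \donttest{
#' rep <- run_pipeline(run_config(simulate = synth_config(
#'   n_patients = 24, n_controls = 12, seed = 3), n_boot = 200))
#' rep$univariate$caloric_cp$roc
#' }
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  patients <- stage("input", {
    if (!is.null(config$patients_csv)) read_cohort(config$patients_csv)
    else generate_cohort(config$simulate)
  })
  controls <- stage("input", {
    if (!is.null(config$controls_csv)) read_cohort(config$controls_csv)
    else if (!is.null(config$patients_csv)) NULL
    else generate_controls(config$simulate)
  })
  if (anyNA(patients$true_side))
    stop("stage `input` failed: patients must carry true_side labels",
         call. = FALSE)

  offset <- NULL; ttests <- NULL
  if (config$bias_correction) {
    if (is.null(controls))
      stop("stage `bias_correction` failed: no comparison group available",
           call. = FALSE)
    offset <- stage("bias_correction", estimate_offset(controls))
    ttests <- stage("bias_correction", list(
      controls = left_right_ttests(controls),
      patients_pre = left_right_ttests(patients),
      patients_post = left_right_ttests(apply_offset(patients, offset))))
    patients_corrected <- apply_offset(patients, offset)
  } else {
    patients_corrected <- patients
  }

  profile <- stage("asymmetry",
                   canonicalize_signs(asymmetry_profile(patients_corrected)))
  truth <- patients$true_side

  desc <- stage("descriptives", {
    pm <- fit_preprocess(profile)
    norm <- pm$train_normalized
    attr(norm, "orientation") <- "canonical"
    tab <- descriptives_table(norm, truth)
    list(table = tab, correlation = metric_correlation(tab))
  })

  univariate <- stage("prediction", {
    out <- lapply(colnames(profile), function(m) {
      sc <- loocv_scores(profile, truth, config$spec, features = m)
      roc <- roc_curve(sc)
      list(scores = sc, roc = roc,
           auc = lpo_auc(profile, truth, config$spec, features = m),
           ci = auc_ci(sc, n_boot = config$n_boot, seed = config$seed),
           oop = optimal_operating_point(roc))
    })
    stats::setNames(out, colnames(profile))
  })
  ranking <- stage("prediction", svm_feature_ranking(profile, truth))
  stepwise <- stage("prediction",
                    stepwise_auc(profile, truth, ranking,
                                 spec = config$spec,
                                 n_boot = config$n_boot,
                                 seed = config$seed))
  grouped <- stage("prediction",
                   grouped_models(profile, truth, spec = config$spec,
                                  n_boot = config$n_boot,
                                  seed = config$seed))
  comparison <- stage("prediction", compare_classifiers(profile, truth))

  structure(list(config = config, config_hash = config_hash(config),
                 seed = config$seed,
                 patients = patients, controls = controls,
                 offset = offset, ttests = ttests, profile = profile,
                 descriptives = desc, univariate = univariate,
                 ranking = ranking, stepwise = stepwise, grouped = grouped,
                 classifier_comparison = comparison),
            class = "vest_report")
}

#' @export
print.vest_report <- function(x, ...) {
  cat("Vestibular affected-side analysis report\n")
  cat(sprintf("  config hash %s, seed %d\n", x$config_hash, x$seed))
  cat(sprintf("  patients: %d, controls: %s\n", nrow(x$patients),
              if (is.null(x$controls)) "none" else nrow(x$controls)))
  if (!is.null(x$offset))
    cat(sprintf("  vHIT offset (L-R): lat %+.3f, ant %+.3f, post %+.3f\n",
                x$offset$lateral, x$offset$anterior, x$offset$posterior))
  cat("  univariate cross-validated AUCs:\n")
  for (m in names(x$univariate))
    cat(sprintf("    %-11s %.3f (pooled-ROC %.3f-%.3f)\n", m,
                x$univariate[[m]]$auc, x$univariate[[m]]$ci[1],
                x$univariate[[m]]$ci[2]))
  cat(sprintf("  stepwise plateau at k = %d (max AUC %.3f)\n",
              attr(x$stepwise, "plateau_k"), max(x$stepwise$auc)))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes machine-readable outputs: the per-patient metric table and
#' held-out scores as CSV, and the descriptive table, univariate ROC
#' summaries, ranking, stepwise trace, grouped models and classifier
#' comparison as JSON. Every file set embeds the configuration hash and
#' seed (in `run_meta.json`). On failure all files written so far are
#' removed.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "vest_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    stop("stage `report` failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    wr <- function(name, fun) {
      path <- file.path(dir, name)
      fun(path)
      written <<- c(written, path)
      path
    }
    wr("metrics.csv", function(p) {
      df <- data.frame(subject_id = rownames(report$profile),
                       as.data.frame(unclass(report$profile)))
      utils::write.csv(df, p, row.names = FALSE, na = "")
    })
    wr("held_out_scores.csv", function(p) {
      scs <- do.call(rbind, lapply(names(report$univariate), function(m)
        cbind(metric = m, report$univariate[[m]]$scores)))
      utils::write.csv(scs, p, row.names = FALSE, na = "")
    })
    js <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                       na = "null", pretty = TRUE)
    wr("results.json", function(p) {
      uni <- lapply(report$univariate, function(u)
        list(auc = u$auc, pooled_roc_auc = u$roc$auc,
             ci = as.numeric(u$ci), oop = u$oop))
      writeLines(js(list(
        descriptives = report$descriptives$table,
        descriptives_correlation = report$descriptives$correlation,
        offset = if (!is.null(report$offset))
          report$offset[c("lateral", "anterior", "posterior")],
        ttests = report$ttests,
        univariate = uni,
        ranking = report$ranking,
        stepwise = list(trace = as.data.frame(report$stepwise),
                        plateau_k = attr(report$stepwise, "plateau_k")),
        grouped = lapply(report$grouped, function(g)
          list(auc = g$auc, pooled_roc_auc = g$roc$auc,
               ci = as.numeric(g$ci), oop = g$oop)),
        classifier_comparison = report$classifier_comparison)), p)
    })
    wr("run_meta.json", function(p) {
      writeLines(js(list(config_hash = report$config_hash,
                         seed = report$seed,
                         n_patients = nrow(report$patients),
                         n_controls = if (is.null(report$controls)) 0
                         else nrow(report$controls),
                         positive_class = 1,
                         timestamp = format(Sys.time(), usetz = TRUE))), p)
    })
    invisible(written)
  }, error = on_fail)
}
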