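#' @title Synthetic vestibular cohort generator
#' @name synthetic-cohort
#'
#' @description
#' Generates patient-like and comparison-group-like raw measurement tables
#' with known ground truth, so that every downstream stage (asymmetry
#' metrics, gain-bias correction, preprocessing, descriptives, side
#' prediction) can be validated end to end. Generation starts at the
#' gain/amplitude/SPV level; no raw eye- or head-velocity traces are
#' simulated.
#'
#' The generator emulates the statistical structure of a unilateral
#' vestibular schwannoma cohort: lateralized deficits on the tumor side, a
#' systematic right-favoring recording bias on monocular vHIT gains (applied
#' identically to patients and controls), per-test-block missingness,
#' occasional gross outliers, and a configurable fraction of patients whose
#' generated asymmetry opposes the true (imaging-given) side.
#'
#' Each subject draws from its own RNG substream derived from
#' `(seed, subject index)`, so enlarging a cohort never changes the
#' measurements of earlier subjects and output is bit-identical across runs
#' for a fixed seed.
NULL

# cohort CSV column contract (order matters; empty cell = missing)
COHORT_COLUMNS <- c("subject_id", "ll", "rl", "la", "ra", "lp", "rp",
                    "cvemp_left", "cvemp_right", "ovemp_left", "ovemp_right",
                    "caloric_right_cold", "caloric_right_warm",
                    "caloric_left_cold", "caloric_left_warm",
                    paste0("svv_", 1:6), "true_side")

MEASUREMENT_COLUMNS <- setdiff(COHORT_COLUMNS, c("subject_id", "true_side"))

# test blocks for block-wise missingness
TEST_BLOCKS <- list(
  vhit = c("ll", "rl", "la", "ra", "lp", "rp"),
  cvemp = c("cvemp_left", "cvemp_right"),
  ovemp = c("ovemp_left", "ovemp_right"),
  caloric = c("caloric_right_cold", "caloric_right_warm",
              "caloric_left_cold", "caloric_left_warm"),
  svv = paste0("svv_", 1:6))

# base amplitude/velocity distributions (see the methods vignette)
CVEMP_BASE_MEAN <- 150; CVEMP_BASE_SD <- 40; CVEMP_BASE_MIN <- 5    # uV
OVEMP_BASE_MEAN <- 10;  OVEMP_BASE_SD <- 3;  OVEMP_BASE_MIN <- 0.5  # uV
CALORIC_SHAPE <- 8; CALORIC_SCALE <- 2.5                            # deg/s
GAIN_FLOOR <- 0.05

# deterministic per-record substream; keeps every derived seed < 2^31
substream_seed <- function(seed, index, stream = 0L) {
  as.integer(((abs(seed) %% 100003) * 20011 + index * 211 + stream) %%
               2147483647)
}

#' Default deficit block of the synthetic generator
#'
#' Effect sizes of the simulated unilateral lesion. Canal gains are drawn
#' from truncated normals (affected lateral mean 0.60 SD 0.10 vs unaffected
#' 0.95 SD 0.05; verticals 0.55/0.90 with the same SDs); the affected side's
#' cVEMP amplitude is multiplied by 0.4 and its (contralaterally recorded)
#' oVEMP pathway amplitude by 0.6; the affected ear's caloric responses are
#' multiplied by 0.35; SVV trials tilt on average 3 degrees toward the
#' affected side with a trial SD of 1.5 degrees.
#'
#' @return A named list of deficit parameters.
#' @seealso [deficit_null()] for a no-effect block.
#' @export
deficit_default <- function() {
  list(lateral_mean = 0.95, lateral_sd = 0.05,
       lateral_affected_mean = 0.60, lateral_affected_sd = 0.10,
       vertical_mean = 0.90, vertical_sd = 0.05,
       vertical_affected_mean = 0.55, vertical_affected_sd = 0.10,
       cvemp_factor = 0.4, ovemp_factor = 0.6, caloric_factor = 0.35,
       svv_tilt = 3, svv_sd = 1.5)
}

#' Null deficit block (no lesion effect)
#'
#' Affected-side distributions equal the unaffected ones, all amplitude and
#' SPV factors are 1 and the SVV tilt is 0, so the generated measurements
#' carry no information about `true_side`. Used for null-calibration
#' studies.
#'
#' @return A named list of deficit parameters.
#' @export
deficit_null <- function() {
  d <- deficit_default()
  d$lateral_affected_mean <- d$lateral_mean
  d$lateral_affected_sd <- d$lateral_sd
  d$vertical_affected_mean <- d$vertical_mean
  d$vertical_affected_sd <- d$vertical_sd
  d$cvemp_factor <- 1; d$ovemp_factor <- 1; d$caloric_factor <- 1
  d$svv_tilt <- 0
  d
}

#' Default measurement-noise block
#'
#' `gain`: additive SD on every VOR gain; `vemp` and `caloric`:
#' multiplicative (relative) SD per measurement; `svv`: between-subject SD
#' (degrees) of the lesion-induced tilt, modelling central compensation and
#' idiosyncratic verticality bias -- this term is what keeps the SVV weakly
#' discriminative at the group level despite a consistent mean tilt.
#'
#' @return A named list with entries `gain`, `vemp`, `caloric`, `svv`.
#' @export
noise_default <- function() {
  list(gain = 0.02, vemp = 0.15, caloric = 0.15, svv = 8)
}

#' Synthetic cohort configuration
#'
#' Validates and assembles the full parameter set of the generator. All
#' arguments have study-level defaults: 68 patients, 33 controls, balanced
#' sides, the [deficit_default()] effect block, a right-favoring monocular
#' vHIT gain bias (left-minus-right: lateral -0.06, anterior -0.01,
#' posterior -0.03), observed missingness rates (oVEMP 4.4\%, cVEMP 0\%,
#' SVV 5.8\%, caloric 7.3\%, vHIT 0\%), a 2\% per-measurement outlier rate
#' and a 5\% chance that a patient's asymmetry opposes the true side.
#'
#' @param n_patients,n_controls cohort sizes (>= 1).
#' @param p_right probability of a right-sided tumor.
#' @param deficit deficit block, see [deficit_default()].
#' @param vhit_bias named numeric `(lateral, anterior, posterior)`
#'   left-minus-right gain offsets applied to every subject.
#' @param missing_rates named numeric `(vhit, cvemp, ovemp, svv, caloric)`
#'   per-test-block missingness probabilities.
#' @param outlier_rate per-measurement probability of a gross outlier
#'   (value tripled; SVV trials shifted by +15 degrees).
#' @param p_flip probability that a patient's deficit is generated as if the
#'   tumor were on the opposite side (the true label is unchanged),
#'   emulating asymmetries unexplained by the tumor.
#' @param noise noise block, see [noise_default()].
#' @param seed integer RNG seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_patients = 68, n_controls = 33, p_right = 0.5,
                         deficit = deficit_default(),
                         vhit_bias = c(lateral = -0.06, anterior = -0.01,
                                       posterior = -0.03),
                         missing_rates = c(vhit = 0, cvemp = 0,
                                           ovemp = 0.044, svv = 0.058,
                                           caloric = 0.073),
                         outlier_rate = 0.02, p_flip = 0.05,
                         noise = noise_default(), seed = 1L) {
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
        x != round(x))
      stop("invalid configuration: `", nm, "` must be a count >= 1",
           call. = FALSE)
  }
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
      stop("invalid configuration: `", nm, "` must be in [0, 1]",
           call. = FALSE)
  }
  chk_count(n_patients, "n_patients"); chk_count(n_controls, "n_controls")
  chk_prob(p_right, "p_right"); chk_prob(p_flip, "p_flip")
  chk_prob(outlier_rate, "outlier_rate")
  need <- c("lateral", "anterior", "posterior")
  if (!all(need %in% names(vhit_bias)))
    stop("invalid configuration: `vhit_bias` must name ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!all(names(TEST_BLOCKS) %in% names(missing_rates)))
    stop("invalid configuration: `missing_rates` must name ",
         paste(names(TEST_BLOCKS), collapse = ", "), call. = FALSE)
  chk_prob(unlist(missing_rates), "missing_rates")
  dneed <- names(deficit_default())
  miss <- setdiff(dneed, names(deficit))
  if (length(miss))
    stop("invalid configuration: `deficit` is missing field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  sds <- unlist(deficit[grep("_sd$", dneed, value = TRUE)])
  if (any(sds < 0))
    stop("invalid configuration: `deficit` SDs must be >= 0", call. = FALSE)
  if (any(unlist(noise) < 0))
    stop("invalid configuration: `noise` SDs must be >= 0", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("invalid configuration: `seed` must be a single integer",
         call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 p_right = p_right, deficit = deficit,
                 vhit_bias = vhit_bias, missing_rates = missing_rates,
                 outlier_rate = outlier_rate, p_flip = p_flip,
                 noise = noise, seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic vestibular cohort configuration\n")
  cat(sprintf("  patients: %d (P(right) = %.2f, P(flip) = %.2f)\n",
              x$n_patients, x$p_right, x$p_flip))
  cat(sprintf("  controls: %d\n", x$n_controls))
  cat(sprintf("  vHIT bias (L-R): lateral %+.3f, anterior %+.3f, posterior %+.3f\n",
              x$vhit_bias[["lateral"]], x$vhit_bias[["anterior"]],
              x$vhit_bias[["posterior"]]))
  cat(sprintf("  missing rates: %s\n",
              paste(sprintf("%s %.1f%%", names(TEST_BLOCKS),
                            100 * unlist(x$missing_rates[names(TEST_BLOCKS)])),
                    collapse = ", ")))
  cat(sprintf("  outlier rate: %.1f%%, seed: %d\n",
              100 * x$outlier_rate, x$seed))
  invisible(x)
}

trunc_norm <- function(n, mean, sd, lo) pmax(stats::rnorm(n, mean, sd), lo)

mult_noise <- function(sd) max(1 + stats::rnorm(1L, 0, sd), 0.05)

# one subject's measurements; gen_side: -1 left lesion, +1 right, 0 none.
# Must always consume the same number of random draws regardless of
# gen_side or outlier settings, so substreams stay aligned across
# configurations.
draw_measurements <- function(config, gen_side, apply_outliers = TRUE) {
  d <- config$deficit; nz <- config$noise; bias <- config$vhit_bias

  g_one <- function(side, lateral) {
    aff <- !is.na(gen_side) && gen_side == side
    if (lateral) {
      if (aff) trunc_norm(1L, d$lateral_affected_mean, d$lateral_affected_sd,
                          GAIN_FLOOR)
      else trunc_norm(1L, d$lateral_mean, d$lateral_sd, GAIN_FLOOR)
    } else {
      if (aff) trunc_norm(1L, d$vertical_affected_mean,
                          d$vertical_affected_sd, GAIN_FLOOR)
      else trunc_norm(1L, d$vertical_mean, d$vertical_sd, GAIN_FLOOR)
    }
  }
  ll <- g_one(-1, TRUE); rl <- g_one(+1, TRUE)
  la <- g_one(-1, FALSE); ra <- g_one(+1, FALSE)
  lp <- g_one(-1, FALSE); rp <- g_one(+1, FALSE)
  gn <- stats::rnorm(6L, 0, nz$gain)
  ll <- ll + gn[1]; rl <- rl + gn[2]; la <- la + gn[3]
  ra <- ra + gn[4]; lp <- lp + gn[5]; rp <- rp + gn[6]
  # right gains inflated by the monocular recording bias (bias = L - R)
  rl <- rl - bias[["lateral"]]
  ra <- ra - bias[["anterior"]]
  rp <- rp - bias[["posterior"]]

  cb <- max(stats::rnorm(1L, CVEMP_BASE_MEAN, CVEMP_BASE_SD), CVEMP_BASE_MIN)
  cvl <- cb * mult_noise(nz$vemp); cvr <- cb * mult_noise(nz$vemp)
  ob <- max(stats::rnorm(1L, OVEMP_BASE_MEAN, OVEMP_BASE_SD), OVEMP_BASE_MIN)
  ovl <- ob * mult_noise(nz$vemp); ovr <- ob * mult_noise(nz$vemp)
  if (!is.na(gen_side) && gen_side == -1) {
    cvl <- cvl * d$cvemp_factor; ovl <- ovl * d$ovemp_factor
  } else if (!is.na(gen_side) && gen_side == +1) {
    cvr <- cvr * d$cvemp_factor; ovr <- ovr * d$ovemp_factor
  }

  # one responsiveness base per subject; ears differ through the lesion
  # factor and per-condition measurement noise
  cal_base <- stats::rgamma(1L, shape = CALORIC_SHAPE, scale = CALORIC_SCALE)
  cal_r <- cal_base; cal_l <- cal_base
  if (!is.na(gen_side) && gen_side == -1) cal_l <- cal_l * d$caloric_factor
  if (!is.na(gen_side) && gen_side == +1) cal_r <- cal_r * d$caloric_factor
  crc <- cal_r * mult_noise(nz$caloric); crw <- cal_r * mult_noise(nz$caloric)
  clc <- cal_l * mult_noise(nz$caloric); clw <- cal_l * mult_noise(nz$caloric)

  side0 <- if (is.na(gen_side)) 0 else gen_side
  tilt <- side0 * (d$svv_tilt + stats::rnorm(1L, 0, nz$svv))
  svv <- stats::rnorm(6L, tilt, d$svv_sd)

  vals <- c(ll = ll, rl = rl, la = la, ra = ra, lp = lp, rp = rp,
            cvemp_left = cvl, cvemp_right = cvr,
            ovemp_left = ovl, ovemp_right = ovr,
            caloric_right_cold = crc, caloric_right_warm = crw,
            caloric_left_cold = clc, caloric_left_warm = clw,
            svv_1 = svv[1], svv_2 = svv[2], svv_3 = svv[3],
            svv_4 = svv[4], svv_5 = svv[5], svv_6 = svv[6])

  # gross outliers (exercises downstream winsorization); the comparison
  # group is screened as normal-functioning and stays clean
  out <- stats::runif(length(vals)) < config$outlier_rate
  if (apply_outliers) {
    is_svv <- grepl("^svv_", names(vals))
    vals[out & !is_svv] <- vals[out & !is_svv] * 3
    vals[out & is_svv] <- vals[out & is_svv] + 15
  }

  gcols <- c("ll", "rl", "la", "ra", "lp", "rp")
  vals[gcols] <- pmax(vals[gcols], 0.01)  # gains must stay positive
  vals
}

build_cohort <- function(config, n, prefix, stream, with_side) {
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i, stream))
    if (with_side) {
      side <- if (stats::runif(1L) < config$p_right) 1L else -1L
      gen_side <- if (stats::runif(1L) < config$p_flip) -side else side
    } else {
      side <- NA_integer_
      gen_side <- NA_integer_
    }
    vals <- draw_measurements(config, gen_side, apply_outliers = with_side)
    rows[[i]] <- c(vals, true_side = as.numeric(side))
  }
  df <- as.data.frame(do.call(rbind, rows))
  df <- cbind(subject_id = sprintf("%s%03d", prefix, seq_len(n)), df)
  df[COHORT_COLUMNS]
}

#' Generate a synthetic patient cohort
#'
#' Draws `n_patients` records with a ground-truth `true_side` (+1 right, -1
#' left). For non-flipped patients the affected side's canal gains, cVEMP
#' amplitude, oVEMP pathway amplitude and caloric responses are reduced and
#' the SVV tilts toward the affected side; every subject additionally
#' carries the configured monocular vHIT gain bias on the right-side gains.
#' Block-wise missingness is injected at the configured rates.
#'
#' @param config a [synth_config()].
#' @return A cohort `data.frame` (one row per subject, the CSV column
#'   contract of [read_cohort()]).
#' @examples
#' cohort <- generate_cohort(synth_config(n_patients = 10, seed = 7))
#' table(cohort$true_side)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  df <- build_cohort(config, config$n_patients, "VS", stream = 1L,
                     with_side = TRUE)
  inject_missingness(df, config$missing_rates, seed = config$seed)
}

#' Generate a synthetic comparison group
#'
#' Control-like records: no lesion deficit, but the same monocular vHIT gain
#' bias and measurement noise as the patient group. Gross outliers are not
#' injected (the comparison group is screened for normal vestibular
#' function). `true_side` is `NA`.
#'
#' @param config a [synth_config()].
#' @return A cohort `data.frame` with `n_controls` rows.
#' @export
generate_controls <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  df <- build_cohort(config, config$n_controls, "CG", stream = 2L,
                     with_side = FALSE)
  inject_missingness(df, config$missing_rates, seed = config$seed,
                     .stream = 10L)
}

#' Inject block-wise missingness
#'
#' Sets whole test blocks (all four caloric conditions, all six SVV trials,
#' both amplitudes of a VEMP test, all six vHIT gains) to missing,
#' independently per record at the configured per-test rate. The vHIT block
#' rate defaults to 0 in [synth_config()], matching complete vHIT
#' acquisition.
#'
#' @param records cohort `data.frame`.
#' @param missing_rates named rates for `vhit`, `cvemp`, `ovemp`, `svv`,
#'   `caloric` (missing names are treated as 0).
#' @param seed integer seed (per-record substreams are derived from it).
#' @param .stream internal substream discriminator.
#' @return The records with blocks blanked to `NA`.
#' @export
inject_missingness <- function(records, missing_rates, seed, .stream = 9L) {
  rates <- stats::setNames(numeric(length(TEST_BLOCKS)), names(TEST_BLOCKS))
  rates[names(missing_rates)[names(missing_rates) %in% names(rates)]] <-
    unlist(missing_rates)[names(missing_rates) %in% names(rates)]
  if (any(rates < 0 | rates > 1))
    stop("invalid configuration: missing rates must be in [0, 1]",
         call. = FALSE)
  for (i in seq_len(nrow(records))) {
    set.seed(substream_seed(seed, i, .stream))
    drop <- stats::runif(length(rates)) < rates
    for (blk in names(rates)[drop])
      records[i, TEST_BLOCKS[[blk]]] <- NA_real_
  }
  records
}
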