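#' @title Left-right asymmetry metrics for laboratory vestibular tests
#' @name asymmetry-metrics
#'
#' @description
#' All per-patient left-right asymmetry statistics used by the package. Every
#' ratio metric is a Jongkees-style normalized difference scaled to percent,
#' so all values lie in \[-100, 100\]. The vHIT metrics (RLLL, RALP, LARP and
#' the composite anterior-posterior measure) are computed from the six
#' semicircular-canal VOR gains; the VEMP asymmetry ratio from left/right
#' peak-to-peak amplitudes; the canal paresis from the four caloric
#' slow-phase-velocity conditions; and the SVV shift as the mean of the six
#' signed adjustment trials.
#'
#' Sign conventions follow the formulas as printed in the clinical
#' literature: RLLL/RALP/LARP are left-minus-right (positive = better left
#' function), while the VEMP asymmetry ratio and caloric canal paresis are
#' right-minus-left. [canonicalize_signs()] converts a profile to a single
#' canonical orientation in which positive always means "right side affected".
#'
#' All functions are vectorized and propagate `NA`; a non-positive
#' denominator among non-missing inputs is a domain error.
NULL

# Canonical column order of the per-patient metric table.
METRIC_COLUMNS <- c("rlll", "ralp", "larp", "cmp_ap",
                    "ovemp_ar", "cvemp_ar", "caloric_cp", "svv_shift")

# Multiplier taking as-printed metric values to the canonical orientation
# (positive = right side affected, i.e. better left-side function).
# RLLL/RALP/LARP and the composite AP measure are already left-minus-right;
# the VEMP asymmetry ratio and the canal paresis are right-minus-left and
# must be negated; SVV tilts toward the lesioned side, so a positive
# (rightward) tilt already points at a right-sided lesion.
CANONICAL_SIGNS <- c(rlll = 1, ralp = 1, larp = 1, cmp_ap = 1,
                     ovemp_ar = -1, cvemp_ar = -1, caloric_cp = -1,
                     svv_shift = 1)

# Pathological thresholds of the test battery.
THRESH_LATERAL_GAIN <- 0.8   # lateral canal VOR gain below this is abnormal
THRESH_VERTICAL_GAIN <- 0.7  # anterior/posterior canal gain threshold
THRESH_CALORIC_CP <- 25      # |canal paresis| percent, strict
THRESH_SVV_DEG <- 2.2        # |mean SVV shift| degrees, strict

jongkees_ratio <- function(num, den, what) {
  bad <- !is.na(den) & den <= 0
  if (any(bad))
    stop("non-positive denominator (", what, ") in ", sum(bad), " case(s)",
         call. = FALSE)
  num / den * 100
}

#' Lateral-canal gain asymmetry (RLLL)
#'
#' `(LL - RL) / (RL + LL) * 100`, the left-minus-right lateral-canal VOR gain
#' asymmetry in percent.
#'
#' @param ll,rl left and right lateral canal VOR gains (dimensionless, > 0).
#' @return Numeric vector of percentages in \[-100, 100\].
#' @examples
#' asym_rlll(0.8, 1.0)
#' @export
asym_rlll <- function(ll, rl) {
  jongkees_ratio(ll - rl, rl + ll, "ll + rl")
}

#' Vertical-plane gain asymmetries (RALP and LARP)
#'
#' The anterior and posterior canals are tested in the two diagonal planes:
#' right-anterior with left-posterior (RALP) and left-anterior with
#' right-posterior (LARP). `asym_ralp()` is `(LP - RA) / (RA + LP) * 100`;
#' `asym_larp()` is `(LA - RP) / (LA + RP) * 100`. Both are left-minus-right
#' within their plane.
#'
#' @param la,ra,lp,rp anterior/posterior canal VOR gains by side.
#' @return Numeric vector of percentages in \[-100, 100\].
#' @examples
#' asym_ralp(lp = 0.9, ra = 0.6)
#' asym_larp(la = 0.6, rp = 0.9)
#' @export
asym_ralp <- function(lp, ra) {
  jongkees_ratio(lp - ra, ra + lp, "ra + lp")
}

#' @rdname asym_ralp
#' @export
asym_larp <- function(la, rp) {
  jongkees_ratio(la - rp, la + rp, "la + rp")
}

#' Composite vertical-canal asymmetries
#'
#' Intermediate composite measures over all four vertical canals.
#' `asym_cmp_a()` is the Jongkees ratio of the diagonal gain products
#' `LA*LP` and `RA*RP`. `asym_cmp_b()` is the plain average of the RALP and
#' LARP asymmetries, `(RALP + LARP) / 2` (computed as fractions, scaled to
#' percent once); algebraically it expands to
#' `(LA*LP - RA*RP) / (LA*LP + RP*LP + RA*LA + RA*RP) * 100`, which differs
#' from `asym_cmp_a()` only by the two cross products `RP*LP` and `RA*LA` in
#' the denominator.
#'
#' @param la,ra,lp,rp anterior/posterior canal VOR gains by side.
#' @return Numeric vector of percentages.
#' @seealso [asym_cmp_ap()] for the final composite measure.
#' @export
asym_cmp_a <- function(la, ra, lp, rp) {
  jongkees_ratio(la * lp - ra * rp, la * lp + ra * rp, "la*lp + ra*rp")
}

#' @rdname asym_cmp_a
#' @export
asym_cmp_b <- function(la, ra, lp, rp) {
  bad1 <- !is.na(ra + lp) & (ra + lp) <= 0
  bad2 <- !is.na(la + rp) & (la + rp) <= 0
  if (any(bad1 | bad2))
    stop("non-positive denominator (ra + lp or la + rp) in ",
         sum(bad1 | bad2), " case(s)", call. = FALSE)
  ((lp - ra) / (ra + lp) + (la - rp) / (la + rp)) / 2 * 100
}

#' Composite anterior-posterior asymmetry (cmpAP)
#'
#' The composite measure comparing the left anterior and posterior canals
#' with the right anterior and posterior canals, via the Jongkees formula
#' applied to the gain *products* `RP*LP` and `RA*LA`:
#' `(RP*LP - RA*LA) / (RP*LP + RA*LA) * 100`. These are the two cross
#' products that distinguish the expanded form of `asym_cmp_b()` from
#' `asym_cmp_a()`.
#'
#' @param la,ra,lp,rp anterior/posterior canal VOR gains by side.
#' @return Numeric vector of percentages in \[-100, 100\].
#' @examples
#' asym_cmp_ap(la = 0.6, ra = 0.6, lp = 0.8, rp = 0.8)  # 28
#' @export
asym_cmp_ap <- function(la, ra, lp, rp) {
  jongkees_ratio(rp * lp - ra * la, rp * lp + ra * la, "rp*lp + ra*la")
}

#' VEMP amplitude asymmetry ratio
#'
#' `(right - left) / (right + left) * 100` from mean peak-to-peak amplitudes
#' (cVEMP: p13n23, pre-tension corrected; oVEMP: n10p15). Note the
#' right-minus-left orientation, opposite to the vHIT metrics.
#'
#' @param right_amp,left_amp peak-to-peak amplitudes (non-negative; not both
#'   zero).
#' @return Numeric vector of percentages in \[-100, 100\].
#' @export
vemp_ar <- function(right_amp, left_amp) {
  jongkees_ratio(right_amp - left_amp, right_amp + left_amp,
                 "right_amp + left_amp; bilaterally absent response")
}

#' Caloric canal paresis (Jongkees formula)
#'
#' `((RC + RW) - (LC + LW)) / (RC + RW + LC + LW) * 100` from the maximal
#' slow-phase velocities of the four irrigation conditions (right/left ear,
#' cold 30C / warm 44C water). Right-minus-left: a negative value means
#' weaker right-ear responses. `|CP| > 25` is conventionally pathological.
#'
#' @param right_cold,right_warm,left_cold,left_warm maximal slow-phase
#'   velocities in degrees/s (non-negative; total must be positive, a zero
#'   total is bilateral areflexia and the side is undefined).
#' @return Numeric vector of percentages in \[-100, 100\].
#' @export
caloric_cp <- function(right_cold, right_warm, left_cold, left_warm) {
  jongkees_ratio((right_cold + right_warm) - (left_cold + left_warm),
                 right_cold + right_warm + left_cold + left_warm,
                 "total caloric response; bilateral areflexia")
}

#' Mean subjective visual vertical shift
#'
#' Arithmetic mean of the available signed SVV adjustment errors (degrees)
#' over the six trials; trials may be individually missing. All-missing rows
#' yield `NA` (handled downstream by imputation).
#'
#' @param trials numeric vector of six trials, or a matrix/data.frame with
#'   six columns (one row per subject).
#' @return Mean shift in degrees (positive = rightward tilt).
#' @export
svv_shift <- function(trials) {
  if (is.data.frame(trials)) trials <- as.matrix(trials)
  if (is.matrix(trials)) {
    if (ncol(trials) != 6L)
      stop("svv trials must have exactly six columns", call. = FALSE)
    out <- rowMeans(trials, na.rm = TRUE)
    out[rowSums(!is.na(trials)) == 0L] <- NA_real_
    return(out)
  }
  if (length(trials) != 6L)
    stop("svv trials must have exactly six entries", call. = FALSE)
  if (all(is.na(trials))) return(NA_real_)
  mean(trials, na.rm = TRUE)
}

#' Per-patient asymmetry profile
#'
#' Computes the eight asymmetry metrics for every row of a cohort table (see
#' [read_cohort()] for the column contract). Metrics whose raw test block is
#' missing come out `NA`; imputation is a downstream preprocessing step.
#'
#' @param records cohort `data.frame` with the raw measurement columns.
#' @return A numeric matrix, one row per subject, columns `rlll`, `ralp`,
#'   `larp`, `cmp_ap`, `ovemp_ar`, `cvemp_ar`, `caloric_cp`, `svv_shift`,
#'   with attribute `orientation = "as_printed"`.
#' @export
asymmetry_profile <- function(records) {
  stopifnot(is.data.frame(records))
  svv <- as.matrix(records[paste0("svv_", 1:6)])
  out <- cbind(
    rlll = asym_rlll(records$ll, records$rl),
    ralp = asym_ralp(records$lp, records$ra),
    larp = asym_larp(records$la, records$rp),
    cmp_ap = asym_cmp_ap(records$la, records$ra, records$lp, records$rp),
    ovemp_ar = vemp_ar(records$ovemp_right, records$ovemp_left),
    cvemp_ar = vemp_ar(records$cvemp_right, records$cvemp_left),
    caloric_cp = caloric_cp(records$caloric_right_cold,
                            records$caloric_right_warm,
                            records$caloric_left_cold,
                            records$caloric_left_warm),
    svv_shift = svv_shift(svv))
  rownames(out) <- as.character(records$subject_id)
  attr(out, "orientation") <- "as_printed"
  out
}

#' Canonicalize asymmetry signs
#'
#' Re-signs an as-printed profile so that a positive value always indicates
#' a right-sided deficit (better left-side function) for every metric:
#' RLLL/RALP/LARP, the composite AP measure and the SVV shift are kept, the
#' VEMP asymmetry ratios and the caloric canal paresis are negated. Applying
#' it to an already canonical profile is an error (the operation is not an
#' involution by design: each profile records its orientation explicitly).
#'
#' @param profile matrix from [asymmetry_profile()] with orientation
#'   `"as_printed"`.
#' @return The profile with orientation `"canonical"`.
#' @export
canonicalize_signs <- function(profile) {
  orient <- attr(profile, "orientation")
  if (identical(orient, "canonical"))
    stop("profile is already in canonical orientation", call. = FALSE)
  if (!identical(orient, "as_printed"))
    stop("profile has no recorded orientation; use asymmetry_profile()",
         call. = FALSE)
  cols <- intersect(colnames(profile), names(CANONICAL_SIGNS))
  out <- profile
  out[, cols] <- sweep(profile[, cols, drop = FALSE], 2,
                       CANONICAL_SIGNS[cols], `*`)
  attr(out, "orientation") <- "canonical"
  out
}

#' Pathological flags per subject
#'
#' Applies the conventional abnormality thresholds of the battery: lateral
#' vHIT gain < 0.8 (either side), vertical canal gain < 0.7 (per plane,
#' either member), `|CP| > 25` percent, `|SVV| > 2.2` degrees. All
#' comparisons are strict, so boundary values are normal. Missing inputs
#' yield `NA` flags.
#'
#' @param records cohort `data.frame` (raw gains are needed for the vHIT
#'   thresholds, which apply to gains, not asymmetries).
#' @param profile optional matrix from [asymmetry_profile()] (as-printed or
#'   canonical; thresholds are two-sided so orientation does not matter).
#'   Recomputed from `records` when omitted.
#' @return Logical matrix with columns `vhit_lateral`, `vhit_anterior`,
#'   `vhit_posterior`, `caloric`, `svv`.
#' @export
pathological_flags <- function(records, profile = NULL) {
  if (is.null(profile)) profile <- asymmetry_profile(records)
  out <- cbind(
    vhit_lateral = pmin(records$ll, records$rl) < THRESH_LATERAL_GAIN,
    vhit_anterior = pmin(records$la, records$ra) < THRESH_VERTICAL_GAIN,
    vhit_posterior = pmin(records$lp, records$rp) < THRESH_VERTICAL_GAIN,
    caloric = abs(profile[, "caloric_cp"]) > THRESH_CALORIC_CP,
    svv = abs(profile[, "svv_shift"]) > THRESH_SVV_DEG)
  rownames(out) <- rownames(profile)
  out
}
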