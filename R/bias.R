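#' @title Monocular vHIT gain-bias correction
#' @name bias-correction
#'
#' @description
#' Monocular vHIT goggles record one eye only and systematically inflate the
#' measured-eye side's VOR gains (typically the right). The correction
#' implemented here estimates the "normative" left-minus-right gain offset
#' per canal pair from a comparison group with control-like vHIT function,
#' and subtracts it from patient gains before any asymmetry is computed.
NULL

CANAL_PAIRS <- list(lateral = c("ll", "rl"),
                    anterior = c("la", "ra"),
                    posterior = c("lp", "rp"))

#' Estimate the normative left-minus-right gain offset
#'
#' For each canal pair (lateral, anterior, posterior), the mean of
#' `left gain - right gain` over all comparison-group subjects with both
#' gains observed. In an unbiased recording this difference would be about
#' zero, so its group mean approximates the recording bias of the monocular
#' goggles.
#'
#' @param controls cohort `data.frame` of the comparison group.
#' @return An object of class `offset_estimate`: per-pair means, group sizes
#'   and standard errors.
#' @export
estimate_offset <- function(controls) {
  stopifnot(is.data.frame(controls))
  est <- lapply(CANAL_PAIRS, function(p) {
    d <- controls[[p[1]]] - controls[[p[2]]]
    d <- d[!is.na(d)]
    if (length(d) < 2L)
      stop("offset estimation needs >= 2 complete ", p[1], "/", p[2],
           " gain pairs", call. = FALSE)
    list(mean = mean(d), n = length(d), se = stats::sd(d) / sqrt(length(d)))
  })
  structure(list(lateral = est$lateral$mean,
                 anterior = est$anterior$mean,
                 posterior = est$posterior$mean,
                 n = vapply(est, `[[`, 0L, "n"),
                 se = vapply(est, `[[`, 0, "se")),
            class = "offset_estimate")
}

#' @export
print.offset_estimate <- function(x, ...) {
  cat("Monocular vHIT left-minus-right gain offsets\n")
  for (p in names(CANAL_PAIRS))
    cat(sprintf("  %-9s %+.4f (n = %d, se = %.4f)\n",
                p, x[[p]], x$n[[p]], x$se[[p]]))
  invisible(x)
}

#' Subtract the gain offset from a cohort's left gains
#'
#' The offset is defined as left-minus-right, so subtracting it from the
#' *left* gain of each pair (right gains untouched) makes the corrected
#' left-minus-right difference equal the raw difference minus the offset.
#' Corrected gains are floored at 0.01 to keep downstream ratio denominators
#' positive; the number of floored values is recorded in the `n_floored`
#' attribute.
#'
#' @param records cohort `data.frame`.
#' @param offset an [estimate_offset()] result.
#' @return The corrected records.
#' @export
apply_offset <- function(records, offset) {
  stopifnot(inherits(offset, "offset_estimate"))
  n_floored <- 0L
  for (p in names(CANAL_PAIRS)) {
    left <- CANAL_PAIRS[[p]][1]
    corrected <- records[[left]] - offset[[p]]
    n_floored <- n_floored + sum(corrected < 0.01, na.rm = TRUE)
    records[[left]] <- pmax(corrected, 0.01)
  }
  attr(records, "n_floored") <- n_floored
  records
}

#' One-sample t-tests on left-minus-right gain differences
#'
#' Classical two-sided one-sample t-tests of the per-subject
#' left-minus-right gain difference against zero, per canal pair. Used to
#' document the recording bias before correction and its removal after
#' correction.
#'
#' @param records cohort `data.frame`.
#' @return A `data.frame` with columns `canal`, `mean_diff`, `t`, `df`, `p`.
#'   Degenerate zero-variance samples report `p = 1` when the mean is also
#'   zero, and the limiting `p = 0` (with a warning) otherwise.
#' @export
left_right_ttests <- function(records) {
  rows <- lapply(names(CANAL_PAIRS), function(pn) {
    p <- CANAL_PAIRS[[pn]]
    d <- records[[p[1]]] - records[[p[2]]]
    d <- d[!is.na(d)]
    if (length(d) < 2L)
      stop("t-test needs >= 2 complete ", pn, " gain pairs", call. = FALSE)
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) {
        tt <- list(statistic = 0, parameter = length(d) - 1L, p.value = 1)
      } else {
        warning("zero-variance nonzero-mean differences for ", pn,
                " canals; reporting the degenerate limit p = 0",
                call. = FALSE)
        tt <- list(statistic = sign(mean(d)) * Inf,
                   parameter = length(d) - 1L, p.value = 0)
      }
    } else {
      ht <- stats::t.test(d, mu = 0, alternative = "two.sided")
      tt <- list(statistic = unname(ht$statistic),
                 parameter = unname(ht$parameter), p.value = ht$p.value)
    }
    data.frame(canal = pn, mean_diff = mean(d), t = tt$statistic,
               df = tt$parameter, p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
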