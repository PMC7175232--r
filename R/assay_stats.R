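# Printed assay formulas: electrolyte leakage, cotyledon greening rate, and
# comparative-Ct (delta-delta-Ct) relative expression.

#' Electrolyte leakage percentage
#'
#' EL = (S1 - S0) / (S2 - S0) x 100, from electrical conductivities measured
#' before shaking (S0), after gentle shaking (S1) and after autoclaving to
#' release all electrolytes (S2). All three must share the same units, which
#' cancel. Values outside `[0, 100]` (S1 below baseline or above total lysis)
#' are returned but flagged with a warning.
#'
#' @param s0,s1,s2 Conductivities (vectorized).
#' @return Percent electrolyte leakage.
#' @export
electrolyte_leakage <- function(s0, s1, s2) {
  if (any(s2 == s0)) stop("S2 equals S0: total-lysis conductivity must exceed baseline")
  el <- (s1 - s0) / (s2 - s0) * 100
  out_of_range <- el < 0 | el > 100
  if (any(out_of_range)) {
    warning(sum(out_of_range), " electrolyte-leakage value(s) outside [0, 100]")
  }
  el
}

#' Cotyledon greening rate
#'
#' @param n_green,n_total Seedling counts (vectorized), `0 <= n_green <=
#'   n_total`, `n_total >= 1`.
#' @return Percent of seedlings with green cotyledons.
#' @export
greening_rate <- function(n_green, n_total) {
  if (any(n_total < 1)) stop("n_total must be >= 1")
  if (any(n_green < 0 | n_green > n_total)) {
    stop("n_green must lie in [0, n_total]")
  }
  100 * n_green / n_total
}

#' Relative expression by the comparative Ct method
#'
#' Fold change \eqn{2^{-\Delta\Delta Ct}} with
#' \eqn{\Delta\Delta Ct = (Ct_{target} - Ct_{ref})_{sample} -
#' (Ct_{target} - Ct_{ref})_{calibrator}}, assuming perfect doubling per
#' cycle (amplification efficiency 2).
#'
#' @param ct_target_sample,ct_ref_sample Target and reference-gene Ct in the
#'   sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator Same in the calibrator.
#' @return Fold change (> 0), vectorized.
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_calibrator, ct_ref_calibrator) {
  ct <- c(ct_target_sample, ct_ref_sample, ct_target_calibrator,
          ct_ref_calibrator)
  if (any(!is.finite(ct)) || any(ct <= 0)) {
    stop("all Ct values must be finite and positive")
  }
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}

#' Mean and standard error over biological replicates
#'
#' Technical qPCR replicates should be averaged to one Ct before
#' [ddct_fold_change()]; biological replicates of any assay statistic are
#' then summarized as mean +/- s.e.m.
#'
#' @param x Numeric vector of per-replicate values.
#' @return List with `mean`, `sem`, `n`.
#' @export
summarise_replicates <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("no non-missing replicate values")
  list(mean = mean(x),
       sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_,
       n = length(x))
}
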