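#' Population doublings from cell counts
#'
#' `PD = log10(N / N0) * 3.33`, the culture-tracking formula for the number
#' of doublings between plating `N0` cells and harvesting `N` (the constant
#' 3.33 is 1 / log10(2), so PD is the base-2 log of the expansion).
#' Cumulative doublings across serial passages are the running sum.
#'
#' @param n Cells harvested (vectorized over passages).
#' @param n0 Cells plated.
#' @param cumulative If `TRUE`, return the running sum across passages.
#' @return Population doublings (numeric).
#' @examples
#' population_doubling(2e5, 1e5) # one doubling ~ 1.002
#' population_doubling(c(4e5, 8e5), c(1e5, 4e5), cumulative = TRUE)
#' @export
population_doubling <- function(n, n0, cumulative = FALSE) {
  if (any(!is.finite(n)) || any(!is.finite(n0)) || any(n <= 0) || any(n0 <= 0)) {
    stopf("cell counts must be finite and positive")
  }
  pd <- log10(n / n0) * 3.33
  if (cumulative) cumsum(pd) else pd
}

#' Relative expression by the delta-delta-Ct method
#'
#' Computes `2^-ddCt` where
#' `ddCt = (Ct_target,test - Ct_ref,test) - (Ct_target,ctrl - Ct_ref,ctrl)`,
#' the standard qPCR relative quantification referenced to a housekeeping
#' gene (here beta-actin). Replicate Ct measurements (e.g. triplicates) are
#' averaged on the Ct scale before the differences are taken.
#'
#' @param ct_target_test,ct_ref_test Ct values of the target and reference
#'   gene in the test sample (vectors of replicates allowed).
#' @param ct_target_ctrl,ct_ref_ctrl Ct values in the control sample.
#' @return The fold change of the target in the test sample relative to the
#'   control sample.
#' @examples
#' ddct_fold_change(24, 20, 25, 20) # ddCt = -1 -> fold change 2
#' @export
ddct_fold_change <- function(ct_target_test, ct_ref_test,
                             ct_target_ctrl, ct_ref_ctrl) {
  cts <- list(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (any(vapply(cts, function(x) any(!is.finite(x)) || any(x <= 0),
                 logical(1)))) {
    stopf("Ct values must be finite and positive")
  }
  m <- vapply(cts, mean, numeric(1))
  ddct <- (m[1L] - m[2L]) - (m[3L] - m[4L])
  2^(-ddct)
}
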