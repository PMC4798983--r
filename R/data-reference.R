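#' Reference wild-type transition rates
#'
#' Mean maximum-likelihood transition rate constants for wild-type (N2)
#' worms during local search on a bare agar surface (mean over five cohorts
#' of 17-31 worms tracked for 10 min at ~30 Hz). These are the bundled
#' reference inputs for the closed-form worked examples: dwell times, steady
#' state, synaptic weights, run lengths and escape-motif limits are all
#' recomputed from them. Being cohort means of per-cohort fits, derived
#' quantities recomputed from them agree with reported per-cohort means only
#' approximately (of order 1%).
#'
#' @return An [rate_set()] object.
#' @examples
#' dwell_times(ss_reference_rates())
#' @export
ss_reference_rates <- function() {
  rate_set(aXR = 1.201, aXF = 1.115, aRX = 0.025, aRY = 0.490,
           aFX = 0.182, aFY = 0.007, aYR = 0.411, aYF = 4.575)
}

#' Reference post-ablation dwell times
#'
#' Mean dwell times in the reverse state (dR) and the long pause state (dX)
#' after laser ablation of each of the five command interneuron classes.
#' Used to bracket the uncoupled dwell time d0 and hence the fundamental
#' switching rate A via [infer_A_bounds()].
#'
#' @return A tibble with columns `ablation`, `dR`, `dX` (seconds).
#' @export
ss_reference_ablation_dwells <- function() {
  tibble(
    ablation = c("AVE", "AVD", "AVA", "AVB", "PVC"),
    dR = c(2.436, 2.367, 1.243, 1.681, 2.396),
    dX = c(0.548, 0.520, 0.582, 0.437, 0.508)
  )
}

#' Reference worked example for the likelihood-ratio test
#'
#' Log-likelihoods of an unconstrained two-cohort fit (12 free parameters)
#' and the fit with the mean pause dwell constrained equal across the two
#' cohorts (11 free parameters), from the AVA-ablation comparison. Used as a
#' worked-example input for [likelihood_ratio_test()].
#'
#' @return A list with `lnL_full`, `lnL_constrained`, `df_full`,
#'   `df_constrained`.
#' @export
ss_reference_lrt_example <- function() {
  list(lnL_full = 894794.075, lnL_constrained = 894784.676,
       df_full = 12L, df_constrained = 11L)
}
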