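#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats median optimize uniroot setNames rcauchy dcauchy runif
#'   rnorm pchisq approx qchisq sd
#' @importFrom utils head tail
#' @import tibble
NULL

# Fixed project-wide state order.
STATES  <- c("F", "R", "X", "Y")
RATE_NAMES <- c("aXF", "aXR", "aFX", "aRX", "aFY", "aRY", "aYF", "aYR")
WEIGHT_NAMES <- c("hF", "hR", "wFF", "wRR", "wFR", "wRF")

# Summed synaptic input is capped before exponentiation so that escape-motif
# limits saturate instead of overflowing.
S_CAP <- 700

#' Transition rate constants of the four-state switch
#'
#' Bundles the eight per-second rate constants of the four-state chain over
#' the locomotory states F (forward), R (reverse) and the two pause states X
#' (both command units off) and Y (both on). Direct F<->R and X<->Y
#' transitions are structurally absent.
#'
#' @param aXF,aXR,aFX,aRX,aFY,aRY,aYF,aYR Non-negative transition rates in
#'   1/s; `aij` is the rate of leaving state `i` for state `j`.
#' @return A named numeric vector of class `ss_rates`.
#' @examples
#' rate_set(aXF = 1.115, aXR = 1.201, aFX = 0.182, aRX = 0.025,
#'          aFY = 0.007, aRY = 0.490, aYF = 4.575, aYR = 0.411)
#' @export
rate_set <- function(aXF, aXR, aFX, aRX, aFY, aRY, aYF, aYR) {
  r <- c(aXF = aXF, aXR = aXR, aFX = aFX, aRX = aRX,
         aFY = aFY, aRY = aRY, aYF = aYF, aYR = aYR)
  validate_rates(r)
}

validate_rates <- function(r) {
  if (!is.numeric(r) || !all(RATE_NAMES %in% names(r))) {
    abort("rates must be a named numeric vector with the eight a_ij entries")
  }
  r <- r[RATE_NAMES]
  if (any(!is.finite(r))) abort("transition rates must be finite")
  if (any(r < 0)) abort("transition rates must be >= 0")
  structure(r, class = "ss_rates")
}

#' @export
print.ss_rates <- function(x, ...) {
  cat("<ss_rates> transition rates (1/s)\n")
  print(setNames(as.numeric(x), names(unclass(x))))
  invisible(x)
}

#' Synaptic weights of the stochastic flip-flop network
#'
#' The six dimensionless weights of the two-unit network (inputs `hF`, `hR`,
#' self-connections `wFF`, `wRR`, cross-connections `wFR`, `wRF`) together
#' with the fundamental switching rate `A` (Hz), the rate at which a unit
#' flips when its summed synaptic input is zero.
#'
#' @param hF,hR External input weights onto the forward and reverse units.
#' @param wFF,wRR Self-connection weights.
#' @param wFR,wRF Cross-connection weights (from F onto R and from R onto F).
#' @param A Fundamental switching rate in Hz; must be positive.
#' @return A list of class `ss_weights`.
#' @export
weight_set <- function(hF, hR, wFF, wRR, wFR, wRF, A = 1) {
  w <- list(hF = hF, hR = hR, wFF = wFF, wRR = wRR, wFR = wFR, wRF = wRF,
            A = A)
  if (!all(vapply(w, is.finite, logical(1)))) abort("weights must be finite")
  if (A <= 0) abort("A must be > 0")
  structure(w, class = "ss_weights")
}

#' @export
print.ss_weights <- function(x, ...) {
  cat("<ss_weights> A =", x$A, "Hz\n")
  print(unlist(x[WEIGHT_NAMES]))
  invisible(x)
}

cap_S <- function(s) pmin(pmax(s, -S_CAP), S_CAP)

#' Convert synaptic weights to transition rates
#'
#' Each unit flips ON at rate `A*exp(S)` and OFF at rate `A*exp(-S)`, where
#' `S` is its summed synaptic input in the current network state. Evaluating
#' the summed inputs in the four states gives the eight rate constants; the
#' result satisfies the two synaptic constraints
#' `aFX*aXF == aRY*aYR` and `aFY*aYF == aRX*aXR` identically.
#'
#' @param w An [weight_set()] object.
#' @return An [rate_set()] object.
#' @export
rates_from_weights <- function(w) {
  stopifnot(inherits(w, "ss_weights"))
  A <- w$A
  r <- c(
    aXF = A * exp(cap_S(w$hF)),
    aXR = A * exp(cap_S(w$hR)),
    aFX = A * exp(cap_S(-w$hF - w$wFF)),
    aRX = A * exp(cap_S(-w$hR - w$wRR)),
    aRY = A * exp(cap_S(w$hF + w$wRF)),
    aFY = A * exp(cap_S(w$hR + w$wFR)),
    aYR = A * exp(cap_S(-w$hF - w$wFF - w$wRF)),
    aYF = A * exp(cap_S(-w$hR - w$wRR - w$wFR))
  )
  validate_rates(r)
}

#' Constraint residuals of a rate set
#'
#' Relative residuals of the two products that must match for a rate set to
#' correspond to valid synaptic weights.
#'
#' @param rates An [rate_set()] object.
#' @return Numeric vector of two relative residuals.
#' @export
constraint_residuals <- function(rates) {
  r <- unclass(rates)
  c(FX = abs(r["aFX"] * r["aXF"] - r["aRY"] * r["aYR"]) /
      max(r["aFX"] * r["aXF"], r["aRY"] * r["aYR"], .Machine$double.xmin),
    RX = abs(r["aFY"] * r["aYF"] - r["aRX"] * r["aXR"]) /
      max(r["aFY"] * r["aYF"], r["aRX"] * r["aXR"], .Machine$double.xmin))
}

#' Convert transition rates to synaptic weights
#'
#' Inverts the synaptic parameterization at a stated fundamental rate `A`.
#' The cross-connection weights do not depend on `A`. Rates must satisfy the
#' synaptic constraints within `tol` (user-supplied rates are checked; rates
#' produced by [rates_from_weights()] or the constrained fit satisfy them by
#' construction).
#'
#' @param rates An [rate_set()] object with strictly positive entries.
#' @param A Fundamental switching rate in Hz.
#' @param tol Relative tolerance on the constraint residuals.
#' @return An [weight_set()] object.
#' @export
weights_from_rates <- function(rates, A, tol = 1e-6) {
  r <- unclass(validate_rates(rates))
  res <- constraint_residuals(rates)
  if (any(res > tol)) {
    abort(sprintf(
      "rates do not satisfy the synaptic constraints (residuals %.3g, %.3g)",
      res[1], res[2]))
  }
  needed <- c("aXF", "aXR", "aFX", "aRX", "aFY", "aRY")
  if (any(r[needed] == 0)) {
    warn("zero rate implies an infinite synaptic weight")
  }
  weight_set(
    hF  = log(r[["aXF"]]) - log(A),
    hR  = log(r[["aXR"]]) - log(A),
    wRF = log(r[["aRY"]] / r[["aXF"]]),
    wFR = log(r[["aFY"]] / r[["aXR"]]),
    wFF = -log(r[["aXF"]] * r[["aFX"]]) + 2 * log(A),
    wRR = -log(r[["aXR"]] * r[["aRX"]]) + 2 * log(A),
    A = A
  )
}

#' Complete six free rates into a constraint-satisfying rate set
#'
#' The fit treats `aXF, aXR, aFX, aRX, aFY, aRY` as free and recomputes the
#' two Y-exit rates from the synaptic constraints:
#' `aYR = aFX*aXF/aRY` and `aYF = aRX*aXR/aFY`.
#'
#' @param free Named numeric vector with the six free rates.
#' @return An [rate_set()] object satisfying the constraints exactly.
#' @export
complete_rates <- function(free) {
  need <- c("aXF", "aXR", "aFX", "aRX", "aFY", "aRY")
  stopifnot(all(need %in% names(free)))
  rate_set(aXF = free[["aXF"]], aXR = free[["aXR"]],
           aFX = free[["aFX"]], aRX = free[["aRX"]],
           aFY = free[["aFY"]], aRY = free[["aRY"]],
           aYR = free[["aFX"]] * free[["aXF"]] / free[["aRY"]],
           aYF = free[["aRX"]] * free[["aXR"]] / free[["aFY"]])
}

#' Dwell time of the fully uncoupled network
#'
#' With all six weights zero every transition occurs at rate `A`, each state
#' has two exits, and every mean dwell time equals `1/(2A)`.
#'
#' @param A Fundamental switching rate in Hz.
#' @return Uncoupled dwell time `d0` in seconds.
#' @export
uncoupled_dwell <- function(A) {
  stopifnot(A > 0)
  1 / (2 * A)
}

#' Infer bounds on the fundamental switching rate from ablation dwell times
#'
#' Ablating command neurons moves the network toward the uncoupled state, so
#' post-ablation dwell times bracket the uncoupled dwell `d0`: `d0` can be no
#' larger than the smallest post-ablation reverse dwell and no smaller than
#' the largest post-ablation X-pause dwell. Since `A = 1/(2 d0)`, the bracket
#' maps to bounds on `A`, reported rounded to two decimals.
#'
#' @param dwells A data frame with columns `dR` and `dX` (seconds), one row
#'   per ablation.
#' @return A tibble with `d0_min`, `d0_max`, `A_min`, `A_max`.
#' @examples
#' infer_A_bounds(ss_reference_ablation_dwells())
#' @export
infer_A_bounds <- function(dwells) {
  stopifnot(is.data.frame(dwells), nrow(dwells) > 0,
            all(c("dR", "dX") %in% names(dwells)))
  d0_min <- max(dwells$dX)
  d0_max <- min(dwells$dR)
  if (d0_min > d0_max) {
    abort("inconsistent dwell table: max dX exceeds min dR")
  }
  tibble(
    d0_min = round(d0_min, 2), d0_max = round(d0_max, 2),
    A_min = round(1 / (2 * d0_max), 2), A_max = round(1 / (2 * d0_min), 2)
  )
}

#' Perturb synaptic weights to emulate mutations
#'
#' `deltaV` shifts both input weights by `magnitude` (a change in tonic
#' membrane potential: hyperpolarizing mutants use negative shifts,
#' depolarizing positive). `deltaR` multiplies all six weights by
#' `magnitude` (a change in input resistance scales every postsynaptic
#' effect; hyperpolarizing-class scaling > 1, depolarizing < 1).
#'
#' @param w An [weight_set()] object.
#' @param mode `"deltaV"` or `"deltaR"`.
#' @param magnitude Shift in weight units (`deltaV`, `|magnitude| <= 1`) or
#'   positive scale factor (`deltaR`).
#' @return A perturbed [weight_set()].
#' @export
perturb_weights <- function(w, mode = c("deltaV", "deltaR"), magnitude) {
  stopifnot(inherits(w, "ss_weights"))
  mode <- match.arg(mode)
  if (mode == "deltaV") {
    if (abs(magnitude) > 1) abort("deltaV shift must satisfy |magnitude| <= 1")
    w$hF <- w$hF + magnitude
    w$hR <- w$hR + magnitude
  } else {
    if (magnitude <= 0) abort("deltaR scale factor must be > 0")
    for (nm in WEIGHT_NAMES) w[[nm]] <- w[[nm]] * magnitude
  }
  w
}

#' @export
tidy.ss_rates <- function(x, ...) {
  tibble(rate = names(unclass(x)), value = as.numeric(x))
}

#' @export
tidy.ss_weights <- function(x, ...) {
  tibble(weight = WEIGHT_NAMES, value = unlist(x[WEIGHT_NAMES]),
         A = x$A)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
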