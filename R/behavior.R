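#' Exit-fate probabilities of the four states
#'
#' For each state, the probability that the next transition is into each of
#' its possible successor states: rate over summed exit rates.
#'
#' @param rates An [rate_set()] object.
#' @return A tibble with `from`, `to`, `prob`; rows within a state sum
#'   to 1.
#' @export
fate_diagram <- function(rates) {
  Q <- build_Q(rates)
  rows <- lapply(STATES, function(s) {
    ex <- Q[s, setdiff(STATES, s)]
    tot <- sum(ex)
    tibble(from = s, to = names(ex),
           prob = if (tot > 0) as.numeric(ex) / tot else NA_real_)
  })
  dplyr::bind_rows(rows) |> dplyr::filter(.data$prob > 0 | is.na(.data$prob))
}

#' Mean run lengths and reversal frequency
#'
#' A forward run spans from one reverse-pause-forward (RPF) transition to
#' the next forward-pause-reverse (FPR) transition; the two transition
#' types strictly alternate, so their frequencies are equal. The FPR
#' frequency follows from the probability of being in F, the exit rates of
#' F and the exit-fate probabilities of the pause states; the mean forward
#' run length is the mean forward speed times the fraction of time forward
#' divided by the reorientation frequency (and likewise for reverse runs).
#' Both the exact expression and the simpler approximation valid when
#' direct F-to-Y transitions are negligible are reported; the two coincide
#' exactly when `aFY = 0`.
#'
#' @param rates An [rate_set()] object.
#' @param v_forward,v_reverse Mean speeds in the forward and reverse states
#'   (um/s, both positive).
#' @return A one-row tibble with `fFPR_per_min`, `mF_mm` (exact),
#'   `mF_approx_mm`, `mR_mm`, `pF`, `pR` and the classified search `mode`.
#'   An infinite run length is returned as `Inf` when the reorientation
#'   frequency is zero.
#' @export
run_lengths <- function(rates, v_forward = 200, v_reverse = 300) {
  stopifnot(v_forward > 0, v_reverse > 0)
  r <- unclass(validate_rates(rates))
  P <- steady_state(build_Q(rates))
  probXR <- r[["aXR"]] / (r[["aXF"]] + r[["aXR"]])
  probYR <- r[["aYR"]] / (r[["aYF"]] + r[["aYR"]])
  fFPR <- P[["F"]] * (r[["aFX"]] * probXR + r[["aFY"]] * probYR)
  if (fFPR <= 0) {
    warn("zero reorientation frequency: infinite run length")
    mF <- Inf; mF_approx <- Inf; mR <- Inf
  } else {
    mF <- v_forward * P[["F"]] / fFPR / 1000          # mm
    denom <- r[["aFX"]] * r[["aXR"]] * (r[["aYF"]] + r[["aYR"]]) +
      r[["aFY"]] * r[["aYR"]] * (r[["aXF"]] + r[["aXR"]])
    mF_exact <- v_forward * (r[["aXF"]] + r[["aXR"]]) *
      (r[["aYF"]] + r[["aYR"]]) / denom / 1000
    mF <- mF_exact
    mF_approx <- v_forward * (r[["aXF"]] + r[["aXR"]]) /
      (r[["aFX"]] * r[["aXR"]]) / 1000
    mR <- v_reverse * P[["R"]] / fFPR / 1000
  }
  tibble(fFPR_per_min = fFPR * 60, mF_mm = mF, mF_approx_mm = mF_approx,
         mR_mm = mR, pF = P[["F"]], pR = P[["R"]],
         mode = classify_mode(mF, fFPR * 60, mR))
}

#' Classify a point in run-length space into a search mode
#'
#' Cutoffs on mean forward run length, reversal frequency and mean reverse
#' run length define the three recognized modes of random search; any
#' combination outside the three boxes is indeterminate. Cropping (the
#' dwelling-dominated exploitation of a food patch) pairs short forward
#' runs with frequent short reversals; local search uses moderate runs and
#' reversal rates; ranging uses long runs and rare reversals.
#'
#' @param mF_mm Mean forward run length (mm).
#' @param fFPR_per_min Reversal frequency (1/min).
#' @param mR_mm Mean reverse run length (mm).
#' @return Factor with levels cropping, local_search, ranging,
#'   indeterminate (vectorized).
#' @export
classify_mode <- function(mF_mm, fFPR_per_min, mR_mm) {
  mode <- dplyr::case_when(
    !is.finite(mF_mm) | !is.finite(fFPR_per_min) | !is.finite(mR_mm) ~
      "indeterminate",
    mF_mm < 0.5 & fFPR_per_min > 6 & mR_mm < 0.5 ~ "cropping",
    mF_mm >= 0.5 & mF_mm < 5 & fFPR_per_min >= 2 & fFPR_per_min < 6 &
      mR_mm >= 0.5 ~ "local_search",
    mF_mm >= 5 & fFPR_per_min < 2 & mR_mm >= 0.5 ~ "ranging",
    TRUE ~ "indeterminate"
  )
  factor(mode, levels = c("cropping", "local_search", "ranging",
                          "indeterminate"))
}

#' Scan a synaptic-weight subspace for available search modes
#'
#' Holds the base weights fixed, scans 1-3 selected weights over a grid,
#' and evaluates run lengths and search mode at every grid point via the
#' synaptic parameterization. Overflow-saturated points come out
#' indeterminate.
#'
#' @param base An [weight_set()]: the wild-type operating point.
#' @param free_weights Character vector (1-3 of hF, hR, wFF, wRR, wFR,
#'   wRF).
#' @param from,to,by Grid limits and step in weight units.
#' @param A Fundamental switching rate (Hz); overrides `base$A` if given.
#' @param v_forward,v_reverse Speeds used for run-length classification.
#' @return A tibble of class `ss_scan`: one row per grid point with the
#'   scanned weight values, `mF_mm`, `mR_mm`, `fFPR_per_min`, `mode`.
#' @export
scan_subspace <- function(base, free_weights, from = -6, to = 6, by = 0.4,
                          A = NULL, v_forward = 200, v_reverse = 300) {
  stopifnot(inherits(base, "ss_weights"),
            length(free_weights) >= 1, length(free_weights) <= 3,
            all(free_weights %in% WEIGHT_NAMES))
  if (!is.null(A)) base$A <- A
  grid_vals <- seq(from, to, by = by)
  grid <- do.call(expand.grid,
                  setNames(rep(list(grid_vals), length(free_weights)),
                           free_weights))
  n <- nrow(grid)
  W <- matrix(rep(unlist(base[WEIGHT_NAMES]), each = n), nrow = n,
              dimnames = list(NULL, WEIGHT_NAMES))
  for (nm in free_weights) W[, nm] <- grid[[nm]]
  A_hz <- base$A
  ex <- function(s) A_hz * exp(cap_S(s))
  r <- cbind(
    aXF = ex(W[, "hF"]), aXR = ex(W[, "hR"]),
    aFX = ex(-W[, "hF"] - W[, "wFF"]), aRX = ex(-W[, "hR"] - W[, "wRR"]),
    aRY = ex(W[, "hF"] + W[, "wRF"]), aFY = ex(W[, "hR"] + W[, "wFR"]),
    aYR = ex(-W[, "hF"] - W[, "wFF"] - W[, "wRF"]),
    aYF = ex(-W[, "hR"] - W[, "wRR"] - W[, "wFR"]))
  P <- t(apply(r, 1, steady_state_raw))
  probXR <- r[, "aXR"] / (r[, "aXF"] + r[, "aXR"])
  probYR <- r[, "aYR"] / (r[, "aYF"] + r[, "aYR"])
  fFPR <- P[, 1] * (r[, "aFX"] * probXR + r[, "aFY"] * probYR)
  denom <- r[, "aFX"] * r[, "aXR"] * (r[, "aYF"] + r[, "aYR"]) +
    r[, "aFY"] * r[, "aYR"] * (r[, "aXF"] + r[, "aXR"])
  mF <- v_forward * (r[, "aXF"] + r[, "aXR"]) * (r[, "aYF"] + r[, "aYR"]) /
    denom / 1000
  mR <- v_reverse * P[, 2] / fFPR / 1000
  out <- dplyr::bind_cols(
    tibble::as_tibble(grid),
    tibble(mF_mm = mF, mR_mm = mR, fFPR_per_min = fFPR * 60,
           mode = classify_mode(mF, fFPR * 60, mR)))
  class(out) <- c("ss_scan", class(out))
  attr(out, "free_weights") <- free_weights
  attr(out, "A") <- base$A
  out
}

#' Summary of a subspace scan: mode availability and plane coverage
#'
#' Coverage is the occupancy fraction of a fixed 30 x 30 binning of the
#' (log10 mF, fFPR) plane over log10 mF in [-1.5, 1.5] (mm) and fFPR in
#' [0, 12] per minute.
#'
#' @param scan An `ss_scan` tibble.
#' @return A one-row tibble with logical columns `cropping`,
#'   `local_search`, `ranging` and numeric `coverage`.
#' @export
scan_summary <- function(scan) {
  modes <- unique(as.character(scan$mode))
  ok <- is.finite(scan$mF_mm) & scan$mF_mm > 0 &
    is.finite(scan$fFPR_per_min)
  lx <- log10(scan$mF_mm[ok])
  fy <- scan$fFPR_per_min[ok]
  inside <- lx >= -1.5 & lx <= 1.5 & fy >= 0 & fy <= 12
  ix <- pmin(pmax(ceiling((lx[inside] + 1.5) / 0.1), 1), 30)
  iy <- pmin(pmax(ceiling(fy[inside] / 0.4), 1), 30)
  cov <- length(unique(ix + 30 * (iy - 1))) / 900
  tibble(cropping = "cropping" %in% modes,
         local_search = "local_search" %in% modes,
         ranging = "ranging" %in% modes,
         coverage = cov)
}

#' @export
autoplot.ss_scan <- function(object, ...) {
  d <- dplyr::filter(object, is.finite(.data$mF_mm), .data$mF_mm > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mF_mm,
                                  y = .data$fFPR_per_min,
                                  colour = .data$mode)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean forward run length (mm)",
                  y = "reversal frequency (1/min)") +
    ggplot2::theme_minimal()
}

#' Limiting behavior of the escape-circuit motifs
#'
#' A strong nociceptive stimulus can excite the reverse unit (Push: input
#' weight hR driven to +Inf), inhibit the forward unit (Pull: hF driven to
#' -Inf), or both (Push-Pull). In the Push limit the chain inhabits only R
#' and Y and the reverse probability saturates at `aYR/(aYR + aRY)`; in
#' the Pull limit it inhabits R and X with `aXR/(aXR + aRX)`; combining
#' both makes R absorbing (`pR = 1`). The expected first latency to a
#' reversal from state F is computed by first-passage analysis on the
#' stimulated chain at a finite stimulus strength (exponentials saturate
#' at the overflow cap).
#'
#' @param rates Baseline (resting) [rate_set()].
#' @param motif `"push"`, `"pull"` or `"push_pull"`.
#' @param A Fundamental switching rate used to form weights (Hz).
#' @param stimulus Stimulus strength in weight units added to the driven
#'   input weight(s) for the latency computation.
#' @param tol Constraint tolerance passed to [weights_from_rates()]
#'   (cohort-mean rate tables satisfy the constraints only approximately).
#' @return A one-row tibble with `motif`, `pR_limit`, `latency_s` and the
#'   stimulus strength used.
#' @export
escape_limit <- function(rates, motif = c("push", "pull", "push_pull"),
                         A = 0.4, stimulus = 15, tol = 0.1) {
  motif <- match.arg(motif)
  r <- unclass(validate_rates(rates))
  pR_limit <- switch(motif,
    push = r[["aYR"]] / (r[["aYR"]] + r[["aRY"]]),
    pull = r[["aXR"]] / (r[["aXR"]] + r[["aRX"]]),
    push_pull = 1
  )
  w <- weights_from_rates(rates, A, tol = tol)
  if (motif %in% c("push", "push_pull")) w$hR <- w$hR + stimulus
  if (motif %in% c("pull", "push_pull")) w$hF <- w$hF - stimulus
  rs <- rates_from_weights(w)
  latency <- first_passage_to_R(rs)
  tibble(motif = motif, pR_limit = pR_limit, latency_s = latency,
         stimulus = stimulus)
}

# steady state from a named row of eight rates; NA on numerical failure
steady_state_raw <- function(r) {
  Q <- matrix(0, 4, 4)
  Q[1, 3] <- r[["aFX"]]; Q[1, 4] <- r[["aFY"]]
  Q[2, 3] <- r[["aRX"]]; Q[2, 4] <- r[["aRY"]]
  Q[3, 1] <- r[["aXF"]]; Q[3, 2] <- r[["aXR"]]
  Q[4, 1] <- r[["aYF"]]; Q[4, 2] <- r[["aYR"]]
  diag(Q) <- -rowSums(Q)
  Qs <- Q / max(abs(Q))
  Qa <- cbind(Qs, 1)
  p <- tryCatch(drop(rep(1, 4) %*% solve(Qa %*% t(Qa))),
                error = function(e) rep(NA_real_, 4))
  if (any(!is.finite(p)) || any(p < -1e-6)) return(rep(NA_real_, 4))
  p <- pmax(p, 0)
  p / sum(p)
}

# expected first-passage time from F to (absorbing) R
first_passage_to_R <- function(rates) {
  Q <- build_Q(rates)
  trans <- c("F", "X", "Y")
  Qt <- Q[trans, trans]
  t_exp <- tryCatch(solve(-Qt, rep(1, 3)), error = function(e) {
    rep(NA_real_, 3)
  })
  t_exp[1]
}
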