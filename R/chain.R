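#' Build the 4x4 rate matrix of the switch
#'
#' Off-diagonal entry (i, j) is the transition rate from state i to state j
#' in the fixed order F, R, X, Y; the F<->R and X<->Y entries are
#' structurally zero because the two command units flip independently, so
#' simultaneous double flips have probability zero. Rows sum to zero.
#'
#' @param rates An [rate_set()] object.
#' @return A 4x4 numeric matrix with dimnames F, R, X, Y.
#' @export
build_Q <- function(rates) {
  r <- unclass(validate_rates(rates))
  Q <- matrix(0, 4, 4, dimnames = list(STATES, STATES))
  Q["F", "X"] <- r[["aFX"]]; Q["F", "Y"] <- r[["aFY"]]
  Q["R", "X"] <- r[["aRX"]]; Q["R", "Y"] <- r[["aRY"]]
  Q["X", "F"] <- r[["aXF"]]; Q["X", "R"] <- r[["aXR"]]
  Q["Y", "F"] <- r[["aYF"]]; Q["Y", "R"] <- r[["aYR"]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Per-frame transition probability matrix by repeated squaring
#'
#' Converts instantaneous rates into the matrix of transition probabilities
#' over one video frame: `M = (eps*Q + I)^K` with `eps = dt/K` and
#' `K = 2^K_exponent`, computed by `K_exponent` serial squarings. With the
#' default `K = 2^30` and behavioural rates, `eps` is tens of picoseconds,
#' so multiple transitions within `eps` are safely ignored and the power is
#' an accurate matrix exponential of `Q*dt`.
#'
#' @param Q Rate matrix from [build_Q()] (any dimension; rows must sum to 0).
#' @param dt Frame duration in seconds.
#' @param K_exponent Base-2 exponent of the subdivision count (default 30).
#' @return A row-stochastic matrix of the same dimension as `Q`.
#' @export
frame_matrix <- function(Q, dt, K_exponent = 30) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q), dt > 0, K_exponent >= 1)
  if (max(abs(rowSums(Q))) > 1e-8 * max(abs(Q), 1)) {
    abort("Q rows must sum to zero")
  }
  # the default 2^30 subdivision keeps eps*max|q| tiny for behavioral
  # rates; effectively instantaneous rates (e.g. the one-pause variant's
  # Y bypass) need a finer subdivision for the power to converge
  qmax <- max(abs(diag(Q)), 1e-12)
  K_exponent <- max(K_exponent, ceiling(log2(dt * qmax / 0.01)))
  eps <- dt / 2^K_exponent
  # square M = I + E via E <- 2E + E^2: keeping the deviation from the
  # identity separate avoids swamping the O(eps) entries in early squarings
  E <- eps * Q
  for (i in seq_len(K_exponent)) E <- 2 * E + E %*% E
  M <- diag(nrow(Q)) + E
  M[M < 0] <- 0
  drift <- max(abs(rowSums(M) - 1))
  if (drift > 1e-12) {
    inform(sprintf("frame matrix row drift %.3g; renormalizing", drift))
    M <- M / rowSums(M)
  }
  M
}

#' Steady-state probabilities of the chain
#'
#' Solves `P*Q = 0` with the normalization `sum(P) = 1` by the
#' normal-equations form `P = U (Qa Qa^T)^-1`, where `Qa` appends a column
#' of ones to `Q`; falls back to a null-space (SVD) solve when the normal
#' equations are ill-conditioned, e.g. in saturated escape-motif limits.
#' For a reducible chain the result concentrates on the absorbing states and
#' a warning is raised.
#'
#' @param Q Rate matrix (rows sum to 0).
#' @return Named probability vector in state order.
#' @export
steady_state <- function(Q) {
  n <- nrow(Q)
  # scale invariance: P*Q = 0 is unchanged by Q/s; improves conditioning
  s <- max(abs(Q))
  if (s == 0) {
    warn("all rates zero; steady state undefined, returning uniform")
    return(setNames(rep(1 / n, n), rownames(Q)))
  }
  Qs <- Q / s
  Qa <- cbind(Qs, 1)
  G <- Qa %*% t(Qa)
  P <- tryCatch({
    p <- drop(rep(1, n) %*% solve(G))
    if (any(!is.finite(p)) || any(p < -1e-8)) stop("ill-conditioned")
    p
  }, error = function(e) {
    v <- svd(t(Qs))$v[, n]  # null vector of Q^T, i.e. left null vector of Q
    v <- abs(v)
    v / sum(v)
  })
  P <- pmax(P, 0)
  P <- P / sum(P)
  exit <- -diag(Q)
  if (any(exit == 0 & P > 1e-12)) {
    warn("chain is reducible; returning absorbing-state distribution")
  }
  setNames(P, rownames(Q))
}

#' Mean dwell times of the four states
#'
#' The mean dwell time in state i is the reciprocal of its summed exit
#' rates, `d_i = -1/q_ii`. A state with zero exit rate has infinite dwell.
#'
#' @param rates An [rate_set()] object.
#' @return Named numeric vector `dF, dR, dX, dY` in seconds.
#' @export
dwell_times <- function(rates) {
  Q <- build_Q(rates)
  exit <- -diag(Q)
  d <- ifelse(exit > 0, 1 / exit, Inf)
  if (any(!is.finite(d))) warn("zero exit rate: infinite dwell time flagged")
  setNames(d, paste0("d", STATES))
}

#' Relabel the pause states so that X has the higher steady-state probability
#'
#' X and Y share one emission density, so their labels are interchangeable
#' in the likelihood; the convention identifies X as the pause state with
#' higher steady-state probability. Swapping the labels exchanges the two
#' synaptic constraints, so a constraint-satisfying rate set stays valid.
#'
#' @param rates An [rate_set()] object.
#' @return An [rate_set()] with labels swapped if needed (attribute
#'   `relabelled` records whether a swap occurred).
#' @export
relabel_pauses <- function(rates) {
  P <- steady_state(build_Q(rates))
  if (P[["X"]] >= P[["Y"]]) {
    attr(rates, "relabelled") <- FALSE
    return(rates)
  }
  r <- unclass(rates)
  out <- rate_set(aXF = r[["aYF"]], aXR = r[["aYR"]],
                  aFX = r[["aFY"]], aRX = r[["aRY"]],
                  aFY = r[["aFX"]], aRY = r[["aRX"]],
                  aYF = r[["aXF"]], aYR = r[["aXR"]])
  attr(out, "relabelled") <- TRUE
  out
}

#' Closed-form summary of the chain
#'
#' @param rates An [rate_set()] object.
#' @param dt Frame duration in seconds.
#' @param K_exponent Squaring exponent for [frame_matrix()].
#' @return An object of class `ss_chain`: list with `Q`, `M`, `P_inf`,
#'   `dwell`, and the exit-fate table.
#' @export
chain_summary <- function(rates, dt = 1 / 29.97, K_exponent = 30) {
  Q <- build_Q(rates)
  structure(list(
    rates = rates,
    Q = Q,
    M = frame_matrix(Q, dt, K_exponent),
    P_inf = steady_state(Q),
    dwell = dwell_times(rates),
    fate = fate_diagram(rates),
    dt = dt
  ), class = "ss_chain")
}

#' @export
print.ss_chain <- function(x, ...) {
  cat("<ss_chain> four-state switch summary\n")
  cat("steady state:", paste(sprintf("%s=%.3f", STATES, x$P_inf),
                             collapse = " "), "\n")
  cat("dwell (s):   ", paste(sprintf("%s=%.3f", names(x$dwell), x$dwell),
                             collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.ss_chain <- function(x, ...) {
  tibble(state = STATES,
         p_inf = as.numeric(x$P_inf),
         dwell_s = as.numeric(x$dwell))
}
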