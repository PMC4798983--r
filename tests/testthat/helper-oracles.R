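# Independent oracles and shared small fixtures for the test suite.

# scaled Taylor-series matrix exponential (independent of frame_matrix's
# repeated-squaring construction)
expm_series <- function(A, scal = 16, terms = 30) {
  n <- nrow(A)
  B <- A / 2^scal
  S <- diag(n)
  Tm <- diag(n)
  for (k in seq_len(terms)) {
    Tm <- Tm %*% B / k
    S <- S + Tm
  }
  for (i in seq_len(scal)) S <- S %*% S
  S
}

# exhaustive path enumeration of the joint likelihood P(v_1..v_T):
# sum over all state paths of Pinf[s1] G[1,s1] * prod M[s_t-1,s_t] G[t,s_t]
enumerate_likelihood <- function(G, M, Pinf) {
  T_ <- nrow(G)
  n <- ncol(G)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), T_)))
  tot <- 0
  for (i in seq_len(nrow(paths))) {
    p <- Pinf[paths[i, 1]] * G[1, paths[i, 1]]
    if (T_ > 1) {
      for (t in 2:T_) {
        p <- p * M[paths[i, t - 1], paths[i, t]] * G[t, paths[i, t]]
      }
    }
    tot <- tot + p
  }
  tot
}

# exhaustive Viterbi: best path by joint probability, ties toward the path
# that is lexicographically smallest (lower state index earlier)
enumerate_viterbi <- function(G, M, Pinf) {
  T_ <- nrow(G)
  n <- ncol(G)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), T_)))
  best <- -Inf
  best_path <- NULL
  for (i in seq_len(nrow(paths))) {
    p <- log(Pinf[paths[i, 1]]) + log(G[1, paths[i, 1]])
    if (T_ > 1) {
      for (t in 2:T_) {
        p <- p + log(M[paths[i, t - 1], paths[i, t]]) +
          log(G[t, paths[i, t]])
      }
    }
    if (p > best + 1e-12) {
      best <- p
      best_path <- paths[i, ]
    }
  }
  best_path
}

# straight-line track builder
straight_track <- function(speed = 200, n = 300, dt = 1 / 29.97, sign = 1L,
                           angle = 0) {
  t <- (seq_len(n) - 1) * dt
  ss_track(time_s = t, x_um = speed * t * cos(angle),
           y_um = speed * t * sin(angle), sign = sign)
}

# a small shared fit, cached across tests to keep the suite fast
tiny_world <- local({
  cache <- new.env()
  function() {
    if (!is.null(cache$val)) return(cache$val)
    rates <- ss_reference_rates()
    em <- synthetic_emissions()
    v <- simulate_cohort(rates, em, n_worms = 3, minutes = 3, seed = 42)
    emf <- fit_emissions(v$v)
    cfg <- run_config(n_replicates = 2, rng_seed = 7)
    fit <- fit_rates(v, emf, cfg)
    cache$val <- list(rates = rates, em = em, v = v, emf = emf, cfg = cfg,
                      fit = fit)
    cache$val
  }
})

# wrap one or more tracks as a cohort (internal constructor)
as_cohort_for_test <- function(...) {
  stochswitch:::as_cohort(dplyr::bind_rows(list(...)))
}
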