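#' @useDynLib stochswitch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# run code with a private RNG stream, restoring the caller's afterwards
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# normalize velocity input to a numeric vector plus 0-based worm starts
velocity_input <- function(v) {
  if (inherits(v, "ss_velocity") || (is.data.frame(v) && "v" %in% names(v))) {
    ids <- if ("worm_id" %in% names(v)) v$worm_id else "worm1"
    runs <- rle(as.character(ids))
    starts <- cumsum(c(0L, head(runs$lengths, -1)))
    list(v = v$v, starts = as.integer(starts), worm_ids = runs$values)
  } else if (is.list(v)) {
    lens <- vapply(v, length, integer(1))
    list(v = unlist(v, use.names = FALSE),
         starts = as.integer(cumsum(c(0L, head(lens, -1)))),
         worm_ids = names(v) %||% paste0("worm", seq_along(v)))
  } else {
    list(v = as.numeric(v), starts = 0L, worm_ids = "worm1")
  }
}

# variant definitions: free rates and how to assemble the chain
variant_spec <- function(variant = c("A", "B", "C")) {
  variant <- match.arg(variant)
  switch(variant,
    A = list(
      variant = "A", n_states = 4, df = 6L,
      free = c("aXF", "aXR", "aFX", "aRX", "aFY", "aRY"),
      assemble = function(free) complete_rates(free),
      floor_rates = function(full) {
        unclass(full)[c("aXF", "aXR", "aFX", "aRX", "aFY", "aRY",
                        "aYF", "aYR")]
      }
    ),
    B = list(
      variant = "B", n_states = 4, df = 4L,
      free = c("aXF", "aXR", "aFX", "aRX"),
      assemble = function(free) {
        complete_rates(c(free, aFY = 1e-10, aRY = 1e-10))
      },
      floor_rates = function(full) {
        unclass(full)[c("aXF", "aXR", "aFX", "aRX")]
      }
    ),
    C = list(
      variant = "C", n_states = 3, df = 6L,
      free = c("aFR", "aFP", "aRF", "aRP", "aPF", "aPR"),
      assemble = function(free) free,
      floor_rates = function(full) full
    )
  )
}

build_Q_variant <- function(spec, rates) {
  if (spec$n_states == 4) return(build_Q(rates))
  Q <- matrix(0, 3, 3, dimnames = list(c("F", "R", "P"), c("F", "R", "P")))
  Q["F", "R"] <- rates[["aFR"]]; Q["F", "P"] <- rates[["aFP"]]
  Q["R", "F"] <- rates[["aRF"]]; Q["R", "P"] <- rates[["aRP"]]
  Q["P", "F"] <- rates[["aPF"]]; Q["P", "R"] <- rates[["aPR"]]
  diag(Q) <- -rowSums(Q)
  Q
}

emission_matrix_variant <- function(spec, em, v) {
  G <- emission_row(em, v)
  if (spec$n_states == 4) G else G[, c(1, 2, 3), drop = FALSE]
}

#' Bayes-filtered log-likelihood of a velocity trace
#'
#' Runs the scaled forward filter: each worm starts at the steady-state
#' probability vector, each frame multiplies by the per-frame transition
#' matrix and the emission row, and the log-likelihood accumulates the
#' pre-normalization inner products. The filter state is normalized every
#' frame so 18,000-frame traces do not underflow.
#'
#' @param v Velocities: an `ss_velocity` tibble, a list of per-worm numeric
#'   vectors, or one numeric vector.
#' @param rates An [rate_set()] object.
#' @param em An `ss_emissions` object.
#' @param dt Frame duration (s).
#' @param K_exponent Squaring exponent for [frame_matrix()].
#' @param posterior Also return per-frame filtered posteriors.
#' @return A list with `loglik`, `per_worm` (named vector) and, when
#'   requested, `posterior` (a tibble with worm_id, frame, pF..pY).
#' @export
filter_loglik <- function(v, rates, em, dt = 1 / 29.97, K_exponent = 30,
                          posterior = FALSE) {
  inp <- velocity_input(v)
  spec <- variant_spec("A")
  Q <- build_Q(rates)
  M <- frame_matrix(Q, dt, K_exponent)
  Pinf <- steady_state(Q)
  G <- emission_row(em, inp$v)
  ends <- c(inp$starts[-1], length(inp$v))
  per <- vapply(seq_along(inp$starts), function(i) {
    idx <- (inp$starts[i] + 1):ends[i]
    cpp_filter_loglik(G[idx, , drop = FALSE], 0L, M, Pinf)
  }, numeric(1))
  names(per) <- inp$worm_ids
  out <- list(loglik = sum(per), per_worm = per)
  if (posterior) {
    post <- lapply(seq_along(inp$starts), function(i) {
      idx <- (inp$starts[i] + 1):ends[i]
      p <- cpp_filter_posterior(G[idx, , drop = FALSE], M, Pinf)$posterior
      colnames(p) <- paste0("p", STATES)
      dplyr::bind_cols(tibble(worm_id = inp$worm_ids[i],
                              frame = seq_along(idx)),
                       tibble::as_tibble(p))
    })
    out$posterior <- dplyr::bind_rows(post)
  }
  out
}

# one random-search pass; returns free rates, loglik, iteration count, trace
random_search_pass <- function(free, loglik_fn, spec, b_init, b_grow,
                               b_shrink, b_stop, proposal_floor,
                               max_redraw = 100, trace_every = 50) {
  cur <- loglik_fn(free)
  b <- b_init
  iter <- 0L
  trace <- list()
  while (b >= b_stop) {
    iter <- iter + 1L
    prop <- NULL
    for (k in seq_len(max_redraw)) {
      cand <- free + rcauchy(length(free), 0, b)
      full <- tryCatch(spec$assemble(setNames(cand, names(free))),
                       error = function(e) NULL)
      if (!is.null(full) && all(spec$floor_rates(full) >= proposal_floor)) {
        prop <- cand
        break
      }
    }
    if (is.null(prop)) {
      b <- b * b_shrink
      next
    }
    ll <- loglik_fn(prop)
    if (is.finite(ll) && ll > cur) {
      free <- prop
      cur <- ll
      b <- b * b_grow
    } else {
      b <- b * b_shrink
    }
    if (iter %% trace_every == 0L) {
      trace[[length(trace) + 1L]] <- c(iter = iter, b_random = b,
                                       loglik = cur)
    }
  }
  tr <- if (length(trace)) {
    tibble::as_tibble(do.call(rbind, trace))
  } else {
    tibble(iter = integer(), b_random = numeric(), loglik = numeric())
  }
  list(free = free, loglik = cur, n_iter = iter, trace = tr)
}

#' Maximum-likelihood transition rates by constrained random optimization
#'
#' Fits the transition rate constants that maximize the filtered likelihood
#' of a cohort's velocity traces. Six of the eight rates are free; the two
#' Y-exit rates are recomputed from the synaptic constraints at every step,
#' so every visited rate set corresponds to valid synaptic weights. Initial
#' guesses are log-uniform on `init_range`; at each iteration every free
#' rate is perturbed by a Cauchy step of width `b_random` (proposals with
#' any rate below the floor are redrawn), `b_random` grows 3% on
#' improvement and shrinks 0.5% otherwise, and the pass ends when
#' `b_random` drops below the stop threshold. The best of `n_replicates`
#' starts is refined with a tighter stop threshold and a 1e-4 Hz rate
#' floor. The fit is deterministic given `config$rng_seed`.
#'
#' @param v Velocities (see [filter_loglik()]).
#' @param em An `ss_emissions` object (shared across the cohort).
#' @param config An [run_config()].
#' @param variant Model variant: `"A"` (two pause states, 6 free
#'   parameters), `"B"` (one pause state: rates into Y pinned at 1e-10,
#'   4 free), `"C"` (general 3-state forward/reverse/pause chain, 6 free,
#'   no synaptic constraints).
#' @param decode Also Viterbi-decode each worm (variant A/B only).
#' @return An object of class `ss_fit`.
#' @export
fit_rates <- function(v, em, config = run_config(), variant = "A",
                      decode = FALSE) {
  spec <- variant_spec(variant)
  inp <- velocity_input(v)
  dt <- (attr(v, "dt") %||% NULL)
  if (is.null(dt)) dt <- 1 / config$frame_rate
  G <- emission_matrix_variant(spec, em, inp$v)
  starts <- inp$starts

  loglik_fn <- function(free) {
    full <- spec$assemble(setNames(free, spec$free))
    Q <- build_Q_variant(spec, full)
    M <- frame_matrix(Q, dt, config$K_exponent)
    Pinf <- steady_state(Q)
    cpp_filter_loglik(G, starts, M, Pinf)
  }

  fit <- with_local_seed(config$rng_seed, {
    reps <- lapply(seq_len(config$n_replicates), function(i) {
      init <- exp(runif(length(spec$free), log(config$init_range[1]),
                        log(config$init_range[2])))
      random_search_pass(setNames(init, spec$free), loglik_fn, spec,
                         config$b_random_init, config$b_grow,
                         config$b_shrink, config$b_stop,
                         config$proposal_floor)
    })
    lls <- vapply(reps, `[[`, numeric(1), "loglik")
    best <- reps[[which.max(lls)]]
    refined <- random_search_pass(best$free, loglik_fn, spec,
                                  config$b_random_init, config$b_grow,
                                  config$b_shrink, config$b_stop_refine,
                                  config$rate_floor_refine)
    list(reps = reps, refined = refined)
  })

  lls <- vapply(fit$reps, `[[`, numeric(1), "loglik")
  best_free <- fit$refined$free
  # fraction of replicates whose rates all sit within 5% of the best set
  agree <- mean(vapply(fit$reps, function(r) {
    all(abs(r$free - best_free) <= 0.05 * pmax(abs(best_free), 1e-12))
  }, logical(1)))

  full <- spec$assemble(setNames(best_free, spec$free))
  if (spec$n_states == 4) full <- relabel_pauses(full)
  loglik <- loglik_fn(if (spec$n_states == 4) {
    unclass(full)[spec$free]
  } else full[spec$free])

  Q <- build_Q_variant(spec, full)
  Pinf <- steady_state(Q)
  per_worm <- filter_variant_per_worm(spec, G, starts, inp, Q, dt, config)

  out <- structure(list(
    rates = full,
    loglik = loglik,
    per_worm_loglik = per_worm,
    df = spec$df,
    variant = spec$variant,
    n_frames = length(inp$v),
    n_worms = length(starts),
    replicates = tibble(replicate = seq_along(lls), loglik = lls,
                        n_iter = vapply(fit$reps, `[[`, integer(1),
                                        "n_iter")),
    replicate_agreement = agree,
    refine_trace = fit$refined$trace,
    chain = if (spec$n_states == 4) {
      chain_summary(full, dt, config$K_exponent)
    } else NULL,
    config = config,
    dt = dt,
    emissions = em
  ), class = "ss_fit")
  if (decode && spec$n_states == 4) {
    out$decoded <- viterbi(v, full, em, dt = dt,
                           K_exponent = config$K_exponent)
  }
  out
}

filter_variant_per_worm <- function(spec, G, starts, inp, Q, dt, config) {
  M <- frame_matrix(Q, dt, config$K_exponent)
  Pinf <- steady_state(Q)
  ends <- c(starts[-1], nrow(G))
  per <- vapply(seq_along(starts), function(i) {
    idx <- (starts[i] + 1):ends[i]
    cpp_filter_loglik(G[idx, , drop = FALSE], 0L, M, Pinf)
  }, numeric(1))
  setNames(per, inp$worm_ids)
}

#' @export
print.ss_fit <- function(x, ...) {
  cat(sprintf("<ss_fit> variant %s: lnL = %.3f (%d worms, %d frames)\n",
              x$variant, x$loglik, x$n_worms, x$n_frames))
  if (inherits(x$rates, "ss_rates")) print(x$rates)
  invisible(x)
}

#' @export
tidy.ss_fit <- function(x, ...) {
  if (inherits(x$rates, "ss_rates")) {
    tidy(x$rates)
  } else {
    tibble(rate = names(x$rates), value = as.numeric(x$rates))
  }
}

#' @export
glance.ss_fit <- function(x, ...) {
  tibble(variant = x$variant, loglik = x$loglik, df = x$df,
         n_worms = x$n_worms, n_frames = x$n_frames,
         replicate_agreement = x$replicate_agreement)
}

#' Most likely state sequence by Viterbi decoding
#'
#' @inheritParams filter_loglik
#' @return A tibble of class `ss_states` with `worm_id`, `frame`, `v`,
#'   `state` (factor F/R/X/Y). Ties break toward the earlier state in the
#'   fixed order.
#' @export
viterbi <- function(v, rates, em, dt = 1 / 29.97, K_exponent = 30) {
  inp <- velocity_input(v)
  Q <- build_Q(rates)
  M <- frame_matrix(Q, dt, K_exponent)
  Pinf <- steady_state(Q)
  G <- emission_row(em, inp$v)
  logM <- log(pmax(M, 1e-300))
  logPinf <- log(pmax(Pinf, 1e-300))
  ends <- c(inp$starts[-1], length(inp$v))
  rows <- lapply(seq_along(inp$starts), function(i) {
    idx <- (inp$starts[i] + 1):ends[i]
    path <- cpp_viterbi(log(G[idx, , drop = FALSE]), logM, logPinf)
    tibble(worm_id = inp$worm_ids[i], frame = seq_along(idx),
           v = inp$v[idx],
           state = factor(STATES[path], levels = STATES))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ss_states", class(out))
  attr(out, "dt") <- dt
  out
}

#' Smoothed state probabilities by the Forward-Backward algorithm
#'
#' @inheritParams filter_loglik
#' @return A tibble with `worm_id`, `frame`, `v` and posterior columns
#'   `pF`, `pR`, `pX`, `pY` conditioned on the entire trace.
#' @export
forward_backward <- function(v, rates, em, dt = 1 / 29.97,
                             K_exponent = 30) {
  inp <- velocity_input(v)
  Q <- build_Q(rates)
  M <- frame_matrix(Q, dt, K_exponent)
  Pinf <- steady_state(Q)
  G <- emission_row(em, inp$v)
  ends <- c(inp$starts[-1], length(inp$v))
  rows <- lapply(seq_along(inp$starts), function(i) {
    idx <- (inp$starts[i] + 1):ends[i]
    p <- cpp_forward_backward(G[idx, , drop = FALSE], M, Pinf)
    colnames(p) <- paste0("p", STATES)
    dplyr::bind_cols(tibble(worm_id = inp$worm_ids[i],
                            frame = seq_along(idx), v = inp$v[idx]),
                     tibble::as_tibble(p))
  })
  dplyr::bind_rows(rows)
}

#' Run-length segmentation of a decoded state sequence
#'
#' @param decoded An `ss_states` tibble from [viterbi()].
#' @return A tibble with one row per visit: `worm_id`, `state`,
#'   `start_frame`, `n_frames`, `duration_s`. The segments tile each trace
#'   exactly.
#' @export
state_segments <- function(decoded) {
  dt <- attr(decoded, "dt") %||% (1 / 29.97)
  decoded |>
    dplyr::group_by(.data$worm_id) |>
    dplyr::group_modify(function(g, key) {
      r <- rle(as.character(g$state))
      tibble(state = factor(r$values, levels = STATES),
             start_frame = cumsum(c(1L, head(r$lengths, -1))),
             n_frames = r$lengths,
             duration_s = r$lengths * dt)
    }) |>
    dplyr::ungroup()
}

#' Likelihood-ratio test for nested model fits
#'
#' `D = 2*(lnL_full - lnL_constrained)` referred to a chi-squared
#' distribution with `df_full - df_constrained` degrees of freedom.
#'
#' @param lnL_full,lnL_constrained Log-likelihoods of the nested fits.
#' @param df_full,df_constrained Free-parameter counts.
#' @param tol Tolerance for a slightly negative D from optimizer noise.
#' @return A one-row tibble with `D`, `df`, `p` (unrounded).
#' @export
likelihood_ratio_test <- function(lnL_full, lnL_constrained, df_full,
                                  df_constrained, tol = 1e-6) {
  D <- 2 * (lnL_full - lnL_constrained)
  if (D < -tol * max(abs(lnL_full), 1)) {
    abort("constrained fit beats full fit: models not nested or fit failed")
  }
  D <- max(D, 0)
  df <- df_full - df_constrained
  if (df <= 0) abort("full model must have more free parameters")
  tibble(D = D, df = df, p = pchisq(D, df, lower.tail = FALSE))
}

#' Fit and compare the standard, one-pause and general 3-state models
#'
#' Fits each requested variant with the same optimizer and data and reports
#' log-likelihoods and free-parameter counts, plus the likelihood-ratio
#' test of the two-pause model against the nested one-pause model.
#'
#' @inheritParams fit_rates
#' @param variants Subset of `c("A", "B", "C")`.
#' @return A list with `fits` (named list of `ss_fit`), `table` (tibble of
#'   variant, loglik, df) and, when A and B are both fitted, `lrt`.
#' @export
compare_models <- function(v, em, config = run_config(),
                           variants = c("A", "B", "C")) {
  fits <- lapply(setNames(variants, variants), function(vt) {
    cfg <- config
    cfg$rng_seed <- config$rng_seed + match(vt, c("A", "B", "C"))
    fit_rates(v, em, cfg, variant = vt)
  })
  tab <- dplyr::bind_rows(lapply(fits, glance))
  out <- list(fits = fits, table = tab)
  if (all(c("A", "B") %in% variants)) {
    out$lrt <- likelihood_ratio_test(fits$A$loglik, fits$B$loglik,
                                     fits$A$df, fits$B$df)
  }
  out
}

#' @export
autoplot.ss_states <- function(object, ...) {
  dt <- attr(object, "dt") %||% (1 / 29.97)
  d <- dplyr::mutate(object, time_s = (.data$frame - 1) * dt)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$v,
                                  colour = .data$state)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::facet_wrap(~worm_id, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "tangential velocity (um/s)") +
    ggplot2::theme_minimal()
}
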