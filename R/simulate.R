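#' Simulate a state sequence from the four-state chain
#'
#' The initial state is drawn from the steady-state distribution (unless
#' given) and each subsequent frame is drawn from the current row of the
#' per-frame transition matrix.
#'
#' @param rates An [rate_set()] object.
#' @param n_frames Number of frames.
#' @param dt Frame duration (s).
#' @param seed Optional integer seed (uses a private RNG stream when
#'   given).
#' @param init Optional initial state ("F", "R", "X" or "Y").
#' @param K_exponent Squaring exponent for [frame_matrix()].
#' @return Factor vector of states with levels F, R, X, Y.
#' @export
simulate_states <- function(rates, n_frames, dt = 1 / 29.97, seed = NULL,
                            init = NULL, K_exponent = 30) {
  Q <- build_Q(rates)
  M <- frame_matrix(Q, dt, K_exponent)
  Pinf <- steady_state(Q)
  draw <- function() {
    s0 <- if (is.null(init)) {
      sample.int(4, 1, prob = Pinf)
    } else match(init, STATES)
    cpp_simulate_states(M, n_frames, s0, runif(n_frames - 1))
  }
  path <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  factor(STATES[path], levels = STATES)
}

#' Draw per-frame velocities for a state sequence
#'
#' Velocities are drawn independently per frame from the state's emission
#' density: positive support in F, negative in R, the central Cauchy in the
#' pause states.
#'
#' @param states Factor/character vector of states.
#' @param em An `ss_emissions` object.
#' @param seed Optional integer seed.
#' @return A tibble with `frame`, `state`, `v` carrying the ground-truth
#'   states alongside the observations.
#' @export
simulate_velocity <- function(states, em, seed = NULL) {
  draw <- function() sample_emission(em, as.character(states))
  v <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  tibble(frame = seq_along(states),
         state = factor(as.character(states), levels = STATES), v = v)
}

#' Simulate a cohort of velocity traces with ground truth
#'
#' The standard synthetic cohort for parameter-recovery experiments:
#' per-worm state sequences from the chain and per-frame velocities from
#' the emission model.
#'
#' @param rates An [rate_set()] object (the generating truth).
#' @param em An `ss_emissions` object (the generating truth).
#' @param n_worms Number of worms.
#' @param minutes Recording duration per worm.
#' @param frame_rate Frames per second.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return An `ss_velocity` tibble with `worm_id`, `frame`, `v` and the
#'   ground-truth `state` column; attributes `dt`, `rates`, `emissions`.
#' @export
simulate_cohort <- function(rates, em, n_worms = 5, minutes = 10,
                            frame_rate = 29.97, seed = 1) {
  dt <- 1 / frame_rate
  n_frames <- round(minutes * 60 * frame_rate)
  out <- with_local_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_worms), function(w) {
      st <- simulate_states(rates, n_frames, dt)
      vel <- simulate_velocity(st, em)
      dplyr::bind_cols(tibble(worm_id = sprintf("worm%02d", w)), vel)
    }))
  })
  class(out) <- c("ss_velocity", class(tibble()))
  attr(out, "dt") <- dt
  attr(out, "rates") <- rates
  attr(out, "emissions") <- em
  out
}

#' Specification of a point-worm simulation
#'
#' The stated world of the point-worm: constant crawl speeds of 200 um/s
#' forward and 300 um/s backward, stationary pauses, a uniformly redrawn
#' heading at every reverse-pause-forward transition, and per-frame
#' Gaussian heading jitter with the (very small) default standard
#' deviation of 0.001 degrees.
#'
#' @param rates An [rate_set()], or `NULL` if `weights` given.
#' @param weights Optional [weight_set()] used to build the rates.
#' @param n_worms,minutes,frame_rate Cohort geometry.
#' @param v_forward,v_reverse Crawl speeds (um/s, positive).
#' @param heading_noise_sd_deg Per-frame heading jitter (degrees).
#' @param emission Velocity observation mode: `"constant-speed"` uses the
#'   point-worm speeds; `"draw"` samples from `em`.
#' @param em Emission model when `emission = "draw"`.
#' @param seed Integer seed.
#' @return A list of class `ss_simspec`.
#' @export
simulation_spec <- function(rates = NULL, weights = NULL, n_worms = 1,
                            minutes = 10, frame_rate = 29.97,
                            v_forward = 200, v_reverse = 300,
                            heading_noise_sd_deg = 0.001,
                            emission = c("constant-speed", "draw"),
                            em = NULL, seed = 1) {
  if (is.null(rates)) {
    if (is.null(weights)) abort("supply rates or weights")
    rates <- rates_from_weights(weights)
  }
  stopifnot(v_forward > 0, v_reverse > 0, minutes > 0, n_worms >= 1)
  structure(list(rates = rates, n_worms = n_worms, minutes = minutes,
                 frame_rate = frame_rate, v_forward = v_forward,
                 v_reverse = v_reverse,
                 heading_noise_sd_deg = heading_noise_sd_deg,
                 emission = match.arg(emission), em = em,
                 seed = as.integer(seed)),
            class = "ss_simspec")
}

simulate_one_track <- function(spec, worm_id, gradient = NULL,
                               kappa = 0, base_weights = NULL) {
  dt <- 1 / spec$frame_rate
  n <- round(spec$minutes * 60 * spec$frame_rate)
  noise_sd <- spec$heading_noise_sd_deg * pi / 180
  chemo <- !is.null(gradient) && kappa != 0
  if (chemo && is.null(base_weights)) {
    abort("chemotaxis requires base weights")
  }
  Q <- build_Q(spec$rates)
  M <- frame_matrix(Q, dt)
  Pinf <- steady_state(Q)

  if (!chemo) {
    s0 <- sample.int(4, 1, prob = Pinf)
    st <- cpp_simulate_states(M, n, s0, runif(n - 1))
  } else {
    st <- integer(n)
    st[1] <- sample.int(4, 1, prob = Pinf)
  }
  x <- numeric(n); y <- numeric(n)
  heading <- runif(1, 0, 2 * pi)
  last_move <- 0L    # 1 = F, 2 = R
  reorient <- logical(n)
  hF0 <- if (chemo) base_weights$hF else NA_real_
  hR0 <- if (chemo) base_weights$hR else NA_real_
  w <- base_weights
  dC <- 0

  for (t in 2:n) {
    if (chemo) {
      w$hF <- hF0 + kappa * dC
      w$hR <- hR0 - kappa * dC
      Mt <- frame_matrix(build_Q(rates_from_weights(w)), dt)
      st[t] <- cpp_simulate_states(Mt, 2L, st[t - 1], runif(1))[2]
    } else {
      st[t] <- st[t]   # already drawn
    }
    s_now <- st[t]
    if (s_now == 1L) {           # F
      if (last_move == 2L) {     # RPF transition: random reorientation
        heading <- runif(1, 0, 2 * pi)
        reorient[t] <- TRUE
      }
      last_move <- 1L
      speed <- spec$v_forward
    } else if (s_now == 2L) {    # R: retrace along the heading
      last_move <- 2L
      speed <- -spec$v_reverse
    } else {
      speed <- 0
    }
    heading <- heading + rnorm(1, 0, noise_sd)
    x[t] <- x[t - 1] + dt * speed * cos(heading)
    y[t] <- y[t - 1] + dt * speed * sin(heading)
    if (chemo) {
      C_prev <- gradient(x[t - 1], y[t - 1])
      dC <- (gradient(x[t], y[t]) - C_prev) / dt
    }
  }
  sign <- ifelse(st == 1L, 1L, ifelse(st == 2L, -1L, NA_integer_))
  sign <- zoo_locf(sign, default = 1L)
  track <- ss_track(time_s = (seq_len(n) - 1) * dt, x_um = x, y_um = y,
                    sign = sign, worm_id = worm_id)
  attr(track, "truth") <- tibble(
    frame = seq_len(n), state = factor(STATES[st], levels = STATES),
    reorientation = reorient)
  track
}

# last-observation-carried-forward for integer vectors
zoo_locf <- function(x, default) {
  idx <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
  out <- ifelse(idx > 0, x[pmax(idx, 1L)], default)
  as.integer(out)
}

#' Simulate point-worm tracks
#'
#' Integrates the position of a point worm: forward motion at `v_forward`
#' along the current heading, reverse motion retracing the heading at
#' `v_reverse`, stationary pauses, a uniform random heading after every
#' reverse-pause-forward transition, and Gaussian per-frame heading
#' jitter. Ground-truth states and reorientation events ride along as a
#' `truth` attribute on each track.
#'
#' @param spec An [simulation_spec()].
#' @return An `ss_cohort` tibble; `attr(cohort, "truth")` holds the
#'   per-worm ground truth tibble.
#' @export
simulate_track <- function(spec) {
  stopifnot(inherits(spec, "ss_simspec"))
  tracks <- with_local_seed(spec$seed, {
    lapply(seq_len(spec$n_worms), function(wi) {
      simulate_one_track(spec, sprintf("worm%02d", wi))
    })
  })
  truth <- dplyr::bind_rows(lapply(tracks, function(tr) {
    dplyr::bind_cols(tibble(worm_id = tr$worm_id[1]), attr(tr, "truth"))
  }))
  out <- as_cohort(dplyr::bind_rows(tracks), label = "simulated")
  attr(out, "truth") <- truth
  attr(out, "rates") <- spec$rates
  out
}

#' Simulate a biased random walk in an attractant gradient
#'
#' Chemosensory coupling: at every frame the input weights are shifted in
#' proportion to the temporal concentration change experienced along the
#' track (`hF` up and `hR` down when climbing the gradient), the rates and
#' per-frame transition matrix are rebuilt, and the state advances under
#' the updated chain. With `kappa = 0` the walk reduces exactly to
#' [simulate_track()] statistics.
#'
#' @param spec An [simulation_spec()].
#' @param kappa Coupling strength: weight units per unit (dC/dt).
#' @param gradient Function of (x, y) in um returning attractant
#'   concentration; default is a Gaussian peak of width 5 mm centred at
#'   `peak_um`.
#' @param peak_um Coordinates of the default peak.
#' @param A Fundamental rate used to express the baseline rates as
#'   weights.
#' @param tol Constraint tolerance passed to [weights_from_rates()].
#' @return An `ss_cohort` tibble with ground truth, as
#'   [simulate_track()].
#' @export
simulate_chemotaxis <- function(spec, kappa, gradient = NULL,
                                peak_um = c(5000, 0), A = 0.4, tol = 0.1) {
  stopifnot(inherits(spec, "ss_simspec"))
  if (is.null(gradient)) {
    gradient <- function(x, y) {
      exp(-((x - peak_um[1])^2 + (y - peak_um[2])^2) / (2 * 5000^2))
    }
  }
  base_w <- weights_from_rates(spec$rates, A, tol = tol)
  tracks <- with_local_seed(spec$seed, {
    lapply(seq_len(spec$n_worms), function(wi) {
      simulate_one_track(spec, sprintf("worm%02d", wi),
                         gradient = gradient, kappa = kappa,
                         base_weights = base_w)
    })
  })
  truth <- dplyr::bind_rows(lapply(tracks, function(tr) {
    dplyr::bind_cols(tibble(worm_id = tr$worm_id[1]), attr(tr, "truth"))
  }))
  out <- as_cohort(dplyr::bind_rows(tracks), label = "chemotaxis")
  attr(out, "truth") <- truth
  attr(out, "rates") <- spec$rates
  out
}
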