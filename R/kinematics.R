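# centered moving average with shrinking windows at the edges
running_mean <- function(x, k) {
  stopifnot(k >= 1, k %% 2 == 1)
  half <- (k - 1) / 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Per-frame velocity, heading and speed
#'
#' Forward-difference velocity `V(t_k) = (R(t_k+1) - R(t_k))/dt`, speed
#' `s = |V|` and unit heading `H = V/s`. Where the speed is zero the heading
#' is undefined; it is carried forward from the last defined heading for
#' autocorrelation purposes and flagged in `heading_defined`.
#'
#' @param track An [ss_track()].
#' @return A tibble with `time_s`, `vx`, `vy`, `speed`, `hx`, `hy`,
#'   `heading_defined`; one row fewer than the track has frames.
#' @export
velocity_and_heading <- function(track) {
  dt <- track_dt(track)
  n <- nrow(track)
  vx <- diff(track$x_um) / dt
  vy <- diff(track$y_um) / dt
  s <- sqrt(vx^2 + vy^2)
  hx <- ifelse(s > 0, vx / s, NA_real_)
  hy <- ifelse(s > 0, vy / s, NA_real_)
  defined <- s > 0
  # carry the last defined heading through zero-speed frames
  idx <- cummax(ifelse(defined, seq_along(s), 0L))
  has <- idx > 0
  hx[has] <- hx[idx[has]]
  hy[has] <- hy[idx[has]]
  tibble(time_s = track$time_s[-n], vx = vx, vy = vy, speed = s,
         hx = hx, hy = hy, heading_defined = defined)
}

#' Signed tangential velocity of a track
#'
#' The observation sequence of the hidden Markov model. The raw positions
#' are smoothed with a centered moving average (default 11 frames,
#' shrinking at the edges), the frame-difference velocity is projected onto
#' the local tangent of the smoothed track, and the head/tail direction
#' sign makes forward motion positive and reverse motion negative. The
#' result is invariant under rotation and translation of the track.
#'
#' @param track An [ss_track()] whose `sign` column is fully resolved
#'   (no zeros).
#' @param window Smoothing window in frames (odd, >= 1).
#' @return A tibble of class `ss_velocity` with `worm_id`, `time_s`, `v`
#'   (um/s); one row fewer than the track has frames.
#' @export
tangential_velocity <- function(track, window = 11) {
  if (any(track$sign == 0L)) {
    abort("track has unresolved direction signs (0); resolve before fitting")
  }
  dt <- track_dt(track)
  n <- nrow(track)
  xs <- running_mean(track$x_um, window)
  ys <- running_mean(track$y_um, window)
  tx <- diff(xs); ty <- diff(ys)
  len <- sqrt(tx^2 + ty^2)
  ok <- len > 0
  tx <- ifelse(ok, tx / len, NA_real_)
  ty <- ifelse(ok, ty / len, NA_real_)
  idx <- cummax(ifelse(ok, seq_along(tx), 0L))
  has <- idx > 0
  tx[has] <- tx[idx[has]]; ty[has] <- ty[idx[has]]
  tx[!has] <- 1; ty[!has] <- 0   # fully stationary so far: arbitrary tangent
  vx <- diff(track$x_um) / dt
  vy <- diff(track$y_um) / dt
  v <- track$sign[-n] * (vx * tx + vy * ty)
  out <- tibble(worm_id = track$worm_id[-n], time_s = track$time_s[-n],
                v = v)
  class(out) <- c("ss_velocity", class(out))
  attr(out, "dt") <- dt
  out
}

#' Tangential velocities for a whole cohort
#'
#' @param cohort An `ss_cohort` tibble.
#' @param window Smoothing window in frames.
#' @return An `ss_velocity` tibble covering all worms.
#' @export
cohort_velocities <- function(cohort, window = 11) {
  out <- dplyr::bind_rows(lapply(cohort_tracks(cohort), tangential_velocity,
                                 window = window))
  class(out) <- c("ss_velocity", class(tibble()))
  attr(out, "dt") <- attr(cohort, "dt")
  out
}

#' @export
autoplot.ss_velocity <- function(object, binwidth = 10, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$v)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth) +
    ggplot2::labs(x = "tangential velocity (um/s)", y = "density") +
    ggplot2::theme_minimal()
}

worm_lag_stats <- function(track, max_lag_frames) {
  vh <- velocity_and_heading(track)
  n <- nrow(vh)                 # number of velocity frames = N - 1
  N <- nrow(track)
  s <- vh$speed
  sbar <- mean(s)
  J <- min(max_lag_frames, n - 2)
  dt <- track_dt(track)
  H <- cbind(vh$hx, vh$hy)
  V <- cbind(vh$vx, vh$vy)
  R <- cbind(track$x_um, track$y_um)
  res <- lapply(0:J, function(j) {
    k <- seq_len(N - j - 1)
    dot <- rowSums(H[k + j, , drop = FALSE] * H[k, , drop = FALSE])
    dot <- pmin(pmax(dot, -1), 1)
    dR <- R[k + j, , drop = FALSE] - R[k, , drop = FALSE]
    c(lag_s = j * dt,
      mean_heading_change = mean(acos(dot)),
      A_s = mean((s[k + j] - sbar) * (s[k] - sbar)),
      A_V = mean(rowSums(V[k + j, , drop = FALSE] * V[k, , drop = FALSE])),
      A_H = mean(dot),
      msd = mean(rowSums(dR^2)))
  })
  out <- tibble::as_tibble(do.call(rbind, res))
  out$worm_id <- track$worm_id[1]
  attr(out, "mean_speed") <- sbar
  out
}

#' Model-independent kinematic summary of a cohort
#'
#' Lag-indexed descriptive statistics averaged over the worms of a cohort:
#' mean absolute heading change, speed autocovariance, velocity and heading
#' autocorrelation, and mean squared displacement, plus the cohort mean
#' speed and the pooled speed histogram. Each per-worm statistic at lag
#' `t_j` averages products of frames `k` and `k + j` over
#' `k = 1 .. N - j - 1`.
#'
#' @param cohort An `ss_cohort` tibble.
#' @param max_lag_s Largest lag, in seconds; truncated with a warning if it
#'   exceeds the track length.
#' @return A list of class `ss_kinematics` with elements `lags` (tibble of
#'   lag-indexed statistics averaged over worms), `per_worm`, `mean_speed`
#'   (um/s) and `speed_hist`.
#' @export
kinematics_summary <- function(cohort, max_lag_s = 30) {
  dt <- attr(cohort, "dt")
  tracks <- cohort_tracks(cohort)
  max_frames <- min(vapply(tracks, nrow, integer(1))) - 2L
  J <- floor(max_lag_s / dt)
  if (J > max_frames) {
    warn("max_lag exceeds track length; truncating")
    J <- max_frames
  }
  per_worm <- dplyr::bind_rows(lapply(tracks, worm_lag_stats,
                                      max_lag_frames = J))
  lags <- per_worm |>
    dplyr::group_by(.data$lag_s) |>
    dplyr::summarise(dplyr::across(
      c("mean_heading_change", "A_s", "A_V", "A_H", "msd"), mean),
      .groups = "drop")
  speeds <- unlist(lapply(tracks,
                          function(tr) velocity_and_heading(tr)$speed))
  brks <- seq(0, max(speeds) + 10, by = 10)
  cnt <- tabulate(findInterval(speeds, brks, all.inside = TRUE),
                  nbins = length(brks) - 1)
  structure(list(
    lags = lags,
    per_worm = per_worm,
    mean_speed = mean(speeds),
    speed_hist = tibble(speed_mid = head(brks, -1) + 5,
                        density = cnt / (sum(cnt) * 10))
  ), class = "ss_kinematics")
}

#' @export
print.ss_kinematics <- function(x, ...) {
  cat("<ss_kinematics>", nrow(x$lags), "lags; mean speed",
      round(x$mean_speed, 1), "um/s\n")
  invisible(x)
}

#' @export
autoplot.ss_kinematics <- function(object, ...) {
  d <- object$lags |>
    tidyr::pivot_longer(-"lag_s", names_to = "statistic")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lag_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "lag (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Undulation frequency from the heading autocorrelation
#'
#' Sinusoidal crawling leaves a transient dip in the heading
#' autocorrelation at the half-period of undulation; the frequency is half
#' the reciprocal of the lag of the first local minimum. A monotone
#' autocorrelation yields `NA` (undefined), not an error.
#'
#' @param ks An `ss_kinematics` object, or a tibble with `lag_s` and `A_H`.
#' @return Frequency in Hz, or `NA_real_` when no local minimum exists.
#' @export
undulation_frequency <- function(ks) {
  d <- if (inherits(ks, "ss_kinematics")) ks$lags else ks
  a <- d$A_H
  n <- length(a)
  if (n < 3) return(NA_real_)
  j <- which(a[2:(n - 1)] < a[1:(n - 2)] & a[2:(n - 1)] <= a[3:n])
  if (!length(j)) return(NA_real_)
  0.5 / d$lag_s[j[1] + 1]
}

#' Signed curvature of a track versus arclength
#'
#' Resamples the path to uniform arclength steps and differentiates the
#' unwrapped tangent angle. On agar the worm moves without slipping, so the
#' path traced by a tracked body point reproduces the worm's posture;
#' positive curvature is a ventral bend once per-worm mirroring has been
#' applied.
#'
#' @param track An [ss_track()] (or any tibble with `x_um`, `y_um`).
#' @param step_um Arclength resampling step in um.
#' @param mirror Flip the sign of curvature (per-worm ventral/dorsal
#'   handedness is supplied by the caller).
#' @return A tibble with `arclength_um`, `x_um`, `y_um`, `curvature`
#'   (1/um).
#' @export
track_curvature <- function(track, step_um = 10, mirror = FALSE) {
  seg <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  s <- c(0, cumsum(seg))
  keep <- c(TRUE, diff(s) > 0)
  s <- s[keep]; x <- track$x_um[keep]; y <- track$y_um[keep]
  if (max(s) < 3 * step_um) abort("track too short for curvature analysis")
  su <- seq(0, max(s), by = step_um)
  xu <- approx(s, x, su)$y
  yu <- approx(s, y, su)$y
  theta <- atan2(diff(yu), diff(xu))
  dtheta <- diff(theta)
  dtheta <- atan2(sin(dtheta), cos(dtheta))  # unwrap to (-pi, pi]
  kappa <- dtheta / step_um
  if (mirror) kappa <- -kappa
  m <- length(kappa)
  tibble(arclength_um = su[seq_len(m) + 1], x_um = xu[seq_len(m) + 1],
         y_um = yu[seq_len(m) + 1], curvature = kappa)
}

#' Curvature profile around a state transition
#'
#' Extracts the track for a stated span leading up to a transition frame
#' (the posture revealed by the path before the pause) and returns its
#' curvature with arclength 0 at the transition, increasing backwards along
#' the body.
#'
#' @param track An [ss_track()].
#' @param transition_frame Frame index of the transition.
#' @param span_mm Required arclength span before the transition (mm);
#'   transitions with less available track are rejected with an error (use
#'   [transition_phases()] for silent exclusion over a set).
#' @param step_um Arclength resampling step.
#' @param mirror Per-worm ventral/dorsal mirroring flag.
#' @return A tibble with `arclength_um` (negative: distance behind the
#'   transition) and `curvature`.
#' @export
curvature_at_transition <- function(track, transition_frame, span_mm = 1.5,
                                    step_um = 10, mirror = FALSE) {
  pre <- track[seq_len(transition_frame), ]
  seg <- sqrt(diff(pre$x_um)^2 + diff(pre$y_um)^2)
  s <- rev(cumsum(rev(seg)))      # arclength remaining up to the transition
  first <- which(c(s, 0) <= span_mm * 1000)[1]
  if (is.na(first) || s[1] < span_mm * 1000) {
    abort("insufficient track span before transition")
  }
  prof <- track_curvature(pre[first:transition_frame, ], step_um = step_um,
                          mirror = mirror)
  prof$arclength_um <- prof$arclength_um - max(prof$arclength_um)
  prof
}

phase_from_profile <- function(prof) {
  k <- prof$curvature
  s <- prof$arclength_um            # negative, 0 at the transition
  down <- which(k[-length(k)] > 0 & k[-1] <= 0)
  if (length(down) < 2) return(NA_real_)
  # distances backwards from the transition of the two crossings nearest it
  z <- sort(-s[down])
  z1 <- z[1]; z2 <- z[2]
  (2 * pi * z1 / (z2 - z1)) %% (2 * pi)
}

#' Locomotory phase of pause-entry transitions
#'
#' For each transition, the phase within the undulatory cycle is computed
#' from the two downward zero crossings of curvature preceding the pause:
#' `phi = 2*pi*z1/(z2 - z1)`, where `z1` and `z2` are the arclength
#' positions of the crossings. Transitions with less than `span_mm` of
#' available track are excluded.
#'
#' @param track An [ss_track()].
#' @param transition_frames Integer vector of transition frame indices.
#' @inheritParams curvature_at_transition
#' @return A tibble with `frame`, `phase` (radians, `NA` when undefined)
#'   and `included`.
#' @export
transition_phases <- function(track, transition_frames, span_mm = 1.5,
                              step_um = 10, mirror = FALSE) {
  rows <- lapply(transition_frames, function(f) {
    prof <- tryCatch(
      curvature_at_transition(track, f, span_mm, step_um, mirror),
      error = function(e) NULL)
    if (is.null(prof)) {
      return(tibble(frame = f, phase = NA_real_, included = FALSE))
    }
    tibble(frame = f, phase = phase_from_profile(prof), included = TRUE)
  })
  dplyr::bind_rows(rows)
}

#' Vector strength and Rayleigh test of a set of phases
#'
#' The vector strength `r` is the magnitude of the mean unit phasor
#' (1 = perfect phase locking, 0 = no preference). The Rayleigh p-value
#' uses the standard finite-n corrected approximation.
#'
#' @param phase Numeric vector of phases in radians (`NA` dropped).
#' @return A one-row tibble with `n`, `r`, `mean_phase`, `p`.
#' @export
vector_strength <- function(phase) {
  phase <- phase[is.finite(phase)]
  n <- length(phase)
  if (n == 0) return(tibble(n = 0L, r = NA_real_, mean_phase = NA_real_,
                            p = NA_real_))
  z <- mean(exp(1i * phase))
  r <- Mod(z)
  R <- n * r
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  tibble(n = n, r = r, mean_phase = Arg(z) %% (2 * pi), p = min(p, 1))
}
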