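#' Per-state velocity emission densities
#'
#' The four states emit signed tangential velocities: both pause states
#' share a central Cauchy density with median 0 and half-width `b` (the worm
#' does not stop instantaneously, so the pause density has long tails), the
#' forward state emits on v > 0 and the reverse state on v < 0. Forward and
#' reverse densities are carried on a uniform velocity grid with linear
#' interpolation and exponential tail extensions so that no finite velocity
#' ever receives exactly zero density (which would give -Inf
#' log-likelihoods on outliers).
#'
#' @name ss_emissions
#' @keywords internal
NULL

EM_FLOOR <- 1e-12

new_emissions <- function(b, grid, gF, gR, tail_scale_F, tail_scale_R,
                          pause_mass, provenance, mass_F = NA_real_,
                          mass_R = NA_real_) {
  structure(list(b = b, grid = grid, gF = gF, gR = gR,
                 tail_scale_F = tail_scale_F, tail_scale_R = tail_scale_R,
                 pause_mass = pause_mass, mass_F = mass_F, mass_R = mass_R,
                 provenance = provenance),
            class = "ss_emissions")
}

#' @export
print.ss_emissions <- function(x, ...) {
  cat("<ss_emissions>", x$provenance, "\n")
  cat(sprintf("  pause Cauchy half-width b = %.2f um/s; pause mass %.3f\n",
              x$b, x$pause_mass))
  invisible(x)
}

# fit exponential tail scale to the outermost bins with appreciable density
fit_tail_scale <- function(grid, g, side, n_bins = 20, default = 50) {
  keep <- if (side > 0) grid > 0 else grid < 0
  v <- abs(grid[keep]); d <- g[keep][order(v)]; v <- sort(v)
  ok <- d > 1e-8
  if (sum(ok) < 5) return(default)
  v <- v[ok]; d <- d[ok]
  idx <- seq(max(1, length(v) - n_bins + 1), length(v))
  if (length(idx) < 3) return(default)
  sl <- stats::coef(stats::lm(log(d[idx]) ~ v[idx]))[2]
  if (!is.finite(sl) || sl >= -1e-6) return(default)
  -1 / sl
}

#' Fit emission densities from pooled cohort velocities
#'
#' Fits the central peak of the pooled signed-velocity distribution with a
#' Cauchy density (median fixed at 0), subtracts the scaled Cauchy from
#' the histogram, clips negative residuals, and splits the residual at
#' v = 0 into the forward (v > 0) and reverse (v < 0) densities, each
#' renormalized to unit area.
#'
#' The half-width and amplitude are estimated together by weighted least
#' squares on the histogram bins within `peak_fit_window`, modelling the
#' bins as scaled Cauchy plus a slowly varying background linear in `|v|`
#' (the tails of the broad movement densities reaching into the window);
#' the background coefficients are constrained non-negative. Bin weights
#' are inverse-density (Poisson-like), which keeps the peak shape rather
#' than the bulk driving the fit.
#'
#' @param v Numeric vector of pooled signed tangential velocities (um/s),
#'   ideally >= 1e4 samples.
#' @param grid_step,grid_max Velocity grid spacing and half-range (um/s).
#' @param peak_fit_window Half-width of the bin window used for the Cauchy
#'   peak fit (um/s).
#' @return An `ss_emissions` object.
#' @export
fit_emissions <- function(v, grid_step = 2, grid_max = 600,
                          peak_fit_window = 50) {
  v <- v[is.finite(v)]
  if (length(v) < 100) abort("too few velocity samples to fit emissions")
  w <- peak_fit_window
  if (sum(abs(v) < w) < 50) {
    abort("no central peak: too few near-zero samples")
  }

  grid <- seq(-grid_max, grid_max, by = grid_step)
  edges <- c(grid - grid_step / 2, grid_max + grid_step / 2)
  vc <- pmin(pmax(v, -grid_max), grid_max)
  counts <- tabulate(findInterval(vc, edges, all.inside = TRUE),
                     nbins = length(grid))
  g_all <- counts / (length(vc) * grid_step)

  sel <- abs(grid) <= w
  x <- grid[sel]
  y <- g_all[sel]
  wt <- 1 / pmax(y, max(y) / 100)
  peak_coef <- function(b) {
    # constrained least squares by subset enumeration: background terms
    # may be dropped but all retained coefficients must be non-negative
    best <- NULL
    for (X in list(cbind(dcauchy(x, 0, b), 1, abs(x)),
                   cbind(dcauchy(x, 0, b), 1),
                   cbind(dcauchy(x, 0, b), abs(x)),
                   cbind(dcauchy(x, 0, b)))) {
      co <- tryCatch(qr.solve(X * sqrt(wt), y * sqrt(wt)),
                     error = function(e) NULL)
      if (is.null(co) || any(co < 0)) next
      rss <- sum(wt * (y - X %*% co)^2)
      if (is.null(best) || rss < best$rss) best <- list(coef = co, rss = rss)
    }
    best
  }
  obj <- function(b) {
    p <- peak_coef(b)
    if (is.null(p)) Inf else p$rss
  }
  b <- optimize(obj, c(1, w + 10))$minimum
  fit <- peak_coef(b)
  if (is.null(fit)) abort("Cauchy peak fit failed")
  scale <- fit$coef[1]

  gP <- dcauchy(grid, 0, b)
  raw <- g_all - scale * gP
  # significance mask for the degenerate-input check: the unclipped
  # residual is smoothed over 5 bins (noise cancels, genuine movement
  # tails survive) and compared with two standard errors
  se2 <- pmax(counts, 1) / (length(vc) * grid_step)^2
  sm <- running_mean(raw, 5)
  se_sm <- sqrt(running_mean(se2, 5) / 5)
  masked <- pmax(raw, 0)
  masked[sm < 2 * se_sm] <- 0
  massF <- sum(masked[grid > 0]) * grid_step
  massR <- sum(masked[grid < 0]) * grid_step
  if (massF < 0.01 || massR < 0.01) {
    abort("residual mass < 1% on one side: no movement state present")
  }

  # movement densities: clipped residual, floored at a small share of the
  # observed pooled density (states overlap, so a hard zero at a velocity
  # the cohort actually visited would be overconfident and fragments
  # decoded runs)
  share_floor <- 0.02
  resid <- pmax(raw, share_floor * g_all)
  gF <- ifelse(grid > 0, resid, 0)
  gR <- ifelse(grid < 0, resid, 0)
  gF <- gF / (sum(gF) * grid_step)
  gR <- gR / (sum(gR) * grid_step)
  pause_mass <- min(1, scale)

  new_emissions(b, grid, gF, gR,
                tail_scale_F = fit_tail_scale(grid, gF, +1),
                tail_scale_R = fit_tail_scale(grid, gR, -1),
                pause_mass = pause_mass,
                provenance = "fitted-from-cohort",
                mass_F = massF, mass_R = massR)
}

#' Synthetic-truth emission model
#'
#' The stated world used to generate synthetic velocity traces: a Cauchy
#' pause core of half-width 18 um/s, a forward density peaking near
#' +200 um/s and a reverse density peaking near -300 um/s (normals truncated
#' to the positive and negative half-lines, discretized on the standard
#' grid).
#'
#' @param b Cauchy half-width of the pause density (um/s).
#' @param forward_mode,forward_sd Mode and width of the forward density.
#' @param reverse_mode,reverse_sd Mode (negative) and width of the reverse
#'   density.
#' @inheritParams fit_emissions
#' @return An `ss_emissions` object with provenance `"synthetic-truth"`.
#' @export
synthetic_emissions <- function(b = 18, forward_mode = 200, forward_sd = 80,
                                reverse_mode = -300, reverse_sd = 100,
                                grid_step = 2, grid_max = 600) {
  grid <- seq(-grid_max, grid_max, by = grid_step)
  gF <- ifelse(grid > 0, stats::dnorm(grid, forward_mode, forward_sd), 0)
  gR <- ifelse(grid < 0, stats::dnorm(grid, reverse_mode, reverse_sd), 0)
  gF <- gF / (sum(gF) * grid_step)
  gR <- gR / (sum(gR) * grid_step)
  new_emissions(b, grid, gF, gR,
                tail_scale_F = forward_sd / 2, tail_scale_R = reverse_sd / 2,
                pause_mass = NA_real_, provenance = "synthetic-truth")
}

# density lookup on the grid with exponential tail extension and floor
eval_grid_density <- function(grid, g, tail_scale, v) {
  out <- approx(grid, g, xout = v, rule = 1)$y
  lo <- min(grid); hi <- max(grid)
  below <- which(v < lo); above <- which(v > hi)
  if (length(below)) out[below] <- g[1] * exp((v[below] - lo) / tail_scale)
  if (length(above)) {
    out[above] <- g[length(g)] * exp(-(v[above] - hi) / tail_scale)
  }
  pmax(out, EM_FLOOR)
}

#' Evaluate the emission densities
#'
#' Returns the per-state density row `G(v) = [gF(v), gR(v), gX(v), gY(v)]`
#' in the fixed state order; the two pause entries are identical. Densities
#' are floored at 1e-12 so log-likelihoods stay finite.
#'
#' @param em An `ss_emissions` object.
#' @param v Numeric vector of velocities (um/s).
#' @return A numeric matrix, `length(v)` rows by 4 columns (F, R, X, Y).
#' @export
emission_row <- function(em, v) {
  stopifnot(inherits(em, "ss_emissions"))
  gP <- pmax(dcauchy(v, 0, em$b), EM_FLOOR)
  gF <- eval_grid_density(em$grid, em$gF, em$tail_scale_F, v)
  gR <- eval_grid_density(em$grid, em$gR, em$tail_scale_R, v)
  gF[v <= 0] <- EM_FLOOR
  gR[v >= 0] <- EM_FLOOR
  cbind(F = gF, R = gR, X = gP, Y = gP)
}

#' Draw velocities from a state's emission density
#'
#' Pause states sample the Cauchy directly; movement states sample the grid
#' density by inverse transform with uniform jitter within bins.
#'
#' @param em An `ss_emissions` object.
#' @param state Character vector of states ("F", "R", "X", "Y"), recycled
#'   against `n`.
#' @param n Number of draws (defaults to `length(state)`).
#' @return Numeric vector of velocities.
#' @export
sample_emission <- function(em, state, n = length(state)) {
  state <- rep_len(state, n)
  out <- numeric(n)
  pause <- state %in% c("X", "Y")
  out[pause] <- rcauchy(sum(pause), 0, em$b)
  step <- em$grid[2] - em$grid[1]
  for (s in c("F", "R")) {
    idx <- which(state == s)
    if (!length(idx)) next
    g <- if (s == "F") em$gF else em$gR
    p <- g / sum(g)
    bins <- sample.int(length(em$grid), length(idx), replace = TRUE, prob = p)
    out[idx] <- em$grid[bins] + runif(length(idx), -step / 2, step / 2)
    # keep draws on the correct side of zero
    if (s == "F") out[idx] <- pmax(out[idx], step / 4)
    if (s == "R") out[idx] <- pmin(out[idx], -step / 4)
  }
  out
}

#' @export
tidy.ss_emissions <- function(x, ...) {
  tibble(v = x$grid, gF = x$gF, gR = x$gR,
         gP = dcauchy(x$grid, 0, x$b))
}

#' @export
autoplot.ss_emissions <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("gF", "gR", "gP"),
                        names_to = "state", values_to = "density")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$v, y = .data$density,
                                  colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "tangential velocity (um/s)",
                  y = "probability density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
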