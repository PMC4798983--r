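test_that("velocity, heading and speed follow the forward difference", {
  dt <- 0.033
  tr <- ss_track(time_s = c(0, dt), x_um = c(0, 33), y_um = c(0, 0),
                 sign = 1L)
  vh <- velocity_and_heading(tr)
  expect_equal(vh$speed, 1000)
  expect_equal(vh$hx, 1)
  expect_equal(vh$hy, 0)
  # stationary track: zero speed, heading flagged undefined
  st <- ss_track(time_s = seq(0, 1, by = 0.1), x_um = rep(1, 11),
                 y_um = rep(2, 11))
  vh0 <- velocity_and_heading(st)
  expect_true(all(vh0$speed == 0))
  expect_true(all(!vh0$heading_defined))
})

test_that("tangential velocity projects speed with the direction sign", {
  tr <- straight_track(speed = 200, n = 200)
  v <- tangential_velocity(tr)
  expect_equal(nrow(v), 199)
  expect_equal(v$v, rep(200, 199), tolerance = 1e-6)
  trR <- straight_track(speed = 200, n = 200, sign = -1L)
  expect_equal(tangential_velocity(trR)$v, rep(-200, 199),
               tolerance = 1e-6)
  # unresolved signs are refused
  tr0 <- straight_track(speed = 200, n = 50, sign = 0L)
  expect_error(tangential_velocity(tr0), "unresolved")
})

test_that("tangential velocity is rotation/translation equivariant and
           handles curvature", {
  dt <- 1 / 29.97
  # circular arc, radius 500 um, speed 200 um/s
  n <- 400
  t <- (seq_len(n) - 1) * dt
  omega <- 200 / 500
  arc <- ss_track(time_s = t, x_um = 500 * cos(omega * t),
                  y_um = 500 * sin(omega * t), sign = 1L)
  v_arc <- tangential_velocity(arc)
  mid <- v_arc$v[20:(n - 20)]
  expect_true(all(abs(mid - 200) / 200 < 0.01))
  # rotating + translating the track leaves v unchanged
  th <- 0.7
  rot <- ss_track(time_s = t,
                  x_um = cos(th) * arc$x_um - sin(th) * arc$y_um + 1234,
                  y_um = sin(th) * arc$x_um + cos(th) * arc$y_um - 987,
                  sign = 1L)
  expect_equal(tangential_velocity(rot)$v, v_arc$v, tolerance = 1e-9)
})

test_that("lag statistics match closed forms on canonical tracks", {
  tr <- straight_track(speed = 150, n = 600)
  co <- as_cohort_for_test(tr)
  ks <- kinematics_summary(co, max_lag_s = 5)
  # constant heading: no heading change, full autocorrelation
  expect_equal(ks$lags$mean_heading_change, rep(0, nrow(ks$lags)),
               tolerance = 1e-9)
  expect_equal(ks$lags$A_H, rep(1, nrow(ks$lags)), tolerance = 1e-9)
  expect_equal(ks$lags$A_H[1], 1)
  # ballistic limit: msd = (s * t)^2; zero at lag 0
  expect_equal(ks$lags$msd[1], 0)
  expect_equal(ks$lags$msd, (150 * ks$lags$lag_s)^2, tolerance = 1e-6)
  # speed autocovariance at lag 0 equals the speed variance
  vh <- velocity_and_heading(tr)
  expect_equal(ks$lags$A_s[1],
               mean((vh$speed - mean(vh$speed))^2), tolerance = 1e-9)
  expect_equal(ks$mean_speed, 150, tolerance = 1e-9)
})

test_that("random reorientation drives mean heading change to pi/2", {
  # isotropic random-heading walk: E[acos(H_k+j . H_k)] = pi/2 at lag >> 1
  set.seed(31)
  dt <- 0.1
  n <- 4000
  ang <- cumsum(c(0, runif(n - 1, -pi, pi)))  # fresh direction every frame
  step <- 10
  tr <- ss_track(time_s = (seq_len(n) - 1) * dt,
                 x_um = cumsum(c(0, step * cos(ang[-n]))),
                 y_um = cumsum(c(0, step * sin(ang[-n]))), sign = 1L)
  ks <- kinematics_summary(as_cohort_for_test(tr), max_lag_s = 2)
  long <- ks$lags[ks$lags$lag_s > 0.5, ]
  expect_equal(mean(long$mean_heading_change), pi / 2, tolerance = 0.05)
  expect_lt(max(abs(long$A_H)), 0.1)
})

test_that("undulation frequency reads the first heading-autocorrelation dip", {
  dt <- 1 / 29.97
  n <- 3000
  t <- (seq_len(n) - 1) * dt
  # sinusoidal heading with half-period 1.4 s -> 2.8 s full period
  make_track <- function(noise_sd = 0) {
    ang <- 0.8 * sin(2 * pi * t / 2.8) + rnorm(n, 0, noise_sd)
    ss_track(time_s = t, x_um = cumsum(10 * cos(ang)),
             y_um = cumsum(10 * sin(ang)), sign = 1L)
  }
  ks <- kinematics_summary(as_cohort_for_test(make_track()), max_lag_s = 4)
  f <- undulation_frequency(ks)
  expect_equal(f, 0.5 / 1.4, tolerance = 0.05)
  # constant heading: no local minimum, undefined rather than an error
  flat <- straight_track(n = 500)
  expect_true(is.na(undulation_frequency(
    kinematics_summary(as_cohort_for_test(flat), max_lag_s = 4))))
  # noisy sinusoid stays within 5%
  set.seed(32)
  ksn <- kinematics_summary(as_cohort_for_test(make_track(0.08)),
                            max_lag_s = 4)
  expect_equal(undulation_frequency(ksn), 0.5 / 1.4, tolerance = 0.05)
})

test_that("pause phases and vector strength behave as constructed", {
  # sinuous path: x advances, y oscillates; constant spatial wavelength
  lambda <- 400
  ds <- 8
  n <- 3000
  x <- cumsum(rep(ds, n))
  y <- 60 * sin(2 * pi * x / lambda)
  tr <- ss_track(time_s = (seq_len(n) - 1) / 29.97, x_um = x, y_um = y,
                 sign = 1L)
  # transitions planted at a fixed position within the undulatory cycle
  fixed <- which(abs((x %% lambda) - 100) < ds)
  fixed <- fixed[fixed * ds > 2000]
  ph_fixed <- transition_phases(tr, fixed, span_mm = 1.5)
  vs_fixed <- vector_strength(ph_fixed$phase)
  expect_gt(vs_fixed$r, 0.9)
  expect_lt(vs_fixed$p, 0.01)
  # transitions planted uniformly across the cycle
  unif <- seq(300, n - 1, by = 23)
  vs_unif <- vector_strength(transition_phases(tr, unif)$phase)
  expect_lt(vs_unif$r, 0.25)
  # identical phases: r = 1 exactly, mean phase recovered
  vs1 <- vector_strength(rep(2.1, 40))
  expect_equal(vs1$r, 1)
  expect_equal(vs1$mean_phase, 2.1)
  expect_lt(vs1$p, 1e-10)
  # Rayleigh p for uniform phases is non-significant
  set.seed(33)
  vs_u <- vector_strength(runif(200, 0, 2 * pi))
  expect_gt(vs_u$p, 0.01)
  # transitions without enough preceding track are excluded, not errors
  short <- transition_phases(tr, c(5L, fixed[1]))
  expect_false(short$included[1])
  expect_true(short$included[2])
})
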