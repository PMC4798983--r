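ref <- ss_reference_rates()

test_that("state sequences reproduce occupancies and dwell statistics", {
  st <- simulate_states(ref, 1e6, seed = 61)
  P <- steady_state(build_Q(ref))
  occ <- table(st) / length(st)
  # sampling error accounts for dwell-time autocorrelation (the effective
  # sample size is n*dt over the correlation time, far below binomial)
  expect_true(all(abs(as.numeric(occ) - as.numeric(P)) < 0.02))
  # dwell times of the generated sequence are geometric; at the video
  # frame interval the geometric mean is dt/(1 - M_ii) (the continuous
  # dwell d_i plus an O(dt) discretization term, ~8% for the brief Y
  # state), so that is the exact oracle
  seg <- rle(as.character(st))
  dt <- 1 / 29.97
  M <- frame_matrix(build_Q(ref), dt)
  d <- dwell_times(ref)
  for (s in c("F", "R", "X", "Y")) {
    lens <- seg$lengths[seg$values == s]
    lens <- lens[-c(1, length(lens))]  # drop censored first/last visits
    expect_equal(mean(lens) * dt, dt / (1 - M[s, s]), tolerance = 0.03)
    # and the continuous dwell is approached for states with d_i >> dt
    if (s %in% c("F", "R")) {
      expect_equal(mean(lens) * dt, as.numeric(d[paste0("d", s)]),
                   tolerance = 0.05)
    }
  }
  # absorbing start: no transitions out of F
  rabs <- rate_set(aXF = 1, aXR = 1, aFX = 0, aRX = 1, aFY = 0, aRY = 1,
                   aYF = 1, aYR = 1)
  suppressWarnings(stF <- simulate_states(rabs, 500, seed = 62,
                                          init = "F"))
  expect_true(all(stF == "F"))
})

test_that("velocity draws respect the emission structure end to end", {
  em <- synthetic_emissions()
  vF <- simulate_velocity(factor(rep("F", 1000), levels = c("F","R","X","Y")),
                          em, seed = 63)
  expect_true(all(vF$v > 0))
  # deterministic under the same seed
  vF2 <- simulate_velocity(factor(rep("F", 1000),
                                  levels = c("F","R","X","Y")), em,
                           seed = 63)
  expect_identical(vF$v, vF2$v)
  co1 <- simulate_cohort(ref, em, n_worms = 2, minutes = 0.5, seed = 64)
  co2 <- simulate_cohort(ref, em, n_worms = 2, minutes = 0.5, seed = 64)
  expect_identical(co1$v, co2$v)
  expect_identical(co1$state, co2$state)
})

test_that("point-worm tracks have the stated deterministic limits", {
  # no pauses or reversals, zero noise: a straight line of length v*T
  rF <- rate_set(aXF = 1, aXR = 1e-6, aFX = 0, aRX = 1, aFY = 0, aRY = 1,
                 aYF = 1, aYR = 1)
  spec <- simulation_spec(rates = rF, n_worms = 1, minutes = 1,
                          heading_noise_sd_deg = 0, seed = 65)
  suppressWarnings(sim <- simulate_track(spec))
  truth <- attr(sim, "truth")
  n <- nrow(sim)
  # once in F it stays: path length equals speed * elapsed time
  inF <- truth$state == "F"
  total <- sqrt(diff(range(sim$x_um))^2 + diff(range(sim$y_um))^2)
  expected <- 200 * sum(inF[-1]) / 29.97
  expect_equal(total, expected, tolerance = 0.01)
  # velocity trace through the kinematics pipeline shows the three peaks
  spec2 <- simulation_spec(rates = ref, n_worms = 2, minutes = 3,
                           seed = 66)
  sim2 <- simulate_track(spec2)
  truth2 <- attr(sim2, "truth")
  vt <- dplyr::bind_rows(lapply(cohort_tracks(sim2), tangential_velocity))
  joined <- dplyr::inner_join(
    dplyr::mutate(vt, key = paste(worm_id, dplyr::row_number())),
    dplyr::mutate(truth2, key = paste(worm_id, frame)), by = "key")
  vF <- joined$v[joined$state == "F"]
  vR <- joined$v[joined$state == "R"]
  vP <- joined$v[joined$state %in% c("X", "Y")]
  expect_equal(mean(vF), 200, tolerance = 0.05)
  expect_equal(mean(vR), -300, tolerance = 0.05)
  expect_lt(mean(abs(vP)), 30)
})

test_that("ensemble MSD crosses from ballistic to diffusive scaling", {
  spec <- simulation_spec(rates = ref, n_worms = 8, minutes = 10,
                          seed = 67)
  sim <- simulate_track(spec)
  dt <- attr(sim, "dt")
  msd_at <- function(track, lags) {
    R <- cbind(track$x_um, track$y_um)
    vapply(lags, function(j) {
      k <- seq_len(nrow(R) - j)
      mean(rowSums((R[k + j, , drop = FALSE] - R[k, , drop = FALSE])^2))
    }, numeric(1))
  }
  lags_short <- round(c(0.3, 0.6) / dt)
  lags_long <- round(c(120, 240) / dt)
  tracks <- cohort_tracks(sim)
  msd_s <- rowMeans(vapply(tracks, msd_at, numeric(2), lags = lags_short))
  msd_l <- rowMeans(vapply(tracks, msd_at, numeric(2), lags = lags_long))
  slope_short <- diff(log(msd_s)) / diff(log(lags_short))
  slope_long <- diff(log(msd_l)) / diff(log(lags_long))
  expect_gt(slope_short, 1.8)   # ballistic below the run timescale
  expect_lt(slope_long, 1.5)    # diffusive beyond the ~30 s reorientation
})

test_that("chemotaxis coupling biases the walk up the gradient", {
  spec <- simulation_spec(rates = ref, n_worms = 12, minutes = 2,
                          seed = 68)
  peak <- c(3000, 0)
  gradient <- function(x, y) {
    exp(-((x - peak[1])^2 + (y - peak[2])^2) / (2 * 5000^2))
  }
  # null coupling reduces to the plain point-worm with the same seed
  null <- simulate_chemotaxis(spec, kappa = 0, gradient = gradient)
  plain <- simulate_track(spec)
  expect_identical(null$x_um, plain$x_um)
  expect_identical(null$y_um, plain$y_um)
  # positive coupling moves the ensemble toward the peak
  chem <- simulate_chemotaxis(spec, kappa = 25, gradient = gradient)
  final_dist <- function(co) {
    ends <- dplyr::slice_tail(dplyr::group_by(co, worm_id), n = 1)
    mean(sqrt((ends$x_um - peak[1])^2 + (ends$y_um - peak[2])^2))
  }
  expect_lt(final_dist(chem), final_dist(null))
  # biased-random-walk signature: more forward motion is spent moving
  # toward the peak than away from it
  truth <- attr(chem, "truth")
  chem_frames <- dplyr::mutate(chem, frame = dplyr::row_number(),
                               .by = "worm_id")
  joined <- dplyr::inner_join(truth, chem_frames,
                              by = c("worm_id", "frame"))
  fwd <- joined[joined$state == "F", ]
  fwd <- dplyr::mutate(fwd, dx = c(diff(x_um), 0), .by = "worm_id")
  up <- fwd$dx * (peak[1] - fwd$x_um) > 0
  expect_gt(mean(up, na.rm = TRUE), 0.5)
})
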