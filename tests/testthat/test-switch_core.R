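ref <- ss_reference_rates()

test_that("Q matrix has the switch structure", {
  Q <- build_Q(ref)
  expect_equal(rowSums(Q), setNames(rep(0, 4), c("F", "R", "X", "Y")))
  expect_equal(Q["F", "F"], -(0.182 + 0.007))
  expect_equal(Q["F", "R"], 0)  # direct F<->R and X<->Y disallowed
  expect_equal(Q["R", "F"], 0)
  expect_equal(Q["X", "Y"], 0)
  expect_equal(Q["Y", "X"], 0)
  expect_error(rate_set(aXF = -1, aXR = 1, aFX = 1, aRX = 1, aFY = 1,
                        aRY = 1, aYF = 1, aYR = 1), ">= 0")
  zero <- rate_set(0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(build_Q(zero), matrix(0, 4, 4,
                                     dimnames = list(c("F","R","X","Y"),
                                                     c("F","R","X","Y"))))
})

test_that("frame matrix agrees with a series-expansion matrix exponential", {
  dt <- 1 / 29.97
  Q <- build_Q(ref)
  M <- frame_matrix(Q, dt)
  expect_lt(max(abs(rowSums(M) - 1)), 1e-12)
  expect_lt(max(abs(M - expm_series(Q * dt))), 1e-9)
  # zero generator
  expect_equal(frame_matrix(matrix(0, 4, 4), dt), diag(4))
  # semigroup property
  M1 <- frame_matrix(Q, 0.02)
  M2 <- frame_matrix(Q, 0.05)
  expect_lt(max(abs(M1 %*% M2 - frame_matrix(Q, 0.07))), 1e-9)
  expect_error(frame_matrix(matrix(1, 4, 4), dt), "sum to zero")
})

test_that("two-state sub-chain matches the telegraph closed form", {
  a <- 0.3   # F -> X
  b <- 1.2   # X -> F
  r <- rate_set(aXF = b, aXR = 0, aFX = a, aRX = 0, aFY = 0, aRY = 0,
                aYF = 0, aYR = 0)
  dt <- 0.033
  M <- frame_matrix(build_Q(r), dt)
  e <- exp(-(a + b) * dt)
  expect_equal(M["F", "F"], b / (a + b) + a / (a + b) * e,
               tolerance = 1e-10)
  expect_equal(M["F", "X"], a / (a + b) * (1 - e), tolerance = 1e-10)
  expect_equal(M["X", "F"], b / (a + b) * (1 - e), tolerance = 1e-10)
  expect_equal(M["R", "R"], 1)
})

test_that("steady state reproduces reported occupancies and symmetry", {
  P <- steady_state(build_Q(ref))
  expect_equal(as.numeric(P["F"]), 0.762, tolerance = 0.005)
  expect_equal(as.numeric(P["R"]), 0.158, tolerance = 0.01)
  expect_lt(max(abs(drop(P %*% build_Q(ref)))), 1e-10)
  sym <- rate_set(1, 1, 1, 1, 1, 1, 1, 1)
  expect_equal(as.numeric(steady_state(build_Q(sym))), rep(0.25, 4))
  # absorbing chain: all mass ends in F, with a warning
  ab <- rate_set(aXF = 1, aXR = 0, aFX = 0, aRX = 0, aFY = 0, aRY = 0,
                 aYF = 1, aYR = 0)
  expect_warning(Pa <- steady_state(build_Q(ab)), "reducible")
  expect_equal(as.numeric(Pa["F"]), 1, tolerance = 1e-8)
})

test_that("dwell times follow the exit-rate reciprocal", {
  d <- dwell_times(ref)
  expect_equal(as.numeric(d["dR"]), 1.945, tolerance = 0.005)
  expect_equal(as.numeric(d["dF"]), 1 / (0.182 + 0.007))
  A <- 0.7
  unc <- rates_from_weights(weight_set(0, 0, 0, 0, 0, 0, A = A))
  expect_equal(as.numeric(dwell_times(unc)),
               rep(uncoupled_dwell(A), 4))
  expect_equal(as.numeric(steady_state(build_Q(unc))), rep(0.25, 4))
  inf <- rate_set(aXF = 0, aXR = 0, aFX = 1, aRX = 1, aFY = 0, aRY = 0,
                  aYF = 1, aYR = 1)
  expect_warning(di <- dwell_times(inf), "infinite")
  expect_true(is.infinite(di["dX"]))
})

test_that("weights and rates are exact inverses under the constraints", {
  w <- weight_set(hF = 1.01, hR = 1.09, wFF = -0.22, wRR = 1.90,
                  wFR = -5.40, wRF = -0.81, A = 0.4)
  r <- rates_from_weights(w)
  expect_lt(max(constraint_residuals(r)), 1e-12)
  w2 <- weights_from_rates(r, A = 0.4)
  expect_equal(unlist(w2[c("hF","hR","wFF","wRR","wFR","wRF")]),
               unlist(w[c("hF","hR","wFF","wRR","wFR","wRF")]),
               tolerance = 1e-10)
  # all-zero weights, A = 1: every rate is 1 Hz
  r0 <- rates_from_weights(weight_set(0, 0, 0, 0, 0, 0, A = 1))
  expect_equal(as.numeric(r0), rep(1, 8))
  # property: round trip identity for random weight sets
  set.seed(11)
  for (i in 1:20) {
    wi <- weight_set(rnorm(1), rnorm(1), rnorm(1), rnorm(1), rnorm(1),
                     rnorm(1), A = runif(1, 0.1, 2))
    ri <- rates_from_weights(wi)
    expect_lt(max(constraint_residuals(ri)), 1e-10)
    wb <- weights_from_rates(ri, wi$A)
    expect_equal(unlist(wb[1:6]), unlist(wi[1:6]), tolerance = 1e-9)
  }
  # cross-connection weights are A-independent
  wA <- weights_from_rates(r, A = 0.4)
  wB <- weights_from_rates(r, A = 0.86)
  expect_identical(wA$wFR, wB$wFR)
  expect_identical(wA$wRF, wB$wRF)
  # rates violating the constraints are refused
  bad <- rate_set(1, 1, 1, 1, 1, 2, 1, 1)
  expect_error(weights_from_rates(bad, 1), "constraints")
})

test_that("strong reverse drive saturates the push-motif rates", {
  w <- weights_from_rates(ref, A = 0.4, tol = 0.1)
  w$hR <- w$hR + 50
  r <- unclass(rates_from_weights(w))
  expect_gt(r["aXR"], 1e15)   # R switches ON immediately
  expect_gt(r["aFY"], 1e15)
  expect_lt(r["aRX"], 1e-15)  # R never switches OFF
  expect_lt(r["aYF"], 1e-15)
})

test_that("ablation dwell table brackets the fundamental switching rate", {
  b <- infer_A_bounds(ss_reference_ablation_dwells())
  expect_equal(b$d0_min, 0.58)
  expect_equal(b$d0_max, 1.24)
  expect_equal(b$A_min, 0.40)
  expect_equal(b$A_max, 0.86)
  # degenerate single-row table gives a point estimate
  pt <- infer_A_bounds(tibble::tibble(dR = 1.0, dX = 1.0))
  expect_equal(pt$A_min, pt$A_max)
  expect_error(infer_A_bounds(tibble::tibble(dR = 0.5, dX = 1.0)),
               "inconsistent")
})

test_that("weight perturbations move dwell times as the model predicts", {
  w <- weights_from_rates(ref, A = 0.4, tol = 0.1)
  d0 <- uncoupled_dwell(0.4)
  d_wt <- dwell_times(rates_from_weights(w))
  # hyperpolarization (deltaV, negative shift) lengthens the X pause
  hyp <- perturb_weights(w, "deltaV", -0.6)
  expect_gt(dwell_times(rates_from_weights(hyp))["dX"], d_wt["dX"])
  dep <- perturb_weights(w, "deltaV", 0.6)
  expect_lt(dwell_times(rates_from_weights(dep))["dX"], d_wt["dX"])
  # depolarizing resistance change (scale 1 - f) pulls dF and dR toward d0
  dr <- perturb_weights(w, "deltaR", 1 - 0.6)
  d_dep <- dwell_times(rates_from_weights(dr))
  expect_lt(abs(d_dep["dF"] - d0), abs(d_wt["dF"] - d0))
  expect_lt(abs(d_dep["dR"] - d0), abs(d_wt["dR"] - d0))
  # identity perturbations
  expect_equal(perturb_weights(w, "deltaV", 0), w)
  expect_equal(perturb_weights(w, "deltaR", 1), w)
  expect_error(perturb_weights(w, "deltaV", 1.5), "magnitude")
})

test_that("pause relabelling preserves the synaptic constraints", {
  set.seed(5)
  for (i in 1:10) {
    w <- weight_set(rnorm(1), rnorm(1), rnorm(1), rnorm(1), rnorm(1),
                    rnorm(1), A = 1)
    r <- rates_from_weights(w)
    rl <- relabel_pauses(r)
    expect_lt(max(constraint_residuals(rl)), 1e-10)
    P <- steady_state(build_Q(rl))
    expect_gte(P[["X"]], P[["Y"]])
  }
})
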