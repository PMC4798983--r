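#' Closed-form reference tables from a rate set
#'
#' Recomputes, from a set of transition rates alone, the standard summary
#' tables: rates with dwell times and steady-state probabilities, synaptic
#' weights at the lower and upper bounds of the fundamental switching
#' rate, the exit-fate table, run lengths with search-mode classification,
#' and the synaptic-constraint residuals. Every cell carries a provenance
#' tag.
#'
#' @param rates An [rate_set()]; defaults to the bundled wild-type
#'   reference rates.
#' @param A_min,A_max Bounds on the fundamental switching rate (Hz).
#' @param v_forward,v_reverse Speeds for the run-length row (um/s).
#' @param dt Frame duration (s).
#' @return A list of class `ss_report` with tibbles `rate_table`,
#'   `weight_table`, `fate_table`, `run_table`, `constraint_residuals`.
#' @export
reproduce_reference_tables <- function(rates = ss_reference_rates(),
                                       A_min = 0.4, A_max = 0.86,
                                       v_forward = 200, v_reverse = 300,
                                       dt = 1 / 29.97) {
  ch <- chain_summary(rates, dt)
  rate_table <- tibble(
    quantity = c(names(unclass(rates)), paste0("d", STATES),
                 paste0("p", STATES)),
    value = c(as.numeric(rates), as.numeric(ch$dwell),
              as.numeric(ch$P_inf)),
    units = c(rep("1/s", 8), rep("s", 4), rep("", 4)),
    provenance = c(rep("fixture", 8), rep("closed-form", 8))
  )
  wmin <- weights_from_rates(rates, A_min, tol = 0.1)
  wmax <- weights_from_rates(rates, A_max, tol = 0.1)
  weight_table <- tibble(
    weight = WEIGHT_NAMES,
    A_min = unlist(wmin[WEIGHT_NAMES]),
    A_max = unlist(wmax[WEIGHT_NAMES]),
    provenance = "closed-form"
  )
  run_table <- run_lengths(rates, v_forward, v_reverse) |>
    dplyr::mutate(provenance = "closed-form")
  structure(list(
    rate_table = rate_table,
    weight_table = weight_table,
    fate_table = dplyr::mutate(fate_diagram(rates),
                               provenance = "closed-form"),
    run_table = run_table,
    constraint_residuals = tibble(
      constraint = c("aFX*aXF = aRY*aYR", "aFY*aYF = aRX*aXR"),
      relative_residual = as.numeric(constraint_residuals(rates)),
      provenance = "closed-form")
  ), class = "ss_report")
}

#' @export
print.ss_report <- function(x, ...) {
  cat("<ss_report>\n\nRates, dwell times, state probabilities:\n")
  print(x$rate_table, n = 16)
  cat("\nSynaptic weights at the A bounds:\n")
  print(x$weight_table)
  cat("\nExit fates:\n")
  print(x$fate_table)
  cat("\nRun lengths / search mode:\n")
  print(x$run_table)
  invisible(x)
}

quantity_fn <- function(quantity) {
  switch(quantity,
    dR = function(r) 1 / (r[["aRX"]] + r[["aRY"]]),
    dX = function(r) 1 / (r[["aXF"]] + r[["aXR"]]),
    dF = function(r) 1 / (r[["aFX"]] + r[["aFY"]]),
    dP = function(r) {
      P <- steady_state_raw(r)
      dX <- 1 / (r[["aXF"]] + r[["aXR"]])
      dY <- 1 / (r[["aYF"]] + r[["aYR"]])
      (P[3] * dX + P[4] * dY) / (P[3] + P[4])
    },
    abort(sprintf("unsupported constrained quantity '%s'", quantity))
  )
}

# complete the 5 remaining free rates + shared quantity value into the
# 6 free rates, or NULL when infeasible
solve_constrained_free <- function(free5, q, quantity) {
  q <- unname(q)
  if (q <= 0) return(NULL)
  if (quantity == "dR") {
    aRY <- 1 / q - free5[["aRX"]]
    if (aRY <= 0) return(NULL)
    return(c(free5, aRY = aRY))
  }
  if (quantity == "dX") {
    aXR <- 1 / q - free5[["aXF"]]
    if (aXR <= 0) return(NULL)
    return(c(free5, aXR = aXR))
  }
  if (quantity == "dF") {
    aFY <- 1 / q - free5[["aFX"]]
    if (aFY <= 0) return(NULL)
    return(c(free5, aFY = aFY))
  }
  # dP: solve aXR numerically
  qf <- quantity_fn("dP")
  f <- function(z) {
    full <- tryCatch(complete_rates(c(free5, aXR = z)),
                     error = function(e) NULL)
    if (is.null(full)) return(NA_real_)
    qf(unclass(full)) - q
  }
  lo <- f(1e-4); hi <- f(50)
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0) return(NULL)
  z <- tryCatch(uniroot(f, c(1e-4, 50))$root, error = function(e) NULL)
  if (is.null(z)) return(NULL)
  c(free5, aXR = z)
}

#' Compare two cohorts by a constrained likelihood-ratio test
#'
#' Tests whether a derived quantity (a dwell time, or the mean pause dwell
#' `dP`) differs between two cohorts. The unconstrained model fits each
#' cohort separately (12 free parameters); the constrained model shares
#' the quantity across cohorts (11 free parameters: the shared value plus
#' five remaining free rates per cohort, with one designated rate solved
#' to reproduce the shared value at every step). The test statistic is
#' referred to chi-squared with one degree of freedom.
#'
#' @param v1,v2 Velocities of the two cohorts (see [filter_loglik()]).
#' @param em1,em2 Emission models of the two cohorts.
#' @param config An [run_config()].
#' @param quantity One of `"dR"`, `"dX"`, `"dF"`, `"dP"`.
#' @return A list of class `ss_compare` with the two unconstrained fits,
#'   the constrained log-likelihood, the shared quantity value, and the
#'   LRT row (`D`, `df`, `p`).
#' @export
cohort_compare <- function(v1, v2, em1, em2, config = run_config(),
                           quantity = "dR") {
  qf <- quantity_fn(quantity)
  cfg1 <- config; cfg1$rng_seed <- config$rng_seed + 11L
  cfg2 <- config; cfg2$rng_seed <- config$rng_seed + 22L
  fit1 <- fit_rates(v1, em1, cfg1)
  fit2 <- fit_rates(v2, em2, cfg2)
  lnL_full <- fit1$loglik + fit2$loglik

  inp1 <- velocity_input(v1); inp2 <- velocity_input(v2)
  dt <- attr(v1, "dt") %||% (1 / config$frame_rate)
  G1 <- emission_row(em1, inp1$v)
  G2 <- emission_row(em2, inp2$v)
  free5_names <- setdiff(c("aXF", "aXR", "aFX", "aRX", "aFY", "aRY"),
                         switch(quantity, dR = "aRY", dX = "aXR",
                                dF = "aFY", dP = "aXR"))

  cohort_lnL <- function(free5, q, G, starts) {
    free6 <- solve_constrained_free(free5, q, quantity)
    if (is.null(free6)) return(NA_real_)
    full <- tryCatch(complete_rates(free6), error = function(e) NULL)
    if (is.null(full)) return(NA_real_)
    if (any(unclass(full) < config$rate_floor_refine)) return(NA_real_)
    Q <- build_Q(full)
    cpp_filter_loglik(G, starts, frame_matrix(Q, dt, config$K_exponent),
                      steady_state(Q))
  }

  par0 <- c(q = mean(c(qf(unclass(fit1$rates)), qf(unclass(fit2$rates)))),
            setNames(unclass(fit1$rates)[free5_names],
                     paste0("c1_", free5_names)),
            setNames(unclass(fit2$rates)[free5_names],
                     paste0("c2_", free5_names)))
  eval_par <- function(p) {
    l1 <- cohort_lnL(setNames(p[2:6], free5_names), p[1], G1, inp1$starts)
    l2 <- cohort_lnL(setNames(p[7:11], free5_names), p[1], G2, inp2$starts)
    if (!is.finite(l1) || !is.finite(l2)) return(-Inf)
    l1 + l2
  }

  res <- with_local_seed(config$rng_seed + 33L, {
    par <- par0
    cur <- eval_par(par)
    if (!is.finite(cur)) {
      abort("constrained optimizer could not initialize; flagged row")
    }
    b <- config$b_random_init
    while (b >= config$b_stop_refine) {
      prop <- par + rcauchy(length(par), 0, b)
      ll <- eval_par(prop)
      if (is.finite(ll) && ll > cur) {
        par <- prop; cur <- ll; b <- b * config$b_grow
      } else {
        b <- b * config$b_shrink
      }
    }
    list(par = par, loglik = cur)
  })

  lrt <- likelihood_ratio_test(lnL_full, res$loglik, 12L, 11L)
  structure(list(fit1 = fit1, fit2 = fit2, quantity = quantity,
                 shared_value = unname(res$par[1]),
                 lnL_full = lnL_full, lnL_constrained = res$loglik,
                 lrt = lrt), class = "ss_compare")
}

#' @export
print.ss_compare <- function(x, ...) {
  cat(sprintf("<ss_compare> %s constrained equal across cohorts\n",
              x$quantity))
  cat(sprintf("  lnL full %.3f (12 df) vs constrained %.3f (11 df)\n",
              x$lnL_full, x$lnL_constrained))
  print(x$lrt)
  invisible(x)
}

#' @export
glance.ss_compare <- function(x, ...) {
  dplyr::bind_cols(tibble(quantity = x$quantity,
                          shared_value = x$shared_value), x$lrt)
}
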