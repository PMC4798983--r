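#' Construct a single worm track
#'
#' A track is a per-frame record of time (s) and planar position (um) with a
#' head/tail direction sign: +1 while the worm crawls head-first, -1 while
#' it retreats tail-first, 0 where the sign is unknown. Frame times must be
#' strictly increasing with uniform spacing (tolerance 1e-6 s).
#'
#' @param time_s,x_um,y_um Numeric vectors of equal length >= 2.
#' @param sign Integer vector in \{-1, 0, 1\}; recycled if length 1.
#' @param worm_id,cohort_id Identifier strings.
#' @return A tibble of class `ss_track` with columns `worm_id`, `time_s`,
#'   `x_um`, `y_um`, `sign`; the frame interval is stored as attribute `dt`.
#' @export
ss_track <- function(time_s, x_um, y_um, sign = 0L, worm_id = "worm1",
                     cohort_id = NA_character_) {
  n <- length(time_s)
  if (n < 2) abort("a track needs at least 2 frames")
  if (length(x_um) != n || length(y_um) != n) {
    abort("time_s, x_um, y_um must have equal length")
  }
  if (!all(is.finite(time_s)) || !all(is.finite(x_um)) ||
      !all(is.finite(y_um))) {
    abort("track coordinates and times must be finite")
  }
  dt <- diff(time_s)
  if (any(dt <= 0)) abort("frame times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6) {
    abort("frame times must be uniformly spaced within 1e-6 s")
  }
  sign <- as.integer(rep_len(sign, n))
  if (!all(sign %in% c(-1L, 0L, 1L))) abort("sign must be -1, 0 or +1")
  out <- tibble(worm_id = worm_id, time_s = time_s, x_um = x_um,
                y_um = y_um, sign = sign)
  attr(out, "dt") <- stats::median(dt)
  attr(out, "cohort_id") <- cohort_id
  class(out) <- c("ss_track", class(out))
  out
}

track_dt <- function(track) {
  attr(track, "dt") %||% stats::median(diff(track$time_s))
}

#' Read worm tracks from a delimited text file
#'
#' Expects a comma-separated table with a header naming at least `time_s`,
#' `x_um` and `y_um`; `sign` and `worm_id` are optional (missing signs are
#' stored as 0 = unknown; a missing `worm_id` column yields a single worm).
#' Each worm's rows are validated as a track.
#'
#' @param path File path.
#' @param cohort_id Optional label for the cohort (genotype / ablation /
#'   sham).
#' @return A tibble of class `ss_cohort` with one row per frame and columns
#'   `worm_id`, `time_s`, `x_um`, `y_um`, `sign`.
#' @examples
#' p <- system.file("extdata", "synthetic_tracks.csv",
#'                  package = "stochswitch")
#' co <- read_tracks(p, cohort_id = "synthetic-demo")
#' cohort_velocities(co)
#' @export
read_tracks <- function(path, cohort_id = NA_character_) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  # columns come in as text and are converted with the exactly rounded
  # base parser (the fast CSV double parser can be off by an ulp, which
  # would break bit-identical round trips)
  d <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("time_s", "x_um", "y_um")
  if (!all(need %in% names(d))) {
    abort(sprintf("missing required column(s): %s",
                  paste(setdiff(need, names(d)), collapse = ", ")))
  }
  for (nm in need) {
    val <- suppressWarnings(as.numeric(d[[nm]]))
    bad <- which(is.na(val) & !is.na(d[[nm]]))
    if (length(bad)) {
      abort(sprintf("malformed value in column %s of %s at line %d",
                    nm, path, bad[1] + 1L))
    }
    d[[nm]] <- val
  }
  if (!"sign" %in% names(d)) d$sign <- 0L
  d$sign <- suppressWarnings(as.integer(d$sign))
  if (!"worm_id" %in% names(d)) d$worm_id <- "worm1"
  tracks <- d |>
    dplyr::group_by(.data$worm_id) |>
    dplyr::group_map(function(g, key) {
      ss_track(g$time_s, g$x_um, g$y_um, g$sign, worm_id = key$worm_id,
               cohort_id = cohort_id)
    })
  as_cohort(dplyr::bind_rows(tracks), label = cohort_id)
}

as_cohort <- function(frames, label = NA_character_) {
  dts <- frames |>
    dplyr::group_by(.data$worm_id) |>
    dplyr::summarise(dt = stats::median(diff(.data$time_s)), .groups = "drop")
  if (nrow(dts) == 0) abort("cohort must contain at least one track")
  if (max(dts$dt) - min(dts$dt) > 1e-6) {
    abort("all tracks in a cohort must share the same frame interval")
  }
  out <- frames[, c("worm_id", "time_s", "x_um", "y_um", "sign")]
  attr(out, "dt") <- stats::median(dts$dt)
  attr(out, "label") <- label
  class(out) <- c("ss_cohort", class(tibble()))
  out
}

#' Split a cohort into per-worm tracks
#'
#' @param cohort An `ss_cohort` tibble.
#' @return A named list of `ss_track` tibbles.
#' @export
cohort_tracks <- function(cohort) {
  label <- attr(cohort, "label")
  ids <- unique(cohort$worm_id)
  setNames(lapply(ids, function(id) {
    g <- cohort[cohort$worm_id == id, ]
    ss_track(g$time_s, g$x_um, g$y_um, g$sign, worm_id = id,
             cohort_id = label)
  }), ids)
}

#' Write tracks to a delimited text file
#'
#' @param cohort An `ss_cohort` or `ss_track` tibble.
#' @param path Output file path.
#' @return `path`, invisibly. Round-trips bit-identically through
#'   [read_tracks()].
#' @export
write_tracks <- function(cohort, path) {
  d <- tibble::as_tibble(cohort)[, c("worm_id", "time_s", "x_um", "y_um",
                                     "sign")]
  # full-precision text so coordinates survive a write/read cycle exactly
  for (nm in c("time_s", "x_um", "y_um")) d[[nm]] <- sprintf("%.17g", d[[nm]])
  readr::write_csv(d, path)
  invisible(path)
}

#' Run configuration for the fitting pipeline
#'
#' Collects the tunable parameters of every pipeline stage. Defaults are
#' the operating conditions of the reference analysis: ~30 Hz video, 11-
#' frame track smoothing, Cauchy pause half-width 18 um/s, frame matrix by
#' 30 squarings, and the random-step optimizer schedule (initial step width
#' 0.01 Hz, x1.03 on success, x0.995 on failure, stop below 1e-3 Hz, 10
#' replicates, refinement stop 1e-5 Hz with rate floor 1e-4 Hz).
#'
#' @param frame_rate Video frame rate in Hz.
#' @param smoothing_window Track smoothing window in frames (odd).
#' @param cauchy_halfwidth_b Pause Cauchy half-width in um/s.
#' @param K_exponent Base-2 exponent for [frame_matrix()].
#' @param b_random_init Initial proposal width of the optimizer (Hz).
#' @param b_grow,b_shrink Multiplicative step-width updates on improvement /
#'   non-improvement.
#' @param b_stop Stop threshold on the proposal width (Hz).
#' @param b_stop_refine Stop threshold of the refinement pass (Hz).
#' @param proposal_floor Proposals with any rate below this are redrawn (Hz).
#' @param rate_floor_refine Hard lower bound on rates in the refinement (Hz).
#' @param n_replicates Number of independent optimizer starts.
#' @param init_range Log-uniform range for initial rate guesses (Hz).
#' @param rng_seed Integer seed driving all randomness downstream.
#' @return A list of class `ss_config`.
#' @export
run_config <- function(frame_rate = 29.97, smoothing_window = 11,
                       cauchy_halfwidth_b = 18, K_exponent = 30,
                       b_random_init = 0.01, b_grow = 1.03,
                       b_shrink = 0.995, b_stop = 1e-3,
                       b_stop_refine = 1e-5, proposal_floor = 0.01,
                       rate_floor_refine = 1e-4, n_replicates = 10,
                       init_range = c(0.01, 10), rng_seed = 1L) {
  cfg <- list(frame_rate = frame_rate, smoothing_window = smoothing_window,
              cauchy_halfwidth_b = cauchy_halfwidth_b,
              K_exponent = K_exponent, b_random_init = b_random_init,
              b_grow = b_grow, b_shrink = b_shrink, b_stop = b_stop,
              b_stop_refine = b_stop_refine, proposal_floor = proposal_floor,
              rate_floor_refine = rate_floor_refine,
              n_replicates = n_replicates, init_range = init_range,
              rng_seed = as.integer(rng_seed))
  pos <- c("frame_rate", "smoothing_window", "cauchy_halfwidth_b",
           "K_exponent", "b_random_init", "b_stop", "b_stop_refine",
           "proposal_floor", "rate_floor_refine", "n_replicates")
  if (any(vapply(cfg[pos], function(x) any(x <= 0), logical(1)))) {
    abort("run_config parameters must be positive")
  }
  if (cfg$K_exponent < 1) abort("K_exponent must be >= 1")
  structure(cfg, class = "ss_config")
}

#' Serialize a fit result to JSON
#'
#' Writes the machine-readable record of a fit: rates, weights at a stated
#' A, log-likelihood, per-replicate results, configuration and seed.
#' Refuses to serialize a fit whose rates are negative.
#'
#' @param fit An `ss_fit` object from [fit_rates()].
#' @param path Output path.
#' @param A Fundamental rate at which the recorded weights are evaluated.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path, A = 0.4) {
  stopifnot(inherits(fit, "ss_fit"))
  if (any(unclass(fit$rates) < 0)) {
    abort("integrity error: fit contains negative rates")
  }
  w <- if (all(unclass(fit$rates) > 0) && fit$variant != "C") {
    unlist(weights_from_rates(fit$rates, A)[WEIGHT_NAMES])
  } else NULL
  rec <- list(
    rates = as.list(unclass(fit$rates)),
    weights = as.list(w), A = A,
    loglik = fit$loglik,
    variant = fit$variant,
    df = fit$df,
    n_frames = fit$n_frames,
    replicates = fit$replicates,
    config = unclass(fit$config)
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized fit result
#'
#' @param path Path written by [write_fit()].
#' @return A list with `rates` (an [rate_set()]), `loglik`, `df`,
#'   `variant`, `n_frames`, `replicates` and `config`.
#' @export
read_fit <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec$rates <- validate_rates(unlist(rec$rates))
  rec$replicates <- tibble::as_tibble(rec$replicates)
  rec
}
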