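#' Efficiency (polar order parameter)
#'
#' Overall ordering of the swarm: `E = |sum_i v_i| / (N * v0)`, the norm of
#' the summed velocity vectors normalized by perfect alignment at the
#' preferred speed. Equals 1 iff all velocities are identical with speed
#' `v0`, is near `N^(-1/2)` for random headings, and may exceed 1 when many
#' agents are faster than `v0` (it is deliberately not clamped). Invariant
#' under global rotation of the velocities and under agent permutation.
#'
#' @param state a [swarm_state()] (or an N x 3 velocity matrix).
#' @param params a [model_params()] object (uses `v0`; `N` is taken from
#'   the state).
#' @return Dimensionless scalar `>= 0`.
#' @examples
#' p <- model_params(N = 2)
#' v <- rbind(c(5, 0, 0), c(0, 5, 0))
#' efficiency(swarm_state(matrix(1, 2, 3), v, L = 50), p)  # sqrt(2)/2
#' @export
efficiency <- function(state, params) {
  v <- if (inherits(state, "swarm_state")) state$velocities else as.matrix(state)
  stopifnot(nrow(v) >= 1, params$v0 > 0)
  sqrt(sum(colSums(v)^2)) / (nrow(v) * params$v0)
}

#' Binder cumulant of an efficiency ensemble
#'
#' Fourth-order moment ratio `B = 1 - <E^4> / (3 <E^2>^2)` with plain
#' arithmetic means over the samples. Scale-invariant; equals 2/3 for a
#' sharp (delta) distribution and tends to 0.4 for samples uniform on
#' [0, 1]. Its system-size behaviour diagnoses whether the order-disorder
#' transition is bimodal (discontinuous). The normalized variant divides
#' by the agent count, as used when comparing system sizes.
#'
#' @param samples numeric vector of efficiency values; at least one must be
#'   nonzero.
#' @param normalize_N optional agent count; when supplied the result is
#'   `B / N`.
#' @return Dimensionless scalar.
#' @examples
#' binder_cumulant(rep(0.9, 10))  # 2/3
#' binder_cumulant(c(0, 0.5))    # 1/3
#' @export
binder_cumulant <- function(samples, normalize_N = NULL) {
  stopifnot(length(samples) >= 1, all(is.finite(samples)))
  m2 <- mean(samples^2)
  if (m2 == 0) stop("Binder cumulant undefined: all samples are zero")
  b <- 1 - mean(samples^4) / (3 * m2^2)
  if (!is.null(normalize_N)) b <- b / normalize_N
  b
}

#' Time of the disorder-to-order transition
#'
#' Earliest recorded time after which the efficiency stays above a
#' threshold for at least a dwell window (a spike shorter than the dwell
#' does not count). Operates on the recorded cadence without interpolation.
#'
#' @param series a data.frame with columns `t` (strictly increasing) and
#'   `E`, as in `run_sim()$series`.
#' @param threshold efficiency threshold in (0, 1).
#' @param dwell minimum time E must remain above threshold (s); default one
#'   recording interval.
#' @return The transition time (s), or `NA_real_` if never.
#' @examples
#' s <- data.frame(t = 0:5, E = c(0.1, 0.1, 0.9, 0.95, 0.97, 0.99))
#' transition_time(s, 0.8)
#' @export
transition_time <- function(series, threshold = 0.8, dwell = NULL) {
  stopifnot(threshold > 0, threshold < 1,
            all(diff(series$t) > 0))
  tt <- series$t
  if (is.null(dwell)) dwell <- if (length(tt) > 1) min(diff(tt)) else 0
  above <- series$E > threshold
  n <- length(tt)
  for (k in seq_len(n)) {
    if (!above[k]) next
    in_window <- tt >= tt[k] & tt <= tt[k] + dwell
    if (all(above[in_window])) return(tt[k])
  }
  NA_real_
}

#' Ensemble histogram of efficiency over ratio-spaced times
#'
#' Distribution of the efficiency across independent runs: at each selected
#' time (recorded times closest to a geometric grid with the given ratio,
#' default `10^(1/30)`), the runs are binned in E with a fixed bin width
#' (default 0.01). The per-time counts always sum to the number of runs.
#'
#' @param runs list of per-run series (data.frames with `t`, `E`); all runs
#'   must share the recording cadence.
#' @param time_ratio ratio between adjacent selected times.
#' @param bin_width efficiency bin width.
#' @return A list of class `ensemble_summary`: `histogram` (data.frame
#'   `time_bin`, `e_bin`, `count`), `times` (selected times), `binder`
#'   (data.frame `t`, `B` per selected time), `n_runs`.
#' @examples
#' p <- desk_params()
#' runs <- replicate(3, data.frame(t = 1:10, E = runif(10)), simplify = FALSE)
#' h <- ensemble_histogram(runs)
#' @export
ensemble_histogram <- function(runs, time_ratio = 10^(1 / 30),
                               bin_width = 0.01) {
  stopifnot(length(runs) >= 1, time_ratio > 1, bin_width > 0)
  t0 <- runs[[1]]$t
  for (r in runs) {
    if (length(r$t) != length(t0) || any(abs(r$t - t0) > 1e-9 * max(1, t0))) {
      stop("all runs must share the same recording cadence")
    }
  }
  tpos <- t0[t0 > 0]
  if (length(tpos) == 0) stop("no positive recorded times")
  # geometric grid spanning the recorded window, snapped to recorded times
  grid <- time_ratio^(seq(floor(log(min(tpos), time_ratio)),
                          ceiling(log(max(tpos), time_ratio))))
  sel <- unique(vapply(grid, function(g) which.min(abs(t0 - g)), integer(1)))
  sel <- sel[t0[sel] > 0]
  times <- t0[sel]
  n_runs <- length(runs)
  emat <- vapply(runs, function(r) r$E[sel], numeric(length(sel)))
  emat <- matrix(emat, nrow = length(sel))
  rows <- lapply(seq_along(sel), function(k) {
    bins <- floor(emat[k, ] / bin_width)
    cnt <- table(bins)
    data.frame(time_bin = times[k],
               e_bin = as.numeric(names(cnt)) * bin_width,
               count = as.integer(cnt))
  })
  hist <- do.call(rbind, rows)
  binder <- data.frame(
    t = times,
    B = vapply(seq_along(sel), function(k) {
      if (all(emat[k, ] == 0)) NA_real_ else binder_cumulant(emat[k, ])
    }, numeric(1)))
  structure(list(histogram = hist, times = times, binder = binder,
                 n_runs = n_runs, bin_width = bin_width,
                 time_ratio = time_ratio),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("ensemble_summary: %d runs over %d ratio-spaced times (ratio %.4f, E bin %.3g)\n",
              x$n_runs, length(x$times), x$time_ratio, x$bin_width))
  invisible(x)
}
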