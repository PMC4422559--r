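# Metabolite trajectories are interpolated on a uniform 1-minute grid over
# minutes 0..10 (11 stamps); transcript trajectories over minutes 0..24
# (25 stamps), where the derivative of the fitted smoothing spline is taken
# analytically from the cubic pieces.  Pre-shift samples (negative minutes)
# are treated as the steady state at t = 0.

MET_GRID <- 0:10
TR_GRID <- 0:24

# map pre-shift stamps to t = 0 and average duplicate stamps
collapse_pre_shift <- function(time, value) {
  keep <- !is.na(value)
  time <- pmax(time[keep], 0)
  value <- value[keep]
  agg <- tapply(value, time, mean)
  tibble(time = as.numeric(names(agg)), value = as.numeric(agg)) |>
    arrange(.data$time)
}

# fit one channel and evaluate (and optionally differentiate) on a grid.
# smoothing: "gcv" (generalized cross-validation), a numeric penalty lambda,
# or 0 for the vanishing-penalty limit = the interpolating cubic spline with
# Forsythe-Malcolm-Moler end conditions (reproduces cubics exactly).
interp_channel <- function(time, value, method, smoothing, grid, deriv = 0L) {
  if (method == "linear") {
    if (deriv != 0L) abort("analytic derivatives require the spline method")
    return(approx(time, value, xout = grid, ties = mean)$y)
  }
  interpolating <- identical(smoothing, 0) || identical(smoothing, 0L)
  if (!interpolating && length(unique(time)) < 4) {
    # a smoothing spline needs >= 4 distinct stamps; with exactly 3 the only
    # well-defined cubic is the interpolant
    interpolating <- TRUE
  }
  if (interpolating) {
    f <- splinefun(time, value, method = "fmm")
    return(f(grid, deriv = deriv))
  }
  fit <- if (identical(smoothing, "gcv")) {
    smooth.spline(time, value, cv = FALSE, keep.data = FALSE)
  } else {
    smooth.spline(time, value, lambda = as.numeric(smoothing), keep.data = FALSE)
  }
  predict(fit, x = grid, deriv = deriv)$y
}

check_coverage <- function(time, lo, hi, min_pts, what) {
  if (length(time) < min_pts) {
    abort(sprintf("%s: need at least %d observed time points, got %d",
                  what, min_pts, length(time)),
          class = "hubmotif_degenerate")
  }
  if (min(time) > lo || max(time) < hi) {
    abort(sprintf("%s: observed range [%g, %g] does not cover [%g, %g]; refusing to extrapolate",
                  what, min(time), max(time), lo, hi),
          class = "hubmotif_degenerate")
  }
}

#' Interpolate a metabolite trajectory on the minute grid
#'
#' Resamples one metabolite's observations onto minutes 0..10, either after
#' averaging replicates per time point (`mode = "average"`) or fitting each
#' replicate independently (`mode = "per_replicate"`).  Two interpolation
#' methods are supported: linear, and cubic smoothing spline (penalty chosen
#' by generalized cross-validation by default; pass `smoothing = 0` for the
#' interpolating-spline limit or a numeric lambda for a fixed penalty).
#'
#' @param data Data frame with columns `time`, `value` and (for
#'   per-replicate mode) `replicate`; rows for one metabolite in one
#'   condition.  Negative times are pre-shift steady-state samples and are
#'   mapped to t = 0.
#' @param method `"linear"` or `"smoothing_spline"`.
#' @param mode `"average"` or `"per_replicate"`.
#' @param smoothing `"gcv"`, a numeric penalty, or 0.
#' @return A tibble with columns `time` (0..10), `channel` (`"avg"` or
#'   `"r<k>"`), `value`; attribute `source_kind = "metabolite_level"`.
#' @examples
#' obs <- tibble::tibble(time = c(0, 10), value = c(1, 3))
#' interpolate_metabolite(obs)$value[6] # midpoint of the line: 2
#' @export
interpolate_metabolite <- function(data,
                                   method = c("linear", "smoothing_spline"),
                                   mode = c("average", "per_replicate"),
                                   smoothing = "gcv") {
  method <- match.arg(method)
  mode <- match.arg(mode)
  data <- as_tibble(data)
  min_pts <- if (method == "linear") 2L else 3L
  if (mode == "average" || !"replicate" %in% names(data)) {
    obs <- collapse_pre_shift(data$time, data$value)
    obs <- obs[obs$time <= max(MET_GRID), ]
    check_coverage(obs$time, 0, max(MET_GRID), min_pts, "metabolite interpolation")
    out <- tibble(time = MET_GRID, channel = "avg",
                  value = interp_channel(obs$time, obs$value, method, smoothing, MET_GRID))
  } else {
    out <- data |>
      group_by(.data$replicate) |>
      group_modify(function(df, key) {
        obs <- collapse_pre_shift(df$time, df$value)
        obs <- obs[obs$time <= max(MET_GRID), ]
        check_coverage(obs$time, 0, max(MET_GRID), min_pts,
                       paste0("metabolite interpolation (replicate ", key$replicate, ")"))
        tibble(time = MET_GRID,
               value = interp_channel(obs$time, obs$value, method, smoothing, MET_GRID))
      }) |>
      ungroup() |>
      mutate(channel = sprintf("r%d", .data$replicate)) |>
      select("time", "channel", "value")
  }
  structure(out, source_kind = "metabolite_level", interp_method = method)
}

#' Time derivative of a transcript trajectory
#'
#' Fits a cubic smoothing spline to one transcript's time course (minutes
#' 0..24) and returns the derivative of the fitted piecewise cubic,
#' evaluated analytically on the 1-minute grid -- no finite differencing.
#'
#' @param data Data frame with columns `time`, `value` (replicates, if any,
#'   are averaged per time point).
#' @param smoothing `"gcv"` (default), a numeric penalty, or 0 for the
#'   interpolating-spline limit.
#' @return A tibble with columns `time` (0..24), `channel = "avg"`, `value`
#'   (d level / d min); attribute `source_kind = "transcript_derivative"`.
#' @export
transcript_derivative <- function(data, smoothing = "gcv") {
  data <- as_tibble(data)
  obs <- collapse_pre_shift(data$time, data$value)
  obs <- obs[obs$time <= max(TR_GRID), ]
  check_coverage(obs$time, 0, max(TR_GRID), 4, "transcript derivative")
  out <- tibble(time = TR_GRID, channel = "avg",
                value = interp_channel(obs$time, obs$value, "smoothing_spline",
                                       smoothing, TR_GRID, deriv = 1L))
  structure(out, source_kind = "transcript_derivative", interp_method = "smoothing_spline")
}
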