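#' Six-parameter impulse model value
#'
#' The product-of-sigmoids impulse curve used to describe transient
#' transcriptional responses:
#' `f(t) = (1/h1) * (h0 + (h1-h0) * s(beta*(t-t1))) * (h2 + (h1-h2) * s(-beta*(t-t2)))`
#' with `s(z) = 1/(1+exp(-z))`.  `h0` is the initial level, `h1` the
#' peak/intermediate level, `h2` the final level, `t1`/`t2` the two
#' transition times (min) and `beta` the common slope.
#'
#' @param params List or one-row data frame with `h0`, `h1`, `h2`, `t1`,
#'   `t2`, `beta`.
#' @param t Time(s) in minutes.
#' @return Numeric vector of levels.
#' @examples
#' p <- list(h0 = 1, h1 = 3, h2 = 3, t1 = 5, t2 = 20, beta = 10)
#' impulse_value(p, c(0, 5, 10)) # approx 1, 2, 3
#' @export
impulse_value <- function(params, t) {
  p <- as.list(params)
  if (p$h1 == 0) abort("h1 must be non-zero")
  (1 / p$h1) *
    (p$h0 + (p$h1 - p$h0) * sigmoid(p$beta * (t - p$t1))) *
    (p$h2 + (p$h1 - p$h2) * sigmoid(-p$beta * (t - p$t2)))
}

impulse_sse <- function(theta, times, levels) {
  # theta: h0, h1, h2, t1, log(t2 - t1), log(beta)
  h1 <- theta[2]
  if (abs(h1) < 1e-9) return(1e12)
  p <- list(h0 = theta[1], h1 = h1, h2 = theta[3], t1 = theta[4],
            t2 = theta[4] + exp(theta[5]), beta = exp(theta[6]))
  r <- impulse_value(p, times) - levels
  s <- sum(r * r)
  if (!is.finite(s)) 1e12 else s
}

theta_to_params <- function(theta) {
  tibble(h0 = theta[1], h1 = theta[2], h2 = theta[3], t1 = theta[4],
         t2 = theta[4] + exp(theta[5]), beta = exp(theta[6]))
}

#' Fit the impulse model to a transcript time course
#'
#' Least-squares fit with seeded multi-start unconstrained optimization
#' (`beta > 0` and `t1 <= t2` are enforced by the parameterization).  Start
#' points draw the transition times from quantiles of the time range, the
#' levels from data quantiles, and `beta` log-uniformly from `[0.1, 10]`.
#'
#' @param times Observation times (minutes), at least 7.
#' @param levels Observed expression levels.
#' @param n_starts Number of optimization starts (default 10).
#' @param seed Integer seed for the starts.
#' @return An `impulse_fit`: list with `params` (one-row tibble), `sse`,
#'   `t_half` (onset time, `NA` with `flag = "flat"` for a flat profile)
#'   and the data.
#' @export
fit_impulse <- function(times, levels, n_starts = 10, seed = 1L) {
  stopifnot(length(times) == length(levels))
  keep <- is.finite(times) & is.finite(levels)
  times <- times[keep]; levels <- levels[keep]
  if (length(times) < 7) abort("impulse fit needs at least 7 time points")
  rng <- range(times)

  if (diff(range(levels)) < 1e-12) {
    c0 <- levels[1]
    params <- tibble(h0 = c0, h1 = if (c0 != 0) c0 else 1e-30, h2 = c0,
                     t1 = rng[1] + diff(rng) / 3, t2 = rng[1] + 2 * diff(rng) / 3,
                     beta = 1)
    fit <- structure(list(params = params, sse = 0, t_half = NA_real_,
                          flag = "flat", times = times, levels = levels),
                     class = "impulse_fit")
    return(fit)
  }

  best <- NULL
  with_rng_seed(seed, {
    qs <- quantile(levels, c(0.05, 0.5, 0.95), names = FALSE)
    for (s in seq_len(n_starts)) {
      t1_0 <- quantile(rng, runif(1, 0.1, 0.6), names = FALSE)
      dt_0 <- runif(1, 0.2, 0.8) * diff(rng)
      beta_0 <- exp(runif(1, log(0.1), log(10)))
      h_0 <- sample(qs)
      theta0 <- c(h_0[1], h_0[2], h_0[3], t1_0, log(dt_0), log(beta_0))
      opt <- tryCatch(
        optim(theta0, impulse_sse, times = times, levels = levels,
              method = "BFGS", control = list(maxit = 500, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(opt)) {
        # Nelder-Mead polish helps escape flat sigmoid gradients
        opt2 <- tryCatch(
          optim(opt$par, impulse_sse, times = times, levels = levels,
                method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-14)),
          error = function(e) opt)
        if (opt2$value < opt$value) opt <- opt2
        if (is.null(best) || opt$value < best$value) best <- opt
      }
    }
  })
  if (is.null(best)) abort("impulse fit failed for every start")
  params <- theta_to_params(best$par)
  ot <- onset_time(params, range = rng)
  structure(list(params = params, sse = best$value, t_half = ot$t_half,
                 flag = ot$flag, times = times, levels = levels),
            class = "impulse_fit")
}

#' Onset time of an impulse response
#'
#' The smallest time at which the fitted curve has covered half of its
#' maximum absolute change from the initial level, located by dense
#' evaluation on a 0.01-min grid with root refinement.  Flat curves (change
#' below tolerance) yield `NA` with flag `"flat"`.
#'
#' @param params Impulse parameters (list or one-row data frame).
#' @param range Time range `c(0, T)` to search.
#' @param tol Relative flatness tolerance.
#' @return List with `t_half` (minutes or `NA`) and `flag` (`"ok"` or
#'   `"flat"`).
#' @export
onset_time <- function(params, range = c(0, 24), tol = 1e-8) {
  grid <- seq(range[1], range[2], by = 0.01)
  f <- impulse_value(params, grid)
  g <- abs(f - f[1])
  m <- max(g)
  if (m < tol * max(1, abs(f[1]))) {
    return(list(t_half = NA_real_, flag = "flat"))
  }
  half <- m / 2
  i <- which(g >= half)[1]
  if (i == 1) return(list(t_half = grid[1], flag = "ok"))
  root <- tryCatch(
    uniroot(function(t) abs(impulse_value(params, t) - f[1]) - half,
            lower = grid[i - 1], upper = grid[i], tol = 1e-6)$root,
    error = function(e) grid[i])
  list(t_half = root, flag = "ok")
}

#' @export
print.impulse_fit <- function(x, ...) {
  cat("<impulse_fit>\n")
  cat(sprintf("  sse = %.4g, t_half = %s min%s\n", x$sse,
              if (is.na(x$t_half)) "NA" else sprintf("%.2f", x$t_half),
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  print(x$params)
  invisible(x)
}

#' @rdname fit_impulse
#' @param x An `impulse_fit`.
#' @param ... Unused.
#' @export
tidy.impulse_fit <- function(x, ...) {
  x$params |>
    pivot_longer(dplyr::everything(), names_to = "term", values_to = "estimate")
}

#' @rdname fit_impulse
#' @export
glance.impulse_fit <- function(x, ...) {
  tibble(sse = x$sse, t_half = x$t_half, flag = x$flag,
         n = length(x$times))
}
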