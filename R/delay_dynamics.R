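#' Delay logistic parameter set
#'
#' Bundles the parameters of the delay logistic growth model
#' \deqn{dx/dt = \mu\, x(t-\tau_1)\,(1 - x(t-\tau_2)/K),}
#' where \eqn{\mu} is the specific growth rate (1/h), \eqn{K} the carrying
#' capacity, \eqn{\tau_1} the reproductive delay and \eqn{\tau_2} the
#' reaction delay (both hours).  With both delays zero the model is the
#' ordinary logistic equation.
#'
#' @param mu Specific growth rate (1/h), finite, `>= 0`.
#' @param K Carrying capacity (abundance units), finite, `> 0`.
#' @param tau1 Reproductive delay (h), `>= 0`.
#' @param tau2 Reaction delay (h), `>= 0`.
#' @param x0 Initial abundance (same units as `K`), `>= 0`.
#' @return An object of class `delay_logistic_params`.
#' @examples
#' delay_logistic_params(mu = 0.5, K = 1, tau1 = 4.02, tau2 = 8.53, x0 = 0.1)
#' @export
delay_logistic_params <- function(mu, K, tau1 = 0, tau2 = 0, x0 = K / 10) {
  stopifnot(is.numeric(mu), is.finite(mu), mu >= 0,
            is.numeric(K), is.finite(K), K > 0,
            is.numeric(tau1), is.finite(tau1), tau1 >= 0,
            is.numeric(tau2), is.finite(tau2), tau2 >= 0,
            is.numeric(x0), is.finite(x0), x0 >= 0)
  structure(list(mu = mu, K = K, tau1 = tau1, tau2 = tau2, x0 = x0),
            class = "delay_logistic_params")
}

#' @export
print.delay_logistic_params <- function(x, ...) {
  cat(sprintf(
    "Delay logistic parameters: mu = %g /h, K = %g, tau1 = %g h, tau2 = %g h, x0 = %g\n",
    x$mu, x$K, x$tau1, x$tau2, x$x0))
  invisible(x)
}

#' Construct a trajectory
#'
#' A trajectory is a time-indexed abundance series: a data frame with
#' strictly increasing `time` (hours) and non-negative finite `value`.
#'
#' @param times Numeric vector, strictly increasing.
#' @param values Numeric vector of the same length, finite and `>= 0`.
#' @return A `data.frame` of class `trajectory` with columns `time`, `value`.
#' @export
trajectory <- function(times, values) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values), length(times) >= 1)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (any(!is.finite(values)) || any(values < 0))
    stop("`values` must be finite and non-negative")
  structure(data.frame(time = as.numeric(times), value = as.numeric(values)),
            class = c("trajectory", "data.frame"))
}

#' Integrate the delay logistic equation
#'
#' Method-of-steps integration with fixed-step classical Runge--Kutta (RK4)
#' and linear interpolation for delayed lookups.  The history is the
#' constant `x0` for `t <= 0` (an inoculation scenario).  Negative
#' excursions, which the delay logistic can produce, are clamped to zero
#' with a warning.
#'
#' @param params A [delay_logistic_params()] object.
#' @param horizon Integration horizon (h), `> 0`.
#' @param dt Step size (h), `> 0`.  When either delay is positive, `dt`
#'   should not exceed the smallest positive delay so that delayed lookups
#'   land on resolved history.
#' @return A [trajectory()] on the grid `seq(0, horizon, by = dt)`.
#' @examples
#' p <- delay_logistic_params(mu = 1, K = 100, x0 = 1)
#' tr <- integrate_dde(p, horizon = 10, dt = 0.01)
#' tail(tr, 1) # approaches K = 100
#' @export
integrate_dde <- function(params, horizon, dt) {
  stopifnot(inherits(params, "delay_logistic_params"))
  if (!is.numeric(horizon) || length(horizon) != 1 || !is.finite(horizon) || horizon <= 0)
    stop("`horizon` must be a positive number")
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a positive number")
  pos <- c(params$tau1, params$tau2)
  pos <- pos[pos > 0]
  if (length(pos) && dt > min(pos) + 1e-12)
    warning("dt exceeds the smallest positive delay; delayed lookups are clamped")
  res <- cpp_dde_logistic(params$mu, params$K, params$tau1, params$tau2,
                          params$x0, horizon, dt)
  if (res$diverged_at >= 0)
    stop(sprintf("delay logistic integration diverged at step %d (t = %g h)",
                 res$diverged_at, res$diverged_at * dt))
  if (res$clamped > 0)
    warning(sprintf("negative abundance clamped to 0 at %d step(s)", res$clamped))
  n <- length(res$values) - 1L
  trajectory(seq(0, by = dt, length.out = n + 1L), res$values)
}

#' Closed-form logistic solution
#'
#' \eqn{x(t) = K x_0 e^{\mu t} / (K + x_0 (e^{\mu t} - 1))}; the zero-delay
#' limit of the delay logistic model, used as an integration oracle.
#'
#' @param t Time(s) (h).
#' @inheritParams delay_logistic_params
#' @return Abundance at `t`.
#' @export
logistic_closed_form <- function(t, mu, K, x0) {
  e <- exp(mu * t)
  K * x0 * e / (K + x0 * (e - 1))
}

#' Classify the dynamic response regime of a trajectory
#'
#' Inspects deviations `x - K` over an analysis window (by default the last
#' half of the samples).  No sign change means asymptotic stabilization;
#' sign changes with successive peak amplitudes decaying by more than `tol`
#' per peak mean convergent fluctuation; anything else is sustained or
#' divergent oscillation.
#'
#' @param traj A [trajectory()].
#' @param K Carrying capacity used as the reference level.
#' @param window Fraction of the series (from the end) to analyse, in (0, 1].
#' @param tol Required fractional decay between successive peak amplitudes.
#' @return One of `"asymptotic_stabilization"`, `"convergent_fluctuation"`,
#'   `"sustained_or_divergent"`.
#' @export
classify_response <- function(traj, K, window = 0.5, tol = 0.05) {
  stopifnot(inherits(traj, "trajectory"), is.numeric(K), K > 0,
            window > 0, window <= 1)
  n <- nrow(traj)
  if (n < 10) stop("insufficient data: trajectory has fewer than 10 samples")
  idx <- seq.int(max(1L, n - ceiling(window * n) + 1L), n)
  e <- traj$value[idx] - K
  eps <- 1e-8 * K
  s <- sign(e)
  s[abs(e) < eps] <- 0
  # indices where the deviation crosses zero (consecutive nonzero opposite signs)
  nz <- which(s != 0)
  if (!length(nz)) return("asymptotic_stabilization")
  runs <- rle(s[nz])
  if (length(runs$values) == 1) return("asymptotic_stabilization")
  # peak amplitude of each constant-sign segment, in order
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  amps <- vapply(seq_along(ends), function(k) {
    seg <- nz[starts[k]:ends[k]]
    max(abs(e[seg]))
  }, numeric(1))
  amps <- amps[amps >= eps]
  if (length(amps) < 2) return("convergent_fluctuation")
  ratios <- amps[-1] / head(amps, -1)
  if (all(ratios < 1 - tol)) "convergent_fluctuation" else "sustained_or_divergent"
}

#' Estimate the specific growth rate from a trajectory
#'
#' Discrete estimator \eqn{\mu = \Delta x / (x \Delta t)} averaged over the
#' per-interval values, using the left endpoint for `x`.
#'
#' @param traj A [trajectory()] with at least 2 samples.
#' @param window Optional index range (integer vector) designating the
#'   exponential-phase samples to use; default is the whole series.
#' @return Estimated specific growth rate (1/h).
#' @examples
#' specific_growth_rate(trajectory(c(0, 1), c(100, 110))) # 0.1
#' @export
specific_growth_rate <- function(traj, window = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  x <- traj$value
  t <- traj$time
  if (!is.null(window)) {
    x <- x[window]
    t <- t[window]
  }
  if (length(x) < 2) stop("need at least 2 samples")
  if (any(x <= 0)) stop("all abundances in the window must be positive")
  mean(diff(x) / (head(x, -1) * diff(t)))
}

#' Identify reproductive and reaction delays by dynamic response optimization
#'
#' Fits the delay logistic model to an observed abundance series by
#' minimizing the sum of squared residuals over \eqn{(\tau_1, \tau_2)}:
#' a coarse grid scan over the search box followed by Nelder--Mead
#' refinement from the best grid point.  `mu` and `K` are fixed externally
#' (estimate them with [specific_growth_rate()] and the series plateau), or
#' co-estimated when `co_estimate = TRUE`.  95% intervals come from a
#' residual bootstrap (resample residuals, refit from the point estimate).
#'
#' @param observed A [trajectory()] on a uniform time grid.
#' @param mu Specific growth rate (1/h) to hold fixed.
#' @param K Carrying capacity to hold fixed.
#' @param bounds List with elements `tau1` and `tau2`, each `c(lower, upper)`
#'   in hours, lower `>= 0`.
#' @param n_boot Number of residual-bootstrap refits for the 95% intervals;
#'   `0` skips the bootstrap and reports degenerate intervals at the point
#'   estimate.
#' @param seed Optional integer seed for the bootstrap resampling.
#' @param grid_n Coarse grid resolution per delay axis.
#' @param co_estimate Also optimize `mu` and `K` (4-parameter Nelder--Mead).
#' @param x0 Initial abundance for the fitted model; defaults to the first
#'   observed value.
#' @return An object of class `delay_estimate`: a list with `tau1_hat`,
#'   `tau2_hat`, `tau1_ci`, `tau2_ci`, `objective` (residual sum of squares),
#'   `bound_hit` (logical), `mu`, `K`, `n_boot`.
#' @export
identify_delays <- function(observed, mu, K,
                            bounds = list(tau1 = c(0, 6), tau2 = c(0, 12)),
                            n_boot = 0, seed = NULL, grid_n = 40,
                            co_estimate = FALSE, x0 = NULL) {
  stopifnot(inherits(observed, "trajectory"))
  dts <- diff(observed$time)
  if (max(dts) - min(dts) > 1e-8 * mean(dts))
    stop("`observed` must be on a uniform time grid")
  b1 <- as.numeric(bounds$tau1)
  b2 <- as.numeric(bounds$tau2)
  stopifnot(length(b1) == 2, length(b2) == 2, all(is.finite(c(b1, b2))),
            b1[1] >= 0, b2[1] >= 0, b1[2] > b1[1], b2[2] > b2[1])
  dt <- mean(dts)
  horizon <- max(observed$time) - observed$time[1]
  x0_from_data <- is.null(x0)
  if (x0_from_data) x0 <- observed$value[1]
  y <- observed$value

  model <- function(tau1, tau2, mu_, K_, x0_ = x0) {
    res <- cpp_dde_logistic(mu_, K_, tau1, tau2, x0_, horizon, dt)
    if (res$diverged_at >= 0) return(NULL)
    res$values
  }
  rss_for <- function(tau1, tau2, mu_, K_, target, x0_ = x0) {
    f <- model(tau1, tau2, mu_, K_, x0_)
    if (is.null(f) || length(f) != length(target)) return(1e300)
    sum((f - target)^2)
  }
  clamp <- function(v, b) pmin(pmax(v, b[1]), b[2])

  fit_taus <- function(target, start = NULL, x0_ = x0) {
    if (is.null(start)) {
      g1 <- seq(b1[1], b1[2], length.out = grid_n)
      g2 <- seq(b2[1], b2[2], length.out = grid_n)
      best <- c(g1[1], g2[1])
      best_v <- Inf
      for (a in g1) for (b in g2) {
        v <- rss_for(a, b, mu, K, target, x0_)
        if (v < best_v) { best_v <- v; best <- c(a, b) }
      }
      start <- best
    }
    obj <- function(th) {
      pen <- sum(pmax(0, b1[1] - th[1], th[1] - b1[2])) +
             sum(pmax(0, b2[1] - th[2], th[2] - b2[2]))
      rss_for(clamp(th[1], b1), clamp(th[2], b2), mu, K, target, x0_) + 1e6 * pen
    }
    op <- stats::optim(start, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 1000))
    list(tau = c(clamp(op$par[1], b1), clamp(op$par[2], b2)), value = op$value)
  }

  if (co_estimate) {
    start0 <- fit_taus(y)
    obj4 <- function(th) {
      if (th[3] <= 0 || th[4] <= 0) return(1e300)
      pen <- sum(pmax(0, b1[1] - th[1], th[1] - b1[2])) +
             sum(pmax(0, b2[1] - th[2], th[2] - b2[2]))
      rss_for(clamp(th[1], b1), clamp(th[2], b2), th[3], th[4], y) + 1e6 * pen
    }
    op <- stats::optim(c(start0$tau, mu, K), obj4, method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 2000))
    mu <- op$par[3]; K <- op$par[4]
    fit <- list(tau = c(clamp(op$par[1], b1), clamp(op$par[2], b2)),
                value = op$value)
  } else {
    fit <- fit_taus(y)
  }

  # a zero lower bound is a meaningful no-delay estimate, not a constraint hit
  tol_b <- 1e-6
  hit <- function(v, b) (b[1] > 0 && abs(v - b[1]) < tol_b) || abs(v - b[2]) < tol_b
  bound_hit <- hit(fit$tau[1], b1) || hit(fit$tau[2], b2)

  tau1_ci <- rep(fit$tau[1], 2)
  tau2_ci <- rep(fit$tau[2], 2)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    fhat <- model(fit$tau[1], fit$tau[2], mu, K)
    r <- y - fhat
    boots <- matrix(NA_real_, n_boot, 2)
    for (bb in seq_len(n_boot)) {
      ystar <- fhat + sample(r, length(r), replace = TRUE)
      # when x0 is taken from the data it is itself noisy, and its error is
      # a dominant component of the delay estimator's error (a shift in x0
      # trades off against tau1 as a time shift); propagate it by refitting
      # with the resampled first observation
      x0_b <- if (x0_from_data) ystar[1] else x0
      boots[bb, ] <- fit_taus(ystar, start = fit$tau, x0_ = x0_b)$tau
    }
    q1 <- stats::quantile(boots[, 1], c(0.025, 0.975), names = FALSE)
    q2 <- stats::quantile(boots[, 2], c(0.025, 0.975), names = FALSE)
    tau1_ci <- c(min(q1[1], fit$tau[1]), max(q1[2], fit$tau[1]))
    tau2_ci <- c(min(q2[1], fit$tau[2]), max(q2[2], fit$tau[2]))
  }

  structure(list(tau1_hat = fit$tau[1], tau2_hat = fit$tau[2],
                 tau1_ci = tau1_ci, tau2_ci = tau2_ci,
                 objective = fit$value, bound_hit = bound_hit,
                 mu = mu, K = K, n_boot = n_boot),
            class = "delay_estimate")
}

#' @export
print.delay_estimate <- function(x, ...) {
  cat(sprintf("Reproductive delay tau1: %.3f h  [%.3f, %.3f]\n",
              x$tau1_hat, x$tau1_ci[1], x$tau1_ci[2]))
  cat(sprintf("Reaction delay     tau2: %.3f h  [%.3f, %.3f]\n",
              x$tau2_hat, x$tau2_ci[1], x$tau2_ci[2]))
  cat(sprintf("RSS: %.4g   (mu = %.4g, K = %.4g, bootstrap n = %d%s)\n",
              x$objective, x$mu, x$K, x$n_boot,
              if (x$bound_hit) ", WARNING: estimate at a search bound" else ""))
  invisible(x)
}

#' Read and write abundance time-series tables
#'
#' Delimited text with a `time` column (hours) and one column per taxon.
#'
#' @param path File path.
#' @return `read_series` returns a data frame; `series_trajectory` extracts
#'   one taxon column as a [trajectory()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("series file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop("series file is empty: ", path)
  if (!"time" %in% names(df)) stop("series file must have a 'time' column")
  for (cn in names(df)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(df[[cn]])))) &
                   !is.na(df[[cn]]) & df[[cn]] != "")
    nas <- which(is.na(df[[cn]]))
    if (length(bad)) stop(sprintf("non-numeric value in column '%s' at row %d",
                                  cn, bad[1]))
    if (length(nas)) stop(sprintf("missing value in column '%s' at row %d",
                                  cn, nas[1]))
    df[[cn]] <- as.numeric(df[[cn]])
  }
  df
}

#' @rdname read_series
#' @param df A series data frame from [read_series()].
#' @param taxon Column name to extract.
#' @export
series_trajectory <- function(df, taxon) {
  if (!taxon %in% names(df))
    stop(sprintf("taxon '%s' not found; available columns: %s", taxon,
                 paste(setdiff(names(df), "time"), collapse = ", ")))
  trajectory(df$time, df[[taxon]])
}

#' @rdname read_series
#' @param series A data frame with a `time` column to write.
#' @export
write_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
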