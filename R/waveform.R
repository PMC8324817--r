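#' Periodic protein-abundance profiles
#'
#' A `periodic_profile` represents a strictly positive concentration waveform
#' x(t) with period `T` (hours), evaluable together with its first derivative
#' at any real time; evaluation reduces t modulo `T`. Profiles can be built
#' from dense samples over one period (interpolated with a periodic cubic
#' spline) or directly from a function.
#'
#' @param times sample times in hours, within one period (first point taken as
#'   the phase origin). Ignored when `f` is given.
#' @param values strictly positive sample values (concentration, nM or
#'   copies/cell) matching `times`.
#' @param period oscillation period T in hours (default 24).
#' @param f optional function of time returning x(t); used instead of samples.
#' @param df optional derivative function for `f`; when absent the derivative
#'   is taken by central differences (step 1e-4 h).
#' @return an object of class `periodic_profile`.
#' @examples
#' p <- periodic_profile(f = function(t) 1 + 0.5 * sin(2 * pi * t / 24))
#' predict(p, c(0, 6, 30))
#' @export
periodic_profile <- function(times = NULL, values = NULL, period = 24,
                             f = NULL, df = NULL) {
  stopifnot(is.numeric(period), length(period) == 1L, period > 0)
  if (!is.null(f)) {
    fun <- function(t) f(t %% period)
    dfun <- if (!is.null(df)) {
      function(t) df(t %% period)
    } else {
      function(t) {
        h <- 1e-4
        (f((t + h) %% period) - f((t - h) %% period)) / (2 * h)
      }
    }
    obj <- structure(list(period = period, f = fun, df = dfun,
                          kind = "function"),
                     class = "periodic_profile")
  } else {
    stopifnot(is.numeric(times), is.numeric(values),
              length(times) == length(values), length(times) >= 3L)
    o <- order(times)
    times <- times[o]; values <- values[o]
    if (anyDuplicated(times)) stop("duplicate sample times in profile")
    if (diff(range(times)) >= period)
      stop("sample times must span less than one period")
    # close the period so the spline sees matching endpoint values
    tt <- c(times, times[1L] + period)
    vv <- c(values, values[1L])
    sf <- stats::splinefun(tt, vv, method = "periodic")
    t0 <- times[1L]
    fun <- function(t) sf(t0 + (t - t0) %% period)
    dfun <- function(t) sf(t0 + (t - t0) %% period, deriv = 1L)
    obj <- structure(list(period = period, f = fun, df = dfun,
                          kind = "spline", times = times, values = values),
                     class = "periodic_profile")
  }
  validate_profile(obj)
  obj
}

validate_profile <- function(p, n_check = 481L) {
  tt <- seq(0, p$period, length.out = n_check)
  v <- p$f(tt)
  if (any(!is.finite(v))) stop("profile evaluates to non-finite values")
  if (any(v <= 0)) stop("profile must be strictly positive over the period")
  invisible(p)
}

#' @export
print.periodic_profile <- function(x, ...) {
  tt <- seq(0, x$period, length.out = 241L)
  v <- x$f(tt)
  cat(sprintf("periodic_profile (%s-backed): T = %g h, range [%.4g, %.4g], mean %.4g\n",
              x$kind, x$period, min(v), max(v), mean(v)))
  invisible(x)
}

#' Evaluate a periodic profile or its derivative
#'
#' @param object a [periodic_profile()].
#' @param t times in hours (any real values; reduced modulo the period).
#' @param deriv 0 for x(t), 1 for x'(t).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.periodic_profile <- function(object, t, deriv = 0L, ...) {
  if (deriv == 0L) object$f(t) else object$df(t)
}

#' Mean of a profile over one period
#'
#' Time average \eqn{\langle x \rangle_t} by trapezoidal quadrature on a dense
#' grid (default step 0.01 h).
#' @param profile a [periodic_profile()].
#' @param dt quadrature step in hours.
#' @return scalar mean concentration.
#' @export
profile_mean <- function(profile, dt = 0.01) {
  tt <- seq(0, profile$period, by = dt)
  trapz_mean(tt, profile$f(tt))
}

## trapezoidal average of y(t) over [t[1], t[n]]
trapz_mean <- function(t, y) {
  n <- length(t)
  sum((y[-1] + y[-n]) * diff(t)) / (2 * (t[n] - t[1L]))
}

trapz_int <- function(t, y) {
  n <- length(t)
  sum((y[-1] + y[-n]) * diff(t)) / 2
}

#' Degradation-rate series over one period
#'
#' Non-negative rates r(t) in 1/h sampled at `times`; periodic extension by
#' wrap-around, evaluation by linear interpolation.
#'
#' @param times hours within one period.
#' @param rates rates in 1/h, same length, all >= 0 (small negative values are
#'   rejected).
#' @param period period in hours.
#' @return object of class `rate_series`.
#' @export
rate_series <- function(times, rates, period = 24) {
  stopifnot(length(times) == length(rates), length(times) >= 2L, period > 0)
  o <- order(times)
  times <- times[o]; rates <- rates[o]
  if (any(!is.finite(rates))) stop("non-finite rates")
  if (any(rates < 0)) stop("rates must be non-negative")
  structure(list(times = times, rates = rates, period = period),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("rate_series: T = %g h, %d points, range [%.4g, %.4g] /h\n",
              x$period, length(x$times), min(x$rates), max(x$rates)))
  invisible(x)
}

#' Evaluate a rate series at arbitrary times (periodic linear interpolation)
#'
#' @param object a [rate_series()].
#' @param t times in hours.
#' @param ... unused.
#' @export
predict.rate_series <- function(object, t, ...) {
  t0 <- object$times[1L]
  tm <- t0 + (t - t0) %% object$period
  tt <- object$times; rr <- object$rates
  if (max(tt) - t0 < object$period - 1e-12) {      # close the period
    tt <- c(tt, t0 + object$period); rr <- c(rr, rr[1L])
  }
  stats::approx(tt, rr, xout = tm, rule = 2)$y
}

#' Logarithmic decline rate of a profile
#'
#' Returns \eqn{-x'(t)/x(t)}, positive during the falling phase of the
#' waveform. This quantity is the pointwise lower bound of any constant
#' degradation rate able to sustain the waveform.
#'
#' @param profile a [periodic_profile()].
#' @param t times in hours.
#' @return rates in 1/h (may be negative in the rising phase).
#' @export
log_decline_rate <- function(profile, t) {
  v <- -profile$df(t) / profile$f(t)
  if (any(!is.finite(v))) stop("non-finite log-decline rate")
  v
}

#' Pointwise lower bound of the degradation rate
#'
#' \eqn{\max(-x'(t)/x(t), 0)}: because synthesis cannot be negative, any
#' feasible degradation rate r(t) satisfies r(t) >= this floor at every t.
#'
#' @inheritParams log_decline_rate
#' @export
degradation_floor <- function(profile, t) {
  pmax(log_decline_rate(profile, t), 0)
}

#' Minimum constant degradation rate sustaining a waveform
#'
#' \eqn{\max_t[-x'(t)/x(t)]} over one period, located on a dense grid
#' (default 0.01 h) and refined with a local continuous optimizer.
#'
#' @param profile a [periodic_profile()].
#' @param dt grid step in hours.
#' @return rate in 1/h (0 for a constant profile).
#' @export
min_constant_rate <- function(profile, dt = 0.01) {
  tt <- seq(0, profile$period, by = dt)
  v <- log_decline_rate(profile, tt)
  i <- which.max(v)
  lo <- tt[max(i - 1L, 1L)]; hi <- tt[min(i + 1L, length(tt))]
  op <- stats::optimize(function(t) log_decline_rate(profile, t),
                        interval = c(lo, hi), maximum = TRUE)
  max(v[i], op$objective, 0)
}

#' Cost lower bound under a constant degradation rate
#'
#' \eqn{c_g = \max_t[-x'/x] \cdot \langle x \rangle_t}: the least average
#' synthesis flux able to sustain the waveform when the degradation rate is
#' constant over the day.
#'
#' @param profile a [periodic_profile()].
#' @param dt grid step in hours.
#' @return cost in concentration/h.
#' @export
cg <- function(profile, dt = 0.01) {
  min_constant_rate(profile, dt = dt) * profile_mean(profile, dt = dt)
}

#' Synthesis rate implied by the abundance/degradation balance
#'
#' g(t) = x'(t) + r(t) x(t). A negative g anywhere marks the (profile, rate)
#' pair as biologically infeasible; the value is still returned.
#'
#' @param profile a [periodic_profile()].
#' @param rates a [rate_series()] (or function of t returning 1/h).
#' @param dt output grid step in hours.
#' @return list with `times`, `g`, `min_g`.
#' @export
synthesis_from_balance <- function(profile, rates, dt = 0.01) {
  tt <- seq(0, profile$period, by = dt)
  r <- eval_rates(rates, tt)
  g <- profile$df(tt) + r * profile$f(tt)
  list(times = tt, g = g, min_g = min(g))
}

eval_rates <- function(rates, t) {
  if (inherits(rates, "rate_series")) predict(rates, t)
  else if (is.function(rates)) rates(t)
  else stop("rates must be a rate_series or a function")
}

#' Proteosynthetic cost of a (profile, degradation-rate) pair
#'
#' The cost is the average protein amount synthesized per unit time over one
#' period, \eqn{\langle g \rangle = \langle r x \rangle}. Both sides of the
#' balance are reported; a negative implied synthesis rate anywhere flags the
#' pair as infeasible.
#'
#' @inheritParams synthesis_from_balance
#' @return object of class `cost_summary`: `mean_synthesis`,
#'   `mean_degradation`, `per_period_amount`, `cg`, `feasible`.
#' @export
synthesis_cost <- function(profile, rates, dt = 0.01) {
  tt <- seq(0, profile$period, by = dt)
  r <- eval_rates(rates, tt)
  x <- profile$f(tt)
  rx <- trapz_mean(tt, r * x)
  g <- profile$df(tt) + r * x
  structure(list(mean_synthesis = trapz_mean(tt, g),
                 mean_degradation = rx,
                 per_period_amount = profile$period * rx,
                 cg = cg(profile, dt = dt),
                 feasible = min(g) >= -1e-9 * max(abs(g))),
            class = "cost_summary")
}

#' @export
print.cost_summary <- function(x, ...) {
  cat(sprintf("cost_summary: <g> = %.6g, <r x> = %.6g, per-period %.6g, cg = %.6g%s\n",
              x$mean_synthesis, x$mean_degradation, x$per_period_amount, x$cg,
              if (x$feasible) "" else " [infeasible: g(t) < 0 somewhere]"))
  invisible(x)
}

#' Rhythmicity of a degradation rate
#'
#' \eqn{\alpha_D = (\max_t r - \min_t r) / \max_t r}: 0 for a constant rate,
#' approaching 1 for a strongly rhythmic one.
#'
#' @param rates a [rate_series()] or numeric vector of rates.
#' @return dimensionless value in [0, 1).
#' @export
alpha_D <- function(rates) {
  r <- if (inherits(rates, "rate_series")) rates$rates else rates
  stopifnot(is.numeric(r), length(r) >= 1L)
  if (max(r) <= 0) stop("alpha_D undefined for an all-zero degradation rate")
  (max(r) - min(r)) / max(r)
}

#' Overlap similarity between two degradation-rate profiles
#'
#' \eqn{S = \int_0^T \min(r, r_E)\,dt / \int_0^T \max(r, r_E)\,dt}, in [0, 1],
#' equal to 1 iff the profiles coincide almost everywhere. Both series are
#' resampled to the union of their grids (plus a uniform grid at `dt`).
#'
#' @param r,rE [rate_series()] objects (or functions of t) with equal periods.
#' @param period period in hours, required when both arguments are functions.
#' @param dt densification step in hours.
#' @return similarity in [0, 1].
#' @export
similarity_S <- function(r, rE, period = NULL, dt = 0.05) {
  per <- period
  for (obj in list(r, rE)) if (inherits(obj, "rate_series")) {
    if (is.null(per)) per <- obj$period
    else if (abs(per - obj$period) > 1e-9) stop("periods differ")
  }
  if (is.null(per)) stop("period must be given when both inputs are functions")
  grid <- seq(0, per, by = dt)
  for (obj in list(r, rE)) if (inherits(obj, "rate_series"))
    grid <- c(grid, obj$times %% per)
  grid <- sort(unique(grid))
  v1 <- eval_rates(r, grid); v2 <- eval_rates(rE, grid)
  den <- trapz_int(grid, pmax(v1, v2))
  if (den <= 0) stop("similarity undefined: both rate profiles are zero")
  trapz_int(grid, pmin(v1, v2)) / den
}

#' Protein half-life from a degradation rate
#'
#' @param rate degradation rate(s) in 1/h, strictly positive.
#' @return half-life ln(2)/rate in hours.
#' @export
half_life <- function(rate) {
  if (any(rate <= 0)) stop("half_life requires a positive rate")
  log(2) / rate
}

#' Minimum synthesis reduction paying off phosphorylation ATP expense
#'
#' Peptide-bond formation releases at least four phosphoryl groups per amino
#' acid, so n phosphorylation events per degraded protein of N amino acids are
#' energetically repaid once phospho-dependent ubiquitination trims at least
#' n/(4N) of the protein synthesis.
#'
#' @param n number of phosphorylation events required for ubiquitination.
#' @param N number of amino acids in the protein.
#' @return dimensionless fraction n/(4N).
#' @export
atp_payoff_fraction <- function(n, N) {
  stopifnot(N >= 1, n >= 0)
  n / (4 * N)
}

#' Read/write a profile or rate series as two-column CSV
#'
#' Files have a header row `time_h,value`; lines starting with `#` are
#' comments.
#'
#' @param path file path.
#' @param period period in hours for the constructed object.
#' @return [read_profile_csv()] returns a [periodic_profile()];
#'   [read_rates_csv()] a [rate_series()].
#' @export
read_profile_csv <- function(path, period = 24) {
  d <- read_two_col(path)
  periodic_profile(d$time_h, d$value, period = period)
}

#' @rdname read_profile_csv
#' @export
read_rates_csv <- function(path, period = 24) {
  d <- read_two_col(path)
  rate_series(d$time_h, d$value, period = period)
}

read_two_col <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_h", "value") %in% names(d)))
    stop("expected columns time_h,value in ", path)
  d
}

#' @rdname read_profile_csv
#' @param object a [periodic_profile()] or [rate_series()].
#' @param dt sampling step for function-backed profiles.
#' @export
write_profile_csv <- function(object, path, dt = 0.25) {
  if (inherits(object, "periodic_profile")) {
    tt <- seq(0, object$period - dt / 2, by = dt)
    d <- data.frame(time_h = tt, value = object$f(tt))
  } else if (inherits(object, "rate_series")) {
    d <- data.frame(time_h = object$times, value = object$rates)
  } else stop("unsupported object")
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
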