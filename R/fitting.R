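## Empirical stages: time-series ingestion, smoothing/spline/normalization,
## empirical degradation-rate profile construction, uniform parameter scans
## and simplex optimization of profile similarity or cost.

#' Time-stamped replicated measurements
#'
#' @param time_h times in hours (CT or ZT labels are both treated as plain
#'   hour coordinates).
#' @param value measured values (relative abundance, 1/h rate, or relative
#'   ubiquitinated fraction, per `kind`).
#' @param replicate optional replicate labels (default all 1).
#' @param kind one of "abundance", "rate", "fraction".
#' @param period period in hours used by periodic operations.
#' @return data frame of class `empirical_series`, sorted by time.
#' @export
empirical_series <- function(time_h, value, replicate = NULL,
                             kind = c("abundance", "rate", "fraction"),
                             period = 24) {
  kind <- match.arg(kind)
  if (is.null(replicate)) replicate <- rep(1L, length(time_h))
  stopifnot(length(time_h) == length(value),
            length(replicate) == length(time_h))
  if (length(unique(time_h)) < 2L)
    stop("an empirical series needs at least 2 distinct time points")
  d <- data.frame(time_h = time_h, value = value, replicate = replicate)
  if (anyDuplicated(d[c("time_h", "replicate")]))
    stop("duplicate (time, replicate) rows")
  d <- d[order(d$time_h, d$replicate), , drop = FALSE]
  rownames(d) <- NULL
  structure(d, class = c("empirical_series", "data.frame"),
            kind = kind, period = period)
}

#' Replicate-averaged values of an empirical series
#'
#' @param series an [empirical_series()].
#' @return data frame with columns time_h, value (mean across replicates).
#' @export
series_means <- function(series) {
  agg <- stats::aggregate(value ~ time_h, data = as.data.frame(series), FUN = mean)
  agg[order(agg$time_h), , drop = FALSE]
}

#' Read a time series from CSV
#'
#' Expects columns `time_h`, `value` and optionally `replicate`; `#` starts a
#' comment line. Rows are sorted by time; duplicate (time, replicate) pairs
#' are rejected.
#'
#' @param path file path.
#' @param kind,period see [empirical_series()].
#' @export
read_timeseries <- function(path, kind = "abundance", period = 24) {
  d <- utils::read.csv(path, comment.char = "#")
  if (nrow(d) == 0L) stop("empty time-series file: ", path)
  if (!all(c("time_h", "value") %in% names(d)))
    stop("expected columns time_h,value in ", path)
  bad <- which(!is.finite(d$time_h) | !is.finite(d$value))
  if (length(bad))
    stop("unparseable rows in ", path, " at data line(s) ",
         paste(bad, collapse = ", "))
  empirical_series(d$time_h, d$value, d$replicate, kind = kind, period = period)
}

#' Centered moving-window average of a series
#'
#' Averages the replicate means within a centered window of `window_hours`
#' (inclusive endpoints). When `periodic` the window wraps around the series
#' period; otherwise it is truncated at the ends.
#'
#' @param series an [empirical_series()].
#' @param window_hours window width in hours, > 0.
#' @param periodic wrap the window around the period?
#' @return an [empirical_series()] with one (smoothed) replicate.
#' @export
moving_average <- function(series, window_hours, periodic = FALSE) {
  stopifnot(window_hours > 0)
  m <- series_means(series)
  span <- diff(range(m$time_h))
  if (!periodic && window_hours >= 2 * span)
    stop("window must be smaller than the series span")
  per <- attr(series, "period")
  half <- window_hours / 2
  sm <- vapply(m$time_h, function(t0) {
    if (periodic) {
      d <- (m$time_h - t0) %% per
      d <- pmin(d, per - d)
      mean(m$value[d <= half + 1e-12])
    } else {
      mean(m$value[abs(m$time_h - t0) <= half + 1e-12])
    }
  }, 0)
  empirical_series(m$time_h, sm, kind = attr(series, "kind"), period = per)
}

#' Normalize a series by a reference
#'
#' `at_time`: divide all values by the replicate average at the reference
#' time (e.g. "normalized by the average at CT 18"). `to_value`: divide by a
#' given constant (e.g. rescale a 0-100 percentage axis to 1).
#'
#' @param series an [empirical_series()].
#' @param mode "at_time" or "to_value".
#' @param reference reference time (h) or value, per `mode`.
#' @export
normalize_series <- function(series, mode = c("at_time", "to_value"),
                             reference) {
  mode <- match.arg(mode)
  ref <- if (mode == "at_time") {
    sel <- abs(series$time_h - reference) < 1e-9
    if (!any(sel)) stop("reference time not present in the series")
    mean(series$value[sel])
  } else reference
  if (!is.finite(ref) || ref == 0) stop("zero or non-finite reference")
  empirical_series(series$time_h, series$value / ref, series$replicate,
                   kind = attr(series, "kind"), period = attr(series, "period"))
}

#' Fit a periodic profile through a smoothing spline
#'
#' Cubic smoothing spline of the replicate means, with the smoothing strength
#' given as a residual-sum-of-squares bound (`smoothing`): the spline is the
#' smoothest curve whose weighted residual sum equals the bound, found by
#' root-finding over the smoothing parameter; `smoothing = 0` interpolates.
#' The fitted curve is resampled and closed into a [periodic_profile()];
#' values below `pos_floor` times the mean are floored there (with a warning)
#' to preserve strict positivity.
#'
#' @param series an [empirical_series()] of abundances.
#' @param smoothing residual-sum bound (default 5, in squared value units).
#' @param period period in hours.
#' @param pos_floor positivity floor as a fraction of the mean.
#' @return a [periodic_profile()].
#' @export
fit_profile_spline <- function(series, smoothing = 5, period = 24,
                               pos_floor = 1e-3) {
  m <- series_means(series)
  if (length(unique(m$time_h)) < 4L)
    stop("need at least 4 distinct time points for a cubic smoothing spline")
  if (stats::sd(m$value) == 0) {
    return(periodic_profile(f = function(t) rep(m$value[1L], length(t)),
                            period = period))
  }
  fitted <- if (smoothing <= 0) {
    m$value
  } else {
    rss <- function(spar) {
      fit <- stats::smooth.spline(m$time_h, m$value, spar = spar)
      sum((stats::predict(fit, m$time_h)$y - m$value)^2)
    }
    lo <- -1.5; hi <- 2
    if (rss(lo) >= smoothing) {
      stats::predict(stats::smooth.spline(m$time_h, m$value, spar = lo),
                     m$time_h)$y
    } else if (rss(hi) <= smoothing) {
      stats::predict(stats::smooth.spline(m$time_h, m$value, spar = hi),
                     m$time_h)$y
    } else {
      sp <- stats::uniroot(function(s) rss(s) - smoothing, c(lo, hi))$root
      stats::predict(stats::smooth.spline(m$time_h, m$value, spar = sp),
                     m$time_h)$y
    }
  }
  floorv <- pos_floor * mean(abs(fitted))
  if (any(fitted < floorv)) {
    warning("fitted profile floored at ", signif(floorv, 3),
            " to preserve positivity")
    fitted <- pmax(fitted, floorv)
  }
  tt <- m$time_h %% period
  keep <- !duplicated(tt)
  periodic_profile(tt[keep], fitted[keep], period = period)
}

#' Abundance-and-ubiquitination empirical stage
#'
#' The pipeline used for circadian abundance/ubiquitination series such as
#' Drosophila TIM: normalize the abundance at a reference time, fit a
#' smoothing spline (cubic, residual bound `smoothing`), derive the
#' log-decline profile -x'/x over the period and its peak phase, and rescale
#' the ubiquitinated-fraction series so its reference average is 1.
#'
#' @param abundance [empirical_series()] of abundances.
#' @param ubiq optional [empirical_series()] of relative ubiquitinated
#'   fractions.
#' @param ref_time_abundance,ref_time_ubiq reference times (hours).
#' @param smoothing spline residual bound (see [fit_profile_spline()]).
#' @param period period in hours.
#' @param dt output grid step.
#' @return list with `profile`, `log_decline` (data frame), `peak_phase_h`,
#'   `degenerate` flag, and `ubiq_rescaled` (when `ubiq` given).
#' @export
tim_stage <- function(abundance, ubiq = NULL, ref_time_abundance = 18,
                      ref_time_ubiq = 0, smoothing = 5, period = 24,
                      dt = 0.05) {
  ab <- normalize_series(abundance, "at_time", ref_time_abundance)
  prof <- fit_profile_spline(ab, smoothing = smoothing, period = period)
  tt <- seq(0, period, by = dt)
  ld <- log_decline_rate(prof, tt)
  degenerate <- diff(range(ld)) < 1e-8
  peak <- if (degenerate) NA_real_ else tt[which.max(ld)] %% period
  out <- list(profile = prof,
              log_decline = data.frame(time_h = tt, rate = ld),
              peak_phase_h = peak, degenerate = degenerate)
  if (!is.null(ubiq))
    out$ubiq_rescaled <- normalize_series(ubiq, "at_time", ref_time_ubiq)
  out
}

#' Empirical degradation-rate profile from sparse rate measurements
#'
#' Builds rE(t) on a dense grid as the pointwise maximum of (a) the linear
#' inter-/extrapolation of the measured rates (terminal segments continued),
#' (b) the waveform's degradation floor max(-x'/x, 0) — optionally
#' pre-smoothed with a centered moving window when the profile derivative is
#' noisy — and (c) the minimum observed rate, which acts as a global lower
#' bound.
#'
#' @param rate_points [empirical_series()] of kind "rate" (>= 2 points).
#' @param x_profile the protein's [periodic_profile()].
#' @param smooth_floor_window optional window (hours) for pre-smoothing the
#'   -x'/x floor.
#' @param dt dense grid step in hours.
#' @return a [rate_series()].
#' @export
build_empirical_rate_profile <- function(rate_points, x_profile,
                                         smooth_floor_window = NULL,
                                         dt = 0.05) {
  m <- series_means(rate_points)
  if (nrow(m) < 2L) stop("need at least 2 rate measurements")
  per <- x_profile$period
  tt <- seq(0, per, by = dt)
  interp <- linear_inter_extrapolate(m$time_h, m$value, tt)
  floorv <- degradation_floor(x_profile, tt)
  if (!is.null(smooth_floor_window)) {
    fs <- empirical_series(tt[-length(tt)], floorv[-length(tt)],
                           kind = "rate", period = per)
    sm <- moving_average(fs, smooth_floor_window, periodic = TRUE)
    floorv <- c(sm$value, sm$value[1L])
  }
  rE <- pmax(interp, floorv, min(m$value))
  rate_series(tt, pmax(rE, 0), period = per)
}

## linear interpolation through (x, y), continuing the terminal segments
linear_inter_extrapolate <- function(x, y, xout) {
  n <- length(x)
  out <- stats::approx(x, y, xout = xout, rule = 1)$y
  if (n >= 2L) {
    sl_lo <- (y[2L] - y[1L]) / (x[2L] - x[1L])
    sl_hi <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
    lo <- xout < x[1L]; hi <- xout > x[n]
    out[lo] <- y[1L] + sl_lo * (xout[lo] - x[1L])
    out[hi] <- y[n] + sl_hi * (xout[hi] - x[n])
  }
  out
}

#' Uniform parameter sampling over per-parameter ranges
#'
#' @param ranges named list; each entry `list(low, high, scale)` with scale
#'   "linear" or "log" (log-uniform draws for rate constants).
#' @param count number of parameter sets.
#' @param seed RNG seed (recorded in the result).
#' @return data frame, one row per set, with attribute `seed`.
#' @export
sample_parameters <- function(ranges, count, seed = 1) {
  stopifnot(count >= 1)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!(r$low < r$high) && r$low != r$high)
      stop("invalid range for ", nm)
    if (identical(r$scale, "log") && r$low <= 0)
      stop("log-scale range must be strictly positive for ", nm)
  }
  set.seed(seed)
  cols <- lapply(ranges, function(r) {
    if (r$low == r$high) rep(r$low, count)
    else if (identical(r$scale, "log"))
      exp(stats::runif(count, log(r$low), log(r$high)))
    else stats::runif(count, r$low, r$high)
  })
  d <- as.data.frame(cols)
  attr(d, "seed") <- seed
  d
}

## assemble model parameters from one sampled row; k tied across sites by
## default (k1 = ... = kn), per the multisite simplification
row_to_params <- function(row, n = 0L, tie_k = TRUE) {
  p <- ub_params(u_bar = row$u_bar, a0 = row$a0, a1 = row$a1, a2 = row$a2,
                 q = row$q, r0 = row$r0,
                 v_bar = row$v_bar %||% 0, b0 = row$b0 %||% 0,
                 b1 = row$b1 %||% 0, s = row$s %||% 0)
  ph <- if (n >= 1L) {
    kk <- if (tie_k || is.null(row$k2)) rep(row$k, n)
      else unlist(row[paste0("k", seq_len(n))])
    phospho_params(n = n, y = row$y, z = row$z %||% 0, k = kk,
                   l = row$l %||% 0)
  } else NULL
  list(params = p, phospho = ph)
}

#' Constrained-simulation scan over sampled parameter sets
#'
#' Runs [constrained_simulate()] for every sampled set against a fixed
#' protein profile and records similarity to an empirical rate profile (when
#' given), proteosynthetic cost, rhythmicity and the feasibility verdict.
#' Integration failures are recorded as infeasible-with-reason; the scan
#' never aborts. Records are independent and order-insensitive.
#'
#' @param x_profile a [periodic_profile()].
#' @param samples data frame from [sample_parameters()] (columns u_bar, a0,
#'   a1, a2, q, r0, and for `n >= 1` also y, k, optionally z, l, v_bar, b0,
#'   b1, s).
#' @param rE optional empirical [rate_series()] for the similarity statistic.
#' @param n number of phosphorylation events (0 = phospho-independent).
#' @param tie_k tie the site rates k1 = ... = kn (default) or use columns
#'   k1..kn.
#' @param ... passed to [constrained_simulate()].
#' @return data frame of class `scan_records`: one row per set with columns
#'   index, S, cost, alpha_D, feasible, reason.
#' @export
scan_parameters <- function(x_profile, samples, rE = NULL, n = 0L,
                            tie_k = TRUE, ...) {
  stopifnot(nrow(samples) >= 1L)
  rec <- lapply(seq_len(nrow(samples)), function(i) {
    pr <- row_to_params(samples[i, , drop = FALSE], n = n, tie_k = tie_k)
    sim <- tryCatch(constrained_simulate(x_profile, pr$params, pr$phospho, ...),
                    error = function(e) e)
    if (inherits(sim, "error"))
      return(data.frame(index = i, S = NA_real_, cost = NA_real_,
                        alpha_D = NA_real_, feasible = FALSE,
                        reason = conditionMessage(sim)))
    if (!sim$feasible)
      return(data.frame(index = i, S = NA_real_, cost = NA_real_,
                        alpha_D = NA_real_, feasible = FALSE,
                        reason = "feasibility violation"))
    Sv <- if (is.null(rE)) NA_real_ else
      similarity_S(rate_series(sim$times, pmax(sim$r, 0),
                               period = x_profile$period), rE)
    data.frame(index = i, S = Sv, cost = sim$cost, alpha_D = sim$alpha_D,
               feasible = TRUE, reason = "")
  })
  out <- do.call(rbind, rec)
  class(out) <- c("scan_records", "data.frame")
  attr(out, "samples") <- samples
  out
}

#' Nelder-Mead optimization of similarity or cost
#'
#' Derivative-free simplex search in log-parameter space starting from a
#' feasible initial set; infeasible evaluations are penalized
#' (1e6 (1 + violation magnitude)), so the simplex retreats into the feasible
#' region. Objectives: maximize the similarity S to an empirical rate
#' profile, or minimize the proteosynthetic cost.
#'
#' @param x_profile a [periodic_profile()].
#' @param rE empirical [rate_series()] (needed for `maximize_S`).
#' @param objective "maximize_S" or "minimize_cost".
#' @param init named numeric vector (or one-row data frame) of the free
#'   parameters, all > 0; must be feasible.
#' @param n phosphorylation events (0 = phospho-independent).
#' @param maxit simplex iteration budget.
#' @param ... passed to [constrained_simulate()].
#' @return list with `par` (best parameter set), `value` (best objective),
#'   `trace` (objective per evaluation), `counts`.
#' @export
optimize_parameters <- function(x_profile, rE = NULL,
                                objective = c("maximize_S", "minimize_cost"),
                                init, n = 0L, maxit = 200, ...) {
  objective <- match.arg(objective)
  if (objective == "maximize_S" && is.null(rE))
    stop("maximize_S needs an empirical rate profile rE")
  init <- unlist(init)
  if (any(init <= 0)) stop("init parameters must be strictly positive")
  nms <- names(init)
  trace <- numeric(0)
  evalfn <- function(logp) {
    row <- as.data.frame(as.list(stats::setNames(exp(logp), nms)))
    pr <- row_to_params(row, n = n)
    sim <- tryCatch(constrained_simulate(x_profile, pr$params, pr$phospho, ...),
                    error = function(e) e)
    bad <- inherits(sim, "error") || !sim$feasible
    val <- if (bad) {
      mag <- if (inherits(sim, "error")) 1 else
        max(0, -min(vapply(sim$violations, function(v) v$magnitude, 0), 0))
      1e6 * (1 + mag)
    } else if (objective == "maximize_S") {
      -similarity_S(rate_series(sim$times, pmax(sim$r, 0),
                                period = x_profile$period), rE)
    } else sim$cost
    trace[length(trace) + 1L] <<- val
    val
  }
  v0 <- evalfn(log(init))
  if (v0 >= 1e6) stop("initial parameter set is infeasible; widen the init")
  opt <- stats::optim(log(init), evalfn, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  best <- stats::setNames(exp(opt$par), nms)
  value <- if (objective == "maximize_S") -opt$value else opt$value
  list(par = best, value = value, trace = trace, counts = opt$counts,
       objective = objective)
}

#' Association between profile similarity and proteosynthetic cost
#'
#' Spearman rank correlation between the similarity S and the cost across
#' feasible scan records, plus the paired table used by the permutation test.
#'
#' @param records a `scan_records` data frame.
#' @return list with `spearman_rho`, `n`, `pairs` (data frame S, cost),
#'   `degenerate` flag (constant S or cost).
#' @export
cost_similarity_association <- function(records) {
  ok <- records$feasible & is.finite(records$S) & is.finite(records$cost)
  d <- records[ok, c("S", "cost")]
  if (nrow(d) < 10L) stop("need at least 10 feasible records")
  degenerate <- stats::sd(d$S) == 0 || stats::sd(d$cost) == 0
  rho <- if (degenerate) NA_real_ else spearman_rho(d$S, d$cost)
  list(spearman_rho = rho, n = nrow(d), pairs = d, degenerate = degenerate)
}
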