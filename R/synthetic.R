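## Synthetic-data generators: circadian waveforms with controllable decline
## sharpness (hence Rmax), noisy replicated samplings, ground-truth
## degradation observations, and power-law proteome tables with tunable
## phospho-cost coupling. All generators are pure functions of their
## specification and seed.

#' Specification of a synthetic circadian waveform
#'
#' The generated waveform is x(t) = mean (1 + b w(t)) with w a unit-amplitude
#' shape: a sinusoid raised to `sharpness` with the sign preserved,
#' time-warped by `asymmetry` through the smooth periodic map
#' t -> t + a T/(2 pi) sin(2 pi t/T).
#'
#' @param period period T in hours.
#' @param mean mean concentration (nM or copies/cell), > 0.
#' @param rel_amplitude relative amplitude b in (0, 1).
#' @param sharpness power-transform exponent >= 1 (1 = pure sinusoid).
#' @param asymmetry warp strength in (-1, 1) (0 = symmetric).
#' @param phase peak phase offset in hours.
#' @return list of class `waveform_spec`.
#' @export
waveform_spec <- function(period = 24, mean = 1, rel_amplitude = 0.5,
                          sharpness = 1, asymmetry = 0, phase = 0) {
  stopifnot(period > 0, mean > 0,
            rel_amplitude > 0, rel_amplitude < 1,
            sharpness >= 1, asymmetry > -1, asymmetry < 1)
  structure(list(period = period, mean = mean, rel_amplitude = rel_amplitude,
                 sharpness = sharpness, asymmetry = asymmetry, phase = phase),
            class = "waveform_spec")
}

#' Generate a periodic profile from a waveform specification
#'
#' @param spec a [waveform_spec()].
#' @return a [periodic_profile()] (function-backed, deterministic).
#' @examples
#' p <- make_profile(waveform_spec(rel_amplitude = 0.5))
#' min_constant_rate(p)   # b w / sqrt(1 - b^2) for a pure sinusoid
#' @export
make_profile <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  T_ <- spec$period; b <- spec$rel_amplitude
  sh <- spec$sharpness; a <- spec$asymmetry; ph <- spec$phase
  f <- function(t) {
    tw <- t + a * T_ / (2 * pi) * sin(2 * pi * t / T_)
    s <- sin(2 * pi * (tw - ph) / T_)
    w <- sign(s) * abs(s)^sh
    spec$mean * (1 + b * w)
  }
  p <- periodic_profile(f = f, period = T_)
  p
}

#' Generate a profile with a prescribed relative decline maximum
#'
#' Bisection on the relative amplitude b (then on the sharpness when b alone
#' cannot reach the target) until |Rmax - target| < `tol`. Enables boundary
#' tests of the feasibility floor U, Y >= Rmax.
#'
#' @param period period in hours.
#' @param mean mean concentration.
#' @param target_Rmax requested Rmax = max(-x'/x)/r0, in (0, 1).
#' @param r0 maximal degradation rate (1/h).
#' @param tol absolute tolerance on the achieved Rmax.
#' @return a [periodic_profile()] with attribute `achieved_Rmax`.
#' @export
profile_with_target_Rmax <- function(period = 24, mean = 1, target_Rmax,
                                     r0, tol = 1e-3) {
  stopifnot(target_Rmax > 0, target_Rmax < 1, r0 > 0)
  target_rate <- target_Rmax * r0     # in 1/h
  rmax_of <- function(b, sh = 1) {
    min_constant_rate(make_profile(waveform_spec(period = period, mean = mean,
                                                 rel_amplitude = b,
                                                 sharpness = sh)))
  }
  b_hi <- 0.995
  if (rmax_of(b_hi) >= target_rate) {
    lo <- 1e-4; hi <- b_hi
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (rmax_of(mid) < target_rate) lo <- mid else hi <- mid
      if (abs(rmax_of(mid) - target_rate) < tol * r0) break
    }
    spec <- waveform_spec(period = period, mean = mean, rel_amplitude = mid)
  } else {
    # steepen a b = 0.9 wave until the target becomes reachable
    b <- 0.9
    if (rmax_of(b, 12) < target_rate)
      stop(sprintf("target Rmax %.3g unreachable; attainable up to about %.3g",
                   target_Rmax, rmax_of(0.995, 12) / r0))
    lo <- 1; hi <- 12
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (rmax_of(b, mid) < target_rate) lo <- mid else hi <- mid
      if (abs(rmax_of(b, mid) - target_rate) < tol * r0) break
    }
    spec <- waveform_spec(period = period, mean = mean, rel_amplitude = b,
                          sharpness = mid)
  }
  p <- make_profile(spec)
  achieved <- min_constant_rate(p) / r0
  if (abs(achieved - target_Rmax) > 10 * tol)
    stop("bisection failed to reach the target Rmax")
  attr(p, "achieved_Rmax") <- achieved
  attr(p, "spec") <- spec
  p
}

#' Noisy replicated sampling of a profile
#'
#' Multiplicative lognormal noise with coefficient of variation `cv`,
#' independent across replicates and time points.
#'
#' @param profile a [periodic_profile()].
#' @param times sampling times in hours.
#' @param cv coefficient of variation of the noise (>= 0).
#' @param n_replicates replicates per time point.
#' @param seed RNG seed.
#' @return an [empirical_series()] of kind "abundance".
#' @export
make_noisy_timeseries <- function(profile, times, cv = 0.1, n_replicates = 2,
                                  seed = 1) {
  stopifnot(cv >= 0, n_replicates >= 1)
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  rows <- do.call(rbind, lapply(seq_len(n_replicates), function(rep) {
    mu <- profile$f(times)
    noise <- if (cv > 0)
      stats::rlnorm(length(times), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    else rep(1, length(times))
    data.frame(time_h = times, value = mu * noise, replicate = rep)
  }))
  empirical_series(rows$time_h, rows$value, rows$replicate,
                   kind = "abundance", period = profile$period)
}

#' Ground-truth degradation observations from a known parameter set
#'
#' Runs the profile-constrained simulation with the given (feasible)
#' parameters, then samples the realized degradation rate r(t) at the
#' observation times with multiplicative lognormal noise.
#'
#' @param x_profile a [periodic_profile()].
#' @param params,phospho model parameters (see [constrained_simulate()]).
#' @param obs_times observation times in hours.
#' @param noise_cv coefficient of variation of the observation noise.
#' @param seed RNG seed.
#' @return list with `sim` (the true `sim_result`) and `observations`
#'   (an [empirical_series()] of kind "rate").
#' @export
make_degradation_truth <- function(x_profile, params, phospho = NULL,
                                   obs_times, noise_cv = 0, seed = 1) {
  sim <- constrained_simulate(x_profile, params, phospho)
  if (!sim$feasible) stop("ground-truth parameters are infeasible for this profile")
  set.seed(seed)
  r_obs <- stats::approx(sim$times, sim$r, xout = obs_times %% x_profile$period)$y
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    r_obs <- r_obs * stats::rlnorm(length(r_obs), -sdlog^2 / 2, sdlog)
  }
  list(sim = sim,
       observations = empirical_series(obs_times, r_obs, kind = "rate",
                                       period = x_profile$period))
}

#' Specification of a synthetic proteome table
#'
#' Abundances follow a truncated power law P(chi) ~ chi^-gamma on
#' [chi_min, chi_max]. A fraction of proteins oscillates and receives a
#' generated waveform series (hence a computable cost bound cg). Phospho
#' labels are drawn from a logit model
#' logit P(phospho) = base + abundance_coeff z(log chi) + rmax_coeff z(Rmax)
#' (z = standardized within the table), so zero coefficients give an
#' exchangeable null.
#'
#' @param n_proteins number of proteins.
#' @param gamma power-law exponent (~1 in circadian proteomes).
#' @param chi_min,chi_max abundance truncation bounds (copies/cell).
#' @param oscillating_fraction fraction of oscillating proteins.
#' @param phospho_base baseline logit of the phospho probability.
#' @param abundance_coeff,rmax_coeff logit-scale couplings.
#' @param noise_cv measurement noise of the oscillating series.
#' @param n_timepoints,n_replicates sampling layout of the series.
#' @return list of class `proteome_spec`.
#' @export
proteome_spec <- function(n_proteins = 1000, gamma = 1,
                          chi_min = 3.0e4, chi_max = 5.4e5,
                          oscillating_fraction = 0.1,
                          phospho_base = 0, abundance_coeff = 0,
                          rmax_coeff = 0, noise_cv = 0.05,
                          n_timepoints = 9, n_replicates = 2) {
  stopifnot(n_proteins >= 1, chi_min > 0, chi_max > chi_min,
            oscillating_fraction >= 0, oscillating_fraction <= 1)
  structure(as.list(environment()), class = "proteome_spec")
}

#' Draw abundances from a truncated power law
#'
#' Inverse-CDF sampling of P(chi) ~ chi^-gamma on [chi_min, chi_max].
#'
#' @param n sample size.
#' @param gamma exponent.
#' @param chi_min,chi_max truncation bounds.
#' @export
rtruncpower <- function(n, gamma, chi_min, chi_max) {
  u <- stats::runif(n)
  if (abs(gamma - 1) < 1e-12) {
    chi_min * (chi_max / chi_min)^u
  } else {
    e <- 1 - gamma
    (u * chi_max^e + (1 - u) * chi_min^e)^(1 / e)
  }
}

#' Generate a synthetic proteome table
#'
#' @param spec a [proteome_spec()].
#' @param seed RNG seed.
#' @return a `proteome_records` data frame (columns id, abundance,
#'   oscillating, phospho, rmax) with the per-protein series in attribute
#'   `series` and the generating spec in attribute `spec`.
#' @export
make_synthetic_proteome <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "proteome_spec"))
  set.seed(seed)
  n <- spec$n_proteins
  chi <- rtruncpower(n, spec$gamma, spec$chi_min, spec$chi_max)
  oscillating <- stats::runif(n) < spec$oscillating_fraction
  # waveform sharpness varies across oscillating proteins -> varying Rmax
  b <- stats::runif(n, 0.2, 0.8)
  sh <- stats::runif(n, 1, 3)
  # closed-form Rmax of the pure sinusoid scaled up by sharpness is a fair
  # per-protein summary without building every profile: use b*w/sqrt(1-b^2)*sh
  rmax_proxy <- b * (2 * pi / 24) / sqrt(1 - b^2) * sh
  z <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  eta <- spec$phospho_base + spec$abundance_coeff * z(log(chi)) +
    spec$rmax_coeff * z(rmax_proxy)
  phospho <- stats::runif(n) < stats::plogis(eta)
  times <- seq(0, 24 - 24 / spec$n_timepoints, length.out = spec$n_timepoints)
  series <- vector("list", n)
  seeds <- sample.int(.Machine$integer.max, n)
  for (i in which(oscillating)) {
    p <- make_profile(waveform_spec(mean = 1, rel_amplitude = b[i],
                                    sharpness = sh[i]))
    series[[i]] <- make_noisy_timeseries(p, times, cv = spec$noise_cv,
                                         n_replicates = spec$n_replicates,
                                         seed = seeds[i])
  }
  rec <- data.frame(id = sprintf("P%05d", seq_len(n)), abundance = chi,
                    oscillating = oscillating, phospho = phospho,
                    rmax = ifelse(oscillating, rmax_proxy, NA_real_))
  class(rec) <- c("proteome_records", "data.frame")
  attr(rec, "series") <- series
  attr(rec, "spec") <- spec
  rec
}
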