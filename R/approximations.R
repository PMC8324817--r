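## Dimensionless reduction of the ubiquitination models and the closed-form
## quasi-steady-state (QSS) approximations of the ubiquitinated fraction
## D = r/r0, together with their validity-condition checkers and the
## feasibility lower bound U, Y >= Rmax.

#' Dimensionless parameters of the ubiquitination models
#'
#' Computes the scaled enzyme activities and combinations used throughout the
#' reduced analysis: U = (a0/r0) q/(a1+q) u_bar,
#' V = (b0/r0) (r0+s)/(b1+r0+s) v_bar, Y = (k1/r0) y, Z = (l1/r0) z,
#' A = r0 (a1+q) / (q (a2+r0)), B = r0/(a2+r0), Q = s/(r0+s),
#' K_i = k_i/k_1, and the concentration scale
#' X_scale = (a0/r0) q/(a1+q) so that X(t) = X_scale x(t).
#'
#' @param params an [ub_params()].
#' @param phospho optional [phospho_params()].
#' @param profile optional [periodic_profile()]; when given, the relative
#'   decline profile R(t) and its extrema are attached (see
#'   [relative_decline()]).
#' @return list of class `dimensionless_params`.
#' @export
to_dimensionless <- function(params, phospho = NULL, profile = NULL) {
  stopifnot(inherits(params, "ub_params"))
  if (params$a1 + params$q <= 0) stop("a1 + q must be positive")
  r0 <- params$r0
  X_scale <- (params$a0 / r0) * params$q / (params$a1 + params$q)
  out <- list(
    U = X_scale * params$u_bar,
    V = if (params$b1 + r0 + params$s > 0)
      (params$b0 / r0) * (r0 + params$s) / (params$b1 + r0 + params$s) *
        params$v_bar else 0,
    A = r0 * (params$a1 + params$q) / (params$q * (params$a2 + r0)),
    B = r0 / (params$a2 + r0),
    Q = if (r0 + params$s > 0) params$s / (r0 + params$s) else 0,
    q_over_r0 = params$q / r0,
    X_scale = X_scale,
    r0 = r0)
  if (!is.null(phospho) && phospho$n >= 1L) {
    out$Y <- phospho$k[1L] / r0 * phospho$y
    out$Z <- phospho$l[1L] / r0 * phospho$z
    out$K <- phospho$k / phospho$k[1L]
    out$n <- phospho$n
  }
  if (!is.null(profile)) out$R <- relative_decline(profile, r0)
  structure(out, class = "dimensionless_params")
}

#' Relative decline profile R(t) and its extrema
#'
#' R(t) = -(1/r0) x'(t)/x(t): the waveform's decline rate in units of the
#' maximal degradation rate. Its maximum Rmax is the feasibility floor for the
#' dimensionless enzyme activities.
#'
#' @param profile a [periodic_profile()].
#' @param r0 maximal degradation rate (1/h).
#' @param dt grid step in hours.
#' @return list with `fn` (function of t), `times`, `R`, `Rmax`, `Rmin`.
#' @export
relative_decline <- function(profile, r0, dt = 0.01) {
  stopifnot(r0 > 0)
  fn <- function(t) log_decline_rate(profile, t) / r0
  tt <- seq(0, profile$period, by = dt)
  R <- fn(tt)
  list(fn = fn, times = tt, R = R,
       Rmax = min_constant_rate(profile, dt = dt) / r0, Rmin = min(R))
}

#' Quasi-steady-state ubiquitinated fraction, phospho-independent
#'
#' D = 1 / (1 + (1/U) (1 - R)): the leading-order closed form for the
#' ubiquitinated fraction when the ubiquitination block equilibrates fast,
#' deubiquitination is off and enzyme sequestration is negligible.
#'
#' @param R relative decline value(s) R(t).
#' @param U dimensionless ubiquitin-ligase activity, > 0.
#' @return dimensionless fraction (in (0, 1] when R <= 1).
#' @export
D_qss <- function(R, U) {
  stopifnot(U > 0)
  1 / (1 + (1 - R) / U)
}

#' Quasi-steady-state fraction with Michaelis-Menten substrate correction
#'
#' D = 1 / (1 + (1/U)(1 - R)(1 + (r0/q) U + (r0/q) X)): extends [D_qss()]
#' with the saturation of ligase binding at high substrate X = X_scale x(t).
#' Reduces to [D_qss()] when U and X are both much smaller than q/r0.
#'
#' @param R relative decline value(s).
#' @param X dimensionless substrate concentration(s).
#' @param U dimensionless ligase activity.
#' @param q_over_r0 ratio q/r0, > 0.
#' @export
D_qss_mm <- function(R, X, U, q_over_r0) {
  stopifnot(q_over_r0 > 0)
  1 / (1 + (1 - R) / U * (1 + U / q_over_r0 + X / q_over_r0))
}

#' Quasi-steady-state fraction under mono-phosphorylation
#'
#' D = 1 / ((1 + (1/U)(1 - R)) (1 - R/Y) + 1/Y): the mono-phosphorylation
#' closed form; Y -> Inf recovers [D_qss()]. A finite kinase activity Y
#' amplifies the rhythmicity carried by R(t).
#'
#' @param R relative decline value(s).
#' @param U,Y dimensionless ligase and kinase activities, > 0.
#' @export
D_qss_phospho <- function(R, U, Y) {
  stopifnot(U > 0, Y > 0)
  1 / ((1 + (1 - R) / U) * (1 - R / Y) + 1 / Y)
}

#' Quasi-steady-state fraction under multisite phosphorylation
#'
#' D = U K1...Kn Y^n / eta_n(R) with eta_n the n-site chain polynomial:
#' eta_n = U prod(K) Y^n + prod(K) Y^n (1 - R)
#'       + sum over chain truncations of
#'         prod(K[1..m]) Y^m (1 - R)(U - R) prod_{i > m+1} (K_i Y - R)
#'       + (1 - R)(U - R)(K1 Y + K2 Y - R) prod_{i >= 3} (K_i Y - R).
#' For n = 1 this reduces algebraically to [D_qss_phospho()]. Among the site
#' activities K_i Y the smallest one dominates the temporal variation of D.
#'
#' @param R relative decline value(s).
#' @param U dimensionless ligase activity, > 0.
#' @param Y dimensionless kinase activity (site 1), > 0.
#' @param K vector of site ratios K_i = k_i/k_1 (K[1] must be 1).
#' @export
D_qss_multisite <- function(R, U, Y, K = 1) {
  n <- length(K)
  stopifnot(n >= 1L, abs(K[1L] - 1) < 1e-12, U > 0, Y > 0)
  sapply(R, function(Rt) {
    one <- 1 - Rt
    if (n == 1L) {
      eta <- U * Y + Y * one + one * (U - Rt)
      return(U * Y / eta)
    }
    top <- U * prod(K) * Y^n
    eta <- top + prod(K) * Y^n * one
    # truncation terms: m = n-1 sites paid, down to m = 2
    if (n >= 3L) {
      for (m in (n - 1L):2L) {
        tail_idx <- if (m + 2L <= n) seq.int(m + 2L, n) else integer(0)
        eta <- eta + prod(K[seq_len(m)]) * Y^m * one * (U - Rt) *
          prod(K[tail_idx] * Y - Rt)
      }
    }
    last_tail <- if (n >= 3L) prod(K[3:n] * Y - Rt) else 1
    eta <- eta + one * (U - Rt) * (K[1L] * Y + K[2L] * Y - Rt) * last_tail
    top / eta
  })
}

#' Closed-form rhythmicity estimate
#'
#' alpha_D ~ (Rmax - Rmin) / (U + 1 - Rmin), from evaluating the
#' quasi-steady-state fraction at the decline extrema. For a waveform
#' symmetric about its peak (Rmin ~ -Rmax) this is 2 Rmax/(U + 1 + Rmax).
#'
#' @param Rmax,Rmin extrema of the relative decline profile.
#' @param U dimensionless ligase activity.
#' @param symmetric if TRUE, substitute Rmin = -Rmax.
#' @export
alpha_D_estimate <- function(Rmax, Rmin = -Rmax, U, symmetric = FALSE) {
  if (symmetric) Rmin <- -Rmax
  if (U + 1 - Rmin <= 0) stop("U + 1 - Rmin must be positive")
  (Rmax - Rmin) / (U + 1 - Rmin)
}

#' Check the validity conditions of the closed-form approximations
#'
#' The leading-order form ([D_qss()]) needs: (i) the ubiquitination block
#' equilibrates within the period, max(1/q, 1/a2, 1/s) << T; (ii) U << q/r0;
#' (iii) V << (r0+s)/r0; (iv) max X << the sequestration bounds. The
#' Michaelis-Menten form ([D_qss_mm()]) instead needs (v) 1/q << T;
#' (vi) max(xEub/xE0) ~ q/(a2+r0) << 1; (vii) max X << U + q/r0 or
#' U << min X + q/r0. Each "<<" is operationalized as ratio <= `margin`.
#'
#' @param params an [ub_params()].
#' @param profile a [periodic_profile()].
#' @param phospho optional [phospho_params()] (checked only through V/Z = 0
#'   assumptions; the conditions proper concern the ubiquitination block).
#' @param margin the numeric reading of "<<" (default 0.1).
#' @return data frame with columns condition, ratio, pass, plus attributes
#'   `leading_ok` (conditions i-iv) and `mm_ok` (v-vii).
#' @export
check_validity_conditions <- function(params, profile, phospho = NULL,
                                      margin = 0.1) {
  dl <- to_dimensionless(params, phospho, profile)
  T_ <- profile$period
  r0 <- params$r0
  Xmax <- dl$X_scale * max(profile$f(seq(0, T_, by = 0.05)))
  Xmin <- dl$X_scale * min(profile$f(seq(0, T_, by = 0.05)))
  inv_or_inf <- function(z) if (z > 0) 1 / z else Inf
  ratios <- c(
    i = max(inv_or_inf(params$q), inv_or_inf(params$a2),
            inv_or_inf(params$s)) / T_,
    ii = dl$U / (params$q / r0),
    iii = dl$V / ((r0 + params$s) / r0),
    iv = Xmax / min(params$q / r0,
                    (params$a2 + r0) / r0 * params$q / (params$a1 + params$q),
                    if (params$b0 > 0)
                      params$a0 / params$b0 * (params$b1 + r0 + params$s) / r0 *
                        params$q / (params$a1 + params$q) else Inf),
    v = inv_or_inf(params$q) / T_,
    vi = params$q / (params$a2 + r0),
    vii = min(Xmax / (dl$U + params$q / r0),
              dl$U / (Xmin + params$q / r0)))
  rep_ <- data.frame(condition = names(ratios), ratio = as.numeric(ratios),
                     pass = as.numeric(ratios) <= margin)
  attr(rep_, "leading_ok") <- all(rep_$pass[rep_$condition %in% c("i", "ii", "iii", "iv")])
  attr(rep_, "mm_ok") <- all(rep_$pass[rep_$condition %in% c("v", "vi", "vii")])
  attr(rep_, "margin") <- margin
  rep_
}

#' Feasibility lower bound on the dimensionless enzyme activities
#'
#' A waveform with relative decline maximum Rmax cannot be sustained unless
#' both the ligase activity U and (for phospho-dependent degradation) the
#' kinase activity Y are at least about Rmax; below that, the feasibility
#' screen of [constrained_simulate()] fails (negative synthesis).
#'
#' @param profile a [periodic_profile()].
#' @param r0 maximal degradation rate (1/h).
#' @return list with `U_min` and `Y_min` (both equal to Rmax).
#' @export
feasibility_lower_bounds <- function(profile, r0) {
  stopifnot(r0 > 0)
  Rmax <- min_constant_rate(profile) / r0
  list(U_min = Rmax, Y_min = Rmax)
}
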