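#' Kinetic parameters of the ubiquitination core
#'
#' Mass-action constants of the ubiquitination/deubiquitination machinery with
#' constant total enzyme pools. All rates are first order (1/h) except the
#' binding rates `a0`, `b0` (1/nM/h); `u_bar`, `v_bar` are total enzyme pools
#' in nM. `r0` is the degradation rate of ubiquitinated protein and the
#' theoretical upper limit of the realized degradation rate r(t).
#'
#' @param u_bar total ubiquitin ligase pool (nM).
#' @param a0,a1,a2 ligase binding (1/nM/h), ligase-unmodified unbinding (1/h),
#'   ligase-ubiquitinated unbinding (1/h).
#' @param q ubiquitination rate of ligase-bound protein (1/h).
#' @param r0 degradation rate of ubiquitinated protein (1/h), > 0.
#' @param v_bar total deubiquitinating enzyme pool (nM); 0 disables the branch.
#' @param b0,b1 deubiquitinase binding (1/nM/h) and unbinding (1/h).
#' @param s deubiquitination-plus-release rate (1/h).
#' @return object of class `ub_params`.
#' @examples
#' ub_params(u_bar = 0.22, a0 = 234.9, a1 = 17880.6, a2 = 15347.2,
#'           q = 262.2, r0 = 1.3)
#' @export
ub_params <- function(u_bar, a0, a1, a2, q, r0,
                      v_bar = 0, b0 = 0, b1 = 0, s = 0) {
  p <- list(u_bar = u_bar, a0 = a0, a1 = a1, a2 = a2, q = q, r0 = r0,
            v_bar = v_bar, b0 = b0, b1 = b1, s = s)
  if (any(vapply(p, function(z) !is.numeric(z) || length(z) != 1L || z < 0,
                 logical(1L))))
    stop("all ub_params entries must be non-negative scalars")
  if (r0 <= 0) stop("r0 must be positive")
  structure(p, class = "ub_params")
}

#' Phosphorylation-chain parameters
#'
#' An n-site phosphorylation chain preceding ubiquitination: kinase pool `y`
#' and phosphatase pool `z` are constant; `k[i]` is the lumped
#' binding+phosphorylation+release rate toward the i-th phosphostate, `l[i]`
#' the lumped phosphatase action removing it (both 1/nM/h). `n = 0` means
#' phospho-independent ubiquitination.
#'
#' @param n number of phosphorylation events required for ubiquitination.
#' @param y,z kinase and phosphatase pools (nM).
#' @param k,l rate vectors of length `n` (scalars are recycled).
#' @return object of class `phospho_params`.
#' @export
phospho_params <- function(n, y, z = 0, k = numeric(0), l = 0) {
  stopifnot(n >= 0, y >= 0, z >= 0)
  if (n > 0) {
    if (length(k) == 0L) stop("k must be given when n >= 1")
    k <- rep_len(k, n); l <- rep_len(l, n)
    if (anyNA(k) || anyNA(l) || any(k < 0) || any(l < 0))
      stop("k and l must be non-negative")
  } else {
    k <- numeric(0); l <- numeric(0)
  }
  structure(list(n = as.integer(n), y = y, z = z, k = k, l = l),
            class = "phospho_params")
}

#' Multi-route degradation parameters
#'
#' Four phosphostates (n = 4 chain), each with its own ubiquitination route
#' (own ligase/deubiquitinase pools and constants). A route is disabled by
#' setting its `u_bar` to zero.
#'
#' @param routes list of 4 route blocks; each a list with entries
#'   `u_bar, a0, a1, a2, q, s, b0, b1, v_bar, r0` (same meaning as in
#'   [ub_params()]).
#' @param phospho a [phospho_params()] with `n = 4`.
#' @return object of class `multiroute_params`.
#' @export
multiroute_params <- function(routes, phospho) {
  stopifnot(inherits(phospho, "phospho_params"), phospho$n == 4L,
            is.list(routes), length(routes) == 4L)
  need <- c("u_bar", "a0", "a1", "a2", "q", "s", "b0", "b1", "v_bar", "r0")
  routes <- lapply(routes, function(r) {
    if (!all(need %in% names(r))) stop("route block missing fields")
    r[need]
  })
  if (all(vapply(routes, function(r) r$u_bar == 0, logical(1L))))
    warning("all routes disabled (every u_bar is 0): pure accumulation")
  structure(list(routes = routes, phospho = phospho),
            class = "multiroute_params")
}

#' Realistic PER2 degradation parameters
#'
#' PER2 carries two phospho-regions: the FASP-site chain (states 1..4, kinase
#' constants `k[1..4]`, phosphatase `l[1..4]`) and the beta-TrCP site
#' (`k_beta`, `l_beta`). Every phosphostate i = 0..4 of the FASP chain can be
#' ubiquitinated by a shared ligase pool `u_bar` through its own block of
#' constants; the beta-site route has its own ligase pool `u_bar_beta` and
#' block. The kinase pool `y` plays the CK1 delta/epsilon role.
#'
#' @param k,l length-4 FASP chain constants (1/nM/h).
#' @param k_beta,l_beta beta-TrCP site constants (1/nM/h).
#' @param y,z kinase and phosphatase pools (nM).
#' @param u_bar,v_bar shared ligase/deubiquitinase pools for states 0..4 (nM).
#' @param blocks list of 5 blocks (states 0..4), each with
#'   `a0, a1, a2, q, s, b0, b1, r0`.
#' @param u_bar_beta,v_bar_beta beta-route enzyme pools (nM).
#' @param beta_block beta-route block with `a0, a1, a2, q, s, b0, b1, r0`.
#' @return object of class `per2_params`.
#' @export
per2_params <- function(k, l, k_beta, l_beta, y, z,
                        u_bar, v_bar, blocks,
                        u_bar_beta, v_bar_beta, beta_block) {
  stopifnot(length(k) == 4L, length(l) == 4L,
            is.list(blocks), length(blocks) == 5L)
  need <- c("a0", "a1", "a2", "q", "s", "b0", "b1", "r0")
  blocks <- lapply(blocks, function(b) {
    if (!all(need %in% names(b))) stop("state block missing fields")
    b[need]
  })
  if (!all(need %in% names(beta_block))) stop("beta block missing fields")
  structure(list(k = k, l = l, k_beta = k_beta, l_beta = l_beta,
                 y = y, z = z, u_bar = u_bar, v_bar = v_bar, blocks = blocks,
                 u_bar_beta = u_bar_beta, v_bar_beta = v_bar_beta,
                 beta_block = beta_block[need]),
            class = "per2_params")
}

## ---- state layouts -------------------------------------------------------
## ub-only  : x0, xE0, xEub, x0ub, xHub
## n >= 1   : x0, xp1..xpn, xE0, xEub, x0ub, xHub
## multiroute (n = 4): x0, xp1..xp4, then per route i: xiE0, xiEub, xi0ub, xiHub
## per2     : x0, xp1..xp4, blocks i=0..4 (4 each), xpb, beta block (4)
## Constrained mode drops x0 (x0 = x(t) - sum of the rest).

block_names <- function(idx) {
  as.vector(vapply(idx, function(i) paste0("x", i, ".",
                                           c("E0", "Eub", "0ub", "Hub")),
                   character(4L)))
}

state_names <- function(variant, n = 0L) {
  switch(variant,
    ub = c("x0", "xE0", "xEub", "x0ub", "xHub"),
    phospho = c("x0", paste0("xp", seq_len(n)), "xE0", "xEub", "x0ub", "xHub"),
    multiroute = c("x0", paste0("xp", 1:4), block_names(1:4)),
    per2 = c("x0", paste0("xp", 1:4), block_names(0:4),
             "xpb", paste0("xb.", c("E0", "Eub", "0ub", "Hub"))),
    stop("unknown variant"))
}

## derivative of the ubiquitination block shared by all variants.
## `enter` is the flux a0*u*substrate feeding xE0.
ub_block_deriv <- function(st, enter, u, v, p) {
  # st = c(xE0, xEub, x0ub, xHub)
  c(enter - (p$a1 + p$q) * st[1L],
    p$q * st[1L] + p$a0 * u * st[3L] - (p$a2 + p$r0) * st[2L],
    p$a2 * st[2L] + p$b1 * st[4L] - (p$b0 * v + p$a0 * u + p$r0) * st[3L],
    p$b0 * v * st[3L] - (p$b1 + p$s + p$r0) * st[4L])
}

#' Right-hand side of the phospho-independent ubiquitination model
#'
#' Mass-action dynamics of free protein, ligase-bound, ubiquitinated and
#' deubiquitinase-bound species, with the free-enzyme concentrations
#' eliminated through the constant pool totals
#' u(t) = u_bar - xE0 - xEub and v(t) = v_bar - xHub.
#'
#' @param state named or ordered numeric vector `(x0, xE0, xEub, x0ub, xHub)`.
#' @param t time in hours.
#' @param params an [ub_params()].
#' @param g synthesis rate: function of t or a constant (nM/h).
#' @return derivative vector in state order.
#' @export
rhs_phospho_independent <- function(state, t, params, g) {
  gv <- if (is.function(g)) g(t) else g
  u <- params$u_bar - state[2L] - state[3L]
  v <- params$v_bar - state[5L]
  x0 <- state[1L]
  blk <- ub_block_deriv(state[2:5], params$a0 * u * x0, u, v, params)
  dx0 <- gv - params$a0 * u * x0 + params$a1 * state[2L] + params$s * state[5L]
  c(dx0, blk)
}

#' Right-hand side of the phospho-dependent ubiquitination model
#'
#' An n-site phosphorylation chain feeds the ubiquitination block: only the
#' fully phosphorylated species binds the ligase. `n = 1` is the
#' mono-phosphorylation model; larger `n` the multisite chain.
#'
#' @param state vector `(x0, xp1..xpn, xE0, xEub, x0ub, xHub)`.
#' @param t time in hours.
#' @param params an [ub_params()].
#' @param phospho a [phospho_params()] with `n >= 1`.
#' @param g synthesis rate: function of t or constant (nM/h).
#' @export
rhs_phospho_dependent <- function(state, t, params, phospho, g) {
  n <- phospho$n
  if (n < 1L) stop("use rhs_phospho_independent for n = 0")
  if (length(state) != n + 5L) stop("state dimension does not match n")
  gv <- if (is.function(g)) g(t) else g
  x0 <- state[1L]
  xp <- state[2:(n + 1L)]
  ub <- state[(n + 2L):(n + 5L)]
  u <- params$u_bar - ub[1L] - ub[2L]
  v <- params$v_bar - ub[4L]
  y <- phospho$y; z <- phospho$z; k <- phospho$k; l <- phospho$l
  dx0 <- gv - k[1L] * y * x0 + l[1L] * z * xp[1L]
  dxp <- numeric(n)
  for (i in seq_len(n)) {
    below <- if (i == 1L) x0 else xp[i - 1L]
    dxp[i] <- k[i] * y * below - l[i] * z * xp[i]
    if (i < n) dxp[i] <- dxp[i] + l[i + 1L] * z * xp[i + 1L] - k[i + 1L] * y * xp[i]
  }
  dxp[n] <- dxp[n] - params$a0 * u * xp[n] + params$a1 * ub[1L] + params$s * ub[4L]
  blk <- ub_block_deriv(ub, params$a0 * u * xp[n], u, v, params)
  c(dx0, dxp, blk)
}

#' Right-hand side of the multi-route degradation model
#'
#' Four phosphostates, each with a dedicated ubiquitination route (own ligase
#' and deubiquitinase pools). The realized degradation rate sums the routes:
#' r(t) = sum_i r_i0 (x_i,Eub + x_i,0ub + x_i,Hub) / x.
#'
#' @param state vector `(x0, xp1..xp4, route blocks 1..4 of 4)`.
#' @param t time in hours.
#' @param params a [multiroute_params()].
#' @param g synthesis rate: function of t or constant (nM/h).
#' @export
rhs_multiroute <- function(state, t, params, g) {
  if (length(state) != 21L) stop("multiroute state must have 21 components")
  gv <- if (is.function(g)) g(t) else g
  ph <- params$phospho
  x0 <- state[1L]; xp <- state[2:5]
  y <- ph$y; z <- ph$z; k <- ph$k; l <- ph$l
  dxp <- numeric(4L)
  dblk <- numeric(16L)
  for (i in 1:4) {
    ri <- params$routes[[i]]
    blk <- state[(6L + 4L * (i - 1L)):(5L + 4L * i)]
    ui <- ri$u_bar - blk[1L] - blk[2L]
    vi <- ri$v_bar - blk[4L]
    below <- if (i == 1L) x0 else xp[i - 1L]
    d <- k[i] * y * below - l[i] * z * xp[i]
    if (i < 4L) d <- d + l[i + 1L] * z * xp[i + 1L] - k[i + 1L] * y * xp[i]
    d <- d - ri$a0 * ui * xp[i] + ri$a1 * blk[1L] + ri$s * blk[4L]
    dxp[i] <- d
    dblk[(4L * (i - 1L) + 1L):(4L * i)] <-
      ub_block_deriv(blk, ri$a0 * ui * xp[i], ui, vi, ri)
  }
  dx0 <- gv - k[1L] * y * x0 + l[1L] * z * xp[1L]
  c(dx0, dxp, dblk)
}

#' Right-hand side of the realistic PER2 degradation model
#'
#' FASP-site chain (states 0..4) with per-state ubiquitination through a
#' shared ligase pool, plus an independent beta-TrCP-site route with its own
#' ligase pool. The shared pool conservation is
#' u_bar = u + sum_i (x_i,E0 + x_i,Eub), i = 0..4.
#'
#' @param state vector of 30 components (see [state_names()] layout `per2`).
#' @param t time in hours.
#' @param params a [per2_params()].
#' @param g synthesis rate: function of t or constant (nM/h).
#' @export
rhs_per2 <- function(state, t, params, g) {
  if (length(state) != 30L) stop("per2 state must have 30 components")
  gv <- if (is.function(g)) g(t) else g
  x0 <- state[1L]; xp <- state[2:5]
  blocks <- lapply(0:4, function(i) state[(6L + 4L * i):(9L + 4L * i)])
  xpb <- state[26L]; bblk <- state[27:30]
  u <- params$u_bar - sum(vapply(blocks, function(b) b[1L] + b[2L], 0))
  v <- params$v_bar - sum(vapply(blocks, function(b) b[4L], 0))
  ub_ <- params$u_bar_beta - bblk[1L] - bblk[2L]
  vb_ <- params$v_bar_beta - bblk[4L]
  y <- params$y; z <- params$z; k <- params$k; l <- params$l
  # substrate of state-i route: xp0 == x0
  sub <- c(x0, xp)
  dblocks <- vector("list", 5L)
  for (i in 0:4) {
    bp <- params$blocks[[i + 1L]]
    dblocks[[i + 1L]] <- ub_block_deriv(blocks[[i + 1L]],
                                        bp$a0 * u * sub[i + 1L], u, v, bp)
  }
  b0p <- params$blocks[[1L]]
  dx0 <- gv - k[1L] * y * x0 + l[1L] * z * xp[1L] -
    params$k_beta * y * x0 + params$l_beta * z * xpb -
    b0p$a0 * u * x0 + b0p$a1 * blocks[[1L]][1L] + b0p$s * blocks[[1L]][4L]
  dxp <- numeric(4L)
  for (i in 1:4) {
    bp <- params$blocks[[i + 1L]]
    below <- if (i == 1L) x0 else xp[i - 1L]
    d <- k[i] * y * below - l[i] * z * xp[i]
    if (i < 4L) d <- d + l[i + 1L] * z * xp[i + 1L] - k[i + 1L] * y * xp[i]
    d <- d - bp$a0 * u * xp[i] + bp$a1 * blocks[[i + 1L]][1L] +
      bp$s * blocks[[i + 1L]][4L]
    dxp[i] <- d
  }
  bb <- params$beta_block
  dxpb <- params$k_beta * y * x0 - params$l_beta * z * xpb -
    bb$a0 * ub_ * xpb + bb$a1 * bblk[1L] + bb$s * bblk[4L]
  dbblk <- ub_block_deriv(bblk, bb$a0 * ub_ * xpb, ub_, vb_, bb)
  c(dx0, dxp, unlist(dblocks), dxpb, dbblk)
}

## dispatch table: full (forward-mode) RHS per variant
full_rhs <- function(variant, params, phospho, g) {
  switch(variant,
    ub = function(t, s) rhs_phospho_independent(s, t, params, g),
    phospho = function(t, s) rhs_phospho_dependent(s, t, params, phospho, g),
    multiroute = function(t, s) rhs_multiroute(s, t, params, g),
    per2 = function(t, s) rhs_per2(s, t, params, g))
}

detect_variant <- function(params, phospho = NULL) {
  if (inherits(params, "multiroute_params")) "multiroute"
  else if (inherits(params, "per2_params")) "per2"
  else if (inherits(params, "ub_params")) {
    if (is.null(phospho) || phospho$n == 0L) "ub" else "phospho"
  } else stop("unrecognized parameter object")
}

## total protein and realized degradation flux for a component matrix
## (columns named per state_names). Returns list(x, rflux) with rflux =
## sum of r_i0 * ub components (units conc/h).
totals_from_components <- function(comp, variant, params) {
  x <- rowSums(comp)
  rflux <- switch(variant,
    ub = params$r0 * (comp[, "xEub"] + comp[, "x0ub"] + comp[, "xHub"]),
    phospho = params$r0 * (comp[, "xEub"] + comp[, "x0ub"] + comp[, "xHub"]),
    multiroute = {
      f <- 0
      for (i in 1:4) {
        ri <- params$routes[[i]]
        f <- f + ri$r0 * (comp[, paste0("x", i, ".Eub")] +
                          comp[, paste0("x", i, ".0ub")] +
                          comp[, paste0("x", i, ".Hub")])
      }
      f
    },
    per2 = {
      f <- 0
      for (i in 0:4) {
        bp <- params$blocks[[i + 1L]]
        f <- f + bp$r0 * (comp[, paste0("x", i, ".Eub")] +
                          comp[, paste0("x", i, ".0ub")] +
                          comp[, paste0("x", i, ".Hub")])
      }
      f + params$beta_block$r0 * (comp[, "xb.Eub"] + comp[, "xb.0ub"] +
                                  comp[, "xb.Hub"])
    })
  list(x = x, rflux = rflux)
}

#' Forward simulation of a degradation model under a given synthesis profile
#'
#' Integrates the chosen model variant from an all-zero initial state under a
#' T-periodic synthesis rate g(t), period by period with a stiff-capable
#' adaptive solver (deSolve lsoda, rtol = atol = 1e-5 by default), until the
#' state at period boundaries changes by less than `tol_period` in relative
#' sup-norm (or `n_periods` is reached). The final period is returned on a
#' dense grid.
#'
#' @param g synthesis rate: function of t (nM/h) or a constant.
#' @param params an [ub_params()], [multiroute_params()] or [per2_params()].
#' @param phospho optional [phospho_params()] (with [ub_params()] only).
#' @param period forcing period T in hours.
#' @param n_periods maximum number of periods to integrate.
#' @param tol_period relative sup-norm convergence threshold between
#'   consecutive period boundaries.
#' @param rtol,atol solver tolerances.
#' @param dt_out output grid step (hours) over the final period.
#' @param state0 optional initial state (defaults to all zero).
#' @return object of class `sim_result` with `times` (final period, shifted to
#'   [0, T]), `components` matrix, `x`, `r`, `g`, `D`, `alpha_D`, `cost`,
#'   `feasible`, `periods_run`, `period_residual`.
#' @export
forward_simulate <- function(g, params, phospho = NULL, period = 24,
                             n_periods = 10, tol_period = 1e-4,
                             rtol = 1e-5, atol = 1e-5, dt_out = 0.05,
                             state0 = NULL) {
  variant <- detect_variant(params, phospho)
  nm <- state_names(variant, if (!is.null(phospho)) phospho$n else 0L)
  if (is.null(state0)) state0 <- stats::setNames(numeric(length(nm)), nm)
  rhs <- full_rhs(variant, params, phospho, g)
  func <- function(t, y, p) list(rhs(t, y))
  y <- state0
  resid <- Inf; k <- 0L
  while (k < n_periods) {
    k <- k + 1L
    tt <- seq((k - 1L) * period, k * period, length.out = 25L)
    sol <- deSolve::ode(y = y, times = tt, func = func, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0) stop("ODE integration failed (forward)")
    ynew <- sol[nrow(sol), -1L]
    scale <- max(abs(ynew), atol)
    resid <- max(abs(ynew - y)) / scale
    y <- ynew
    if (resid < tol_period && k >= 2L) break
  }
  tt <- seq((k) * period, (k + 1L) * period, by = dt_out)
  sol <- deSolve::ode(y = y, times = tt, func = func, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  comp <- sol[, -1L, drop = FALSE]
  colnames(comp) <- nm
  tot <- totals_from_components(comp, variant, params)
  tloc <- tt - tt[1L]
  r <- tot$rflux / tot$x
  gv <- if (is.function(g)) vapply(tt, g, 0) else rep(g, length(tt))
  res <- structure(list(times = tloc, components = comp, x = tot$x, r = r,
                        g = gv, D = r / r0_of(params),
                        alpha_D = alpha_D(r),
                        cost = trapz_mean(tloc, tot$rflux),
                        feasible = TRUE, violations = list(),
                        periods_run = k, period_residual = resid,
                        variant = variant),
                   class = "sim_result")
  res
}

r0_of <- function(params) {
  if (inherits(params, "ub_params")) params$r0
  else if (inherits(params, "multiroute_params"))
    max(vapply(params$routes, function(r) r$r0, 0))
  else if (inherits(params, "per2_params"))
    max(c(vapply(params$blocks, function(b) b$r0, 0), params$beta_block$r0))
  else stop("unrecognized parameter object")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result (%s): %d output times over T = %g h\n",
              x$variant, length(x$times), max(x$times)))
  cat(sprintf("  alpha_D = %.4f, cost = %.6g, feasible = %s (periods = %d, residual = %.3g)\n",
              x$alpha_D, x$cost, x$feasible, x$periods_run, x$period_residual))
  if (!x$feasible && length(x$violations))
    for (v in x$violations)
      cat(sprintf("  violation: %s <= 0 first at t = %.2f h (magnitude %.3g)\n",
                  v$quantity, v$time, v$magnitude))
  invisible(x)
}

#' Export a simulation result as tidy data
#'
#' @param sim a `sim_result`.
#' @return data frame with columns time, component, value (components plus the
#'   derived x, r, g, D series).
#' @export
sim_to_tidy <- function(sim) {
  comp <- cbind(sim$components, x = sim$x, r = sim$r, g = sim$g, D = sim$D)
  data.frame(time = rep(sim$times, ncol(comp)),
             component = rep(colnames(comp), each = length(sim$times)),
             value = as.vector(comp))
}

#' Read and write kinetic parameter sets as YAML
#'
#' The YAML carries a `variant` tag (`ub`, `phospho`, `multiroute`, `per2`)
#' and the corresponding fields; units are the package conventions (nM, 1/h,
#' 1/nM/h).
#'
#' @param path file path.
#' @export
read_params_yaml <- function(path) {
  d <- yaml::read_yaml(path)
  variant <- d$variant %||% "ub"
  d$variant <- NULL
  switch(variant,
    ub = do.call(ub_params, d),
    phospho = {
      ub <- do.call(ub_params, d$ub)
      ph <- do.call(phospho_params, d$phospho)
      list(params = ub, phospho = ph)
    },
    multiroute = multiroute_params(d$routes, do.call(phospho_params, d$phospho)),
    per2 = do.call(per2_params, d),
    stop("unknown variant in ", path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_params_yaml
#' @param params parameter object (optionally a list of `params` + `phospho`).
#' @export
write_params_yaml <- function(params, path) {
  d <- if (inherits(params, "ub_params")) {
    c(list(variant = "ub"), unclass(params))
  } else if (is.list(params) && !is.null(params$params) &&
             inherits(params$params, "ub_params")) {
    list(variant = "phospho", ub = unclass(params$params),
         phospho = unclass(params$phospho))
  } else if (inherits(params, "multiroute_params")) {
    list(variant = "multiroute", routes = params$routes,
         phospho = unclass(params$phospho))
  } else if (inherits(params, "per2_params")) {
    c(list(variant = "per2"), unclass(params))
  } else stop("unsupported parameter object")
  yaml::write_yaml(d, path)
  invisible(path)
}
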