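# Shared fixtures: reference parameter set, standard waveforms, and small
# independent oracles used across the test files.

# reference ubiquitination constants of the phospho-independent benchmark
bench_ub_params <- function(u_bar = 0.22) {
  ub_params(u_bar = u_bar, a0 = 234.9, a1 = 17880.6, a2 = 15347.2,
            q = 262.2, r0 = 1.3)
}

bench_phospho <- function(n = 1, y = 152.7, k = 0.013, z = 0, l = 0) {
  phospho_params(n = n, y = y, z = z, k = k, l = l)
}

sin_profile <- function(b = 0.5, mean = 1, period = 24) {
  make_profile(waveform_spec(period = period, mean = mean, rel_amplitude = b))
}

# dense-grid maximization oracle for max_t[-x'/x], independent of
# min_constant_rate's refinement path
grid_max_decline <- function(profile, dt = 1e-3) {
  tt <- seq(0, profile$period, by = dt)
  max(-profile$df(tt) / profile$f(tt))
}

# fine-grid quadrature oracle for the overlap similarity
quad_similarity <- function(f1, f2, period, n = 20001L) {
  tt <- seq(0, period, length.out = n)
  v1 <- f1(tt); v2 <- f2(tt)
  h <- tt[2L] - tt[1L]
  int <- function(y) sum((y[-1] + y[-length(y)]) / 2) * h
  int(pmin(v1, v2)) / int(pmax(v1, v2))
}

# damped-Newton root finder with numerical Jacobian: the independent oracle
# for algebraic steady states of the model right-hand sides
newton_root <- function(fn, x0, tol = 1e-10, maxit = 200L) {
  x <- x0
  for (it in seq_len(maxit)) {
    fx <- fn(x)
    if (max(abs(fx)) < tol) return(x)
    n <- length(x)
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- max(1e-8, 1e-6 * abs(x[j]))
      xp <- x; xp[j] <- xp[j] + h
      J[, j] <- (fn(xp) - fx) / h
    }
    step <- solve(J, -fx)
    lam <- 1
    repeat {
      xn <- x + lam * step
      if (max(abs(fn(xn))) < max(abs(fx)) || lam < 1e-6) break
      lam <- lam / 2
    }
    x <- xn
  }
  stop("newton_root did not converge")
}

# pseudo-steady-state linear-solve oracle for the multisite ubiquitinated
# fraction: solves the n-site chain fixed point at a frozen decline value R
pss_multisite_oracle <- function(R, U, Y, K) {
  n <- length(K)
  A <- matrix(0, n + 1L, n + 1L)
  b <- numeric(n + 1L)
  for (i in seq_len(n)) {
    nxt <- if (i < n) K[i + 1L] * Y else U
    if (i == 1L) {
      A[1L, ] <- A[1L, ] - K[1L] * Y      # W0 = 1 - sum(W) - D
      b[1L] <- -K[1L] * Y
      A[1L, 1L] <- A[1L, 1L] - nxt + R
    } else {
      A[i, i - 1L] <- A[i, i - 1L] + K[i] * Y
      A[i, i] <- A[i, i] - nxt + R
    }
  }
  A[n + 1L, n] <- U
  A[n + 1L, n + 1L] <- -(1 - R)
  solve(A, b)[n + 1L]
}

# ranges used by scans in the tests: log-uniform around the benchmark set
bench_ranges <- function(u_lo = 0.05, u_hi = 1) {
  list(u_bar = list(low = u_lo, high = u_hi, scale = "log"),
       a0 = list(low = 80, high = 700, scale = "log"),
       a1 = list(low = 6e3, high = 5e4, scale = "log"),
       a2 = list(low = 6e3, high = 5e4, scale = "log"),
       q = list(low = 90, high = 800, scale = "log"),
       r0 = list(low = 0.6, high = 3, scale = "log"))
}
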