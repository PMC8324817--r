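# Empirical pipeline: ingestion, smoothing, empirical rate profiles,
# parameter scans and simplex optimization.

test_that("time-series CSV ingestion sorts, validates and rejects bad input", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("# comment", "time_h,value", "12,2.0", "0,1.0", "6,1.5"), f)
  s <- read_timeseries(f)
  expect_equal(s$time_h, c(0, 6, 12))
  expect_equal(s$value, c(1.0, 1.5, 2.0))
  # shuffled rows give the identical series
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("time_h,value", "6,1.5", "12,2.0", "0,1.0"), f2)
  expect_equal(as.data.frame(read_timeseries(f2)), as.data.frame(s))
  f3 <- tempfile(fileext = ".csv")
  writeLines("time_h,value", f3)
  expect_error(read_timeseries(f3), "empty")
  expect_error(empirical_series(c(1, 1, 2), c(2, 3, 4), c(1, 1, 1)),
               "duplicate")
})

test_that("moving average keeps constants, reproduces the 3-point toy, wraps", {
  s <- empirical_series(c(0, 4, 8, 12), rep(2.5, 4))
  expect_equal(moving_average(s, 3)$value, rep(2.5, 4))
  toy <- empirical_series(c(0, 1, 2), c(1, 4, 1))
  sm <- moving_average(toy, 2)
  expect_equal(sm$value[2], 2.0)           # mean(1, 4, 1)
  expect_equal(sm$value[1], 2.5)           # mean(1, 4): truncated end
  # a vanishing window returns the replicate means
  sm0 <- moving_average(toy, 1e-6)
  expect_equal(sm0$value, c(1, 4, 1))
  expect_error(moving_average(toy, 50), "span")
  # periodic wrap pulls in the other end of the cycle
  per <- empirical_series(seq(0, 21, by = 3), c(5, 1, 1, 1, 1, 1, 1, 5),
                          period = 24)
  smp <- moving_average(per, 6, periodic = TRUE)
  expect_equal(smp$value[1], mean(c(5, 1, 5)))
})

test_that("smoothing spline honours the residual bound and degenerate input", {
  set.seed(3)
  tt <- seq(0, 21, by = 3)
  vals <- 1 + 0.5 * sin(2 * pi * tt / 24) + rnorm(8, 0, 0.05)
  s <- empirical_series(tt, vals)
  p0 <- fit_profile_spline(s, smoothing = 0)     # interpolates
  expect_equal(p0$f(tt), vals, tolerance = 1e-6)
  # residual sum grows monotonically with the smoothing bound
  rss_of <- function(sm) {
    p <- fit_profile_spline(s, smoothing = sm)
    sum((p$f(tt) - vals)^2)
  }
  r <- vapply(c(0.001, 0.01, 0.1), rss_of, 0)
  expect_true(all(diff(r) >= -1e-9))
  # constant data give a constant profile at any smoothing
  sc <- empirical_series(tt, rep(2, 8))
  pc <- fit_profile_spline(sc, smoothing = 5)
  expect_equal(pc$f(c(1, 7, 13)), rep(2, 3), tolerance = 1e-9)
})

test_that("normalization modes behave and are scale-free", {
  s <- empirical_series(c(0, 6, 12, 18), c(2, 3, 4, 5))
  n1 <- normalize_series(s, "at_time", 18)
  expect_equal(n1$value[n1$time_h == 18], 1)
  s2 <- empirical_series(c(0, 6, 12, 18), 7 * c(2, 3, 4, 5))
  n2 <- normalize_series(s2, "at_time", 18)
  expect_equal(n2$value, n1$value, tolerance = 1e-12)
  n3 <- normalize_series(s, "to_value", 100)
  expect_equal(n3$value, s$value / 100)
  expect_error(normalize_series(s, "at_time", 3), "not present")
})

test_that("abundance stage recovers the decline peak of a known waveform", {
  p <- make_profile(waveform_spec(rel_amplitude = 0.5, sharpness = 1.5))
  tt <- seq(0, 22, by = 2)
  ser <- empirical_series(tt, p$f(tt))   # noise-free sampling
  st <- tim_stage(ser, ref_time_abundance = 18, smoothing = 0)
  grid <- seq(0, 24, by = 0.05)
  true_peak <- grid[which.max(log_decline_rate(p, grid))]
  dphase <- min(abs(st$peak_phase_h - true_peak),
                24 - abs(st$peak_phase_h - true_peak))
  expect_lt(dphase, 1.5)
  expect_false(st$degenerate)
  # constant abundance has no decline peak
  stc <- tim_stage(empirical_series(tt, rep(3, length(tt))),
                   ref_time_abundance = 18)
  expect_true(stc$degenerate)
  # ubiquitination series rescaled to 1 at its reference
  ub <- empirical_series(c(0, 6, 12, 18), c(100, 60, 40, 80),
                         kind = "fraction")
  st2 <- tim_stage(ser, ub, ref_time_abundance = 18, ref_time_ubiq = 0,
                   smoothing = 0)
  expect_equal(st2$ubiq_rescaled$value[st2$ubiq_rescaled$time_h == 0], 1)
})

test_that("empirical rate profile combines interpolant, floor and minimum rate", {
  # constant profile: floor is 0, so the interpolant and min-rate rule decide
  const <- periodic_profile(f = function(t) rep(1, length(t)))
  pts <- empirical_series(c(4, 12), c(0.2, 0.6), kind = "rate")
  rE <- build_empirical_rate_profile(pts, const)
  expect_equal(predict(rE, 8), 0.4, tolerance = 1e-6)       # linear between
  expect_equal(predict(rE, 2), 0.2, tolerance = 1e-6)       # clamped at min
  # the terminal segment is continued linearly past the last point
  expect_equal(predict(rE, 16), 0.6 + 0.05 * 4, tolerance = 1e-6)
  # a sharp waveform lifts rE above a too-low measurement via the floor
  p <- sin_profile(b = 0.7)
  t_fall <- seq(0, 24, by = 0.05)[which.max(degradation_floor(p, seq(0, 24, by = 0.05)))]
  pts2 <- empirical_series(c(t_fall, (t_fall + 12) %% 24), c(0.01, 0.02),
                           kind = "rate")
  rE2 <- build_empirical_rate_profile(pts2, p)
  expect_equal(predict(rE2, t_fall), degradation_floor(p, t_fall),
               tolerance = 1e-3)
  # rE dominates floor and min-rate everywhere
  gg <- seq(0, 24, by = 0.25)
  expect_true(all(predict(rE2, gg) >= pmax(degradation_floor(p, gg), 0.01) - 1e-9))
})

test_that("uniform sampling is reproducible, in range, and uniform", {
  rng <- list(a = list(low = 1, high = 3, scale = "linear"),
              b = list(low = 1e-2, high = 1e2, scale = "log"),
              c = list(low = 5, high = 5, scale = "linear"))
  s1 <- sample_parameters(rng, 500, seed = 7)
  s2 <- sample_parameters(rng, 500, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(s1$a >= 1 & s1$a <= 3))
  expect_true(all(s1$b >= 1e-2 & s1$b <= 1e2))
  expect_true(all(s1$c == 5))
  ks <- suppressWarnings(stats::ks.test((s1$a - 1) / 2, "punif"))
  expect_gt(ks$p.value, 0.01)
  kslog <- suppressWarnings(stats::ks.test(log(s1$b / 1e-2) / log(1e4), "punif"))
  expect_gt(kslog$p.value, 0.01)
  expect_error(sample_parameters(list(a = list(low = 2, high = 1,
                                               scale = "linear")), 5),
               "invalid range")
})

test_that("scan records are order-insensitive and self-similarity reaches 1", {
  p <- sin_profile(b = 0.5)
  sam <- sample_parameters(bench_ranges(), 12, seed = 21)
  rec <- scan_parameters(p, sam, n = 0)
  expect_equal(nrow(rec), 12)
  # permuting the sample order permutes the records identically
  perm <- sample(12)
  rec_p <- scan_parameters(p, sam[perm, , drop = FALSE], n = 0)
  expect_equal(rec_p$cost, rec$cost[perm], tolerance = 1e-10)
  # a feasible record scored against its own simulated rate has S = 1
  i <- which(rec$feasible)[1]
  pr <- circadeg:::row_to_params(sam[i, , drop = FALSE], n = 0)
  sim <- constrained_simulate(p, pr$params)
  rE <- rate_series(sim$times, pmax(sim$r, 0))
  rec2 <- scan_parameters(p, sam[i, , drop = FALSE], rE = rE, n = 0)
  expect_gt(rec2$S[1], 0.999)
})

test_that("an all-infeasible range yields an explicit empty feasible set", {
  p <- sin_profile(b = 0.5)
  rng <- bench_ranges(u_lo = 1e-5, u_hi = 2e-5)   # ligase far below Rmax
  rec <- scan_parameters(p, sample_parameters(rng, 5, seed = 2), n = 0)
  expect_true(all(!rec$feasible))
  expect_true(all(nzchar(rec$reason)))
  expect_error(cost_similarity_association(rec), "at least 10")
})

test_that("simplex optimization improves the objective and recovers truth", {
  p <- sin_profile(b = 0.5)
  truth_row <- data.frame(u_bar = 0.22, a0 = 234.9, a1 = 17880.6,
                          a2 = 15347.2, q = 262.2, r0 = 1.3)
  pr <- circadeg:::row_to_params(truth_row, n = 0)
  sim <- constrained_simulate(p, pr$params)
  rE <- rate_series(sim$times, pmax(sim$r, 0))
  init <- unlist(truth_row) * c(2.4, 0.6, 1.7, 0.5, 1.9, 1.5)  # perturbed
  opt <- optimize_parameters(p, rE, "maximize_S", init = init, n = 0,
                             maxit = 150)
  S_init <- {
    pri <- circadeg:::row_to_params(as.data.frame(as.list(init)), n = 0)
    simi <- constrained_simulate(p, pri$params)
    similarity_S(rate_series(simi$times, pmax(simi$r, 0)), rE)
  }
  expect_gte(opt$value, S_init)
  expect_gte(opt$value, 0.95)
  expect_error(optimize_parameters(p, rE, "maximize_S",
                                   init = c(u_bar = 1e-6, a0 = 234.9,
                                            a1 = 17880.6, a2 = 15347.2,
                                            q = 262.2, r0 = 1.3), n = 0),
               "infeasible")
})

test_that("cost-similarity association behaves like a rank statistic", {
  S <- seq(0.1, 0.9, length.out = 20)
  rec <- data.frame(index = 1:20, S = S, cost = 1 - S, alpha_D = 0.1,
                    feasible = TRUE, reason = "")
  a <- cost_similarity_association(rec)
  expect_equal(a$spearman_rho, -1)
  rec2 <- rec; rec2$cost <- exp(5 * rec$cost)    # monotone transform
  expect_equal(cost_similarity_association(rec2)$spearman_rho, -1)
  set.seed(9)
  rec3 <- rec; rec3$cost <- runif(20)
  expect_lt(abs(cost_similarity_association(rec3)$spearman_rho), 0.6)
})
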