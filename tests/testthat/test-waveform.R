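# Waveform functionals: decline rates, cost bounds, rhythmicity, similarity.

test_that("log decline rate matches closed forms and sign convention", {
  const <- periodic_profile(f = function(t) rep(2, length(t)))
  expect_equal(log_decline_rate(const, c(0, 7, 23)), rep(0, 3), tolerance = 1e-8)

  # exponential decay segment embedded in a long-period profile behaves
  # log-linearly: -x'/x = 0.1 within the segment
  expdec <- periodic_profile(f = function(t) exp(-0.1 * t), df = function(t) -0.1 * exp(-0.1 * t),
                             period = 240)
  expect_equal(log_decline_rate(expdec, c(5, 50, 100)), rep(0.1, 3),
               tolerance = 1e-10)

  p <- sin_profile(b = 0.5)
  b <- 0.5; w <- 2 * pi / 24
  closed <- b * w / sqrt(1 - b^2)
  expect_equal(min_constant_rate(p), closed, tolerance = 1e-6)
  expect_equal(grid_max_decline(p), closed, tolerance = 1e-5)
})

test_that("minimum constant rate is zero for constant and grows with amplitude", {
  const <- periodic_profile(f = function(t) rep(1, length(t)))
  expect_equal(min_constant_rate(const), 0, tolerance = 1e-9)
  r_small <- min_constant_rate(sin_profile(b = 0.3))
  r_big <- min_constant_rate(sin_profile(b = 0.6))
  expect_gt(r_big, r_small)
})

test_that("degradation floor clips the rising phase and bounds feasible rates", {
  p <- sin_profile(b = 0.5)
  rising <- 3    # x' > 0 shortly after the trough
  falling <- 15  # x' < 0 after the peak
  expect_identical(degradation_floor(p, rising), 0)
  expect_equal(degradation_floor(p, falling), log_decline_rate(p, falling))
  # any sustained r(t) must dominate the floor pointwise: the floor itself,
  # fed back through the balance, yields g >= 0 everywhere
  bal <- synthesis_from_balance(p, function(t) degradation_floor(p, t))
  expect_gte(bal$min_g, -1e-9)
})

test_that("cg is homogeneous in scale and matches the sinusoid closed form", {
  p1 <- sin_profile(b = 0.5, mean = 1)
  p3 <- sin_profile(b = 0.5, mean = 3)
  expect_equal(cg(p1), 0.5 * (2 * pi / 24) / sqrt(0.75), tolerance = 1e-5)
  expect_equal(cg(p3), 3 * cg(p1), tolerance = 1e-8)
  const <- periodic_profile(f = function(t) rep(5, length(t)))
  expect_equal(cg(const), 0, tolerance = 1e-8)
})

test_that("synthesis cost balances <g> = <r x> and reduces to known cases", {
  p <- sin_profile(b = 0.4)
  # constant profile, constant rate
  const <- periodic_profile(f = function(t) rep(2, length(t)))
  cs <- synthesis_cost(const, function(t) rep(0.3, length(t)))
  expect_equal(cs$mean_degradation, 0.6, tolerance = 1e-10)
  expect_equal(cs$mean_synthesis, 0.6, tolerance = 1e-8)
  # r == min constant rate reproduces cg
  rmin <- min_constant_rate(p)
  cs2 <- synthesis_cost(p, function(t) rep(rmin, length(t)))
  expect_equal(cs2$mean_degradation, cg(p), tolerance = 1e-8)
  # the pointwise floor never costs more than the constant-rate bound
  cs3 <- synthesis_cost(p, function(t) degradation_floor(p, t))
  expect_lte(cs3$mean_degradation, cg(p) + 1e-10)
  # balance identity for an arbitrary admissible rate
  cs4 <- synthesis_cost(p, function(t) 0.5 + 0.2 * cos(2 * pi * t / 24))
  expect_lt(abs(cs4$mean_synthesis - cs4$mean_degradation) /
              cs4$mean_degradation, 1e-6)
})

test_that("alpha_D follows its definition and scale invariance", {
  tt <- seq(0, 24, by = 0.1)
  expect_equal(alpha_D(rate_series(tt, rep(0.7, length(tt)))), 0)
  r <- 1.0 + 0.3 * cos(2 * pi * tt / 24)
  expect_equal(alpha_D(r), 0.6 / 1.3, tolerance = 1e-6)
  # a 62.5% trough-to-peak increase means a 1.625 peak/trough ratio
  r2 <- 0.4 * (1 + 0.625 * (1 + cos(2 * pi * tt / 24)) / 2)
  expect_equal(max(r2) / min(r2), 1.625, tolerance = 1e-9)
  expect_equal(alpha_D(r2), 0.625 / 1.625, tolerance = 1e-9)
  expect_equal(alpha_D(5 * r), alpha_D(r), tolerance = 1e-12)
  expect_error(alpha_D(rep(0, 10)), "all-zero")
})

test_that("similarity S has its fixed points, symmetry and quadrature value", {
  tt <- seq(0, 24, by = 0.1)
  r1 <- rate_series(tt, 0.5 + 0.2 * sin(2 * pi * tt / 24))
  expect_equal(similarity_S(r1, r1), 1, tolerance = 1e-9)
  c2 <- rate_series(tt, rep(0.8, length(tt)))
  c1 <- rate_series(tt, rep(0.4, length(tt)))
  expect_equal(similarity_S(c2, c1), 0.5, tolerance = 1e-9)
  r2 <- rate_series(tt, 0.6 + 0.25 * cos(2 * pi * tt / 24 + 1))
  expect_equal(similarity_S(r1, r2), similarity_S(r2, r1), tolerance = 1e-12)
  # common rescaling leaves S unchanged
  r1s <- rate_series(tt, 3 * predict(r1, tt))
  r2s <- rate_series(tt, 3 * predict(r2, tt))
  expect_equal(similarity_S(r1s, r2s), similarity_S(r1, r2), tolerance = 1e-9)
  # brute-force quadrature oracle on random smooth pairs
  set.seed(4)
  for (i in 1:5) {
    a <- runif(1, 0.3, 1); b <- runif(1, 0, 0.25); ph <- runif(1, 0, 2 * pi)
    f1 <- function(t) a + b * sin(2 * pi * t / 24 + ph)
    f2 <- function(t) 0.5 + 0.2 * cos(2 * pi * t / 24)
    expect_equal(similarity_S(f1, f2, period = 24, dt = 0.02),
                 quad_similarity(f1, f2, 24), tolerance = 1e-3)
  }
})

test_that("synthesis_from_balance reports negative g under r = 0 on a falling wave", {
  p <- sin_profile(b = 0.5)
  bal <- synthesis_from_balance(p, function(t) rep(0, length(t)))
  expect_lt(bal$min_g, 0)  # pure decay cannot track the falling phase
  # <g> = <r x> for arbitrary periodic inputs
  r <- function(t) 0.4 + 0.1 * sin(2 * pi * t / 24 + 0.7)
  bal2 <- synthesis_from_balance(p, r)
  lhs <- mean(bal2$g[-length(bal2$g)])
  cs <- synthesis_cost(p, r)
  expect_lt(abs(lhs - cs$mean_degradation) / cs$mean_degradation, 1e-5)
})

test_that("half-life inverts the rate and the ATP payoff bound is n/(4N)", {
  expect_equal(half_life(log(2)), 1, tolerance = 1e-12)
  expect_equal(half_life(1.3), log(2) / 1.3, tolerance = 1e-12)
  expect_equal(half_life(2 * 1.3), half_life(1.3) / 2, tolerance = 1e-12)
  expect_equal(half_life(log(2) / half_life(0.37)), half_life(0.37),
               tolerance = 1e-12)
  expect_error(half_life(0))
  expect_equal(atp_payoff_fraction(4, 100), 0.01)
  expect_equal(atp_payoff_fraction(0, 100), 0)
  expect_equal(atp_payoff_fraction(1, 500), 5e-4)
})

test_that("profile CSV round-trips and rejects malformed input", {
  p <- sin_profile(b = 0.3)
  f <- tempfile(fileext = ".csv")
  write_profile_csv(p, f, dt = 0.25)
  p2 <- read_profile_csv(f)
  tt <- seq(0, 24, by = 0.5)
  expect_equal(p2$f(tt), p$f(tt), tolerance = 1e-4)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_profile_csv(bad), "time_h")
})

test_that("profile invariants hold across random generated waveforms", {
  set.seed(11)
  for (i in 1:25) {
    spec <- waveform_spec(mean = exp(runif(1, -1, 3)),
                          rel_amplitude = runif(1, 0.05, 0.9),
                          sharpness = runif(1, 1, 4),
                          asymmetry = runif(1, -0.8, 0.8),
                          phase = runif(1, 0, 24))
    p <- make_profile(spec)
    tt <- seq(0, 24, by = 0.25)
    expect_true(all(p$f(tt) > 0))
    expect_equal(p$f(tt), p$f(tt + 24), tolerance = 1e-10)
    expect_equal(p$df(3.21), p$df(3.21 + 48), tolerance = 1e-8)
    # constant-rate bound dominates the pointwise-floor cost
    fl <- synthesis_cost(p, function(t) degradation_floor(p, t))
    expect_lte(fl$mean_degradation, cg(p) * (1 + 1e-8))
  }
})
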