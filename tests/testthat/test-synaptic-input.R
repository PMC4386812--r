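test_that("von Mises concentration inverts the vector strength", {
  expect_equal(kappa_from_vs(0), 0)
  expect_error(kappa_from_vs(1))
  # frozen anchor from a Bessel-ratio bisection oracle
  k6 <- o_bisect(function(k) besselI(k, 1, TRUE) / besselI(k, 0, TRUE) - 0.6,
                 1e-6, 10)
  expect_equal(kappa_from_vs(0.6), k6, tolerance = 1e-7)
  expect_equal(k6, 1.51574, tolerance = 1e-4)
  for (r in c(0.1, 0.3, 0.6, 0.9)) {
    k <- kappa_from_vs(r)
    expect_equal(besselI(k, 1, TRUE) / besselI(k, 0, TRUE), r,
                 tolerance = 1e-8)
  }
})

test_that("alpha kernel has the printed peak and half-width", {
  tau <- 0.1 / 2.446
  expect_equal(alpha_kernel(-1e-9), 0)
  expect_equal(alpha_kernel(tau), 1.3)  # peak at t = tau_alpha
  # half-amplitude crossings of x e^(1-x) = 1/2, located numerically
  f <- function(x) x * exp(1 - x) - 0.5
  x1 <- o_bisect(f, 0.01, 1)
  x2 <- o_bisect(function(x) -f(x), 1, 6)
  expect_equal(x2 - x1, 2.446, tolerance = 1e-3)
  expect_equal(alpha_kernel(x1 * tau), 1.3 / 2, tolerance = 1e-6)
})

test_that("conductance traces superpose kernels linearly", {
  expect_equal(as.numeric(conductance_from_trains(list(), 1, 0.01)),
               rep(0, 101))
  g1 <- conductance_from_trains(0.205, 2, 0.005)
  t <- seq(0, 2, by = 0.005)
  ker <- alpha_kernel(t - 0.205)
  ker[t - 0.205 > 10 * 0.1 / 2.446] <- 0  # truncation applied by the builder
  expect_equal(as.numeric(g1), ker, tolerance = 1e-12)
  # linearity: conductance of a union equals the sum of the parts, exactly
  set.seed(1)
  a <- sort(runif(50, 0, 10)); b <- sort(runif(70, 0, 10))
  gu <- conductance_from_trains(list(a, b), 10, 0.01)
  expect_equal(as.numeric(gu),
               as.numeric(conductance_from_trains(a, 10, 0.01)) +
                 as.numeric(conductance_from_trains(b, 10, 0.01)),
               tolerance = 1e-12)
  expect_true(all(gu >= 0))
})

test_that("mean conductance equals rate times the kernel integral", {
  # oracle: integral of the unitary kernel by quadrature
  I_alpha <- integrate(alpha_kernel, 0, 2)$value
  expect_equal(I_alpha, 1.3 * exp(1) * 0.1 / 2.446, tolerance = 1e-6)
  set.seed(20)
  M <- 300; dur <- 2000
  trains <- lapply(seq_len(M), function(i) generate_poisson_train(500, dur))
  g <- conductance_from_trains(trains, dur, 0.01)
  n_ev <- sum(lengths(trains))
  expect_gt(n_ev, 2e5)
  target <- M * 0.5 * I_alpha          # 300 fibers at 500 Hz -> ~21.7 nS
  se <- target / sqrt(n_ev)            # Poisson-count driven
  expect_lt(abs(mean(g) - target), 3 * se)
  expect_equal(target, 21.67, tolerance = 1e-2)
})

test_that("homogeneous Poisson trains have the right counts and intervals", {
  expect_length(generate_poisson_train(0, 100), 0)
  set.seed(2)
  counts <- replicate(300, length(generate_poisson_train(500, 1000)))
  se <- sqrt(500 / 300)
  expect_lt(abs(mean(counts) - 500), 2 * se)
  set.seed(3)
  tr <- generate_poisson_train(500, 2e5)   # ~1e5 events
  ks <- suppressWarnings(stats::ks.test(diff(tr), "pexp", 0.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("phase-locked trains have the right rate and vector strength", {
  p <- input_params()
  set.seed(4)
  trains <- lapply(1:100, function(i) generate_phase_locked_train(p, 2000))
  n <- sum(lengths(trains))
  expect_lt(abs(n / (100 * 2) - 500), 2 * sqrt(n) / (100 * 2))
  pooled <- unlist(trains)
  vs <- vector_strength(pooled, 4000)
  expect_gt(n, 5e4)
  expect_lt(abs(vs - 0.6), 2 * sqrt((1 - 0.6^2) / n) + 0.005)
  # r = 0 degenerates to a homogeneous train
  p0 <- input_params(r = 0)
  set.seed(5)
  t0 <- generate_phase_locked_train(p0, 5000)
  expect_lt(vector_strength(t0, 4000), 0.05)
})

test_that("thinning reproduces the von Mises phase distribution", {
  p <- input_params()
  set.seed(6)
  pooled <- unlist(lapply(1:60, function(i) generate_phase_locked_train(p, 4000)))
  expect_gt(length(pooled), 1e5)
  ph <- (2 * pi * 4000 * pooled / 1000) %% (2 * pi)
  brk <- seq(0, 2 * pi, length.out = 21)
  obs <- table(cut(ph, brk))
  kap <- kappa_from_vs(0.6)
  dens <- function(th) exp(kap * cos(th)) / (2 * pi * besselI(kap, 0))
  pr <- vapply(seq_len(20), function(i)
    integrate(dens, brk[i], brk[i + 1])$value, 0)
  chi <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = pr / sum(pr)))
  expect_gt(chi$p.value, 0.01)
})

test_that("binaural combination shifts the contralateral trace circularly", {
  set.seed(7)
  a <- sort(runif(200, 0, 10)); b <- sort(runif(200, 0, 10))
  gi <- conductance_from_trains(a, 10, 0.0125)
  gc <- conductance_from_trains(b, 10, 0.0125)
  g0 <- binaural_conductance(gi, gc, 0)
  expect_equal(as.numeric(g0), as.numeric(gi) + as.numeric(gc))
  # a full-cycle shift is one stimulus period: 0.25 ms = 20 grid steps here
  g2pi <- binaural_conductance(gi, gc, 2 * pi)
  n <- length(gc)
  expect_equal(as.numeric(g2pi),
               as.numeric(gi) + as.numeric(gc)[c(21:n, 1:20)])
  expect_error(binaural_conductance(gi, gc[-1], 0), "length")
})

test_that("antiphase inputs cancel the stimulus-frequency component", {
  p <- input_params()
  set.seed(8)
  drv <- binaural_drive(p, 500, 0.0125)
  fourier_4k <- function(g) {
    t <- seq(0, by = 0.0125, length.out = length(g))
    Mod(mean(as.numeric(g) * exp(-2i * pi * 4 * t)))
  }
  f0 <- fourier_4k(binaural_conductance(drv$ipsi, drv$contra, 0, 4000))
  fpi <- fourier_4k(binaural_conductance(drv$ipsi, drv$contra, pi, 4000))
  expect_lt(fpi, f0 / 10)
})

test_that("vector strength estimator behaves at the extremes", {
  expect_equal(vector_strength(3.21, 4000), 1)
  expect_error(vector_strength(numeric(0), 4000))
  # spikes uniform over cycles -> vanishing vector strength
  set.seed(9)
  u <- runif(4000, 0, 1000)
  expect_lt(vector_strength(u, 4000), 3 * sqrt(pi / (4 * 4000)) + 0.02)
})
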