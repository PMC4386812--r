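test_that("compiled stepper matches the plain-R reference step for step", {
  dt <- 0.005
  dur <- 5
  g <- sine_drive(dur, dt, mean = 30, amp = 25)  # strong enough to spike
  n <- length(g) - 1
  for (v in all_variants) {
    m <- nl_model(v)
    dt_v <- if (v == "two_comp_active_if") 0.001 else dt
    g_v <- sine_drive(dur, dt_v, mean = 30, amp = 25)
    n_v <- length(g_v) - 1
    sim <- simulate_nl(m, g_v, 0, dur, dt_v, record_d = TRUE)
    st <- initial_state(m)
    every <- max(1, n_v %/% 200)
    for (i in seq_len(n_v)) {
      st <- euler_step(st, m, g_v[i], 0, dt_v)
      if (i %% every == 0) {
        j <- i + 1
        expect_equal(st$V_soma, sim$V_soma[j], tolerance = 1e-10,
                     label = paste(v, "V at step", i))
        if (!is.null(sim$d))
          expect_equal(st$d, sim$d[j], tolerance = 1e-10)
      }
    }
    expect_equal(st$spike_times %||% numeric(0),
                 as.numeric(sim$spike_times), tolerance = 1e-9,
                 label = paste(v, "spike times"))
  }
})

test_that("a held membrane is a fixed point of the stepper", {
  for (v in spiking_variants) {
    m <- nl_model(v)
    Ib <- find_holding_current(m, -61)
    sim <- simulate_nl(m, 0, Ib, 5, 0.001,
                       init = initial_state(m, -61))
    expect_lt(max(abs(sim$V_soma - (-61))), 1e-6)
    expect_length(sim$spike_times, 0)
  }
})

test_that("zero input from rest stays at rest and never spikes", {
  for (v in all_variants) {
    m <- nl_model(v)
    dt <- if (v == "two_comp_active_if") 0.001 else 0.01
    sim <- simulate_nl(m, 0, 0, 20, dt)
    expect_length(sim$spike_times, 0)
    expect_lt(diff(range(sim$V_soma)), 1e-6)
  }
})

test_that("relaxation to rest agrees with the steady-state root", {
  for (v in all_variants) {
    m <- nl_model(v)
    dt <- if (v == "two_comp_active_if") 0.001 else 0.005
    vr <- resting_potential(m)
    sim <- simulate_nl(m, 0, 0, 50, dt, init = initial_state(m, vr - 3))
    expect_lt(abs(sim$V_soma[length(sim$V_soma)] - vr), 1e-3)
  }
})

test_that("simulations are deterministic given identical inputs", {
  p <- input_params()
  m <- nl_model("one_comp_active_if")
  run <- function() {
    set.seed(321)
    tr <- lapply(1:20, function(i) generate_phase_locked_train(p, 200))
    g <- conductance_from_trains(tr, 200, 0.01) * 10
    simulate_nl(m, g, 0, 200, 0.01)
  }
  a <- run(); b <- run()
  expect_identical(a$spike_times, b$spike_times)
  expect_identical(a$V_soma, b$V_soma)
})

test_that("no two spikes are closer than the refractory period", {
  p <- input_params()
  set.seed(99)
  drv <- binaural_drive(p, 2000, 0.01)
  g <- binaural_conductance(drv$ipsi, drv$contra, 0, p$f_stim)
  for (v in c("one_comp_active_if", "one_comp_passive_if")) {
    m <- nl_model(v)
    sim <- simulate_nl(m, g, 0, 2000, 0.01)
    expect_gt(length(sim$spike_times), 100)
    expect_true(all(diff(sim$spike_times) >= m$generator$T_ref - 1e-9))
  }
})

test_that("two-compartment refractory invariant at its stable step size", {
  p <- input_params()
  set.seed(99)
  drv <- binaural_drive(p, 500, 0.001)
  g <- binaural_conductance(drv$ipsi, drv$contra, 0, p$f_stim)
  m2 <- nl_model("two_comp_active_if")
  sim <- simulate_nl(m2, g, 0, 500, 0.001)
  expect_gt(length(sim$spike_times), 20)
  expect_true(all(diff(sim$spike_times) >= m2$generator$T_ref - 1e-9))
})

test_that("recursive spike-current state equals the closed-form sum", {
  p <- input_params()
  set.seed(42)
  drv <- binaural_drive(p, 500, 0.01)
  g <- binaural_conductance(drv$ipsi, drv$contra, 0, p$f_stim)
  m <- nl_model("one_comp_active_if")
  sim <- simulate_nl(m, g, 0, 500, 0.01, record_spike_current = TRUE)
  expect_gt(length(sim$spike_times), 50)
  gen <- m$generator
  idx <- seq(1, length(sim$times), by = 37)
  for (j in idx) {
    t <- sim$times[j]
    past <- sim$spike_times[sim$spike_times <= t + 1e-12]
    s1_cf <- sum(gen$A1 * exp(-(t - past) / gen$tau1))
    s2_cf <- sum(gen$A2 * exp(-(t - past) / gen$tau2))
    denom <- max(1, s1_cf + s2_cf)
    expect_lt(abs(sim$s1[j] + sim$s2[j] - s1_cf - s2_cf) / denom, 1e-9)
  }
})

test_that("forward Euler converges at first order on subthreshold runs", {
  m <- nl_model("non_spiking")
  dur <- 100
  err <- sapply(c(0.02, 0.01, 0.005), function(dt) {
    g1 <- sine_drive(dur, dt)
    g2 <- sine_drive(dur, dt / 2)
    v1 <- simulate_nl(m, g1, 0, dur, dt)$V_soma
    v2 <- simulate_nl(m, g2, 0, dur, dt / 2, record_stride = 2)$V_soma
    max(abs(v1 - v2))
  })
  expect_gt(err[1] / err[2], 1.8)
  expect_gt(err[2] / err[3], 1.8)
})

test_that("the KLVA gate stays within [0,1] under default drive", {
  p <- input_params()
  set.seed(8)
  drv <- binaural_drive(p, 1000, 0.015)
  g <- binaural_conductance(drv$ipsi, drv$contra, 0, p$f_stim)
  sim <- simulate_nl(nl_model("one_comp_active_if"), g, 0, 1000, 0.015,
                     record_d = TRUE)
  expect_false(sim$d_clamped)
  expect_true(all(sim$d >= 0 & sim$d <= 1))
})

test_that("numerical divergence raises unless explicitly tolerated", {
  m2 <- nl_model("two_comp_active_if")
  p <- input_params()
  set.seed(3)
  drv <- binaural_drive(p, 50, 0.01)
  g <- binaural_conductance(drv$ipsi, drv$contra, 0, p$f_stim)
  expect_error(simulate_nl(m2, g, 0, 50, 0.01), "non-finite")
  sim <- simulate_nl(m2, g, 0, 50, 0.01, allow_divergence = TRUE)
  expect_false(is.na(sim$diverged_at_step))
  expect_true(anyNA(sim$V_soma))
})

test_that("trace bookkeeping: lengths, strides, input validation", {
  m <- nl_model("one_comp_passive_if")
  sim <- simulate_nl(m, 0, 0, 10, 0.01)
  expect_length(sim$V_soma, 10 / 0.01 + 1)
  sim2 <- simulate_nl(m, 0, 0, 10, 0.01, record_stride = 100)
  expect_length(sim2$V_soma, 11)
  expect_equal(sim2$times, seq(0, 10, by = 1))
  expect_error(simulate_nl(m, rep(1, 5), 0, 10, 0.01), "cover")
  expect_error(simulate_nl(m, 0, 0, 10, -0.01))
  expect_error(simulate_nl(m, rep(-1, 1001), 0, 10, 0.01), "negative")
})
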