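test_that("zero step current never spikes from the holding potential", {
  for (v in spiking_variants) {
    m <- nl_model(v)
    dt <- if (v == "two_comp_active_if") 0.001 else 0.01
    r <- classify_step_response(m, 0, dt = dt)
    expect_equal(as.character(r$class), "no_spike", label = v)
  }
})

test_that("step ladders separate phasic and tonic regimes", {
  lad <- step_response_ladder(nl_model("one_comp_active_if"),
                              I_steps = seq(0, 800, by = 50))
  cls <- rle(as.character(lad$class))$values
  expect_equal(cls, c("no_spike", "phasic", "tonic"))
  ladp <- step_response_ladder(nl_model("one_comp_passive_if"),
                               I_steps = seq(0, 800, by = 50))
  expect_false("phasic" %in% ladp$class)
})

test_that("phasic classification is stable in the step duration", {
  m <- nl_model("one_comp_active_if")
  # middle of the phasic band found on the ladder above
  for (dur in c(50, 100, 200)) {
    r <- classify_step_response(m, 350, step_dur = dur)
    expect_equal(as.character(r$class), "phasic", label = paste("dur", dur))
  }
})

test_that("rate-phase curves are periodic and modulated", {
  p <- input_params()
  m <- nl_model("one_comp_active_if")
  set.seed(31)
  rp <- rate_phase_curve(m, p, deltas = c(-2 * pi, -pi, 0, pi, 2 * pi),
                         duration_s = 2)
  tab <- rp$curve
  r0 <- tab$rate[tab$delta == 0]
  # common input realisation: a 2*pi shift reuses the same events
  expect_lt(abs(tab$rate[1] - r0), 3 * (tab$se[1] + tab$se[3]))
  expect_gt(rp$in_phase_rate, rp$out_of_phase_rate)
  expect_equal(rp$modulation_depth, rp$in_phase_rate - rp$out_of_phase_rate)
})

test_that("spike-rate summaries carry counting-noise standard errors", {
  p <- input_params()
  set.seed(12)
  rp <- rate_phase_curve(nl_model("one_comp_active_if"), p,
                         deltas = 0, duration_s = 1)
  expect_equal(rp$curve$se, sqrt(rp$curve$rate * 0.98) / 0.98,
               tolerance = 0.05)
})

test_that("in-phase rate is non-increasing in the refractory period", {
  p <- input_params()
  set.seed(13)
  sw <- sweep_refractory(nl_model("one_comp_active_if"), p,
                         t_refs = c(0.8, 1.2, 1.6), duration_s = 2)
  d <- diff(sw$table$in_phase_rate)
  tol <- 2 * (sw$table$se_in[-1] + sw$table$se_in[-3])
  expect_true(all(d <= tol))
  expect_false(is.na(sw$in_phase_change_08_16))
})

test_that("threshold sweep rates fall with threshold; interval is interior", {
  p <- input_params()
  set.seed(14)
  sw <- sweep_threshold(nl_model("one_comp_active_if"), p,
                        thresholds = seq(-59.3, -57.3, by = 0.4),
                        duration_s = 2)
  tab <- sw$table
  tol <- 2 * (tab$se_in[-1] + tab$se_in[-nrow(tab)])
  expect_true(all(diff(tab$in_phase_rate) <= tol))
  expect_true(all(diff(tab$out_of_phase_rate) <= tol))
  expect_gt(sw$criterion_interval$width, 0)
})

test_that("reliability discrepancies grow with the step and flag divergence", {
  p <- input_params(M = 60)
  m <- nl_model("one_comp_active_if")
  set.seed(15)
  rel <- reliability_max_dt(m, p, dt_us = c(2, 10, 30), dt_ref_us = 0.5,
                            n_traces = 1, duration_s = 0.2)
  expect_true(all(diff(rel$table$max_discrepancy_mV) > 0))
  expect_true(all(rel$table$max_discrepancy_mV > 0))
  expect_error(reliability_max_dt(m, p, dt_us = c(0.75), dt_ref_us = 0.5,
                                  n_traces = 1, duration_s = 0.1),
               "integer multiples")
  set.seed(16)
  rel2 <- reliability_max_dt(nl_model("two_comp_active_if"), p,
                             dt_us = c(1, 10), dt_ref_us = 0.5,
                             n_traces = 1, duration_s = 0.2)
  expect_equal(rel2$table$max_discrepancy_mV[2], Inf)  # node instability
  expect_equal(rel2$min_unreliable_dt_us, 10)
})

test_that("replaying a run's own spikes reproduces its trajectory", {
  p <- input_params()
  m <- nl_model("one_comp_active_if")
  set.seed(17)
  drv <- binaural_drive(p, 300, 0.01)
  g <- binaural_conductance(drv$ipsi, drv$contra, 0, p$f_stim)
  a <- simulate_nl(m, g, 0, 300, 0.01)
  b <- simulate_nl(m, g, 0, 300, 0.01, forced_spikes = a$spike_times)
  expect_gt(length(a$spike_times), 50)
  expect_equal(b$V_soma, a$V_soma, tolerance = 1e-12)
})
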