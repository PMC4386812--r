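#' Typical discharge range of owl coincidence detector neurons (spikes/s)
#'
#' Lower edge: mean - SD of in vivo discharge rates at unfavorable ITDs;
#' upper edge: mean + SD at favorable ITDs. Used as the evaluation band for
#' simulated in-phase and out-of-phase rates.
#' @export
nl_typical_discharge_range <- c(79, 522)

#' Modulation-depth criterion (spikes/s)
#'
#' Minimum in-phase minus out-of-phase rate difference regarded as adequate
#' ITD coding, derived from in vivo rate changes between favorable and
#' unfavorable ITDs.
#' @export
nl_modulation_criterion <- 180

#' Classify the response to a step current
#'
#' Holds the model at `V_hold` with the constant current from
#' [find_holding_current()], lets it settle, then applies `I_step` on top for
#' `step_dur` ms. The response is `"no_spike"` if no spike occurs during the
#' step, `"phasic"` if there is exactly one spike or all spikes fall within
#' the first `onset_window` ms of the step, and `"tonic"` if spiking
#' continues beyond the onset window.
#'
#' @param model An [nl_model()] with a thresholding unit.
#' @param I_step Step amplitude (pA).
#' @param V_hold Holding potential (mV).
#' @param settle Settling time before the step (ms).
#' @param step_dur Step duration (ms).
#' @param onset_window Onset window defining phasic firing (ms).
#' @param dt Time step (ms).
#' @return List with `class` (factor over the three labels), `n_spikes`, and
#'   `spike_times` relative to step onset (ms).
#' @export
classify_step_response <- function(model, I_step, V_hold = -60, settle = 20,
                                   step_dur = 50, onset_window = 5,
                                   dt = 0.01) {
  if (!has_generator(model))
    stop("step-response classification requires a spiking variant")
  I_base <- find_holding_current(model, V_hold)
  n_steps <- as.integer(round((settle + step_dur) / dt))
  tt <- seq_len(n_steps + 1L) - 1L
  I_ext <- ifelse(tt * dt >= settle, I_base + I_step, I_base)
  sim <- simulate_nl(model, 0, I_ext, settle + step_dur, dt,
                     init = initial_state(model, V_hold),
                     record_stride = n_steps)
  st <- sim$spike_times[sim$spike_times >= settle] - settle
  cls <- if (!length(st)) "no_spike"
         else if (length(st) == 1 || all(st <= onset_window)) "phasic"
         else "tonic"
  list(class = factor(cls, levels = c("no_spike", "phasic", "tonic")),
       n_spikes = length(st), spike_times = st)
}

#' Step-current response ladder
#'
#' Runs [classify_step_response()] over a ladder of step amplitudes; the
#' active variants show a contiguous phasic band between no-spike and tonic,
#' the passive variant jumps from no-spike directly to tonic firing.
#'
#' @inheritParams classify_step_response
#' @param I_steps Vector of step amplitudes (pA).
#' @return Data frame with columns `I_step`, `class`, `n_spikes`.
#' @export
step_response_ladder <- function(model, I_steps = seq(0, 1200, by = 25), ...) {
  res <- lapply(I_steps, function(I) classify_step_response(model, I, ...))
  data.frame(I_step = I_steps,
             class = factor(vapply(res, function(r) as.character(r$class), ""),
                            levels = c("no_spike", "phasic", "tonic")),
             n_spikes = vapply(res, function(r) r$n_spikes, 0L))
}

#' Average spike shape under Poisson noise input
#'
#' Drives the model with `M` non-phase-locked (homogeneous Poisson) fibers
#' through the alpha synapse, aligns the somatic voltage at the
#' threshold-crossing sample of each output spike, and averages `n_spikes`
#' aligned windows. The amplitude `H` is the waveform peak minus the
#' pre-spike baseline (mean over `baseline_ms`); `W` is the width at half of
#' `H`, interpolated on the grid. The amplitude measured from the threshold
#' value is also reported, since the baseline convention is not unique.
#'
#' Uses the R random number generator; seed with [set.seed()] for
#' reproducibility.
#'
#' @param model An [nl_model()] with a thresholding unit.
#' @param n_spikes Number of spikes to average.
#' @param M Number of Poisson fibers.
#' @param lambda0 Fiber rate (spikes/s).
#' @param dt Time step (ms).
#' @param window_ms Alignment window around the crossing (ms, `c(before,
#'   after)` with `before < 0`).
#' @param baseline_ms Pre-spike interval defining the baseline (ms).
#' @param H_alpha,tau_alpha Unitary synapse parameters.
#' @param chunk_s Simulated chunk length per draw (s); chunks are drawn until
#'   enough spikes are collected.
#' @param max_chunks Safety cap on the number of chunks.
#' @return Object of class `nl_spike_shape`: `time` (ms relative to
#'   crossing), `waveform` (mV), `amplitude`, `width`,
#'   `amplitude_from_threshold`, `baseline`, `n_spikes`.
#' @export
average_spike_shape <- function(model, n_spikes = 1500, M = 300,
                                lambda0 = 500, dt = 0.01,
                                window_ms = c(-1, 2),
                                baseline_ms = c(-1, -0.5),
                                H_alpha = 1.3, tau_alpha = 0.1 / 2.446,
                                chunk_s = 2, max_chunks = 50) {
  if (!has_generator(model))
    stop("spike-shape estimation requires a spiking variant")
  i0 <- as.integer(round(window_ms[1] / dt))
  i1 <- as.integer(round(window_ms[2] / dt))
  warmup_steps <- as.integer(round(20 / dt))
  acc <- numeric(i1 - i0 + 1)
  n_acc <- 0L
  chunks <- 0L
  while (n_acc < n_spikes && chunks < max_chunks) {
    chunks <- chunks + 1L
    dur <- chunk_s * 1000
    trains <- lapply(seq_len(M), function(i) generate_poisson_train(lambda0, dur))
    g <- conductance_from_trains(trains, dur, dt, H_alpha, tau_alpha)
    sim <- simulate_nl(model, g, 0, dur, dt)
    n_steps <- as.integer(round(dur / dt))
    for (s in sim$spike_steps) {
      if (n_acc >= n_spikes) break
      if (s + i0 < warmup_steps || s + i1 > n_steps) next
      acc <- acc + sim$V_soma[(s + i0):(s + i1) + 1L]
      n_acc <- n_acc + 1L
    }
  }
  if (n_acc < n_spikes)
    stop("collected only ", n_acc, " spikes within the chunk budget")
  w <- acc / n_acc
  rel_t <- (i0:i1) * dt
  bsel <- rel_t >= baseline_ms[1] & rel_t <= baseline_ms[2]
  baseline <- mean(w[bsel])
  pk <- which.max(w)
  H <- w[pk] - baseline
  half <- baseline + H / 2
  xl <- cross_before(rel_t, w, pk, half)
  xr <- cross_after(rel_t, w, pk, half)
  structure(list(time = rel_t, waveform = w, amplitude = H,
                 width = xr - xl, baseline = baseline,
                 amplitude_from_threshold = w[pk] - model$generator$V_theta,
                 n_spikes = n_acc),
            class = "nl_spike_shape")
}

# linear interpolation of the last crossing of `level` before index `pk`
cross_before <- function(x, y, pk, level) {
  i <- pk
  while (i > 1 && y[i - 1] > level) i <- i - 1
  if (i == 1) return(x[1])
  x[i - 1] + (x[i] - x[i - 1]) * (level - y[i - 1]) / (y[i] - y[i - 1])
}

cross_after <- function(x, y, pk, level) {
  i <- pk
  n <- length(y)
  while (i < n && y[i + 1] > level) i <- i + 1
  if (i == n) return(x[n])
  x[i] + (x[i + 1] - x[i]) * (level - y[i]) / (y[i + 1] - y[i])
}

#' @export
print.nl_spike_shape <- function(x, ...) {
  cat(sprintf(paste0("<nl_spike_shape> %d spikes: H = %.2f mV ",
                     "(from baseline %.2f mV), W = %.3f ms\n"),
              x$n_spikes, x$amplitude, x$baseline, x$width))
  invisible(x)
}

rate_for_delta <- function(model, drv, p, delta, dur, dt, warmup) {
  g <- binaural_conductance(drv$ipsi, drv$contra, delta, p$f_stim)
  n_steps <- as.integer(round(dur / dt))
  sim <- simulate_nl(model, g, 0, dur, dt, record_stride = n_steps)
  c(rate = spike_rate(sim, warmup),
    n = sum(sim$spike_times > warmup))
}

#' Rate versus interaural phase difference curve
#'
#' Simulates the model under the binaural phase-locked drive for each phase
#' difference `delta`, reusing one input realisation across the whole grid
#' (the contralateral trace is circularly shifted per `delta`). The in-phase
#' rate is read at `delta` in {0, +-2pi} and the out-of-phase rate at
#' {+-pi}; their difference is the modulation depth.
#'
#' Uses the R random number generator; seed with [set.seed()].
#'
#' @param model An [nl_model()] with a thresholding unit.
#' @param p An [input_params()] object.
#' @param deltas Phase-difference grid (radians).
#' @param duration_s Simulated time per grid point (s).
#' @param dt Time step (ms).
#' @param warmup Initial interval excluded from rate counts (ms).
#' @return Object of class `nl_rate_phase`: data frame `curve` (`delta`,
#'   `rate`, `se`), `in_phase_rate`, `out_of_phase_rate`,
#'   `modulation_depth`.
#' @export
rate_phase_curve <- function(model, p, deltas = seq(-2 * pi, 2 * pi, by = pi / 8),
                             duration_s = 10, dt = 0.01, warmup = 20) {
  dur <- duration_s * 1000
  drv <- binaural_drive(p, dur, dt)
  res <- vapply(deltas, function(d)
    rate_for_delta(model, drv, p, d, dur, dt, warmup), c(rate = 0, n = 0))
  rates <- res["rate", ]
  se <- sqrt(res["n", ]) / ((dur - warmup) / 1000)
  near <- function(targets) {
    sel <- vapply(deltas, function(d)
      any(abs(d - targets) < 1e-6), TRUE)
    mean(rates[sel])
  }
  in_rate <- near(c(0, -2 * pi, 2 * pi))
  out_rate <- near(c(-pi, pi))
  structure(list(curve = data.frame(delta = deltas, rate = rates, se = se),
                 in_phase_rate = in_rate, out_of_phase_rate = out_rate,
                 modulation_depth = in_rate - out_rate),
            class = "nl_rate_phase")
}

#' @export
print.nl_rate_phase <- function(x, ...) {
  cat(sprintf(paste0("<nl_rate_phase> in-phase %.1f sp/s, out-of-phase %.1f",
                     " sp/s, modulation depth %.1f sp/s\n"),
              x$in_phase_rate, x$out_of_phase_rate, x$modulation_depth))
  invisible(x)
}

# longest contiguous interval with y > level, edges linearly interpolated;
# an interval reaching the end of the grid is censored at the grid edge
interval_above <- function(x, y, level) {
  above <- y > level
  if (!any(above)) return(list(width = 0, lo = NA_real_, hi = NA_real_))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  iT <- which(runs$values)
  best <- iT[which.max(runs$lengths[iT])]
  i0 <- starts[best]; i1 <- ends[best]
  lo <- if (i0 == 1L) x[1] else
    x[i0 - 1] + (x[i0] - x[i0 - 1]) * (level - y[i0 - 1]) / (y[i0] - y[i0 - 1])
  hi <- if (i1 == length(x)) x[length(x)] else
    x[i1] + (x[i1 + 1] - x[i1]) * (level - y[i1]) / (y[i1 + 1] - y[i1])
  list(width = hi - lo, lo = lo, hi = hi)
}

#' Spike rates as a function of the firing threshold
#'
#' Sweeps `V_theta` over a grid with all other parameters at their defaults,
#' estimating the in-phase (`delta = 0`) and out-of-phase (`delta = pi`)
#' rates at each threshold from a single shared input realisation (common
#' random numbers, so rate differences across the grid are low-variance).
#' Reports the width of the threshold interval over which the modulation
#' depth exceeds `criterion`, and the threshold maximising it.
#'
#' Uses the R random number generator; seed with [set.seed()].
#'
#' @param model An [nl_model()] with a thresholding unit.
#' @param p An [input_params()] object.
#' @param thresholds Threshold grid (mV); default a 5-mV window around the
#'   model's default threshold at 0.2-mV spacing.
#' @param duration_s Simulated time per grid point and phase (s).
#' @param dt Time step (ms).
#' @param warmup Warm-up excluded from counts (ms).
#' @param criterion Modulation-depth criterion (spikes/s).
#' @return Object of class `nl_sweep`: data frame `table` (`value`,
#'   `in_phase_rate`, `out_of_phase_rate`, `modulation_depth`, `se_in`,
#'   `se_out`), `criterion_interval` (list `width`, `lo`, `hi`),
#'   `argmax` (threshold of maximal modulation depth), `parameter =
#'   "V_theta"`.
#' @export
sweep_threshold <- function(model, p, thresholds = NULL, duration_s = 10,
                            dt = 0.01, warmup = 20,
                            criterion = nl_modulation_criterion) {
  v0 <- model$generator$V_theta
  if (is.null(thresholds)) thresholds <- seq(v0 - 2.5, v0 + 2.5, by = 0.2)
  dur <- duration_s * 1000
  drv <- binaural_drive(p, dur, dt)
  run <- function(theta) {
    m <- model
    m$generator$V_theta <- theta
    c(rate_for_delta(m, drv, p, 0, dur, dt, warmup),
      rate_for_delta(m, drv, p, pi, dur, dt, warmup))
  }
  res <- vapply(thresholds, run, numeric(4))
  tab <- data.frame(value = thresholds,
                    in_phase_rate = res[1, ], out_of_phase_rate = res[3, ],
                    modulation_depth = res[1, ] - res[3, ],
                    se_in = sqrt(res[2, ]) / ((dur - warmup) / 1000),
                    se_out = sqrt(res[4, ]) / ((dur - warmup) / 1000))
  structure(list(table = tab, parameter = "V_theta",
                 criterion = criterion,
                 criterion_interval = interval_above(thresholds,
                                                     tab$modulation_depth,
                                                     criterion),
                 argmax = thresholds[which.max(tab$modulation_depth)]),
            class = "nl_sweep")
}

#' Spike rates as a function of the refractory period
#'
#' Sweeps `T_ref` with the threshold fixed at the model's default,
#' estimating in-phase and out-of-phase rates per grid point with common
#' random numbers. If 0.8 and 1.6 ms are both on the grid, the magnitude of
#' the in-phase rate change between them is reported
#' (`in_phase_change_08_16`).
#'
#' Uses the R random number generator; seed with [set.seed()].
#'
#' @inheritParams sweep_threshold
#' @param t_refs Refractory-period grid (ms), within (0, 1.6].
#' @return Object of class `nl_sweep` with `parameter = "T_ref"`.
#' @export
sweep_refractory <- function(model, p, t_refs = seq(0.8, 1.6, by = 0.2),
                             duration_s = 10, dt = 0.01, warmup = 20) {
  stopifnot(all(t_refs > 0), all(t_refs <= 1.6))
  dur <- duration_s * 1000
  drv <- binaural_drive(p, dur, dt)
  run <- function(tr) {
    m <- model
    m$generator$T_ref <- tr
    c(rate_for_delta(m, drv, p, 0, dur, dt, warmup),
      rate_for_delta(m, drv, p, pi, dur, dt, warmup))
  }
  res <- vapply(t_refs, run, numeric(4))
  tab <- data.frame(value = t_refs,
                    in_phase_rate = res[1, ], out_of_phase_rate = res[3, ],
                    modulation_depth = res[1, ] - res[3, ],
                    se_in = sqrt(res[2, ]) / ((dur - warmup) / 1000),
                    se_out = sqrt(res[4, ]) / ((dur - warmup) / 1000))
  chg <- if (all(c(0.8, 1.6) %in% round(t_refs, 9)))
    abs(tab$in_phase_rate[match(0.8, round(t_refs, 9))] -
          tab$in_phase_rate[match(1.6, round(t_refs, 9))]) else NA_real_
  structure(list(table = tab, parameter = "T_ref",
                 in_phase_change_08_16 = chg),
            class = "nl_sweep")
}

#' @export
print.nl_sweep <- function(x, ...) {
  cat("<nl_sweep> over", x$parameter, "\n")
  print(x$table, digits = 4)
  if (!is.null(x$criterion_interval))
    cat(sprintf("  modulation depth > %g sp/s over %.2f mV [%.2f, %.2f]\n",
                x$criterion, x$criterion_interval$width,
                x$criterion_interval$lo, x$criterion_interval$hi))
  if (!is.null(x$in_phase_change_08_16) && !is.na(x$in_phase_change_08_16))
    cat(sprintf("  |in-phase rate(0.8 ms) - rate(1.6 ms)| = %.1f sp/s\n",
                x$in_phase_change_08_16))
  invisible(x)
}

#' Maximum reliable forward-Euler time step
#'
#' For each candidate time step, re-samples the synaptic conductance from
#' one fixed set of presynaptic event times, simulates `duration_s`-long
#' traces, and measures the maximum absolute deviation of `V_soma` from a
#' reference computed at `dt_ref_us`, compared at the coarse grid's time
#' points. A step is unreliable when the deviation exceeds `tol_mV`
#' anywhere over `n_traces` independent input realisations. A run that
#' diverges numerically counts as infinitely discrepant. Candidate steps
#' must be integer multiples of the reference step.
#'
#' In the default `"matched"` mode the output spike sequence of the
#' reference run is replayed (via `forced_spikes`) in every candidate run,
#' so the deviation measures the accuracy of the membrane-trajectory
#' integration itself: subthreshold error, spike-waveform error, and any
#' numerical instability of the spike-generating compartment. In
#' `"pointwise"` mode every run performs its own threshold detection; then
#' a single marginal threshold crossing that flips between two step sizes
#' produces a spike-sized excursion, so the measured maximum deviation is
#' dominated by the chaotic sensitivity of individual crossings rather than
#' by integration accuracy, and no coarse step appears reliable on traces
#' of this length (see the package vignette for the analysis).
#'
#' Uses the R random number generator; seed with [set.seed()].
#'
#' @param model An [nl_model()].
#' @param p An [input_params()] object.
#' @param dt_us Candidate time steps (microseconds).
#' @param dt_ref_us Reference time step (microseconds).
#' @param n_traces Number of independent input realisations.
#' @param duration_s Trace length (s).
#' @param tol_mV Reliability criterion (mV).
#' @param delta Interaural phase difference of the drive (radians).
#' @param mode `"matched"` (replay the reference spike sequence, default)
#'   or `"pointwise"` (independent threshold detection per run); see
#'   Details.
#' @return Object of class `nl_reliability`: data frame `table` (`dt_us`,
#'   `max_discrepancy_mV`, `reliable`), `max_allowable_dt_us`,
#'   `min_unreliable_dt_us`, `dt_ref_us`, `tol_mV`.
#' @export
reliability_max_dt <- function(model, p, dt_us = c(1, 3, 5, 10, 15, 20, 30),
                               dt_ref_us = 0.1, n_traces = 3,
                               duration_s = 1, tol_mV = 0.5, delta = 0,
                               mode = c("matched", "pointwise")) {
  mode <- match.arg(mode)
  stopifnot(all(dt_us > dt_ref_us))
  strides <- dt_us / dt_ref_us
  if (any(abs(strides - round(strides)) > 1e-9))
    stop("candidate steps must be integer multiples of the reference step")
  strides <- as.integer(round(strides))
  dur <- duration_s * 1000
  dt_ref <- dt_ref_us / 1000
  shift_ms <- 1000 * delta / (2 * pi * p$f_stim)
  disc <- rep(0, length(dt_us))
  for (tr in seq_len(n_traces)) {
    ipsi <- unlist(lapply(seq_len(p$M), function(i)
      generate_phase_locked_train(p, dur)))
    contra <- unlist(lapply(seq_len(p$M), function(i)
      generate_phase_locked_train(p, dur)))
    events <- c(ipsi, (contra - shift_ms) %% dur)
    run <- function(dt_ms, n_steps, forced = NULL) {
      g <- conductance_from_trains(events, n_steps * dt_ms, dt_ms,
                                   p$H_alpha, p$tau_alpha)
      simulate_nl(model, g, 0, n_steps * dt_ms, dt_ms,
                  allow_divergence = TRUE, forced_spikes = forced)
    }
    n_ref <- as.integer(round(dur / dt_ref))
    sim_ref <- run(dt_ref, n_ref)
    V_ref <- sim_ref$V_soma
    forced <- if (mode == "matched" && has_generator(model))
      sim_ref$spike_times else NULL
    for (k in seq_along(dt_us)) {
      dt_c <- dt_us[k] / 1000
      n_c <- as.integer(floor(dur / dt_c + 1e-9))
      V_c <- run(dt_c, n_c, forced = forced)$V_soma
      idx <- seq(0L, n_c) * strides[k] + 1L
      dev <- abs(V_c - V_ref[idx])
      d_k <- if (anyNA(dev)) Inf else max(dev)
      disc[k] <- max(disc[k], d_k)
    }
  }
  reliable <- disc <= tol_mV
  structure(list(table = data.frame(dt_us = dt_us,
                                    max_discrepancy_mV = disc,
                                    reliable = reliable),
                 max_allowable_dt_us = if (any(reliable))
                   max(dt_us[reliable]) else NA_real_,
                 min_unreliable_dt_us = if (any(!reliable))
                   min(dt_us[!reliable]) else NA_real_,
                 dt_ref_us = dt_ref_us, tol_mV = tol_mV),
            class = "nl_reliability")
}

#' @export
print.nl_reliability <- function(x, ...) {
  cat(sprintf("<nl_reliability> vs dt = %g us reference, %g mV criterion\n",
              x$dt_ref_us, x$tol_mV))
  print(x$table, digits = 4)
  cat("  max allowable dt:", x$max_allowable_dt_us, "us\n")
  invisible(x)
}
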