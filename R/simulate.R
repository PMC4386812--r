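#' Initial dynamical state of a model
#'
#' The KLVA gate starts at its voltage equilibrium, the spike-current
#' components at zero, and (for the two-compartment variant) the node at its
#' conditional steady state given `V_soma`.
#'
#' @param model An [nl_model()].
#' @param V0 Initial somatic potential (mV); `"rest"` (default) solves for
#'   the resting potential.
#' @return A list with components `V_soma`, `V_node`, `d`, `s1`, `s2`,
#'   `t_last_spike`.
#' @export
initial_state <- function(model, V0 = "rest") {
  if (identical(V0, "rest")) V0 <- resting_potential(model)
  stopifnot(is.numeric(V0), length(V0) == 1, is.finite(V0))
  list(V_soma = V0,
       V_node = if (has_node(model)) node_steady_state(model, V0) else NA_real_,
       d = if (has_klva(model)) klva_gate(V0, model$kinetics)$d_inf else NA_real_,
       s1 = 0, s2 = 0,
       t_last_spike = NULL)
}

#' Advance one forward-Euler step (reference implementation)
#'
#' A plain-R transcription of one step of the integration scheme used by
#' [simulate_nl()]: forward Euler on the membrane potentials and the gate,
#' exact exponential decay of the spike-current components, then threshold
#' detection at the end of the step (disabled during the refractory period).
#' A detected crossing is located within the step by linear interpolation of
#' the monitored potential; the spike-current components receive their
#' exactly decayed values `A_i * exp(-(t_end - T_theta)/tau_i)` and the
#' charge the transient would have delivered before the step end is deposited
#' on the spike-generating compartment as a voltage impulse, so that the
#' injected waveform is charge-conserving and timed from the crossing itself
#' (making spike times and post-spike trajectories nearly independent of the
#' step size). If the potential still exceeds threshold when the refractory
#' period ends, the next crossing is stamped at `t_last + T_ref` exactly.
#' Intended for testing and for stepping through the scheme interactively;
#' long simulations should use the compiled path in [simulate_nl()].
#'
#' @param state State list as returned by [initial_state()], plus components
#'   `t` (ms) and `step` (integer index) if continuing a run (both default
#'   to 0).
#' @param model An [nl_model()].
#' @param g_syn Synaptic conductance during the step (nS).
#' @param I_ext External current during the step (pA).
#' @param dt Time step (ms).
#' @return The updated state; a crossed threshold appends the end-of-step
#'   time to `state$spike_times`.
#' @export
euler_step <- function(state, model, g_syn, I_ext, dt) {
  stopifnot(dt > 0, g_syn >= 0)
  s <- model$soma
  V <- state$V_soma
  step <- if (is.null(state$step)) 0L else state$step

  V_mon_old <- if (has_node(model)) state$V_node else V
  I_spk <- state$s1 + state$s2
  I_soma <- s$g_leak_soma * (s$E_L - V) + g_syn * (s$E_syn - V) + I_ext
  if (has_klva(model)) {
    gk <- klva_gate(V, model$kinetics)
    I_soma <- I_soma + s$g_klva_bar * state$d * (s$E_K - V)
  }
  if (has_node(model)) {
    n <- model$node
    I_soma <- I_soma + n$g_axon * (state$V_node - V)
    I_node <- n$g_leak_node * (s$E_L - state$V_node) +
      n$g_axon * (V - state$V_node) + model$generator$I_const + I_spk
    state$V_node <- state$V_node + dt * I_node / n$C_node
  } else if (has_generator(model)) {
    I_soma <- I_soma + model$generator$I_const + I_spk
  }
  state$V_soma <- V + dt * I_soma / s$C_soma
  if (has_klva(model))
    state$d <- state$d + dt * (gk$d_inf - state$d) / gk$tau_d
  if (has_generator(model)) {
    g <- model$generator
    state$s1 <- state$s1 * exp(-dt / g$tau1)
    state$s2 <- state$s2 * exp(-dt / g$tau2)
  }
  state$step <- step + 1L
  state$t <- state$step * dt

  vals <- c(state$V_soma,
            if (has_node(model)) state$V_node,
            if (has_klva(model)) state$d)
  if (!all(is.finite(vals)))
    stop("non-finite membrane state at t = ", state$t, " ms")

  if (has_generator(model)) {
    g <- model$generator
    V_mon <- if (has_node(model)) state$V_node else state$V_soma
    free <- is.null(state$t_last_spike) ||
      state$t - state$t_last_spike >= g$T_ref - 1e-12
    if (V_mon >= g$V_theta && free) {
      T_theta <- if (V_mon_old < g$V_theta) {
        (step + (g$V_theta - V_mon_old) / (V_mon - V_mon_old)) * dt
      } else {
        step * dt
      }
      if (!is.null(state$t_last_spike))
        T_theta <- max(T_theta, state$t_last_spike + g$T_ref)
      state$spike_times <- c(state$spike_times, T_theta)
      state$t_last_spike <- T_theta
      x1 <- (state$t - T_theta) / g$tau1
      x2 <- (state$t - T_theta) / g$tau2
      dQ <- g$A1 * g$tau1 * (1 - exp(-x1)) + g$A2 * g$tau2 * (1 - exp(-x2))
      if (has_node(model)) {
        state$V_node <- state$V_node + dQ / model$node$C_node
      } else {
        state$V_soma <- state$V_soma + dQ / s$C_soma
      }
      state$s1 <- state$s1 + g$A1 * exp(-x1)
      state$s2 <- state$s2 + g$A2 * exp(-x2)
    }
  }
  state
}

#' Simulate a model neuron with forward-Euler integration
#'
#' Integrates the chosen model variant under a synaptic conductance trace and
#' an external current, recording the membrane potential(s) and output spike
#' times. Deterministic given identical inputs. See [euler_step()] for the
#' per-step scheme.
#'
#' @param model An [nl_model()].
#' @param g_syn Synaptic conductance (nS): a scalar or a vector sampled on
#'   the `dt` grid covering `[0, duration]` (length `duration/dt + 1`,
#'   piecewise-constant per step).
#' @param I_ext External somatic current (pA): scalar or per-grid-point
#'   vector.
#' @param duration Simulated time (ms).
#' @param dt Time step (ms).
#' @param init `"rest"` or a state list from [initial_state()].
#' @param record_stride Record every `record_stride`-th grid point (the
#'   time step itself is unaffected). `duration/dt` must be divisible by it.
#' @param record_d,record_spike_current Also record the KLVA gate /
#'   spike-current component traces.
#' @param allow_divergence If `TRUE`, a numerically diverging run (non-finite
#'   state, possible when `dt` exceeds the stability bound of the model)
#'   returns with `diverged_at_step` set and the remaining trace `NA`,
#'   instead of raising an error.
#' @param forced_spikes Optional sorted vector of spike times (ms). When
#'   given, threshold detection is bypassed and the stereotyped spike
#'   currents are injected at exactly these times (replay of a recorded
#'   spike sequence).
#' @return An object of class `nl_sim`: list with `times`, `V_soma`,
#'   optionally `V_node`, `d`, `s1`, `s2`, plus `spike_times` (ms),
#'   `dt`, `duration`, `d_clamped`, `diverged_at_step`, `final` (state for
#'   continuation) and the model.
#' @export
simulate_nl <- function(model, g_syn, I_ext = 0, duration, dt,
                        init = "rest", record_stride = 1L,
                        record_d = FALSE, record_spike_current = FALSE,
                        allow_divergence = FALSE, forced_spikes = NULL) {
  stopifnot(dt > 0, duration > 0)
  n_steps <- as.integer(round(duration / dt))
  stopifnot(n_steps >= 1)
  if (length(g_syn) == 1) g_syn <- rep(g_syn, n_steps + 1L)
  if (length(g_syn) < n_steps + 1L)
    stop("g_syn must cover [0, duration] at resolution dt (length ",
         n_steps + 1L, ")")
  if (any(g_syn < 0)) stop("negative synaptic conductance")
  record_stride <- as.integer(record_stride)
  stopifnot(record_stride >= 1, n_steps %% record_stride == 0)

  if (identical(init, "rest")) init <- initial_state(model)
  init_cpp <- list(V_soma = init$V_soma,
                   V_node = if (is.null(init$V_node)) NA_real_ else init$V_node,
                   d = if (is.null(init$d)) NA_real_ else init$d,
                   s1 = init$s1, s2 = init$s2,
                   t_last_spike = init$t_last_spike)

  out <- cpp_simulate(model_cpp_spec(model), as.numeric(g_syn),
                      as.numeric(I_ext), dt, n_steps, init_cpp,
                      record_stride, record_d, record_spike_current,
                      allow_divergence,
                      if (is.null(forced_spikes)) numeric(0)
                      else as.numeric(forced_spikes))

  res <- list(times = seq(0, n_steps, by = record_stride) * dt,
              V_soma = out$V_soma, V_node = out$V_node, d = out$d,
              s1 = out$s1, s2 = out$s2,
              spike_times = out$spike_times,
              spike_steps = out$spike_steps,
              dt = dt, duration = duration,
              record_stride = record_stride,
              d_clamped = out$d_clamped,
              diverged_at_step = if (out$diverged_at_step > 0)
                out$diverged_at_step else NA_integer_,
              final = out$final,
              model = model)
  class(res) <- "nl_sim"
  res
}

#' @export
print.nl_sim <- function(x, ...) {
  cat(sprintf("<nl_sim> %s: %g ms at dt = %g ms, %d spikes\n",
              x$model$variant, x$duration, x$dt, length(x$spike_times)))
  if (!is.na(x$diverged_at_step))
    cat("  ! diverged at step", x$diverged_at_step, "\n")
  if (isTRUE(x$d_clamped))
    cat("  ! KLVA gate clamped to [0,1] during the run\n")
  invisible(x)
}

#' Mean spike rate of a simulation after a warm-up period
#'
#' @param sim An `nl_sim` object.
#' @param warmup Initial interval excluded from the count (ms).
#' @return Rate in spikes/s.
#' @export
spike_rate <- function(sim, warmup = 20) {
  n <- sum(sim$spike_times > warmup)
  1000 * n / (sim$duration - warmup)
}
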