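#' Net somatic current at a candidate steady state
#'
#' Sum of all stationary currents at the soma with the KLVA gate at its
#' voltage equilibrium (`d = d_inf(V)`), zero synaptic conductance, and (for
#' the two-compartment variant) the node eliminated at its own steady state
#' given `V_soma`. The constant generator current `I_const` is included
#' wherever the variant has a thresholding unit (directly in the soma for the
#' single-compartment models, through the nodal balance for the
#' two-compartment model). A value of zero means `V_soma` is an equilibrium.
#'
#' @param model An [nl_model()].
#' @param V_soma Somatic potential (mV).
#' @param I_ext External current injected at the soma (pA).
#' @return Residual current (pA).
#' @export
steady_state_residual <- function(model, V_soma, I_ext = 0) {
  s <- model$soma
  res <- s$g_leak_soma * (s$E_L - V_soma) + I_ext
  if (has_klva(model)) {
    di <- klva_gate(V_soma, model$kinetics)$d_inf
    res <- res + s$g_klva_bar * di * (s$E_K - V_soma)
  }
  if (has_node(model)) {
    res <- res + model$node$g_axon * (node_steady_state(model, V_soma) - V_soma)
  } else if (has_generator(model)) {
    res <- res + model$generator$I_const
  }
  res
}

#' Nodal steady state conditional on the somatic potential
#'
#' Solves the (linear) nodal current balance
#' `g_leak_node (E_L - V_node) + g_axon (V_soma - V_node) + I_const = 0`
#' with the spike current at rest.
#'
#' @inheritParams steady_state_residual
#' @return Nodal potential (mV).
#' @export
node_steady_state <- function(model, V_soma) {
  if (!has_node(model)) stop("model has no nodal compartment")
  n <- model$node
  (n$g_leak_node * model$soma$E_L + n$g_axon * V_soma +
     model$generator$I_const) / (n$g_leak_node + n$g_axon)
}

#' Constant current holding the soma at a target potential
#'
#' The residual is affine in `I_ext`, so the holding current is obtained in
#' closed form as minus the zero-current residual; the result is checked to
#' satisfy `steady_state_residual(model, V_hold, I_base) = 0` to within
#' 1e-6 pA and to lie within a +-10 nA physiological window.
#'
#' @param model An [nl_model()].
#' @param V_hold Holding potential (mV), in (-90, -40).
#' @return Holding current `I_base` (pA).
#' @export
find_holding_current <- function(model, V_hold) {
  stopifnot(V_hold > -90, V_hold < -40)
  I_base <- -steady_state_residual(model, V_hold, I_ext = 0)
  if (abs(I_base) > 1e4)
    stop("no holding current within +-10 nA of zero")
  stopifnot(abs(steady_state_residual(model, V_hold, I_base)) < 1e-6)
  I_base
}

#' Resting membrane potential
#'
#' Root of the steady-state current balance with no external or synaptic
#' input, located by bisection inside `interval`.
#'
#' @param model An [nl_model()].
#' @param interval Search bracket (mV).
#' @return Resting potential (mV).
#' @export
resting_potential <- function(model, interval = c(-80, -40)) {
  f <- function(V) steady_state_residual(model, V, I_ext = 0)
  if (sign(f(interval[1])) == sign(f(interval[2])))
    stop("no resting potential bracketed in (", interval[1], ", ",
         interval[2], ") mV")
  uniroot(f, interval, tol = 1e-10)$root
}

#' Slope input resistance at a holding potential
#'
#' Probes the stationary current-voltage relation with small current steps
#' `+-dI` about the holding current and returns the central-difference slope
#' `dV/dI`. For the active variants this is the differential (slope)
#' resistance, which includes the voltage dependence of the KLVA activation
#' curve; it is the quantity that in vivo small-step measurements report.
#'
#' @param model An [nl_model()].
#' @param V_hold Holding potential (mV).
#' @param dI Probe current amplitude (pA), at most 20.
#' @return Resistance (MOhm).
#' @export
input_resistance <- function(model, V_hold = -61, dI = 10) {
  stopifnot(dI > 0, dI <= 20)
  I_base <- find_holding_current(model, V_hold)
  solve_v <- function(I) {
    f <- function(V) steady_state_residual(model, V, I)
    uniroot(f, c(V_hold - 5, V_hold + 5), tol = 1e-12)$root
  }
  dV <- solve_v(I_base + dI) - solve_v(I_base - dI)
  # mV per pA = GOhm; report MOhm
  1000 * dV / (2 * dI)
}

#' Membrane time constant from the slope resistance
#'
#' `R_slope * C_soma` (MOhm x pF = microseconds), returned in ms.
#'
#' @inheritParams input_resistance
#' @return Time constant (ms).
#' @export
membrane_time_constant <- function(model, V_hold = -61, dI = 10) {
  input_resistance(model, V_hold, dI) * model$soma$C_soma / 1000
}

#' Small-signal membrane impedance magnitude
#'
#' Linearises the somatic compartment about a holding potential and returns
#' the impedance magnitude at the given frequency. The KLVA contribution
#' enters as the usual phenomenological inductive branch
#' \eqn{\bar g\, (V-E_K)\, d_\infty'(V) / (1 + i\omega\tau_d)} plus the
#' instantaneous chord term \eqn{\bar g\, d_\infty(V)}; in the
#' two-compartment variant the node loads the soma through the axial
#' conductance. `include_klva` and `include_axon` switch those branches off
#' to reproduce "RC only", "RC + KLVA" and "RC + axon" conditions.
#'
#' @param model An [nl_model()].
#' @param freq Stimulus frequency (Hz); may be a vector.
#' @param V_hold Potential about which to linearise (mV).
#' @param include_klva Include the KLVA branch (if the variant has one).
#' @param include_axon Include the axial load (two-compartment variant).
#' @return Impedance magnitude (MOhm), same length as `freq`.
#' @export
impedance_magnitude <- function(model, freq, V_hold = -61,
                                include_klva = TRUE, include_axon = TRUE) {
  stopifnot(all(freq >= 0))
  s <- model$soma
  omega <- 2 * pi * freq / 1000           # rad/ms
  Y <- complex(real = s$g_leak_soma, imaginary = 0) +
    1i * omega * s$C_soma                 # nS
  if (include_klva && has_klva(model)) {
    g <- klva_gate(V_hold, model$kinetics)
    Y <- Y + s$g_klva_bar * g$d_inf +
      s$g_klva_bar * (V_hold - s$E_K) * klva_dinf_slope(V_hold) /
        (1 + 1i * omega * g$tau_d)
  }
  if (include_axon && has_node(model)) {
    n <- model$node
    Yn <- n$g_leak_node + 1i * omega * n$C_node
    Y <- Y + n$g_axon * Yn / (n$g_axon + Yn)
  }
  1000 / Mod(Y)                            # 1/nS = GOhm -> MOhm
}
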