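#' Synaptic input parameters
#'
#' Parameters of the binaural phase-locked drive: each side contributes `M`
#' independent nucleus magnocellularis fibers firing as (inhomogeneous)
#' Poisson processes at mean rate `lambda0`, phase-locked to the tonal
#' stimulus frequency `f_stim` with vector strength `r`; each presynaptic
#' spike injects a unitary alpha conductance of amplitude `H_alpha` and
#' half-amplitude width `W_alpha` (= 2.446 tau_alpha). The interaural phase
#' difference `delta` shifts the contralateral conductance in time by
#' `delta / (2 pi f_stim)`.
#'
#' @param f_stim Stimulus frequency (Hz).
#' @param lambda0 Mean fiber rate (spikes/s).
#' @param r Vector strength of the fibers, in `[0, 1)`.
#' @param M Number of fibers per side.
#' @param H_alpha Unitary conductance amplitude (nS).
#' @param W_alpha Unitary conductance half-amplitude width (ms).
#' @param delta Interaural phase difference (radians).
#' @return An object of class `nl_input_params`; `tau_alpha` (ms) is derived
#'   as `W_alpha / 2.446`.
#' @export
input_params <- function(f_stim = 4000, lambda0 = 500, r = 0.6, M = 150,
                         H_alpha = 1.3, W_alpha = 0.1, delta = 0) {
  stopifnot(f_stim > 0, lambda0 > 0, r >= 0, r < 1, M >= 1,
            H_alpha > 0, W_alpha > 0)
  structure(list(f_stim = f_stim, lambda0 = lambda0, r = r, M = as.integer(M),
                 H_alpha = H_alpha, W_alpha = W_alpha,
                 tau_alpha = W_alpha / 2.446, delta = delta),
            class = "nl_input_params")
}

#' Von Mises concentration from a target vector strength
#'
#' Inverts the first circular moment of the von Mises distribution,
#' `I1(kappa)/I0(kappa) = r`, to 1e-10.
#'
#' @param r Vector strength in `[0, 1)`.
#' @return Concentration `kappa >= 0`.
#' @export
kappa_from_vs <- function(r) {
  stopifnot(length(r) == 1, r >= 0)
  if (r >= 1) stop("vector strength must be < 1")
  if (r == 0) return(0)
  f <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE) - r
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  uniroot(f, c(1e-12, upper), tol = 1e-12)$root
}

#' Homogeneous Poisson spike train
#'
#' @param rate_hz Intensity (spikes/s).
#' @param duration Train length (ms).
#' @return Sorted spike times (ms) within `[0, duration]`.
#' @export
generate_poisson_train <- function(rate_hz, duration) {
  stopifnot(rate_hz >= 0, duration > 0)
  n <- rpois(1, rate_hz / 1000 * duration)
  sort(runif(n, 0, duration))
}

#' Phase-locked spike train (inhomogeneous Poisson by thinning)
#'
#' Realises a Poisson process with the von Mises periodic intensity
#' \deqn{\lambda(t) = \lambda_0 \exp(\kappa \cos(2\pi f t - \phi)) /
#'       I_0(\kappa)}
#' by thinning a homogeneous process at the intensity maximum. The mean rate
#' is exactly `lambda0` and the theoretical vector strength is
#' `I1(kappa)/I0(kappa) = r`.
#'
#' @param p An [input_params()] object (uses `f_stim`, `lambda0`, `r`).
#' @param duration Train length (ms).
#' @param phase Locking phase `phi` (radians); the fibers of one side all
#'   share the same phase.
#' @return Sorted spike times (ms).
#' @export
generate_phase_locked_train <- function(p, duration, phase = 0) {
  stopifnot(duration > 0)
  if (p$r == 0) return(generate_poisson_train(p$lambda0, duration))
  kappa <- kappa_from_vs(p$r)
  lam_max <- p$lambda0 * exp(kappa) /
    besselI(kappa, 0)                    # peak intensity, spikes/s
  t <- generate_poisson_train(lam_max, duration)
  if (!length(t)) return(t)
  accept <- runif(length(t)) <
    exp(kappa * (cos(2 * pi * p$f_stim * t / 1000 - phase) - 1))
  t[accept]
}

#' Unitary synaptic conductance waveform
#'
#' \deqn{\alpha(t) = H_\alpha (t/\tau_\alpha) e^{1 - t/\tau_\alpha}
#'       \ (t \ge 0), \quad 0\ (t<0)}
#' peaking at `H_alpha` at `t = tau_alpha`, with half-amplitude width
#' `2.446 tau_alpha`.
#'
#' @param t Time since the presynaptic spike (ms); may be a vector.
#' @param H_alpha Amplitude (nS).
#' @param tau_alpha Time-to-peak (ms).
#' @return Conductance (nS).
#' @export
alpha_kernel <- function(t, H_alpha = 1.3, tau_alpha = 0.1 / 2.446) {
  ifelse(t >= 0, H_alpha * (t / tau_alpha) * exp(1 - t / tau_alpha), 0)
}

#' Conductance trace from spike trains
#'
#' Superposes one alpha kernel per presynaptic event, sampled on the
#' simulation grid. Kernels are truncated `trunc_mult * tau_alpha` after
#' onset (residual below 3e-4 of the peak at the default).
#'
#' @param trains A list of spike-time vectors (ms) or a single vector.
#' @param duration Trace length (ms).
#' @param dt Grid spacing (ms).
#' @param H_alpha,tau_alpha Kernel parameters (see [alpha_kernel()]).
#' @param trunc_mult Kernel truncation point in units of `tau_alpha`.
#' @return Numeric conductance trace (nS) of length `duration/dt + 1`, with
#'   attributes `dt` and `duration`.
#' @export
conductance_from_trains <- function(trains, duration, dt,
                                    H_alpha = 1.3, tau_alpha = 0.1 / 2.446,
                                    trunc_mult = 10) {
  stopifnot(dt > 0)
  if (!is.list(trains)) trains <- list(trains)
  n_grid <- as.integer(round(duration / dt)) + 1L
  times <- unlist(trains, use.names = FALSE)
  g <- cpp_alpha_conductance(as.numeric(times), n_grid, dt,
                             H_alpha, tau_alpha, trunc_mult)
  structure(g, dt = dt, duration = duration)
}

#' Combine bilateral conductances with an interaural phase difference
#'
#' `g_syn(t) = g_ipsi(t) + g_contra(t + delta / (2 pi f_stim))`: the
#' contralateral trace is advanced by the phase delay, rounded to the nearest
#' grid step and wrapped circularly so that rate-phase curves are stationary
#' in `delta`.
#'
#' @param ipsi,contra Conductance traces on the same grid (as returned by
#'   [conductance_from_trains()]).
#' @param delta Interaural phase difference (radians).
#' @param f_stim Stimulus frequency (Hz).
#' @return Combined conductance trace (nS).
#' @export
binaural_conductance <- function(ipsi, contra, delta, f_stim = 4000) {
  if (length(ipsi) != length(contra))
    stop("ipsi and contra traces differ in length")
  dt <- attr(ipsi, "dt")
  if (!is.null(attr(contra, "dt")) && !isTRUE(all.equal(dt, attr(contra, "dt"))))
    stop("ipsi and contra traces differ in dt")
  shift_ms <- 1000 * delta / (2 * pi * f_stim)
  k <- as.integer(round(shift_ms / dt)) %% length(contra)
  if (k != 0) contra <- c(contra[(k + 1):length(contra)], contra[1:k])
  structure(as.numeric(ipsi) + as.numeric(contra),
            dt = dt, duration = attr(ipsi, "duration"))
}

#' Generate the full binaural drive for one stimulus condition
#'
#' Draws `M` phase-locked fibers per side (all locked to phase zero),
#' filters each side through the alpha synapse, and returns the two traces so
#' that different interaural phases can be formed from the same realisation
#' via [binaural_conductance()] (common random numbers across a sweep).
#'
#' @param p An [input_params()] object.
#' @param duration Trace length (ms).
#' @param dt Grid spacing (ms).
#' @return List with conductance traces `ipsi` and `contra` and the spike
#'   trains that generated them (`trains_ipsi`, `trains_contra`).
#' @export
binaural_drive <- function(p, duration, dt) {
  one_side <- function() {
    lapply(seq_len(p$M), function(i) generate_phase_locked_train(p, duration))
  }
  ti <- one_side()
  tc <- one_side()
  list(ipsi = conductance_from_trains(ti, duration, dt, p$H_alpha, p$tau_alpha),
       contra = conductance_from_trains(tc, duration, dt, p$H_alpha, p$tau_alpha),
       trains_ipsi = ti, trains_contra = tc)
}

#' Vector strength of a spike train
#'
#' Magnitude of the mean unit phasor of the spike phases at frequency `f`:
#' `|mean(exp(2 pi i f t))|`. 1 means perfect locking, 0 a uniform phase
#' distribution.
#'
#' @param times Spike times (ms).
#' @param f Reference frequency (Hz).
#' @return Vector strength in `[0, 1]`.
#' @export
vector_strength <- function(times, f) {
  if (!length(times)) stop("vector strength of an empty train is undefined")
  ph <- 2 * pi * f * times / 1000
  Mod(mean(complex(argument = ph)))
}
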