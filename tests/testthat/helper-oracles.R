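# Independent scalar implementations used as oracles for the package code.
# These deliberately re-derive quantities from the printed rate expressions
# and circuit equations rather than calling package internals.

`%||%` <- function(a, b) if (is.null(a)) b else a

o_alpha <- function(V) 0.20 * exp((V + 60) / 21.8)
o_beta  <- function(V) 0.17 * exp(-(V + 60) / 14)
o_dinf  <- function(V) o_alpha(V) / (o_alpha(V) + o_beta(V))

# plain bisection, independent of stats::uniroot
o_bisect <- function(f, lo, hi, tol = 1e-10) {
  stopifnot(sign(f(lo)) != sign(f(hi)))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# steady-state somatic current balance per variant, written out longhand
o_residual <- function(variant, V, I_ext = 0) {
  switch(variant,
    one_comp_passive_if = 240 * (-60 - V) + 200 + I_ext,
    one_comp_active_if  = 48 * (-60 - V) + 192 * o_dinf(V) * (-75 - V) +
                            200 + I_ext,
    non_spiking         = 48 * (-60 - V) + 192 * o_dinf(V) * (-75 - V) + I_ext,
    two_comp_active_if  = {
      Vn <- (2 * (-60) + 117.8 * V + 200) / (2 + 117.8)
      48 * (-60 - V) + 192 * o_dinf(V) * (-75 - V) + 117.8 * (Vn - V) + I_ext
    })
}

all_variants <- c("two_comp_active_if", "one_comp_active_if",
                  "one_comp_passive_if", "non_spiking")
spiking_variants <- setdiff(all_variants, "non_spiking")

# small sinusoidal conductance drive evaluated analytically on any grid
sine_drive <- function(duration, dt, mean = 20, amp = 10, f_khz = 4) {
  t <- seq(0, duration, by = dt)
  pmax(0, mean + amp * sin(2 * pi * f_khz * t))
}

# spike rate within 1-s blocks, for paired standard errors under common
# random numbers
block_rates <- function(spike_times, duration, block = 1000) {
  edges <- seq(0, duration, by = block)
  counts <- graphics::hist(spike_times, breaks = edges, plot = FALSE)$counts
  1000 * counts / block
}
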