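#' Construct a reduced nucleus laminaris neuron model
#'
#' Builds one of the four reduced coincidence-detector model variants with
#' the published default membrane and thresholding parameters. All defaults
#' may be overridden through `soma`, `node`, `generator` and `kinetics`
#' (partial lists are merged into the defaults).
#'
#' The variants are:
#' \describe{
#'   \item{`two_comp_active_if`}{soma (leak + KLVA + synapse) coupled through
#'     an axial conductance to a small nodal compartment that carries the
#'     integrate-and-fire spike generator; threshold is monitored on
#'     `V_node`.}
#'   \item{`one_comp_active_if`}{single somatic compartment with leak, KLVA
#'     and the spike generator injecting directly into the soma.}
#'   \item{`one_comp_passive_if`}{as above but without KLVA; the leak
#'     conductance is raised to 240 nS to preserve the resting membrane
#'     resistance.}
#'   \item{`non_spiking`}{subthreshold-only soma with leak and KLVA; no
#'     thresholding unit and no constant generator current.}
#' }
#'
#' Units throughout: mV, ms, nS, pF, pA.
#'
#' @param variant Model variant name (see Details).
#' @param soma Named list overriding somatic parameters `C_soma`,
#'   `g_leak_soma`, `g_klva_bar`, `E_L`, `E_K`, `E_syn`.
#' @param node Named list overriding nodal parameters `C_node`,
#'   `g_leak_node`, `g_axon` (two-compartment variant only).
#' @param generator Named list overriding thresholding-unit parameters
#'   `I_const`, `A1`, `A2`, `tau1`, `tau2`, `V_theta`, `T_ref` (absent for
#'   the non-spiking variant).
#' @param kinetics A [klva_kinetics()] object (ignored by the passive
#'   variant).
#' @return An object of class `nl_model`.
#' @examples
#' m <- nl_model("one_comp_active_if")
#' m$generator$V_theta # -58.3 mV
#' @export
nl_model <- function(variant = c("two_comp_active_if", "one_comp_active_if",
                                 "one_comp_passive_if", "non_spiking"),
                     soma = list(), node = list(), generator = list(),
                     kinetics = klva_kinetics()) {
  variant <- match.arg(variant)

  soma_default <- list(C_soma = 24, g_leak_soma = 48, g_klva_bar = 192,
                       E_L = -60, E_K = -75, E_syn = 0)
  if (variant == "one_comp_passive_if") {
    soma_default$g_leak_soma <- 240
    soma_default$g_klva_bar <- NULL
    soma_default$E_K <- NULL
  }
  node_default <- list(C_node = 0.2, g_leak_node = 2, g_axon = 117.8)
  gen_default <- switch(variant,
    two_comp_active_if = list(I_const = 200, A1 = 4000, A2 = 3000,
                              tau1 = 0.02, tau2 = 0.2,
                              V_theta = -56.7, T_ref = 0.9),
    one_comp_active_if = list(I_const = 200, A1 = 3500, A2 = 3000,
                              tau1 = 0.02, tau2 = 0.2,
                              V_theta = -58.3, T_ref = 0.9),
    one_comp_passive_if = list(I_const = 200, A1 = 4000, A2 = 4000,
                               tau1 = 0.02, tau2 = 0.2,
                               V_theta = -58.6, T_ref = 0.9),
    non_spiking = NULL)

  check_override <- function(given, default, block) {
    if (is.null(default)) {
      if (length(given))
        stop(sprintf("variant '%s' has no '%s' block", variant, block),
             call. = FALSE)
      return(NULL)
    }
    bad <- setdiff(names(given), names(default))
    if (length(bad))
      stop(sprintf("unknown field(s) in '%s' block: %s", block,
                   paste(bad, collapse = ", ")), call. = FALSE)
    modifyList(default, given)
  }

  soma <- check_override(soma, soma_default, "soma")
  node <- check_override(node, if (variant == "two_comp_active_if") node_default else NULL,
                         "node")
  generator <- check_override(generator, gen_default, "generator")

  m <- structure(list(variant = variant, soma = soma, node = node,
                      generator = generator,
                      kinetics = if (variant != "one_comp_passive_if") kinetics else NULL),
                 class = "nl_model")
  validate_nl_model(m)
  m
}

validate_nl_model <- function(m) {
  s <- m$soma
  stopifnot(s$C_soma > 0, s$g_leak_soma >= 0, s$E_L < s$E_syn)
  if (has_klva(m)) {
    stopifnot(s$g_klva_bar >= 0, s$E_K < s$E_L)
    stopifnot(inherits(m$kinetics, "klva_kinetics"))
  }
  if (has_node(m)) {
    stopifnot(m$node$C_node > 0, m$node$g_leak_node >= 0, m$node$g_axon >= 0)
  }
  if (has_generator(m)) {
    g <- m$generator
    stopifnot(g$tau1 > 0, g$tau2 > 0, g$T_ref >= 0, g$A1 >= 0, g$A2 >= 0)
  }
  invisible(m)
}

has_node <- function(m) identical(m$variant, "two_comp_active_if")
has_generator <- function(m) !identical(m$variant, "non_spiking")
has_klva <- function(m) !identical(m$variant, "one_comp_passive_if")

#' Flat parameter list consumed by the compiled stepper
#' @noRd
model_cpp_spec <- function(m) {
  spec <- list(has_node = has_node(m), has_gen = has_generator(m),
               has_klva = has_klva(m))
  spec <- c(spec, m$soma)
  if (has_klva(m)) spec$tau_scale <- klva_tau_scale(m$kinetics)
  if (has_node(m)) spec <- c(spec, m$node)
  if (has_generator(m)) spec <- c(spec, m$generator)
  spec
}

#' @export
print.nl_model <- function(x, ...) {
  cat("<nl_model>", x$variant, "\n")
  fmt <- function(b) paste(sprintf("%s = %g", names(b), unlist(b)),
                           collapse = ", ")
  cat("  soma:     ", fmt(x$soma), "\n")
  if (!is.null(x$node)) cat("  node:     ", fmt(x$node), "\n")
  if (!is.null(x$generator)) cat("  generator:", fmt(x$generator), "\n")
  if (!is.null(x$kinetics))
    cat(sprintf("  kinetics:  Q10 = %g (%s), T0 = %g C, T1 = %g C\n",
                x$kinetics$Q10, x$kinetics$q10_convention,
                x$kinetics$T0, x$kinetics$T1))
  invisible(x)
}

#' Transient current emitted by the thresholding unit
#'
#' The stereotyped spike-associated current injected when the monitored
#' potential crosses threshold:
#' \deqn{I_{spike}(t) = A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}\ (t \ge 0),
#'       \quad 0\ (t < 0)}
#' measured from the crossing time. In the single-compartment models this
#' current stands in for the back-propagating spike from the remote
#' initiation site.
#'
#' @param t Time since threshold crossing (ms); may be a vector.
#' @param generator Thresholding-unit parameter list (e.g.
#'   `nl_model(...)$generator`).
#' @return Current (pA), zero for negative `t`.
#' @export
spike_current <- function(t, generator) {
  g <- generator
  ifelse(t >= 0,
         g$A1 * exp(-t / g$tau1) + g$A2 * exp(-t / g$tau2),
         0)
}
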