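#' Default run configuration
#'
#' Fully-resolved nested configuration for one model variant, with every
#' membrane, thresholding, kinetics, input and integration field at its
#' published default. Any field can be overridden in a config file; unknown
#' keys are rejected at load time. Units: mV, ms, nS, pF, pA; `dt_us` in
#' microseconds.
#'
#' @param variant Model variant name (see [nl_model()]).
#' @return Nested named list with blocks `model`, `input`, `integration`,
#'   `seed`.
#' @export
default_config <- function(variant = "one_comp_active_if") {
  m <- nl_model(variant)
  model <- list(variant = variant, soma = m$soma)
  if (!is.null(m$node)) model$node <- m$node
  if (!is.null(m$generator)) model$generator <- m$generator
  if (!is.null(m$kinetics))
    model$kinetics <- unclass(m$kinetics)
  p <- input_params()
  list(model = model,
       input = unclass(p)[setdiff(names(unclass(p)), "tau_alpha")],
       integration = list(dt_us = 10, duration_ms = 1000, warmup_ms = 20),
       seed = 1L)
}

config_schema <- function(variant) {
  cfg <- default_config(variant)
  rapply(cfg, function(x) NA, how = "replace")
}

check_config_keys <- function(given, schema, path = "") {
  bad <- setdiff(names(given), names(schema))
  if (length(bad))
    stop("unknown config key(s) at '", path, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (nm in names(given)) {
    if (is.list(schema[[nm]])) {
      if (!is.list(given[[nm]]))
        stop("config key '", path, nm, "' must be a block", call. = FALSE)
      check_config_keys(given[[nm]], schema[[nm]], paste0(path, nm, "/"))
    }
  }
  invisible(TRUE)
}

merge_config <- function(base, given) {
  for (nm in names(given)) {
    base[[nm]] <- if (is.list(given[[nm]]) && is.list(base[[nm]]))
      merge_config(base[[nm]], given[[nm]]) else given[[nm]]
  }
  base
}

#' Load a run configuration
#'
#' Reads a YAML config file, validates it against the schema of its variant
#' (unknown keys and blocks not applicable to the variant are errors, with
#' the offending path in the message), and merges it into the full defaults.
#' An empty or missing file yields the defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param variant Variant used when the file does not specify one.
#' @return Resolved configuration list (see [default_config()]).
#' @export
load_config <- function(path = NULL, variant = "one_comp_active_if") {
  given <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(given)) given <- list()
  if (!is.null(given$model$variant)) variant <- given$model$variant
  variant <- match.arg(variant, c("two_comp_active_if", "one_comp_active_if",
                                  "one_comp_passive_if", "non_spiking"))
  given$model$variant <- NULL
  schema <- config_schema(variant)
  check_config_keys(given, schema)
  cfg <- merge_config(default_config(variant), given)
  cfg$model$variant <- variant
  cfg
}

#' Write a configuration to YAML
#'
#' Round-trip stable with [load_config()].
#'
#' @param cfg Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Build the model and input objects described by a configuration
#'
#' @param cfg Configuration list from [load_config()].
#' @return List with `model` ([nl_model()]), `input` ([input_params()]) and
#'   the `integration` block.
#' @export
config_objects <- function(cfg) {
  mb <- cfg$model
  kin <- if (!is.null(mb$kinetics)) do.call(klva_kinetics, mb$kinetics)
         else klva_kinetics()
  model <- nl_model(mb$variant,
                    soma = mb$soma %||% list(),
                    node = mb$node %||% list(),
                    generator = mb$generator %||% list(),
                    kinetics = kin)
  input <- do.call(input_params, cfg$input)
  list(model = model, input = input, integration = cfg$integration,
       seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
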