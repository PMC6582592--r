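# Project configuration: one YAML file validated up front, before any
# compute, with every problem reported at once.

config_spec <- function() {
  list(
    schema_version = "numeric",
    seed = "numeric",
    paths = list(
      state_table = "input_file", climate = "input_file",
      initial_state = "input_file", initial_r = "input_file",
      soil_depth = "input_file", soil_fertility = "input_file",
      region = "input_file", model = "string", examples = "string",
      trajectory = "string", attributes = "string", out_dir = "string"),
    species = list(codes = "character", thermal_optimum = "numeric"),
    states = list(n_height_classes = "numeric", n_lai_classes = "numeric"),
    kernel = list(
      seed = "numeric", base = "numeric", midpoint = "numeric",
      steepness = "numeric", temp_effect = "numeric", temp_ref = "numeric",
      neigh_coef = "numeric", therm_sel = "numeric", logit_sd = "numeric",
      max_height_step = "numeric"),
    model = list(
      type = "string", hidden = "numeric", dropout = "numeric",
      learning_rate = "numeric", batch_size = "numeric",
      epochs = "numeric", l2 = "numeric", climate_encoding = "string",
      use_shares = "logical", keys = "character", alpha = "numeric"),
    climate = list(
      region_temp = "numeric", region_precip = "numeric",
      seasonal_amplitude = "numeric", temp_sd = "numeric",
      precip_cv = "numeric"),
    run = list(
      years = "numeric", start_year = "numeric", output_every = "numeric",
      horizon = "numeric", initial_R = "numeric", R_cap = "numeric",
      rows = "numeric", cols = "numeric"))
}

check_node <- function(value, spec, path, errors) {
  if (is.list(spec)) {
    if (!is.list(value)) {
      return(c(errors, paste0(path, ": expected a mapping")))
    }
    unknown <- setdiff(names(value), names(spec))
    if (length(unknown))
      errors <- c(errors, paste0(path, ": unknown key(s) ",
                                 paste(unknown, collapse = ", ")))
    for (k in intersect(names(value), names(spec)))
      errors <- check_node(value[[k]], spec[[k]], paste0(path, "$", k),
                           errors)
    return(errors)
  }
  ok <- switch(spec,
               numeric = is.numeric(value),
               string = is.character(value) && length(value) == 1L,
               character = is.character(value),
               logical = is.logical(value),
               input_file = is.character(value) && length(value) == 1L)
  if (!ok)
    errors <- c(errors, paste0(path, ": expected ", spec, ", got ",
                               class(value)[1]))
  if (identical(spec, "input_file") && ok && !file.exists(value))
    errors <- c(errors, paste0(path, ": file not found: ", value))
  errors
}

#' Load and validate a project configuration
#'
#' Reads a YAML configuration, rejects unknown keys and type
#' mismatches, and verifies that every referenced input file exists —
#' all before any computation, with every problem listed in one error.
#'
#' @param path Path to a YAML file.
#' @return The validated configuration list (class `project_config`)
#'   with a `config_hash` attribute.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  errors <- check_node(cfg, config_spec(), "config", character(0))
  if (is.null(cfg$schema_version))
    errors <- c(errors, "config$schema_version is required")
  if (length(errors))
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  attr(cfg, "config_hash") <- config_hash(cfg)
  class(cfg) <- c("project_config", "list")
  cfg
}

#' Save a configuration to YAML
#' @param cfg A configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  attr(cfg, "config_hash") <- NULL
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Hash of a configuration
#' @param cfg A configuration list.
#' @return A short character hash, stable across save/load.
#' @export
config_hash <- function(cfg) {
  attr(cfg, "config_hash") <- NULL
  digest::digest(unclass(cfg), algo = "xxhash64")
}
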