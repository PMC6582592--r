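# Tabular readers/writers shared across modules. All formats are plain
# text; files carry an optional leading comment line embedding the run's
# seed and configuration hash for provenance.

provenance_header <- function(seed = NULL, config_hash = NULL) {
  paste0("seed=", if (is.null(seed)) "NA" else seed,
         " config_hash=", if (is.null(config_hash)) "NA" else config_hash)
}

write_csv_with_header <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write / read a trajectory as CSV
#'
#' Long format: one row per (cell, year) with `cell` (linear index into
#' the site grid), `year`, `state_id` and `R`.
#'
#' @param trajectory A [simulate_trajectories()] result.
#' @param path File path.
#' @param header Optional provenance comment.
#' @return `read_trajectory` returns a `trajectory` object.
#' @export
write_trajectory <- function(trajectory, path, header = NULL) {
  Y <- trajectory$years
  df <- data.frame(
    cell = rep(trajectory$cells, Y + 1L),
    year = rep(trajectory$start_year + 0:Y, each = nrow(trajectory$states)),
    state_id = as.vector(trajectory$states),
    R = as.vector(trajectory$R))
  write_csv_with_header(df, path, header)
}

#' @param rows,cols Grid dimensions of the originating site grid.
#' @param scenario Scenario tag to attach.
#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, rows, cols, scenario = 1L) {
  df <- utils::read.csv(path, comment.char = "#")
  cells <- sort(unique(df$cell))
  years <- sort(unique(df$year))
  n <- length(cells)
  S <- matrix(NA_integer_, n, length(years))
  RT <- S
  ci <- match(df$cell, cells); yi <- match(df$year, years)
  S[cbind(ci, yi)] <- df$state_id
  RT[cbind(ci, yi)] <- df$R
  if (anyNA(S)) stop("trajectory file has missing (cell, year) pairs")
  structure(list(states = S, R = RT, cells = cells, rows = rows,
                 cols = cols, start_year = years[1],
                 years = length(years) - 1L,
                 scenario = as.integer(scenario), seed = NA_integer_),
            class = "trajectory")
}

#' Write / read an example set as CSV
#'
#' The context columns plus the two label columns `label_dR` (0 =
#' censored) and `label_state` (empty where censored).
#'
#' @param examples An `example_set`.
#' @param path File path.
#' @param header Optional provenance comment.
#' @return `read_examples` returns an `example_set`.
#' @export
write_examples <- function(examples, path, header = NULL) {
  df <- cbind(examples$context, label_dR = examples$dR,
              label_state = examples$S_star)
  write_csv_with_header(df, path, header)
}

#' @param state_table The [state_table] the examples refer to.
#' @param horizon Prediction horizon the labels were extracted with.
#' @rdname write_examples
#' @export
read_examples <- function(path, state_table, horizon = 10L) {
  df <- utils::read.csv(path, comment.char = "#")
  lab <- c("label_dR", "label_state")
  if (!all(lab %in% names(df)))
    stop("example file lacks label columns")
  structure(list(context = df[, setdiff(names(df), lab), drop = FALSE],
                 dR = as.integer(df$label_dR),
                 S_star = as.integer(df$label_state),
                 n_states = n_states(state_table),
                 pool = state_table$pool, horizon = as.integer(horizon)),
            class = "example_set")
}

#' Write / read an attribute database as CSV
#'
#' Long format `state_id`, `R_key`, `attribute`, `value`.
#'
#' @param db An [build_attribute_db()] database.
#' @param path File path.
#' @param header Optional provenance comment.
#' @return `read_attribute_db` returns an `attribute_db`.
#' @export
write_attribute_db <- function(db, path, header = NULL) {
  write_csv_with_header(as.data.frame(db$dt), path, header)
}

#' @param R_cap Residence cap the database was built with.
#' @rdname write_attribute_db
#' @export
read_attribute_db <- function(path, R_cap = 50L) {
  df <- utils::read.csv(path, comment.char = "#")
  names(df)[names(df) == "R_key"] <- "residence_time"
  build_attribute_db(df, R_cap = R_cap)
}

mat2list <- function(m) list(dim = dim(m), data = as.vector(m))
list2mat <- function(l) matrix(unlist(l$data), l$dim[1], l$dim[2])

#' Save / load a transition model
#'
#' Serializes a fitted `dnn_model` or `tabulated_model` to JSON at full
#' numeric precision, including (for the neural model) the weights, the
#' fitted feature scaler and the feature-schema hash; loading refuses
#' nothing, but prediction fails if the schema of the target state table
#' differs from the one the model was trained under.
#'
#' @param model The model object.
#' @param path Output `.json` path.
#' @return `load_model` returns the model object.
#' @export
save_model <- function(model, path) {
  ser_params <- function(pl)
    c(list(n_layers = pl$n_layers),
      lapply(pl[setdiff(names(pl), "n_layers")], function(x)
        if (is.matrix(x)) mat2list(x) else list(dim = NULL, data = x)))
  if (inherits(model, "dnn_model")) {
    obj <- list(
      type = "dnn",
      two_networks = isTRUE(model$config$two_networks),
      params = if (isTRUE(model$config$two_networks))
        lapply(model$params, ser_params)
      else ser_params(model$params),
      schema = list(columns = model$schema$columns,
                    scaled_columns = model$schema$scaled_columns,
                    n_states = model$schema$n_states,
                    pool = model$schema$pool,
                    climate_encoding = model$schema$climate_encoding,
                    horizon = model$schema$horizon,
                    R_cap = model$schema$R_cap,
                    hash = model$schema$hash),
      scaler = model$scaler, keep_columns = model$keep_columns,
      realized_states = model$realized_states,
      n_states = model$n_states, horizon = model$horizon,
      config = unclass(model$config), seed = model$seed)
  } else if (inherits(model, "tabulated_model")) {
    obj <- list(type = "tabulated", keys = model$keys, bins = model$bins,
                R_cap = model$R_cap,
                key_names = rownames(model$p_dR),
                p_dR = mat2list(model$p_dR),
                p_state = mat2list(model$p_state),
                marg_dR = model$marg_dR, marg_state = model$marg_state,
                n_states = model$n_states, horizon = model$horizon,
                alpha = model$alpha)
  } else stop("cannot serialize model of class ", class(model)[1])
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "dnn")) {
    deser_params <- function(pl) {
      params <- list(n_layers = pl$n_layers)
      for (nm in setdiff(names(pl), "n_layers")) {
        p <- pl[[nm]]
        params[[nm]] <- if (is.null(p$dim)) as.numeric(p$data)
          else matrix(as.numeric(unlist(p$data)), p$dim[1], p$dim[2])
      }
      params
    }
    params <- if (isTRUE(obj$two_networks))
      lapply(obj$params, deser_params) else deser_params(obj$params)
    schema <- obj$schema
    class(schema) <- "feature_schema"
    scaler <- obj$scaler
    scaler$mean <- stats::setNames(as.numeric(scaler$mean), scaler$cols)
    scaler$sd <- stats::setNames(as.numeric(scaler$sd), scaler$cols)
    config <- obj$config
    class(config) <- "mlp_config"
    dnn_model_obj(params, schema, scaler, as.integer(obj$keep_columns),
                  as.integer(obj$realized_states), as.integer(obj$horizon),
                  config, obj$seed, NULL)
  } else if (identical(obj$type, "tabulated")) {
    p_dR <- list2mat(obj$p_dR); p_state <- list2mat(obj$p_state)
    rownames(p_dR) <- obj$key_names; rownames(p_state) <- obj$key_names
    structure(list(keys = obj$keys,
                   bins = if (length(obj$bins)) obj$bins else list(),
                   R_cap = obj$R_cap, p_dR = p_dR, p_state = p_state,
                   marg_dR = as.numeric(obj$marg_dR),
                   marg_state = as.numeric(obj$marg_state),
                   n_states = as.integer(obj$n_states),
                   horizon = as.integer(obj$horizon), alpha = obj$alpha),
              class = "tabulated_model")
  } else stop("unrecognized model file: ", path)
}
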