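# Predictor assembly for the transition classifier. The layout is fixed
# and hashed so that a model can refuse feature vectors built under a
# different schema.

#' Feature schema for the transition classifier
#'
#' Fixed-order feature layout: state one-hot (`s0..s<N-1>`), residence
#' time (years, capped at `R_cap`), soil depth, soil fertility, the
#' monthly climate window over the next 10 years (120 temperature then
#' 120 precipitation values, or 12+12 decadal monthly means under the
#' `"decadal"` encoding), tier-1 and tier-2 species shares (pool order)
#' and distance to the simulated-area edge (m, capped at 1,000). State
#' spaces beyond 1,024 states would need an embedding input and are
#' rejected.
#'
#' @param state_table A [state_table].
#' @param climate_encoding `"monthly"` (240 raw values) or `"decadal"`
#'   (24 means across the window's 10 years).
#' @param horizon Climate window length in years (default 10).
#' @param R_cap Residence-time cap for scaling (default 100).
#' @return An object of class `feature_schema` with the column names and
#'   a digest hash.
#' @export
feature_schema <- function(state_table, climate_encoding = c("monthly", "decadal"),
                           horizon = 10L, R_cap = 100L) {
  climate_encoding <- match.arg(climate_encoding)
  nS <- n_states(state_table)
  if (nS > 1024L)
    stop("state spaces over 1,024 states need an embedding input, ",
         "which this implementation does not provide")
  pool <- state_table$pool$species
  clim <- if (climate_encoding == "monthly") {
    c(paste0("tmean_y", rep(seq_len(horizon), each = 12), "_m", 1:12),
      paste0("prec_y", rep(seq_len(horizon), each = 12), "_m", 1:12))
  } else {
    c(paste0("tmean_m", 1:12), paste0("prec_m", 1:12))
  }
  cols <- c(paste0("s", seq_len(nS) - 1L), "R", "soil_depth",
            "soil_fertility", clim, paste0("t1_", pool),
            paste0("t2_", pool), "edge_dist")
  scaled <- c("R", "soil_depth", "soil_fertility", clim, "edge_dist")
  structure(list(columns = cols, scaled_columns = scaled,
                 n_states = nS, pool = pool,
                 climate_encoding = climate_encoding,
                 horizon = as.integer(horizon), R_cap = as.integer(R_cap),
                 hash = digest::digest(list("feature_schema/v1", cols))),
            class = "feature_schema")
}

# (region, year) -> 24-column monthly matrix lookup for fast window
# assembly.
climate_lookup <- function(climate) {
  validate_climate(climate)
  cl <- climate[order(climate$region, climate$year, climate$month), ]
  key <- paste(cl$region, cl$year)
  ukey <- unique(key)
  tm <- matrix(cl$tmean, ncol = 12L, byrow = TRUE)
  pr <- matrix(cl$precip, ncol = 12L, byrow = TRUE)
  list(key = ukey, tmean = tm, precip = pr)
}

#' Build the feature matrix for a set of cell contexts
#'
#' Deterministically assembles the raw feature matrix in schema order
#' and, when a scaler is given, z-scales the scaled column block with
#' the training-set constants. Share and one-hot columns are never
#' rescaled (they live in `[0, 1]` already).
#'
#' @param context A context data.frame as produced by
#'   [extract_training_examples()] (or the simulation engine), with
#'   columns `state`, `R`, `soil_depth`, `soil_fertility`, `region`,
#'   `year`, `edge_dist` and the tier share columns.
#' @param climate Climate table covering each row's `year` to
#'   `year + horizon - 1`.
#' @param schema A [feature_schema()].
#' @param scaler Optional scaler from [fit_scaler()].
#' @return Numeric matrix `nrow(context) x length(schema$columns)`.
#' @export
build_features <- function(context, climate, schema, scaler = NULL) {
  stopifnot(inherits(schema, "feature_schema"))
  n <- nrow(context)
  if (any(context$state < 0 | context$state >= schema$n_states))
    stop("context contains state ids outside the schema's state space")
  lk <- climate_lookup(climate)
  H <- schema$horizon
  tm <- matrix(NA_real_, n, 12L * H)
  pr <- matrix(NA_real_, n, 12L * H)
  for (y in seq_len(H)) {
    rows <- match(paste(context$region, context$year + y - 1L), lk$key)
    if (anyNA(rows))
      stop("climate window incomplete: missing region-year ",
           paste(context$region[which(is.na(rows))[1]],
                 context$year[which(is.na(rows))[1]] + y - 1L))
    tm[, (y - 1L) * 12L + 1:12] <- lk$tmean[rows, , drop = FALSE]
    pr[, (y - 1L) * 12L + 1:12] <- lk$precip[rows, , drop = FALSE]
  }
  if (schema$climate_encoding == "decadal") {
    dm <- function(m) sapply(1:12, function(mo)
      rowMeans(m[, seq(mo, 12L * H, by = 12L), drop = FALSE]))
    tm <- matrix(dm(tm), n); pr <- matrix(dm(pr), n)
  }
  onehot <- matrix(0, n, schema$n_states)
  onehot[cbind(seq_len(n), context$state + 1L)] <- 1
  t1 <- as.matrix(context[, paste0("t1_", schema$pool), drop = FALSE])
  t2 <- as.matrix(context[, paste0("t2_", schema$pool), drop = FALSE])
  X <- cbind(onehot,
             pmin(context$R, schema$R_cap),
             context$soil_depth, context$soil_fertility,
             tm, pr, t1, t2,
             pmin(context$edge_dist, 1000))
  colnames(X) <- schema$columns
  if (!is.null(scaler)) {
    if (!identical(scaler$hash, schema$hash))
      stop("scaler was fitted under a different feature schema")
    j <- match(scaler$cols, colnames(X))
    X[, j] <- sweep(sweep(X[, j, drop = FALSE], 2, scaler$mean), 2,
                    scaler$sd, "/")
  }
  X
}

#' Fit a feature scaler on a training matrix
#'
#' Per-column mean and standard deviation over the schema's scaled
#' columns (residence time, soils, climate, edge distance); constant
#' columns get unit scale.
#'
#' @param X Raw (unscaled) feature matrix from [build_features()].
#' @param schema The [feature_schema()] used to build `X`.
#' @return A scaler list consumed by [build_features()].
#' @export
fit_scaler <- function(X, schema) {
  j <- match(schema$scaled_columns, colnames(X))
  mu <- colMeans(X[, j, drop = FALSE])
  sd_ <- apply(X[, j, drop = FALSE], 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  list(cols = schema$scaled_columns, mean = mu, sd = sd_,
       hash = schema$hash)
}
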