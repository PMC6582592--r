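# Synthetic succession trajectories from the ground-truth kernel.
# Emulates the per-cell annual output of a process-based landscape
# simulator: residence-time-dependent, climate-modified transition
# hazards with neighbourhood-dependent target states.

#' Simulate per-cell annual state trajectories
#'
#' Runs the truth kernel on every active cell of a site grid for `years`
#' annual steps. Each year, every cell leaves its state with probability
#' [kernel_hazard()] (evaluated at the region's annual mean temperature)
#' and, if it leaves, draws a successor from
#' [kernel_target_distribution()] using the start-of-year neighbourhood
#' shares (synchronous update). Residence time resets to 0 in transition
#' years and increments by exactly 1 otherwise.
#'
#' @param kernel A [make_truth_kernel()] object.
#' @param site A [site_grid].
#' @param climate Climate table covering years `start_year` to
#'   `start_year + years + horizon - 1` for every region on the grid
#'   (the extra horizon allows training-example extraction at the end of
#'   the series).
#' @param years Number of annual steps (`>= 1`).
#' @param initial_states Integer matrix (or single id) of initial state
#'   ids.
#' @param seed Integer seed.
#' @param start_year First simulated calendar year (default 1).
#' @param initial_R Initial residence times (matrix or scalar, default 0).
#' @param horizon Prediction horizon used for the coverage check
#'   (default 10).
#' @param scenario Integer tag stored with the trajectory (used for
#'   train/validation splits by climate scenario).
#' @param state_table The [state_table] the kernel was built on.
#' @return An object of class `trajectory`: matrices `states` and `R` of
#'   dimension `n_active_cells x (years + 1)` (column `t+1` holds year
#'   `start_year + t`), plus bookkeeping (`cells`, grid dims, scenario).
#' @export
simulate_trajectories <- function(kernel, site, climate, years,
                                  initial_states, seed = 1L,
                                  start_year = 1L, initial_R = 0L,
                                  horizon = 10L, scenario = 1L,
                                  state_table = NULL) {
  stopifnot(inherits(kernel, "truth_kernel"), inherits(site, "site_grid"),
            years >= 1L)
  check_climate_coverage(climate, start_year, start_year + years + horizon - 1L)
  nr <- site$rows; nc <- site$cols
  if (length(initial_states) == 1L)
    initial_states <- matrix(as.integer(initial_states), nr, nc)
  if (length(initial_R) == 1L)
    initial_R <- matrix(as.integer(initial_R), nr, nc)
  if (any(initial_states[site$active] < 0 |
          initial_states[site$active] >= kernel$n_states, na.rm = TRUE))
    stop("initial state id outside the kernel's state space")
  cells <- which(site$active)
  n <- length(cells)
  S <- matrix(NA_integer_, n, years + 1L)
  RT <- matrix(NA_integer_, n, years + 1L)
  S[, 1L] <- initial_states[cells]
  RT[, 1L] <- initial_R[cells]
  at <- annual_mean_temp(climate)
  temp_of <- function(yr) {
    key <- paste(site$region[cells], yr)
    at$tmean[match(key, paste(at$region, at$year))]
  }
  need_shares <- kernel$neigh_coef != 0
  if (is.null(state_table))
    stop("state_table is required (species weights for target draws)")
  set.seed(as.integer(seed))
  smat <- matrix(NA_integer_, nr, nc)
  for (t in seq_len(years)) {
    cur <- S[, t]; curR <- RT[, t]
    temp <- temp_of(start_year + t - 1L)
    h <- kernel_hazard(kernel, cur, curR, temp)
    leave <- stats::runif(n) < h
    S[, t + 1L] <- cur
    RT[, t + 1L] <- curR + 1L
    if (any(leave)) {
      idx <- which(leave)
      if (need_shares) {
        smat[] <- NA_integer_; smat[cells] <- cur
        sh <- share_rasters(smat, site$active, state_table)
        shm <- shares_at(sh, cells[idx])
        probs <- kernel_target_distribution(kernel, cur[idx], shm$t1,
                                            shm$t2, temp[idx])
      } else {
        probs <- kernel_target_distribution(kernel, cur[idx],
                                            temp = temp[idx])
      }
      pick <- sample_rows(probs)
      S[idx, t + 1L] <- pick - 1L
      RT[idx, t + 1L] <- 0L
    }
  }
  structure(list(states = S, R = RT, cells = cells, rows = nr, cols = nc,
                 start_year = as.integer(start_year),
                 years = as.integer(years),
                 scenario = as.integer(scenario), seed = as.integer(seed)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", nrow(x$states), "cells x", x$years,
      "years (scenario", x$scenario, ")\n")
  invisible(x)
}

#' Extract training examples from a trajectory
#'
#' One example per (cell, year) with at least `horizon` years of
#' trajectory remaining. The timing label is the number of years until
#' the next state change (`1..horizon`), or the censored class 0 when no
#' change occurs within the horizon; the target-state label is the state
#' entered at that change (absent for censored rows). Predictor context
#' (state, residence time, soils, neighbourhood shares, edge distance,
#' annual temperature, region, year) is assembled per example; the
#' monthly climate window is attached later by the feature builder.
#'
#' @param trajectory A [simulate_trajectories()] result.
#' @param site The [site_grid] the trajectory was run on.
#' @param climate Climate table (for the annual-temperature column).
#' @param state_table The [state_table].
#' @param horizon Prediction horizon in years (default 10).
#' @param stride Keep every `stride`-th eligible year per cell
#'   (default 1 = every cell-year, the densest extraction).
#' @param max_examples Optional cap; a uniform subsample of this size is
#'   drawn with `seed`.
#' @param seed Seed for the subsample.
#' @return An object of class `example_set`: `context` (data.frame),
#'   `dR` (integer labels, 0 = censored), `S_star` (integer ids, `NA`
#'   where censored), `n_states`, `pool`.
#' @export
extract_training_examples <- function(trajectory, site, climate, state_table,
                                      horizon = 10L, stride = 1L,
                                      max_examples = NULL, seed = 1L) {
  stopifnot(inherits(trajectory, "trajectory"))
  Y <- trajectory$years
  if (Y <= horizon) stop("trajectory must be longer than the horizon")
  S <- trajectory$states; RT <- trajectory$R
  n <- nrow(S)
  # next-change year index (1-based column) after each column, Inf if none
  nxt <- matrix(Inf, n, Y + 1L)
  for (t in Y:1) {
    changed <- S[, t + 1L] != S[, t]
    nxt[, t] <- ifelse(changed, t + 1L, nxt[, t + 1L])
  }
  elig_t <- seq(1L, Y - horizon + 1L, by = stride)  # col t = year t-1 offset
  cell_idx <- rep(seq_len(n), times = length(elig_t))
  col_idx <- rep(elig_t, each = n)
  if (!is.null(max_examples) && length(cell_idx) > max_examples) {
    set.seed(as.integer(seed))
    keep <- sample.int(length(cell_idx), max_examples)
    keep <- sort(keep)
    cell_idx <- cell_idx[keep]; col_idx <- col_idx[keep]
  }
  flat <- cbind(cell_idx, col_idx)
  dR_raw <- nxt[flat] - col_idx
  dR <- ifelse(dR_raw <= horizon, dR_raw, 0L)
  S_star <- rep(NA_integer_, length(dR))
  has <- dR > 0L
  S_star[has] <- S[cbind(cell_idx[has], col_idx[has] + dR[has])]
  year <- trajectory$start_year + col_idx - 1L
  cells <- trajectory$cells[cell_idx]
  rows <- (cells - 1L) %% site$rows + 1L
  cols <- (cells - 1L) %/% site$rows + 1L
  edge <- edge_distance(site$active)
  at <- annual_mean_temp(climate)
  temp <- at$tmean[match(paste(site$region[cells], year),
                         paste(at$region, at$year))]
  # tier shares at each example's year: group by year, one raster pass each
  P <- length(state_table$pool$species)
  t1m <- matrix(0, length(dR), P); t2m <- matrix(0, length(dR), P)
  smat <- matrix(NA_integer_, site$rows, site$cols)
  for (tc in unique(col_idx)) {
    rowsel <- which(col_idx == tc)
    smat[] <- NA_integer_
    smat[trajectory$cells] <- S[, tc]
    sh <- share_rasters(smat, site$active, state_table)
    shm <- shares_at(sh, cells[rowsel])
    t1m[rowsel, ] <- shm$t1; t2m[rowsel, ] <- shm$t2
  }
  colnames(t1m) <- paste0("t1_", state_table$pool$species)
  colnames(t2m) <- paste0("t2_", state_table$pool$species)
  context <- data.frame(
    cell = cells, year = year, state = S[flat], R = RT[flat],
    soil_depth = site$soil_depth[cells],
    soil_fertility = site$soil_fertility[cells],
    region = site$region[cells], edge_dist = edge[cells],
    tmean_annual = temp, scenario = trajectory$scenario)
  context <- cbind(context, as.data.frame(t1m), as.data.frame(t2m))
  structure(list(context = context, dR = as.integer(dR),
                 S_star = S_star, n_states = n_states(state_table),
                 pool = state_table$pool, horizon = as.integer(horizon)),
            class = "example_set")
}

#' @export
print.example_set <- function(x, ...) {
  cat("<example_set>", length(x$dR), "examples,",
      sum(x$dR == 0L), "censored,", x$n_states, "states\n")
  invisible(x)
}

#' Combine example sets
#'
#' Row-binds example sets from different trajectories or climate
#' scenarios; pools and state-space sizes must match.
#'
#' @param ... `example_set` objects.
#' @return A combined `example_set`.
#' @export
bind_examples <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L)
  if (length(unique(vapply(xs, `[[`, integer(1), "n_states"))) != 1L)
    stop("example sets come from different state spaces")
  structure(list(context = do.call(rbind, lapply(xs, `[[`, "context")),
                 dR = unlist(lapply(xs, `[[`, "dR")),
                 S_star = unlist(lapply(xs, `[[`, "S_star")),
                 n_states = xs[[1]]$n_states, pool = xs[[1]]$pool,
                 horizon = xs[[1]]$horizon),
            class = "example_set")
}

#' Subset an example set
#' @param x An `example_set`.
#' @param idx Integer or logical row index.
#' @return The subset `example_set`.
#' @export
subset_examples <- function(x, idx) {
  structure(list(context = x$context[idx, , drop = FALSE],
                 dR = x$dR[idx], S_star = x$S_star[idx],
                 n_states = x$n_states, pool = x$pool,
                 horizon = x$horizon),
            class = "example_set")
}

#' Stationary state occupancy of the kernel
#'
#' Treats the kernel at fixed temperature and fixed neighbourhood shares
#' as a Markov chain on (state, residence time) pairs, with residence
#' time capped at `R_max`, and power-iterates its transition matrix. The
#' marginal over states is the long-run occupancy an unbounded
#' simulation converges to. States that cannot be left (hazard 0 at
#' every residence time) are reported as absorbing instead.
#'
#' @param kernel A truth kernel.
#' @param temp Fixed annual mean temperature.
#' @param t1,t2 Fixed tier share vectors (default all zero).
#' @param R_max Residence-time cap of the chain (default 150; hazards
#'   must have saturated well below this for the cap to be harmless).
#' @param tol,max_iter Power-iteration controls.
#' @return A list with `occupancy` (named numeric over state ids, sums
#'   to 1), `converged`, and `absorbing` (integer ids, possibly empty).
#' @export
analytic_stationary <- function(kernel, temp, t1 = NULL, t2 = NULL,
                                R_max = 150L, tol = 1e-12,
                                max_iter = 20000L) {
  nS <- kernel$n_states
  P <- ncol(kernel$weights)
  if (is.null(t1)) t1 <- numeric(P)
  if (is.null(t2)) t2 <- numeric(P)
  rmax_h <- vapply(seq_len(nS) - 1L, function(s)
    max(kernel_hazard(kernel, rep(s, R_max + 1L), 0:R_max, temp)),
    numeric(1))
  absorbing <- which(rmax_h <= 0) - 1L
  tg <- kernel_target_distribution(kernel, 0:(nS - 1L),
                                   matrix(t1, nS, P, byrow = TRUE),
                                   matrix(t2, nS, P, byrow = TRUE),
                                   rep(temp, nS))
  nR <- R_max + 1L
  idx <- function(s, r) s * nR + r + 1L  # 0-based s, r
  # dense transition matrix on the (S, R) chain
  M <- matrix(0, nS * nR, nS * nR)
  for (s in 0:(nS - 1L)) {
    h <- kernel_hazard(kernel, rep(s, nR), 0:R_max, temp)
    for (r in 0:R_max) {
      from <- idx(s, r)
      M[from, idx(0:(nS - 1L), 0L)] <-
        M[from, idx(0:(nS - 1L), 0L)] + h[r + 1L] * tg[s + 1L, ]
      stay <- idx(s, min(r + 1L, R_max))
      M[from, stay] <- M[from, stay] + 1 - h[r + 1L]
    }
  }
  v <- rep(1 / (nS * nR), nS * nR)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    v2 <- as.vector(v %*% M)
    if (sum(abs(v2 - v)) < tol) { v <- v2; converged <- TRUE; break }
    v <- v2
  }
  occ <- vapply(0:(nS - 1L), function(s) sum(v[idx(s, 0:R_max)]), numeric(1))
  names(occ) <- as.character(0:(nS - 1L))
  list(occupancy = occ / sum(occ), converged = converged,
       absorbing = absorbing)
}
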