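# Annual-time-step raster simulation of state transitions.
#
# Scheduling semantics: the timing head is queried once when a cell
# enters a state (and again after each censored 10-year window). A draw
# of k in 1..10 schedules the transition k years ahead; the censored
# class schedules nothing and the cell is re-queried 10 years later. At
# the scheduled year the target state is drawn from the state head using
# features current at that time. All cells update synchronously from the
# start-of-year landscape snapshot, so per-cell update order cannot
# create artifacts.

#' Initialize a landscape
#'
#' @param site A [site_grid].
#' @param initial_states Integer matrix of state ids (or a single id);
#'   `NA` permitted on inactive cells.
#' @param initial_R Matrix or scalar of initial residence times.
#' @param year Calendar year the initial snapshot represents.
#' @return An object of class `landscape`.
#' @export
init_landscape <- function(site, initial_states, initial_R = 0L,
                           year = 0L) {
  stopifnot(inherits(site, "site_grid"))
  nr <- site$rows; nc <- site$cols
  if (length(initial_states) == 1L)
    initial_states <- matrix(as.integer(initial_states), nr, nc)
  if (length(initial_R) == 1L)
    initial_R <- matrix(as.integer(initial_R), nr, nc)
  state <- matrix(as.integer(initial_states), nr, nc)
  state[!site$active] <- NA_integer_
  if (any(is.na(state[site$active])))
    stop("active cells must carry a valid initial state")
  R <- matrix(as.integer(initial_R), nr, nc)
  R[!site$active] <- NA_integer_
  structure(list(site = site, state = state, R = R,
                 sched = matrix(NA_integer_, nr, nc),
                 last_query = matrix(NA_integer_, nr, nc),
                 edge = edge_distance(site$active),
                 year = as.integer(year),
                 attributes = list()),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat("<landscape> year", x$year, "-", sum(x$site$active), "active cells,",
      length(unique(x$state[x$site$active])), "distinct states\n")
  invisible(x)
}

# Context data.frame for a set of (linear) cell indices, given a share
# raster snapshot and the annual temperature table.
build_context <- function(ls, cells, year, shares, at,
                          state_override = NULL, R_override = NULL) {
  site <- ls$site
  st <- if (is.null(state_override)) ls$state[cells] else state_override
  R <- if (is.null(R_override)) ls$R[cells] else R_override
  temp <- at$tmean[match(paste(site$region[cells], year),
                         paste(at$region, at$year))]
  shm <- shares_at(shares, cells)
  pool <- colnames(shm$t1)
  ctx <- data.frame(cell = cells, year = year, state = st, R = R,
                    soil_depth = site$soil_depth[cells],
                    soil_fertility = site$soil_fertility[cells],
                    region = site$region[cells],
                    edge_dist = ls$edge[cells],
                    tmean_annual = temp)
  colnames(shm$t1) <- paste0("t1_", pool)
  colnames(shm$t2) <- paste0("t2_", pool)
  cbind(ctx, as.data.frame(shm$t1), as.data.frame(shm$t2))
}

#' Sample transition offsets from timing distributions
#'
#' Draws one class per row of a timing-head matrix: class k in
#' `1..horizon` becomes a schedule offset of k years; the censored class
#' becomes `NA` (no transition scheduled within the horizon).
#'
#' @param p_dR Matrix `n x (horizon+1)`; column 1 is the censored class.
#' @return Integer vector of offsets with `NA` for censored draws.
#' @export
sample_schedule <- function(p_dR) {
  cls <- sample_rows(p_dR) - 1L
  ifelse(cls == 0L, NA_integer_, cls)
}

#' Advance a landscape by one year
#'
#' Applies scheduled transitions, increments residence times elsewhere,
#' re-queries cells whose censored window expired, draws fresh schedules
#' for cells that entered a new state, and (optionally) refreshes
#' ecosystem attributes from the attribute database. See the package
#' vignette for the precise event ordering.
#'
#' @param ls A [init_landscape()] object at year `year - 1`.
#' @param model A transition model (the prediction contract).
#' @param climate Climate table covering `year` to `year + horizon - 1`.
#' @param year The year to advance to (`ls$year + 1`).
#' @param state_table The [state_table].
#' @param attribute_db Optional [build_attribute_db()] database.
#' @param streams [rng_streams()] with streams `schedule`, `state`,
#'   `attribute`.
#' @param horizon Prediction horizon (default 10).
#' @param annual_temp Optional precomputed [annual_mean_temp()] table
#'   (computed from `climate` when absent; [run_simulation()] passes it
#'   once instead of recomputing it every year).
#' @return The updated landscape.
#' @export
step_landscape <- function(ls, model, climate, year, state_table,
                           attribute_db = NULL, streams, horizon = 10L,
                           annual_temp = NULL) {
  stopifnot(inherits(ls, "landscape"), year == ls$year + 1L)
  site <- ls$site
  active <- site$active
  n_active_before <- sum(active)
  at <- if (is.null(annual_temp)) annual_mean_temp(climate) else annual_temp
  shares <- share_rasters(ls$state, active, state_table)  # snapshot
  due <- active & !is.na(ls$sched) & ls$sched == year
  requery <- active & is.na(ls$sched) &
    !is.na(ls$last_query) & (year - ls$last_query >= horizon)
  # residence-time law: +1 everywhere, reset on transition below
  newR <- ls$R + 1L
  new_state <- ls$state
  due_cells <- which(due)
  if (length(due_cells)) {
    ctx <- build_context(ls, due_cells, year, shares, at,
                         R_override = newR[due_cells])
    pred <- stats::predict(model, ctx, climate)
    pick <- with_stream(streams, "state", sample_rows(pred$p_state))
    new_state[due_cells] <- pick - 1L
    newR[due_cells] <- 0L
  }
  ls$state <- new_state
  ls$R <- newR
  ls$sched[due_cells] <- NA_integer_
  need_sched <- sort(c(due_cells, which(requery)))
  if (length(need_sched)) {
    ctx2 <- build_context(ls, need_sched, year, shares, at)
    pred2 <- stats::predict(model, ctx2, climate)
    off <- with_stream(streams, "schedule", sample_schedule(pred2$p_dR))
    ls$sched[need_sched] <- year + off
    ls$last_query[need_sched] <- year
  }
  if (!is.null(attribute_db)) {
    cells <- which(active)
    for (a in unique(attribute_db$dt$attribute)) {
      vals <- with_stream(streams, "attribute",
                          sample_attributes(attribute_db, ls$state[cells],
                                            ls$R[cells], a))
      m <- ls$attributes[[a]]
      if (is.null(m)) m <- matrix(NA_real_, site$rows, site$cols)
      m[cells] <- vals
      ls$attributes[[a]] <- m
    }
  }
  ls$year <- as.integer(year)
  stopifnot(sum(site$active) == n_active_before,
            !any(is.na(ls$state[site$active])))
  ls
}

#' Run a simulation
#'
#' Draws initial schedules for every active cell at the starting year,
#' then advances the landscape year by year, recording per-year state
#' occupancy and, at the configured cadence, full state snapshots and
#' landscape summaries. Identical seeds give bit-identical outputs.
#'
#' @param ls Initial [init_landscape()].
#' @param model Transition model.
#' @param climate Climate table covering
#'   `ls$year` to `ls$year + years + horizon - 1`.
#' @param years Number of annual steps (`>= 0`).
#' @param state_table The [state_table].
#' @param seed Integer master seed.
#' @param attribute_db Optional attribute database.
#' @param output_every Snapshot/summary cadence in years (default 10).
#' @param horizon Prediction horizon (default 10).
#' @return An `output_bundle`: `occupancy` (matrix `(years+1) x
#'   n_states` of active-cell state frequencies), `snapshots` (state
#'   matrices by year), `summaries` ([landscape_summary()] rows by
#'   year), the final `landscape`, `seed`.
#' @export
run_simulation <- function(ls, model, climate, years, state_table,
                           seed = 1L, attribute_db = NULL,
                           output_every = 10L, horizon = 10L) {
  stopifnot(inherits(ls, "landscape"), years >= 0L)
  check_climate_coverage(climate, ls$year,
                         ls$year + years + horizon - 1L)
  streams <- rng_streams(seed, c("schedule", "state", "attribute"))
  active <- ls$site$active
  nS <- n_states(state_table)
  occ <- matrix(0, years + 1L, nS,
                dimnames = list(ls$year + 0:years, seq_len(nS) - 1L))
  occ_of <- function(l) tabulate(l$state[active] + 1L, nS) / sum(active)
  occ[1L, ] <- occ_of(ls)
  # initial schedules from the starting-year context
  at <- annual_mean_temp(climate)
  shares <- share_rasters(ls$state, active, state_table)
  cells <- which(active)
  ctx <- build_context(ls, cells, ls$year, shares, at)
  pred <- stats::predict(model, ctx, climate)
  off <- with_stream(streams, "schedule", sample_schedule(pred$p_dR))
  ls$sched[cells] <- ls$year + off
  ls$last_query[cells] <- ls$year
  if (!is.null(attribute_db)) {
    for (a in unique(attribute_db$dt$attribute)) {
      vals <- with_stream(streams, "attribute",
                          sample_attributes(attribute_db, ls$state[cells],
                                            ls$R[cells], a))
      m <- matrix(NA_real_, ls$site$rows, ls$site$cols)
      m[cells] <- vals
      ls$attributes[[a]] <- m
    }
  }
  snapshots <- list(); summaries <- list()
  take <- function(y) y == ls$year + years ||
    (output_every > 0L && (y - occ_year0) %% output_every == 0L)
  occ_year0 <- ls$year
  snapshots[[as.character(ls$year)]] <- ls$state
  summaries[[as.character(ls$year)]] <-
    landscape_summary(ls, state_table)
  end_year <- ls$year + years
  while (ls$year < end_year) {
    y <- ls$year + 1L
    ls <- step_landscape(ls, model, climate, y, state_table,
                         attribute_db, streams, horizon, annual_temp = at)
    occ[y - occ_year0 + 1L, ] <- occ_of(ls)
    if (take(y)) {
      snapshots[[as.character(y)]] <- ls$state
      summaries[[as.character(y)]] <- landscape_summary(ls, state_table)
    }
  }
  structure(list(occupancy = occ, snapshots = snapshots,
                 summaries = summaries, landscape = ls,
                 seed = as.integer(seed)),
            class = "output_bundle")
}

#' @export
print.output_bundle <- function(x, ...) {
  cat("<output_bundle>", nrow(x$occupancy) - 1L, "simulated years,",
      length(x$snapshots), "snapshots\n")
  invisible(x)
}

#' Landscape-scale summary of states and attributes
#'
#' Frequencies of composition classes (the `n_top` most frequent plus an
#' `"other"` bin), height-class and LAI-class distributions over active
#' cells (each block sums to 1), and quantiles of any attributes present
#' on the landscape.
#'
#' @param ls A [init_landscape()] object.
#' @param state_table The [state_table].
#' @param n_top Number of composition classes reported individually
#'   (default 18).
#' @return A list with `composition`, `height`, `lai` (named frequency
#'   vectors) and `attributes` (data.frame of quantiles and the mean).
#' @export
landscape_summary <- function(ls, state_table, n_top = 18L) {
  active <- ls$site$active
  if (!any(active)) stop("landscape has no active cells")
  st <- ls$state[active]
  comp_keys <- vapply(state_table$states, function(s)
    composition_key(s$composition), character(1))
  ck <- comp_keys[st + 1L]
  freq <- sort(table(ck) / length(ck), decreasing = TRUE)
  if (length(freq) > n_top) {
    top <- freq[seq_len(n_top)]
    comp <- c(as.numeric(top), other = sum(freq[-seq_len(n_top)]))
    names(comp) <- c(names(top), "other")
  } else comp <- stats::setNames(as.numeric(freq), names(freq))
  hts <- vapply(state_table$states, `[[`, integer(1), "height_class")
  lais <- vapply(state_table$states, `[[`, integer(1), "lai_class")
  height <- tabulate(hts[st + 1L] + 1L,
                     state_table$n_height_classes) / length(st)
  names(height) <- paste0("h", seq_len(state_table$n_height_classes) - 1L)
  lai <- tabulate(lais[st + 1L] + 1L,
                  state_table$n_lai_classes) / length(st)
  names(lai) <- paste0("l", seq_len(state_table$n_lai_classes) - 1L)
  attrs <- NULL
  if (length(ls$attributes)) {
    attrs <- do.call(rbind, lapply(names(ls$attributes), function(a) {
      v <- ls$attributes[[a]][active]
      q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)
      data.frame(attribute = a, min = q[1], q25 = q[2], median = q[3],
                 q75 = q[4], max = q[5], mean = mean(v, na.rm = TRUE),
                 row.names = NULL)
    }))
  }
  list(composition = comp, height = height, lai = lai, attributes = attrs)
}
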