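# Ecosystem attributes linked to state x residence-time classes.
# Empirical sample vectors, not fitted densities: attribute changes are
# assessed nonparametrically.

#' First-order Hill number (exponential Shannon diversity)
#'
#' `D = exp(-sum p_i log p_i)` over the normalized positive shares: the
#' effective number of equally abundant species. By convention `D = 0`
#' for a community with no vegetation (all shares zero), although
#' `exp(H) >= 1` for any non-empty community; the zero flags bare cells.
#'
#' @param shares Non-negative numeric vector of abundance shares (any
#'   scale; normalized internally, zero-padding is harmless).
#' @return A single non-negative number.
#' @export
#' @examples
#' hill_diversity(rep(1, 4))        # 4
#' hill_diversity(c(0.5, 0.3, 0.2)) # about 2.80
hill_diversity <- function(shares) {
  if (any(!is.finite(shares)) || any(shares < 0))
    stop("shares must be finite and non-negative")
  s <- shares[shares > 0]
  if (length(s) == 0L) return(0)
  p <- s / sum(s)
  exp(-sum(p * log(p)))
}

#' Build an attribute database
#'
#' Groups attribute records under (state id, residence-time key), with
#' residence times at or above `R_cap` pooled into the cap key. Group
#' sizes conserve the record count.
#'
#' @param records A data.frame with columns `state_id`,
#'   `residence_time`, `attribute`, `value` (long format; one row per
#'   measured attribute value).
#' @param R_cap Residence-time cap in years (default 50).
#' @return An object of class `attribute_db`.
#' @export
build_attribute_db <- function(records, R_cap = 50L) {
  req <- c("state_id", "residence_time", "attribute", "value")
  if (is.null(records) || nrow(records) == 0L) {
    dt <- data.table::data.table(state_id = integer(0), R_key = integer(0),
                                 attribute = character(0), value = numeric(0))
    return(structure(list(dt = dt, R_cap = as.integer(R_cap)),
                     class = "attribute_db"))
  }
  if (!all(req %in% names(records)))
    stop("records need columns: ", paste(req, collapse = ", "))
  if (any(records$residence_time < 0)) stop("residence_time must be >= 0")
  dt <- data.table::as.data.table(records[, req])
  dt[, `:=`(R_key = pmin(as.integer(residence_time), as.integer(R_cap)),
            state_id = as.integer(state_id))]
  dt <- dt[, list(state_id, R_key, attribute, value)]
  data.table::setkey(dt, attribute, state_id, R_key)
  structure(list(dt = dt, R_cap = as.integer(R_cap)),
            class = "attribute_db")
}

#' @export
print.attribute_db <- function(x, ...) {
  ng <- nrow(unique(x$dt[, list(state_id, R_key)]))
  cat("<attribute_db>", nrow(x$dt), "values,",
      length(unique(x$dt$attribute)), "attribute(s),",
      ng, "S x R combinations (R capped at", x$R_cap, ")\n")
  invisible(x)
}

#' Sample attribute values for many cells at once
#'
#' For each (state, residence time) pair one value is drawn uniformly
#' from the stored sample vector of (state, min(R, R_cap)). If that
#' exact key holds no samples, the nearest stored residence key of the
#' same state is used; states with no stored samples at all yield `NA`
#' with a warning.
#'
#' @param db An [attribute_db].
#' @param state_id,R Integer vectors (recycled to common length).
#' @param attribute Attribute name.
#' @return Numeric vector of sampled values.
#' @export
sample_attributes <- function(db, state_id, R, attribute) {
  n <- max(length(state_id), length(R))
  state_id <- rep_len(as.integer(state_id), n)
  R_key <- pmin(rep_len(as.integer(R), n), db$R_cap)
  # compute the filter outside the bracket: `attribute` would otherwise
  # resolve to the column of the same name inside data.table scope
  sel <- db$dt[["attribute"]] == attribute
  sub <- db$dt[sel]
  if (nrow(sub) == 0L) stop("unknown attribute '", attribute, "'")
  out <- rep(NA_real_, n)
  # resolve fallback keys: nearest stored R_key per state
  avail <- sub[, list(keys = list(sort(unique(R_key)))), by = state_id]
  amap <- stats::setNames(avail$keys, avail$state_id)
  kmap <- sub[, list(vals = list(value)), by = list(state_id, R_key)]
  kidx <- stats::setNames(kmap$vals, paste(kmap$state_id, kmap$R_key))
  missing_states <- FALSE
  req <- paste(state_id, R_key)
  for (grp in split(seq_len(n), req)) {
    s <- state_id[grp[1]]; r <- R_key[grp[1]]
    keys <- amap[[as.character(s)]]
    if (is.null(keys)) { missing_states <- TRUE; next }
    if (!(r %in% keys)) r <- keys[which.min(abs(keys - r))]
    v <- kidx[[paste(s, r)]]
    out[grp] <- if (length(v) == 1L) v else v[sample.int(length(v),
                                                        length(grp),
                                                        replace = TRUE)]
  }
  if (missing_states)
    warning("no stored samples for some states; returning NA")
  out
}

#' Sample one attribute value
#' @inheritParams sample_attributes
#' @return A single numeric value (or `NA` with a warning).
#' @export
sample_attribute <- function(db, state_id, R, attribute) {
  sample_attributes(db, state_id[1], R[1], attribute)
}

#' Summarize an attribute database
#'
#' Per-attribute group statistics (mean, min, max and size per S x R
#' combination), the number of combinations, and the grand mean computed
#' as the unweighted mean of group means (every S x R class counts
#' equally, however many samples it holds).
#'
#' @param db An [attribute_db].
#' @return A list per attribute, each with `groups` (data.frame),
#'   `n_combinations` and `grand_mean`.
#' @export
summarize_attributes <- function(db) {
  if (nrow(db$dt) == 0L) stop("attribute database is empty")
  out <- list()
  for (a in unique(db$dt$attribute)) {
    g <- db$dt[db$dt$attribute == a,
               list(mean = mean(value), min = min(value),
                    max = max(value), n = .N),
               by = list(state_id, R_key)]
    data.table::setkey(g, state_id, R_key)
    out[[a]] <- list(groups = as.data.frame(g),
                     n_combinations = nrow(g),
                     grand_mean = mean(g$mean))
  }
  out
}

#' Synthesize attribute records from a trajectory
#'
#' Emulates the attribute output of a process-based simulator: live tree
#' carbon grows with height class, LAI class and residence time (with
#' lognormal noise), and tree species diversity is the first-order Hill
#' number of the state's member shares (equal within mixtures) with
#' mild noise; bare cells carry zero carbon and zero diversity.
#'
#' @param trajectory A [simulate_trajectories()] result.
#' @param state_table The [state_table].
#' @param thin Keep every `thin`-th cell-year record (default 1).
#' @param seed Integer seed.
#' @return A long-format record data.frame for [build_attribute_db()].
#' @export
attribute_records_from_trajectory <- function(trajectory, state_table,
                                              thin = 1L, seed = 1L) {
  S <- trajectory$states; RT <- trajectory$R
  idx <- seq(1L, length(S), by = thin)
  set.seed(as.integer(seed))
  sid <- as.vector(S)[idx]; rt <- as.vector(RT)[idx]
  hts <- vapply(state_table$states, `[[`, integer(1), "height_class")
  lais <- vapply(state_table$states, `[[`, integer(1), "lai_class")
  nmem <- vapply(state_table$states, function(s)
    length(s$composition$members), integer(1))
  # carbon: height does the heavy lifting, LAI and residence refine it
  base_c <- (hts[sid + 1L] * 4 + 2) * 4 * (0.6 + 0.25 * lais[sid + 1L])
  carbon <- base_c * pmin(1, (rt + 5) / 25) *
    stats::rlnorm(length(sid), 0, 0.15)
  carbon[nmem[sid + 1L] == 0L] <- 0
  div <- vapply(nmem[sid + 1L], function(k)
    if (k == 0L) 0 else exp(-sum(rep(1 / k, k) * log(rep(1 / k, k)))),
    numeric(1))
  div <- pmax(0, div + stats::rnorm(length(sid), 0, 0.1) * (div > 0))
  data.frame(
    state_id = rep(sid, 2L), residence_time = rep(rt, 2L),
    attribute = rep(c("live_carbon", "tree_diversity"),
                    each = length(sid)),
    value = c(carbon, div))
}
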