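# Discrete vegetation state space: composition x height class x LAI class.

#' Create a species pool
#'
#' A species pool fixes the set and the order of species codes used by a
#' state table. The order matters: mixture members are serialized in pool
#' order and neighbourhood share vectors follow it.
#'
#' @param species Character vector of unique, non-empty species codes
#'   (e.g. `"piab"`, `"fasy"`).
#' @param thermal_optimum Optional numeric vector (degrees C) of the same
#'   length, the temperature at which each species performs best. Only the
#'   synthetic succession kernel consumes it.
#' @return An object of class `species_pool`.
#' @export
#' @examples
#' species_pool(c("piab", "fasy", "lade"), thermal_optimum = c(5, 9, 4))
species_pool <- function(species, thermal_optimum = NULL) {
  species <- as.character(species)
  if (length(species) < 1L) stop("species pool must contain at least one code")
  if (anyDuplicated(species)) stop("species codes must be unique")
  if (any(!nzchar(species))) stop("species codes must be non-empty")
  if (!is.null(thermal_optimum)) {
    if (length(thermal_optimum) != length(species))
      stop("thermal_optimum must have one value per species")
    thermal_optimum <- as.numeric(thermal_optimum)
    names(thermal_optimum) <- species
  }
  structure(list(species = species, thermal_optimum = thermal_optimum),
            class = "species_pool")
}

#' @export
print.species_pool <- function(x, ...) {
  cat("<species_pool>", length(x$species), "species:",
      paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

#' Height class of a canopy
#'
#' Dominant canopy height is binned into 4 m classes, half-open on the
#' right: class k covers heights in \[4k, 4k+4). The top class is open
#' ended, so with the default 26 classes the last bin is \[100, Inf).
#'
#' @param height Numeric vector of dominant heights in metres, `>= 0`.
#' @param n_height_classes Number of height classes (default 26).
#' @return Integer vector of class indices in `0:(n_height_classes-1)`.
#' @export
#' @examples
#' height_class(22)   # 5, the [20, 24) bin
#' height_class(103)  # capped at 25
height_class <- function(height, n_height_classes = 26L) {
  if (any(!is.finite(height)) || any(height < 0))
    stop("height must be finite and >= 0")
  pmin(as.integer(floor(height / 4)), as.integer(n_height_classes) - 1L)
}

#' LAI class of a cell
#'
#' Leaf area index is cut into three functional classes: sparsely
#' vegetated (LAI <= 2), moderately vegetated (2 < LAI <= 4) and densely
#' vegetated (LAI > 4). Boundaries belong to the lower class.
#'
#' @param lai Numeric vector of leaf area index values, `>= 0`.
#' @return Integer vector with values 0, 1 or 2.
#' @export
#' @examples
#' lai_class(c(2, 3, 4, 4.5))  # 0 1 1 2
lai_class <- function(lai) {
  if (any(!is.finite(lai)) || any(lai < 0))
    stop("lai must be finite and >= 0")
  ifelse(lai <= 2, 0L, ifelse(lai <= 4, 1L, 2L))
}

#' Composition class from species biomass shares
#'
#' Shares are interpreted as relative biomass and normalized to sum to
#' one before thresholding, so the classification is invariant to
#' rescaling all shares by a positive constant (unless all shares are
#' zero, which yields the bare class). A cell is dominated when the most
#' abundant species holds more than 66% of the biomass; otherwise it is a
#' mixture of all species holding more than 20% each. If no species
#' clears 20% (possible only with more than five species present) the
#' most abundant species forms a singleton mixture, which keeps the
#' classifier total. Ties break in pool order.
#'
#' @param shares Named numeric vector of non-negative biomass shares,
#'   names drawn from the pool; may be empty. The raw (pre-normalization)
#'   values must not sum to more than 1 + 1e-6.
#' @param pool A [species_pool].
#' @return A list of class `composition_class` with fields `kind` (one of
#'   `"bare"`, `"dominated"`, `"mixture"`) and `members` (character
#'   vector in pool order; empty for bare).
#' @export
#' @examples
#' pool <- species_pool(c("piab", "fasy", "lade"))
#' composition_class(c(piab = 0.8, fasy = 0.2), pool)  # dominated piab
composition_class <- function(shares, pool) {
  stopifnot(inherits(pool, "species_pool"))
  if (length(shares) == 0L)
    return(structure(list(kind = "bare", members = character(0)),
                     class = "composition_class"))
  if (is.null(names(shares)) || any(!nzchar(names(shares))))
    stop("shares must be named by species code")
  unknown <- setdiff(names(shares), pool$species)
  if (length(unknown))
    stop("unknown species code(s): ", paste(unknown, collapse = ", "))
  if (any(!is.finite(shares)) || any(shares < 0))
    stop("shares must be finite and non-negative")
  if (sum(shares) > 1 + 1e-6)
    stop("shares sum to more than 1")
  # fixed pool order so that argmax ties resolve deterministically
  v <- stats::setNames(numeric(length(pool$species)), pool$species)
  v[names(shares)] <- v[names(shares)] + shares
  tot <- sum(v)
  if (tot == 0)
    return(structure(list(kind = "bare", members = character(0)),
                     class = "composition_class"))
  p <- v / tot
  imax <- which.max(p)
  if (p[imax] > 0.66) {
    return(structure(list(kind = "dominated",
                          members = pool$species[imax]),
                     class = "composition_class"))
  }
  members <- pool$species[p > 0.20]
  if (length(members) == 0L) members <- pool$species[imax]
  if (length(members) > 4L)  # > 4 shares each > 0.2 cannot sum to <= 1
    stop("internal error: more than four mixture members")
  structure(list(kind = "mixture", members = members),
            class = "composition_class")
}

#' @export
print.composition_class <- function(x, ...) {
  cat("<composition_class>", composition_key(x), "\n")
  invisible(x)
}

composition_key <- function(comp) {
  switch(comp$kind,
         bare = "bare",
         dominated = paste0("D:", comp$members),
         mixture = paste0("M:", paste(comp$members, collapse = "+")))
}

state_key <- function(comp, height_class, lai_class) {
  paste0(composition_key(comp), "|h", height_class, "|l", lai_class)
}

#' Create a state table
#'
#' A state table holds the registered vegetation states of a project and
#' provides constant-time lookup by id and by class triple. In `"open"`
#' mode [classify()] registers unseen triples on the fly; in `"closed"`
#' mode an unseen triple is an error. State ids are dense integers
#' starting at 0.
#'
#' @param pool A [species_pool].
#' @param n_height_classes Number of 4 m height classes (default 26,
#'   covering 0 to 100 m plus an open-ended top bin).
#' @param n_lai_classes Number of LAI classes (fixed at 3 in the default
#'   scheme).
#' @param mode `"open"` or `"closed"`.
#' @return An object of class `state_table` (an environment).
#' @export
state_table <- function(pool, n_height_classes = 26L, n_lai_classes = 3L,
                        mode = c("open", "closed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pool, "species_pool"),
            n_height_classes >= 1L, n_lai_classes >= 1L)
  e <- new.env(parent = emptyenv())
  e$pool <- pool
  e$n_height_classes <- as.integer(n_height_classes)
  e$n_lai_classes <- as.integer(n_lai_classes)
  e$mode <- mode
  e$states <- list()
  e$key2id <- new.env(parent = emptyenv(), hash = TRUE)
  class(e) <- "state_table"
  e
}

#' @export
print.state_table <- function(x, ...) {
  cat("<state_table>", n_states(x), "states,",
      length(x$pool$species), "species,",
      x$n_height_classes, "height classes,",
      x$n_lai_classes, "LAI classes, mode:", x$mode, "\n")
  invisible(x)
}

#' Number of registered states
#' @param table A [state_table].
#' @return Integer count.
#' @export
n_states <- function(table) length(table$states)

#' Register a state in a table
#'
#' Adds the (composition, height class, LAI class) triple if absent and
#' returns its id. Bare composition forces height class 0 and LAI class 0.
#'
#' @param table A [state_table].
#' @param composition A `composition_class`.
#' @param height_class,lai_class Integer class indices.
#' @return The integer state id.
#' @export
register_state <- function(table, composition, height_class, lai_class) {
  stopifnot(inherits(table, "state_table"),
            inherits(composition, "composition_class"))
  if (composition$kind == "bare") {
    height_class <- 0L
    lai_class <- 0L
  }
  height_class <- as.integer(height_class)
  lai_class <- as.integer(lai_class)
  if (height_class < 0L || height_class >= table$n_height_classes)
    stop("height_class out of range")
  if (lai_class < 0L || lai_class >= table$n_lai_classes)
    stop("lai_class out of range")
  bad <- setdiff(composition$members, table$pool$species)
  if (length(bad))
    stop("composition members not in pool: ", paste(bad, collapse = ", "))
  key <- state_key(composition, height_class, lai_class)
  if (!is.null(table$key2id[[key]])) return(table$key2id[[key]])
  id <- length(table$states)  # dense 0-based ids
  st <- structure(list(state_id = id, composition = composition,
                       height_class = height_class, lai_class = lai_class),
                  class = "vegetation_state")
  table$states[[id + 1L]] <- st
  assign(key, id, envir = table$key2id)
  id
}

#' Classify raw measurements into a state id
#'
#' Applies the three axis classifiers and looks the resulting triple up
#' in the table. Bare cells (zero total biomass share) map to the bare
#' state regardless of the height and LAI arguments.
#'
#' @param table A [state_table].
#' @param shares Named biomass shares (see [composition_class()]).
#' @param height Dominant height in metres.
#' @param lai Leaf area index.
#' @return The integer state id.
#' @export
classify <- function(table, shares, height, lai) {
  stopifnot(inherits(table, "state_table"))
  comp <- composition_class(shares, table$pool)
  if (comp$kind == "bare") {
    h <- 0L; l <- 0L
  } else {
    h <- height_class(height, table$n_height_classes)
    l <- lai_class(lai)
  }
  key <- state_key(comp, h, l)
  id <- table$key2id[[key]]
  if (is.null(id)) {
    if (table$mode == "closed")
      stop("unknown state ", key, " in closed-mode table")
    id <- register_state(table, comp, h, l)
  }
  id
}

#' Decode a state id
#' @param table A [state_table].
#' @param state_id Integer id in `0:(n_states(table)-1)`.
#' @return The `vegetation_state` object.
#' @export
decode_state <- function(table, state_id) {
  if (state_id < 0L || state_id >= n_states(table))
    stop("state_id ", state_id, " not registered")
  table$states[[as.integer(state_id) + 1L]]
}

#' @export
print.vegetation_state <- function(x, ...) {
  cat("<state ", x$state_id, "> ",
      state_key(x$composition, x$height_class, x$lai_class), "\n", sep = "")
  invisible(x)
}

#' Per-state species weights
#'
#' For each registered state, the weight it contributes to neighbourhood
#' species shares: 1 for the dominant of a dominated state, 1/k for each
#' member of a k-species mixture, 0 everywhere else (and for bare).
#'
#' @param table A [state_table].
#' @return Numeric matrix `n_states x pool size`, species in pool order.
#' @export
state_species_weights <- function(table) {
  P <- length(table$pool$species)
  W <- matrix(0, nrow = n_states(table), ncol = P,
              dimnames = list(NULL, table$pool$species))
  for (st in table$states) {
    m <- st$composition$members
    if (length(m)) W[st$state_id + 1L, m] <- 1 / length(m)
  }
  W
}

#' Size of the full combinatorial state space
#'
#' Counts composition classes under the implemented rule (bare, one
#' dominated class per species, and all mixtures of one to four species)
#' and multiplies by the number of height and LAI classes. The
#' composition factor can be overridden so that an externally given
#' per-axis factor is used verbatim; with `n_composition = 6597`,
#' `n_height_classes = 26` and `n_lai_classes = 3` the total is 514,566.
#'
#' @param pool_size Number of species in the pool (`>= 1`).
#' @param n_height_classes,n_lai_classes Per-axis class counts.
#' @param n_composition Optional override for the composition factor.
#' @param max_mixture Largest mixture size under the implemented rule
#'   (4: five shares each above 20% cannot sum to at most 1).
#' @return A list with `count`, `n_composition`, `n_height_classes` and
#'   `n_lai_classes`. `count` is a double, exact up to 1e9.
#' @export
#' @examples
#' enumerate_state_space(20, n_composition = 6597)$count  # 514566
enumerate_state_space <- function(pool_size, n_height_classes = 26L,
                                  n_lai_classes = 3L, n_composition = NULL,
                                  max_mixture = 4L) {
  stopifnot(pool_size >= 1L)
  if (is.null(n_composition)) {
    k <- seq_len(min(max_mixture, pool_size))
    n_composition <- 1 + pool_size + sum(choose(pool_size, k))
  }
  list(count = n_composition * n_height_classes * n_lai_classes,
       n_composition = n_composition,
       n_height_classes = as.integer(n_height_classes),
       n_lai_classes = as.integer(n_lai_classes))
}

#' Write a state table to CSV
#'
#' Columns: `state_id`, `composition_kind`, `members` ("+"-joined codes
#' in pool order, empty for bare), `height_class`, `lai_class`. Rows are
#' ordered by state id. The species pool is not stored in the file and
#' must be supplied again when reading.
#'
#' @param table A [state_table].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_state_table <- function(table, path) {
  stopifnot(inherits(table, "state_table"))
  df <- data.frame(
    state_id = vapply(table$states, `[[`, integer(1), "state_id"),
    composition_kind = vapply(table$states,
                              function(s) s$composition$kind, character(1)),
    members = vapply(table$states, function(s)
      paste(s$composition$members, collapse = "+"), character(1)),
    height_class = vapply(table$states, `[[`, integer(1), "height_class"),
    lai_class = vapply(table$states, `[[`, integer(1), "lai_class"),
    stringsAsFactors = FALSE)
  df <- df[order(df$state_id), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a state table from CSV
#'
#' Inverse of [write_state_table()]. Ids must be dense `0:(N-1)` with no
#' duplicates and all member codes must exist in `pool`.
#'
#' @param path CSV file written by [write_state_table()].
#' @param pool The [species_pool] the table was built with.
#' @param n_height_classes,n_lai_classes Axis sizes of the table.
#' @param mode Table mode, see [state_table()].
#' @return A [state_table].
#' @export
read_state_table <- function(path, pool, n_height_classes = 26L,
                             n_lai_classes = 3L, mode = c("open", "closed")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(members = "character"))
  req <- c("state_id", "composition_kind", "members",
           "height_class", "lai_class")
  if (!all(req %in% names(df)))
    stop("state table file lacks required columns: ",
         paste(setdiff(req, names(df)), collapse = ", "))
  if (anyDuplicated(df$state_id))
    stop("duplicate state_id in state table file")
  df <- df[order(df$state_id), ]
  if (!identical(as.integer(df$state_id), seq_len(nrow(df)) - 1L))
    stop("state ids must be dense 0..N-1")
  tab <- state_table(pool, n_height_classes, n_lai_classes, mode = "open")
  for (i in seq_len(nrow(df))) {
    kind <- df$composition_kind[i]
    members <- if (nzchar(df$members[i]))
      strsplit(df$members[i], "+", fixed = TRUE)[[1]] else character(0)
    bad <- setdiff(members, pool$species)
    if (length(bad))
      stop("species code(s) not in pool: ", paste(bad, collapse = ", "))
    if (kind == "dominated" && length(members) != 1L)
      stop("dominated state must have exactly one member (row ", i, ")")
    if (kind == "mixture" && !(length(members) %in% 1:4))
      stop("mixture must have 1-4 members (row ", i, ")")
    members <- pool$species[pool$species %in% members]  # pool order
    comp <- structure(list(kind = kind, members = members),
                      class = "composition_class")
    id <- register_state(tab, comp, df$height_class[i], df$lai_class[i])
    if (id != df$state_id[i])
      stop("state table rows are not consistent with dense registration")
  }
  tab$mode <- match.arg(mode)
  tab
}
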