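# Time-invariant site rasters at 100 m grain.

#' Create a site grid
#'
#' Bundles the congruent, time-invariant rasters of a simulated
#' landscape: soil depth, soil fertility, climate region id and the
#' active mask (cells outside the simulated area are inactive). Cell
#' size is fixed at 100 m, i.e. one hectare per cell.
#'
#' @param soil_depth Numeric matrix, cm.
#' @param soil_fertility Numeric matrix, unitless index in `[0, 1]`.
#' @param region Integer matrix of climate region ids (default all 1).
#' @param active Logical matrix; `NA` site values also deactivate cells.
#' @return An object of class `site_grid`.
#' @export
site_grid <- function(soil_depth, soil_fertility, region = NULL,
                      active = NULL) {
  soil_depth <- as.matrix(soil_depth)
  soil_fertility <- as.matrix(soil_fertility)
  d <- dim(soil_depth)
  if (!identical(d, dim(soil_fertility)))
    stop("site rasters must be congruent")
  if (is.null(region)) region <- matrix(1L, d[1], d[2])
  if (is.null(active)) active <- matrix(TRUE, d[1], d[2])
  region <- matrix(as.integer(region), d[1], d[2])
  active <- matrix(as.logical(active), d[1], d[2])
  active <- active & is.finite(soil_depth) & is.finite(soil_fertility) &
    !is.na(region)
  structure(list(rows = d[1], cols = d[2], cell_size = 100,
                 soil_depth = soil_depth, soil_fertility = soil_fertility,
                 region = region, active = active),
            class = "site_grid")
}

#' @export
print.site_grid <- function(x, ...) {
  cat("<site_grid>", x$rows, "x", x$cols, "cells (",
      sum(x$active), "active ),", length(unique(x$region[x$active])),
      "climate region(s)\n")
  invisible(x)
}

#' Generate a random site grid
#'
#' Soil depth is drawn uniformly between `depth_range` values, fertility
#' uniformly in `fert_range`; spatial autocorrelation is deliberately
#' absent (site effects in the synthetic kernel are mild). Regions split
#' the grid into `n_regions` horizontal bands of equal height.
#'
#' @param rows,cols Grid dimensions.
#' @param n_regions Number of climate regions (horizontal bands).
#' @param depth_range,fert_range Ranges for the two soil rasters.
#' @param seed Integer seed.
#' @return A [site_grid].
#' @export
make_site_grid <- function(rows, cols, n_regions = 1L,
                           depth_range = c(30, 150),
                           fert_range = c(0.2, 1), seed = 1L) {
  set.seed(as.integer(seed))
  sd_ <- matrix(stats::runif(rows * cols, depth_range[1], depth_range[2]),
                rows, cols)
  sf <- matrix(stats::runif(rows * cols, fert_range[1], fert_range[2]),
               rows, cols)
  band <- pmin(n_regions, 1L + (seq_len(rows) - 1L) %/%
                 max(1L, ceiling(rows / n_regions)))
  region <- matrix(as.integer(band), rows, cols)
  site_grid(sd_, sf, region = region)
}
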