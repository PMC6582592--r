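# Monthly climate series per climate region.

#' Generate a synthetic monthly climate series
#'
#' Produces monthly mean temperature and precipitation sums per climate
#' region and calendar year: a region mean plus a seasonal sine cycle
#' plus white noise (temperature), and a baseline scaled by a seasonal
#' cycle with multiplicative noise, floored at zero (precipitation).
#' Only the transition classifier consumes the monthly resolution; the
#' synthetic truth kernel works from annual means, which builds realistic
#' redundancy into the predictors.
#'
#' @param years Integer vector of calendar years to cover.
#' @param region_temp Named (or unnamed) numeric vector of region annual
#'   mean temperatures in degrees C; one region per element.
#' @param region_precip Annual precipitation totals in mm per region
#'   (recycled; default 1000).
#' @param seasonal_amplitude Half-range of the seasonal temperature
#'   cycle in degrees C (default 8).
#' @param temp_sd Standard deviation of monthly temperature noise
#'   (default 1).
#' @param interannual_sd Standard deviation of a shared year effect on
#'   temperature (default 0.5 degrees C), the year-to-year variability of
#'   annual means.
#' @param trend Linear warming trend in degrees C per year (default 0);
#'   climate-change scenarios differ in this term.
#' @param precip_cv Coefficient of variation of monthly precipitation
#'   noise (default 0.3).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `region`, `year`, `month`,
#'   `tmean`, `precip`, of class `c("climate_table", "data.frame")`.
#' @export
make_climate <- function(years, region_temp, region_precip = 1000,
                         seasonal_amplitude = 8, temp_sd = 1,
                         interannual_sd = 0.5, trend = 0,
                         precip_cv = 0.3, seed = 1L) {
  stopifnot(length(years) >= 1L, length(region_temp) >= 1L)
  region_precip <- rep_len(region_precip, length(region_temp))
  set.seed(as.integer(seed))
  n_reg <- length(region_temp)
  years <- as.integer(years)
  year_effect <- stats::rnorm(length(years), 0, interannual_sd) +
    trend * (years - years[1])
  names(year_effect) <- years
  grid <- expand.grid(month = 1:12, year = years, region = seq_len(n_reg))
  season <- -cos(2 * pi * (grid$month - 0.5) / 12)  # peak in July
  tmean <- region_temp[grid$region] + seasonal_amplitude * season +
    year_effect[as.character(grid$year)] +
    stats::rnorm(nrow(grid), 0, temp_sd)
  pbase <- region_precip[grid$region] / 12
  precip <- pmax(0, pbase * (1 + 0.3 * season) *
                   (1 + stats::rnorm(nrow(grid), 0, precip_cv)))
  out <- data.frame(region = grid$region, year = grid$year,
                    month = grid$month, tmean = tmean, precip = precip)
  out <- out[order(out$region, out$year, out$month), ]
  rownames(out) <- NULL
  class(out) <- c("climate_table", "data.frame")
  out
}

#' Annual mean temperature per region and year
#'
#' @param climate A climate table as produced by [make_climate()] or
#'   [read_climate()].
#' @return A `data.frame` with columns `region`, `year`, `tmean`.
#' @export
annual_mean_temp <- function(climate) {
  validate_climate(climate)
  agg <- stats::aggregate(tmean ~ region + year, data = climate, FUN = mean)
  agg[order(agg$region, agg$year), ]
}

validate_climate <- function(climate) {
  req <- c("region", "year", "month", "tmean", "precip")
  if (!all(req %in% names(climate)))
    stop("climate table needs columns: ", paste(req, collapse = ", "))
  invisible(climate)
}

# Assert that every region covers years [from, to] with all 12 months.
check_climate_coverage <- function(climate, from, to) {
  validate_climate(climate)
  need <- from:to
  for (r in unique(climate$region)) {
    sub <- climate[climate$region == r, ]
    cnt <- table(factor(sub$year, levels = need))
    if (any(cnt < 12L))
      stop("climate region ", r, " does not cover years ", from, "-", to,
           " with 12 months each (first gap: year ",
           need[which(cnt < 12L)[1]], ")")
  }
  invisible(TRUE)
}

#' Read / write a climate table as CSV
#'
#' Plain CSV with columns `region`, `year`, `month`, `tmean`, `precip`.
#'
#' @param path File path.
#' @return `read_climate` returns the climate `data.frame`.
#' @export
read_climate <- function(path) {
  out <- utils::read.csv(path, comment.char = "#")
  validate_climate(out)
  class(out) <- c("climate_table", "data.frame")
  out
}

#' @param climate Climate table to write.
#' @param header Optional comment line (e.g. seed and config hash) to
#'   embed at the top of the file.
#' @rdname read_climate
#' @export
write_climate <- function(climate, path, header = NULL) {
  validate_climate(climate)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(climate, con, row.names = FALSE)
  invisible(path)
}
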