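# Named independent RNG streams (L'Ecuyer-CMRG substreams) so that, e.g.,
# toggling attribute sampling does not perturb the scheduling draws.

#' Create named independent random-number streams
#'
#' Derives one L'Ecuyer-CMRG substream per name from a single master
#' seed. Draws taken on one stream (via [with_stream()]) do not disturb
#' the others, which keeps simulations reproducible when optional
#' features that consume random numbers are switched on or off.
#'
#' @param seed Integer master seed (< 2^31).
#' @param names Character vector of stream names.
#' @return An object of class `rng_streams`.
#' @export
rng_streams <- function(seed, names) {
  stopifnot(length(names) >= 1L, !anyDuplicated(names))
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv())
  e$state <- list()
  for (nm in names) {
    e$state[[nm]] <- s
    s <- parallel::nextRNGStream(s)
  }
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  class(e) <- "rng_streams"
  e
}

#' Evaluate an expression on a named RNG stream
#'
#' Swaps the stream's state into the session RNG, evaluates `expr`, and
#' saves the advanced state back, restoring whatever RNG state the
#' session had before.
#'
#' @param streams An [rng_streams] object.
#' @param name Stream name.
#' @param expr Expression consuming random numbers.
#' @return The value of `expr`.
#' @export
with_stream <- function(streams, name, expr) {
  stopifnot(inherits(streams, "rng_streams"))
  if (is.null(streams$state[[name]])) stop("no RNG stream named ", name)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", streams$state[[name]], envir = globalenv())
  on.exit({
    streams$state[[name]] <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
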