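# Small internal helpers.

# Draw one category per row of a probability matrix (inverse CDF).
# Returns 1-based column indices. Rows are renormalized defensively and
# the last cumulative value forced to 1 so runif can never fall past it.
sample_rows <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  probs <- probs / rowSums(probs)
  cum <- t(apply(probs, 1, cumsum))
  if (nrow(probs) == 1L) cum <- matrix(cum, nrow = 1L)
  cum[, ncol(cum)] <- 1
  u <- stats::runif(nrow(probs))
  max.col(cum >= u, ties.method = "first")
}

# Argmax per row, first-winner tie-break.
row_argmax <- function(m) max.col(m, ties.method = "first")

# Top-k membership: is `truth` (1-based col index) among the k largest
# entries of its row?
row_topk_hit <- function(m, truth, k) {
  vapply(seq_len(nrow(m)), function(i) {
    ord <- order(m[i, ], decreasing = TRUE)[seq_len(min(k, ncol(m)))]
    truth[i] %in% ord
  }, logical(1))
}
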