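# Neighbourhood species shares and edge distance on the 100 m raster.
#
# Tier 1 = the 8 immediately adjacent cells; tier 2 = cells whose centre
# lies within 300 m of the focal cell centre, excluding the focal cell
# and tier 1 (20 cells). Out-of-bounds and inactive cells contribute
# weight 0 but stay in the denominator, so shares shrink near edges.

tier1_offsets <- function() {
  off <- expand.grid(di = -1:1, dj = -1:1)
  off[!(off$di == 0 & off$dj == 0), ]
}

tier2_offsets <- function() {
  off <- expand.grid(di = -3:3, dj = -3:3)
  d2 <- off$di^2 + off$dj^2
  off[d2 <= 9 & d2 > 2, ]  # drop focal (0) and the 8 tier-1 cells (<= 2)
}

# Shift a matrix by (di, dj) with zero fill: result[i, j] = M[i+di, j+dj].
shift_matrix <- function(M, di, dj, fill = 0) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(fill, nr, nc)
  ri <- max(1, 1 - di):min(nr, nr - di)
  rj <- max(1, 1 - dj):min(nc, nc - dj)
  if (length(ri) && length(rj))
    out[ri, rj] <- M[ri + di, rj + dj, drop = FALSE]
  out
}

#' Neighbourhood species-share rasters
#'
#' For every cell and species, the mean species weight over the tier's
#' cells (see [state_species_weights()] for per-state weights). The
#' divisor is the full tier size (8 and 20), so missing neighbours count
#' as zero seed pressure.
#'
#' @param state_mat Integer matrix of state ids (`NA` outside the area).
#' @param active Logical matrix of active cells.
#' @param state_table A [state_table].
#' @return A list with `t1` and `t2`, each an array
#'   `rows x cols x pool size` (species in pool order).
#' @export
share_rasters <- function(state_mat, active, state_table) {
  W <- state_species_weights(state_table)
  P <- ncol(W)
  nr <- nrow(state_mat); nc <- ncol(state_mat)
  o1 <- tier1_offsets(); o2 <- tier2_offsets()
  t1 <- array(0, c(nr, nc, P), dimnames = list(NULL, NULL, colnames(W)))
  t2 <- t1
  for (p in seq_len(P)) {
    Wp <- matrix(0, nr, nc)
    ok <- active & !is.na(state_mat)
    Wp[ok] <- W[state_mat[ok] + 1L, p]
    s1 <- matrix(0, nr, nc); s2 <- matrix(0, nr, nc)
    for (k in seq_len(nrow(o1)))
      s1 <- s1 + shift_matrix(Wp, o1$di[k], o1$dj[k])
    for (k in seq_len(nrow(o2)))
      s2 <- s2 + shift_matrix(Wp, o2$di[k], o2$dj[k])
    t1[, , p] <- s1 / nrow(o1)
    t2[, , p] <- s2 / nrow(o2)
  }
  list(t1 = t1, t2 = t2)
}

# Extract per-cell share matrices (cells x pool) from share_rasters output.
shares_at <- function(sh, cells) {
  P <- dim(sh$t1)[3]
  n <- length(cells)
  m1 <- matrix(0, n, P, dimnames = list(NULL, dimnames(sh$t1)[[3]]))
  m2 <- m1
  nrc <- dim(sh$t1)[1] * dim(sh$t1)[2]
  for (p in seq_len(P)) {
    m1[, p] <- sh$t1[cells + (p - 1L) * nrc]
    m2[, p] <- sh$t2[cells + (p - 1L) * nrc]
  }
  list(t1 = m1, t2 = m2)
}

#' Neighbourhood species shares of one cell
#'
#' Reference per-cell implementation (explicit offset loop), independent
#' of the raster convolution used inside the simulation loop; the two
#' must agree everywhere.
#'
#' @param state_mat Integer matrix of state ids.
#' @param active Logical matrix.
#' @param row,col Focal cell (1-based).
#' @param state_table A [state_table].
#' @return List with named share vectors `t1` and `t2`.
#' @export
neighbourhood_shares <- function(state_mat, active, row, col, state_table) {
  W <- state_species_weights(state_table)
  acc <- function(off) {
    tot <- numeric(ncol(W))
    for (k in seq_len(nrow(off))) {
      i <- row + off$di[k]; j <- col + off$dj[k]
      if (i >= 1 && i <= nrow(state_mat) && j >= 1 && j <= ncol(state_mat) &&
          active[i, j] && !is.na(state_mat[i, j]))
        tot <- tot + W[state_mat[i, j] + 1L, ]
    }
    stats::setNames(tot / nrow(off), colnames(W))
  }
  list(t1 = acc(tier1_offsets()), t2 = acc(tier2_offsets()))
}

#' Distance to the edge of the simulated area
#'
#' Chebyshev cell distance to the nearest inactive or out-of-bounds
#' cell, in metres (cell size 100 m), capped at 1,000 m. A cell on the
#' raster boundary or adjacent to an inactive hole is at 100 m.
#'
#' @param active Logical matrix of active cells.
#' @return Numeric matrix of distances; 0 for inactive cells.
#' @export
edge_distance <- function(active) {
  dist <- matrix(0, nrow(active), ncol(active))
  cur <- active
  o1 <- tier1_offsets()
  for (k in 1:10) {
    dist[cur] <- k * 100
    eroded <- cur
    for (m in seq_len(nrow(o1)))
      eroded <- eroded & shift_matrix(cur, o1$di[m], o1$dj[m], fill = FALSE)
    cur <- eroded
    if (!any(cur)) break
  }
  dist[cur] <- 1000  # everything surviving 10 erosions is at the cap
  dist
}

#' Distance to edge of a single cell (reference implementation)
#'
#' Scans Chebyshev rings outward until an inactive or out-of-bounds
#' cell is found; used to cross-check [edge_distance()].
#'
#' @inheritParams neighbourhood_shares
#' @return Distance in metres, capped at 1,000.
#' @export
edge_distance_at <- function(active, row, col) {
  if (!active[row, col]) return(0)
  for (k in 1:10) {
    ii <- (row - k):(row + k); jj <- (col - k):(col + k)
    ring_has_gap <- any(ii < 1 | ii > nrow(active)) ||
      any(jj < 1 | jj > ncol(active)) ||
      {
        sub <- active[pmax(1, pmin(nrow(active), ii)),
                      pmax(1, pmin(ncol(active), jj)), drop = FALSE]
        !all(sub)
      }
    if (ring_has_gap) return(k * 100)
  }
  1000
}
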