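# Synthetic succession kernel, trajectories, extraction, stationary
# oracle.

test_that("kernel hazard follows the logistic closed form", {
  pool <- fix_pool(2)
  tab <- fix_flat_table(pool)
  kern <- make_truth_kernel(tab, seed = 1, base = 0.4, midpoint = 10,
                            steepness = 0.3, temp_effect = 0.02,
                            temp_ref = 8)
  # independent closed-form evaluation
  h_oracle <- function(R, T_) pmin(1, pmax(0,
    0.4 * plogis(0.3 * (R - 10)) + 0.02 * (T_ - 8)))
  for (R in c(0, 5, 10, 30)) for (T_ in c(4, 8, 12))
    expect_equal(kernel_hazard(kern, 0L, R, T_), h_oracle(R, T_))
  expect_equal(kernel_hazard(kern, 0L, 10L, 8), 0.4 / 2)  # midpoint
  # clamping
  kern2 <- make_truth_kernel(tab, seed = 1, base = 1, midpoint = 0,
                             steepness = 5, temp_effect = 1, temp_ref = 0)
  expect_true(all(kernel_hazard(kern2, 0L, 0:50, 40) <= 1))
})

test_that("target distributions normalize and respect support", {
  pool <- fix_pool(3)
  tab <- example_state_table(pool)
  kern <- make_truth_kernel(tab, seed = 2, neigh_coef = 2, therm_sel = 0.5)
  n <- 20L
  set.seed(3)
  sid <- sample(0:(n_states(tab) - 1L), n, replace = TRUE)
  t1 <- matrix(runif(n * 3), n, 3)
  probs <- kernel_target_distribution(kern, sid, t1, t1 * 0.5,
                                      temp = runif(n, 5, 12))
  expect_equal(rowSums(probs), rep(1, n))
  expect_true(all(probs >= 0))
  hts <- vapply(tab$states, `[[`, integer(1), "height_class")
  for (i in seq_len(n)) {
    sup <- which(probs[i, ] > 0) - 1L
    expect_false(sid[i] %in% sup)                       # no self loop
    expect_true(all(hts[sup + 1L] <= hts[sid[i] + 1L] + 1L))
  }
})

test_that("absorbing and deterministic kernels simulate exactly", {
  pool <- fix_pool(2)
  tab <- fix_flat_table(pool)
  site <- make_site_grid(4, 5, seed = 1)
  climate <- fix_climate(30)
  # hazard 0 everywhere: every cell keeps its state, R counts years
  absorbing <- make_truth_kernel(tab, seed = 1, base = 0)
  tr <- simulate_trajectories(absorbing, site, climate, 20,
                              initial_states = 1L, seed = 2,
                              state_table = tab)
  expect_true(all(tr$states == 1L))
  expect_identical(tr$R[3, ], 0:20)
  # hazard 1 with a single successor: deterministic annual flip
  flip <- make_truth_kernel(tab, seed = 1, base = 1, midpoint = -60,
                            steepness = 1)
  tr2 <- simulate_trajectories(flip, site, climate, 9,
                               initial_states = 0L, seed = 3,
                               state_table = tab)
  expect_identical(tr2$states[1, ], rep(c(0L, 1L), 5))
  expect_true(all(tr2$R[, 2:10] == 0L))
})

test_that("trajectories obey the residence-time bookkeeping law", {
  pool <- fix_pool(3)
  tab <- example_state_table(pool)
  kern <- make_truth_kernel(tab, seed = 4, base = 0.3, midpoint = 4,
                            steepness = 0.5, neigh_coef = 1)
  site <- make_site_grid(8, 8, seed = 5)
  climate <- fix_climate(50)
  tr <- simulate_trajectories(kern, site, climate, 40, 1L, seed = 6,
                              state_table = tab)
  dR <- tr$R[, -1] - tr$R[, -41]
  changed <- tr$states[, -1] != tr$states[, -41]
  expect_true(all(dR[!changed] == 1L))
  expect_true(all(tr$R[, -1][changed] == 0L))
  # climate coverage shorter than years + horizon errors
  expect_error(simulate_trajectories(kern, site, fix_climate(20), 40, 1L,
                                     seed = 6, state_table = tab),
               "does not cover")
})

test_that("extraction labels match a brute-force per-cell scan", {
  pool <- fix_pool(3)
  tab <- example_state_table(pool)
  kern <- make_truth_kernel(tab, seed = 7, base = 0.35, midpoint = 3,
                            steepness = 0.6)
  site <- make_site_grid(5, 6, seed = 8)
  climate <- fix_climate(60)
  tr <- simulate_trajectories(kern, site, climate, 50, 2L, seed = 9,
                              state_table = tab)
  ex <- extract_training_examples(tr, site, climate, tab, horizon = 10)
  # every eligible cell-year appears exactly once
  expect_identical(length(ex$dR), nrow(tr$states) * (50L - 10L + 1L))
  # independent event scan, cell by cell and year by year
  for (i in seq_len(nrow(tr$states))) {
    s <- tr$states[i, ]
    for (tcol in seq_len(41)) {
      row <- which(ex$context$cell == tr$cells[i] &
                     ex$context$year == tcol)
      expect_length(row, 1L)
      nxt <- which(s[(tcol + 1):51] != s[tcol])
      if (length(nxt) && nxt[1] <= 10) {
        expect_identical(ex$dR[row], nxt[1])
        expect_identical(ex$S_star[row], s[tcol + nxt[1]])
      } else {
        expect_identical(ex$dR[row], 0L)
        expect_true(is.na(ex$S_star[row]))
      }
    }
  }
  # label consistency: uncensored labels reconstruct the state sequence
  has <- ex$dR > 0L
  i <- match(ex$context$cell, tr$cells)
  for (r in sample(which(has), 200)) {
    stretch <- tr$states[i[r], ex$context$year[r] + 0:(ex$dR[r] - 1L)]
    expect_true(all(stretch == ex$context$state[r]))
    expect_identical(tr$states[i[r], ex$context$year[r] + ex$dR[r]],
                     ex$S_star[r])
  }
  # absorbing cells are always censored
  absorbing <- make_truth_kernel(tab, seed = 1, base = 0)
  tra <- simulate_trajectories(absorbing, site, climate, 30, 2L,
                               seed = 10, state_table = tab)
  exa <- extract_training_examples(tra, site, climate, tab)
  expect_true(all(exa$dR == 0L))
  expect_true(all(is.na(exa$S_star)))
})

test_that("analytic stationary distribution handles the closed forms", {
  pool <- fix_pool(2)
  tab <- fix_flat_table(pool)
  # symmetric two-state chain with equal constant hazards
  sym <- make_truth_kernel(tab, seed = 1, base = 0.4, midpoint = 0,
                           steepness = 0)  # plogis(0) = 1/2 at all R
  st <- analytic_stationary(sym, temp = 8, R_max = 80)
  expect_true(st$converged)
  expect_equal(unname(st$occupancy), c(0.5, 0.5), tolerance = 1e-9)
  # absorbing state soaks up all mass and is reported
  abs2 <- make_truth_kernel(tab, seed = 1, base = c(0.5, 0))
  st2 <- analytic_stationary(abs2, temp = 8, R_max = 80)
  expect_identical(st2$absorbing, 1L)
  expect_equal(unname(st2$occupancy[2]), 1, tolerance = 1e-6)
})

test_that("simulated occupancy converges to the stationary oracle", {
  pool <- fix_pool(3)
  tab <- fix_flat_table(pool)
  kern <- make_truth_kernel(tab, seed = 12, base = c(0.3, 0.15, 0.25),
                            midpoint = c(5, 12, 8),
                            steepness = c(0.4, 0.2, 0.3))
  stat <- analytic_stationary(kern, temp = 8, R_max = 120)
  site <- make_site_grid(40, 50, seed = 13)
  climate <- fix_climate(260, temp_sd = 0, interannual_sd = 0)
  set.seed(14)
  init <- matrix(sample(0:2, 2000, TRUE), 40, 50)
  tr <- simulate_trajectories(kern, site, climate, 250, init, seed = 15,
                              state_table = tab)
  occ <- tabulate(tr$states[, 251] + 1L, 3) / 2000
  se <- sqrt(stat$occupancy * (1 - stat$occupancy) / 2000)
  expect_true(all(abs(occ - stat$occupancy) <= 3 * se + 1e-9))
})
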