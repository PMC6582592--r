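# Raster engine: neighbourhood shares, edge distance, scheduling, the
# annual step, full runs and summaries.

test_that("tier offsets have the documented sizes", {
  expect_identical(nrow(vegtrans:::tier1_offsets()), 8L)
  expect_identical(nrow(vegtrans:::tier2_offsets()), 20L)
})

test_that("neighbourhood shares match the per-cell reference", {
  pool <- fix_pool(3)
  tab <- example_state_table(pool)
  piab_id <- classify(tab, c(piab = 1), 5, 3)
  nr <- 7L; nc <- 7L
  active <- matrix(TRUE, nr, nc)
  # all eight neighbours dominated by piab -> tier-1 share 1
  smat <- matrix(piab_id, nr, nc)
  sh <- neighbourhood_shares(smat, active, 4, 4, tab)
  expect_equal(unname(sh$t1["piab"]), 1)
  expect_equal(unname(sh$t1["fasy"]), 0)
  # corner cell has only three in-bounds neighbours: 3/8
  shc <- neighbourhood_shares(smat, active, 1, 1, tab)
  expect_equal(unname(shc$t1["piab"]), 3 / 8)
  # tier 2 of a centre cell in a uniform landscape is saturated
  expect_equal(unname(sh$t2["piab"]), 1)
  # random fixture: raster computation equals the per-cell loop
  set.seed(41)
  smat2 <- matrix(sample(0:(n_states(tab) - 1L), nr * nc, TRUE), nr, nc)
  active2 <- matrix(runif(nr * nc) > 0.15, nr, nc)
  smat2[!active2] <- NA_integer_
  ras <- share_rasters(smat2, active2, tab)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ref <- neighbourhood_shares(smat2, active2, i, j, tab)
    expect_equal(unname(ras$t1[i, j, ]), unname(ref$t1), tolerance = 1e-12)
    expect_equal(unname(ras$t2[i, j, ]), unname(ref$t2), tolerance = 1e-12)
  }
})

test_that("edge distance is capped Chebyshev distance to non-area", {
  active <- matrix(TRUE, 21, 21)
  d <- edge_distance(active)
  expect_equal(d[1, 1], 100)     # boundary cell
  expect_equal(d[11, 11], 1000)  # centre of a 21 x 21 block hits the cap
  active2 <- matrix(TRUE, 9, 9)
  active2[5, 5] <- FALSE         # inactive hole
  d2 <- edge_distance(active2)
  expect_equal(d2[5, 6], 100)
  expect_equal(d2[5, 5], 0)
  # matrix version equals the ring-scan reference everywhere
  set.seed(42)
  a3 <- matrix(runif(30 * 25) > 0.1, 30, 25)
  d3 <- edge_distance(a3)
  for (i in seq_len(30)) for (j in seq_len(25))
    expect_equal(d3[i, j], edge_distance_at(a3, i, j))
})

test_that("schedule sampling maps classes to offsets", {
  p <- matrix(0, 3, 11)
  p[1, 4] <- 1  # class 3 -> offset 3
  p[2, 1] <- 1  # censored -> none
  p[3, 11] <- 1
  set.seed(43)
  off <- sample_schedule(p)
  expect_identical(off, c(3L, NA_integer_, 10L))
  # uniform head: frequencies uniform within binomial error
  set.seed(44)
  u <- matrix(1 / 11, 10000, 11)
  offs <- sample_schedule(u)
  cnt <- table(factor(offs, 1:10))
  expect_true(all(abs(cnt / 10000 - 1 / 11) < 3 * sqrt(0.09 / 10000) + 0.01))
  expect_equal(mean(is.na(offs)), 1 / 11, tolerance = 0.015)
})

test_that("the annual step obeys the residence and conservation laws", {
  pool <- fix_pool(2)
  tab <- fix_flat_table(pool)
  site <- make_site_grid(6, 6, seed = 45)
  site$active[1, ] <- FALSE
  climate <- fix_climate(40)
  streams <- rng_streams(46, c("schedule", "state", "attribute"))
  at <- annual_mean_temp(climate)
  # absorbing model: nothing is ever scheduled, R just advances
  absorbing <- tabulate_kernel(make_truth_kernel(tab, seed = 1, base = 0),
                               temp = 8)
  ls <- init_landscape(site, 0L, year = 1L)
  ls1 <- step_landscape(ls, absorbing, climate, 2L, tab,
                        streams = streams, annual_temp = at)
  expect_true(all(ls1$state[site$active] == 0L))
  expect_true(all(ls1$R[site$active] == 1L))
  expect_true(all(is.na(ls1$state[!site$active])))
  # deterministic flip: hazard 1, single successor
  flip <- tabulate_kernel(make_truth_kernel(tab, seed = 1, base = 1,
                                            midpoint = -60, steepness = 1),
                          temp = 8)
  ls <- init_landscape(site, 0L, year = 1L)
  shares <- share_rasters(ls$state, site$active, tab)
  cells <- which(site$active)
  ctx <- vegtrans:::build_context(ls, cells, 1L, shares, at)
  pred <- predict(flip, ctx)
  ls$sched[cells] <- 1L + with_stream(streams, "schedule",
                                      sample_schedule(pred$p_dR))
  ls$last_query[cells] <- 1L
  ls2 <- step_landscape(ls, flip, climate, 2L, tab, streams = streams,
                        annual_temp = at)
  expect_true(all(ls2$state[site$active] == 1L))
  expect_true(all(ls2$R[site$active] == 0L))
})

test_that("runs conserve cells, obey the residence law, and reproduce", {
  pool <- fix_pool(3)
  tab <- fix_flat_table(pool)
  kern <- make_truth_kernel(tab, seed = 47, base = 0.3, midpoint = 4,
                            steepness = 0.5)
  driver <- tabulate_kernel(kern, temp = 8, R_max = 100)
  site <- make_site_grid(15, 15, seed = 48)
  site$active[1:3, 1:3] <- FALSE
  climate <- fix_climate(80, temp_sd = 0, interannual_sd = 0)
  set.seed(49)
  init <- matrix(sample(0:2, 225, TRUE), 15, 15)
  ls0 <- init_landscape(site, init, year = 1L)
  # years = 0: outputs the initial state only
  b0 <- run_simulation(ls0, driver, climate, 0, tab, seed = 50)
  expect_identical(nrow(b0$occupancy), 1L)
  expect_identical(b0$snapshots[["1"]], ls0$state)
  # bit-identical outputs under an identical seed
  b1 <- run_simulation(ls0, driver, climate, 40, tab, seed = 51,
                       output_every = 10)
  b2 <- run_simulation(ls0, driver, climate, 40, tab, seed = 51,
                       output_every = 10)
  expect_identical(b1$occupancy, b2$occupancy)
  expect_identical(b1$snapshots, b2$snapshots)
  expect_identical(b1$landscape$R, b2$landscape$R)
  b3 <- run_simulation(ls0, driver, climate, 40, tab, seed = 52,
                       output_every = 10)
  expect_false(identical(b1$occupancy, b3$occupancy))
  # attribute sampling must not perturb the transition draws
  rec <- data.frame(state_id = rep(0:2, each = 4),
                    residence_time = rep(c(0, 5), 6),
                    attribute = "live_carbon", value = runif(12, 10, 50))
  db <- build_attribute_db(rec)
  b4 <- run_simulation(ls0, driver, climate, 40, tab, seed = 51,
                       output_every = 10, attribute_db = db)
  expect_identical(b1$snapshots, b4$snapshots)
  expect_true(all(is.finite(b4$landscape$attributes$live_carbon[site$active])))
  # step-by-step residence law
  streams <- rng_streams(53, c("schedule", "state", "attribute"))
  at <- annual_mean_temp(climate)
  ls <- b1$landscape
  for (y in ls$year + 1:5) {
    prev_state <- ls$state; prev_R <- ls$R
    ls <- step_landscape(ls, driver, climate, y, tab, streams = streams,
                         annual_temp = at)
    act <- site$active
    moved <- ls$state[act] != prev_state[act]
    expect_true(all(ls$R[act][moved] == 0L))
    expect_true(all(ls$R[act][!moved] == prev_R[act][!moved] + 1L))
    expect_identical(sum(act), 216L)  # conservation
  }
})

test_that("landscape summaries rank composition classes with 'other'", {
  # 30 composition classes, known frequency ranking
  pool <- species_pool(sprintf("sp%02d", 1:30))
  tab <- state_table(pool)
  for (sp in pool$species)
    register_state(tab, composition_class(stats::setNames(1, sp), pool),
                   0L, 0L)
  freqs <- 30:1
  states <- rep(0:29, times = freqs)  # state i appears 30 - i times
  site <- make_site_grid(15, 31, seed = 54)
  ls <- init_landscape(site, matrix(states, 15, 31), year = 1L)
  s <- landscape_summary(ls, tab, n_top = 18)
  expect_length(s$composition, 19L)
  expect_identical(names(s$composition)[1], "D:sp01")
  expect_identical(names(s$composition)[19], "other")
  # independent hand ranking
  tally <- sort(table(states), decreasing = TRUE) / length(states)
  expect_equal(unname(s$composition["other"]),
               unname(sum(tally[19:30])), tolerance = 1e-12)
  expect_equal(sum(s$composition), 1)
  expect_equal(sum(s$height), 1)
  expect_equal(sum(s$lai), 1)
  # uniform landscape: one class at frequency 1
  ls2 <- init_landscape(site, 3L, year = 1L)
  s2 <- landscape_summary(ls2, tab)
  expect_identical(unname(s2$composition), 1)
  expect_identical(names(s2$composition), "D:sp04")
})
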