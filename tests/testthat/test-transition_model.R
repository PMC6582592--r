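# Feature building, tabulated and neural models, evaluation.

test_that("feature layout matches the declared schema arithmetic", {
  pool <- fix_pool(3)
  tab <- example_state_table(pool)
  schema <- feature_schema(tab)
  nS <- n_states(tab)
  expect_length(schema$columns, nS + 1 + 2 + 240 + 2 * 3 + 1)
  sch24 <- feature_schema(tab, "decadal")
  expect_length(sch24$columns, nS + 1 + 2 + 24 + 2 * 3 + 1)
  climate <- fix_climate(20)
  ctx <- fix_context(4, pool, state = c(0L, 1L, 2L, 5L), R = 0:3)
  X <- build_features(ctx, climate, schema)
  expect_identical(dim(X), c(4L, length(schema$columns)))
  expect_true(all(is.finite(X)))
  # determinism: identical contexts give identical vectors
  expect_identical(X[1, ], build_features(ctx[1, ], climate, schema)[1, ])
  # one-hot block is exactly one per row
  expect_equal(unname(rowSums(X[, 1:nS])), rep(1, 4))
  # missing climate months error
  expect_error(build_features(fix_context(1, pool, year = 50L),
                              fix_climate(20), schema),
               "climate window incomplete")
  # unknown state errors
  bad <- fix_context(1, pool, state = 99L)
  expect_error(build_features(bad, climate, schema), "state ids")
})

test_that("the scaler standardizes exactly the scaled block", {
  pool <- fix_pool(2)
  tab <- fix_flat_table(pool)
  schema <- feature_schema(tab, "decadal")
  climate <- fix_climate(30)
  set.seed(21)
  ctx <- fix_context(200, pool, state = sample(0:1, 200, TRUE),
                     R = sample(0:40, 200, TRUE),
                     year = sample(1:15, 200, TRUE))
  ctx$soil_depth <- runif(200, 30, 150)
  ctx$soil_fertility <- runif(200)
  ctx$edge_dist <- sample(c(100, 300, 700), 200, TRUE)
  X <- build_features(ctx, climate, schema)
  sc <- fit_scaler(X, schema)
  Xs <- build_features(ctx, climate, schema, sc)
  j <- match(schema$scaled_columns, colnames(Xs))
  expect_equal(unname(colMeans(Xs[, j])), rep(0, length(j)),
               tolerance = 1e-10)
  expect_equal(unname(apply(Xs[, j], 2, sd)), rep(1, length(j)),
               tolerance = 1e-10)
  # share columns are untouched
  expect_identical(Xs[, "t1_piab"], X[, "t1_piab"])
  # schema hash mismatch is refused
  sc$hash <- "bogus"
  expect_error(build_features(ctx, climate, schema, sc),
               "different feature schema")
})

test_that("tabulated model reproduces hand-counted conditionals", {
  pool <- fix_pool(2)
  tab <- fix_flat_table(pool)
  # 20-row fixture keyed on (state, R): hand-countable
  ctx <- fix_context(20, pool,
                     state = rep(c(0L, 1L), each = 10),
                     R = rep(c(0L, 0L, 5L, 5L), 5))
  dR <- c(rep(1L, 6), rep(0L, 4), rep(3L, 8), 2L, 2L)
  S_star <- ifelse(dR == 0L, NA_integer_, rep(c(1L, 0L), each = 10))
  ex <- fix_examples(ctx, dR, S_star, tab)
  m <- fit_tabulated(ex, keys = c("state", "R"))
  # hand count for key state 0, R 0: rows 1,2,5,6,9,10 -> dR 1,1,0,0,1,1
  p <- predict(m, fix_context(1, pool, state = 0L, R = 0L))
  expect_equal(p$p_dR[1, 2], 4 / 6)
  expect_equal(p$p_dR[1, 1], 2 / 6)
  expect_equal(p$p_state[1, 2], 1)  # every state-0 transition went to 1
  # single-example table is a point mass
  m1 <- fit_tabulated(subset_examples(ex, 1), keys = c("state", "R"))
  p1 <- predict(m1, fix_context(1, pool, state = 0L, R = 0L))
  expect_equal(p1$p_dR[1, 2], 1)
  # unseen key backs off to the marginal
  pm <- predict(m, fix_context(1, pool, state = 1L, R = 99L))
  expect_equal(unname(pm$p_dR[1, ]),
               as.numeric(table(factor(dR, 0:10))) / 20, tolerance = 1e-12)
})

test_that("tabulated model keyed on truth inputs approaches Bayes", {
  pool <- fix_pool(3)
  tab <- fix_flat_table(pool)
  kern <- make_truth_kernel(tab, seed = 22, base = 0.35, midpoint = 4,
                            steepness = 0.5)
  site <- make_site_grid(40, 50, seed = 23)
  climate <- fix_climate(70, temp_sd = 0.5, interannual_sd = 0)
  tr <- simulate_trajectories(kern, site, climate, 60, 0L, seed = 24,
                              state_table = tab)
  ex <- extract_training_examples(tr, site, climate, tab)  # 102,000 rows
  m <- fit_tabulated(ex, keys = c("state", "R"), R_cap = 40)
  truth <- kernel_model(kern)
  met <- evaluate_model(m, ex, climate, reference = truth)
  expect_lt(met$mean_tv_state, 0.02)
  # 11-way timing head carries more per-key sampling noise at ~800
  # examples per (state, R) key
  expect_lt(met$mean_tv_dR, 0.03)
})

test_that("evaluation metrics behave on exact and shuffled labels", {
  pool <- fix_pool(2)
  tab <- fix_flat_table(pool)
  # deterministic mapping: state 0 always transits to 1 at dR = 3
  set.seed(25)
  n <- 400L
  ctx <- fix_context(n, pool, state = rep(c(0L, 1L), n / 2),
                     R = sample(0:5, n, TRUE))
  dR <- ifelse(ctx$state == 0L, 3L, 5L)
  S_star <- ifelse(ctx$state == 0L, 1L, 0L)
  ex <- fix_examples(ctx, dR, S_star, tab)
  m <- fit_tabulated(ex, keys = "state")
  met <- evaluate_model(m, ex)
  expect_equal(met$top1_dR, 1)
  expect_equal(met$top1_state, 1)
  expect_equal(met$top3_state, 1)
  expect_gte(met$top3_state, met$top1_state)
  # label shuffling pushes accuracy to the majority-class rate
  set.seed(26)
  ex_shuf <- ex
  ex_shuf$dR <- sample(c(rep(3L, 260), rep(5L, 140)))
  m2 <- fit_tabulated(ex_shuf, keys = "state")
  met2 <- evaluate_model(m2, ex_shuf)
  expect_equal(met2$top1_dR, 260 / 400, tolerance = 0.08)
})

test_that("the neural model learns a deterministic mapping exactly", {
  pool <- fix_pool(2)
  tab <- fix_flat_table(pool)
  climate <- fix_climate(20)
  set.seed(27)
  n <- 600L
  ctx <- fix_context(n, pool, state = sample(0:1, n, TRUE),
                     R = sample(0:8, n, TRUE),
                     year = sample(1:5, n, TRUE))
  dR <- ifelse(ctx$state == 0L, 3L, 0L)
  S_star <- ifelse(ctx$state == 0L, 1L, NA_integer_)
  ex <- fix_examples(ctx, dR, S_star, tab)
  cfg <- mlp_config(hidden = c(16, 16), dropout = 0, epochs = 40,
                    batch_size = 64, learning_rate = 3e-3,
                    climate_encoding = "decadal")
  m <- fit_dnn(ex, climate, tab, config = cfg, seed = 28)
  met <- evaluate_model(m, ex, climate)
  expect_equal(met$top1_dR, 1)
  expect_equal(met$top1_state, 1)
  # seeded training is reproducible
  m2 <- fit_dnn(ex, climate, tab, config = cfg, seed = 28)
  p1 <- predict(m, ex$context, climate)
  p2 <- predict(m2, ex$context, climate)
  expect_identical(p1, p2)
  # predictions are normalized distributions
  expect_equal(rowSums(p1$p_dR), rep(1, n), tolerance = 1e-9)
  expect_equal(rowSums(p1$p_state), rep(1, n), tolerance = 1e-9)
  # states unseen in training carry zero probability
  expect_true(all(p1$p_state[, setdiff(1:2, 2)] == 0))
})

test_that("models survive JSON serialization round trips", {
  pool <- fix_pool(2)
  tab <- fix_flat_table(pool)
  climate <- fix_climate(20)
  set.seed(29)
  ctx <- fix_context(120, pool, state = sample(0:1, 120, TRUE),
                     R = sample(0:5, 120, TRUE))
  dR <- sample(0:10, 120, TRUE)
  S_star <- ifelse(dR == 0, NA_integer_, sample(0:1, 120, TRUE))
  ex <- fix_examples(ctx, dR, S_star, tab)
  for (two in c(FALSE, TRUE)) {
    cfg <- mlp_config(hidden = c(8, 8), dropout = 0, epochs = 2,
                      climate_encoding = "decadal", two_networks = two)
    m <- fit_dnn(ex, climate, tab, config = cfg, seed = 30)
    f <- withr::local_tempfile(fileext = ".json")
    save_model(m, f)
    m2 <- load_model(f)
    pa <- predict(m, ctx, climate); pb <- predict(m2, ctx, climate)
    expect_equal(pa$p_dR, pb$p_dR, tolerance = 1e-12)
    expect_equal(pa$p_state, pb$p_state, tolerance = 1e-12)
  }
  tm <- fit_tabulated(ex, keys = c("state", "R"))
  f2 <- withr::local_tempfile(fileext = ".json")
  save_model(tm, f2)
  tm2 <- load_model(f2)
  pa <- predict(tm, ctx); pb <- predict(tm2, ctx)
  expect_equal(pa, pb, tolerance = 1e-12)
})
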