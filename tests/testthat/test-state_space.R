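# State-space module: classifiers, table, enumeration, serialization.

test_that("height classifier bins, caps and rejects", {
  expect_identical(height_class(22), 5L)    # the [20, 24) bin
  expect_identical(height_class(0), 0L)
  expect_identical(height_class(103), 25L)  # capped top class
  # cap rule against explicit bin-edge enumeration
  edges <- seq(0, 104, by = 4)
  for (h in c(0, 3.99, 4, 17, 22, 95.9, 99.9, 100, 250)) {
    expected <- min(findInterval(h, edges, left.open = FALSE), 26) - 1L
    expect_identical(height_class(h), as.integer(expected))
  }
  expect_error(height_class(-1), "height")
  # monotone step function
  hs <- sort(runif(200, 0, 130))
  expect_true(all(diff(height_class(hs)) >= 0))
})

test_that("LAI classifier uses left-closed boundaries", {
  expect_identical(lai_class(3), 1L)
  expect_identical(lai_class(2), 0L)   # LAI <= 2 is sparse
  expect_identical(lai_class(4), 1L)   # 2 < LAI <= 4 is moderate
  expect_identical(lai_class(4.0001), 2L)
  expect_error(lai_class(-0.1), "lai")
  ls <- sort(runif(200, 0, 8))
  expect_true(all(diff(lai_class(ls)) >= 0))
})

test_that("composition classifier applies both thresholds", {
  pool <- fix_pool(6)
  cc <- composition_class(c(piab = 0.80, fasy = 0.20), pool)
  expect_identical(cc$kind, "dominated")
  expect_identical(cc$members, "piab")
  expect_identical(composition_class(numeric(0), pool)$kind, "bare")
  cc <- composition_class(c(fasy = 0.50, piab = 0.45, quro = 0.05), pool)
  expect_identical(cc$kind, "mixture")
  expect_setequal(cc$members, c("fasy", "piab"))
  # exactly 66% is not "> 66%"
  cc <- composition_class(c(piab = 0.66, fasy = 0.34), pool)
  expect_identical(cc$kind, "mixture")
  # no species above 20% -> singleton mixture of the argmax
  sh <- stats::setNames(rep(1 / 6, 6), pool$species)
  cc <- composition_class(sh, pool)
  expect_identical(cc$kind, "mixture")
  expect_identical(cc$members, pool$species[1])  # pool-order tie-break
  expect_error(composition_class(c(xxxx = 1), pool), "unknown species")
  expect_error(composition_class(c(piab = 0.9, fasy = 0.2), pool),
               "sum")
})

test_that("composition classification is scale invariant unless bare", {
  pool <- fix_pool(4)
  set.seed(1)
  for (i in 1:50) {
    sh <- stats::setNames(runif(4), pool$species)
    sh <- sh / sum(sh)
    for (k in c(1, 0.5, 0.01)) {
      a <- composition_class(sh, pool)
      b <- composition_class(sh * k, pool)
      expect_identical(a$kind, b$kind)
      expect_identical(a$members, b$members)
    }
  }
  # all-zero shares trigger the bare rule regardless of names
  expect_identical(composition_class(c(piab = 0, fasy = 0), pool)$kind,
                   "bare")
})

test_that("classify composes the three axes and registers in open mode", {
  pool <- fix_pool(3)
  tab <- state_table(pool)
  id <- classify(tab, c(piab = 0.8), 22, 3)
  st <- decode_state(tab, id)
  expect_identical(st$composition$kind, "dominated")
  expect_identical(st$composition$members, "piab")
  expect_identical(st$height_class, 5L)
  expect_identical(st$lai_class, 1L)
  expect_identical(classify(tab, c(piab = 0.8), 22, 3), id)  # determinism
  bare_id <- classify(tab, numeric(0), 0, 0)
  expect_identical(decode_state(tab, bare_id)$composition$kind, "bare")
  # bare forces height/LAI class 0 whatever the raw measurements say
  expect_identical(classify(tab, numeric(0), 30, 5), bare_id)
  tab$mode <- "closed"
  expect_error(classify(tab, c(fasy = 1), 80, 5), "unknown state")
})

test_that("classify/decode are a bijection over registered states", {
  pool <- fix_pool(4)
  tab <- state_table(pool)
  set.seed(7)
  for (i in 1:60) {
    sh <- runif(4) * sample(c(1, 1, 0), 4, TRUE)
    sh <- stats::setNames(sh / max(1, sum(sh)), pool$species)
    classify(tab, sh, runif(1, 0, 110), runif(1, 0, 8))
  }
  lai_mid <- c(1, 3, 5)
  for (st in tab$states) {
    comp <- st$composition
    sh <- if (comp$kind == "bare") numeric(0)
      else stats::setNames(rep(1 / length(comp$members),
                               length(comp$members)), comp$members)
    if (comp$kind == "dominated") sh[] <- 1
    if (comp$kind == "mixture" && length(comp$members) == 1L) {
      # a singleton mixture: its member holds (0.2, 0.66], the rest of
      # the biomass is spread below the 20% threshold
      rest <- setdiff(pool$species, comp$members)
      sh <- stats::setNames(c(0.6, rep(0.4 / length(rest), length(rest))),
                            c(comp$members, rest))
    }
    expect_identical(
      classify(tab, sh, st$height_class * 4 + 1, lai_mid[st$lai_class + 1]),
      st$state_id)
  }
})

test_that("state-space enumeration matches the subset-counting oracle", {
  # independent oracle: brute-force subset enumeration for a small pool
  brute <- function(P) {
    n_mix <- 0L
    for (k in 1:min(4, P)) n_mix <- n_mix + ncol(utils::combn(P, k))
    1L + P + n_mix
  }
  for (P in c(1, 2, 5, 8)) {
    e <- enumerate_state_space(P, n_height_classes = 7, n_lai_classes = 3)
    expect_equal(e$n_composition, brute(P))
    expect_equal(e$count, brute(P) * 7 * 3)
  }
  expect_equal(enumerate_state_space(1, 1, 1)$count, 3)  # bare + dom + mix
  # closed form for the full pool: 1 + P + sum_k C(P, k)
  e20 <- enumerate_state_space(20)
  expect_equal(e20$n_composition, 1 + 20 + sum(choose(20, 1:4)))
  # the override factor is used verbatim
  expect_equal(enumerate_state_space(20, n_composition = 6597)$count,
               6597 * 26 * 3)
})

test_that("state tables round-trip through CSV", {
  pool <- fix_pool(4)
  tab <- state_table(pool)
  set.seed(11)
  for (i in 1:10) {
    sh <- runif(4)
    classify(tab, stats::setNames(sh / sum(sh), pool$species),
             runif(1, 0, 50), runif(1, 0, 6))
  }
  f <- withr::local_tempfile(fileext = ".csv")
  write_state_table(tab, f)
  tab2 <- read_state_table(f, pool)
  expect_identical(n_states(tab2), n_states(tab))
  for (st in tab$states) {
    st2 <- decode_state(tab2, st$state_id)
    expect_identical(st2$composition, st$composition)
    expect_identical(st2$height_class, st$height_class)
    expect_identical(st2$lai_class, st$lai_class)
  }
  # the reloaded table classifies the reference example to the same id
  id1 <- classify(tab, c(piab = 0.8), 22, 3)
  expect_identical(classify(tab2, c(piab = 0.8), 22, 3), id1)
  # duplicate ids are rejected
  df <- utils::read.csv(f, colClasses = c(members = "character"))
  df$state_id[2] <- df$state_id[1]
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_state_table(f, pool), "duplicate")
})
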