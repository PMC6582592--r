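# Standing validation experiments. Each function defines one synthetic
# world (kernel, landscape, climate) and measures one property of the
# pipeline against an oracle; the test suite and the acceptance report
# both run these, so the worlds are defined here once.

#' Oracle-equivalence experiment
#'
#' A three-state kernel with residence-dependent hazards is tabulated
#' exactly and drives the raster engine on 5,000 cells under constant
#' climate; the engine's late-run state occupancy must match the
#' analytic stationary distribution of the (state, residence-time)
#' Markov chain.
#'
#' @param seed Integer seed.
#' @param rows,cols Grid size (default 50 x 100 = 5,000 cells).
#' @param years Simulated years (default 300).
#' @param tail_years Years averaged for the occupancy estimate
#'   (default 50).
#' @return A list with `occupancy_sim`, `occupancy_analytic`,
#'   `max_abs_diff` and the elapsed time.
#' @export
experiment_oracle_equivalence <- function(seed = 1L, rows = 50L,
                                          cols = 100L, years = 300L,
                                          tail_years = 50L) {
  t0 <- Sys.time()
  pool <- species_pool(c("piab", "fasy", "quro"))
  tab <- state_table(pool)
  for (sp in pool$species)
    register_state(tab, composition_class(stats::setNames(1, sp), pool),
                   0L, 0L)
  kern <- make_truth_kernel(tab, seed = seed + 1L,
                            base = c(0.3, 0.15, 0.25),
                            midpoint = c(5, 12, 8),
                            steepness = c(0.4, 0.2, 0.3),
                            temp_effect = 0, logit_sd = 1)
  stat <- analytic_stationary(kern, temp = 8, R_max = 150L)
  site <- make_site_grid(rows, cols, seed = seed + 2L)
  climate <- make_climate(1:(years + 20L), region_temp = 8, temp_sd = 0,
                          interannual_sd = 0, seed = seed + 3L)
  driver <- tabulate_kernel(kern, temp = 8, R_max = 150L)
  set.seed(seed + 4L)
  init <- matrix(sample(0:2, rows * cols, replace = TRUE), rows, cols)
  ls0 <- init_landscape(site, init, year = 1L)
  bundle <- run_simulation(ls0, driver, climate, years, tab,
                           seed = seed + 5L, output_every = 0L)
  tail_idx <- (years - tail_years + 2L):(years + 1L)
  occ <- colMeans(bundle$occupancy[tail_idx, , drop = FALSE])
  list(occupancy_sim = occ, occupancy_analytic = stat$occupancy,
       max_abs_diff = max(abs(occ - stat$occupancy)),
       n_cells = rows * cols, years = years,
       elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

# The 8-state world of the recovery experiment: two species, four
# height classes each, temperature-modified hazards, state-dependent
# targets. Three climate scenarios differ in their warming trend (the
# held-out scenario lies between the training scenarios, as a held-out
# climate-model trajectory would).
recovery_world <- function(seed, rows, cols, years, n_per_scenario,
                           horizon = 10L) {
  pool <- species_pool(c("piab", "fasy"), thermal_optimum = c(6.5, 9.5))
  tab <- state_table(pool)
  lai_of <- c(0L, 1L, 2L, 2L)
  for (sp in pool$species) for (h in 0:3)
    register_state(tab, composition_class(stats::setNames(1, sp), pool),
                   h, lai_of[h + 1L])
  kern <- make_truth_kernel(tab, seed = seed + 1L, base = 0.25,
                            midpoint = 8, steepness = 0.35,
                            temp_effect = 0.015, temp_ref = 8,
                            therm_sel = 0, logit_sd = 1)
  trends <- c(0, 0.03, 0.015)  # degC/yr; scenario 3 is held out
  exs <- list(); clims <- list()
  for (i in 1:3) {
    site <- make_site_grid(rows, cols, seed = seed + 10L + i)
    site$region[] <- i
    climate <- make_climate(1:(years + horizon),
                            region_temp = stats::setNames(7, i),
                            trend = trends[i], seed = seed + 20L + i)
    climate$region <- i
    set.seed(seed + 30L + i)
    init <- matrix(sample(0:(n_states(tab) - 1L), rows * cols,
                          replace = TRUE), rows, cols)
    traj <- simulate_trajectories(kern, site, climate, years, init,
                                  seed = seed + 40L + i,
                                  state_table = tab, scenario = i)
    exs[[i]] <- extract_training_examples(traj, site, climate, tab,
                                          horizon = horizon,
                                          max_examples = n_per_scenario[i],
                                          seed = seed + 50L + i)
    clims[[i]] <- climate
  }
  climate_all <- do.call(rbind, clims)
  class(climate_all) <- c("climate_table", "data.frame")
  list(pool = pool, tab = tab, kern = kern,
       train = bind_examples(exs[[1]], exs[[2]]), test = exs[[3]],
       climate = climate_all)
}

#' Parameter-recovery experiment
#'
#' Trains the neural model on 2 x 10^5 examples from two warming
#' scenarios of an 8-state temperature-dependent kernel and evaluates
#' it on a held-out third scenario against (a) the tabulated Bayes
#' oracle keyed on the kernel's true inputs (state, residence time,
#' annual temperature) and (b) the kernel's exact target distributions
#' (mean total-variation distance).
#'
#' @param seed Integer seed.
#' @param n_train Training examples across the two training scenarios.
#' @param n_test Held-out examples.
#' @param rows,cols,years Per-scenario trajectory dimensions.
#' @param config [mlp_config()] for the neural model. The default uses
#'   two separate trunks and the decadal climate encoder — the
#'   appropriate capacity at this sample size (see the vignette).
#' @return A list with `metrics_dnn`, `metrics_oracle`, `metrics_bayes`
#'   (the kernel evaluated against itself), the top-1 differences and
#'   the elapsed time.
#' @export
experiment_recovery <- function(seed = 1L, n_train = 200000L,
                                n_test = 40000L, rows = 40L, cols = 50L,
                                years = 110L,
                                config = mlp_config(
                                  hidden = c(48, 48), dropout = 0.15,
                                  l2 = 1e-3, epochs = 20L,
                                  batch_size = 512L, lr_decay = 0.92,
                                  climate_encoding = "decadal",
                                  two_networks = TRUE)) {
  t0 <- Sys.time()
  w <- recovery_world(seed, rows, cols, years,
                      n_per_scenario = c(rep(ceiling(n_train / 2), 2),
                                         n_test))
  truth <- kernel_model(w$kern)
  oracle <- fit_tabulated(w$train, keys = c("state", "R", "tmean_annual"),
                          bins = list(tmean_annual = seq(3, 13, 0.5)),
                          R_cap = 60L)
  dnn <- fit_dnn(w$train, w$climate, w$tab, config = config,
                 seed = seed + 60L)
  m_or <- evaluate_model(oracle, w$test, w$climate, reference = truth)
  m_dnn <- evaluate_model(dnn, w$test, w$climate, reference = truth)
  m_bayes <- evaluate_model(truth, w$test, w$climate, reference = truth)
  list(metrics_dnn = m_dnn, metrics_oracle = m_or, metrics_bayes = m_bayes,
       diff_top1_dR = m_dnn$top1_dR - m_or$top1_dR,
       diff_top1_state = m_dnn$top1_state - m_or$top1_state,
       mean_tv_state = m_dnn$mean_tv_state,
       n_train = length(w$train$dR), n_test = length(w$test$dR),
       elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Spatial-context ablation experiment
#'
#' On a kernel whose target states depend only on neighbourhood seed
#' pressure (species-symmetric base weights, so local dominance arises
#' purely from spatial feedback), two identical networks are trained
#' with and without the tier-share features; held-out target-state
#' accuracy must be strictly higher with spatial context.
#'
#' @param seed Integer seed.
#' @param n_examples Total examples (half train, half held-out cell
#'   block).
#' @param rows,cols,years Trajectory dimensions.
#' @param epochs Training epochs for both networks.
#' @return A list with `top1_state_with`, `top1_state_without`,
#'   `advantage` and the elapsed time.
#' @export
experiment_ablation <- function(seed = 1L, n_examples = 60000L,
                                rows = 40L, cols = 50L, years = 100L,
                                epochs = 12L) {
  t0 <- Sys.time()
  pool <- species_pool(c("piab", "fasy", "quro"),
                       thermal_optimum = c(6, 9, 12))
  tab <- example_state_table(pool)
  kern <- make_truth_kernel(tab, seed = seed + 1L, base = 0.25,
                            midpoint = 6, steepness = 0.4,
                            temp_effect = 0, neigh_coef = 4,
                            therm_sel = 0, logit_sd = 0)
  site <- make_site_grid(rows, cols, seed = seed + 2L)
  climate <- make_climate(1:(years + 10L), region_temp = 8,
                          seed = seed + 3L)
  set.seed(seed + 4L)
  init <- matrix(sample(0:(n_states(tab) - 1L), rows * cols,
                        replace = TRUE), rows, cols)
  traj <- simulate_trajectories(kern, site, climate, years, init,
                                seed = seed + 5L, state_table = tab)
  ex <- extract_training_examples(traj, site, climate, tab,
                                  max_examples = n_examples,
                                  seed = seed + 6L)
  hold <- ex$context$cell > rows * cols / 2  # held-out cell block
  train <- subset_examples(ex, !hold)
  test <- subset_examples(ex, hold)
  base_cfg <- list(hidden = c(48, 48), dropout = 0.1, l2 = 1e-4,
                   epochs = epochs, batch_size = 512L, lr_decay = 0.92,
                   climate_encoding = "decadal")
  d_with <- fit_dnn(train, climate, tab,
                    config = do.call(mlp_config, base_cfg),
                    seed = seed + 7L)
  d_without <- fit_dnn(train, climate, tab,
                       config = do.call(mlp_config,
                                        c(base_cfg, use_shares = FALSE)),
                       seed = seed + 7L)
  m_with <- evaluate_model(d_with, test, climate)
  m_without <- evaluate_model(d_without, test, climate)
  list(top1_state_with = m_with$top1_state,
       top1_state_without = m_without$top1_state,
       advantage = m_with$top1_state - m_without$top1_state,
       n_train = length(train$dR), n_test = length(test$dR),
       elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Thermal-gradient zonation experiment
#'
#' A 200 x 50 landscape with a linear 5.5 degree C north-south
#' temperature gradient is initialized with random states from a
#' three-species thermally structured kernel and simulated for 300
#' years with the exact kernel model. Vegetation must self-organize
#' into species bands ordered cold to warm: the Spearman correlation
#' between row index and the thermal optimum of each row's modal
#' dominant species is the zonation statistic.
#'
#' @param seed Integer seed.
#' @param rows,cols Grid size (gradient runs along rows).
#' @param years Simulated years (default 300).
#' @param temp_range Temperature range across rows (default 5.5 C).
#' @return A list with `spearman_rho`, `row_modal_optimum`, the final
#'   landscape's modal species per row and the elapsed time.
#' @export
experiment_gradient <- function(seed = 1L, rows = 200L, cols = 50L,
                                years = 300L, temp_range = 5.5) {
  t0 <- Sys.time()
  pool <- species_pool(c("piab", "fasy", "quro"),
                       thermal_optimum = c(6, 8.25, 10.5))
  tab <- example_state_table(pool)
  kern <- make_truth_kernel(tab, seed = seed + 1L, base = 0.25,
                            midpoint = 6, steepness = 0.4,
                            neigh_coef = 1, therm_sel = 1.2,
                            logit_sd = 0.5)
  site <- make_site_grid(rows, cols, n_regions = rows, seed = seed + 2L)
  temps <- seq(5.5, 5.5 + temp_range, length.out = rows)  # cold -> warm
  climate <- make_climate(1:(years + 15L), region_temp = temps,
                          temp_sd = 0.5, seed = seed + 3L)
  set.seed(seed + 4L)
  init <- matrix(sample(0:(n_states(tab) - 1L), rows * cols,
                        replace = TRUE), rows, cols)
  ls0 <- init_landscape(site, init, year = 1L)
  bundle <- run_simulation(ls0, kernel_model(kern), climate, years, tab,
                           seed = seed + 5L, output_every = 0L)
  fin <- bundle$landscape$state
  dom <- vapply(tab$states, function(s)
    if (length(s$composition$members) == 1L) s$composition$members
    else NA_character_, character(1))
  opt <- pool$thermal_optimum
  modal_sp <- vapply(seq_len(rows), function(i) {
    sp <- dom[fin[i, ] + 1L]
    sp <- sp[!is.na(sp)]
    if (!length(sp)) NA_character_ else names(which.max(table(sp)))
  }, character(1))
  row_opt <- opt[modal_sp]
  rho <- stats::cor(seq_len(rows), row_opt, method = "spearman",
                    use = "complete.obs")
  list(spearman_rho = rho, row_modal_species = modal_sp,
       row_modal_optimum = unname(row_opt), temps = temps,
       elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}
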