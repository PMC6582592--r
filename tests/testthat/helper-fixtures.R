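# Shared fixtures: tiny worlds built in code at test time.

fix_pool <- function(n = 3L) {
  codes <- c("piab", "fasy", "quro", "lade", "abal", "pisy")[seq_len(n)]
  species_pool(codes, thermal_optimum = seq(6, 12, length.out = n))
}

# n dominated states at height 0 / LAI 0 (mutually reachable under the
# height-step rule), optionally plus bare.
fix_flat_table <- function(pool, bare = FALSE) {
  tab <- state_table(pool)
  if (bare)
    register_state(tab, composition_class(numeric(0), pool), 0L, 0L)
  for (sp in pool$species)
    register_state(tab, composition_class(stats::setNames(1, sp), pool),
                   0L, 0L)
  tab
}

fix_climate <- function(years = 60L, temp = 8, regions = 1,
                        seed = 1L, ...) {
  make_climate(1:(years + 12L), region_temp = rep(temp, regions),
               seed = seed, ...)
}

# Minimal hand-built context data.frame accepted by build_features and
# the tabulated models.
fix_context <- function(n, pool, state = 0L, R = 0L, year = 1L,
                        region = 1L, temp = 8) {
  ctx <- data.frame(cell = seq_len(n), year = year, state = state, R = R,
                    soil_depth = 100, soil_fertility = 0.5,
                    region = region, edge_dist = 500, tmean_annual = temp)
  for (sp in pool$species) {
    ctx[[paste0("t1_", sp)]] <- 0
    ctx[[paste0("t2_", sp)]] <- 0
  }
  ctx
}

# Wrap a context + labels into an example_set.
fix_examples <- function(ctx, dR, S_star, state_table, horizon = 10L) {
  structure(list(context = ctx, dR = as.integer(dR),
                 S_star = as.integer(S_star),
                 n_states = n_states(state_table),
                 pool = state_table$pool, horizon = as.integer(horizon)),
            class = "example_set")
}
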