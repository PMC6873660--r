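# Shared fixtures, built once per test run and cached for all test files.

.fixtures <- new.env(parent = emptyenv())

# Desk-scale base world (forward simulation + cultivars); ~10 s, built once.
desk_base_world <- function() {
  if (is.null(.fixtures$bw)) {
    set.seed(560401)
    .fixtures$bw <- build_base_world("desk")
  }
  .fixtures$bw
}

# Desk world with a fresh trait architecture drawn under the given seed.
desk_world <- function(seed = 1) {
  set.seed(seed)
  attach_traits(desk_base_world())
}

# Tiny segregating population: quick mutation-drift burn-in from monomorphic.
toy_pop <- function(n = 400, n_chr = 2, loci = 150, mu = 5e-3, gens = 150,
                    seed = 7) {
  set.seed(seed)
  pop <- founder_population(n, n_chr, loci)
  for (g in seq_len(gens)) pop <- random_mate(pop, mu = mu)
  pop$lineage <- "hexaploid"
  pop
}

# Miniature world over a toy population: full trait architecture at small
# counts, full-scale-preset structure. Used for stage tests that need full-scale
# cardinalities on a cheap genome.
toy_world <- function(seed = 7, n = 400, h2 = NULL) {
  key <- paste0("tw_", seed, "_", n, "_", paste(h2, collapse = "_"))
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  pop <- toy_pop(n = n, seed = seed)
  set.seed(seed + 1)
  specs <- trait_specs(n_qtl = 20, n_large = c(HD = 3, Q = 3))
  if (!is.null(h2)) specs$h2 <- rep_len(h2, nrow(specs))
  targets <- correlation_targets(n_shared = 12)
  qtl <- assign_qtl(pop, specs, targets)
  effects <- simulate_trait_effects(qtl, specs, targets)
  panel <- build_snp_panel(pop, qtl, 40)
  w <- structure(list(base = pop, cultivars = NULL, specs = specs,
                      targets = targets, qtl = qtl, effects = effects,
                      panel = panel, preset = "full"),
                 class = "sim_world")
  .fixtures[[key]] <- w
  w
}

# 20 toy cultivars drawn from a toy world's base population.
toy_cultivars <- function(world, n_cultivars = 20, size = 30, seed = 11) {
  set.seed(seed)
  lapply(seq_len(n_cultivars), function(i) {
    cv <- subset_pop(world$base, sample.int(n_ind(world$base), size))
    cv$lineage <- "cultivar"
    cv
  })
}

# Build a population directly from a haplotype matrix (loci x 2N), 1 chrom.
pop_from_hap <- function(H, pos = NULL, chrom_len = 100) {
  if (is.null(pos)) pos <- seq(0.5, chrom_len - 0.5, length.out = nrow(H))
  new_population(list(H), list(pos), chrom_len, lineage = "toy")
}

# Minimal scheme-like configuration list for single-stage unit tests.
toy_cfg <- function(...) {
  base <- list(topcross_cull_frac = 0.2, topcross_pool_frac = 0.6,
               topcross_select = 5, plot_seeds = 20, plots_selected = 4,
               clones_per_plot = 5, within_plot_keep_frac = 0.8,
               rows_selected = 5, field_trial_size = 20, synthetic_size = 2,
               field_plot_size = 10, pool_sample = 20, n_cultivars = 4,
               f1_per_pair = 1, seeds_per_f1 = 10, speedgs_pop = 40,
               top_pairs = 10, speedgs_cross = c(4L, 1L), sb_rounds = 1L)
  utils::modifyList(base, list(...))
}
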