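test_that("crossing stage produces the configured family structure", {
  world <- toy_world()
  cvs <- toy_cultivars(world, 4, size = 12)
  set.seed(71)
  cfg <- toy_cfg(n_cultivars = 4, f1_per_pair = 1, seeds_per_f1 = 10)
  out <- stage_crossing(cvs, world, cfg)
  expect_equal(n_ind(out$pop), 20) # 2 pairs x 1 F1 population x 10 seeds
  expect_equal(length(unique(out$family)), 2)
  expect_equal(as.vector(table(out$family)), c(10, 10))
  expect_error(stage_crossing(cvs[1:3], world, cfg), "exactly")
})

test_that("topcross selection culls early HD then samples the SY pool", {
  set.seed(72)
  n <- 50
  pheno <- cbind(HD = rnorm(n), SY = rnorm(n), FY = 0, Q = 0, Per = 0)
  cohort <- list(pheno = pheno)
  cfg <- toy_cfg(topcross_select = 5)
  sel <- stage_topcross(cohort, cfg)
  expect_length(sel$selected, 5)
  # none of the selected are in the earliest (lowest-HD) 20%
  hd_cull <- order(pheno[, "HD"])[1:10]
  expect_length(intersect(sel$selected, hd_cull), 0)
  expect_setequal(sel$pollen, setdiff(1:n, hd_cull))
  # all selected lie in the SY top-30 among the 40 HD survivors
  surv <- setdiff(1:n, hd_cull)
  sy_pool <- surv[order(-pheno[surv, "SY"])][1:30]
  expect_true(all(sel$selected %in% sy_pool))
  # deterministic under a fixed seed
  set.seed(5); s1 <- stage_topcross(cohort, cfg)
  set.seed(5); s2 <- stage_topcross(cohort, cfg)
  expect_identical(s1, s2)
})

test_that("small-plot stage selects plots and clones by the FY+Per index", {
  # near-unit heritability makes plot phenotypes essentially plot mean TBVs,
  # so the winners are predictable from the TBVs by a brute-force oracle
  world <- toy_world(seed = 19, h2 = 0.999)
  set.seed(73)
  n <- 60
  parents <- subset_pop(world$base, sample.int(n_ind(world$base), n))
  cfg <- toy_cfg(plot_seeds = 20, plots_selected = 4, clones_per_plot = 5)
  set.seed(74)
  sp <- stage_small_plots(parents, mothers = 1:10, pollen = 11:60,
                          world = world, cfg = cfg,
                          state = refresh_error_variances(
                            true_breeding_value(parents, world$effects),
                            world$specs))
  expect_equal(n_ind(sp$rows$pop), 20) # 4 plots x 5 clones
  expect_equal(nrow(sp$records$Z), 10) # every plot genotyped
  expect_true(all(sp$records$Z >= 0 & sp$records$Z <= 2))
  expect_equal(ncol(sp$records$pheno), 5)
  # brute-force plot ranking oracle on the plot phenotypes
  idx <- scale(sp$records$pheno[, "FY"]) + scale(sp$records$pheno[, "Per"])
  expect_setequal(unique(sp$plot_index), order(-idx)[1:4])
})

test_that("single-row selection ranks by Q or by the SY+Q index", {
  set.seed(75)
  pheno <- cbind(HD = rnorm(10), FY = 0, SY = rnorm(10), Q = rnorm(10), Per = 0)
  rows <- list(pheno = pheno)
  cfg <- toy_cfg(rows_selected = 5)
  sel_q <- stage_single_rows(rows, cfg, use_sy = FALSE)
  expect_setequal(sel_q, order(-pheno[, "Q"])[1:5])
  sel_sq <- stage_single_rows(rows, cfg, use_sy = TRUE)
  oracle <- order(-(scale(pheno[, "SY"]) + scale(pheno[, "Q"])))[1:5]
  expect_setequal(sel_sq, oracle)
  expect_error(stage_single_rows(list(pheno = pheno[1:3, ]), cfg), "fewer")
})

test_that("synthetics are HD-contiguous groups of the configured size", {
  set.seed(76)
  hd <- rnorm(500)
  cfg <- toy_cfg(field_trial_size = 50, synthetic_size = 10)
  syn <- stage_synthetics(500, hd, rank_values = NULL, cfg)
  expect_length(syn, 50)
  expect_true(all(lengths(syn) == 10))
  expect_setequal(unlist(syn), 1:500)
  # contiguity in the HD ordering
  his <- vapply(syn, function(g) max(hd[g]), 0)
  los <- vapply(syn, function(g) min(hd[g]), 0)
  expect_true(all(los[-1] >= his[-50]))
  # size-5 variant keeps 50 synthetics from the top 250 by rank
  cfg5 <- toy_cfg(field_trial_size = 50, synthetic_size = 5)
  rk <- rnorm(500)
  syn5 <- stage_synthetics(500, hd, rk, cfg5)
  expect_length(syn5, 50)
  expect_true(all(lengths(syn5) == 5))
  expect_setequal(unlist(syn5), order(-rk)[1:250])
  # all-equal HD still partitions cleanly
  syn_tie <- stage_synthetics(100, rep(0, 100), NULL,
                              toy_cfg(field_trial_size = 20, synthetic_size = 5))
  expect_true(all(lengths(syn_tie) == 5))
})

test_that("field trial releases exactly 20 cultivars from the large plots", {
  world <- toy_world()
  set.seed(77)
  pool <- subset_pop(world$base, 1:125)
  cfg <- toy_cfg(field_trial_size = 25, synthetic_size = 5,
                 field_plot_size = 10)
  syn <- stage_synthetics(125, rnorm(125), NULL, cfg)
  ft <- stage_field_trial(pool, syn, world, cfg)
  expect_length(ft$cultivars, 20)
  expect_true(all(vapply(ft$cultivars, n_ind, 0L) == 10))
  expect_equal(nrow(ft$records$Z), 25)
  expect_error(stage_field_trial(pool, syn[1:10], world, cfg), "at least 20")
})

test_that("initial-population designs control full-sib family sizes", {
  world <- toy_world()
  cvs <- toy_cultivars(world, 20, size = 30)
  cfg <- toy_cfg(n_cultivars = 20, speedgs_pop = 40)
  set.seed(78)
  a <- make_initial_population(cvs, c(40, 1), world, cfg)
  expect_equal(n_ind(a$pop), 40)
  expect_true(all(table(a$family) == 1))
  b <- make_initial_population(cvs, c(10, 4), world, cfg)
  expect_equal(n_ind(b$pop), 40)
  expect_true(all(table(b$family) == 4))
  expect_error(make_initial_population(cvs, c(7, 3), world, cfg), "product")
})

test_that("the SpeedGS stage enumerates pairs and sizes progeny correctly", {
  world <- toy_world()
  set.seed(79)
  cand <- speedgs:::new_cohort(subset_pop(world$base, 1:4), world)
  ref_n <- 12
  refZ <- dosage(world$base, loci = world$panel$loci,
                 individuals = 30 + seq_len(ref_n))
  reftbv <- true_breeding_value(world$base, world$effects,
                                individuals = 30 + seq_len(ref_n))
  models <- sapply(world$specs$trait, function(tr)
    fit_brr(refZ, reftbv[, tr] + rnorm(ref_n), h2 = 0.5, method = "ridge"),
    simplify = FALSE)
  cfg <- toy_cfg(speedgs_cross = c(2L, 3L), top_pairs = 4, sb_rounds = 2)
  out <- speedgs_stage(cand, models, world, cfg)
  expect_equal(out$n_candidate_pairs, n_candidate_pairs(6)) # 6 plants in round 2
  expect_equal(n_ind(out$cohort$pop), 6) # 2 crosses x 3 progeny
  expect_equal(nrow(out$accuracy), 2 * 5) # rounds x traits
  expect_error(speedgs_stage(cand, models, world,
                             toy_cfg(sb_rounds = 9)), "between 1 and 6")
})
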