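# A "cohort" is a plain list holding a breedpop plus per-plant bookkeeping:
#   pop: breedpop; tbv: n x 5 matrix; pheno: n x 5 matrix or NULL;
#   gebv: n x 5 matrix or NULL; family: integer vector or NULL.

new_cohort <- function(pop, world, family = NULL) {
  list(pop = pop, tbv = true_breeding_value(pop, world$effects),
       pheno = NULL, gebv = NULL, family = family)
}

subset_cohort <- function(cohort, idx) {
  list(pop = subset_pop(cohort$pop, idx),
       tbv = cohort$tbv[idx, , drop = FALSE],
       pheno = if (!is.null(cohort$pheno)) cohort$pheno[idx, , drop = FALSE],
       gebv = if (!is.null(cohort$gebv)) cohort$gebv[idx, , drop = FALSE],
       family = cohort$family[idx])
}

# merge populations with identical genome layout into one breedpop
merge_pops <- function(pops) {
  hap <- lapply(seq_len(n_chrom(pops[[1]])), function(k)
    do.call(cbind, lapply(pops, function(p) p$hap[[k]])))
  new_population(hap, pops[[1]]$map, pops[[1]]$chrom_len,
                 generation = pops[[1]]$generation, lineage = pops[[1]]$lineage)
}

# z-standardize with a guard for zero spread
std <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# indices of the n largest values; ties broken by a seeded uniform draw
top_n_idx <- function(x, n) {
  order(-x, runif(length(x)))[seq_len(n)]
}

# indices of the n smallest values
bottom_n_idx <- function(x, n) top_n_idx(-x, n)

#' Crossing stage: 20 cultivars to the F1 topcross cohort
#'
#' Cultivars are paired into 10 disjoint random pairs; five random plants are
#' drawn per cultivar; each pair contributes `f1_per_pair` F1 populations
#' (one dam from the first cultivar crossed to one sire from the second) of
#' `seeds_per_f1` seeds, giving 10 x 5 x 100 = 5,000 F1 plants at full scale.
#'
#' @param cultivars list of exactly `n_cultivars` cultivar `breedpop`s.
#' @param world simulation world (effects, panel, specs) as built by
#'   [build_world()].
#' @param cfg a [scheme_config()].
#' @return a cohort with `family` labelling the F1 population of each plant.
#' @export
stage_crossing <- function(cultivars, world, cfg) {
  if (length(cultivars) != cfg$n_cultivars)
    stop(sprintf("crossing stage requires exactly %d cultivars", cfg$n_cultivars))
  pairing <- matrix(sample(length(cultivars)), ncol = 2)
  pops <- list(); fam <- integer(0); fam_id <- 0L
  for (r in seq_len(nrow(pairing))) {
    a <- cultivars[[pairing[r, 1]]]; b <- cultivars[[pairing[r, 2]]]
    plants_a <- sample.int(n_ind(a), min(cfg$f1_per_pair, n_ind(a)))
    plants_b <- sample.int(n_ind(b), min(cfg$f1_per_pair, n_ind(b)))
    dams <- rep(plants_a, each = cfg$seeds_per_f1)
    sires <- rep(plants_b, each = cfg$seeds_per_f1)
    pops[[r]] <- make_progeny(a, dams, b, sires, mu = 0, lineage = "F1")
    fam <- c(fam, rep(fam_id + seq_len(cfg$f1_per_pair),
                      each = cfg$seeds_per_f1))
    fam_id <- fam_id + cfg$f1_per_pair
  }
  new_cohort(merge_pops(pops), world, family = fam)
}

#' Topcross stage: two-step phenotypic selection on HD then SY
#'
#' Discards the earliest-heading 20% (lowest HD phenotype), ranks the
#' survivors by SY phenotype, forms the pool of the top 60% (of the original
#' count) and returns a uniform random draw of `topcross_select` plants from
#' that pool. The HD-surviving plants serve as the pollen pool of the
#' following small-plot stage.
#'
#' @param cohort phenotyped topcross cohort (needs HD and SY phenotypes).
#' @param cfg a [scheme_config()].
#' @return list with `selected` (indices), `pollen` (HD-surviving indices).
#' @export
stage_topcross <- function(cohort, cfg) {
  n <- nrow(cohort$pheno)
  n_cull <- floor(cfg$topcross_cull_frac * n)
  n_pool <- floor(cfg$topcross_pool_frac * n)
  if (n - n_cull < n_pool || cfg$topcross_select > n_pool)
    stop("topcross cohort too small for the cull and pool sizes")
  culled <- bottom_n_idx(cohort$pheno[, "HD"], n_cull)
  survivors <- setdiff(seq_len(n), culled)
  pool <- survivors[top_n_idx(cohort$pheno[survivors, "SY"], n_pool)]
  selected <- sample(pool, cfg$topcross_select)
  list(selected = selected, pollen = survivors)
}

# plot-level phenotypes: plot mean TBV plus one error deviate per plot with
# variance set so plot-level heritability equals the trait's h2
plot_phenotypes <- function(plot_tbv, specs) {
  out <- plot_tbv
  for (tr in colnames(plot_tbv)) {
    h2 <- specs$h2[specs$trait == tr]
    v <- stats::var(plot_tbv[, tr])
    s2 <- v * (1 - h2) / h2
    out[, tr] <- plot_tbv[, tr] +
      if (s2 > 0) rnorm(nrow(plot_tbv), sd = sqrt(s2)) else 0
  }
  out
}

# pooled genotypes + plot phenotypes for a set of plots, for the reference
genotype_plots <- function(pop, groups, plot_tbv, specs, world, cfg,
                           stage, cycle) {
  Z <- t(vapply(groups, function(g)
    pool_plot_genotype(pop, g, world$panel, cfg$pool_sample),
    numeric(length(world$panel$loci))))
  pheno <- plot_phenotypes(plot_tbv, specs)
  list(Z = Z, pheno = pheno,
       meta = data.frame(cycle = cycle, stage = stage,
                         plot = seq_along(groups)))
}

#' Small-plot stage: half-sib plots, plot selection, within-plot cloning
#'
#' Each selected mother is planted to a plot of `plot_seeds` half-sib
#' progeny (pollen drawn from the pollen pool). Plots are phenotyped for FY
#' and Per at plot level; the top `plots_selected` plots by the equal-weight
#' standardized FY + Per index are kept; within each kept plot the top 80%
#' of plants by individual standardized FY + Per are eligible and
#' `clones_per_plot` random eligible plants are cloned into single rows.
#' All plots are genotyped (pooled) for the reference population.
#'
#' @param mother_pop population holding mothers and pollen parents.
#' @param mothers indices of the plot mothers.
#' @param pollen indices of the pollen pool.
#' @param world simulation world.
#' @param cfg a [scheme_config()].
#' @param state named error-variance vector for individual phenotypes.
#' @param cycle cycle index for the reference records.
#' @return list with `rows` (cloned-plant cohort), `records` (reference
#'   rows), `plot_index` (plot of origin of each row plant).
#' @export
stage_small_plots <- function(mother_pop, mothers, pollen, world, cfg, state,
                              cycle = NA_integer_) {
  if (cfg$clones_per_plot > floor(cfg$within_plot_keep_frac * cfg$plot_seeds))
    stop("plot size too small for the within-plot cloning rule")
  n_plots <- length(mothers)
  dams <- rep(mothers, each = cfg$plot_seeds)
  sires <- sample(pollen, length(dams), replace = TRUE)
  while (any(bad <- sires == dams))
    sires[bad] <- sample(pollen, sum(bad), replace = TRUE)
  prog <- make_progeny(mother_pop, dams, mother_pop, sires, mu = 0,
                       lineage = "small_plot")
  cohort <- new_cohort(prog, world,
                       family = rep(seq_len(n_plots), each = cfg$plot_seeds))
  groups <- split(seq_len(n_ind(prog)), cohort$family)
  plot_tbv <- do.call(rbind, lapply(groups, function(g)
    colMeans(cohort$tbv[g, , drop = FALSE])))
  records <- genotype_plots(prog, groups, plot_tbv, world$specs, world, cfg,
                            "small_plots", cycle)
  idx_fy <- std(records$pheno[, "FY"]) + std(records$pheno[, "Per"])
  keep_plots <- top_n_idx(idx_fy, cfg$plots_selected)
  cohort$pheno <- phenotype(cohort$tbv, state)
  clones <- integer(0)
  for (pl in keep_plots) {
    g <- groups[[pl]]
    ind <- std(cohort$pheno[g, "FY"]) + std(cohort$pheno[g, "Per"])
    elig <- g[top_n_idx(ind, floor(cfg$within_plot_keep_frac * length(g)))]
    clones <- c(clones, sample(elig, cfg$clones_per_plot))
  }
  rows <- subset_cohort(cohort, clones)
  rows$family <- rep(keep_plots, each = cfg$clones_per_plot)
  list(rows = rows, records = records,
       plot_index = rep(keep_plots, each = cfg$clones_per_plot))
}

#' Single-row stage: selection on Q (phenotypic program) or SY + Q
#'
#' Rows are individually phenotyped. The phenotypic program selects the top
#' `rows_selected` rows on the Q phenotype; SpeedGS schemes use the
#' equal-weight standardized SY + Q index instead.
#'
#' @param rows row cohort (phenotyped).
#' @param cfg a [scheme_config()].
#' @param use_sy use the SY + Q index (SpeedGS variants) instead of Q only.
#' @return indices of the selected rows.
#' @export
stage_single_rows <- function(rows, cfg, use_sy = FALSE) {
  n <- nrow(rows$pheno)
  if (n < cfg$rows_selected) stop("fewer rows than the selection target")
  score <- if (use_sy) std(rows$pheno[, "SY"]) + std(rows$pheno[, "Q"])
           else rows$pheno[, "Q"]
  top_n_idx(score, cfg$rows_selected)
}

#' Synthetics stage: group selected plants by heading date
#'
#' Takes the top `field_trial_size * synthetic_size` plants of the input by
#' `rank_values` (already the stage-appropriate index; `NULL` ranks by
#' nothing and uses all plants), sorts them by heading date (`hd_values`,
#' phenotype or GEBV depending on the scheme) and partitions them
#' consecutively, so each synthetic contains plants with similar heading
#' dates and flowering is synchronized within a synthetic.
#'
#' @param n_input number of candidate plants.
#' @param hd_values heading-date values used for grouping.
#' @param rank_values selection index (higher better) or `NULL`.
#' @param cfg a [scheme_config()].
#' @return list of integer index groups, one per synthetic.
#' @export
stage_synthetics <- function(n_input, hd_values, rank_values, cfg) {
  n_syn <- cfg$field_trial_size
  size <- min(cfg$synthetic_size, n_input %/% n_syn)
  if (size < 2) stop("not enough plants to form synthetics of size >= 2")
  need <- n_syn * size
  pool <- if (need == n_input) seq_len(n_input)
          else if (is.null(rank_values)) sample.int(n_input, need)
          else top_n_idx(rank_values, need)
  pool <- pool[order(hd_values[pool], runif(length(pool)))]
  split(pool, rep(seq_len(n_syn), each = size))
}

#' Field-trial stage: large plots from synthetic seed lots, cultivar release
#'
#' Each synthetic's seed lot is produced by random mating among its member
#' plants; the resulting large plots are phenotyped for FY and Per at plot
#' level, and the top 20 plots on the equal-weight standardized FY + Per
#' index become the next cycle's cultivars. Plots are genotyped (pooled) for
#' the reference population in SpeedGS schemes.
#'
#' @param pop population holding the synthetic members.
#' @param synthetics list of member index groups from [stage_synthetics()].
#' @param world simulation world.
#' @param cfg a [scheme_config()].
#' @param cycle cycle index for reference records.
#' @return list with `cultivars` (list of 20 `breedpop`s), `records`.
#' @export
stage_field_trial <- function(pop, synthetics, world, cfg,
                              cycle = NA_integer_) {
  if (length(synthetics) < 20) stop("need at least 20 field plots")
  m <- cfg$field_plot_size
  dams <- sires <- integer(0)
  for (g in synthetics) {
    d <- sample(g, m, replace = TRUE)
    s <- sample(g, m, replace = TRUE)
    while (any(bad <- s == d)) s[bad] <- sample(g, sum(bad), replace = TRUE)
    dams <- c(dams, d); sires <- c(sires, s)
  }
  prog <- make_progeny(pop, dams, pop, sires, mu = 0, lineage = "field_plot")
  fam <- rep(seq_along(synthetics), each = m)
  tbv <- true_breeding_value(prog, world$effects)
  groups <- split(seq_len(n_ind(prog)), fam)
  plot_tbv <- do.call(rbind, lapply(groups, function(g)
    colMeans(tbv[g, , drop = FALSE])))
  records <- genotype_plots(prog, groups, plot_tbv, world$specs, world, cfg,
                            "field_trial", cycle)
  idx <- std(records$pheno[, "FY"]) + std(records$pheno[, "Per"])
  winners <- top_n_idx(idx, 20L)
  cultivars <- lapply(winners, function(w) {
    cv <- subset_pop(prog, groups[[w]])
    cv$lineage <- "cultivar"
    cv
  })
  list(cultivars = cultivars, records = records)
}

#' Initial population for a SpeedGS cycle
#'
#' Pairwise cultivar crossing as in the crossing stage, but with a
#' configurable number of distinct parent pairs spread evenly over the 10
#' cultivar pairs and a configurable number of progeny per pair, the product
#' equalling the SpeedGS initial population size. More crosses draw more
#' distinct plants per cultivar, reducing full-sib family sizes.
#'
#' @param cultivars list of `n_cultivars` cultivar `breedpop`s.
#' @param design `c(crosses, progeny_per_cross)`.
#' @param world simulation world.
#' @param cfg a [scheme_config()].
#' @return a cohort of `speedgs_pop` plants; `family` labels full-sib
#'   families.
#' @export
make_initial_population <- function(cultivars, design, world, cfg) {
  design <- as.integer(design)
  if (prod(design) != cfg$speedgs_pop)
    stop(sprintf("initial design product must be %d", cfg$speedgs_pop))
  n_crosses <- design[1]; n_prog <- design[2]
  pairing <- matrix(sample(length(cultivars)), ncol = 2)
  per_pair <- rep(n_crosses %/% nrow(pairing), nrow(pairing))
  extra <- n_crosses %% nrow(pairing)
  if (extra > 0) per_pair[seq_len(extra)] <- per_pair[seq_len(extra)] + 1L
  pops <- list(); fam <- integer(0); fam_id <- 0L
  for (r in seq_len(nrow(pairing))) {
    if (per_pair[r] == 0L) next
    a <- cultivars[[pairing[r, 1]]]; b <- cultivars[[pairing[r, 2]]]
    pick <- function(pop, k) {
      if (k <= n_ind(pop)) sample.int(n_ind(pop), k)
      else sample.int(n_ind(pop), k, replace = TRUE)
    }
    dams <- rep(pick(a, per_pair[r]), each = n_prog)
    sires <- rep(pick(b, per_pair[r]), each = n_prog)
    pops[[length(pops) + 1L]] <- make_progeny(a, dams, b, sires, mu = 0,
                                              lineage = "initial")
    fam <- c(fam, rep(fam_id + seq_len(per_pair[r]), each = n_prog))
    fam_id <- fam_id + per_pair[r]
  }
  new_cohort(merge_pops(pops), world, family = fam)
}

#' SpeedGS stage: genomic selection with speed-breeding rounds
#'
#' Per round: all candidates are genotyped on the SNP panel, per-trait GEBVs
#' are predicted and combined into the selection index (weights Per 0.35,
#' FY 0.25, SY 0.15, Q 0.15, HD 0.1 on GEBVs standardized within the
#' cohort); all candidate parent pairs are scored by parent-average index;
#' the crossing scheme draws its pairs at random from the top `top_pairs`
#' candidates and produces the next round's cohort by meiosis without
#' mutation. Prediction accuracy (Pearson correlation of GEBV and TBV per
#' trait) is recorded on each round's candidates.
#'
#' @param cohort initial-population cohort.
#' @param models list of per-trait [fit_brr()] models.
#' @param world simulation world.
#' @param cfg a [scheme_config()].
#' @return list with `cohort` (final round's output, GEBVs attached) and
#'   `accuracy` (data.frame: round, trait, accuracy).
#' @export
speedgs_stage <- function(cohort, models, world, cfg) {
  if (cfg$sb_rounds < 1 || cfg$sb_rounds > 6)
    stop("sb_rounds must be between 1 and 6")
  wts <- stats::setNames(world$specs$index_weight, world$specs$trait)
  acc <- list()
  n_pairs_seen <- NA_real_
  gebv_of <- function(ch) {
    Z <- dosage(ch$pop, loci = world$panel$loci)
    vapply(names(models), function(tr) predict_gebv(models[[tr]], Z),
           numeric(n_ind(ch$pop)))
  }
  for (round in seq_len(cfg$sb_rounds)) {
    cohort$gebv <- gebv_of(cohort)
    acc[[round]] <- data.frame(
      round = round, trait = colnames(cohort$gebv),
      accuracy = vapply(colnames(cohort$gebv), function(tr)
        gebv_accuracy(cohort$gebv[, tr], cohort$tbv[, tr]), 0),
      row.names = NULL)
    index <- as.vector(apply(cohort$gebv, 2, std) %*% wts[colnames(cohort$gebv)])
    n <- length(index)
    i <- rep(seq_len(n - 1), times = (n - 1):1)
    j <- sequence((n - 1):1, from = 2:n)
    score <- index[i] + index[j]
    n_pairs_seen <- length(score)
    keep <- top_n_idx(score, min(cfg$top_pairs, length(score)))
    pick <- sample(keep, cfg$speedgs_cross[1])
    dams <- rep(i[pick], each = cfg$speedgs_cross[2])
    sires <- rep(j[pick], each = cfg$speedgs_cross[2])
    prog <- make_progeny(cohort$pop, dams, cohort$pop, sires, mu = 0,
                         lineage = "speedgs")
    fam <- rep(seq_len(cfg$speedgs_cross[1]), each = cfg$speedgs_cross[2])
    cohort <- new_cohort(prog, world, family = fam)
  }
  cohort$gebv <- gebv_of(cohort)
  list(cohort = cohort, accuracy = do.call(rbind, acc),
       n_candidate_pairs = n_pairs_seen)
}
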