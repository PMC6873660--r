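`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the simulation world
#'
#' Convenience wrapper running the whole setup at a preset scale: forward
#' simulation of the hexaploid base population, derivation of the 20 founder
#' cultivars, QTL assignment, correlated trait effects and the masked SNP
#' panel. Heavy at full scale; minutes at desk scale.
#'
#' @param preset `"desk"` or `"full"`.
#' @param verbose print forward-simulation progress.
#' @return list of class `sim_world`: `base`, `cultivars`, `specs`,
#'   `targets`, `qtl`, `effects`, `panel`, `preset`.
#' @export
build_world <- function(preset = c("desk", "full"), verbose = FALSE) {
  preset <- match.arg(preset)
  bw <- build_base_world(preset, verbose = verbose)
  attach_traits(bw)
}

#' @rdname build_world
#' @export
build_base_world <- function(preset = c("desk", "full"), verbose = FALSE) {
  preset <- match.arg(preset)
  ps <- base_preset(preset)
  base <- run_forward(ps$params, ps$schedule, verbose = verbose)
  cultivars <- derive_cultivars(base, ps$cultivar$n, ps$cultivar$founders,
                                ps$cultivar$generations,
                                crossover_mean = ps$params$crossover_mean)
  structure(list(base = base, cultivars = cultivars, preset = preset,
                 preset_cfg = ps),
            class = "base_world")
}

#' @rdname build_world
#' @param bw a `base_world` from [build_base_world()]; trait architecture,
#'   effects and panel are (re)drawn on it, which is cheap and gives
#'   replicate-level variation in genetic architecture.
#' @export
attach_traits <- function(bw) {
  ps <- bw$preset_cfg
  specs <- trait_specs(n_qtl = ps$traits$n_qtl, n_large = ps$traits$n_large,
                       var_large = ps$traits$var_large)
  targets <- correlation_targets(n_shared = ps$traits$n_shared)
  qtl <- assign_qtl(bw$base, specs, targets)
  effects <- simulate_trait_effects(qtl, specs, targets)
  panel <- build_snp_panel(bw$base, qtl, ps$panel_size)
  structure(list(base = bw$base, cultivars = bw$cultivars, specs = specs,
                 targets = targets, qtl = qtl, effects = effects,
                 panel = panel, preset = bw$preset, preset_cfg = ps),
            class = "sim_world")
}

# reference population accumulator
ref_new <- function() list(Z = NULL, pheno = NULL, meta = NULL)

ref_add <- function(ref, records) {
  list(Z = rbind(ref$Z, records$Z), pheno = rbind(ref$pheno, records$pheno),
       meta = rbind(ref$meta, records$meta))
}

#' Reference population size
#' @param ref a reference population accumulator from [run_warmup()].
#' @export
ref_size <- function(ref) if (is.null(ref$Z)) 0L else nrow(ref$Z)

# train one BRR model per trait on the current reference
train_models <- function(ref, world, method = "ridge", ...) {
  stats::setNames(lapply(world$specs$trait, function(tr) {
    h2 <- world$specs$h2[world$specs$trait == tr]
    fit_brr(ref$Z, ref$pheno[, tr], h2 = h2, method = method, ...)
  }), world$specs$trait)
}

# one full phenotypic-selection cycle; returns next cultivars, reference
# records and the cycle's initial (topcross) cohort
ps_cycle <- function(cultivars, world, cfg, cycle = NA_integer_) {
  f1 <- stage_crossing(cultivars, world, cfg)
  state <- refresh_error_variances(f1$tbv, world$specs)
  f1$pheno <- phenotype(f1$tbv, state)
  tc <- stage_topcross(f1, cfg)
  sp <- stage_small_plots(f1$pop, tc$selected, tc$pollen, world, cfg, state,
                          cycle)
  rows <- sp$rows
  rows$pheno <- phenotype(rows$tbv, state)
  sel <- stage_single_rows(rows, cfg, use_sy = FALSE)
  selrows <- subset_cohort(rows, sel)
  syn <- stage_synthetics(length(sel), selrows$pheno[, "HD"],
                          selrows$pheno[, "Q"], cfg)
  ft <- stage_field_trial(selrows$pop, syn, world, cfg, cycle)
  list(cultivars = ft$cultivars, small_records = sp$records,
       field_records = ft$records, initial = f1, state = state)
}

#' Phenotypic warm-up cycles
#'
#' Runs the phenotypic-selection program for the warm-up cycles, genotyping
#' every small plot into the starting reference population. The result is
#' scheme-independent and can be shared across SpeedGS configurations of the
#' same replicate (paired comparisons).
#'
#' @param world a `sim_world`.
#' @param cfg any [scheme_config()] of the same preset (its warm-up sizes
#'   are used).
#' @return list with `cultivars`, `reference`, `cycles`.
#' @export
run_warmup <- function(world, cfg) {
  ps_cfg <- scheme_config("PS", preset = cfg$preset,
                          warmup_cycles = cfg$warmup_cycles)
  cultivars <- world$cultivars
  ref <- ref_new()
  for (cyc in seq_len(cfg$warmup_cycles)) {
    out <- ps_cycle(cultivars, world, ps_cfg, cycle = cyc)
    cultivars <- out$cultivars
    ref <- ref_add(ref, out$small_records)
  }
  list(cultivars = cultivars, reference = ref, cycles = cfg$warmup_cycles)
}

# weighted standardized GEBV index
gebv_index <- function(gebv, specs) {
  wts <- stats::setNames(specs$index_weight, specs$trait)
  as.vector(apply(gebv, 2, std) %*% wts[colnames(gebv)])
}

# one SpeedGS cycle for schemes S1-S4
gs_cycle <- function(cultivars, world, cfg, reference, cycle, first) {
  if (first && is.null(cfg$initial_design)) {
    f1 <- stage_crossing(cultivars, world, cfg)
    initial <- subset_cohort(f1, sample.int(n_ind(f1$pop), cfg$speedgs_pop))
  } else {
    design <- cfg$initial_design %||% cfg$default_initial
    initial <- make_initial_population(cultivars, design, world, cfg)
  }
  state <- refresh_error_variances(initial$tbv, world$specs)
  models <- train_models(reference, world)
  sgs <- speedgs_stage(initial, models, world, cfg)
  out <- sgs$cohort
  small_records <- NULL
  if (cfg$scheme %in% c("S1", "S2")) {
    mothers <- top_n_idx(gebv_index(out$gebv, world$specs),
                         cfg$topcross_select)
    sp <- stage_small_plots(out$pop, mothers, seq_len(n_ind(out$pop)),
                            world, cfg, state, cycle)
    small_records <- sp$records
    rows <- sp$rows
    if (cfg$scheme == "S1") {
      rows$pheno <- phenotype(rows$tbv, state)
      sel <- stage_single_rows(rows, cfg, use_sy = TRUE)
      selrows <- subset_cohort(rows, sel)
      score <- std(selrows$pheno[, "SY"]) + std(selrows$pheno[, "Q"])
      syn <- stage_synthetics(length(sel), selrows$pheno[, "HD"], score, cfg)
      syn_pop <- selrows$pop
    } else { # S2: no single-row phenotypes; GEBV index replaces them
      Z <- dosage(rows$pop, loci = world$panel$loci)
      rows$gebv <- vapply(names(models), function(tr)
        predict_gebv(models[[tr]], Z), numeric(n_ind(rows$pop)))
      score <- std(rows$gebv[, "SY"]) + std(rows$gebv[, "Q"])
      syn <- stage_synthetics(nrow(rows$gebv), rows$gebv[, "HD"], score, cfg)
      syn_pop <- rows$pop
    }
  } else if (cfg$scheme == "S3") {
    rows <- out
    rows$pheno <- phenotype(rows$tbv, state)
    sel <- stage_single_rows(rows, cfg, use_sy = TRUE)
    selrows <- subset_cohort(rows, sel)
    score <- std(selrows$pheno[, "SY"]) + std(selrows$pheno[, "Q"])
    syn <- stage_synthetics(length(sel), selrows$pheno[, "HD"], score, cfg)
    syn_pop <- selrows$pop
  } else { # S4: synthetics straight from the SpeedGS output, on GEBVs
    score <- std(out$gebv[, "SY"]) + std(out$gebv[, "Q"])
    syn <- stage_synthetics(nrow(out$gebv), out$gebv[, "HD"], score, cfg)
    syn_pop <- out$pop
  }
  ft <- stage_field_trial(syn_pop, syn, world, cfg, cycle)
  if (!is.null(small_records)) reference <- ref_add(reference, small_records)
  reference <- ref_add(reference, ft$records)
  list(cultivars = ft$cultivars, initial = initial,
       accuracy = sgs$accuracy, reference = reference, state = state)
}

# per-cycle metrics on an initial population cohort
initial_metrics <- function(cohort, world, baseline) {
  Z <- dosage(cohort$pop, loci = world$panel$loci)
  G <- grm_vanraden(Z, baseline$freq)
  p <- colMeans(Z) / 2
  list(mean_tbv = colMeans(cohort$tbv),
       F = inbreeding_F(G),
       he = mean(2 * p * (1 - p)))
}

#' Run one breeding program
#'
#' Executes the configured scheme: the phenotypic program runs its warm-up
#' plus tracked cycles; SpeedGS schemes run the phenotypic warm-up (or reuse
#' a supplied one), then the configured number of SpeedGS cycles, retraining
#' the prediction model once per cycle on the growing reference population.
#' After the last cycle one extra initial population is generated purely to
#' record the final genetic-gain point. All metrics are computed on the
#' initial population of each tracked cycle, with the first tracked cycle as
#' baseline: standardized gain per trait, VanRaden inbreeding F and per-cycle
#' rate dF (baseline allele frequencies), panel heterozygosity, and per-round
#' GEBV accuracy.
#'
#' @param cfg a [scheme_config()].
#' @param world a `sim_world` from [build_world()].
#' @param warmup optional precomputed [run_warmup()] result to share across
#'   configurations of one replicate.
#' @return object of class `program_result`: `gain`, `accuracy`,
#'   `inbreeding` data.frames, plus `cfg` and `years_per_cycle`.
#' @export
run_program <- function(cfg, world, warmup = NULL) {
  stopifnot(inherits(cfg, "scheme_config"), inherits(world, "sim_world"))
  if (cfg$preset != world$preset)
    stop("configuration and world use different presets")
  initials <- list()
  acc <- list()
  if (cfg$scheme == "PS") {
    cultivars <- world$cultivars
    for (cyc in seq_len(cfg$warmup_cycles + cfg$n_cycles)) {
      out <- ps_cycle(cultivars, world, cfg, cycle = cyc)
      cultivars <- out$cultivars
      if (cyc > cfg$warmup_cycles)
        initials[[length(initials) + 1L]] <- out$initial
    }
    final <- stage_crossing(cultivars, world, cfg)
    initials[[length(initials) + 1L]] <- final
  } else {
    if (is.null(warmup)) warmup <- run_warmup(world, cfg)
    cultivars <- warmup$cultivars
    reference <- warmup$reference
    for (cyc in seq_len(cfg$n_cycles)) {
      out <- gs_cycle(cultivars, world, cfg, reference,
                      cycle = cfg$warmup_cycles + cyc, first = (cyc == 1L))
      cultivars <- out$cultivars
      reference <- out$reference
      initials[[cyc]] <- out$initial
      acc[[cyc]] <- cbind(cycle = cyc, out$accuracy)
    }
    design <- cfg$initial_design %||% cfg$default_initial
    initials[[cfg$n_cycles + 1L]] <-
      make_initial_population(cultivars, design, world, cfg)
  }
  base_cohort <- initials[[1]]
  baseline <- list(
    freq = colMeans(dosage(base_cohort$pop, loci = world$panel$loci)) / 2,
    tbv = base_cohort$tbv)
  mets <- lapply(initials, initial_metrics, world = world, baseline = baseline)
  n_pts <- length(initials)
  Fs <- vapply(mets, `[[`, 0, "F")
  gain <- do.call(rbind, lapply(seq_len(n_pts), function(c) {
    data.frame(cycle = c, year = (c - 1) * cycle_length(cfg),
               trait = colnames(base_cohort$tbv),
               mean_tbv = mets[[c]]$mean_tbv,
               delta_sigma_g = vapply(colnames(base_cohort$tbv), function(tr)
                 delta_sigma_g(initials[[c]]$tbv[, tr], baseline$tbv[, tr]), 0),
               row.names = NULL)
  }))
  # genomic F can pass 1 under extreme drift from the baseline frequencies;
  # the per-cycle rate is undefined from such a predecessor
  dF <- c(NA, ifelse(Fs[-n_pts] < 1,
                     (Fs[-1] - Fs[-n_pts]) / (1 - Fs[-n_pts]), NA))
  inb <- data.frame(cycle = seq_len(n_pts),
                    year = (seq_len(n_pts) - 1) * cycle_length(cfg),
                    F = Fs, delta_F = dF,
                    he = vapply(mets, `[[`, 0, "he"))
  structure(list(gain = gain,
                 accuracy = if (length(acc)) do.call(rbind, acc) else NULL,
                 inbreeding = inb, cfg = cfg,
                 years_per_cycle = cycle_length(cfg)),
            class = "program_result")
}

#' Flatten a program result into a tidy metric table
#'
#' @param res a `program_result`.
#' @return data.frame with columns `scheme`, `sb_rounds`, `crossing_scheme`,
#'   `cycle`, `year`, `trait`, `metric`, `value`.
#' @export
ledger_table <- function(res) {
  cfg <- res$cfg
  tag <- function(df, trait, metric, value, round = NA) {
    data.frame(scheme = cfg$scheme, sb_rounds = cfg$sb_rounds,
               crossing_scheme = cfg$crossing_scheme, cycle = df$cycle,
               year = df$year, trait = trait, sb_round = round,
               metric = metric, value = value, row.names = NULL)
  }
  out <- rbind(
    tag(res$gain, res$gain$trait, "mean_tbv", res$gain$mean_tbv),
    tag(res$gain, res$gain$trait, "delta_sigma_g", res$gain$delta_sigma_g),
    tag(res$inbreeding, NA, "F", res$inbreeding$F),
    tag(res$inbreeding, NA, "delta_F", res$inbreeding$delta_F),
    tag(res$inbreeding, NA, "he", res$inbreeding$he))
  if (!is.null(res$accuracy)) {
    acc <- res$accuracy
    acc$year <- (acc$cycle - 1) * res$years_per_cycle
    out <- rbind(out, tag(acc, acc$trait, "accuracy", acc$accuracy,
                          round = acc$round))
  }
  out
}
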