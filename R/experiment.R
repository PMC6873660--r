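#' Experiment configuration
#'
#' A replicated experiment over a grid of scheme configurations. Replicate
#' seeds are derived deterministically from the master seed; the base
#' population and cultivars are simulated once per experiment, while each
#' replicate redraws the trait architecture, runs its own phenotypic warm-up
#' and shares that warm-up across all grid cells (paired comparisons).
#'
#' @param cells data.frame with columns `scheme`, `sb_rounds`,
#'   `crossing_scheme`, and optionally `synthetic_size`,
#'   `initial_crosses`, `initial_progeny` (defaults: [scenario_grid()]).
#' @param replicates replicate count (100 in the study; desk default 10).
#' @param seed master seed.
#' @param preset `"desk"` or `"full"`.
#' @param n_cycles tracked cycles per program.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(cells = scenario_grid(), replicates = 10,
                              seed = 1, preset = c("desk", "full"),
                              n_cycles = 4) {
  preset <- match.arg(preset)
  stopifnot(replicates >= 1, all(c("scheme", "sb_rounds", "crossing_scheme")
                                 %in% names(cells)))
  structure(list(cells = cells, replicates = as.integer(replicates),
                 seed = as.integer(seed), preset = preset,
                 n_cycles = as.integer(n_cycles)),
            class = "experiment_config")
}

cell_config <- function(cell, preset, n_cycles) {
  init <- NULL
  if (!is.null(cell$initial_crosses) && !is.na(cell$initial_crosses))
    init <- c(cell$initial_crosses, cell$initial_progeny)
  scheme_config(scheme = cell$scheme, sb_rounds = cell$sb_rounds,
                crossing_scheme = cell$crossing_scheme,
                synthetic_size = if (!is.null(cell$synthetic_size) &&
                                     !is.na(cell$synthetic_size))
                  cell$synthetic_size else NULL,
                initial_design = init, n_cycles = n_cycles, preset = preset)
}

#' Run a replicated experiment
#'
#' @param config an [experiment_config()].
#' @param base_world optional precomputed [build_base_world()] result (reused
#'   across calls, e.g. in tests).
#' @param verbose print per-replicate progress to stderr.
#' @return list of class `experiment_result`: `ledger` (tidy data.frame with
#'   `replicate` + [ledger_table()] columns) and `manifest`.
#' @export
run_experiment <- function(config, base_world = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max, config$replicates)
  cell_seeds <- matrix(sample.int(.Machine$integer.max,
                                  config$replicates * nrow(config$cells)),
                       config$replicates, nrow(config$cells))
  if (is.null(base_world)) {
    set.seed(rep_seeds[1] %% 1000003L + 1L)
    base_world <- build_base_world(config$preset)
  }
  cfgs <- lapply(seq_len(nrow(config$cells)), function(i)
    cell_config(as.list(config$cells[i, , drop = FALSE]), config$preset,
                config$n_cycles))
  rows <- list()
  for (r in seq_len(config$replicates)) {
    set.seed(rep_seeds[r])
    world <- attach_traits(base_world)
    warmup <- run_warmup(world, cfgs[[1]])
    for (i in seq_along(cfgs)) {
      set.seed(cell_seeds[r, i])
      res <- run_program(cfgs[[i]], world,
                         warmup = if (cfgs[[i]]$scheme == "PS") NULL
                                  else warmup)
      tab <- ledger_table(res)
      rows[[length(rows) + 1L]] <- cbind(replicate = r, tab)
    }
    if (verbose) message(sprintf("replicate %d/%d done", r,
                                 config$replicates))
  }
  ledger <- do.call(rbind, rows)
  manifest <- list(
    package_version = as.character(utils::packageVersion("speedgs")),
    preset = config$preset, replicates = config$replicates,
    master_seed = config$seed, replicate_seeds = rep_seeds,
    n_cycles = config$n_cycles,
    cells = config$cells)
  structure(list(ledger = ledger, manifest = manifest),
            class = "experiment_result")
}

#' Summarize an experiment ledger
#'
#' Per-cell replicate means and standard deviations of every metric, and all
#' pairwise scenario contrasts at the final cycle via two-sample t-tests
#' with significance at `alpha`.
#'
#' @param ledger tidy ledger from [run_experiment()] (`$ledger`).
#' @param alpha significance level for contrasts (0.01 in the study design).
#' @return list with `means` and `tests` data.frames (`tests` is `NULL` with
#'   a single replicate).
#' @export
summarize_ledger <- function(ledger, alpha = 0.01) {
  key <- interaction(ledger$scheme, ledger$sb_rounds, ledger$crossing_scheme,
                     drop = TRUE)
  ledger$cell <- as.character(key)
  means <- stats::aggregate(
    value ~ cell + scheme + sb_rounds + crossing_scheme + cycle + trait +
      sb_round + metric,
    data = transform(ledger, trait = ifelse(is.na(trait), "-", trait),
                     sb_round = ifelse(is.na(sb_round), -1, sb_round)),
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v)), na.action = stats::na.omit)
  means <- cbind(means[setdiff(names(means), "value")],
                 mean = means$value[, "mean"], sd = means$value[, "sd"])
  n_rep <- length(unique(ledger$replicate))
  tests <- NULL
  if (n_rep >= 2) {
    last <- max(ledger$cycle)
    fin <- ledger[ledger$cycle == last & !is.na(ledger$value), , drop = FALSE]
    combos <- unique(fin[, c("trait", "metric")])
    out <- list()
    for (k in seq_len(nrow(combos))) {
      sub <- fin[identical_or_both_na(fin$trait, combos$trait[k]) &
                   fin$metric == combos$metric[k], , drop = FALSE]
      cells <- unique(sub$cell)
      if (length(cells) < 2) next
      for (a in seq_along(cells)) for (b in seq_along(cells)) if (a < b) {
        va <- sub$value[sub$cell == cells[a]]
        vb <- sub$value[sub$cell == cells[b]]
        if (length(va) < 2 || length(vb) < 2) next
        ct <- compare_scenarios(va, vb, alpha = alpha)
        out[[length(out) + 1L]] <- data.frame(
          metric = combos$metric[k], trait = combos$trait[k],
          cell_a = cells[a], cell_b = cells[b],
          mean_a = mean(va), mean_b = mean(vb),
          t = ct$t, p_value = ct$p_value, significant = ct$significant)
      }
    }
    tests <- if (length(out)) do.call(rbind, out) else NULL
  }
  list(means = means, tests = tests)
}

identical_or_both_na <- function(x, v) {
  if (is.na(v)) is.na(x) else !is.na(x) & x == v
}
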