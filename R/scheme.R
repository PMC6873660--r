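ps_stage_durations <- c(crossing = 1, topcross = 2, small_plots = 2,
                        single_rows = 3, synthetics = 1, field_trial = 2)

scheme_stage_names <- list(
  PS = c("crossing", "topcross", "small_plots", "single_rows", "synthetics",
         "field_trial"),
  S1 = c("speedgs", "small_plots", "single_rows", "synthetics", "field_trial"),
  S2 = c("speedgs", "small_plots", "synthetics", "field_trial"),
  S3 = c("speedgs", "single_rows", "synthetics", "field_trial"),
  S4 = c("speedgs", "synthetics", "field_trial"))

stage_durations <- function(scheme) {
  dur <- c(ps_stage_durations, speedgs = 1)
  dur[scheme_stage_names[[scheme]]]
}

#' Breeding scheme configuration
#'
#' Declarative description of one breeding program: the phenotypic-selection
#' baseline (`PS`) or one of the four SpeedGS scenarios (`S1`-`S4`) that
#' replace the crossing and topcross stages with a one-year speed-breeding /
#' genomic-selection stage and omit zero, one or both of the small-plot and
#' single-row stages.
#'
#' @param scheme one of `"PS"`, `"S1"`, `"S2"`, `"S3"`, `"S4"`.
#' @param sb_rounds speed-breeding rounds within the SpeedGS year (1-3 in the
#'   study grid, up to 6 supported).
#' @param crossing_scheme `"1000x1"` (many crosses, one progeny each) or
#'   `"100x10"` (fewer crosses, ten progeny each); sizes scale with preset.
#' @param synthetic_size plants per synthetic population (10 default, 5
#'   variant).
#' @param initial_design `NULL` for the default (first SpeedGS cycle: random
#'   subsample of the topcross cohort; later cycles: 50 crosses x 20
#'   progeny), or `c(crosses, progeny)` with product equal to the SpeedGS
#'   initial population size (variants 100x10, 200x5, 1000x1).
#' @param n_cycles tracked breeding cycles after warm-up (4 in the study).
#' @param warmup_cycles phenotypic warm-up cycles building the starting
#'   reference population (4 at full scale).
#' @param preset `"full"` (full-scale sizes) or `"desk"` (reduced sizes,
#'   same structure).
#' @return object of class `scheme_config`.
#' @export
scheme_config <- function(scheme = c("PS", "S1", "S2", "S3", "S4"),
                          sb_rounds = 3,
                          crossing_scheme = c("1000x1", "100x10"),
                          synthetic_size = NULL, initial_design = NULL,
                          n_cycles = 4, warmup_cycles = NULL,
                          preset = c("full", "desk")) {
  scheme <- match.arg(scheme)
  crossing_scheme <- match.arg(crossing_scheme)
  preset <- match.arg(preset)
  if (scheme != "PS" && (sb_rounds < 1 || sb_rounds > 6))
    stop("sb_rounds must be between 1 and 6")
  big_field <- scheme %in% c("S3", "S4")
  sizes <- if (preset == "full") {
    list(n_cultivars = 20L, n_cross_pairs = 10L, f1_per_pair = 5L,
         seeds_per_f1 = 100L, topcross_cull_frac = 0.2,
         topcross_pool_frac = 0.6, topcross_select = 100L,
         plot_seeds = 500L, plots_selected = 40L, clones_per_plot = 25L,
         within_plot_keep_frac = 0.8, rows_selected = 500L,
         field_trial_size = if (big_field) 100L else 50L,
         field_plot_size = 100L, speedgs_pop = 1000L, top_pairs = 10000L,
         pool_sample = 20L,
         speedgs_cross = if (crossing_scheme == "1000x1") c(1000L, 1L)
                         else c(100L, 10L),
         default_initial = c(50L, 20L))
  } else {
    list(n_cultivars = 20L, n_cross_pairs = 10L, f1_per_pair = 5L,
         seeds_per_f1 = 12L, topcross_cull_frac = 0.2,
         topcross_pool_frac = 0.6, topcross_select = 60L,
         plot_seeds = 40L, plots_selected = 25L, clones_per_plot = 10L,
         within_plot_keep_frac = 0.8, rows_selected = 125L,
         field_trial_size = if (big_field) 50L else 25L,
         field_plot_size = 30L, speedgs_pop = 200L, top_pairs = 500L,
         pool_sample = 20L,
         speedgs_cross = if (crossing_scheme == "1000x1") c(200L, 1L)
                         else c(40L, 5L),
         default_initial = c(50L, 4L))
  }
  if (is.null(synthetic_size)) synthetic_size <- if (preset == "full") 10L else 5L
  if (is.null(warmup_cycles)) warmup_cycles <- if (preset == "full") 4L else 2L
  if (!is.null(initial_design)) {
    initial_design <- as.integer(initial_design)
    if (length(initial_design) != 2L ||
        prod(initial_design) != sizes$speedgs_pop)
      stop(sprintf("initial_design product must equal the SpeedGS initial population size (%d)",
                   sizes$speedgs_pop))
  }
  cfg <- structure(c(list(scheme = scheme, sb_rounds = as.integer(sb_rounds),
                          crossing_scheme = crossing_scheme,
                          synthetic_size = as.integer(synthetic_size),
                          initial_design = initial_design,
                          n_cycles = as.integer(n_cycles),
                          warmup_cycles = as.integer(warmup_cycles),
                          preset = preset),
                     sizes),
                   class = "scheme_config")
  validate_scheme_config(cfg)
  cfg
}

validate_scheme_config <- function(cfg) {
  with(cfg, {
    topcross_n <- n_cross_pairs * f1_per_pair * seeds_per_f1
    if (2 * n_cross_pairs != n_cultivars)
      stop("cultivar pairing requires n_cultivars = 2 * n_cross_pairs")
    if (topcross_select > floor(topcross_pool_frac * topcross_n))
      stop("topcross selection larger than the eligible pool")
    rows_n <- plots_selected * clones_per_plot
    if (rows_selected > rows_n)
      stop("single-row selection exceeds the number of rows")
    if (clones_per_plot > floor(within_plot_keep_frac * plot_seeds))
      stop("cannot clone more plants than the within-plot keep fraction allows")
    if (field_trial_size < 20)
      stop("field trial must contain at least the 20 future cultivars")
  })
  invisible(cfg)
}

#' Stage table of a scheme
#'
#' @param cfg a [scheme_config()].
#' @return data.frame with `stage` and `duration_years`.
#' @export
stage_table <- function(cfg) {
  dur <- stage_durations(cfg$scheme)
  data.frame(stage = names(dur), duration_years = as.numeric(dur),
             row.names = NULL)
}

#' Cycle length in years
#'
#' Sum of stage durations: 11 years for the phenotypic program, 9/6/7/4 for
#' scenarios one to four.
#' @param cfg a [scheme_config()].
#' @export
cycle_length <- function(cfg) sum(stage_table(cfg)$duration_years)

#' The full SpeedGS scenario grid
#'
#' All combinations of the four SpeedGS schemes, one to three speed-breeding
#' rounds and the two crossing schemes.
#' @return data.frame with columns `scheme`, `sb_rounds`, `crossing_scheme`.
#' @export
scenario_grid <- function() {
  g <- expand.grid(scheme = c("S1", "S2", "S3", "S4"), sb_rounds = 1:3,
                   crossing_scheme = c("1000x1", "100x10"),
                   stringsAsFactors = FALSE)
  g[order(g$scheme, g$sb_rounds, g$crossing_scheme), , drop = FALSE]
}

#' Candidate cross count among k parents
#' @param k number of parents.
#' @export
n_candidate_pairs <- function(k) as.numeric(k) * (k - 1) / 2

#' Starting reference population size
#'
#' The reference population opens with the small plots genotyped during the
#' phenotypic warm-up cycles (4 cycles x 100 plots = 400 at full scale).
#' @param cfg a [scheme_config()].
#' @export
reference_start_size <- function(cfg) cfg$warmup_cycles * cfg$topcross_select

#' Reference population growth per SpeedGS cycle
#'
#' Scenarios with a small-plot stage add its plots plus the field-trial
#' plots (150 at full scale); scenarios three and four add field-trial plots
#' only (100 at full scale, where the field trial is enlarged).
#' @param cfg a [scheme_config()].
#' @export
reference_growth <- function(cfg) {
  if (cfg$scheme %in% c("S1", "S2"))
    cfg$topcross_select + cfg$field_trial_size
  else cfg$field_trial_size
}

#' Read / write scheme configurations as YAML
#'
#' @param cfg a [scheme_config()].
#' @param path file path.
#' @export
write_scheme_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_scheme_config
#' @export
read_scheme_config <- function(path) {
  x <- yaml::read_yaml(path)
  scheme_config(scheme = x$scheme, sb_rounds = x$sb_rounds,
                crossing_scheme = x$crossing_scheme,
                synthetic_size = x$synthetic_size,
                initial_design = unlist(x$initial_design),
                n_cycles = x$n_cycles, warmup_cycles = x$warmup_cycles,
                preset = x$preset)
}
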