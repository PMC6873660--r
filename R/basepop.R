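#' Base-population simulation parameters
#'
#' Demographic and genomic parameters of the forward-in-time simulation of
#' the allohexaploid base population. The hexaploid behaves as a diploid with
#' `3 * n_chromosomes_diploid` independent diploid chromosomes; each diploid
#' progenitor lineage carries `n_chromosomes_diploid` chromosomes.
#'
#' @param n_individuals population size per lineage after expansion.
#' @param n_chromosomes_diploid chromosomes per diploid progenitor (7 at full
#'   scale, so the hexaploid ends with 21).
#' @param loci_per_chromosome loci per chromosome, equally spaced.
#' @param chromosome_length genetic length per chromosome in cM.
#' @param mutation_rate per-locus per-generation allele-flip probability mu.
#' @param crossover_mean Poisson mean crossovers per chromosome per meiosis.
#' @param expansion_generations generations over which a newly formed taxon
#'   grows geometrically from its founder size to `n_individuals`.
#' @param founder_size number of founders of a newly formed taxon.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_individuals = 1e4, n_chromosomes_diploid = 7,
                       loci_per_chromosome = 1e5, chromosome_length = 100,
                       mutation_rate = 1e-5, crossover_mean = 1,
                       expansion_generations = 100,
                       founder_size = max(2L, round(n_individuals / 10))) {
  stopifnot(n_individuals > 0, n_chromosomes_diploid > 0,
            loci_per_chromosome > 0, chromosome_length > 0,
            mutation_rate >= 0, mutation_rate < 1, crossover_mean >= 0,
            expansion_generations > 0, founder_size >= 2,
            founder_size <= n_individuals)
  structure(list(n_individuals = as.integer(n_individuals),
                 n_chromosomes_diploid = as.integer(n_chromosomes_diploid),
                 loci_per_chromosome = as.integer(loci_per_chromosome),
                 chromosome_length = chromosome_length,
                 mutation_rate = mutation_rate,
                 crossover_mean = crossover_mean,
                 expansion_generations = as.integer(expansion_generations),
                 founder_size = as.integer(founder_size)),
            class = "sim_params")
}

#' Demographic event schedule
#'
#' Generation indices of the speciation and hybridization events that build
#' the hexaploid from a common diploid ancestor: three speciations fork the
#' three diploid progenitors, the first two hybridize into the tetraploid,
#' and the tetraploid x third-diploid cross forms the hexaploid, which then
#' evolves to `end_generation` to reach mutation-drift equilibrium.
#'
#' @param speciation_generations increasing vector of three fork generations.
#' @param tetraploid_hybridization generation of the 2x + 2x -> 4x event.
#' @param hexaploid_hybridization generation of the 4x + 2x -> 6x event.
#' @param end_generation final generation of the run.
#' @param equilibrium_check_interval generations between heterozygosity
#'   checkpoints recorded on the hexaploid lineage.
#' @return object of class `event_schedule`.
#' @export
event_schedule <- function(speciation_generations = c(8000, 8200, 15000),
                           tetraploid_hybridization = 16000,
                           hexaploid_hybridization = 25000,
                           end_generation = 105000,
                           equilibrium_check_interval = 5000) {
  g <- c(speciation_generations, tetraploid_hybridization,
         hexaploid_hybridization, end_generation)
  if (length(speciation_generations) != 3L)
    stop("exactly three speciation events are required")
  if (any(diff(speciation_generations) <= 0))
    stop("speciation generations must be strictly increasing")
  if (tetraploid_hybridization <= speciation_generations[2])
    stop("tetraploid hybridization must follow the first two speciations")
  if (hexaploid_hybridization <= max(tetraploid_hybridization,
                                     speciation_generations[3]))
    stop("hexaploid hybridization must follow the tetraploid and the third diploid")
  if (end_generation <= hexaploid_hybridization)
    stop("end_generation must follow the hexaploid hybridization")
  structure(list(speciation_generations = as.integer(speciation_generations),
                 tetraploid_hybridization = as.integer(tetraploid_hybridization),
                 hexaploid_hybridization = as.integer(hexaploid_hybridization),
                 end_generation = as.integer(end_generation),
                 equilibrium_check_interval = as.integer(equilibrium_check_interval)),
            class = "event_schedule")
}

# one generation for a possibly still-expanding lineage
advance_lineage <- function(pop, params, target = params$n_individuals,
                            mu = params$mutation_rate) {
  N <- n_ind(pop)
  n_next <- if (N < target) {
    growth <- (params$n_individuals / params$founder_size)^
      (1 / params$expansion_generations)
    min(target, max(N + 1L, ceiling(N * growth)))
  } else target
  random_mate(pop, n_offspring = n_next, mu = mu,
              crossover_mean = params$crossover_mean)
}

#' Hybridize two populations into a higher-ploidy taxon
#'
#' Forms an amphidiploid: each hybrid offspring carries the union of the two
#' parental chromosome sets, and for each parental set it receives two
#' recombined gametes from two distinct random parents of that population, so
#' every chromosome remains an independent diploid chromosome.
#'
#' @param pop_a,pop_b parental `breedpop`s (distinct lineages).
#' @param n_offspring number of hybrid founders to create.
#' @param crossover_mean Poisson mean crossovers per chromosome.
#' @param lineage lineage label of the hybrid.
#' @return a `breedpop` whose chromosome count is the sum of the parents'.
#' @export
hybridize <- function(pop_a, pop_b, n_offspring = NULL, crossover_mean = 1,
                      lineage = "hybrid") {
  if (n_ind(pop_a) == 0L || n_ind(pop_b) == 0L)
    stop("cannot hybridize an empty population")
  if (identical(pop_a$lineage, pop_b$lineage))
    stop("hybridizing a population with itself is not allowed")
  if (is.null(n_offspring)) n_offspring <- min(n_ind(pop_a), n_ind(pop_b))
  half <- function(pop) {
    N <- n_ind(pop)
    dams <- sample.int(N, n_offspring, replace = TRUE)
    sires <- sample.int(N, n_offspring, replace = TRUE)
    while (any(bad <- sires == dams))
      sires[bad] <- sample.int(N, sum(bad), replace = TRUE)
    make_progeny(pop, dams, pop, sires, mu = 0,
                 crossover_mean = crossover_mean)
  }
  a <- half(pop_a); b <- half(pop_b)
  new_population(c(a$hap, b$hap), c(a$map, b$map),
                 c(a$chrom_len, b$chrom_len),
                 generation = max(pop_a$generation, pop_b$generation) + 1L,
                 lineage = lineage)
}

#' Forward simulation of the allohexaploid base population
#'
#' Runs the full demographic history: a monomorphic common diploid ancestor
#' accumulates mutation-drift variation; three speciation events fork the
#' three diploid progenitors (each founded by a random sample that expands
#' geometrically); two hybridizations form the tetraploid and then the
#' hexaploid; the hexaploid evolves to `end_generation`. Every generation
#' applies random mating between distinct parents, Poisson crossovers and
#' per-locus mutation. Parental lineages are retired once their descendants
#' exist.
#'
#' @param params a [sim_params()].
#' @param schedule an [event_schedule()].
#' @param verbose print progress every checkpoint.
#' @return the hexaploid `breedpop` at `end_generation`, with attribute
#'   `he_trace`: data.frame of heterozygosity checkpoints per lineage.
#' @export
run_forward <- function(params, schedule, verbose = FALSE) {
  stopifnot(inherits(params, "sim_params"), inherits(schedule, "event_schedule"))
  sp <- schedule$speciation_generations
  live <- list(ancestor = founder_population(
    params$founder_size, params$n_chromosomes_diploid,
    params$loci_per_chromosome, params$chromosome_length, "ancestor"))
  trace <- list()
  fork <- function(pop, lab) {
    founders <- sample.int(n_ind(pop), min(params$founder_size, n_ind(pop)))
    out <- subset_pop(pop, founders)
    out$lineage <- lab
    out
  }
  for (g in seq_len(schedule$end_generation)) {
    if (g == sp[1]) live$diploid1 <- fork(live$ancestor, "diploid1")
    if (g == sp[2]) live$diploid2 <- fork(live$ancestor, "diploid2")
    if (g == sp[3]) {
      live$diploid3 <- fork(live$ancestor, "diploid3")
      live$ancestor <- NULL # third progenitor formed; ancestor retired
    }
    if (g == schedule$tetraploid_hybridization) {
      if (is.null(live$diploid1) || is.null(live$diploid2))
        stop("tetraploid hybridization scheduled before both diploids exist")
      live$tetraploid <- hybridize(live$diploid1, live$diploid2,
                                   n_offspring = params$founder_size,
                                   crossover_mean = params$crossover_mean,
                                   lineage = "tetraploid")
      live$diploid1 <- live$diploid2 <- NULL
    }
    if (g == schedule$hexaploid_hybridization) {
      if (is.null(live$tetraploid) || is.null(live$diploid3))
        stop("hexaploid hybridization scheduled before its parents exist")
      live$hexaploid <- hybridize(live$tetraploid, live$diploid3,
                                  n_offspring = params$founder_size,
                                  crossover_mean = params$crossover_mean,
                                  lineage = "hexaploid")
      live$tetraploid <- live$diploid3 <- NULL
    }
    for (nm in names(live)) {
      live[[nm]] <- advance_lineage(live[[nm]], params)
      live[[nm]]$generation <- g
    }
    if (g %% schedule$equilibrium_check_interval == 0L) {
      for (nm in names(live))
        trace[[length(trace) + 1L]] <-
          data.frame(generation = g, lineage = nm, he = observed_he(live[[nm]]))
      if (verbose)
        message(sprintf("generation %d: %s", g,
                        paste(sprintf("%s He=%.4f", names(live),
                                      vapply(live, observed_he, 0)),
                              collapse = ", ")))
    }
  }
  out <- live$hexaploid
  if (is.null(out)) stop("schedule ended before the hexaploid was formed")
  attr(out, "he_trace") <- do.call(rbind, trace)
  out
}

#' Derive founder cultivars from the base population
#'
#' Each cultivar is founded by a random draw of plants from the base
#' population and evolved through additional generations of random mating
#' with no mutation, mimicking independent breeding histories of commercial
#' cultivars.
#'
#' @param base hexaploid base `breedpop`.
#' @param n_cultivars number of cultivars (20 in the full design).
#' @param founders_per_cultivar founder plants per cultivar (1,000 full scale).
#' @param generations generations of closed random mating per cultivar (100).
#' @param crossover_mean Poisson mean crossovers per chromosome.
#' @return list of `breedpop`s labelled `cultivar01`, ...
#' @export
derive_cultivars <- function(base, n_cultivars = 20,
                             founders_per_cultivar = 1000,
                             generations = 100, crossover_mean = 1) {
  if (founders_per_cultivar > n_ind(base))
    stop("founders_per_cultivar exceeds the base population size")
  lapply(seq_len(n_cultivars), function(i) {
    cv <- subset_pop(base, sample.int(n_ind(base), founders_per_cultivar))
    cv$lineage <- sprintf("cultivar%02d", i)
    g <- 0L
    while (g < generations) {
      cv <- random_mate(cv, mu = 0, crossover_mean = crossover_mean)
      g <- g + 1L
    }
    cv
  })
}

#' Scale presets for the simulator
#'
#' `"full"` is the full-scale configuration (cluster-sized: 10^4 individuals,
#' 21 x 10^5 loci, ~10^5 generations). `"desk"` is a reduced configuration
#' that preserves the scaled mutation-drift parameter 4*Ne*mu = 0.4 and all
#' structural ratios so the same code paths run on one CPU in minutes.
#'
#' @param preset `"full"` or `"desk"`.
#' @return list with elements `params` ([sim_params()]), `schedule`
#'   ([event_schedule()]), `cultivar` (derivation sizes), `traits`
#'   (trait-architecture sizes), `panel_size` (SNP panel size).
#' @export
base_preset <- function(preset = c("desk", "full")) {
  preset <- match.arg(preset)
  if (preset == "full") {
    list(preset = "full",
         params = sim_params(1e4, 7, 1e5, 100, 1e-5, 1, 100),
         schedule = event_schedule(c(8000, 8200, 15000), 16000, 25000,
                                   105000, 5000),
         cultivar = list(n = 20L, founders = 1000L, generations = 100L),
         traits = list(n_qtl = 1000L, n_shared = 500L,
                       n_large = c(HD = 20L, Q = 100L), var_large = 0.5),
         panel_size = 100000L)
  } else {
    # Ne=300 with mu chosen so 4*Ne*mu = 0.4 as at full scale
    list(preset = "desk",
         params = sim_params(300, 1, 1000, 100, 0.4 / (4 * 300), 1, 20,
                             founder_size = 60),
         schedule = event_schedule(c(400, 420, 750), 800, 1250, 2000, 250),
         cultivar = list(n = 20L, founders = 100L, generations = 25L),
         traits = list(n_qtl = 200L, n_shared = 100L,
                       n_large = c(HD = 20L, Q = 20L), var_large = 0.5),
         panel_size = 500L)
  }
}
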