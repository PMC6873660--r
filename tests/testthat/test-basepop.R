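test_that("a locus fixed in the founders stays fixed without mutation", {
  set.seed(1)
  pop <- founder_population(30, 2, 50)
  pop$hap <- lapply(pop$hap, function(h) { h[] <- 1L; h }) # fixed at allele 1
  for (g in 1:15) pop <- random_mate(pop, mu = 0)
  expect_true(all(allele_freq(pop) == 1))
})

test_that("new mutations per gamete match the binomial mean L * mu", {
  set.seed(2)
  mu <- 1e-5; L <- 1000
  pop <- founder_population(50, 1, L)
  n_off <- 50000 # 1e5 gametes
  dams <- sample.int(50, n_off, replace = TRUE)
  sires <- (dams %% 50) + 1L
  prog <- make_progeny(pop, dams, pop, sires, mu = mu)
  mutants <- sum(prog$hap[[1]]) # founders monomorphic 0: every 1 is a mutation
  rate <- mutants / (2 * n_off)
  expect_equal(rate, L * mu, tolerance = 0.3) # 0.01 +/- 3 MC SE
  expect_gt(rate, 0.007)
  expect_lt(rate, 0.013)
})

test_that("crossover count per chromosome per meiosis is Poisson(lambda)", {
  set.seed(3)
  L <- 1000
  pop <- founder_population(2, 1, L)
  # both parents heterozygous everywhere: switches in a gamete = crossovers
  pop$hap[[1]][, c(2, 4)] <- 1L
  n_off <- 15000 # 3e4 meioses
  prog <- make_progeny(pop, rep(1L, n_off), pop, rep(2L, n_off), mu = 0,
                       crossover_mean = 1)
  switches <- colSums(prog$hap[[1]][-1, , drop = FALSE] !=
                        prog$hap[[1]][-L, , drop = FALSE])
  expect_equal(mean(switches), 1.0, tolerance = 0.02)
})

test_that("hybridization concatenates chromosome sets (7+7=14, 14+7=21)", {
  set.seed(4)
  make_dip <- function(lab) {
    p <- founder_population(10, 7, 20, lineage = lab)
    p$hap <- lapply(p$hap, function(h) { h[] <- rbinom(length(h), 1, .5); h })
    p
  }
  d1 <- make_dip("diploid1"); d2 <- make_dip("diploid2"); d3 <- make_dip("diploid3")
  tet <- hybridize(d1, d2, n_offspring = 10, lineage = "tetraploid")
  expect_equal(n_chrom(tet), 14)
  hex <- hybridize(tet, d3, n_offspring = 10, lineage = "hexaploid")
  expect_equal(n_chrom(hex), 21)
  expect_equal(n_ind(hex), 10)
  # every chromosome still diploid: dosages within 0..2 by construction
  expect_true(all(dosage(hex) %in% 0:2))
  expect_error(hybridize(d1, d1), "itself")
})

test_that("run_forward executes the full demographic history", {
  set.seed(5)
  params <- sim_params(n_individuals = 40, n_chromosomes_diploid = 1,
                       loci_per_chromosome = 80, mutation_rate = 1e-3,
                       expansion_generations = 5, founder_size = 10)
  sched <- event_schedule(c(5, 6, 10), 12, 15, 40, 10)
  hex <- run_forward(params, sched)
  expect_equal(n_chrom(hex), 3)
  expect_equal(n_ind(hex), 40)
  expect_equal(hex$generation, 40)
  expect_equal(hex$lineage, "hexaploid")
  tr <- attr(hex, "he_trace")
  expect_true(is.data.frame(tr) && nrow(tr) > 0)
  expect_true(all(tr$he >= 0 & tr$he <= 0.5))
})

test_that("event schedules must be internally consistent", {
  expect_error(event_schedule(c(10, 5, 20), 30, 40, 50), "speciation")
  expect_error(event_schedule(c(5, 6, 10), 4, 40, 50), "tetraploid")
  expect_error(event_schedule(c(5, 6, 10), 12, 11, 50), "hexaploid")
  expect_error(event_schedule(c(5, 6, 10), 12, 15, 15), "end_generation")
})

test_that("cultivar derivation draws independent closed populations", {
  pop <- toy_pop(n = 200, n_chr = 1, loci = 100, gens = 80)
  set.seed(6)
  cvs <- derive_cultivars(pop, n_cultivars = 3, founders_per_cultivar = 40,
                          generations = 4)
  expect_length(cvs, 3)
  expect_true(all(vapply(cvs, n_ind, 0L) == 40))
  # no mutation: an allele absent from the base never appears in a cultivar
  absent <- allele_freq(pop) == 0
  for (cv in cvs) expect_true(all(allele_freq(cv)[absent] == 0))
  expect_error(derive_cultivars(pop, 2, founders_per_cultivar = 1000, 1),
               "exceeds")
})

test_that("expansion grows a founded taxon geometrically to the target", {
  set.seed(7)
  params <- sim_params(n_individuals = 64, n_chromosomes_diploid = 1,
                       loci_per_chromosome = 20, mutation_rate = 0,
                       expansion_generations = 6, founder_size = 8)
  pop <- founder_population(8, 1, 20)
  sizes <- integer(0)
  for (g in 1:8) {
    pop <- speedgs:::advance_lineage(pop, params)
    sizes <- c(sizes, n_ind(pop))
  }
  expect_true(all(diff(sizes) >= 0))
  expect_equal(sizes[length(sizes)], 64)
  expect_true(sizes[1] > 8) # growing from the first generation on
})
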