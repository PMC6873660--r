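#' @useDynLib speedgs, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom var sd cor setNames
NULL

#' Population of diploid-behaving genomes
#'
#' A `breedpop` holds per-chromosome haplotype matrices for a set of
#' individuals. The allohexaploid crop is treated as a diploid organism with
#' independent diploid chromosomes, so every chromosome carries exactly two
#' haplotypes per individual and allelic dosage at a locus is 0, 1 or 2.
#'
#' @param hap list of integer matrices, one per chromosome, `loci x 2N` with
#'   0/1 alleles; columns `2i-1`, `2i` are the haplotypes of individual `i`.
#' @param map list of numeric vectors of map positions in cM, one per
#'   chromosome, non-decreasing.
#' @param chrom_len numeric vector of chromosome lengths in cM.
#' @param generation integer generation index.
#' @param lineage character label for the taxon (e.g. `"ancestor"`,
#'   `"diploid1"`, `"tetraploid"`, `"hexaploid"`, `"cultivar"`).
#' @return an object of class `breedpop`.
#' @export
new_population <- function(hap, map, chrom_len, generation = 0L,
                           lineage = "base") {
  stopifnot(is.list(hap), is.list(map), length(hap) == length(map),
            length(chrom_len) == length(hap))
  nc <- vapply(hap, ncol, 0L)
  if (length(unique(nc)) != 1L || nc[1] %% 2L != 0L)
    stop("all chromosomes must carry the same even number of haplotype columns")
  for (k in seq_along(hap)) {
    if (nrow(hap[[k]]) != length(map[[k]]))
      stop("map length must equal locus count on chromosome ", k)
  }
  structure(list(hap = hap, map = map, chrom_len = as.numeric(chrom_len),
                 generation = as.integer(generation), lineage = lineage),
            class = "breedpop")
}

#' Number of individuals in a population
#' @param pop a `breedpop`.
#' @export
n_ind <- function(pop) ncol(pop$hap[[1]]) %/% 2L

#' Number of chromosomes
#' @param pop a `breedpop`.
#' @export
n_chrom <- function(pop) length(pop$hap)

#' Total locus count across chromosomes
#' @param pop a `breedpop`.
#' @export
n_loci <- function(pop) sum(vapply(pop$hap, nrow, 0L))

#' @export
print.breedpop <- function(x, ...) {
  cat(sprintf("<breedpop> %s: %d individuals, %d chromosomes, %d loci, generation %d\n",
              x$lineage, n_ind(x), n_chrom(x), n_loci(x), x$generation))
  invisible(x)
}

#' Founder population with uniform allele state
#'
#' Creates a monomorphic starting population (all alleles 0): variation then
#' accumulates by mutation-drift during the forward simulation.
#'
#' @param n number of individuals.
#' @param n_chromosomes number of chromosomes.
#' @param loci_per_chromosome loci per chromosome, equally spaced on the map.
#' @param chrom_len chromosome length in cM (recycled across chromosomes).
#' @param lineage lineage label.
#' @export
founder_population <- function(n, n_chromosomes, loci_per_chromosome,
                               chrom_len = 100, lineage = "ancestor") {
  stopifnot(n > 0, n_chromosomes > 0, loci_per_chromosome > 0)
  chrom_len <- rep_len(chrom_len, n_chromosomes)
  hap <- map <- vector("list", n_chromosomes)
  for (k in seq_len(n_chromosomes)) {
    hap[[k]] <- matrix(0L, loci_per_chromosome, 2L * n)
    # loci equally spaced, offset from the ends so crossovers are observable
    step <- chrom_len[k] / loci_per_chromosome
    map[[k]] <- seq(step / 2, chrom_len[k] - step / 2,
                    length.out = loci_per_chromosome)
  }
  new_population(hap, map, chrom_len, generation = 0L, lineage = lineage)
}

#' Subset individuals of a population
#' @param pop a `breedpop`.
#' @param individuals integer indices of the individuals to keep.
#' @export
subset_pop <- function(pop, individuals) {
  stopifnot(all(individuals >= 1), all(individuals <= n_ind(pop)))
  cols <- as.vector(rbind(2L * individuals - 1L, 2L * individuals))
  hap <- lapply(pop$hap, function(h) h[, cols, drop = FALSE])
  new_population(hap, pop$map, pop$chrom_len, pop$generation, pop$lineage)
}

#' Global locus table
#'
#' Loci are indexed globally in chromosome order; this returns the mapping
#' from global index to chromosome and map position.
#'
#' @param pop a `breedpop`.
#' @return data.frame with columns `locus`, `chrom`, `within`, `pos_cM`.
#' @export
locus_table <- function(pop) {
  L <- vapply(pop$hap, nrow, 0L)
  data.frame(locus = seq_len(sum(L)),
             chrom = rep(seq_along(L), L),
             within = unlist(lapply(L, seq_len), use.names = FALSE),
             pos_cM = unlist(pop$map, use.names = FALSE))
}

#' Allelic dosage matrix
#'
#' @param pop a `breedpop`.
#' @param loci global locus indices (default: all loci).
#' @param individuals individual indices (default: all).
#' @return integer matrix, individuals x loci, entries in 0:2, columns in the
#'   order of `loci`.
#' @export
dosage <- function(pop, loci = NULL, individuals = NULL) {
  if (is.null(individuals)) individuals <- seq_len(n_ind(pop))
  if (is.null(loci)) loci <- seq_len(n_loci(pop))
  L <- vapply(pop$hap, nrow, 0L)
  offs <- cumsum(c(0L, L[-length(L)]))
  chrom <- findInterval(loci - 1L, cumsum(L)) + 1L
  out <- matrix(0L, length(individuals), length(loci))
  for (k in unique(chrom)) {
    sel <- which(chrom == k)
    out[, sel] <- cpp_dosage(pop$hap[[k]], as.integer(individuals),
                             as.integer(loci[sel] - offs[k]))
  }
  out
}

#' Allele frequencies
#'
#' Frequency of the `1` allele at each locus.
#' @param pop a `breedpop`.
#' @param loci global locus indices (default: all).
#' @export
allele_freq <- function(pop, loci = NULL) {
  if (is.null(loci)) {
    unlist(lapply(pop$hap, rowMeans), use.names = FALSE)
  } else {
    af <- unlist(lapply(pop$hap, rowMeans), use.names = FALSE)
    af[loci]
  }
}

#' Observed expected-heterozygosity
#'
#' Mean over loci of \eqn{2p(1-p)} with `p` the allele frequency in the
#' population, the biallelic form of expected heterozygosity.
#' @param pop a `breedpop`.
#' @param loci optional global locus indices.
#' @export
observed_he <- function(pop, loci = NULL) {
  if (n_ind(pop) == 0L) stop("empty population")
  p <- allele_freq(pop, loci)
  mean(2 * p * (1 - p))
}

#' Generate progeny from chosen parent pairs
#'
#' Each offspring receives one recombined gamete from its dam and one from its
#' sire; chromosomes assort independently. Dams and sires may live in
#' different populations with the same genome layout (e.g. two cultivars).
#'
#' @param dam_pop,sire_pop `breedpop`s with identical maps.
#' @param dams,sires parallel vectors of individual indices, one offspring per
#'   entry.
#' @param mu per-locus mutation probability (allele flip); 0 during breeding.
#' @param crossover_mean Poisson mean crossovers per chromosome per meiosis.
#' @param lineage lineage label of the progeny population.
#' @return a `breedpop` of `length(dams)` offspring.
#' @export
make_progeny <- function(dam_pop, dams, sire_pop = dam_pop, sires, mu = 0,
                         crossover_mean = 1, lineage = dam_pop$lineage) {
  stopifnot(length(dams) == length(sires))
  if (!isTRUE(all.equal(dam_pop$chrom_len, sire_pop$chrom_len)))
    stop("parent populations have different genome layouts")
  m <- length(dams)
  hap <- vector("list", n_chrom(dam_pop))
  for (k in seq_len(n_chrom(dam_pop))) {
    g1 <- cpp_gametes(dam_pop$hap[[k]], as.integer(dams), dam_pop$map[[k]],
                      dam_pop$chrom_len[k], crossover_mean, mu)
    g2 <- cpp_gametes(sire_pop$hap[[k]], as.integer(sires), sire_pop$map[[k]],
                      sire_pop$chrom_len[k], crossover_mean, mu)
    h <- matrix(0L, nrow(g1), 2L * m)
    h[, seq(1L, 2L * m, 2L)] <- g1
    h[, seq(2L, 2L * m, 2L)] <- g2
    hap[[k]] <- h
  }
  new_population(hap, dam_pop$map, dam_pop$chrom_len,
                 generation = dam_pop$generation + 1L, lineage = lineage)
}

#' One generation of random mating (no selfing)
#'
#' Parents are drawn uniformly with replacement; dam and sire of an offspring
#' are always distinct individuals, reflecting the self-incompatibility of
#' allogamous species.
#'
#' @param pop a `breedpop` with at least 2 individuals.
#' @param n_offspring size of the next generation (default: same size).
#' @param mu per-locus mutation probability.
#' @param crossover_mean Poisson mean crossovers per chromosome.
#' @export
random_mate <- function(pop, n_offspring = n_ind(pop), mu = 0,
                        crossover_mean = 1) {
  N <- n_ind(pop)
  if (N < 2L) stop("random mating needs at least two individuals")
  dams <- sample.int(N, n_offspring, replace = TRUE)
  sires <- sample.int(N, n_offspring, replace = TRUE)
  while (any(bad <- sires == dams))
    sires[bad] <- sample.int(N, sum(bad), replace = TRUE)
  make_progeny(pop, dams, pop, sires, mu = mu, crossover_mean = crossover_mean)
}
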