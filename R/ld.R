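#' Expected linkage-disequilibrium r-squared
#'
#' Sved's drift-recombination expectation with the finite-sample correction:
#' \eqn{E(r^2) = 1/(2 + 4 Ne C) + 1/n}, with `C` the genetic distance in
#' Morgan and `n` the sample size used to estimate r-squared.
#'
#' @param Ne effective population size.
#' @param C genetic distance in Morgan (may be a vector).
#' @param n sample size.
#' @export
expected_ld <- function(Ne, C, n) {
  stopifnot(Ne > 0, all(C >= 0), n > 0)
  1 / (2 + 4 * Ne * C) + 1 / n
}

#' Expected heterozygosity at mutation-drift equilibrium
#'
#' Biallelic-locus equilibrium expectation
#' \eqn{E(He) = 4 Ne \mu / (8 Ne \mu + 1)}, which accounts for the presence
#' of only two alleles per locus (back-mutation model).
#'
#' @param Ne effective population size.
#' @param mu per-locus per-generation mutation rate.
#' @export
expected_he <- function(Ne, mu) {
  stopifnot(Ne > 0, mu >= 0)
  4 * Ne * mu / (8 * Ne * mu + 1)
}

#' Pairwise linkage disequilibrium within chromosomes
#'
#' r-squared computed as the squared Pearson correlation of allelic
#' indicators over haplotypes, for every pair of loci on the same chromosome
#' with minor allele frequency above `maf_min`, summarized in genetic
#' distance bins.
#'
#' @param pop a `breedpop`.
#' @param maf_min minor-allele-frequency threshold (pairs restricted to loci
#'   with MAF > `maf_min`; default 0.05).
#' @param bin_width distance bin width in Morgan for the summary.
#' @param max_pairs_per_chrom optional cap on pairs per chromosome (random
#'   subsample, for very dense maps).
#' @return object of class `ld_summary`: list with `pairs` (data.frame of
#'   `distance_M`, `r2`), `bins` (data.frame of `mid_M`, `mean_r2`, `n`),
#'   `heterozygosity`, `n_hap`, and `empty` flag when no pair qualifies.
#' @export
ld_r2 <- function(pop, maf_min = 0.05, bin_width = 0.01,
                  max_pairs_per_chrom = NULL) {
  if (n_ind(pop) == 0L) stop("empty population")
  dist_all <- r2_all <- list()
  for (k in seq_len(n_chrom(pop))) {
    H <- pop$hap[[k]]
    p <- rowMeans(H)
    keep <- which(pmin(p, 1 - p) > maf_min)
    if (length(keep) < 2L) next
    Ht <- t(H[keep, , drop = FALSE]) # haplotypes x loci
    cc <- suppressWarnings(cor(Ht))
    pos <- pop$map[[k]][keep] / 100 # cM -> Morgan
    ut <- upper.tri(cc)
    d <- abs(outer(pos, pos, "-"))[ut]
    r2 <- cc[ut]^2
    ok <- is.finite(r2)
    d <- d[ok]; r2 <- r2[ok]
    if (!is.null(max_pairs_per_chrom) && length(r2) > max_pairs_per_chrom) {
      sub <- sample.int(length(r2), max_pairs_per_chrom)
      d <- d[sub]; r2 <- r2[sub]
    }
    dist_all[[k]] <- d; r2_all[[k]] <- r2
  }
  d <- unlist(dist_all); r2 <- unlist(r2_all)
  he <- observed_he(pop)
  if (!length(r2)) {
    out <- list(pairs = data.frame(distance_M = numeric(), r2 = numeric()),
                bins = data.frame(mid_M = numeric(), mean_r2 = numeric(),
                                  n = integer()),
                heterozygosity = he, n_hap = 2L * n_ind(pop), empty = TRUE)
    class(out) <- "ld_summary"
    return(out)
  }
  brk <- seq(0, max(d) + bin_width, by = bin_width)
  bin <- cut(d, brk, include.lowest = TRUE)
  bins <- data.frame(mid_M = (brk[-length(brk)] + brk[-1]) / 2,
                     mean_r2 = as.numeric(tapply(r2, bin, mean)),
                     n = as.integer(table(bin)))
  bins <- bins[!is.na(bins$mean_r2) & bins$n > 0, , drop = FALSE]
  out <- list(pairs = data.frame(distance_M = d, r2 = r2), bins = bins,
              heterozygosity = he, n_hap = 2L * n_ind(pop), empty = FALSE)
  class(out) <- "ld_summary"
  out
}

#' @export
print.ld_summary <- function(x, ...) {
  cat(sprintf("<ld_summary> %d pairs, He = %.4f%s\n", nrow(x$pairs),
              x$heterozygosity, if (x$empty) " (no qualifying pair)" else ""))
  invisible(x)
}
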