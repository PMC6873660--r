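test_that("expected LD and heterozygosity closed forms evaluate correctly", {
  expect_equal(expected_ld(1e4, 0.01, 100), 1 / (2 + 4e4 * 0.01) + 1 / 100)
  expect_equal(expected_ld(1e4, 0.01, 100), 0.0124875621890547, tolerance = 1e-12)
  # C = 0 and huge n: first term alone, 1/2
  expect_equal(expected_ld(5, 0, 1e9), 0.5, tolerance = 1e-8)
  # very distant loci: only the sample-size term remains
  expect_equal(expected_ld(1e4, 1e9, 50), 1 / 50, tolerance = 1e-6)
  expect_equal(round(expected_he(1e4, 1e-5), 4), 0.2222)
  expect_equal(expected_he(1e4, 0), 0)
  expect_equal(expected_he(1e4, 1e-4), 4 / 9)
})

test_that("observed heterozygosity is the mean of 2p(1-p) over loci", {
  H <- rbind(c(1L, 0L, 0L, 0L), # p = 1/4 -> 0.375
             c(1L, 1L, 0L, 0L), # p = 1/2 -> 0.5
             c(1L, 1L, 1L, 1L)) # fixed   -> 0
  pop <- pop_from_hap(H)
  expect_equal(observed_he(pop), mean(c(0.375, 0.5, 0)))
  # all fixed
  H2 <- matrix(0L, 3, 4)
  expect_equal(observed_he(pop_from_hap(H2)), 0)
})

test_that("r2 is 1 for loci in perfect coupling and ~0 for independent loci", {
  set.seed(8)
  col <- rbinom(400, 1, 0.5)
  H <- rbind(matrix(col, 1), matrix(col, 1)) # identical allele columns
  storage.mode(H) <- "integer"
  ld <- ld_r2(pop_from_hap(H), maf_min = 0.05)
  expect_equal(ld$pairs$r2, 1)
  # independent loci at freq 0.5, large haplotype sample
  H3 <- matrix(rbinom(2 * 4000, 1, 0.5), nrow = 2)
  storage.mode(H3) <- "integer"
  ld3 <- ld_r2(pop_from_hap(H3), maf_min = 0.05)
  expect_lt(ld3$pairs$r2, 0.01)
})

test_that("ld_r2 matches a hand-computed Pearson correlation on a printed panel", {
  # 3 haplotypes (not a valid diploid count alone, use 4 with a duplicate)
  H <- rbind(c(1L, 0L, 1L, 0L),
             c(1L, 1L, 0L, 0L))
  pop <- pop_from_hap(H)
  r_hand <- cor(c(1, 0, 1, 0), c(1, 1, 0, 0))^2
  ld <- ld_r2(pop, maf_min = 0.05)
  expect_equal(ld$pairs$r2, r_hand)
})

test_that("ld_r2 equals the brute-force per-pair oracle on small panels", {
  for (seed in 1:5) {
    set.seed(seed)
    L <- 8
    H <- matrix(rbinom(L * 60, 1, runif(1, .2, .8)), nrow = L)
    storage.mode(H) <- "integer"
    pop <- pop_from_hap(H)
    ld <- ld_r2(pop, maf_min = 0.05)
    p <- rowMeans(H)
    keep <- which(pmin(p, 1 - p) > 0.05)
    oracle <- c()
    if (length(keep) >= 2) {
      for (a in seq_along(keep)[-length(keep)])
        for (b in (a + 1):length(keep))
          oracle <- c(oracle, cor(H[keep[a], ], H[keep[b], ])^2)
      oracle <- oracle[is.finite(oracle)]
      expect_equal(sort(ld$pairs$r2), sort(oracle), tolerance = 1e-12)
    }
  }
})

test_that("no qualifying pair yields an empty, flagged summary", {
  H <- matrix(0L, 5, 10) # monomorphic everywhere
  ld <- ld_r2(pop_from_hap(H))
  expect_true(ld$empty)
  expect_equal(nrow(ld$pairs), 0)
})

test_that("binned mean r2 decays with genetic distance in the base population", {
  world <- desk_world(101)
  set.seed(102)
  ld <- ld_r2(world$base, maf_min = 0.05, bin_width = 0.1)
  bins <- ld$bins[ld$bins$n > 500, , drop = FALSE]
  expect_gte(nrow(bins), 5)
  inversions <- sum(diff(bins$mean_r2) > 0)
  # monotone decay, allowing one noise inversion per 10 bins
  expect_lte(inversions, max(1, nrow(bins) %/% 10))
  # near-distance LD clearly above the far-distance background
  expect_gt(bins$mean_r2[1], bins$mean_r2[nrow(bins)])
})
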