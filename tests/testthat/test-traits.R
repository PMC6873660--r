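test_that("the large-effect variance multiplier solves the variance partition", {
  # l * m / (l * m + (n - l)) = e
  oracle <- function(e, n, l) uniroot(function(m)
    l * m / (l * m + (n - l)) - e, c(1e-9, 1e6))$root
  expect_equal(scaled_variance_m(0.5, 1000, 20), 49)
  expect_equal(scaled_variance_m(0.5, 1000, 20), oracle(0.5, 1000, 20),
               tolerance = 1e-6)
  expect_equal(scaled_variance_m(0.5, 1000, 100), 9)
  expect_equal(scaled_variance_m(0.5, 1000, 100), oracle(0.5, 1000, 100),
               tolerance = 1e-6)
  expect_equal(scaled_variance_m(0, 1000, 20), 0)
  expect_lt(scaled_variance_m(1e-4, 1000, 20), 0.01)
  expect_error(scaled_variance_m(0.5, 1000, 0), "positive")
  expect_error(scaled_variance_m(0.5, 10, 10), "smaller")
})

test_that("raw effect sampling respects the per-trait mixtures", {
  specs <- trait_specs() # full-scale architecture
  set.seed(31)
  r <- sample_raw_effects(specs)
  expect_equal(dim(r$R), c(1000, 5))
  expect_equal(colSums(r$large), c(FY = 0, HD = 20, SY = 0, Q = 100, Per = 0))
  expect_equal(var(r$R[, "FY"]), 1, tolerance = 0.2)
  # HD large-effect class explains ~half the effect variance (100 draws)
  shares <- replicate(100, {
    x <- sample_raw_effects(specs)
    sum(x$R[x$large[, "HD"], "HD"]^2) / sum(x$R[, "HD"]^2)
  })
  expect_equal(mean(shares), 0.5, tolerance = 0.06) # 0.5 +/- 0.03
  # determinism under a fixed seed
  set.seed(77); a <- sample_raw_effects(specs)
  set.seed(77); b <- sample_raw_effects(specs)
  expect_identical(a, b)
})

test_that("Cholesky rescaling imposes the target correlation exactly", {
  # small instance with hand-chosen rows: empirical correlation equals C
  R <- cbind(c(3, -1, 0.5, 2, -2, 1), c(0.2, 1.5, -0.7, 0.1, 0.9, -1.2))
  C <- matrix(c(1, 0.3, 0.3, 1), 2)
  out <- correlate_effects(R, C)
  expect_equal(unname(cov(out$RS)), diag(2), tolerance = 1e-12)
  expect_equal(unname(cor(out$final)), C, tolerance = 1e-12)
  # identity target: output is the rescaled matrix itself
  out_id <- correlate_effects(R, diag(2))
  expect_equal(out_id$final, out_id$RS)
  # mixture columns at scale: recovery of a 0.3 target
  set.seed(32)
  Rbig <- cbind(rnorm(20000), c(rnorm(400, sd = 7), rnorm(19600)))
  out_big <- correlate_effects(Rbig, C)
  expect_equal(cor(out_big$final)[1, 2], 0.3, tolerance = 1e-10)
  # degenerate input is rejected with guidance
  expect_error(correlate_effects(cbind(1:4, 2 * (1:4)), C), "rank deficient")
})

test_that("full-architecture targets hold with the mixture preserved", {
  specs <- trait_specs()
  targets <- correlation_targets()
  set.seed(33)
  r <- sample_raw_effects(specs)
  # correlate the FY/SY/HD trio directly (all-shared limit of the block rule)
  trio <- c("FY", "HD", "SY")
  out <- correlate_effects(r$R[, trio], targets$C[trio, trio])
  expect_equal(unname(cor(out$final)), unname(targets$C[trio, trio]),
               tolerance = 1e-10)
})

test_that("QTL assignment enforces sharing, MAF and disjointness", {
  world <- toy_world()
  q <- world$qtl
  expect_length(intersect(q$traits$FY$loci, q$traits$SY$loci), 12)
  expect_length(intersect(q$traits$FY$loci, q$traits$HD$loci), 12)
  expect_length(intersect(q$traits$SY$loci, q$traits$HD$loci), 12)
  expect_length(intersect(q$traits$FY$loci, q$traits$Q$loci), 0)
  expect_length(intersect(q$traits$Q$loci, q$traits$Per$loci), 0)
  p <- allele_freq(world$base)
  for (tr in names(q$traits)) {
    maf <- pmin(p[q$traits[[tr]]$loci], 1 - p[q$traits[[tr]]$loci])
    expect_true(all(maf > 0.05))
    expect_length(q$traits[[tr]]$loci, 20)
  }
  # large effects sit on private loci so the shared block stays unit-variance
  hd <- world$effects$traits$HD
  expect_false(any(hd$is_large & hd$is_shared))
  expect_equal(sum(hd$is_large), 3)
})

test_that("breeding values are dosage-weighted sums of QTL effects", {
  H <- rbind(c(1L, 0L), c(1L, 1L), c(0L, 0L)) # one plant, dosages 1, 2, 0
  pop <- pop_from_hap(H)
  eff <- structure(list(traits = list(
    FY = list(loci = 1:3, effects = c(0.5, -1, 2)))), class = "trait_effects")
  expect_equal(unname(true_breeding_value(pop, eff)[1, 1]), -1.5)
  # all-zero dosages
  pop0 <- pop_from_hap(matrix(0L, 3, 2))
  expect_equal(unname(true_breeding_value(pop0, eff)[1, 1]), 0)
  # one QTL, effect 2, dosage 2
  pop2 <- pop_from_hap(matrix(1L, 1, 2))
  eff2 <- structure(list(traits = list(FY = list(loci = 1, effects = 2))),
                    class = "trait_effects")
  expect_equal(unname(true_breeding_value(pop2, eff2)[1, 1]), 4)
})

test_that("phenotypes realize the nominal heritability", {
  set.seed(34)
  tbv <- matrix(rnorm(20000, sd = 2), ncol = 1, dimnames = list(NULL, "Per"))
  specs <- trait_specs()
  ev <- refresh_error_variances(tbv, specs)
  expect_equal(unname(ev["Per"]), var(tbv[, 1]) * 0.9 / 0.1) # h2 = 0.1 -> 9x
  ph <- phenotype(tbv, ev)
  fit <- coef(lm(tbv[, 1] ~ ph[, 1]))[2]
  expect_equal(unname(fit), 0.1, tolerance = 0.3) # slope ~ h2 +/- 0.03
  # h2 = 1: phenotype equals TBV
  ph1 <- phenotype(tbv, c(Per = 0))
  expect_identical(ph1, tbv)
})

test_that("realized genetic correlations track the targets across draws", {
  cors <- t(vapply(1:8, function(s) {
    w <- desk_world(400 + s)
    cc <- cor(true_breeding_value(w$base, w$effects))
    c(cc["FY", "SY"], cc["FY", "HD"], cc["SY", "HD"], cc["Q", "Per"])
  }, numeric(4)))
  m <- colMeans(cors)
  expect_equal(m[1], 0.2, tolerance = 0.5)  # +/- 0.1 at 8 draws
  expect_equal(m[2], 0.3, tolerance = 0.34)
  expect_lt(abs(m[3]), 0.1)
  expect_lt(abs(m[4]), 0.1)
})
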