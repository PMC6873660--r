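test_that("the SNP panel excludes QTL and respects MAF and size", {
  world <- toy_world()
  expect_length(world$panel$loci, 40)
  expect_length(intersect(world$panel$loci, world$qtl$all_loci), 0)
  p <- allele_freq(world$base)[world$panel$loci]
  expect_true(all(pmin(p, 1 - p) > 0.05))
  set.seed(42); a <- build_snp_panel(world$base, world$qtl, 40)
  set.seed(42); b <- build_snp_panel(world$base, world$qtl, 40)
  expect_identical(a, b)
  expect_error(build_snp_panel(world$base, world$qtl, 1e6), "eligible")
})

test_that("pooled plot genotypes are twice the sample allele frequency", {
  # 20 plants homozygous alternate at locus 1; 10 het / 10 ref at locus 2;
  # all reference at locus 3
  H <- matrix(0L, 3, 40)
  H[1, ] <- 1L
  H[2, seq(1, 39, 2)[1:10]] <- 1L
  pop <- pop_from_hap(H)
  panel <- structure(list(loci = 1:3, base_freq = c(.5, .5, .5)),
                     class = "snp_panel")
  row <- pool_plot_genotype(pop, 1:20, panel, sample_size = 20)
  expect_equal(as.vector(row), c(2, 0.5, 0))
  expect_false(attr(row, "undersized"))
  row2 <- pool_plot_genotype(pop, 1:5, panel, sample_size = 20)
  expect_true(attr(row2, "undersized"))
})

test_that("the ridge path solves (X'X + lambda I)^-1 X'y exactly", {
  set.seed(51)
  for (dims in list(c(12, 6), c(5, 10))) { # primal and dual branches
    Z <- matrix(rnorm(dims[1] * dims[2]), dims[1])
    y <- rnorm(dims[1])
    lam <- 3.7
    fit <- fit_brr(Z, y, method = "ridge", lambda = lam)
    Zc <- scale(Z, center = TRUE, scale = FALSE)
    beta_o <- solve(crossprod(Zc) + diag(lam, ncol(Z)),
                    crossprod(Zc, y - mean(y)))
    expect_equal(fit$beta, drop(beta_o), tolerance = 1e-10)
  }
})

test_that("Gibbs BRR with fixed variances converges to the ridge oracle", {
  set.seed(52)
  Z <- matrix(rnorm(15 * 10), 15)
  y <- drop(Z %*% rnorm(10, sd = .5)) + rnorm(15)
  ridge <- fit_brr(Z, y, h2 = 0.5, method = "ridge")
  gibbs <- fit_brr(Z, y, h2 = 0.5, method = "gibbs", iterations = 6000,
                   burn_in = 1000, fix_variances = TRUE)
  scale_ref <- max(abs(ridge$beta))
  expect_lt(max(abs(gibbs$beta - ridge$beta)) / scale_ref, 0.02)
  # free-variance sampler also runs and lands in the same neighbourhood
  set.seed(53)
  gibbs2 <- fit_brr(Z, y, h2 = 0.5, method = "gibbs", iterations = 2500,
                    burn_in = 500)
  expect_gt(cor(gibbs2$beta, ridge$beta), 0.9)
  # determinism under a fixed seed
  set.seed(54); g1 <- fit_brr(Z, y, method = "gibbs", iterations = 200, burn_in = 50)
  set.seed(54); g2 <- fit_brr(Z, y, method = "gibbs", iterations = 200, burn_in = 50)
  expect_identical(g1, g2)
})

test_that("degenerate phenotypes give an intercept-only model", {
  Z <- matrix(rnorm(20), 5)
  expect_warning(fit <- fit_brr(Z, rep(2, 5)), "constant")
  expect_true(all(fit$beta == 0))
  expect_equal(predict_gebv(fit, Z), rep(2, 5))
})

test_that("GEBV prediction is the dosage-effect product", {
  fit <- structure(list(intercept = 0, beta = 0.5, col_center = 0,
                        method = "ridge"), class = "brr_fit")
  g <- predict_gebv(fit, matrix(c(0, 1, 2), 3))
  expect_equal(diff(g), c(0.5, 0.5)) # (0, 0.5, 1.0) up to centering
  expect_error(predict_gebv(fit, matrix(0, 1, 3)), "match")
})

test_that("prediction accuracy is the Pearson correlation with TBV", {
  expect_equal(gebv_accuracy(1:5, 1:5), 1)
  expect_equal(gebv_accuracy(1:5, -(1:5)), -1)
  expect_equal(gebv_accuracy(c(1, 2, 3, 4), c(1, 2, 4, 3)), 0.8)
  expect_true(is.na(gebv_accuracy(rep(1, 4), 1:4)))
})

test_that("a larger reference population does not hurt accuracy", {
  world <- desk_world(600)
  set.seed(601)
  cfg <- scheme_config("S4", sb_rounds = 1, preset = "desk")
  deltas <- vapply(1:5, function(r) {
    wu <- run_warmup(world, cfg)
    f1 <- stage_crossing(wu$cultivars, world, cfg)
    cand <- subset_cohort(f1, sample.int(n_ind(f1$pop), cfg$speedgs_pop))
    Z <- dosage(cand$pop, loci = world$panel$loci)
    acc_for <- function(ref) {
      mean(vapply(world$specs$trait, function(tr) {
        h2 <- world$specs$h2[world$specs$trait == tr]
        fit <- fit_brr(ref$Z, ref$pheno[, tr], h2 = h2, method = "ridge")
        gebv_accuracy(predict_gebv(fit, Z), cand$tbv[, tr])
      }, 0))
    }
    small <- list(Z = wu$reference$Z[1:30, ], pheno = wu$reference$pheno[1:30, ])
    acc_for(wu$reference) - acc_for(small)
  }, 0)
  expect_gt(mean(deltas), -0.02)
})
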