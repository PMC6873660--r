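#' Build the genotyping SNP panel
#'
#' Uniform random draw without replacement from loci with base-population
#' minor allele frequency above `maf_min`, excluding every trait's QTL
#' (causal variants are never genotyped). Panel loci may later drift to
#' fixation; they are kept in the panel regardless.
#'
#' @param base hexaploid base `breedpop`.
#' @param qtl a [assign_qtl()] result (its loci are excluded).
#' @param size panel size (100,000 at full scale).
#' @param maf_min MAF eligibility threshold in the base population.
#' @return object of class `snp_panel`: list with `loci` (sorted global
#'   indices) and `base_freq` (allele frequencies at those loci in the base
#'   population, the fixed allele coding reference).
#' @export
build_snp_panel <- function(base, qtl, size, maf_min = 0.05) {
  p <- allele_freq(base)
  eligible <- setdiff(which(pmin(p, 1 - p) > maf_min), qtl$all_loci)
  if (length(eligible) < size)
    stop(sprintf("only %d eligible non-QTL loci for a panel of %d",
                 length(eligible), size))
  loci <- sort(sample(eligible, size))
  structure(list(loci = loci, base_freq = p[loci]), class = "snp_panel")
}

#' Pooled plot genotype
#'
#' Plots are genotyped as a pool: the dosage row is 2 x the allele frequency
#' among a random sample of plants (20 at full scale), i.e. the mean allelic
#' dosage of the sampled plants, a fractional value in [0, 2] per SNP.
#'
#' @param pop `breedpop` containing the plot members.
#' @param members indices of the plot's member plants.
#' @param panel a [build_snp_panel()] result.
#' @param sample_size plants sampled for genotyping (default 20). If the plot
#'   has fewer members, all are pooled and the result carries attribute
#'   `undersized = TRUE`.
#' @return numeric vector of pooled dosages, one per panel SNP.
#' @export
pool_plot_genotype <- function(pop, members, panel, sample_size = 20) {
  undersized <- length(members) < sample_size
  take <- if (undersized) members else sample(members, sample_size)
  row <- colMeans(dosage(pop, loci = panel$loci, individuals = take))
  attr(row, "undersized") <- undersized
  row
}

#' Fit a Bayesian ridge regression marker-effect model
#'
#' Gaussian prior with one common effect variance across SNPs. Two paths:
#' `method = "gibbs"` runs a blocked Gibbs sampler with scaled-inverse-
#' chi-square hyperpriors on the effect and residual variances (posterior
#' mean of the SNP effects is returned); `method = "ridge"` solves the
#' equivalent ridge system at a fixed variance ratio, the fast deterministic
#' path used by scheme runs. With variances fixed, the Gibbs posterior mean
#' converges to the ridge solution.
#'
#' @param Z reference genotype matrix (rows = plots/plants, columns = panel
#'   SNPs; fractional pooled dosages allowed).
#' @param y phenotype vector.
#' @param h2 trait heritability used to set the prior variance ratio.
#' @param method `"ridge"` or `"gibbs"`.
#' @param iterations,burn_in Gibbs settings (50,000 / 10,000 at full scale;
#'   reduce for small instances).
#' @param df_prior degrees of freedom of both scaled-inv-chi-square priors.
#' @param fix_variances if `TRUE` (Gibbs), keep effect and residual variances
#'   fixed at their prior modes instead of sampling them (oracle-comparison
#'   mode).
#' @param lambda optional explicit ridge penalty overriding the `h2`-derived
#'   ratio.
#' @return object of class `brr_fit`: `intercept`, `beta`, `method`,
#'   `col_center`, and for Gibbs the sampled variance summaries.
#' @export
fit_brr <- function(Z, y, h2 = 0.5, method = c("ridge", "gibbs"),
                    iterations = 2000, burn_in = 500, df_prior = 5,
                    fix_variances = FALSE, lambda = NULL) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  stopifnot(nrow(Z) == length(y), nrow(Z) >= 2)
  if (stats::var(y) == 0) {
    warning("constant phenotype vector; returning an intercept-only model")
    return(structure(list(intercept = y[1], beta = rep(0, ncol(Z)),
                          method = method, col_center = colMeans(Z)),
                     class = "brr_fit"))
  }
  ctr <- colMeans(Z)
  Zc <- sweep(Z, 2, ctr)
  yc <- y - mean(y)
  n <- nrow(Zc); p <- ncol(Zc)
  sum_col_var <- sum(apply(Zc, 2, stats::var))
  if (is.null(lambda)) {
    # prior variance ratio from h2: sigma_b^2 = h2 var(y) / sum_j var(z_j)
    sigma_b2 <- h2 * stats::var(y) / max(sum_col_var, .Machine$double.eps)
    sigma_e2 <- (1 - h2) * stats::var(y)
    lambda <- sigma_e2 / sigma_b2
  } else {
    sigma_b2 <- stats::var(y) * h2 / max(sum_col_var, .Machine$double.eps)
    sigma_e2 <- lambda * sigma_b2
  }
  if (method == "ridge") {
    beta <- ridge_solve(Zc, yc, lambda)
    return(structure(list(intercept = mean(y), beta = beta, method = "ridge",
                          lambda = lambda, col_center = ctr),
                     class = "brr_fit"))
  }
  # blocked Gibbs: beta | variances is multivariate normal around the ridge
  # solution; variances get scaled-inv-chi-square updates
  S_b <- sigma_b2 * (df_prior + 2) / df_prior # prior mode = sigma_b2
  S_e <- sigma_e2 * (df_prior + 2) / df_prior
  ZtZ <- crossprod(Zc)
  Zty <- crossprod(Zc, yc)
  beta <- rep(0, p)
  sb2 <- sigma_b2; se2 <- sigma_e2
  beta_sum <- rep(0, p); n_keep <- 0L
  sb2_kept <- se2_kept <- numeric(max(iterations - burn_in, 0L))
  for (it in seq_len(iterations)) {
    Cmat <- ZtZ + diag(se2 / sb2, p)
    ch <- chol(Cmat)
    mu <- backsolve(ch, forwardsolve(t(ch), Zty))
    beta <- drop(mu + backsolve(ch, rnorm(p)) * sqrt(se2))
    if (!fix_variances) {
      sb2 <- (sum(beta^2) + df_prior * S_b) /
        stats::rchisq(1, df = df_prior + p)
      res <- yc - Zc %*% beta
      se2 <- (sum(res^2) + df_prior * S_e) /
        stats::rchisq(1, df = df_prior + n)
    }
    if (it > burn_in) {
      beta_sum <- beta_sum + beta
      n_keep <- n_keep + 1L
      sb2_kept[n_keep] <- sb2; se2_kept[n_keep] <- se2
    }
  }
  structure(list(intercept = mean(y), beta = beta_sum / n_keep,
                 method = "gibbs", lambda = lambda, col_center = ctr,
                 sigma_b2 = mean(sb2_kept), sigma_e2 = mean(se2_kept)),
            class = "brr_fit")
}

# ridge solution (X'X + lambda I)^-1 X'y via the cheaper of the primal and
# dual forms
ridge_solve <- function(Zc, yc, lambda) {
  n <- nrow(Zc); p <- ncol(Zc)
  if (p <= n) {
    drop(solve(crossprod(Zc) + diag(lambda, p), crossprod(Zc, yc)))
  } else {
    K <- tcrossprod(Zc)
    alpha <- solve(K + diag(lambda, n), yc)
    drop(crossprod(Zc, alpha))
  }
}

#' Predict genomic estimated breeding values
#'
#' `GEBV = Z beta` plus the model intercept (which cancels in any ranking).
#'
#' @param fit a [fit_brr()] model.
#' @param Z candidate dosage matrix with columns matching the training panel.
#' @return numeric vector of GEBVs.
#' @export
predict_gebv <- function(fit, Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) != length(fit$beta))
    stop("candidate genotype columns do not match the trained panel")
  drop(sweep(Z, 2, fit$col_center) %*% fit$beta) + fit$intercept
}

#' Accuracy of genomic prediction
#'
#' Pearson correlation between GEBVs and true breeding values. Returns `NA`
#' (recorded as missing) when either side has zero variance.
#'
#' @param gebv,tbv numeric vectors of equal length (at least 3).
#' @export
gebv_accuracy <- function(gebv, tbv) {
  stopifnot(length(gebv) == length(tbv), length(gebv) >= 3)
  if (stats::sd(gebv) == 0 || stats::sd(tbv) == 0) return(NA_real_)
  cor(gebv, tbv)
}
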