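#' Default trait architecture table
#'
#' The five selection traits of the simulated forage breeding program:
#' heading date (HD), forage yield (FY), seed yield (SY), quality (Q) and
#' persistency (Per), with their narrow-sense heritabilities, QTL counts,
#' large-effect class sizes, the fraction of effect variance carried by the
#' large class, and the SpeedGS selection-index weights (weights sum to 1).
#'
#' @param n_qtl QTL per trait (1,000 at full scale).
#' @param n_large named vector of large-effect QTL counts for HD and Q.
#' @param var_large fraction of effect variance explained by the large class
#'   where one exists.
#' @return data.frame with one row per trait, class `trait_specs`.
#' @export
trait_specs <- function(n_qtl = 1000, n_large = c(HD = 20, Q = 100),
                        var_large = 0.5) {
  stopifnot(n_large["HD"] < n_qtl, n_large["Q"] < n_qtl,
            var_large >= 0, var_large < 1)
  out <- data.frame(
    trait = c("FY", "HD", "SY", "Q", "Per"),
    h2 = c(0.3, 0.7, 0.4, 0.3, 0.1),
    n_qtl = as.integer(n_qtl),
    n_large = as.integer(c(0, n_large["HD"], 0, n_large["Q"], 0)),
    var_fraction_large = c(0, var_large, 0, var_large, 0),
    index_weight = c(0.25, 0.1, 0.15, 0.15, 0.35),
    stringsAsFactors = FALSE)
  stopifnot(abs(sum(out$index_weight) - 1) < 1e-12)
  class(out) <- c("trait_specs", "data.frame")
  out
}

#' Genetic-correlation targets and pleiotropy structure
#'
#' Target genetic correlations (FY-SY 0.2, FY-HD 0.3, all other pairs 0) and
#' the pleiotropy design: one block of QTL shared among FY, SY and HD.
#'
#' @param n_shared number of QTL shared among FY, SY and HD (500 full scale).
#' @return list with `C` (5x5 named correlation matrix), `shared_traits`,
#'   `n_shared`.
#' @export
correlation_targets <- function(n_shared = 500) {
  traits <- c("FY", "HD", "SY", "Q", "Per")
  C <- diag(5)
  dimnames(C) <- list(traits, traits)
  C["FY", "SY"] <- C["SY", "FY"] <- 0.2
  C["FY", "HD"] <- C["HD", "FY"] <- 0.3
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  stopifnot(all(ev > 0))
  list(C = C, shared_traits = c("FY", "HD", "SY"),
       n_shared = as.integer(n_shared))
}

#' Variance multiplier for the large-effect QTL class
#'
#' With `l` large-effect QTL of effect variance `m` and `n - l` small QTL of
#' unit effect variance, the large class explains a fraction `e` of total
#' effect variance when \eqn{m = e (n - l) / (l (1 - e))}.
#'
#' @param e fraction of effect variance for the large class, in (0, 1);
#'   `e = 0` returns 0.
#' @param n total QTL count.
#' @param l large-effect QTL count, `0 < l < n` (required unless `e = 0`).
#' @export
scaled_variance_m <- function(e, n, l) {
  stopifnot(e >= 0, e < 1, n > 0)
  if (e == 0) return(0)
  if (l <= 0) stop("l must be positive when e > 0")
  if (l >= n) stop("l must be smaller than n")
  e * (n - l) / (l * (1 - e))
}

#' Sample raw (uncorrelated) QTL effects
#'
#' One column per trait: traits without a large-effect class draw all effects
#' from N(0, 1); HD and Q draw `n_large` effects from N(0, m) with `m` from
#' [scaled_variance_m()] (variance-`m` normal) and the rest from N(0, 1).
#'
#' @param specs a [trait_specs()] table.
#' @param large_rows optional named list giving, per trait with a large
#'   class, the row indices to flag as large; default: a uniform random draw.
#' @return list with `R` (`n_qtl x 5` matrix, columns named by trait) and
#'   `large` (logical matrix of the same shape flagging large effects).
#' @export
sample_raw_effects <- function(specs, large_rows = NULL) {
  n <- specs$n_qtl[1]
  R <- matrix(0, n, nrow(specs), dimnames = list(NULL, specs$trait))
  large <- matrix(FALSE, n, nrow(specs), dimnames = list(NULL, specs$trait))
  for (i in seq_len(nrow(specs))) {
    tr <- specs$trait[i]
    l <- specs$n_large[i]
    R[, i] <- rnorm(n)
    if (l > 0) {
      m <- scaled_variance_m(specs$var_fraction_large[i], n, l)
      rows <- if (!is.null(large_rows[[tr]])) large_rows[[tr]]
              else sample.int(n, l)
      R[rows, i] <- rnorm(l, sd = sqrt(m))
      large[rows, i] <- TRUE
    }
  }
  list(R = R, large = large)
}

#' Impose a target correlation on columns of an effect matrix
#'
#' The Cholesky-rescaling method for correlating effects drawn from unequal-
#' variance distributions: the empirical column covariance `S = cov(R)` is
#' factorized `S = L L'`, `RS = R L'^{-1}` has exactly identity empirical
#' covariance, and `final = RS D'` with `C = D D'` has exactly the target
#' empirical correlation `C`. Columns are centered internally so the result
#' is exact in the empirical (n - 1 denominator) sense.
#'
#' @param R numeric matrix, `n x p`, `n > p`, with positive-definite
#'   empirical covariance.
#' @param C target `p x p` correlation matrix (symmetric, unit diagonal,
#'   positive definite).
#' @return list of class `effect_matrix` with `R`, `L` (lower-triangular
#'   factor of `cov(R)`), `RS`, and `final` (the correlated effects, same
#'   dimnames as `R`).
#' @export
correlate_effects <- function(R, C) {
  R <- as.matrix(R)
  p <- ncol(R)
  stopifnot(nrow(C) == p, ncol(C) == p,
            isTRUE(all.equal(unname(C), unname(t(C)))),
            isTRUE(all.equal(unname(diag(C)), rep(1, p))))
  S <- stats::cov(R)
  U_S <- tryCatch(chol(S), error = function(e)
    stop("empirical covariance of R is rank deficient; increase the number of rows"))
  U_C <- chol(C)
  ctr <- scale(R, center = TRUE, scale = FALSE)
  RS <- ctr %*% solve(U_S) # cov(RS) = I exactly
  final <- RS %*% U_C      # cov(final) = C exactly
  dimnames(final) <- dimnames(RS) <- dimnames(R)
  structure(list(R = R, L = t(U_S), RS = RS, final = final),
            class = "effect_matrix")
}

#' Assign QTL positions for all traits
#'
#' Samples QTL without replacement from loci with base-population minor
#' allele frequency above `maf_min`. FY, SY and HD share one block of
#' `n_shared` loci; their private blocks and the Q and Per sets are mutually
#' disjoint draws.
#'
#' @param base hexaploid base `breedpop` (its allele frequencies define
#'   eligibility).
#' @param specs a [trait_specs()] table.
#' @param targets a [correlation_targets()] list.
#' @param maf_min MAF eligibility threshold (default 0.05).
#' @return list of class `qtl_set`: per-trait `loci` (global indices) and
#'   `is_shared` flags, plus `shared_loci`, `all_loci`, `freq` (base allele
#'   frequency at every assigned locus, named by locus).
#' @export
assign_qtl <- function(base, specs, targets, maf_min = 0.05) {
  p_all <- allele_freq(base)
  eligible <- which(pmin(p_all, 1 - p_all) > maf_min)
  n <- specs$n_qtl[1]
  ns <- targets$n_shared
  need <- ns + 3L * (n - ns) + 2L * n
  if (length(eligible) < need)
    stop(sprintf("only %d eligible loci (MAF > %g) but %d QTL required",
                 length(eligible), maf_min, need))
  draw <- sample(eligible, need)
  shared <- draw[seq_len(ns)]
  rest <- draw[-seq_len(ns)]
  take <- function(k) { out <- rest[seq_len(k)]; rest <<- rest[-seq_len(k)]; out }
  trio <- targets$shared_traits
  sets <- list()
  for (tr in specs$trait) {
    if (tr %in% trio) {
      loci <- c(shared, take(n - ns))
      sets[[tr]] <- list(loci = loci,
                         is_shared = c(rep(TRUE, ns), rep(FALSE, n - ns)))
    } else {
      sets[[tr]] <- list(loci = take(n), is_shared = rep(FALSE, n))
    }
  }
  structure(list(traits = sets, shared_loci = shared,
                 all_loci = sort(unique(unlist(lapply(sets, `[[`, "loci")))),
                 freq = stats::setNames(p_all[draw], draw)),
            class = "qtl_set")
}

#' Simulate trait effects on an assigned QTL set
#'
#' Draws raw per-trait effects (large-effect classes of HD and Q are placed
#' on their private loci) and imposes the target genetic correlations
#' block-wise: the shared FY/SY/HD block receives correlated effects via
#' [correlate_effects()] with a within-block correlation inflated by the
#' inverse of each trait's shared-block variance share, so the genome-wide
#' genetic correlation matches the target. Variance shares use per-locus
#' \eqn{2p(1-p)} weights at the base-population frequencies.
#'
#' @param qtl a [assign_qtl()] result.
#' @param specs a [trait_specs()] table.
#' @param targets a [correlation_targets()] list.
#' @return list of class `trait_effects`: per-trait `loci`, `effects`,
#'   `is_large`, `is_shared`; plus `block_corr` (the inflated within-block
#'   correlation actually imposed).
#' @export
simulate_trait_effects <- function(qtl, specs, targets) {
  n <- specs$n_qtl[1]
  ns <- targets$n_shared
  trio <- targets$shared_traits
  eff <- list()
  for (i in seq_len(nrow(specs))) {
    tr <- specs$trait[i]
    set <- qtl$traits[[tr]]
    l <- specs$n_large[i]
    e_vec <- rnorm(n)
    is_large <- rep(FALSE, n)
    if (l > 0) {
      m <- scaled_variance_m(specs$var_fraction_large[i], n, l)
      private <- which(!set$is_shared)
      rows <- sample(private, l) # large class kept off the shared block
      e_vec[rows] <- rnorm(l, sd = sqrt(m))
      is_large[rows] <- TRUE
    }
    eff[[tr]] <- list(loci = set$loci, effects = e_vec,
                      is_large = is_large, is_shared = set$is_shared)
  }
  # within-block correlation inflated by the shared variance shares
  w <- function(p) 2 * p * (1 - p)
  share <- vapply(trio, function(tr) {
    p <- qtl$freq[as.character(eff[[tr]]$loci)]
    v <- ifelse(eff[[tr]]$is_large,
                scaled_variance_m(specs$var_fraction_large[specs$trait == tr],
                                  n, max(1L, specs$n_large[specs$trait == tr])),
                1)
    v[!eff[[tr]]$is_large] <- 1
    sum(w(p)[eff[[tr]]$is_shared] * v[eff[[tr]]$is_shared]) / sum(w(p) * v)
  }, 0)
  Cb <- diag(3)
  dimnames(Cb) <- list(trio, trio)
  for (a in trio) for (b in trio) if (a != b) {
    rho <- targets$C[a, b] / sqrt(share[a] * share[b])
    if (abs(rho) >= 1)
      stop("shared block too small to carry the target correlation; ",
           "increase n_shared")
    Cb[a, b] <- rho
  }
  ev <- eigen(Cb, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("inflated within-block correlation matrix is not positive definite")
  block <- sapply(trio, function(tr) eff[[tr]]$effects[eff[[tr]]$is_shared])
  corr <- correlate_effects(block, Cb)
  for (tr in trio) eff[[tr]]$effects[eff[[tr]]$is_shared] <- corr$final[, tr]
  structure(list(traits = eff, block_corr = Cb, specs = specs),
            class = "trait_effects")
}

#' True breeding values
#'
#' TBV of each plant for each trait: the sum over that trait's QTL of allelic
#' dosage (0/1/2) times the true effect.
#'
#' @param pop a `breedpop`.
#' @param effects a [simulate_trait_effects()] result.
#' @param individuals optional subset of individuals.
#' @return numeric matrix, individuals x traits (columns named by trait).
#' @export
true_breeding_value <- function(pop, effects, individuals = NULL) {
  all_loci <- sort(unique(unlist(lapply(effects$traits, `[[`, "loci"))))
  Z <- dosage(pop, loci = all_loci, individuals = individuals)
  col_of <- match(unlist(lapply(effects$traits, `[[`, "loci")),
                  all_loci)
  out <- matrix(0, nrow(Z), length(effects$traits),
                dimnames = list(NULL, names(effects$traits)))
  at <- 0L
  for (tr in names(effects$traits)) {
    ef <- effects$traits[[tr]]
    idx <- col_of[at + seq_along(ef$loci)]
    out[, tr] <- Z[, idx, drop = FALSE] %*% ef$effects
    at <- at + length(ef$loci)
  }
  out
}

#' Per-cycle error variances for constant heritability
#'
#' Rescales the environmental error variance of each trait from the current
#' cohort's TBV variance so realized narrow-sense heritability stays at its
#' nominal value throughout the breeding program:
#' \eqn{\sigma_e^2 = Var(TBV) (1 - h^2) / h^2}.
#'
#' @param tbv TBV matrix (individuals x traits) of the cohort defining the
#'   cycle's genetic variance.
#' @param specs a [trait_specs()] table.
#' @return named vector of error variances, class `trait_state` semantics.
#' @export
refresh_error_variances <- function(tbv, specs) {
  v <- apply(tbv, 2, stats::var)
  h2 <- specs$h2[match(colnames(tbv), specs$trait)]
  stats::setNames(v * (1 - h2) / h2, colnames(tbv))
}

#' Simulate phenotypes
#'
#' Adds independent normal environmental deviates per trait:
#' `Pheno = TBV + e`, `e ~ N(0, sigma_e^2)`.
#'
#' @param tbv TBV matrix (individuals x traits).
#' @param error_variances named vector from [refresh_error_variances()].
#' @return phenotype matrix of the same shape.
#' @export
phenotype <- function(tbv, error_variances) {
  out <- tbv
  for (tr in colnames(tbv)) {
    s2 <- error_variances[[tr]]
    out[, tr] <- tbv[, tr] + if (s2 > 0) rnorm(nrow(tbv), sd = sqrt(s2)) else 0
  }
  out
}
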