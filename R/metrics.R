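#' Standardized genetic gain
#'
#' Gain of a later cycle's initial population over the baseline cycle,
#' standardized by the baseline TBV standard deviation:
#' \eqn{\Delta\sigma_g = (\bar{TBV}_{ci} - \bar{TBV}_{c5}) / sd(TBV_{c5})}.
#'
#' @param tbv_ci TBVs of the later cycle's initial population (one trait).
#' @param tbv_c5 TBVs of the baseline-cycle initial population.
#' @export
delta_sigma_g <- function(tbv_ci, tbv_c5) {
  s <- stats::sd(tbv_c5)
  if (!is.finite(s) || s == 0)
    stop("baseline TBV standard deviation is zero; gain undefined")
  (mean(tbv_ci) - mean(tbv_c5)) / s
}

#' VanRaden method-1 genomic relationship matrix
#'
#' `G = W W' / (2 sum p (1 - p))` where `W` is the dosage matrix centered by
#' `2p` and `p` are fixed baseline allele frequencies (the initial population
#' of the first tracked cycle). SNPs monomorphic at baseline contribute zero
#' to `W` and are retained.
#'
#' @param Z dosage matrix, individuals x SNPs.
#' @param base_freq baseline allele frequencies, one per SNP column.
#' @return `n x n` relationship matrix.
#' @export
grm_vanraden <- function(Z, base_freq) {
  Z <- as.matrix(Z)
  stopifnot(ncol(Z) == length(base_freq))
  denom <- 2 * sum(base_freq * (1 - base_freq))
  if (denom <= 0)
    stop("all SNPs monomorphic at baseline; relationship matrix undefined")
  W <- sweep(Z, 2, 2 * base_freq)
  tcrossprod(W) / denom
}

#' Mean inbreeding coefficient from a GRM
#'
#' The population mean inbreeding coefficient is the average diagonal of the
#' genomic relationship matrix minus one.
#'
#' @param G square relationship matrix.
#' @export
inbreeding_F <- function(G) {
  stopifnot(nrow(G) == ncol(G))
  mean(diag(G)) - 1
}

#' Rate of inbreeding between neighboring cycles
#'
#' \eqn{\Delta F = (F_c - F_{c-1}) / (1 - F_{c-1})}.
#'
#' @param f_c inbreeding coefficient at cycle `c`.
#' @param f_prev inbreeding coefficient at cycle `c - 1` (must be < 1).
#' @export
delta_F <- function(f_c, f_prev) {
  if (any(f_prev >= 1)) stop("previous-cycle F must be below 1")
  (f_c - f_prev) / (1 - f_prev)
}

#' Two-sample comparison of replicate-level scenario results
#'
#' Two-sample Student's t-test (pooled variance by default, Welch by flag)
#' with significance declared at `alpha` (0.01 in the study design).
#'
#' @param values_a,values_b replicate values of the two scenarios (>= 2 each).
#' @param alpha significance level.
#' @param welch use the Welch unequal-variance form instead of pooled.
#' @return list with `t`, `df`, `p_value`, `significant`, `degenerate` (zero
#'   pooled variance).
#' @export
compare_scenarios <- function(values_a, values_b, alpha = 0.01,
                              welch = FALSE) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    same <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    return(list(t = if (same) 0 else Inf, df = NA_real_,
                p_value = if (same) 1 else 0,
                significant = !same, degenerate = TRUE))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, significant = tt$p.value < alpha,
       degenerate = FALSE)
}
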