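#' Export genotypes as VCF
#'
#' Writes phased diploid genotypes (GT) for the population's pseudo-
#' chromosomes, contigs named `chr01`, `chr02`, ... with 1-based physical
#' positions mapped from the genetic map at the 1 cM = 1 Mb convention.
#'
#' @param pop a `breedpop`.
#' @param path output file path (plain-text `.vcf`).
#' @param loci optional global locus indices to export (default: all).
#' @param individuals optional individual subset.
#' @export
write_vcf <- function(pop, path, loci = NULL, individuals = NULL) {
  if (is.null(individuals)) individuals <- seq_len(n_ind(pop))
  lt <- locus_table(pop)
  if (!is.null(loci)) lt <- lt[lt$locus %in% loci, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=speedgs",
               sprintf("##contig=<ID=chr%02d,length=%d>",
                       seq_len(n_chrom(pop)),
                       round(pop$chrom_len * 1e6) + 1L),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  samples <- sprintf("ind%04d", individuals)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  for (k in unique(lt$chrom)) {
    sub <- lt[lt$chrom == k, , drop = FALSE]
    H <- pop$hap[[k]][sub$within, , drop = FALSE]
    c1 <- H[, 2L * individuals - 1L, drop = FALSE]
    c2 <- H[, 2L * individuals, drop = FALSE]
    gt <- matrix(paste(c1, c2, sep = "|"), nrow = nrow(sub))
    lines <- paste(sprintf("chr%02d", k),
                   round(sub$pos_cM * 1e6) + 1L,
                   sprintf("locus%d", sub$locus), "A", "T", ".", "PASS",
                   ".", "GT",
                   apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Export the QTL table
#'
#' Delimited text with one row per trait-QTL: trait, chromosome, map
#' position, true effect, large-effect and shared-block flags.
#'
#' @param effects a [simulate_trait_effects()] result.
#' @param pop a `breedpop` supplying the locus map.
#' @param path output path (tab-separated).
#' @export
write_qtl_table <- function(effects, pop, path) {
  lt <- locus_table(pop)
  out <- do.call(rbind, lapply(names(effects$traits), function(tr) {
    ef <- effects$traits[[tr]]
    data.frame(trait = tr, locus = ef$loci,
               chrom = lt$chrom[ef$loci], position_cM = lt$pos_cM[ef$loci],
               effect = ef$effects, is_large = ef$is_large,
               is_shared = ef$is_shared)
  }))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a tidy metric ledger
#'
#' @param ledger data.frame from [ledger_table()] or [run_experiment()].
#' @param path output path (tab-separated).
#' @export
write_ledger <- function(ledger, path) {
  utils::write.table(ledger, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export per-trait SNP effect estimates
#'
#' @param models named list of [fit_brr()] fits (one per trait).
#' @param panel the [build_snp_panel()] used for training.
#' @param pop a `breedpop` supplying the locus map.
#' @param path output path (tab-separated).
#' @export
write_model_dump <- function(models, panel, pop, path) {
  lt <- locus_table(pop)
  out <- data.frame(locus = panel$loci, chrom = lt$chrom[panel$loci],
                    position_cM = lt$pos_cM[panel$loci])
  for (tr in names(models)) out[[paste0("beta_", tr)]] <- models[[tr]]$beta
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
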