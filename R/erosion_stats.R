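# Genome-level erosion summary: per-replicon pseudogene:gene ratios,
# coding fraction, GC content, gene inventories.

#' GC content of a genome, in percent
#'
#' 100 * (G+C) / (A+C+G+T); N is excluded from the denominator. Aggregated
#' over all replicons.
#'
#' @param genome a [genome_set()], or a single nucleotide string.
#' @return percent GC.
#' @export
gc_content <- function(genome) {
  seqs <- if (inherits(genome, "genome_set")) genome$seqs else normalize_dna(genome)
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (s in seqs) {
    tab <- table(factor(strsplit(s, "", fixed = TRUE)[[1]],
                        levels = c("A", "C", "G", "T", "N")))
    counts <- counts + tab[c("A", "C", "G", "T")]
  }
  denom <- sum(counts)
  if (denom == 0) stop("GC content undefined: sequence is all N")
  100 * unname(counts["G"] + counts["C"]) / denom
}

#' Coding fraction of a genome, in percent
#'
#' 100 * (nucleotides covered by the union of intact CDS intervals) / total
#' genome length. Overlapping CDS are counted once; pseudogenes are
#' excluded.
#'
#' @param genome a [genome_set()].
#' @param features a [feature_set()] carrying final call status.
#' @return percent of the genome covered by intact coding sequence.
#' @export
coding_fraction <- function(genome, features) {
  cds <- features[features$ftype == "CDS", , drop = FALSE]
  covered <- 0L
  for (rid in unique(cds$replicon_id)) {
    x <- cds[cds$replicon_id == rid, ]
    ir <- IRanges::reduce(IRanges::IRanges(x$start + 1L, x$end))
    covered <- covered + sum(IRanges::width(ir))
  }
  100 * covered / sum(replicon_lengths(genome))
}

.count_block <- function(feats) {
  n_cds <- sum(feats$ftype == "CDS")
  n_pseudo <- sum(feats$ftype == "pseudogene")
  n_rna <- sum(feats$ftype %in% c("tRNA", "rRNA"))
  list(n_genes_total = n_cds + n_pseudo + n_rna,
       n_cds_intact = n_cds, n_pseudogenes = n_pseudo, n_rna_genes = n_rna)
}

#' Genome erosion summary
#'
#' Per-replicon and genome-total gene inventories, erosion ratios
#' (pseudogenes : predicted genes, where predicted genes = intact CDS + RNA
#' genes; the variant that also counts pseudogenes in the denominator is
#' reported alongside), GC content, coding fraction, and the pseudogene
#' percentage of all genes.
#'
#' @param genome a [genome_set()].
#' @param features a [feature_set()] carrying final call status.
#' @return object of class `erosion_summary`.
#' @export
erosion_summary <- function(genome, features) {
  per <- list()
  for (rid in names(genome$seqs)) {
    feats <- features[features$replicon_id == rid, , drop = FALSE]
    b <- .count_block(feats)
    n_pred <- b$n_cds_intact + b$n_rna_genes
    per[[rid]] <- c(b, list(
      erosion_ratio = if (n_pred > 0) b$n_pseudogenes / n_pred else NA_real_,
      erosion_ratio_incl_pseudo = if (b$n_genes_total > 0)
        b$n_pseudogenes / b$n_genes_total else NA_real_,
      length_bp = unname(nchar(genome$seqs[[rid]])),
      gc_percent = gc_content(genome$seqs[[rid]])))
  }
  tot <- .count_block(features)
  structure(list(
    per_replicon = per,
    genome_totals = c(tot, list(
      erosion_ratio = if (tot$n_cds_intact + tot$n_rna_genes > 0)
        tot$n_pseudogenes / (tot$n_cds_intact + tot$n_rna_genes) else NA_real_,
      length_bp = sum(replicon_lengths(genome)),
      gc_percent = gc_content(genome))),
    coding_fraction_percent = coding_fraction(genome, features),
    pseudogene_percent_of_genes = pseudogene_percent(
      tot$n_pseudogenes, tot$n_cds_intact, tot$n_rna_genes)),
    class = "erosion_summary")
}

#' Pseudogene percentage of all genes from raw counts
#'
#' 100 * n_pseudogenes / (n_pseudogenes + n_cds_intact + n_rna_genes). The
#' denominator counts every predicted gene including RNA genes.
#'
#' @param n_pseudogenes,n_cds_intact,n_rna_genes gene counts.
#' @return percent of genes that are pseudogenes.
#' @export
pseudogene_percent <- function(n_pseudogenes, n_cds_intact, n_rna_genes = 0) {
  total <- n_pseudogenes + n_cds_intact + n_rna_genes
  if (total == 0) return(0)
  100 * n_pseudogenes / total
}

# Flat per-replicon table (plus TOTAL row) for erosion.tsv.
erosion_table <- function(summary) {
  rows <- lapply(names(summary$per_replicon), function(rid) {
    p <- summary$per_replicon[[rid]]
    data.frame(replicon_id = rid, n_genes_total = p$n_genes_total,
               n_cds_intact = p$n_cds_intact, n_pseudogenes = p$n_pseudogenes,
               n_rna_genes = p$n_rna_genes,
               erosion_ratio = round(p$erosion_ratio, 4),
               length_bp = p$length_bp, gc_percent = round(p$gc_percent, 1))
  })
  t <- summary$genome_totals
  rows[[length(rows) + 1L]] <- data.frame(
    replicon_id = "TOTAL", n_genes_total = t$n_genes_total,
    n_cds_intact = t$n_cds_intact, n_pseudogenes = t$n_pseudogenes,
    n_rna_genes = t$n_rna_genes, erosion_ratio = round(t$erosion_ratio, 4),
    length_bp = t$length_bp, gc_percent = round(t$gc_percent, 1))
  do.call(rbind, rows)
}

#' @export
print.erosion_summary <- function(x, ...) {
  cat("Genome erosion summary\n")
  cat(sprintf("  total length: %d bp, GC %.1f%%\n",
              x$genome_totals$length_bp, x$genome_totals$gc_percent))
  cat(sprintf("  genes: %d total = %d intact CDS + %d pseudogenes + %d RNA\n",
              x$genome_totals$n_genes_total, x$genome_totals$n_cds_intact,
              x$genome_totals$n_pseudogenes, x$genome_totals$n_rna_genes))
  cat(sprintf("  pseudogenes: %.1f%% of genes\n",
              x$pseudogene_percent_of_genes))
  cat(sprintf("  intact coding fraction: %.1f%% of the genome\n",
              x$coding_fraction_percent))
  for (rid in names(x$per_replicon)) {
    p <- x$per_replicon[[rid]]
    cat(sprintf("  %s: %d:%d pseudogenes:predicted (ratio %.3f)\n", rid,
                p$n_pseudogenes, p$n_cds_intact + p$n_rna_genes,
                p$erosion_ratio))
  }
  invisible(x)
}
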