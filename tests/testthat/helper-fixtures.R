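# Shared fixtures. Heavy objects (the default synthetic run) are built once
# per session and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) assign(key, force(expr), envir = .cache)
  .cache[[key]]
}

# Default study-condition run: genome + pseudogene calls under the default
# synthetic configuration.
default_run <- function() cached("default_run", {
  cfg <- synth_config(seed = 42L)
  refs <- random_proteome(150L, seed = 42L)
  gen <- generate_genome(cfg, refs)
  called <- call_pseudogenes(gen$genome, gen$features, refs)
  list(cfg = cfg, refs = refs, gen = gen, called = called)
})

# IS-detection products on the same default genome.
default_is_run <- function() cached("default_is_run", {
  run <- default_run()
  fams <- find_repeat_families(run$gen$genome)
  hits <- scan_homology(run$gen$genome, run$gen$is_families)
  remnants <- merge_fragments(hits, fams)
  list(fams = fams, hits = hits, remnants = remnants)
})

# Caller performance against the truth table. A split event counts as
# recovered only when both fragments are flagged.
eval_caller <- function(gen, called) {
  truth <- gen$truth
  pg <- truth[truth$kind == "pseudogene", , drop = FALSE]
  recovered <- vapply(seq_len(nrow(pg)), function(i) {
    fids <- if (pg$class[i] == "split")
      paste0(pg$event_id[i], c("_f1", "_f2")) else pg$event_id[i]
    all(fids %in% called$calls$feature_id)
  }, logical(1))
  intact <- truth[truth$kind == "intact_gene" &
                    !is.na(truth$source_protein_id), , drop = FALSE]
  fp <- sum(intact$event_id %in% called$calls$feature_id)
  list(sensitivity = mean(recovered), fp = fp, n_intact = nrow(intact),
       fpr = fp / nrow(intact), n_pseudo = nrow(pg))
}

# One synthetic gene backtranslated from a given protein at a fixed seed.
make_gene <- function(protein, seed = 1L) {
  set.seed(seed)
  erosionscan:::.backtranslate(protein, 0.383)
}

# A single-gene genome: spacer + gene + spacer on one replicon.
single_gene_genome <- function(gene_dna, seed = 1L, flank = 400L) {
  set.seed(seed)
  left <- erosionscan:::random_dna(flank, 0.383)
  right <- erosionscan:::random_dna(flank, 0.383)
  genome <- genome_set(c(chr = paste0(left, gene_dna, right)))
  features <- feature_set(data.frame(
    feature_id = "g1", replicon_id = "chr", start = flank,
    end = flank + nchar(gene_dna), strand = "+", ftype = "CDS",
    product = "p", cog_category = NA_character_, stringsAsFactors = FALSE),
    genome)
  list(genome = genome, features = features)
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
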