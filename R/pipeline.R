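# Pipeline orchestration: synth -> pseudogene calling -> IS scan -> erosion
# stats -> COG enrichment -> gene sets, as one reproducible run writing a
# machine-readable report.

#' Assemble a pipeline configuration
#'
#' Either `synth` (a [synth_config()], plus `n_ref_proteins`) or the paths
#' `genome`/`features`/`refs` must be provided. All stochastic stages flow
#' from `seed`.
#'
#' @param outdir output directory.
#' @param synth optional [synth_config()] to generate the inputs.
#' @param genome,features,refs input paths (FASTA, GFF3, protein FASTA)
#'   when not generating.
#' @param is_library optional path to an IS library FASTA; the synthetic
#'   route uses the generated family consensi.
#' @param gene_sets optional list with `tsv` and `faa` paths.
#' @param caller a [caller_config()].
#' @param is a [is_config()].
#' @param enrichment list(B, ...) for [simulated_pvalue()].
#' @param seed integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, synth = NULL, genome = NULL,
                            features = NULL, refs = NULL, is_library = NULL,
                            gene_sets = NULL, caller = caller_config(),
                            is = is_config(), enrichment = list(B = 2000L),
                            seed = 1L) {
  if (is.null(synth)) {
    paths <- list(genome = genome, features = features, refs = refs)
    absent <- names(paths)[vapply(paths, is.null, logical(1))]
    if (length(absent))
      stop_validation("config missing path(s) ",
                      paste(absent, collapse = ", "),
                      ": genome, features and refs are required without a synth block")
    for (p in unlist(paths))
      if (!file.exists(p)) stop_validation("path does not exist: ", p)
  }
  structure(list(outdir = outdir, synth = synth, genome = genome,
                 features = features, refs = refs, is_library = is_library,
                 gene_sets = gene_sets, caller = caller, is = is,
                 enrichment = enrichment, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: outdir, seed, genome, features, refs,
#' is_library, gene_sets (tsv, faa), caller, is, enrichment and synth
#' blocks whose fields override the respective config defaults.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth <- NULL
  if (!is.null(y[["synth"]])) synth <- do.call(synth_config, y[["synth"]])
  caller <- do.call(caller_config, y[["caller"]] %||% list())
  iscfg <- do.call(is_config, y[["is"]] %||% list())
  pipeline_config(outdir = y[["outdir"]] %||% "erosionscan_out",
                  synth = synth, genome = y[["genome"]],
                  features = y[["features"]], refs = y[["refs"]],
                  is_library = y[["is_library"]],
                  gene_sets = y[["gene_sets"]],
                  caller = caller, is = iscfg,
                  enrichment = y[["enrichment"]] %||% list(B = 2000L),
                  seed = y[["seed"]] %||% 1L)
}

#' Run the full erosion-analysis pipeline
#'
#' Stages run in dependency order; the report aggregates the erosion
#' summary, the chi-squared enrichment result, the IS census and the
#' gene-set statuses. A second run with an identical configuration and
#' seed produces identical report content.
#'
#' @param cfg a [pipeline_config()] or path to its YAML form.
#' @param quiet suppress progress messages.
#' @return list with genome, features (post-call), calls, remnants, census,
#'   stats, cog, geneset, report (the report.json content) and manifest.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  say <- function(...) if (!quiet) message("[erosionscan] ", ...)
  is_families <- NULL
  if (!is.null(cfg$synth)) {
    say("generating synthetic genome (seed ", cfg$synth$seed, ")")
    refs <- random_proteome(cfg$synth$n_genes + 30L, seed = cfg$synth$seed)
    gen <- generate_genome(cfg$synth, refs)
    genome <- gen$genome; features <- gen$features
    ref_proteins <- refs
    is_library <- gen$is_families
    is_families <- gen$is_families
    truth <- gen$truth
  } else {
    say("reading inputs")
    genome <- read_genome_fasta(cfg$genome)
    features <- read_features_gff(cfg$features, genome)
    aa <- Biostrings::readAAStringSet(cfg$refs)
    names(aa) <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
    ref_proteins <- as.character(aa)
    is_library <- NULL
    if (!is.null(cfg$is_library)) {
      nt <- Biostrings::readDNAStringSet(cfg$is_library)
      names(nt) <- vapply(strsplit(names(nt), "\\s+"), `[`, character(1), 1L)
      is_library <- as.character(nt)
    }
    truth <- NULL
  }

  say("calling pseudogenes over ", sum(features$ftype == "CDS"), " CDS")
  called <- call_pseudogenes(genome, features, ref_proteins,
                             cfg$caller, scoring_scheme())

  say("scanning for insertion-sequence remnants")
  families <- find_repeat_families(genome, cfg$is)
  hits <- if (!is.null(is_library) && length(is_library))
    scan_homology(genome, is_library, cfg$is) else
    data.frame()
  remnants <- merge_fragments(hits, families, cfg$is)
  cons_len <- setNames(lapply(families, function(f) nchar(f$consensus)),
                       vapply(families, `[[`, character(1), "family_id"))
  if (!is.null(is_library) && length(is_library))
    cons_len <- c(cons_len, as.list(setNames(nchar(is_library),
                                             names(is_library))))
  census <- census_transposase_orfs(genome, remnants, cfg$is, cons_len)

  say("computing erosion summary")
  stats <- erosion_summary(genome, called$features)

  say("testing COG enrichment")
  cog <- tryCatch(
    simulated_pvalue(build_cog_table(called$features),
                     B = cfg$enrichment$B %||% 2000L, seed = cfg$seed),
    validation_error = function(e) NULL)

  geneset <- NULL
  if (!is.null(cfg$gene_sets)) {
    say("classifying gene sets")
    entries <- read_gene_set(cfg$gene_sets$tsv, cfg$gene_sets$faa)
    geneset <- classify_gene_set(entries, genome, called$features,
                                 cfg$caller, scoring_scheme())
  }

  say("writing outputs to ", cfg$outdir)
  extra <- list(
    is_census = list(n_distinct_sites = nrow(remnants),
                     n_raw_fragments = sum(remnants$n_fragments),
                     n_orfs = census$n_orfs, n_long = census$n_long),
    seed = cfg$seed)
  if (!is.null(geneset))
    extra$geneset <- lapply(split(geneset$status, geneset$gene_name),
                            identity)
  manifest <- write_outputs(called$features, stats, cfg$outdir,
                            cog_result = cog, extra = extra)
  # remnant features and per-site table
  if (nrow(remnants)) {
    rem_feats <- feature_set(data.frame(
      feature_id = remnants$site_id, replicon_id = remnants$replicon_id,
      start = remnants$start, end = remnants$end,
      strand = ifelse(remnants$strand %in% c("+", "-"), remnants$strand, "+"),
      ftype = "IS_remnant", product = remnants$family_id,
      cog_category = NA_character_, stringsAsFactors = FALSE))
    for (i in seq_len(nrow(rem_feats))) {
      si <- match(rem_feats$feature_id[i], census$per_remnant$site_id)
      rem_feats$attrs[[i]] <- c(
        family = remnants$family_id[match(rem_feats$feature_id[i],
                                          remnants$site_id)],
        status = census$per_remnant$status[si],
        n_fragments = as.character(
          remnants$n_fragments[match(rem_feats$feature_id[i],
                                     remnants$site_id)]))
    }
    write_features_gff(rem_feats, file.path(cfg$outdir, "remnants.gff3"))
  }
  if (!is.null(geneset))
    write.table(geneset, file.path(cfg$outdir, "geneset_status.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth))
    write_truth_tsv(truth, file.path(cfg$outdir, "truth.tsv"))

  report <- jsonlite::read_json(file.path(cfg$outdir, "report.json"))
  invisible(list(genome = genome, features = called$features,
                 calls = called$calls, remnants = remnants, census = census,
                 stats = stats, cog = cog, geneset = geneset,
                 truth = truth, is_families = is_families,
                 report = report, manifest = manifest))
}
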