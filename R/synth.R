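# Synthetic genome generator: multi-replicon genomes at a configurable GC,
# genes back-translated from a reference proteome, planted pseudogenes of
# four classes (internal stop, frameshift, ORF split, truncation), planted
# insertion sequences with terminal inverted repeats (intact and
# fragmented), and per-gene COG labels with a configurable
# pseudogene-enrichment skew. Every planted event is truth-tagged.

#' Synthetic genome configuration
#'
#' Defaults emulate the genome architecture of an eroding cyanobacterial
#' endosymbiont at desk scale: one chromosome plus two plasmids, G+C 38.3%,
#' 31.2% of genes pseudogenized, insertion sequences 700-3000 bp with 20-bp
#' terminal inverted repeats, and pseudogene odds skewed across COG
#' categories (replication/recombination/repair most affected, translation
#' and envelope biogenesis least).
#'
#' @param n_replicons number of replicons.
#' @param replicon_lengths length of each replicon (bp).
#' @param gc_target genome-wide G+C fraction in (0,1).
#' @param n_genes number of protein-coding genes.
#' @param pseudogene_fraction fraction of genes planted as pseudogenes;
#'   the planted count is `floor(n_genes * pseudogene_fraction)`.
#' @param class_mix named fractions over the four pseudogene classes,
#'   summing to 1.
#' @param n_rna_genes number of (stand-in) RNA genes.
#' @param n_is_elements number of insertion-sequence insertions.
#' @param n_is_families number of distinct IS families.
#' @param is_length_range length range (bp) of IS consensus sequences.
#' @param tir_length terminal inverted repeat length (bp).
#' @param fragmented_is_fraction fraction of IS insertions planted as
#'   fragmented (internal stop or two pieces with a short gap).
#' @param cog_skew named multipliers on the odds that a gene of that COG
#'   category is chosen for pseudogenization (unnamed categories get 1).
#' @param seed integer seed; every random choice in the generator flows
#'   from it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_replicons = 3L,
                         replicon_lengths = c(120000L, 40000L, 20000L),
                         gc_target = 0.383,
                         n_genes = 120L,
                         pseudogene_fraction = 0.312,
                         class_mix = c(internal_stop = 0.35, frameshift = 0.30,
                                       split = 0.15, truncated = 0.20),
                         n_rna_genes = 8L,
                         n_is_elements = 9L,
                         n_is_families = 3L,
                         is_length_range = c(700L, 3000L),
                         tir_length = 20L,
                         fragmented_is_fraction = 0.3,
                         cog_skew = c(L = 4, Q = 2, J = 0.4, M = 0.5),
                         seed = 1L) {
  stopifnot(length(replicon_lengths) == n_replicons,
            gc_target > 0, gc_target < 1,
            abs(sum(class_mix) - 1) < 1e-9,
            all(names(class_mix) %in%
                  c("internal_stop", "frameshift", "split", "truncated")),
            is_length_range[1] >= 700L || is_length_range[1] < is_length_range[2],
            tir_length > 0)
  structure(list(n_replicons = as.integer(n_replicons),
                 replicon_lengths = as.integer(replicon_lengths),
                 gc_target = gc_target, n_genes = as.integer(n_genes),
                 pseudogene_fraction = pseudogene_fraction,
                 class_mix = class_mix, n_rna_genes = as.integer(n_rna_genes),
                 n_is_elements = as.integer(n_is_elements),
                 n_is_families = as.integer(n_is_families),
                 is_length_range = as.integer(is_length_range),
                 tir_length = as.integer(tir_length),
                 fragmented_is_fraction = fragmented_is_fraction,
                 cog_skew = cog_skew, seed = as.integer(seed)),
            class = "synth_config")
}

#' Random reference proteome
#'
#' Uniform-composition amino-acid sequences, each starting with M. A
#' convenience source of homologs for the generator and tests.
#'
#' @param n number of proteins.
#' @param len_range length range (aa).
#' @param seed integer seed.
#' @return named character vector of proteins (`ref_0001`, ...).
#' @export
random_proteome <- function(n, len_range = c(80L, 300L), seed = 1L) {
  set.seed(seed)
  aas <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], character(0))
  lens <- seq.int(len_range[1], len_range[2])
  out <- vapply(seq_len(n), function(i) {
    len <- if (length(lens) == 1L) lens else sample(lens, 1L)
    paste0("M", paste(sample(aas, len - 1L, replace = TRUE), collapse = ""))
  }, character(1))
  setNames(out, sprintf("ref_%04d", seq_len(n)))
}

SENSE_CODONS <- NULL  # codon -> GC count, filled lazily

.sense_codons <- function() {
  code <- BACTERIAL_CODE
  sense <- names(code)[code != "*"]
  gcc <- vapply(strsplit(sense, ""), function(x) sum(x %in% c("G", "C")), 1L)
  setNames(gcc, sense)
}

# Per-base GC probability p such that codon sampling with weights
# p^gc * (1-p)^(3-gc) hits the genome GC target for this amino-acid
# composition. Solved once per generated genome.
.solve_codon_gc <- function(aa_freq, gc_target) {
  by_aa <- codons_for_aa()
  by_aa <- by_aa[names(by_aa) != "*"]
  gc_of <- function(codon) sum(strsplit(codon, "")[[1]] %in% c("G", "C"))
  expected_gc <- function(p) {
    tot <- 0
    for (aa in names(aa_freq)) {
      cods <- by_aa[[aa]]
      if (is.null(cods)) next
      g <- vapply(cods, gc_of, 1L)
      w <- p^g * (1 - p)^(3 - g)
      tot <- tot + aa_freq[[aa]] * sum(w * g) / sum(w)
    }
    tot / (3 * sum(unlist(aa_freq)))
  }
  lo <- expected_gc(0.02); hi <- expected_gc(0.98)
  if (gc_target <= lo) return(0.02)
  if (gc_target >= hi) return(0.98)
  stats::uniroot(function(p) expected_gc(p) - gc_target,
                 c(0.02, 0.98), tol = 1e-5)$root
}

# Back-translate a protein with codons sampled at per-base GC probability p.
# Starts with ATG (proteins start with M) and ends with a stop codon.
.backtranslate <- function(protein, p) {
  by_aa <- codons_for_aa()
  gc_of <- function(cods) vapply(strsplit(cods, ""),
                                 function(x) sum(x %in% c("G", "C")), 1L)
  aa <- strsplit(protein, "")[[1]]
  cods <- character(length(aa))
  cods[1] <- "ATG"
  for (i in seq_along(aa)[-1]) {
    cand <- by_aa[[aa[i]]]
    if (is.null(cand)) cand <- "NNN"
    g <- gc_of(cand)
    w <- p^g * (1 - p)^(3 - g)
    cods[i] <- if (length(cand) == 1L) cand else sample(cand, 1L, prob = w)
  }
  stops <- c("TAA", "TAG", "TGA")
  g <- gc_of(stops)
  w <- p^g * (1 - p)^(3 - g)
  paste0(paste(cods, collapse = ""), sample(stops, 1L, prob = w))
}

# Random open reading frame (ATG + sense codons + stop) of roughly n_nt.
.random_orf <- function(n_nt, p) {
  n_codons <- max(3L, floor(n_nt / 3L))
  sense <- .sense_codons()
  w <- p^sense * (1 - p)^(3 - sense)
  body <- sample(names(sense), n_codons - 2L, replace = TRUE, prob = w)
  stops <- c(TAA = 1, TAG = 2, TGA = 2)
  ws <- p^stops * (1 - p)^(3 - stops)
  paste0("ATG", paste(body, collapse = ""), sample(names(stops), 1L, prob = ws))
}

#' Plant a pseudogenizing lesion into a gene
#'
#' Mutates an intact coding sequence into one of four pseudogene classes:
#' `internal_stop` replaces at least two internal sense codons by stop
#' codons; `frameshift` applies at least two indels of length not divisible
#' by three; `split` inserts an intervening ORF of at least 150 bp
#' mid-gene; `truncated` keeps only a prefix (default at most 29% of the
#' original). The returned detail map records everything needed to verify
#' the lesion.
#'
#' @param gene_dna intact coding sequence (length a multiple of 3, start
#'   codon first, stop codon last).
#' @param class one of internal_stop, frameshift, split, truncated.
#' @param gc_p per-base GC probability used for inserted sequence.
#' @param kept_fraction prefix fraction for class truncated.
#' @param n_stops stops planted for class internal_stop.
#' @param n_indels indels planted for class frameshift.
#' @return list with `dna` (mutated sequence) and `detail` (named list).
#' @export
plant_pseudogene <- function(gene_dna, class, gc_p = 0.37,
                             kept_fraction = NULL, n_stops = 2L,
                             n_indels = 2L) {
  n <- nchar(gene_dna)
  if (n %% 3L != 0L) stop_validation("gene length not a multiple of 3")
  if (n < 150L) stop("gene too short (<150 bp) to host a planted lesion")
  n_codons <- n %/% 3L
  detail <- list(class = class)
  if (class == "internal_stop") {
    # internal codons only: never the start, never the terminal stop
    pos <- sort(sample(seq(5L, n_codons - 4L), n_stops))
    stops <- sample(c("TAA", "TAG", "TGA"), n_stops, replace = TRUE)
    for (i in seq_len(n_stops))
      substr(gene_dna, 3L * (pos[i] - 1L) + 1L, 3L * pos[i]) <- stops[i]
    detail$n_stops_planted <- n_stops
    detail$stop_codon_positions <- pos
    return(list(dna = gene_dna, detail = detail))
  }
  if (class == "frameshift") {
    # indel nucleotide positions spaced across the gene interior
    anchors <- round(seq(0.3, 0.7, length.out = n_indels) * n)
    sizes <- sample(c(-2L, -1L, 1L, 2L), n_indels, replace = TRUE)
    out <- gene_dna
    shift <- 0L
    positions <- integer(0)
    for (i in seq_len(n_indels)) {
      at <- anchors[i] + shift
      if (sizes[i] > 0L) {
        ins <- random_dna(sizes[i], gc_p)
        out <- paste0(substr(out, 1L, at), ins, substr(out, at + 1L, nchar(out)))
        shift <- shift + sizes[i]
      } else {
        out <- paste0(substr(out, 1L, at), substr(out, at - sizes[i] + 1L, nchar(out)))
        shift <- shift + sizes[i]
      }
      positions <- c(positions, at)
    }
    detail$indel_positions <- positions
    detail$indel_sizes <- sizes
    return(list(dna = out, detail = detail))
  }
  if (class == "split") {
    insert_len <- sample(180:300, 1L)
    insert <- .random_orf(insert_len, gc_p)
    cut_codon <- round(n_codons / 2)
    at <- 3L * cut_codon
    out <- paste0(substr(gene_dna, 1L, at), insert,
                  substr(gene_dna, at + 1L, n))
    detail$insert_start <- at
    detail$insert_len <- nchar(insert)
    detail$frag1_len <- at
    detail$frag2_len <- n - at
    return(list(dna = out, detail = detail))
  }
  if (class == "truncated") {
    if (is.null(kept_fraction)) kept_fraction <- runif(1, 0.15, 0.29)
    keep_codons <- max(5L, floor(kept_fraction * n_codons))
    out <- substr(gene_dna, 1L, 3L * keep_codons)
    detail$kept_fraction <- keep_codons / n_codons
    detail$requested_kept_fraction <- kept_fraction
    return(list(dna = out, detail = detail))
  }
  stop_validation("unknown pseudogene class: ", class)
}

#' Build an insertion-sequence family consensus
#'
#' Consensus = TIR + transposase ORF (filling the interior) + reverse
#' complement of the TIR.
#'
#' @param length total element length (bp), 700-3000.
#' @param tir_length terminal inverted repeat length (bp).
#' @param gc_p per-base GC probability.
#' @return nucleotide string of the consensus.
#' @export
make_is_family <- function(length, tir_length = 20L, gc_p = 0.37) {
  stopifnot(length >= 700L, length <= 3000L)
  if (tir_length >= length / 2) stop_validation("tir_length >= element length / 2")
  tir <- random_dna(tir_length, gc_p)
  interior <- length - 2L * tir_length
  orf <- .random_orf(interior, gc_p)
  pad <- random_dna(interior - nchar(orf), gc_p)
  paste0(tir, orf, pad, revcomp(tir))
}

#' Plant one insertion-sequence copy
#'
#' Intact copies are the consensus verbatim. Fragmented copies either carry
#' an internal stop in the transposase ORF or are emitted as two pieces
#' separated by a recorded gap (below the detector's merge window).
#'
#' @param family_consensus consensus from [make_is_family()].
#' @param tir_length TIR length used to build the consensus.
#' @param fragmented whether to degrade the copy.
#' @param gc_p per-base GC probability for gap sequence.
#' @return list with `pieces` (one or two nucleotide strings), `gap_seq`
#'   (string between the pieces, "" when intact) and `detail`.
#' @export
plant_is_element <- function(family_consensus, tir_length = 20L,
                             fragmented = FALSE, gc_p = 0.37) {
  L <- nchar(family_consensus)
  if (L < 700L || L > 3000L) stop_validation("IS consensus length out of range")
  if (tir_length >= L / 2) stop_validation("tir_length >= consensus length / 2")
  if (!fragmented)
    return(list(pieces = family_consensus, gap_seq = "",
                detail = list(mode = "intact", fragment_count = 1L)))
  mode <- sample(c("internal_stop", "two_pieces"), 1L)
  if (mode == "internal_stop") {
    # ORF starts right after the left TIR; hit a codon mid-ORF
    orf_codons <- (L - 2L * tir_length) %/% 3L
    codon <- sample(seq(orf_codons %/% 3L, 2L * orf_codons %/% 3L), 1L)
    at <- tir_length + 3L * (codon - 1L) + 1L
    substr(family_consensus, at, at + 2L) <- "TAA"
    list(pieces = family_consensus, gap_seq = "",
         detail = list(mode = "internal_stop", fragment_count = 1L,
                       stop_codon = codon))
  } else {
    cut <- sample(seq(round(0.3 * L), round(0.7 * L)), 1L)
    gap <- sample(100:500, 1L)
    list(pieces = c(substr(family_consensus, 1L, cut),
                    substr(family_consensus, cut + 1L, L)),
         gap_seq = random_dna(gap, gc_p),
         detail = list(mode = "two_pieces", fragment_count = 2L,
                       cut_at = cut, gap = gap))
  }
}

# Deterministic largest-remainder apportionment of n over fractions.
.apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Generate a synthetic genome with planted erosion events
#'
#' Genes are back-translated from sampled reference proteins with codon
#' usage biased toward the GC target; intergenic spacers are random at the
#' GC target; a configured fraction of genes is pseudogenized by
#' [plant_pseudogene()]; insertion sequences are planted by
#' [plant_is_element()]; COG labels are drawn per gene with pseudogene
#' odds multiplied by the configured skew. The annotation records every
#' gene as CDS — deciding pseudogene status is the caller's job, and the
#' truth table holds the ground truth.
#'
#' @param cfg a [synth_config()].
#' @param ref_proteome named character vector of proteins, at least
#'   `cfg$n_genes` of them.
#' @return list with `genome` ([genome_set()]), `features`
#'   ([feature_set()]), `truth` (data.frame, one row per planted event with
#'   a `detail` list column) and `is_families` (named character vector of
#'   family consensi).
#' @export
generate_genome <- function(cfg, ref_proteome) {
  if (length(ref_proteome) < cfg$n_genes)
    stop_validation("reference proteome smaller than n_genes")
  set.seed(cfg$seed)
  rep_ids <- c("chromosome", paste0("plasmid_", seq_len(max(0, cfg$n_replicons - 1L))))
  rep_ids <- rep_ids[seq_len(cfg$n_replicons)]
  lens <- setNames(cfg$replicon_lengths, rep_ids)

  # --- plan genes -----------------------------------------------------------
  gene_refs <- sample(names(ref_proteome), cfg$n_genes)
  cogs <- sample(COG_CATEGORIES, cfg$n_genes, replace = TRUE)
  n_pseudo <- floor(cfg$n_genes * cfg$pseudogene_fraction + 1e-9)
  skew <- setNames(rep(1, length(COG_CATEGORIES)), COG_CATEGORIES)
  skew[names(cfg$cog_skew)] <- cfg$cog_skew
  pseudo_idx <- sample(cfg$n_genes, n_pseudo, prob = skew[cogs])
  classes <- rep(NA_character_, cfg$n_genes)
  mix <- cfg$class_mix[c("internal_stop", "frameshift", "split", "truncated")]
  mix[is.na(mix)] <- 0
  names(mix) <- c("internal_stop", "frameshift", "split", "truncated")
  counts <- .apportion(n_pseudo, mix)
  classes[pseudo_idx] <- rep(names(mix), counts)

  # codon-choice GC pressure for back-translation (distinct from the raw
  # per-base probability used for spacers and free ORFs)
  aa_freq <- table(strsplit(paste(ref_proteome[gene_refs], collapse = ""), "")[[1]])
  gc_p <- .solve_codon_gc(as.list(aa_freq), cfg$gc_target)

  # assign genes, RNA genes and IS elements to replicons by length
  assign_rep <- function(n) sample(rep_ids, n, replace = TRUE, prob = lens)
  gene_rep <- assign_rep(cfg$n_genes)
  rna_rep <- assign_rep(cfg$n_rna_genes)
  fam_ids <- sprintf("ISfam_%02d", seq_len(cfg$n_is_families))
  fam_len <- sample(seq(cfg$is_length_range[1], cfg$is_length_range[2]),
                    cfg$n_is_families, replace = TRUE)
  families <- setNames(
    vapply(fam_len, make_is_family, character(1),
           tir_length = cfg$tir_length, gc_p = cfg$gc_target),
    fam_ids)
  is_fam <- rep(fam_ids, length.out = cfg$n_is_elements)
  is_rep <- assign_rep(cfg$n_is_elements)
  n_frag <- floor(cfg$fragmented_is_fraction * cfg$n_is_elements + 1e-9)
  is_fragmented <- rep(c(TRUE, FALSE),
                       c(n_frag, cfg$n_is_elements - n_frag))[
                         sample(cfg$n_is_elements)]

  # --- build items ----------------------------------------------------------
  # each item: list(kind, id, seq, strand, subfeatures = local 0-based
  # intervals, truth detail)
  items <- list()
  for (g in seq_len(cfg$n_genes)) {
    rid <- gene_refs[g]
    dna <- .backtranslate(ref_proteome[[rid]], gc_p)
    cls <- classes[g]
    detail <- list()
    if (!is.na(cls)) {
      planted <- plant_pseudogene(dna, cls, gc_p = cfg$gc_target)
      dna <- planted$dna
      detail <- planted$detail
    }
    gid <- sprintf("gene_%04d", g)
    sub <- if (!is.na(cls) && cls == "split") {
      a <- detail$frag1_len; b <- detail$insert_len
      list(list(id = paste0(gid, "_f1"), start = 0L, end = a,
                ftype = "CDS", product = rid, cog = cogs[g]),
           list(id = paste0(gid, "_ins"), start = a, end = a + b,
                ftype = "CDS", product = "hypothetical protein",
                cog = NA_character_),
           list(id = paste0(gid, "_f2"), start = a + b, end = nchar(dna),
                ftype = "CDS", product = rid, cog = cogs[g]))
    } else {
      list(list(id = gid, start = 0L, end = nchar(dna),
                ftype = "CDS", product = rid, cog = cogs[g]))
    }
    items[[length(items) + 1L]] <- list(
      kind = if (is.na(cls)) "intact_gene" else "pseudogene",
      id = gid, seq = dna, strand = sample(c("+", "-"), 1L),
      replicon = gene_rep[g], sub = sub, class = cls,
      source_protein_id = rid, cog = cogs[g], detail = detail)
  }
  for (r in seq_len(cfg$n_rna_genes)) {
    rid <- sprintf("rna_%03d", r)
    items[[length(items) + 1L]] <- list(
      kind = "rna_gene", id = rid, seq = random_dna(75L, cfg$gc_target),
      strand = sample(c("+", "-"), 1L), replicon = rna_rep[r],
      sub = list(list(id = rid, start = 0L, end = 75L, ftype = "tRNA",
                      product = "tRNA", cog = NA_character_)),
      class = NA_character_, source_protein_id = NA_character_,
      cog = NA_character_, detail = list())
  }
  for (e in seq_len(cfg$n_is_elements)) {
    fam <- is_fam[e]
    planted <- plant_is_element(families[[fam]], cfg$tir_length,
                                is_fragmented[e], cfg$gc_target)
    seqs <- planted$pieces
    full <- paste0(seqs[1], planted$gap_seq,
                   if (length(seqs) > 1L) seqs[2] else "")
    sub <- if (length(seqs) == 1L) {
      list(list(id = sprintf("is_%03d", e), start = 0L, end = nchar(full),
                ftype = "other", product = fam, cog = NA_character_))
    } else {
      list(list(id = sprintf("is_%03d_p1", e), start = 0L,
                end = nchar(seqs[1]), ftype = "other", product = fam,
                cog = NA_character_),
           list(id = sprintf("is_%03d_p2", e),
                start = nchar(seqs[1]) + nchar(planted$gap_seq),
                end = nchar(full), ftype = "other", product = fam,
                cog = NA_character_))
    }
    items[[length(items) + 1L]] <- list(
      kind = "is_element", id = sprintf("is_%03d", e), seq = full,
      strand = sample(c("+", "-"), 1L), replicon = is_rep[e],
      sub = sub, class = NA_character_, source_protein_id = fam,
      cog = NA_character_, detail = c(planted$detail, list(family = fam)))
  }

  # --- lay items onto replicons --------------------------------------------
  feat_rows <- list()
  truth_rows <- list()
  seqs <- setNames(vector("list", length(rep_ids)), rep_ids)
  for (rep_id in rep_ids) {
    mine <- items[vapply(items, function(x) x$replicon == rep_id, logical(1))]
    mine <- mine[sample(length(mine))]
    chunks <- character(0)
    pos <- 0L
    for (it in mine) {
      spacer <- random_dna(sample(100:400, 1L), cfg$gc_target)
      chunks <- c(chunks, spacer)
      pos <- pos + nchar(spacer)
      emitted <- if (it$strand == "-") revcomp(it$seq) else it$seq
      item_start <- pos
      chunks <- c(chunks, emitted)
      pos <- pos + nchar(emitted)
      L <- nchar(it$seq)
      for (sf in it$sub) {
        if (it$strand == "+") {
          gs <- item_start + sf$start; ge <- item_start + sf$end
        } else {
          gs <- item_start + (L - sf$end); ge <- item_start + (L - sf$start)
        }
        if (sf$ftype != "other")
          feat_rows[[length(feat_rows) + 1L]] <- data.frame(
            feature_id = sf$id, replicon_id = rep_id,
            start = gs, end = ge, strand = it$strand, ftype = sf$ftype,
            product = sf$product, cog_category = sf$cog,
            stringsAsFactors = FALSE)
      }
      truth_rows[[length(truth_rows) + 1L]] <- list(
        event_id = it$id,
        kind = if (it$kind == "rna_gene") "intact_gene" else it$kind,
        class = it$class, replicon_id = rep_id,
        start = item_start, end = item_start + nchar(emitted),
        strand = it$strand, source_protein_id = it$source_protein_id,
        cog_category = it$cog,
        detail = c(it$detail, list(kind0 = it$kind)))
    }
    body <- paste(chunks, collapse = "")
    if (nchar(body) > lens[[rep_id]])
      stop("replicon ", rep_id, " too short for requested content (needs ",
           nchar(body), " bp)")
    seqs[[rep_id]] <- paste0(body, random_dna(lens[[rep_id]] - nchar(body),
                                              cfg$gc_target))
  }
  genome <- genome_set(vapply(seqs, identity, character(1)),
                       setNames(c("circular", rep("circular",
                                                  length(rep_ids) - 1L)),
                                rep_ids))
  feats <- do.call(rbind, feat_rows)
  truth <- data.frame(
    event_id = vapply(truth_rows, `[[`, character(1), "event_id"),
    kind = vapply(truth_rows, `[[`, character(1), "kind"),
    class = vapply(truth_rows, function(x) x$class %||% NA_character_, character(1)),
    replicon_id = vapply(truth_rows, `[[`, character(1), "replicon_id"),
    start = vapply(truth_rows, `[[`, numeric(1), "start"),
    end = vapply(truth_rows, `[[`, numeric(1), "end"),
    strand = vapply(truth_rows, `[[`, character(1), "strand"),
    source_protein_id = vapply(truth_rows, function(x)
      x$source_protein_id %||% NA_character_, character(1)),
    cog_category = vapply(truth_rows, function(x)
      x$cog_category %||% NA_character_, character(1)),
    stringsAsFactors = FALSE)
  truth$detail <- lapply(truth_rows, `[[`, "detail")
  list(genome = genome, features = feature_set(feats, genome),
       truth = truth, is_families = families)
}

#' Write a truth table to TSV
#'
#' The detail map is serialized as `key=value` pairs joined by `;`.
#'
#' @param truth truth data.frame from [generate_genome()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  flat <- truth
  flat$detail <- vapply(truth$detail, function(d) {
    if (!length(d)) return("")
    paste(paste0(names(d), "=",
                 vapply(d, function(v) paste(v, collapse = ","), character(1))),
          collapse = ";")
  }, character(1))
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
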