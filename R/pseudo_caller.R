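# Rule-based pseudogene calling. A coding region is called a pseudogene
# when it is interrupted by more than one premature stop codon or
# frameshift (combined), when it is split by an intervening open reading
# frame, or when it covers less than 30% of the full-length reference
# protein.

#' Caller configuration
#'
#' @param interruption_threshold minimum combined count of premature stops
#'   and frameshifts for a pseudogene call ("more than one" = 2).
#' @param truncation_fraction reference coverage below which a candidate is
#'   called truncated (default 0.30 of the full-length reference).
#' @param split_max_gap maximum genomic gap (bp) between two fragments of a
#'   split gene.
#' @param flank_nt candidate regions are extended this many nucleotides on
#'   each side so truncation is measured against evidence, not annotation
#'   edges.
#' @param min_presence_score minimum chain score, on the bit scale, for a
#'   reference to count as present at all (used by split detection and
#'   gene-set classification).
#' @return object of class `caller_config`.
#' @export
caller_config <- function(interruption_threshold = 2L,
                          truncation_fraction = 0.30,
                          split_max_gap = 5000L,
                          flank_nt = 90L,
                          min_presence_score = 50) {
  stopifnot(interruption_threshold >= 1L,
            truncation_fraction > 0, truncation_fraction < 1)
  structure(list(interruption_threshold = as.integer(interruption_threshold),
                 truncation_fraction = truncation_fraction,
                 split_max_gap = as.integer(split_max_gap),
                 flank_nt = as.integer(flank_nt),
                 min_presence_score = min_presence_score),
            class = "caller_config")
}

#' Classify one candidate from its chained alignment
#'
#' @param chain a [chain_blocks()] result against the best-scoring reference.
#' @param cfg a [caller_config()].
#' @return list with `status` ("intact" or "pseudogene"), `class`
#'   (internal_stop / frameshift / truncated or NA), and the evidence counts.
#'   An empty chain (no homolog found) is intact with note "no_evidence".
#' @export
classify_candidate <- function(chain, cfg = caller_config()) {
  ev <- list(n_stops = chain$n_stops, n_frameshifts = chain$n_frameshifts,
             aligned_fraction = chain$aligned_fraction, note = "")
  has_chain <- !is.null(chain$blocks) && nrow(chain$blocks) > 0
  if (!has_chain)
    return(c(list(status = "intact", class = NA_character_),
             modifyList(ev, list(note = "no_evidence"))))
  interruptions <- chain$n_stops + chain$n_frameshifts
  if (interruptions >= cfg$interruption_threshold) {
    cls <- if (chain$n_stops > chain$n_frameshifts) "internal_stop" else "frameshift"
    return(c(list(status = "pseudogene", class = cls), ev))
  }
  if (chain$aligned_fraction < cfg$truncation_fraction)
    return(c(list(status = "pseudogene", class = "truncated"), ev))
  c(list(status = "intact", class = NA_character_), ev)
}

# Build an index from amino-acid k-mers to reference ids, used to shortlist
# references before full alignment.
.ref_kmer_index <- function(ref_proteins, k = 5L) {
  idx <- new.env(parent = emptyenv())
  for (id in names(ref_proteins)) {
    p <- ref_proteins[[id]]
    n <- nchar(p)
    if (n < k) next
    kmers <- unique(substring(p, 1:(n - k + 1L), k:n))
    for (km in kmers) assign(km, c(get0(km, envir = idx), id), envir = idx)
  }
  idx
}

.shortlist_refs <- function(region_dna, idx, k = 5L, top = 5L) {
  hits <- character(0)
  for (f in 0:2) {
    aa <- translate_dna(substr(region_dna, f + 1L, nchar(region_dna)))
    n <- nchar(aa)
    if (n < k) next
    kmers <- unique(substring(aa, 1:(n - k + 1L), k:n))
    for (km in kmers) hits <- c(hits, get0(km, envir = idx))
  }
  if (!length(hits)) return(character(0))
  tab <- sort(table(hits), decreasing = TRUE)
  names(tab)[seq_len(min(top, length(tab)))]
}

# Best chained alignment of one region against shortlisted references.
# Ties broken by longest reference, then lexicographic id (determinism).
.best_chain <- function(region_dna, ref_proteins, idx, scoring, cfg) {
  cand <- .shortlist_refs(region_dna, idx, top = 3L)
  if (!length(cand)) cand <- names(ref_proteins)[seq_len(min(3, length(ref_proteins)))]
  best <- NULL
  for (id in cand) {   # shortlist order: most shared k-mers first
    blocks <- three_frame_align(region_dna, ref_proteins[[id]], scoring)
    ch <- chain_blocks(blocks, nchar(ref_proteins[[id]]), scoring)
    ch$ref_protein_id <- id
    if (is.null(best) || ch$score > best$score ||
        (ch$score == best$score &&
         nchar(ref_proteins[[id]]) > nchar(ref_proteins[[best$ref_protein_id]])) ||
        (ch$score == best$score &&
         nchar(ref_proteins[[id]]) == nchar(ref_proteins[[best$ref_protein_id]]) &&
         id < best$ref_protein_id))
      best <- ch
    # a near-complete clean hit cannot be displaced by a later candidate
    if (ch$aligned_fraction >= 0.98 && ch$n_stops + ch$n_frameshifts == 0L)
      break
  }
  best
}

#' Detect genes split by an intervening open reading frame
#'
#' Two features whose best reference hits are essentially non-overlapping
#' segments (reference overlap < 20% of the shorter segment) of the same
#' reference protein, in consistent order for their strand, within
#' `split_max_gap` of each other, and with at least one intervening
#' annotated ORF of a different product, are flagged as one split-gene
#' event.
#'
#' @param features a [feature_set()] restricted to coding features.
#' @param chains named list (by feature_id) of best chained alignments.
#' @param cfg a [caller_config()].
#' @return data.frame with columns feature_id, event_id, partner_id;
#'   zero rows when nothing is split.
#' @export
detect_split_orf <- function(features, chains, cfg = caller_config()) {
  out <- data.frame(feature_id = character(0), event_id = character(0),
                    partner_id = character(0))
  cds <- features[features$ftype %in% c("CDS", "pseudogene"), , drop = FALSE]
  if (nrow(cds) < 3) return(out)
  refs <- vapply(cds$feature_id, function(id) {
    ch <- chains[[id]]
    if (is.null(ch) || is.null(ch$blocks) || nrow(ch$blocks) == 0 ||
        protein_bits(ch$score) < cfg$min_presence_score)
      NA_character_ else ch$ref_protein_id
  }, character(1))
  ev <- 0L
  for (rid in unique(refs[!is.na(refs)])) {
    members <- which(refs == rid)
    if (length(members) < 2) next
    for (a in members) for (b in members) {
      if (a >= b) next
      if (cds$replicon_id[a] != cds$replicon_id[b]) next
      if (cds$strand[a] != cds$strand[b]) next
      # genomic order with a upstream of b
      up <- if (cds$start[a] <= cds$start[b]) a else b
      dn <- if (up == a) b else a
      gap <- cds$start[dn] - cds$end[up]
      if (gap < 0 || gap > cfg$split_max_gap) next
      ca <- chains[[cds$feature_id[up]]]; cb <- chains[[cds$feature_id[dn]]]
      # coverage union per fragment: overlap measured on covered residues so
      # a stray low-scoring block cannot veto a genuine split
      ia <- IRanges::reduce(IRanges::IRanges(ca$blocks$ref_start + 1L,
                                             ca$blocks$ref_end))
      ib <- IRanges::reduce(IRanges::IRanges(cb$blocks$ref_start + 1L,
                                             cb$blocks$ref_end))
      ov <- sum(IRanges::width(IRanges::intersect(ia, ib)))
      shorter <- min(sum(IRanges::width(ia)), sum(IRanges::width(ib)))
      if (shorter <= 0 || ov / shorter >= 0.20) next
      # consistent order: the upstream fragment's main block covers the
      # earlier reference segment on '+', the later segment on '-'
      main_a <- ca$blocks$ref_start[which.max(ca$blocks$score)]
      main_b <- cb$blocks$ref_start[which.max(cb$blocks$score)]
      ok_order <- if (cds$strand[up] == "+") main_a <= main_b else main_a >= main_b
      if (!ok_order) next
      # at least one intervening annotated ORF with a different product
      between <- cds$start > cds$end[up] - 1 & cds$end < cds$start[dn] + 1 &
        cds$replicon_id == cds$replicon_id[up]
      between[c(up, dn)] <- FALSE
      if (!any(between & cds$product != cds$product[up])) next
      ev <- ev + 1L
      eid <- sprintf("split_%03d", ev)
      out <- rbind(out, data.frame(
        feature_id = cds$feature_id[c(up, dn)], event_id = eid,
        partner_id = cds$feature_id[c(dn, up)]))
    }
  }
  # a feature belongs to at most one event; keep the first
  out[!duplicated(out$feature_id), , drop = FALSE]
}

#' Call pseudogenes over an annotated genome
#'
#' For every CDS feature the candidate region (the feature interval extended
#' by `flank_nt` on each side, on the feature's strand) is aligned against
#' the reference proteins; the best-scoring reference is chosen and the
#' calling rules applied; the split rule is applied across features.
#'
#' @param genome a [genome_set()].
#' @param features a [feature_set()] with the CDS annotation.
#' @param ref_proteins named character vector (or AAStringSet) of reference
#'   proteins.
#' @param cfg a [caller_config()].
#' @param scoring a [scoring_scheme()].
#' @return list with `features` (the updated [feature_set()], ftype set to
#'   pseudogene where called, evidence in attrs) and `calls` (data.frame of
#'   pseudogene calls: feature_id, class, n_stops, n_frameshifts,
#'   aligned_fraction, ref_protein_id, evidence_note).
#' @export
call_pseudogenes <- function(genome, features, ref_proteins,
                             cfg = caller_config(),
                             scoring = scoring_scheme()) {
  if (length(ref_proteins) == 0)
    stop_validation("empty reference protein set")
  ref_proteins <- setNames(toupper(as.character(ref_proteins)),
                           names(ref_proteins))
  idx <- .ref_kmer_index(ref_proteins)
  cds_idx <- which(features$ftype == "CDS")
  chains <- list()
  results <- list()
  for (i in cds_idx) {
    fid <- features$feature_id[i]
    region <- extract_region(genome, features$replicon_id[i],
                             features$start[i] - cfg$flank_nt,
                             features$end[i] + cfg$flank_nt,
                             features$strand[i])
    ch <- .best_chain(region, ref_proteins, idx, scoring, cfg)
    chains[[fid]] <- ch
    results[[fid]] <- classify_candidate(ch, cfg)
  }
  splits <- detect_split_orf(features[cds_idx, , drop = FALSE], chains, cfg)
  calls <- list()
  for (i in cds_idx) {
    fid <- features$feature_id[i]
    res <- results[[fid]]
    is_split <- fid %in% splits$feature_id
    if (is_split && res$status == "intact") {
      res$status <- "pseudogene"
      res$class <- "split"
      res$note <- paste0("split:", splits$event_id[splits$feature_id == fid])
    }
    if (res$status == "pseudogene") {
      features$ftype[i] <- "pseudogene"
      ch <- chains[[fid]]
      features$attrs[[i]] <- c(features$attrs[[i]],
        pseudo_class = res$class,
        n_stops = as.character(res$n_stops),
        n_frameshifts = as.character(res$n_frameshifts),
        aligned_fraction = sprintf("%.4f", res$aligned_fraction))
      calls[[fid]] <- data.frame(
        feature_id = fid, class = res$class,
        n_stops = res$n_stops, n_frameshifts = res$n_frameshifts,
        aligned_fraction = res$aligned_fraction,
        ref_protein_id = ch$ref_protein_id %||% NA_character_,
        evidence_note = res$note, stringsAsFactors = FALSE)
    } else if (nzchar(res$note)) {
      features$attrs[[i]] <- c(features$attrs[[i]], note = res$note)
    }
  }
  call_df <- if (length(calls)) do.call(rbind, c(calls, make.row.names = FALSE))
             else data.frame(feature_id = character(0), class = character(0),
                             n_stops = integer(0), n_frameshifts = integer(0),
                             aligned_fraction = numeric(0),
                             ref_protein_id = character(0),
                             evidence_note = character(0))
  list(features = features, calls = call_df, chains = chains)
}
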