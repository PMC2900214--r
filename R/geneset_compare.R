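# Gene-set status classification (minimal bacterial set, cyanobacterial
# core/shell, or custom lists) and best-reciprocal-hit ortholog pairing.

#' Best reciprocal hits between two proteomes
#'
#' All-vs-all local protein alignment; a pair (a, b) is reported when b is
#' a's best hit and a is b's best hit. Score ties are broken by id order
#' and flagged ambiguous.
#'
#' @param proteome_a,proteome_b named character vectors of proteins.
#' @param scoring a [scoring_scheme()].
#' @param min_score pairs scoring below this are not considered hits.
#' @return data.frame (id_a, id_b, score, ambiguous).
#' @export
best_reciprocal_hits <- function(proteome_a, proteome_b,
                                 scoring = scoring_scheme(), min_score = 30) {
  if (!length(proteome_a) || !length(proteome_b))
    stop_validation("both proteomes must be nonempty")
  ids_a <- names(proteome_a); ids_b <- names(proteome_b)
  scores <- matrix(-Inf, length(ids_a), length(ids_b),
                   dimnames = list(ids_a, ids_b))
  for (a in ids_a) for (b in ids_b) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(proteome_a[[a]]), Biostrings::AAString(proteome_b[[b]]),
      substitutionMatrix = scoring$substitution,
      gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend,
      type = "local")
    scores[a, b] <- Biostrings::score(pa)
  }
  out <- list()
  for (a in ids_a) {
    row <- scores[a, ]
    if (max(row) < min_score) next
    best_b <- ids_b[which(row == max(row))]
    amb_a <- length(best_b) > 1L
    b <- sort(best_b)[1L]
    col <- scores[, b]
    if (max(col) < min_score) next
    best_a <- ids_a[which(col == max(col))]
    amb_b <- length(best_a) > 1L
    if (sort(best_a)[1L] == a) {
      out[[length(out) + 1L]] <- data.frame(
        id_a = a, id_b = b, score = scores[a, b],
        ambiguous = amb_a || amb_b, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(id_a = character(0), id_b = character(0),
                      score = numeric(0), ambiguous = logical(0)))
  do.call(rbind, out)
}

#' Classify a curated gene set against a called genome
#'
#' Each entry's reference protein is aligned (with the pseudogene caller's
#' chain machinery) against the annotated coding regions; the best match
#' above `min_presence_score` determines the status, copied from that
#' feature's call. An intact copy anywhere overrides pseudogene copies
#' elsewhere. Entries with no match are absent.
#'
#' @param entries data.frame with columns set_name, gene_name, ref_protein.
#' @param genome a [genome_set()].
#' @param features a [feature_set()] with final call status (run
#'   [call_pseudogenes()] first).
#' @param cfg a [caller_config()].
#' @param scoring a [scoring_scheme()].
#' @return data.frame (set_name, gene_name, status, matched_feature_id,
#'   score); status is one of intact, pseudogene, absent.
#' @export
classify_gene_set <- function(entries, genome, features,
                              cfg = caller_config(),
                              scoring = scoring_scheme()) {
  if (is.null(entries) || nrow(entries) == 0)
    stop_validation("empty gene set")
  coding <- features[features$ftype %in% c("CDS", "pseudogene"), , drop = FALSE]
  regions <- lapply(seq_len(nrow(coding)), function(i)
    extract_region(genome, coding$replicon_id[i],
                   coding$start[i] - cfg$flank_nt,
                   coding$end[i] + cfg$flank_nt, coding$strand[i]))
  # shortlist candidate features per entry by shared amino-acid 5-mers
  feat_prot <- setNames(lapply(regions, function(r) {
    vapply(0:2, function(f) translate_dna(substr(r, f + 1L, nchar(r))),
           character(1))
  }), coding$feature_id)
  idx <- new.env(parent = emptyenv())
  k <- 5L
  for (fid in names(feat_prot)) {
    for (aa in feat_prot[[fid]]) {
      n <- nchar(aa)
      if (n < k) next
      for (km in unique(substring(aa, 1:(n - k + 1L), k:n)))
        assign(km, unique(c(get0(km, envir = idx), fid)), envir = idx)
    }
  }
  out <- list()
  for (e in seq_len(nrow(entries))) {
    prot <- toupper(entries$ref_protein[e])
    n <- nchar(prot)
    cand <- character(0)
    if (n >= k) {
      for (km in unique(substring(prot, 1:(n - k + 1L), k:n)))
        cand <- c(cand, get0(km, envir = idx))
    }
    cand <- names(sort(table(cand), decreasing = TRUE))
    cand <- utils::head(cand, 8L)
    best <- NULL
    for (fid in sort(cand)) {
      i <- which(coding$feature_id == fid)
      blocks <- three_frame_align(regions[[i]], prot, scoring)
      ch <- chain_blocks(blocks, n, scoring)
      if (protein_bits(ch$score) < cfg$min_presence_score) next
      hit <- list(feature_id = fid, score = ch$score,
                  status = if (coding$ftype[i] == "pseudogene")
                    "pseudogene" else "intact")
      if (is.null(best)) best <- list(all = list(hit), top = hit)
      else {
        best$all[[length(best$all) + 1L]] <- hit
        if (hit$score > best$top$score) best$top <- hit
      }
    }
    status <- "absent"; matched <- NA_character_; sc <- NA_real_
    if (!is.null(best)) {
      # an intact copy anywhere overrides pseudogene copies elsewhere, but
      # only when it is a comparable match, not a marginal spurious hit
      intacts <- Filter(function(h)
        h$status == "intact" && h$score >= 0.5 * best$top$score, best$all)
      if (length(intacts)) {
        scs <- vapply(intacts, `[[`, numeric(1), "score")
        pick <- intacts[[which.max(scs)]]
      } else pick <- best$top
      status <- pick$status
      matched <- pick$feature_id; sc <- pick$score
    }
    out[[e]] <- data.frame(set_name = entries$set_name[e] %||% "custom",
                           gene_name = entries$gene_name[e],
                           status = status, matched_feature_id = matched,
                           score = sc, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Read a gene set from TSV + protein FASTA
#'
#' The TSV has columns set_name, gene_name, protein_id; proteins come from
#' the FASTA by id.
#'
#' @param tsv_path TSV file.
#' @param faa_path amino-acid FASTA file.
#' @return entries data.frame for [classify_gene_set()].
#' @export
read_gene_set <- function(tsv_path, faa_path) {
  tab <- read.delim(tsv_path, stringsAsFactors = FALSE)
  need <- c("set_name", "gene_name", "protein_id")
  if (!all(need %in% names(tab)))
    stop_validation("gene-set TSV needs columns: ", paste(need, collapse = ", "))
  aa <- Biostrings::readAAStringSet(faa_path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  missing <- setdiff(tab$protein_id, ids)
  if (length(missing))
    stop_validation("proteins missing from FASTA: ",
                    paste(missing, collapse = ", "))
  tab$ref_protein <- as.character(aa)[match(tab$protein_id, ids)]
  tab
}
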