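# Insertion-sequence remnant detection: de-novo repeat families from
# canonical k-mer seeds with greedy consensus extension, terminal inverted
# repeat search, seeded homology scanning against an IS library with
# Karlin-Altschul E-values, merging of split fragments into distinct
# insertion sites, and a transposase ORF census.

#' IS detector configuration
#'
#' @param min_repeat_len minimum de-novo repeat consensus length (bp).
#' @param min_copies minimum copy number for a repeat family.
#' @param k k-mer size for repeat seeding.
#' @param e_value_max homology hit cutoff.
#' @param merge_max_gap maximum gap (bp) between fragments merged into one
#'   insertion site; default mirrors the IS length ceiling.
#' @param tir_min_len,tir_max_offset,tir_max_mismatch,tir_max_len terminal
#'   inverted repeat search window.
#' @param transposase_min_aa ORFs longer than this count as long
#'   transposases.
#' @return object of class `is_config`.
#' @export
is_config <- function(min_repeat_len = 600L, min_copies = 3L, k = 16L,
                      e_value_max = 1e-5, merge_max_gap = 3000L,
                      tir_min_len = 10L, tir_max_offset = 50L,
                      tir_max_mismatch = 2L, tir_max_len = 60L,
                      transposase_min_aa = 200L) {
  stopifnot(min_repeat_len > 0, min_copies >= 2, k >= 8, e_value_max > 0,
            merge_max_gap > 0, tir_min_len > 0, transposase_min_aa > 0)
  structure(list(min_repeat_len = as.integer(min_repeat_len),
                 min_copies = as.integer(min_copies), k = as.integer(k),
                 e_value_max = e_value_max,
                 merge_max_gap = as.integer(merge_max_gap),
                 tir_min_len = as.integer(tir_min_len),
                 tir_max_offset = as.integer(tir_max_offset),
                 tir_max_mismatch = as.integer(tir_max_mismatch),
                 tir_max_len = as.integer(tir_max_len),
                 transposase_min_aa = as.integer(transposase_min_aa)),
            class = "is_config")
}

# All k-mers of a sequence together with their reverse complements, as
# parallel character vectors.
.kmers_with_rc <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(list(kmer = character(0), rc = character(0)))
  starts <- 1:(L - k + 1L)
  km <- substring(seq, starts, starts + k - 1L)
  rcseq <- revcomp(seq)
  rc <- substring(rcseq, L - starts - k + 2L, L - starts + 1L)
  list(kmer = km, rc = rc)
}

#' Find de-novo repeat families
#'
#' Canonical k-mers occurring at least `min_copies` times seed a greedy
#' bidirectional consensus extension: at each step the majority base across
#' the active copies extends the consensus, copies drifting below 80%
#' identity are dropped, and extension stops when fewer than `min_copies`
#' copies remain. Families whose consensus is shorter than
#' `min_repeat_len` are discarded. Regions claimed by a family are not
#' re-seeded.
#'
#' @param genome a [genome_set()].
#' @param cfg an [is_config()].
#' @return list of repeat families, each a list with family_id, consensus,
#'   copies (data.frame replicon_id/start/end/strand) and tir (from
#'   [find_tirs()], or NULL).
#' @export
find_repeat_families <- function(genome, cfg = is_config()) {
  k <- cfg$k
  km_all <- character(0); rep_all <- character(0); pos_all <- integer(0)
  strand_all <- character(0)
  for (rid in names(genome$seqs)) {
    kk <- .kmers_with_rc(genome$seqs[[rid]], k)
    if (!length(kk$kmer)) next
    canon <- pmin(kk$kmer, kk$rc)
    km_all <- c(km_all, canon)
    rep_all <- c(rep_all, rep(rid, length(canon)))
    pos_all <- c(pos_all, seq_along(canon) - 1L)  # 0-based kmer start
    strand_all <- c(strand_all, ifelse(kk$kmer <= kk$rc, "+", "-"))
  }
  if (!length(km_all)) return(list())
  tab <- table(km_all)
  seeds <- names(tab)[tab >= cfg$min_copies & !grepl("N", names(tab))]
  if (!length(seeds)) return(list())
  sel <- which(km_all %in% seeds)
  posmap <- split(sel, km_all[sel])
  # most frequent seeds first; alphabetical within a count for determinism
  posmap <- posmap[order(-lengths(posmap), names(posmap))]
  covered <- lapply(genome$seqs, function(s) rep(FALSE, nchar(s)))

  W <- 3500L
  families <- list()
  for (sname in names(posmap)) {
    ii <- posmap[[sname]]
    free <- vapply(ii, function(i)
      !covered[[rep_all[i]]][pos_all[i] + 1L], logical(1))
    ii <- ii[free]
    if (length(ii) < cfg$min_copies) next
    # oriented context per copy: the canonical k-mer sits at local offset
    # `off` inside `ctx`
    ctx <- character(length(ii)); off <- integer(length(ii))
    for (j in seq_along(ii)) {
      i <- ii[j]
      L <- nchar(genome$seqs[[rep_all[i]]])
      lo <- max(0L, pos_all[i] - W)
      hi <- min(L, pos_all[i] + k + W)
      win <- substr(genome$seqs[[rep_all[i]]], lo + 1L, hi)
      if (strand_all[i] == "+") {
        ctx[j] <- win; off[j] <- pos_all[i] - lo
      } else {
        ctx[j] <- revcomp(win); off[j] <- hi - (pos_all[i] + k)
      }
    }
    ext <- .extend_consensus(ctx, off, k, cfg)
    cons <- ext$consensus
    if (nchar(cons) < cfg$min_repeat_len) next
    # keep only copies that actually supported the consensus; seed matches
    # dropped at the first steps (e.g. the far arm of a terminal inverted
    # repeat) are not copies of the element
    support <- (ext$left + k + ext$right) >= 0.5 * nchar(cons)
    if (sum(support) < cfg$min_copies) next
    ii <- ii[support]
    ext$left <- ext$left[support]
    ext$right <- ext$right[support]
    copies <- data.frame(replicon_id = rep_all[ii], strand = strand_all[ii],
                         start = NA_integer_, end = NA_integer_)
    for (j in seq_along(ii)) {
      i <- ii[j]
      if (strand_all[i] == "+") {
        copies$start[j] <- pos_all[i] - ext$left[j]
        copies$end[j] <- pos_all[i] + k + ext$right[j]
      } else {
        copies$start[j] <- pos_all[i] - ext$right[j]
        copies$end[j] <- pos_all[i] + k + ext$left[j]
      }
      rng <- max(1L, copies$start[j] + 1L):min(nchar(genome$seqs[[rep_all[i]]]),
                                               copies$end[j])
      covered[[rep_all[i]]][rng] <- TRUE
    }
    families[[length(families) + 1L]] <- list(
      family_id = sprintf("repfam_%02d", length(families) + 1L),
      consensus = cons, copies = copies,
      tir = find_tirs(cons, cfg))
  }
  .dedup_families(families)
}

# Greedy bidirectional extension of a seed shared by all contexts.
# Returns the consensus and per-copy left/right extents.
.extend_consensus <- function(ctx, off, k, cfg) {
  n <- length(ctx)
  lens <- nchar(ctx)
  extend_dir <- function(dir) {
    active <- rep(TRUE, n)
    win <- 25L
    recent <- matrix(FALSE, n, win)  # rolling mismatch window per copy
    steps <- 0L
    reach <- integer(n)   # per-copy extent in this direction
    cons <- character(0)
    repeat {
      steps <- steps + 1L
      at <- if (dir > 0) off + k + steps else off - steps + 1L
      ch <- rep(NA_character_, n)
      ok <- active & at >= 1L & at <= lens
      ch[ok] <- substring(ctx[ok], at[ok], at[ok])
      active[active & !ok] <- FALSE
      if (sum(active) < cfg$min_copies) break
      tabc <- sort(table(ch[active]), decreasing = TRUE)
      maj <- names(tabc)[1L]
      slot <- (steps - 1L) %% win + 1L
      recent[, slot] <- active & ch != maj
      # a copy stays only while its identity over the last `win` columns
      # is at least 80%
      drop <- active & steps >= 8L & rowSums(recent) / min(steps, win) > 0.20
      reach[active & !drop] <- steps
      active[drop] <- FALSE
      if (sum(active) < cfg$min_copies) break
      cons <- c(cons, maj)
      if (steps >= 3400L) break
    }
    list(cons = cons, reach = reach)
  }
  right <- extend_dir(+1L)
  left <- extend_dir(-1L)
  seed <- substr(ctx[1L], off[1L] + 1L, off[1L] + k)
  list(consensus = paste0(paste(rev(left$cons), collapse = ""), seed,
                          paste(right$cons, collapse = "")),
       left = left$reach, right = right$reach)
}

.dedup_families <- function(families) {
  if (length(families) < 2) return(families)
  keep <- rep(TRUE, length(families))
  ord <- order(-vapply(families, function(f) nrow(f$copies), 1L))
  claimed <- list()
  overlaps <- function(a, b) {
    a$replicon_id == b$replicon_id &&
      min(a$end, b$end) - max(a$start, b$start) >
        0.5 * min(a$end - a$start, b$end - b$start)
  }
  for (fi in ord) {
    f <- families[[fi]]
    dup <- FALSE
    for (cl in claimed) {
      for (ci in seq_len(nrow(f$copies))) {
        a <- f$copies[ci, ]
        for (cj in seq_len(nrow(cl))) {
          if (overlaps(a, cl[cj, ])) { dup <- TRUE; break }
        }
        if (dup) break
      }
      if (dup) break
    }
    if (dup) keep[fi] <- FALSE else claimed[[length(claimed) + 1L]] <- f$copies
  }
  families[keep]
}

#' Find the terminal inverted repeat of an element
#'
#' Searches for the longest pair (left prefix starting within
#' `tir_max_offset` of the element start, right suffix ending within
#' `tir_max_offset` of the element end) such that the left arm equals the
#' reverse complement of the right arm with at most `tir_max_mismatch`
#' mismatches and length at least `tir_min_len`. Ties prefer the longest,
#' then the outermost pair.
#'
#' @param element nucleotide string.
#' @param cfg an [is_config()].
#' @return list(length, left_offset, right_offset, left_seq, right_seq) or
#'   NULL when no TIR is found.
#' @export
find_tirs <- function(element, cfg = is_config()) {
  L <- nchar(element)
  if (L < 2L * cfg$tir_min_len) return(NULL)
  el <- strsplit(element, "", fixed = TRUE)[[1]]
  rc <- strsplit(revcomp(element), "", fixed = TRUE)[[1]]
  max_len <- min(cfg$tir_max_len, floor((L - 1) / 2))
  max_off <- min(cfg$tir_max_offset, L)
  for (len in seq(max_len, cfg$tir_min_len)) {
    best <- NULL
    for (a in 0:max_off) {
      if (a + len > L) break
      left <- el[(a + 1L):(a + len)]
      for (b in 0:max_off) {
        if (b + len > L - a - len) break  # arms must not overlap
        mm <- sum(left != rc[(b + 1L):(b + len)])
        if (mm <= cfg$tir_max_mismatch && (is.null(best) || a + b < best$off)) {
          best <- list(off = a + b, a = a, b = b, mm = mm)
        }
      }
    }
    if (!is.null(best)) {
      return(list(length = len, left_offset = best$a, right_offset = best$b,
                  left_seq = substr(element, best$a + 1L, best$a + len),
                  right_seq = substr(element, L - best$b - len + 1L, L - best$b),
                  mismatches = best$mm))
    }
  }
  NULL
}

KA_LAMBDA <- 1.33
KA_K <- 0.621

#' Bit score and E-value for a raw +1/-2 alignment score
#'
#' Karlin-Altschul statistics with fixed constants for the +1/-2 scoring
#' system; E-values are comparable within a run, not across tools.
#'
#' @param raw_score raw alignment score.
#' @param m,n effective genome and library lengths.
#' @return list(bits, e_value).
#' @export
karlin_altschul <- function(raw_score, m, n) {
  bits <- (KA_LAMBDA * raw_score - log(KA_K)) / log(2)
  list(bits = bits, e_value = m * n * 2^(-bits))
}

#' Scan a genome for homology to an IS library
#'
#' Shared 11-mers seed windows that are realigned with a local +1/-2
#' gapped alignment (gap open -5, extend -2); scores are converted to bit
#' scores and E-values with fixed Karlin-Altschul constants and hits at or
#' above `e_value_max` are discarded. Both strands are scanned. Library
#' coordinates are reported in the orientation of the hit so that fragment
#' coordinates ascend along the genome.
#'
#' @param genome a [genome_set()].
#' @param is_library named character vector of IS nucleotide sequences.
#' @param cfg an [is_config()].
#' @return data.frame of hits: replicon_id, start, end, strand,
#'   library_seq_id, raw_score, bits, e_value, lib_start, lib_end
#'   (0-based half-open, oriented).
#' @export
scan_homology <- function(genome, is_library, cfg = is_config()) {
  if (!length(is_library)) stop_validation("empty IS library")
  is_library <- setNames(vapply(is_library, normalize_dna, character(1)),
                         names(is_library))
  k <- 11L
  m_len <- sum(replicon_lengths(genome))
  n_len <- sum(nchar(is_library))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = FALSE)
  empty <- data.frame(replicon_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      library_seq_id = character(0), raw_score = numeric(0),
                      bits = numeric(0), e_value = numeric(0),
                      lib_start = integer(0), lib_end = integer(0))
  # oriented library: '+' as given, '-' reverse complemented
  lib_or <- list()
  for (id in names(is_library)) {
    lib_or[[paste0(id, "|+")]] <- is_library[[id]]
    lib_or[[paste0(id, "|-")]] <- revcomp(is_library[[id]])
  }
  lib_kmers <- unique(unlist(lapply(lib_or, function(s) {
    n <- nchar(s)
    if (n < k) character(0) else unique(substring(s, 1:(n - k + 1L), k:n))
  })))
  hits <- list()
  for (rid in names(genome$seqs)) {
    gseq <- genome$seqs[[rid]]
    L <- nchar(gseq)
    if (L < k) next
    gk <- substring(gseq, 1:(L - k + 1L), k:L)
    sel <- which(gk %in% lib_kmers)
    if (!length(sel)) next
    gmap <- split(sel, gk[sel])
    for (key in names(lib_or)) {
      s <- lib_or[[key]]
      n <- nchar(s)
      if (n < k) next
      lk <- substring(s, 1:(n - k + 1L), k:n)
      gpos <- sort(unique(unlist(gmap[unique(lk[lk %in% names(gmap)])])))
      if (!length(gpos)) next
      cl <- cumsum(c(1L, diff(gpos) > 300L))
      for (ci in unique(cl)) {
        p <- gpos[cl == ci]
        lo <- max(1L, min(p) - 30L)
        hi <- min(L, max(p) + k + 30L)
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(substr(gseq, lo, hi)),
          Biostrings::DNAString(s),
          substitutionMatrix = submat, gapOpening = 5, gapExtension = 2,
          type = "local")
        raw <- Biostrings::score(pa)
        ka <- karlin_altschul(raw, m_len, n_len)
        if (ka$e_value >= cfg$e_value_max) next
        pat <- Biostrings::pattern(pa); sub <- Biostrings::subject(pa)
        parts <- strsplit(key, "|", fixed = TRUE)[[1]]
        hits[[length(hits) + 1L]] <- data.frame(
          replicon_id = rid,
          start = lo - 1L + Biostrings::start(pat) - 1L,
          end = lo - 1L + Biostrings::end(pat),
          strand = parts[2], library_seq_id = parts[1],
          raw_score = raw, bits = ka$bits, e_value = ka$e_value,
          lib_start = Biostrings::start(sub) - 1L,
          lib_end = Biostrings::end(sub), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  # drop hits nested in a better hit of the same library sequence
  out <- out[order(out$replicon_id, out$library_seq_id, out$strand,
                   -out$raw_score), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(out)) > i &
                 out$replicon_id == out$replicon_id[i] &
                 out$library_seq_id == out$library_seq_id[i] &
                 out$strand == out$strand[i] &
                 pmin(out$end, out$end[i]) - pmax(out$start, out$start[i]) >
                   0.5 * (out$end - out$start))
    keep[j] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$replicon_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge homology fragments into distinct insertion sites
#'
#' Fragments of one family on one replicon and strand whose gap is at most
#' `merge_max_gap` and whose library coordinates are compatible
#' (essentially non-overlapping and ascending along the genome) are merged
#' into a single insertion-site record. Applying the merge to its own
#' output changes nothing.
#'
#' @param hits data.frame from [scan_homology()] (and/or repeat-family
#'   copies converted to the same shape; missing library coordinates are
#'   treated as compatible).
#' @param families optional list from [find_repeat_families()]; hits
#'   overlapping a family copy inherit that family id.
#' @param cfg an [is_config()].
#' @return data.frame of remnants: site_id, replicon_id, start, end,
#'   strand, family_id, n_fragments, with a `fragments` list column of
#'   per-fragment data.frames.
#' @export
merge_fragments <- function(hits, families = NULL, cfg = is_config()) {
  empty <- data.frame(site_id = character(0), replicon_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), family_id = character(0),
                      n_fragments = integer(0))
  if (is.null(hits) || nrow(hits) == 0) {
    empty$fragments <- list()
    return(empty)
  }
  h <- hits
  if (is.null(h$lib_start)) h$lib_start <- NA_integer_
  if (is.null(h$lib_end)) h$lib_end <- NA_integer_
  h$family_id <- h$library_seq_id %||% rep(NA_character_, nrow(h))
  if (!is.null(families) && length(families)) {
    # de-novo family ids only label hits that lack a library assignment;
    # fragments sharing a library sequence must stay in one group
    for (i in which(is.na(h$family_id))) {
      for (f in families) {
        cp <- f$copies
        ov <- cp$replicon_id == h$replicon_id[i] &
          pmin(cp$end, h$end[i]) - pmax(cp$start, h$start[i]) >
            0.5 * (h$end[i] - h$start[i])
        if (any(ov)) { h$family_id[i] <- f$family_id; break }
      }
    }
  }
  if (is.null(h$family_id)) h$family_id <- NA_character_
  h$family_id[is.na(h$family_id)] <- "unassigned"
  h <- h[order(h$replicon_id, h$family_id, h$strand, h$start), , drop = FALSE]
  groups <- split(seq_len(nrow(h)),
                  paste(h$replicon_id, h$family_id, h$strand, sep = "\r"))
  sites <- list()
  for (g in groups) {
    cur <- g[1L]
    members <- list(g[1L])
    if (length(g) > 1L) for (i in g[-1L]) {
      last <- members[[length(members)]]
      prev <- last[length(last)]
      gap <- h$start[i] - max(h$end[last])
      lib_ok <- is.na(h$lib_start[i]) || is.na(h$lib_end[prev]) ||
        h$lib_start[i] >= h$lib_end[prev] - 20L
      if (gap <= cfg$merge_max_gap && lib_ok) {
        members[[length(members)]] <- c(last, i)
      } else {
        members[[length(members) + 1L]] <- i
      }
    }
    for (mem in members) {
      frag <- h[mem, c("replicon_id", "start", "end", "strand",
                       "lib_start", "lib_end"), drop = FALSE]
      rownames(frag) <- NULL
      sites[[length(sites) + 1L]] <- list(
        replicon_id = h$replicon_id[mem[1L]],
        start = min(h$start[mem]), end = max(h$end[mem]),
        strand = h$strand[mem[1L]], family_id = h$family_id[mem[1L]],
        fragments = frag)
    }
  }
  ord <- order(vapply(sites, `[[`, character(1), "replicon_id"),
               vapply(sites, `[[`, numeric(1), "start"))
  sites <- sites[ord]
  out <- data.frame(
    site_id = sprintf("site_%03d", seq_along(sites)),
    replicon_id = vapply(sites, `[[`, character(1), "replicon_id"),
    start = as.integer(vapply(sites, `[[`, numeric(1), "start")),
    end = as.integer(vapply(sites, `[[`, numeric(1), "end")),
    strand = vapply(sites, `[[`, character(1), "strand"),
    family_id = vapply(sites, `[[`, character(1), "family_id"),
    n_fragments = vapply(sites, function(s) nrow(s$fragments), 1L),
    stringsAsFactors = FALSE)
  out$fragments <- lapply(sites, `[[`, "fragments")
  out
}

# Longest ORF lengths (aa, excluding the stop) in all six frames of a
# nucleotide string; start codon ATG, table 11 stops.
.orf_lengths <- function(dna, min_codons = 50L) {
  out <- integer(0)
  for (s in c(dna, revcomp(dna))) {
    for (f in 0:2) {
      aa <- translate_dna(substr(s, f + 1L, nchar(s)))
      if (!nzchar(aa)) next
      stops <- c(0L, which(strsplit(aa, "")[[1]] == "*"))
      for (si in seq_len(length(stops) - 1L)) {
        seg <- substr(aa, stops[si] + 1L, stops[si + 1L] - 1L)
        m <- regexpr("M", seg, fixed = TRUE)
        if (m > 0) {
          len <- nchar(seg) - m + 1L
          if (len >= min_codons) out <- c(out, len)
        }
      }
    }
  }
  out
}

#' Census of transposase ORFs over insertion-site remnants
#'
#' Counts open reading frames (ATG to in-frame stop, bacterial code, at
#' least 50 codons) overlapping each remnant; remnants carrying an ORF that
#' spans at least 80% of the family consensus are marked
#' `intact_transposase`, the rest `fragmented`.
#'
#' @param genome a [genome_set()].
#' @param remnants data.frame from [merge_fragments()].
#' @param cfg an [is_config()].
#' @param consensus_lengths named lengths (bp) of family consensi (from
#'   de-novo families or the IS library); remnants without one fall back to
#'   their own span.
#' @return list with n_orfs, n_long (ORFs longer than `transposase_min_aa`)
#'   and per_remnant (data.frame site_id, family_id, n_orfs, max_orf_aa,
#'   status).
#' @export
census_transposase_orfs <- function(genome, remnants, cfg = is_config(),
                                    consensus_lengths = NULL) {
  rows <- list()
  n_long <- 0L
  for (i in seq_len(nrow(remnants))) {
    dna <- extract_region(genome, remnants$replicon_id[i],
                          remnants$start[i], remnants$end[i], "+")
    lens <- .orf_lengths(dna)
    n_long <- n_long + sum(lens > cfg$transposase_min_aa)
    cons_len <- consensus_lengths[[remnants$family_id[i]]] %||%
      (remnants$end[i] - remnants$start[i])
    max_aa <- if (length(lens)) max(lens) else 0L
    intact <- length(lens) > 0 && 3L * (max_aa + 1L) >= 0.8 * cons_len
    rows[[i]] <- data.frame(site_id = remnants$site_id[i],
                            family_id = remnants$family_id[i],
                            n_orfs = length(lens), max_orf_aa = max_aa,
                            status = if (intact) "intact_transposase"
                                     else "fragmented",
                            stringsAsFactors = FALSE)
  }
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(0), family_id = character(0),
               n_orfs = integer(0), max_orf_aa = integer(0),
               status = character(0))
  list(n_orfs = sum(per$n_orfs), n_long = n_long, per_remnant = per)
}
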