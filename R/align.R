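# Frameshift-aware translated alignment: local protein HSPs in each of the
# three forward frames of a candidate region, then a collinear chain that
# charges a penalty per frame change. Frame changes in the chain are the
# frameshift evidence; '*' residues inside aligned blocks are the premature
# stop evidence.

#' Scoring scheme for translated alignment
#'
#' @param substitution amino-acid substitution matrix; default BLOSUM62
#'   (the '*' row scores stops as strong mismatches without terminating a
#'   local block).
#' @param gap_open,gap_extend negative gap penalties.
#' @param frameshift_penalty negative penalty charged per frame change when
#'   chaining blocks.
#' @param min_block_score minimum local-alignment score for a block to be
#'   retained.
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(substitution = NULL, gap_open = -11,
                           gap_extend = -1, frameshift_penalty = -15,
                           min_block_score = 35) {
  if (is.null(substitution)) substitution <- blosum62_matrix()
  stopifnot(gap_open <= gap_extend, gap_extend < 0, frameshift_penalty < 0)
  structure(list(substitution = substitution, gap_open = gap_open,
                 gap_extend = gap_extend,
                 frameshift_penalty = frameshift_penalty,
                 min_block_score = min_block_score),
            class = "scoring_scheme")
}

# Bit-score conversion for raw BLOSUM62(-11/-1) local protein scores,
# gapped Karlin-Altschul constants lambda = 0.267, K = 0.041.
protein_bits <- function(raw_score) {
  (0.267 * raw_score - log(0.041)) / log(2)
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Batched local alignments of several queries against one reference.
# Returns a data.frame with one row per query (score < min_block_score
# rows flagged by keep = FALSE).
.local_protein_hsps <- function(aa_queries, ref_protein, scoring) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(aa_queries), Biostrings::AAString(ref_protein),
    substitutionMatrix = scoring$substitution,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend,
    type = "local")
  p <- Biostrings::pattern(pa)
  s <- Biostrings::subject(pa)
  data.frame(score = Biostrings::score(pa),
             q_start = Biostrings::start(p), q_end = Biostrings::end(p),
             r_start = Biostrings::start(s), r_end = Biostrings::end(s),
             pattern_aln = as.character(p), subject_aln = as.character(s),
             keep = Biostrings::score(pa) >= scoring$min_block_score,
             stringsAsFactors = FALSE)
}

# Split one gapped local alignment at score valleys (X-drop), so that two
# well-matching stretches bridged by a low-scoring run (e.g. a frameshifted
# middle) come out as separate blocks, the way BLAST reports separate HSPs.
# Returns sub-blocks as 0-based half-open query/reference amino-acid
# offsets relative to the full sequences.
.split_hsp <- function(pattern_aln, subject_aln, q_start, r_start, scoring,
                       xdrop = 35) {
  P <- strsplit(pattern_aln, "", fixed = TRUE)[[1]]
  S <- strsplit(subject_aln, "", fixed = TRUE)[[1]]
  mat <- scoring$substitution
  ncols <- length(P)
  col_score <- numeric(ncols)
  in_gap <- FALSE
  for (cc in seq_len(ncols)) {
    if (P[cc] == "-" || S[cc] == "-") {
      col_score[cc] <- if (in_gap) scoring$gap_extend else
        scoring$gap_open + scoring$gap_extend
      in_gap <- TRUE
    } else {
      col_score[cc] <- mat[P[cc], S[cc]]
      in_gap <- FALSE
    }
  }
  q_cum <- cumsum(P != "-")   # non-gap query chars up to each column
  r_cum <- cumsum(S != "-")
  segs <- list()
  i <- 1L
  while (i <= ncols) {
    cur <- 0; maxv <- 0; maxpos <- i - 1L
    j <- i
    while (j <= ncols) {
      cur <- cur + col_score[j]
      if (cur > maxv) { maxv <- cur; maxpos <- j }
      if (cur < 0 || maxv - cur > xdrop) break
      j <- j + 1L
    }
    if (maxv > 0 && maxpos >= i) {
      q0 <- q_start - 1L + if (i > 1L) q_cum[i - 1L] else 0L
      r0 <- r_start - 1L + if (i > 1L) r_cum[i - 1L] else 0L
      segs[[length(segs) + 1L]] <- data.frame(
        q_start0 = q0, q_end0 = q_start - 1L + q_cum[maxpos],
        r_start0 = r0, r_end0 = r_start - 1L + r_cum[maxpos],
        score = maxv)
    }
    i <- max(j, maxpos) + 1L
  }
  if (!length(segs)) return(NULL)
  do.call(rbind, segs)
}

#' Align a candidate region against a reference protein in three frames
#'
#' Local alignments are computed independently in each of the three forward
#' frames of the given (already strand-oriented) region. Up to `max_hsps`
#' non-overlapping blocks are extracted per frame by iterative masking.
#' Internal stop codons inside an aligned block are counted and scored as
#' strong mismatches; they never terminate the block.
#'
#' @param region_dna nucleotide string, candidate region on its own strand.
#' @param ref_protein amino-acid string of the reference.
#' @param scoring a [scoring_scheme()].
#' @param max_hsps maximum blocks extracted per frame.
#' @return data.frame of alignment blocks with columns frame (0/1/2),
#'   region_start/region_end (nt offsets, 0-based half-open),
#'   ref_start/ref_end (aa offsets, 0-based half-open), score,
#'   n_internal_stops. Zero rows when the region is shorter than 30 nt or
#'   nothing scores above threshold.
#' @export
three_frame_align <- function(region_dna, ref_protein, scoring = scoring_scheme(),
                              max_hsps = 4L) {
  empty <- data.frame(frame = integer(0), region_start = integer(0),
                      region_end = integer(0), ref_start = integer(0),
                      ref_end = integer(0), score = numeric(0),
                      n_internal_stops = integer(0))
  region_dna <- normalize_dna(region_dna)
  if (nchar(region_dna) < 30L) return(empty)
  ref_protein <- toupper(ref_protein)
  frames_aa <- vapply(0:2, function(f)
    translate_dna(substr(region_dna, f + 1L, nchar(region_dna))), character(1))
  frame_chars <- lapply(frames_aa, function(a)
    if (nzchar(a)) strsplit(a, "", fixed = TRUE)[[1]] else character(0))
  masked <- frames_aa
  active <- nzchar(frames_aa)
  out <- list()
  ref_cov <- IRanges::IRanges()
  for (it in seq_len(max_hsps)) {
    idx <- which(active)
    if (!length(idx)) break
    hsps <- .local_protein_hsps(masked[idx], ref_protein, scoring)
    for (j in seq_along(idx)) {
      fi <- idx[j]
      if (!hsps$keep[j]) { active[fi] <- FALSE; next }
      f <- fi - 1L
      # X-drop segmentation: report well-matching stretches separately
      segs <- .split_hsp(hsps$pattern_aln[j], hsps$subject_aln[j],
                         hsps$q_start[j], hsps$r_start[j], scoring)
      if (!is.null(segs)) {
        segs <- segs[segs$score >= scoring$min_block_score, , drop = FALSE]
        for (si in seq_len(nrow(segs))) {
          n_stop <- sum(frame_chars[[fi]][
            (segs$q_start0[si] + 1L):segs$q_end0[si]] == "*")
          out[[length(out) + 1L]] <- data.frame(
            frame = f,
            region_start = f + 3L * segs$q_start0[si],
            region_end = f + 3L * segs$q_end0[si],
            ref_start = segs$r_start0[si], ref_end = segs$r_end0[si],
            score = segs$score[si], n_internal_stops = n_stop)
        }
      }
      # mask the whole aligned stretch so the next round finds new evidence
      substr(masked[fi], hsps$q_start[j], hsps$q_end[j]) <-
        strrep("*", hsps$q_end[j] - hsps$q_start[j] + 1L)
      ref_cov <- IRanges::reduce(c(ref_cov,
        IRanges::IRanges(hsps$r_start[j], hsps$r_end[j])))
    }
    # stop once the reference is essentially covered
    if (sum(IRanges::width(ref_cov)) >= 0.97 * nchar(ref_protein)) break
  }
  if (!length(out)) return(empty)
  blocks <- do.call(rbind, out)
  blocks[order(blocks$region_start, blocks$ref_start), , drop = FALSE]
}

# Chainability: j may follow i if both region and reference coordinates
# advance, allowing a small overlap (local HSPs around an indel usually
# share a few residues at the breakpoint).
.chainable <- function(b, i, j, slack_nt = 135L, slack_aa = 45L) {
  if (b$region_end[j] <= b$region_end[i] || b$ref_end[j] <= b$ref_end[i])
    return(FALSE)
  ov_nt <- b$region_end[i] - b$region_start[j]
  ov_aa <- b$ref_end[i] - b$ref_start[j]
  # overlap allowed up to the slack, but a block may never be mostly
  # swallowed by its chain partner
  ov_nt <= min(slack_nt,
               0.75 * (b$region_end[i] - b$region_start[i]),
               0.75 * (b$region_end[j] - b$region_start[j])) &&
    ov_aa <= min(slack_aa,
                 0.75 * (b$ref_end[i] - b$ref_start[i]),
                 0.75 * (b$ref_end[j] - b$ref_start[j]))
}

#' Chain alignment blocks into a frameshift-aware alignment
#'
#' Selects the maximum-total-score chain of blocks collinear in both region
#' and reference coordinates, charging `frameshift_penalty` per frame
#' change between consecutive blocks.
#'
#' @param blocks data.frame from [three_frame_align()].
#' @param ref_len full reference protein length (aa).
#' @param scoring a [scoring_scheme()].
#' @return object of class `chained_alignment`: list with blocks (the chosen
#'   chain), score, n_frameshifts, n_stops, aligned_fraction.
#' @export
chain_blocks <- function(blocks, ref_len, scoring = scoring_scheme()) {
  if (is.null(blocks) || nrow(blocks) == 0) {
    return(structure(list(blocks = blocks, score = 0, n_frameshifts = 0L,
                          n_stops = 0L, aligned_fraction = 0),
                     class = "chained_alignment"))
  }
  b <- blocks[order(blocks$region_start, blocks$ref_start), , drop = FALSE]
  n <- nrow(b)
  best <- b$score         # best chain score ending at i
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      if (.chainable(b, i, j)) {
        cand <- best[i] + b$score[j] +
          if (b$frame[i] != b$frame[j]) scoring$frameshift_penalty else 0
        if (cand > best[j]) {
          best[j] <- cand
          prev[j] <- i
        }
      }
    }
  }
  endi <- which.max(best)
  path <- endi
  while (!is.na(prev[path[1L]])) path <- c(prev[path[1L]], path)
  chain <- b[path, , drop = FALSE]
  rownames(chain) <- NULL
  covered <- 0L
  if (ref_len > 0) {
    ir <- IRanges::reduce(IRanges::IRanges(chain$ref_start + 1L, chain$ref_end))
    covered <- sum(IRanges::width(ir))
  }
  structure(list(
    blocks = chain,
    score = best[endi],
    n_frameshifts = sum(diff(chain$frame) != 0),
    n_stops = sum(chain$n_internal_stops),
    aligned_fraction = if (ref_len > 0) min(1, covered / ref_len) else 0),
    class = "chained_alignment")
}

#' @export
print.chained_alignment <- function(x, ...) {
  cat(sprintf(
    "chained_alignment: %d block(s), score %.1f, %d frameshift(s), %d stop(s), aligned fraction %.3f\n",
    if (is.null(x$blocks)) 0L else nrow(x$blocks), x$score,
    x$n_frameshifts, x$n_stops, x$aligned_fraction))
  invisible(x)
}
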