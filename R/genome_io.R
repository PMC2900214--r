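# On-disk formats and the internal coordinate convention.
#
# Every interval inside the package is 0-based, half-open [start, end).
# 1-based inclusive coordinates exist only at the GFF3 boundary:
# start_gff = start_internal + 1, end_gff = end_internal.

#' Construct a genome set
#'
#' A genome is a named set of replicon sequences plus a topology flag per
#' replicon. Sequences are uppercase over {A,C,G,T,N}.
#'
#' @param seqs named character vector of nucleotide sequences; names are
#'   replicon ids and must be unique.
#' @param topology named character vector, values "circular" or "linear";
#'   defaults to linear for every replicon.
#' @return object of class `genome_set`.
#' @export
genome_set <- function(seqs, topology = NULL) {
  if (length(seqs) == 0) stop_validation("genome has no replicons")
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop_validation("every replicon needs an id")
  if (anyDuplicated(ids))
    stop_validation("duplicate replicon ids: ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- vapply(seqs, normalize_dna, character(1))
  if (any(nchar(seqs) < 1)) stop_validation("empty replicon sequence")
  if (is.null(topology)) topology <- setNames(rep("linear", length(ids)), ids)
  topology <- topology[ids]
  topology[is.na(topology)] <- "linear"
  names(topology) <- ids
  structure(list(seqs = seqs, topology = topology), class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set with", length(x$seqs), "replicon(s):\n")
  for (id in names(x$seqs))
    cat(sprintf("  %s  %d bp  %s\n", id, nchar(x$seqs[[id]]), x$topology[[id]]))
  invisible(x)
}

replicon_lengths <- function(genome) nchar(genome$seqs)

# Extract [start, end) from a replicon; strand "-" returns the reverse
# complement (sequences are never stored reversed).
extract_region <- function(genome, replicon_id, start, end, strand = "+") {
  s <- genome$seqs[[replicon_id]]
  if (is.null(s)) stop_validation("unknown replicon: ", replicon_id)
  start <- max(0L, start)
  end <- min(nchar(s), end)
  if (end <= start) return("")
  out <- substr(s, start + 1L, end)
  if (strand == "-") revcomp(out) else out
}

#' Read a genome from FASTA
#'
#' Lowercase is normalized to uppercase and every non-ACGT letter is
#' collapsed to N. Topology defaults to linear unless the header carries a
#' `circular=true` tag; `assume_circular = TRUE` overrides all records.
#'
#' @param path FASTA file.
#' @param assume_circular mark every replicon circular regardless of header.
#' @return a [genome_set()].
#' @export
read_genome_fasta <- function(path, assume_circular = FALSE) {
  ss <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                 error = function(e) stop_validation("FASTA format error in ",
                                                     path, ": ", conditionMessage(e)))
  if (length(ss) == 0) stop_validation("empty FASTA file: ", path)
  headers <- names(ss)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop_validation("duplicate FASTA ids: ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  circ <- grepl("circular=true", headers, ignore.case = TRUE) | assume_circular
  genome_set(setNames(as.character(ss), ids),
             setNames(ifelse(circ, "circular", "linear"), ids))
}

#' Write a genome to FASTA
#'
#' @param genome a [genome_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  hdr <- ifelse(genome$topology == "circular",
                paste0(names(genome$seqs), " circular=true"),
                names(genome$seqs))
  ss <- Biostrings::DNAStringSet(genome$seqs)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

FEATURE_TYPES <- c("CDS", "pseudogene", "tRNA", "rRNA", "IS_remnant", "other")

#' Construct a feature set
#'
#' A feature set is a data.frame of annotated intervals with the internal
#' 0-based half-open convention, ordered by (replicon, start).
#'
#' @param df data.frame with columns feature_id, replicon_id, start, end,
#'   strand, ftype, product, cog_category; an optional `attrs` list column
#'   carries extra key=value attributes.
#' @param genome optional [genome_set()]; when given, intervals and seqids
#'   are validated against it.
#' @return object of class `feature_set` (a data.frame).
#' @export
feature_set <- function(df, genome = NULL) {
  need <- c("feature_id", "replicon_id", "start", "end", "strand", "ftype")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_validation("missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$product)) df$product <- rep("", nrow(df))
  if (is.null(df$cog_category)) df$cog_category <- rep(NA_character_, nrow(df))
  if (is.null(df$attrs)) df$attrs <- replicate(nrow(df), character(0), simplify = FALSE)
  if (nrow(df)) {
    if (anyDuplicated(df$feature_id))
      stop_validation("duplicate feature ids: ",
                      paste(unique(df$feature_id[duplicated(df$feature_id)]), collapse = ", "))
    if (any(df$end <= df$start))
      stop_validation("features with end <= start: ",
                      paste(df$feature_id[df$end <= df$start], collapse = ", "))
    if (!all(df$strand %in% c("+", "-")))
      stop_validation("strand must be '+' or '-'")
    if (!all(df$ftype %in% FEATURE_TYPES))
      stop_validation("unknown ftype: ",
                      paste(setdiff(df$ftype, FEATURE_TYPES), collapse = ", "))
    bad_cog <- !is.na(df$cog_category) & !(df$cog_category %in% COG_CATEGORIES)
    if (any(bad_cog))
      stop_validation("invalid COG category: ",
                      paste(unique(df$cog_category[bad_cog]), collapse = ", "))
    if (!is.null(genome)) {
      unknown <- setdiff(unique(df$replicon_id), names(genome$seqs))
      if (length(unknown))
        stop_validation("features reference unknown replicons: ",
                        paste(unknown, collapse = ", "))
      lens <- replicon_lengths(genome)[df$replicon_id]
      if (any(df$start < 0) || any(df$end > lens))
        stop_validation("feature interval outside replicon bounds: ",
                        paste(df$feature_id[df$start < 0 | df$end > lens], collapse = ", "))
    }
    df <- df[order(df$replicon_id, df$start, df$feature_id), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("feature_set", "data.frame")
  df
}

empty_feature_set <- function() {
  feature_set(data.frame(feature_id = character(0), replicon_id = character(0),
                         start = integer(0), end = integer(0),
                         strand = character(0), ftype = character(0),
                         product = character(0), cog_category = character(0),
                         stringsAsFactors = FALSE))
}

# --- GFF3 ------------------------------------------------------------------

GFF_TYPE_MAP <- c(CDS = "CDS", pseudogene = "pseudogene", tRNA = "tRNA",
                  rRNA = "rRNA", IS_remnant = "IS_remnant")

gff_unescape <- function(x) {
  x <- gsub("%3B", ";", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%2C", ",", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

parse_gff_attrs <- function(s) {
  if (is.na(s) || s == "." || s == "") return(character(0))
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  kv <- kv[vapply(kv, length, 1L) == 2L]
  setNames(gff_unescape(vapply(kv, `[`, character(1), 2L)),
           vapply(kv, `[`, character(1), 1L))
}

format_gff_attrs <- function(attrs) {
  if (!length(attrs)) return(".")
  paste(paste0(names(attrs), "=", gff_escape(unname(attrs))), collapse = ";")
}

#' Read features from GFF3
#'
#' GFF 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention. A `pseudo=true` attribute or type `pseudogene`
#' maps to ftype pseudogene; a `cog=X` attribute populates the COG
#' category.
#'
#' @param path GFF3 file.
#' @param genome [genome_set()] whose replicon ids the seqid column must match.
#' @return a [feature_set()].
#' @export
read_features_gff <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(empty_feature_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 1L) < 9L))
    stop_validation("malformed GFF line(s) in ", path)
  m <- do.call(rbind, parts)
  seqid <- m[, 1]; type <- m[, 3]
  start_gff <- as.integer(m[, 4]); end_gff <- as.integer(m[, 5])
  strand <- m[, 7]
  unknown <- setdiff(unique(seqid), names(genome$seqs))
  if (length(unknown))
    stop_validation("GFF seqids not in genome: ", paste(unknown, collapse = ", "))
  if (any(end_gff < start_gff))
    stop_validation("GFF end < start at line(s) ",
                    paste(which(end_gff < start_gff), collapse = ", "))
  attrs <- lapply(m[, 9], parse_gff_attrs)
  get_attr <- function(a, k) if (k %in% names(a)) a[[k]] else NA_character_
  ids <- vapply(attrs, get_attr, character(1), "ID")
  ids[is.na(ids)] <- paste0("feature_", seq_len(length(lines)))[is.na(ids)]
  ftype <- ifelse(type %in% names(GFF_TYPE_MAP), GFF_TYPE_MAP[type], "other")
  pseudo <- vapply(attrs, function(a) identical(tolower(get_attr(a, "pseudo")), "true"), logical(1))
  ftype[pseudo & ftype == "CDS"] <- "pseudogene"
  cog <- vapply(attrs, get_attr, character(1), "cog")
  product <- vapply(attrs, get_attr, character(1), "product")
  product[is.na(product)] <- ""
  reserved <- c("ID", "product", "cog", "pseudo")
  extra <- lapply(attrs, function(a) a[setdiff(names(a), reserved)])
  df <- data.frame(feature_id = ids, replicon_id = seqid,
                   start = start_gff - 1L, end = end_gff,
                   strand = ifelse(strand %in% c("+", "-"), strand, "+"),
                   ftype = ftype, product = product,
                   cog_category = cog, stringsAsFactors = FALSE)
  df$attrs <- extra
  feature_set(df, genome)
}

#' Write features to GFF3
#'
#' @param features a [feature_set()].
#' @param path output file.
#' @param source value for the GFF source column.
#' @return `path`, invisibly.
#' @export
write_features_gff <- function(features, path, source = "erosionscan") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    gff_type <- ifelse(features$ftype %in% names(GFF_TYPE_MAP),
                       features$ftype, "region")
    attr_str <- vapply(seq_len(nrow(features)), function(i) {
      a <- c(ID = features$feature_id[i])
      if (nzchar(features$product[i])) a <- c(a, product = features$product[i])
      if (!is.na(features$cog_category[i])) a <- c(a, cog = features$cog_category[i])
      if (features$ftype[i] == "pseudogene") a <- c(a, pseudo = "true")
      a <- c(a, unlist(features$attrs[[i]]))
      format_gff_attrs(a)
    }, character(1))
    writeLines(paste(features$replicon_id, source, gff_type,
                     features$start + 1L, features$end, ".",
                     features$strand, ".", attr_str, sep = "\t"), con)
  }
  invisible(path)
}

#' Write the standard output bundle of a run
#'
#' Writes `calls.gff3` (pseudogene and IS_remnant features with their
#' evidence attributes), `erosion.tsv`, `cog_table.tsv` and `report.json`
#' into a directory and returns a manifest of files with row counts.
#'
#' @param calls a [feature_set()] carrying final call status.
#' @param stats an [erosion_summary()] result (or NULL).
#' @param outdir output directory, created if absent.
#' @param cog_result optional result of [simulated_pvalue()].
#' @param extra optional named list merged into report.json.
#' @return data.frame manifest (file, rows), invisibly.
#' @export
write_outputs <- function(calls, stats = NULL, outdir, cog_result = NULL,
                          extra = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  manifest <- data.frame(file = character(0), rows = integer(0))
  add <- function(f, n) rbind(manifest, data.frame(file = f, rows = n))

  keep <- calls[calls$ftype %in% c("pseudogene", "IS_remnant"), , drop = FALSE]
  class(keep) <- class(calls)
  gff_path <- file.path(outdir, "calls.gff3")
  write_features_gff(keep, gff_path)
  manifest <- add("calls.gff3", nrow(keep))

  ero_path <- file.path(outdir, "erosion.tsv")
  ero_df <- if (is.null(stats)) {
    data.frame(replicon_id = character(0), n_genes_total = integer(0),
               n_cds_intact = integer(0), n_pseudogenes = integer(0),
               n_rna_genes = integer(0), erosion_ratio = numeric(0),
               length_bp = integer(0), gc_percent = numeric(0))
  } else erosion_table(stats)
  write.table(ero_df, ero_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- add("erosion.tsv", nrow(ero_df))

  cog_path <- file.path(outdir, "cog_table.tsv")
  cog_df <- if (is.null(cog_result)) {
    data.frame(category = character(0), n_intact = integer(0),
               n_pseudo = integer(0), pct_pseudo = numeric(0),
               residual = numeric(0))
  } else cog_table_report(cog_result)
  write.table(cog_df, cog_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- add("cog_table.tsv", nrow(cog_df))

  report <- list(
    pseudogene_fraction = if (is.null(stats)) NA_real_ else
      stats$pseudogene_percent_of_genes / 100,
    per_replicon = if (is.null(stats)) list() else stats$per_replicon,
    chisq = if (is.null(cog_result)) list() else unclass(cog_result)[
      c("statistic", "df", "B", "b_exceed", "p_simulated", "seed")]
  )
  if (!is.null(extra)) report <- c(report, extra)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- add("report.json", 1L)
  invisible(manifest)
}
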