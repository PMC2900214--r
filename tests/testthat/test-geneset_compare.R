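# Affine-gap Smith-Waterman (Gotoh) in plain R: the independent oracle for
# the library-backed alignments used by best_reciprocal_hits.
sw_local <- function(a, b, mat, gap_open = 11, gap_ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in A (consumes B)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in B (consumes A)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_ext, E[i, j - 1] - gap_ext)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_ext, F[i - 1, j] - gap_ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

test_that("identical proteomes pair one-to-one; missing proteins unpair", {
  set.seed(70)
  pa <- random_proteome(6L, len_range = c(40L, 60L), seed = 70L)
  brh <- best_reciprocal_hits(pa, pa)
  expect_equal(nrow(brh), 6L)
  expect_identical(brh$id_a, brh$id_b)
  expect_false(any(brh$ambiguous))

  pb <- pa[-3]
  brh2 <- best_reciprocal_hits(pa, pb)
  expect_false(names(pa)[3] %in% brh2$id_a)
  expect_equal(nrow(brh2), 5L)
})

test_that("BRH pairs agree with an exhaustive Smith-Waterman oracle", {
  set.seed(71)
  pa <- random_proteome(6L, len_range = c(35L, 55L), seed = 71L)
  names(pa) <- paste0("a", seq_along(pa))
  # proteome b: noisy copies of a (point substitutions), shuffled order
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pb <- vapply(pa, function(p) {
    x <- strsplit(p, "")[[1]]
    at <- sample(seq_along(x), 3L)
    x[at] <- sample(aas, 3L, replace = TRUE)
    paste(x, collapse = "")
  }, character(1))
  names(pb) <- paste0("b", seq_along(pb))
  perm <- sample(length(pb))
  pb <- pb[perm]

  mat <- erosionscan:::blosum62_matrix()
  sc <- matrix(0, length(pa), length(pb),
               dimnames = list(names(pa), names(pb)))
  for (i in names(pa)) for (j in names(pb))
    sc[i, j] <- sw_local(pa[[i]], pb[[j]], mat)
  oracle_pairs <- character(0)
  for (i in names(pa)) {
    jb <- names(pb)[which.max(sc[i, ])]
    if (names(pa)[which.max(sc[, jb])] == i && max(sc[i, ]) >= 30)
      oracle_pairs <- c(oracle_pairs, paste(i, jb))
  }
  got <- best_reciprocal_hits(pa, pb)
  expect_setequal(paste(got$id_a, got$id_b), oracle_pairs)
  # and the scores themselves agree with the oracle
  for (r in seq_len(nrow(got)))
    expect_equal(got$score[r], sc[got$id_a[r], got$id_b[r]])
})

test_that("gene-set entries are classified intact / pseudogene / absent", {
  run <- default_run()
  truth <- run$gen$truth
  tg <- truth[truth$kind %in% c("intact_gene", "pseudogene") &
                !is.na(truth$source_protein_id) &
                startsWith(truth$event_id, "gene_"), ]
  pick_int <- utils::head(tg$source_protein_id[tg$kind == "intact_gene"], 4)
  pick_pse <- utils::head(
    tg$source_protein_id[tg$kind == "pseudogene" & tg$class != "split"], 4)
  absent <- setdiff(names(run$refs), tg$source_protein_id)[1:2]
  entries <- data.frame(
    set_name = "toy", gene_name = paste0("g", 1:10),
    ref_protein = unname(run$refs[c(pick_int, pick_pse, absent)]),
    stringsAsFactors = FALSE)
  st <- classify_gene_set(entries, run$gen$genome, run$called$features)
  expect_equal(st$status,
               c(rep("intact", 4), rep("pseudogene", 4), rep("absent", 2)))
  expect_true(all(is.na(st$matched_feature_id[st$status == "absent"])))
  expect_true(all(!is.na(st$matched_feature_id[st$status != "absent"])))
  expect_error(classify_gene_set(entries[0, ], run$gen$genome,
                                 run$called$features), "empty")
})

test_that("an intact copy anywhere overrides a pseudogene copy", {
  prot <- random_proteome(1L, len_range = c(150L, 150L), seed = 72L)[[1]]
  gene <- make_gene(prot, seed = 72L)
  set.seed(73)
  broken <- plant_pseudogene(gene, "internal_stop")$dna
  spacer <- function(n, s) { set.seed(s); erosionscan:::random_dna(n, 0.383) }
  genome <- genome_set(c(
    chromosome = paste0(spacer(300, 1), gene, spacer(300, 2)),
    plasmid = paste0(spacer(300, 3), broken, spacer(300, 4))))
  feats <- feature_set(data.frame(
    feature_id = c("chr_copy", "pl_copy"),
    replicon_id = c("chromosome", "plasmid"),
    start = 300L, end = c(300L + nchar(gene), 300L + nchar(broken)),
    strand = "+", ftype = "CDS", product = "p",
    stringsAsFactors = FALSE), genome)
  called <- call_pseudogenes(genome, feats, c(refP = prot))
  expect_equal(called$calls$feature_id, "pl_copy")
  entries <- data.frame(set_name = "toy", gene_name = "dupGene",
                        ref_protein = prot, stringsAsFactors = FALSE)
  st <- classify_gene_set(entries, genome, called$features)
  expect_equal(st$status, "intact")
  expect_equal(st$matched_feature_id, "chr_copy")
  # order independence: shuffling features does not change the status
  shuf <- feature_set(as.data.frame(called$features[c(2, 1), ]))
  st2 <- classify_gene_set(entries, genome, shuf)
  expect_equal(st2$status, "intact")
})

test_that("gene sets load from TSV plus protein FASTA", {
  prots <- random_proteome(3L, len_range = c(30L, 40L), seed = 74L)
  faa <- tempfile(fileext = ".faa")
  writeLines(c(rbind(paste0(">", names(prots)), unname(prots))), faa)
  tsv <- write_tmp(c("set_name\tgene_name\tprotein_id",
                     paste("minimal", "dnaA", names(prots)[1], sep = "\t"),
                     paste("core", "pfkA", names(prots)[2], sep = "\t")),
                   ".tsv")
  entries <- read_gene_set(tsv, faa)
  expect_equal(nrow(entries), 2L)
  expect_equal(entries$ref_protein[1], unname(prots[1]))
  bad <- write_tmp(c("set_name\tgene_name\tprotein_id",
                     "minimal\tdnaA\tnope"), ".tsv")
  expect_error(read_gene_set(bad, faa), "missing")
})
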