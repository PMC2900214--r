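mk_chain <- function(n_stops, n_frameshifts, fraction, empty = FALSE) {
  structure(list(
    blocks = if (empty) data.frame() else
      data.frame(frame = 0L, region_start = 0L, region_end = 30L,
                 ref_start = 0L, ref_end = 10L, score = 50,
                 n_internal_stops = n_stops),
    score = 50, n_stops = n_stops, n_frameshifts = n_frameshifts,
    aligned_fraction = fraction), class = "chained_alignment")
}

test_that("the calling rules fire exactly as specified", {
  cfg <- caller_config()
  expect_equal(classify_candidate(mk_chain(0, 0, 1.0), cfg)$status, "intact")
  r <- classify_candidate(mk_chain(2, 0, 0.95), cfg)
  expect_equal(r$status, "pseudogene")
  expect_equal(r$class, "internal_stop")
  r <- classify_candidate(mk_chain(0, 0, 0.25), cfg)
  expect_equal(r$status, "pseudogene")
  expect_equal(r$class, "truncated")
  # one interruption is tolerated under the default threshold of 2
  expect_equal(classify_candidate(mk_chain(1, 0, 0.90), cfg)$status, "intact")
  # mixed interruptions combine; frameshifts win ties
  r <- classify_candidate(mk_chain(1, 1, 0.90), cfg)
  expect_equal(r$class, "frameshift")
  r <- classify_candidate(mk_chain(2, 1, 0.90), cfg)
  expect_equal(r$class, "internal_stop")
  # no homolog at all: intact, flagged no_evidence
  r <- classify_candidate(mk_chain(0, 0, 0, empty = TRUE), cfg)
  expect_equal(r$status, "intact")
  expect_equal(r$note, "no_evidence")
  # thresholds are knobs
  strict <- caller_config(interruption_threshold = 3L)
  expect_equal(classify_candidate(mk_chain(2, 0, 0.95), strict)$status,
               "intact")
  lax <- caller_config(truncation_fraction = 0.20)
  expect_equal(classify_candidate(mk_chain(0, 0, 0.25), lax)$status, "intact")
})

test_that("truncation boundary: 29% kept is called, 31% kept is not", {
  prot <- random_proteome(1L, len_range = c(199L, 199L), seed = 31L)[[1]]
  gene <- make_gene(prot, seed = 31L)
  refs <- c(refA = prot)
  for (kept in c(0.29, 0.31)) {
    set.seed(40)
    planted <- plant_pseudogene(gene, "truncated", kept_fraction = kept)
    fx <- single_gene_genome(planted$dna, seed = 41L)
    res <- call_pseudogenes(fx$genome, fx$features, refs)
    if (kept == 0.29) {
      expect_equal(res$calls$class, "truncated")
    } else {
      expect_equal(nrow(res$calls), 0L)
    }
  }
})

test_that("caller recovers planted pseudogenes on the default conditions", {
  run <- default_run()
  perf <- eval_caller(run$gen, run$called)
  expect_gte(perf$sensitivity, 0.95)
  expect_lte(perf$fpr, 0.01)
  # classes recovered for non-split plants match the planted classes
  pg <- run$gen$truth[run$gen$truth$kind == "pseudogene" &
                        run$gen$truth$class != "split", ]
  calls <- run$called$calls
  matched <- merge(pg[, c("event_id", "class")], calls,
                   by.x = "event_id", by.y = "feature_id")
  expect_gt(mean(matched$class.x == matched$class.y), 0.9)
})

test_that("an all-intact genome yields zero calls, deterministically", {
  cfg <- synth_config(n_genes = 30L, pseudogene_fraction = 0,
                      n_is_elements = 0L, n_rna_genes = 2L,
                      replicon_lengths = c(60000L, 20000L, 10000L),
                      seed = 12L)
  refs <- random_proteome(40L, seed = 12L)
  gen <- generate_genome(cfg, refs)
  res1 <- call_pseudogenes(gen$genome, gen$features, refs)
  expect_equal(nrow(res1$calls), 0L)
  res2 <- call_pseudogenes(gen$genome, gen$features, refs)
  expect_identical(res1$calls, res2$calls)
  expect_identical(res1$features$ftype, res2$features$ftype)
})

test_that("raising thresholds never increases calls (monotonicity)", {
  run <- default_run()
  base_calls <- run$called$calls
  stricter <- call_pseudogenes(run$gen$genome, run$gen$features, run$refs,
                               caller_config(interruption_threshold = 3L))
  expect_lte(nrow(stricter$calls), nrow(base_calls))
  lower_trunc <- call_pseudogenes(run$gen$genome, run$gen$features, run$refs,
                                  caller_config(truncation_fraction = 0.15))
  expect_lte(sum(lower_trunc$calls$class == "truncated"),
             sum(base_calls$class == "truncated"))
})

test_that("split detection obeys the overlap, order and gap rules", {
  feats <- feature_set(data.frame(
    feature_id = c("f1", "mid", "f2"), replicon_id = "chr",
    start = c(0L, 400L, 700L), end = c(300L, 650L, 1000L), strand = "+",
    ftype = "CDS", product = c("refX", "other", "refX"),
    stringsAsFactors = FALSE))
  blk <- function(rs, re, score = 400) data.frame(
    frame = 0L, region_start = 0L, region_end = 3L * (re - rs),
    ref_start = rs, ref_end = re, score = score, n_internal_stops = 0L)
  ch <- function(rs, re, id = "refX") structure(
    list(blocks = blk(rs, re), score = 400, n_stops = 0L,
         n_frameshifts = 0L, aligned_fraction = (re - rs) / 200,
         ref_protein_id = id), class = "chained_alignment")
  chains <- list(f1 = ch(0, 95), mid = ch(0, 80, id = "refY"),
                 f2 = ch(100, 200))
  hits <- detect_split_orf(feats, chains)
  expect_setequal(hits$feature_id, c("f1", "f2"))
  expect_equal(length(unique(hits$event_id)), 1L)

  # two paralogs covering >80% of the same reference: not split
  chains2 <- list(f1 = ch(0, 180), mid = ch(0, 80, id = "refY"),
                  f2 = ch(5, 190))
  expect_equal(nrow(detect_split_orf(feats, chains2)), 0L)

  # fragments 10 kb apart exceed the default split_max_gap
  far <- feats
  far$start[far$feature_id == "f2"] <- 10700L
  far$end[far$feature_id == "f2"] <- 11000L
  far <- feature_set(as.data.frame(far))
  expect_equal(nrow(detect_split_orf(far, chains)), 0L)
})
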