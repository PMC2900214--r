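random_genome <- function(n, seed, gc = 0.383) {
  set.seed(seed)
  genome_set(c(chr = erosionscan:::random_dna(n, gc)))
}

plant_copies <- function(host, insert, positions) {
  s <- host$seqs[["chr"]]
  for (p in sort(positions, decreasing = TRUE))
    s <- paste0(substr(s, 1, p), insert, substr(s, p + 1, nchar(s)))
  genome_set(c(chr = s))
}

test_that("repeat families require copy number and consensus length", {
  host <- random_genome(200000L, seed = 50L)
  expect_length(find_repeat_families(host), 0L)

  set.seed(51)
  el <- make_is_family(900L, gc_p = 0.383)
  g5 <- plant_copies(host, el, c(10000, 50000, 90000, 130000, 170000))
  fams <- find_repeat_families(g5)
  expect_length(fams, 1L)
  expect_equal(nrow(fams[[1]]$copies), 5L)
  expect_gte(nchar(fams[[1]]$consensus), 600L)
  # planted TIR is recovered on the consensus
  expect_false(is.null(fams[[1]]$tir))
  expect_gte(fams[[1]]$tir$length, 15L)

  set.seed(52)
  short <- erosionscan:::random_dna(500L, 0.383)
  g3 <- plant_copies(host, short, c(20000, 80000, 140000))
  expect_length(find_repeat_families(g3), 0L)
})

test_that("TIR search honours length, offset and mismatch bounds", {
  set.seed(53)
  tir <- erosionscan:::random_dna(20L, 0.5)
  mid <- erosionscan:::random_dna(760L, 0.383)
  el <- paste0(tir, mid, revcomp(tir))
  hit <- find_tirs(el)
  expect_gte(hit$length, 20L)
  expect_equal(hit$left_offset + hit$right_offset, 0L)

  expect_null(find_tirs(strrep("A", 400)))

  flip <- function(s, i) { substr(s, i, i) <- chartr("ACGT", "GTAC",
                                                     substr(s, i, i)); s }
  el2 <- flip(flip(el, 3), 9)          # 2 mismatches in the left arm
  expect_gte(find_tirs(el2)$length, 18L)
  el3 <- flip(el2, 15)                 # 3 mismatches
  # the full 20-bp arm now exceeds the mismatch budget; only a shorter
  # inner arm (skipping mutated positions) can still qualify
  got <- find_tirs(el3)
  expect_true(is.null(got) || got$length < 20L)
})

test_that("homology scanning finds planted library sequence with tiny E", {
  host <- random_genome(50000L, seed = 54L)
  set.seed(55)
  lib <- c(el1 = make_is_family(1200L, gc_p = 0.383))
  g <- plant_copies(host, lib[["el1"]], 25000L)
  hits <- scan_homology(g, lib)
  expect_gte(nrow(hits), 1L)
  top <- hits[which.max(hits$raw_score), ]
  expect_lt(top$e_value, 1e-50)
  expect_lte(abs(top$start - 25000L), 5L)
  expect_gte(top$end - top$start, 1150L)

  # shuffled library against a random genome: nothing survives 1e-5
  set.seed(56)
  shuf <- paste(sample(strsplit(lib[["el1"]], "")[[1]]), collapse = "")
  expect_equal(nrow(scan_homology(host, c(shuf = shuf))), 0L)
})

test_that("Karlin-Altschul bits and E-values follow the stated formula", {
  ka <- karlin_altschul(100, m = 1e6, n = 1e4)
  expect_equal(ka$bits, (1.33 * 100 - log(0.621)) / log(2))
  expect_equal(ka$e_value, 1e6 * 1e4 * 2^(-ka$bits))
  # E strictly decreases as the raw score grows
  es <- vapply(1:60, function(s) karlin_altschul(s, 1e6, 1e4)$e_value,
               numeric(1))
  expect_true(all(diff(es) < 0))
})

test_that("fragment merging follows the gap rule and is idempotent", {
  hit <- function(start, end, lib_start, lib_end, fam = "el1")
    data.frame(replicon_id = "chr", start = start, end = end, strand = "+",
               library_seq_id = fam, raw_score = end - start,
               bits = 100, e_value = 1e-30,
               lib_start = lib_start, lib_end = lib_end,
               stringsAsFactors = FALSE)
  near <- rbind(hit(1000L, 1400L, 0L, 400L), hit(1900L, 2400L, 420L, 920L))
  m1 <- merge_fragments(near)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$n_fragments, 2L)
  expect_equal(c(m1$start, m1$end), c(1000L, 2400L))

  far <- rbind(hit(1000L, 1400L, 0L, 400L), hit(6500L, 7000L, 420L, 920L))
  expect_equal(nrow(merge_fragments(far)), 2L)

  # overlapping library coordinates mean two independent insertions
  twin <- rbind(hit(1000L, 2200L, 0L, 1200L), hit(2500L, 3700L, 0L, 1200L))
  expect_equal(nrow(merge_fragments(twin)), 2L)

  # idempotence: re-merging the merged fragments changes nothing
  refrag <- do.call(rbind, lapply(seq_len(nrow(m1)), function(i) {
    fr <- m1$fragments[[i]]
    fr$library_seq_id <- m1$family_id[i]
    fr
  }))
  m2 <- merge_fragments(refrag)
  expect_equal(nrow(m2), nrow(m1))
  expect_equal(m2$start, m1$start)
  expect_equal(m2$end, m1$end)
})

test_that("planted insertion sites are recovered as distinct sites", {
  run <- default_run()
  isr <- default_is_run()
  truth_is <- run$gen$truth[run$gen$truth$kind == "is_element", ]
  overlap_counts <- vapply(seq_len(nrow(truth_is)), function(i) {
    sum(isr$remnants$replicon_id == truth_is$replicon_id[i] &
          pmin(isr$remnants$end, truth_is$end[i]) -
            pmax(isr$remnants$start, truth_is$start[i]) >
            0.5 * (truth_is$end[i] - truth_is$start[i]))
  }, numeric(1))
  expect_gte(mean(overlap_counts >= 1), 0.9)      # distinct-site recall
  expect_true(all(overlap_counts <= 1))           # never double-counted
  # every remnant interval overlaps at least one homology hit
  for (i in seq_len(nrow(isr$remnants))) {
    expect_true(any(isr$hits$replicon_id == isr$remnants$replicon_id[i] &
                      isr$hits$start < isr$remnants$end[i] &
                      isr$hits$end > isr$remnants$start[i]))
  }
  # re-merging the output changes nothing
  refrag <- do.call(rbind, lapply(seq_len(nrow(isr$remnants)), function(i) {
    fr <- isr$remnants$fragments[[i]]
    fr$library_seq_id <- isr$remnants$family_id[i]
    fr
  }))
  m2 <- merge_fragments(refrag, isr$fams)
  expect_equal(nrow(m2), nrow(isr$remnants))
})

test_that("the transposase ORF census separates intact from fragmented", {
  host <- random_genome(30000L, seed = 57L)
  set.seed(58)
  el <- make_is_family(760L, gc_p = 0.383)      # ~240-codon transposase
  broken <- el
  substr(broken, 20L + 3L * 99L + 1L, 20L + 3L * 99L + 3L) <- "TAA"
  g <- plant_copies(host, el, 8000L)
  g <- plant_copies(g, broken, 20000L)
  rem <- data.frame(site_id = c("s1", "s2"), replicon_id = "chr",
                    start = c(8000L, 20000L), end = c(8760L, 20760L),
                    strand = "+", family_id = "el1",
                    n_fragments = 1L, stringsAsFactors = FALSE)
  cen <- census_transposase_orfs(g, rem,
                                 consensus_lengths = list(el1 = 760L))
  expect_gte(cen$n_long, 1L)
  expect_lte(cen$n_long, cen$n_orfs)
  st <- setNames(cen$per_remnant$status, cen$per_remnant$site_id)
  expect_equal(unname(st["s1"]), "intact_transposase")
  expect_equal(unname(st["s2"]), "fragmented")
})
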