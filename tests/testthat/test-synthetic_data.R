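test_that("planted pseudogene count follows the configured fraction", {
  cfg <- synth_config(n_genes = 100L, pseudogene_fraction = 0.312,
                      seed = 11L)
  refs <- random_proteome(120L, seed = 11L)
  gen <- generate_genome(cfg, refs)
  expect_equal(sum(gen$truth$kind == "pseudogene"), 31L)
  expect_equal(sum(gen$truth$kind == "is_element"), cfg$n_is_elements)
})

test_that("identical config and seed give byte-identical output", {
  cfg <- synth_config(seed = 3L)
  refs <- random_proteome(150L, seed = 3L)
  g1 <- generate_genome(cfg, refs)
  g2 <- generate_genome(cfg, refs)
  expect_identical(g1$genome$seqs, g2$genome$seqs)
  expect_identical(g1$truth$event_id, g2$truth$event_id)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_genome_fasta(g1$genome, f1); write_genome_fasta(g2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("emitted GC tracks the target on a 500 kb replicon", {
  cfg <- synth_config(n_replicons = 1L, replicon_lengths = 500000L,
                      n_genes = 150L, seed = 8L)
  refs <- random_proteome(180L, seed = 8L)
  gen <- generate_genome(cfg, refs)
  expect_lt(abs(gc_content(gen$genome) / 100 - 0.383), 0.01)
})

test_that("plant_pseudogene produces the advertised lesion per class", {
  prot <- random_proteome(1L, len_range = c(99L, 99L), seed = 5L)[[1]]
  gene <- make_gene(prot)        # 300 bp including the stop codon
  expect_equal(nchar(gene), 300L)

  set.seed(21)
  ps <- plant_pseudogene(gene, "internal_stop")
  aa <- translate_dna(ps$dna)
  internal <- substr(aa, 2, nchar(aa) - 1)
  expect_gte(lengths(regmatches(internal, gregexpr("*", internal,
                                                   fixed = TRUE))), 2L)

  tr <- plant_pseudogene(gene, "truncated", kept_fraction = 0.25)
  expect_equal(nchar(tr$dna), 75L)

  set.seed(22)
  sp <- plant_pseudogene(gene, "split")
  expect_gte(sp$detail$insert_len, 150L)
  expect_equal(nchar(sp$dna),
               sp$detail$frag1_len + sp$detail$insert_len +
                 sp$detail$frag2_len)

  expect_error(plant_pseudogene(strrep("ATG", 20), "internal_stop"),
               "too short")
})

test_that("compensating frameshift indels restore the downstream frame", {
  prot <- random_proteome(1L, len_range = c(120L, 120L), seed = 6L)[[1]]
  gene <- make_gene(prot, seed = 6L)
  # find a plant whose two indel sizes cancel (e.g. -1 then +1)
  found <- FALSE
  for (s in 1:60) {
    set.seed(s)
    fs <- plant_pseudogene(gene, "frameshift")
    if (sum(fs$detail$indel_sizes) == 0 &&
        all(abs(fs$detail$indel_sizes) == 1L)) { found <- TRUE; break }
  }
  expect_true(found)
  expect_equal(nchar(fs$dna), nchar(gene))  # net length change zero
  # reading frame downstream of the second indel is restored
  tail_orig <- substr(gene, nchar(gene) - 59L, nchar(gene))
  tail_mut <- substr(fs$dna, nchar(fs$dna) - 59L, nchar(fs$dna))
  expect_identical(translate_dna(tail_orig), translate_dna(tail_mut))
  # every planted indel has a length not divisible by 3
  expect_true(all(fs$detail$indel_sizes %% 3L != 0L))
})

test_that("IS elements carry terminal inverted repeats and a long ORF", {
  set.seed(9)
  cons <- make_is_family(900L, tir_length = 20L, gc_p = 0.383)
  expect_equal(nchar(cons), 900L)
  expect_identical(substr(cons, 1, 20), revcomp(substr(cons, 881, 900)))

  intact <- plant_is_element(cons, 20L, fragmented = FALSE)
  expect_length(intact$pieces, 1L)
  orf_aa <- erosionscan:::.orf_lengths(intact$pieces, min_codons = 50L)
  expect_gte(max(orf_aa), 200L)   # intact transposase >= 200 codons

  set.seed(10)
  frag <- plant_is_element(cons, 20L, fragmented = TRUE)
  expect_true(frag$detail$mode %in% c("internal_stop", "two_pieces"))
  if (frag$detail$mode == "two_pieces") {
    expect_length(frag$pieces, 2L)
    expect_identical(paste0(frag$pieces[1], frag$pieces[2]), cons)
  }
  expect_error(make_is_family(900L, tir_length = 500L), "tir_length")
})

test_that("every truth record re-verifies against the emitted genome", {
  run <- default_run()
  gen <- run$gen
  for (i in seq_len(nrow(gen$truth))) {
    tr <- gen$truth[i, ]
    d <- tr$detail[[1]]
    seqi <- extract_region(gen$genome, tr$replicon_id, tr$start, tr$end,
                           tr$strand)
    if (tr$kind == "pseudogene" && tr$class == "internal_stop") {
      aa <- strsplit(translate_dna(seqi), "")[[1]]
      expect_true(all(aa[d$stop_codon_positions] == "*"),
                  label = tr$event_id)
    } else if (tr$kind == "pseudogene" && tr$class == "truncated") {
      expect_lte(d$kept_fraction, 0.29 + 1e-9)
      expect_equal(nchar(seqi) %% 3L, 0L)
    } else if (tr$kind == "pseudogene" && tr$class == "split") {
      ins <- substr(seqi, d$insert_start + 1L,
                    d$insert_start + d$insert_len)
      aa <- translate_dna(ins)
      expect_identical(substr(aa, 1, 1), "M")
      expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    } else if (tr$kind == "is_element" && d$fragment_count == 1L) {
      tirlen <- run$cfg$tir_length
      expect_identical(
        substr(seqi, 1, tirlen),
        revcomp(substr(seqi, nchar(seqi) - tirlen + 1L, nchar(seqi))),
        label = tr$event_id)
    } else if (tr$kind == "is_element" && d$fragment_count == 2L) {
      expect_equal(nchar(seqi), d$cut_at + d$gap +
                     (nchar(gen$is_families[[d$family]]) - d$cut_at))
    } else if (tr$kind == "intact_gene" &&
               !is.na(tr$source_protein_id) &&
               startsWith(tr$event_id, "gene_")) {
      aa <- translate_dna(seqi)
      expect_identical(substr(aa, 1, nchar(aa) - 1L),
                       run$refs[[tr$source_protein_id]],
                       label = tr$event_id)
    }
  }
})

test_that("oversubscribed replicons raise a capacity error", {
  cfg <- synth_config(n_replicons = 1L, replicon_lengths = 5000L,
                      n_genes = 60L, n_is_elements = 0L,
                      n_is_families = 1L, seed = 1L)
  refs <- random_proteome(80L, seed = 1L)
  expect_error(generate_genome(cfg, refs), "too short")
  expect_error(generate_genome(synth_config(seed = 1L),
                               random_proteome(10L, seed = 1L)),
               "smaller than n_genes")
})
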