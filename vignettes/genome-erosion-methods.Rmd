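---
title: "Measuring genome erosion: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genome erosion: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erosionscan)
```

# The scientific setting

Obligate endosymbionts — here the model is a cyanobacterium living inside
the leaf cavities of a water fern — experience relaxed purifying selection:
deleterious mutations in genes the host environment renders superfluous are
not purged, pseudogenes accumulate, and mobile elements proliferate and
then decay. `erosionscan` measures that erosion from a genome sequence and
its gene annotation: which coding regions are dead, where insertion
sequences (ISs) have landed and fallen apart, how erosion differs between
replicons, and whether it is concentrated in particular functional
categories.

# Pseudogene calling

## The rules

A candidate coding region is called a pseudogene when any of three rules
fires:

* **Interruptions.** The combined count of premature stop codons and
  frameshifts is at least `interruption_threshold` (default 2, i.e. "more
  than one"). The threshold is a config knob: one interruption can be a
  sequencing or annotation artifact, so a single hit is tolerated by
  default.
* **Truncation.** The best reference protein is covered over less than
  `truncation_fraction` (default 0.30) of its full length.
* **Split.** Two annotated features hit essentially non-overlapping
  segments (reference overlap < 20% of the shorter) of the same reference
  protein, in order consistent with their strand, within `split_max_gap`
  (default 5000 bp), with at least one intervening annotated ORF of a
  different product.

The class label reports the dominant evidence: more stops than frameshifts
gives `internal_stop`, otherwise `frameshift`; a bare coverage failure
gives `truncated`; the split rule gives `split`. A region with no homolog
at all is left intact and flagged `no_evidence` — absence of evidence is
not evidence of erosion.

## The alignment engine

Evidence comes from local protein alignment of the candidate region —
extended by `flank_nt` = 90 nt on each side so truncation is measured
against evidence rather than annotation edges — against a reference
protein set, in each of the three forward frames of the annotated strand
(reverse-strand evidence for a stranded feature is out of scope). The
local aligner is `Biostrings::pairwiseAlignment` with BLOSUM62,
gap open −11, gap extend −1. Three refinements make it frameshift-aware:

* **Stops do not terminate blocks.** `*` scores −4 against everything
  (the BLOSUM62 stop row), is counted, and the block continues — a
  premature stop is evidence, not a boundary.
* **X-drop segmentation.** Smith–Waterman happily bridges two strong
  stretches across a low-scoring middle (exactly what a frameshifted
  segment looks like in the wrong frame). Each alignment is therefore
  split at score valleys: scanning the per-column scores, a block is cut
  wherever the running score falls more than 35 points below its maximum,
  and sub-blocks below `min_block_score` (35) are dropped. This
  reproduces BLAST's separate-HSP behaviour.
* **Collinear chaining.** The maximum-total-score chain of blocks
  increasing in both region and reference coordinates is selected by
  dynamic programming, charging `frameshift_penalty` (−15) per frame
  change. Blocks around an indel overlap a little (local alignments
  overrun the breakpoint, sometimes by a weakly positive-scoring margin),
  so an overlap of up to 135 nt / 45 aa is allowed — but never more than
  75% of either block's span, so a marginal spurious block fully contained
  in a real one cannot join the chain and inflate the interruption count.
  Chain frame changes are the frameshift count; block stop counts sum;
  covered reference length (union) over full reference length is the
  aligned fraction.

Reference selection is the highest chain score, ties broken by longer
reference then lexicographic id, for determinism. Translation uses the
bacterial code (table 11, TGA is a stop); codons containing N translate to
X and never count as stops. A k-mer prefilter (shared amino-acid 5-mers)
shortlists references before alignment; a near-complete clean hit stops
the search early.

## What the numbers mean

`n_stops + n_frameshifts >= 2` fires the interruption rule;
`aligned_fraction < 0.30` fires the truncation rule. The truncation
fraction is measured on the reference protein's coordinates (covered aa ÷
full-length aa), not on the candidate's nucleotides, because the rule is
about how much of the full-length product could still be made. Whether the
original annotation protocols measured against a profile length or a
best-hit length is not knowable from the outside; best-hit length is used
here and is the honest choice given that profiles are out of scope.

# The synthetic genome generator

The generator exists so every downstream stage can be tested against known
truth. Its defaults are the study conditions: three replicons (chromosome
120 kb + plasmids 40 kb and 20 kb — a desk-scale rendering of a
chromosome-plus-two-plasmids architecture), G+C target 0.383, 120 genes of
which `floor(0.312 * n)` are pseudogenized, IS elements 700–3000 bp with
20-bp terminal inverted repeats, and pseudogene odds skewed across COG
categories (defaults L ×4, Q ×2, J ×0.4, M ×0.5 — replication/repair
enriched, translation and envelope biogenesis depleted, the qualitative
pattern expected in an eroding endosymbiont).

Genes are back-translated from sampled reference proteins. Codon choice is
weighted by per-base GC pressure `p^g (1-p)^(3-g)`; `p` is solved once per
genome (by `uniroot`) so that the expected coding GC equals the target
given the sampled amino-acid composition — the genetic code, not a real
codon-usage table, is the only constraint, because GC content is the only
compositional property the downstream statistics touch. Intergenic
spacers, gap fills and free ORFs are sampled directly at the target GC.

Planted lesions per class:

* `internal_stop`: two internal sense codons replaced by stops (positions
  recorded).
* `frameshift`: two indels of size ±1/±2 at recorded positions — always
  at least two, so planted frameshift genes unambiguously trigger the
  ≥ 2-interruption rule; single-interruption genes are reserved for
  boundary tests.
* `split`: a random ORF of ≥ 150 bp (ATG + sense codons + stop) inserted
  at the midpoint codon boundary; the annotation carries the two fragments
  and the intervening ORF as three CDS features.
* `truncated`: only a prefix kept; the kept fraction defaults to
  U(0.15, 0.29) and the boundary tests plant 0.29 / 0.31 pairs around the
  0.30 threshold.

IS families are TIR + transposase ORF + reverse-complement TIR; fragmented
copies either carry an internal stop or are emitted as two pieces with a
recorded gap below the detector's merge window. Every planted event has
one truth record whose defining property is re-verified from the emitted
sequence in the test suite.

What the generator does **not** emulate: phylogenetic divergence between
genes and their references (genes are exact back-translations, so the
aligner sees near-perfect homology), real codon usage, rearrangements,
assembly artifacts, or annotation errors. Passing the recovery tests
therefore demonstrates that the calling rules and evidence bookkeeping are
implemented correctly, not that sensitivity would be 95% on diverged real
genomes, where homology detection itself becomes the limiting factor.

# IS-remnant detection

Repeat discovery seeds on canonical 16-mers (a k-mer and its reverse
complement count as one) occurring at least `min_copies` = 3 times, and
extends a majority consensus outwards while at least 3 copies stay within
80% identity over a rolling 25-column window; consensus shorter than
`min_repeat_len` = 600 bp is discarded, claimed regions are not re-seeded,
and seed matches that supported less than half the consensus (such as the
far arm of a terminal inverted repeat matching its own element) are not
counted as copies. The rolling window matters: cumulative identity would
let thousands of matching columns amortize the mismatches at element
boundaries and extend the consensus far into the flanks.

Library homology uses 11-mer seeding, windows realigned with a local
+1/−2 alignment (gap open −5, extend −2), bit scores
S = (λ·raw − ln K)/ln 2 with fixed λ = 1.33, K = 0.621, and
E = m·n·2^(−S) with m the genome and n the library length. The constants
are documented approximations: E-values are comparable within a run, not
across tools. Hits at E ≥ 1e-5 are discarded.

Fragments of one family on one replicon and strand merge into one
insertion site when the genomic gap is at most `merge_max_gap` = 3000 bp
(the IS length ceiling) *and* their library coordinates are compatible —
ascending along the genome (hits store library coordinates in hit
orientation, so this works on both strands) and non-overlapping within a
20-bp slack. The library-coordinate condition is what keeps two intact
copies that happen to sit close together from being merged into one site,
and it makes the merge idempotent. Hits that already carry a library
assignment keep it; de-novo family ids only label unassigned repeat
copies — re-assigning library hits by overlap could split one fragmented
element across two repeat families.

The ORF census counts ORFs (ATG to in-frame stop, ≥ 50 codons, six
frames) overlapping each site; sites with an ORF spanning ≥ 80% of the
family consensus are `intact_transposase`, the rest `fragmented`. ORFs
longer than `transposase_min_aa` = 200 are tallied separately, since a
transposase shorter than that is most likely dead. Both the distinct-site
count and the raw fragment count are reported, since a site census and a
fragment census answer different questions.

# Erosion statistics

GC excludes N from the denominator. The coding fraction covers the union
of intact CDS intervals only — pseudogenes are, by definition, not coding.
The per-replicon erosion ratio divides pseudogenes by predicted genes,
where predicted genes = intact CDS + RNA genes; the variant that includes
pseudogenes in the denominator is computed alongside
(`erosion_ratio_incl_pseudo`) because published per-replicon ratios do not
always state which convention they use. The genome-wide pseudogene
percentage uses all genes (intact CDS + pseudogenes + RNA genes) as the
denominator, the convention under which an inventory of 1689 pseudogenes,
3668 intact CDS and 56 RNA genes yields 31.2%.

# COG enrichment

The contingency table is categories × {intact, pseudogene}; genes without
a category are excluded and counted separately; genes with multiple
category letters would take the first listed (the generator emits one).
The statistic is the plain Pearson sum Σ(obs − exp)²/exp with df =
categories − 1.

The null for the simulated p-value permutes the intact/pseudogene labels
across genes while keeping each category's gene count fixed — conditioning
on both margins, the conventional choice for a simulated-p chi-squared
test. The estimator is add-one, p = (b + 1)/(B + 1): it is never zero, and
at the default B = 2000 its floor is 1/2001 = 0.0004998 — the value an
analysis reports when the observed table is more extreme than every
replicate. Whether one conditions on both margins or only on category
sizes does not change that floor. Per-cell Pearson residuals
(obs − exp)/√exp are reported for the pseudogene column; their squares sum
to the statistic (a machine-precision identity asserted in the tests), and
positive values mean pseudogene overrepresentation.

# Gene-set comparison

Each entry's reference protein is aligned with the same chain machinery
against every annotated coding region (k-mer shortlisting first). Presence
requires a chain score of at least `min_presence_score` = 50 on the bit
scale (gapped BLOSUM62 Karlin–Altschul constants λ = 0.267, K = 0.041;
50 bits ≈ raw 118) — raw-score floors let marginal spurious matches
through. The status is copied from the matched feature's call, with one
biological override: an intact copy anywhere trumps pseudogene copies
elsewhere (a plasmid pseudogene whose chromosomal counterpart is intact is
not a lost function). The override only considers matches scoring at least
half the best match, so a weak spurious intact hit cannot mask a genuine
pseudogenization. Entries with no qualifying match are absent. BRH pairing
is plain best-reciprocal local alignment with ties broken by id order and
flagged ambiguous.

# Numerical and engineering choices

* Internal coordinates are 0-based half-open everywhere; 1-based inclusive
  only at the GFF3 boundary. Ambiguity codes collapse to N on read; minus
  strand features are reverse-complemented on extraction, never stored
  reversed.
* Translation is a precomputed 64-codon lookup (table 11) — the generic
  fuzzy-codon translator rebuilds its code map per call and dominated the
  caller's runtime by an order of magnitude.
* All randomness flows from explicit integer seeds (`synth_config(seed)`,
  `simulated_pvalue(seed)`, pipeline `seed`); identical configuration and
  seed reproduce every output byte for byte.
* Problem sizes in the tests — 120-gene genomes on 180 kb, 9 IS
  insertions, B = 2000 replicates (10⁵ for the convergence check) — are
  chosen so the whole suite runs in about two minutes while each planted
  event class still occurs several times per run.
* The pipeline interface is the exported functions plus `run_pipeline()`
  over a config object or YAML file; stage functions are usable
  independently and everything `run_pipeline` writes can be regenerated
  from them.

# Known limitations

* Pseudogene calling needs a homolog: eroded genes with no relative in the
  reference set are invisible (`no_evidence`), and truncation is relative
  to the best hit, not a profile.
* The frameshift count is evidence-based, not mutation-based: compensating
  indels close together can merge into the surrounding blocks, and an
  indel whose shifted segment happens to resemble the reference weakly can
  be absorbed; the interruption total, not the exact class split, is the
  robust quantity.
* Karlin–Altschul constants are fixed approximations; E-values should not
  be compared against other tools' outputs.
* De-novo repeat discovery assumes near-identical copies (≥ 80% identity
  window); anciently diverged element families are found only via the
  library route.
* The generator's homology is exact, so recovery rates on synthetic data
  are upper bounds for real, diverged genomes.
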