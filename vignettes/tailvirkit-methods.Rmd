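---
title: "Methods: depth-stratified viral community analysis in tailvirkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-stratified viral community analysis in tailvirkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

tailvirkit implements the analysis chain used to characterise viral
communities in depth-stratified sulfidic mine tailings: curation of viral
scaffolds predicted by two upstream detectors, species-level vOTU
clustering, library-size-normalized abundance, in-silico virus–host
linking, indicator-COG inference between surface and deep layers, and the
permutation statistics relating viral communities to prokaryotic
communities and geochemistry. This vignette records the models, the
tunable parameters, and the design decisions behind each stage. Every
number quoted here is recomputed by the test suite or by
`scripts/acceptance.R`; the vignette states no result those runs do not
produce.

## Study design the package assumes

Two cores are sectioned into depth layers (six in core A, five in core B;
eleven libraries total). Layers near the surface are strongly oxidized
and extremely acidic (pH ≈ 2); deep layers are unaltered and near-neutral
(pH ≈ 7). Metagenomic reads from each layer are assembled, genes are
predicted and annotated externally, and two viral predictors are run
upstream: a protein-family screen applied to scaffolds ≥ 5 kb and a
category-based detector (VirSorter-style categories 1–6, with prophage
coordinates for categories 4–5) applied to scaffolds ≥ 3 kb. The package
consumes these call tables together with the assembly FASTA, the gene
table, per-library mapped-nucleotide counts, host genome bins, and the
sample geochemistry table. Read QC, assembly, gene calling, homology
search, binning, and the detectors themselves are out of scope by design:
their outputs are this package's inputs.

## Curation of viral scaffolds

A gene is *virus-specific* when its free-text functional annotation
matches a hallmark keyword (capsid, phage, terminase, baseplate / base
plate, prohead, virion, holing, virus, viral, tape measure / tapemeasure,
neck, tail, p22, head, T4, prophage); *integrase* genes count as hallmark
genes alongside these. Matching is case-insensitive and whole-token:
text is lower-cased and split on non-alphanumerics, single-token keywords
must equal a token, and two-word keywords must appear as adjacent tokens.
A bare substring rule would let "head" fire inside "heady" and "T4"
inside "T4SS"; since the original procedure was manual curation, an
explicit conservative rule stands in for human judgement. The
vocabulary is configurable; "holin" is included as a synonym of the
listed "holing", which is almost certainly a typo for the phage lysis
protein — keeping both is faithful and useful.

A gene is *unknown* when it carries no functional assignment: empty COG
id and function text empty or equal to a configured synonym of
"hypothetical protein". Genes shorter than 1 kb are flagged *short* (a
reported property of indicator-COG carriers; the flag gates nothing).

Detector calls are merged per scaffold. Category 4/5 prophage
predictions are trimmed so the region runs from the start of the first
hallmark gene inside the prediction to the end of the last one; a
prediction with no hallmark gene (or no genes) is rejected. Trimming
never enlarges a region and is idempotent. A protein-family
whole-scaffold call is dropped whenever any prophage call exists on the
same scaffold, so an integrated virus is represented by its trimmed
region rather than its host's scaffold. A scaffold called whole by both
detectors yields one candidate recorded as `both`. Categories 3 and 6
are discarded with a log message (only 1, 2, 4, 5 participate in the
published procedure). When both detectors call the same scaffold whole,
the whole scaffold is used without trimming, since only prophage
categories are trimmed.

A candidate is finally **accepted** when it contains at least one
hallmark gene, or when unknown genes account for ≥ 80 % of its genes
(the hallmark clause wins ties in the recorded reason). The 80 % rule is
evaluated over the genes of the trimmed region for prophages — whether
the original procedure counted the whole scaffold is not stated, and the
trimmed region is the entity that enters the catalogue. Candidates with
zero genes are rejected: the unknown fraction is undefined there.

## vOTU clustering and the aligner

Curated sequences are clustered into species-level vOTUs at ≥ 95 %
average nucleotide identity (ANI) over ≥ 85 % of the shorter sequence
(alignment fraction, AF). The algorithm is greedy longest-first centroid
clustering (UCLUST-style): sequences are sorted by length (ties broken
by id), each unassigned sequence seeds a vOTU, and every remaining
unassigned sequence meeting both thresholds against the seed joins it.
The published work names the thresholds but not the algorithm;
longest-first centroid clustering is common vOTU practice, makes
membership conditions checkable against the representative, and renders
the partition invariant to input order.

ANI/AF come from the package's own seeded aligner: exact 15-mer anchors
(unique in both sequences, N-free) grouped by diagonal; each anchored
diagonal is scanned gaplessly with an x-drop rule (match +1, mismatch −2,
drop 20); segments are merged non-overlapping, highest score first, with
overlapping parts of lower-scoring segments trimmed and slivers below
the anchor size discarded. ANI is identities over aligned columns across
the merged segments; AF divides the aligned length by the shorter
sequence's length. Both orientations are tried and the better one kept,
because assembly strand is arbitrary. Ns never count as matches —
conservative identity. Pairs sharing fewer than five distinct 15-mers in
either orientation are skipped as unrelated (a 95 %-ANI pair of ≥ 3 kb
shares hundreds). Sequences shorter than the anchor size fall back to
full Needleman–Wunsch, which is trivial at that size. The aligner is
gapless by design: under the package's substitution-divergence model of
relatedness, homologous regions lie on exact diagonals, and
indel-containing pairs split into collinear segments whose merged
statistics remain accurate to within the tested tolerance (±0.01 of a
full dynamic-programming oracle on random ≤ 5 kb pairs).

## Abundance

Normalized coverage of an entity (scaffold, trimmed prophage region,
gene, or vOTU) in a library is the average per-base coverage
(mapped nucleotides / entity length) divided by the library's read count
and multiplied by the mean read count over all libraries present in the
input — the scaling constant is recomputed per run. vOTU-level coverage
pools members before normalization: summed mapped nucleotides over
summed member lengths (coverage-weighted pooling; the source procedure
does not specify a pooling rule). Relative abundance of a group of
catalogue entries in a layer is the group's summed normalized coverage
over the community total; it is 0 for an absent group and undefined
(reported `NA`) in a library with zero viral signal. Richness counts
vOTUs with normalized coverage above a presence threshold whose default
is 0 — any mapped signal counts — because no detection cutoff is stated;
the threshold is configurable, and richness can equally be computed at
scaffold level by passing unaggregated coverage.

## Virus–host linking

Three independent evidence types are emitted, one row each; the package
deliberately does not reconcile conflicting evidence because each type
has its own error profile.

* **CRISPR protospacers.** Arrays are detected as maximal runs of ≥ 3
  identical direct repeats of 23–47 nt separated by spacers of 20–50 nt,
  seeded on exact 23-mers with compatible spacing and extended in both
  directions while all occurrences stay identical; overlapping
  candidates resolve by most repeats, then longest span. Exact repeats
  only: stricter than fuzzy repeat finders, but it removes a heuristic
  dependency while preserving the downstream contract — a spacer links a
  virus only when it occurs as an exact, full-length substring on either
  strand (zero mismatches; windows containing N never match). An
  explicit E-value clause would be redundant: an exact ≥ 20 nt match is
  already far beyond chance. Arrays on unbinned scaffolds yield links
  flagged `unbinned` rather than being dropped.
* **Prophage containment.** Each accepted prophage whose parent scaffold
  belongs to a bin links to that bin. A scaffold in two bins is a
  binning-integrity error.
* **Shared genomic content.** The same seeded aligner compares each
  curated (non-prophage) virus to every binned scaffold; a link requires
  merged aligned length ≥ 2.5 kb, identity ≥ 70 %, and raw score ≥ 50
  (match +1 / mismatch −2). The raw score stands in for a bit score:
  reproducing Karlin–Altschul calibration is out of scope, and once the
  length and identity clauses hold, any hit's E-value is astronomically
  small, so length and identity are the binding constraints.

## Indicator COGs and AMGs

Per-COG normalized coverage sums gene-level normalized coverage over all
curated viral genes annotated with the COG; COG-less genes are pooled in
an `unassigned` row so column totals are conserved, and that pool is
never tested. Surface and deep groups are an explicit input, not
inferred from depth: the published grouping is shown only graphically.
The synthetic default takes the top **two** layers of each core as
surface (4 vs 7 libraries). With a single top layer per core the exact
two-sided rank-sum p can never fall below 2/55 ≈ 0.036, which no
realistic Benjamini–Hochberg family survives at q < 0.05 — a grouping
under which the design cannot in principle detect anything is not a
usable default; two layers per core is the smallest surface group with
non-degenerate power (minimum exact p = 2/330 ≈ 0.006) and matches the
visual extent of the published surface cluster.

The two-sample comparison is the two-sided rank-sum test with mid-ranks
for ties. The p-value is exact — complete enumeration of all
`choose(n1 + n2, n1)` assignments of the pooled ranks — whenever that
count is ≤ 2 × 10^5, which covers every split of an 11-library design;
larger problems use the normal approximation with tie correction and
continuity correction. Benjamini–Hochberg adjustment runs across all
testable COGs in one family; COGs that are zero everywhere are
untestable and are skipped before the family is formed (whether the
original 2002-COG family included single-sample COGs is not stated).
Indicators are COGs with q below alpha (default 0.05), with direction
given by the larger group mean. The published mention of 99 % confidence
intervals is ambiguous and not implemented as an additional filter.

The AMG report lists every curated scaffold carrying ≥ 1 gene annotated
COG0175 (PAPS/sulfonucleotide reductase, the assimilatory sulfate
reduction step), with the gene ids, whether a hallmark gene occurs on
both sides of the AMG, per-layer normalized coverage of the scaffold and
the gene(s), and the surface/deep rank-sum p of the carrier. AMG
phylogenetics is out of scope; the sequences are exposed for external
tree building.

## Community statistics

Bray–Curtis dissimilarity, PCoA by classical scaling (double-centred
−d²/2; negative eigenvalues are reported but excluded from the
proportion-explained denominator, an explicit absolute-value-free
convention), PCA of z-scored geochemistry (n − 1 denominator), ANOSIM
(rank-based R), one-factor PERMANOVA (distance-based partition: SS_total
= Σd²/n; R² = 1 − SS_within/SS_total; pseudo-F with g − 1 and n − g
degrees of freedom), Mantel (Pearson r over the n(n−1)/2 pairs, joint
row/column permutation of the second matrix), and Pearson correlation
with the t-transform p. All permutation tests take `permutations`
(default 999) and a seed, use the add-one convention
p = (1 + #{perm ≥ obs}) / (1 + permutations) — so p is never 0 and
matches the convention of the standard vegan implementations — and
accept a user-supplied permutation matrix, in which case p is the exact
proportion over the supplied rows; the tests exploit this to verify
agreement with complete enumeration at small n. These statistics are
implemented in-package because the contracts require exhaustive-
enumeration agreement and seeded reproducibility; the vegan
implementations serve as independent cross-checks in the test suite, and
the statistics agree with them exactly on shared inputs. The
average-linkage heatmap ordering of indicator COGs (log10, row z-scores,
Euclidean distance) is a plotting convenience and non-inferential.

## The synthetic community generator

`simulate_bundle()` emits every input the pipeline reads, plus a ground
truth for scoring. What it plants, and why those defaults:

* **Design**: 2 cores, 6 + 5 layers; depth-monotone pH from ≈ 2.2 at the
  surface to ≈ 7.0 at depth; EC declining and TOC, TP, Fe²⁺/TFe rising
  with depth; SO₄/TS falling — the qualitative gradients of oxidising
  tailings. Library read counts are uniform on 0.8–1.2 million:
  realistic relative spread for the scaled-down problem.
* **vOTUs**: free-virus clusters at 98 % within- and 80 % between-cluster
  pairwise identity, straddling the 95 % threshold with wide margins on
  both sides, full-length overlap so AF ≈ 1. The per-branch substitution
  rate is solved from identity(r) = (1−r)² + r²/3, the exact expectation
  for two i.i.d.-mutated copies of one ancestor. Mutations are i.i.d.
  per site, uniform over the three alternative bases, no indels by
  default — this keeps identity and AF analytically controllable.
* **Annotations** are written directly as function-text tokens ("phage
  capsid protein", "hypothetical protein", ...) so the keyword classifier
  is exercised without any homology search. Two of six free-virus
  clusters take the ≥ 80 %-unknown acceptance route; the rest carry
  hallmark genes. Decoy scaffolds with predominantly annotated metabolic
  genes receive false detector calls and must be rejected.
* **Prophages** sit inside host scaffolds with hallmark genes at both
  region edges, so boundary trimming must recover the planted region
  exactly; the emitted detector region is padded by one flanking host
  gene on each side so trimming has work to do. One prophage-bearing
  scaffold also receives a protein-family whole-scaffold call to
  exercise the dedup rule.
* **Abundance**: coverage is log-normal around planted layer effects and
  converted to mapped nucleotides as coverage × length (rounded), the
  inputs of the normalization formula. Free-virus clusters switch on at
  evenly spaced activation depths (richness rises strictly with depth);
  prophage summed relative abundance targets an affine function of pH
  with slope −0.09 per pH unit (≈ 0.50 at pH 2 down to ≈ 0.05 at pH 7) —
  no effect size is published for this relation, so the default is
  chosen, once, to make sign recovery robust at n = 11 and is documented
  as arbitrary; a slope of 0 yields a null. AMG carriers (> 10 kb,
  hallmark-flanked COG0175) and the two surface-associated indicator
  carriers use an 8-fold step between the surface and deep groups,
  comfortably above the 4-fold property the tests assert under
  log-normal noise of sd 0.3. Null COGs ride only on always-present,
  trend-free viruses, so any indicator call on them is a genuine false
  positive.
* **Hosts**: 8 bins (3 archaeal — Euryarchaeota/Thermoplasmatota —
   dominating the surface; 5 bacterial phyla dominating depth). CRISPR
  arrays are appended to host scaffolds: 4 identical 30-nt repeats
  alternating with 32-nt spacers; planted links copy a protospacer
  verbatim or reverse-complemented from **singleton** viruses (so vOTU
  siblings cannot carry coincidental copies), and decoy spacers differ
  from their viral source by one central substitution — recoverable by
  nothing short of exact matching. One AMG carrier shares a ~3 kb block
  at ~95 % identity with a binned scaffold for the shared-content rule.
* **Prokaryotes**: 40 OTUs; archaeal fraction ≈ 0.68 at the surface
  falling to ≈ 0.06 at depth; bacterial OTUs activate with depth so
  prokaryotic richness rises in parallel with viral richness.
* **RNG**: one root seed; every sub-generator derives a child stream
  from a label hash, so adding a feature never perturbs existing draws,
  and identical seeds reproduce bundles byte-for-byte.

What the generator does **not** emulate: real genome content and gene
order, homology-search noise in annotations, assembly fragmentation and
chimerism, strain microdiversity within clusters beyond i.i.d.
substitutions, indels (available as an option but off by default),
degenerate or fuzzy CRISPR repeats, and compositional correlations among
geochemical variables. Passing tests therefore demonstrate that the
rules and statistics are implemented correctly and recover planted
structure under the stated noise model — not that the pipeline is robust
to every artefact of real metagenomes.

## Numerical choices and degenerate inputs

Internal coordinates are 0-based half-open everywhere; on-disk gene
tables are 1-based inclusive (GFF convention) with the dialect recorded
in a header comment, and the conversion is an involution. Zero-length
entities are errors in normalization; zero-total libraries make relative
abundance `NA`; an input bundle with no detector calls produces an empty
catalogue and headered empty outputs rather than an error. Permutation
p-values are compared with a 10⁻¹² slack when counting `perm ≥ obs` to
avoid floating-point ties. Eigenvalues below machine-epsilon scale are
treated as zero in PCoA. Clustering ties (equal lengths) break
lexicographically; representative choice is therefore deterministic.

## Problem sizes used by the tests

The default bundle holds ~30 scaffolds (~0.4 Mb of sequence), ~300
genes, and 11 libraries; the test suite runs one full pipeline pass,
20 replicate bundles for the indicator/false-positive and
prophage-slope properties, 100 aligner-versus-dynamic-programming pairs,
and exhaustive permutation enumerations at n ≤ 6 — sizes chosen so the
distributional claims are testable exactly while a complete run stays
comfortably interactive.

## Known limitations

The aligner is gapless between anchors; heavily indel-divergent pairs
near the 95 % threshold would be split conservatively (lower AF), which
errs toward over-splitting vOTUs. CRISPR detection requires exact
repeats and will miss degenerate arrays a fuzzy finder would report.
The indicator analysis assumes a two-group design; gradients are better
served by the correlation machinery. Multi-evidence host links are
reported, not adjudicated. The published supplementary statistics can be
recomputed with `supplement_stats()` only after exporting the
article's supplementary spreadsheets as TSV; the package does not
redistribute them.
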