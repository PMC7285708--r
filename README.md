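# tailvirkit

Viral community analysis for depth-stratified, sulfidic mine-tailings
metagenomes.

Mine tailings dumps oxidise from the top down: surface layers are
extremely acidic (pH ≈ 2), metal- and sulfate-rich, while deep layers
remain unaltered and near-neutral. Viruses in such cores track both
their prokaryotic hosts and the geochemical gradient, but extracting
that signal from bulk metagenomes takes a long chain of curation and
statistics. tailvirkit implements that chain as a tested, reusable R
pipeline for anyone analysing viral communities in stratified extreme
environments:

1. **Curation** — merge the calls of two upstream viral predictors (a
   protein-family screen on scaffolds ≥ 5 kb and a category-based
   detector on scaffolds ≥ 3 kb), flag hallmark genes by a whole-token
   keyword vocabulary (capsid, terminase, tail, ..., integrase), trim
   prophage predictions to hallmark-gene boundaries, deduplicate, and
   accept candidates that carry hallmark genes or are ≥ 80 %
   functionally unknown.
2. **vOTU clustering** — greedy longest-first clustering at ≥ 95 %
   average nucleotide identity over ≥ 85 % of the shorter sequence
   (`ani ≥ 0.95`, `af ≥ 0.85`), with an in-package seeded k-mer/x-drop
   aligner validated against full dynamic programming.
3. **Abundance** — normalized coverage
   `(mapped_nt / length) / library_reads × mean(library_reads)`,
   relative abundance as a share of the viral community total, and vOTU
   richness per layer.
4. **Host prediction** — CRISPR protospacers (exact, zero-mismatch,
   either strand; arrays found by an exact direct-repeat detector),
   prophage containment in binned scaffolds, and shared genomic content
   (≥ 2.5 kb, ≥ 70 % identity, score ≥ 50).
5. **Functional profiles** — per-COG normalized coverage, indicator COGs
   between surface and deep layer groups (exact rank-sum test,
   Benjamini–Hochberg, q < 0.05), and a report of viral scaffolds
   carrying the assimilatory-sulfate-reduction gene COG0175 (PAPS
   reductase), the auxiliary metabolic gene of interest in sulfidic
   systems.
6. **Community statistics** — Bray–Curtis / standardized-Euclidean
   distances, PCoA/PCA, ANOSIM, PERMANOVA, Mantel (999 permutations,
   add-one p-values, seeded), and Pearson correlations of richness and
   prophage abundance with geochemistry.

A seeded synthetic mine-tailings community generator
(`simulate_bundle()`) plants all of this structure — pH gradient,
richness gradients, archaea-dominated surface, prophage/pH slope,
deep-enriched AMG carriers, CRISPR links with decoys — with a machine-
readable ground truth, so every stage is scored end-to-end.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on the fitted statistics, and `plot_*()` /
`autoplot()` helpers for ordinations, depth profiles, the prophage–pH
regression, and indicator-COG heatmaps.

## Worked example

```r
library(tailvirkit)

demo <- demo_run(seed = 0)   # simulate a community, run the whole pipeline
demo
```

```
tailvirkit demo (seed 0)
curated catalogue: 20 viral sequences (recall 1.00, 0 false positives)
vOTUs: 16 (ARI vs planted partition: 1.000)
host links: 4 spacer (recall 1.00, 0 decoy), 5 prophage, 1 shared-content
prophage relative abundance vs pH: Pearson r = -0.998 (p = 3.03e-12)
vOTU richness vs depth: Spearman rho = A 1.00, B 1.00
viral vs prokaryotic richness: Pearson r = 0.992
indicator COGs: 3 called; planted recall 1.00; 0 null false positives
AMG (COG0175) scaffolds: 3 found; deep/surface coverage ratio 6.9
depth groups: ANOSIM R = 1.000, PERMANOVA R2 = 0.787
Mantel: viral~prokaryotic r = 0.652; viral~geochemistry r = 0.783
```

Reading the report: all 20 planted viral sequences (free phages, three
COG0175 carriers, two surface-associated viruses, five prophages) pass
curation with no decoy accepted; clustering reproduces the planted
species partition exactly (adjusted Rand index 1.0); all four planted
CRISPR links are recovered with none of the one-mismatch decoys; the
summed relative abundance of prophages falls steeply with pH (more
lysogeny under acid stress); viral richness rises with depth in both
cores in step with prokaryotic richness; the three planted indicator
COGs (COG0175 deep; an archaeal integrase and a portal-protein COG at
the surface) are recovered at q < 0.05 with the correct direction; and
the viral community separates cleanly between surface and deep layers.

Individual stages compose with the pipe:

```r
bundle <- simulate_bundle(sim_config(seed = 1))
cat    <- identify_viruses(bundle$scaffolds, bundle$genes, bundle$calls)
votus  <- cat |> dplyr::filter(accepted) |>
  dplyr::select(id = viral_id, seq) |> cluster_votus()
res    <- run_tailings_pipeline(bundle, pipeline_config(rng_seed = 1))
tidy(res)                       # one row per fitted statistic
glance(res)                     # catalogue / vOTU / link counts
plot_prophage_ph(res$prophage_ra, bundle$samples)
```

A thin command-line wrapper lives at `inst/scripts/tailvirkit.R`
(`simulate`, `run-all`, `demo` subcommands).

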