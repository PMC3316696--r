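---
title: "Assessing a COI barcode reference library"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing a COI barcode reference library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coibarcode)
```

## The problem

A DNA barcode reference library is a set of short standardized
mitochondrial sequences — for animals the ~650-bp 5' fragment of
cytochrome oxidase subunit I (COI) — each tied to a vouchered, identified
specimen. Before such a library can be used to identify unknowns or to
flag undescribed diversity, three questions must be answered:

1. **Are the sequences trustworthy?** Nuclear copies of mitochondrial
   genes (NUMTs), contamination and poor reads masquerade as barcodes.
2. **Does the marker resolve the taxonomy?** Do species, genera and
   families come out as coherent, well-supported clusters, and how does
   that degrade when fewer taxa are sampled or shorter fragments are
   used?
3. **How much undescribed diversity does the library suggest?** Deeply
   divergent lineages that cannot be assigned to any named species are
   candidate species.

`coibarcode` implements a complete assessment pipeline for these
questions, together with a simulator that generates taxonomically
structured COI-like libraries with known ground truth, so every stage of
the pipeline is testable end to end without any sequence download.

## The pipeline

`barcode_pipeline()` is the central entry point. Its stages, in order:

**Quality control.** A record passes if it (i) carries at least 600
non-gap bases — 90% of the standard 664-column barcode region, the usual
yardstick for a high-quality read; (ii) contains no internal stop codon
in the reading frame chosen by `detect_frame()` (the offset minimizing
total in-frame stops; ties break low); and (iii) is not a divergence
outlier, i.e. its minimum K2p distance to every other record does not
exceed a cutoff (default 0.35). Stops are screened under the vertebrate
mitochondrial code (stops TAA, TAG, AGA, AGG) since COI is mitochondrial;
the standard nuclear code is available for NUMT screening. Codons
containing gaps or ambiguities cannot be called stops and are skipped,
and the terminal codon is exempt — "internal" means before the last
complete codon. There is no community consensus on a numeric value for
"suspicious" divergence, so the outlier cutoff is an explicit, documented
parameter rather than a hidden constant.

**Distances.** Pairwise p (raw mismatch proportion) and Kimura
2-parameter distances,

$$ d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q), $$

with $P$ and $Q$ the transition and transversion proportions over
*comparable* sites — pairwise deletion, meaning a column is dropped for a
pair only when either member has a gap or ambiguity there. Pairwise
deletion preserves information when read lengths vary (real libraries
span 604–664 bp); complete deletion would discard columns globally. When
a logarithm argument is non-positive the K2p distance is undefined
(substitution saturation); such entries are flagged `NA`, excluded from
averages and rejected by the tree builder with an explicit error rather
than silently patched, because saturation should be visible, not hidden.
`saturation_table()` gives the classic transition/transversion-versus-
divergence plot data for eyeballing saturation.

**Trees and support.** `neighbor_joining()` is a deterministic
Saitou–Nei implementation with the Studier–Keppler Q criterion. Ties in Q
break to the smallest pair of positions in the current label order and
the joined node takes the first member's position, so results are
identical across platforms; negative branch lengths are clamped to zero
without redistributing the difference (display-safe, topology
unchanged). `bootstrap_support()` performs the standard Felsenstein
column bootstrap: resample alignment columns with replacement, rebuild
distances and the NJ tree, and score each internal edge of the reference
tree by the percentage of replicates containing the same bipartition.
Replicates with undefined distances are dropped and counted; more than
10% dropped aborts the analysis. Trees are unrooted throughout; newick
I/O (supports as internal node labels) goes through **ape**.

**Monophyly scoring.** On an unrooted tree, a group is monophyletic when
its leaf set is one side of some bipartition — the convexity criterion,
equivalent to rooted monophyly for any root outside the group and
invariant to rerooting (the analysis never needs to choose an outgroup).
`score_all_groups()` applies this to every genus or family; groups with a
single member are excluded rather than trivially counted, and
non-monophyletic groups report support `NA` rather than 0 — no edge
corresponds to them, so they have no support to report.

**Species delimitation.** Following standard distance-threshold
barcoding practice, the pipeline (i) finds well-supported sister species:
two-leaf cherries of nominal, confamilial, heterospecific records with
edge support above 70; (ii) averages their distances per family to get
family-specific thresholds (K2p and p separately); (iii) groups
candidate/unidentified records of each family into lineages by
single-linkage below the threshold (conservative merging prevents
counting one candidate twice); and (iv) flags a lineage when its minimum
distance to any nominal record — "closest relative", operationalized as a
matrix minimum, not a tree-path distance — exceeds the family threshold.
Running the rule under the K2p and p thresholds separately yields a
candidate range: the minimum counts lineages flagged under both models,
the maximum under at least one. Families that yield no qualifying sister
pair get no threshold; their unidentified records are reported as
unresolved instead of borrowing a global threshold, because divergence
scales differ strongly between families.

**Experiments.** `run_subsampling()` draws random subsets of 75/50/25/10%
of the *species* (all conspecific records of a chosen species travel
together; counts round half-away-from-zero with a floor of three
species), rebuilds tree and supports per subset, and scores every genus
and family. `run_fragment_series()` does the same for 450/300/200/100-bp
prefixes of the barcode region (truncation is by alignment column — the
barcode region is a fixed coordinate system). `species_uniqueness()`
checks whether a prefix still separates every species pair.
Exclusion is post hoc: a genus reduced to one member in a subset is
excluded from that replicate's scores, not prevented from occurring.

## The simulator

`simulate_coi_dataset()` generates libraries that emulate a multi-family
reptile-like assemblage:

* **Taxonomy and trees.** Per family, a pure-birth species tree rescaled
  so the mean interspecific path equals `2 * species_depth`; genera are
  carved out as monophyletic clades of the ultrametric tree, so genus
  sizes vary naturally around their nominal value. Families join a star
  backbone with stems of at least `min_family_stem` so each family is a
  genuinely old lineage. Conspecific samples, when requested, attach as
  shallow radiations at `intraspecific_depth`.
* **Sequences.** A stop-free root sequence drawn uniformly over sense
  codons evolves down the tree under a two-parameter (kappa) process —
  the same model family the K2p distance inverts, which makes
  estimator-consistency checks exact in expectation. Any codon that
  mutates into an in-frame stop is reverted to its parent state, so
  generated data pass the stop screen by construction (`stop_free =
  FALSE` gives the pure process for estimator checks). Optional
  gamma-distributed site rates are available for robustness checks but
  off by default.
* **Planted lineages.** Extra records with `status = "unidentified"`
  hang off a nominal anchor at a chosen multiple of the family's expected
  sister-species divergence. A multiplier of 2 is a true candidate
  species; 0.5 is a decoy that a correct pipeline must not flag. Because
  the new record extends the anchor's tip, its nearest-nominal distance
  equals the target in expectation.

Default parameters (8 families × 3 genera × 4 species × 1 sample,
664 columns, kappa 4, depths 0.175/0.10/0.005 substitutions per site)
give within-family mean interspecific divergences near 20% K2p and
family thresholds near 7–14% — the ranges reported for real squamate
COI libraries. `min_species_separation` (default 0.08) enforces that any
two nominal species are at least ~8% apart, emulating a curated
reference set of well-delimited species; without it, pure-birth trees
produce sister species almost indistinguishable at barcode length, which
no "good species" reference set would contain.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: indels and alignment error, NUMTs (beyond what
the QC screens are tested on synthetically), introgression and
incomplete lineage sorting (which make real genera non-monophyletic),
codon-position rate structure beyond the optional gamma rates, and
geographically structured intraspecific variation.

## Numerical choices and edge cases

* Distances are computed in full precision and only rounded (percent,
  one decimal) in user-facing summary tables.
* The `>70` (sister-pair) and `>90` (well-supported) bootstrap cutoffs
  are exclusive, matching their conventional reading; both are
  parameters.
* NJ tie-breaks and the bootstrap's single seeded RNG stream (replicate
  *r* of condition *k* uses substream `seed + 10000k + r`) make every
  experiment bit-reproducible; the test suite asserts byte-identical
  reruns.
* Degenerate inputs fail loudly: fewer than 3 taxa for NJ, undefined
  distances in NJ input, empty alignments, unknown genetic codes,
  fragment lengths beyond the alignment.
* An all-gap record after truncation is dropped from that condition and
  reported, not silently scored.

## Problem sizes used in the checks

The packaged tests and the acceptance script run the full pipeline on
simulated libraries of ~100–125 records with 100 bootstrap replicates,
100 random additive matrices for NJ consistency, 200 replicate pairs per
divergence level for estimator consistency, 8–20 replicate libraries for
planted-candidate recovery, and 5–10 subsets per sampling fraction.
These sizes give Monte-Carlo error comfortably below the assertion
margins while keeping a complete run on a single core in minutes; the
semantics at the paper-scale settings (1000 bootstrap replicates, 100
subsets per fraction) are identical and exposed through the same
configuration objects.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_coi_dataset(sim_config(seed = 11))
fit <- barcode_pipeline(sim$alignment, bootstrap_reps = 100, seed = 11)
fit
summary(fit)
plot(fit)
```

The printed object reports QC counts, genus/family monophyly, the number
of well-supported sister pairs and the candidate-species range;
`summary()` returns the per-family table (reference species, mean
divergence, pairs, thresholds, candidates). With the default simulation
both planted candidate lineages are recovered and both decoys are
rejected, so the range is exactly the number of planted deep lineages.

## Known limitations

* Thresholds derived from very few sister pairs (one pair is common in
  small families) are noisy; the per-family `n_pairs` column should
  temper interpretation, as it must for real libraries.
* The candidate range only reflects model disagreement (K2p vs p); it
  does not propagate bootstrap or threshold uncertainty.
* Single-linkage lineage grouping can chain intermediate haplotypes into
  one lineage; that is the conservative direction for counting.
* NJ is the method assessed here by design; likelihood or Bayesian trees
  are out of scope.
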