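---
title: "TIP-chip analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TIP-chip analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the signal model assumed of transposon-insertion-profiling (TIP-chip)
tiling-array data, the statistical procedures applied to it, the parameters
that matter, and the design decisions taken where the method description
left genuine freedom. Nothing here asserts an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The signal model

A TIP-chip experiment amplifies, by vectorette PCR from a primer inside an
active transposable-element family (L1Hs, AluYa5/8, AluYb8/9), the genomic
sequence between each insertion and the nearest restriction site of the
digest, in four parallel single-enzyme reactions that are pooled, labelled,
and hybridized to a genomic tiling array. The computational consequences,
which are all the pipeline relies on, are:

* an insertion present in a sample elevates the log2 intensity ratio of the
  *consecutive* probes lying under its pooled amplicons (the "amplicon
  footprint"), a few kilobases wide;
* the footprint lies on one side of the insertion point, determined by
  which element strand the family primer reads out of;
* probes elsewhere fluctuate around zero;
* probes overlapping annotated repeats are unreliable and are masked out.

The pipeline makes no assumption about the *shape* of the intensity
distribution beyond signal exceeding background, but the synthetic
generator must commit to one (below).

## Peak calling

`call_peaks()` implements a descending-threshold sliding-window caller.
With parameters (`peak_params()`):

| parameter | default | units | role |
|---|---|---|---|
| `p_start`, `p_step`, `n_steps` | 90, 1, 76 | percentile | threshold grid: T(p) = p-th percentile of the track's unmasked intensities, p = 90, 89, …, 14 |
| `window_bp` | 1500 | bp | maximum start-to-start gap between consecutive supporting probes |
| `min_probes_above` | 4 | probes | probes that must exceed T(p) |
| `floor_value` | 2 | log2 ratio | absolute floor every run probe must exceed |
| `max_peaks` | 5000 | peaks | truncation of the ranked list |

A candidate at level p is a maximal run of unmasked probes, each above
`floor_value`, consecutive probes within `window_bp`, with at least
`min_probes_above` probes above T(p). Each genomic peak is reported once
with the highest p at which it is detected; lower-level detections that
overlap an existing call merge into it. Output ordering is deterministic:
rank threshold, then maximum intensity, then genomic position.

Two interpretation decisions, documented rather than asserted as fact:

* The caller's original setting string "min probes > 4, all probes > 2" is
  read as *≥ 4 probes above the sliding percentile threshold* and *every
  probe in the run above an absolute log2-ratio floor of 2*. Both numbers
  are exposed as parameters.
* Window semantics: `window_bp` constrains the gap between consecutive
  supporting probes. This reproduces sliding-window behaviour without an
  explicit (undocumented) step size, and is what the brute-force oracle in
  the test suite enumerates level by level.
* Percentile thresholds are computed per array track, not per chromosome:
  thresholds describe the array-wide intensity distribution.

Because a run's membership depends only on the floor and the window — not
on T(p) — the implementation computes each run's rank in closed form (the
first grid threshold beaten by the run's `min_probes_above`-th largest
intensity). The test suite verifies exact agreement with an independent
enumerator that loops over all 77 levels and merges explicitly, on 200+
randomized small tracks (acceptance criterion 1).

## Cutoff calibration

Insertions fixed in the reference genome assembly are known positives:
ranking peaks and counting cumulative distinct reference matches (within a
1 kb margin, same family group) gives a recovery curve that rises while the
list traverses signal and flattens when it reaches noise.
`find_inflection()` locates the knee as the index of **maximum elevation
above the chord** joining the curve's first and last points; ties break to
the smallest index, and perfectly linear or constant curves (or curves
entirely below their chord) raise a degenerate-curve error. The *signed*
elevation is deliberate: recovery curves are concave, and the signed form
uniquely identifies the first point of a plateau (e.g. the step curve
0,0,0,10,10,10 gives index 4, where the absolute distance would tie indices
3 and 4). A discrete second-difference method is available behind
`method = "second_diff"`.

`calibrate_peaks()` accepts a knee only when the curve genuinely flattens:
post-knee reference recovery below half the pre-knee rate **and** a
post-knee reference drought too long to arise by chance if reference hits
were randomly interleaved among true peaks (hypergeometric tail, 0.01).
Otherwise it falls back to the fixed family cutoffs (retain peaks with
rank threshold strictly above 70 for L1, 60 for Alu). The second condition
matters on clean tracks: a ranked list that is essentially all signal ends
with a short run of true-but-nonreference peaks, which the raw chord knee
would cut off. On such tracks the honest answer is "no usable inflection",
and the fixed percentile cutoffs — which are themselves the published
approximation to the inflection — apply.

## Locus building and classification

Per-line peaks become panel-level loci by margin-expanded transitive
overlap within a family group (AluYa/AluYb collapse to Alu; the margin
defaults to 1 kb and is shared with database matching, whose stated
working range is 1–2 kb). The merge rule is the package's own: the original
description reports panel loci without defining the merge. Classification
order is: reference database match → `reference`; known-polymorphic match
→ `known_polymorphic`; otherwise ≥ 2 carrier lines → `novel_polymorphic`;
else `singleton`. Database membership deliberately precedes carrier counts,
and a locus matching both reference and polymorphic records keeps the
`reference` category with a `ref_and_poly` flag so it can be counted in
both groups in panel summaries. Singleton fractions are reported among
non-reference loci. `deletion_flag()` lists reference loci absent from at
most `max_absent` lines (default 1) — the parsimonious reading of a
missing fixed insertion is a genomic deletion in that line.

Gene context (`exon_overlap_report()`) is assigned from the locus
*midpoint* (3'UTR exon → coding exon → intron → flank), with a partial-
overlap flag when the locus interval straddles an exon boundary; array
resolution does not support base-pair breakpoints, so midpoint containment
is the honest granularity.

## Enrichment

`hypergeom_pvalue(k, K, n, N)` is the exact upper tail P(X ≥ k) for
drawing n insertion-bearing genes from a universe of N of which K belong
to the set. The ≥ (not >) convention is the standard over-representation
reading; genes count once however many insertions they carry; and every
gene set is intersected with the array universe first — enrichment is
relative to what the array could have seen. No correction across sets is
applied by default (set-level raw p-values are reported); a Bonferroni
flag exists. Known limitation: the test does not condition on gene length,
and longer genes attract more insertions under a uniform landing model; a
permutation mode was considered and left out of scope, with the bias
documented here instead.

## Association

COMPARE-style pattern matching of a binary seed against continuous
profiles specializes to the point-biserial correlation: Pearson r between
the 0/1 presence vector and the profile, p-value from
t = r·sqrt((n−2)/(1−r²)) on n−2 df, two-sided. Perfect separation is
clamped to the smallest positive double so p stays in (0, 1]. Decisions:

* **Bonferroni family** = the number of tests actually performed in the
  run (not tests per feature class); configurable by running classes
  separately.
* **Singletons are tested in cis only** (features anchored within 30 kb of
  the locus interval on the same chromosome); their trans associations are
  dominated by false positives. Unanchored features are always trans.
* **Minor-count guard**: non-singleton loci need ≥ 2 carrier lines
  (`min_minor_count`); the guard applies to the carrier side only, so a
  locus present in n−1 of n lines is still tested. (Applying it to the
  smaller of the two groups would contradict the intent of testing
  near-fixed loci, so the carrier-side reading was chosen.)
* Missing phenotype values are dropped pairwise; `n_lines_used` is
  recorded; not-estimable pairs are excluded with a reason code.

`manhattan_export()` places every association at its locus start
coordinate, so all features of one locus stack vertically at one x
position.

## The synthetic generator: what it emulates, and what it does not

`simulate_panel()` states a world in which every downstream property is
measurable against planted truth:

* **Panel structure**: `n_cell_lines` (default 20) lines sharing
  `n_reference` insertions present everywhere, known/novel polymorphic
  insertions with allele frequencies uniform on `allele_freq_range`
  (default 0.1–0.9; known conditioned on ≥ 1 carrier, novel on ≥ 2), and
  singletons in exactly one line. Defaults (35/20/20/25 per family, three
  families) give ~300 insertions, the scale of the end-to-end acceptance
  run.
* **Array**: `n_genes` (default 200) gene loci with ±10 kb flanks, tiled
  at `probe_spacing_bp` = 250 bp — the spacing implied by ~2.1 M probes
  covering ~17 % of a 3.1 Gb genome; 50-mer probes; a panel-wide 2 %
  repeat-mask fraction. Gene models carry exons and 3'UTRs for the
  gene-context report.
* **Restriction maps**: four enzymes, each a Poisson process with 2500 bp
  mean spacing. Sites are a point process, not sequence motifs: the
  pipeline consumes footprints, and motif realism would add nothing
  testable.
* **Footprints**: the digests are amplified separately and pooled, so the
  footprint spans from the insertion to the **farthest of the per-enzyme
  nearest sites** on the strand-dictated side (plus strand → rightward).
  The maximum of four Exp(2500) gaps has mean ≈ 5.2 kb and median
  ≈ 4.2 kb, consistent with the published ~5 kb example peak; a
  nearest-union-site model was rejected because pooling four digests would
  then *shrink* footprints to ~0.6 kb, contradicting that observation.
* **Placement**: uniform over the tiled space, rejecting candidates whose
  realized footprint (i) leaves its tiled region — an amplicon running off
  the probed array is not recoverable, and planting it would make
  parameter recovery fail for reasons unrelated to the code under test —
  or (ii) comes within `min_separation_bp` (default 5 kb, i.e. above twice
  the merge margin) of a same-group footprint, so planted events are
  resolvable as distinct loci by construction. Exhausting placement
  attempts raises a capacity error.
* **Intensities**: Gaussian on the log2 scale — footprint probes
  N(`signal_mean` = 8, `signal_sd` = 1), background N(0,
  `baseline_sd` = 0.3). No noise model was published; these parameters are
  config-exposed and all acceptance properties are stated relative to
  them.
* **Phenotypes**: standard-normal null features per line; planted features
  add `effect_size` (default 3 SD) times the carrier indicator; cis
  features are anchored within 30 kb of their locus, half the null
  features get random anchors, the rest are unanchored.

What it does **not** emulate: PCR chemistry and amplification bias,
realistic chromosome counts or cancer-type-specific insertion rates,
batch effects between arrays, probe-sequence effects, or insertions whose
amplicons fall off the array (excluded by construction, see above). A
green end-to-end test therefore establishes that the *computational*
pipeline recovers a signal with the stated structure — not that the assay
itself has any particular sensitivity on real cells.

Determinism: one master seed; each generator stage reseeds from a derived
child seed, so identical configurations are byte-identical and stages can
be re-run independently.

## Numerical choices and degenerate inputs

* Percentiles use R's default type-7 quantile; the oracle uses the same
  primitive, so equivalence checks test the algorithm, not quantile
  conventions.
* All coordinates are 0-based half-open; writers emit BED conventions.
* Strict inequalities: probes must *exceed* floor and threshold; fixed
  cutoffs keep ranks strictly above 70/60; database matching uses
  half-open `[start − margin, end + margin)`.
* Fewer unmasked probes than `min_probes_above` → empty result with a
  warning; empty peak list → empty recovery curve; degenerate curve →
  error caught by `calibrate_peaks`, which falls back to fixed cutoffs;
  constant phenotype or single-group presence → not-estimable, excluded
  with reason code.
* The planted-effect power criterion (3 SD effect, 10/20 carriers,
  Bonferroni family 1000) has theoretical power ≈ 0.87 (noncentral t,
  ncp ≈ 6.7 against the two-sided 5 × 10⁻⁵ critical value); seeded runs
  fluctuate around it, which is why the criterion is stated at ≥ 0.80
  over 100 replicates.

## Known limitations

* Breakpoints are not resolved below probe spacing, and insertion strand
  is not predicted from peak shape.
* The enrichment test ignores gene length (see above).
* The knee-acceptance heuristic assumes reference insertions are
  intensity-exchangeable with other true peaks; a family whose reference
  members systematically hybridize weaker would flatten the curve early.
* CLI configuration files are JSON rather than YAML (no YAML dependency in
  the supported stack).
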