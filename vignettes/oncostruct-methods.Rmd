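---
title: "Methods: structural context metrics for cancer missense mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural context metrics for cancer missense mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncostruct)
```

## The problem and the model

Somatic mutation catalogues from tumour sequencing are overwhelmingly
composed of passenger mutations, so variant-level interpretation is noisy.
`oncostruct` works at the gene level instead, asking two questions of the
collective set of missense mutations observed in a protein:

1. Are the observed mutations more **structurally damaging** than expected if
   mutations landed at random on the protein? Loss-of-function selection in
   tumour suppressors produces exactly this excess.
2. Do the mutated residues **cluster in three-dimensional space**?
   Gain-of-function selection concentrates mutations around functional sites,
   the hallmark of oncogenes.

Both questions are answered with deliberately simple, nonparametric
statistics so that proteins with very different sizes, stability scales and
structure quality remain comparable.

### Rank-normalised stability perturbation (ΔΔG_rank)

Predicted stability changes (ΔΔG, kcal/mol, from a predictor such as FoldX,
consumed here as input tables) have awkward distributional properties: the
bulk sits below ~3 kcal/mol, occasional outliers are enormous, and the scale
differs between proteins. We therefore rank-normalise within each protein.
For the complete landscape of possible substitutions we take absolute ΔΔG
(magnitude of perturbation corresponds to damage in either direction), rank
ascending with **average ranks for ties**, and map to

$$\Delta\Delta G_\mathrm{rank} = \frac{\mathrm{rank}(|\Delta\Delta G|) - 1}{n - 1}.$$

Average tie-ranks are what make the landscape mean *exactly* 0.5 regardless
of ties (the sum of average ranks is always $n(n+1)/2$); the normalisation
denominator $n-1$ pins the extremes to 0 and 1. Both properties are asserted
to 1e-12 in the test suite. Because ranks are invariant under any strictly
monotone transform of $|\Delta\Delta G|$, the metric is insensitive to
predictor miscalibration of scale — only the ordering of substitutions
matters.

The gene-level statistic is the **ΔΔG_rank difference**: mean ΔΔG_rank of the
observed mutation set minus the mean over the possible-but-unobserved
substitutions, with a two-sided Wilcoxon rank-sum p-value on the two sets of
rank values. The "possible" background is the set of entries in the
protein's stability table; when a coding sequence is available the background
can be restricted to substitutions reachable by a single nucleotide change
(`filter_snv_reachable()`), and without one a codon-agnostic union over the
residue's codons is used and flagged. Observed mutations lacking a ΔΔG entry
are dropped from stability analyses and counted, so coverage is always
visible.

### Extent of Disease Clustering (EDC)

For each residue of a subunit we find $D_{min}$, the Cα:Cα distance to the
nearest mutated residue *other than itself*, average $\log D_{min}$
separately over mutated and non-mutated residues, and report

$$\mathrm{EDC} = \bar{D}_{\text{non-mutated}} / \bar{D}_{\text{mutated}}.$$

The log tames the heavy right tail of nearest-neighbour distances; its base
cancels in the ratio (verified numerically), and natural log is used. Under
uniform placement both groups see the same distance field and EDC ≈ 1; a
spatial cluster shrinks $\bar{D}_{\text{mutated}}$ and pushes EDC above 1.
The averaging convention — mutated residues also use
nearest-*other*-mutated distance — follows the formula's "all other residues
with disease mutation"; a lone mutated residue would have undefined
$D_{min}$, which the ≥ 5-residue reporting threshold prevents.

Distances are computed within a single subunit. Residues without a Cα and,
for predicted models, residues with pLDDT below the confidence threshold are
excluded from both numerator and denominator (and counted); experimental
structures use all residues. Coincident Cα coordinates (zero distance) raise
an error rather than being clamped: they indicate broken input.

### Multiplicity and candidate ranking

Per-gene Wilcoxon p-values are Bonferroni-thresholded at $p \le \alpha/N$
with $N$ the number of genes actually tested in each structure source,
computed from the data at run time. (Published analyses of this kind print
thresholds that do not exactly equal $\alpha/N$ for their printed $N$; we
compute rather than hard-code.) Candidate tables are built by ranking
positive-difference genes on their most significant p across structure
sources, and separately ranking genes by recurrent EDC; ties break on larger
absolute difference and then gene name so rankings are deterministic.

## Thresholds and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| RSA interior bound | 0.30 (inclusive) | – | published location rule |
| RSA surface bound | 0.50 (inclusive) | – | published location rule |
| pLDDT exclusion | < 70 (70 retained) | 0–100 | "less than 70" is strict |
| recurrence filter | ≥ 7 (7 retained) | samples | "at least seven times" |
| EDC residue minimum | 5 | residues | reporting threshold |
| mapping identity | > 90 (strict) | % | mapping rule |
| mapping length | ≥ 50 | residues | mapping rule |
| α | 0.05 | – | conventional |
| SASA probe | 1.4 | Å | water probe radius |
| SASA points | 960 | per atom | <2% error vs 1920 (tested) |

Every boundary is exercised at its exact value in the test suite, and all
thresholds are echoed into the headers of every pipeline output table.

## Numerical and design choices

* **Wilcoxon implementation.** Small pooled samples (≤ 40 by default) use an
  exact conditional distribution of the rank sum computed by dynamic
  programming over doubled midranks — exact *with ties*, which classical
  no-tie tables cannot provide; larger samples use the tie-corrected normal
  approximation with continuity correction. Both paths are validated against
  exhaustive subset enumeration (all shapes with pooled n ≤ 12) and against
  `stats::wilcox.test` where that is exact.
* **Fisher's exact test** p-values come from the standard hypergeometric
  two-sided rule; the reported effect size is the sample (cross-product)
  odds ratio, with zero cells giving 0/∞ unless the Haldane 0.5 correction
  is requested.
* **Location classes.** The printed interval rule (interior ≤ 0.3 < interface
  < 0.5 ≤ surface) conflicts with the conventional burial-on-assembly
  definition of an interface; both are provided (`interface_mode =
  "delta_rsa"` calls interface where isolated-chain RSA exceeds assembly
  RSA), the printed rule is the default, and the discrepancy is documented
  rather than resolved.
* **Reference max-ASA** defaults to the Tien et al. (2013) theoretical scale
  (Miller and empirical Tien scales are selectable); the scale used is
  recorded in output metadata. Coarse-grained Cα-only models normalise
  against the full sphere of a 3 Å per-residue pseudo-atom instead.
* **Chain mapping** uses global alignment with free end gaps and identity
  counted over aligned (non-gap) columns; ambiguous residue-to-chain choices
  resolve by best resolution, then largest assembly, then lexicographic
  structure id (the last tie-break is unstated in the source methodology and
  chosen for determinism). Non-standard residues are excluded from models;
  multi-model files contribute their first model only.
* **Degenerate inputs** fail loudly: empty structures, zero margins,
  landscapes with < 2 variants, all-mutated proteins and coincident
  coordinates are errors, while below-threshold EDC/enrichment cases are
  explicit skips with reasons, not silent omissions.

## What the synthetic generators emulate

The generators produce the three ingredients the pipeline consumes, with
controlled statistical structure:

* **Chains**: straight lines and ideal helices (for geometry-sensitive
  tests) and compact self-avoiding random walks (3.8 Å Cα spacing, ≥ 3.5 Å
  non-consecutive separation, centroid-biased steps) as a stand-in for
  globular folds.
* **Stability landscapes**: log-normal |ΔΔG| (median 1 kcal/mol by default,
  so the bulk sits below ~3 kcal/mol with occasional large outliers,
  matching the skew of real predictor output), destabilising with
  probability 0.85; an optional heavy-tail mixture component.
* **Mutation cohorts** with truth labels: TSG-like genes draw 75% of
  observed variants from the top 30% of |ΔΔG| (f = 0.75, q = 0.7);
  oncogene-like genes draw 75% from a spatial cluster of the 5% of residues
  nearest a random centre, with hotspot-like recurrence (zero-truncated
  geometric, mean 12, vs mean 3 elsewhere, so the ≥ 7 filter retains a
  realistic minority); neutral genes draw uniformly. These effect sizes were
  fixed once, at values chosen to be strong but not trivial, before any
  recovery measurement.

Everything is seed-deterministic, and bundles written by `simulate_bundle()`
go through the same PDB/CSV/TSV readers as real data, so synthetic runs
exercise the genuine I/O paths.

**What passing tests do and do not show.** The synthetic chains are not real
folds (no secondary-structure packing, no domains), the landscapes have no
residue-level correlation (real destabilising positions cluster in the
core), mutation placement ignores trinucleotide mutational signatures, and
recurrence is independent of position except where implanted. Recovery of
implanted signals (AUC > 0.9 on a 200-gene cohort for both the damage and
clustering rankings, verified in the acceptance tests) therefore
demonstrates correctness of the machinery and sensitivity under idealised
conditions — not performance on real tumour data, where passenger noise,
structure coverage and mapping artefacts are all harsher.

## Problem sizes used in validation

The test suite validates the EDC null (1,000 uniform mutation sets of 10
residues on 200-residue compact chains, mean within ±0.05 of 1), clustered
behaviour (200 replicates, EDC > 1 in ≥ 95%), oracle equivalence (100 random
EDC instances to 1e-12; exhaustive Wilcoxon/Fisher enumeration at pooled
n ≤ 12), and parameter recovery on a 200-gene cohort of 200-residue
proteins with 50 observed variants per gene. These sizes keep the full suite
around a minute on one CPU while leaving the estimates' Monte Carlo error
well inside the asserted tolerances.

## Known limitations

* ΔΔG values are consumed, never predicted; the analysis inherits whatever
  biases the upstream predictor has.
* The secondary-structure fallback is a Cα-geometry heuristic, flagged
  approximate; it is no substitute for DSSP output when available.
* Gene-to-protein mapping assumes one canonical protein per gene; isoform
  resolution is the caller's responsibility.
* Recurrence thresholding is a blunt instrument against passenger noise; a
  background mutational model (e.g. signature-aware expected recurrence)
  would be a natural extension.
* EDC has no per-protein significance test here — values are compared
  across genes, not tested individually.
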