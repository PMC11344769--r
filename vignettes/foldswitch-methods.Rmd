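---
title: "Assessing dual-conformation predictions of fold-switching proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing dual-conformation predictions of fold-switching proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldswitch)
```

## The problem

Fold-switching proteins adopt two distinct experimentally determined
conformations from a single amino-acid sequence, typically differing in
secondary and/or tertiary structure over a contiguous *fold-switching
region*. Structure predictors of the AlphaFold family emit ensembles of
models with per-residue confidence (plDDT, 0–100). Judging whether such an
ensemble captures *both* conformations — and whether the predictor's
confidence metrics can tell good from spurious models — requires a
region-restricted, threshold-based bookkeeping that is easy to get subtly
wrong. This package implements that bookkeeping as a tested pipeline, with
a synthetic-data generator so every stage can be exercised without any
structure downloads or predictor runs.

## The assessment model

**Correspondence and superposition.** Predictions and experimental
references share a sequence, so residues are paired by author numbering
(`correspondence()`); no sequence-independent structural alignment is
attempted. This is the package's main deliberate divergence from workflows
built on TM-align: here the alignment is fixed by identity and only the
rigid superposition is optimized. Superposition uses the Kabsch algorithm
(`kabsch()`), the closed-form SVD solution of the least-squares rigid-fit
problem.

**TM-score.** For aligned residue deviations $d_i$ under a superposition,

$$\mathrm{TM} = \max_{\text{superpositions}} \frac{1}{L_{norm}}
\sum_{i} \frac{1}{1 + (d_i/d_0)^2}, \qquad
d_0(L) = 1.24\,(L-15)^{1/3} - 1.8,$$

with $d_0$ floored at 0.5 Å so short fold-switching regions remain
scorable. Superpositions are seeded from the full correspondence and from
contiguous fragments of length $n/2$ and $n/4$ (minimum 4, tiled across
the chain); each seed is refined by re-superposing on residues with
$d_i$ below an inclusion cutoff that starts at $d_0$ and grows by a factor
of 1.5 whenever fewer than 4 residues qualify, to a fixed point (50
iterations cap). Exact score ties keep the earliest seed, making the
result deterministic. $L_{norm}$ is the number of *reference* residues in
the assessed region — scores are normalized by the reference, and this
choice is recorded in every result (`normalized_by`).

**Classification.** With region TM-scores $(t_1, t_2)$ against the Fold1
and Fold2 references and threshold $\tau = 0.6$: a model is FOLD1 if
$t_1 > \tau \ge t_2$, FOLD2 if $t_2 > \tau \ge t_1$, the larger score wins
when both exceed $\tau$, and OTHER (experimentally unobserved) otherwise.
Equality with $\tau$ deliberately does *not* exceed it: the defining
phrases are "greater than 0.6" and "less than 0.6", leaving exact equality
open, and we resolve it conservatively toward OTHER. A both-above tie
$t_1 = t_2 > \tau$ goes to Fold1.

**Fold ordering.** Which experimental conformation is "Fold1" is decided
by a designated baseline run: the reference winning the region TM-score in
a majority of baseline models (3 of 5 for the standard five-model run)
becomes Fold1. For even splits the larger mean region TM wins, and the
fallback is flagged — there is no silent tie-breaking.

**Success and difficulty.** A conformation is predicted when at least one
model is assigned to it ($N_{ij} \ge 1$); a pair succeeds overall when both
are. Pairs are labelled Complex when amyloid/domain-swapped, when the
whole-structure backbone RMSD between the two folds exceeds 10 Å, *or*
when the inter-fold region TM falls below 0.5 — the source phrasing is
ambiguous between AND and OR; we read OR (either kind of large
conformational change suffices) because the amyloid route is added as a
separate "too", implying the geometric criteria are themselves
alternatives. The conjunction is configurable for sensitivity analysis.

**Confidence machinery.** A model's confidence fraction is the percentage
of residues with plDDT ≥ 70 (boundary inclusive); categories are Medium /
Good / High at ≥ 70 / 80 / 90 % (inclusive, highest met wins). Reranking
sorts by descending fraction with ties broken by descending mean plDDT and
then model id — the tie-breaks are not specified by the source analysis
and were chosen to make Top1/Top10 pools reproducible. The false-positive
rate is the fraction of confident models (mean plDDT ≥ 70) labelled OTHER,
reported as absent when no model is confident. The exact one-sided
binomial test (`binomial_onesided()`) is exposed generically rather than
hard-coding any particular enrichment comparison, whose null construction
is not fully specified in the source analysis.

## Alanine masking

`generate_masked_msas()` slides an 11-residue window in steps of 1 along
the fold-switching region. For each window, every residue with a heavy
atom within 4.0 Å of any window heavy atom — *except* residues within 4
positions of the window in primary sequence (boundary excluded, so
distance exactly 4 is still excluded) — has its alignment column converted
to alanine in every row but the target. Gaps and A3M lowercase insertions
are untouched; byte-identical masks from adjacent windows are collapsed,
keeping the earliest. Contacts are computed on the Fold1 reference by
default (configurable): the source procedure does not state which
structure defined contacts, and Fold1 is the conformation the predictor
already favors, which is the signal the masking aims to disrupt.

## Template preparation and composite scoring

`strip_to_template()` reduces a structure to \{N, CA, C, O, CB\},
constructs an ideal beta carbon for glycine (local-frame construction from
N, CA, C, normalized to the canonical 1.522 Å bond so it is exactly
rigid-motion covariant), and standardizes MSE→MET / SEC→CYS. The composite
quality score is $(plDDT/100)^a\, pTM^b\, TM^c$ with $a=b=c=1$ by default:
the source analysis names the three ingredients but not their combination,
so the product — the simplest monotone combination that is zero when any
ingredient is zero — is the documented assumption, configurable through
exponent weights and echoed into every report.

## Flexibility and structural probes

Normalized B-factors use $BF_{norm} = (BF - \mu_{BF})/\sigma_{BF}$ over a
chain with the *sample* (n−1) standard deviation (the convention is not
stated at the source; it is recorded in the output metadata). Residues at
$BF_{norm} \ge 2$ are flexible. Because "a region is flexible" admits both
a region-level reading (any flexible residue) and a residue-level one,
`region_flexibility()` reports both. Contact maps default to 8 Å between
CB atoms (CA for glycine) with a minimum intrachain sequence separation of
5 — unstated upstream, so fully configurable and stamped into outputs.
Constant-B-factor chains are a hard degenerate-input error rather than a
silent division by zero.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* **Backbones** are chained with ideal bond geometry and canonical
  dihedrals (helix −57/−47, strand −139/+135; coil drawn uniformly from
  the broad allowed region φ ∈ [−160, −50], ψ ∈ [−60, 170]).
* **Toy pairs** (default 60 residues, region 20–45) share a sequence and
  differ in secondary structure exactly and only across the region
  (helix ↔ strand); coil torsions are resampled until the inter-fold
  region TM is below 0.5, so every generated pair is a fold switch by the
  pipeline's own measure. References carry crystal-like B-factors
  (normal, mean 30 Å², sd 10).
* **Ensembles** draw each model from a mixture — perturbed copies of
  either reference, or a decoy built from a *shuffled* secondary-structure
  string (protein-like enough to exercise TM refinement, unlike random
  coordinates). Fold-class copies are perturbed to a backbone RMSD of
  0.5 Å, the deviation scale of near-native predictor output; larger noise
  would push region TM-scores toward the 0.6 boundary and conflate
  mixture recovery with threshold sensitivity. plDDT profiles are drawn
  per class (confident: mean 85, sd 8; unconfident: mean 55, sd 10) with a
  polarity switch: `"with"` gives correct classes the high confidence,
  `"against"` gives it to decoys, emulating confidence metrics that select
  against experimentally observed conformations.
* **Seeds** are explicit everywhere; a master seed fans out through a
  fixed integer counter scheme, so fixtures are reproducible and distinct
  seeds give distinct realizations.

What passing on these fixtures shows: the metric, classification,
reranking and reporting machinery is correct at its boundaries and
recovers planted mixtures at realistic noise. What it does not show:
anything about real predictor behavior — real ensembles have correlated,
structured errors, partially disordered regions, and numbering
discrepancies between prediction and experiment that the generator does
not emulate (regions must be specified per reference in the registry for
that reason).

## Problem sizes and numerical choices

Validation runs use 500-model ensembles across five replicate pairs
(2500 models), sizes at which binomial confidence intervals on recovered
mixture fractions are a few percentage points wide. Degenerate inputs are
errors, not warnings: fewer than 3 superposition points, constant
B-factors, empty correspondences, regions with no aligned residues.
Altloc resolution keeps the highest occupancy (ties: alphabetically first
identifier). plDDT stored on a 0–1 scale is detected by a chain maximum
≤ 1 and rescaled ×100, overridable where a genuinely all-zero-confidence
chain must be preserved.

## Known limitations

* Correspondences are author-numbering identity maps; point mutations are
  tolerated (mismatched pairs are dropped with a warning) but indels
  between prediction and reference are not aligned around.
* TM-scores are normalized by the reference only; swapping arguments
  changes the score when lengths differ.
* The package consumes predictor outputs (plDDT, pTM) and never runs a
  predictor; composite-score rankings are therefore only as good as the
  scores supplied.
* mmCIF support covers the `atom_site` loop (the part relevant to
  assessment), not assemblies, symmetry expansion, or multi-datablock
  files.
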