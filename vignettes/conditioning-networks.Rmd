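---
title: "Methods: responder stratification and signed miR-target networks"
author: "IPoCnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: responder stratification and signed miR-target networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IPoCnet)
```

This vignette documents the models, conventions and numerical choices
behind each pipeline stage, and what the synthetic-data generators do and
do not emulate.

## Responder stratification

Plasma troponin I after reperfusion is a right-skewed injury marker, so
all stratification happens on the log scale, where a responder /
non-responder mixture becomes a clean one-dimensional two-component
Gaussian problem. `splitResponders()` fits the mixture by EM with **free
component variances** and a **deterministic initialization** at the 25th
and 75th percentiles of log TnI (no random restarts: the same data always
give the same labels). Assignment is by posterior probability of the
lower-mean component, with ties at exactly 0.5 assigned to the responder
class — a fixed, documented tie-break rather than an arbitrary one.

Two guards protect against spurious splits in unimodal arms: if the EM
fails to converge within 500 iterations (log-likelihood tolerance
1e-10), or the fitted component means are closer than `min_separation`
(default 0.5) pooled component SDs, the fit is declared degenerate and the
method falls back to a threshold rule: responder iff log TnI lies below
the midpoint of the median log TnI of the IPC and I/R reference arms
(the geometric midpoint in ng/mL). No published numeric TnI cut exists
for this split; both methods here are declared conventions of this
package, and the degeneracy flag is always reported. Labels are invariant
under rescaling of all concentrations (assay calibration does not change
the split).

## Differential expression

The DE stage is a deliberately small two-group negative-binomial Wald
fit — the study design only needs pairwise contrasts against I/R and
Sham, so no multi-factor design matrices, outlier replacement or
independent filtering are implemented.

* **Normalization** (`medianOfRatios()`): reference = per-feature
  geometric mean over samples, restricted to features with no zero count;
  size factor = median ratio to the reference. If no all-nonzero feature
  exists the function stops with an explicit error rather than silently
  switching reference.
* **Dispersion** (`estimateDispersion()`): per-feature method-of-moments
  on normalized counts, `max(0, (s² − μ)/μ²)`, using the pooled
  *within-group* variance when group labels are supplied so planted group
  differences do not masquerade as overdispersion. Raw estimates are
  shrunk toward the mean dispersion of their log-mean quantile bin with
  weight 0.3 (default): at the study's sequencing depth and with five to
  twenty samples per group the raw MoM estimate is noisy, and a modest
  trend shrinkage stabilizes it without erasing genuine feature-specific
  overdispersion. Estimates are floored at 1e-8 (constant features have
  sample variance zero and would otherwise report a negative estimate).
* **Contrast** (`nbWaldContrast()`): the group mean parameter is the
  size-factor-weighted normalized mean `sum(k)/sum(s)`; with equal size
  factors this is the exact NB maximum-likelihood estimate, and its
  delta-method variance equals the Fisher-information variance (the test
  suite verifies both against an independent fixed-theta GLM fit). The
  Wald statistic is two-sided against a standard normal. A group whose
  count sum is exactly zero receives a pseudo-count of 0.5 reads (that
  group only), keeping the fold change finite; such features carry a
  `zero_group` flag instead of being silently altered.
* **Multiplicity**: Benjamini-Hochberg adjusted p-values are always
  emitted alongside raw p. The classical screen downstream uses raw
  p ≤ 0.05 (the significance convention of the emulated study); `padj` is
  provided as the principled default for users who want FDR control.
* **qPCR**: `ddctFoldChange()` implements plain double-delta-Ct
  (`fold = 2^(−ΔΔCt)`) with group-mean ΔCt. The original quantification
  protocol is cited but not reproduced in the source study; ΔΔCt is this
  package's declared stand-in.
* **Cascade** (`statsCascade()`): Shapiro-Wilk gates at the same alpha as
  the final test; the Levene step uses the classic mean-centred statistic
  (the convention of the SPSS lineage this cascade mirrors). Non-normal
  samples go to Mann-Whitney (Wilcoxon signed-rank when paired).
* **Post hoc** (`anovaSnk()`): Student-Newman-Keuls on ordered means with
  `qtukey` critical values; sub-ranges of a non-significant range are not
  tested (the defining protection of the stepwise procedure). Unequal n
  uses the Tukey-Kramer standard error. No installed package provides
  SNK, so the stepwise procedure is implemented here on top of
  `stats::aov`/`qtukey` and checked against a hand-computed oracle.

Alpha defaults to 0.05 throughout, the threshold convention of the
emulated study design.

## Regulation calls and the protective-pattern filter

`callRegulation()` uses `p <= alpha` (boundary values are significant)
and an optional magnitude gate `lfc_min` (default 0). A significant
feature with log2FC exactly 0 is `unchanged`: a direction-based rule
cannot use directionless significance.

`protectiveMirFilter()` encodes the selection rule: regulated by injury,
reversed in responders, reversed in IPC (default; `require_ipc = FALSE`
gives the looser reading in which only the responder reversal matters —
the source wording is ambiguous, so both modes exist and both are
tested), and **not** reversed in non-responders. "No protective change"
in non-responders deliberately includes *same-direction* significant
changes: a further enhancement of the injury response is non-protective,
and the emulated study observed exactly that in a minority of miRs. The
implementation is verified against an exhaustive 81-combination truth
table.

`classifyMrnaPattern()` partitions features by which conditioning arms
regulate them versus I/R into eight mutually exclusive, exhaustive
categories. The bundled panel fixture
(`inst/extdata/mrna_panel_significance.tsv`) transcribes the printed
significance markers of a 36-transcript qPCR panel; note its printed
block header for the responder-only group (n = 21) disagrees with both
the accompanying text (23) and the marker-level count (22) — the package
reports computed counts and makes no attempt to reconcile the source's
internal discrepancy.

## The signed network

Interaction filtering uses **strict** inequalities (score > 80.0,
mirSVR < −1.2) because those are the printed conventions of the
thresholds being mirrored; boundary records are dropped, and the test
suite pins both boundaries. Each (miR, target) pair contributes at most
one edge regardless of how many source databases report it — provenance
is kept as a union string — so database redundancy cannot inflate node
strength.

The weight convention is the genuinely open design point: "weights 1 or
−1 for edges to up- or down-regulated miR nodes" does not fix the
mapping. The default (`convention = "repression"`) sets weight =
−sign(miR direction): strength then predicts the target's expected
expression change under miR-mediated repression (up-miR ⇒ target down ⇒
−1), which matches the stated purpose of the score. The `"literal"`
convention inverts every weight; since both conventions are global sign
flips, rankings by |strength| are identical, and the choice is exposed as
a configuration switch for sensitivity analysis. Node strength itself is
the plain signed degree sum; ranking is by |strength| descending, then
strength descending, then target id — a total, deterministic order.

## Mitochondrial reconciliation

The identifier cascade follows the priority order Ensembl → RGD → NCBI
id → symbol → description, the order in which the identifier columns are
conventionally enumerated; no precedence is published, so the order is a
fixed package convention. Symbol matching is case-insensitive (symbols
vary in case across sources); description matching is exact (fuzzy
description matching invites false joins). A symbol matching two or more
annotation rows is *excluded and flagged* rather than resolved
arbitrarily — a silently mis-mapped target corrupts the subnetwork, an
excluded one only shrinks it. The mito filter keeps matched genes with a
GO-mitochondrial flag **or** IMPI score strictly above 0.7, after
restricting the annotation to the known/predicted mitochondrial classes.

## What the generators emulate — and what they do not

The defaults of `simConfig()` are the study conditions of the emulated
design: 4 arms x 20 rats, responder fraction 0.4 (8 responders / 12
non-responders, assigned exactly, not sampled), 627 expressed miRs, 286
differentially expressed with 82 up- and 77 down-regulated by injury,
responder-arm reversal of 23/82 up- and 20/77 down-regulated miRs, a
small non-responder "further enhanced" minority (4 up, 1 down), and
TnI mixture components centred at 8 vs 60 ng/mL (sdlog 0.35) — roughly
the 8-fold separation that makes the observed bimodality visible. IPC
reversal fractions are not printed as counts anywhere; the defaults
(up 0.5, down 0.85) encode the qualitative statement that nearly all
down-regulated miRs were affected by some conditioning, chosen once as a
realistic setting and not tuned. Library-size factors span 4-fold
(log-uniform 0.5-2), NB dispersion defaults to 0.1, planted |log2FC|
magnitudes are uniform on 1-3. Identifier aliasing is a deterministic
cycle of column blanking and case mutation over a seeded 20% of
annotation rows.

Everything derives from one global seed through counter-based
per-generator substreams, so adding a generator never changes another
generator's output and every table is byte-reproducible.

The generators do **not** emulate: read-level sequencing artefacts (the
pipeline starts at the count matrix), correlated miR co-regulation,
batch effects, echocardiography time series (only summary fields), real
database structure (interaction tables are uniform draws over a
vocabulary), or animal dropout. Passing tests therefore demonstrate that
the machinery recovers planted structure under clean NB sampling — not
that it is robust to the full messiness of a wet-lab dataset.

## Problem sizes and runtime choices

The test suite runs the full generator at its default size (627 x 80)
only where the defaults are the point; recovery and property tests use
scaled-down instances (60-300 features, 10-20 samples per group, random
bipartite graphs up to 50 x 50, 100 stratification seeds, 2000-feature
null calibration), sizes chosen so the whole suite completes in well
under a minute while keeping every estimate's sampling error far from
the asserted bounds.

## Known limitations

* The NB Wald fit has no Cook's-distance outlier handling; single
  aberrant samples can drive a contrast.
* The MoM dispersion estimator is biased upward for very low means; the
  trend shrinkage mitigates but does not remove this.
* The mixture stratifier assumes exactly two components; a genuinely
  trimodal response pattern would be folded into two classes (the
  degeneracy guard does not detect over- rather than under-separation).
* Description-level identifier matching is exact-string; legitimate
  matches with trivially reformatted descriptions are missed (and
  reported as unmatched rather than guessed).
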