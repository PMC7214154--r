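# IPoCnet

Responder stratification and signed miR–target network analysis for
ischaemic conditioning studies in R.

## The problem

Ischaemic post-conditioning (IPoC) — brief cycles of reperfusion and
re-occlusion at the end of an index ischaemia — protects some hearts and
not others. In a four-arm rat design (Sham, ischaemia/reperfusion I/R,
pre-conditioning IPC, post-conditioning IPoC), plasma cardiac troponin I
(TnI, a surrogate for infarct size) is bimodal in the IPoC arm: a
"responder" subgroup with near-IPC levels and a "non-responder" subgroup
indistinguishable from I/R. Downstream, the interesting molecular signal is
the set of miRNAs whose I/R-induced change is *reversed* in responders but
not in non-responders, and the mitochondria-related genes those miRs are
predicted to regulate.

`IPoCnet` implements that analysis end to end, for anyone running (or
re-analysing) a conditioning study from a miR count matrix:

1. **Stratification** — a two-component Gaussian mixture on log TnI
   (EM, deterministic quartile initialization, posterior ≥ 0.5 assignment,
   degeneracy guard with a geometric-midpoint threshold fallback).
2. **Differential expression** — median-of-ratios normalization,
   method-of-moments NB dispersion with trend shrinkage, and a two-group
   negative-binomial Wald contrast: for groups *t*, *r* with size factors
   *s<sub>j</sub>*,

   q̂<sub>g</sub> = Σ<sub>j∈g</sub> k<sub>ij</sub> / Σ<sub>j∈g</sub> s<sub>j</sub>,  log2FC = log₂(q̂<sub>t</sub>/q̂<sub>r</sub>),  Var(log q̂<sub>g</sub>) = (Σs<sub>j</sub> + α q̂ Σs<sub>j</sub>²) / (q̂ (Σs<sub>j</sub>)²)

   with Wald z = log2FC/SE against N(0,1). Benjamini–Hochberg adjustment,
   plus the classical cascade (Shapiro–Wilk → Levene → t/Welch or
   Mann–Whitney) and one-way ANOVA with Student–Newman–Keuls post hoc for
   qPCR-style group tables.
3. **Protective-pattern filter** — a miR is selected when it is regulated
   by I/R, reversed in IPoC responders (and, by default, in IPC), and shows
   no opposite change in non-responders.
4. **Signed bipartite network** — interactions from validated tables
   (kept unconditionally), prediction scores (kept iff score > 80.0) and
   mirSVR-style scores (kept iff score < −1.2) are merged, deduplicated
   and signed: an up-regulated miR contributes a −1 edge to each target
   (predicted repression), a down-regulated miR +1. The **node strength**
   of a target is the sum of its incident edge weights; its sign predicts
   the direction of the target's expression change.
5. **Mitochondrial subnetwork** — target identifiers are reconciled
   against an IMPI-style annotation through a fixed cascade
   (Ensembl → RGD → NCBI id → case-insensitive symbol → description;
   ambiguous hits excluded), kept iff GO-mitochondrial or IMPI score
   > 0.7, and the induced subnetwork re-scored.

A first-class synthetic-data module generates every input with planted
ground truth (responder labels, per-contrast log2 fold changes, library
sizes, score distributions, identifier aliasing), so the full pipeline is
testable without downloads.

## Worked example

```r
library(IPoCnet)
res <- runPipeline(pipelineConfig(seed = 11), "demo_run")
res$stratification
res$mito_network
reportSummary("demo_run", top_k = 5)
```

prints

```
TniStratification: 8 responder(s), 12 non-responder(s)
  method: mixture
SignedBipartiteNet with 10 miR node(s), 20 target node(s), 25 edge(s)
  top target by |strength|: Gene0005 (strength -2)
Pipeline run (seed 11, config 90fe2d264a3336ce02cc320ad9c436d9)
Stratification: 8 responders / 12 non-responders (mixture method)
Differential expression: 344 of 627 miRs regulated in any contrast
  injury: 87 up (25.3%), 101 down (29.4%) of 344
Protective-pattern miRs selected: 31
...
Top 5 mitochondrial targets by |strength|:
  Gene0005     strength -2 (degree 2)
```

The mixture recovers the planted 8/12 responder split from the bimodal TnI
distribution; the p ≤ 0.05 screen over the four contrasts finds 344 of 627
simulated miRs regulated somewhere (286 are planted; the excess is the
expected 5% false-positive load over four contrasts); 31 miRs survive the
protective-pattern filter; and the strongest mitochondrial target carries
strength −2, i.e. two selected up-regulated miRs are predicted to repress
it. Every stage writes a TSV/CSV/JSON output (with a config-hash comment
line) into the run directory, plus a `manifest.json` with per-stage counts.

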