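---
title: "Shared-disease miRNA prioritization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared-disease miRNA prioritization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharedmiR)
```

`sharedmiR` chains five analysis stages — disease gene-set intersection,
multi-source miRNA-target ranking, hypergeometric enrichment, interaction
network hub analysis, and qPCR/ELISA group statistics — behind a single
orchestrator with a synthetic-data layer that plants known structure in
every input. This vignette explains each model, its assumptions, the
tunable parameters, and the design decisions taken where the design was
genuinely open.

## Disease gene sets

A disease gene set is the union of term-level gene lists from a
DisGeNET-style association table, after a provenance filter (source class
in {curated, literature} by default, minimum score 0 — a provenance filter
without a score cutoff). `gene_id` is the primary identifier everywhere;
gene symbols are carried as annotation only, because symbols are unstable
and collide. Duplicate (gene, term) rows collapse to the maximum score. The
shared set is the plain intersection of the two unions; all serialized sets
are sorted lexicographically so diffs and checksums are stable.

Assumption worth stating: both diseases' tables must use one identifier
namespace. The package does not attempt ortholog or alias resolution.

## miRNA ranking

Predictions from `n_sources` databases are aggregated with union semantics
by default (`min_sources = 1`), matching the idea of capturing consensus
across tools without requiring agreement; raising `min_sources` turns this
into a source-count consensus. Per-miRNA counts are taken against the
shared set and against each *full* disease universe rather than the
exclusive sets — the published count layout is only consistent with
universe counting (a miRNA's disease-B count can exceed the size of the
B-only set) — although counting against exclusive sets works too by
passing those sets.

The ranking key is the shared-target count, descending. The tie-break
(disease-B count desc, disease-A count desc, then miRNA id) is a package
decision; only the primary key is inherited from the workflow this
implements. The top decile is ⌈0.1·M⌉ records. The reported listing order
of top miRNAs in the source workflow does not follow a pure descending sort
of its printed counts; `sharedmiR` documents its deterministic rule and
makes no attempt to reproduce an unstated secondary key.

`oner_cluster()` interprets the four-cluster assignment as ordered
equal-frequency binning of the shared-target count, with tied counts always
inheriting the cluster of their first (highest) occurrence, so counts are
monotone non-increasing across cluster boundaries. The OneR tooling
originally used for this step is not specified at the algorithm level;
equal-frequency binning is the standard reading of a one-dimensional OneR
discretization and is fully deterministic.

## Enrichment

The test is the one-sided (over-representation) upper-tail hypergeometric,
which coincides with one-sided Fisher's exact; depletion testing is out of
scope. The Benjamini–Hochberg family is *all terms within one library*,
adjusted per library — never across libraries. The background size `N` is a
configurable constant ("human genome" scale, default the simulated universe
size of 20000); the workflow this emulates does not state its N, so N is
surfaced rather than hard-coded. Ranks are assigned over all tested terms
by ascending (adjusted p, raw p, term name) — the tie rule is a package
choice — and results are then filtered to adjusted p < `alpha` (0.05) and
truncated to `top_k` (5).

Numerically, the tail probability is delegated to `stats::phyper`, whose
log-space tail evaluation is stable for the extreme p-values planted
libraries produce; the test suite checks it against direct probability-mass
summation with exact log binomial coefficients for every configuration with
N ≤ 30 at 1e-12 relative error.

## Interaction network

Nodes are the shared genes targeted by the two top-ranked miRNAs, grouped
A-only / shared / B-only by which miRNA targets them. Edges keep the
best-scored record of each unordered pair, drop self-loops, and must reach
`min_confidence` (default 0.4, the conventional STRING medium-confidence
cutoff; the emulated workflow states none). Degree is the sole centrality,
since "number of connections" is the stated hub criterion.

Cross-group edges are *retained for degree computation but hidden from the
per-group display* by default: connectivity is assessed before the grouped
layout hides between-group interactions. Because it is unstated whether the
original degrees were computed before or after hiding, both modes exist
(`drop_cross_group`). Hub lists take the top 20 (shared) / 15 (per-miRNA)
genes by (degree desc, id asc); the circular layout places hubs clockwise
from angle 0, evenly spaced on the unit circle, in rank order.

## qPCR and ELISA statistics

Relative expression is the efficiency-adjusted (Pfaffl-type) ratio
`E_t^ΔCt_t / E_r^ΔCt_r` with ΔCt = calibrator − sample; with both
efficiencies at 2 it reduces exactly to `2^-ΔΔCt`. Decisions taken where
the emulated workflow is silent:

* **Calibrator** — the mean Ct of the control (discopathy) group in plasma
  and of peritumoral tissue, configurable. Any calibrator cancels in fold
  changes of group means, so this choice affects scale, not conclusions.
* **Detectability** — Ct > 40 becomes missing, never zero; zeros would bias
  group means downward.
* **Efficiency default** — 2.0 per analyte when the input omits one.
* **t-test** — unpaired pooled-variance by default (only "t-test" is
  stated); a paired mode exists because tumor/peritumoral samples are
  patient-matched.
* **Reporting rounding** — half-up to 2 decimals for fold changes (1
  decimal where the emulated report prints one), with the unrounded value
  retained.

The ANOVA is computed from first principles (between/within mean squares)
and Fisher's LSD uses the pooled within-group MSE and its degrees of
freedom with no multiplicity adjustment — that is the LSD definition, and
it matches the stated analysis. `stats::aov` serves as the independent
cross-check in tests. Spike-in QC flags samples whose cel-miR-39-3p Ct
deviates from the cohort mean by more than 2 cohort SDs; flagged samples
are reported, not dropped. ELISA concentrations are converted to analyte
mass in the assayed volume and divided by total protein (pg/ng), flagged
against the kit's 9.38–600 pg/mL detection range. Box-plot summaries use
type-7 quantiles and 1.5·IQR whiskers.

## The synthetic-data layer

The generators emulate the *shape* of the real inputs, not their biology:

* **Associations** — the disease-set sizes and their overlap are planted
  exactly (defaults 2177, 3377, 953 with 28 and 14 terms), not sampled, so
  set-arithmetic results are reproducible by construction. Genes are
  assigned to terms so every term is non-empty; scores are uniform on
  [0, 1], which carries no evidence semantics.
* **Predictions** — planted-top miRNAs (default 14 of 140, i.e. exactly the
  top decile) target each shared gene with probability 0.5 versus a 0.05
  background; each pair is attributed to each of 14 sources with
  probability 0.7 (dropout 0.3), keeping at least one source. The planted
  rate is chosen so planted shared-target counts (~477) sit at the scale of
  the published top counts (483 of 953).
* **GMT libraries** — planted terms draw ≥ 60% of members from a designated
  pool; background terms are uniform.
* **Interactome** — planted hubs form the initial clique of a
  preferential-attachment graph and additionally attract each incoming node
  with probability 0.25, which makes the planted hubs the unambiguous
  top-degree ground truth rather than merely the likeliest one; a
  configuration model with a prescribed degree sequence is available via
  `igraph::sample_degseq`.
* **qPCR** — Gaussian noise on the Ct scale (multiplicative on expression,
  the conventional qPCR error model), within-group SD 0.3 Ct and 10
  samples per group by default; planted log2 effects default to the
  published group-mean ratios (plasma miR-16-5p 1.76/2.0/5.7,
  miR-32-5p 1.1/1.4/3.6, tissue miR-16-5p 1.6 vs 1.1). Reference (U6) and
  spike-in SDs of 0.15 Ct are package choices. Ct values are emitted at
  3-decimal instrument resolution. The real study's per-sample variance and
  effective n are unpublished; these SDs must not be read as estimates of
  that study's variability.

Each generator draws from its own RNG stream (`seed` plus a stable
per-generator offset), so adding one generator never perturbs another's
output, and a fixed config + seed gives byte-identical files.

What passing tests do and do not show: planted recovery demonstrates that
the pipeline's arithmetic and ordering are correct and well-calibrated
under a known generative model. Real association tables have correlated
evidence, term overlap and annotation bias; real prediction databases are
not conditionally independent sources; real interactomes have community
structure beyond degree; and real Ct data have batch and extraction
effects. None of those are simulated, so planted-truth recovery says
nothing about biological validity on real data.

## Problem sizes and runtime choices

The test suite exercises the study-scale configuration (20000-gene
universe, 140 miRNAs, 14 sources) for single-run checks and planted-top
recovery over 50 seeds; hub recovery uses 100 seeds on 150-node graphs,
enrichment recovery 50 seeds on 200-gene universes, qPCR fold recovery 200
seeds at n = 10/group and SD 0.3 Ct, and ANOVA calibration 10,000 null
simulations at 3 × 10. These sizes keep the full suite within a few
minutes on one CPU while leaving Monte-Carlo error well inside the asserted
tolerances.

## Known limitations

* Disease terms are taken as given lists; no ontology expansion.
* Aggregation treats all prediction sources as exchangeable; no
  validated-versus-predicted weighting.
* Degree is the only centrality; no community detection or betweenness.
* ELISA standard-curve fitting is out of scope — concentrations are inputs.
* The pipeline reports statistics; it renders no figures beyond layout
  coordinates and box-plot summary tables.
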