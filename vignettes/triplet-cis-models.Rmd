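---
title: "Triplet cis-regulatory models: methods and design"
author: "tripletCis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triplet cis-regulatory models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripletCis)
```

## The problem

Orphan CpG islands (oCGIs) — CpG islands overlapping neither a promoter
nor an enhancer — show methylation changes in glioma that track the
expression of distal genes. Given per-sample methylation of an oCGI (O)
and an enhancer (E) and expression of a gene (G), all three inside one
topologically associating domain (TAD), the package asks which of nine
regulatory architectures best explains the joint distribution, and whether
the relationship is concordant with the direction of the two methylation
subtypes (C1/C2) of the cohort.

## Element definitions

CpG islands are expanded to 500 bp windows centered on their midpoint
(`floor((start + end) / 2)` in 0-based coordinates, ±250 bp) and
overlapping windows are merged into their union. Two boundary policies are
worth stating because the literal rule is silent on them:

* **CGIs longer than 500 bp.** A strict 500 bp window would discard
  covered CpGs. We take the union of the original span and the centered
  window and flag the element (`longCgi`), so probe coverage is never
  lost.
* **Windows clamped at position 0** are truncated and flagged.

Promoters run 1500 bp upstream to 500 bp downstream of each annotated
TSS, oriented by strand; every alternative TSS yields its own promoter.
A CGI window overlapping any promoter is `promoter_overlap`; otherwise
overlapping any enhancer, `enhancer_overlap`; the remainder are orphans.
Overlap with a gene body is recorded as a secondary annotation only — the
operational oCGI definition removes promoter and enhancer overlaps, not
genic ones. All coordinates in files follow the BED convention (0-based,
half-open); exactly abutting intervals do not overlap.

## Methylation preprocessing

Quality control applies three filters in order: SNP-containing probes,
probes observed in fewer than 20 % of samples, samples observed in fewer
than 20 % of remaining probes ("observed" = non-missing β — β values have
no notion of expression-style zero inflation). Missing values are then
imputed by k nearest neighbours with the conventional defaults k = 10,
rowmax = 0.5, colmax = 0.8: the distance between probes is the mean
squared difference over jointly observed samples, donors must be observed
in the target sample, distance ties break by probe order, and rows beyond
rowmax fall back to row-mean (then column-mean) imputation. Probes are
aggregated to region means by half-open containment; regions without
probes are flagged and excluded from screening. β states use the
thresholds hypo < 0.32 and hyper > 0.79, with both boundaries assigned to
hemi (the printed state definitions are strict inequalities).

## Pairing and the MI screen

Elements join the TAD containing their midpoint; genes the TAD containing
their TSS (regulation is modeled at the promoter). Candidate pairs are the
TAD-restricted products (oCGI × genes) and (enhancers × genes), annotated
with midpoint–TSS distance and the number of distinct TSSs strictly
between the anchors.

Association strength is plug-in mutual information (nats) on
equal-frequency 3-bin discretizations (vectors with at most three distinct
values are used as-is; the 3-bin default mirrors the three-state
methylation vocabulary and is invariant to monotone transforms, so raw or
log expression give identical MI). Significance comes from a permutation
null — `p = (1 + #{MI_perm ≥ MI_obs}) / (nPerm + 1)` with 999 permutations
by default and a mandatory seed — followed by Benjamini–Hochberg
adjustment, applied separately to the oCGI–gene and enhancer–gene
families because the two screens act as separate criteria. Pairs with
adjusted p < 0.05 combine, per gene and TAD, into every
oCGI-pair × enhancer-pair triplet.

## The nine structures and model selection

The nine candidate networks over {O, E, G} and their factorizations:

| id | factorization | edges |
|---|---|---|
| oCGI_direct | P(O)·P(G|O)·P(E) | O→G |
| oCGI_cascade | P(O)·P(E|O)·P(G|E) | O→E, E→G |
| oCGI_coresponsive | P(O)·P(E|O)·P(G|O) | O→E, O→G |
| oCGI_composite | P(O)·P(E|O)·P(G|O:E) | O→E, O→G, E→G |
| enhancer_direct | P(O)·P(G|E)·P(E) | E→G |
| enhancer_cascade | P(E)·P(O|E)·P(G|O) | E→O, O→G |
| enhancer_coresponsive | P(E)·P(O|E)·P(G|E) | E→O, E→G |
| enhancer_composite | P(E)·P(O|E)·P(G|O:E) | E→O, E→G, O→G |
| co_dominated | P(O)·P(E)·P(G|O:E) | O→G, E→G |

**Backends.** The default gaussian backend fits each node by linear
regression on its parents with MLE variance, on raw β for O and E and
log1p expression for G; per-node parameters are `#parents + 2`
(coefficients, intercept, variance). A discrete backend (β states ×
expression tertiles, multinomial conditional tables, 0.5 pseudo-counts on
empty cells only, `(levels−1)·∏ parent levels` parameters) is available
via `backend = "discrete"`; it feeds the same AIC machinery. β-state
classification otherwise enters only the concordance annotations.

**Markov equivalence.** Structures with the same skeleton and
v-structures have identical maximized likelihood; the nine models collapse
into six classes, computed structurally and verified empirically
(intra-class logL agreement within 1e-8). AIC cannot separate class
members, so observing both members of a class as distinct calls requires
an extra criterion: we break the (exact) AIC tie by dominance, assigning
the oCGI-dominated member when MI(O,G) ≥ MI(E,G) and the
enhancer-dominated member otherwise, and annotate the tie. This is the
least arbitrary signal available; any such rule is a convention, and the
annotation preserves the ambiguity.

**Validity testing.** Each structure must be consistent with the data's
(in)dependence pattern at α = 0.05 (configurable):

* an *edge* means no conditioning set separates the pair, so dependence
  must be detected both marginally and given the third node (Fisher-z
  partial correlation under the gaussian backend, G² under the discrete
  one). Requiring both conditioning sets is the constraint-based
  (PC-algorithm) reading of adjacency; with a single test, a structure
  with one spurious extra edge validates on a single α-level accident and
  then always beats the true nested model's AIC (the 3.84 test threshold
  exceeds the AIC penalty of 2), which caps single-edge-structure
  recovery near 90 %. Under the two-set requirement the two null
  statistics are only weakly correlated and spurious validation needs
  both to fail simultaneously.
* an *absent edge* implies a (conditional) independence, tested with its
  d-separating witness: the empty set for the co-dominated collider
  (O and E marginally independent), the middle node for chains and forks.
  In the two direct models the isolated node's factor P(·) is one joint
  statement — independence from both other nodes — and is tested as such
  (overall regression F-test, or G² against the combined factor).
* relations untestable at the available sample size never invalidate a
  model.

The selected model is the valid structure with the smallest
AIC = 2k − 2·logL; when no structure is valid the triplet is left
unassigned with a reason. The co-dominated model is the only two-edge
structure in its class precisely because of its v-structure: conditioning
on G induces dependence between otherwise independent O and E.

## Concordance and cis scores

Given two-cluster labels, a triplet whose dominant element(s) — oCGI,
enhancer, or both for co_dominated — have strictly lower mean β in C2
*and* whose gene has strictly higher mean log1p expression in C2 is
labeled C2_UP; C1_UP mirrors this. Expression is compared on the log1p
scale (the fitting scale): natural-scale means of right-skewed expression
are dominated by their tail and are an unreliable direction readout.
Methylation is compared on the β scale, with per-cluster β states
recorded as annotation rather than enforced — the rule is stated on
levels, the states supply vocabulary. Co-dominated triplets whose two
elements move in opposite directions are dropped with reason
"dominant elements disagree".

The cis score of a sample is the arithmetic mean of expression over a
direction-labeled gene set; samples are stratified at the cohort median
(a balanced, deterministic split — no split rule is prescribed by the
definitions the score derives from). Gene sets are exported per
direction; per-model-type subsets can be formed from the call table since
the calls carry the selected structure.

## The synthetic-data generator

The generator emulates the minimal structure the pipeline needs:
non-overlapping TADs on one chromosome, each with one CGI (placed clear of
promoters and enhancers), one enhancer, one target gene and optional decoy
genes; every fifth TAD carries a decoy CGI inside the promoter to exercise
classification. Per triplet, (O, E, G) are sampled forward along a chosen
factorization:

* source methylation nodes draw from Beta distributions anchored to the
  state thresholds — Beta(8,2) vs Beta(2,8) across clusters for
  single-source structures (hyper vs hypo), Beta(2,2) when no cluster
  direction is simulated;
* the co-dominated structure instead uses a mild within-hemi shift
  (Beta(10.33, 9.67) vs Beta(9.67, 10.33), a mean difference of ~0.033 ≈
  0.3 within-cluster SD). A large shared cluster shift would correlate O
  and E marginally and destroy the very v-structure that identifies the
  collider; the chosen size keeps the induced correlation (~0.02) below
  detectability at n = 300 while leaving a reliable direction signal;
* child methylation nodes follow a linear link on the β scale
  (coefficient 0.9, noise SD 0.08, out-of-range noise redrawn);
  log-expression is linear in its standardized methylation parents with
  coefficient −1 (methylation represses) and noise SD 0.5 around baseline
  4, emitted as `expm1` so that the backend's `log1p` recovers the
  generating scale exactly. Generating links live on the scales the
  gaussian backend fits; curvature between generation and fitting scales
  would miscalibrate the independence tests and make recovery rates
  meaningless as a check of the selection machinery;
* probes scatter around regional means with logit-normal noise (SD 0.15),
  and missingness is injected completely at random (2 % by default).

Defaults describe a 300-sample, 50/50 two-cluster cohort. Reproducibility
comes from per-triplet substreams seeded by (seed, triplet index), so
bundles are byte-identical across runs for a fixed configuration.

What the generator does **not** emulate: realistic 450K probe design,
array batch effects, copy-number confounding, cluster-correlated
missingness, or shared trans-acting factors. Passing tests therefore
demonstrate that the statistical machinery recovers known generating
structures under its own assumptions — not that those assumptions hold in
tumor cohorts.

The end-to-end recovery bundle draws structures only from the four
equivalence classes in which both the oCGI–gene and enhancer–gene pairs
are genuinely associated (the cascades/co-responsives, composites, and
co-dominated): under the direct models one element is independent of the
gene by construction, so the MI screen removes those triplets before any
model is fit — recovering them end-to-end is impossible by design, and
their recovery is instead checked at the model-selection stage across all
six classes.

## Numerical choices and degenerate inputs

* Equal-frequency discretization uses rank binning with first-occurrence
  tie-breaks: deterministic, at the cost of order sensitivity for heavily
  tied vectors.
* Permutation p-values use the add-one estimator; permuted MI values tie
  the observed value within 1e-12 count as exceedances, keeping the test
  valid (conservative) under ties.
* Zero-variance nodes are an error under the gaussian backend (named in
  the message); residual variances below 1e-12 are floored.
* AIC ties are resolved within 1e-8; cross-class exact ties (measure-zero
  in practice) fall back to enumeration order with the tie annotated.
* Problem sizes in the shipped tests — 50-sample equivalence datasets,
  100 replicates per class at n = 300, a 1000-pair calibration at n = 100
  with 199 permutations, and one 100-TAD end-to-end bundle at n = 300
  with 999 permutations — were chosen so each property is measured with
  useful precision while the whole suite stays comfortably interactive.

## Known limitations

* Only the nine fixed three-node candidates are scored; no structure
  search, larger networks, latent confounders, or causal-effect
  estimates.
* The dominance tie-break is a convention; likelihood cannot distinguish
  Markov-equivalent members, and calls inside two-member classes should
  be interpreted at class resolution when the tie flag is set.
* The gaussian backend assumes roughly linear β–expression relationships;
  strongly sigmoidal couplings are better served by the discrete backend
  at some power cost.
* TAD assignment is by midpoint/TSS containment; elements straddling
  boundaries contribute to exactly one TAD.
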