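---
title: "Placing dark proteins into pathway context: methods and design"
author: "darkpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Placing dark proteins into pathway context: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkpath)
```

## The problem

Roughly a third of human proteins — the understudied or "dark" proteins
(target development level `Tdark`) — have little or no functional
annotation, and most of them are absent from curated pathway
knowledgebases. `darkpath` implements a guilt-by-association framework for
placing such proteins into the context of curated, reaction-level
pathways:

1. **Predict functional interactions (FIs).** A probability random forest
   is trained on binary gene-pair feature channels (co-expression
   memberships, physical PPIs including orthology-mapped model-organism
   interactions, domain-domain interactions, shared GO biological-process
   annotation, similarity sets), with FIs extracted from curated complexes
   and reactions as positives and random pairs as negatives.
2. **Quantify interacting pathways.** For each protein, its predicted FI
   partners are used as a query gene set against every pathway, yielding a
   binomial **enrichment score**; a fuzzy-logic Boolean-network simulation
   of each pathway yields **simulation scores** under all-activating and
   all-inhibiting assumptions about the predicted FIs.
3. **Validate.** Agreement with an independent co-expression channel and
   with the literature (embedding similarity between pathway descriptions
   and gene-matched abstracts) is measured by per-gene correlations and
   skew statistics.

Every external input (pathway database, feature channels, expression
matrix, abstract corpus) is emulated by deterministic synthetic generators
so the full pipeline runs offline and is testable end-to-end.

## The pathway data model

A `PathwayDatabase` holds genes, physical entities (proteins, complexes,
sets, small molecules), reactions (inputs, outputs, catalysts, activators,
inhibitors) and a DAG of pathways whose leaves are reactions. Gene sets
propagate upwards: `eventGeneSet()` returns every gene reachable through
an event's descendant reactions, flattening complex and set membership.

**Reference FI extraction.** The extraction rule is a declared, auditable
convention covering the dominant pair classes of curated-network
construction: (i) every two distinct protein components of a common
complex (nested complexes and sets flattened), (ii) every
input-protein/catalyst-protein pair, (iii) every pair of distinct input
proteins of a reaction. Regulator-derived pairs are excluded by default
(`includeRegulators = FALSE`) because regulation edges are directional
while the FI set is undirected; the flag restores them for sensitivity
analyses.

## Feature channels and vetting

Channels are **binary**: a pair is a member or it is not. Continuous
sources are binarised upstream — co-expression by taking the top `pct`
percent of Spearman-correlated pairs (`topPercentilePairs()`, ties broken
by value descending then canonical pair key), interaction databases by
score thresholds (`readPairChannel(minScore=)`).

Expression QC follows the bulk RNA-seq conventions: samples with RIN
$\le 6.0$ are removed (the boundary is inclusive), then groups with fewer
than 30 samples; counts are normalised to counts-per-million and samples
whose standardised first-principal-component score is $\ge 3$ (computed on
gene-centred $\log_2(\mathrm{cpm}+1)$, with the component oriented so its
heavier tail is positive) are flagged as outliers before correlation.
Whether correlations use cpm or log-cpm is immaterial for Spearman (the
transform is monotone), which the test-suite checks explicitly.

Each candidate channel is vetted by its odds ratio against the reference
FIs over a pair universe (by default, all pairs over the genes common to
the channel's and the FI set's gene spaces — the published universe is
unstated, so it is configurable). Zero cells get the Haldane–Anscombe
+0.5 correction so vetting stays defined for sparse channels. Channels
with odds ratio **strictly greater than 5.0** are retained.

## The FI classifier

The classifier contract is a probabilistic binary classifier with
per-feature importances; the implementation is a probability random
forest with the published hyperparameters as defaults
(`classifierConfig()`: 200 trees, maximum depth 10, balanced class
weights, minimum leaf size 1, fixed random state 42). Negatives are drawn
uniformly without replacement from non-FI pairs — known positives are the
only exclusions, matching the "random pairs" protocol. Evaluation repeats
stratified 75/25 splits ten times and averages AUC, precision, recall and
F1; the final model is refit on all data. Pairs with predicted score
$\ge 0.8$ (inclusive) form the predicted FI set.

The published protocol used a 1:100 positive:negative ratio, which is
kept as the default of `buildTrainingSet()`. The synthetic pipeline uses
1:10 (`runSyntheticPipeline(negRatio = 10)`): a 200-gene universe has
19,900 pairs, so a 1:100 ratio with ~150 positives is arithmetically
impossible; `buildTrainingSet()` refuses such requests and states the
maximum attainable ratio.

## Interacting-pathway scores

**Enrichment score.** For a gene with $n$ predicted partners inside a
universe of $N$ genes and a pathway of size $K$ with overlap $k$, the
p-value is the upper binomial tail
$P(X \ge k),\ X \sim \mathrm{Binomial}(n, K/N)$. p-values are adjusted by
Benjamini–Hochberg **within the gene across pathways** (as the per-gene
design dictates; no global adjustment across genes), and the enrichment
score is $-\log_{10}(\mathrm{FDR})$ with the FDR floored at $10^{-300}$ so
scores stay finite. The background universe defaults to all genes in the
database and can be widened to all protein-coding genes. The success
probability $K/N$ is a declared convention (the published
parameterisation is not printed).

**Simulation scores.** Each pathway compiles to a bipartite fuzzy-logic
Boolean network: activity-bearing entity nodes in $[0,1]$ and reaction
transfer nodes. The update rule is synchronous discrete time: reaction
firing is the fuzzy-AND (min) of Hill-transformed input and catalyst
activities, damped by $\prod(1-h(\mathrm{inhibitor}))$ and fuzzy-OR
(max) combined with activator contributions; a produced entity takes the
max firing of its producers; sources hold their initial value. The Hill
curve is $h(x) = x^n/(K^n + x^n)$ with defaults $K = 0.5$, $n = 4$ (a
symmetric sigmoid: $h(K) = 0.5$), horizon 100 steps, convergence
tolerance $10^{-6}$. The upstream simulator's exact fuzzy norms, Hill
parameters, initial conditions and horizon are not restated in the
source material, so all are exposed as configuration with these defaults.

A gene's impact on a pathway is measured by two perturbed runs — one
treating all of its FIs into the pathway as activating (strength $s$ =
the FI prediction score, max-combined with the target's activity each
step), one as inhibiting (activity multiplied by $1-s$) — against a
baseline run without injection. Both injection rules keep activities in
$[0,1]$ and make $s=0$ the *exact* null, which the tests verify to
bit-identity. The per-node impact is the trapezoidal
area-under-curve difference divided by the horizon, signed and in
$[-1,1]$; `average_activation` and `average_inhibition` are the means
over the pathway's deduplicated reaction-output entities. Impact runs use
a fixed-length horizon (no early stopping) so baseline and perturbed
traces align. Scores are reported signed; `scaleScores()` provides the
min-max $[0,1]$ display variant (a constant vector maps to 0.5 by
convention). Note that an activation injection onto a clamped source
already at activity 1 is a no-op; impact fixtures therefore initialise
sources below saturation (e.g. `initSource = 0.25`).

## Literature annotation score

Abstracts are matched to a gene by simple word-boundary text matching on
its aliases. All-uppercase aliases (gene symbols) are matched
case-sensitively, mixed-case or multi-word protein names
case-insensitively — a minimal rule that curbs false hits of short
symbols inside longer tokens while staying "simple text matching". The
similarity between a pathway and an abstract is the mean cosine between
the abstract's embedding and the embeddings of the pathway's summation
text plus the summations of all events inside it (events without text are
skipped, not zero-filled). A gene's annotation score for a pathway ranks
its matched abstracts by mean similarity across all pathways under
analysis, keeps at most $k = 1000$, and averages the kept abstracts'
similarities to the queried pathway.

The embedding provider is pluggable (`$dim`, deterministic
`$embed(text)`). The shipped `pseudoEmbedder()` is a deterministic
hash-based bag-of-words embedding into 384 dimensions (hash buckets
mapped to fixed pseudo-random directions built from a trigonometric
construction; no RNG state is touched). It honours the same contract as a
production sentence-embedding model while making tests exact and
dependency-free; it captures token overlap, not semantics, so annotation
scores on synthetic corpora measure vocabulary sharing only.

## Validation statistics

Two score tables (genes × pathways) are compared gene-by-gene with
Pearson correlations over shared pathways; genes with fewer than 10
shared pathways, or a zero-variance vector, are excluded as missing
rather than scored 0. `skewSummary()` tests the positive/negative split
of correlations with an exact two-sided binomial proportion test (the
source names only a "proportion test"; the exact test is the conservative
choice at these n) and compares $-\log_{10}(p)$ and $|r|$ between sign
groups with both Welch t and Mann–Whitney tests, since the published
two-sample test is not named.

The single-cell-style channel replaces the recursive co-expression
workflow of the original toolchain with plain Spearman correlation on
cpm-normalised expression: downstream logic consumes only the top 0.1% of
*positively* correlated pairs, and the synthetic generator plants
structure that plain correlation detects, so the recursive refinement
adds nothing at desk scale.

## Synthetic study conditions

`syntheticConfig()` fixes the desk-scale conditions used by the tests and
the acceptance script: 200 genes in 5 two-level pathways (15–25 genes
each, two complexes and a reaction chain per pathway, ~30% of genes
tagged Tdark); six channels with odds-ratio targets 150/60/40/25/15/1 at
a 2% base rate — mirroring real channels, where the strongest features
hit more than half of all positives and therefore sit far above the 5.0
gate, plus one null channel; a Poisson-lognormal count matrix (120
samples, log-scale noise SD 1.0) whose first pathway's genes share a
latent factor at $\rho = 0.7$, with one planted low-RIN sample and one
planted composition outlier; and 160 abstracts over 20 planted genes,
half reusing the target pathway's private vocabulary. What passing tests
show is that the machinery recovers *planted* structure of realistic
strength; they say nothing about biological truth on real data, where
feature channels are correlated, class balance is far more extreme and
literature language is not bag-of-words.

## Worked example

```{r pipeline, eval = FALSE}
res <- runSyntheticPipeline(syntheticConfig(seed = 42))
res$report$auc                 # held-out AUC, mean of 10 splits
res$selection$reports          # odds-ratio vetting report
featureImportance(res$model)   # normalised channel importances
head(res$enrichment)           # gene x pathway enrichment scores
```

## Numerical choices and degenerate inputs

* Pair keys are canonical `"A|B"` strings in C-locale order; all pair
  sets are deduplicated, self-pair-free and radix-sorted, which is what
  makes reruns byte-identical.
* Ties in top-percentile selection break by (value desc, key asc);
  negative sampling and all generators route randomness through a
  seed-scoped RNG that restores the caller's state.
* Constant genes yield missing (not zero) correlations; genes without
  partners yield empty enrichment records with a warning; unmatched genes
  yield missing annotation scores.
* `bhAdjust()` refuses p-values outside (0,1]; `binomialPValue(k=0)`
  returns exactly 1.
* Evaluation uses `floor(holdout * n)` per class with at least one
  validation sample per class.

## Known limitations

* The FI extraction rule is a convention; the upstream network's exact
  pair classes are not restated in the source material.
* Binary channels discard evidence strength; continuous variants are out
  of scope.
* The fuzzy-logic update semantics are one defensible choice among
  several (synchronous only; no ODE or stochastic semantics).
* The pseudo-embedder is a test double for the embedding contract, not a
  language model.
* Desk-scale synthetic results (problem sizes above) are qualitative
  analogues of full-scale results, not reproductions of them.
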