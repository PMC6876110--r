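---
title: "Methods: disease-associated metabolite networks and RWR prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease-associated metabolite networks and RWR prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabonet)
```

## Overview

`metabonet` predicts candidate disease-related metabolites in four stages:
disease–disease functional similarity, collaborative-filtering metabolite
profiles, evidence-fused network construction, and random-walk-with-restart
(RWR) ranking. This vignette records the model assumptions, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic benchmark does and does not establish.

## Disease similarity

Two diseases are considered similar when their annotated gene sets are
strongly cross-connected in a weighted gene functional network, and when
they share a specific (information-rich) common ancestor in the disease
ontology.

* **Gene-set cross-connectivity.** `disease_fun_sim(Ga, Gb, net)` averages
  best-match connection weights in both directions. The best-match form —
  $R_G(g) = 1$ on membership, else the maximum edge weight from $g$ into
  $G$ — keeps each contribution in $[0,1]$, makes identical sets score
  exactly 1, and is monotone under added cross edges (a property the test
  suite enforces). The underlying fused gene network is consumed as an
  input edge list; its construction is out of scope.
* **MICA discounting.** The raw similarity multiplies by
  $|G_a||G_b|/|G_{MICA}|^2$ where $|G_{MICA}|$ is the propagated gene
  count (union over the term and all descendants) of the most informative
  common ancestor. Propagation is what makes the root a universal fallback
  ancestor and information content monotone along IS_A paths. We define
  $IC(t) = -\log(|G_t|/|G_{root}|)$; only the argmax matters, so any
  strictly decreasing transform of $|G_t|$ selects the same ancestor
  (asserted as a test). Ties break by smaller $|G_t|$, then lexicographic
  term id, making the choice deterministic.
* **Normalization.** Raw scores can exceed 1 (the ratio factor is
  unbounded). `all_pairs_similarity()` divides every off-diagonal entry by
  the off-diagonal maximum (`normalization_mode = "max"`), which preserves
  ratios and lands in $[0,1]$; `"none"` is available for inspection. The
  diagonal is fixed at 1. If every pair scores zero the matrix stays zero
  off-diagonal, with a warning, and downstream profiles collapse to 0/1
  incidence vectors.
* **Annotation scope.** Eq.-level gene sets $G_a, G_b$ use *direct*
  annotations by default; only $|G_{MICA}|$ uses propagated counts. A
  `annotation = "propagated"` switch exists because the choice is not
  determined by the method's definition; with it, self-similarity is
  exactly 1.

## Collaborative-filtering profiles and the DMN

Each metabolite $m$ with a nonempty direct disease set $DR_m$ becomes a
vector over the disease universe $D$ (all diseases appearing in the
association snapshot): 1 on its own diseases, else the maximum normalized
similarity from the candidate disease to any disease in $DR_m$. This is
item-based collaborative filtering with disease similarity as the
item–item kernel. Metabolites with no associated disease are excluded
(their relevance is undefined), with a warning.

Edge weights are cosine similarities of profile vectors — in $[0,1]$
because all entries are nonnegative. Edges are kept when **strictly
above** the threshold (default 0.01; chosen where the edge-count decline
levels off on real association data). Strictness at the boundary is a
deliberate, configurable reading of "filter weak links"; the boundary case
is pinned by a test. The node set keeps all profiled metabolites, so a
high threshold yields isolated nodes rather than a shrunken universe; the
threshold sweep reports edge counts so degenerate settings are visible
(an edgeless network gives all-tied RWR scores and AUC 0.5, not skipped
cases).

## Evidence fusion

Text-mining scores $ST \in [0,1]$ (raw 0–1000 channel scores can be
rescaled on ingest with `scale = 1000`) are fused per edge by the noisy-OR
rule $1-(1-\mathrm{DMN})(1-ST)$: the two channels are treated as
independent evidence sources, a missing channel contributes 0, and the
fused weight dominates both inputs. The fused network's edge set is the
union of DMN edges and text-mining pairs restricted to the DMN node set —
the node universe is fixed by the association data, and literature pairs
outside it are counted and skipped.

## Random walk with restart

Transitions are column-stochastic: each node's outgoing probabilities are
proportional to its edge weights; isolated nodes are self-absorbing so
the matrix stays stochastic. The walker iterates
$p \leftarrow (1-r)\,W p + r\,p_0$ with $p_0$ uniform over the seed set,
stopping when the $L_1$ change drops below `tolerance`.

* `restart = 0.7`: the paper-scale literature on disease-gene network
  propagation standardly uses 0.6–0.8; the method's source does not state
  a value, so 0.7 is the default and the parameter is exposed everywhere
  (function, CLI, config).
* `tolerance = 1e-10` ($L_1$), `max_iterations = 10000`: for $r \ge 0.1$
  the iteration contracts at rate $(1-r)$, so convergence takes a few
  dozen iterations; exceeding the cap is a hard error (exit code 3 in the
  CLI), never a silent truncation.
* For $r > 0$ the fixed point is unique:
  $p = r\,(I-(1-r)W)^{-1} p_0$. `rwr_solve_oracle()` computes it by dense
  solve and serves as the in-package oracle; the iterative and closed-form
  routes agree within $10^{-8}$ on random graphs (tested).

Non-seed nodes are ranked by descending score with ties broken by sorted
metabolite id, so rankings are deterministic.

## Two-snapshot evaluation

Seeds are a disease's metabolites in the earlier snapshot; positives are
metabolites newly associated in the later snapshot that exist as network
nodes; the candidate pool is every non-seed node, and negatives are the
pool minus positives (the standard choice; the protocol's source does not
define the negative pool). AUC is the Mann–Whitney concordance with ties
counted half, computed by midranks and verified against an all-pairs
counting oracle. The summary is the unweighted mean across diseases.
A metabolite-seeded mode ranks co-associated metabolites from a single
seed node.

## Synthetic data: what it emulates, and what a green test means

The generator plants the statistical structure the method assumes:
functionally related metabolites share diseases. Diseases, genes and
metabolites are partitioned into `n_modules` modules; each disease draws
~60% of its module's gene pool (high within-module gene overlap → high
functional similarity), the gene network is dense and strong within
modules (edge prob. 0.5, weights 0.6–0.95) and sparse and weak across
(0.03, 0.05–0.2), and metabolites associate with their module's diseases
with probability `within_module_assoc_prob = 0.6` against a cross-module
floor of 0.05. The benchmark scale — 3 modules, 12 diseases, 60
metabolites, 60 genes, 15 withheld associations — is fixed by the
acceptance criteria; probabilities were chosen once as a plausible
"strong structure" regime and are not tuned.

Two design points deserve record:

* **Text-mining concordance.** A concordant text-mining pair links two
  *truly co-associated* metabolites (sharing a disease in the full
  association set, withheld pairs included), with probability
  `textmining_concordance = 0.9`; otherwise pairs are uniform noise.
  This encodes the mechanism by which fusion is expected to help:
  literature reflects associations the earlier snapshot lacks. A purely
  module-level notion of concordance produces text edges nearly
  independent of the withheld positives and cannot realize the fusion
  benefit the evaluation is designed to detect.
* **Null calibration.** With equal within/cross probabilities and
  unstructured text mining, evaluation AUC sits near 0.45 rather than
  exactly 0.5: a metabolite whose association was withheld has one fewer
  earlier-snapshot association, hence slightly lower network degree and
  RWR score. This is a protocol artifact of two-snapshot validation
  itself, not an implementation bias; it is inside the accepted
  0.5 ± 0.1 band and worth knowing about when interpreting real-data
  AUCs near chance.

What a green benchmark establishes: the pipeline recovers planted
co-association structure (mean AUC ≈ 0.9 at this scale) and concordant
fusion does not hurt. What it does not establish: performance on real
association data, whose degree distributions, annotation depth and
literature coverage are far more skewed than the module model; entity
counts and AUC figures from any particular database snapshot are
explicitly out of scope.

## Vocabulary mapping

Free-text disease names are resolved against a combined vocabulary of
ontology names/synonyms and MEDIC-style names/synonyms, after a
normalization that lowercases, strips punctuation to spaces and collapses
whitespace (idempotent; property-tested). Matching is exact on normalized
strings — fuzzy matching is deliberately out of scope. One name mapping
to several terms is retained as a set; at mapping time the ambiguity
policy is `"drop"` (default, reported) or `"first"` (lexicographically
smallest term id, still reported). Mapping failure is data, not an error:
mapped + unmapped + ambiguous-dropped rows always account for the
deduplicated input.

## Degenerate inputs and numerical edges

* Both gene sets empty → similarity 0 with a warning; $|G_{MICA}| = 0$
  (only possible in that same case) → 0 with a warning.
* Cosine of a zero vector is a hard error; it cannot occur for retained
  metabolites, whose own-disease dimensions are 1.
* Cosine values are clamped at 1 to absorb $+\epsilon$ roundoff from the
  normalized cross-product; identical profiles score 1 within $10^{-12}$.
* Edge stores are keyed by lexicographically sorted unordered pairs;
  re-reading a written network reproduces weights exactly (15 significant
  digits), and any weight outside $[0,1]$ — including a corrupted file —
  is a hard error naming the line.
* All randomness in the generator runs under one seed with the caller's
  RNG state saved and restored; identical configs produce byte-identical
  bundles and pipeline outputs.

## Known limitations

* The gene-set connection weight $R_G(g)$ is the best-match (max) form;
  the original fused-network definition is not recoverable from the
  method's description, and alternatives (mean of top-k) would change raw
  scores but not the package's contracts.
* Max-normalization of disease similarity is one of several defensible
  readings of "normalize"; min-max or rank normalization would change
  profile values. The mode is a config switch, and the default is pinned
  by tests.
* The evaluation never reweights per-disease AUCs by case size; a disease
  with one positive counts as much as one with twenty.
* Real OBO files use many tags this parser ignores (xrefs, relationships
  other than IS_A); only id/name/synonym/is_a/is_obsolete are honoured.
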