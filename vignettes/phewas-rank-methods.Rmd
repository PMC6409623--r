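---
title: "PheWASRank: methods, parameters and design choices"
author: "PheWASRank authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PheWASRank: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PheWASRank)
```

# The problem

Phenome-wide and genome-wide association scans produce gene-level p-values
whose individual associations are usually too weak to act on: a breast
cancer scan may nominate well over a thousand genes, of which only a
modest fraction recurs in curated disease databases. PheWASRank implements
a systems-genetics remedy: treat the per-gene evidence as heat and let a
directed gene-dependency network redistribute it, so that genes supported
both by their own association signal *and* by the signal of the genes that
depend on them rise to the top. The prioritized list then feeds enrichment
validation and target-based drug repositioning.

# The propagation model

Every gene enters with an initial score
$f_j = -\log_{10} p_j$ (`computeInitialScores()`; the base is
configurable, and p-values are clamped to $[10^{-300}, 1]$ so the score
stays finite — a p-value of exactly 0 maps to 300 rather than an error).
The damped fixed-point iteration

$$r_j^{(n)} \;=\; (1-d)\,f_j \;+\; d \sum_{i=1}^{N}
  \frac{w_{ij}}{\deg_i}\, r_i^{(n-1)}$$

redistributes the evidence: $w_{ij}=1$ is the dependency edge
$i \to j$, and $\deg_i$ is the out-degree of $i$, so every gene splits its
current score equally among the genes that depend on it. Genes with
out-degree zero (dangling nodes) propagate nothing — there is no
teleportation term, keeping the update exactly as printed above.

Key analytic facts, each enforced by a test:

* For $0 \le d < 1$ the update is a contraction in the one-norm (the
  column sums of the normalized adjacency are at most 1), so the fixed
  point exists, is unique, and the iteration converges from any start. We
  start at $r^{(0)} = f$; the start affects only the iteration count.
* The fixed point solves $(I - dP^\top)r = (1-d)f$ with $P$ the
  out-degree-normalized adjacency. `geneRankClosedForm()` solves this
  directly and serves as an internal oracle: iterative and closed-form
  scores agree to $10^{-6}$ per component on randomized instances.
* The map is linear in $f$: scaling all initial scores by $c>0$ scales
  every $r_j$ by exactly $c$ and leaves the ranking unchanged. A
  consequence worth knowing: the ranking is insensitive to the *global
  scale* of the evidence but not to affine shifts, so no additional
  normalization of $f$ is applied.
* $d = 0$ reproduces the raw $-\log p$ ordering exactly; $d = 0.5$ (the
  default) gives the association evidence and the network equal weight.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `d` | 0.5 | network weight; 0 = raw evidence only |
| `epsilon` | 1e-5 | one-norm convergence threshold of the iteration |
| `maxIter` | 1000 | iteration cap (a safety net: non-convergence below the cap is mathematically impossible for `d < 1` and is flagged as a defect) |
| `logBase` | 10 | base of the $-\log p$ transform |
| `pMin` | 1e-300 | lower clamp for p-values |

## The analysis universe and edge orientation

By default the ranking runs on the intersection of the scored genes and
the network nodes, with the network restricted to that universe — the
natural choice when the scan and the network come from different sources.
`keepUnscored = TRUE` instead retains all network nodes with $f = 0$,
letting purely topological evidence surface.

Ties in the final scores are broken by gene identifier in C-locale radix
order, so output files are identical across platforms and locales.

Edge orientation deserves care. The engine's convention is that an edge
$i \to j$ means "gene $j$'s phenotype-relevant signal depends on gene
$i$", and score flows *from* the depended-upon gene *to* its dependents.
Dependency networks in the wild are written in both conventions, and the
orientation of a given edge file usually cannot be recovered from its
metadata; `geneRank(..., transpose = TRUE)` flips every edge at
propagation time so both conventions are supported without rewriting
files.

# Constructing the dependency network (optional stage)

When no dependency network is available, `buildDependencyNetwork()` infers
one from an expression matrix plus a binary prognosis phenotype. The
procedure is a deliberate concretization chosen for this package — simple,
oracle-testable, and phenotype-anchored:

1. Expression rows are discretized by equal-frequency binning
   (`nBins = 3`); ties go to the lower bin, and rows with fewer distinct
   values than bins collapse (with a warning).
2. For each gene $j$, the plug-in mutual information
   $I(X_j; y)$ with the phenotype is tested by permutation of the
   phenotype labels only (`nPerm = 1000` shared shuffles, p =
   (1 + exceedances)/(nPerm + 1)); permuting labels preserves the
   gene–gene correlation structure under the null.
3. For each ordered pair $(i, j)$ with $j$ significant at `alpha = 0.05`,
   the edge $i \to j$ is drawn when conditioning on $X_i$ removes at least
   a fraction `tau = 0.5` of $j$'s phenotype information:
   $[I(X_j;y) - I(X_j;y\,|\,X_i)]\,/\,I(X_j;y) \ge \tau$.

The estimators are maximum-likelihood (plug-in) without bias correction:
with equal-frequency bins and the moderate sample sizes this stage
demands (at least 8 samples per class, realistically dozens), the bias is
shared between the marginal and conditional terms of the drop ratio, and
the plug-in form can be verified against exhaustive contingency-table
enumeration in the tests. Two limitations are documented rather than
patched: no multiplicity control is applied across the $O(N^2)$ ordered
pair tests (the per-pair `alpha` governs the marginal screen only), and
equivalence with any particular published dependency network cannot be
claimed — the procedure is this package's own.

# Validation statistics

* **2x2 chi-squared** (`chiSquare2x2()`): uncorrected Pearson statistic
  $N(ad-bc)^2/((a{+}b)(c{+}d)(a{+}c)(b{+}d))$ with 1 df. No Yates
  correction is applied — the uncorrected test is what the standard
  strategy-vs-reference comparisons in this literature report, and the
  corrected variant does not reproduce them. Zero marginals raise an
  error rather than returning 1.
* **Top-of-list KS** (`ksTopEnrichment()`): two-sample, one-sided on rank
  positions, $D = \sup_k[F_\text{targets}(k) - F_\text{background}(k)]$,
  with the asymptotic one-sided p-value $\exp(-2D^2 nm/(n+m))$. The
  statistic depends only on the ordering, so it is invariant under
  monotone transforms of the scores. A two-sided option delegates to
  `stats::ks.test`. One-sided was chosen because the scientific question
  — are known-drug targets concentrated *at the top* of the list? — is
  directional; the null simulations in the test suite confirm the
  one-sided p-values are super-uniform (conservative) at the sizes used.
* **Over-representation** (`overRepresentation()`): hypergeometric upper
  tail per gene set, BH-adjusted across the collection. The default
  universe is the analysis universe (the ranked genes), not the genome:
  enrichment claims should be relative to the genes the method could have
  chosen.
* Percentages (`overlapStats()`, `clinicalSupportRate()`) are reported to
  two decimals, matching reporting practice in this literature.

# Drug prediction

`predictAgents()` uses the inclusive one-hit rule: an agent is a candidate
when at least one of its targets lies in the prioritized gene set. This is
the weakest defensible rule and deliberately so — requiring multiple hits
would silently favor promiscuous agents, and the clinical-support
comparison (`compareSupport()`) between two strategies is meaningful under
any fixed rule as long as both arms use the same one. Clinical support is
an input flag (from user curation or the simulator), never scraped.

# The synthetic-data generators

`simulateAll()` emulates every input with a planted truth so that each
stage, and the chain of all of them, has a recoverable signal:

* **Scores**: planted disease genes (fraction `piDisease = 0.05` of
  `nGenes = 2000`) draw $p \sim \mathrm{Beta}(a, 1)$ with
  `betaA = 0.2`; null genes draw $p \sim U(0,1)$. Beta$(a,1)$ is the
  standard one-parameter enrichment model: $a$ alone controls the signal,
  and $a = 1$ recovers the uniform null exactly.
* **Network**: homophilous preferential attachment. Nodes arrive in random
  order; each draws `mEdges = 20` distinct neighbours among those present,
  with weight $(\text{in-degree}+1) \times$ `homophily` (= 8) when both
  endpoints are planted disease genes. This is the minimal generator
  giving both a heavy-tailed degree profile and a planted disease module.
  The attachment record "new gene chose existing gene" states that the
  *new* gene depends on the established one, while the propagation engine
  sends score from depended-upon genes to their dependents; the recovery
  benchmark therefore propagates with `transpose = TRUE` (see the
  orientation discussion above). The mean degree of 20 reflects the
  density typical of phenotype-anchored dependency screens, which retain
  far more edges than physical interaction maps; it also gives each gene
  enough in-flow for propagation to average over, which is what makes the
  planted module recoverable at all.
* **Reference database**: disease genes enter with probability
  `dbSensitivity = 0.8`, null genes with `dbFpr = 0.05` — an imperfect,
  contaminated registry rather than an oracle.
* **Drug targets**: `nAgents = 300` agents with `targetsPerAgent = 3`
  distinct targets; a fraction `piSupported = 0.2` is flagged clinically
  supported and draws targets with weight `supportEnrichment = 8` on
  disease genes. (The supported fraction is a generator-specific knob:
  some fraction of the simulated pharmacopoeia must carry support labels
  for support rates to be estimable; 0.2 approximates the coverage of
  clinical-activity annotation in curated drug–target registries.)
* **Expression/phenotype**: a balanced binary phenotype; a three-gene
  disease chain carries the signal (first gene mean-shifted by `effect`,
  downstream genes autoregressive on their upstream neighbour with
  coefficient 0.8); all other genes are standard normal.

Every generator is a pure function of (config, seed); stage seeds derive
from the config seed by fixed offsets, so individual stages are
independently reproducible and byte-identical on disk across runs.

## What the simulations do and do not show

The generators plant exactly the structure the method exploits — a
disease-gene module that is both score-enriched and topologically
assortative. Passing the recovery benchmark therefore demonstrates that
the implementation extracts a planted signal of realistic shape, not that
any particular real disease behaves this way. Real association data add
LD structure among gene scores, hub biases of curated networks,
ascertainment bias of reference databases, and target promiscuity of real
pharmacopoeias, none of which is emulated. The benchmark's two arms (the
propagated ordering vs the raw $-\log p$ ordering) and its
uninformative-network control (`homophily = 1`, where the two orderings
should perform within 0.02 AUROC of each other) are designed as a paired
falsification test of the propagation step specifically.

Problem sizes were chosen to exercise the asymptotics the statistics rely
on while staying comfortable on a laptop: the recovery benchmark runs 20
replicates of the 2000-gene condition, rank-engine equivalence is checked
on 100 random networks up to 200 nodes, the KS and permutation
calibrations use 500 and 200 null replicates, and exhaustive enumeration
oracles run on universes up to 30 genes.

# Numerical choices and degenerate inputs

* p-values of exactly 0 are clamped up to `pMin`, never rejected;
  negative p-values or values above 1 are errors.
* Self-loops are dropped (with a warning) at network construction: the
  score-splitting semantics is ill-posed for self-dependency. Duplicate
  edges collapse silently.
* Ranking ties break lexicographically (C locale); an empty score map
  yields an empty, valid ranked list.
* `converged = FALSE` (residual above `epsilon` after `maxIter` sweeps)
  triggers a warning — for `d < 1` it can only indicate an implementation
  fault, so it is surfaced loudly rather than absorbed.
* The one-norm residual is non-increasing across sweeps (a property of
  the contraction); the full residual trace is kept on the result object
  so this is checkable on every run.

# Known limitations

* The propagation assumes a *binary* dependency network; edge confidence
  weights are not supported.
* No teleportation term means score mass drains at dangling nodes; on
  networks dominated by sinks the propagated ordering approaches
  $(1-d)f$, i.e. the raw ordering.
* The dependency-inference stage is quadratic in gene count and intended
  for focused panels (hundreds of genes), not transcriptome-wide runs.
* KS p-values use the asymptotic one-sided bound; for very small target
  sets they are conservative.
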