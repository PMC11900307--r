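---
title: "Multiscale network diffusion for herb prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale network diffusion for herb prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

## The problem and the model

Herbal medicines act through many compounds hitting many protein targets at
once, so single-target screens miss most of what they do. `herbnet` ranks
herbs against a disease by comparing how the herb's targets and the disease's
genes each propagate through a *multiscale interactome*: a heterogeneous
graph joining

* an undirected protein–protein interaction (`pp`) layer,
* undirected protein–to–biological-function annotations (`pf`), and
* a directed child-to-parent function hierarchy (`ff`).

For any entity with a target set — a herb (union of its compounds' targets),
a single compound, or the disease — we compute a **diffusion profile**: the
stationary distribution of a biased random walk with restart (RWR) seeded at
those targets. Writing $s$ for the restart distribution (uniform over the
seeds by default) and $T$ for the one-step transition matrix, the profile is
the fixed point of

$$ p = r\,s + (1 - r)\,T^{\top} p, $$

with restart probability $r$. The walk is *biased* through five
class-transition weights — `w_pp`, `w_pf`, `w_fp`, and the hierarchy moves
`w_f_up` (child to parent) and `w_f_down` — so the move distribution at a
node divides its probability among neighbors in proportion to the weight of
each neighbor's class transition. Nodes with no outgoing mass (isolated
nodes, or all-zero weights toward their neighbor classes, which is an error)
hand their probability back to $s$, so $p$ is always a proper distribution.

Herbs are ranked by the **correlation score** between their profile and the
disease profile over the full node vector (proteins *and* functions):
entities influencing the same network regions correlate highly. Alongside
the correlation, each herb's target set is tested for direct overlap with
the disease genes by the hypergeometric upper tail
$P(X \ge k)$ with $X \sim \mathrm{Hypergeom}(N, K, n)$, and summarized by the
fold enrichment $(k/n)/(K/N)$.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `r` | 0.5 | restart probability; larger values localize the profile around the seeds (at `r = 1` the profile *is* the seed distribution) |
| `w_pp, w_pf, w_fp, w_f_up, w_f_down` | 1 | class-transition bias weights (dimensionless ratios; only relative size matters) |
| `tol` | 1e-6 | L1 convergence threshold of the power iteration |
| `max_iter` | 500 | iteration cap; exceeding it is an error, not a silent return |
| `min_components` | 3 | herbs with fewer target-linked compounds are dropped before ranking |
| `k` (mechanism) | 20 | per-profile top-k nodes fed into mechanism extraction |
| `lfc_min`, DEG `alpha` | 1.0, 0.05 | DEG thresholds; fold-change inclusive, adjusted p strict |
| similarity cutoff | 80 | external summary-score screen, inclusive |

Neutral bias defaults (`r = 0.5`, all weights 1) were chosen so that the
package's testable contracts — fixed-point residuals, conservation,
locality, Monte-Carlo agreement — hold independently of any tuning; the
weights are the knobs a user turns to emphasize, say, function-mediated
propagation (`w_pf > w_pp`). The package deliberately does not optimize
these hyperparameters.

## Ranking, overlap, and open choices

Several aspects of the statistic were genuinely open; the package fixes them
as follows and exposes the alternative where one is defensible:

* **Seed construction.** A herb's restart support is the union of *all* its
  compounds' on-network targets with uniform weights, not a top-50 list:
  union-of-targets is the only construction derivable from the catalog
  alone, and it keeps per-herb overlap denominators equal to the actual
  target counts. The per-herb pathway count (`pathway_count()`, the number
  of compounds hitting each target) and `top_targets()` remain available,
  and `prioritize(overlap_from_top_n = )` reproduces the capped variant of
  the overlap denominator.
* **Fold enrichment** is $(k/n)/(K/N)$ with both the marked-set size $K$
  (on-network disease genes) and universe $N$ (network protein count by
  default) explicit inputs.
* **Correlation method** defaults to Pearson on the full profile vector;
  Spearman is a flag.
* **Significance flag.** Herbs failing `p < alpha` are flagged, never
  dropped; `alpha >= 1` disables the flag.

## Enrichment statistics

Over-representation analysis follows the standard recipe: per term a
hypergeometric upper-tail p (computed through the survival function, log
capable), Benjamini–Hochberg adjustment across the library's tested terms,
and a **combined score** $-\ln(p)\cdot z$. The z-score uses the exact
hypergeometric null mean $nK/N$ and variance rather than a rank-based
empirical background: the empirical background would require precomputed
randomizations that are not reproducible from the inputs, whereas the exact
moments are. The combined score uses the raw p by default
(`combine_on = "adjusted"` switches), and a term blocklist of regular
expressions can exclude, e.g., sets explicitly tied to named diseases.

## Mechanism subnetworks

For a compound (or herb) and the disease, the mechanism subnetwork is built
from the top-`k = 20` most-visited nodes of each profile (seeds excluded by
default, ties broken by node id), the compound's targets, and the on-network
disease genes, with the induced multiscale edges plus anchor edges from the
compound and disease labels. Compound targets with no link to the disease
side are removed to a fixpoint. "Linked" is interpreted as *direct
adjacency* to any disease gene, disease top-k, or compound top-k node — the
minimal, deterministic reading — with a `link_hops = 2` variant behind a
flag; a target that is itself a disease gene always counts as linked. The
top node of each profile is flagged `critical`. Exports (GraphML, Cytoscape
JSON, TSV) serialize role and layer tags; GraphML is written as a directed
graph so anchor and hierarchy orientations survive a round-trip.

## The synthetic benchmark

`synthetic_config()` defines the desk-scale study conditions every test runs
under: 200 proteins in a connected preferential-attachment layer (m = 2,
linear attachment — biological interactomes are heavy-tailed), 40 functions
in a 3-level hierarchy with one or two parents per non-root term, Poisson(2)
annotations per protein, a connected 15-protein disease module densified to
internal pp density 0.30, and 20 herbs of 5 compounds with 4 targets each.
One planted herb draws each target "proximally" with probability
`p_in = 0.8`, decoys with `p_bg = 0.05`; all other draws are uniform.

A proximal draw picks a uniform disease-module gene and keeps it or steps to
one of its direct interactors with equal chance. This two-step draw is
deliberate: the module's full adjacency shell in a scale-free graph is
dominated by hubs, and sampling that shell uniformly spreads the planted
signal so thin that the benchmark stops discriminating planted from decoy
herbs — concentrating proximal draws on the module core and its first shell
is what makes the planted construction a meaningful positive control.
Setting `p_in = p_bg` is the matching negative control, under which the
planted label should be statistically invisible.

The DEG generator draws null genes from log2FC ~ Normal(0, 0.3) with uniform
p, and spikes 100 of 2000 genes at effect ≥ 2.0 with adjusted p below 0.009.
All randomness flows from one master seed through named substreams
(network / disease / catalog / deg), so each piece regenerates independently
and a fixture directory is byte-reproducible.

What the generator does *not* emulate: correlated annotation structure
(real GO terms are nested and redundant), degree-correlated target
ascertainment bias in compound–target databases, multi-module diseases, and
compound promiscuity distributions. Passing the planted-herb benchmark
therefore shows the pipeline recovers a graph-proximal signal under clean
conditions; it does not certify performance on literature-biased catalogs.

## Numerical choices

* Power iteration stops when the L1 change falls below `tol`; every profile
  additionally satisfies the fixed-point residual bound checked in the test
  suite. Non-convergence raises an error carrying the last residual.
* Profile entries below 1e-12 are clamped to zero after normalization for
  stable serialization; profile TSVs print 17 significant digits and
  round-trip exactly.
* All rankings break ties by entity/node id ascending, so every ordering in
  the package is total and deterministic.
* The Monte-Carlo walker (`mc_profile()`) simulates the chain literally in
  compiled code using R's RNG stream; it exists as an independent oracle for
  the power iteration and is never used in the analysis path.
* Degenerate inputs fail loudly: empty seed sets, zero-variance profiles,
  inconsistent hypergeometric counts, class-conflicting network files, and
  walkers trapped by all-zero weights are all errors with specific messages.

## Problem sizes in the test suite

The suite exercises the diffusion contracts on 20 random heterogeneous
networks of at most 30 nodes (with a 10^6-step Monte-Carlo comparison on
each), sweeps the hypergeometric oracle exhaustively for universes up to
N = 12, compares the BH adjustment against its brute-force definition on
1000 random vectors, and runs the planted-herb benchmark and its negative
control over 50 generator seeds each at the default conditions above. These
sizes were chosen so the whole suite completes in well under a minute per
module while still covering every contract.

## Known limitations

* The restart parameter and bias weights are consumed as given; no
  hyperparameter search is provided.
* Identifiers are opaque strings; harmonization to a common gene namespace
  is the caller's responsibility (a two-column mapping file is supported).
* Overlap p-values across herbs are reported raw, matching the ranked-table
  convention of reporting per-herb overlap tests; no across-herb
  multiple-testing correction is applied.
* Connectivity-map-style similarity scores are consumed from a table, never
  computed.
* The function hierarchy is traversed with direction-aware weights but no
  ontology semantics (no term namespaces, no obsolescence handling).
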