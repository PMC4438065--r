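---
title: "Anatomical network analysis: models, conventions, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomical network analysis: models, conventions, and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cranet)
```

## The model

`cranet` treats a skull as a binary, undirected, unweighted network:
nodes are bones, links are physical articulations (sutures and
synchondroses). The coding is a symmetric 0/1 adjacency matrix with zero
diagonal. Bone contacts are primary sites of bone growth and stress
diffusion, so the contact topology captures developmental and functional
co-dependences among bones independently of shape and size. Two
assumptions are enforced at validation rather than merely documented:
the graph is **connected** (a skull is one articulated unit; a
disconnected coding is a data error and raises an error, never a
warning) and entries are **strictly 0/1** (no suture-length weighting —
the model is purely topological). Paired bones carry `_l`/`_r` suffixes;
unpaired midline bones carry none. This labeling convention is load-
bearing: mirror-module detection and anchor-based module naming both
parse it.

## Module detection

Detection is deterministic and has three stages.

**Topological overlap.** The similarity between bones $i$ and $j$ is
$TO_{ij} = J(n_i, n_j) / \min_k(i,j)$: shared neighbors over the
smaller neighborhood. Its two boundary statements anchor the
convention: bones wired to all the same other bones must score 1, and
bones sharing no neighbor must score 0. The subtlety is whether the
pair itself counts toward the neighborhoods. The default
(`open_neighborhood`) excludes the pair from both numerator and
denominator, which is the only reading under which *mutually adjacent*
bones with identical remaining neighborhoods — exactly the situation of
left/right counterpart bones that meet at the midline — reach
$TO = 1$. Two alternatives are selectable: `raw_degree` (denominator
$\min(k_i, k_j)$ unadjusted) and `gtom1`, the generalized topological
overlap at one step, $(J + A_{ij})/(\min(k_i,k_j) + 1 - A_{ij})$,
included because it is the classic clustering-input TOM of the
coexpression literature. One degenerate case is fixed by convention: if
a pair-excluded neighborhood is empty (a pendant bone and its only
contact), the overlap is 0; the pendant simply joins late in the
dendrogram. Diagonal entries are defined as 1.

**Hierarchical clustering.** Bones are clustered on the dissimilarity
$1 - TO$ with average linkage (UPGMA) by default — the standard
companion of TOM-based module detection; complete and single linkage
are selectable for sensitivity analysis. The linkage is a genuine free
choice: nothing in the method pins it down, so the partition
configuration used is recorded in every result and in the study
report's provenance block.

**Q-scan over dendrogram cuts.** Every partition obtainable from the
dendrogram — all cluster counts $1..N$ — is scored with Newman's
modularity

$$Q = \frac{1}{2K}\sum_{i,j}\left[A_{ij} - \frac{k_i k_j}{2K}\right]
\delta(m_i, m_j),$$

the sum running over all ordered pairs including $i = j$; equivalently
$\sum_c (e_c - a_c^2)$. The $i=j$ inclusion is the standard reading and
is what makes the single-module partition score exactly 0; the
implementation is verified to $10^{-12}$ against the literal double sum
and against `igraph::modularity`. The search space is deliberately
restricted to dendrogram cuts — not free Q-optimization and not
stochastic community detection (Louvain, infomap, ...) — because the
method is a similarity-clustering procedure whose candidate partitions
come from the tree; this keeps the whole stage deterministic and
reproducible. Cuts are taken by cluster count rather than by height, so
every cardinality remains reachable when merge heights tie. Q ties are
broken toward fewer modules (tolerance $10^{-12}$), then lower cut
height. The summary statistic is $M = n_{\text{modules}} \times Q$,
which is 0 exactly when the best partition is the trivial single
module.

**Derived structure.** The two-cluster cut of the same dendrogram gives
the *macromodules* — in primates, the facial and cranial regions; the
report flags any connectivity module that straddles the first split.
Module pairs whose sided bones map onto each other under the l/r swap
are reported as *specular* (mirror) pairs, with midline bones inside
them flagged as arbitrarily assigned — an unpaired bone is equally
connected to both sides, so its side membership carries no signal.
Modules are named by anchor bones (occipital → neurocranial, ethmoid →
midfacial, all palatines → palatal, premaxilla → premaxillary, priority
in that order with conflicts logged); the names are positional
conveniences only and carry no developmental claim.

## Complexity

Five parameters: $N$ (bones), $K$ (contacts), density
$D = 2K/(N(N-1))$, mean clustering coefficient $C$, and degree
heterogeneity $H$. Two conventions deserve comment.

$C$ is the average over *all* bones of the Watts–Strogatz local
coefficient $c_i = 2\tau_i / (k_i(k_i-1))$, with $c_i = 0$ for bones of
degree < 2 — they are kept in the average (denominator $N$), not
dropped, so that "average over all nodes" means what it says.

$H$ is dispersion of the degree sequence relative to its mean. The
default is **population variance / mean**; the older anatomical-network
literature sometimes uses sd/mean (the coefficient of variation), and
published skull values (H ≈ 0.46–0.67 at mean degree ≈ 5.5) are
consistent with variance/mean, not sd/mean (≈ 0.3 on the same
networks). Both are implemented; the convention used is recorded in the
profile and the report, because the two are not comparable across
studies.

## The comparative stage

**Phylogenetic signal.** Abouheif's test uses a topology-only proximity
matrix: the weight between two tips is the reciprocal of the product of
the numbers of direct descendants of every internal node on the path
between them (MRCA included, tips excluded). Rows are normalized and
the statistic is the Moran-type autocorrelation
$C_{mean} = z^\top \tilde W z / z^\top z$ on the centered trait.
Significance comes from permuting trait values across tips; p-values
use the add-one convention $(b+1)/(m+1)$ and are exactly reproducible
given (seed, n\_perm). The default alternative is one-sided for
positive autocorrelation, the conventional direction for this test;
two-sided is selectable. Blomberg's K is provided as a second signal
test: observed over Brownian-expected ratio of the ordinary to the
phylogenetically corrected mean squared error around the GLS mean, with
the same permutation scheme. Both tests refuse constant traits and
mismatched tip sets.

**Contrast correlations.** The near-decomposability question — does
modularity promote complexity? — is tested by Pearson correlation of
Felsenstein's independent contrasts of M against each complexity
parameter. Because contrast signs are arbitrary, the correlation is
computed **through the origin** with $n_{\text{contrasts}} - 1$ degrees
of freedom; a with-intercept variant is available for sensitivity
analysis. The default p-value is two-sided: although the hypothesis
predicts positive correlation, negative correlations are a meaningful
outcome (they falsify the positive-feedback account), so a one-sided
default would prejudge the answer. Polytomies are rejected rather than
zero-resolved; trees for this analysis are expected to be fully
bifurcating. Contrasts themselves are delegated to `ape::pic` behind
strict validation; they are cross-checked in the test suite against a
hand-computed pruning recursion.

**The battery.** `run_study()` reports six signal tests (M, N, K, D, C,
H) and five correlations (M against each complexity parameter) with
**raw p-values** — no multiplicity correction, matching how such
batteries are conventionally reported; a Bonferroni column is printed
alongside, clearly marked as an extension, so readers can apply the
stricter criterion if they prefer. Taxa and tree tips must match
exactly; the pipeline aborts on a mismatch rather than silently
intersecting, because a dropped taxon changes every contrast. Summary
tables use type-7 (linear interpolation) quantiles, the convention of
R's `summary()`.

## The synthetic world

The generator exists so that every stage can be exercised and
calibrated without access to real codings. Its defaults are fixed to
the scale of adult primate skulls and are not tuning knobs:

* **9 bilateral pairs + 3–6 midline bones** → 21–24 bones, matching the
  observed range; the named bone set (`primate_bone_names()`) is the
  standard 14-bone complement (23 nodes with 5 midline bones).
* **target density 0.25**, the typical contact density of primate
  skulls (observed ≈ 0.22–0.30).
* Edges are sampled by **symmetry orbit**: a left-side contact is
  always mirrored on the right, a midline bone touches both members of
  a pair or neither. Orbits are activated in random order until the
  edge count reaches `round(target_density * N(N-1)/2)`, so the
  realized density lands on the target up to orbit granularity rather
  than fluctuating binomially. An `asymmetry_rate` (default 0) can
  break the mirror for robustness experiments.
* Disconnected draws are **repaired** by adding minimal bridging
  orbits (cheaper than rejection at low density); repairs are counted
  in an attribute.
* Planted layouts assign blocks to left-side units and sample orbits
  at within/between densities (defaults 0.9/0.05), giving ground-truth
  partitions for recovery tests.
* Yule trees are rescaled to unit height so signal-test calibrations
  are comparable across seeds; Brownian traits add independent normal
  increments with variance $\sigma^2 \times$ branch length.

What the generator does **not** emulate: real suture anatomy (which
bone can touch which), spatial embedding, allometry, or any
taxon-specific structure. A green recovery test therefore establishes
that the *algorithm* finds planted connectivity structure at skull
scale — not that real skulls have such structure, which only real
codings can show. Conversely the calibration tests (signal-test size on
white noise, BM variance, contrast-correlation type-I error) establish
that the statistical machinery has its nominal properties under the
model it assumes.

## Numerical choices

* Q tie tolerance $10^{-12}$; ties resolved toward fewer modules, then
  lower cut height.
* Dendrogram cuts by cluster count (`cutree(k = 1..N)`), robust to tied
  merge heights.
* TO of a pair with an empty pair-excluded neighborhood is 0.
* Permutation p-values: $(b+1)/(m+1)$, never exactly 0; with $m = 199$
  the achievable size at $\alpha = 0.05$ is exact.
* All generators run under an isolated, restored RNG state: calling
  them does not perturb the caller's random stream, and every seeded
  result is bit-reproducible.

## Limitations

* The exact TO variant and linkage behind published skull partitions
  are not recoverable from method descriptions alone; the
  convention × linkage grid is exposed precisely so users can calibrate
  against deposited matrices when they have them.
* M conflates module count and partition quality by construction; two
  skulls can share M with different organizations. Report Q and
  n_modules alongside, as the study report does.
* Abouheif's test ignores branch lengths entirely; Blomberg's K uses
  them fully. Disagreement between the two is informative, not an
  error.
* The through-origin reading of the contrasts correlation is an
  interpretive choice (the standard one for contrasts); the
  with-intercept variant quantifies its influence.
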