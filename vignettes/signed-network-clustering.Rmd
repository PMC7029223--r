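---
title: "Clustering signed association networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering signed association networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signetclust)
```

## The problem

Microbial association networks carry signed edges: taxa co-occur (positive
weight) or exclude one another (negative weight). Classical community
detection either ignores the sign, drops negative edges, or rescales them
away, losing the one piece of information that is robust across inference
tools. `signetclust` clusters signed weighted undirected networks so that
positive edges end up inside clusters and negative edges between them — the
"enemy of my enemy is my friend" reading of indirect effects: the indirect
effect of one node on another along a path is the product of the edge
weights, so a path through a single negative edge is a negative effect.

## Score-matrix diffusion

The weighted adjacency matrix $W$ (zero diagonal — input graphs are simple)
is iterated with three steps per round:

1. **Expansion**: $M \leftarrow M^2$, propagating indirect effects along
   paths of doubling length.
2. **Max-abs normalization**: $M \leftarrow M / \max|M|$. Unlike the
   column-stochastic normalization of Markov-chain clustering, this keeps
   every sign.
3. **Inflation**: $x \leftarrow x + 1/x$ on every nonzero entry, then
   normalize again. For $|x| \le 1$ this maps magnitudes into $[2, \infty)$
   with the sign preserved and the ordering compressed; under repeated
   rounds entries are driven to the fixed points $\pm 1$.

Convergence is declared when $100\,E \le \varepsilon$, where $E$ is the mean
*absolute* change over the nonzero entries since the previous round. The
error accumulator is absolute rather than signed: a signed sum would cancel
across oscillating entries and report convergence that never happened.

### Structural balance decides the route

A signed graph is structurally balanced when every cycle has a positive sign
product — equivalently (Harary), when its nodes two-color so that positive
edges stay within a color and negative edges cross. On balanced graphs the
diffusion converges, every entry reaching $\pm 1$ in the two-block pattern,
and no entry's sign ever conflicts with the adjacency matrix. On unbalanced
graphs the recurrence enters a *flip-flop* equilibrium and alternates
forever.

Rather than detecting flip-flops empirically, `is_balanced()` runs the
two-coloring test per connected component — deterministic, $O(V+E)$, and it
also produces a witness: the two-coloring when balanced, or a cycle with a
negative sign product when not. `cluster_signed()` routes on this test:
balanced graphs go through `converge_balanced()`, unbalanced graphs through
the subset consensus below.

### Unbalanced graphs: subset consensus

`score_unbalanced()` draws $K$ random subsets of
$\lceil F \cdot |E| \rceil$ edges. On each subset, balanced connected
components are iterated to convergence and their scores embedded at their
nodes' positions; the full subset matrix receives exactly **one**
expansion–inflation pass (a second would already reintroduce flip-flops),
and the two contributions are added and normalized. A consensus matrix keeps
a position only when more than $R \cdot K$ subsets agree on its sign, summing
the subset values there, and is finally normalized.

Two boundary choices are worth recording. The agreement test is strict
(`> R·K`) as specified by the count comparison, but unanimity always
qualifies — otherwise $R = 1$ could never be satisfied by any position.
And a subset whose matrix is entirely zero (possible when the sampled edges
isolate every node) is discarded with a warning, effectively reducing $K$;
if every subset degenerates, the run aborts with an explicit error rather
than returning an empty matrix.

### Oscillators

During flip-flop iteration the limits $\pm 1$ are approached only by a few
entries: an *oscillator* node's diagonal entry approaches $+1$ while some
entry in its row approaches $-1$; everything else oscillates near zero.
Because the alternating states reach their extremes at different iterations,
`detect_oscillators()` tracks per-node extrema across the whole trajectory
(the per-iteration snapshot can miss both) and flags nodes whose diagonal
maximum reaches $1 - \mathrm{tol}$ with a row minimum below
$-1 + \mathrm{tol}$. The tolerance defaults to 0.01; no value is prescribed
by the method itself, and the detected set is insensitive to it over a wide
range because the relevant entries sit hard against the limits.

## From scores to clusters

Rows of the scoring matrix are feature vectors: nodes in the same cluster
have near-identical rows. They are clustered by agglomerative Ward linkage
on Euclidean distances (`stats::hclust`, `ward.D2` — the Euclidean-distance
Ward variant, matching the common machine-learning implementation), cut at
each candidate $k$.

The cluster number is chosen by the **sparsity score**

$$s = \frac{1}{|N|}\left[\,|e_{w<0} \notin C| + |e_{w>0} \in C|
      - |e_{w<0} \in C| - |e_{w>0} \notin C|\,\right]$$

with $C$ the intracluster edge set and $N$ all edges: $s \in [-1, 1]$, $+1$
when every positive edge is internal and every negative edge cut, $-1$ for
the mirror image. The search range defaults to $k \in [2, 4]$ — the method
deliberately produces a small number of clusters separated by weakly
assigned nodes — with ties broken toward fewer clusters. Cluster ids are
relabelled canonically (decreasing size, then lexicographically smallest
member) so runs are stable under node permutation.

High scores accumulating on central nodes can split off tiny clusters.
Clusters below `minsize` (default 0.1) as a fraction of the node count are
dissolved: the remaining submatrix is re-clustered with the same
$k$-selection, and each removed node is attached to the retained cluster
with the highest mean shortest-path weight product. "Shortest" is
fewest-hop; when several shortest paths tie, the weight product is averaged
over all of them, consistent with how the mean edge product below treats
ties. This runs as a single pass, not recursively — a second dissolution
round could oscillate on adversarial inputs. If *every* cluster falls below
the threshold, the original assignment is kept with a warning.

## Weak assignments

For node $v$ and oscillator $t$, the **mean edge product** averages, over
all fewest-hop paths from $v$ to $t$, the product of edge weights scaled by
the graph's maximum absolute weight:

$$P_{v,t} = \frac{1}{|n|}\sum_{i=1}^{|n|} \delta_i(v,t).$$

Node $v$ is flagged *weak* when, for some oscillator $t$ in its own cluster,
(i) $P_{v,t} \le 0$, or (ii) $|P_{v,t}|$ falls below the `edgescale`
threshold. Criterion (ii) uses the absolute value: the sign of the evidence
is criterion (i)'s job, the threshold asks only whether the evidence is
*weak*. With several same-cluster oscillators, any single trigger flags the
node (the conservative reading). When no oscillator shares $v$'s cluster,
criterion (ii) is not evaluated by default; `all_oscillators = TRUE` extends
it to every oscillator for users who want the stricter filter. Flags
annotate the membership — no node is ever removed — and the flagged set is
monotone nondecreasing in `edgescale`, since criterion (ii) is a threshold.

Defaults: `edgescale = 0.8` is the conservative default for well-resolved
networks; 0.3 is the preset for noisy benchmark networks, where the default
flags nearly everything. Balanced graphs have no oscillators, hence no weak
flags — the balanced route is the confident regime.

## Robustness by rewiring

`cluster_robustness()` rewires a fraction of edges by double-edge swaps
(edges $a\!-\!b$, $c\!-\!d$ become $a\!-\!d$, $c\!-\!b$): every node keeps
its degree exactly, weights travel with their edges, and swaps creating
self-loops or parallel edges are rejected. Each of `n_replicates` rewired
replicates is re-clustered end to end; agreement with the original
assignment is summarized as percentile confidence intervals of Jaccard
similarities — per cluster (best-matching replicate cluster, original →
replicate direction only) and per node (overlap of co-member sets). Swap
count is `round(fraction·|E|/2)`, so a vanishing fraction is an exact
identity and all intervals collapse to $(1, 1)$. Defaults — 100 replicates,
95% percentile intervals, fraction 0.1 — are conventional choices; the
method itself prescribes only "a fraction" and "a confidence interval".
Weak nodes stay in the member sets by default (`exclude_weak` switches them
out). Note that on very dense graphs few legal swaps exist; the achieved
fraction is reported in a warning when the budget cannot be met.

## The synthetic benchmark

### gLV generator

`generate_glv()` emulates a community of $n$ species under generalized
Lotka-Volterra dynamics $\dot x = x \circ (b + A x)$ across environmental
conditions:

* **Interactions** $A$: off-diagonal entries present with probability
  `connectivity` (default 5%), values $\mathrm{U}(-0.5, 0.5)$, diagonal
  $-1$ (self-limitation). Interactions subordinate to self-limitation keep
  most random communities feasible; matrices that still cause population
  explosions are regenerated (budget 100).
* **Environment**: three factors with strengths $|\mathcal N(3,1)|$; per
  condition one factor is positive and the rest negative, the positive slot
  rotating so each condition's cumulative effect vector is unique. Each
  factor touches a random 30% of species (effects $\mathcal N(1,1)$);
  species untouched by all factors keep a base growth rate
  $\mathrm{U}(0,1)$ in every condition.
* **Samples**: 50 per condition, each the endpoint of a fixed-step Euler
  integration ($\Delta t = 0.02$, horizon 5 — a few multiples of the $O(1)$
  growth timescale) from independent random initial abundances, with an
  extinction floor at 0 during integration and a threshold of $10^{-6}$ at
  the endpoint. Initial-condition variation is what gives within-condition
  variability; endpoints are near steady state without being identical.

The factor-subset structure matters: species loaded on the factors form a
dense, environmentally induced signed core in the inferred correlation
network (about half the significant edges negative), while unaffected
species correlate only through the sparse interaction matrix and attach as
a weak periphery. That combination — dense core, connectivity-1 periphery —
is what distinguishes interaction-driven networks from the bicluster
networks below, and it is emergent, not imposed. Ground truth is K-means on
the species abundance profiles with $k$ = number of conditions (10
restarts, seeded).

### Bicluster generator

`generate_biclusters()` plants additive signal blocks (positive feature and
sample loadings) on a Gaussian background, each block active in its own
window of samples; features of one block co-vary positively and features of
blocks with disjoint activity windows anti-correlate, so signed structure
exists without any interaction topology. The matrix is shifted by its
minimum to keep abundances nonnegative — Pearson and Spearman correlations
are invariant to the shift. Networks inferred from these data are far
denser than the gLV networks (there is no sparse periphery to attach).

### Inference, noise, evaluation

`infer_network()` keeps Pearson (or Spearman) correlations with two-sided
$p < \alpha$ (default 0.05) via the $t$ approximation on the correlation
coefficient; constant rows are excluded with a warning. Noise operations
reproduce the benchmark's stress tests: `permute_fraction()` shuffles a
chosen fraction of matrix cells (globally by default, with per-row and
per-column variants as a switch), `add_multinomial_noise()`
resamples each sample from a multinomial with total = 1000 × the original
sample sum, and `shift_weights()` maps weights affinely from $[-1,1]$ to
$[0,1]$.

`evaluate_clusters()` scores predictions against truth through the
contingency matrix: complex-wise sensitivity Sn, cluster-wise positive
predictive value PPV, their geometric mean Acc, and the overlap-penalizing
separation Sep (geometric mean of row- and column-normalized products — a
perfect assignment scores 1 on all four). Weak nodes count as unassigned
and leave the table. Assignments with one cluster above 80% of assigned
nodes or more than 50 clusters are flagged pathological rather than scored
at face value.

### What the benchmark does and does not show

Passing tests on these generators shows the pipeline recovers planted
signed structure under correlation noise, partial observation (subset
consensus), and degree-preserving perturbation. It does **not** show
performance on real data: the generators have no compositionality (no
sum-to-one constraint), no sequencing depth variation except the explicit
multinomial option, no temporal autocorrelation, and truth labels come from
K-means on abundances, which is itself an approximation of "environmental
response group". The problem sizes used in the tests (100 species, 50
samples/condition, 10-replicate ensembles) are the package's chosen
defaults for a desk-scale benchmark.

## Numerical choices and degenerate inputs

* Entries with magnitude below $10^{-12}$ are treated as zero before
  inflation: subnormal survivors of repeated squaring would otherwise send
  $1/x$ to infinity during flip-flop iteration. They carry no usable sign
  at that magnitude.
* An all-zero matrix anywhere in the diffusion is an explicit error
  (degenerate state), as is an edgeless input graph or a consensus in which
  no position reaches agreement.
* Zero-weight edges are dropped at construction (no sign information);
  duplicate edges with conflicting weights are an error naming the pair —
  averaging could silently flip a sign.
* All randomness (subset sampling, rewiring, generators) flows from
  explicit integer seeds; identical seeds give bit-identical results, which
  the tests assert.

## Limitations

Networks with few or no negative edges are outside the design envelope: the
sparsity criterion then mostly separates central from peripheral nodes, and
`select_assignment()` says so in a message. Directed graphs are not
supported — the diffusion degenerates toward zero on them. The dense
scoring matrix costs $O(n^2)$ memory and $O(n^3)$ per squaring, and unlike
Markov-chain clustering no pruning is possible, because intermediate
matrices grow denser as entries head to $\pm 1$; networks of a few thousand
nodes are the practical ceiling.
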