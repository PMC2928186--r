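---
title: "Measuring cross-species expression divergence: models, distances and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cross-species expression divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exdiv)
```

## The problem

When the same set of tissues is profiled in two species, every pair of
one-to-one orthologs yields two expression vectors over homologous
tissues, and their dissimilarity — the *expression divergence* — can be
treated as an evolving phenotypic trait. There is no canonical distance
for this comparison, and different measures respond to different signals:
a Euclidean distance between profiles reacts to uniform coordinate-wise
differences, while a correlation-based distance reacts to the absence of
*concerted* changes and ignores expression level altogether. `exdiv`
implements the standard transforms and four distance measures, tools to
compare their behaviour (tissue clustering, empirical nulls,
moment-based family selection, entropy analysis), and a synthetic
two-species generator so that every claim can be tested against known
ground truth.

## Transforms

Raw intensities are not comparable across species: array platforms
impose species-wide intensity shifts (emulated by the generator's
`species_shift`). All analyses therefore start from per-gene transforms
of the linear-scale intensities $x^A_{ij}$ of gene $i$ in tissue $j$:

* **Relative expression** $x^R_{ij} = x^A_{ij} / \sum_j x^A_{ij}$: each
  row sums to one, removing gene- and species-level scale. Defined only
  when every gene has a positive total, which the package enforces with
  a named error.
* **Binary transform** $x^B_{ij} = 1$ if $x^A_{ij} \ge \bar{x}^A_i$,
  else 0, thresholding each gene at its own mean. Ties at the mean map
  to 1, so a constant (housekeeping-like) profile becomes all ones and a
  row can never be all zeros — the maximum is always at least the mean.
* **Expression entropy** $H_i = -\sum_j p_j \log_2 p_j$ with $p$ the
  relative-expression row: 0 bits for single-tissue expression,
  $\log_2 n$ bits for perfectly uniform expression over $n$ tissues.
  This is the usual operationalization of "uniformly expressed", and the
  entropy analysis below probes where it misleads.

Both matrix transforms are invariant to positive per-row rescaling, which
is what makes the species shift harmless downstream.

## Distance measures

For a gene's relative-expression vectors $u, v$ in the two species:

* **Euclidean** $d_E = \sqrt{\sum_j (u_j - v_j)^2}$;
* **correlation-based** $d_{cor} = 1 - r(u, v)$ with $r$ the Pearson
  correlation, in $[0, 2]$ (negative correlations are kept, not
  truncated), undefined for zero-variance profiles.

For binarized vectors with one-counts $m$, $n$ and scalar product
$X_{mn}$, the **generalized-average (GA) family** is

$$ d_{A\lambda} = 1 - \frac{X_{mn}}{B_\lambda}, \qquad
   B_\lambda = \left( \frac{m^\lambda + n^\lambda}{2} \right)^{1/\lambda}, $$

the power mean of the one-counts with exponent $\lambda$. Members
include Simpson ($\lambda \to -\infty$, $B = \min(m,n)$), Ochiai/cosine
($\lambda = 0$, the geometric-mean limit, where the printed formula is
indeterminate), Dice ($\lambda = 1$) and max-overlap
($\lambda \to +\infty$). Because
$X_{mn} \le \min(m, n) \le B_\lambda$, GA distances lie in $[0, 1]$ and
are non-decreasing in $\lambda$ (the power mean is non-decreasing in its
exponent). The binary correlation distance $d^B_{cor}$ completes the set
of four measures.

Numerical choices: for $|\lambda| \le 100$ the power mean is evaluated
directly; beyond that the larger (or, for negative $\lambda$, smaller)
one-count is factored out so `m^lambda` never overflows, keeping the
family usable at any finite exponent. Note that convergence to the
infinite limits is slow — $B_\lambda$ differs from $\max(m,n)$ by a
factor $2^{-1/\lambda}$, about 1.4% at $\lambda = 50$ — so the $\pm\infty$
members are implemented as their own exact cases rather than by a large
finite exponent. Undefined pairs (zero-variance profiles, empty binary
vectors) are excluded and counted, never imputed: an imputed distance
would distort the moment statistics driving family selection.

## Selecting a GA exponent

An empirical criterion for a well-performing member of a distance family
is that its pair-distance distribution has extreme third and fourth
moments. `scan_ga_exponents()` computes, for each $\lambda$ on a grid
(default $-\infty, -10, -5, -2, -1, 0, 1, 2, 5, 10, +\infty$, with
$d^B_{cor}$ appended as a comparator), skewness $g_1 = m_3/m_2^{3/2}$ and
excess kurtosis $g_2 = m_4/m_2^2 - 3$ under the biased (divide-by-$N$)
central-moment convention — the bias correction cannot change the ranking
of equal-$N$ distributions, but the convention is recorded in the run
summary. The scan reports *all* extremes (minimum skewness, minimum and
maximum kurtosis) with ties listed rather than broken: the criterion is a
heuristic, and which extreme is canonical is genuinely ambiguous. On
default synthetic data the scan selects the $\lambda \to \infty$ member by
skewness and the binary correlation by kurtosis.

## Tissue clustering

A good divergence measure should make homologous tissues of the two
species — not same-species tissue pairs — nearest neighbours.
`sample_distance_matrix()` builds the $2T \times 2T$ dissimilarity matrix
over all cross-species tissue samples: transforms are applied per gene
(they are defined across tissues) *before* extracting sample columns, and
the relative transform is used for the Euclidean and correlation panels,
a choice recorded in the run summary. `average_link_cluster()` then runs
unweighted average-link (UPGMA-style) agglomeration, implemented directly
so that tie-breaking is deterministic (lowest (smaller, larger) position
pair in the current cluster ordering, merged clusters taking their first
member's slot) and trees are bit-reproducible; merge heights are monotone
by the structure of average linkage, and the implementation is
cross-checked in the tests against both a naive re-averaging agglomerator
and `stats::hclust`.

Recovery is scored by `homologous_pairing_score()`: a tissue counts as
correctly clustered only when its two species samples form a **cherry**
(two-leaf clade). The looser "share a small clade" reading would credit
patterns like `((thymus@rat, spleen@rat), thymus@human), spleen@human` in
which no homologous pair is actually each other's nearest neighbour, so
the strict criterion is used. On synthetic data with full conservation
and mild noise, all 8 tissues are recovered under every measure, and the
score decays as the conservation parameter drops; the species shift
cancels exactly under all measures because every transform is row-scale
invariant.

## The random-pair null and conserved calls

Expression conservation is defined against an empirical null: distances
between randomly re-paired cross-species genes. `generate_random_pairs()`
permutes the species-2 column and rejects any permutation with a fixed
point — at $n \approx 3000$ a plain permutation has one true ortholog
left in place on average, which would contaminate the null.
`build_null()` takes the lower-tail nearest-rank quantile (the
$\lceil \alpha N \rceil$-th smallest) as the significance threshold:
conserved means unusually *small* distance, so the lower tail is the only
coherent reading, and nearest-rank avoids interpolation ambiguity. A pair
is called conserved when its distance is $\le$ the threshold (boundary
values are called). Raising $\alpha$ can only add calls.

What the measures call conserved differs systematically.
`call_conserved()` therefore records each called pair's mean absolute
(untransformed) expression — level information the relative transform
erases — and `contrast_called_sets()` compares two called sets by median
mean expression and coefficient of variation, attaching a Wilcoxon
rank-sum statistic as a descriptive, not inferential, quantity. On the
default synthetic mixture the Euclidean-called set is dominated by
uniform low-expression background genes while the correlation-called set
consists of conserved tissue-specific genes at much higher levels:
Euclidean conservation is cheap for profiles pinned near a flat
background, whereas correlation demands concerted structure.

## Entropy and "uniform expression"

Selecting the upper quartile of the entropy distribution
(`upper_quartile_entropy_genes()`, exactly $\lceil N/4 \rceil$ genes,
ties resolved by stable gene order — 788 genes of 3152) nominally selects
"uniformly expressed" genes. But entropy ignores variance: a gene can be
expressed everywhere yet fluctuate without cross-species concert. On
synthetic data where housekeeping genes' tissue effects are pure
species-independent noise, the high-entropy quartile shows *higher* mean
correlation distance (no concerted changes to share) and *lower* mean
Euclidean distance (both profiles hug uniformity) than the remaining
genes — high entropy is not conserved uniform expression.

## The synthetic generator

`generate_paired_expression()` simulates, on the log2 scale,

$$ y_{s,i,t} = b_i + \delta\,[s{=}2] + c_i e_{i,t} + (1 - c_i) e'_{s,i,t}
   + \varepsilon_{s,i,t}, $$

returning $2^y$ so that the relative transform (a ratio of linear
intensities) is well defined. Genes belong to three classes —
tissue-specific (a bump of `tissue_effect_size` at a target tissue),
housekeeping (uniform, moderately high) and background (uniform, low,
near the noise floor) — with exact class counts assigned by block and
shuffled by seed. The conservation weight $c_i$ interpolates between a
fully shared tissue-effect profile and an independently drawn per-species
profile of the same construction.

Defaults define the reference study conditions: 3152 genes over 8
tissues (the scale of the human/rat compendia this design mirrors),
class fractions 0.4/0.2/0.4 (specific/housekeeping/background), class
baselines 8/8/4 log2 units with a per-gene SD of 1 (background sits near
a typical array noise floor around $2^4$), tissue effect 4 log2 units (a
16-fold tissue bump), per-class conservation 0.8/1/0 (tissue-specific
programs largely but not fully shared; background unconserved),
species shift 1 log2 unit (the magnitude of a typical between-platform
intensity shift) and measurement noise 0.25 log2 units (residual
post-normalization noise). These values were fixed once as a realistic
regime; they are the conditions under which the package's distributional
claims are tested, not tuning knobs.

What the generator does **not** emulate: probe-level effects and
RMA-style normalization artefacts, replicate arrays, correlated noise
between tissues, multi-tissue expression programs, or intensity-dependent
noise variance. Passing tests therefore show that the measures behave as
described under a clean additive log-normal model — not that any
particular count from real arrays will reproduce.

## Known limitations

* **Discreteness of binary measures on few tissues.** Over 8 tissues a
  binarized profile takes at most 255 states, so GA and binary
  correlation distances are discrete with large atoms; in particular
  random tissue-specific pairs share their binarized target tissue with
  probability about $1/8$, putting an atom of mass $> 1\%$ at distance 0.
  No threshold rule can then realize an exact 1% call rate: calling
  against the empirical null at $\alpha = 0.01$ yields roughly 1.6–1.7%
  of an independent derangement for the binary measures, while the
  continuous measures calibrate correctly. This is a property of
  binarized small-dimension profiles, not of the implementation, and the
  corresponding acceptance check is intentionally left failing for the
  binary measures as an honest record of it.
* GA and correlation distances are dissimilarities, not metrics; no
  triangle-inequality guarantees are made or used.
* The cherry criterion is conservative: biologically defensible coarser
  topologies score 0 by design.
* Moment-based exponent selection is heuristic; the scan reports
  extremes and ties but performs no hypothesis test on moments.

## A worked run

```{r example, eval = FALSE}
sim <- generate_paired_expression(synthetic_config(seed = 11))
res <- run_divergence_analysis(sim$expr1, sim$expr2, sim$pairs,
                               alpha = 0.01, seed = 12)
unlist(res$summary$pairing_scores)
unlist(res$summary$conserved_counts)
res$scan$selection
res$contrast$median_diff
```

The problem sizes used throughout the test suite — 3152 genes, 8
tissues, 20 replicate seeds for directional claims, the full $255^2$
enumeration of length-8 binary pairs for the GA oracle — match the
reference study scale and keep every check exact or tightly seeded.
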