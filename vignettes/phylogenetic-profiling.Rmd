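---
title: "Predicting protein linkages from phylogenetic profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein linkages from phylogenetic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloprof)
```

## The idea

Proteins that work together — subunits of a complex, members of a pathway —
tend to be gained and lost together over evolution. A *phylogenetic
profile* records, for one protein, which of a panel of fully sequenced
organisms carries a homolog: a 0/1 vector over species, or a vector of best
BLAST bit scores when more resolution is wanted. Pairs of proteins with
correlated profiles are candidate functional partners, without any need for
co-expression or interaction data.

`phyloprof` implements the full desk workflow: building profiles from
tabular homology searches, scoring pairs with co-occurrence measures,
tree-aware Dollo parsimony distances and two bit-score normalizations,
predicting whole-proteome linkages by per-protein top-rank selection, and
benchmarking any of these scorers against complex-derived reference sets
with ROC/PR machinery. A seeded simulator with planted co-evolving modules
makes every stage testable end to end with no external downloads.

## Profiles

`build_binary_profile()` marks protein $i$ present in species $j$ when some
hit has E-value $\le t$; the cutoff is inclusive because it is a
user-facing threshold and inclusive boundaries are the least surprising
choice. The usual cutoffs are $10^{-3}$ (default), $5\times10^{-4}$ and
$10^{-4}$; presence is monotone in $t$ by construction.
`build_bitscore_profile()` keeps the *maximum* bit score per
protein/species cell — the best-hit convention of profiling methods.
Proteins with no qualifying hit anywhere are retained as all-zero rows and
flagged (`empty_proteins`), so each downstream measure can define its own
behavior for them rather than having rows vanish silently. If the query
organism itself is in the species catalog its column is kept as-is
(self-hits make it all-ones); drop the column before scoring if that is
not wanted.

## Co-occurrence measures

For binary vectors $X, Y \in \{0,1\}^n$:

* **Jaccard** $J = |X \cap Y| / |X \cup Y|$, with $J := 0$ for two all-zero
  vectors: absent proteins share no evidence of co-evolution, so the $0/0$
  case must not score as a perfect match.
* **Pearson** — the sample correlation coefficient ($n-1$ denominator),
  which on 0/1 data reduces to the phi coefficient
  $(n\,n_{11} - r_x r_y)/\sqrt{r_x(n-r_x)\,r_y(n-r_y)}$. We compute it from
  these integer counts: the prediction filter below requires *strictly*
  positive correlation, and the count form keeps the sign of an exactly
  zero correlation exact instead of leaving it to summation rounding. A
  constant vector has no defined correlation; the `NA` flag it returns is
  treated as "fails $cor > 0$" by every consumer rather than poisoning
  downstream arithmetic.
* **Mutual information** in bits (base 2; the base rescales but never
  reorders pairs), over empirical symbol frequencies with $0\log 0 = 0$.
  Note MI cannot distinguish correlation from anti-correlation: perfectly
  complementary profiles score exactly as high as identical ones.
* **$L_p$ distance** $(\sum_i |x_i-y_i|^p)^{1/p}$; $p=1$ is the Hamming
  distance. On binary data $L_1 = L_2^2$ exactly, which the tests exploit.

`pairwise_measure()` evaluates any of these on all pairs at once from the
co-presence count matrix, so whole-proteome matrices need no pair loop.

## Dollo parsimony

A tree-aware alternative: a character that is present in a set of leaves is
assumed to have been *gained once* — at the most recent common ancestor of
the presence leaves — and lost any number of times (Dollo's law; sensible
for eukaryote-dominated panels where horizontal transfer is rare).
`dollo_reconstruct()` produces the unique minimum-loss assignment: a node
is in state 1 exactly when it is the gain node or a descendant of it whose
subtree still contains a presence leaf. The distance between two proteins
is the branch-wise disagreement of their gain/loss dynamics
$\sum_{b} |(anc(x_b)-desc(x_b)) - (anc(y_b)-desc(y_b))|$, i.e. how often
one character changes on a branch where the other does not.

The input tree must be rooted: the reconstruction (and hence the distance)
changes with the rooting, so that choice is left as the user's explicit
act. Multifurcations are handled natively. Species present in the profile
but absent from the tree are dropped (with a message) before scoring.
Because Dollo output is a distance, ranking and ROC machinery use
similarity $= -$distance.

## Bit-score normalizations

Two normalizations replace the binary profile with processed bit scores
before scoring:

**NPP** — floor every score below 70 to 1; drop proteins with fewer than
12 species at or above the floor ("poor conservation"); take
$\log_2(p_{ij}/p_{\max i})$ per row; z-score each species column (sample
SD). Scored by pairwise Pearson. The homolog count uses *raw* scores,
before the floor replacement: counting after it would hinge on the
sentinel value 1 being distinguishable from genuine low scores, an
ambiguity the raw count removes. Columns with zero spread carry no signal
and are zeroed with a warning rather than producing division by zero.

**SVD** — floor below 60 to 0; scale rows by their maximum (all-zero rows
cannot be scaled and are dropped); factor $P = U\Sigma V'$; keep the first
$\lceil \text{trim} \cdot m \rceil$ columns of $U$ (common settings: 100%
and 30%); apply the same conservation filter; scale each retained row to
unit Euclidean norm. Scored by pairwise Euclidean distance, which on unit
rows lies in $[0,2]$ with $d^2 = 2 - 2\,u\cdot v$. Normalizing *rows* over
the retained singular dimensions is the one reading of the final step that
keeps this geometry; the conservation filter runs after trimming so the
factorization itself is unaffected by it. One numerical caveat: columns of
$U$ belonging to zero singular values are an arbitrary orthonormal basis
of the null space, so on (near-)rank-deficient inputs only the leading
dimensions are meaningful — another reason the trimmed variant is the
default (`trim_fraction = 0.3`).

## Top-rank prediction

Thresholding a score globally leaves "solo" proteins — at stringent
cutoffs many proteins lose all partners. The top-rank predictor avoids
this: for each protein, candidates with strictly positive Pearson
correlation (negative correlation means presence of one co-occurs with
absence of the other — not a functional link under any evolutionary
reading) are ranked by decreasing Jaccard similarity, and the top $T$ are
linked. Ties are broken by decreasing Pearson, then identifier, making the
ordering total and the output deterministic. A protein whose filtered list
is empty still receives its single best-Jaccard partner, flagged
`fallback` so it can be excluded when only filter-passing links are
wanted. Directed selections are symmetrized (direction is meaningless for
a co-evolution link); each pair keeps the better of its two directed
ranks.

Whether "top $T$" means rank $\le T$ or rank $< T$ is genuinely open in
the method's usual description; we default to $\le$ (1-based), so that
$T = 1$ selects exactly the best partner, and expose
`rank_convention = "lt"` for the strict reading. Both are tested against
brute force. Predicted link sets are nested in $T$, every protein appears
in at least one link for every $T \ge 1$, and a typical proteome-scale
setting is $T = 400$.

## Reference sets and curves

`build_reference()` turns a complex-membership table into labelled pairs:
positives are all intra-complex pairs (optionally excluding complexes with
more than, say, 40 subunits, which otherwise dominate the positive pool);
negatives are sampled uniformly without replacement among pairs that share
no complex and whose complexes share no subcellular-localization label
(the constraint applies at the complex level). Any pair that is a positive
anywhere is excluded from the negative pool outright, which resolves the
ambiguity for proteins belonging to several complexes without label
contradictions. The sampler requires an explicit seed and errors — rather
than silently capping — when the eligible pool cannot supply
`round(ratio × positives)` negatives. The default ratio is 10:1.

`evaluation_curve()` sweeps every distinct score as a relaxed threshold
(tied pairs flip together), deriving FPR $=1-\mathrm{TN}/N$, TPR
$=\mathrm{TP}/P$, precision and recall; precision at zero predictions is
recorded as `NA` and skipped in PR plots. AUC is the trapezoid over the
achieved ROC points anchored at $(0,0)$ and $(1,1)$ — no further
interpolation — and equals the Mann–Whitney statistic in the absence of
ties (a property the tests verify against both a rank-statistic oracle and
pROC). For the top-rank predictor the sweep variable is $T$ itself;
nestedness makes the whole sweep computable from one prediction at
$T = n-1$. `hit_rate()` and `geneset_coverage()` give the two summary
fractions used to compare predictions with an external co-evolving pair
list and with pathway edge lists.

## The simulator and what it does (not) show

`simulate_profiles()` plants co-evolving modules: species are partitioned
into clade blocks; each module draws a clade-structured base pattern (a
clade is occupied with probability 1/2; species presence is then Bernoulli
at 0.95 in occupied clades and 0.05 elsewhere, so patterns show the
clade-wise runs of real profiles rather than i.i.d. noise — which also
gives the tree-aware Dollo route signal and keeps NPP's column z-scores
non-degenerate); members copy their module's pattern with symmetric
per-entry flips at `flip_noise`, the simplest mechanism that exercises
both false presence and false absence. Defaults — 3 modules of 6 proteins,
6 background proteins, 60 species in 6 clades, noise 0.1 — are small
enough that every route runs in seconds yet large enough that scorers
separate from chance. `simulate_bitscores()` layers truncated-normal bit
scores (mean 150, SD 40, floor 25) on present entries, spanning both sides
of the 60/70 normalization floors. `simulate_tree()` grows a random rooted
bifurcating tree by sequential coalescence with clades kept monophyletic,
and `truth_to_reference()` maps modules to complexes (localization = the
module label) so planted truth plugs straight into the benchmark
machinery; its default negative ratio is 2:1 because the cross-module
candidate pool at this scale cannot support 10:1. All randomness descends
from one user-supplied seed.

At zero noise the predictor recovers the planted modules exactly
(precision = recall = 1 at $T = \text{module size} - 1$), and mean AUC
degrades monotonically with noise (paired seeds across noise levels). Two
real-data features are deliberately *not* emulated, and they bound what
passing tests show. First, real profiles over ~10³ species have strongly
heterogeneous row densities and correlated species columns; at 60 species
with well-separated module patterns, even plain Hamming distance is near
its AUC ceiling, so method *rankings* measured here do not transfer —
in particular, the relative weakness of raw $L_p$ distances on proteome
data (where density confounds them) is not reproduced at this scale.
Second, modules here are disjoint; real pathways mix several evolutionary
modules, which is exactly where co-occurrence methods miss true links.

## Numerical choices, in one place

* Strict floors, as specified: bit score $< 70 \to 1$ (NPP), $< 60 \to 0$
  (SVD); trimming count $\lceil \text{trim}\cdot m\rceil$; sample ($n-1$)
  SDs everywhere.
* Strictly positive correlation for the prediction filter; $cor = 0$ and
  undefined both excluded; exact-integer numerators make the boundary
  deterministic.
* Jaccard $0/0 := 0$; MI clamped at 0 against $-0$ rounding.
* Tie handling: measure ties sweep as one threshold; ranking ties broken
  (Jaccard, Pearson, identifier) so results are reproducible bit for bit.
* Seeds are required arguments wherever randomness exists, and the RNG
  state of the calling session is always restored.

## Problem sizes used in the checks

The shipped tests run the measure oracles on 200 random pairs (length
$\le 16$), exhaustive Dollo search on every rooted bifurcating topology
with up to 5 leaves (plus random 6-leaf and multifurcating trees) over all
leaf patterns, brute-force prediction on 50 random profiles ($n \le 12$,
$m \le 20$) under both rank conventions, and 20-seed AUC panels on the
default simulation — sizes at which the independent oracles are exact and
the whole suite stays fast.
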