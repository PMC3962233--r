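---
title: "Methods: multivariate models behind jamuda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivariate models behind jamuda}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jamuda)
```

## The data model

A Jamu formulary is three binary tables sharing axes: the formula × plant
incidence matrix $X$ ($I \times J$, $x_{ij} = 1$ when formula $i$ lists
plant $j$), a single efficacy class per formula over $L$ classes
(dummy-coded into $Y$, $I \times L$, rows summing to one), and a plant ×
activity annotation $A$ ($J \times K$). The three-way predictor is their
product, $x_{ijk} = x_{ij} a_{jk}$. Mixing ratios are deliberately absent:
registrations state ingredient lists only, so presence–absence is the
honest resolution, and we keep all-zero plant columns (with a message)
so the plant axis stays aligned with $A$.

Unfolding concatenates the $K$ frontal slabs activity-major: column
$(k-1)J + j$ of the $I \times JK$ matrix holds plant $j$ under activity
$k$. This pairing is what makes the trilinear score identity
$t_i = \sum_j\sum_k x_{ijk} w^J_j w^K_k = [X\,(w^K \otimes w^J)]_i$
hold literally, and `fold(matricize(X3))` is the exact inverse.

## PCA biplot

The exploratory stage works on the $J \times L$ frequency table ($n_{jl}$ =
formulas of class $l$ using plant $j$). We center columns and
eigendecompose the sample covariance (divisor $n-1$) — covariance PCA, not
correlation: the columns are counts on a common scale and rescaling would
equalize classes with very different usage variability, which is exactly
the signal the biplot is meant to show. Eigenvectors are sign-fixed
(largest-magnitude entry positive) for determinism. Both classic scalings
are exposed: `alpha = 0` plots raw scores against unit loadings; `alpha = 1`
moves the singular values onto the variable vectors so vector length tracks
column variability. Both produce the same rank-2 reconstruction, so the
projection interpretation (point onto axis ≈ centered frequency) is
scaling-invariant.

## PLS-DA

`fit_pls()` is NIPALS PLS2 on mean-centered blocks (no autoscaling by
default — unit-variance scaling of rare binary plant columns inflates their
influence dramatically; a flag restores it). The inner iteration starts
from the largest-variance $Y$ column, converges on the score vector at
relative tolerance $10^{-12}$ (cap 500 iterations), and the coefficient
matrix uses the corrected-weight identity
$B = W (P^\top W)^{-1} Q^\top$, under which $T = X_c W(P^\top W)^{-1}$ holds
exactly and $\hat Y = X_c B + \bar y$ matches the accumulated
per-component regressions to machine precision. Class assignment is row
argmax of $\hat Y$ with ties to the lower class index. Percentages in
confusion summaries are rounded to one decimal, matching the reporting
convention of the field.

The component count is a required core parameter; the CLI defaults to
10-fold cross-validated selection because no canonical value exists for
this family of data. On the synthetic default world, 5 components saturate
accuracy.

### Two deflation conventions, one model

Classic NIPALS deflates $X$ by $t p^\top$; the trilinear model (below)
forces weight-based deflation $t w^\top$, because only then does the
projector-corrected weight matrix
$\tilde w_c = \prod_{q<c}(I - w_q w_q^\top)\, w_c$ reproduce the deflated
scores from the *original* centered data. We verified, numerically and by
span arguments, that the two conventions give identical fitted values,
predictions, and (for full-column-rank $X$) coefficients at every
component count, but *different individual score vectors* beyond component
1; neither score path is "wrong", they are different bases of the same
fitted subspace. `fit_pls(deflation = "weights")` exposes the second
convention, and the $K = 1$ reduction of the trilinear fitter reproduces
its scores to $10^{-8}$ while matching the classic fitted values — the
form in which the reduction oracle is testable at all.

## Permutation significance of coefficients

Main-ingredient plants are detected by permutation: whole rows of $Y$ are
shuffled (preserving the one-class-per-formula structure), the model is
refitted with identical settings, and two-sided add-one p-values
$p_{jl} = (1 + \#\{|b^*_{jl}| \ge |b_{jl}|\})/(B+1)$ are computed per
(plant, class). Two-sidedness is the conservative choice — a plant could in
principle suppress a class. Defaults $B = 999$, $\alpha = 0.05$, no
multiplicity correction (Benjamini–Hochberg behind a flag), matching the
reporting style of raw per-efficacy significance counts. Degenerate
permuted fits are resampled and logged. Under exchangeability the add-one
p-value is exact, and the calibration test confirms the aggregate rejection
rate at $\alpha = 0.05$ on null data sits inside the 99% binomial band.

## Trilinear N-PLS-DA

Per component, with $u$ the unit $Y$-weight: reshape
$X_{\mathrm{unf}}^\top (Y_{\mathrm{res}} u)$ to $J \times K$, take its
leading singular pair as $(w^J, w^K)$ (signs fixed through $w^J$, with
$w^K$ flipped along so the score is preserved), score
$t = X_{\mathrm{unf}}(w^K \otimes w^J)$, update
$u \propto Y_{\mathrm{res}}^\top t$, iterate to convergence. $X$ is
deflated by $t w^\top$; $Y$ is re-regressed on all scores after each
component ($B_{\mathrm{inner}} = (T^\top T)^{-1} T^\top Y_c$), and
$B_{\mathrm{NPLS}} = \tilde W B_{\mathrm{inner}}$ predicts new tensors
directly from their centered unfolding. The printed corrected-weight
formula in the source literature starts its product at $w_2$; we implement
the standard form with $\tilde w_1 = w_1$, which the $T = X\tilde W$
contract verifies to machine precision. $X$ is centered across the
observation mode of the unfolded matrix — the convention under which the
corrected-weight identity is exact; no scaling, for the same reason as in
PLS-DA.

Centering choices, the $K=1$ reduction, the rank-1 recovery construction,
and the triple score-identity (double sum = Kronecker = corrected weights)
are each regression-tested to $10^{-8}$.

### Activity significance

Which activities matter for which efficacy is read from the activity-mode
weights: any $\max_c |w^K_{kc}| \ge 0.3$ is called significant, the
standard weight rule for sample sizes of 350 or more (a warning fires below
that). One-vs-rest binary-response models (default $C = 2$) are fitted per
class rather than one joint 9-response model: the joint model's weights
have no clean activity-to-class attribution, whereas one-vs-rest makes the
call unambiguous; the joint variant is available (`mode = "joint"`, with a
documented heuristic attribution) for comparison. With $C = 2$ the first
component is typically dominated by the broadly-shared (general)
activities — they are carried by every class's main plants, so they
accumulate squared covariance from all of them — and the second component
isolates the class-specific activities; both groups therefore clear the
0.3 rule in the scenarios tested.

## Ward clustergram

The activity × efficacy significance calls are clustered by Ward linkage
on Euclidean distances, rows and columns independently, all-zero rows
dropped first. We hand-roll the Lance–Williams recursion because the
contract pins details generic implementations leave open: heights are Ward
*objective increments*
$\frac{|A||B|}{|A|+|B|}\lVert \bar a - \bar b\rVert^2$ (not the
square-root dialect), and ties — common on binary rows — are resolved
deterministically toward the lowest-index pair, with candidates within
$10^{-8}$ relative tolerance treated as tied (exact float equality is not
stable between the recursion and direct centroid evaluation). The merge
sequence is regression-tested against an exhaustive oracle that scores
every candidate merge from centroids at every step. Trees serialize to
Newick with height-difference branch lengths; no optimal leaf ordering is
attempted.

## The synthetic world

`jamu_config()` states a generative model with the documented structure:
formulas draw a class independently from the published 9-class prevalences
(72, 249, 22, 980, 398, 840, 311, 107, 159 out of 3138); each class owns a
disjoint set of main plants used with probability `p_main` (default 0.6)
against a `p_support = 0.02` background; each class owns disjoint specific
activities carried by its mains, a small set of general activities is
carried by all mains, and spurious plant–activity links occur at 0.02.
Sizes the source data do not pin down scale with the problem: ~19% of
plants are mains (90 of 465, evenly split), `round(K/2L)` specific
activities per class and `round(6K/46)` general ones — the proportions of
the canonical formulary. For $L \ne 9$ the class prevalences default to
uniform: the published sizes are a property of the 9-class system, and a
truncated subset would smuggle in an arbitrary imbalance (a 1.3%-prevalence
class at $I = 1000$ would be a statement about small-class behaviour the
recovery scenario does not intend). Three RNG streams (labels, usage,
activities) derive from one master seed so the blocks are independently
stable.

What a green recovery test establishes — and what it does not: the
generator has independent formulas, disjoint main-plant sets, and
class-conditionally independent Bernoulli usage. Real formularies have
correlated plant co-usage, overlapping main sets, regional structure, and
annotation noise that is anything but independent. Green means the chain
recovers the structure it assumes when that structure is present at
realistic sizes; it does not certify performance on real data, and the
published 71.6% accuracy is reproduced only at the arithmetic level (from
the printed confusion counts), not re-derived from raw data, which are not
distributed.

## Numerical choices and limitations

* Convergence: $10^{-12}$ relative on score vectors, 500 iterations, fits
  abort (naming the component) rather than return silently unconverged.
* Degenerate inputs: constant PCA input warns and returns a zero spectrum;
  zero-variance $Y$ refuses to fit; permutation replicates that fail are
  resampled and logged; `alpha = 1` biplots refuse zero eigenvalues.
* Full-size tensors ($3138 \times 465 \times 46$) unfold to ~0.5 GB per
  copy; the implementation is dense, so pipelines at that scale need a few
  GB of memory. Tests and examples run scaled-down configurations.
* No sparse PLS, no factor rotation, no Tucker/PARAFAC generality, no
  alternative classifiers: the scope is the binary-formulary chain
  described above.
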