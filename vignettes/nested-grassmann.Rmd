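---
title: "Nested Grassmann dimensionality reduction: model, algorithms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested Grassmann dimensionality reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestedGrassmann)
```

## The model

A sample here is a $p$-dimensional linear subspace of $\mathbb{R}^n$ or
$\mathbb{C}^n$, i.e. a point of the Grassmann manifold $Gr(p,n)$, stored as
an $n \times p$ matrix with orthonormal columns.  All comparisons between
subspaces go through principal angles $\theta_1 \le \dots \le \theta_p$
(arccosines of the singular values of $X^H Y$), giving the geodesic distance
$d_g = (\sum_i \theta_i^2)^{1/2}$ under the canonical invariant metric and
the projection (chordal) distance
$d_p = (\sum_i \sin^2\theta_i)^{1/2} = \|P_X - P_Y\|_F/\sqrt2$.

The reduction family is the *nested Grassmann* embedding
$$\iota_{A,B}(\mathcal X) = \mathrm{span}(AX + B), \qquad
  A \in St(m,n),\; B \in \mathbb{F}^{n\times p},\; A^H B = 0,$$
with projection $\pi_A(\mathcal X) = \mathrm{span}(A^H X)$.  When $B = 0$
the embedding is isometric and its image is a totally geodesic submanifold;
a nonzero $B$ shifts the image off any geodesic submanifold.  That extra
freedom is the point of the method: principal geodesic analysis (PGA) must
anchor a geodesic submanifold at the Fréchet mean, which is a poor summary
for widely spread data, while a nested Grassmann submanifold can follow the
data.

**Unsupervised fit.**  `ng_fit()` minimizes the mean squared reconstruction
error
$$L_u(A,B) = \frac1N \sum_{i=1}^N d^2\!\left(\mathrm{span}(X_i),\,
  \mathrm{span}(A A^H X_i + (I - AA^H)B)\right)$$
over $Gr(m,n) \times \mathbb{F}^{n\times p}$ ($L_u$ only depends on
$\mathrm{span}(A)$).  When $m > n/2$ the optimization variable is the
$(n-m)$-dimensional orthogonal complement of $\mathrm{span}(A)$, which makes
the one-dimension-drop fits of the chain cheap.

**Supervised fit.**  With class labels, `sng_fit()` minimizes
$$L_s(A) = \frac1{N^2}\sum_{i,j} a(\mathcal X_i, \mathcal X_j)\,
  d^2(\mathrm{span}(A^H X_i), \mathrm{span}(A^H X_j)),$$
where the affinity $a = g_w - g_b \in \{-1,0,1\}$ marks mutual
within-class ($\nu_w$) and between-class ($\nu_b$) nearest neighbors under
the geodesic distance.  $L_s$ carries no offset, so the returned map has
$B = 0$.

**The chain.**  `png_fit()` applies one-dimension drops
$Gr(p,n) \to Gr(p,n-1) \to \dots \to Gr(p,p+1)$, switches to lines through
the orthogonal-complement diffeomorphism $Gr(p,p+1) \cong Gr(1,p+1)$, and
continues to $Gr(1,2)$, whose Fréchet mean is the *nested Grassmann mean*
(NGM); on $Gr(1,2) \cong \mathbb{RP}^1$, a half circle, that mean is
unique.  Each step records a principal-score block (below), and the ratio
of expressed variance at every level supports choosing a working dimension,
exactly as scree plots do for PCA; the package reports the table and leaves
the cut-off to the user.

**Principal scores.**  A drop $Gr(p,m+1)\to Gr(p,m)$ loses exactly $p$ real
($2p$ complex) dimensions.  For a sample $X$ with reconstruction
$\tilde X = \iota(\pi(X))$, the fiber coordinate is
$V = X^H A_\perp$ ($A_\perp$ the unit completion of the step's column
space), and the score vector is $d_g(\tilde X, X)\, V/\|V\|$, so its norm is
the per-step reconstruction distance.  ($\|V\| = 1$ does not hold
identically, so $V$ is explicitly normalized and the raw norms are kept in
an attribute for audit.)  Complex scores are flattened to interleaved
real/imaginary pairs.  At the bottom, the real chain records the signed
angle to the NGM in the $[0,\pi)$ chart, wrapped to $(-\pi/2, \pi/2]$; the
complex chain ends on complex $Gr(1,2)$, which has two real dimensions, so
the final block is the two-coordinate tangent representation of the log map
at the NGM.  Either way the score table has exactly $p(n-p)$ real columns
($2p(n-p)$ complex) — one per manifold dimension, an exact accounting of
the information in the data.

**PGA baseline.**  `pga_fit()` computes the Fréchet mean by Karcher
iteration, log-maps every sample, and runs centered, unscaled PCA on the
vectorized tangent coordinates (flattened identically to the scores).  Its
cumulative tangent-variance ratios are the standard tangent-PCA convention
and are what the package compares PNG score-PCA ratios against.

## Tunable parameters

* `distance` (`"projection"`, default, or `"geodesic"`): the metric inside
  $L_u$/$L_s$.  Projection distance has an analytic gradient and is cheaper
  by an SVD per sample; the two give expressed variances that agree to a
  few times $10^{-4}$ in the simulations below, so the default favors
  speed.  Expressed variance itself is *always* geodesic, so fits and PGA
  are compared on one scale regardless of the fitting metric.
* `max_iter = 500`, `grad_tol = 1e-6`: Riemannian-gradient-norm stopping
  rule.  Radians-scale problems converge far earlier; tighten `grad_tol`
  when reconstruction residuals near machine precision matter.
* `init` (`"pca"` default): $A_0$ spans the top-$m$ left singular vectors
  of the horizontally stacked representatives, $B_0 = 0$.  This makes
  noiseless recovery deterministic and fast; `"random"` (seeded) and
  `"natural"` (coordinate subspace) are available.
* `nu_w`, `nu_b`: neighbor counts for the supervised affinity; defaults
  `min(5, smallest class - 1)` and `5`, the usual graph-embedding practice.
  Distance ties are broken by smallest sample index, so affinities are
  deterministic.
* `ng_simulate(N, n, m, p, sigma, b_scale)`: `sigma` is the *geodesic*
  length (radians) of the tangential perturbation, so
  $d_g(X_i, \tilde X_i) = \sigma$ exactly; `b_scale = 0.1` is the standard
  deviation of the offset entries ("N(0, 0.1)" is read as a standard
  deviation; pass `b_scale = sqrt(0.1)` for the variance reading).
* Every stochastic function takes an explicit `seed` and restores the
  caller's RNG state; identical seeds give bitwise-identical results on a
  given platform.

## What the generator emulates — and does not

`ng_simulate()` reproduces the simulation protocol the method was designed
around: low-dimensional coordinates uniform on $St(p,m)$, a uniform frame
$A$, Gaussian offset $B$, and tangential noise of *constant* magnitude
$\sigma$ in a uniformly random horizontal direction.  Real data differ in
ways the generator does not model: noise magnitudes vary per sample,
perturbations need not be tangential or isotropic, the underlying structure
need not be exactly a nested-Grassmann image, and shape data carry
landmark-level noise that maps nonlinearly into $Gr(1,\mathbb{C}^{k-1})$.
Passing the recovery and comparison tests therefore shows the estimator is
correct and well-behaved under its own model, not that it wins on any
particular real data set.

Because the low-dimensional coordinates are uniform over all of $St(p,m)$,
the simulated data are *not* clustered around their Fréchet mean at any
$\sigma$.  PGA is handicapped in this regime even when the submanifold is
geodesic — its tangent-space linearization spreads variance across more
components — which is why the PNG-vs-PGA gap in cumulative explained
variance stays noticeable (about 0.1–0.17 in our runs) even at
$\sigma = 0.01$, rather than vanishing.

## Numerical choices

* **Orthonormalization** is modified Gram–Schmidt with one
  reorthogonalization pass — the unique thin QR factor with real positive
  diagonal.  Base `qr()` column-pivots on complex input, which silently
  permutes representatives; the nested-map algebra (exact
  project-after-embed, composition, offset realignment) needs the
  unpivoted convention.  Inputs with condition number above $10^{12}$ are
  rejected as rank-deficient.
* **Offset convention.**  $L_u$ reconstructs
  $\mathrm{span}(AA^HX + (I-AA^H)B)$, which embeds the *un-normalized*
  projected representative, whereas $\iota(\pi(X))$ embeds its
  QR-normalized representative; for $B \ne 0$ the two conventions differ by
  a right factor.  `ng_fit()` optimizes $L_u$ (which keeps the exact
  $O(m)$ symmetry and the complement-parameterization speed-up), then
  realigns $B$ by least squares over the per-sample QR factors — exact
  whenever the data lie on the fitted submanifold, where that factor is
  constant.  The reported `value` is the reconstruction error through
  `ng_reconstruct()` (embed-after-project), which is exactly idempotent;
  the monotone `loss_trace` is of the optimization surrogate.
* **Composition** of maps multiplies the frames and rescales the outer
  offset by the inner Gram–Cholesky factor,
  $B_c = A_oB_i + B_o\,\mathrm{chol}(I + B_i^HB_i)$, making
  `ng_embed(ng_compose(o, i), X)` agree with the two-step embedding to
  machine precision.
* **Optimizer**: Riemannian steepest descent with Barzilai–Borwein steps,
  clamped to $[10^{-10}, 10^4]$, and a monotone Armijo backtracking line
  search (sufficient-decrease constant $10^{-4}$); retraction by QR.  The
  loss trace is nonincreasing by construction.  Geodesic-distance fits use
  central-difference gradients projected to the tangent space.
* **Principal angles** use arccosines of singular values of $X^HY$
  (clamped to $[0,1]$), refined for angles below $\pi/4$ by arcsines of the
  singular values of the perpendicular component $Y - X(X^HY)$ — plain
  arccos loses half the significant digits near zero, which would spoil
  the $10^{-8}$-level round-trip guarantees.
* **Fréchet means** use Karcher fixed-point iteration (unit step,
  initialized at the first data point, `tol = 1e-9` on the mean tangent,
  `max_iter = 200`), erroring with the last iterate attached on
  non-convergence.  The log map requires all principal angles below
  $\pi/2$; samples at the cut locus raise an error naming the obstruction.
* **Deterministic representatives**: one-dimensional subspaces are
  canonicalized by making their largest-modulus coordinate real and
  positive; completions ($A_\perp$, complement swap) inherit this, so
  score signs are reproducible.  Degenerate inputs (rank-deficient bases,
  zero-variance datasets, identical-landmark shapes, classes smaller than
  $\nu_w + 1$) raise informative errors rather than propagating NaNs.

## Design choices where the construction was open

* The chain refits both $A$ and $B$ at every level, including the
  line-valued levels after the complement switch.
* The supervised chain builds the affinity once, from the original-space
  geodesic distances, and keeps it fixed across levels
  (`rebuild_affinity = TRUE` rebuilds per level); a fixed graph keeps the
  per-level objectives comparable.
* The supervised loss defaults to the projection distance for the same
  efficiency reason as the unsupervised one; it carries no offset because
  the loss contains none.
* Score PCA is centered and unscaled: the columns share units (radians),
  and rescaling would discard the information-accounting property.
* Shape variance is reported on the unscaled Grassmann geodesic metric
  (no Fubini–Study scale factor), consistent with every other distance in
  the package.
* The Helmert submatrix uses negative leading entries
  $h_j = -(j(j+1))^{-1/2}$; the shape representation is invariant to this
  convention, but the matrix itself is pinned by tests.

## Known limitations

* $\iota_{A,B}$ with $B \ne 0$ is representative-dependent in the abstract;
  the package makes every representative deterministic (QR convention,
  canonical lines), so results are well-defined and reproducible, but
  score *signs* are convention-bound, as fiber coordinates must be.
* The per-level losses are non-convex; different initializations can reach
  different local minima.  The PCA initialization is deterministic and
  recovers exact embeddings from noiseless data, but no global-optimality
  claim is made.
* Expressed-variance ratios along the chain are typically nonincreasing
  but not guaranteed to be — non-isometric embeddings can locally expand
  distances, and occasional small bumps (we observed up to ~0.04 at
  $\sigma = 0.5$) are genuine, not numerical error.
* Geodesic-distance fitting uses numerical gradients and is roughly an
  order of magnitude slower than projection-distance fitting; it exists to
  verify the two agree, and the projection default is recommended.
* Tests and the acceptance script run at desk scale — $N = 50$ samples,
  ambient dimensions up to 10 (shapes: $k = 8$ landmarks), 3–10 repetitions
  per comparison — chosen so the full suite completes in minutes while
  leaving the Monte-Carlo checks comfortable margins.  Nothing in the
  implementation is specific to these sizes; corpus-callosum-scale shape
  data ($k$ in the hundreds) simply cost more per SVD.
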