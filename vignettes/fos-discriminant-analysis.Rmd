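---
title: "Discriminant analysis for functions on surfaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminant analysis for functions on surfaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosda)
```

## The problem

A *function on a surface* (FoS) is a pair $(M_i, z_i)$: a subject-specific
closed two-dimensional surface $M_i \subset \mathbb{R}^3$ carrying a scalar
map $z_i : M_i \to \mathbb{R}$. The motivating data type is a cortical
surface coupled with its cortical thickness map (in mm), with the goal of
predicting a binary diagnostic label $g_i$ from the pair. Two obstacles
make this non-standard: each predictor lives on its *own* nonlinear
domain, and the space of such domains is itself non-Euclidean, so neither
ordinary multivariate nor classical functional classifiers apply
directly.

`fosda` addresses this with a two-stage construction:

1. **Linear representation.** All surfaces are assumed
   vertex-corresponded to a common template $M$. Each subject is encoded
   as a pair $(v_i, x_i)$: a smooth velocity field
   $v_i : \mathbb{R}^3 \to \mathbb{R}^3$ in an RKHS $V(\mathbb{R}^3)$
   whose flow $\phi_{v_i}$ deforms the template onto the subject surface,
   and the spatially normalized map $x_i = z_i \circ \phi_{v_i}$ on the
   template. Both components live in linear function spaces, and the
   representation is invertible: any pair of directions
   $(\beta^G, \beta^F)$ maps back to a curve of valid FoSs
   $(\phi_{\bar v + c_1 \beta^G}(M),\; c_2 \beta^F \circ
   \phi^{-1}_{\bar v + c_1\beta^G})$, which is what makes the fitted
   classifier interpretable in the original anatomical terms.

2. **Penalized least-squares discriminant.** The two-class functional
   discriminant direction is estimated directly as a regression, with no
   covariance estimation and no principal-component truncation. With
   auxiliary responses $y_i = -n/n_1$ for class 1 and $y_i = +n/n_2$ for
   class 2, the estimator solves
   $$\min_{\beta^G,\beta^F}\;
   \sum_i \big(y_i - \langle v_i, \beta^G\rangle
   - \langle x_i, \beta^F\rangle\big)^2
   + \lambda_1 \|\beta^G\|^2_{V(\mathbb{R}^3)}
   + \lambda_2 J(\beta^F),$$
   where $J(\beta) = \|\Delta_M \beta\|^2_{L^2(M)}
   + \varepsilon\|\beta\|^2_{L^2(M)}$ is a Laplace–Beltrami roughness
   penalty plus a small shrinkage term. The population minimizer of the
   unpenalized risk is the discriminant direction
   $\beta_0 = L_C^{-1}(\mu_2 - \mu_1)$, so the regression view and the
   discriminant view coincide. Subjects are scored by
   $\langle v^* - \bar v, \beta^G\rangle + \langle x^* - \bar x,
   \beta^F\rangle$ and thresholded.

## Discretization

The map component is discretized with linear finite elements on the
template mesh: sparse mass matrix $M_{jj'} = \int \psi_j \psi_{j'}$ and
stiffness matrix $S_{jj'} = \int \nabla_M\psi_j\cdot\nabla_M\psi_{j'}$
(assembled exactly; products of affine basis functions need no quadrature
rule). The penalty matrix is $D = S\tilde M^{-1} S + \varepsilon M$ with
$\tilde M$ the row-sum lumped mass; the lumped inverse is used
deliberately — the consistent $M^{-1}$ is dense and would destroy
sparsity. The geometric component uses the representer theorem: the
fitted $\beta^G$ is a combination of the kernel sections of the training
fields, so only the $n \times n$ Gram matrix
$\Sigma_{ij} = \int\!\!\int v_i(p)^T K(p,q) v_j(q)\,dp\,dq$ is needed.

Both blocks are stacked into one augmented sparse least-squares problem
whose normal equations reproduce the penalized objective exactly:
rows $[\Sigma,\; XM]$, $[0,\; \sqrt{\lambda_2}\tilde M^{-1/2} S]$,
$[0,\; \sqrt{\lambda_2\varepsilon}\, R_M]$,
$[\sqrt{\lambda_1} L_\Sigma,\; 0]$, with right-hand side $(y, 0)$, where
$R_M^T R_M = M$ (sparse Cholesky) and $L_\Sigma^T L_\Sigma = \Sigma$
(pivoted Cholesky after a jitter of $10^{-10}\,\mathrm{tr}(\Sigma)/n$ —
any such factor yields the same quadratic form). The system is solved by
LSQR without ever forming the normal matrix; the suite checks agreement
with dense normal-equation solves to $10^{-6}$ relative error.

### Numerical choices

- **Degenerate triangles** (area below $10^{-12}$ times the squared
  bounding-box diagonal) are hard errors, never skipped: a silently
  dropped element corrupts $D$.
- **Eigenpairs** of $S\phi = \theta M\phi$ (used by the noise generator
  and diagnostics) are computed by ARPACK shift-invert with shift
  $-10^{-8}$, which is robust next to the zero eigenvalue of a closed
  mesh; meshes with at most a few hundred vertices use a dense solve.
  Eigenvectors are returned $M$-orthonormal.
- **Shrinkage default** $\varepsilon = 10^{-3}\theta_2^2$, with
  $\theta_2$ the first nonzero Laplace–Beltrami eigenvalue of the
  template, keeps the bending and shrinkage parts of $J$ commensurate.
  On a unit sphere $\theta_2 = 2$, so $\varepsilon = 4\times10^{-3}$.
- **Objective scaling.** The augmented form carries no $1/n$ factor, so
  the $\lambda$ values are $n$ times those of the averaged objective;
  model selection over a grid absorbs this.
- **Gram quadrature.** $\Sigma$ is approximated on the velocity control
  points with unit weights; the overall scale is absorbed into
  $\lambda_1$ by the selection grid. Scoring of new subjects reuses the
  identical quadrature, so train and test inner products are consistent.
- **LSQR** stops at a relative residual-gradient norm of $10^{-10}$
  (configurable); hitting the iteration cap is a warning, not an error,
  and returns the current iterate.
- **Threshold selection** maximizes Youden's J over midpoints of
  consecutive distinct scores (so perfectly separated classes get the
  midpoint of the separating gap; ties break toward the smallest
  threshold), or picks the smallest threshold achieving a requested
  specificity.
- **Tie-breaks in model selection** go to larger penalties (larger
  $\lambda_2$, then $\lambda_1$), favoring smoother estimates.

## The deformation model

The construction of the diffeomorphic operator is deliberately simple: a
*stationary* velocity field integrated by explicit Euler over $t \in
[0,1]$ in a configurable number of sub-steps (default 8). For the small,
smooth fields this package targets, the flow of a stationary field is a
diffeomorphism; rather than assert this, `deform_mesh` reports a
diagnostic — the fraction of faces whose orientation flipped — and the
simulators treat any flip as an error. This is a documented design
choice, not an implementation of a full time-varying large-deformation
registration: it preserves the contract that matters for the statistics
(invertible, topology-preserving reconstruction and trajectories) at a
fraction of the cost.

Velocity estimation minimizes the summed squared distances between
flowed template vertices and target vertices plus
$\gamma\|v\|^2_{V(\mathbb{R}^3)}$. With one Euler step this is a linear
ridge problem solved in closed form, reducing to
$(K + \gamma I)\alpha = Q - \Xi$ when the control points are the
template vertices. With more steps, a Gauss–Newton iteration on the flow
endpoint (exact adjoint gradient, approximate Gauss–Newton metric,
backtracking line search) refines the one-step solution; the line search
makes the objective non-increasing by construction, which the test suite
asserts per iteration.

The kernel is a scalar Gaussian times the identity,
$K(p,q) = \exp(-\|p-q\|^2/\sigma^2) I_3$, with
$\sigma = 0.2\times$ the template bounding-box diagonal by default; the
kernel family is otherwise unconstrained by the model, which only
requires a smooth RKHS, and the Gaussian is the conventional choice.
Control points default to a farthest-point subsample of template
vertices ($m = \min(s, 512)$), bounding the kernel algebra while
covering the surface. The mean field $\bar v$ is the coefficient-wise
mean: with a shared kernel and control set this coincides with the field
minimizing the mean squared RKHS distance.

Alignment removes translation, rotation, and scale by generalized
Procrustes analysis (unit centroid size, rotations with determinant +1,
template iterated to a relative change of $10^{-8}$) before velocities
are estimated.

## The quadratic extension

When the two classes plausibly differ in covariance structure, not only
in mean, the linear rule is extended to an approximate quadratic one:
two class-specific directions are fitted by penalized least squares,
$\beta_1$ against the target 1 on class 1 and $\beta_2$ against $-1$ on
class 2, each with its own penalty, reusing the same augmented solver.
Subjects are then projected to $u_i = (\langle x_i, \beta_1\rangle,
\langle x_i, \beta_2\rangle)$ and classified in this plane. The
projection-space rule in the source framework is a modified Fisher
criterion whose exact form is not available; this package substitutes
two-component Gaussian quadratic discrimination on the projections
(per-class 2-D means and covariances, priors from training frequencies),
which preserves the stated structure — project, then assign — with a
standard, testable rule. The acceptance suite verifies the intended
behavior: under unequal class covariances the quadratic rule beats the
linear one; under equal covariances the two are within simulation noise.

## The synthetic-data generator

Real cortical datasets are access-restricted, so the package ships a
generator that emulates the statistical structure the model assumes and
makes every stage testable offline.

- **Template**: unit icosphere by 1-to-4 subdivision (12, 42, 162, 642,
  2562, ... vertices), closed and outward-oriented.
- **Maps**: $x_i = m_{g_i} + \sum_{j\ge 2}\sqrt{\tilde\theta_j}
  \zeta_{ij}\phi_j$ with iid standard normal scores over
  Laplace–Beltrami eigenfunctions of the template and a power-law
  spectrum $\tilde\theta_j = a_g^2 j^{-\text{decay}_g}$ (decay $> 1$, so
  the spectrum is summable; the constant mode is excluded so the noise
  is spatially zero-mean). The baseline is 2.5 mm, the scale of adult
  cortical thickness. Class means differ by $\delta$ times a Gaussian
  bump profile. The bump is *mean-centered*: because the noise excludes
  the constant mode, an uncentered contrast would hand the classifier a
  noise-free global-offset direction along which the classes separate
  perfectly — a degenerate regime no real data exhibits.
- **Per-class spectra** (`noise_amp`, `decay` of length 2) give the
  unequal-covariance regime used to stress the quadratic extension.
- **Geometries**: subject velocity fields are a class-mean smooth field
  ($\pm$ half the geometric amplitude) plus an independent smooth random
  field per subject, with amplitudes specified as RMS vertex
  displacements; deformations that flip any face abort with an error.
- **Ground truth** is returned alongside the data: the generating
  contrast, class means, and mean geometric effect, plus the exact
  representations, so representation error can be isolated from fitting
  error. Everything derives from one scenario seed; identical scenarios
  reproduce bit for bit.

Two contrast modes exist because two different questions are asked of
the generator. In `"bump"` mode the class *means* differ by the bump —
natural for classification studies. In `"cov_aligned"` mode the true
*discriminant direction* $\beta_0$ is the centered bump and the mean
difference is $L_C\beta_0$; this is the right construction for studying
estimation of $\beta_0$ itself, because the estimator targets
$L_C^{-1}(\mu_2-\mu_1)$, which in `"bump"` mode is not the bump (and for
rank-deficient $C$ need not exist at all). Under the mixture the exact
population direction acquires the scalar correction
$\beta_0/(1 + q/4)$ with $q = \langle \mu_2-\mu_1, \beta_0\rangle$,
which the risk computations use.

What the generator does *not* emulate: FreeSurfer segmentation
artifacts, misregistration, cortical folding geometry, or non-Gaussian
thickness variation. Passing tests demonstrate correctness of the
estimator under its own assumptions, not performance on real cortical
data.

## Study conditions used by the verification suite

The acceptance checks run scaled-down simulation studies; their
conditions are fixed here once.

- **Recovery** (direction estimation): template level 3 ($s = 642$),
  $n = 200$ (100 per class), `cov_aligned` contrast with $\delta = 2$,
  bump width 1.0, `noise_amp` 2, decay 1.3, $k = 40$ modes; $\lambda_2$
  tuned over the ladder $10^{-5}, \dots, 10^2$ by the recovery cosine
  itself (an oracle tuning, appropriate when the question is what the
  estimator can achieve at the right penalty); 10 replicates, median
  $M$-inner-product cosine $\ge 0.9$. The broad bump concentrates its
  energy in the lowest harmonic levels, where the per-mode
  signal-to-noise $\propto a\, b_j \sqrt{n \tilde\theta_j}$ allows
  consistent estimation at this $n$.
- **Risk convergence**: same design at level 2 ($s = 162$),
  $n \in \{50, 100, 200, 400\}$, per-$n$ oracle-tuned $\lambda_2$, risk
  evaluated against the mixture-corrected $\beta_0$ on 400 fresh
  subjects, 10 replicates; medians non-increasing in $n$.
- **Null calibration**: all effects zero, level 2, $n = 40$ train and
  test, 50 replicates; mean test AUC in $[0.45, 0.55]$.
- **Linear vs quadratic**: level 2, 60 per class, $\delta = 0.5$,
  per-class amplitudes $(0.7, 2)$ for the unequal regime and $(1, 1)$
  for the equal one, both methods tuned on a validation set; 10
  replicates.
- **Round trip / pipeline**: level 2 with geometric effects on
  (amplitude 0.1, per-subject noise 0.03 in template units, 42 control
  points); the pipeline study uses $\delta = 1.5$, 30 per class, a
  50/20/30 split, and a small $\lambda$ grid.

These sizes keep each study in the minutes range on one CPU while
preserving the qualitative regimes of interest.

## Known limitations

- Vertex correspondence across subjects is assumed, not computed; there
  is no registration. The pullback is an index map, exact under the
  assumption and meaningless without it.
- The Euler flow is first-order; for large deformations the flipped-face
  diagnostic will fire before accuracy degrades gracefully. Increase
  `steps` or reduce amplitudes.
- The Gram quadrature on control points is a coarse approximation of the
  double integral; it is adequate because only relative geometry between
  subjects enters the classifier, and the scale is absorbed by
  $\lambda_1$ selection.
- Binary PLY files are not read; mesh I/O is deliberately limited to the
  ASCII OFF/PLY dialects.
- The final choice of penalties in applied work is often a compromise
  between accuracy and interpretability of the directions; the package
  automates only the AUC-maximizing grid rule and returns the full audit
  table for human judgment.
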