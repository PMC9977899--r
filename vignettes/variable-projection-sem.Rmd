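---
title: "Variable projection for least squares SEM estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable projection for least squares SEM estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snllsem)
```

## The model

`snllsem` works with linear structural equation models in RAM notation.
A random vector $x \in \mathbb{R}^m$ collects the observed and latent
variables (observed first) and satisfies

$$x = \gamma + \Lambda x + \varepsilon, \qquad
  \mathbb{V}[\varepsilon] = \Omega,$$

where $\Lambda$ holds the directed effects (factor loadings, regression
paths), the symmetric $\Omega$ holds the undirected effects (variances
and error covariances), and $\gamma$ holds mean terms.  Whenever
$I - \Lambda$ is invertible, the implied moments of the observed
variables are

$$\Sigma(\theta) = F (I-\Lambda)^{-1} \Omega (I-\Lambda)^{-T} F^T,
  \qquad \mu(\theta) = F (I-\Lambda)^{-1} \gamma,$$

with $F = [\,I \mid 0\,]$ the filter selecting the observed block.  The
least squares estimator minimizes

$$F_{LS}(\theta) = (s - \sigma(\theta))^T V (s - \sigma(\theta)),$$

where $\sigma = \operatorname{vech}\Sigma(\theta)$, $s =
\operatorname{vech} S$ for the sample covariance $S$, and $V$ is a fixed
symmetric weight matrix: $\tfrac12 D^T (S^{-1} \otimes S^{-1}) D$ for
GLS (with $D$ the duplication matrix), the identity for ULS, or any
user-supplied symmetric matrix.

## Why the parameters separate

Path tracing makes the key structural fact visible.  Every implied
covariance is a sum over *treks* -- walks without colliding arrowheads --
and each trek monomial contains exactly **one** undirected factor (a
variance or covariance), because error covariances are not transitive.
Hence, with the directed parameters $\theta_\Lambda$ held fixed,
$\sigma$ is an *affine* function of the undirected parameters:

$$\sigma = G(\theta_\Lambda)\,\theta_\Omega + c(\theta_\Lambda),$$

and likewise $\mu$ is affine in the mean parameters $\theta_\gamma$.
The entries of $G$ are sums of products of entries of $B =
(I-\Lambda)^{-1}$ taken at the stored index tuples: the vech positions
$\mathcal{D}$ crossed with the $\Omega$-parameter positions
$\mathcal{C}$ (and the $\gamma$ positions $\mathcal{A}$ for the mean
block).  Two bookkeeping rules keep the identity exact for every model
the syntax can express:

* **equality constraints** (one label at several positions) sum the
  columns of all tied positions into one column;
* **fixed nonzero constants** in $\Omega$ or $\gamma$ contribute to the
  offset $c(\theta_\Lambda)$ rather than to $G$.

Both rules are forced by linearity and are verified by a property test
(`G %*% theta + offset == vech(implied_sigma())` to 1e-10 over random
models with ties and constants).

The affine structure means the linear parameters never need iterative
optimization.  For fixed $\theta_\Lambda$ the conditional minimizer is

$$\hat\theta_\Omega = (G^T V G)^{+} G^T V (s - c),$$

and substituting it back yields the *reduced* objective
$F_{SNLLS}(\theta_\Lambda)$, a function of the directed parameters
alone.  `fit_snlls()` minimizes that reduced objective and finishes with
one linear solve; `fit_full_ls()` minimizes $F_{LS}$ over all of
$\theta$ and is kept as the reference implementation -- at the same
weight matrix both routes reach the same point estimates, which the test
suite checks to 1e-4 over random factor models.

We use the Moore--Penrose pseudoinverse (singular values below
$10^{-10}\,d_{\max}$ truncated) wherever a textbook formula writes an
inverse, so rank-deficient $G$ -- e.g. duplicated columns from
unmerged ties -- degrades gracefully to the minimum-norm solution
instead of failing.

## Gradients

The reduced gradient is assembled analytically.  From
$\partial B_{kl} / \partial \Lambda_{ij} = B_{ki} B_{jl}$ and the
product rule we obtain the Jacobian of every $G$ entry with respect to
every directed parameter (summed over tied positions), exposed as
`build_dG()` in `vec` order.  Because the profiled linear parameters
satisfy the normal equations, the envelope theorem gives the exact
reduced gradient

$$\frac{\partial F_{SNLLS}}{\partial (\theta_\Lambda)_n}
  = -2\, r^T V \left( \frac{\partial G}{\partial (\theta_\Lambda)_n}
  \hat\theta_\Omega + \frac{\partial c}{\partial (\theta_\Lambda)_n}
  \right),$$

with $r$ the residual at the conditional solution.  This form stays
valid under locally constant rank of $G$.  No closed-form reference for
the assembled gradient is used for validation; instead both `build_dG()`
and `reduced_gradient()` are checked against central finite differences
(step 1e-6, relative tolerance 1e-5) on random models, including ties
and fixed constants.

## The trek engine as an independent oracle

`implied_cov_trek()` recomputes any implied covariance by enumerating
treks and summing their monomials, entirely without matrix inversion:
a trek factors into a directed path from an anchor into the source
(traversed backwards), the anchor (a top node contributing its variance,
or a bidirected covariance edge), and a directed path to the target.  On
an acyclic directed part this factorization is finite; graphs with
directed cycles are refused (the trek series may be infinite), while the
matrix pipeline still handles them whenever $I - \Lambda$ is invertible.
Agreement between the two routes to 1e-10 on random models is the
package's strongest correctness guarantee, because they share no code
beyond the model object.

## Numerical choices

* **vech order** is column-major over the lower triangle, fixed once and
  used identically by `vech()`, `duplication_matrix()`, `index_maps()`
  and `build_G()`; any internally consistent order would do, so the
  duplication matrix is tested only through the identity
  $D\,\mathrm{vech}(M) = \mathrm{vec}(M)$.
* **Singularity guard**: $I - \Lambda$ with reciprocal condition number
  below 1e-12 is treated as singular; during optimization such points
  return a large objective value so the line search backs off, and at a
  solution they mark the fit as non-converged.
* **Optimizer**: `stats::nlminb` (a quasi-Newton method) with the
  analytic gradient, `rel.tol = 1e-12`, at most 500 iterations.  A fit
  is *converged* when the objective is finite and either the optimizer
  stopped on its own relative-change test or the gradient sup-norm at
  the solution is at most `grad_tol = 1e-6`.  The gradient tolerance is
  deliberately not tighter: near weakly identified optima the PORT code
  reports "singular convergence" with gradient norms around 1e-7 while
  sitting at the same minimum the reduced optimization reaches, and
  1e-6 separates those from genuinely failed runs.  Non-convergence is
  a recorded outcome, never an exception.
* **Starting values**: only the directed parameters need starts under
  variable projection; the default is 0.5 per free directed parameter
  (a deliberately simple stand-in for regression-based loading starts),
  user-overridable per label.  The full optimization additionally
  starts free variances at the matching sample variance (0.05 for
  latent variables), covariances at 0 and means at the sample mean --
  the kind of simple defaults standard SEM software uses.
* **Variance positivity is not enforced**: the linear solve is
  unconstrained, matching the estimator analyzed; negative variance
  estimates are reported with a warning.
* **Covariance denominator** is $N$ by default (switchable to $N-1$);
  the choice only rescales $s$ and $V$ jointly and does not move the
  optimum for GLS/ULS.

## What the simulator emulates -- and what it does not

`simulate_data()` draws i.i.d. multivariate-normal rows from a model's
implied moments, which is exactly the regime in which GLS is derived.
The built-in convergence study (`convergence_study()`) uses the
two-factor, six-indicator population model with deliberately weak
loadings (0.8/0.6 after the fixed marker, structural path 0.25, unit
variances), where small-sample non-convergence is common.  Passing
tests therefore demonstrate correctness of the estimators and the
claimed convergence advantage *under correct specification and
normality*; they say nothing about robustness to excess kurtosis,
missing data, categorical indicators or misspecified structure, none of
which the generator produces.

The study's default scale is 200 replications per sample size over
$N \in \{10, 20, \ldots, 100\}$, a grid-and-size choice made once to
keep a full run in the minutes range on a single core while leaving the
directional contrasts far from their decision boundaries; both
estimators always see the identical simulated dataset and identical GLS
weight per replication.  "Iterations" are the optimizer's own major
iteration count, so cross-software comparisons of iteration numbers are
qualitative only.

## Design choices where the design was open

* The two loadings fixed at 1 in the study population model are treated
  as *fixed for identification* (marker-variable convention), not as
  free parameters whose population value happens to be 1; the free
  parameter count is 13.
* The mean-block weight in the stacked objective is block-diagonal,
  $S^{-1}$ for GLS and the identity for ULS, user-overridable via
  `weight_matrix(..., V_mu = )`.  Cross-block weighting is not
  supported.
* Cross-block equality constraints (a label shared between, say,
  $\Lambda$ and $\Omega$) are rejected at parse time: they would break
  the separability that the whole method rests on.
* The iteratively reweighted route to maximum likelihood (`irls_ml()`)
  restarts the weight from the sample covariance, so its first sweep is
  exactly the GLS fit; it is provided as a corollary, not as a
  competitive ML optimizer.

## Known limitations

* Trek enumeration is exponential in pathological dense graphs; it is
  an oracle for small models, not a production pipeline.
* No standard errors or test statistics are computed; at the optimum
  the estimates are ordinary (weighted) least squares estimates, so
  standard LS machinery applies unchanged.
* Single group, continuous indicators, no multilevel structure.
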