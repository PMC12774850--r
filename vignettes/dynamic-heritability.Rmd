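---
title: "Estimating dynamic variance components and heritability from one measurement per individual"
author: "gprebe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dynamic variance components and heritability from one measurement per individual}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Carcass traits, wood quality, frost damage: many quantitative traits can be
measured only once per individual, often destructively. Longitudinal designs
are then impossible, yet a sample that spans a wide range of ages (or
temperatures, weights, latitudes, ...) is *group-level longitudinal*: the
population collectively covers the covariate axis even though no individual
does. `gprebe` estimates how the additive-genetic variance
$\sigma^2_G(t)$, the residual variance $\sigma^2_E(t)$, and the narrow-sense
heritability

$$h^2(t) = \frac{\sigma^2_G(t)}{\sigma^2_G(t) + \sigma^2_E(t)}$$

change along such a continuous covariate $t$, from data with exactly one
phenotype and one covariate value per individual, plus an additive
relationship matrix $G$ (pedigree- or marker-derived).

## Model

The phenotype vector follows the linear mixed model
$y = X\beta + u + e$ where the genetic effects $u$ and residuals $e$ are
independent Gaussians whose variances depend on the covariate:
$u \sim N(0,\, D_G G D_G)$ and $e \sim N(0,\, D_E^2)$, with
$(D_G)_{ii} = \sigma_G(t_i)$ and $(D_E)_{ii} = \sigma_E(t_i)$. The diagonal
scaling of $G$ lets relatedness transmit a covariate-dependent amount of
variance, while residuals stay independent across individuals. The phenotypic
covariance is $K = D_G G D_G + D_E^2$.

Three modelling commitments are worth making explicit:

* **Smoothness, not a basis.** The log-variance curves
  $s_{E/G}(t) = \log \sigma^2_{E/G}(t)$ carry zero-mean Gaussian-process
  priors with Matérn covariance (magnitude $\tau^2$, smoothness $\nu$,
  length-scale $\ell$). No polynomial or spline basis is chosen; smoothness is
  a prior, not a parameterization, and the log transform guarantees positive
  variances. This is the main contrast with random-regression models, which
  commit to a basis for per-individual effect curves.
* **Restricted likelihood.** The posterior is built on the REML
  (error-contrast) form of the likelihood,
  $\ell_R = -\tfrac12\log|K| - \tfrac12\log|X^\top K^{-1}X| -
  \tfrac12 y^\top P y$ with
  $P = K^{-1} - K^{-1}X(X^\top K^{-1}X)^{-1}X^\top K^{-1}$, so the fixed
  effects $\beta$ are never estimated and translation of $y$ along the column
  space of $X$ leaves the fit exactly unchanged.
* **One measurement per individual.** Each individual appears at a single
  covariate value $t_i$; $Z = I$ and the curves are identified through the
  population, not through repeated measures.

## Discretization and priors

The curves are represented by their values at $N$ uniformly spaced grid
points spanning the observed covariate range ($N = 50$ by default; the grid
size is the number of MCMC parameters per curve). Evaluating the likelihood
requires curve values at the measurement points, obtained by GP conditional-
mean interpolation, a fixed linear map $W$ with rows
$c_*^\top C_g^{-1}$. Two numerical details: a diagonal jitter of
$10^{-8}\tau^2$ (escalating tenfold up to $10^{-4}\tau^2$ only if the
Cholesky factorization fails) keeps the grid covariance well conditioned, and
the jitter is treated as a nugget — it also enters the cross-covariance at
zero distance — so interpolation reproduces the knots exactly, and duplicate
covariate values simply repeat rows of $W$. User-supplied prediction points
outside the grid are clamped to the nearest endpoint with a warning; the grid
always spans the data, so fitting never hits this path.

Hyperparameter defaults, and why:

| parameter | default | rationale |
|---|---|---|
| magnitude $\tau^2$ | 1 | after scaling (below), 95% of prior variance mass on the original scale falls in $(e^{-1.96}, e^{1.96}) \approx (0.14,\ 7.1)$ |
| smoothness $\nu$ | 1.5 | once mean-square differentiable curves; closed-form kernel |
| length-scale $\ell$ | covariate range | regular curves with room for local variation; raise it for straighter curves |
| grid size $N$ | 50 | resolves curves the prior can express while keeping $2N$ MCMC dimensions modest |

Phenotypes are scaled to sample variance exactly 2 before fitting (divide by
$\mathrm{sd}(y)/\sqrt{2}$): at $h^2 = 0.5$ both components then average 1,
i.e. 0 on the log scale, matching the zero-mean prior. All reported variances
are rescaled back to original units by the squared factor; heritability is
scale-free. The hyperparameters are fixed, not estimated — joint sampling of
$\tau^2, \nu, \ell$ with the curves is deliberately out of scope.

## Estimation

**MAP first.** A damped Newton ascent maximizes the log-posterior, replacing
the Hessian with the *Bayesian average-information* matrix
$\mathrm{BAI} = \mathrm{AI} + \mathrm{blockdiag}(C_g^{-1}, C_g^{-1})$, where
$\mathrm{AI}_{ij} = \tfrac12 y^\top P (\partial K/\partial s_i) P
(\partial K/\partial s_j) P y$ is the average of observed and expected
information, kept in the positive (information) convention so the update
$s \leftarrow s + \alpha\,\mathrm{BAI}^{-1} \nabla \log \pi$ with backtracking
$\alpha$ is a monotone ascent. Initialization at $s = 0$ (the prior mean —
sensible precisely because of the variance-2 scaling), tolerance
$\lVert\nabla\rVert_\infty < 10^{-4}$, at most 100 iterations. If BAI is
numerically non-PD, a ridge of $10^{-8}\,\mathrm{tr}/2N$ is added,
escalating tenfold.

**Then preconditioned MALA.** The chain uses the Langevin proposal
$s' = s + \tau A \nabla\log\pi(s) + \sqrt{2\tau}\,A^{1/2}\varepsilon$ with
Metropolis–Hastings correction, where $A = \mathrm{BAI}(\hat s_{MAP})^{-1}$
is computed **once** at the MAP (a global preconditioner; recomputing
curvature every iteration would triple the per-iteration cost for little
gain, and chains converge within a few thousand iterations under the global
one). $A^{1/2}$ comes from a symmetric eigendecomposition. The step size is
adapted on the log scale during burn-in by Robbins–Monro targeting the MALA
optimum acceptance rate 0.574 and frozen afterwards; defaults are 5000 total
iterations with the first half discarded. Non-finite proposals are rejected
outright.

Each MALA iteration costs one Cholesky factorization and inversion of the
$n \times n$ matrix $K$ (the gradient needs the dense projection $P$ for the
trace term), so runtime scales as $n^3$ per iteration; at $n$ in the high
hundreds a full default fit takes minutes on one core.

**Summaries.** Every kept state is transformed to variance curves
($\exp$, then rescaling) and heritability *per sample*; pointwise posterior
means and 2.5/97.5% quantiles form the point estimates and 95% credible
bands (pointwise, not simultaneous). Bands therefore respect the range
constraints automatically: variances positive, $h^2 \in [0,1]$.

## The simulation generators

`sim_gp_replicate()` draws data from the model's own generative assumptions:
log-variance curves from a smooth Matérn GP ($\nu = 2.5$, $\ell = 1$,
$\tau^2 = 1$ — smoother than the analysis prior), covariates uniform on
$[-1, 1]$, a relationship matrix $G_{ij} = e^{-200|u_i - u_j|}$ from standard-
uniform $u$ (unit diagonal, strong local relatedness blocks), and
$y = r\mathbf{1} + Lw$ with $L$ the Cholesky factor of $K$, $w$ standard
normal, and intercept $r \sim U(0,1)$. Truth curves are recorded after
interpolation to the covariate points, in that order (interpolate, then
exponentiate), matching how the data were built.

`sim_rrm_replicate()` generates from a *different* model family —
order-$q$ polynomial random regressions ($q \in \{1,2\}$) whose
per-individual coefficient covariances $L_G L_G^\top$, $L_E L_E^\top$ have
lower-triangular entries drawn $U(-1,1)$ — giving variance curves that are
polynomials of order $2q$, outside the GP analysis model. Degenerate draws
(numerically zero truth variance somewhere) are resampled and logged. The
Kronecker-structured covariance is assembled per pair as
$K_{ij} = G_{ij}\,\phi_i^\top \Sigma_G \phi_j + 1[i{=}j]\,
\phi_i^\top \Sigma_E \phi_i$.

What the generators deliberately do **not** emulate: genotype-derived
relationship matrices with realistic LD structure, non-Gaussian residuals,
covariate measurement error, and missingness. Passing the recovery tests
shows the estimator is correct under its stated assumptions and robust to
polynomial-shaped truths; it does not certify performance on any particular
real population.

## Accuracy metric and replication scales

Accuracy is the normalized mean squared error
$\mathrm{NMSE} = \lVert\hat\sigma^2 - \sigma^2\rVert^2 /
\lVert\sigma^2\rVert^2$, evaluated at the measured covariate points (that is
where the generators define truth per individual; posterior-mean curves are
interpolated from the grid to those points). Replicated benchmarks report the
median and raw median absolute deviation across replicates, with
per-replicate seeds expanded from a master seed by a recorded counter scheme.

The package's desk-scale replication choices, stated once here and used by
the test suite and the acceptance script: benchmark cells run $n = 500$
individuals with 5 replicates and 1500 MALA iterations in the acceptance
script, and 3 replicates with 1000 iterations inside the test suite (the
full-scale study mirrored by those cells used $n = 1000$, 100 replicates,
5000 iterations; median NMSE grows as $n$ shrinks and the genetic-curve NMSE
is strongly right-skewed across replicates, so desk-scale medians sit above
full-scale ones). The in-suite recovery checks use $n = 500$ with 800
iterations for band coverage, and $n \in \{200, 500, 1000\}$ with 400
iterations for the sample-size monotonicity check. With the
information-preconditioned sampler started at the MAP, a few hundred kept
samples already pin the posterior mean to well within the replicate-to-
replicate spread; chain length mainly tightens the bands.

## Design choices that were genuinely open

* **Information-matrix sign convention.** AI is stored positive
  (semidefinite); BAI adds the prior precision; the Newton step *adds*
  $\mathrm{BAI}^{-1}\nabla$. Any other sign pairing turns the update into a
  descent step.
* **NMSE evaluation points.** Truths are defined per individual, so curves
  are compared at the measured covariate points rather than at grid points.
* **Burn-in.** No published discard rule; default is the first 50%,
  configurable.
* **Scaling.** "Variance 2" is enforced exactly (divide by
  $\mathrm{sd}/\sqrt 2$); a description of the same step as dividing by half
  the standard deviation would yield variance 4 and break the
  zero-log-mean argument, so the variance-2 reading is implemented.
* **Back-transformation.** Summaries are reported in original data units
  (factor$^2$); the scaled-scale chain is kept in the fit object for anyone
  who wants the unitless view.

## Limitations

Fixed GP hyperparameters (no joint estimation); uniform grids only; two
random terms only (no dominance/epistasis); diagonal $D$ matrices, so
gene–covariate interaction enters only through variance scaling, not through
sign-switching effect profiles; dense linear algebra, practical to a few
thousand individuals. Uncertainty grows sharply near the covariate
boundaries and in sparsely sampled covariate regions — the credible bands
show this honestly rather than hiding it.

## A worked run

```{r, eval = FALSE}
library(gprebe)
rep <- sim_gp_replicate(n = 500, seed = 1)
fit <- gprebe(rep$y, rep$t, rep$G, iterations = 2000, seed = 2)
print(fit)
plot(fit, truth = rep)
est <- interp_curves(fit, rep$t)
c(genetic = nmse(est$sigmaG2, rep$sigma_g2),
  residual = nmse(est$sigmaE2, rep$sigma_e2))
```

The same pipeline is scriptable from a shell via `inst/cli/gprebe`
(subcommands `fit`, `simulate`, `benchmark`).
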