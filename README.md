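# gprebe

Dynamic variance components and heritability from **one measurement per
individual**, by Gaussian-process restricted Bayesian estimation.

## The problem

Many traits — carcass quality, wood density, frost damage — can be measured
only once per individual, often destructively, so longitudinal designs are
impossible. But a sample spanning a wide range of a continuous covariate
(age, temperature, weight, ...) is *group-level longitudinal*: the population
collectively covers the axis no individual can. `gprebe` is for quantitative
geneticists who want to know how the additive-genetic variance σ²_G(t), the
residual variance σ²_E(t), and the narrow-sense heritability

    h²(t) = σ²_G(t) / (σ²_G(t) + σ²_E(t))

change along that covariate, given per-individual phenotypes y, covariate
values t, and an additive relationship matrix G (pedigree- or
marker-derived). It also covers reaction-norm settings, where the covariate
is an environmental variable measured once per individual.

## The model and estimator

Phenotypes follow the mixed model y = Xβ + u + e with
u ~ N(0, D_G G D_G), e ~ N(0, D_E²), where (D_G)_ii = σ_G(t_i) and
(D_E)_ii = σ_E(t_i): relatedness transmits a covariate-dependent amount of
variance while residuals stay independent. The log-variance curves carry
zero-mean Matérn Gaussian-process smoothing priors, represented at 50 grid
points spanning the data and carried to the measurement points by GP
interpolation — smoothness is a prior, not a basis choice.

The posterior is built on the **restricted (REML) likelihood**

    ℓ_R = −½ log|K| − ½ log|XᵀK⁻¹X| − ½ yᵀPy,   K = D_G G D_G + D_E²,

so fixed effects are never estimated. Inference: Newton ascent to the MAP
with the Hessian replaced by the Bayesian average-information (BAI) matrix,
then Metropolis-adjusted Langevin (MALA) sampling preconditioned with the
inverse BAI frozen at the MAP, with step size adapted to the 0.574 optimal
acceptance rate during burn-in. Point estimates are pointwise posterior
means; uncertainty is pointwise 95% credible bands, computed per sample so
variances stay positive and h² stays in [0, 1] by construction.

## Worked example

```r
library(gprebe)

rep <- sim_gp_replicate(n = 500, seed = 1)   # data with known truth curves
fit <- gprebe(rep$y, rep$t, rep$G, iterations = 2000, seed = 2)
print(fit)
#> Dynamic variance-component fit (GP restricted Bayesian estimation)
#>   n = 500, grid = 50 points on [-0.9963, 0.9922]
#>   MALA: 2000 iterations, acceptance rate 0.54, step size 0.305
#>   MAP converged in 10 Newton iterations (grad sup-norm 8.9e-05)
#>   posterior-mean heritability: 0.58 to 0.94 across the grid

head(fit$summary, 3)
#>            t sigmaE2_mean sigmaE2_lo sigmaE2_hi sigmaG2_mean sigmaG2_lo
#> 1 -0.9963263    0.9728838  0.5472582   1.676148     1.350050  0.7279685
#> 2 -0.9557450    0.9386199  0.5567179   1.575907     1.338062  0.7476991
#> 3 -0.9151638    0.9027857  0.5630328   1.476719     1.327263  0.7526131
#>   sigmaG2_hi   h2_mean     h2_lo     h2_hi
#> 1   2.141571 0.5767230 0.3313851 0.7571177
#> 2   2.089637 0.5832386 0.3470858 0.7554311
#> 3   2.048131 0.5904983 0.3662950 0.7511506

est <- interp_curves(fit, rep$t)             # curves at the covariate points
c(genetic = nmse(est$sigmaG2, rep$sigma_g2),
  residual = nmse(est$sigmaE2, rep$sigma_e2))
#>    genetic   residual
#> 0.02865272 0.01767738
```

Each summary row is one grid point: posterior mean and 95% band for the
residual variance, genetic variance and heritability in the original data
units. The MALA acceptance rate sits near the adaptation target, and both
posterior-mean curves land within ~3% (normalized mean squared error) of
the generating truth for this replicate.

The same pipeline is available from a shell:

```sh
inst/cli/gprebe simulate --generator gp --n 500 --seed 1 --out sim
inst/cli/gprebe fit --phenotype sim_phenotypes.csv --covariate-column covariate \
    --grm sim_grm.txt --id-column id --seed 2 --out fit
inst/cli/gprebe benchmark --generator rrm1 --n 300 --replicates 5 --seed 3 --out bench
```

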