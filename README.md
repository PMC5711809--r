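# mstfit

Robust Bayesian and least-squares estimation of binding affinity from
titration data, built for MicroScale Thermophoresis (MST) dose–response
curves but applicable to any scalar titration readout.

## The problem

MST titrations measure a normalized fluorescence response of a labelled
protein (here: human survivin against peptide ligands) across a serial
two-fold dilution of its binding partner. Two practical nuisances make the
classical analysis fragile:

* **Outliers.** A few percent signal change per binding event means that
  aggregation, adsorption or pipetting slips routinely produce anomalous
  points. Non-linear least squares (NLLSQ) weighs each point by its squared
  residual, so a single outlier can displace the estimated dissociation
  constant by an order of magnitude; manual outlier rejection reintroduces
  subjective bias.
* **Concentration error.** Serial dilution compounds pipetting error
  multiplicatively: each step multiplies the previous concentration by
  `N_a / (N_a + N_b)` with `N_a, N_b` normal pipetted volumes, a biased
  random walk whose spread grows down the series.

## The model

The response at ligand concentration `c` follows the law of mass action
for a 1:1 complex with the labelled partner at fixed concentration `c_fl`:

    f(c) = U + (B − U) · (c_fl + c + K_D − sqrt((c_fl + c + K_D)² − 4 c_fl c)) / (2 c_fl)

where `U` and `B` are the unbound and fully bound response plateaus. The
robust model observes each point through a Student-t likelihood with
location `f(c)`, integer degrees of freedom `ν ∈ [1, 30]` and
precision-like scale `λ`, under bounded priors: `K_D ~ U(1, 10⁶)` nM,
`U, B ~ U(0, 1000)`, `c_fl ~ N(c_fl,nom, τ = 10·c_fl,nom)` truncated to
`(0, 10⁵)` nM, `ν ~ U{1..30}`, `λ ~ U(0, 100)`. The joint posterior is
sampled by MCMC (JAGS; 5000 kept iterations after 1000 warm-up by
default). The heavy t tails let outliers live in the tails instead of
dragging the curve. The classical comparator is a 3-parameter
Levenberg–Marquardt fit with per-parameter confidence intervals from the
F-statistic profile criterion `RSS(p) < RSS·(1 + F(1, N−P) / (N−P))`.

Binding free energy is reported as `ΔG = RT ln K_D` (K_D in molar, 1 M
reference state, default T = 297.15 K).

## Worked example

```r
library(mstfit)

# a benchmark dataset: true KD 5 uM, plateaus 780/800, noise sd 1,
# 3 replicate 16-point dilution series, 20% uniform outliers
d <- generate_dataset(case_params(1, seed = 42))

fit <- fit_bayes(d, mcmc = mcmc_config(seed = 42))
summary(fit)
#> Robust Bayesian binding fit: 48 points; 95% HDI; T = 297.15 K
#>       parameter   median hdi_lower hdi_upper
#>           kd_nM 4094.000 3289.0000  4923.000
#>               u  800.300  799.5000   801.300
#>               b  780.100  779.6000   780.600
#>          cfl_nM   50.000   49.9100    50.090
#>              nu    1.000    1.0000     1.000
#>          lambda    2.099    0.6794     4.351
#>  delta_G_kJ_mol  -30.650  -31.1300   -30.140
#> max split R-hat 1.004; min ESS 708

summary(fit_nllsq(d))
#> NLLSQ binding fit: 48 points, RSS 813.882, converged TRUE
#>   kd_nM  2656  [1180, 6264]
#>   u      799.5  [797.2, 802]
#>   b      781.3  [778.8, 783.5]
#>   delta G = -31.7 kJ/mol at 297.15 K
```

Against the true K_D of 5 µM the robust posterior median (4.1 µM, HDI
3.3–4.9 µM) sits much closer than the outlier-dragged NLLSQ estimate
(2.7 µM), and the NLLSQ confidence interval (1.2–6.3 µM) is several times
wider than the credible interval — the typical pattern on contaminated
data. `plot(fit)` overlays the data, a swarm of posterior binding curves
and the median curve; `compare_affinities(fit_a, fit_b)` turns two
posteriors into `P(K_D_A < K_D_B)`.

A command-line front end with `simulate` / `fit-bayes` / `fit-nllsq` /
`compare` / `fnorm` / `benchmark` subcommands lives at
`inst/cli/mstfit.R`.

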