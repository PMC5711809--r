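---
title: "Robust Bayesian estimation of binding affinity from MST titrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust Bayesian estimation of binding affinity from MST titrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstfit)
```

## Scope and model

MicroScale Thermophoresis (MST) quantifies binding by the change in a
normalized fluorescence response of a labelled protein as an unlabelled
partner is titrated across a serial dilution. `mstfit` estimates the
dissociation constant $K_D$ of a 1:1 interaction from such titrations by
two routes: a robust Bayesian model and a classical non-linear
least-squares (NLLSQ) fit, deliberately kept side by side so their
behaviour on imperfect data can be compared.

Both routes share the deterministic response model. With the labelled
partner at fixed concentration $c_{fl}$ and ligand at $c$, mass action
gives the bound fraction as the physical root of the binding quadratic,
and the expected response

$$f(c) = U + (B-U)\,
  \frac{c_{fl}+c+K_D-\sqrt{(c_{fl}+c+K_D)^2-4c_{fl}c}}{2c_{fl}},$$

interpolating between the unbound plateau $U$ (no ligand) and the bound
plateau $B$ (saturation). We evaluate the root in the conjugate form
$2c/(s+\sqrt{s^2-4c_{fl}c})$, $s = c_{fl}+c+K_D$: the naive numerator is
a difference of nearly equal numbers at trace $c$ and loses all
significant digits exactly where binding curves have their low plateau.
The bound fraction is clamped to $[0,1]$ against floating-point
excursions. A bisection solver for the underlying equilibrium polynomial
is kept in the test suite as an independent oracle for this closed form.

### Observation model and priors

The robust model assumes each observed response $D(c)$ follows a
Student-t distribution centred on $f(c)$:

$$p(D \mid \mu, \nu, \lambda) =
  \frac{\Gamma\!\left(\tfrac{\nu+1}{2}\right)}
       {\Gamma\!\left(\tfrac{\nu}{2}\right)}
  \sqrt{\frac{\lambda}{\pi\nu}}
  \left[1+\frac{\lambda (D-\mu)^2}{\nu}\right]^{-\frac{\nu+1}{2}},$$

with integer degrees of freedom $\nu$ and a precision-like scale
$\lambda$. Small $\nu$ gives heavy tails: an aberrant point far from the
curve costs only logarithmically, so it settles in the tail instead of
dragging the location. $\nu$ is itself estimated, letting the data choose
between near-Cauchy ($\nu=1$) and near-normal ($\nu=30$) regimes. On
heavily contaminated data the posterior typically collapses to small
$\nu$ — that is the robustness mechanism working, not a pathology.

Priors are bounded and weak: $K_D \sim \mathcal U(1, 10^6)$ nM,
$U, B \sim \mathcal U(0, 1000)$ (the per-mil response window),
$\nu \sim \mathcal U\{1..30\}$, $\lambda \sim \mathcal U(0, 100)$, and
$c_{fl} \sim \mathcal N(c_{fl,\mathrm{nom}}, \tau = 10\,c_{fl,\mathrm{nom}})$
truncated to $(0, 10^5)$ nM. Two of these deserve comment.

* The $c_{fl}$ prior precision scaling linearly with the nominal
  concentration is unusual (a CoV-style width would scale the *standard
  deviation* with concentration); it makes the prior extremely tight at
  nanomolar scale (sd $\approx 0.045$ nM at 50 nM). We keep it as the
  reference behaviour because $c_{fl}$ is fixed by the experimental
  setup and nearly known; `prior_config(cfl_tau = ...)` overrides it.
* $K_D$ is sampled on its natural scale under a flat prior. This weights
  the prior mass towards large $K_D$; a scale-free alternative
  (`kd_log10 = TRUE`) samples $\log_{10} K_D$ uniformly instead, but is
  off by default to keep the flat-prior reference behaviour.

When responses fall outside the $(0, 1000)$ window (raw fluorescence
counts, say), `fit_bayes()` maps them affinely into it, samples, and maps
$U$, $B$ and $\lambda$ back, recording the map in the fit — rescaling,
never silent truncation.

### Sampling

The joint posterior of $(K_D, U, B, c_{fl}, \nu, \lambda)$ is sampled via
JAGS: adaptive Metropolis/slice-within-Gibbs updates for the continuous
parameters and categorical Gibbs for the integer $\nu$, whose
discreteness rules out gradient-based samplers. We chose JAGS over a
hand-rolled sampler for the same reason the model itself is worth using:
a battle-tested engine removes a whole class of correctness risk, and the
model's JAGS `dt(mu, lambda, nu)` observation node is exactly the density
above. Defaults are 5000 kept iterations after 1000 discarded warm-up
iterations in a single chain, which mixes well on 16–160-point titrations
(typical minimum effective sample sizes in the hundreds). Chains are
seeded individually (`seed + chain − 1`), so every fit is reproducible
from its configuration. With `n_chains >= 2` the fit reports a
split-chain $\widehat R$; values above 1.05 raise a warning — advisory,
never an error, since a long single chain is the reference configuration.

Posterior summaries use the median as the headline point estimate and the
95% highest density interval (HDI) — the narrowest contiguous interval
holding 95% of the draws, computed by an exact sorted-window scan (ties
broken to the lowest window). For skewed marginals like $K_D$ the HDI is
asymmetric around the median; that is expected.

### The classical comparator

`fit_nllsq()` minimizes the residual sum of squares with the MINPACK
Levenberg–Marquardt implementation (`minpack.lm::nls.lm`), with $K_D$
optimized on the log scale to keep it positive. $c_{fl}$ is held at its
nominal value, so $P = 3$ parameters; treating $c_{fl}$ as free would
change the degrees of freedom in the interval criterion below and is not
the comparator's standard form. Default starting values are data-driven
and scale-free: $U_0$ and $B_0$ from the mean response at the three
lowest/highest concentrations, $K_{D,0}$ at the geometric mean of the
concentration range.

Confidence intervals come from the F-statistic profile criterion: the
interval for parameter $p$ is the set where the re-minimized profile
$\mathrm{RSS}(p)$ stays below
$\mathrm{RSS}\,(1 + F_{1,N-P}(0.95)/(N-P))$. Profiling $K_D$ exploits
that the model is linear in $(U, B)$ at fixed $K_D$ (an exact
least-squares solve per profile point); profiling $U$ or $B$ re-runs the
one-dimensional nonlinear minimization warm-started at the optimum.
Endpoints are located by outward bracketing (multiplicative steps for
$K_D$) and root finding to $|\mathrm{RSS}(p_{end}) - \mathrm{thr}| <
10^{-6}\,\mathrm{RSS}$. A profile that never reaches the threshold inside
the search window ($[10^{-3}, 10^6]$ nM for $K_D$, $\pm 10\times$ the
response range for $U$, $B$) is reported at the window edge and flagged
open-ended — the signature of an unidentified parameter, e.g. a titration
that never approaches saturation. The criterion is also available in the
joint-region form $1 + P\,F_{P,N-P}/(N-P)$ via `threshold = "joint"`.
With near-zero RSS (noiseless data) the threshold collapses onto the
minimum and the interval degenerates to the estimate, by construction.

## What the synthetic generator emulates

`generate_dataset()` builds benchmark datasets whose error structure is
deliberately *not* what either fitter assumes:

1. **Serial-dilution error.** Each replicate gets a fresh simulated
   two-fold dilution: step $k$ multiplies the previous concentration by
   $N_{a,k}/(N_{a,k}+N_{b,k})$, both volumes normal around the targeted
   volume with the pipette's CoV and redrawn if non-positive (a physical
   volume cannot be $\le 0$; at realistic CoV the truncation is
   unobservable). Draws are consumed pairwise per step, so the series is
   Markov in the step index. Errors compound multiplicatively, and the
   ratio's asymmetry biases late concentrations low once CoV reaches a
   few percent — at CoV $\le 1\%$ (ISO 8655 pipettes) the deviation is
   negligible on the log scale. The fitters only ever see the *targeted*
   concentrations, as a real analyst would.
2. **Measurement noise** is i.i.d. normal at response level, applied once
   per observation (it does not scale with dilution step).
3. **Outliers.** $\lfloor 0.2\,N\rfloor$ points (exactly; chosen without
   replacement across the whole dataset) are replaced by draws from a
   uniform covering the $U$–$B$ range widened by $0.25\,|B-U|$ on both
   sides — anomalies anywhere in (and slightly beyond) the plausible
   response range, with no relation to the curve.

The ten-case benchmark grid (`table1_cases()`) varies true $K_D$
(0.05–5 µM), amplitude ($|B-U|$ 5 or 20), noise sd (0.5–2), pipette
volume sd (0.1 or 0.2 µl) and replicate count (1/3/10). Three constants
are not part of the published grid and were fixed here once, at values a
practitioner would call typical, and kept: labelled-partner concentration
50 nM; stock ligand at $100 \times K_D$ (so the 16-point two-fold series
spans roughly $100\,K_D$ down to $0.003\,K_D$, bracketing the sigmoid);
and a 10 µl targeted transfer volume, which converts the grid's absolute
volume sd of 0.1–2 µl into CoV 1–20%. All are overridable per dataset.
The generator does **not** emulate ligand-induced fluorescence quenching,
aggregation, adsorption, or capillary-shape artifacts — passing the
benchmark says nothing about those failure modes, and on real data with
structured (non-uniform, curve-correlated) anomalies the robust model's
advantage may be smaller.

Trace reduction (`fnorm()`) turns raw time traces into responses as the
per-mil hot/cold window ratio, $1000 \cdot \bar F_{hot}/\bar F_{cold}$,
with the cold window at $(-3, -1)$ s before the IR pulse and the hot
window at $(27, 29)$ s — late enough that the fast temperature-jump
response and the slower thermophoretic depletion have both developed; the
single ratio deliberately reports their combination. The per-mil scale
matches the instrument convention and the $\sim$700–930 response
magnitudes the plateaus' priors anticipate (`scale = 1` gives a plain
ratio). Optional cold-anchored detrending (fit a line on the cold window,
reference the hot mean to its extrapolation) cancels linear
photobleaching exactly.

## Problem sizes and reproducibility

The simulation-study checks in the test suite run the full sampler
configuration (5000 kept draws) on datasets of 16–160 points: ten seeds
each of benchmark cases 8 and 2 for recovery, one fixed-seed pass over
all ten cases for HDI coverage, and fifty seeded case-1 datasets for the
robustness comparison against NLLSQ — sizes at which a complete fit takes
seconds, so the whole study is a desk-scale computation. Unit tests use
shorter chains (1500–3000 draws), which suffice for point-estimate
checks. Every random quantity (dilution draws, noise, outlier placement,
MCMC) is a deterministic function of an explicit integer seed.

## Known limitations

* Single-site 1:1 binding only: no cooperativity, kinetics, or
  enthalpy/entropy decomposition; $\Delta G = RT\ln K_D$ at the 1 M
  reference state is the only thermodynamic output.
* The flat $K_D$ prior is informative on the log scale; for very weak or
  very tight binders relative to the bounds, use `kd_log10 = TRUE` and
  check sensitivity.
* A posterior median inside the HDI of a *single* dataset does not
  certify calibration; the coverage property is a statement across
  repeated simulated experiments.
* The NLLSQ profile CI search window is finite by design; truly flat
  profiles are reported open-ended rather than infinite.
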