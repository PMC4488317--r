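---
title: "Methods: crop-growth-model informed whole-genome prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crop-growth-model informed whole-genome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmwgp)
```

## The problem

Conventional whole-genome prediction (WGP) regresses a phenotype such as
grain yield directly on genome-wide markers. That works well for additive
traits and across-environment means, but yield is the end product of
nonlinear physiological dynamics interacting with weather and management.
Two consequences follow: purely additive marker models miss the *biological
epistasis* that arises when additive effects on component traits combine
nonlinearly into yield, and they carry no environmental input at all, so
they cannot anticipate genotype-by-environment (G×E) rank changes in an
environment that contributed no training data.

`cgmwgp` implements an alternative: embed a deterministic maize crop growth
model (CGM) inside the estimation of marker effects. Four physiological
traits — total leaf number (TLN), area of the largest leaf (AM, cm²),
solar radiation use efficiency (SRE, g MJ⁻¹) and thermal units to
physiological maturity (MTU, °C·day) — are treated as latent variables,
each a linear function of the observed markers:

$$
y_{\tau i} = \mu_\tau + \mathbf{z}_i \mathbf{u}_\tau,
\qquad \tau \in \{\mathrm{TLN}, \mathrm{AM}, \mathrm{SRE}, \mathrm{MTU}\},
$$

and yield for line $i$ in environment $k$ is the CGM evaluated at those
traits under that environment's weather and management,
$F(\cdot)_{ik}$. The likelihood of the joint parameter vector
$\theta = [\mu_{TLN},\dots,\mu_{MTU},\mathbf{u}_{TLN},\dots,\mathbf{u}_{MTU}]$
is intractable, so $\theta$ is estimated by approximate Bayesian
computation (ABC) rejection sampling: draw $\theta$ from its prior,
simulate yields through the CGM plus Gaussian noise, and accept the draw
when the Euclidean distance to the observed yields falls below a tolerance
$\epsilon$.

## The crop growth model

`simulate_genotype()` advances a daily time step from sowing. The
structure is the classical radiation-capture formulation for temperate
maize:

* **Thermal time.** Daily increment $\max(0, T_{avg} - T_{base})$ with
  $T_{base} = 8$ °C.
* **Phenology.** Emergence after 87 °Cd; one leaf fully expands per
  phyllochron of 21 °Cd; silking follows the last leaf by 50 °Cd;
  effective grain fill starts 100 °Cd after silking; growth stops at the
  earlier of MTU and the end of the season (the season cap is enforced
  regardless of maturity).
* **Canopy.** Individual leaf area follows a bell curve around the largest
  leaf, $A(x) = AM \exp(a (x - x_0)^2 + b (x - x_0)^3)$ with
  $a = -0.0344$, $b = 0.000731$ and $x_0 = 0.67\,\mathrm{TLN}$; leaf area
  per plant (LAPP) is the running sum over expanded leaves, interpolated
  within the currently expanding leaf so non-integer TLN (e.g. 14.5) is
  meaningful. Senescence removes a fraction of expanded area that rises
  quadratically from silking to complete senescence 800 °Cd later.
* **Growth.** Daily dry matter is intercepted radiation times conversion
  efficiency, $DM_g = SR \times SRE \times (1 - e^{-k\,LAPP\,PPOP})$ with
  extinction coefficient $k = 0.4$.
* **Grain.** Harvest index rises linearly at 0.015 day⁻¹ once grain fill
  starts, capped at 0.5; grain yield is harvest index times cumulative
  biomass.

The cited literature for this model family does not pin down a unique
coefficient set, so the defaults in `cgm_params()` are a single frozen,
physiologically reasonable choice, shipped as configuration and
overridable. Two internal-consistency constraints drove the choice. First,
silking plus the grain-fill lag must precede the lower end of the MTU
interval for every TLN in $[6, 23]$ (with the defaults,
$87 + 23 \times 21 + 50 + 100 = 720 < 1050$ °Cd), so every genotype in the
simulated ranges has a positive potential grain-fill window. Second, the
senescence schedule is deliberately a fixed thermal-time program after
silking, *not* a function of MTU: this makes "raising MTU beyond what the
season can supply" exactly neutral, which is the saturation behaviour the
physiology implies.

These choices generate the mechanisms the method exploits. Yield over TLN
follows an optimum curve: low TLN forfeits canopy, high TLN delays silking
and forfeits grain-fill time, so intermediate TLN wins, most sharply in a
short season. The engine is total: negative SRE or AM are clamped to zero,
non-positive TLN gives no canopy, non-positive MTU means immediate
maturity. ABC proposes absurd parameter values routinely; they must earn
large distances, not exceptions.

## Environments and synthetic weather

An environment is weather from sowing plus management:
season length and plant population (`cgm_environment()`). The default pair
mimics a US Corn Belt contrast: sowing April 15, 120 days, 8 plants m⁻²
versus sowing May 15, 130 days, 10 plants m⁻². Weather is synthesised as a
sinusoidal annual cycle (temperature mean 8 °C, amplitude 12.5 °C, peak
day-of-year 200; radiation mean 13–14 MJ m⁻² day⁻¹, amplitude 9) with
i.i.d. Gaussian day-to-day noise (σ = 3 °C, 3.5 MJ).

The climate mean was calibrated — once, as part of the design — so the
short season accumulates roughly 1000–1100 °Cd, *below* the entire
simulated MTU interval, while the long season accumulates 1300–1400 °Cd
and matures nearly everything. The consequence is that maturity genetics
are inert in the short environment and active in the long one, and late
canopies are unrewarded only in the short season. That asymmetry produces
crossover G×E with a between-environment Spearman correlation of true
yields around 0.5–0.7 across replicate datasets, the regime in which
environment-aware prediction can demonstrate its value. A real-weather
counterpart (two specific Illinois years) sits in the same regime; no
attempt is made to digitise actual station records, and `read_weather()`
accepts real CSV series when they are available.

What the generator does *not* emulate: water and nitrogen stress, soil
processes, within-day dynamics, spatial field trends, non-Gaussian
measurement error, and weather autocorrelation beyond the seasonal curve.
Passing tests therefore demonstrate internal correctness of the method
under a known data-generating process — the proof-of-concept setting —
not performance on real trials.

## The synthetic population

One chromosome of 1.5 Morgan carries 140 equidistant SNPs. Doubled-haploid
lines are single gametes doubled; meiosis uses Poisson crossover counts
with uniform breakpoints (Haldane model, no interference) and a fair-coin
starting parent. Forty random markers become QTL — ten per trait, disjoint
— with standard-Normal additive effects, and are removed from the observed
panel (leaving 100 markers). Raw per-trait QTL scores are rescaled
affinely so the realized population minimum and maximum land on the trait
interval endpoints (TLN [6, 23], AM [700, 800], SRE [1.5, 1.7], MTU
[1050, 1250]). The interval-endpoint map was chosen over a mean-centred
alternative because it guarantees containment; with symmetric effects the
population mean lands near the midpoint anyway, and the realized mean is
recorded. Phenotypes add Gaussian noise with variance
$v_e = \mathrm{var}(F(\cdot)_{ik})(1 - h^2)/h^2$ per environment, giving a
within-environment heritability of $h^2 = 0.85$ by construction.

Each dataset replicate takes one master seed; sub-seeds for weather,
meiosis, architecture and noise are derived deterministically from it
(`derive_seeds()`), so replicates are independent and each stage is
individually reproducible.

## Priors, tolerance, and the sampler

Priors are independent Normals. To emulate imperfect extraneous
information, the prior means and variances are perturbed: each intercept
mean is drawn once per estimation run from
$U[0.8\,\bar{\tau}, 1.2\,\bar{\tau}]$ (average relative bias 10%), each
trait's shared marker-effect variance from
$U[0.8\,\mathrm{var}(\tau)/M, 1.2\,\mathrm{var}(\tau)/M]$, and the noise
variance from $U[0.8\,v_e, 1.2\,v_e]$. Intercept prior standard deviations
are fixed at (2.25, 150, 0.3, 225) for (TLN, AM, SRE, MTU). The shared
marker-effect variance is BayesC-style shrinkage held constant — it is not
estimated. Hyper-draws happen once per run, not per proposal, and are
recorded with the fit.

The tolerance is tuned empirically: simulate `n_pilot` prior predictive
distances exactly as in the main run and take the lower empirical quantile
(linear interpolation) at the target acceptance rate. The distance is the
unstandardised Euclidean norm on yields; whether the square root is taken
is immaterial to acceptance (monotone transform), and the square root is
used. The model operator adds $N(0, \sigma_e^2)$ noise to the
deterministic CGM yield — with a fully deterministic operator the sampled
distribution would not converge to the posterior as $\epsilon \to 0$.

The rejection sampler vectorises proposals in batches (a flattened
growth-model pass over all line-by-proposal combinations) and partitions
work across workers with independent derived RNG streams and fixed
per-worker acceptance quotas, so results are identical for a given seed
and worker count regardless of scheduling. Posterior predictions average
the deterministic CGM over accepted draws under the *target* environment's
weather — this is where environment-specific prediction enters. No noise
is added to predictions (it has mean zero).

## The GBLUP benchmark

`fit_gblup()` is a self-contained ridge-type genomic mixed model
$y = \beta_0 + \mathbf{z}_i \mathbf{u} + e$. Variance components come from
REML via the one-dimensional spectral profile likelihood (eigendecomposition
of $ZZ'$ after projecting out the intercept), optimised on
$\log \lambda$ with a grid bracket plus golden-section refinement at
tolerance 1e-8; effects are recovered in the kernel form
$\mathbf{u} = Z'(ZZ' + \lambda I)^{-1}(y - \beta_0)$, which is robust to
rank-degenerate marker matrices. Markers are recoded $\{0,1\} \to
\{-1,+1\}$; results are invariant to affine recoding up to the intercept.
Constant phenotypes yield $\mathbf{u} = 0$ rather than an error. GBLUP
predictions carry no environmental input, so observed- and new-environment
predictions are identical by construction — the structural handicap the
comparison is about.

## Experiment design and problem sizes

`run_replicated_experiment()` reproduces the estimation/testing protocol:
per replicate, generate a dataset, choose a random estimation set, fit
each method separately per estimation environment, predict all test lines
in both environments, and score the Pearson correlation against *true*
performance (noiseless CGM yield from true traits — using truth rather
than noisy phenotypes removes $h^2$ attenuation from the metric).
Negative-accuracy replicates are retained in averages. The rank
correlation between environments is Spearman's, computed on test-set true
yields.

The shipped default is a desk-scale preset chosen to run a full replicated
experiment in minutes on one CPU: 225 lines (25 estimation, 200 test), 28
markers with 8 hidden QTL (2 per trait), target acceptance 1e-3, 50
posterior samples, 5 replicates. The full-scale configuration (1550
lines, 50/1500 split, 140 markers, 40 QTL, acceptance ≈ 1e-6, 100
posterior samples, 50 replicates) is expressible through the same
`experiment_config()` arguments but demands on the order of 10⁸
growth-model evaluations per fit — cluster-scale computing. At desk scale
the accuracies are lower and noisier than at full scale; what is preserved
is the mechanism and the direction of the comparison: CGM-WGP ahead of
GBLUP in the observed environment and markedly ahead in the new
environment, where GBLUP has no environmental information at all.

## Numerical and degenerate-input choices

* Leaf-count formulas are evaluated continuously; the per-line leaf count
  used for the area profile is capped at 50 as a numerical guard against
  extreme proposals.
* Zero-day seasons, all-equal phenotypes, empty QTL architectures and
  rank-degenerate marker matrices are all defined states, not errors;
  degenerate raw-score variance in trait rescaling is an error naming the
  trait, since it would make the affine map undefined.
* The tolerance quantile uses R's default type-7 (linear interpolation)
  convention; with expected pilot acceptances below one the quantile
  extrapolates and a warning is emitted.
* The ABC attempt budget (default 1e9) turns a hopeless tolerance into an
  informative error reporting the realized acceptance rate.

## Known limitations

* The CGM coefficient set is one defensible choice, not a fitted or
  literature-certified calibration; all qualitative claims are designed to
  hold for any physiologically sane set, but absolute yields shift with
  the coefficients.
* ABC rejection at desk-scale tolerances inflates posterior spread; the
  posterior is approximate by construction and latent traits are only
  weakly identified from single-environment yield data (prediction is
  identified even when parameters are not).
* The latent-trait linear model is additive within traits; pleiotropic or
  correlated QTL, dominance, multi-chromosome genomes and sequential
  Monte Carlo samplers are out of scope.
* Only two environments are modelled; the G×E the generator produces is
  entirely season-length- and weather-driven (no soil or stress axes).
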