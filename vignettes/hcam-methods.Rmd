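---
title: "Hospital compare additive models: methods and design choices"
author: "hcam authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hospital compare additive models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcam)
```

## The problem

Profiling hospitals on patient mortality requires separating three things
that raw death rates confound: the case mix a hospital happens to treat, a
smooth effect of hospital-level attributes such as volume, and a residual
hospital-specific effect. The classical tool is a random-intercept logistic
regression, but two of its standard assumptions are fragile on registry
data: the Gaussian law of the hospital random effect, and linearity of the
attribute effect on the logit scale. A third difficulty is specific to ICU
mortality: a sizeable group of patients carries essentially no mortality
risk, so zeros are over-represented relative to any one-part Bernoulli
model.

`hcam` implements a family of models that relaxes all three assumptions.

## The models

**HCAM** (hospital compare additive model). For patient $j$ in hospital
$h$ with covariates $X_{hj}$, outcome $Y_{hj}\in\{0,1\}$ and hospital
attribute $V_h$:

$$\mathrm{logit}\, p_{hj} = b_h + f(V_h) + X_{hj}^\top\beta,$$

with $E[f(V_h)] = 0$ for identifiability (the overall level lives in the
random-effect location).

*Attribute effect.* $f$ is represented by a B-spline basis of degree $d$
with $q$ equally spaced interior knots on the attribute affinely mapped to
$[0,1]$, $m_n = q + d + 1$ basis functions. Each basis column is centered by
its mean over the $H$ sample hospitals, which enforces the constraint
exactly for every coefficient vector $\gamma$ and reduces the effective
rank to $m_n - 1$ (the lost direction is the constant, deliberately). A
quantile knot option is provided for skewed attributes such as volume.
Out-of-domain evaluations clamp to the boundary: B-spline extrapolation
beyond the build domain is polynomial and wild, and bootstrap resamples
routinely step slightly outside the observed range.

*Random effect.* $b_h = \sigma z_h + a$ where $z_h$ has the
semi-nonparametric (SNP) density
$h_K(z) \propto P_K(z)^2\,\phi(z)$, a squared degree-$K$ polynomial times
the standard normal density. The constraint $E[P_K(Z)^2]=1$ (equivalently
$\xi^\top A\xi = 1$ with $A$ the matrix of standard-normal raw moments)
makes $h_K$ integrate to one. $K=0$ is exactly Gaussian; $K=2$ already
admits bimodal and skewed shapes. The constraint surface is parameterized
by $K$ hyperspherical angles through $\xi = A^{-1/2}c(\varphi)$, with the
sign fixed by $\xi_0 \ge 0$; any smooth bijection onto the surface would
do, this one is standard and easy to test. Moments of $g_K$ are closed-form
in Gaussian raw moments; sampling uses a 10,001-point inverse-CDF grid over
$a \pm 10\sigma$, accurate far beyond test tolerances since $P_K^2\phi$ has
no usable rejection envelope.

**ZI-HCAM.** A latent at-risk status $S_{hj}$ with
$\mathrm{logit}\,\rho_{hj} = T_{hj}^\top\theta$ multiplies the at-risk
mortality $\pi_{hj}$ (same linear predictor as HCAM), so
$P(Y_{hj}=1) = \rho_{hj}\pi_{hj}$. The zero-inflation part is a pure
fixed-effect logistic: no random effect enters $\rho$. Writing
$\tau = T^\top\theta$ and $\kappa$ for the HCAM predictor, each patient
contributes
$Y(\tau+\kappa) + (1-Y)\log(1+e^\tau+e^\kappa) - \log(1+e^\tau) -
\log(1+e^\kappa)$,
which is $\log(\rho\pi)$ for deaths and $\log(1-\rho\pi)$ for survivors —
an identity the tests verify symbolically on random $(\tau,\kappa)$.

## Likelihood and fitting

The marginal likelihood integrates each hospital's conditional likelihood
against $g_K$. Each one-dimensional integral is evaluated by adaptive
Gauss–Hermite quadrature: nodes are centered at the mode and scaled by the
curvature of the *Bernoulli-times-Gaussian-base* part of the log
integrand — that part is concave, so the vectorized damped-Newton mode
search is globally safe — and the squared polynomial $P_K^2$ is folded into
the integrand at the nodes. Node sums use log-sum-exp. The default is 21
nodes; because the nodes adapt per hospital, the log likelihood moves by
less than $10^{-4}$ relative when the count is varied 15 to 41 (a test),
and the reduced-scale experiments below use 9 nodes for speed, which is
indistinguishable at those tolerances.

Maximization is quasi-Newton (BFGS) with central-difference numerical
gradients (step $10^{-6}$ on unit scale). $\sigma$ is optimized as
$\log\sigma$. Convergence is declared on the optimizer's relative
log-likelihood criterion ($10^{-8}$); a gradient-norm test near machine
scale is not meaningful here because finite-difference noise is of order
$|\ell|\,\varepsilon/h \approx 0.06$ at $|\ell|\approx 600$.

Two warm-start details matter:

* $K$ is fitted along an ascending grid. Embedding the previous $\xi$
  padded with a zero top coefficient stays on the constraint surface, so
  each richer model starts at the previous solution exactly and the
  log likelihood is non-decreasing in $K$ (a tested invariant).
* That embedded point is a *stationary point* of the richer likelihood:
  the first-order directions of the new angles coincide with mean and
  variance perturbations already optimized through $(a,\sigma)$, a
  degeneracy familiar from mixture models. Quasi-Newton therefore cannot
  leave it. The fitter runs two additional perturbed-angle starts
  ($\pm 0.35$) and keeps the best optimum; an angle-grid scan at the
  scale of the experiments below found no better optima than this
  multi-start reaches.
* Zero-inflated fits are warm-started from a no-random-effect ZIB logistic
  fit (closed-form likelihood, no integration), which removed occasional
  slow ridge-following from the naive $\theta$ start.

$K$ is selected by BIC (ties to the smaller $K$), with
$p\log N$ computed on the patient count $N$ — the observation count is the
natural sample size for a likelihood that is a product over patients,
though the choice is a convention and AIC is also reported.

Empirical-Bayes hospital effects are posterior modes under the fitted
$g_K$, found by a dense-grid argmax with parabolic refinement: for $K>0$
the posterior can be multimodal, which rules out plain Newton. Posterior
means by quadrature are available as an option.

## Standardization and ranking

With $p_{\mathcal H}(X)$ the fitted probability that a patient with
covariates $X$ would die if treated at hospital $\mathcal H$ (empirical-
Bayes mode for $b_{\mathcal H}$; times $\rho(T)$ under ZIB):

* $P_h$: average of $p_h$ over hospital $h$'s own patients;
* $E_h$: each of $h$'s patients averaged over all hospitals, uniformly or
  with weights $w_{\mathcal H}$ summing to 1 ($w = n/N$ is the volume
  weighting); uniform weights reproduce the unweighted definition exactly;
* indirect rate $P^{IS}_h = (P_h/E_h)\cdot OR$, reported unclipped;
* direct rate $P^{DS}_h$: hospital $h$'s average over the covariates of
  all $N$ patients in the study. The printed inner summation limit in some
  accounts of this estimand is inconsistent with its $1/N$ normalizer; the
  sum over all patients is the only reading that makes the weights sum to
  one, and is what is implemented.

Ranks ascend in rate (1 = best), ties broken by hospital input order;
quartile labels 1–4 by rank position with group sizes differing by at most
one. Interval estimates use the registry-style resampling scheme: draws of
$m$ patient cases *without* replacement (canonically 2000 draws of 2000),
rates recomputed under the fixed fitted parameters, percentile intervals.
A with-replacement switch exists; per-replicate refitting is available
behind a flag but is not the default, as thousands of ML refits are not
proportionate for interval estimation on the case-mix component.

## The simulation harness

The generator reproduces the benchmark designs: $H$ hospitals of $n_h$
patients, $V_h \sim U(-1,1)$, $X \sim N(0, I_3)$,
$\beta = (3, 0.5, -5)$, four fixed-effect shapes
($f_1 = 2v$, $f_2 = (v-0.5)^2 - 0.5833$, $f_3 = v\cos^3 3v$,
$f_4 = e^{-2v}\sin 6v - 0.5748$) and seven mean-zero unit-variance
random-effect laws (normal; uniform; centered exponential; log-normal with
$\sigma$ solving $(e^{\sigma^2}-1)e^{\sigma^2}=1$, i.e. $0.6937$, shifted
by $e^{\sigma^2/2} = 1.2720$; symmetric two-component mixture with
component mean $\sqrt{1-0.28^2} = 0.96$; an asymmetric mixture; a $\pm 1$
discrete law), plus the bimodal mixture
$0.7N(-1.5,0.7^2) + 0.3N(2,0.7^2)$ in raw (mean $-0.45$, variance
$3.0625$) and standardized form. The exact mean of $e^{-2v}\sin 6v$ under
$U(-1,1)$ is $0.57493$ by the closed-form antiderivative; the conventional
constant $0.5748$ is kept in $f_4$ for comparability, leaving a residual
mean of about $10^{-4}$.

The ZIB design draws a separate covariate $X^* \sim N(1, 1.5^2)$ and sets
$S \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\theta X^*))$, $Y = 0$
whenever $S = 0$. Whether $X^*$ *replaces* the first mortality covariate
is ambiguous in the design's description; the default keeps it separate
(switch `share_s_covariate` for the other reading), so the printed event
proportions (32% at $\theta=2$, 11% at $\theta=-2$) are matched
qualitatively — strong zero inflation, ordering preserved — not digit for
digit. All randomness flows from one seed through named substreams
(`b`, `V`, `X`, `S`, `Y`, split), so components are independently
reproducible; forcing $\rho \equiv 1$ reproduces the one-part generator
byte for byte.

Metrics: $\mathrm{ISE} = H^{-1}\sum_h(\hat f(V_h) - f(V_h))^2$,
$\mathrm{RD} = \|\hat\beta - \beta\\|/\|\beta\|$, AUC with DeLong 95%
intervals, and accuracy/F1/PPV at a classification threshold equal to the
training-split observed event rate.

### What the generator does and does not emulate

It reproduces the benchmark's distributions, effect sizes and cluster
geometry exactly, which is what the recovery experiments need. It does not
emulate unequal cluster sizes (real registries range over two orders of
magnitude), covariate correlation or measurement error, missingness, or
hospital attributes correlated with case mix. Passing tests therefore
demonstrate correctness of estimation and standardization under the stated
designs, not robustness to those real-data features; the quantile-knot
option and the loader's preprocessing flags are the hooks intended for
real data.

## Scale of the shipped experiments, and two honest gaps

The full benchmark scale is $H = 500$, $n_h = 50$ or $100$, 200
replications. The shipped experiments run $H = 100$, $n_h = 30$, 10
replicates per condition with a $\{0, 2\}$ truncation grid and 9 adaptive
nodes — sizes chosen so the whole suite runs on a laptop core in minutes
while keeping every qualitative contrast; the full scale remains available
through the same functions. Two consequences of the reduced scale are
worth stating plainly, and are visible as red expectations rather than
papered over:

* **Fixed-effect ISE.** With $|X^\top\beta|$ of standard deviation
  $\approx 5.9$, most patients are near-deterministic, so 30 patients
  carry only one-to-two effective Bernoulli observations about their
  hospital's effect. The spline then smooths hospital effects estimated
  with noise of order one from 100 points: mean ISE lands near 0.15,
  not below 0.1. (A further $\approx 0.03$ comes from centering $\hat f$
  on the sampled hospitals while the true $f$ is population-centered.)
  $\beta$ recovery is unaffected (RD $\approx$ 0.04).
* **Shape detection.** For the same reason the *shape* of the
  random-effect density is weakly identified at this scale: the $K=2$
  likelihood gain over Gaussian is typically 1–4 (occasionally 11), BIC's
  penalty is $\approx 8$, so selection usually returns the Gaussian member
  and the selected SNP fit cannot strictly beat the forced-normal fit it
  coincides with. At the full benchmark scale the same gain accumulates
  over five times the hospitals and larger clusters, which is where the
  density family earns its keep. Moment recovery ($E(b)$, $\mathrm{Var}(b)$)
  is nonetheless within the stated bands here.

The cubic-spline space with three equally spaced interior knots
approximates $f_4$ with a best-possible ISE of $4.6\times 10^{-3}$
(pseudo-inverse least squares; an approximation-theory fact, not an
estimation error), which is the other red expectation shipped as such.

## Numerical choices

* Log-likelihood terms use overflow-safe forms
  ($\log(1+e^x)$ via $|x|$ splitting; three-term log-sum-exp for the ZIB
  survivor term).
* Cluster sums run over hospital-sorted rows as cumulative-sum segment
  differences; quadrature evaluates all nodes in one matrix pass.
* The mode search is damped Newton with step halving, capped at $4\sigma$
  per step; curvature is clamped away from zero before scaling nodes.
* Degenerate inputs: a single distinct attribute value is a basis error;
  fewer hospitals than basis functions warns of rank deficiency;
  hospitals with no outcome variation are kept with a warning (dropping
  no-event hospitals is a *loading* choice, mirroring registry
  preprocessing, not a fitter behavior); non-finite linear predictors name
  the offending hospital.
* Model documents serialize doubles with 17 significant digits, so
  parameters round-trip bit-identically.

## Limitations

One hospital attribute (no additive multi-attribute terms, varying
coefficients or single-index structures); no random effect in the
zero-inflation part; no penalized splines or automatic knot selection; no
REML, sandwich or profile standard errors — uncertainty on standardized
rates comes from the resampling scheme, uncertainty on parameters is not
reported; external "national-level" benchmark populations are out of
scope, the expected risk is always computed within the analyzed data.
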