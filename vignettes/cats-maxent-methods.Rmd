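---
title: "Methods: trait-constrained maximum entropy prediction of relative abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-constrained maximum entropy prediction of relative abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwmaxent)
```

## The model and its assumptions

The CATS (Community Assembly by Trait Selection) model treats community
assembly as statistical inference: if local conditions filter individuals by
their traits, the community-weighted mean (CWM) trait values of a plot carry
the imprint of that filtering, and the least-committal prediction of species
relative abundances consistent with those CWMs is the maximum entropy
distribution relative to a prior. For species $i = 1,\dots,S$ with trait
values $t_{ij}$ and prior $q$ (uniform unless stated), the model solves

$$\max_p \; -\sum_i p_i \log\frac{p_i}{q_i}
\quad\text{s.t.}\quad \sum_i p_i t_{ij} = \mathrm{CWM}_j,\; \sum_i p_i = 1 ,$$

whose solution is $p_i \propto q_i \exp(\sum_j \lambda_j t_{ij})$. The
$\lambda_j$ are the quantities of ecological interest: a positive value means
species with larger trait $j$ are over-represented relative to the prior,
holding the other constrained traits fixed.

Assumptions worth keeping in mind: species are exchangeable a priori (the
uniform prior); traits act through community-level means only; and plots are
solved independently — no spatial or temporal coupling.

## Preprocessing

`preprocess_traits()` applies, in order:

1. **Natural log** to traits flagged `log_transform` in the metadata
   (phenology dates and durations, sizes, specific leaf area, dry-matter
   contents, leaf chemistry — traits whose species distributions are
   right-skewed). The log base only rescales $\lambda$, so conclusions about
   sign and ranking are base-invariant; natural log is used throughout.
2. **Translation by $+|x_{\min}|$** for any column left with negative values.
   The iterative-scaling fitting algorithm requires nonnegative features, and
   $\lambda$ is provably invariant to translating a trait and its constraint
   together (a tested property), so this costs nothing.
3. **Unit-variance scaling** (division by the sample SD across species,
   $n-1$ denominator) when `standardize = TRUE`. Columns are deliberately
   *not* centred: centring would reintroduce negative values, while scaling
   alone already makes $|\lambda|$ comparable across traits, which is all the
   importance ranking needs. $\lambda$ on a scaled trait equals the raw
   $\lambda$ times the SD (scale covariance, also tested).

Binary presence/absence-type traits (floating leaves, perennial growth form,
tubers) use the 1 = no / 2 = yes coding and pass through unchanged apart from
scaling; they are validated to take no other values.

## Solving the constrained problem

Two solvers share one convergence rule — iteration stops when the largest
change in any single predicted relative abundance between two iterations
falls below `tol` (default $10^{-7}$):

- **`method = "dual"`** (default, compiled): damped Newton ascent on the dual
  log-likelihood $g(\lambda) = b^\top\lambda - \log \sum_i q_i e^{t_i^\top
  \lambda}$, with backtracking line search and a tiny ridge on the Hessian.
  Typically converges in 5–20 iterations.
- **`method = "iis"`** (reference): classical Improved Iterative Scaling,
  each sweep solving one monotone 1-d equation per trait. Kept as the
  independent cross-check of the fixed point; it is markedly slower near
  boundary solutions.

The p-change rule rather than a gradient rule matters for a specific reason:
when a constraint lies on (or numerically at) the boundary of the trait
convex hull — e.g. when the observed distribution contains zeros and the
constraint set pins it exactly — the dual optimum is at infinity, $p$ still
converges, and a gradient criterion would never fire. Multipliers are capped
at `lambda_cap` (default $10^3$ on unit-variance traits); a fit that hits the
cap, or a constraint outside the hull, is returned with `converged = FALSE`
and best-effort values, never silently.

Degenerate inputs: zero constraints ($m = 0$) return the prior exactly;
constraints already satisfied by the prior return $\lambda = 0$; missing or
non-finite trait values are hard errors. With $m > S - 1$ constraints
$\lambda$ is not identifiable and a warning is emitted. Near-collinear trait
sets leave $\hat p$ stable but make individual $\lambda$ ill-conditioned;
`solve_all_plots()` reports the condition number of the centred trait matrix
and warns above $10^8$ rather than regularizing silently.

## Fit statistic

`variance_explained()` pools all plot × species pairs:
$R^2 = 1 - \sum(obs - pred)^2 / \sum(obs - \overline{obs})^2$ with grand-mean
centring — the natural reading of an observed-versus-predicted scatter across
communities. The squared Pearson correlation is reported alongside since the
two can differ when predictions are biased; per-plot $R^2$ values are
returned for diagnostics. With a full-rank trait set of $m = S - 1$
constraints the observed distribution is the unique feasible point, so the
observed-CWM fit is structurally near-perfect; the statistic is informative
for $m \ll S$.

## Permutation test

`permutation_test()` permutes whole trait rows among species — trait vectors
stay intact, preserving trait covariance, while the species-to-abundance link
is broken — recomputes CWMs from the observed abundances, refits every plot
and records the pooled variance explained. The test is one-sided with the
add-one p-value $(1 + \#\{null \ge obs\})/(1 + n_{perm})$; `exhaustive =
TRUE` enumerates all $S!$ permutations (the p-value is then the exact
fraction, identity included). Two caveats are inherent and worth stating:
with nearly as many constraints as species *any* permutation fits almost
perfectly, so the test has no power at $m \approx S-1$ and should be run on
a low-dimensional trait set; and non-convergent permuted fits contribute
their best-effort statistic rather than being dropped, which is conservative.

## Trait selection and gradient models

**Backward elimination** starts from all traits, removes the trait with the
smallest mean $|\lambda|$ across plots (ties broken by trait-table column
order, deterministically), and refits down to one trait. Because each step
removes a constraint, the recorded variance explained is monotone
non-increasing toward the full set — a tested invariant (tolerance $10^{-6}$
for solver noise).

**Gradient-fitted constraints** ask a sharper question: how much community
structure does the environment alone predict? `fit_cwm_vs_depth()` fits, per
trait, the Gaussian random-intercept model $\mathrm{CWM} = \beta_0 + \beta_1
d + u_{site} + \varepsilon$ and returns fixed-effect fitted CWMs — the
constraint a plot's depth alone implies. The reported $R^2$ is the marginal
(fixed-effects-only) variance fraction, matching the fixed-effect prediction
being used; singular fits (one site, or no between-site variance) fall back
to OLS with the classical $R^2$ and a warning. `forward_gradient_order()`
enters traits by descending gradient $R^2$ and solves with the fitted CWMs.
Because regression predictions are unconstrained they can fall outside a
trait's convex hull, where no maxent solution exists; such values are
clipped to the hull with a $10^{-6}$ relative inset and counted. Fitted
constraints discard all within-gradient information, so their variance
explained is strictly below the observed-CWM value on noisy data — a tested
ordering.

**$\lambda$–depth trends.** For the directional question — does a trait's
filtering flip from favouring to penalizing along the gradient? —
`lambda_depth_trend()` regresses per-plot $\lambda$ (from fits on
unstandardized, nonnegative traits, so magnitudes keep their trait units) on
depth with site random intercepts (Satterthwaite F tests; OLS fallback as
above; plots with non-converged fits are excluded, not imputed). Two flags
are returned: `direction_shift`, a pure sign change of the fitted line
between the shallowest and deepest plot, and `significant_shift`, the same
conjoined with depth-effect $p < \alpha$ (default 0.05). The pure sign-change
flag alone is uninformative for unfiltered traits: their mean $\lambda$ is
near zero, so a noisy fitted line crosses zero inside the range much of the
time regardless of any real trend. The significance-qualified flag is the
operational detector; in the validation scenario below its false-positive
rate on unfiltered traits runs slightly above the nominal 5% (the sampling
error of $\lambda$ varies along the gradient as communities become more
concentrated, which mildly inflates the F test), which is why the
specificity bound used in validation is 10% rather than 5%.

## The synthetic generator

`synthetic_truth()` describes a survey: by default 17 species, 7 sites with
6 plots each at 0.5 m depth intervals from 0.5 to 3.0 m (42 plots), and 16
traits mirroring a macrophyte trait set (three binary 1/2 traits, thirteen
lognormal continuous traits on realistic scales). Log abundance of species
$i$ in plot $k$ is

$$\log A_{ik} = \sum_j \beta_j(d_k)\, z_{ij}
 - \sum_j \frac{(z_{ij} - \mathrm{opt}_j(d_k))^2}{2\sigma_j^2}
 + u_{s(k)} + \varepsilon_{ik},$$

where $z_{ij}$ is the species' centred unit-variance trait score *on the
trait's working (log where flagged) scale* — so selection is
exponential-linear in the same features the model fits, and in the noise-free
limit the generator is exactly a CATS model with known $\lambda$ —
$\beta_j(d)$ a directional filter with linear depth dependence,
an optional Gaussian niche kernel with depth-drifting optimum, $u_s \sim
N(0, 0.2^2)$ a site effect, and $\varepsilon \sim N(0, 0.5^2)$ lognormal
multiplicative noise. Structural zeros are applied by independent thinning
(default 10%) to exercise boundary handling, keeping at least one species
per plot. Defaults were chosen once as field-plausible magnitudes: filtering
strengths up to 1.2 SD per trait, site-to-site scatter small relative to
abundance noise, and a thinning rate producing the sparse corners real
biomass tables show.

What the generator does *not* emulate: intraspecific trait variation,
spatial autocorrelation among plots, temporal dynamics, and observation
error in the traits themselves. Passing validation therefore shows the
pipeline recovers known filtering under the stated noise model, not that
real surveys satisfy that model.

## Validation scenarios and problem sizes

The test suite and `scripts/acceptance.R` use deliberately scaled
experiments, chosen as the smallest sizes at which each property is
informative:

- solver-versus-oracle agreement on random instances with $S \le 4$,
  $m \le 2$ against a primal constrained-entropy maximizer (null-space
  parametrization + `constrOptim`), and IIS/dual cross-checks on interior
  instances up to $S = 10$;
- permutation calibration: 200 neutral datasets (8 species, 12 plots, 2
  unfiltered traits), 199 permutations each — rejection at $\alpha = 0.05$
  expected inside the binomial band [0.02, 0.09];
- direction-shift detection: `flip_filter_truth()` (filter running +1.25 →
  −1.25 SD across 0.5–3.0 m, two unfiltered traits, 42 plots), 50–100
  replicates — detection expected ≥ 90%, per-noise-trait flags ≤ 10%;
- backward elimination: two opposed filters plus one null trait, 12 species,
  16 plots, 50 replicates — the null trait should leave first in ≥ 90%.

## Known limitations

- Individual $\lambda$ values are ill-conditioned when traits are
  near-collinear or $m$ approaches $S-1$; predictions $\hat p$ remain stable.
  The condition-number warning is the intended guard.
- The permutation test is uninformative at $m \approx S - 1$ (see above).
- `significant_shift` inherits the mild anticonservatism of unweighted
  F tests under gradient-dependent $\lambda$ noise.
- Fitted-CWM constraints assume CWMs respond linearly to depth; curvature in
  real responses loads into the residual and deflates the gradient $R^2$.
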