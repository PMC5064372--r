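---
title: "Competitive MST binding analysis: model, processing and fitting choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive MST binding analysis: model, processing and fitting choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstcompete)
```

## The measurement problem

Low-affinity protein interactions in complex biological matrices are hard to
quantify: a direct titration of a weak binder (dissociation constants in the
hundreds of nanomolar) to completion requires unattainable ligand
concentrations, and the binder of interest — here α-1-antitrypsin (AAT) in
blood plasma, interacting with neutrophil elastase (NE) — cannot be purified
away from its person-specific environment without destroying exactly the
effect one wants to measure.

The competition format this package analyses works around both problems. A
catalytically inactive, fluorescently labeled enzyme E (NE) is equilibrated
with diluted plasma containing the weak inhibitor I1 (AAT), and a
high-affinity competitor I2 (elafin) is titrated in. Microscale
thermophoresis (MST) reads out the fraction of bound enzyme: in a
microscopic temperature gradient, bound and free enzyme deplete from the
heated spot to different degrees, so the per-capillary fluorescence
depletion tracks the bound fraction. As I2 outcompetes I1, the depletion
moves from the I1-dominated baseline to the fully-bound plateau; the height
of that transition — the *thermophoretic amplitude* — reports jointly on the
concentration of I1 and its affinity to E.

## The equilibrium model

Two reversible 1:1 equilibria share one enzyme:

$$K_{D}(EI_1) = \frac{[E]_f\,[I_1]_f}{[EI_1]}, \qquad
  K_{D}(EI_2) = \frac{[E]_f\,[I_2]_f}{[EI_2]},$$

with mass conservation for E, I1 and I2. Eliminating the complexes gives a
single conservation identity in the free enzyme concentration $e$:

$$f(e) = e\left(1 + \frac{[I_1]}{K_{D1} + e} + \frac{[I_2]}{K_{D2} + e}\right)
  - [E] = 0 .$$

$f$ is strictly increasing on $[0, [E]]$ with $f(0) < 0 \le f([E])$, so the
physical root is unique. `solve_competitive_equilibrium()` finds it by
bracketed root finding plus a few Newton polish steps; this is
unconditionally stable at any concentration scale. Algebraically the same
elimination yields a cubic whose smallest non-negative real root in the
bound fraction $x = ([EI_1]+[EI_2])/[E]$ is the physical solution;
`solve_equilibrium_cubic()` implements that route (with coefficients scaled
to units of $[E]$ to keep the companion matrix well conditioned at
sub-nanomolar totals) and is retained purely as an independent algebraic
cross-check — the test suite requires the two routes to agree to
$10^{-8}$ in $x$, alongside a brute-force bisection oracle.

Degenerate inputs are handled by continuous limits: $[I_2] = 0$ or
$K_{D2} = \infty$ simply drop the second term. With a single ligand the
solution collapses to the familiar quadratic (ligand-depletion) law

$$x = \frac{(K_D + E + L) - \sqrt{(K_D + E + L)^2 - 4EL}}{2E},$$

which `fraction_bound_single()` evaluates in the cancellation-free form
$2L/(b + \sqrt{b^2 - 4EL})$; a discriminant driven negative by rounding is
clamped to zero rather than propagating NaN.

## From fluorescence traces to binding curves

Each capillary yields a fluorescence time trace with an IR-laser on/off
schedule (25/5 s for the amplitude assay, 20/5 s for the K_D assay). The
processing chain mirrors standard MST practice:

1. **Background subtraction** — the trace of a plasma-only capillary is
   subtracted pointwise (`subtract_background()`); grids must agree to
   1 µs unless interpolation is requested explicitly.
2. **Depletion** — `compute_depletion()` returns
   $(1 - \bar F_{hot}/\bar F_{cold}) \times 1000$ ‰. The cold window
   defaults to the last 1 s before laser-on and the hot window to the last
   1 s before laser-off ("equilibrated thermophoresis"); the assay
   literature does not dictate window widths, so both are configurable.
   The readout is invariant under a gain factor on the whole trace.
   The sign convention makes depletion *positive* when fluorescence drops
   in the heated spot; since bound enzyme depletes more than free enzyme,
   competition curves rise with titrant and amplitudes are positive. Note
   that whether one reports $\bar F_{hot}/\bar F_{cold}$ itself or
   $1 - \bar F_{hot}/\bar F_{cold}$ changes only the offset and sign of
   curves, never the fitted amplitude magnitude or any K_D.
3. **Aggregation** — `aggregate_replicates()` records the per-concentration
   mean, sample SD ($n-1$; missing for a single replicate) and $n$,
   matching the triplicate design.
4. **Baseline alignment** — independent experiments show instrumental
   offsets; at saturating competitor every curve reports the same
   fully-bound state, so `align_baselines()` shifts each curve by a
   constant until its saturation plateau (mean over points with
   concentration ≥ max/4, i.e. the top steps of a 1:1 series — "high end
   range" is not quantified further in the assay description) matches a
   common reference. A curve whose plateau region still slopes by more
   than 25% of the curve's dynamic range per decade is judged
   non-saturating and passed through unshifted with a warning; the 25%
   threshold separates genuinely rising curves (which slope by roughly
   half the range per decade near their midpoint) from technical noise on
   a saturated plateau. Shifting is a pure translation, so fitted
   amplitudes are unaffected — the suite checks this to $10^{-9}$.

## Fitting

### Amplitude fit

`fit_amplitude()` fits $D(c) = t + A\,x(E_{tot}, c, K_D)$ by weighted least
squares with weights $1/\mathrm{SD}_i^2$ (the conventional reading of a
"weighted fit"; if any SD is missing or zero the curve is fitted unweighted
and flagged). $K_D$ is profiled: for a fixed $K_D$, $A$ and $t$ are exact
weighted-linear-regression solutions, leaving a smooth one-dimensional
objective in $\log_{10} K_D$ that is scanned on a 61-point grid over
$[10^{-13}, 10^{-3}]$ M and refined by golden-section search. This replaces
multistart nonlinear optimisation with a deterministic procedure that
cannot silently converge to a local minimum outside the scanned range, and
it makes the fit exactly equivariant under shifts and rescalings of the
depletion axis. $A$ is deliberately unconstrained in sign; with this
package's depletion convention a competition curve has $A > 0$, and a
negative fitted $A$ is a diagnostic, not an error. Standard errors come
from the Gauss–Newton covariance $s^2 (J^\top W J)^{-1}$; on a flat curve
the $K_D$ column of $J$ vanishes, the covariance is singular, and the fit
is flagged `kd_identifiable = FALSE` instead of failing.

One subtlety is worth stating precisely: the competition curve is exactly
representable by the single-site quadratic model only in the limit where
free competitor is undepleted ($[I_1]_f \approx [I_1]$). With
$[E] = 500$ pM against tens of nanomolar I1 the approximation error is at
the $10^{-5}$ relative level — irrelevant in practice, but it means the
zero-noise round trip through the generator is exact to $10^{-6}$ only
with $I_1 = 0$; the suite asserts exactness there and 0.1% recovery in the
competition configuration.

### Global K_D fit

For the direct K_D measurement the inhibitor itself is titrated (no
competitor), curves are aligned, then normalized so the mean depletion at
the lowest concentration maps to 0 and at the highest to 1
(`normalize_curve()`, an affine map applied to values and SDs alike, and
idempotent); on that scale the curve reads as the proportion of bound
enzyme. `global_fit_kd()` then fits a single shared $K_D$ across all points
of all replicate curves with amplitude fixed at 1 and offset at 0.

Two estimator choices deserve their rationale:

* **Unweighted by default.** Per-point SDs estimated from three technical
  replicates carry only two degrees of freedom; their inverse squares are
  wildly variable weights, and in simulation at the four-replicate design
  they roughly triple the dispersion of the recovered $K_D$ relative to the
  unweighted fit. The assay description attaches weighting to the amplitude
  fit only, so the global fit is unweighted unless `weights = "sd"` is
  requested.
* **Jackknife uncertainty.** `kd_sd` is the leave-one-curve-out jackknife
  standard error $\sqrt{\tfrac{m-1}{m}\sum_i (\hat\theta_{(i)} -
  \bar\theta_{(\cdot)})^2}$. With $m = 4$ curves this SE has three degrees
  of freedom, so a $\pm 2\,\mathrm{SD}$ interval has a *nominal* coverage
  of $P(|t_3| \le 2) \approx 86\%$, not 95% — the calibration test asserts
  coverage consistent with that sampling theory, and users quoting
  mean ± SD from four measurements should keep the small-$m$ caveat in
  mind. The endpoint normalization also introduces a small downward bias
  (a few percent at 500 nM, ~6–7% at 1300 nM with the default design)
  because the highest titration point does not fully saturate; this is a
  property of the normalize-then-fit procedure itself, is well inside the
  reported uncertainties, and is deliberately not "corrected", since the
  package implements the assay's stated analysis.

### Cohort comparison

`compare_groups()` is a two-sided Mann–Whitney U test with midranks.
For $n_1 n_2 \le 400$ the permutation distribution of the rank sum is
computed exactly by the Streitberg–Röhmel shift convolution on doubled
midranks (exact even under ties); larger designs use the normal
approximation with tie and continuity corrections. The implementation is
cross-checked in the suite against brute-force enumeration of all
assignments up to $n_1, n_2 \le 6$ and against the reference
implementation in `stats::wilcox.test` where the latter is exact. Group
medians are reported alongside, as is conventional for nonparametric
comparisons.

### Titration endpoint

The functional (inhibition-competent) inhibitor concentration is read from
a residual-activity titration: activities are normalised to the
zero-inhibitor point (making the endpoint invariant to a uniform gain
error), an ordinary least-squares line is fitted through points with
normalised activity in $[0.1, 0.9]$ — the standard linear window for
tight-binding titrations, below the baseline region and above the
stoichiometric break — and the equivalence point is the x-intercept. How
the original assay computed its endpoint is not documented; this
linear-intercept rule is a standard, stated substitute, not a claim about
that procedure.

## The synthetic world

The generator exists so that every stage can be exercised against known
ground truth. Its defaults state the assay conditions once:

| parameter | default | origin |
|---|---|---|
| enzyme total | 500 pM (amplitude) / 5 nM (K_D) | assay designs |
| dilution | 1:1, 17 steps (2^16 ≈ five orders of magnitude) | assay designs |
| replicates | 3 technical × 3 (amplitude) or 4 (K_D) experiments | assay designs |
| plasma fraction | 7.5% | assay designs |
| IR on/off | 25/5 s (amplitude), 20/5 s (K_D) | assay designs |
| K_D(E–I2), elafin–NE | 0.2 nM, configurable | not printed in the assay description; must be ≪ 500 pM enzyme so the high end saturates |
| I1 total in the amplitude assay | 75 nM | ZZ-deficient plasma AAT (~1.5–2 µM) after 12-fold + 1:1 dilution |
| depletion of free / bound E | 20 / 50 ‰ | typical MST contrast; only the difference matters |
| technical noise | 5% of the 30 ‰ dynamic range | chosen to make recovery nontrivial but achievable |
| per-experiment offset | 10% of the dynamic range | the baseline shifts alignment removes |
| trace model | exponential approach, τ = 1.5 s each way, F0 = 1000 a.u. | phenomenological; hot window ≫ τ makes window means exact |

Depletion is linear in the bound fraction,
$D = D_{free} + (D_{bound} - D_{free})\,x$, with a single $D_{bound}$ for
both complexes — the depletion readout reports *how much* enzyme is bound,
not by which inhibitor. Every generated artifact embeds its seed, design,
signal model and noise-free expected values, and regenerating from that
record is bit-identical.

What the generator does **not** emulate: photobleaching kinetics,
capillary adsorption, temperature-gradient physics beyond the exponential
phenomenology, and — importantly — any mechanistic model of *why* plasma
modulates $K_D(EI_1)$. Different plasma environments are represented
simply as different true $K_{D1}$ values. A green end-to-end test therefore
establishes that the analysis chain recovers the parameters of this stated
world; it cannot establish anything about real plasma biochemistry.

## Numerical and degenerate-input policy

* All concentrations are carried in molar internally; interfaces accept
  unit-suffixed strings (`"500pM"`, `"5nM"`) because silent pM/nM mix-ups
  are the dominant practical failure mode.
* Root finding is bracketed on $[0, [E]]$; the solver cannot escape the
  physical range, and failure to bracket cannot occur for validated
  inputs.
* $K_D$ searches are bounded in $[10^{-13}, 10^{-3}]$ M in log space; an
  optimum within $10^{-6}$ log-units of a bound sets `kd_pinned`.
* A single replicate leaves the SD missing, which downstream falls back to
  unweighted fitting rather than an error or an infinite weight.
* Single-curve global fits are allowed (with a warning in the workflow
  runner) and return `kd_sd = NA`.

## Known limitations

* Only the reversible encounter equilibrium is modeled; the irreversible
  second step of the serpin mechanism (absent here by design, the enzyme
  being catalytically dead) is out of scope.
* The two-K_D competitive model is used for simulation and interpretation
  only; data fitting uses the single-site quadratic law, as in the assay's
  own analysis. Apparent amplitude-fit parameters on competition curves
  inherit the free-competitor approximation discussed above.
* The cohort generator draws log-normal amplitudes; real cohort
  distributions are unknown, so its power estimates are illustrative
  summaries of the stated world, not claims about clinical data.
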