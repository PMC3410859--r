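---
title: "Multi-parameter skeletal phenotype screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-parameter skeletal phenotype screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonescreen)
```

# The screening problem

Knockout mouse programmes produce strains faster than any laboratory can
characterise them in depth. A skeletal screen must decide, from bones of as
few as two mice per strain, which strains carry functionally significant
abnormalities of bone structure and strength and deserve follow-up.
`bonescreen` implements a staged decision algorithm for that setting:

1. **Univariate structural screen.** Six structural parameters — bone
   mineral content (BMC, summarised as the median calibrated grey level of
   a digital microradiograph), bone length and cortical thickness by x-ray
   microradiography; trabecular bone volume fraction (BV/TV), trabecular
   number (Tb.N) and trabecular thickness (Tb.Th) by micro-CT — are
   compared with a wild-type reference range. A strain is flagged when any
   strain-mean parameter lies more than $k$ SD from the reference mean
   (default $k = 2$, two-sided).
2. **Multivariate screen.** Simultaneous moderate deviations escape the
   univariate gate, so robust Mahalanobis distances over the six
   structural parameters are computed from a minimum volume ellipsoid
   (MVE) estimate of location and scatter, and strains with squared
   distance above $\chi^2_6(1-\alpha)$ are flagged (default
   $\alpha = 0.025$).
3. **Shortlist and biomechanical confirmation.** Structural outliers,
   Mahalanobis outliers and strains annotated by the upstream broad
   primary phenotype screen form a shortlist whose bones undergo
   destructive 3-point bend testing. Any of six biomechanical parameters
   beyond $k$ SD flags the strain.
4. **Major phenotypes and functional classification.** Strains with a
   biomechanical flag *and* corroborating structural/statistical evidence
   are called major phenotypes and placed in one of four functional
   categories of bone strength.

# The load–displacement model

A destructive 3-point bend test records load against midshaft
displacement. The parametric curve model (`curve_model()`) consists of:

- a linear elastic phase of slope $k$ (stiffness, N/mm) up to the yield
  load $L_y$;
- a quadratic hardening arc from $(d_y, L_y)$ rising to the maximum load
  $L_{max}$ at its apex;
- the descending branch of the same parabola down to the fracture load
  $L_f$; and
- a terminal drop to zero at fracture.

The *ductility* parameter scales the half-span of the parabola. At
ductility 1 the arc meets the elastic phase with a continuous slope; larger
values lengthen the post-yield phase (the slope at yield drops below $k$,
producing the visible knee seen in real records) and strictly increase the
proportion of energy dissipated prior to fracture. We chose this
single-parabola geometry because it is the simplest smooth shape with the
qualitative features of published bend-test records, has closed-form
energies (`curve_model_energies()`), and gives the calibration below a
strictly monotone target function.

**Ductility calibration.** `calibrate_ductility()` solves, by
`uniroot()`, for the ductility at which the model's true dissipated
proportion at fracture equals a target (the wild-type reference value is
86.2%). The proportion is bounded below by the elastic floor
$1 - \mathrm{ESE}_F / W_{min}$, so unreachable targets fail loudly.

**Physical consistency of cohort draws.** When per-mouse biomechanical
phenotypes are drawn from the multivariate normal model, occasional draws
combine a deep fracture load with a wide hardening arc such that the target
dissipated proportion would require ductility below 1 — an arc rising
*above* the elastic line, which real bones do not do. `cohort_curve_models()`
therefore raises the curve's fracture load to the smallest value at which
the target proportion is reachable at ductility $\ge 1$. The cohort table
keeps the drawn phenotype; only the synthetic curve geometry is adjusted.
This clamp affects roughly a third of draws under the default moments,
shifting the curve-level mean fracture load up by about 0.5 N while leaving
stiffness and the dissipated proportion — the quantities the calibration
targets — unbiased.

# Curve analysis

`analyze_curve()` recovers the six biomechanical parameters:

- **Elastic region** (`find_elastic_region()`): among all contiguous
  windows of at least 10 samples on the rising limb with loads between 10%
  and 80% of the maximum, the window maximising the linear-fit $R^2$ is
  selected; ties within $10^{-9}$ (exactly linear limbs) resolve to the
  widest, then earliest, window. The bounds are configurable; the defaults
  exclude toe-in effects at low load and the hardening arc at high load.
- **Stiffness** (`fit_stiffness()`): ordinary least-squares slope of load
  on displacement over that window.
- **Yield** (`detect_yield()`): the curve is lightly smoothed (5-sample
  running mean) and scanned for the first run of 5 consecutive samples
  below 95% of the elastic-line prediction — the secant-deviation
  criterion. Because the curve is still rising there, the crossing itself
  systematically overestimates the yield load, so by default the crossing
  is walked back to the last sample whose raw load is within
  $\max(3\hat\sigma,\; 2\times10^{-5}\cdot\text{prediction})$ of the
  elastic fit ($\hat\sigma$ = residual SD of the fit). On noise-free
  generated curves this recovers the true yield to well under 1%; under
  load noise the departure point inherits an upward bias of order
  $\sqrt{\text{tolerance}}$, comparable to the assay's repeatability. A
  curve that never deviates (pure triangle) yields at the maximum load and
  is flagged.
- **Maximum and fracture** (`detect_max()`, `detect_fracture()`): global
  maximum; and the load at the last sample before the record first falls
  below 10% of the maximum (the terminal-drop rule). Records with no drop
  are assigned their final load and flagged.
- **Energies**: work energy $W$ is the trapezoidal area under the curve to
  the maximum-load and fracture samples. Elastic stored energy is the
  right-triangle area $L^2/(2k)$ with the vertex at the point of interest
  and hypotenuse slope $k$. Dissipated energy is $W - \mathrm{ESE}$,
  clipped at zero (with a flag) when noise drives it marginally negative,
  and the proportion $\mathrm{DE}/(\mathrm{DE}+\mathrm{ESE}) =
  \mathrm{DE}/W$ quantifies ductility. The identity
  $\mathrm{DE} + \mathrm{ESE} = W$ holds exactly before clipping.
- **Angular transform**: proportions are reported alongside
  $\arcsin\sqrt{p}$, the classical variance-stabilising transform.
  Radians are the default (degrees by configuration); the choice is a
  reporting convention and does not affect any decision rule.

# Densitometry

Raw radiographic pixel values are calibrated against two phantom standards
imaged in the same frame: a linear map sends the polyester standard to grey
level 0 and the steel standard to grey level 255, rounding half-up,
clipping out-of-span values and reporting the clip count
(`calibrate_grey_levels()`). Grey levels are treated as half-open unit bins
$[g, g+1)$. The per-bone BMC summary is the median grey level — the
smallest level whose cumulative count reaches half the pixels. The 16-band
pseudocolor summary collapses the 256 levels into equal-width intervals of
16.

Distributions are compared with the two-sample Kolmogorov–Smirnov
statistic on the binned ECDFs, reported on the percent scale:
$D = 100\,\max_g |F_a(g) - F_b(g)|$. Critical values use
$D_{crit} = 100\, c(\alpha) \sqrt{(n+m)/(nm)}$ with tabled coefficients
$c = 1.36,\ 1.63,\ 1.95$ at $\alpha = 0.05, 0.01, 0.001$ — at
$n = m = 1024$ pixels these give 6.01, 7.20 and 8.62 — and the asymptotic
coefficient $\sqrt{-\ln(\alpha/2)/2}$ elsewhere. Ties are handled by the
binning itself; the per-comparison sample size is an argument because
subsampling conventions vary between laboratories.

# Reference ranges and the univariate screen

Reference ranges use the sample mean and the $n-1$ SD of the wild-type
cohort, with symmetric bands at 1, 2 and 3 SD. Screening operates on
*strain means*: the strain-mean SD distance $z = (\bar x_s - \mu_{WT}) /
\sigma_{WT}$ is the screened statistic, flagged two-sided at $|z| > k$.
Per-mouse values are carried in the tables but do not drive the headline
gates; with 2–6 mice per strain the strain mean is the natural unit of
inference, and two-sided flagging is required because both low- and
high-BMC phenotypes are of interest. Missing values mark a strain
incomplete rather than silently passing it.

# Robust multivariate outliers

The MVE estimator (`mve_estimate()`) seeks, among ellipsoids containing at
least $h = \lfloor (n+p+1)/2 \rfloor$ of the $n$ observations, the one of
minimum volume. The search draws elemental subsets of $p+1$ observations;
each subset's mean and covariance define a shape that is inflated by the
$h$-th smallest squared Mahalanobis distance $m_h$, giving volume
$\propto \sqrt{\det(S)\, m_h^p}$; the minimiser wins. Enumeration is
exhaustive whenever $\binom{n}{p+1}$ does not exceed the subset budget
(default 10,000), which also makes the estimator affine-equivariant on
small inputs. Singular subsets are skipped.

The winning scatter is rescaled by $m_h / \chi^2_p(0.5)$ so that squared
robust distances are chi-squared comparable, and then refined by the
standard one-step reweighting: observations within the 97.5% chi-squared
quantile of the initial metric are averaged classically with a consistency
factor for the truncation. We run two reweighting passes — the first
cleans up the crude elemental-subset shape, the second trims against an
already-consistent metric — because without reweighting the raw MVE
scatter is too irregular for its distances to track the $\chi^2_p$ tail,
and the null flag rate would exceed the nominal $\alpha$. With it, the
flag rate on clean multivariate normal data matches $\alpha$ within
Monte-Carlo error (verified at $n = 10{,}000$, $p = 6$ in the test suite).
`reweight = FALSE` exposes the raw estimator for oracle comparisons.

Outlier calling uses $d_i^2 > \chi^2_p(1-\alpha)$ with $\alpha = 0.025$ by
default; the stricter 99.7% confidence gate is a configuration choice. Two
fit populations are supported: the default fits the MVE on the knockout
strain-mean z-scores themselves (the robustness tolerates the outlying
strains), and a wild-type-anchored mode fits location and scatter on the
wild-type mice instead. Principal component scores (`pca_scores()`, a
centered eigendecomposition via `prcomp`) support visual confirmation.

# Major phenotypes and functional classification

A strain is a **major phenotype** when it carries a biomechanical flag and
corroborating evidence: a structural flag, a Mahalanobis flag, or a
primary-screen annotation graded *major*. A biomechanically flagged strain
whose only other evidence is a *minor* primary annotation is demoted — its
abnormality is not corroborated by any quantitative measure. Strains
outside the shortlist with a single outlier biomechanical parameter are
reported separately.

Classification (`classify_strain()`) uses three strain-mean z-scores:
maximum load (weak below $-k$, strong above $+k$), the proportion of
energy dissipated prior to fracture (brittle below $-k$), and the sign of
the BMC z-score. The observed clusters map to *weak–flexible–low BMC*,
*weak–brittle–low BMC* and *strong–brittle–high BMC*; everything else is
normal (strong and flexible). Combinations outside the observed clusters
— say, strong with low BMC — are not forced into a category: they return
normal with a review flag, because forcing them would fabricate a cluster
the screen has no evidence for.

# The synthetic cohort generator

The generator stands in for the study population: 77 wild-type mice in 18
control cohorts' place, and 100 knockout strains of 2–6 mice each (sizes
uniform on 2–6). Per-mouse phenotypes are multivariate normal over the
twelve parameters. The reference biomechanical moments are the published
values — stiffness $30.2 \pm 4.1$ N/mm, yield $8.9 \pm 0.9$ N, maximum
$10.7 \pm 0.9$ N, fracture $6.4 \pm 1.7$ N, and a mean 86.2% of energy
dissipated prior to fracture. Moments that are not printed as numbers in
the source text (the six structural parameters, the SDs of the two energy
proportions) are package placeholders flagged `placeholder = TRUE` in
`wt_parameter_defaults()`; the micro-CT placeholder SDs were informed by
the reported assay coefficients of variation, and all of them should be
replaced by laboratory reference data in real use. The default correlation
imposes 0.5 among BMC, cortical thickness and the three load parameters
and independence elsewhere, mirroring the reported pattern that bone
strength tracks mineral and cortical measures but not trabecular ones.

Planted phenotypes shift strain draws by per-parameter effect sizes in
wild-type SD units; the default patterns put $\pm 4$ SD on the defining
parameters of each category. Truth labels travel with the tables so
recovery is checkable. A deterministic grey-level histogram generator with
an exact target median supports the densitometry path.

What the generator does *not* emulate: non-normal phenotype distributions,
litter and cohort batch effects, measurement error structure beyond
additive Gaussian load noise, real radiograph geometry (only flat
phantom-style histograms), and age or sex variation (the emulated
population is female and of fixed age). Passing tests therefore
demonstrate that the algorithms are correct and calibrated under the
stated statistical model, not that the model captures every feature of
real colony data.

A companion deterministic table, `synthetic_strain_table()`, reconstructs
the *flag structure* of the published 100-strain screen (gate counts,
named major strains, recorded Mahalanobis distances, primary annotations)
for end-to-end tests of the gating logic; it is synthetic throughout and
is documented as such.

# Numerical choices and problem sizes

- Curve sampling step 0.002 mm; load noise SD 0.03 N by default (a
  realistic load-cell noise floor for a 100 N-class test frame).
- Yield: secant fraction 0.95, persistence 5 samples, departure tolerance
  $\max(3\hat\sigma, 2\times 10^{-5}\,\text{pred})$; fracture drop
  threshold 0.10; all configurable.
- Energy identity enforced to $10^{-9}$ relative; ESE closed form matches
  numeric integration to $10^{-6}$.
- MVE subset budget 10,000 (5,000 inside the screen pipeline), exhaustive
  below it; chi-squared consistency at the median; two reweighting
  passes at the 97.5% quantile.
- Test-suite problem sizes: 77-mouse wild-type cohorts; 100–150-strain
  knockout cohorts; planted-recovery measured over 240 planted strains in
  four batches; null calibration of the Mahalanobis flag rate at
  $n = 10{,}000$; KS comparisons at 1024 pixels.

# Known limitations

- Yield detection on smooth, slope-continuous records is intrinsically
  tolerance-limited; under heavy noise the departure point biases upward.
  The defaults favour the noise levels of modern test frames.
- The MVE search is stochastic above the exhaustive threshold; screen
  results fix the subset seed for reproducibility.
- The four-category classification is deliberately conservative:
  unobserved combinations are flagged for review, not assigned.
- Grey-level work is histogram-based; no segmentation of real radiographs
  is attempted, and cortical thickness and bone length enter as tabulated
  values.
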