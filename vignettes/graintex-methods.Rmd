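---
title: "Weibull texture statistics and co-trained grading of granular images: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weibull texture statistics and co-trained grading of granular images: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graintex)
```

## The problem

Images of granulated products — rice on a conveyor, lotus seeds, greige
cloth — consist of hundreds of stochastically packed, locally homogeneous
particles. There is no clean foreground/background split, so per-object
segmentation (and with it all shape-per-grain features) is unreliable.
`graintex` instead characterizes the *distribution* of local contrast
structure: oriented derivative-filter responses are summarized by a
parametric model of their histogram, and those model parameters are the
texture features used for quality grading. Because grading labels are
expensive (laboratory assays), the classifier is semi-supervised: two
complementary learners label confident unlabeled samples for each other.

## Steerable Gaussian-derivative filtering

A filter template is a weighted sum of mixed derivatives of an isotropic
Gaussian, $\sum_t w_t\,\sigma^{e_t}\,\partial_x^{i_t}\partial_y^{j_t}
G_\sigma$. Rotating such a template by $\theta$ is equivalent to substituting
$\partial_{x'} = \cos\theta\,\partial_x + \sin\theta\,\partial_y$ and
$\partial_{y'} = -\sin\theta\,\partial_x + \cos\theta\,\partial_y$ and
expanding: the rotated response is an *exact* linear combination of the
responses to all same-order derivative kernels. A 60-direction sweep
therefore costs a handful of base convolutions plus 60 weighted sums, not 60
convolutions. `steering_coefficients()` performs the operator expansion
numerically and the identity is validated in the test suite against an
independent oracle — dense convolution with the analytically rotated,
resampled kernel — at relative error below $10^{-6}$ on interior pixels
(measured: $\sim 10^{-15}$).

Angles are measured counter-clockwise from the +x (column) axis; responses at
$\theta$ and $\theta + \pi$ differ only by the parity $(-1)^m$ of each
derivative order, so sweeps sample $[0, \pi)$.

Six classical detector templates are built in (`gdf_template("T1")` …
`"T6"`): three edge detectors of increasing order, two ridge detectors and a
wedge detector. Two printed constants in the sources that introduced them are
typographically ambiguous (plausibly missing radical signs); the package
implements the literal constants with a `radical_constants` switch. This
choice is deliberately low-stakes: a global rescaling of a template rescales
the fitted location and scale parameters and leaves the shape parameter
untouched (a tested property), so downstream classification features are
robust to it. The wedge angle of T6 is never specified by its source; the
default is $\phi = \pi/2$, exposed as a parameter.

### Numerical choices

* **Kernels.** Sampled closed forms (Hermite polynomial × Gaussian) on the
  integer grid, support half-width $\lceil 4\sigma \rceil$ (configurable).
  Odd-order kernels are exactly antisymmetric; even-order kernels carry a
  small truncation residue ($\sim 10^{-5}$ relative at $\sigma = 1$), which
  is why constant-image annihilation is exact for odd orders and only
  approximate for even ones.
* **Convolution.** True convolution (kernel flipped), computed as two
  separable 1-D passes; equality with dense 2-D convolution is tested to
  $10^{-10}$.
* **Boundaries.** Mirror (symmetric) padding everywhere. All distribution
  fitting and feature statistics use interior pixels only, dropping a margin
  of one kernel half-width, so padding artifacts never enter the features.
* **Intensities.** 8-bit inputs are mapped to $[0,1]$ (divide by 255) before
  filtering, fixing the units of the fitted scale parameter.

## The integral-form Weibull model

Filter-response histograms of granular textures are modelled by the
symmetric three-parameter family

$$f(x;\mu,\lambda,\beta) = C\,
  e^{-\frac{1}{\lambda}\left|\frac{x-\mu}{\beta}\right|^{\lambda}},\qquad
  C = \frac{\lambda}{2\,\lambda^{1/\lambda}\,\beta\,\Gamma(1/\lambda)},$$

a sequential-fragmentation argument: repeated random fragmentation of a
scene produces Weibull-type distributions of structure sizes and contrasts.
The location $\mu$ tracks global reflectance, the scale $\beta$ the contrast
width, and the shape $\lambda$ the granularity regime: $\lambda = 2$ is
Gaussian, $\lambda = 1$ Laplace, $\lambda \to 0$ a symmetric power law
(fractal dimension $D_f = -3\lambda$, exposed as
`wd_fractal_dimension()`), and $\lambda \gg 2$ the "regular" regime of very
fine, densely packed texture. Fits with $\lambda > 10$ are reported as-is
with a warning, not clamped — pure periodic patterns genuinely live there.

Maximum likelihood has no closed form; `fit_wd_mle()` minimizes the negative
log-likelihood by Nelder–Mead over $(\mu, \log\lambda, \log\beta)$ (log
transforms enforce positivity). Initialization is the sample median,
$\lambda_0 = 2$, and the sample standard deviation; the simplex runs at
relative tolerance $10^{-8}$ with at most 2000 iterations (both
configurable). Sampling for tests uses the gamma transform
$X = \mu + S\beta(\lambda G)^{1/\lambda}$, $G \sim \Gamma(1/\lambda, 1)$,
$S$ a fair sign, which gives the exact moment identity
$E|X-\mu|^\lambda = \beta^\lambda$ used as an oracle.

Goodness of fit uses binned $\chi^2$ and Kullback–Leibler divergence in the
model-to-empirical direction $\sum_i f_i \log(f_i/h_i)$ (the package also
offers the conventional empirical-to-model direction). No binning rule is
canonical; the package uses equal-width bins over the sample range with
$\lceil 2 n^{1/3} \rceil$ bins clipped to $[16, 256]$, renormalizes the
binned model mass so both vectors are probability distributions (hence KLD
$\ge 0$ and exact zero for self-consistent bins), and merges bins whose
model probability falls below $10^{-12}$.

Fitting uses raw signed responses, not magnitudes: the family is symmetric
about $\mu$ and the derivative responses of a stationary texture are
naturally near-symmetric about zero.

## The feature vector

For each template, scale $\sigma$ and direction $\theta_j = (j-1)\pi/N$, the
triple $(\hat\mu, \hat\beta, \hat\lambda)$ of the fitted response
distribution is emitted, directions fastest, then scales, then regions:
first the global image, then each cell of a non-overlapping subimage grid.
The defaults follow the standard operating point: $N = 60$ directions, five
scales $[0.5, \sqrt2/2, 1, \sqrt2, 2]$ (a geometric ladder of ratio
$\sqrt2$; the printed source list is garbled and this is its only consistent
reading, configurable), and a $2\times2$ grid — $5 \times 60 \times 3 \times
(4+1) = 4500$ features per template. The dimensional contract is asserted on
every extraction.

Implementation notes:

* Base responses are computed once per (image, scale) and reused across all
  directions — this is precisely the payoff of steerability.
* Local blocks are obtained by splitting the *filtered* response into grid
  cells (intersected with the interior margin), not by filtering subimages
  separately; remainder pixels join the last cell in each axis.
* Per-direction fits warm-start from the previous direction's parameters
  (adjacent directions have similar distributions; roughly a 3× speedup).
  Warm and cold starts agree within fit tolerance (tested at 2%).
* Extraction is deterministic: identical image and configuration give a
  bit-identical vector.

The same template set is applied to the global and local blocks; whether the
original experiments did so is not documented, and applying one set
uniformly keeps the layout regular.

## Base classifiers

Labels are coded $-1$ ("high quality") and $+1$ (other); both learners are
regressions onto these codes, thresholded at 0, with the boundary score 0
mapping to $-1$.

**TPSRC** is thin-plate-spline regression: $h(x) = \omega_0 + \omega^\top x
+ \sum_j \psi_j \phi(\|x - x_j\|)$ with $\phi(r) = r^2\log r$, fitted by the
standard augmented system with side conditions $\sum\psi_j = 0$,
$\sum\psi_j x_j = 0$. The Green's function is used in exactly this form for
every feature dimension. The smoothing parameter $\eta$ is selected by
generalized cross-validation over a log grid $10^{-6} \dots 10^2$ when not
fixed; $\eta \to 0$ interpolates (tested to $10^{-6}$). A singular system
triggers an automatic $\eta$ bump with a warning.

**MARSC** is multivariate adaptive regression splines: a forward pass
greedily adds reflected hinge pairs (parent basis × unused variable ×
data-value knot) minimizing residual squared error, a backward pass deletes
basis functions keeping the subset minimizing the generalized
cross-validation error $\mathrm{GCV} = (RSS/M)/(1 - C(K)/M)^2$ with
$C(K) = K(d/2+1)$, $d = 3$. Defaults: at most $\min(21, n/2)$ terms, product
degree 2 (configurable to 3), knots at observed data values. Knot candidacy
uses Friedman's adaptive minimum span and end span (at $\alpha = 0.05$)
rather than every observation: edge knots give single observations enormous
leverage and make out-of-range predictions erratic, which destabilized
co-training refits in development. Setting `minspan = 1, endspan = 0`
restores the exhaustive-knot behavior (and exact recovery of noise-free
planted hinges, which the tests exercise).

## COSC-Boosting

The co-training loop. Per iteration, a pool of $M' = 100$ samples is drawn
with replacement from the unlabeled set (one seeded generator drives all
draws; the drawn indices are logged per iteration so any run can be
replayed). A pool sample is a *candidate* only if (a) TPSRC and MARSC assign
it the same thresholded label and (b) appending it with that label decreases
— or leaves unchanged — both classifiers' squared error on their labeled
sets (the confidence $\sum_i [(y_i - h(x_i))^2 - (y_i - h^*(x_i))^2] \ge 0$,
evaluated on the current augmented labeled set of the classifier being
refined). Each classifier's most confident candidate then augments the
*other* classifier's labeled set: the printed pseudocode of the source
algorithm assigns the TPSRC pick to both sets, contradicting its own prose
("each labels the unlabeled samples for the other"); the package implements
cross-teaching and offers the literal variant via `cross_teach = FALSE`.
Ties in confidence resolve to the earliest-drawn candidate. Accepted samples
are removed from the reservoir by default (`remove_accepted = FALSE`
restores the literal with-replacement reading). Both classifiers are
retrained once per iteration after the picks are fixed; the loop stops early
when neither labeled set changed, or after `max_iterations`. The final
predictor is the score average $(h_{TPSRC} + h_{MARSC})/2$, thresholded at
0; with an empty unlabeled set the model degenerates exactly to this plain
two-classifier ensemble.

When $\eta$ is GCV-selected, it is re-selected once per iteration and held
fixed across that iteration's candidate refits — otherwise selection noise,
not the candidate, would dominate the confidence comparison.

Per-group classification error, its unweighted mean over groups and the
pooled error over all samples (`ce_metrics()`) are all reported in percent.

## Synthetic fixtures

No public image corpus accompanies the method, so the generators are
first-class:

* `generate_granular_image()` renders stochastically placed shaded ellipses
  (anti-aliased ~1-pixel soft edges, Lambertian-like linear shading along
  the major axis, per-particle intensity jitter, Gaussian pixel noise,
  clipped to $[0,1]$). Soft edges matter: hard steps make the response
  histogram of a pure pattern bimodal and the Weibull fit degenerate, which
  is also why the striped test fixture carries pixel noise. Orientation can
  be isotropic or concentrated at an angle, which the directional features
  must (and do) detect.
* `generate_ss_dataset()` draws two Gaussian classes with means at
  $\pm m$ on every coordinate and exactly
  $\mathrm{round}(\text{label rate} \times n)$ labeled samples per class,
  with the hidden truth retained for evaluation.

What these fixtures do *not* emulate: real grain-surface reflectance,
correlated illumination gradients, camera noise statistics, and the
high-dimensional, strongly structured feature distributions of real produce
images. Passing tests therefore demonstrate the correctness of the
machinery and the qualitative behavior of the method, not field accuracy on
any particular product.

## The co-training benchmark

`cosc_benchmark()` fixes the study conditions used in the acceptance tests:
two Gaussian classes in $k = 4$ dimensions with means at $\pm 0.8$ per
coordinate (unit within-class sd), 200 samples per class, 10% label rate,
$M' = 100$, up to 30 iterations, 20 seeds. The MARS side runs additive
(degree-1) splines with at most 8 terms: the generator's Bayes boundary is
linear, so an additive spline class is the appropriate complementary learner
at 40 labeled points, and degree-2 products only add variance there. The
benchmark asserts the qualitative semi-supervised property — the mean final
error over seeds does not exceed the mean error of the initial
two-classifier ensemble — rather than any particular error value: with 40
labeled points the per-seed improvement is small (fractions of a percentage
point) and noisy, and a sign constraint on the mean is what the method's
design actually guarantees to test.

## Problem sizes

Unit tests run a reduced tier (96×96 images, 1 template, 2 scales, 12
directions, 2×2 grid — 360 features in a few seconds); the full
60-direction, 5-scale operating point is exercised through its dimensional
contract and per-component checks. The steerability oracle covers all six
templates at $\sigma \in \{0.5, 1, 2\}$ and 16 angles on a 64×64 image.
Parameter-recovery fits use $10^4$ samples; the co-training benchmark uses
the conditions above. These sizes were chosen so the whole suite documents
the method at laptop scale.

## Known limitations

* The Weibull location parameter of near-symmetric derivative responses is
  weakly identified (it hovers near zero); its intensity-covariance is
  therefore tested on the scale of $\hat\beta$.
* MARS model selection is discrete; single added samples can change the
  selected basis. Friedman spans mitigate but do not remove this.
* The per-direction fits assume unimodal, symmetric response histograms;
  strictly periodic patterns violate this and land in the $\lambda \gg 2$
  regime by design.
* No multi-class extension: the grading task is two-class by construction.
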