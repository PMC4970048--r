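# graintex

Texture statistics and semi-supervised quality grading for images of
granulated products — rice, seeds, grain, fabric: scenes made of hundreds of
stochastically packed, locally homogeneous particles where per-object
segmentation fails and the *distribution* of local structure is the signal.

`graintex` is for image-analysis and quality-inspection work where (a) the
objects of interest cannot be segmented individually and (b) ground-truth
quality labels are scarce because they come from manual grading or
laboratory assays.

## The method

1. **Steerable Gaussian-derivative filtering.** A detector template
   $G_{\kappa,\sigma} = \sum_t w_t\,\sigma^{e_t}\,
   \partial_x^{i_t}\partial_y^{j_t} G_\sigma$ is steerable: its response at
   any orientation $\theta$ is an exact weighted sum
   $\sum_{m,i} \alpha_{m,i}(\theta)\, I_{m,i}$ of a few base responses
   $I_{m,i} = I * \partial_x^i \partial_y^{m-i} G_\sigma$. A 60-direction
   sweep costs a handful of convolutions. Six classical edge/ridge/wedge
   templates (T1–T6) are built in.

2. **Integral-form Weibull modeling.** Each oriented response histogram is
   fitted by maximum likelihood (Nelder–Mead) with
   $f(x;\mu,\lambda,\beta) = C\, e^{-\frac{1}{\lambda}
   \left|\frac{x-\mu}{\beta}\right|^{\lambda}}$,
   $C = \lambda / (2\lambda^{1/\lambda} \beta\, \Gamma(1/\lambda))$.
   The triple $(\hat\mu, \hat\beta, \hat\lambda)$ per direction × scale ×
   region (global + subimage grid) is the texture feature vector — at the
   standard operating point, $5 \times 60 \times 3 \times 5 = 4500$ features
   per template. $\lambda$ tracks granularity ($2$ = Gaussian, $1$ =
   Laplace, $\to 0$ = power law), $\beta$ contrast width, $\mu$ global
   reflectance.

3. **COSC-Boosting.** Two complementary classifiers — thin-plate-spline
   regression (TPSRC, global radial-basis view) and multivariate adaptive
   regression splines (MARSC, per-factor/interaction view) — are co-trained:
   per iteration each labels its most *confident* unlabeled sample for the
   other, where confidence is the decrease of squared error on the labeled
   set and candidacy requires both classifiers to agree on the label. The
   final grade is the thresholded score average.

## Worked example

```r
library(graintex)

# a synthetic granulated-product image (128 x 128, 120 shaded particles)
img <- generate_granular_image(granular_image_spec(seed = 1))

# Weibull fit of one steered filter response (edge template T1, sigma = 1,
# response at 45 degrees)
resp <- oriented_response(img, "T1", sigma = 1, theta = pi / 4)
fit <- fit_wd_mle(as.numeric(interior_values(resp)))
print(fit)
#> WD fit (n = 14400): mu = -0.00031691, lambda = 0.49161, beta = 0.019008
#>   nll = -28151.9, chi2 = 0.0875, kld = 0.05267, converged = TRUE
```

The shape estimate $\hat\lambda \approx 0.49$ puts this texture deep in the
heavy-tailed fragmentation regime (well below the Gaussian value 2), as
expected for a field of discrete particles; $\hat\beta \approx 0.019$ is the
contrast width of the edge response in [0,1] intensity units, and
$\hat\mu \approx 0$ says the response is symmetric, as a derivative filter
on a stationary texture should be. The fit diagnostics ($\chi^2 = 0.0875$,
KLD = 0.053) score the binned model against the empirical histogram.

```r
# a reduced-tier texture feature vector: 1 template, 2 scales, 12 directions,
# 2x2 subimage grid -> 2 * 12 * 3 * 5 = 360 features
cfg <- feature_config(template_names = "T2", n_directions = 12,
                      scales = c(0.5, 1), subimage_grid = c(2, 2))
fv <- extended_features(img, cfg, source_id = "demo")
print(fv)
#> Feature vector 'demo': 360 values (1 templates x 2 scales x 12 directions
#>   x 3 params x 5 regions)
round(fv$values[1:6], 4)
#>     T2.global.s01.d01.mu   T2.global.s01.d01.beta T2.global.s01.d01.lambda
#>                  -0.0021                   0.0272                   0.4643
#>     T2.global.s01.d02.mu   T2.global.s01.d02.beta T2.global.s01.d02.lambda
#>                  -0.0019                   0.0295                   0.4668

# semi-supervised grading on a seeded two-class benchmark (10% labeled)
d <- generate_ss_dataset(ss_dataset_spec(n_per_class = 200, k = 4,
                                         separation = 1.6, label_rate = 0.10,
                                         seed = 1))
model <- cosc_fit(d$labeled, d$unlabeled,
                  cosc_config(max_iterations = 30, seed = 1001, eta = NULL,
                              mars_options = list(max_terms = 8, max_degree = 1)))
print(model)
#> COSC-Boosting model: 40 original labels, L1 = 46, L2 = 46, 7 iteration(s)
pred <- ensemble_predict(model, d$unlabeled)
ce_metrics(pred$labels, d$truth)$ace_ts
#> [1] 7.5
```

Starting from 40 labeled samples, the loop accepted 6 virtually labeled
samples per classifier over 7 iterations and grades the 360 unseen samples
with 7.5% pooled classification error.

A command-line pipeline wrapping the same functions (extract / train /
predict / simulate) lives at `inst/cli/graintex.R`; see the methods vignette
(`vignettes/graintex-methods.Rmd`) for the model details, parameter
conventions and design choices.

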