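# infoest

Non-parametric estimation of differential entropy, Kullback–Leibler (KL)
divergence, and mutual information from multi-dimensional continuous samples.

Applying information theory to real data requires estimating quantities such
as

- entropy `H(X) = −∫ p(x) log p(x) dx`,
- KL divergence `D_KL(p‖q) = ∫ p(x) log(p(x)/q(x)) dx`, and
- mutual information `I(X;Y) = ∫∫ p(x,y) log( p(x,y) / (p(x) p(y)) ) dx dy`

from a finite sample, without knowing the densities. All quantities are in
nats (natural logarithm). `infoest` implements the three estimator families a
practitioner will encounter, behind a uniform interface, together with a
benchmark suite for judging which one to trust on data like theirs:

- **Kernel density estimation (KDE)** — multivariate Gaussian kernel with
  Silverman's bandwidth `h = (n(d+2)/4)^(−1/(d+4))`, as resubstitution
  (mean log-density at the sample points) or integral (adaptive quadrature of
  the fitted density) plug-in estimates: `kde_entropy()`, `kde_kl()`,
  `kde_mi()`.
- **Binning** — per-dimension histograms sized by Sturges', Scott's, or
  Freedman–Diaconis' rule with empty bins excluded, plus the one-dimensional
  Quantile Spacing entropy estimator: `bin_entropy()`, `bin_kl()`,
  `bin_mi()`, `qs_entropy()`.
- **k-nearest neighbors** — estimators that skip density estimation entirely:
  Kozachenko–Leonenko entropy (`knn_entropy()`), the Wang et al. two-sample
  KL estimator (`knn_kl()`), and the Kraskov–Stögbauer–Grassberger mutual
  information estimator under the maximum norm (`kraskov_mi()`), backed by an
  exact kd-tree (`knn_distances()`).

Eight synthetic benchmark cases (`builtin_cases()`) — 1-D uniform, normal,
and normal mixture; 2-D normal, normal mixture, and gamma-exponential; 4-D
and 10-D correlated normals — come with analytical reference values where a
closed form exists (`analytic_reference()`) and adaptive-quadrature
references otherwise (`numeric_reference()`). A seeded sweep harness
(`sweep_config()`, `run_sweep()`, `summarize_records()`) reproduces the
accuracy evaluation: repeated samples per size, every estimator applied to
the same data, aggregated into mean, 2.5/97.5 percentile band, and relative
error against the reference.

## Worked example

Entropy of a correlated 4-D normal (unit variances, pairwise covariance 0.5),
true value `½ ln((2πe)^4 det Σ)`:

```r
library(infoest)

case <- builtin_cases()[[7]]          # 4-D normal benchmark case
case_reference(case, "entropy")$value
#> [1] 5.094179

x <- draw_sample(case$p, 10000, seed = 1)
knn_entropy(x, k = 1)                 # Kozachenko-Leonenko
#> [1] 5.090496
bin_entropy(x, rule = "sturges")      # histogram with quantization correction
#> [1] 4.845744
kde_entropy(x)                        # Gaussian-kernel resubstitution
#> [1] 4.942163
```

At 10,000 points the k-NN estimate is within 0.1% of the truth, KDE is a few
percent low, and the 4-D histogram underestimates by about 5% — the central,
reproducible finding of the benchmark: distance-based estimation degrades
most gracefully with dimension.

A small sweep with confidence bands:

```r
cfg <- sweep_config(2, "entropy", list(est_knn(1), est_binning("scott")),
                    sizes = c(100, 1000, 10000), seeds = 1:20)
summarize_records(run_sweep(cfg))
#>   case quantity estimator    variant     n n_seeds     mean     p2.5    p97.5 reference     rel_error error_type
#> 1    2  entropy   binning rule=scott   100      20 2.278156 2.176888 2.426288  2.335229 -2.444004e-02   relative
#> 2    2  entropy   binning rule=scott  1000      20 2.331397 2.290789 2.365237  2.335229 -1.640854e-03   relative
#> 3    2  entropy   binning rule=scott 10000      20 2.335163 2.325622 2.345743  2.335229 -2.853531e-05   relative
#> 4    2  entropy       knn        k=1   100      20 2.275666 1.871462 2.510228  2.335229 -2.550632e-02   relative
#> 5    2  entropy       knn        k=1  1000      20 2.344716 2.275672 2.414866  2.335229  4.062306e-03   relative
#> 6    2  entropy       knn        k=1 10000      20 2.336409 2.315286 2.360791  2.335229  5.052190e-04   relative
```

A thin command-line front end is installed at
`system.file("cli", "infoest.R", package = "infoest")` with subcommands
`list-cases`, `run`, and `summarize`.

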