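# SwarmThresh

Multilevel Otsu thresholding for grayscale images, driven by an adaptive
hybrid swarm metaheuristic — for researchers benchmarking
histogram-based segmentation on histopathology-style images, and for
anyone who needs reproducible, oracle-validated multilevel thresholds
with a full quality-metric suite.

## The problem and the method

Segmenting an 8-bit image into $k+1$ intensity classes means choosing
$k$ thresholds $T = \{t_1 < \dots < t_k\}$. The classic criterion is
Otsu's: maximize the between-class variance of the gray-level histogram
$p_j$,

$$\max_T\; J(T) = \sum_{i=1}^{k+1} \omega_i (\mu_i - \mu_T)^2,
\qquad \omega_i = \sum_{j=t_{i-1}+1}^{t_i} p_j,$$

with $\mu_i$ the class means and $\mu_T$ the global mean — equivalently,
minimize the within-class variance. Exhaustive search over
$\binom{255}{k}$ combinations is infeasible beyond small $k$, so
thresholds are found with swarm metaheuristics.

The package's centerpiece, `runSCSOWOA()`, is a two-phase hybrid: the
first $\lfloor \lambda T_{max} \rfloor$ iterations (default
$\lambda = 0.6$, $T_{max} = 100$) explore with sand cat swarm
optimization (SCSO); its incumbent is then handed to a whale
optimization algorithm (WOA) population that exploits for the remaining
iterations via encircling and logarithmic-spiral moves with a linearly
decaying coefficient. Canonical PSO, GWO, WOA and SCSO baselines run
under the same interface and identical evaluation budget
($N(T_{max}+1)$ objective calls, exactly), plus an exhaustive
brute-force oracle for small instances. Around the optimizer sit
preprocessing, class-mean reconstruction, full-reference metrics (PSNR,
SSIM, FSIM), overlap metrics (Dice, Jaccard, Hausdorff), correlation
diagnostics, a seeded synthetic fixture generator, and a benchmarking
harness.

## Worked example

```r
library(SwarmThresh)

# a seeded trimodal mixture image (dark nuclei / cytoplasm / background)
mix <- makeMixtureImage(data.frame(mean = c(60, 130, 200), sd = c(10, 12, 8),
                                   weight = c(0.4, 0.35, 0.25)),
                        size = c(128L, 128L), seed = 1)
h   <- computeHistogram(mix$image)
fit <- runSCSOWOA(h, k = 2, hybridConfig(), seed = 1)
fit
#> SwarmFit [ scsowoa ] seed 1
#>   J = 3118.377  thresholds: 96.8431, 164.111

bruteForceThresholds(h, 2)       # exhaustive optimum: t = (95, 165), J* = 3118.397

seg <- applyThresholds(mix$image, bestThresholds(fit))
round(metricReport(mix$image, reconstruction(seg)), 4)
#>      psnr   ssim   fsim pearson_r spearman_rho ...
#> 1 27.9653 0.9831 0.9791    0.9837        0.937 ...
```

The hybrid's two continuous thresholds floor to bins one step from the
exhaustive optimum and reach 99.999% of its objective value (the
objective is piecewise-constant, so nearby bins often tie or nearly
tie). `metricReport()` scores the class-mean reconstruction against the
original: with only two thresholds the three generating modes are
already separated well enough for an SSIM of 0.98. Pixel-level Pearson
and Spearman correlations near 1 confirm the reconstruction preserves
intensity relationships; the neighbor-pixel correlation is ~0 here
because mixture fixtures are spatially i.i.d. by design (use
`makeBlobImage()` for spatially structured fixtures).

A protocol-shaped sweep (algorithms × threshold counts × 10 seeded
runs, mean ± sd tables) is one call:

```r
res <- runBenchmark(syntheticBenchmarkImages(),
                    algorithms = c("scsowoa", "scso", "woa"),
                    kValues = c(2L, 6L, 12L), nRuns = 10L)
res$summaryPooled
```

A thin CLI wraps the same functions
(`inst/scripts/swarmthresh.R threshold | benchmark | make-fixtures`).

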