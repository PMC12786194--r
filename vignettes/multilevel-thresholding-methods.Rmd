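---
title: "Multilevel Otsu thresholding with a hybrid sand-cat/whale optimizer: methods and design notes"
author: "SwarmThresh authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SwarmThresh)
```

## The model

Multilevel thresholding partitions the gray levels $\{0,\dots,L-1\}$ of an
8-bit image into $k+1$ classes by $k$ thresholds
$T = \{t_1 < \dots < t_k\}$. SwarmThresh selects $T$ by maximizing the Otsu
between-class variance of the normalized histogram $p_j$:

$$J(T) = \sum_{i=1}^{k+1} \omega_i\, (\mu_i - \mu_T)^2,
\qquad
\omega_i = \sum_{j=t_{i-1}+1}^{t_i} p_j,\quad
\mu_i = \frac{1}{\omega_i}\sum_{j=t_{i-1}+1}^{t_i} j\,p_j,\quad
\mu_T = \sum_{j=0}^{L-1} j\,p_j.$$

Maximizing $J$ is equivalent to minimizing the within-class variance, since
their sum is the (fixed) total histogram variance — an identity the test
suite asserts to $10^{-9}$ relative on random inputs. The objective depends
on the image only through its histogram, so a run costs $O(L)$ per
evaluation regardless of image size.

### Boundary and degeneracy conventions

The search domain is continuous, $t_i \in [1, L-1]$, but the histogram is
discrete: any real threshold between two integer bins induces the identical
partition, so evaluation floors each threshold. This makes $J$
piecewise-constant on the continuous domain; flooring is exact, not an
approximation. Class $i$ covers bins
$\lfloor t_{i-1}\rfloor < j \le \lfloor t_i\rfloor$, with class 1 starting
at bin 0 (the lower sentinel is a 0-boundary, chosen because the class-mass
summation limits start at $t_{i-1}+1$; the text of the source formulation
never pins down the lower edge, so this is the convention adopted and
documented here). After sorting, thresholds whose floors coincide are
collapsed for evaluation — the empty class contributes exactly 0 to $J$ —
while the agent's continuous position is left untouched. Empty classes
define $\mu_i = 0$ and skip the term, avoiding 0/0 without affecting $J$.

### The exhaustive oracle

`bruteForceThresholds()` enumerates all $\binom{L-1}{k}$ integer
combinations and is the ground truth the metaheuristics are validated
against. Ties — frequent, because empty histogram regions produce plateaus
of bit-identical $J$ — are broken by the lexicographically smallest vector,
so oracle output is deterministic. A guard cap (default $10^6$
combinations) keeps it an oracle, not a production path.

## The hybrid optimizer

The hybrid splits a budget of $T_{max}$ iterations (default 100) for a
population of $N$ agents (default 30) into two phases controlled by the
switch ratio $\lambda$ (default 0.6):
$T_{SCSO} = \lfloor \lambda T_{max}\rfloor$ iterations of sand cat swarm
exploration followed by $T_{WOA} = T_{max} - T_{SCSO}$ iterations of whale
exploitation — 60 and 40 under the defaults.

**Exploration (SCSO).** Each agent either takes the directional-hunting
step $X \leftarrow X + r_1 X^* - r_2 X$ or the difference-attraction step
$X \leftarrow X + r_3 (X^* - X)$, with $r_{1,2,3} \sim U(0,1)$ and $X^*$
the best-so-far. The source formulation presents both rules without a
selection rule, so a fair per-agent coin picks between them — the simplest
symmetric reading. An orientation angle per agent,
$\theta_{t+1} = \theta_t + \alpha \sin(\omega t + \phi)$, is advanced and
recorded; it is *not* coupled to movement by default because the
formulation defines the recurrence but never specifies a coupling. Setting
`scsoTheta = TRUE` enables a documented extension in which $r_3$ is
modulated by $|\sin\theta_i|$.

**Handoff.** After the exploration phase the incumbent best is carried into
a freshly randomized whale population as its first agent. Elitism is
therefore preserved across the phase boundary: the best-so-far trace is
non-decreasing over all $T_{max}$ iterations.

**Exploitation (WOA).** With $a$ decreasing linearly from $a_0 = 2$ to 0
*within the phase* ($a = a_0 - t\,a_0/T_{WOA}$), each agent draws
$p \sim U(0,1)$: with $p < 0.5$ it encircles the best,
$X \leftarrow X^* - A\,|C X^* - X|$ where $A = 2ar - a$, $C = 2r'$, unless
$|A| \ge 1$, in which case it searches around a random agent; with
$p \ge 0.5$ it takes the logarithmic spiral
$X \leftarrow |X^* - X|\, e^{bl}\cos(2\pi l) + X^*$, $l \sim U(-1,1)$,
$b = 1$. This is the canonical whale algorithm. The source's pseudocode
instead branches on $|A|$ alone with no spiral; both readings are
implemented (`woaBranchMode = "canonical"` / `"pseudocode"`) rather than
silently picking one, and the same policy is applied to the
exploration-step ambiguity (`scsoUpdateMode = "equation"` /
`"mean_attraction"`). Canonical mode draws the $A$- and $C$-uniforms
independently, as standard; pseudocode mode shares a single draw as
written there.

### Contracts

Three properties are enforced and tested rather than merely intended:

* **Budget.** Exactly $N(T_{max}+1)$ objective evaluations per run — $N$
  at initialization plus $N$ per iteration. Fresh whale-phase agents are
  first evaluated after their first move, so the handoff adds none. With
  $\lambda = 0$ the exploration phase degenerates to the initialization
  (whose best seeds the whale phase); a full population is initialized and
  evaluated even then, keeping the budget exact.
* **Elitism.** The best solution is updated only on strict improvement
  (ties keep the incumbent, for determinism) and never regresses.
* **Determinism.** One RNG stream per run, seeded from the `seed`
  argument; identical inputs give bit-identical thresholds and traces. The
  caller's RNG state is saved and restored. `logDraws = TRUE` records
  every uniform draw, and the step functions accept explicit draws, which
  is how the unit tests replay single steps against hand-traced updates.

Out-of-bounds positions are hard-clamped to $[1, L-1]$ (the simplest
contract; the source formulation does not state one). Baselines — PSO
($w = 0.5$, $c_1 = c_2 = 2$, zero initial velocities), GWO ($a: 2 \to 0$
linear), standalone WOA ($a: 2 \to 0$ over the full run) and standalone
SCSO — run under the same interface, bounds, budget and elitism contracts.

## Segmentation and reconstruction

`preprocessImage()` produces the working representation: luminance
conversion ($0.299R + 0.587G + 0.114B$), bilinear resize to 256×256
(skipped when already conforming, so an 8-bit grayscale input of the right
size passes through bit-identically), normalization to $[0,1]$ and
quantization back to 0..255 with round-half-to-even. Flip/rotation
augmentation is deliberately excluded from this path: it serves dataset
balancing in training pipelines and has no meaning for a deterministic
per-image evaluation.

`applyThresholds()` labels each pixel by its threshold class and builds the
**class-mean reconstruction**: each pixel replaced by the rounded
(half-to-even) mean intensity of its class, with empty classes assigned
their bin-range midpoint. The reconstruction rule is flagged prominently
because the evaluation protocol being reproduced never states how the
"segmented image" fed to PSNR/SSIM/FSIM is formed. Class-mean replacement
is the standard convention in multilevel-thresholding work and the unique
rule that ties the metrics to the objective: the reconstruction's MSE
equals the within-class variance, so maximizing $J$ is exactly maximizing
reconstruction PSNR. The test suite asserts this identity numerically and
verifies that the exhaustive optimum attains the maximum PSNR among random
threshold sets.

How a multilevel label map becomes a *binary* mask for Dice/Jaccard/
Hausdorff is likewise unstated in the protocol; the package leaves the
class-subset-to-foreground mapping to the caller (any comparison of a
thresholded label map against a binary ground truth must choose one; the
acceptance computations use intensity-above-threshold on a fixture whose
generating mask is known).

## Metrics

* **PSNR** $= 10\log_{10}(255^2/\mathrm{MSE})$, with identical inputs
  reported as a documented 100 dB cap so tables stay finite.
* **SSIM** is the classic mean structural similarity: 11×11 Gaussian
  window, $\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$, dynamic range 255,
  averaged over the valid filter region. Verified against an established
  reference implementation to $10^{-6}$ on seeded fixtures (values frozen
  into the suite).
* **FSIM** combines phase-congruency similarity ($T_1 = 0.85$) and Scharr
  gradient similarity ($T_2 = 160$), weighted by the pointwise maximum
  phase-congruency map. Phase congruency uses a 4-scale, 4-orientation
  log-Gabor bank (minimum wavelength 6, multiplier 2, $\sigma_{onf} =
  0.55$, angular spread $\pi/4/1.2$, noise compensation $k = 2$) — the
  published parameterization. Since the evaluation protocol names the
  metrics without parameters, all constants are surfaced as arguments. A
  constant image pair has zero phase congruency everywhere; the documented
  fallback returns 1 for identical inputs and the unweighted similarity
  mean otherwise, never NaN.
* **Overlap**: Dice, Jaccard (two empty masks count as perfect agreement;
  one empty mask gives 0 and an undefined Hausdorff), and the symmetric
  Hausdorff distance as the max of the two directed max–min Euclidean
  distances.
* **Correlation diagnostics**: Pearson and Spearman (average ranks for
  ties) between original and reconstruction, and between horizontally
  adjacent pixel pairs of the reconstruction. The neighbor-pair definition
  (direction, pooling) is not fixed by the protocol being reproduced;
  horizontal-only is the documented default, with vertical pooling behind
  a flag. Constant inputs yield NA with a warning rather than an arbitrary
  number.

## Synthetic data: what it emulates and what it does not

`makeMixtureImage()` draws each pixel independently from a Gaussian
mixture truncated to $[0,255]$ — truncation by rejection, not clipping,
because clipping would pile spurious mass at 0/255 and corrupt tests that
compare the empirical histogram with the analytic density (total-variation
distance ≤ 0.02 at 256×256). The standard suite (two-, three- and
five-mode mixtures) emulates the multi-modal gray-level histograms of
stained tissue — dark nuclei, mid-gray cytoplasm, bright background — with
fully known parameters. `makeBlobImage()` adds spatial structure: noisy
disks on a background with the exact generating mask returned, supporting
overlap-metric and visual checks.

What the generators do **not** emulate: spatial texture within classes
(mixture pixels are i.i.d., so neighbor-pixel correlation is near zero on
mixtures — spatial diagnostics are only meaningful on the blob fixture),
stain-color variation, illumination gradients, and the long-tailed
structures of real histopathology. Passing tests therefore demonstrate the
correctness of the optimization and evaluation machinery on controlled
histograms, not clinical performance on tissue images.

The bimodal fixture (means 60/180, sd 10) deserves one note: its modes are
so well separated that the inter-mode bins are empty, making the optimal
threshold a wide plateau of bit-identical $J$. Recovery on this fixture
means attaining the exhaustive optimum's objective value with a threshold
strictly between the modes — the optimal *bin* is non-unique by
construction, and which representative an optimizer returns is arbitrary
(the oracle's own representative is fixed only by its tie-break rule).

## Problem sizes and defaults

The package defaults mirror the evaluation protocol: $N = 30$ agents,
$T_{max} = 100$ iterations, $\lambda = 0.6$, 10 independent runs per
condition (run $r$ seeded `baseSeed + r - 1`), threshold counts 2–12, and
summary tables reporting mean ± sample standard deviation ($n-1$
denominator; the protocol does not specify, so the choice is documented in
the harness). Benchmarks aggregate both pooled over images × runs and
per-image-first, since the protocol's pooling is ambiguous. The bundled
synthetic suite uses 128×128 fixtures: the objective sees only the
histogram, so fixture size affects only histogram noise, and 128×128 keeps
the full test suite and benchmark sweeps comfortably interactive. The
across-seed stability comparison of the hybrid against its constituents is
made at suite level (the mean over fixtures and threshold counts of the
per-condition across-seed standard deviation of $J$), the level at which
the stability claim is framed; per-condition orderings fluctuate with seed
noise, as expected for stochastic optimizers.

## Known limitations

* Gray-level histograms only: no 2-D (spatial) histograms, no entropy
  criteria, no per-channel color thresholding, no stain deconvolution.
* The comparator set is PSO/GWO/WOA/SCSO; hybrid comparators whose update
  rules are not published in the formulation being reproduced are out of
  scope.
* Wall-clock timings are recorded by the harness but never asserted:
  they are hardware-dependent.
* FSIM agreement with other implementations is expected to ~$10^{-3}$:
  boundary handling in the gradient convolution and FFT rounding differ
  legitimately between ports.
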