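---
title: "Screening environment-disease networks with fuzzy cognitive maps"
author: "fcmscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening environment-disease networks with fuzzy cognitive maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`fcmscreen` treats a daily multivariate panel — air pollutants,
meteorological variables and per-disease hospital-admission counts — as
the trajectory of a *fuzzy cognitive map* (FCM): a signed, weighted,
directed and possibly cyclic graph over "concepts" whose activations
evolve in discrete time. After min–max normalization of every column to
$[0,1]$, the activation of concept $i$ follows

$$u_i(t+1) \;=\; f\!\Big(\sum_{\ell=1}^{k}\sum_{j=1}^{n} w^{(\ell)}_{ji}\,u_j(t-\ell+1)\Big),
\qquad f(x) = \frac{1}{1+e^{-\lambda x}},$$

where $k \in \{1,2,3\}$ is the lag order, $w^{(\ell)}_{ji} \in [-1,1]$ is
the influence of concept $j$ at lag $\ell$ on concept $i$, and
$\lambda$ (default 5) sets the sigmoid steepness. The steepness has
little effect on the inferred structure because it only rescales the
weights' effective gain; it is kept configurable.

Weights are stored *source-major*: `fcmWeights(m)[[l]][j, i]` is the
edge $j \to i$ at lag $l$. One accessor convention, used everywhere.

### The directional-feedback mask

Disease incidence cannot plausibly alter tomorrow's weather or pollutant
load on this time scale, so every disease $\to$ environment entry is
frozen at exactly zero during optimization (`buildMask()`). All other
influences — environment $\to$ environment, environment $\to$ disease,
disease $\to$ disease, and self-loops — are learnable. The optimizer's
genome covers only the learnable entries, which is equivalent to
optimizing the full matrix and zeroing the forbidden block, but smaller.

## Weight inference by differential evolution

The weights are inferred by minimizing the sum of squared one-step
prediction errors over all concepts and all rows with a full lag window
(rows $t > k$). Two prediction modes exist: *teacher forcing* (each row
predicted from observed history; the default, stable on long daily
panels) and *free run* (the model rolls forward on its own predictions;
available for diagnostics). The loss is optimized by differential
evolution (DE):

* **crossover** forms a perturbed vector $v_i + F\,(v_1 - v_2)$ from the
  target and two distinct random donors, clipped to $[-1,1]$;
* **mutation** builds the trial by taking each element from the
  perturbed vector with probability CR, with one pre-drawn forced index
  always taken so the trial never trivially equals the incumbent;
* **greedy selection** keeps the lower-loss of incumbent and trial; ties
  keep the incumbent, so the best loss is non-increasing by
  construction.

Runs terminate at `maxEpochs` or when the best loss improves by less
than `convergenceTol` (default $10^{-8}$) over a stall window (default
50 epochs). The multi-start protocol (`multiRestartFit()`) repeats the
run `nRestarts` times (default 10) for each candidate order in
`orders`, with deterministic sub-seeds derived from the master seed, and
selects the candidate with the best *training* fitness — never the test
error. The chronological first 75% of rows train the model; the last 25%
are scored as mean absolute error with the training normalization
bounds.

Package defaults are conventional DE practice at this genome size
(population 50, $F = 0.5$, CR $= 0.3$, 500 epochs). For the study-sized
end-to-end experiments shipped in the tests and acceptance script we
instead use CR $= 0.9$, population 40, up to 1000 epochs and 5 restarts:
on the tiny synthetic study this configuration reaches clearly lower
training fitness at comparable runtime (CR near 1 mixes correlated
coordinates faster when columns are collinear), and training fitness is
the method's own selection criterion. Each epoch evaluates the whole
trial population in one matrix product, which is what makes multi-start
protocols affordable in pure R.

## Path-based screening

A learned weight matrix is dense; read literally it would connect every
pair of concepts and make all path counts identical. Screening therefore
works on a sparsified graph (`thresholdGraph()`): higher-order lag
matrices are collapsed per edge (largest-magnitude lag weight by
default, sum optionally) and edges with $|w| < \varepsilon$ (default
0.05) are dropped. Self-loops are excluded — a simple path cannot
revisit its start — but self-weights remain in the serialized model.

For an ordered pair the package enumerates every *simple path* (no
repeated node) up to `maxLen` edges (default 4; unbounded enumeration is
factorial in $n$, and every output records the cap used). A path's
weight is the **product** of its edge weights, so sign semantics compose
along the path; multiple paths aggregate by **signed sum**. Two
statistics feed the screening: the number of simple paths, and the
absolute mean of path-weight sums over the environment factors. Both are
pure functions of the serialized model plus $(\varepsilon,
\texttt{maxLen})$, so every table can be recomputed from the model JSON
alone. Rankings use a stable tie rule: metric descending, then label
ascending. Environment nodes may serve as intermediates on
disease-to-disease paths (restrictable via
`diseaseOnlyIntermediates = TRUE`).

The Top-$k$ screening (`screenTopK()`, $k = 5$ by default, clamped to
the number of diseases) retains a disease when it appears in any Top-$k$
list (by mean path count or by absolute mean weight, in the
per-disease "singular" study or the joint "overall" study) and orders
its associated factors by absolute path-weight sum.

## The synthetic study

Real admission data of this kind are rarely shareable, so the package
generates its own study (`makeStudyFixture()`), with a known ground
truth so that every pipeline stage is testable end to end.

* **Environment.** Each factor is baseline + seasonal sine (period
  365.25 d) + Gaussian noise. Collinear factors are correlated mixtures
  of a parent's z-scores — PM10 tracks PM2.5 at $r = 0.9$; minimum and
  maximum temperature ($r = 0.97$), dew point ($0.9$) and humidity
  ($0.5$) track temperature — so the sample correlation concentrates on
  the requested value and the variance-inflation diagnostics have
  something real to find.
* **Admissions.** A ground-truth FCM (mask-respecting) drives latent
  disease activations on the normalized environment; the latent maps
  linearly to a mean daily rate $\mu_d(t) = \text{base}_d \cdot
  u_d(t)/0.5$ and counts are drawn negative-binomial. Rare conditions
  produce many zero-count days naturally.
* **Scales.** `tiny` (4 factors, 2 diseases, 300 days) runs the whole
  pipeline in seconds; `paper_like` mirrors a full study: 15 factors, 10
  diseases, daily from 2019-01-01 to 2024-06-30 (2008 rows), base rates
  graded over two orders of magnitude (8.1/day down to 0.03/day).

Two design choices in the tiny ground truth deserve comment. First,
each disease carries a negative self-loop: without it the injected
environmental effect drives the sigmoid into its flat tail and the
seasonal signal is squashed before it reaches the counts. A
self-loop never enters a simple path, so temperature $\to$ D1 remains
the *only* environment-to-D1 influence — the scenario the end-to-end
recovery experiments require. Second, the tiny fixture uses
negative-binomial size 20 (variance about twice Poisson at its base
rates, typical of daily ophthalmology admissions), the mildest level at
which the injected effect is reliably identifiable from 300 days: an FCM
has no intercept term, so any systematic offset between the predicted
sigmoid level and the skew-compressed normalized counts leaks into
spurious weights on collinear factors, and heavier overdispersion makes
that leakage rival a genuine effect. The `paper_like` fixture keeps the
heavier default (size 5) deliberately, as a harder, more realistic
panel; it is a data-shape fixture, not a recovery benchmark.

What passing the synthetic tests does *not* show: robustness to missing
data (ingestion rejects it), holiday/weekday structure, pandemic-era
structural breaks, or measurement error in the environmental series —
none of which the generator emulates.

## Numerical and procedural choices

* **Normalization** is per column over the supplied rows; constant
  columns are a hard error naming the column. Test data reuse the
  training bounds and are clipped to $[0,1]$.
* **Loss scoring** starts at the first row with a full lag window
  ($t = k+1$), for every order.
* **Weight bounds** $[-1,1]$ are enforced by clipping DE proposals, the
  conventional FCM range.
* **Donor sampling** draws two individuals distinct from each other and
  from the target, avoiding null moves.
* **Determinism.** Every stochastic step derives from one master seed
  (counter-based sub-seeds per order, restart and study model); repeated
  runs produce byte-identical artifacts, and the study manifest records
  everything needed to reproduce them. No wall-clock information enters
  any artifact.
* **Degenerate inputs.** An empty thresholded graph is a warning, not an
  error; `k` larger than the disease count is clamped with a warning;
  exactly collinear columns yield an infinite VIF rather than an error.

### The recovery benchmarks

Noise-free parameter recovery demands care: under teacher forcing a
noise-free dataset must be an exact free-run trajectory of the
generating map, and most random sparse FCMs collapse to a fixed point
within a few steps, leaving the weights unidentifiable. The benchmark
ground truths shipped in the tests (one order-1 map on 4 concepts, one
order-2 map on 3 concepts) were therefore selected, once, by searching
random sparse matrices for aperiodic trajectories with non-degenerate
row diversity; their trajectories (burn-in of 20 steps discarded,
$T = 200$) identify the weights essentially uniquely, and the DE
optimizer recovers them to a training loss below $10^{-3}$ with sign
agreement on the true edges and weight correlation $\ge 0.8$.

Problem sizes used throughout the shipped experiments — 300-day tiny
studies, $T = 200$ recovery trajectories, 10-repetition screening
experiments — were chosen as the smallest scales at which the
corresponding claims are statistically meaningful.

## Limitations

* The FCM has no intercept; systematic level offsets are absorbed by
  weights on whatever predictors are available (see the dispersion
  discussion above). This is inherent to the formulation, not an
  implementation artifact.
* Simple-path statistics carry no significance assessment; they are
  descriptive screening metrics, and the $\varepsilon$ and `maxLen`
  settings materially shape them (all outputs record both).
* DE is stochastic: different seeds give different fitted matrices with
  similar fitness, especially under collinearity. The multi-start
  protocol mitigates but does not remove this.
* Min–max normalization is sensitive to single-day outliers, which
  compress the remaining signal; robust scaling is out of scope.
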