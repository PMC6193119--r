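---
title: "Methods: static, dynamic and structural connectivity with group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: static, dynamic and structural connectivity with group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connstates)
```

## Overview

`connstates` implements a multimodal brain-connectivity analysis chain for
cohorts split into abdominal and non-abdominal obesity groups by the
waist–hip ratio (WHR): males with WHR > 0.9 and females with WHR > 0.85 are
classified as abdominal obesity, with boundary values non-abdominal. The
chain has three measurement arms and two inference stages:

* **Structural arm.** A directed fiber-probability matrix per subject
  (entry *i, j*: probability that probabilistic-tractography streamlines
  seeded in region *i* reach region *j*). Degree centrality (DC) is the
  directed in+out degree: the column sum plus the row sum of the raw
  probabilities at each node, diagonal excluded.
* **Static functional arm.** Per subject, the Pearson correlation matrix of
  node time series is soft-thresholded with the unsigned map
  $w_{ij} = ((r_{ij} + 1)/2)^\beta$ (default $\beta = 6$), Fisher
  r-to-z transformed ($z = \operatorname{atanh} w$, diagonal zeroed first),
  and summarised by undirected DC (column sums).
* **Dynamic functional arm.** A tapered sliding window yields a sequence of
  windowed covariances per subject; each is inverted under an L1 penalty
  (graphical lasso), scaled to partial correlations, and the windows are
  clustered into recurring brain states by K-means. Per subject and state,
  the member windows are averaged and pushed through the same
  soft-threshold / Fisher-z / DC summary.
* **Group inference.** Per-node group differences in DC are tested by label
  permutation with Benjamini–Hochberg (BH) FDR across nodes.
* **Brain–behaviour inference.** Each of the four EDE-Q subscales
  (restraint, eating, shape, weight concern) is regressed on the DC of
  identified nodes with age as a covariate; p-values are BH-corrected
  across the full family of regions/networks × subscales.

Everything is driven by a synthetic-cohort generator with planted ground
truth, so the whole chain is verifiable without imaging data.

## The dynamic-connectivity model

### Windowing

The window length is chosen so one full cycle of the slowest fluctuation of
interest fits inside: `window_length_from_frequency(tr, min_freq)` returns
$\mathrm{round}((1/f_{\min})/\mathrm{TR})$. At TR = 0.645 s and
$f_{\min} = 0.009$ Hz this gives 172 time points (111 s). The window is a
rectangle convolved with a Gaussian kernel of standard deviation
`taper_sigma` (default 3 time points, truncated at ±3σ) and normalised to
sum to one; interior weights are flat and only the edges taper. The
windowed covariance is the taper-weighted covariance
$S = \sum_k u_k (x_k - \bar x_u)(x_k - \bar x_u)^\top$, and the number of
windows is exactly $\lfloor (t - L)/\mathrm{stride} \rfloor + 1$.

### Precision estimation

For each window the precision matrix $\theta$ maximises

$$\log\det\theta - \operatorname{tr}(S\theta) - \lambda \|\theta\|_1,$$

with the penalty on off-diagonal entries only — the standard graphical
lasso convention, which keeps the full-shrinkage limit at
$\theta = \mathrm{diag}(1/S_{ii})$ (penalising the diagonal would change
that limit and is never done in the sliding-window literature this follows).
The solver is block coordinate descent over columns of the working
covariance with a coordinate-descent lasso inner loop, implemented in
C++ (RcppArmadillo). It is verified against three oracles: the
unpenalised solution equals $S^{-1}$; the two-variable problem has the
closed-form solution obtained by soft-thresholding the off-diagonal
covariance; and no single off-diagonal perturbation of ±1e−4 improves the
objective by more than 1e−8. Off-diagonal support is monotone
non-increasing in $\lambda$.

The penalty can be fixed or selected per subject by V-fold
cross-validation: windows are split into *contiguous* blocks (contiguity
respects the temporal dependence of overlapping windows), $\theta$ is fit
on the average training-block covariance, and the unpenalised
log-likelihood $\log\det\theta - \operatorname{tr}(S_{\mathrm{test}}\theta)$
is scored on each held-out block's average covariance; ties go to the
smaller penalty. Note that this criterion is *prediction*-optimal: it is
well known to under-penalise relative to exact-zero support selection, so
"recovered support" in the tests is read as edges with non-negligible
partial correlation ($|\rho| > 0.05$) rather than exact zeros.

### Partial-correlation scaling

Estimated precisions are rescaled to partial correlations
$\rho_{ij} = -\theta_{ij} / \sqrt{\theta_{ii}\theta_{jj}}$, which puts every
window and subject on a common \[−1, 1\] scale before clustering. The
source methodology does not name the scale of its regularised dynamic
matrices; partial correlation is the choice that makes matrices comparable
across windows and subjects.

### States, state count, and matching

Group-level states are K-means clusters (squared Euclidean distance on
vectorised upper triangles, 10 seeded restarts, 300-iteration cap) of all
subjects' windows, indexed in descending occupancy. The Hartigan–Wong
algorithm with multiple restarts never returns empty clusters, so no
explicit empty-cluster repair is needed. The state count is chosen by
silhouette voting: each subject's windows are clustered for every candidate
k, the silhouette-maximising k is that subject's vote, and the most common
vote wins; vote ties are broken by the elbow criterion (largest second
difference of the mean normalised within-cluster dispersion), then by the
smaller k. Participant-level states (same k) are matched to group states
greedily: starting from the participant cluster explaining the largest
share of that subject's window dispersion, each is assigned the free group
state with the highest Pearson correlation of vectorised mean matrices.
Per-state DC is then computed from each subject's state-averaged matrix
through the same soft-threshold/Fisher-z path as the static arm, a
deliberate consistency choice since the source methodology does not state
whether state averages were re-thresholded.

## Group and behaviour statistics

The permutation test statistic is the difference in group mean DC per node
(the simplest statistic consistent with "differences in DC values");
group labels are reshuffled preserving group sizes (default 5000 draws),
and the two-sided p-value uses the add-one estimator
$p = (1 + \#\{|d^\ast| \ge |d|\})/(1 + B)$ so p is never exactly zero.
BH-FDR is applied across nodes with the strict rejection rule q < α.

Demographic tables are checked with the Pearson chi-square test without
continuity correction (sex × group) and two-sample t-tests reconstructed
from summary statistics (pooled variance by default, Welch available);
the pooled form reproduces the published BMI comparison best.

The behaviour regressions are ordinary least squares
$\mathrm{EDEQ} = \beta \cdot \mathrm{DC} + \beta_{\mathrm{age}} \cdot
\mathrm{age} + C$, with one or several DC predictors (the multimodal
variant). Both the per-coefficient p and the model F-test p are reported;
the F-test p feeds the BH family correction across regions/networks ×
four subscales. Because the single- and combined-modality models are
nested, the unadjusted $R^2$ of the combined model is necessarily at least
as large as either single-modality model; the meaningful question, mirrored
by the tests, is whether both arms carry signal at once.

## The synthetic cohort generator

The generator emulates the statistical structure the chain assumes, with
known ground truth:

* **States.** k sparse precision matrices with ~`sparsity`·p(p−1)/2
  nonzero pairs. Patterns are sampled preferring pairs unused by earlier
  states and low-degree endpoints, magnitudes are 0.4–0.6 with random sign,
  and the diagonal is set to 0.05 + 1.6·(row sum of |off-diagonals|):
  strict diagonal dominance guarantees positive definiteness even after
  the group effect scales off-diagonals by up to 1.6, while keeping the
  implied partial correlations large (≈0.3–0.6) so states are far apart —
  the regime the state-recovery checks are defined for. Each matrix is
  finally rescaled to unit implied marginal variances (partial
  correlations are invariant), mimicking variance-normalised signals.
* **Dynamics.** A Markov chain with uniform initial state, exit
  probability 1/`dwell_mean` and uniform jumps among the other states —
  the simplest process with a controllable geometric dwell. Time series
  are zero-mean Gaussian draws from the active state's precision.
* **Group effect.** In the abdominal group, precision entries touching
  `group_effect_nodes` are scaled by `group_effect_size`, and the same
  scaling is applied to the rows/columns of a shared base fiber matrix
  (uniform on \[0, 0.3\], zero diagonal), clipped to \[0, 1\]. Sharing one
  base matrix keeps structural DC differences attributable to the planted
  effect alone (at the cost of zero within-group structural variance, which
  is why null-calibration checks use the functional arm).
* **Demographics and behaviour.** Sexes balanced; age uniform on
  \[20, 70\]; BMI normal around group means 31.4 / 29.8, truncated at 25
  (an overweight cohort); WHR drawn from non-overlapping sex-specific bands
  so the WHR classifier reproduces the intended groups exactly. EDE-Q
  subscales are β·(standardised structural DC + standardised static
  functional DC at the first effect node) + β_age·age + subscale constant +
  Gaussian noise, truncated at zero. Generating the scores from *both* a
  structural and a functional channel makes the combined-modality
  regression ordering a planted property rather than an accident.

What the generator does **not** emulate: hemodynamics, spatial maps,
scanner drift, physiological artifacts, motion — all of which live in the
out-of-scope preprocessing that precedes this chain. Passing tests
therefore certify the statistical machinery, not robustness to real fMRI
noise.

## Numerical and design choices

* Diagonals are zeroed before the Fisher transform (atanh(1) diverges) and
  excluded from every centrality; self-edges carry no information.
* Betweenness uses edge length 1/weight (the standard weighted-connectome
  convention); zero-weight edges are non-edges; hub nodes have
  mean-normalised betweenness strictly above 1.5.
* The soft-threshold map is read as $((r+1)/2)^\beta$, the canonical
  unsigned weighted-network form, with β = 6.
* A single global seed is expanded to per-stage seeds by fixed offsets, so
  every stage is independently reproducible and the full chain is
  deterministic given (data, seed).
* Verification problem sizes: state recovery uses cohorts of 10 subjects
  per group, p = 10 nodes, t = 1200 time points, 3 planted states with mean
  dwell 40; the windowing for that check is 16 time points with stride 10
  and taper σ = 3, with λ = 0.05. The window is deliberately shorter than
  the dwell so windows straddling a state switch stay a minority — with a
  40-TR dwell, a 172-TR window would mix several states in every window.
  Larger simulations only sharpen the same comparisons.

## Known limitations

* Betweenness on weighted graphs is implemented only for the 1/weight
  length transform; binarised betweenness is intentionally not provided.
* Cross-validated penalty selection optimises prediction, not support
  recovery; exact-zero support from CV-selected penalties is conservative
  at large sample sizes (see above).
* Whether the state count should be selected from subject-level or
  group-level silhouettes is ambiguous in the source methodology;
  subject-level voting is implemented.
* The permutation test assumes exchangeability of subjects under the null;
  with very small groups (< ~5 per group) the discrete null makes q-values
  coarse.
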