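---
title: "Methods: dyadic personality-synchrony analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic personality-synchrony analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

# The analysis

`dyadsync` tests whether people with similar personalities respond to
naturalistic stimuli with more similar neural activity. Every statistic
lives on the *dyad*: for $n$ subjects there are $n(n-1)/2$ unordered
pairs, and each pair carries similarity predictors (personality,
socio-demographics, gaze) and synchrony outcomes (region-level fMRI
correlations, EEG correlated-component ISC). Because the dyads of one
study share subjects, the rows of that table are not independent, and the
central inferential device is a subject-shuffling (Mantel-style)
permutation test rather than ordinary regression p-values.

## Synchrony measures

**NM-synchrony** is the Pearson correlation of two subjects'
spatially-averaged region time series, computed after concatenating runs
in acquisition order. Runs excluded for a subject (motion, sleep) are
dropped; a dyad uses only the runs retained by *both* subjects, so the two
series always align sample-for-sample.

**NP-synchrony** summarizes similarity of spatially distributed voxel
patterns over time. The default computes, at each timepoint, the Pearson
correlation across voxels between the two subjects' spatial patterns,
Fisher-z transforms each, averages, and back-transforms. An alternative
reading — per-voxel temporal correlation averaged over voxels on the z
scale — is available via `np_synchrony(method = "voxel")`. The two
variants answer subtly different questions: the timepoint variant needs
spatial structure (a spatially constant signal yields zero), while the
voxel variant reduces exactly to NM when all voxels replicate the region
signal; the test suite pins both behaviors down. The timepoint-wise
reading is the default because "pattern similarity over time" is
conventionally a statement about spatial topographies.

**EEG ISC** uses dyadic correlated components analysis. With
channel-centered epochs $X_1, X_2$, let $R_{11}, R_{22}$ be within-subject
covariances and $R_{12}$ the cross-covariance. Components are the
eigenvectors of $R_w^{-1} R_b$ with $R_w = R_{11}+R_{22}$ and
$R_b = R_{12}+R_{12}^\top$, i.e. projections maximizing correlation
between subjects rather than variance (the PCA analogue for two brains).
The reported dyad value averages the projected-time-course correlations of
the top 3 components per image, then across images. We report projection
correlations rather than raw eigenvalues — the two coincide when the
subjects' projected variances are equal, and the correlation is the
interpretable quantity; `dyad_isc(use = "eigenvalues")` switches.

**Gaze similarity** converts each subject's fixations on an image into a
dwell-time-weighted histogram on a grid over the unit square and compares
two subjects by exact earth mover's distance with the Euclidean
ground metric between cell centers. The dyad value is the negated mean EMD
over shared images, so all predictors point "higher = more similar".

## Inference

Outcome and predictors are z-scored across dyads before OLS, so every
coefficient is a standardized beta (a single-predictor beta equals the
dyadic Pearson correlation — an identity the tests assert). The
permutation test draws a random permutation $\pi$ of subjects and assigns
dyad $(i,j)$ the predictor value of dyad $(\pi(i), \pi(j))$. Because every
dyadic predictor is a symmetric function of the two subjects' attributes,
this relabeling is mathematically identical to recomputing the predictor
from permuted subject-level attributes, and it preserves the dependence
structure of the dyad table. The two-sided p-value uses the $+1$
correction, $p = (1 + \#\{|\beta^*| \ge |\beta|\})/(B+1)$, so the floor at
$B = 1000$ permutations is $0.001$. Covariates stay fixed under
permutation: the test targets the partial effect of the shuffled
predictor.

Region-wise results are corrected by Benjamini-Hochberg FDR within each
synchrony measure. Per-network one-sample t-tests on regional coefficient
distributions are descriptive (regional betas share dyads and are not
independent; the function documents this). Mediation follows the
classical standardized OLS path decomposition ($a$, $b$, $c$, $c'$,
indirect $= ab = c - c'$, an identity tested to $10^{-8}$); permutation
p-values shuffle the subject labels underlying $X$ for $a$, those
underlying $M$ for $b$, and both independently for the indirect effect,
whose null is the product $a^* b^*$. Effect-size comparisons across $k$
focal effects use a pooled-variance t-test with $2k-2$ df (six focal
effects give df $= 10$).

# The synthetic study generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline is validated. Each subject carries a latent trait
vector $p_i \in \mathbb{R}^5$ (i.i.d. standard normal). Every region (and
every EEG latent source, and every voxel independently) emits

$$x_i(t) = a\,s(t) + \gamma \sum_k p_{ik}\, g_k(t) + \epsilon_i(t),$$

where $s$ and $g_k$ are unit-variance smooth signals shared by all
subjects (moving-average filtered white noise, window 5 samples — ISC
methods presuppose temporally structured shared signal) and $\epsilon_i$
is subject-specific Gaussian noise. The expected dyadic correlation is
then available in closed form (`expected_dyad_correlation()`), which gives
the pipeline an oracle: empirical NM-synchrony on long generated series
must match it (the suite requires absolute error $< 0.02$ at $T = 50{,}000$,
and observes $\approx 0.003$). Setting $\gamma = 0$ makes synchrony
personality-independent — the null model used for type-I calibration.

Surveys render facet latents (correlated 0.75 with their parent trait)
onto the Likert scale, add item noise, reflect every second item
(reverse-keyed), clip and round. EEG sources are mixed to channels by a
fixed unit-norm full-rank forward matrix plus sensor noise at
$\sigma/2$; with $\sigma = 0$ all subjects' epochs are identical. Gaze
fixation targets are drawn from a mixture over per-image attractors whose
weights interpolate, with `gaze_coupling`, between a shared prior and a
softmax of an attractor-by-trait loading applied to $p_i$; durations are
gamma (mean $\approx 300$ ms, floor 50 ms).

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `shared_signal_weight` ($a$) | 1 | signal SD | anchors stimulus-driven ISC |
| `trait_coupling` ($\gamma$) | 0.3 | signal SD per trait unit | mean ISC $\approx a^2/(a^2+5\gamma^2+\sigma^2) \approx 0.18$, realistic for naturalistic viewing |
| `noise_sd` ($\sigma$) | 2 | signal SD | dominant idiosyncratic variance |
| `item_noise_sd` | 1 | Likert points | yields split-half similarity reliability $\approx 0.3$ for a 10-item form, matching short inventories |
| `gaze_coupling` | 0.5 | mixing weight | mid-range coupling of viewing to traits |
| `facet_cor` | 0.75 | correlation | facets cohere with, but are not identical to, their trait |
| `signal_smooth` | 5 | samples | smooth shared dynamics without hiding temporal detail |

Design constants default to the study designs being emulated: 66 subjects,
214 regions (200 cortical across seven networks + 14 subcortical), 4 runs;
or, via `gen_config_eeg()`, 225 subjects, 60-item faceted inventory
(5 traits $\times$ 3 facets $\times$ 4 items, 1-5 scale), 104 images in 26
categories, 32 channels at 500 Hz with 3-s epochs. These were chosen once
and are not tuned.

## What the generator does and does not emulate

It reproduces the *statistical* structure the analysis assumes: shared
smooth stimulus-driven signal, trait-weighted shared components, dyadic
exchangeability under the null, item-level measurement noise, set-valued
ethnicity, run structure and exclusions. It deliberately omits
hemodynamics, realistic EEG spectra and topographies, saccade dynamics,
atlas geometry, and any stimulus-level variation in coupling ($\gamma$ is
held constant across stimuli). Passing tests therefore certify the
*machinery* — estimator correctness, calibration, power under a known
coupling — not that real fMRI/EEG data satisfy the generative model;
effect sizes on real data depend on measurement reliabilities the
generator only schematically reproduces.

# Numerical choices

- **Fisher-z of $r = \pm 1$:** correlations are clipped to
  $\pm(1 - 10^{-7})$ before `atanh`, so identical patterns average
  finitely (NP of identical input returns 1 within $10^{-6}$).
- **CorrCA regularization:** $R_w \leftarrow (1-s)R_w +
  s\,\overline{\operatorname{diag} R_w}\, I$ with $s = 0.05$ by default;
  $s = 0$ on rank-deficient data errors with an instruction to regularize.
  The non-symmetric product can yield complex eigenpairs in degenerate
  cases; real parts are taken and re-sorted (standard for this
  eigenproblem).
- **EMD:** solved exactly on the support of the two histograms by a
  transportation simplex (northwest-corner start, MODI pivoting, entering
  cell = most negative reduced cost, leaving cell = minimum flow on the
  cycle's negative positions with first-index tie-break). Correctness is
  enforced two ways: frozen comparisons against an independent LP solution
  and, on every solve exercised in tests, an LP duality certificate
  (feasible potentials with matching objective). The default grid is
  $32 \times 32$ on the unit square; normalizing coordinates by screen
  size makes EMD comparable across images and screens. Fixations are
  binned by duration only (no spatial kernel), matching a dwell-time
  reading of fixation maps; cells are half-open with closed upper edges so
  boundary fixations are kept.
- **Degenerate inputs:** zero-variance series, empty fixation lists,
  all-excluded runs, Canberra zero-denominator coordinates, and
  rank-deficient designs raise errors naming the problem; zero-variance
  timepoints/voxels inside NP are dropped with a warning. Missing survey
  responses are an error — short inventories admit no defensible
  imputation. Per-dyad failures inside the synchrony table become flagged
  `NA` cells rather than aborting the table.
- **Seeds:** a single master seed; substreams by fixed offsets (profiles
  +1, fMRI +2, EEG +3, gaze +4, inference +10), all within 32-bit range.
  Identical config implies bit-identical datasets (tested).

# Design choices on genuinely open points

- **Split-half reliability of personality similarity** splits items
  odd/even within each facet (balanced, deterministic) and scores each
  half; similarity is computed on scores, not raw items. Item-level
  halving was chosen for the short inventory where trait-level halving is
  impossible.
- **Split-half reliability of fMRI synchrony** (runs {1,3} vs {2,4})
  correlates *region-averaged* per-dyad synchrony by default — the
  minimal-variance summary — with `per_region = TRUE` exposed.
- **Political-ideology contrast** within a joint model is a Wald test on
  the difference of two standardized coefficients using the fitted
  coefficient covariance (`coefficient_contrast()`).
- **Per-facet similarity** is the negated absolute difference of the
  single facet score; the overall faceted measure is the Euclidean
  distance over all 15 facet scores.

# Problem sizes used for validation

The suite validates at reduced scale, chosen to exercise every code path
with stable statistics: type-I calibration uses 200 replicate null studies
(14 subjects, 199 permutations each; KS uniformity at 0.01 plus a
rejection-rate band), power uses 50 replicates at 40 subjects and
$\gamma = 1$, coupling monotonicity averages 10 replicates per
$\gamma \in \{0, 0.25, 0.5, 1\}$, and the end-to-end smoke study runs 20
subjects, 10 regions, 8 channels, 20 images and 500 permutations — the
same configuration `scripts/acceptance.R` reports on. Oracle agreement
uses a single $T = 50{,}000$ dyad.

# Known limitations

- The per-network t-tests inherit the dependence of regional coefficients;
  they are summaries, not tests with nominal error control.
- The transportation simplex is quadratic-ish in the support size; it is
  intended for sparse fixation histograms (tens of occupied cells), not
  dense $32 \times 32 \times 32 \times 32$ problems.
- The generator's coupling is linear and homoscedastic; real
  personality-synchrony coupling may be stimulus-specific and nonlinear.
- No attenuation correction is applied anywhere: reported relationships
  are raw, and measurement unreliability bounds them above.
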