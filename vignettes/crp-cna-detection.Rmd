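---
title: "Detecting copy number aberrations with the conditional random pattern model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting copy number aberrations with the conditional random pattern model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpcna)
library(dplyr)
set.seed(1)
```

## The problem

Somatic copy number aberrations (CNAs) — gains and losses of genomic
segments relative to the normal two copies — drive many tumors. SNP arrays
measure them indirectly: a test sample's probe intensities are compared
against two-copy references and summarised as a per-marker log2-ratio,
which sits near 0 at two copies, below 0 in losses and above 0 in gains.
After whole-genome amplification, or in samples contaminated with normal
cells, the signal-to-noise ratio (SNR) of this track is poor: naive
per-marker thresholding floods the genome with one-marker false calls and
misses true regions. The remedy is a sequence model that borrows strength
from the neighbourhood of each marker.

`crpcna` implements a conditional random pattern (CRP) model for this task.
Like an HMM it is a linear chain over hidden copy-number states, but the
per-locus observation term is not a single emission: it scores the locus
against every *pattern* of contiguous neighbours that could share its
state, and lets the best-matching pattern speak for the locus. This gives
the model an explicit minimum-run prior — isolated outliers cannot win —
while retaining exact, fast inference.

## The model

For a chromosome with ordered markers $t = 1, \dots, T$, observed
log2-ratios $x_t$ and hidden copy numbers $y_t$ drawn from a state set of
size $K$ (default $\{0,1,2,3,4\}$), the conditional distribution is

$$p(\mathbf{y} \mid \mathbf{x}) = \frac{\exp \psi(\mathbf{y}, \mathbf{x})}{Z(\mathbf{x})},
\qquad
\psi(\mathbf{y}, \mathbf{x}) = \sum_{t} \big[ f_{TP}(y_{t-1}, y_t) + f_{LE}(x_{t-m+1..t+m-1}, y_t) \big],$$

with the transition term omitted at $t = 1$ (a uniform prior over the first
state is a constant across states, so it cancels from both the argmax and
the normalized path probability and is left out of the score).

### Transition potentials: Haldane's map function

Copy-number state should persist across densely spaced markers and decay
over large gaps. The probability that the state *changes* between two
consecutive markers separated by $d$ Mb is modelled with Haldane's map
function,

$$\theta(d) = \tfrac{1}{2}\left(1 - e^{-2 \rho d}\right),$$

with $\rho$ the genetic map rate (`morgans_per_mb`, default 0.01 Morgan/Mb
— the familiar 1 cM/Mb genome-wide average). The log transition potential
is $\log(1-\theta)$ for staying and $\log \theta - \log(K-1)$ for moving,
i.e. the change mass is split uniformly over the $K - 1$ alternative
states; rows of the exponentiated potential therefore sum to one for every
distance. Whether a $2 \to 3$ change should be cheaper than $2 \to 0$ is a
modelling question on which we take the neutral position (uniform split);
informative priors over specific transitions would slot into the same
matrix. $\theta$ is clamped below at `theta_floor` ($10^{-10}$) so
zero-distance gaps cannot produce $-\infty$ potentials, and above just
under $1/2$.

### Local evidence: candidate run patterns

The model assumes a credible CNA spans at least $m$ consecutive markers
(default $m = 4$). To score state $y_t$ at a locus, consider the
$2m - 1$-marker window centred there. Any contiguous run of at least $m$
window positions that contains the centre is a candidate layout of "markers
sharing the centre's state"; there are $m + (m-1) + \dots + 1 = m(m+1)/2$
of them — ten for $m = 4$:

```{r patterns}
enumerate_patterns(4)
```

Pattern $P$'s raw score is the joint Gaussian log-likelihood of its member
observations under state $y_t$. Because patterns contain between $m$ and
$2m - 1$ factors, raw terms are on different scales; each is rescaled to
the *geometric mean* of its factors — the mean log-likelihood over the
pattern's offsets — and the local evidence is the maximum rescaled term:

$$f_{LE} = \max_P \frac{1}{|P|} \sum_{j \in P} \log p(x_{t+j} \mid y_t).$$

The exact algebraic form of this rescaling was a genuinely open design
point; we chose the geometric mean because it is the minimal transformation
under which a constant window scores identically under every pattern, so
pattern cardinality confers no advantage by itself. A consequence worth
knowing: evidence is a *per-observation* quantity, directly comparable to a
single emission log-density.

Near chromosome ends the window is truncated: patterns are intersected with
the offsets that exist (the centre always does) rather than padded with
fabricated observations.

### Emissions

Each state $i$ emits log2-ratios as $\mathcal{N}(\mu_i, \sigma_i^2)$.
Defaults for the five-state model are $\mu = (-2.0, -0.45, 0, 0.38, 0.8)$
with common $\sigma = 0.25$. The one- and three-copy means are empirical
values for compressed SNP-array data (arrays under-report the nominal
$\log_2(1/2) = -1$ and $\log_2(3/2) = 0.585$ shifts); **the zero- and
four-copy means are extrapolations** beyond what arrays measure reliably
and should be overridden wherever calibration data exist.
`crp_model_3state()` provides the loss/normal/gain configuration
($\mu = (-0.27, 0, 0.27)$, $\sigma = 0.1$) appropriate for array-CGH-style
tracks. In practice parameters are estimated from pre-known regions —
cytogenetically confirmed monosomy and trisomy chromosomes — with
`fit_emission_params()`, which takes per-state sample means and standard
deviations and falls back to supplied values for unobserved states.

### Inference

`viterbi_decode()` runs three exact log-space recursions per chromosome:
the Viterbi maximisation (best path), the forward sum (normalizer
$Z(\mathbf{x})$, reported as the normalized best-path probability
$\max_y \delta_T(y) / Z(\mathbf{x})$) and forward–backward (per-locus
posterior state probabilities). All run in $O(TK^2)$ plus $O(TKm)$ for the
evidence, the same asymptotic cost as an HMM; the evidence term is
vectorized over loci via cumulative sums because every pattern is a
contiguous run, and the chain recursions are compiled code. Log-space
arithmetic keeps sequences of $10^6$ markers free of underflow. Exact
Viterbi ties are broken toward the state closest to the normal copy number
(parsimony toward "no aberration"), deterministically. Chromosomes are
decoded independently — no transition spans a chromosome boundary.

Maximal constant-state runs become segments (`segments_from_path()`), each
carrying its marker span, BED-style base-pair interval, and the mean
posterior of its assigned state. Segments shorter than $m$ are flagged, not
removed. When parameter bias produces too many calls, low-confidence
aberrant segments can be reassigned to normal with `filter_segments(fit,
min_probability)`, which operates on segment mean posteriors.

```{r decode-demo}
model <- crp_model(states = 1:3, means = c(-0.45, 0, 0.38), sds = 0.08)
probes <- tibble::tibble(
  marker = sprintf("m%03d", 1:200), chrom = "chr1", pos = 1:200 * 1e4,
  log2ratio = rnorm(200, 0, 0.08)
)
probes$log2ratio[61:100] <- rnorm(40, 0.38, 0.08)
fit <- viterbi_decode(probes, model)
fit$segments
glance(fit)
```

## Feature extraction

When starting from normalized intensity tables rather than ready-made
log2-ratios, `normalize_to_common_mean()` rescales every sample to a common
autosomal mean (default 1000), `select_best_fit_references()` ranks
candidate references by the standard deviation of the marker-wise
log-ratio against the test (flat ratio = good two-copy reference; the
statistic is scale-blind, which is exactly why mean normalization comes
first), and `log2_ratio_series()` forms
$\log_2(\text{test}_i / \overline{\text{ref}_i})$ over the selected panel.
The selection statistic and the default panel size ($m_\text{refs} = 3$)
are this package's choices — the best-fit concept is standard, its formula
is not — and both are recorded in the output metadata. The two-copy
reference assumption is load-bearing: references carrying CNVs at a marker
bias that marker's ratio. Note also that mean normalization absorbs part of
any large aberrant fraction into the baseline (the classic compression
effect), so contrasts, not absolute levels, are the stable quantity.

## The simulators

Two generators reproduce the standard validation designs at the
log2-ratio level, with ground truth:

* `simulate_sequences()` — per SNR level, 100 independent sequences of 300
  points; four regions of 5, 10, 20 and 40 markers at mean 0.4 on a zero
  baseline, noise $\mathcal{N}(0, \sigma)$ with $\sigma = 0.4/\text{SNR}$,
  SNR ladder $\{2, 1.3, 1\}$. Regions are placed uniformly at random with
  at least 5 normal markers between them so adjacent regions cannot merge
  (the placement rule is ours; some separation is needed for region-level
  metrics to be well defined).
* `simulate_array_design()` — the genome-wide design: per reference sample
  and SNR level, one deletion genome (copy 1, mean −0.45) and one
  amplification genome (copy 3, mean +0.38), each with exactly one region
  per autosome (22 regions), lengths uniform on 4–100 markers, SNR ladder
  $\{5, 2, 1.25\}$; the default 3 references give 18 samples. Noise is
  $\mathcal{N}(0, |\mu_\text{region}|/\text{SNR})$ on every marker: the
  original design injects intensity-proportional noise at probe level
  inside real array files, and this is its natural re-expression one level
  up, recorded as such in the manifest.

Desk-scale sizes are deliberate: 150 markers per autosome (enough to hold
a 100-marker region with margin) at 10 kb spacing, and 10 replicate seeds
in the performance checks. A single master seed expands into per-unit
child seeds, so datasets are bitwise reproducible and units are
independent.

What the simulators do *not* emulate — and hence what passing tests do not
establish about real arrays: genomic waves and GC/PCR-length artifacts,
marker-density variation, probe-specific variance, normal-cell
contamination shrinking the effective shift, and reference panels that are
not cleanly two-copy. Performance numbers from these designs are
upper bounds for real data with matched SNR.

## Evaluation: the seven metrics

`contingency()` reduces calls and truth to binary aberrant/normal and
counts at two resolutions: per marker (tp/fp/fn/tn) and per region — a
truth region is *detected* if at least one of its markers is called
aberrant; a predicted region (maximal run of aberrant calls) is *true* if
at least one of its markers lies in any truth region. Copy-number values
are ignored for detection. `compute_metrics()` then reports SNP-level
recall/precision ($sr$, $sp$), region-level recall/precision ($rr$, $rp$),
the hybrid products $hr = sr \cdot rr$ and $hp = sp \cdot rp$, and the
f-score $f = 2 h_p h_r / (h_p + h_r)$.

Two conventions circulate for the hybrid cells — the straight products
above and a crossed variant ($hr \approx sp \cdot rr$,
$hp \approx sr \cdot rp$) — and published benchmark tables exist in both,
mutually inconsistently. This package implements the straight products;
the test suite pins both conventions against their respective benchmark
tables and asserts the inconsistency rather than hiding it. Degenerate 0/0
ratios score 1 when the paired error count is also zero (an empty truth
matched by an empty prediction is perfect) and 0 otherwise.

## Numerical and design notes

* All dynamic programming in log space; posterior rows renormalized to sum
  to 1 within $10^{-9}$.
* Marker positions are 1-based in probe tables; BED outputs are 0-based
  half-open; segment marker indices are 0-based half-open.
* Inter-marker distance is $(p_t - p_{t-1})/10^6$ Mb.
* `m` trades sensitivity for robustness: larger windows suppress more
  noise but miss shorter regions; $m = 4$ reflects the judgement that
  sub-4-marker calls are unreliable at realistic SNR. The pattern count
  grows only quadratically, so larger `m` stays cheap.
* Viterbi tie-breaking (toward normal) matters only on measure-zero exact
  ties, but makes degenerate configurations (identical emission
  parameters) decode deterministically to all-normal.
* Non-finite log2-ratios are refused by name rather than imputed; callers
  should filter or impute upstream, explicitly.

## Limitations

The model calls total copy number from log2-ratios only: no B-allele
frequencies (so copy-neutral LOH is invisible), no contamination model (in
heavily admixed tumors the effective shifts shrink toward 0 and emission
means must be re-fitted), and no learning of transition parameters from
data. Emission fitting requires pre-known regions or trustworthy defaults.
These boundaries are deliberate; methods that model them are different
tools.
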