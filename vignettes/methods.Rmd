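---
title: "Dating divergence and admixture: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating divergence and admixture: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixclock)
```

admixclock implements a two-clock approach to dating events in the history
of an admixing species, built around the case of human-specialist *Aedes
aegypti*: a coalescent clock for events thousands of generations deep,
calibrated against a historical migration record, and an ancestry
tract-length clock for events tens of generations deep. This vignette
explains the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## The coalescent clock and its calibration

Cross-coalescence tools report results in mutation-scaled time: a scaled
time $t$ converts to calendar years as

$$\text{years} = \frac{t}{\mu}\, g,$$

with $\mu$ the per-site per-generation mutation rate and $g$ the generation
time in years. Calendar dates therefore depend on $(\mu, g)$ only through
$g/\mu$ — neither parameter is identified separately, and for many insects
neither is well measured. The calibration idea is to pin the ratio with an
independently dated migration event: rescale the inferred migration density
$m(t)$ into calendar years for a candidate $(\mu, g)$, project it onto the
calendar grid of a historical event record (here, counts in 25-year bins
between 1500 and 1875), and score the match with the Bhattacharyya
coefficient

$$BC(p, q) = \sum_i \sqrt{p_i\, q_i} \in [0, 1],$$

computed on the record's own bin grid. `scan_scaling_grid()` maps the
surface over a $(\mu, g)$ grid; because only $g/\mu$ matters, the surface is
constant along rays through the origin and the output reports the
best-matching ridge ratio. `calibrate_mu()` fixes $g$ (default 0.067 years,
the common literature value of 15 generations per year for *Ae. aegypti*)
and maximizes $BC$ over $\mu$ alone.

Parameters that matter:

* `present_year` (default 2017) anchors "years before present". Samples in
  the motivating study were collected around 2016–2018; the result is
  insensitive to a few years either way because the record bins are 25
  years wide.
* `truncate` (default `TRUE`): migration mass older than 1875 or younger
  than 1500 is discarded before normalizing, so the comparison is between
  shapes inside the record window. Cross-coalescence analyses place
  additional, much older migration at the original specialist–generalist
  split; including that mass in the normalization (`truncate = FALSE`)
  deflates every in-window weight by a constant factor and lowers all $BC$
  values without moving the argmax ridge appreciably. Truncation is the
  default because the comparison of interest is the in-window shape; the
  flag exposes the other convention.
* Grid defaults: $\mu \in [10^{-9}, 10^{-8}]$ (60 log-spaced points),
  $g \in [0.05, 0.1]$ (30 linear points) — the span of plausible insect
  mutation rates and of reasonable *Ae. aegypti* generation times.
* $BC$ is computed on the 25-year record grid directly, with no
  interpolation onto a finer grid: the record is the coarser measurement
  and sets the resolution.

Numerics: the 1-D calibration runs a 60-point coarse log-grid followed by
golden-section refinement (`stats::optimize`) to a relative tolerance of
$10^{-3}$ on $\mu$; there is no randomness anywhere in calibration. A grid
point whose rescaled trajectory misses the record window entirely scores
$BC = 0$ rather than erroring, so scans over wide grids are robust.

`rescale_calibrated_date()` converts a dated event between mutation-rate
scenarios (dates scale as $\mu_{\text{old}}/\mu_{\text{new}}$ at fixed
$g$): a 5000-year-old divergence under $\mu = 4.85\times10^{-9}$ becomes
roughly 10,100 years under $\mu = 2.4\times10^{-9}$, and 3000 years under a
rate $1/0.6$ times higher.

## The single-pulse local-ancestry HMM

At ancestry-informative sites (panel allele-frequency difference strictly
greater than 0.3, at least 10 sampled alleles per panel, thinned so no two
retained sites are closer than 10 kb), diploid genotypes are modeled with a
three-state HMM over specialist dosage $k \in \{0, 1, 2\}$. Under a single
admixture pulse $T$ generations ago with specialist proportion $\alpha$,
the haploid ancestry chain over genetic distance $d$ (Morgans) is

$$Q(d) = e^{-dT} I + (1 - e^{-dT}) \Pi,$$

with $\Pi$ the rank-one matrix with stationary row $(\alpha, 1-\alpha)$.
This family is exactly closed under composition
($Q(d_1)Q(d_2) = Q(d_1+d_2)$), which the test suite asserts to $10^{-12}$.
The diploid transition matrix is the product chain of two independent
haploids collapsed to dosage; the initial distribution at each chromosome
start is the stationary binomial $((1-\alpha)^2,\, 2\alpha(1-\alpha),\,
\alpha^2)$. Emissions convolve panel frequencies with a symmetric genotype
error $\varepsilon$ (default 0.01, matching the generator's default):
dosage 2 emits $\mathrm{Binomial}(2, a)$ with
$a = p_A(1-\varepsilon) + (1-p_A)\varepsilon$, dosage 0 the analogue with
$p_B$, and dosage 1 the law of one draw from each. Missing genotypes emit
probability 1 in every state.

Design choices:

* **Unphased dosage states.** The HMM runs on diploid genotypes directly,
  with independent-haplotype product transitions, so no phasing step is
  needed. This matches the model class of single-pulse ancestry-HMM tools.
* **Forward–backward uses per-site scaling constants** rather than
  log-sum-exp at every cell, for speed; the tests assert equivalence with
  an independent pure-R log-space forward pass and with brute-force
  enumeration over all $3^n$ paths on small instances.
* **Viterbi ties break toward lower dosage** — conservative toward calling
  no admixture. "Viterbi posteriors" is ambiguous between hard Viterbi
  paths and posterior decoding, so both are exposed (`viterbi()`,
  `forward_backward()`); hard paths are the default input to
  ancestry-proportion profiles.
* **Tract bounds** are placed midway between the last inside-site and the
  first outside-site (unbiased under uniform site placement; the
  convention is stated because none is standard); runs touching a
  chromosome end are bounded by the outermost site. Output is 0-based
  half-open BED.
* **Masking** of selection-outlier regions applies to timing estimation
  only; tract calling and visualization run unmasked. Selection inflates
  tract lengths, biasing timing young, but the unmasked genome-wide tract
  picture is what one wants to see.

`estimate_pulse_time()` maximizes the summed log-likelihood across
individuals over $T$ with a 40-point log-grid on $[1, 10^4]$ generations
plus golden-section refinement; it is deterministic, and a likelihood flat
to within $10^{-8}$ relative triggers a warning and a flagged midpoint
return. Only the product $dT$ is identified, so a correct genetic map
matters: doubling all inter-site distances halves $\hat T$, a property the
tests assert. `estimate_alpha()` iterates between re-estimating $T$ and
updating $\alpha$ as half the mean posterior dosage, to a tolerance of
$10^{-4}$ (at most 50 iterations).

Confidence intervals come from a block bootstrap: contiguous blocks of
`block_sites` ancestry-informative sites are resampled with replacement,
each resampled block restarting the chain (so no artificial linkage is
created across block joins), and the 2.5/97.5 percentiles over `n_boot`
re-estimates (default 80) form the interval. The default block size is
1000 sites, the scale used with genome-wide site sets of order $10^5$
sites. At the desk scale used throughout the tests (4500 sites), 1000-site
blocks would leave only five resampling units, far too few for a stable
percentile interval; the test-suite experiments therefore size blocks as
`ceiling(n_sites / 80)`, preserving the 80-resampling-block design at the
smaller site count. Block length still spans many times the ancestry
correlation length ($\approx 1/T$ Morgans), which is what block resampling
must respect.

## f3, ancestry profiles, and the circular permutation test

`f3_test()` computes the Patterson-style statistic per site,
$(p_X - p_A)(p_X - p_B) - h_X/n_X$ with
$h_X = p_X(1-p_X)\,n_X/(n_X-1)$, averaged over sites passing a pooled
minor-allele-frequency filter (default 0.05, strict). A consistently
intermediate focal population drives the mean negative. The standard error
is a delete-one block jackknife over contiguous blocks of 500 SNPs by
default; the SNP-count block unit follows the convention of the tools used
for such scans, the exact size not being critical on homogeneous data (the
tests check order-of-magnitude stability across block sizes). The
statistic is exactly symmetric in the two sources.

`ancestry_profile()` averages decoded dosage across individuals at each
site. `circular_permutation_test()` asks whether two populations' profiles
co-locate along the genome more than chance allows: each permutation
rotates every chromosome of one profile by an independent uniform offset,
preserving the within-chromosome value multiset and autocorrelation while
destroying the cross-population alignment. The p-value is one-sided (the
hypothesis is excess similarity; two-sided by flag) with the add-one
convention $p = (1 + \#\{r_{\text{null}} \ge r_{\text{obs}}\})/(1 +
n_{\text{perm}})$, so the smallest attainable value at 1000 permutations is
$1/1001 \approx 0.001$.

## Power simulations

`place_tracts()` implants non-overlapping heterozygous donor tracts of a
fixed length (defaults 500 kb, 1 Mb, 2 Mb, 10 Mb; 5 tracts per chromosome,
rejection-sampled with a 1000-attempt cap) onto an unadmixed background:
inside a tract the genotype is one background allele plus the donor
haplotype allele. When the background is available phased, the drawn
haplotype's allele is used; otherwise the background allele is drawn from
the unphased genotype. `run_power_experiment()` decodes each replicate
with the HMM and scores bp-level sensitivity and precision with half-open
interval arithmetic; per-replicate seeds derive from the master seed by
fixed splitting, so results are byte-reproducible. Sites called specialist
in at least 95% of replicates (configurable) are flagged as recurrent
regions — the signature of specialist segments genuinely present in the
background rather than artifacts of any single placement.

## What the synthetic-data generator does and does not emulate

The generator produces every input with known ground truth:

* **Migration trajectories** are manufactured from a calendar-domain
  density (a record, or a Gaussian pulse) mapped to mutation-scaled time
  under a known $(\mu_0, g_0)$, on a log-spaced segment grid (default 32
  segments, a free choice) augmented with the exact scaled images of the
  record's bin edges so the piecewise-constant density represents the
  source exactly. Noise-free trajectories plateau at cumulative migration
  exactly 1.
* **Panels** follow a Balding–Nichols model: ancestral frequencies uniform
  on $(0.05, 0.95)$, panel frequencies Beta-distributed around them with
  differentiation `fst` (default 0.3 where a differentiated pair is
  needed; `fst = 0` returns identical panels exactly).
* **Admixed genomes** simulate each haplotype's ancestry as the
  alternating-exponential (Markov) tract process in genetic distance —
  specialist tracts $\mathrm{Exp}((1-\alpha)T)$, generalist tracts
  $\mathrm{Exp}(\alpha T)$ per Morgan — which is *exactly* the generative
  model the HMM assumes. That is deliberate: it makes parameter-recovery
  tests clean. It also means passing tests demonstrate correct inference
  under the model, not robustness to what real data add: multi-pulse or
  continuous admixture, drift since admixture, linkage within source
  panels, phasing or calling error structure, selection on introgressed
  tracts. A hook for an external coalescent simulator is the natural
  extension and is not required by anything here.
* **Genomes** default to three chromosomes of 100 Mb at 1 cM/Mb — a
  desk-scale echo of the three large *Ae. aegypti* chromosomes — with
  optional lognormal recombination-rate heterogeneity that preserves each
  chromosome's total map length.
* **Records** are unimodal counts on the fixed 25-year 1500–1875 grid,
  largest-remainder-rounded so the total is preserved exactly. No real
  event record ships with the package; users supply one as 3-column TSV.

Problem sizes in the test suite are deliberately modest — panels of a few
thousand sites, 6–15 diploids, 100-replicate bootstrap-coverage and
20-replicate power experiments — the scale at which every experiment
re-runs from scratch in minutes on one CPU while leaving the estimators
enough data to recover truth within the tolerances asserted.

## Degenerate inputs and edge conventions

* The last time segment of a trajectory may have an infinite right
  boundary (serialized as `inf`); positive migration density on an
  infinite-width segment has no finite mass and is dropped with a warning.
* `alpha = 0` or `1` in the genome simulator produces exactly unadmixed
  genomes (single tract per chromosome); the HMM itself requires
  $\alpha \in (0,1)$.
* Sites with identical genetic positions (zero distance) are legal: the
  transition is the identity.
* A dosage run shorter than `min_sites` (default 2) is not emitted as a
  tract, suppressing single-site blips.
* Rotation offsets in the permutation test include 0, so the identity
  permutation is part of the null support; uniqueness of loci per
  chromosome is the caller's responsibility.

## Known limitations

* The tract-length clock shares the usual non-identifiability: only $dT$
  enters the likelihood, so map errors translate multiplicatively into
  $\hat T$.
* The single-pulse model misattributes continuous gene flow to one
  intermediate pulse time; no multi-pulse estimator is provided.
* The f3 jackknife uses SNP-count blocks, not genetic-length blocks;
  on strongly heterogeneous linkage maps genetic-length blocks would be
  preferable.
* The calibration assumes the historical record's shape is the true
  migration intensity up to binning; systematic lags between the record
  and effective migration shift the calibrated ratio accordingly, which is
  why alternative-scenario rescaling is a first-class operation.
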