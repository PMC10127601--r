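---
title: "Methods: strain dynamics, the stochastic logistic model, and macroecological laws"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain dynamics, the stochastic logistic model, and macroecological laws}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainstability)
```

This vignette documents the models, estimators and design choices behind
`strainstability`, in the spirit of a methods supplement: what is
computed, under which assumptions, which knobs matter, and what the
synthetic validation does and does not demonstrate.

## Data model

The unit of analysis is one species in one host, observed as a
longitudinal series of per-site allele counts: at genomic site $i$ and
sample $t$, a reference count $r_{ti}$, alternate count $a_{ti}$ and
depth $d_{ti} = r_{ti} + a_{ti}$ (`snv_table`). Alongside the SNV tables
the pipeline consumes a species relative-abundance table and per-sample
collection days. Positions are 1-based, matching common SNV-caller
output.

## Diversity and its stationarity

Within-sample nucleotide diversity is estimated as

$$\pi = \frac{1}{|G|}\sum_{i}\left[
  \frac{r_i}{d_i}\frac{a_i}{d_i-1} + \frac{a_i}{d_i}\frac{r_i}{d_i-1}
\right],$$

the read-resampling (without replacement) estimate of per-site
heterozygosity, and its cross-sample analogue $\pi_{BT}$ uses plug-in
frequencies from the two samples. The fixation index between the initial
sample and sample $j$ is $F_{ST} = [\pi_{BT} - (\pi_i+\pi_j)/2]/\pi_{BT}$.

Three conventions matter:

* **Depth filter and the $|G|$ denominator.** Sites below 5x depth are
  excluded — allele frequencies are unusable there — and $|G|$ counts
  only the sites that pass (both samples for $\pi_{BT}$). Dividing by the
  full genome length instead would deflate $\pi$ wherever coverage drops,
  confounding diversity with depth. The convention used is recorded in
  the output attributes.
* **Negative $F_{ST}$ values are kept.** The within-sample estimator
  carries a finite-depth correction ($d-1$ denominators), so
  near-identical samples give slightly negative $F_{ST}$. Clipping at
  zero would censor exactly the small-magnitude fluctuations whose time
  structure the stationarity test must see.
* **Normalization.** $F_{ST}' = F_{ST}$ divided by the species' mean
  pairwise $F_{ST}$ across unrelated hosts, so $F_{ST}' \approx 1$ means
  an intra-host change of between-host magnitude. When no cross-host
  panel is available the pipeline uses normalizer 1 and flags it.

Stationarity of each $F_{ST}'$ series is assessed with an augmented
Dickey-Fuller test: null = unit root (nonstationary), rejection =
stationary. The regression includes a constant but no deterministic
trend, because under the stationary hypothesis $F_{ST}'$ has no natural
trend; lag order is chosen by AIC over a Schwert-rule window with all
candidate fits sharing one estimation sample, and p-values use
MacKinnon's approximate asymptotic distribution for the constant-only
case. The implementation was verified to agree with the standard
`statsmodels` routine to ten decimal places, including the selected lag.
No multiple-testing correction is applied across species: each species
gets its own $P < 0.05$ call, which is how such per-species calls are
conventionally reported. A constant series is called stationary by
convention and flagged degenerate. The initial $F_{ST}'$ value (the
baseline against itself) is dropped before testing.

## Strain phasing

Conspecific strains that colonized the host independently differ at
$O(10^3)$–$O(10^4)$ fixed core-genome sites. At each such site the
alternate-allele frequency tracks the frequency of the carrying strain —
up to which allele was labelled "alternate" — so strain phasing reduces
to finding large clusters of SNVs with tightly correlated trajectories.
The minimum reported cluster size (strictly > 1,000 SNVs) is set at the
known scale of between-strain divergence, which deliberately excludes
within-host lineage diversification (tens to hundreds of SNVs). No
qualifying cluster means a single strain.

### Noise-corrected correlation

The key numerical obstacle is that binomial read sampling attenuates the
Pearson correlation between same-strain sites: at depth $d$ the observed
frequency adds a sampling variance of $p(1-p)/d$, so at 20–50x two sites
tracking the same strain correlate at only ~0.3–0.8 even though their
underlying trajectories are identical. A fixed threshold on the raw
correlation therefore cannot work across depths. Instead, each site's
sampling variance is estimated by the time average of $f(1-f)/(d-1)$
(exactly unbiased for $p(1-p)/d$) and subtracted from its trajectory
variance before forming the correlation. Same-strain pairs then
correlate near $\pm 1$ at any depth, while different-strain pairs keep
their true-signal correlation, and a single threshold (default 0.8)
applies throughout. Sites whose variance does not exceed their noise
floor carry no trajectory signal and are dropped, as are sites never
observed at intermediate frequency (default window 0.1–0.9).

### Clustering, assignment and polarization

Candidate sites are clustered by average-linkage agglomeration on
$1 - |\rho|$ (the absolute value makes membership invariant to ref/alt
label flips). Three thresholds are deliberately tiered:

* the dendrogram is cut at half the tolerance ($|\rho| \ge 0.9$ for the
  default 0.8): average linkage averages away per-pair noise, and
  over-fragmentation is repairable while a spurious union of two strains
  is not;
* fragments are repaired by merging clusters whose *centroids* correlate
  above $1-(1-0.8)/4 = 0.95$: centroids are medians over hundreds of
  sites and essentially noise-free, so genuinely distinct strains almost
  never reach this level while fragments of one strain always do;
* individual sites are assigned to the centroid they correlate with
  best, at the user-facing threshold (0.8), which also resolves
  membership ties.

For very large candidate sets the pairwise stage runs on an evenly
spaced subsample (default cap 3,000 sites) and all remaining candidates
enter through centroid assignment.

Within a cluster each member is polarized — kept or mirrored as $1-f$ —
by the sign of its correlation with the centroid, and the centroid is the
per-timepoint median of polarity-aligned frequencies (median rather than
mean for robustness to mis-assigned sites; the choice is invisible on
clean data). With three or more strains a global orientation question
remains: a centroid may track a strain's frequency or its mirror, and
the mirror choice changes the inferred residual strain. The package
resolves it compositionally: over all $2^m$ orientation combinations it
picks the one whose centroid sum least violates $\sum_k c_k(t) \le 1$.
With the correct orientations the sum is $1 - f_{\mathrm{residual}} \le 1$,
while any mirrored combination overshoots 1 systematically.

Strain frequencies are the oriented centroids plus a residual background
strain at $1 - \sum_k c_k$ (clipped to $[0,1]$), renormalized to sum to
exactly 1; strain abundances multiply frequencies by species relative
abundance. A strain is reported "detected" at a time point when its
frequency is at least 0.05; the threshold affects reporting only, never
the abundance arithmetic.

**Known limitation.** If two strain-frequency trajectories are
themselves correlated above the threshold in absolute value — e.g. a
three-strain species in which the third strain barely fluctuates, making
$f_2 \approx c - f_1$ — no polarity-invariant correlation method can
separate them, and the two strains will be phased as one. This is an
identifiability limit of trajectory clustering, not an implementation
artifact.

## The stochastic logistic model

Each population (strain or species) is modelled by

$$\frac{dx}{dt} = \frac{x}{\tau}\left(1 - \frac{x}{K}\right) +
  \sqrt{\frac{\sigma}{\tau}}\, x\, \eta(t),$$

logistic growth toward carrying capacity $K$ with multiplicative
environmental noise of amplitude $\sigma$; the stationary distribution is
a gamma with shape $2/\sigma - 1$ and scale $K\sigma/2$ (proper for
$0 < \sigma < 2$, hence the hard $\sigma < 2$ bound everywhere). Its
mean is $K(1-\sigma/2)$ and variance $K^2(\sigma/2)(1-\sigma/2)$, so
with training mean $m$ and variance $v$,

$$\sigma = \frac{2v}{m^2+v}, \qquad K = m + \frac{v}{m}.$$

$K$ and $\sigma$ are therefore not fitted parameters but moment
functions. The training window is the first $\lceil T/3\rceil$ samples
by index (not calendar span — the information content scales with the
number of observations, and the grids are close to regular). $\tau$ is
not identifiable from stationary moments; it defaults to 1 day,
comparable to gut bacterial generation and washout timescales, and the
test statistics below were chosen to be robust to it. When a strain's
relative abundance is analysed, the fitted $\sigma$ absorbs the
compositional noise of the rest of the community on top of the strain's
own fluctuations, so it is an effective, not a microscopic, amplitude.

### Goodness of fit

A population consistent with the trained SLM should, in the held-out
two-thirds of the series: (s1) keep its training mean; (s2) keep its
training variance; (s3) revert toward $K$. The test statistics are the
absolute held-out-minus-training mean difference, the absolute log
variance ratio, and the regression slope of increments $\Delta x$ on
$(x - K)$ across held-out transitions.

The null distribution is a full parametric bootstrap: surrogate
trajectories are simulated from the fitted SLM **over the entire day
grid** (initialized at the first observation), each surrogate is split
into the same training/held-out windows, *refitted on its own training
window*, and its statistics are computed against its own refitted
moments. Propagating the training-window estimation noise into the null
this way is essential: conditioning on the observed fit as if exact
leaves the surrogates underdispersed, and in simulation inflates the
type-I error from the nominal 0.05 to ~0.22. With the refitting
construction the measured type-I error is ~0.056 over 500 true-SLM
replicates, and a 60-day strain-replacement trajectory is rejected ~98%
of the time (both measured in `tests/testthat/test-acceptance.R`).

P-values use the two-sided rank convention $(r+1)/(B+1)$ (never exactly
zero), combined as $\min(1, 3\min_k p_k)$ (Bonferroni over the three
statistics); a population passes at $p \ge 0.05$. Default $B = 1000$
surrogates; a zero-variance training window is flagged degenerate and
skipped. The p-value is invariant to positive rescaling of abundances,
as $K$ scales and $\sigma$ is dimensionless.

### Numerical integration

Trajectories are integrated by Euler–Maruyama under the Itô
interpretation with substep $\min(0.02\tau,\ 0.02)$ days, floored at
$10^{-12}$: the multiplicative noise term can carry a discrete Euler step
across zero, and the floor prevents absorption while being far below any
abundance of interest. At these substeps the stationary distribution of
simulated series matches the analytic gamma to Kolmogorov–Smirnov
distance < 0.005 at $10^5$ sampled days. The integrator is written in
C++ (Rcpp) and draws from R's RNG, so seeded runs are bit-reproducible.

## Macroecology

Taylor's law is fitted by OLS of $\log_{10}$ variance on $\log_{10}$
mean across populations; populations with zero variance or nonpositive
mean are excluded with a warning. The two analytic anchors are
$\alpha = 1$ for a panel whose only variability is multinomial
compositional sampling (variance $\approx m(1-m)/N$) and $\alpha = 2$
for SLM populations sharing one $\sigma$ (variance
$= K^2(\sigma/2)(1-\sigma/2) \propto$ mean$^2$); both are reproduced
within $\pm 0.02$ by the acceptance script.

For the abundance fluctuation distribution, each population's abundances
are log-transformed and standardized to zero mean and unit variance
(natural log; any base gives identical z-scores). Zero abundances — a
strain undetected at a time point — are dropped before the log for the
AFD but retained in the Taylor moments, where they are genuine
observations of a small population; a half-minimum pseudo-abundance was
considered and rejected as it injects an arbitrary scale. The
standardized distributions are binned on a fixed grid of 20 even bins
spanning $[-4, 4]$ standardized units (generous coverage for gamma-like
AFDs; configurable), and the across-population mean of the bin densities
is fitted with the standardized log-gamma density

$$g(z \mid a) = \sqrt{\psi_1(a)}\,
  \frac{e^{a u - e^{u}}}{\Gamma(a)},\qquad
  u = \psi(a) + z\sqrt{\psi_1(a)},$$

which is scale-free, leaving the single shape parameter $a$ (under the
SLM, $a = 2/\sigma - 1$). One numerical detail matters: the data are
bin-*averaged* densities, so the model is averaged over each bin too
(Simpson's rule) before least squares — evaluating the model at bin
midpoints biases the recovered shape upward by ~6% at this bin width.
Taylor fits pool all strains (across hosts where applicable) rather than
fitting per host: the law is a cross-population statement and per-host
panels are small; a per-host fit can be obtained by subsetting.

## The synthetic-data generator

The generator emulates the study conditions the analysis is designed
for: a host carrying a handful of species, each with 1–4 strains whose
abundances follow independent SLMs around fixed carrying capacities
(defaults: $K$ log-uniform in 0.005–0.05, $\sigma = 0.5$, $\tau = 1$
day, started at stationarity), an unmodelled background component closing
the composition; 60–200 samples at day gaps drawn from $\{1,2,3,7\}$
with weights $(0.45, 0.35, 0.15, 0.05)$ (median interval 1–2 days,
occasional week-long gaps); per-site depths Poisson with intensity
proportional to species relative abundance, scaled to a target mean
depth (default 50x); binomial read sampling at the true site frequency;
and per-site randomization of which allele is labelled alternate, so
roughly half of all observed trajectories are mirror images and the
polarization logic is always exercised.

Fixed differences are laid out as private marker blocks: each of the
$k-1$ non-background strains carries `n_fixed_diffs` sites on which it
alone differs from the background haplotype. Any strain then differs
from the background at exactly `n_fixed_diffs` sites and two marker
strains differ at twice that. Giving *every* pair exactly the same
divergence would require all $k$ biallelic site partitions, which
necessarily produces $k$ trajectory clusters rather than $k-1$ and would
break the convention that the $k$-th strain is the residual background;
the private-block layout keeps the cluster count at $k-1$, matching how
the phaser reports strains. Within-strain polymorphism defaults to zero
(strains are clonal backgrounds); a jitter knob exists because real
strains are not perfectly monomorphic, but no published value pins its
scale.

Replacement events — an initially rare strain ramping to dominance over
a set duration, as observed in real hosts — are imposed on the
within-species frequencies with a logistic ramp, rescaling the remaining
strains proportionally. They provide the alternative hypothesis for the
goodness-of-fit power analysis.

What passing on synthetic data does **not** show: robustness to
reference-mapping artifacts (shared genes between species, read
mis-assignment), to within-strain evolution (sweeps would appear as
sub-clusters), to depth heterogeneity along the genome, or to
compositional coupling between species beyond the shared denominator.
Those belong to the read-processing layer, which this package
deliberately consumes rather than reimplements.

## Problem sizes used in validation

The automated checks run at deliberately chosen scales: stationary-gamma
agreement at $10^5$ sampled days; moment-estimator recovery at
$n = 10^5$ (within 2%); goodness-of-fit calibration over 500 true-SLM
replicates of ~90 time points with 300 surrogates each; replacement
power over 100 replicates; strain phasing over 40 communities (2 and 3
strains at 20x and 50x, 1,500 fixed differences each); ADF size over
2,000 unit-root series of length 200. The `n_boot` default for a single
user-facing test remains 1,000.

## Degenerate inputs, ties, and conventions

* Samples with no site passing the depth filter yield `NA` diversity;
  $F_{ST}$ is undefined (`NA`) when $\pi_{BT} = 0$ — for a species with
  no between-sample diversity the whole stationarity question is moot,
  and the pipeline reports it as untested rather than inventing a value.
* Constant series: stationary-by-convention for the ADF (flagged), a
  degenerate skipped fit for the SLM.
* Zero-variance site trajectories have undefined polarity and are
  excluded from centroid refinement.
* Cluster membership ties go to the centroid with the highest
  correlation; cluster order is by decreasing size; seeded runs of every
  stochastic stage are bit-reproducible.
* The species-inclusion defaults (median depth $\ge$ 10x, present in
  $\ge$ 50% of samples) are ordinary coverage/prevalence screens and are
  fully configurable.
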