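---
title: "Cost-thresholded connectivity analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-thresholded connectivity analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costnet)
```

## The analysis in one paragraph

`costnet` characterizes task-state functional brain networks from ROI
time series. Each subject's preprocessed BOLD series (one column per
ROI) is globally z-scored per run, restricted to one task condition with
the first seconds of every block discarded for the hemodynamic delay,
and concatenated across runs. Pairwise Pearson correlations between the
62 ROIs give a symmetric connectivity matrix, which is binarized at a
fixed *wiring cost* — the fraction of retained node pairs — rather than
at a fixed correlation threshold, so that groups are compared on
networks of identical density. On the resulting binary graphs the
package computes global efficiency (mean inverse shortest path length,
unreachable pairs contributing zero), local efficiency (mean efficiency
of each node's neighbourhood subgraph) and cost efficiency (global
efficiency minus cost), locates the cost range with the small-world
property and the cost-efficiency peak, forms majority-vote group
networks, and runs edge-wise group statistics: two-sample t-tests on
Fisher-z edge strengths, correlations of edge strength with subcortical
activity and with response time (RT), and Wilcoxon comparisons of
shortest path lengths from the primary motor cortex.

## Network construction

**Normalization.** A run is z-scored against the pooled mean and pooled
sample SD of *all* its entries (frames x ROIs). Pooling preserves
relative amplitude differences between ROIs within a run, which
column-wise scaling would erase; with roughly 146 x 62 values per run
the n-1 convention in the pooled SD is immaterial, and the sample
estimator is used as the conventional choice.

**Block trimming.** The first `trim_seconds` (default 10 s) of every
contiguous same-condition block are dropped. Seconds convert to frames
as `ceiling(trim / TR)` — at TR 3.5 s a 10-s trim always removes 3
frames. Rounding up guarantees at least the requested delay is
discarded; the trim is exposed as a parameter with that conservative
default. A block shorter than its trim contributes zero
frames and logs a warning rather than failing: short blocks are a data
property, not a user error.

**Cost thresholding.** At cost $c$ on $N$ nodes,
$K = \mathrm{round}(c\,N(N-1)/2)$ edges are retained (half away from
zero, so the count does not depend on the parity of the nearest
integer). Ranking is by *signed* correlation, largest first:
anticorrelated pairs are never made edges before positively correlated
ones, so a thresholded network always has a positive minimal retained
correlation at realistic costs. Ties at the cutoff break by
lexicographic node-pair order — an arbitrary but deterministic
convention, so degenerate inputs stay reproducible. The smallest
retained correlation
(the *minimal correlation ratio*) is stored on the network.

**Group networks.** An edge enters a group's common network if strictly
more than half of the group's subjects have it
(support $\ge \lfloor n/2 \rfloor + 1$); with 14 and 12 subjects the
thresholds are 8 and 7. Total connectivity is the retained percentage
of the $N(N-1)/2$ possible pairs.

## Efficiency metrics and null models

Distances are unweighted breadth-first path lengths; unreachable pairs
contribute 0 to global efficiency (the Latora–Marchiori convention),
which keeps the measure defined on the disconnected graphs that low
costs produce. Local efficiency of a node is the global efficiency of
the subgraph induced on its neighbours, 0 for nodes of degree < 2.

The small-world criterion at a given cost requires
$E_{glob}^{rand} > E_{glob}^{obs} > E_{glob}^{latt}$ and
$E_{loc}^{obs} > E_{loc}^{rand}$. The random reference preserves every
node's degree exactly by repeated double-edge swaps — the standard null
for brain graphs — with 10 accepted swaps per edge and 20 realizations
per cost as defaults; the reference construction and realization counts
are this package's convention and are recorded in the output metadata.
The attempt budget is bounded
(20 attempts per requested swap) and the realized swap count is
attached to the result: a star graph, for which no legal swap exists,
simply comes back unchanged. The lattice reference is a ring lattice
filled in increasing neighbour-offset order, deterministic by
construction. The reported small-world range is the longest contiguous
run of grid points satisfying the criterion; an empty range is
signalled explicitly rather than coerced to a degenerate interval.

The default cost grid is 0.01–0.50 in steps of 0.005. For the group
analyses the per-subject curves are averaged point-wise, and the
cost-efficiency peak is read off a shape-preserving monotone
piecewise-cubic Hermite interpolant (Fritsch–Carlson, `monoH.FC`)
evaluated on a 0.001-step grid — the open-source equivalent of
shape-preserving spline smoothing; ties at the maximum resolve to the
smallest cost.

## Group statistics

Edge strengths are compared on the Fisher scale ($z = \mathrm{atanh}\,
r$), which stabilizes the variance of correlation estimates. The
group test is the pooled-variance Student t-test (two-sided, $p < .05$
uncorrected), a conventional default for this analysis; a
`var_equal = FALSE` switch gives the Welch form for sensitivity checks.
An edge with zero variance in both groups has no defined p-value and is
flagged degenerate instead of silently dropped. Edge–activity and
edge–RT relations are Pearson correlations across subjects within a
group; the subcortical activity variable is either the mean normalized
task signal of the 10 subcortical ROIs or surrogate contrast t-values.
In the RT analysis, cortico-subcortical pairs whose cortical node is a
DLPFC region are tested uncorrected — a single pre-specified
directional hypothesis — while all remaining pairs are
Benjamini–Hochberg adjusted at 0.05 (the package's FDR procedure of
choice). The cortical node list for the RT analysis is a configuration
input; it defaults to the distinct cortical members of the significant
group-difference edges.

Path lengths from the left/right M1 are compared with a two-sided
Wilcoxon rank-sum test per (source, target) pair. Unreachable pairs are
excluded from that pair's test and counted in the output — imputing a
finite length would bias group means, and the exclusion count keeps the
censoring visible. R's `wilcox.test` computes the exact distribution
for small samples without ties and a tie-corrected normal approximation
otherwise; integer path lengths essentially always tie, so the
approximation is the operative branch at these sample sizes.

## The synthetic cohort generator

No raw data accompany this analysis — the generator exists so that
every stage is verifiable by parameter recovery. Each ROI belongs to
one of four communities (dorsal motor, ventral visual, prefrontal,
subcortical) and its series follows a unit-variance latent factor
model:

$$x_i(t) = a f_{c(i)}(t) + \sum_{e \ni i} b_e\, g_e(t) +
  \sqrt{1 - a^2 - \textstyle\sum_e b_e^2}\;\varepsilon_i(t),
  \qquad a = \sqrt{\rho},$$

with community factors $f_c$, planted-edge factors $g_e$, and white
noise, all standard normal. A factor model is the simplest generative
structure with controllable pairwise correlations and modular topology;
under it the population correlation of a planted edge is
$a_i a_j[c(i)=c(j)] + b_e^2$ in closed form, which is the independent
oracle for the generator's convergence tests. A configuration whose
loadings exceed a ROI's unit variance budget is rejected naming that
ROI — in a factor model this is the only way the implied covariance can
fail to be realizable.

Defaults mirror the study conditions the analysis assumes: two groups
of 14 ("HV") and 12 ("PD") subjects, 4 runs of 146 frames at TR 3.5 s,
62 ROIs, an interleaved SI/ET/CTL block design with about 20 presses
per condition per run, and within-community correlation
$\rho = 0.25$. Six planted edges (base loading 0.55, population
$r \approx 0.30$ cross-community) carry per-subject coupling scalars,
normal with SD 0.2 truncated at $1 \pm 2.5$ SD: one shared scalar
drives the five *attenuated* edges — halved in group 2, planting the
HV > PD effect — and the subcortical activity offsets (positive for
striatal, negative for thalamic ROIs, planting the opposed
activity-coupling signs); two independent scalars drive a
DLPFC–putamen and a VLPFC–putamen edge and enter the RT model with
slopes −500 and +500 ms per unit coupling (noise SD 60 ms, intercept
900 ms), planting the negative DLPFC and positive VLPFC edge–RT
correlations at magnitudes (|r| ≈ 0.5–0.7 at n = 14) comparable to what
such a study reports. Button presses are i.i.d. truncated-normal
inter-press intervals around the subject's model-implied RT, so the
behavioural summary recovers the planted RT. Surrogate subcortical
t-values are scaled shared-coupling plus noise, standing in for a
contrast computed upstream of this package. Per-subject seeds derive
from the master seed by an integer mix, so cohorts are bit-reproducible
and subjects independent.

What the generator deliberately omits: hemodynamic-response
convolution, scanner drift, motion, physiological noise, and spatial
autocorrelation between neighbouring ROIs. Passing recovery tests
therefore demonstrates that the *pipeline* is correct and calibrated —
not that the planted factor model is a faithful model of BOLD data.
Group networks built from the synthetic covariance are, for instance,
more consistent across subjects than real ones, so the synthetic
total-connectivity percentages run higher than values observed in vivo.

There is also a small 4-D volume fixture (`simulate_volume_fixture()`)
whose 3x3x3-voxel ROI cubes carry known signals, used to verify the
extraction path: cube averaging after nearest-voxel affine mapping,
with cubes always 27 voxels regardless of voxel anisotropy.

## Verification strategy and problem sizes

The test suite checks every metric against independent oracles:
breadth-first distances against Floyd–Warshall (and igraph) on 500
random graphs of up to 25 nodes; efficiencies against brute-force
subgraph enumeration; the pooled t, exact Wilcoxon and
Benjamini–Hochberg adjustments against closed forms and exhaustive
permutation enumeration at small n. Statistical calibration uses 2000
zero-effect cohorts (14 vs 12 subjects, 12 ROIs spanning all four
communities, one 104-frame run) and requires each test's empirical
type-I error at $\alpha = .05$ to lie in [0.03, 0.07]; parameter
recovery uses 100 full-size planted cohorts and requires each of the
three planted sign patterns in at least 90% of replicates. The
calibration is defined by its replicate count and acceptance band; a
compact cohort keeps the replicate count high at a fixed runtime
without changing what is being calibrated. The acceptance script
evaluates efficiency curves on a
0.02-step grid with 5 null realizations per cost; the coarser-than-
default grid is a deliberate problem-size choice for the scripted run
and is recorded in its manifest.

## Known limitations

* Metrics are defined for binary undirected graphs only; weighted
  small-world indices and modularity/hub analyses are out of scope.
* The double-edge-swap null can fail to mix on extreme degree sequences
  (stars); the realized swap count is reported so such cases are
  visible.
* The Wilcoxon path-length test at n = 14 vs 12 with integer distances
  is conservative (empirical size ≈ 0.044 at nominal 0.05).
* `fisher_z` rejects |r| = 1; degenerate duplicate series must be
  resolved upstream.
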