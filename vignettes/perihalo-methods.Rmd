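---
title: "Quantitation methods in perihalo"
author: "perihalo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitation methods in perihalo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

perihalo implements the quantitative layer of a class of experiments in
lymphatic immunobiology: lymphatic endothelial cells (LECs) release
exosome-rich vesicle fractions that accumulate as perivascular "halos"
around lymphatic vessels and modulate how dendritic cells navigate
toward those vessels. The measurable consequences span several assay
families — single-cell migration tracks, cell-shape morphometry,
immunofluorescence line profiles, 6-plex TMT proteomics, spatial
point-to-vessel statistics, transwell kinetics and nanoparticle tracking
— and this package provides one tested implementation of each statistic,
plus synthetic generators that emulate every input with known ground
truth. Units are minutes, micrometres and degrees throughout; all
geometry is 2D.

## Cell-track statistics

A track is an ordered series of positions $(x_i, y_i)$ at strictly
increasing times $t_i$. With an upgradient unit vector $\hat g$ and the
start-to-end vector $\vec d$:

* track length $L = \sum_i \lVert \Delta_i \rVert$ over steps
  $\Delta_i$;
* displacement $\lVert \vec d \rVert$ and upgradient displacement
  $\vec d \cdot \hat g$ (signed);
* chemotactic displacement $= (\vec d \cdot \hat g) / L$;
* chemotactic index $= \cos\Theta$ with $\Theta$ the angle between
  $\hat g$ and $\vec d$;
* speed $= L / (t_n - t_1)$;
* migratory angle change $= |\Delta\theta|$ between the headings of
  consecutive steps, wrapped into $[0°, 180°]$ — the squared-difference
  form under a square root reduces to an absolute value, and wrapping
  prevents a 350° step from masquerading as a large turn.

Design choices worth noting. Zero-length tracks have undefined ratio
statistics; these are reported as missing, never as zero, and excluded
from group means — silently zeroing them would bias every group mean
toward apparent immobility. Zero-length *steps* carry no heading and are
skipped in the angle-change sequence. Both aggregations of angle change
are exposed — the per-cell mean (`track_metrics()`) and the pooled
per-time-point values (`step_angle_changes()`) — because published
per-time-point summaries cannot always be attributed to one or the
other. The displacement filter (`filter_by_displacement()`) is inclusive
at the threshold and defaults to 24.1 µm, the convention for 3D-collagen
assays; confined assays state no number, so there the threshold is a
config knob the caller must set.

Endpoint-angle histograms (`angle_histogram()`) use sectors centred on
0° (straight upgradient lies in the middle of a sector, not on an edge),
and drop zero-displacement tracks.

Group summaries use two-sided Welch t-tests. Degenerate inputs are
handled explicitly: two identical constant groups give $p = 1$, constant
groups with different means give $p = 0$ (the textbook statistic is
0/0 and NaN there).

## Morphometry

Circularity is $4\pi A / P^2$ with the area from the shoelace formula
and the perimeter as polygonal arc length; it is 1 for a disk and
decreases as protrusions deepen. Contours are polygons in physical
units; raster masks must be vectorized upstream, because pixel-counted
perimeters carry a systematic positive bias that makes closed-form
checks (square $\pi/4$, equilateral triangle $\pi\sqrt3/9$) impossible.
Self-intersecting polygons are rejected by an $O(n^2)$ crossing test
(skipped above 2000 vertices, where the cost would dominate and
generator output is known simple).

## Halo band width and diameter ratio

A cross-sectional fluorescence profile of a vessel shows, per channel,
two intensity bands (the vessel walls for a vessel marker such as
podoplanin; the perivascular shell for an exosome marker such as CD9).
The band-width estimate $\sigma$ proceeds as: moving-average smoothing
(default 3 samples); the dominant local maximum on each side of the
profile midline, subject to a prominence cut of 10% of the channel's
dynamic range; then, walking outward from each maximum, the adjacent
fluorescence minimum — the first sample within the prominence cut of
the channel floor, or the first valley from which the signal rises
again by at least the prominence (plain noise dips are ignored), with
the running outward minimum as the edge fallback.

The source sentence defining $\sigma$ is grammatically ambiguous, so
both defensible readings are implemented. The default,
`sigma_mode = "band"`, sums the per-side maximum-to-minimum distances —
a width that grows with halo extent. The alternative,
`sigma_mode = "span"`, reports the full outer-minima separation. (The
literal third reading, outer-minima span minus inter-maxima span, is
algebraically identical to `"band"` and therefore not a separate
option.) Neither reading is claimed to be the original authors' intent.
The halo diameter ratio is $\sigma_{marker} / \sigma_{vessel}$;
detection failure in either channel — a flat profile, or no prominent
maximum on one side — propagates as an explicit failed status, never a
number.

$\sigma$ is invariant under affine intensity rescaling (all thresholds
are range-relative) and under reversal of the distance axis. On
noise-free Gaussian bands of sd $s$, the floor crossing sits at
$s\sqrt{2\ln 10} \approx 2.15\,s$ from the peak, which is the analytic
expectation the tests check against. Under heavy noise (10% of band
amplitude) the 3-sample default undersmooths badly; the robustness test
uses a 15-sample (3 µm) window, still below the smallest band sd. Even
then the ratio estimate carries a small smoothing bias toward 1
(≈ −7% at a true ratio of 2), inherent to fixed-window smoothing of
bands of unequal width — users comparing channels of very different
widths at high noise should treat ratios as slightly conservative.

## TMT quantitation

Reporter intensities (6 channels, 3 steady-state vs 3 TNFα-stimulated)
are processed as: (1) per-channel median normalization — zeros are
non-detections and excluded — followed by multiplication by each
sample's measured input protein concentration divided by the minimum
concentration, making intensities proportional to protein amounts;
(2) Top3 interprotein abundance, the mean of a protein's three most
intense peptides per channel (all detected peptides when fewer than
three); (3) per-protein treated/reference abundance ratios with two
p-values: `p_sample`, a Welch t-test on log10 abundances (3 vs 3), and
`p_ratio`, a one-sample t-test of peptide-level log10 ratios against 0,
Benjamini–Hochberg adjusted across proteins. A protein is significant
iff both `p_sample` and the adjusted `p_ratio` fall below α (default
0.05).

Two deliberate choices here. First, the decision *rule* (both p-values
< α) follows the original pipeline, but the underlying tests do not
reimplement the isobar package's noise model — the rule is what the
method prescribes; the tests behind it are stated plainly and are
configurable. Proteins with a single usable peptide have no `p_ratio`
and are never flagged. Second, the common median target is the minimum
of the per-channel medians. No target is prescribed anywhere — only
that medians end up equal — and the minimum-median target is the one
choice that makes the whole normalization exactly idempotent once the
concentration scaling (whose smallest factor is 1) is applied;
idempotence in turn is what makes "normalize twice" a harmless no-op in
pipelines. The target cancels from every ratio, so the choice affects
nothing downstream.

Derived views: the heat-map matrix is
$\log_{10}(\text{abundance} / \text{mean of the reference-group
samples})$ per protein; the ratio-density view is the histogram of
per-protein log10 ratios plus an overall fold change defined as the
ratio of summed group-mean abundances. Note the two senses of "overall
regulation": symmetric log-scale spikes leave the log-ratio histogram
centred on 0 while the arithmetic sum ratio exceeds 1 (e.g. 1.25 for
±1 log2 spikes), because the arithmetic mean of $2$ and $1/2$ is 1.25.
Cluster enrichment divides the mean interprotein abundance of a
cluster's members by the mean over all quantified proteins, per group,
with a Welch t-test (cluster vs all, log10 scale) attached; unmatched
cluster ids are reported, and a cluster with no quantified member is an
error rather than a silent 1.

## Spatial and assay statistics

The point-to-vessel statistic measures each cell's Euclidean distance
to the nearest point of any vessel polyline. "Normalized to the overall
vessel density" has no published formula; the package normalizes the
mean minimum distance by its expectation under complete spatial
randomness (CSR), estimated by seeded Monte-Carlo with uniform points
in the field (n ≥ 10,000). This statistic is dimensionless, equals 1
under no attraction, falls below 1 when cells accumulate near vessels,
and is invariant under joint rescaling — the properties a density
normalization needs. The raw mean distance and the vessel length
density are reported alongside so no information is hidden behind the
normalization.

The adhesion rule counts a cell as an adherent track iff it has a run
of consecutive detections whose dwell time (run length × frame
interval) reaches 3 s; interrupted runs do not add up. Transwell
calibration fits an ordinary least-squares line (free intercept) of
cell count on fluorescence through the standard curve and inverse-maps
readings, clipping at zero — a fluorescence reading below the blank
cannot mean negative cells. NTA averaging is the bin-wise mean of
replicate histograms with identical binning, with
concentration-weighted mean diameter, modal bin centre and total
concentration as summaries. Pore coverage is
$100\,\pi (d/2)^2 \rho$ with $d$ in µm and $\rho$ in pores/cm²
(3 µm at $8\times10^5$/cm² gives 5.65%, printed as 5.7%).

## The synthetic world

Each generator emulates one input class with retrievable ground truth;
all randomness flows through one explicit seed per call and the global
RNG stream is restored afterwards.

**Tracks.** A wrapped-normal biased persistent random walk: each step's
mean heading is the direction of
$p\,\hat u_{prev} + b(1+\pi_r)\,\hat g$ (persistence $p$, bias $b$,
protrusion $\pi_r$), with heading noise of sd
$40°(1+\pi_r)$ and realized speed $v_0/(1+\pi_r)$. Protrusion is thus a
minimal chemokinesis mechanism: more angular exploration and stronger
gradient coupling at the cost of speed — the direction of all three
published effects, by construction, which is exactly what a generator
for property tests should encode and all that a green test establishes.
Defaults ($v_0 = 4$ µm/min, $dt = 1$ min, noise 40°) are plausible
dendritic-cell scales chosen once; no published speed or persistence
scale exists for these assays, so defaults are free parameters of the
stated world, not calibrated estimates.

**Peptide tables.** Protein base abundances are log-normal (meanlog
$\ln 10^6$, sdlog 1), peptide counts $1 + \text{Poisson}(4)$, peptide
efficiencies log-normal (sdlog 0.5), spiked group fold changes
multiplicative, and peptide noise log-normal with CV
`peptide_cv`. With `peptide_cv = 0` and unit concentrations the
pipeline is an exact fixed point (spiked ratios recovered to machine
precision) provided the spiked peptides do not straddle the channel
median — the test spikes a far-above-median protein for exactly this
reason.

**Profiles.** Background plus two Gaussian bands per channel at
`vessel_center ± halfwidth`. The band sd defaults to `halfwidth / 4`:
the downstream estimator measures band *decay length*, so the shape
must scale with the offset for a halfwidth ratio of 2 to be recoverable
as a diameter ratio of 2 — a generator with fixed band sd would make
that recovery impossible no matter how good the estimator.

**Vessel fields, size histograms, contours, transwell kinetics.**
Poisson cell counts placed near polylines / uniformly / repelled;
log-normal diameter mixtures parameterized so the density mode is 83 nm
(the inflammatory-fraction scale); star polygons
$r(\varphi) = R(1 + a\cos k\varphi)$ whose circularity is monotone
decreasing in $a$; logistic arrival curves with a linear fluorescence
map and a clean standard curve.

What the generators deliberately do not emulate: photorealistic images,
3D walks, diffusion-reaction gradient shapes, isobaric interference and
co-isolation artifacts in reporter channels, or instrument-specific NTA
binning quirks. A green test therefore establishes correctness of the
statistics on idealized inputs with known truth — not robustness to
every artifact of real microscopes and spectrometers.

## Numerical conventions and limitations

Angles are wrapped into $(-180°, 180°]$; ties in halo peak selection
break toward the profile midline (and symmetrically, so mirrored
profiles give identical widths). Intensity zeros are missing data, not
measurements. JSON is the only config format (no YAML parser is a
package dependency). The t2–t7 style printed proteomics counts can only
be recomputed when the study's supplementary protein table is supplied
by the user; nothing in this package fabricates those inputs. The
published inter-pore "mean distance of 52.63 µm" is not derivable from
the printed pore density under lattice or Poisson nearest-neighbour
models and is not reproduced.
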