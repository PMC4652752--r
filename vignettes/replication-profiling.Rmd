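---
title: "Replication profiling of circular chromosomes: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replication profiling of circular chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(repliprofile)
```

This vignette explains the science the package implements, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where the design
was genuinely open.

## Marker frequency analysis

Sequencing an exponentially growing bacterial culture over-represents
origin-proximal DNA: a locus replicated at time $t$ after initiation is
present, across the age distribution of an asynchronous steady-state
population, at relative copy number

$$M(x) = 2^{-t_{\mathrm{rep}}(x)/\tau_d},$$

where $\tau_d$ is the doubling time. The measured quantity is the
per-bin enrichment of uniquely mapping reads in the exponential sample
over a non-replicating stationary-phase control,
$E_i = (c_i/\sum c)/(s_i/\sum s)$. The control cancels multiplicative
per-bin mappability bias exactly in expectation, because the same bias
multiplies both libraries. Totals are taken over unmasked bins (control
count zero, or user-excluded), which makes the stationary-weighted mean
of $E$ exactly 1; masked bins propagate through smoothing and minima
searches without ever contributing to a fit.

The copy-number law above is a modelling assumption, not a measured
fact: it is the minimal steady-state model that generates the observed
exponential-phase gradients. It ignores overlapping replication rounds
(multifork replication in fast-growing cells), which compress the
origin-to-terminus ratio in real data but leave the *relative* geometry
— gradients, minima, steps — intact, which is all the analysis uses.

## Periodic LOESS and the outlier rule

The profile is smoothed with locally weighted quadratic regression:
at each bin the $q = \mathrm{round}(f \cdot n)$ nearest *unmasked*
points by circular distance are fitted with tricube weights
$w = (1-(d/d_{\max})^3)^3$ in local coordinates re-centred at the bin,
so the fit is continuous through the coordinate wrap. Defaults: span
$f = 0.10$ (≈460 kbp at 1 kb bins on the 4.64 Mbp model genome, reported
rounded to 10 kbp), degree 2 (fixed), one remove-and-refit pass with the
squared-residual cutoff $(E_i - \hat E_i)^2 > 0.02$ on the linear
enrichment scale. Ties at the $q$-th neighbour are included; because
$d_{\max}$ is the distance of the furthest selected point, tied boundary
points carry zero weight and the fit is unchanged by their inclusion —
this also makes the implementation agree to numerical precision with a
generic non-periodic LOESS applied to the profile tiled three times.
Removal passes are idempotent once all residuals are in-bounds. If the
local system degenerates (too few distinct points carrying weight), the
fit falls back to the tricube-weighted mean for that bin.

Two implementation notes. The unmasked regular-grid case collapses to a
single convolution kernel applied by circular shifts; the masked case
uses a two-pointer sweep (the $q$-nearest window start is monotone in
the target bin) with the local normal equations solved in normalized
coordinates $u/d_{\max}$ for conditioning.

## The fork-kinetics simulator

All origins fire simultaneously at $t = 0$; each launches a clockwise
and a counterclockwise fork at `fork_speed_bp_per_s` (default 1000, the
upper range of measured fork speeds). Inside an annotated slow zone a
fork moves at `head_on_factor` (default 0.25) times full speed when it
opposes the direction of transcription and `codirectional_factor`
(default 0.9) otherwise; these two factors are free parameters of the
model, chosen once as plausible magnitudes for replication–transcription
conflict at heavily transcribed *rrn* operons, and are not anchored to
any measured value. The `rpo_star` flag rescales every factor $f$ to
$1 - 0.5(1-f)$, emulating an RNA-polymerase-destabilising mutation that
relieves half of the conflict. Polar *ter* sites arrest a fork arriving
in their blocking orientation with probability `efficiency` (default 1;
partial permeability is exposed but not anchored); the arrested fork
waits until the converging fork arrives and both fuse. With
`tus_active = FALSE` every site is transparent. Barrier elements (e.g. a
*tetO* operator array) impose a fixed pause. Converging forks meeting
inside a bin fuse at the exactly interpolated position, so fusion
positions are sub-bin accurate.

`t_rep[i]` is defined as the time the *start coordinate* of bin $i$ is
replicated — zero exactly at origin bins. The one deliberate exception:
a bin whose start a blocked fork is touching inherits the converging
fork's fusion time, because the body of that bin waits for the far fork;
this makes the terminus bin of a trapped configuration carry the fusion
time (copy number $2^{-t_{\mathrm{fuse}}/\tau_d}$), which is the
physically meaningful summary.

A configuration in which every path into a region is blocked (two
opposed traps) is reported as an explicit error, not an infinite loop.
All randomness (count noise, bias, partial trap passage) flows from one
integer seed through deterministic per-operation substreams, so a run is
reproducible from `simulation_params(seed = ...)` alone.

Default study conditions: doubling times follow the measured growth of
the modelled strains (19.9 min wild-type-like, 20.6 dual-origin-like,
39.8 for the ectopic-origin-only strain), depth 100 reads per 1 kb bin,
shared lognormal mappability bias with `bias_sd_log` 0–0.3, Poisson
counts. The generator emulates the statistical structure of real MFA
data — origin-centred gradients, the trap step, steeper head-on zones,
shared bias, count noise — but not multifork replication, replication
restart, GC skew in mappability, or cell-cycle heterogeneity beyond the
steady-state age distribution; passing tests on simulated data therefore
validate the analysis machinery, not those aspects of real libraries.

## The bundled chromosome model

The model genome is 4.64 Mbp with the native origin at 3.923 Mbp and the
ectopic origin at 0.344 Mbp. The native-origin coordinate deserves a
note: the arithmetic midpoints 1.603, 2.1335 and 4.4535 Mbp are mutually
consistent only with 3.923 (an antipode of 1.603; a pair-midpoint of
2.1335 with 0.344), so 3.923 is shipped as the working coordinate even
though the origin region is often quoted as "3.92 Mbp". The *dif* site
(1.589), *rrnH* (0.229) and the *rrnCABE* cluster (3.94–4.21) are placed
at their documented coordinates; the ten *ter* sites and *rrnD*/*rrnG*
are literature-scale approximations, and only their polarity semantics
(which fork orientation each site blocks) are asserted by tests. In the
bundled arrangement all seven *rrn* zones are transcribed co-directionally
with wild-type replication, so a fork from the ectopic origin meets
*rrnH* and *rrnCABE* head-on — the conflict geometry the analysis is
designed to expose.

## Minima, midpoints and what "recovered" means

Termination minima are taken on the outlier-refit LOESS curve, split at
origin positions into open arcs (an origin bin can never be a terminus);
ties break toward the smaller coordinate and a minimum on an arc
boundary is flagged suspect. Positions are reported at bin resolution
(bin starts, Mbp to 3 decimals); shifts from the arithmetic midpoints
are signed along the clockwise coordinate.

Two accuracy regimes matter, and they are different in kind. On a
near-symmetric profile (wild-type-like), the noise-free LOESS minimum
coincides with the simulated fork-fusion point to within one bin, but
the terminus trough is shallow, so under Poisson noise at depth 100 the
located minimum jitters by tens of kb. On a trap configuration the
profile has a step at the innermost blocking site; the smoothing window
displaces the noise-free minimum from the fusion point by an
*attenuation shift* (bounded by half the window, ~140 kb at default
settings — the same systematic displacement visible in real profiles,
where minima sit beyond the innermost trap site), but the step makes the
minimum's *location* highly stable under count noise (95% of seeded
replicates within 20 kb of the noise-free location at depth 100). The
test suite checks each property in the regime where it is meaningful.

Gradient deviation scores formalize "locally steeper than the arm":
per-bin central differences of $\log_2$ fitted values, region mean over
arm median, with the arm baseline excluding all annotated regions and an
$\varepsilon = 10^{-6}$ guard signalling flat arms as undefined. On an
unsmoothed exponential track a head-on factor $f$ scores $1/f$ exactly;
on the default 460 kbp smooth the score of an 8 kb operon is strongly
attenuated toward 1, so scores are best read comparatively (same
smoothing, different strains), not as absolute slowdown factors.

## Inversion detection

Mapping reads from a rearranged chromosome onto the reference
arrangement turns an inversion into two discontinuities; reversing the
inverted segment restores continuity. The detector minimizes the mean
squared adjacent difference (roughness) over single-segment reversals.
Three numerical facts shaped the design. First, candidate junctions are
found as local maxima of the absolute second difference of a lightly
smoothed profile (span 0.02), excluding ±20 kb windows around annotated
origins, *ter* sites and barriers — genuine profile kinks that are not
rearrangement junctions. Second, that same smoothing blurs a junction
over ~90 bins, so candidates sit on the *shoulders* of the smeared jump,
roughly ±19 bins off, and the roughness objective must be evaluated on
the raw enrichment track, where the jump is sharp. Third, the
improvement landscape is a spike, not a basin: reversing a segment whose
endpoints are even slightly off relocates the jumps without removing
them. The search therefore scans a ±25-bin grid around *every* candidate
pair, exploiting the fact that a circular segment reversal changes only
the two boundary adjacencies, so each grid point costs O(1).

Reversing a segment or its complement restores continuity equally (the
two results are reflections), so a call is canonicalized to the shorter
arc — the parsimonious choice, and the correct one for the ~800 kb case
the detector is modelled on; depth data alone cannot distinguish the
two. The call threshold (20% roughness reduction) is a working default
with no external anchor; an un-called result is a valid outcome. Under
an active fork trap the trap step contributes a large fixed share of the
total roughness, so even a perfect recovery removes only part of it
(~45% in the modelled case) — the threshold is set with that in mind.

## Growth curves

Doubling times are estimated by ordinary least squares of
$\log_2(\mathrm{cfu})$ on time over a window, 60–180 min after dilution
by default (the reliably exponential phase of a batch culture); the
estimate is the reciprocal slope, exactly scale-invariant in cfu units.
Automatic window selection is deliberately out of scope — the window is
a judgement call on real data — and zero counts inside the window are an
error rather than silently dropped. A 1% fast-growing suppressor
subpopulation (doubling 20 min inside a 40 min parent) biases the 60–180
min estimate by under 10%, which is why biphasic curves are flagged by
convexity of the log-counts rather than absorbed into the fit.
Measured doubling times of the wet-lab strains are inputs to the
simulator, not quantities the package can reproduce.

## Problem sizes and limitations

The test suite and the acceptance script run the full 4640-bin model
genome for end-to-end checks and 100–1000-bin genomes for kinetic unit
tests; the noisy-minima stability property uses 100 seeded replicates at
depth 100 per bin. Known limitations: single synchronous initiation
round (no multifork replication); at most two origins; only single
inversions (no nested or multiple rearrangements, translocations or
duplications); GFF3 output cannot represent slow zones wrapping through
coordinate zero (split them); and the inversion detector assumes
junction jumps exceed local noise after 1 kb binning.
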