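---
title: "Models and methods: kinetochore dynamics in spermatocyte meiosis"
author: "ktmeiosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: kinetochore dynamics in spermatocyte meiosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktmeiosis)
```

## The measurement problem

Live imaging of *Drosophila* spermatocytes with tagged centromeres
(Cid/Cenp-A-EGFP, Mis12-EGFP) and chromatin (His2Av-mRFP) yields 3D+t
stacks in which eight kinetochore (KT) dots per cell move through the two
meiotic divisions. The quantities of interest are per-pair kinematics —
the KT speed $V_{KT}$, the angle $A_{KT}$ between the intra-pair axis and
the spindle axis, and the inter-KT distance $D_{KT}$ — from which division
phases and behavioral events are scored: nuclear envelope breakdown
(NEBD), the prometaphase A/B sub-division (before/after the onset of
KT-microtubule interactions), metaphase, anaphase, telophase and
interphase onsets; polar-equatorial excursions; KT re-orientation events;
transient sister-centromere "breathing"; and, in homolog-conjunction
mutants, univalent classes I/II/III.

No public dataset accompanies these measurements, so the package pairs the
analysis chain with a generative simulator whose control preset is
calibrated to the published values. All recovery claims in the test suite
are claims about this simulator; see "What the simulator does and does not
emulate" below for how far that carries to real data.

## The generative model

Each *unit* of motion is a KT pair: a bivalent in M I (two homolog KT
dots), a conjoined sister-KT dot in interkinesis, a dyad in M II, a
univalent in `mnm`/`tef` presets. A unit has an anchor path $C_i(t)$, an
intra-pair axis $u_i(t)$ and a separation $D_i(t)$; members sit at
$C_i \pm \tfrac{1}{2} D_i u_i$.

* **Prometaphase A** (5 ± 1.5 min): all anchors share a slow concerted
  drift (0.003 um/s) plus Ornstein-Uhlenbeck (OU) jitter (positional s.d.
  0.08 um, relaxation time 30 s). The pair axis points in a random,
  persistently misaligned direction (35-85 degrees off the spindle axis).
* **Prometaphase B** (9.75 ± 3 min in M I, 7 ± 2 min in M II): scripted
  itineraries of ballistic poleward jumps (speeds 1.25-1.6 times the
  0.12 um/s jump-speed scale) alternating with slower plate-directed
  congression moves (0.035 um/s; univalent presets return fast, as their
  shuttling never stops). The first jump of the cell defines the A-to-B
  boundary; during jumps the pair axis rotates into the motion direction
  over ~25 s. Pairs settle into jointly drawn, minimally spaced
  (>= 1.5 um) plate positions; the last pair settles exactly at the
  metaphase-onset boundary. Itineraries that do not fit a short
  prometaphase B first shed pole-and-back loops, then speed up uniformly.
* **Metaphase** (18 ± 3 min): OU jitter of s.d. 0.05 um around the plate
  slot; the axis wobbles 2-8 degrees around the spindle axis; bivalent
  $D_{KT}$ is stretched (1.10 ± 0.08 um, up from a 0.40 um resting
  distance).
* **Anaphase** (10 min, matching the convention that the
  metaphase-to-anaphase transition precedes telophase onset by about 10
  minutes): members move deterministically along the spindle axis to
  opposite poles at 0.03 um/s and hold; jitter is frozen so the true pair
  distance is non-decreasing.
* **Telophase / interphase**: positions hold; the transitions are carried
  by a chromatin-decondensation proxy signal (two upward steps), because
  the published scoring uses mitochondrial autofluorescence and chromatin
  shape, neither of which is modeled. NEBD is likewise carried by a
  nucleoplasmic proxy that drops sigmoidally at the boundary.

Excursion counts are controlled generatively: a pair completes
$1 + 2m$ polar-equatorial transits ($m$ extra pole-and-back loops,
$m \sim \mathrm{Poisson}$), calibrated so the configured per-pair mean is
2 for controls and 7 for univalent presets. One re-orientation event per
control cell is scheduled as a congression to the plate followed by two
antagonistic supra-threshold jumps (to beyond the plate band on the far
side, then back past the plate toward the home pole), a construction that
adds no completed transits; in a configurable fraction (default 0.2) the
partner KT is displaced toward the opposite pole between the two jumps
(transient bi-orientation subtype).

Sister separations: M II dyads start at 300 ± 160 nm at NEBD II, rise
MT-independently to ~420 nm within 5 min, then to a bi-oriented plateau
of 950 ± 100 nm as each dyad settles. Interkinesis dots rest at ~100 nm
with breathing events injected as a Poisson process (0.17 events per dot
per hour; durations 20-40 s with a 15% minority up to 3 min; amplitudes
0.7-1.0 times the 550 nm maximum). Univalent classes are assigned
multinomially (30/38/32%): class I univalents stretch to ~330 nm during
the metaphase-like period and split conspicuously (0.8-1.3 um) at or
shortly after the inferred metaphase-to-anaphase transition (telophase
onset minus 10 min); class III univalents depart poleward 3-8 min before
it; class II stay unresolved at the plate.

### Cyst structure and variance decomposition

Cells of a cyst progress almost synchronously. Phase durations are drawn
per cyst and per cell with a 30% / 70% split of the configured variance
between a cyst-shared and a per-cell component, so that per-cell
dispersions match the published standard deviations while cells within a
cyst remain correlated; each cell additionally receives a clock offset
(s.d. `cyst_jitter_min`, default 1.5 min, clamped at twice the s.d.).
With `cyst_jitter_min = 0` both the offsets and the per-cell duration
components vanish and all cells of a cyst share identical boundaries.
One root seed drives everything; per-cell seeds are derived with
`child_seed()`, so runs are bit-reproducible.

## Optics and rendering

`optics_config()` defaults emulate the highest-resolution acquisition
mode: 100 x 100 x 300 nm voxels, Gaussian PSF with 120 nm lateral and
350 nm axial sigma, 2000 expected photons at a KT peak, background 100
photons, Gaussian camera noise (s.d. 5), 10 s frame interval. Each KT is
a point emitter; blobs are Gaussian because the PSF dominates
sub-resolution objects. Noise is Poisson photon noise plus additive
camera noise.

## Analysis-side choices

* **Detection**: Laplacian-of-Gaussian at the sigma implied by the 500 nm
  nominal dot diameter ($\sigma = d / 2\sqrt{3}$); threshold is the larger
  of 25% of the strongest response and 8 response standard deviations, so
  blank frames yield no detections without per-dataset tuning. Positions
  are intensity-weighted centroids (voxel-center convention, um);
  a duplicate-merge radius of half the nominal diameter removes plateau
  double-maxima.
* **Sister-separation estimation**: if two distinct maxima are resolvable
  (sub-voxel parabolic refinement), their distance is reported
  (`resolved = TRUE`). Otherwise the blob's intensity second moments are
  diagonalized in-plane; for a symmetric two-emitter model
  $\lambda_{major} = \sigma^2 + d^2/4$ and $\lambda_{minor} = \sigma^2$,
  so $d = 2\sqrt{\lambda_{major} - \lambda_{minor}}$. Using the minor axis
  as the PSF reference makes the estimate robust to pixelation and
  uniform noise, which cancel in the difference. The axial direction is
  not used (z-resolution is insufficient for sister resolution), and the
  value is an upper-bound-style estimate. Estimates below 150 nm are
  reported censored at the floor: the manual two-sphere procedure this
  automates could not have produced smaller values either.
* **Tracking**: constant-velocity prediction with a 3 um gate. Per frame,
  the assignment minimizing total predicted distance is found exactly per
  contention cluster (clusters are tiny; ties break toward lower
  indices). Sequential nearest-first greedy — the obvious alternative —
  systematically swapped pair members whenever a KT jumped nearly along
  the axis through its partner, which is why the global criterion is
  used. Gaps up to 3 frames are closed by flagged linear interpolation
  (unresolvable stretches in the source data usually lasted less than
  four time points). Two post-passes operate on the linked set: fragment
  stitching (a rapid jump can out-run the gate and restart a track) and a
  trajectory-smoothness swap repair that exchanges track tails wherever
  that lowers the summed squared acceleration in a 5-frame window.
* **Pairing**: exhaustive enumeration of all perfect matchings (105 for
  8 KTs) minimizing the summed mean intra-pair distance over the
  prometaphase-metaphase window, validated by anaphase divergence;
  a second matching within 5% of the optimum triggers an ambiguity
  warning. With simulator ground truth supplied, pairing is copied
  (evaluation mode).
* **Spindle frame**: pair vectors averaged over up to 35 metaphase frames,
  each oriented so all origins migrate to the same pole during anaphase
  (the post-anaphase displacement of each member decides); without
  anaphase information the first principal component is used and flagged
  as unoriented. The plate center is the median of per-KT mean positions —
  a mean would be dragged by pole-parked class III univalents.
* **Phase scoring**: NEBD at the steepest sustained drop of the
  nucleoplasmic proxy; the A-to-B boundary at the first KT speed above an
  adaptive threshold (3 times the 95th percentile of the cell's own
  prometaphase-A speeds, with a 0.06 um/s fallback and a 0.02 um/s floor)
  — self-calibrating across noise levels, since no absolute jump speed is
  published; metaphase onset at the first frame from which every pair
  simultaneously sits in the plate band (half-width 1.5 um) with
  $A_{KT} < 30$ degrees and $V_{KT} < 0.03$ um/s for 6 consecutive frames
  (60 s, the shortest window robust to metaphase jitter in simulations);
  anaphase onset where the per-pair sustained $D_{KT}$ step exceeds
  0.3 um, scored when the majority of pairs has started to separate;
  telophase and interphase at the two largest sustained upward steps of
  the decondensation proxy. Every boundary is either scored (tagged
  `signal` or `kinematics`) or explicitly `unscored`.
* **Zones**: the equatorial band is the published 3 um plate band (one
  quarter of the 12 um pole-to-pole distance, which itself is inferred
  from that ratio); the polar zones are the symmetric complement — the
  outer quarters of the axis. An excursion is one completed transit
  between the two zones, in either direction; leaving a zone without
  reaching the other does not count.
* **Re-orientations**: supra-threshold jump runs classified by axial
  direction; only jumps ending beyond the plate band on the side they
  head to count as poleward, so fast plate-directed returns are ignored.
  Sign-alternating consecutive poleward jumps of one KT give an event;
  events of the two co-moving members of one pair within 60 s are merged.
* **Breathing**: an event is a maximal run of at least 2 frames (about
  20 s at the 10 s cadence) with `resolved = TRUE`; the rate normalizes
  by observed dot-hours, treating the configured rate as a true per-hour
  Poisson rate (the published normalization is ambiguous between full IK
  duration and observed track length; the difference is below the
  counting noise).
* **Univalent classes**: the metaphase-to-anaphase anchor is inferred as
  telophase onset minus 10 min (configurable; classification is refused
  without a scored telophase). Class I requires plate residency (>= 60%
  of metaphase-like frames in the band) and a sustained sister split
  above 600 nm at or after the anchor; class III requires sustained
  polar-zone residency during the metaphase-like period without a split;
  class II is the remainder.

## What the simulator does and does not emulate

Emulated: phase-structured motion with the published durations and
dispersions, cyst synchrony, genotype phenomenology (checkpoint-null entry
shortening; loss of jumps with or without residual congression; univalent
shuttling, time-dependent stabilization at 25 min, class structure and
fractions; metaphase arrest), breathing statistics, the M II
sister-separation time course, acquisition geometry and counting noise.

Not emulated: photobleaching, stage drift, cyst packing geometry,
mitochondrial autofluorescence, microtubule images, chromosome-identity
information (the His2Av morphology used for manual track correction and
chromosome assignment), merotelic-attachment geometry, and anaphase B
spindle elongation. Passing recovery tests therefore demonstrates that the
analysis chain is correct and well-calibrated for data of this structure
and noise level — not that it is robust to every artifact of real
recordings. A known fundamental limit: two KT pairs jumping simultaneously
along nearly parallel paths within the association gate cannot always be
disambiguated from kinematics alone (identity accuracy on control
simulations is ~97-98% overall, >95% required, with failures concentrated
in prometaphase B); the source workflow resolved such stretches manually
using the chromatin channel.

## Numerical conventions and problem sizes

Lengths are um internally (nm for reported separations); times are
seconds on the recording clock (minutes in summaries); voxel indices are
0-based with positions at voxel centers. Phase-duration draws are
truncated at ±2.5 s.d. (and at 20% of the mean), symmetric about the
mean. Degenerate inputs error early: non-positive durations or intervals,
plate band wider than the pole distance, overlapping zones, odd track
counts, uncalibrated stacks, emitters outside the rendered volume.

The shipped tests and the acceptance script run simulations at the
published cohort sizes (13 cysts; 6, 9, 5 and 10-20 cells; 92 dots; 44
and 51 rendered blob pairs; 224 univalents in 28 cells) with trajectories
at the 10 s cadence for roughly an hour of cell time; movie rendering is
used only where detection itself is under test, at region or
reduced-volume scale. These sizes were chosen to mirror the study design
they emulate.
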