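---
title: "Methods: quantifying cardiac junctional nanodomains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cardiac junctional nanodomains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perinexus)
```

## The scientific problem

Cardiac action potentials propagate between myocytes across the
intercalated disk (ID). Beyond gap-junction (GJ) coupling, an ephaptic
mechanism has been proposed in which sodium channels concentrated in the
*perinexus* — the nanodomain ringing each GJ plaque, where apposed
membranes approach within ~30 nm — transmit depolarization through the
narrow extracellular cleft. Testing this idea requires quantitative
answers across very different modalities: where sodium-channel protein
clusters sit relative to GJ plaques (single-molecule localization
microscopy), how wide the perinexal cleft is (electron microscopy), how
strongly cells adhere (impedance sensing), and what happens to conduction
when perinexal adhesion is disturbed (optical mapping, ECG).

`perinexus` implements each of those quantitative analyses, paired with a
seeded synthetic-data generator per modality. The generators store their
ground truth, so every analysis can be validated by parameter recovery —
which is what the test suite and `scripts/acceptance.R` do.

## Relative localization analysis (two-channel 3D localization data)

**Model.** Localization microscopy yields coordinate lists, not images.
Reference-channel clusters (GJ plaques, e.g. connexin43) are detected,
partner-channel clusters (e.g. the sodium channel pore subunit or its
adhesion subunit) are detected independently, and each partner cluster is
classified by its signed edge-to-edge distance to the nearest reference
cluster: *overlapping* (negative distance), *adjacent* (0–200 nm, the
perinexal zone measured from the GJ cluster edge), or *distant* (> 200
nm).

**Steps and parameters.**

* *Registration.* Channels are aligned with a least-squares rigid
  transform (Kabsch/SVD) estimated from fiducial beads paired by mutual
  nearest neighbour within a 500 nm gate. Fewer than three usable pairs,
  or collinear fiducials, are hard errors — a rotation cannot be
  identified from a line of beads.
* *Cluster detection.* Density-based clustering (DBSCAN; compiled
  grid-indexed implementation in `src/`): a point with at least
  `min_points = 5` neighbours within `radius_nm = 30` is a core point;
  clusters are connected components of core points plus borders; clusters
  below `min_cluster_size = 10` are discarded. The 30 nm radius sits near
  three times the 10 nm localization precision; all three are exposed.
* *Voxelization.* Cluster volume and surface come from an axis-aligned,
  origin-anchored voxel grid (`voxel_nm = 20`): a voxel is occupied when
  its center lies within `dilation_nm` of a member point (default: the
  table's median localization precision), with the containing voxels as a
  fallback so occupancy is never empty. Origin anchoring makes grids of
  different clusters commensurable, so overlap is a plain key
  intersection.
* *Signed distance.* Disjoint clusters: minimum distance between surface
  voxel centers (positive). Overlapping clusters: minus the maximum depth
  of any shared voxel inside the reference occupancy (depth = distance to
  the nearest reference surface voxel center plus half a voxel, a
  discrete distance transform), so fully engulfed clusters report minus
  the reference inradius. Ties between equidistant reference clusters go
  to the lower cluster id and are counted.

**Numerical error of the voxel geometry.** The center-marking occupancy
rule leaves each cluster surface ambiguous by up to half a voxel diagonal
(the extreme point may sit just beyond the last qualifying center), so an
edge-to-edge distance carries up to one voxel diagonal of discretization
error overall. The tests assert exactly that bound against a brute-force
pairwise-minimum oracle, using `dilation_nm` at least half the voxel
diagonal so every point is guaranteed to mark a voxel. For volume
anchors (a densely sampled 100 nm sphere at 10 nm voxels) the same rule
recovers the analytic volume to a few percent, which an
"any-voxel-touched" rule would not (it inflates thin structures by the
half-shell).

**Overlap denominator.** The fraction of *partner* volume shared is the
primary statistic; the reference-denominated fraction is reported
alongside, since the field's "degree of overlap" is used both ways. No
quantitative "tangential overlap" subclass is invented — the full
overlap-fraction distribution is returned instead.

**Generator.** Reference clusters are uniformly filled oriented disks
(radius 100–180 nm by default, thickness 40 nm — plaque-like geometry);
partner clusters are ellipsoids planted along a random in-plane direction
at a controlled hull-to-hull distance, so each has an exact class label.
Molecule counts scale with cluster volume (defaults 2×10^5 and
1.3×10^5 molecules/µm³), keeping local density — and hence detectability
at the 30 nm clustering radius — size-independent. Localization noise is
anisotropic Gaussian (σ 10 nm lateral, 25 nm axial); background is
uniform Poisson (0.5 /µm³); an optional rigid misregistration is applied
to the partner channel and its fiducials. Planted edge distances are
drawn away from the 0 and 200 nm class boundaries (overlapping
U[−120,−30], adjacent U[60,140], distant U[280,600] nm): voxel dilation
inflates both hulls by ~2× the dilation and noise spreads extreme points
by a further ~2σ, so distances within ~60 nm of a boundary have genuinely
ambiguous labels and are not meaningful recovery targets. What the
generator does *not* emulate: blinking photophysics, repeated
localizations of single fluorophores, drift, and irregular plaque shapes
— so passing recovery tests demonstrates the geometry pipeline, not
robustness to photophysical artifacts.

## Conduction analysis (optical mapping)

**Model.** Activation time at each pixel is the time of the maximum
first derivative of the optical action potential. The discrete derivative
peak is refined to sub-frame precision by parabolic interpolation of the
three samples around it — at 1000 frames/s, frame quantization would
otherwise dominate velocity error at physiological speeds. Pixels whose
derivative peak-to-noise ratio (peak over the MAD of the derivative)
falls below `snr_min = 5` are masked; a flat trace is always masked.

**Velocity.** The velocity vector is v = g/|g|² with g the activation
surface gradient (ms/mm). Two surface estimates are provided:

* `method = "local"` (default): a quadratic fitted in a 7×7-pixel window
  around each pixel, gradient evaluated at the center. This tracks the
  curved isochrones of point-paced waves.
* `method = "global"`: a single six-coefficient parabolic surface fitted
  to all valid pixels (`fit_parabolic_surface()`), retained for
  comparison and for smooth, broadly planar maps.

The local mode is the default because a global quadratic cannot represent
a point-source wave: along a ray from the pacing site the elliptical-wave
surface is conical (T ∝ r), a quadratic fit gives T ≈ αr² + β, and its
gradient 2αr implies speed 1/(2αr) — hyperbolically varying where the
true speed is constant. A windowed quadratic has no such structural bias;
its residual bias is third-order in the window size over the distance to
the pacing site, which also fixes the remaining defaults: windows of 9+
pixels visibly bias the recovered fast axis on curved isochrones, and
pixels within `2 × window_px` of the pacing site (where curvature is
strongest) are excluded from velocity summaries, alongside a gradient
floor that masks the singularity itself.

**CV_L, CV_T, anisotropy.** The fast axis is found by a 1° angular scan:
for each candidate axis, the mean speed of vectors whose *direction* lies
within ±15° (mod 180°) of it; the argmax is refined parabolically. CV_L
is the wedge mean at the fast axis, CV_T at its perpendicular, AR their
ratio. Two properties of this estimator are worth knowing. First, on a
truly elliptical wave the ±15° wedge admits off-axis vectors that are
slower than CV_L near the fast axis and faster than CV_T near the slow
axis, giving a small intrinsic compression of AR (a few percent at AR
2.5) — visible in the recovery tests, which still pass at the 5%
tolerance. Second, the scan curve is flat near its peak, so under
measurement noise the axis estimate scatters several degrees even when
CV_L and CV_T are stable; the acceptance checks therefore anchor the
axis on noiseless movies, while noisy movies are used for the
activation-time recovery checks.

**APD.** Duration from activation to the first crossing of
peak − level×amplitude after the peak (linear interpolation), amplitude
measured against the pre-activation median. The default level 0.8
(APD80) is a convention choice, exposed as a parameter; `level = 0`
either errors or returns the full-trace duration, per an explicit flag.

**Generator.** A kinematic wave: activation time
t(p) = t0 + sqrt((u/CV_L)² + (v/CV_T)²) in the rotated fiber frame,
sigmoidal upstroke, plateau, exponential repolarization, Gaussian noise.
No ionic model, no motion artifact, no optical blurring: tests against it
validate the extraction chain, not robustness to contraction artifacts
(experimentally suppressed by mechanical stabilization and excitation-
contraction uncouplers).

## Junctional resistance (impedance series)

The junctional quantity is deliberately simple, matching practice: at
each time point, the unweighted mean over in-band frequencies
(62.5–4000 Hz inclusive) of the real impedance. No equivalent-circuit
inversion is attempted — the band-averaged real component *is* the
reported quantity. Downstream summaries: baseline normalization (trace
over baseline-window mean), attachment kinetics (R(t0+24 h) − R(t0),
nearest-sample lookup) and dose–response tables (per-dose mean ± SE over
replicates; SE reported as missing for single replicates). The generator
builds Re Z(f,t) = R_electrode(f) + R_junction(t)·g(f) with g ≡ 1 on the
band by construction and a capacitive imaginary part; the default grid is
62.5×2^(0:10) Hz every 90 s for 3 h (121 time points). Band-averaging
suppresses measurement noise by 1/sqrt(n_freq); with the default grid
seven frequencies fall in band. Note the 3σ/sqrt(n_freq) bound on the
*maximum* error over 121 time points is a ~3-sigma event bound, not a
guarantee — over many seeds a few percent of series will graze it.

## Inter-membrane width profiles (electron microscopy traces)

Membrane A is sampled at fixed arc-length steps (5 nm) from the
GJ-edge anchor (s = 0); the width at s is the minimum point-to-segment
distance to membrane B. Samples where the foot of the projection falls
strictly beyond an end of B are masked with a warning — B does not span
opposite A there. Zones: s = 0 is the edge itself, 0 < s ≤ 150 nm is
perinexal, beyond is non-junctional; both bounds are parameters. The
nearest-point metric is robust to local curvature but has two knowable
biases: for steeply diverging membranes it reads d·cos(arctan d′) rather
than d (the perpendicular foot is upstream), and under digitization
jitter the minimum over many segments sits ~2σ below the true
separation. A `normal_projection` option measures along the local normal
of A instead, which is unbiased for diverging membranes and is what the
linear-ramp recovery test uses. Summaries pool hierarchically — profile
means, then heart means, then condition mean ± SE across hearts — because
the reporting unit in this field is the heart, not the image.

## ECG beats, intervals and tachycardia

Beats are peaks of the rectified, running-median-detrended trace
(minimum prominence 0.4 of the largest deflection, 60 ms refractory);
peaks within ±10 ms of a pacing stimulus are flagged paced. Ventricular
tachycardia follows an explicit rule: a maximal run of at least three
consecutive non-paced beats in which *every* inter-beat interval is
shorter than 130 ms. The every-interval reading is the default; a mean
cycle-length mode is provided because the rule's boundary is genuinely
ambiguous. Episode minimum-duration filtering is a reporting option, not
part of detection. The detector is tested for exact agreement with an
exhaustive enumeration of qualifying windows over a thousand random
beat/flag sequences.

QRS duration uses outermost derivative-threshold crossings (10% of the
window's maximum |dV/dt|, quiet gaps under 5 ms bridged) around the R
peak, after 5 ms moving-average smoothing — without smoothing, white
noise of a few percent of the QRS amplitude exceeds the 10% derivative
threshold everywhere. QT runs from QRS onset to the T-wave end located
by the tangent method (steepest T-downslope tangent intersected with the
isoelectric baseline, estimated from the pre-QRS median); an
unidentifiable T wave yields a masked QT with a warning, not an error.
The generator's complexes are raised-cosine QRS waves (sharply defined
onset/offset of known width) and half-sine T waves whose geometric end
the tangent method recovers exactly in the noiseless limit.

## Reproducibility and the pipeline

Every generator derives its RNG stream from a global seed and a
per-modality label (`substream_seed()`), so adding one generator to a
pipeline never perturbs another's draws, and identical config + seed is
byte-identical output. `run_stage()` validates configs against known
keys (typos are errors), writes every output plus a manifest (stage,
seed, package version, config echo and md5) sufficient to re-run the
stage bit-identically; `run_pipeline()` chains a generator stage with its
analysis stage. Stage determinism is asserted at file-hash level in the
tests.

## Problem sizes

The recovery checks run at sizes chosen to exercise the estimators well
inside their operating range while keeping the suite quick: the
relative-localization scene plants 300 reference + 300 partner clusters
(~250k localizations) in a 47×47×3 µm field; optical movies are 80×80
pixels at 1000 frames/s; impedance series use the full 121-point, 3-hour
grid; width profiles use 300–400 nm traces at 2 nm digitization; the VT
oracle covers 1000 random sequences.

## Known limitations

* The generators are statistical stand-ins: no photophysics, no ionic
  electrophysiology, no instrument transfer functions. Recovery on them
  validates the estimators' geometry and logic, not immunity to every
  experimental artifact.
* Voxel geometry carries one-voxel-diagonal distance ambiguity and
  inflates thin-lens overlaps by their half-shell; both are quantified in
  the tests rather than hidden.
* The ±15° wedge-mean CV estimator slightly compresses high anisotropy
  ratios and its axis estimate is noise-sensitive (flat scan peak).
* The QT tangent method assumes a monophasic T wave returning to a
  stable baseline.
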