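---
title: "Morphometry of the IHC/ANF synaptic region: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry of the IHC/ANF synaptic region: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`anfmorph` quantifies the synaptic pole of cochlear inner hair cells
(IHCs) from segmented volume-EM label stacks: which auditory-nerve fibers
(ANFs) still make a ribbon synapse after noise exposure, how far
non-synaptic terminals have retracted, how mitochondrial content is
distributed along each fiber, and how much efferent (lateral
olivocochlear) innervation each fiber receives. This vignette explains
the measurement models, the tunable parameters, the synthetic phantom
that stands in for unreleased EM volumes, and the numerical choices and
limitations a careful user should know about.

## The substrate: anisotropic label volumes

The input is a 3D integer label lattice `[row, col, slice]` with a voxel
geometry (defaults 5 nm in-plane, 20 nm slice thickness — the common
FIB-SEM acquisition geometry — giving 500 nm^3 voxels) and a label table
assigning every non-zero id to a class (IHC, ANF, MITO, RIBBON, EFFERENT)
and, for mitochondria, a parent fiber. Slice index increases toward the
IHC apex; all reported coordinates are 0-based and all distances are
physical nanometres under anisotropic scaling. I/O goes through
multi-page TIFF (via the `tiff` package) or a minimal NRRD reader/writer,
with a JSON sidecar for geometry, label table and the modiolar/pillar
dividing plane.

Mitochondrion instances arrive pre-assigned to parent fibers in the
label table (segmentation models for these data are trained on
mitochondria within ANFs, so the assignment is part of the input). For
tables lacking parents, a majority face-adjacency fallback can be
computed, flagged in the output.

### Perimeter and circularity

Per-slice 2D profiles (8-connected components) report two distinct
boundary measures, and the distinction matters:

* `perimeter_nm` is the exact crack (voxel-edge) contour length — the
  natural exact measure for a digital region (a single voxel has
  perimeter 4 x 5 nm = 20 nm).
* `circularity` is the normalized isoperimetric index 4&pi;A/P^2
  computed with a **Crofton 4-direction perimeter estimate**, capped
  at 1.

The crack perimeter cannot be used inside the circularity index: for any
digital region the crack-contour index is bounded above by &pi;/4 =
0.785, and a perfectly circular disc scores &pi;^2/16 = 0.617 — an
estimator under which the standard "reject profiles below 0.8" rule
would reject everything, including perfect cross-sections. The Crofton
estimator is asymptotically correct for smooth shapes (a digitized disc
of radius 30 px scores 0.98), which is what makes the 0.8 threshold
scientifically meaningful; it was validated numerically against an
independent implementation of the same estimator on identical masks.
Tiny profiles (a few voxels) overshoot 1 through discretization, hence
the cap, mirroring common practice in 2D particle analysis.

## Fiber-wise mitochondrial profiling

`build_fiber_series()` measures, per occupied slice, the fiber's
outer-contour area and circularity (2D holes filled, so organelle labels
carved out of the fiber still count toward its cross-section) and the
per-instance mitochondrial profile areas and counts.

The longitudinal analysis divides each fiber at 200 acquisition slices
(4 um at 20-nm sections) from its terminus: the distal part is the
*terminal region*, the rest *pre-terminal*. "Distalmost" is counted in
acquisition slices, not arc length, so obliquely running fibers have
terminal regions shorter than 4 um of path — this matches how such data
are analyzed in practice and is recorded in output metadata. Fibers
spanning fewer than 200 slices are entirely terminal and flagged
truncated. Within the terminal region the *mito-peak* is the contiguous
50-slice window with the highest mean mitochondrial cross-sectional
area; ties break toward the terminus (terminal swellings concentrate
mitochondria, so a tie should resolve distally), and the window's middle
slice is the peak center used to align profiles across fibers
(`peak_aligned_profile()`).

Pre-terminal slices whose fiber circularity falls below 0.8 are flagged
and excluded from area statistics ("stretched" profiles where the fiber
runs parallel to the section plane); terminal slices are never filtered,
since terminal swellings are legitimately non-circular. The filter
applies only to fiber-area statistics and mitochondrial attribution in
the pre-terminal region.

`mito_profile_stats()` samples every 10th occupied slice (the stride is
a parameter) and reports the cohort mean number of mitochondrial
profiles per section and the mean single-profile area. Profile areas are
reported in nm^2; group comparisons should use the unit-free ratio
(percent change), which is independent of the area unit.

## Ribbons, synapses and fiber classification

Presynaptic ribbons are 3D connected components (26-connectivity) of the
RIBBON-class mask. Each record carries the voxel-count volume, the
extent of the voxel centers along the first principal axis (the "length"
— a rotation-stable reading of the ribbon's long axis; Feret diameter
would be noisier on thin voxelized solids), and a hollow-core flag set
when the instance encloses a background cavity under 6-connected
background flooding (the electron-lucent core some ribbons show).

`link_synapses()` pairs each ribbon with the nearest fiber **apposition
zone** — ANF voxels face-adjacent to an IHC — within the 200-nm pairing
radius, and groups ribbons sharing a fiber–IHC apposition into one
synapse. Pairing against apposed voxels rather than any fiber voxel is
what the biology dictates (a synapse lives at the contact) and is also
what keeps pairing unambiguous when terminals pack at sub-micron
spacing. Equidistant candidates break deterministically toward the lower
fiber id, logged. When PSD annotations are supplied, a fiber counts as
synaptic only if a post-synaptic density was annotated for it; without
annotations, ribbon apposition alone suffices and the mode is visible as
`psd_present = NA`.

Fiber classification is a three-way partition asserted on every report:

* **synaptic** — owns at least one synapse;
* **non-synaptic contact** — membrane face-apposed to an IHC over at
  least 5 consecutive slices (the only persistence criterion stated for
  these data is the efferent five-slice rule, so contact borrows it; the
  run length is a parameter);
* **non-synaptic retracted** — neither, with the distance to the nearest
  IHC measured surface-to-surface from the fiber's terminal 4-um
  segment (pre-terminal portions legitimately pass near IHCs and are
  excluded).

Orphan ribbons are those with no fiber surface within 500 nm. The
pairing radius (200 nm) and orphan radius (500 nm) are package defaults
— the source data do not pin them — and both are surfaced in
`analysis_params()`.

Ribbon-centric virtual re-sectioning (`build_section_frame()`,
`resection()`) fits a least-squares plane to the IHC surface voxels
within 500 nm of the ribbon centroid, orients the normal away from the
IHC interior, projects the ribbon's principal axis onto the membrane
plane, and resamples the lattice (nearest neighbour) in the cross,
longitudinal or membrane-parallel plane. Near-spherical ribbons fall
back to their second principal axis and are flagged.

## Efferent synapse scoring

Lateral olivocochlear contacts are scored from per-slice annotation
tables — apposition and thickening are grayscale judgements and arrive
as flags, vesicles as point coordinates, and the membrane as a traced
polyline. A slice qualifies when the membranes are apposed, at least 5
vesicle centers lie within two vesicle diameters (2 x 35 nm by default;
the criterion is expressed in vesicle-diameter units so the default
cancels) of the trace, and thickening is annotated; maximal runs of at
least 5 consecutive qualifying slices become plaques. Overlapping runs
are merged, so a slice belongs to at most one plaque of a contact.

Plaque surface area is the serial-trace length times the slice
thickness — a ruled surface between sections, the simplest estimator
consistent with a one-pixel-wide membrane trace. The estimator lives in
one function (`plaque_area()`) and is straightforward to swap. Vesicle
"clustering" is a per-slice count within the distance limit; no
clustering algorithm is applied, because the criterion is stated
per-slice, not algorithmically.

## Spatial classification and statistics

Modiolar/pillar assignment is the sign of the distance to a dividing
plane: a single plane per stack (the convention of confocal analyses) or
one plane per IHC (`assign_side_per_ihc()`; IHC poles are often
staggered, and the two definitions can disagree on borderline fibers).
Locations exactly on the plane go modiolar by convention, logged. A
fiber's location is its synapse centroid, or its closest IHC approach
when non-synaptic.

Group comparisons use the Mann-Whitney test for two groups and
Kruskal-Wallis followed by Dunn's multiple-comparisons test for more
(`compare_groups()`); the 0.05 threshold is reported, never enforced.
Dunn's test is implemented in the package (mid-rank z statistics with
tie correction); no adjustment family is standard-by-name for it, so the
pairwise p-values are Bonferroni-adjusted, and that choice is recorded in
the output. Mann-Whitney p-values are exact for small tie-free samples
(verified in the tests against full enumeration over rank assignments)
and use the normal approximation with continuity and tie correction
otherwise. Percentages use half-up integer rounding throughout
(`fraction_report()`, `percent_change()`); note that published tables
occasionally round inconsistently, so a reproduced percentage can differ
by one point from a printed one (37/59 is 62.71% — 63 under half-up).

Stack reports assert three identities on every run: synaptic +
non-synaptic = total fibers; contact + retracted = non-synaptic; the
ribbon-multiplicity histogram sums to the synapse count. Synapse counts
are also normalized to a 20-um cochlear span for comparison across
stacks of slightly different extent.

## The synthetic phantom

No EM volumes of this kind are publicly deposited, so the package ships
a generator (`generate_phantom()`) whose presets emulate the three study
conditions. The planted quantities are the *printed counts* of those
conditions, apportioned exactly (largest remainder), never sampled:

* control: 71/75 fibers synaptic (stacks of 33 and 41 fibers; the
  default preset uses 41), 69 single / 2 double ribbons, half of the
  non-synaptic fibers in contact;
* 1 day: 59 fibers, 37 non-synaptic (21 in contact), synapse
  multiplicity 15/5/2, one orphan ribbon, +51.2% mitochondrial profile
  count and +15% profile area versus control, efferent plaques of mean
  0.666 um^2 at 3.98 per fiber;
* 1 week: 59 fibers, 31 non-synaptic (15 in contact), multiplicity
  19/8/1, mitochondrial and efferent content back at control values
  (0.496 um^2, 3.78 per fiber).

Retraction gaps are planted at deterministic normal quantiles around
2.1 um so the planted mean is exact. Sides are planted balanced against
a recorded dividing plane, with modiolar fibers mitochondrion-poorer and
efferent-poorer than pillar fibers, as in control ears.

Geometrically, each phantom renders two IHC basal poles as hemispheres
protruding from the top of the stack and each ANF as a tube rising from
the habenular face, curved by a smooth lateral drift field shared by all
fibers (so curvature never drives two tubes into each other).
Attachment sites come from a sunflower spiral on the basal cap thinned
to a minimum 3D separation larger than two swollen terminal radii.
Synaptic and contact terminals embed vertically into the hemisphere so
that the membrane apposition persists over many slices; retracted
terminals stop where their surface-to-surface distance to the hemisphere
equals the planted gap. Ribbons are flattened elliptical cylinders just
inside the membrane at the middle of the apposed patch, side-by-side for
multi-ribbon synapses with gaps that can never merge under
26-connectivity; a fraction carry a carved-out core, recorded as hollow
only when the cavity is verifiably enclosed at the phantom resolution.
Efferent plaques are planted as straight serial traces of exactly known
area (real-valued vertex coordinates), with vesicle clouds inside the
criterion distance, plus deliberate sub-threshold contacts (four-slice
runs) that a correct scorer must reject.

Three phantom choices deserve explicit notice:

* **Lattice.** The default lattice is 512 x 512 x 400 voxels at
  (40, 40, 20) nm — the slice thickness and ~20-um span of the real
  stacks, with the in-plane pitch coarsened 8x so that a full stack
  generates and analyzes in seconds; the geometry is configurable up to
  the native 5-nm pitch.
* **Mitochondrial densities.** Mitochondria are placed on six
  non-overlapping radial lanes per fiber (interval-scheduled along z),
  with the mito-peak planted as 2–3 elongated cylindrical mitochondria
  spanning exactly the 50-slice window — their constant cross-section
  gives the planted peak sharp edges, so the best-window search is
  pinned to the recorded center. Non-overlapping packing caps the
  per-slice profile count at about 6, so the absolute planted densities
  sit ~20% below the real-data means (control cohort ~1.7 profiles per
  slice); the group *ratios* (+51.2% count, +15% area), which are what
  the recovery tests measure, are preserved exactly.
* **Ribbon sizes.** Per-group ribbon length/volume distributions are not
  numerically published; the presets use plausible ranges (broadened
  after exposure at 1 day) and are clearly non-source values.

What passing phantom tests do and do not show: they demonstrate that the
pipeline recovers planted classifications, multiplicities, peak
positions, areas and effect sizes exactly or within stated tolerances on
clean, watertight label masks. Real segmentations add boundary noise
beyond the phantom's radius jitter, touching or split instances,
oblique terminals, and annotation disagreement — the phantom
deliberately does not model proofreading errors, so recovery rates on
real data will be bounded by segmentation quality, not by the pipeline.

## Numerical choices and degenerate inputs

* In-plane connectivity is 8 for 2D profiles and 26 for 3D instances
  (background flooding uses the complementary 4/6 connectivity), the
  combination that keeps thin EM structures visually continuous.
* Peak-window ties resolve toward the terminus; equidistant ribbon
  pairings resolve toward the lower fiber id; on-plane locations
  resolve modiolar. All three are logged.
* An empty trace list yields plaque area 0 with a warning; fibers
  without plaques report zero totals and an absent mean; a report with
  an empty exposed group skips comparisons with a notice.
* Synapses with more than three ribbons raise a validation warning, not
  an error (three is the observed maximum).
* Re-sections extending beyond the lattice are padded with background
  and flagged.

## Problem sizes in the tests

The unit tests exercise constructed micro-volumes (up to 64^3) against
brute-force flood-fill and enumeration oracles, plus a reduced
one-IHC/8-fiber phantom at 256 x 256 x 400. The acceptance suite runs
the three condition presets at the full default lattice for seeds 1–20
each (60 stacks), recovering every planted classification, multiplicity
histogram, orphan count and mito-peak center, and the pooled
mitochondrial effect sizes within +-5 percentage points. The statistical
calibration check runs 2000 null replicates of the two-group test.

## Known limitations

* Terminal regions are counted in acquisition slices, not arc length;
  no skeletonization/centerline parameterization is provided.
* Vesicle-halo quantification at afferent synapses and PSD thickness are
  out of scope (qualitative in the source data).
* The efferent area estimator ignores in-plane membrane tilt between
  sections; for strongly tilted plaques it underestimates area (the
  estimator is pluggable).
* The phantom plants one synapse per synaptic fiber; branched fibers
  and double synapses onto one IHC (rare in control data) are analyzed
  correctly if present in real labels but are not generated.
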