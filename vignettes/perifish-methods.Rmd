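---
title: "Methods: the %DAPI coordinate system, molecule classification and enrichment statistics"
author: "periFISH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the %DAPI coordinate system, molecule classification and enrichment statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periFISH)
```

## Scope and model

periFISH quantifies where single mRNA molecules sit relative to the
nuclear border of trypanosome cells, using three coupled measurement
procedures plus two supporting statistical modules:

1. a **%DAPI coordinate system**: a position is expressed as the percent
   of the peak DAPI intensity along a profile running from the cytoplasm
   (0%) over the nuclear rim (100%) towards the DAPI-dark nucleolus;
2. **smFISH molecule analysis**: diffraction-limited spots from up to
   three probe colours (5' = red, internal = infrared, 3' = green) are
   detected, grouped into molecules, classified by colour combination
   (intact, 5' part, 3' part, read-through, single probe) and by
   location (nucleus / nuclear periphery / cytoplasm), and scored for
   5'-first export orientation;
3. an **S0-moderated Welch test with permutation FDR** for label-free
   nuclear proteome enrichment, with missing-not-at-random imputation;
4. **Q-rich window scanning** (60-mers with at least seven glutamines)
   and **reciprocal-best-hit homology classification** for the
   sequence-level characterisation of enriched proteins.

Because the original microscope images and proteome are not required,
every procedure is exercised against a synthetic-data module with exact
ground truth. The simulator is a first-class, tested component, not a
fixture.

## The synthetic cell and its forward model

The cell is an ellipsoid (semi-axes 1.7 x 2.6 x 2.6 um) containing an
ellipsoidal nucleus (1.0 x 1.2 x 1.2 um, i.e. ~2.5 um diameter as in
procyclic trypanosomes) with a DAPI-dark spherical nucleolus (radius
0.4 um) at its centre. The DAPI channel follows a logistic edge in the
normalised ellipsoid coordinate $u$ ($u = 1$ on the nuclear surface):

$$ s(u) = \frac{1}{1 + e^{(u-1)/w}}, $$

with edge width $w = 0.10$ (about 0.12 um physically). On the
cytoplasmic flank of any profile the normalised %DAPI therefore equals
$100\,s(u)$ in closed form, which gives the package an analytic oracle:
the generator places molecules by inverting this relation, and the
measurement side must recover the same classes from rendered voxels.
The pore-ring marker is a Gaussian shell peaked at $u = 1$ (so the
analytic border sits at 50 %DAPI by construction), and the cytoplasmic
marker fills the cell minus the nucleus.

Probe spots render as 3D Gaussians at the PSF sigma (0.4 um axial,
0.2 um lateral at a 100-nm voxel pitch), discretely normalised so an
isolated spot integrates exactly to the photon budget (default 20,000
counts). Noise is Poisson on signal plus background by default; a
Gaussian mode exists for variance-controlled tests and `"none"` gives
the exact forward model. All of these widths sit at or above the voxel
pitch deliberately: a structure narrower than a voxel aliases on the
grid and interpolated border estimates pick up half-voxel artefacts, so
sub-voxel edge widths are not meaningful acquisition settings for this
model.

Placement rules make the ground truth consistent with the band
classifier that will be applied downstream: cytoplasmic molecules keep
all probes below 8 %DAPI (analytically), nuclear molecules above 70%,
and periphery molecules put at least one probe inside the 10-66.6%
band, which with these widths is also within one lateral PSF sigma of
the geometric surface. Periphery molecules carrying both the 5' and the
internal probe are built radially: with probability
`orientation_fraction` (a Bernoulli draw per molecule) the 5' probe
sits outside the internal one — the geometry expected if the 5' end
leads export. Probes of one molecule stay within the 0.5-um compaction
limit observed for single mRNAs, far below the 7.5-um extended length
of the 22,197-nt reporter (`mrna_contour_length(22197)`).

Two packing constraints protect the measurement stages: probes of
different molecules stay at least 0.7 um apart (pairing radius 0.5 um
plus margin, so grouping cannot bridge molecules), and same-colour
probes stay at least 3 PSF-normalised sigma apart so rendered spots
remain optically resolvable. The second constraint can be disabled
(`resolve_sigma = 0`) for dense scenes consumed as ground truth without
imaging, e.g. the orientation studies.

What the simulator does **not** emulate: deconvolution artefacts,
chromatic shift, uneven illumination, autofluorescence, clustered
transcription sites, or cell-to-cell variation in DAPI brightness.
Passing tests therefore demonstrate the correctness of the estimators
under a known forward model, not robustness to every real-world
nuisance.

## Profiles and the nuclear border

`extract_profile()` samples channels by linear interpolation at evenly
spaced arc positions (default step: half the smallest voxel dimension;
0.05 um in the calibration studies). `normalize_profile()` rescales each
channel affinely to 0-100 with a robust minimum (1st percentile) by
default; the %DAPI read-out is invariant under positive affine
transforms of the raw intensities, and normalising twice is the
identity. A `dapi_coordinate` carries an explicit side flag
(cytoplasmic vs nucleolar flank) because a bare percentage is ambiguous
— all classification rules operate on the cytoplasmic flank, where the
10-66.6% band and the 33.3% reference cut are meaningful.

Two border calibrations are implemented. The **pore-marker method**
takes the marker argmax along each profile (ties resolve to the sample
nearest the cytoplasmic end; a parabolic sub-sample refinement damps
grid aliasing of the narrow ring) and reports the %DAPI there. The
**intersection method** normalises marker and DAPI to 0-100 and takes
the first transversal sign change of their difference from the
cytoplasmic end, located by linear interpolation; tangency and identical
curves are rejected as non-transversal. Per-nucleus profile sets use
four orthogonal in-plane rays from outside the nucleus towards the
DAPI-weighted centroid (the original analysis drew four profiles per
nucleus by hand; the angular placement was not reported, so equally
spaced rays are the default and the count is configurable).

Both calibration methods run on the **focus plane** (maximum-variance z
plane, lowest index on ties). Using a max projection instead is
supported but inappropriate for the intersection method in this
geometry: cytoplasm above and below the nucleus projects into the
nuclear footprint, the marker curve never falls, and the crossing
degenerates towards ~100 %DAPI. This is a deliberate deviation from an
earlier design sketch that put all non-ring profiles on projections.

Per-spot %DAPI measurements, by contrast, run on the max projection
(matching how the images were scored), with the ray built from the
stack border through the spot towards the DAPI centroid. Spots whose
ray cannot be constructed are flagged and their molecules excluded from
tallies rather than guessed.

## Spot detection, grouping and classification

Detection finds 3D local maxima above median + k*MAD (k = 5) on a
lightly smoothed copy of the channel (Gaussian, sigma = 1 voxel — the
matched-filter step; without it a Poisson background of ~10 counts
yields order-one false maxima per channel across ~10^5 voxels), merges
candidates within one PSF, and refines each peak by least-squares
fitting of a 3D Gaussian to the raw patch, giving sub-voxel positions
(~0.01 um error noise-free, well under one voxel RMS under Poisson
noise).

Grouping repeatedly merges the closest admissible cluster pair, where
admissible means no shared channel and complete linkage at most the
0.5-um pairing radius. The globally closest admissible pair is always a
mutual nearest-neighbour pair, so this is order-independent MNN linking
with a hard cap. It is a *local* linker, not a global assignment
optimiser: adversarial cross patterns exist where a globally optimal
matching links more pairs. In the regime the data come from — molecules
compact within the cap and separated by more than it — the optimum is
unique and the two coincide, which is what the exhaustive-enumeration
oracle test checks.

Species follow the colour-combination rules (three segments of one gene
= intact; 5'+internal = 5' part; internal+3' = 3' part; any combination
spanning two gene ids = read-through; one channel = single probe).
Location uses the band rule: any signal inside 10-66.6 %DAPI (edges
inclusive — the source text does not state inclusivity, so it is
configurable) makes the molecule peripheral; all signals below 10% on
the cytoplasmic flank make it cytoplasmic; everything else, including
nucleolar-flank signals, is nuclear. The cytoplasm/nucleus split
outside the band is our decision: the only hard rule the source states
is the periphery band, while the 33.3% cut is probabilistic and is
reported as a calibration statistic, not used as a classifier.

Orientation analysis considers molecules with both a 5' and an internal
signal whose connecting segment intersects the nucleus mask (projected
DAPI at half maximum; the original criterion — a line intersecting the
nucleus — was visual, and the mask test is our formalisation). Among
eligible molecules it reports the fraction with the 5' signal at lower
%DAPI, i.e. further out. With zero eligible molecules the fraction is
reported as undefined, never as 0. Because analysis runs on
projections, a 5' end looping behind the nucleus in z can masquerade as
3'-to-5' orientation in real data; the simulator places periphery
molecules near the equatorial plane, so this projection artefact is
deliberately absent from the validation suite.

## Enrichment statistics

The LFQ pipeline mirrors the standard nuclear-proteome workflow:
remove reverse/contaminant/only-by-site rows; keep proteins with at
least 2 of 3 replicates quantified *in at least one condition* (the
source phrase is ambiguous between "per condition" and "overall"; the
one-condition reading retains on/off proteins, which the biology
requires — granule components absent without drug treatment; the
per-condition variant is available); log2 transform; impute missing
values per sample column from a normal with width 0.3 and downshift 1.8
column sds (per-column rather than global imputation follows the
conventional use of those parameters); then the moderated test

$$ d = \frac{\bar{x}_2 - \bar{x}_1}{se_{\text{Welch}} + s_0}, \qquad s_0 = 0.5 .$$

The null distribution comes from 250 random balanced relabellings of
the six sample columns, sampled with replacement from the C(6,3) = 20
balanced splits *minus the observed labelling and its mirror*: with
only 20 splits, keeping the identity imposes a hard floor of 2/20 = 10%
on the estimated FDR whenever real effects exist, making a 5% target
unreachable. An exact-enumeration mode (all 18 informative splits) is
provided for deterministic tests. The estimated FDR at a cutoff is the
mean (optionally median) permutation exceedance count over the observed
exceedance count; the significance frontier is the smallest observed
|d| where it drops to the target, two-sided and symmetric. With
$s_0 = 0$ the statistic reduces exactly to the Welch t (tested to
1e-10 against `t.test`).

Power at triplicate depth deserves honesty: with n = 3 per group a
planted log2 shift equal to twice the within-group sd corresponds to a
Welch t of ~2.4, and against a 200-protein permutation null at FDR 0.05
only ~10% of such proteins are recovered. This is a property of the
design, not of the implementation; at the simulator's default effect
size (log2 = 2, the on/off-like enrichment of granule components)
recall is essentially complete at a realised FDR near the nominal
level. Both recall values are recomputed by `scripts/acceptance.R`.

## Sequence statistics

`qrich_scan()` divides a protein into consecutive non-overlapping
60-mers from residue 1 (division, not sliding; a sliding mode exists
for sensitivity analysis) and counts windows with at least seven of the
scored residue; the trailing remainder shorter than one window is not
scored, and the density is windows per 100 aa of the full length. The
scored residue is glutamine (Q) by default: the statistic is named
Q-rich and prion-like regions are glutamine-rich, although the source
legend says "glutamate" — the residue is a parameter precisely because
of that discrepancy. The frame offset is also a parameter (default 0);
whether the original scan used other frames is unstated.

`rbh_classify()` takes forward and reverse tabular hit sets per taxon:
the top hit minimises e-value, with ties broken by higher bit score and
then lexicographic subject id; a protein has a homologue in a taxon
when the reverse top hit of its forward top hit is the protein itself
and the e-value condition (e < 1e-5) holds. The legend leaves open
which hit the cutoff applies to; the default applies it to the reverse
hit per the literal sentence, with forward/both available. Categories
count the taxa with homologues (0 of 4 = unique). No alignment program
is run; hit tables are inputs.

## Numerical choices and degenerate inputs

* Coordinates are physical um, order (z, y, x), voxel centres at
  half-integer multiples of the pitch; stated once here and used
  everywhere.
* Argmax ties resolve to the lowest index throughout (focus plane,
  profile peaks, marker peaks).
* Profile normalisation rejects constant channels; intersection rejects
  non-transversal contact; `percent_dapi` rejects queries outside the
  profile support; degenerate (zero-length) rays are errors.
* `sam_welch_test` refuses matrices with missing values (impute first)
  and zero-variance rows when $s_0 = 0$; imputation refuses columns
  with fewer than two observed values.
* All randomness flows through explicit seeds; generators save and
  restore the caller's RNG state, and `derive_seed()` gives every
  pipeline stage its own deterministic child seed below 2^31.

## Validation problem sizes

The shipped suite uses sizes chosen so the whole validation runs on a
laptop-class single core in minutes while keeping Monte-Carlo error
well inside the asserted tolerances: 40 jittered scenes (160 profiles)
for border calibration; 25 scenes x 8 molecules (n = 200 eligible) per
orientation fraction; one noise-free and 50 Poisson renders of a
14-molecule scene for end-to-end counts; 25 simulations of 200 proteins
for the null-FDR check; 2 x 10^4 draws for imputation moments; 1,000
random sequences against the brute-force window oracle.
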