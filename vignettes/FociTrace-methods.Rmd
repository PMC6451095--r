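---
title: "Quantifying DNA-bound single molecules in living bacteria: models and methods"
author: "FociTrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA-bound single molecules in living bacteria: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and physical picture

FociTrace quantifies DNA binding of fluorescently labelled proteins in
rod-shaped bacteria from single-molecule wide-field movies. The analysis
rests on diffusional contrast: at 34–100 ms exposures a freely diffusing
protein (D ≈ 10 µm²/s) travels microns per frame and blurs into a uniform
cytosolic haze, whereas a DNA-bound copy (D ≈ 10⁻⁵ µm²/s) is effectively
immobile and images as a diffraction-limited spot. Counting, weighing and
placing those spots — per cell, over time, across two spectral channels —
is what every module here does, and a synthetic-microscopy generator plus a
stochastic trajectory simulator provide ground truth for all of it.

# Cell geometry

Cells are modelled as spherocylinders: a cylinder of length $L - W$ capped
by hemispheres of diameter $W$. The closed forms

$$A = (L - W)\,W + \pi (W/2)^2, \qquad
  V = \pi (W/2)^2 (L - W) + \tfrac{4}{3}\pi (W/2)^3$$

convert outline measurements into areas (µm²) and volumes (fL); volumes
feed concentration estimates (one molecule in 1.66 fL is 1 nM). Outlines
are closed polygons in µm; generated outlines use 64 vertices, which keeps
the polygon area within a fraction of a percent of the closed form. The
included mask segmenter (connected components, convex hulls, border-cell
rejection) is a deliberately minimal stand-in: real pipelines typically
import outlines from a dedicated segmentation tool, which is why outlines
also round-trip through a plain CSV format.

# The synthetic time lapse

`generateTimelapse()` emulates the structure of a damage-response imaging
experiment. Its defaults are the study conditions the package is tested
under, chosen once:

- 100 nm pixels on a 512 px frame (so the 218 nm colocalization radius is
  2.18 px) and a PSF sigma of 1.3 px, typical for a high-NA objective at
  ~540 nm with this pixel size.
- Snapshots every 10 min for 3 h; a damage event at t = 0; filamentation
  from 30 min, modelled as exponential elongation at a specific rate of
  0.017 min⁻¹ — chosen so cells roughly triple in length over the hour
  after onset, matching the co-ordinated growth of focus counts from ~2 to
  ~6 per cell at constant focus density. An optional static subpopulation
  (fraction of cells that never filament) emulates damage-signalling
  mutants; a preset with exponentially decaying focus density after the
  damage event emulates replication shutdown.
- Channel A at 0.79 foci/µm² — about 2.2 foci in a fresh ~2.8 µm² cell —
  switching from monomeric to dimeric foci at 30 min; channel B sparse
  (0.15 foci/µm²), monomeric, relocating from central to peripheral
  placement at 30 min. Focus counts are Poisson in cell area, so the
  density stays constant as cells elongate.
- 18 label copies per cell at t = 0, scaled with cell volume thereafter
  (constant concentration, hence constant mean cell intensity);
  autofluorescence equivalent to 2.5 molecules; 100 camera counts per
  molecule.
- Camera model: Poisson shot noise scaled so a one-molecule focus has
  integrated mean/sd = `snr` (default 30, i.e. ~900 detected photons per
  molecule per frame, realistic for bright YFP-class labels under strong
  excitation), plus Gaussian read noise (sd 1 count) and a constant
  100-count offset. EM-gain excess noise is not modelled separately; it is
  absorbed into the effective `snr`.

Free (unbound) copies are rendered as a uniform per-cell background, not as
explicit diffusing emitters — the uniform haze is exactly what diffusional
contrast predicts for these exposure times, and Brownian-dynamics rendering
is out of scope. Identical configurations, including the seed, produce
bit-identical frames and tables; every random draw goes through a
deterministic child-seed derivation.

What the generator does **not** emulate: optical aberrations and depth
effects, membrane autofluorescence structure, cell crowding and overlap,
segmentation errors, stage drift, or uneven illumination (a synthetic
radial profile is provided separately to exercise flat-fielding). Passing
the round-trip tests therefore validates the analysis logic, not its
robustness to every artefact of real data.

## Spatial placement modes

Foci are placed by short-axis mode: `central` draws width coordinates from
a zero-mean normal with sd = 0.1·W, putting ~95% within 0.2 µm of the
centre spline of a 1 µm cell (nucleoid/replisome-like); `peripheral` is an
equal mixture of normals at ±0.3·W with sd 0.08·W (membrane-proximal);
`uniform` is uniform over the polygon. Along the long axis, positions are
uniform over the extent admissible for the drawn width coordinate, so the
modes are exact statements about the short-axis density only.

# Focus detection

Detection operates per cell outline:

1. **Candidates** are 3×3 local maxima of the band-pass (difference of
   Gaussians, σ₁ = PSF σ, σ₂ = 4σ₁) image inside the outline dilated by one
   pixel (so membrane-adjacent peaks are not lost to the pixel grid), above
   a lenient 2×MAD gate.
2. **Background** is the median inside the outline excluding 3σ disks
   around candidates, with a low-quantile fallback for crowded cells, and a
   robust noise floor.
3. **Acceptance** requires the raw peak to clear the background by
   `minPeakSnr` (default 3) noise sigmas, the matched-filter (band-pass)
   peak to clear the band-pass noise, the fitted amplitude to clear a
   slightly stricter gate, and the background-subtracted flux in a 2σ disk
   (clipped to the cell) to clear the accumulated pixel noise — the last
   test is what separates PSF-sized spots from single bright pixels.
4. **Fitting** is least-squares 2D Gaussian (free position, σ bounded,
   local offset) restricted to in-cell pixels so the sharp cell boundary
   cannot masquerade as a broad spot; an intensity-weighted centroid is the
   fallback. A broadened single fit triggers a two-component
   deconvolution with the PSF σ fixed, accepted only when it wins on BIC,
   is separated by >1.8 px, and both components are supported by data.
5. Accepted spots are **subtracted sequentially** (brightest first) so
   overlapping candidates cannot double-count photons, a residual pass
   re-scans for shoulder peaks, and components closer than one PSF σ are
   merged (much dimmer peaks inside 3σ of an accepted focus are treated as
   fit residue).

The `minPeakSnr` default of 3 is a documented choice validated on synthetic
data only; the integrated intensity reported per focus is the Gaussian
integral 2πAσ², background-subtracted.

# Stoichiometry and copy numbers

The single-molecule intensity unit is calibrated from discrete steps in
burst-acquisition trajectories: change points are found by binary
segmentation (split where the residual sum of squares drops most, accept
when the level change exceeds three frame-noise sigmas; exact-zero frame
differences are excluded from the noise estimate because fully bleached,
shot-noise-free frames carry no noise information), and the unit is the
mean of the dominant mode of the step-magnitude distribution, which rejects
occasional two-molecule steps. Trajectory extraction sums a disk ROI
clipped to the cell and subtracts, per frame, the median of the remaining
in-cell pixels — an annulus in a 1-µm-wide cell would sample non-cell
pixels and imprint the bleaching of the diffuse pool on the trajectory as a
slow drift.

Copy numbers divide the offset-subtracted integrated cell fluorescence of
the first burst frame by the unit and subtract a population-constant
autofluorescence equivalent (default 2.5 molecules); negative corrected
values clamp to zero with a warning rather than erroring, since the
correction is a population mean applied per cell. Using the first frame
minimizes photobleaching bias; with a 1 s bleach lifetime and 34 ms frames
about 2–3% of the signal is already lost within the first exposure, a bias
the recovery tests accept. Concentrations use each cell's spherocylinder
volume.

Bound fractions are the product of foci per cell and molecules per focus
over copies per cell, in percent — doubling the per-focus stoichiometry at
fixed focus density and copy number exactly doubles the bound fraction,
which is the arithmetic behind a monomer-to-dimer transition taking ~11%
to ~22% at two foci and 18 copies.

# Colocalization

Colocalization is directional: an A focus is "with B" when at least one B
centroid in the same cell lies within the search radius, boundary
inclusive ("within 218 nm" resolves ties inclusively). Matching is
at-least-one-partner rather than exclusive assignment, which reproduces the
asymmetric percentages of channels with different focus counts; cross-cell
matches are disallowed. The chance baseline is analytic: per cell,
min(1, n_B·πr²/A), averaged over cells — disk overlap is summed and
clamped rather than unioned, a good approximation at the low per-cell
focus counts this baseline is meant for (the package tests it against a
Monte-Carlo oracle to half a percentage point). Distance histograms use
annuli of equal area, r_k = r_max·√(k/n), so a uniform scatter is flat.
The generator can force a configurable fraction of channel-A foci to carry
a coincident channel-B partner (30 nm jitter) to create true colocalization
above chance.

# Autocorrelation decomposition

Trajectory ACFs are mean-subtracted and variance-normalized,
G(0) = 1, using the biased (1/N) estimator for stability at long lags.
Ensemble means carry per-lag SEMs. The mean ACF is fitted from the first
nonzero lag (0.034 s for burst data) with single- and double-exponential
decays; the double model is kept when it improves the AIC (the selection
criterion is a documented choice), components are ordered so τ_m < τ_l,
and the amplitude missing at lag zero is the short component
a_s = 1 − a_m − a_l, its uncertainty taken from the ensemble SEM at the
first fitted lag. Fits use Levenberg–Marquardt with bounded, data-derived
starting values (a log-linear decay estimate), retrying from a second
start before failing. τ_m and τ_l are free by default; callers comparing
conditions can fix the model order instead.

Photobleaching is not corrected before fitting; validation ensembles keep
the bleach lifetime much longer than the fitted timescales so the
decomposition reflects binding kinetics. Two estimator facts matter when
comparing simulated ACFs with closed forms and are encoded in the test
oracles: frame integration of a telegraph process rescales all nonzero
lags by (cosh kΔt − 1)/(kΔt − 1 + e^(−kΔt)), and the mean-subtracted
sample ACF has a first-order negative bias of (S/N)(1 − ρ) with S the
correlation sum — at 300-frame trajectories with second-scale dwell times
the finite-length truncation visibly shortens fitted timescales, which is
why timescale-recovery tests use longer trajectories.

# The trajectory simulator

Three stages generate an intensity trajectory: (i) a complex binds and
leaves DNA as a continuous-time two-state Markov chain with exponential
dwell times at fixed rates (reading "user-defined distributions of rates"
as the degenerate single-rate case), initialized from the stationary
distribution and integrated onto the frame grid as the fraction of each
frame spent bound — more faithful than per-frame Bernoulli switching when
dwells approach the 34 ms frame; (ii) each of N molecules binds and leaves
the complex by the same mechanism; (iii) each molecule draws an exponential
photobleaching budget that is spent only while the molecule is emitting
(illumination-coupled, the natural choice under continuous excitation; a
wall-clock mode exists). A molecule contributes signal only while it is on
the complex, the complex is on DNA, and its bleach budget is unspent.
Poissonian noise is applied per frame with a scale of snr² photons per
single-molecule signal, so one molecule has per-frame mean/sd = snr and k
simultaneously emitting molecules have k-fold variance — the reduced
relative noise of brighter foci is what shrinks the short ACF component
when complexes permanently carry two molecules instead of one, and the
built-in comparison runs both ensembles with identical seeds and all other
parameters equal.

# Problem sizes and numerical choices

The test and validation scales were chosen to give comfortable statistical
power at interactive runtimes: detection round trips use 100 cells at the
default density and SNR; copy-number/unit recovery uses 60 cells with
100-frame burst stacks at a 1 s bleach lifetime, curating isolated,
non-polar events for step calibration exactly as an analyst curates
single-molecule return events; ACF oracles use 150–200 trajectories of
4000–5000 frames; the dimer comparison uses ten replicate pairs of 150
trajectories; Monte-Carlo baselines use 10⁴ placements. Detection recall
and false positives are scored at a 2 px (one PSF FWHM-scale) matching
radius — the natural scale for counting — while localization quality is
reported separately as the median centroid error of matched foci, and
isolated spots are additionally required to be found exactly once within
1 px. Degenerate inputs are handled explicitly: zero-variance trajectories
are dropped from ACF ensembles with a message, empty focus lists give
empty (not erroneous) histograms, constant trajectories raise a
calibration error, and an ACF that is zero beyond lag zero returns the
degenerate pure-noise decomposition a_s = 1.

# Known limitations

- The detector's two-emitter deconvolution does not resolve pairs below
  ~2 px separation at single-molecule SNR; such pairs are reported as one
  focus between the true positions, exactly as any PSF-fitting peak caller
  would.
- Step calibration assumes steps dominated by single-molecule magnitudes;
  heavily overlapping foci or sub-frame blinking would contaminate the
  magnitude distribution (blinking photophysics is out of scope).
- The chance-colocalization baseline ignores disk overlap within a cell;
  at several partner foci per µm² it would overestimate chance.
- The generator's idealizations listed above mean that performance numbers
  from synthetic data are upper bounds for real microscopy.
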