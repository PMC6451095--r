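# FociTrace

Single-molecule focus quantification and binding kinetics for live-cell
bacterial fluorescence microscopy.

## The problem

In live *E. coli* imaged at single-molecule sensitivity, a fluorescent
fusion protein that is bound to DNA barely moves (D ≈ 10⁻⁵ µm²/s) and shows
up as a diffraction-limited **focus**, while its freely diffusing pool
(D ≈ 10 µm²/s) blurs into uniform cell background at 34–100 ms exposures.
That diffusional contrast turns wide-field movies into a quantitative assay
of DNA binding. FociTrace implements the full analysis chain for such
experiments:

- **Focus detection** inside cell outlines (band-pass candidate search,
  2D Gaussian fitting with two-emitter deconvolution, sequential
  fit-and-subtract) and per-cell statistics: foci per cell, focus density
  (foci per µm² of cell area), mean cell intensity, cell length over time.
- **Stoichiometry**: calibration of the single-molecule intensity unit from
  photobleaching steps (change-point detection on burst trajectories),
  copy numbers per cell with autofluorescence correction,

  n = max(0, I_cell / I₁ − n_auto),

  concentrations C = n/(V·N_A) via spherocylindrical cell volumes, molecules
  per focus, and the bound fraction
  100 · (foci/cell) · (molecules/focus) / (copies/cell).
- **Directional colocalization** of two focus channels at a fixed search
  radius (default 218 nm = 2.18 px), with equal-area distance histograms
  and an analytic chance baseline: per cell, min(1, n_B·πr²/A), averaged
  over cells.
- **Binding kinetics** by autocorrelation: normalized ACFs
  G(τ) = ⟨δI(t)·δI(t+τ)⟩/⟨δI²⟩ of focus-intensity trajectories (300 × 34 ms
  burst frames), ensemble means with per-lag SEM, and decomposition into a
  sub-frame short amplitude a_s plus exponentials
  a_m·e^(−τ/τ_m) + a_l·e^(−τ/τ_l) fitted beyond the first lag, with
  a_s + a_m + a_l = 1.
- **Short-axis localization**: signed width coordinates relative to the
  cell centre spline (membrane at ±0.5 µm for a 1-µm cell), width
  histograms, and time × width line-scan contours of focus-enhanced
  intensity.
- **Synthetic data**: a ground-truthed microscopy generator (spherocylinder
  cells that filament after a damage event, constant focus density,
  monomer→dimer stoichiometry switches, central/peripheral placement
  modes, Poisson + read-noise camera) and a stochastic trajectory simulator
  (complex on/off DNA, molecule exchange, illumination-coupled
  photobleaching, Poissonian noise) with a built-in one- versus
  two-molecule comparison.

## Worked example

```r
library(FociTrace)

cfg <- timelapseConfig(nCells = 40L, duration = 30, interval = 10, seed = 7)
tl  <- generateTimelapse(cfg)

# detect channel-A foci at t = 0 in every field
det0 <- do.call(rbind, lapply(seq_along(tl@frames), function(fd) {
  ids  <- unique(tl@cellTable$cell_id[tl@cellTable$field == fd])
  cset <- new("CellSet", cells = Filter(function(x) cellId(x) %in% ids,
                                        tl@cells[[1]]@cells))
  foci(detectFoci(tl@frames[[fd]][[1]][["A"]], cset))
}))
head(det0[, c("cell_id", "x_um", "y_um", "intensity", "snr")], 3)
#>    cell_id     x_um     y_um intensity      snr
#> 1 cell_001 27.86520 1.651409 108.57786 7.223671
#> 2 cell_001 26.45562 1.561326 103.67046 6.897182
#> 3 cell_001 28.18162 1.529354  99.69331 6.632583

st <- perCellStats(new("FocusSet", records = det0, pixelSize = 0.1),
                   tl@cells[[1]])
st$summary
#>   mean_foci_per_cell sem_foci_per_cell mean_length_um mean_density n_cells
#> 1                  2         0.2454718       3.039616    0.6963477      40

# molecules per focus against the 100-count single-molecule unit
table(moleculesPerFocus(det0$intensity, 100)$n_molecules)
#>  0  1  2  3
#>  1 68 10  1

# two monomeric foci among 18 copies: ~11% of molecules are DNA bound
boundFraction(st$summary$mean_foci_per_cell, 1, 18)
#> [1] 11.11111
```

The detected foci average two per cell with mostly one molecule each
(intensities near the 100-count unit), so with 18 labelled copies per cell
about 11% of the protein is DNA bound at any instant; if the same foci
became dimers, the bound fraction would double to ~22%.

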