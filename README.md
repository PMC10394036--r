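# pshg — polarization-resolved SHG mapping of collagen orientation

`pshg` implements the image-analysis workflow behind polarization-resolved
second harmonic generation (P-SHG) microscopy of fibrillar collagen, with
the corneal stroma as its model system. The stroma is a stack of 1–3 µm
lamellae of parallel collagen fibrils; epi-detected SHG images are spatially
featureless, but the modulation of the SHG signal with the excitation
polarization angle encodes the in-plane fibril orientation in every voxel.
The package turns 4-D polarimetric stacks (depth × polarization angle × y ×
x photon counts) into depth-resolved orientation maps and lamella
orientation statistics, and ships a synthetic lamellar-cornea phantom so the
whole chain is testable without experimental data.

## The model

A collagen fibril at in-plane orientation φ excited with linear polarization
at angle θ emits

```
I(θ) = K [ (χ_xxx cos²Δ + χ_xyy sin²Δ)² + χ_xyy² sin²(2Δ) ],   Δ = θ − φ,
```

a trigonometric polynomial in 2Δ:

```
I(θ) = a0 + a2 cos(2(θ−φ)) + a4 cos(4(θ−φ)).
```

The pipeline stages are:

1. **Polarimetry** — 6×6 spatial pre-averaging of each polarization frame,
   then per-pixel discrete Fourier projection of the 18-angle series:
   φ = arg(c₂)/2, ⟨SHG⟩ = a₀, and a coefficient of determination R²
   against the phase-locked single-fibril reconstruction. Pixels with
   R² < 0.7 (voids, striae, lamellar crossings) are eliminated.
2. **Distributions** — 1°-bin circular histograms per depth, per stromal
   third, or full thickness; integer-degree angular registration; L1
   distances normalized to the maximum of 2; 40 µm sliding-window distance
   depth profiles; and the perpendicular-acquisition averaging protocol
   (second stack acquired with the sample rotated 90°, its distributions
   rotated back and averaged) that cancels opposite depth-dependent
   polarization distortions.
3. **Mixture fitting** — the lamella orientation distribution is fitted by
   an isotropic term plus two axial von Mises peaks (nasal–temporal and
   inferior–superior), `p(φ) = c_iso/π + Σ c_j exp(κ_j cos 2(φ−μ_j))/(π I0(κ_j))`,
   reporting weights, concentrations, peak separation Δμ and fit R².
4. **Structure tensor** — an independent orientation measurement on
   striated (trans-detected-style) images via the gradient structure tensor
   with coherency filtering, and the depth profile of the mean folded
   angular difference against the P-SHG maps.
5. **Phantom** — ground-truth stroma volumes (stacked lamellae drawn from
   configurable depth-varying orientation laws, keratocyte and stria voids,
   partial-volume mixing, Poisson photon-counting noise) rendered into
   epi-polarimetric stacks and striated validation images.

## Worked example

A voxel containing an equal crossing of two lamellae at 0° and 60°
(susceptibility ratio 1.4) — exactly the situation the R² filter exists
for:

```r
library(pshg)
proto <- acquisition_protocol()                 # 18 angles, 0..170 deg
opt   <- fibril_optics(chi_xxx = 1.4, chi_xyy = 1)
counts <- array(0, c(1, 18, 1, 1))
counts[1, , 1, 1] <- 0.5 * forward_intensity(opt, 0,  proto$angles_deg) +
                     0.5 * forward_intensity(opt, 60, proto$angles_deg)
m <- extract_orientation(pshg_stack(counts, proto))
```

```
phi = 30.0 deg, R2 = 0.500, phi2/phi4 discrepancy = 45.0 deg
```

The harmonic analysis reports the bisector orientation (30°), but the
sign-constrained reconstruction scores it R² = 0.5, so `filter_by_r2()` at
the 0.7 threshold removes it; the 4th-harmonic phase discrepancy (45°,
its maximum) flags the same voxel independently. Fitting the mixture model
to its own exactly binned full-thickness law recovers the generating
parameters:

```r
f <- fit_mixture(binned_mixture(cornea_orientation_laws()$full))
```

```
fitted: delta_mu = 86.0 deg, c_iso = 0.54, kappa_NT = 5.20, R2 = 1.000
```

## The analysis workflow

The numbered scripts under `analysis/` run the full synthetic study and
write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_phantom.R` | 540 µm phantom (268 lamellae at seed 1) + two perpendicular noisy acquisitions |
| `02_extract_orientation.R` | smoothing, extraction, R² filtering (92.6 % valid pixels at seed 1) |
| `03_depth_distributions.R` | histograms, registration (recovers the 90° rotation), distance profiles, perpendicular averaging |
| `04_fit_mixture.R` | von Mises mixture fits per stromal third vs the generating laws |
| `05_structure_tensor_validation.R` | structure tensor on striated renderings vs P-SHG maps (mean difference 4.1° at seed 1) |

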