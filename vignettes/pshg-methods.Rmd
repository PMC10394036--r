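---
title: "Methods: orientation mapping from polarization-resolved SHG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orientation mapping from polarization-resolved SHG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pshg)
```

## The measurement model

Fibrillar collagen is a strong second-harmonic generator. For a fibril with
cylindrical and Kleinman symmetry lying in the image plane at orientation
$\varphi$, excitation with linear polarization at angle $\theta$ yields

$$I(\theta) = K\left[\left(\chi_{xxx}\cos^2\Delta + \chi_{xyy}\sin^2\Delta\right)^2
  + \chi_{xyy}^2\sin^2 2\Delta\right], \qquad \Delta = \theta-\varphi,$$

which expands exactly into a truncated Fourier series in the doubled angle,

$$I(\theta) = a_0 + a_2\cos 2(\theta-\varphi) + a_4\cos 4(\theta-\varphi),$$

with $a_0 = K[(\chi_x+\chi_y)^2/4 + (\chi_x-\chi_y)^2/8 + \chi_y^2/2]$,
$a_2 = K(\chi_x^2-\chi_y^2)/2$ and $a_4 = K[(\chi_x-\chi_y)^2/8 -
\chi_y^2/2]$. Two properties matter downstream: $a_2 > 0$ whenever
$\chi_{xxx} > \chi_{xyy}$, and $a_4 < 0$ whenever the susceptibility ratio
$\rho = \chi_{xxx}/\chi_{xyy} < 3$ — the regime of fibrillar collagen. The
closed forms are verified in the test suite against an independent
quadrature projection of the forward model (criterion: agreement to
1e-10 over random optics).

The ratio $\rho$ is not critical for orientation extraction (it only sets
the modulation contrast); the package default is 1.4, a plausible value for
corneal collagen, used consistently in the phantom and in all precision
assessments.

## Per-pixel extraction and the R² filter

The acquisition samples $I(\theta)$ on a uniform grid of $N$ angles covering
180° ($N = 18$, every 10°, by default; at least 9 are required to resolve
the 4th harmonic). Per pixel we take discrete Fourier projections
$c_n = (2/N)\sum_k I_k e^{in\theta_k}$; on a uniform grid these are exact
for a truncated series, so for noise-free single-fibril data the recovered
$\hat\varphi = \arg(c_2)/2 \in [0°, 180°)$ equals the ground truth to
machine precision (the round-trip test requires 1e-6 degrees across a full
phantom). The mean signal is $\langle\mathrm{SHG}\rangle = a_0$, the
arithmetic mean over the polarization series.

The coefficient of determination compares the data with the **phase-locked,
sign-constrained** reconstruction

$$\hat I(\theta) = a_0 + |c_2|\cos 2(\theta-\hat\varphi)
  + \hat a_4 \cos 4(\theta-\hat\varphi),
  \qquad \hat a_4 = \min(0,\; p_4),$$

where $p_4$ is the signed projection of the series onto the
$\hat\varphi$-locked 4th-harmonic basis. The constraint is the crux of the
design. An unconstrained signed projection reconstructs *any* incoherent
mixture of equal-ratio fibrils exactly (each fibril contributes harmonics
with phases $2\varphi_i$ and $4\varphi_i$; their sums are still two
harmonics, which an unconstrained two-harmonic model absorbs), so R² would
never flag lamellar crossings. Locking both phases to $\hat\varphi$ and
clamping $\hat a_4 \le 0$ — the single-fibril sign for $\rho < 3$ — makes
R² drop exactly where the cylindrical-symmetry hypothesis fails. The
canonical example, an equal incoherent mix of 0° and 60° lamellae at
$\rho = 1.4$, gives $\hat\varphi = 30°$ and R² = 0.500: at this ratio
$|a_4| = a_2$, the mixed 4th harmonic arrives phase-locked but
sign-flipped, is clamped to zero, and contributes exactly half the
modulation energy to the residual. The 0.7 filter therefore removes it.

Numerical choices:

* degeneracy guard: pixels with $a_0 = 0$ or $|c_2| < \varepsilon a_0$
  ($\varepsilon = 10^{-3}$) have no defined orientation and are invalid
  rather than assigned an arbitrary angle;
* the 6×6 uniform pre-averaging filter is applied to the polarization
  frames *before* extraction (it conditions the estimate's signal-to-noise
  ratio), with reflect padding; for even windows the support covers offsets
  $-2..+3$;
* orientation convention: degrees, measured from the +X image axis toward
  +Y (row index), period 180°;
* a complementary flag, the $\varphi_2/\varphi_4$ discrepancy, measures the
  deviation of the 4th-harmonic phase from its single-fibril expectation
  $4\varphi + 180°$, folded to $[0°, 45°]$; it is 0 for any single fibril
  and 45° for the equal crossing above.

With 100 photons/pixel/angle (the default photon budget), Poisson noise,
and 6×6 averaging, the circular standard deviation of $\hat\varphi$ on a
uniform field is about 0.7° (computed by `scripts/acceptance.R`), and a
Monte-Carlo test verifies the expected $a_0^{-1/2}$ scaling over two
decades of photon count.

## Orientation distributions, registration, distances

Valid orientations are histogrammed into 180 half-open 1° bins (values
wrapped mod 180°), normalized per slice to the number of valid pixels —
per-slice rather than per-window normalization, so each depth contributes a
proper distribution regardless of how many of its pixels survive
filtering. Depth regions follow the anatomical convention: the stromal
range is split into three equal thirds (anterior / middle / posterior);
when a slice count is not divisible by 3 the remainder goes to the
posterior third.

The distance between two normalized histograms is the L1 sum of bin
differences, at most 2, and reported normalized to $[0, 1]$. Registration
searches all 180 integer-degree circular shifts (bin resolution; sub-bin
registration is deliberately out of scope) and breaks ties by the smallest
folded shift. The "anterior region" used for registration is the first
third of the depth range. Depth profiles average the raw distances over a
±20 µm sliding window truncated at the volume boundaries, then normalize.

The perpendicular-acquisition protocol addresses depth-dependent
polarization distortions that rotate with the sample: the second stack is
acquired with the sample physically rotated 90°, its distributions are
numerically rotated back by exactly 90 bins and averaged bin-wise with the
first stack's. Opposite distortions then cancel; the test suite constructs
explicit $\pm g$ multiplicative distortions around a shared truth and
verifies the average is strictly closer (L1) to the truth than either
input.

## The von Mises mixture

Lamella orientation distributions are quantified by

$$p(\varphi) = \frac{c_{\mathrm{iso}}}{\pi}
 + c_{\mathrm{NT}} M(\varphi\,|\,\mu_{\mathrm{NT}}, \kappa_{\mathrm{NT}})
 + c_{\mathrm{IS}} M(\varphi\,|\,\mu_{\mathrm{IS}}, \kappa_{\mathrm{IS}}),
 \qquad M(\varphi\,|\,\mu,\kappa) =
   \frac{e^{\kappa\cos 2(\varphi-\mu)}}{\pi I_0(\kappa)},$$

with doubled angles because orientations are axial. The normalization
$C(\kappa) = \pi I_0(\kappa)$ makes each component integrate to 1 on
$[0°, 180°)$ (verified by quadrature to 1e-8). The weights are constrained
to the simplex — fitted weight tables then sum to 100 % by construction —
via a softmax parameterization; concentrations are kept in $(0, 100)$ by a
scaled logistic; peak locations are free circular parameters.

The objective is least squares on the binned densities, matching the
situation where the fit is applied to a measured (plotted) distribution and
allowing a fit R² to be reported; a maximum-likelihood variant
(`fit_mixture_ml()`) is available for raw samples. Initialization places
the peaks at the two highest histogram modes separated by at least 30°
(fallback 0° and 90°), $\kappa = 3$, equal weights; four deterministic
perturbations of this start are also optimized (BFGS then Nelder-Mead
polish) and the best kept, so fits are reproducible without RNG. Labels:
the peak nearer the 0° (nasal–temporal) axis of the registered frame is
NT. Fits with peak separation $\Delta\mu < 10°$ or a peak weight below
0.01 are flagged degenerate — $\Delta\mu$ is not identifiable there — and
optimizer failure on all starts returns a flagged failure, never a silent
garbage fit. Recovery tests require: exact binned laws reproduced within
0.02 in weights, 2° in $\mu$, 10 % in $\kappa$ across random draws, and
$10^5$-sample histograms fitted with $\mu$ bias under 2°.

Sampling from the model (for tests) composes a categorical component draw
with a Best–Fisher von Mises rejection sampler on the doubled-angle circle.

## Structure-tensor validation

Striated images — the synthetic stand-in for trans-detected SHG, whose
interference striations run along the fibrils — are analyzed with the
gradient structure tensor: central-difference gradients (reflect padding),
6-pixel uniform window averaging of $J_{xx}, J_{xy}, J_{yy}$ (a Gaussian
window option approximates OrientationJ's weighting more closely), stripe
orientation $\tfrac12\operatorname{atan2}(-2J_{xy},\, J_{yy}-J_{xx})$ in
the package's y-down image frame, and coherency
$(\lambda_{\max}-\lambda_{\min})/(\lambda_{\max}+\lambda_{\min})$, defined
as 0 where the trace vanishes. The angular comparison against P-SHG maps
uses the folded circular difference $\min(d, 180°-d)$ — a plain absolute
difference would call 179° vs 1° a 178° disagreement — averaged per depth
over pixels with both R² ≥ 0.7 and coherency ≥ 0.7 (0.2 is exposed as a
display-only threshold).

Two known numerical artifacts are documented rather than hidden: central
differences on a period-$T$ sinusoid bias the orientation by up to ~1.4°
at $T = 5$ px away from the symmetry angles (0°, 45°, 90°), and the
reflect-padded boundary band of about one window width carries errors of a
few degrees while retaining high coherency. Both are small against the 6°
end-to-end acceptance bound and are absent at 45° and in image interiors,
which the unit tests exploit.

## What the phantom emulates — and what it does not

`build_phantom()` partitions a 540 µm (default) depth axis into lamellae
with thicknesses uniform in 1–3 µm, draws each lamella's orientation from
a per-third mixture law (defaults: the `cornea_orientation_laws()`
parameterization — broad IS-dominated peaks anteriorly, sharp NT-dominated
peaks posteriorly, peak separations 74°/83°/87°), mixes straddled voxels
in proportion to axial overlap, and stamps keratocytes (15×6×3 µm
flattened in-plane ellipsoids at 2×10⁻⁵ µm⁻³ ≈ 20,000 cells/mm³, a
realistic stromal density) and striae (2 µm planar bands tilted 20° from
the surface, anchored at the posterior face) as signal voids. Rendering
uses the forward model with the intensity scale set to the configured
photon budget (default $a_0$ = 100 counts/pixel/angle) and Poisson noise.
Partial-volume voxels mix **intensities** by default — epi-detected SHG has
a ~100 nm coherence length, far below the lamella thickness, so fields
from distinct lamellae do not interfere — with a coherent field-sum switch
available, since coherent mixing is exactly what degrades the single-fibril
model in thicker-coherence geometries. All stochastic draws flow from one
seed, and same-seed runs are bit-identical.

The phantom deliberately omits: out-of-plane lamella inclination (the
anterior obliquity is represented only as depth-varying in-plane laws),
optical aberrations, birefringence, depolarization and corneal curvature.
Consequently the perpendicular-protocol distances measured on the phantom
reflect only sampling and noise (the analysis scripts find ~0.02), not the
depth-dependent polarization artifact the protocol exists to correct in
real corneas — the averaging step is validated instead on constructed
opposite distortions. Passing tests therefore demonstrate correctness of
the algorithms under the stated noise model, not robustness to every
optical nuisance of deep-tissue imaging.

A second caveat is finite-lamella sampling: a 540 µm stack contains only a
few hundred lamellae, and a regional histogram built from ~90 discrete
lamella orientations is intrinsically spiky. Regional mixture fits on one
phantom therefore show inflated $\kappa$ and modest fit R² relative to the
generating law — visible in `analysis/04_fit_mixture.R` — whereas peak
locations and $\Delta\mu$ are recovered well. Averaging over many corneas
(as a real study does) or longer stacks removes this; the fit-recovery
tests use exact binned laws and large samples to separate estimator
correctness from this sampling effect.

## Problem sizes

Defaults were chosen so the full test suite runs in about a minute and the
analysis scripts in a few minutes on one CPU: 64×64 lateral fields, 540
depth planes for the narrative analysis, 20–48 plane phantoms for
end-to-end tests, 128×128 single-plane fields (≥10⁴ interior pixels) for
precision estimates, and 10⁵–10⁶ draws for sampling checks. All are
configuration parameters, not algorithmic limits.
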