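# Synthetic lamellar-cornea phantom: ground-truth orientation volumes and
# rendering of epi-detected polarimetric stacks and trans-detected-style
# striated images, with Poisson photon-counting noise.

#' Acquisition protocol for a polarization series
#'
#' Describes how a polarimetric stack is sampled: the ordered list of linear
#' excitation polarization angles and the voxel pitch. The default is the
#' standard corneal protocol: 18 angles every 10 degrees from 0 to 170, 1 um
#' pixels, 1 um axial steps.
#'
#' @param angles_deg strictly increasing polarization angles in `[0, 180)`.
#' @param pixel_size_um lateral sampling (um).
#' @param axial_step_um axial sampling (um).
#' @return an object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(angles_deg = seq(0, 170, by = 10),
                                 pixel_size_um = 1, axial_step_um = 1) {
  stopifnot(all(diff(angles_deg) > 0), all(angles_deg >= 0),
            all(angles_deg < 180), pixel_size_um > 0, axial_step_um > 0)
  structure(list(angles_deg = as.numeric(angles_deg),
                 pixel_size_um = pixel_size_um,
                 axial_step_um = axial_step_um),
            class = "acquisition_protocol")
}

#' Polarimetric image stack
#'
#' Photon-count frames indexed `(z, angle, y, x)` plus the acquisition
#' protocol they were recorded with.
#'
#' @param counts 4-D numeric array `(nz, n_angles, ny, nx)`, non-negative.
#' @param protocol an [acquisition_protocol()].
#' @return an object of class `pshg_stack`.
#' @export
pshg_stack <- function(counts, protocol) {
  stopifnot(length(dim(counts)) == 4, all(counts >= 0, na.rm = TRUE),
            inherits(protocol, "acquisition_protocol"),
            dim(counts)[2] == length(protocol$angles_deg))
  structure(list(counts = counts, protocol = protocol), class = "pshg_stack")
}

#' Reference depth-varying orientation laws for the human corneal stroma
#'
#' Isotropic + two-von-Mises parameterizations of the lamella orientation
#' distribution in the anterior, middle and posterior thirds of the stroma
#' and over its full thickness, with the nasal-temporal (NT) peak on the X
#' axis (`mu_NT = 0`) and the inferior-superior (IS) peak at the regional
#' peak separation. Weights are in fractions summing to 1. These serve as
#' the phantom generator's default orientation laws: broad, IS-dominated
#' peaks anteriorly, sharpening and shifting toward NT posteriorly.
#'
#' @return named list of [vm_mixture()] objects:
#'   `anterior`, `middle`, `posterior`, `full`.
#' @export
cornea_orientation_laws <- function() {
  list(
    anterior  = vm_mixture(c_iso = 0.36, c_nt = 0.23, mu_nt_deg = 0,
                           kappa_nt = 1.6, c_is = 0.41, mu_is_deg = 74,
                           kappa_is = 1.8),
    middle    = vm_mixture(c_iso = 0.47, c_nt = 0.32, mu_nt_deg = 0,
                           kappa_nt = 3.9, c_is = 0.21, mu_is_deg = 83,
                           kappa_is = 3.7),
    posterior = vm_mixture(c_iso = 0.41, c_nt = 0.39, mu_nt_deg = 0,
                           kappa_nt = 6.4, c_is = 0.20, mu_is_deg = 87,
                           kappa_is = 7.4),
    full      = vm_mixture(c_iso = 0.54, c_nt = 0.26, mu_nt_deg = 0,
                           kappa_nt = 5.2, c_is = 0.20, mu_is_deg = 86,
                           kappa_is = 4.1)
  )
}

#' Specification of a synthetic lamellar stroma
#'
#' Structural and noise parameters of the phantom. Defaults emulate a central
#' human corneal stroma: 540 um of stacked 1-3 um lamellae whose in-plane
#' orientations follow the depth-varying laws of
#' [cornea_orientation_laws()], sparse keratocyte voids (flattened in-plane
#' ellipsoids at a realistic stromal cell density), a couple of oblique
#' striae rising from the posterior face, and a mean photon budget of 100
#' counts per pixel per polarization angle.
#'
#' @param stroma_thickness_um total depth (um).
#' @param lamella_thickness_range_um `(min, max)` per-lamella thickness (um).
#' @param orientation_law either a single [vm_mixture()] applied at all
#'   depths, or a list of three (anterior, middle, posterior thirds).
#' @param keratocyte_density voids per um^3 (default 2e-5, i.e. 20,000 cells
#'   per mm^3).
#' @param stria_count number of oblique low-signal bands.
#' @param noise_mean_counts target angle-averaged photon count `a0` per pixel
#'   in tissue voxels.
#' @param nx,ny lateral field size in pixels.
#' @param pixel_size_um,axial_step_um voxel pitch (um).
#' @param seed RNG seed making the phantom reproducible.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(stroma_thickness_um = 540,
                         lamella_thickness_range_um = c(1, 3),
                         orientation_law = cornea_orientation_laws()[
                           c("anterior", "middle", "posterior")],
                         keratocyte_density = 2e-5,
                         stria_count = 2,
                         noise_mean_counts = 100,
                         nx = 64, ny = 64,
                         pixel_size_um = 1, axial_step_um = 1,
                         seed = 1) {
  r <- lamella_thickness_range_um
  stopifnot(stroma_thickness_um > 0, length(r) == 2, r[1] > 0, r[2] >= r[1],
            keratocyte_density >= 0, stria_count >= 0, noise_mean_counts >= 0,
            nx >= 1, ny >= 1, pixel_size_um > 0, axial_step_um > 0)
  if (r[1] > stroma_thickness_um)
    stop("minimum lamella thickness exceeds the stroma thickness")
  if (inherits(orientation_law, "vm_mixture"))
    orientation_law <- list(orientation_law)
  stopifnot(all(vapply(orientation_law, inherits, TRUE, "vm_mixture")),
            length(orientation_law) %in% c(1L, 3L))
  structure(list(stroma_thickness_um = stroma_thickness_um,
                 lamella_thickness_range_um = r,
                 orientation_law = orientation_law,
                 keratocyte_density = keratocyte_density,
                 stria_count = stria_count,
                 noise_mean_counts = noise_mean_counts,
                 nx = as.integer(nx), ny = as.integer(ny),
                 pixel_size_um = pixel_size_um,
                 axial_step_um = axial_step_um,
                 seed = seed),
            class = "phantom_spec")
}

#' Build a ground-truth lamellar phantom
#'
#' Partitions the depth axis into lamellae with thicknesses drawn uniformly
#' from the configured range, assigns each lamella one in-plane orientation
#' drawn from the depth-appropriate mixture law, computes per-plane
#' partial-volume mixing where a voxel's axial footprint straddles a lamella
#' boundary, and stamps keratocytes (flattened ellipsoids, long axes
#' in-plane, default 15 x 6 x 3 um) and striae (2 um-thick planar bands
#' tilted 20 degrees from the surface, anchored at the posterior face) as
#' signal voids. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `lamellar_phantom` with elements:
#'   `phi_deg[nz]` primary orientation per plane, `phi2_deg[nz]` secondary
#'   orientation where a plane straddles a boundary, `mix_fraction[nz]` in
#'   `[0, 0.5]` (0 = pure), `void_mask[nz, ny, nx]`, lamella `boundaries_um`
#'   and `lamella_phi_deg`, and the generating `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  zmax <- spec$stroma_thickness_um
  r <- spec$lamella_thickness_range_um
  dz <- spec$axial_step_um
  nz <- round(zmax / dz)
  # depth partition into lamellae
  th <- numeric(0)
  while (sum(th) < zmax)
    th <- c(th, stats::runif(1, r[1], r[2]))
  bounds <- pmin(cumsum(th), zmax)
  lo <- c(0, bounds[-length(bounds)])
  centers <- (lo + bounds) / 2
  laws <- spec$orientation_law
  third <- if (length(laws) == 1L) rep(1L, length(centers)) else
    pmin(3L, 1L + floor(centers / (zmax / 3)))
  lam_phi <- vapply(seq_along(centers), function(i)
    sample_mixture(laws[[third[i]]], 1L), numeric(1))
  # per-plane primary/secondary lamella and partial-volume fraction
  z_lo <- (seq_len(nz) - 1) * dz
  z_hi <- z_lo + dz
  phi <- numeric(nz); phi2 <- rep(NA_real_, nz); mixf <- numeric(nz)
  for (k in seq_len(nz)) {
    ov <- pmax(0, pmin(bounds, z_hi[k]) - pmax(lo, z_lo[k]))
    top2 <- order(ov, decreasing = TRUE)[1:2]
    phi[k] <- lam_phi[top2[1]]
    f <- if (length(lam_phi) > 1) ov[top2[2]] / sum(ov) else 0
    if (f > 1e-12) {
      phi2[k] <- lam_phi[top2[2]]
      mixf[k] <- f
    }
  }
  # keratocyte and stria voids
  void <- array(FALSE, c(nz, spec$ny, spec$nx))
  px <- spec$pixel_size_um
  x_um <- (seq_len(spec$nx) - 0.5) * px
  y_um <- (seq_len(spec$ny) - 0.5) * px
  z_um <- (seq_len(nz) - 0.5) * dz
  vol <- zmax * spec$nx * px * spec$ny * px
  n_ker <- stats::rpois(1, spec$keratocyte_density * vol)
  semi <- c(7.5, 3, 1.5)  # um, in-plane long axes
  if (n_ker > 0) {
    for (i in seq_len(n_ker)) {
      cx <- stats::runif(1, 0, spec$nx * px)
      cy <- stats::runif(1, 0, spec$ny * px)
      cz <- stats::runif(1, 0, zmax)
      al <- stats::runif(1, 0, pi)
      kz <- which(abs(z_um - cz) <= semi[3])
      if (!length(kz)) next
      dxm <- outer(y_um - cy, x_um - cx, function(yy, xx)
        (xx * cos(al) + yy * sin(al)))
      dym <- outer(y_um - cy, x_um - cx, function(yy, xx)
        (-xx * sin(al) + yy * cos(al)))
      for (k in kz) {
        inside <- (dxm / semi[1])^2 + (dym / semi[2])^2 +
          ((z_um[k] - cz) / semi[3])^2 <= 1
        void[k, , ][inside] <- TRUE
      }
    }
  }
  if (spec$stria_count > 0) {
    tilt <- deg2rad(20); half_th <- 1  # 2 um-thick band
    for (s in seq_len(spec$stria_count)) {
      al <- stats::runif(1, 0, pi)
      u0 <- stats::runif(1, 0, spec$nx * px)
      u <- outer(y_um, x_um, function(yy, xx) xx * cos(al) + yy * sin(al))
      for (k in seq_len(nz)) {
        zs <- zmax - tan(tilt) * (u - u0)
        hit <- abs(z_um[k] - zs) * cos(tilt) <= half_th
        void[k, , ][hit] <- TRUE
      }
    }
  }
  structure(list(phi_deg = phi, phi2_deg = phi2, mix_fraction = mixf,
                 void_mask = void, boundaries_um = bounds,
                 lamella_phi_deg = lam_phi, nz = nz, spec = spec),
            class = "lamellar_phantom")
}

#' Per-voxel ground-truth fields of a phantom
#'
#' Expands the per-plane representation to full `(nz, ny, nx)` arrays:
#' `orientation_field()` gives the primary ground-truth orientation (NA in
#' voids), `amplitude_field()` the signal scale (0 in voids, 1 in tissue),
#' `mix_fraction_field()` the secondary-lamella fraction.
#'
#' @param phantom a `lamellar_phantom`.
#' @return a 3-D array `(nz, ny, nx)`.
#' @export
orientation_field <- function(phantom) {
  stopifnot(inherits(phantom, "lamellar_phantom"))
  d <- dim(phantom$void_mask)
  out <- array(rep(phantom$phi_deg, prod(d[2:3])), d)
  out[phantom$void_mask] <- NA_real_
  out
}

#' @rdname orientation_field
#' @export
amplitude_field <- function(phantom) {
  stopifnot(inherits(phantom, "lamellar_phantom"))
  out <- array(1, dim(phantom$void_mask))
  out[phantom$void_mask] <- 0
  out
}

#' @rdname orientation_field
#' @export
mix_fraction_field <- function(phantom) {
  stopifnot(inherits(phantom, "lamellar_phantom"))
  d <- dim(phantom$void_mask)
  array(rep(phantom$mix_fraction, prod(d[2:3])), d)
}

#' Rotate a phantom by 90 degrees in the image plane
#'
#' Emulates the physical rotation of the sample under the objective used by
#' the perpendicular-acquisition protocol: every orientation gains 90 degrees
#' (mod 180) and the void geometry is rotated in-plane.
#'
#' @param phantom a `lamellar_phantom` (square field).
#' @return the rotated `lamellar_phantom`.
#' @export
rotate_phantom_90 <- function(phantom) {
  stopifnot(inherits(phantom, "lamellar_phantom"))
  d <- dim(phantom$void_mask)
  if (d[2] != d[3]) stop("in-plane rotation requires a square field")
  phantom$phi_deg <- (phantom$phi_deg + 90) %% 180
  phantom$phi2_deg <- (phantom$phi2_deg + 90) %% 180
  phantom$lamella_phi_deg <- (phantom$lamella_phi_deg + 90) %% 180
  v <- phantom$void_mask
  for (k in seq_len(d[1]))
    v[k, , ] <- t(matrix(v[k, , ], d[2], d[3]))[d[3]:1, ]
  phantom$void_mask <- v
  phantom
}

#' Render an epi-detected polarimetric stack from a phantom
#'
#' Every pure tissue voxel emits the single-fibril polarization response at
#' its ground-truth orientation; partial-volume voxels emit, by default, the
#' intensity-weighted (incoherent) sum of the two straddled lamellae's
#' responses with weights `(1 - f, f)` — justified by the ~100 nm epi
#' coherence length — with an optional coherent field-sum mode; void voxels
#' emit 0. With `noise = TRUE` each count is Poisson-distributed around the
#' model mean. The intensity scale is set so that tissue voxels have an
#' angle-averaged mean of `mean_counts` photons.
#'
#' @param phantom a `lamellar_phantom`.
#' @param optics a [fibril_optics()]; only the `chi` ratio matters once
#'   `mean_counts` fixes the scale.
#' @param protocol an [acquisition_protocol()].
#' @param noise logical, apply Poisson photon-counting noise.
#' @param seed RNG seed for the noise draw (required for reproducibility
#'   when `noise = TRUE`).
#' @param mean_counts target angle-averaged counts per tissue pixel; default
#'   taken from the phantom spec. `NULL` keeps the raw optics scale.
#' @param mixing `"incoherent"` (default) or `"coherent"` partial-volume
#'   combination.
#' @return a [pshg_stack()].
#' @export
render_epi_stack <- function(phantom, optics = fibril_optics(),
                             protocol = acquisition_protocol(),
                             noise = TRUE, seed = NULL,
                             mean_counts = phantom$spec$noise_mean_counts,
                             mixing = c("incoherent", "coherent")) {
  stopifnot(inherits(phantom, "lamellar_phantom"),
            inherits(optics, "fibril_optics"),
            inherits(protocol, "acquisition_protocol"))
  mixing <- match.arg(mixing)
  if (!is.null(mean_counts)) {
    a0_unit <- coefficients_from_optics(optics)[["a0"]]
    optics$k_scale <- optics$k_scale * mean_counts / a0_unit
  }
  th <- protocol$angles_deg
  nth <- length(th)
  d <- dim(phantom$void_mask)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  amp <- amplitude_field(phantom)
  counts <- array(0, c(nz, nth, ny, nx))
  for (k in seq_len(nz)) {
    f <- phantom$mix_fraction[k]
    if (f > 0) {
      if (mixing == "incoherent") {
        i_th <- (1 - f) * forward_intensity(optics, phantom$phi_deg[k], th) +
          f * forward_intensity(optics, phantom$phi2_deg[k], th)
      } else {
        i_th <- coherent_mix_intensity(optics, phantom$phi_deg[k],
                                       phantom$phi2_deg[k], f, th)
      }
    } else {
      i_th <- forward_intensity(optics, phantom$phi_deg[k], th)
    }
    plane <- matrix(amp[k, , ], ny, nx)
    for (t in seq_len(nth)) counts[k, t, , ] <- i_th[t] * plane
  }
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    counts[] <- stats::rpois(length(counts), counts)
  }
  pshg_stack(counts, protocol)
}

# Coherent field-sum combination of two lamellae within one voxel: the SHG
# fields (not intensities) add, with amplitude weights (1-f, f). In-plane
# field components per fibril, rotated to the lab frame.
coherent_mix_intensity <- function(optics, phi_a, phi_b, f, theta_deg) {
  cx <- optics$chi_xxx; cy <- optics$chi_xyy
  field <- function(phi) {
    dd <- deg2rad(theta_deg - phi)
    ep <- cx * cos(dd)^2 + cy * sin(dd)^2
    eq <- cy * sin(2 * dd)
    pr <- deg2rad(phi)
    cbind(ep * cos(pr) - eq * sin(pr), ep * sin(pr) + eq * cos(pr))
  }
  e <- (1 - f) * field(phi_a) + f * field(phi_b)
  optics$k_scale * rowSums(e^2)
}

#' Render a striated image from a per-pixel orientation field
#'
#' Produces a sinusoidal stripe pattern whose iso-intensity lines run along
#' the local orientation — the synthetic stand-in for trans-detected SHG
#' images, whose interference striations run along the collagen fibrils.
#' Intensity is `0.5 (1 + cos(2 pi s / period))` with `s` the coordinate
#' perpendicular to the local orientation; NA orientations (voids) render
#' dark.
#'
#' @param phi_deg matrix of per-pixel orientations (degrees), NA = void.
#' @param period_um stripe period (um), must exceed the pixel size.
#' @param pixel_size_um lateral sampling (um).
#' @return image matrix in `[0, 1]`.
#' @export
render_stripes <- function(phi_deg, period_um = 5, pixel_size_um = 1) {
  stopifnot(is.matrix(phi_deg), period_um > pixel_size_um)
  ny <- nrow(phi_deg); nx <- ncol(phi_deg)
  x <- matrix((seq_len(nx) - 0.5) * pixel_size_um, ny, nx, byrow = TRUE)
  y <- matrix((seq_len(ny) - 0.5) * pixel_size_um, ny, nx)
  pr <- deg2rad(phi_deg)
  s <- -x * sin(pr) + y * cos(pr)
  img <- 0.5 * (1 + cos(2 * pi * s / period_um))
  img[is.na(phi_deg)] <- 0
  img
}

#' Render a trans-detected-style striated image of one phantom plane
#'
#' @param phantom a `lamellar_phantom`.
#' @param stripe_period_um stripe period (um), must exceed the pixel size.
#' @param depth_index plane index (1-based).
#' @return image matrix in `[0, 1]`; voids dark.
#' @export
render_trans_image <- function(phantom, stripe_period_um = 5, depth_index) {
  stopifnot(inherits(phantom, "lamellar_phantom"),
            depth_index >= 1, depth_index <= phantom$nz)
  phi <- orientation_field(phantom)[depth_index, , ]
  render_stripes(matrix(phi, dim(phantom$void_mask)[2]),
                 stripe_period_um, phantom$spec$pixel_size_um)
}
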