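# Shared fixtures and independent oracles.

# Quadrature projection of the forward model on the 2nd/4th harmonics:
# midpoint rule on a dense uniform grid (spectrally exact for the band-
# limited polarization response), independent of the closed form under test.
quad_coefficients <- function(optics, n = 4096) {
  th <- (seq_len(n) - 0.5) * 180 / n
  i <- forward_intensity(optics, 0, th)
  c(a0 = mean(i),
    a2 = 2 * mean(i * cos(2 * th * pi / 180)),
    a4 = 2 * mean(i * cos(4 * th * pi / 180)))
}

# Noise-free polarization stack of a spatially uniform single fibril.
single_fibril_stack <- function(phi_deg, optics = fibril_optics(),
                                protocol = acquisition_protocol(),
                                ny = 2, nx = 2) {
  nth <- length(protocol$angles_deg)
  counts <- array(0, c(1, nth, ny, nx))
  for (t in seq_len(nth))
    counts[1, t, , ] <- forward_intensity(optics, phi_deg,
                                          protocol$angles_deg[t])
  pshg_stack(counts, protocol)
}

# Equal incoherent mixture of two fibril orientations in every pixel.
mixed_fibril_stack <- function(phi_a, phi_b, f = 0.5,
                               optics = fibril_optics(),
                               protocol = acquisition_protocol(),
                               ny = 2, nx = 2) {
  nth <- length(protocol$angles_deg)
  counts <- array(0, c(1, nth, ny, nx))
  for (t in seq_len(nth)) {
    th <- protocol$angles_deg[t]
    counts[1, t, , ] <- (1 - f) * forward_intensity(optics, phi_a, th) +
      f * forward_intensity(optics, phi_b, th)
  }
  pshg_stack(counts, protocol)
}

# A deterministic, non-trivial 180-bin test distribution.
lumpy_distribution <- function(seed = 42) {
  set.seed(seed)
  orientation_distribution(stats::runif(180)^3 + 0.01)
}

roll_dist <- function(d, k) pshg:::roll_distribution(d, k)

# Single-plane phantom with a fixed constant orientation and no voids.
flat_phantom <- function(phi_deg, nx = 32, ny = 32, nz_um = 1,
                         mean_counts = 100, seed = 1) {
  spec <- phantom_spec(stroma_thickness_um = nz_um,
                       lamella_thickness_range_um = c(nz_um, nz_um),
                       orientation_law = vm_mixture(0, 1, 0, 50, 0, 90, 1),
                       keratocyte_density = 0, stria_count = 0,
                       noise_mean_counts = mean_counts,
                       nx = nx, ny = ny, seed = seed)
  ph <- build_phantom(spec)
  ph$phi_deg[] <- phi_deg
  ph$phi2_deg[] <- NA_real_
  ph$mix_fraction[] <- 0
  ph
}
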