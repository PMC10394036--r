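# Depth-resolved orientation distributions: 1-degree circular histograms,
# angular registration, normalized L1 distances, sliding-window depth
# profiles, and the perpendicular-acquisition averaging protocol.

#' Construct an orientation distribution from bin densities
#'
#' Wraps a pre-computed 180-bin (1 degree) density vector as an
#' `orientation_distribution`, e.g. a model law evaluated on the bin grid.
#' The vector is renormalized to unit mass.
#'
#' @param density non-negative numeric vector of length 180.
#' @param n_valid pixel count annotation (default 0).
#' @param depth_range_um optional `(z_lo, z_hi)` annotation (um).
#' @return an `orientation_distribution`.
#' @export
orientation_distribution <- function(density, n_valid = 0,
                                     depth_range_um = NULL) {
  stopifnot(length(density) == 180, all(density >= 0))
  s <- sum(density)
  structure(list(density = if (s > 0) density / s else density,
                 n_valid = n_valid, depth_range_um = depth_range_um,
                 empty = s == 0),
            class = "orientation_distribution")
}

#' Evaluate a mixture law on the histogram bin grid
#'
#' Exact binned version of [mixture_pdf()]: the per-radian density at the
#' 180 bin centers, normalized to unit mass — the noise-free counterpart of
#' a measured orientation histogram, used for fit-recovery checks.
#'
#' @param params a [vm_mixture()].
#' @return an `orientation_distribution`.
#' @export
binned_mixture <- function(params) {
  orientation_distribution(mixture_pdf(params, 0:179 + 0.5))
}

#' Normalized circular orientation histogram
#'
#' Counts valid-pixel orientations into 180 half-open bins `[k, k+1)` degrees
#' and normalizes by the total number of valid pixels. Input can be an
#' `orientation_map` (optionally restricted to a slab of depth planes) or a
#' bare numeric vector of orientations.
#'
#' @param x an `orientation_map` or numeric vector of angles in degrees.
#' @param z_range optional integer vector of depth-plane indices to include.
#' @param depth_range_um optional `(z_lo, z_hi)` annotation stored on the
#'   result (um).
#' @return an object of class `orientation_distribution`: `density` (180
#'   bins, summing to 1 when non-empty), `n_valid`, `depth_range_um`,
#'   `empty` flag. Zero valid pixels gives an all-zero, `empty = TRUE`
#'   distribution rather than NaNs.
#' @export
orientation_histogram <- function(x, z_range = NULL, depth_range_um = NULL) {
  if (inherits(x, "orientation_map")) {
    phi <- x$phi_deg
    val <- x$valid
    if (!is.null(z_range)) {
      phi <- phi[z_range, , , drop = FALSE]
      val <- val[z_range, , , drop = FALSE]
    }
    phi <- phi[val & !is.na(phi)]
  } else {
    phi <- x[!is.na(x)]
  }
  phi <- wrap_orientation(phi)
  n <- length(phi)
  dens <- if (n > 0) tabulate(floor(phi) + 1L, nbins = 180L) / n else
    rep(0, 180)
  structure(list(density = dens, n_valid = n,
                 depth_range_um = depth_range_um, empty = n == 0),
            class = "orientation_distribution")
}

# Circular shift of a 180-bin density: mass at bin i moves to bin i + k.
roll_distribution <- function(dist, k) {
  stopifnot(inherits(dist, "orientation_distribution"))
  k <- ((round(k)) %% 180L)
  if (k != 0)
    dist$density <- dist$density[((seq_len(180) - 1 - k) %% 180) + 1]
  dist
}

#' L1 distance between two orientation distributions
#'
#' Sum over bins of the absolute density difference. Two normalized
#' distributions are at most 2 apart (disjoint supports), so the normalized
#' form divides by 2 to land in `[0, 1]`.
#'
#' @param dist_a,dist_b `orientation_distribution` objects on the same
#'   binning.
#' @param normalized divide the raw distance by 2 (default TRUE).
#' @return the (normalized) distance.
#' @export
l1_distance <- function(dist_a, dist_b, normalized = TRUE) {
  stopifnot(inherits(dist_a, "orientation_distribution"),
            inherits(dist_b, "orientation_distribution"),
            length(dist_a$density) == length(dist_b$density))
  d <- sum(abs(dist_a$density - dist_b$density))
  if (normalized) d / 2 else d
}

#' Angular registration of two orientation distributions
#'
#' Exhaustively searches the 180 integer-degree circular shifts of `dist_b`
#' and returns the rotation of `dist_b` relative to `dist_a` that minimizes
#' their L1 distance, i.e. the shift `k` such that un-rotating `dist_b` by
#' `k` best matches `dist_a`. Ties are broken by the smallest folded absolute
#' shift, then by the smaller (positive) representative.
#'
#' @param dist_a,dist_b non-empty `orientation_distribution` objects.
#' @return integer shift in degrees, in `[0, 180)`; satisfies
#'   `register_distributions(d, roll(d, k)) == k`.
#' @export
register_distributions <- function(dist_a, dist_b) {
  stopifnot(!dist_a$empty, !dist_b$empty)
  ks <- 0:179
  costs <- vapply(ks, function(k)
    l1_distance(dist_a, roll_distribution(dist_b, -k), normalized = FALSE),
    numeric(1))
  best <- ks[costs <= min(costs) + 1e-12]
  fold <- pmin(best, 180 - best)
  best[order(fold, best)][1]
}

#' Split a depth range into stromal thirds
#'
#' Three contiguous equal spans covering `[z_lo, z_hi)`, the anterior /
#' middle / posterior analysis regions. With `n_slices` given, returns slice
#' index ranges instead; when the slice count is not divisible by 3 the
#' remainder goes to the posterior third.
#'
#' @param z_lo,z_hi depth range (um), `z_hi > z_lo`.
#' @param n_slices optional number of equally spaced depth planes in the
#'   range (must be at least 3).
#' @return with `n_slices = NULL`, a list of three `c(lo, hi)` spans (um);
#'   otherwise a list of three integer index vectors.
#' @export
split_thirds <- function(z_lo, z_hi, n_slices = NULL) {
  stopifnot(z_hi > z_lo)
  if (is.null(n_slices)) {
    b <- z_lo + (z_hi - z_lo) * c(0, 1, 2, 3) / 3
    return(list(anterior = c(b[1], b[2]), middle = c(b[2], b[3]),
                posterior = c(b[3], b[4])))
  }
  if (n_slices < 3) stop("need at least 3 depth slices to split into thirds")
  k <- floor(n_slices / 3)
  list(anterior = seq_len(k), middle = seq_len(k) + k,
       posterior = seq((2 * k + 1), n_slices))
}

#' Depth profile of the registered distance between two stacks
#'
#' Per-depth orientation histograms are computed for both map stacks, the
#' second is un-rotated by the (pre-computed) registration shift, and at
#' every depth the raw L1 distances are averaged over a sliding axial window
#' (default +/- 20 um, truncated at the volume boundaries) and normalized to
#' the maximum distance of 2. Depths whose histograms are empty are dropped
#' from the window average.
#'
#' @param maps_a,maps_b `orientation_map` stacks on the same z grid.
#' @param shift_deg registration shift of `maps_b` relative to `maps_a`
#'   (from [register_distributions()] on the anterior region).
#' @param window_um full sliding-window width (um, default 40).
#' @param axial_step_um z spacing (um).
#' @return data frame `depth_um`, `distance` (normalized, `[0, 1]`),
#'   `n_slices` (slices contributing to the window), with attribute
#'   `registration_shift_deg`.
#' @export
distance_profile <- function(maps_a, maps_b, shift_deg = 0, window_um = 40,
                             axial_step_um = 1) {
  stopifnot(inherits(maps_a, "orientation_map"),
            inherits(maps_b, "orientation_map"))
  nz <- dim(maps_a$phi_deg)[1]
  if (dim(maps_b$phi_deg)[1] != nz)
    stop("map stacks must share the same z grid")
  ha <- lapply(seq_len(nz), function(k) orientation_histogram(maps_a, k))
  hb <- lapply(seq_len(nz), function(k)
    roll_distribution(orientation_histogram(maps_b, k), -shift_deg))
  raw <- vapply(seq_len(nz), function(k) {
    if (ha[[k]]$empty || hb[[k]]$empty) NA_real_
    else l1_distance(ha[[k]], hb[[k]], normalized = FALSE)
  }, numeric(1))
  half <- max(0L, floor((window_um / 2) / axial_step_um))
  dist <- vapply(seq_len(nz), function(k) {
    w <- raw[max(1, k - half):min(nz, k + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE) / 2
  }, numeric(1))
  out <- data.frame(depth_um = (seq_len(nz) - 0.5) * axial_step_um,
                    distance = dist,
                    n_slices = vapply(seq_len(nz), function(k)
                      sum(!is.na(raw[max(1, k - half):min(nz, k + half)])),
                      numeric(1)))
  attr(out, "registration_shift_deg") <- shift_deg
  out
}

#' Average two perpendicular-acquisition distributions
#'
#' Implements the protocol that compensates opposite depth-dependent
#' polarization distortions: the distribution extracted from the stack
#' acquired with the sample physically rotated by 90 degrees is numerically
#' rotated back by exactly 90 bins and averaged bin-wise with the first
#' acquisition's distribution, then renormalized.
#'
#' @param dist_1 distribution from the reference acquisition.
#' @param dist_2_rotated_input distribution from the 90-degree-rotated
#'   acquisition (still in its own frame).
#' @return the averaged `orientation_distribution`.
#' @export
average_perpendicular <- function(dist_1, dist_2_rotated_input) {
  b <- roll_distribution(dist_2_rotated_input, -90)
  dens <- (dist_1$density + b$density) / 2
  s <- sum(dens)
  structure(list(density = if (s > 0) dens / s else dens,
                 n_valid = dist_1$n_valid + b$n_valid,
                 depth_range_um = dist_1$depth_range_um,
                 empty = s == 0),
            class = "orientation_distribution")
}
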