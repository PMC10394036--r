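# Internal helpers shared across modules: angle conventions and the uniform
# box filter used both for polarimetric pre-averaging and for structure-tensor
# window averaging.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an orientation to [0, 180)
#'
#' Orientations are axial (period 180 degrees): a fibril at 190 degrees is the
#' same fibril as at 10 degrees.
#'
#' @param phi_deg numeric vector of angles in degrees.
#' @return angles wrapped to `[0, 180)`.
#' @export
wrap_orientation <- function(phi_deg) phi_deg %% 180

#' Folded angular difference between two orientations
#'
#' Absolute difference between axial angles (period 180 degrees), folded to
#' `[0, 90]`: the smallest rotation mapping one orientation onto the other.
#' Handles the wrap-around, so `angular_difference(179, 1)` is 2, not 178.
#'
#' @param phi_a_deg,phi_b_deg orientations in degrees (vectorized).
#' @return folded differences in degrees, in `[0, 90]`.
#' @export
angular_difference <- function(phi_a_deg, phi_b_deg) {
  d <- abs(phi_a_deg - phi_b_deg) %% 180
  pmin(d, 180 - d)
}

# Uniform w x w moving average with reflect (symmetric) boundary padding.
# For even w the window covers offsets -(w/2 - 1) .. +w/2 in each dimension.
# Implemented with an integral image so cost is independent of w.
box_filter <- function(m, w) {
  stopifnot(is.matrix(m), w >= 1, w == round(w))
  if (w == 1) return(m)
  n <- nrow(m); p <- ncol(m)
  if (w > n || w > p) stop("box_filter: window larger than the frame")
  lo <- floor((w - 1) / 2); hi <- w - 1 - lo
  ridx <- c(rev(seq_len(lo)), seq_len(n), seq(n, by = -1L, length.out = hi))
  cidx <- c(rev(seq_len(lo)), seq_len(p), seq(p, by = -1L, length.out = hi))
  mp <- m[ridx, cidx, drop = FALSE]
  # windowed sums along rows
  cs <- rbind(0, apply(mp, 2, cumsum))
  rs <- cs[(w + 1):(n + w), , drop = FALSE] - cs[1:n, , drop = FALSE]
  # then along columns
  cs2 <- cbind(0, t(apply(rs, 1, cumsum)))
  out <- cs2[, (w + 1):(p + w), drop = FALSE] - cs2[, 1:p, drop = FALSE]
  out / (w * w)
}

# Gaussian-window smoothing (separable), used for the OrientationJ-style
# Gaussian weighting option of the structure tensor. sigma in pixels.
gaussian_filter <- function(m, sigma) {
  stopifnot(is.matrix(m), sigma > 0)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * (seq(-half, half) / sigma)^2)
  k <- k / sum(k)
  n <- nrow(m); p <- ncol(m)
  ridx <- c(rev(seq_len(half)), seq_len(n), seq(n, by = -1L, length.out = half))
  cidx <- c(rev(seq_len(half)), seq_len(p), seq(p, by = -1L, length.out = half))
  mp <- m[ridx, cidx, drop = FALSE]
  out <- apply(mp, 2, function(col) stats::filter(col, k, sides = 2))
  out <- out[(half + 1):(half + n), , drop = FALSE]
  out <- t(apply(out, 1, function(row) stats::filter(row, k, sides = 2)))
  out[, (half + 1):(half + p), drop = FALSE]
}

# Circular (axial) standard deviation of orientations in degrees: angles are
# doubled, the resultant length R of the doubled angles gives
# sd = sqrt(-2 log R) / 2 (Mardia & Jupp), converted back to degrees.
circular_sd_axial <- function(phi_deg) {
  z <- exp(2i * deg2rad(phi_deg))
  r <- Mod(mean(z))
  rad2deg(sqrt(-2 * log(r)) / 2)
}

# Circular mean of full-circle angles in degrees (used on doubled angles).
circular_mean_deg <- function(angles_deg) {
  z <- mean(exp(1i * deg2rad(angles_deg)))
  rad2deg(Arg(z)) %% 360
}
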