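# Gradient structure tensor on striated images: local stripe orientation
# with a coherency confidence measure, and the pixel-wise angular comparison
# of structure-tensor maps against polarimetric orientation maps.

#' Gradient structure tensor orientation and coherency
#'
#' Computes per-pixel image gradients by central differences (reflect
#' padding), window-averages the tensor components `J_xx`, `J_xy`, `J_yy`,
#' and returns the orientation of the iso-intensity structures together with
#' the coherency `(l_max - l_min) / (l_max + l_min)` of the tensor
#' eigenvalues (1 = perfectly oriented texture, 0 = isotropic; set to 0
#' where the tensor trace vanishes, with undefined orientation).
#'
#' Orientations are measured in the package's image frame (x = column,
#' y = row, counter-clockwise from +X toward +Y), so a stripe pattern
#' rendered along `phi` by [render_stripes()] is recovered at `phi`.
#'
#' @param image numeric matrix (at least `window` in both dimensions).
#' @param window averaging window in pixels (default 6).
#' @param weighting `"box"` (uniform, default) or `"gaussian"` (sigma =
#'   window / 2, closer to OrientationJ's weighting).
#' @return an object of class `structure_tensor_map` with matrices
#'   `orientation_deg` (`[0, 180)`, NA where undefined), `coherency`
#'   (`[0, 1]`) and `valid`.
#' @export
structure_tensor <- function(image, window = 6,
                             weighting = c("box", "gaussian")) {
  stopifnot(is.matrix(image), nrow(image) >= window, ncol(image) >= window)
  weighting <- match.arg(weighting)
  n <- nrow(image); p <- ncol(image)
  # central differences with reflected edges
  gx <- (image[, c(2:p, p - 1)] - image[, c(2, 1:(p - 1))]) / 2
  gy <- (image[c(2:n, n - 1), ] - image[c(2, 1:(n - 1)), ]) / 2
  smooth <- if (weighting == "box") function(m) box_filter(m, window)
  else function(m) gaussian_filter(m, window / 2)
  jxx <- smooth(gx * gx)
  jyy <- smooth(gy * gy)
  jxy <- smooth(gx * gy)
  tr <- jxx + jyy
  disc <- sqrt((jxx - jyy)^2 + 4 * jxy^2)
  coh <- ifelse(tr > .Machine$double.eps, disc / tr, 0)
  orient <- (rad2deg(0.5 * atan2(-2 * jxy, jyy - jxx))) %% 180
  undef <- tr <= .Machine$double.eps
  orient[undef] <- NA_real_
  structure(list(orientation_deg = orient, coherency = coh, valid = !undef,
                 window = window, weighting = weighting),
            class = "structure_tensor_map")
}

#' Filter a structure-tensor map by coherency
#'
#' @param map a `structure_tensor_map`.
#' @param threshold coherency cutoff in `[0, 1]` (0.7 for the quantitative
#'   comparisons; lower values such as 0.2 are display-only).
#' @return the map with `valid` restricted to `coherency >= threshold`.
#' @export
coherency_filter <- function(map, threshold = 0.7) {
  stopifnot(inherits(map, "structure_tensor_map"),
            threshold >= 0, threshold <= 1)
  map$valid <- map$valid & map$coherency >= threshold
  map$coherency_threshold <- threshold
  map
}

#' Depth profile of the P-SHG vs structure-tensor angular difference
#'
#' For every depth plane, the mean folded angular difference between the
#' polarimetric orientation map and the structure-tensor orientation map is
#' computed over the pixels valid under both filters (`R^2 >= r2_min` and
#' coherency `>= coh_min`); the number of contributing pixels `N(Z)` is
#' recorded and depths with none are flagged NA.
#'
#' @param pshg an `orientation_map` stack.
#' @param st a list of `structure_tensor_map`s, one per depth plane.
#' @param r2_min R^2 filter threshold (default 0.7).
#' @param coh_min coherency filter threshold (default 0.7).
#' @param axial_step_um z spacing (um) for the depth column.
#' @return data frame `depth_um`, `mean_abs_diff_deg` (`[0, 90]`, NA where
#'   no valid pixels), `n_valid`.
#' @export
compare_maps <- function(pshg, st, r2_min = 0.7, coh_min = 0.7,
                         axial_step_um = 1) {
  stopifnot(inherits(pshg, "orientation_map"), is.list(st))
  nz <- dim(pshg$phi_deg)[1]
  if (length(st) != nz) stop("one structure-tensor map per depth plane required")
  out <- data.frame(depth_um = (seq_len(nz) - 0.5) * axial_step_um,
                    mean_abs_diff_deg = NA_real_, n_valid = 0L)
  for (k in seq_len(nz)) {
    s <- st[[k]]
    stopifnot(inherits(s, "structure_tensor_map"))
    pphi <- matrix(pshg$phi_deg[k, , ], dim(pshg$phi_deg)[2])
    pval <- matrix(pshg$valid[k, , ], dim(pshg$phi_deg)[2])
    pr2 <- matrix(pshg$r2[k, , ], dim(pshg$phi_deg)[2])
    if (!all(dim(pphi) == dim(s$orientation_deg)))
      stop("P-SHG and structure-tensor grids do not match")
    ok <- pval & !is.na(pr2) & pr2 >= r2_min &
      s$valid & s$coherency >= coh_min & !is.na(s$orientation_deg)
    n <- sum(ok)
    out$n_valid[k] <- n
    if (n > 0)
      out$mean_abs_diff_deg[k] <-
        mean(angular_difference(pphi[ok], s$orientation_deg[ok]))
  }
  out
}
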