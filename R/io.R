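# File formats and rendering: multi-page TIFF stacks with JSON sidecars,
# orientation-map TIFF export, HSV color renderings and transverse (XZ)
# reconstructions.

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path)

#' Write / read a polarimetric stack as multi-page TIFF + JSON sidecar
#'
#' Pages are ordered z-major then angle (all angles of plane 1, then plane
#' 2, ...), stored as 16-bit unsigned counts; the sidecar records the
#' acquisition protocol, array dimensions and provenance so the round trip
#' is lossless for integer counts up to 65535.
#'
#' @param stack a [pshg_stack()] with integer-valued counts.
#' @param path output TIFF path (`.tif`); the sidecar is written next to it
#'   with extension `.json`.
#' @param provenance optional character scalar stored in the sidecar.
#' @return `write_stack` invisibly returns `path`; `read_stack` returns the
#'   [pshg_stack()].
#' @export
write_stack <- function(stack, path, provenance = NULL) {
  stopifnot(inherits(stack, "pshg_stack"))
  d <- dim(stack$counts)
  if (max(stack$counts) > 65535)
    stop("counts exceed the 16-bit TIFF range")
  pages <- vector("list", d[1] * d[2])
  i <- 1L
  for (z in seq_len(d[1])) for (t in seq_len(d[2])) {
    pages[[i]] <- matrix(round(stack$counts[z, t, , ]) / 65535, d[3], d[4])
    i <- i + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(format = "pshg_stack", page_order = "z_major_then_angle",
               nz = d[1], n_angles = d[2], ny = d[3], nx = d[4],
               count_scale = 65535,
               protocol = stack$protocol[c("angles_deg", "pixel_size_um",
                                           "axial_step_um")],
               provenance = provenance)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing JSON sidecar for stack: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$nz) || is.null(meta$n_angles))
    stop("corrupt sidecar: missing stack dimensions in ", sc)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) != meta$nz * meta$n_angles)
    stop("TIFF page count (", length(pages), ") does not match sidecar (",
         meta$nz * meta$n_angles, ")")
  counts <- array(0, c(meta$nz, meta$n_angles, meta$ny, meta$nx))
  i <- 1L
  for (z in seq_len(meta$nz)) for (t in seq_len(meta$n_angles)) {
    counts[z, t, , ] <- pages[[i]]
    i <- i + 1L
  }
  proto <- acquisition_protocol(unlist(meta$protocol$angles_deg),
                                meta$protocol$pixel_size_um,
                                meta$protocol$axial_step_um)
  pshg_stack(counts, proto)
}

#' Write an orientation map stack as TIFF channels
#'
#' Three pages per depth plane: orientation in tenths of degrees (65535 =
#' undefined), `R^2 * 1e4`, and mean SHG counts — all 16-bit — plus a
#' validity-mask TIFF alongside.
#'
#' @param map an `orientation_map`.
#' @param path output TIFF path; the mask is written to `*_mask.tif`.
#' @return invisibly, `path`.
#' @export
write_orientation_map <- function(map, path) {
  stopifnot(inherits(map, "orientation_map"))
  d <- dim(map$phi_deg)
  pages <- list(); masks <- list()
  for (k in seq_len(d[1])) {
    phi <- matrix(map$phi_deg[k, , ], d[2])
    enc <- round(phi * 10)
    enc[is.na(enc)] <- 65535
    r2 <- matrix(pmax(0, map$r2[k, , ]), d[2])
    r2[is.na(r2)] <- 0
    shg <- matrix(map$mean_shg[k, , ], d[2])
    pages <- c(pages, list(enc / 65535, round(r2 * 1e4) / 65535,
                           pmin(round(shg), 65535) / 65535))
    masks <- c(masks, list(matrix(as.numeric(map$valid[k, , ]), d[2])))
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  tiff::writeTIFF(masks, sub("\\.tiff?$", "_mask.tif", path),
                  bits.per.sample = 8L)
  invisible(path)
}

#' HSV rendering of an orientation map
#'
#' Hue codes the orientation (`phi / 180` of the color wheel). Two modes:
#' `value = "r2"` uses full saturation with brightness = `R^2`;
#' `value = "shg"` uses saturation = `R^2` and brightness = the mean SHG
#' signal (normalized to its maximum). Invalid pixels are black.
#'
#' @param map an `orientation_map`.
#' @param z depth-plane index (default 1).
#' @param value `"r2"` or `"shg"` brightness source.
#' @return an `(ny, nx, 3)` RGB array in `[0, 1]`.
#' @export
render_hsv <- function(map, z = 1, value = c("r2", "shg")) {
  stopifnot(inherits(map, "orientation_map"))
  value <- match.arg(value)
  d <- dim(map$phi_deg)
  phi <- matrix(map$phi_deg[z, , ], d[2])
  r2 <- matrix(pmin(1, pmax(0, map$r2[z, , ])), d[2])
  ok <- matrix(map$valid[z, , ], d[2]) & !is.na(phi)
  h <- (phi %% 180) / 180
  h[!ok] <- 0
  r2[!ok | is.na(r2)] <- 0
  if (value == "r2") {
    s <- matrix(1, d[2], d[3]); v <- r2
  } else {
    shg <- matrix(map$mean_shg[z, , ], d[2])
    mx <- max(shg, na.rm = TRUE)
    v <- if (mx > 0) shg / mx else shg * 0
    s <- r2
  }
  v[!ok] <- 0
  rgb <- grDevices::col2rgb(grDevices::hsv(h, pmin(1, s), pmin(1, v))) / 255
  out <- array(0, c(d[2], d[3], 3))
  out[, , 1] <- matrix(rgb[1, ], d[2])
  out[, , 2] <- matrix(rgb[2, ], d[2])
  out[, , 3] <- matrix(rgb[3, ], d[2])
  out
}

#' Transverse (XZ) reconstruction of a volume along one line
#'
#' Resamples one image line across all depths into an XZ section, the view
#' in which stacked lamellae, keratocytes and striae are recognizable. The
#' physical aspect ratio (axial step over pixel size) is attached as an
#' attribute for plotting.
#'
#' @param arr3d array `(nz, ny, nx)` (e.g. `mean_shg` of a map stack or
#'   [orientation_field()] of a phantom).
#' @param line row (`axis = "y"`) or column (`axis = "x"`) index to extract.
#' @param axis which in-plane axis the line runs along.
#' @param pixel_size_um,axial_step_um voxel pitch (um).
#' @return matrix `(nz, nx or ny)` with attribute `aspect_ratio` =
#'   `axial_step_um / pixel_size_um`.
#' @export
transverse_reconstruction <- function(arr3d, line, axis = c("y", "x"),
                                      pixel_size_um = 1, axial_step_um = 1) {
  stopifnot(length(dim(arr3d)) == 3, dim(arr3d)[1] >= 2)
  axis <- match.arg(axis)
  out <- if (axis == "y") arr3d[, line, ] else arr3d[, , line]
  attr(out, "aspect_ratio") <- axial_step_um / pixel_size_um
  out
}

#' Write an orientation distribution as CSV
#'
#' Columns `bin_start_deg` (degrees) and `density` (fraction per 1-degree
#' bin); the header comment line states units.
#'
#' @param dist an `orientation_distribution`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_distribution_csv <- function(dist, path) {
  stopifnot(inherits(dist, "orientation_distribution"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# bin_start_deg: degrees; density: fraction per 1-degree bin",
             con)
  utils::write.csv(data.frame(bin_start_deg = 0:179,
                              density = round(dist$density, 9)),
                   con, row.names = FALSE)
  invisible(path)
}

#' Polar-plot coordinates of an orientation distribution
#'
#' Orientations carry no polarity, so the half-circle distribution is
#' extended to `phi + 180` for display; returns the closed polygon in
#' Cartesian coordinates for a base-graphics or grid polar plot.
#'
#' @param dist an `orientation_distribution`.
#' @param smooth_deg optional plotting re-bin width in degrees (default 5).
#' @return data frame `angle_deg`, `radius`, `x`, `y` over `[0, 360)`.
#' @export
polar_plot_coords <- function(dist, smooth_deg = 5) {
  stopifnot(inherits(dist, "orientation_distribution"))
  k <- max(1L, round(smooth_deg))
  g <- floor((0:179) / k)
  r_half <- as.numeric(tapply(dist$density, g, mean))[g + 1]
  ang <- c(0:179, 180:359)
  r <- c(r_half, r_half)
  data.frame(angle_deg = ang, radius = r,
             x = r * cos(deg2rad(ang)), y = r * sin(deg2rad(ang)))
}
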