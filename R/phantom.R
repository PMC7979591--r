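#' Geometric phantom specification
#'
#' A 2D digital liver phantom: an elliptical liver on a background, with
#' optional small circular "vessels" excluded from liver parenchyma.
#' Stands in for patient anatomy so the full pipeline is testable
#' without any acquisition.
#'
#' @param grid_shape Integer vector (rows, cols).
#' @param pixel_spacing Pixel size in mm (> 0), isotropic.
#' @param liver_center Ellipse centre in pixel coordinates (row, col).
#' @param liver_axes Ellipse semi-axes in mm (row, col direction).
#' @param vessels List of vessels, each `list(center = c(row, col),
#'   radius_mm = r)`; must lie inside the liver.
#' @return An object of class `"hepiron_phantom_spec"`.
#' @export
phantom_spec <- function(grid_shape, pixel_spacing, liver_center,
                         liver_axes, vessels = list()) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 4L),
            pixel_spacing > 0, length(liver_center) == 2L,
            length(liver_axes) == 2L, all(liver_axes > 0))
  ax_px <- liver_axes / pixel_spacing
  if (liver_center[1] - ax_px[1] < 1 || liver_center[1] + ax_px[1] > grid_shape[1] ||
      liver_center[2] - ax_px[2] < 1 || liver_center[2] + ax_px[2] > grid_shape[2]) {
    stop("liver ellipse does not fit inside the grid")
  }
  for (v in vessels) {
    d <- (v$center - liver_center) * pixel_spacing
    if (sum((d / liver_axes)^2) > 1) stop("vessel lies outside the liver")
  }
  structure(list(grid_shape = grid_shape, pixel_spacing = pixel_spacing,
                 liver_center = liver_center, liver_axes = liver_axes,
                 vessels = vessels),
            class = "hepiron_phantom_spec")
}

.pixel_grids <- function(shape) {
  list(row = matrix(seq_len(shape[1]), shape[1], shape[2]),
       col = matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE))
}

#' Label map of a phantom
#'
#' @param spec A [phantom_spec()].
#' @return Character matrix with values `"background"`, `"liver"`,
#'   `"vessel"` (pixel-centre inclusion rule).
#' @export
phantom_labels <- function(spec) {
  g <- .pixel_grids(spec$grid_shape)
  dr <- (g$row - spec$liver_center[1]) * spec$pixel_spacing
  dc <- (g$col - spec$liver_center[2]) * spec$pixel_spacing
  lab <- matrix("background", spec$grid_shape[1], spec$grid_shape[2])
  lab[(dr / spec$liver_axes[1])^2 + (dc / spec$liver_axes[2])^2 <= 1] <- "liver"
  for (v in spec$vessels) {
    if (v$radius_mm <= 0) next # zero-area disc contains no pixel
    dvr <- (g$row - v$center[1]) * spec$pixel_spacing
    dvc <- (g$col - v$center[2]) * spec$pixel_spacing
    lab[dvr^2 + dvc^2 <= v$radius_mm^2 & lab == "liver"] <- "vessel"
  }
  lab
}

#' Build parameter maps for a phantom
#'
#' Assigns a [tissue_state()] to each region and returns per-voxel
#' water, fat and R2* maps.
#'
#' @param spec A [phantom_spec()].
#' @param liver_state Tissue state of liver parenchyma.
#' @param vessel_state Tissue state of vessel voxels (default: water-only
#'   slow-decaying blood surrogate).
#' @param background_state Tissue state outside the body region
#'   (default: zero signal).
#' @return List of matrices `w`, `f`, `r2star` plus the `labels` matrix
#'   and the `spec`.
#' @export
make_phantom <- function(spec, liver_state,
                         vessel_state = tissue_state(60, 0, 30),
                         background_state = tissue_state(0, 0, 0)) {
  stopifnot(inherits(spec, "hepiron_phantom_spec"))
  lab <- phantom_labels(spec)
  pick <- function(field) {
    m <- matrix(background_state[[field]], spec$grid_shape[1],
                spec$grid_shape[2])
    m[lab == "liver"] <- liver_state[[field]]
    m[lab == "vessel"] <- vessel_state[[field]]
    m
  }
  list(w = pick("w"), f = pick("f"), r2star = pick("r2star"),
       labels = lab, spec = spec)
}

#' Simulate a multi-echo acquisition of a phantom
#'
#' Draws the magnitude signal at every voxel and echo as a Rice variate
#' around the noiseless forward model of the protocol.  In
#' fat-saturated mode (the CHESS reference sequence) the fat amplitude
#' is attenuated to `residual_fat * f` before simulation, emulating
#' imperfect spectral saturation.  Noise is independent across voxels
#' and echoes.
#'
#' @param maps Parameter maps from [make_phantom()] (or any list with
#'   matrices `w`, `f`, `r2star` of equal shape).
#' @param proto A [protocol()].
#' @param sigma Noise standard deviation (>= 0); 0 gives the noiseless
#'   forward model exactly.
#' @param fat_saturated Emulate CHESS fat saturation.
#' @param residual_fat Residual fat fraction surviving saturation
#'   (default 0.05).
#' @param spectrum Fat spectrum (default [default_fat_spectrum()]).
#' @param seed Optional integer; when given, acquisition is reproducible.
#' @return 3D array rows x cols x echoes.
#' @export
acquire <- function(maps, proto, sigma, fat_saturated = FALSE,
                    residual_fat = 0.05, spectrum = default_fat_spectrum(),
                    seed = NULL) {
  if (!all(dim(maps$w) == dim(maps$f)) ||
      !all(dim(maps$w) == dim(maps$r2star))) {
    stop("parameter maps must share the same shape")
  }
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  te <- echo_times(proto)
  cf <- fat_dephasing(spectrum, te, proto$field_strength)
  f_eff <- if (fat_saturated) residual_fat * maps$f else maps$f
  shape <- dim(maps$w)
  out <- array(0, c(shape, length(te)))
  for (k in seq_along(te)) {
    nu <- sqrt(pmax(maps$w^2 + 2 * maps$w * f_eff * Re(cf[k]) +
                      f_eff^2 * Mod(cf[k])^2, 0)) * exp(-maps$r2star * te[k])
    out[, , k] <- if (sigma == 0) nu else {
      matrix(rician_sample(as.vector(nu), sigma), shape[1], shape[2])
    }
  }
  out
}
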