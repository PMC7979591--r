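#' Region-of-interest specification
#'
#' A circular liver ROI, as placed by a reader: two in the right lobe
#' and one in the left.  The study protocol used diameters of 10-13 mm
#' giving areas of 0.72-1.15 cm^2; [roi_mask()] warns when a rasterized
#' mask falls outside that band.
#'
#' @param center Pixel coordinates (row, col) of the ROI centre.
#' @param diameter_mm Diameter in mm; default bounds \[10, 13\] mm are
#'   checked unless `diameter_bounds` is widened.
#' @param label One of `"right_lobe_1"`, `"right_lobe_2"`, `"left_lobe"`.
#' @param diameter_bounds Allowed diameter range in mm.
#' @return An object of class `"hepiron_roi_spec"`.
#' @export
roi_spec <- function(center, diameter_mm,
                     label = c("right_lobe_1", "right_lobe_2", "left_lobe"),
                     diameter_bounds = c(10, 13)) {
  label <- match.arg(label)
  stopifnot(length(center) == 2L, diameter_mm > 0)
  if (diameter_mm < diameter_bounds[1] || diameter_mm > diameter_bounds[2]) {
    stop(sprintf("ROI diameter %.1f mm outside the allowed [%g, %g] mm",
                 diameter_mm, diameter_bounds[1], diameter_bounds[2]))
  }
  structure(list(center = center, diameter_mm = diameter_mm, label = label),
            class = "hepiron_roi_spec")
}

#' Rasterize an ROI to a boolean mask
#'
#' A pixel belongs to the mask iff its centre lies within
#' `diameter_mm / 2` of the ROI centre.  If the resulting physical area
#' (pixel count times pixel area) falls outside \[0.72, 1.15\] cm^2 a
#' warning is raised — the mask is still returned.
#'
#' @param spec A [roi_spec()].
#' @param grid_shape Integer (rows, cols) of the image grid.
#' @param pixel_spacing Pixel size in mm.
#' @return Logical matrix of `grid_shape`.
#' @export
roi_mask <- function(spec, grid_shape, pixel_spacing) {
  stopifnot(inherits(spec, "hepiron_roi_spec"))
  r_mm <- spec$diameter_mm / 2
  r_px <- r_mm / pixel_spacing
  if (spec$center[1] - r_px < 1 || spec$center[1] + r_px > grid_shape[1] ||
      spec$center[2] - r_px < 1 || spec$center[2] + r_px > grid_shape[2]) {
    stop("ROI circle does not fit inside the grid")
  }
  g <- .pixel_grids(grid_shape)
  d2 <- ((g$row - spec$center[1])^2 + (g$col - spec$center[2])^2) *
    pixel_spacing^2
  mask <- d2 <= r_mm^2
  if (!any(mask)) { # circle smaller than one pixel: keep the centre pixel
    mask[round(spec$center[1]), round(spec$center[2])] <- TRUE
  }
  area_cm2 <- sum(mask) * (pixel_spacing / 10)^2
  if (area_cm2 < 0.72 || area_cm2 > 1.15) {
    warning(sprintf("ROI mask area %.3f cm^2 outside the protocol band [0.72, 1.15] cm^2",
                    area_cm2))
  }
  mask
}

#' Default co-registered ROI set
#'
#' Three 10-mm ROIs placed inside the default phantom liver, off the
#' vessels: two in the right lobe, one in the left lobe.  The same
#' pixel coordinates are applied to every sequence (manual
#' co-registration emulation).
#'
#' @return List of three [roi_spec()] objects.
#' @export
default_roi_set <- function() {
  list(roi_spec(c(12, 20), 10, "right_lobe_1"),
       roi_spec(c(21, 13), 10, "right_lobe_2"),
       roi_spec(c(16, 24), 10, "left_lobe"))
}

#' Per-patient ROI summary of R2* maps
#'
#' The study's per-patient statistic: for each sequence, the unweighted
#' mean of the three ROI means of the R2* map.  The identical masks are
#' applied to every sequence.
#'
#' @param maps_by_sequence Named list of R2* matrices (one per
#'   sequence), all the same shape.
#' @param rois List of exactly three [roi_spec()] objects.
#' @param pixel_spacing Pixel size in mm.
#' @param patient_id Optional label.
#' @return List with `patient_id`, `per_sequence_r2star` (named numeric
#'   vector), `roi_means` (sequences x ROIs matrix) and `rois`.
#' @export
patient_r2star <- function(maps_by_sequence, rois, pixel_spacing,
                           patient_id = NA_character_) {
  if (length(rois) != 3L) stop("exactly three ROIs are required")
  shape <- dim(maps_by_sequence[[1]])
  masks <- lapply(rois, roi_mask, grid_shape = shape,
                  pixel_spacing = pixel_spacing)
  roi_means <- t(vapply(maps_by_sequence, function(m) {
    vapply(masks, function(msk) mean(m[msk], na.rm = TRUE), numeric(1))
  }, numeric(3)))
  colnames(roi_means) <- vapply(rois, `[[`, character(1), "label")
  list(patient_id = patient_id,
       per_sequence_r2star = rowMeans(roi_means),
       roi_means = roi_means,
       rois = rois)
}

#' Serialize an ROI set to JSON
#'
#' @param rois List of [roi_spec()] objects.
#' @param path Output path.
#' @return `path`, invisibly; `read_roi_set()` returns the list back.
#' @export
write_roi_set <- function(rois, path) {
  jsonlite::write_json(lapply(rois, function(r) {
    list(center = r$center, diameter_mm = r$diameter_mm, label = r$label)
  }), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(doc)), function(i) {
    roi_spec(unlist(doc$center[i]), doc$diameter_mm[i], doc$label[i])
  })
}
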