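#' Liver iron concentration calibration equation
#'
#' An affine map from R2* (1/s) at 1.5 T to liver iron concentration in
#' micromol Fe per gram dry tissue: `Fe = slope * R2* + intercept`.
#'
#' @param slope Slope in micromol g^-1 s (> 0).
#' @param intercept Intercept in micromol/g (any sign).
#' @param label Provenance label (e.g. `"henninger"`).
#' @return An object of class `"hepiron_calibration"`.
#' @export
calibration_equation <- function(slope, intercept, label = "unnamed") {
  if (!is.numeric(slope) || slope <= 0) stop("'slope' must be > 0")
  structure(list(slope = slope, intercept = intercept, label = label),
            class = "hepiron_calibration")
}

#' @export
print.hepiron_calibration <- function(x, ...) {
  cat(sprintf("<calibration '%s'> Fe (umol/g) = %.3f * R2* %+.3f\n",
              x$label, x$slope, x$intercept))
  invisible(x)
}

#' Registry of published LIC calibration equations
#'
#' Loads the packaged registry: the four literature calibrations used in
#' the study (Henninger 0.436 R2* + 4.964; Wood 0.455 R2* - 3.617;
#' Garbowski 0.573 R2* - 2.507; Hankins 0.502 R2* - 8.145) plus the two
#' cross-calibrations derived for the Dixon sequences (qDixon
#' 0.434 R2* + 6.135; qDixon-WIP 0.429 R2* + 5.682).  All are 1.5-T
#' equations with LIC in micromol/g dry weight.
#'
#' @param path Optional path to an alternative JSON registry.
#' @return Named list of [calibration_equation()] objects.
#' @export
calibration_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "calibrations.json",
                        package = "hepiron", mustWork = TRUE)
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(doc, function(d) {
    calibration_equation(d$slope, d$intercept, d$label)
  })
  names(out) <- vapply(out, `[[`, character(1), "label")
  out
}

#' Write a calibration registry to JSON
#'
#' @param registry Named list of [calibration_equation()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_registry <- function(registry, path) {
  jsonlite::write_json(unname(lapply(registry, function(eq) {
    list(label = eq$label, slope = eq$slope, intercept = eq$intercept)
  })), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Evaluate a calibration equation
#'
#' Affine evaluation `slope * r2star + intercept`.  Negative LIC values
#' are possible for calibrations with negative intercepts at very low
#' R2*; they are returned as-is with attribute `"flagged_negative"`
#' marking the affected entries.
#'
#' @param eq A [calibration_equation()].
#' @param r2star R2* value(s) in 1/s (>= 0).
#' @return LIC in micromol/g (vectorized).
#' @export
lic <- function(eq, r2star) {
  stopifnot(inherits(eq, "hepiron_calibration"))
  if (any(r2star < 0)) stop("'r2star' must be >= 0")
  out <- eq$slope * r2star + eq$intercept
  if (any(out < 0)) attr(out, "flagged_negative") <- which(out < 0)
  out
}

#' Cross-sequence regression line
#'
#' The regression of one sequence's R2* on another's,
#' `y = slope * x + intercept` (both in 1/s), used to transfer a LIC
#' calibration between sequences.
#'
#' @param slope Unitless slope (!= 0).
#' @param intercept Intercept in 1/s.
#' @param x_label,y_label Sequence names of the predictor and response.
#' @return An object of class `"hepiron_regression_line"`.
#' @export
regression_line <- function(slope, intercept, x_label = "x", y_label = "y") {
  if (slope == 0) stop("regression slope must be non-zero")
  structure(list(slope = slope, intercept = intercept,
                 x_label = x_label, y_label = y_label),
            class = "hepiron_regression_line")
}

#' Compose a LIC calibration with a cross-sequence regression
#'
#' Given a calibration `Fe = a * x + b` valid for sequence `x` and a
#' regression `y = m * x + c` of the target sequence on `x`, substitute
#' the inverted regression `x = (y - c) / m` to express the calibration
#' in the target sequence's R2*:
#' `Fe = (a / m) * y + (b - a * c / m)`.
#'
#' @param base A [calibration_equation()] for the regression's `x`
#'   sequence.
#' @param reg A [regression_line()] mapping the base sequence to the
#'   target sequence.
#' @param label Label of the composed equation.
#' @return A [calibration_equation()] in the target sequence's R2*.
#' @export
compose_calibration <- function(base, reg,
                                label = paste0(base$label, "@", reg$y_label)) {
  stopifnot(inherits(base, "hepiron_calibration"),
            inherits(reg, "hepiron_regression_line"))
  calibration_equation(slope = base$slope / reg$slope,
                       intercept = base$intercept -
                         base$slope * reg$intercept / reg$slope,
                       label = label)
}

#' Invert a regression line
#'
#' @param reg A [regression_line()] `y = m x + c`.
#' @return The line `x = y / m - c / m`, with axis labels exchanged.
#' @export
invert_regression <- function(reg) {
  stopifnot(inherits(reg, "hepiron_regression_line"))
  regression_line(1 / reg$slope, -reg$intercept / reg$slope,
                  x_label = reg$y_label, y_label = reg$x_label)
}

IRON_MOLAR_MASS <- 55.845 # g/mol

#' Convert liver iron concentration between mg/g and micromol/g
#'
#' `mgg_to_umolg()` multiplies by 1000 / 55.845 (iron molar mass);
#' the clinical threshold of 2 mg/g corresponds to about 36 micromol/g.
#'
#' @param x LIC value(s), >= 0.
#' @return Converted value(s).
#' @export
mgg_to_umolg <- function(x) {
  if (any(x < 0)) stop("LIC must be >= 0")
  x * 1000 / IRON_MOLAR_MASS
}

#' @rdname mgg_to_umolg
#' @export
umolg_to_mgg <- function(x) {
  if (any(x < 0)) stop("LIC must be >= 0")
  x * IRON_MOLAR_MASS / 1000
}

#' Classify iron burden from LIC
#'
#' Two classifications used in the study: a binary pathologic-iron call
#' (`"yes"` iff LIC strictly exceeds `yes_no_threshold`, default
#' 36 micromol/g, i.e. 2 mg/g) and an ordinal severity grade in the
#' style of the EASL guideline, computed as the number of group
#' boundaries strictly exceeded (group 0 to `length(boundaries)`).
#' Boundary ties fall in the lower class (the thresholds are read as
#' strict "greater than").  The numeric EASL boundaries are
#' configuration, not constants: they must be supplied explicitly when
#' the ordinal grade is requested.
#'
#' @param lic LIC value(s) in micromol/g.
#' @param yes_no_threshold Binary threshold (default 36 micromol/g).
#' @param easl_boundaries Increasing numeric vector of group boundaries
#'   in micromol/g (typically three, giving groups 0-3), or `NULL` to
#'   skip the ordinal grade.
#' @return A data frame with columns `yes_no` (factor no/yes) and, when
#'   boundaries are given, `easl_group` (ordered factor).
#' @export
classify_iron <- function(lic, yes_no_threshold = 36,
                          easl_boundaries = NULL) {
  yes_no <- factor(ifelse(lic > yes_no_threshold, "yes", "no"),
                   levels = c("no", "yes"))
  out <- data.frame(yes_no = yes_no)
  if (!is.null(easl_boundaries)) {
    if (is.unsorted(easl_boundaries, strictly = TRUE)) {
      stop("'easl_boundaries' must be strictly increasing")
    }
    grp <- vapply(lic, function(v) sum(v > easl_boundaries), numeric(1))
    out$easl_group <- factor(grp, levels = 0:length(easl_boundaries),
                             ordered = TRUE)
  }
  out
}
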