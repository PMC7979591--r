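#' Multi-peak fat spectrum
#'
#' The triglyceride proton spectrum used for chemical-shift modelling:
#' a set of resonances at chemical shifts relative to water (ppm, fat
#' peaks are negative, i.e. at lower frequency than water at positive
#' gyromagnetic ratio convention) with relative amplitudes that sum to 1.
#'
#' @param shift_ppm Numeric vector of chemical shifts relative to water,
#'   in ppm.
#' @param amplitude Numeric vector of relative amplitudes; must sum to 1
#'   within 1e-9.
#' @return An object of class `"hepiron_fat_spectrum"`.
#' @seealso [default_fat_spectrum()], [fat_dephasing()]
#' @export
fat_spectrum <- function(shift_ppm, amplitude) {
  if (length(shift_ppm) < 1L) stop("spectrum must have at least one peak")
  if (length(shift_ppm) != length(amplitude)) {
    stop("'shift_ppm' and 'amplitude' must have the same length")
  }
  if (!all(is.finite(shift_ppm)) || !all(is.finite(amplitude))) {
    stop("peak shifts and amplitudes must be finite")
  }
  if (abs(sum(amplitude) - 1) > 1e-9) {
    stop("peak amplitudes must sum to 1 (within 1e-9)")
  }
  structure(list(shift_ppm = as.numeric(shift_ppm),
                 amplitude = as.numeric(amplitude)),
            class = "hepiron_fat_spectrum")
}

#' Default six-peak liver fat spectrum
#'
#' Loads the packaged six-peak liver triglyceride spectrum (main
#' methylene peak near -3.4 ppm) from its JSON data file.  The vendor's
#' exact peak table is unpublished; this is a standard literature
#' spectrum, shipped as data so it can be swapped without touching code.
#'
#' @return A [fat_spectrum()].
#' @export
default_fat_spectrum <- function() {
  path <- system.file("extdata", "fat_spectrum_6peak.json",
                      package = "hepiron", mustWork = TRUE)
  read_fat_spectrum(path)
}

#' Read / write a fat spectrum as JSON
#'
#' @param path File path of a JSON document with fields `shift_ppm` and
#'   `amplitude` (parallel arrays).
#' @return `read_fat_spectrum()` returns a [fat_spectrum()];
#'   `write_fat_spectrum()` returns `path` invisibly.
#' @export
read_fat_spectrum <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  fat_spectrum(doc$shift_ppm, doc$amplitude)
}

#' @rdname read_fat_spectrum
#' @param spectrum A [fat_spectrum()].
#' @export
write_fat_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "hepiron_fat_spectrum"))
  jsonlite::write_json(
    list(shift_ppm = spectrum$shift_ppm, amplitude = spectrum$amplitude),
    path, digits = NA)
  invisible(path)
}

# proton gyromagnetic ratio over 2*pi, MHz/T
GAMMA_BAR_MHZ_PER_T <- 42.577

#' Complex fat dephasing factor
#'
#' Evaluates the complex-valued dephasing factor of the fat signal at a
#' given echo time: `c(te) = sum_p a_p * exp(2i*pi*df_p*te)` where the
#' off-resonance frequency of peak p is
#' `df_p = shift_ppm_p * 1e-6 * gamma_bar * B0` with
#' gamma_bar = 42.577 MHz/T.  At `te = 0` the factor is exactly 1; its
#' modulus never exceeds 1 because the peak amplitudes sum to 1.
#'
#' @param spectrum A [fat_spectrum()].
#' @param te Echo time(s) in seconds (>= 0); vectorized.
#' @param field_strength Field strength in tesla (> 0).
#' @return Complex vector, one factor per echo time.
#' @export
fat_dephasing <- function(spectrum, te, field_strength = 1.5) {
  stopifnot(inherits(spectrum, "hepiron_fat_spectrum"))
  if (any(te < 0)) stop("'te' must be >= 0")
  if (field_strength <= 0) stop("'field_strength' must be > 0")
  df_hz <- spectrum$shift_ppm * 1e-6 * GAMMA_BAR_MHZ_PER_T * 1e6 *
    field_strength
  # outer product: peaks x echo times
  phase <- outer(df_hz, te, function(f, t) 2 * pi * f * t)
  as.vector(crossprod(spectrum$amplitude, exp(1i * phase)))
}
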