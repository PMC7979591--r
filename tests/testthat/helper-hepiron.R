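# shared fixtures and independent oracles

# quadrature oracle for the Rice first moment: integral of x * pdf,
# written with the exponentially scaled Bessel so it is stable at high SNR
rice_mean_quad <- function(nu, sigma) {
  stats::integrate(function(x) {
    x^2 / sigma^2 * exp(-(x - nu)^2 / (2 * sigma^2)) *
      besselI(x * nu / sigma^2, 0, expon.scaled = TRUE)
  }, 0, nu + 12 * sigma, rel.tol = 1e-11, abs.tol = 1e-13)$value
}

the_spectrum <- default_fat_spectrum()
proto_megre <- protocol_preset("me-gre")
proto_qdx <- protocol_preset("qdixon")
proto_wip <- protocol_preset("qdixon-wip")

# noiseless forward series for a tissue state on a protocol
forward_series <- function(w, f, r2star, proto, sigma = 0,
                           spectrum = the_spectrum) {
  expected_signal(tissue_state(w, f, r2star), spectrum, proto, sigma)
}

# ROI-averaged draw: mean magnitude over nvox independent voxels
roi_mean_draw <- function(nu, sigma, nvox) {
  colMeans(matrix(rician_sample(rep(nu, each = nvox), sigma), nvox))
}

all_pairs <- c("henninger_wood", "henninger_garbowski", "henninger_hankins",
               "garbowski_wood", "garbowski_hankins", "hankins_wood")
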