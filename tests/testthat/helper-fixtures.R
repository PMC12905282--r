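# Shared fixture builders; everything is generated in code at test time.

# Analytic solid-sphere scattering curve with a realistic sigma floor
sphere_curve <- function(R = 30, I0 = 1e4, n = 300, qmax = 0.35) {
  q <- seq(0.004, qmax, length.out = n)
  I <- I0 * sphere_form_amplitude(q, R)^2
  scattering_curve(q, I, sigma = 0.01 * I + 1e-4 * max(I))
}

# Pure Guinier-law (Gaussian) curve
gaussian_curve <- function(Rg = 20, I0 = 5e3, n = 800, qmax = NULL) {
  if (is.null(qmax)) qmax <- 8 / Rg
  q <- seq(1e-3, qmax, length.out = n)
  I <- I0 * exp(-q^2 * Rg^2 / 3)
  scattering_curve(q, I, sigma = 0.005 * I + 1e-5 * I0)
}

# The constructed nuclear-aggregate fixture: 100x100 nucleus of uniform
# intensity 10 with one 10x10 aggregate at intensity 110 (local background
# 10); relative intensity = 10000/110000 by hand computation.
aggregate_fixture <- function() {
  ch <- matrix(10, 100, 100)
  ch[41:50, 41:50] <- 110
  img <- cell_image(list(green = ch, fish = matrix(7, 100, 100)))
  lab <- matrix(0L, 100, 100)
  lab[41:50, 41:50] <- 1L
  masks <- structure(list(nucleus = matrix(TRUE, 100, 100),
                          cytoplasm = matrix(FALSE, 100, 100),
                          spots = matrix(0L, 100, 100),
                          aggregates = lab),
                     class = "segmentation_masks")
  list(image = img, masks = masks, expected = 10000 / 110000)
}

# Default two-sets ground truth used across ITC tests: each ligand
# saturates two macromolecule monomers (n1 + n2 = 0.5), second site
# 100-fold tighter.
cooperative_truth <- function() two_sets_model(0.25, 0.25, 1e6, 1e8, -8, -12)
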