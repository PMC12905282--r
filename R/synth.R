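#' Simulate a noisy ITC isotherm with known ground truth
#'
#' Evaluates the forward per-injection heat model for the given binding
#' model and protocol and adds Gaussian noise of the stated standard
#' deviation to each injection heat. At zero noise the output equals
#' \code{\link{injection_heats}} exactly (same code path). The generating
#' parameters are embedded as the \code{"truth"} attribute so recovery
#' tests never have to re-derive them.
#'
#' @param model a \code{\link{one_set_model}} or \code{\link{two_sets_model}}.
#' @param protocol a \code{\link{titration_protocol}}.
#' @param noise_sd per-injection heat noise SD in kcal.
#' @param seed optional integer seed.
#' @param dilution dilution convention (see \code{\link{injection_heats}}).
#' @return an \code{isotherm} with \code{sigma} set to \code{noise_sd} and a
#'   \code{"truth"} attribute (model, protocol, noise_sd, seed).
#' @export
gen_itc <- function(model, protocol, noise_sd = 0, seed = NULL,
                    dilution = c("perfusion", "displaced")) {
  dilution <- match.arg(dilution)
  if (!is.null(seed)) set.seed(seed)
  iso <- injection_heats(model, protocol, dilution)
  if (noise_sd > 0) {
    iso$q <- iso$q + stats::rnorm(nrow(iso), sd = noise_sd)
    iso$q_per_mol <- iso$q / (protocol$Xs * iso$dV)
  }
  iso$sigma <- noise_sd
  attr(iso, "truth") <- list(model = model, protocol = protocol,
                             noise_sd = noise_sd, seed = seed,
                             dilution = dilution)
  iso
}

#' Define a peak-list perturbation scenario
#'
#' Describes how the "after" state differs from a base peak list: a set of
#' residues receiving deterministic shift offsets (binding-site residues), a
#' set whose peak heights are scaled (interface residues broadened by
#' oligomerisation; factor 0 removes the peak entirely), and Gaussian jitter
#' applied to every assigned shift in both dimensions (proton jitter = sd;
#' nitrogen jitter = sd / 0.14 so both dimensions contribute comparable
#' combined-shift noise).
#'
#' @param base a \code{\link{peak_list}}.
#' @param perturbed_residues integer residue ids receiving shift offsets.
#' @param offset_H,offset_N offsets in ppm applied to perturbed residues.
#' @param broadened_residues residue ids whose heights are scaled.
#' @param height_factor multiplicative height factor (0 = peak absent).
#' @param jitter_sd proton-dimension jitter SD in ppm (default 0.005).
#' @param seed integer seed.
#' @return a list of class \code{peaklist_scenario}.
#' @export
peaklist_scenario <- function(base, perturbed_residues = integer(0),
                              offset_H = 0.1, offset_N = 0,
                              broadened_residues = integer(0),
                              height_factor = 0.1,
                              jitter_sd = 0.005, seed = NULL) {
  stopifnot(inherits(base, "peak_list"),
            all(perturbed_residues %in% base$residue_id),
            all(broadened_residues %in% base$residue_id),
            jitter_sd >= 0, height_factor >= 0)
  structure(list(base = base, perturbed_residues = as.integer(perturbed_residues),
                 offset_H = offset_H, offset_N = offset_N,
                 broadened_residues = as.integer(broadened_residues),
                 height_factor = height_factor,
                 jitter_sd = jitter_sd, seed = seed),
            class = "peaklist_scenario")
}

#' A generic 90-residue base peak list
#'
#' Shifts drawn once from typical amide ranges (deterministic given the
#' seed); convenient as the \code{base} of a \code{\link{peaklist_scenario}}.
#'
#' @param n_residues number of residues.
#' @param seed integer seed.
#' @return a \code{\link{peak_list}}.
#' @export
random_peak_list <- function(n_residues = 90L, seed = 1L) {
  set.seed(seed)
  peak_list(residue_id = seq_len(n_residues),
            deltaH = stats::runif(n_residues, 6.5, 9.5),
            deltaN = stats::runif(n_residues, 105, 130),
            height = stats::runif(n_residues, 50, 150),
            condition = "base")
}

#' Generate a before/after pair of peak lists
#'
#' @param scenario a \code{\link{peaklist_scenario}}.
#' @return list with \code{before} and \code{after} peak lists; ground truth
#'   (perturbed and broadened residue sets) in the \code{"truth"} attribute.
#' @export
gen_peaklists <- function(scenario) {
  stopifnot(inherits(scenario, "peaklist_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  before <- scenario$base
  after <- scenario$base
  n <- nrow(after)
  if (scenario$jitter_sd > 0) {
    after$deltaH <- after$deltaH + stats::rnorm(n, sd = scenario$jitter_sd)
    after$deltaN <- after$deltaN + stats::rnorm(n, sd = scenario$jitter_sd / 0.14)
  }
  ip <- after$residue_id %in% scenario$perturbed_residues
  after$deltaH[ip] <- after$deltaH[ip] + scenario$offset_H
  after$deltaN[ip] <- after$deltaN[ip] + scenario$offset_N
  ib <- after$residue_id %in% scenario$broadened_residues
  after$height[ib] <- after$height[ib] * scenario$height_factor
  if (scenario$height_factor == 0) {
    after$status[ib] <- "absent"
    after$deltaH[ib] <- NA_real_
    after$deltaN[ib] <- NA_real_
  }
  attr(after, "condition") <- "after"
  out <- list(before = before, after = after)
  attr(out, "truth") <- list(perturbed = scenario$perturbed_residues,
                             broadened = scenario$broadened_residues,
                             offset_H = scenario$offset_H,
                             offset_N = scenario$offset_N,
                             height_factor = scenario$height_factor,
                             jitter_sd = scenario$jitter_sd,
                             seed = scenario$seed)
  out
}

#' Simulate a SAXS curve from a bead model
#'
#' Debye-formula intensity with per-point noise whose SD follows the
#' counting-statistics heuristic sigma ~ sqrt(I/q) (fewer counts per ring at
#' high q), scaled so the median point-wise signal-to-noise ratio equals
#' \code{snr}. Exact Rg and Dmax from the bead coordinates are embedded as
#' ground truth.
#'
#' @param model a \code{\link{bead_model}}.
#' @param q momentum-transfer grid (1/A), positive increasing.
#' @param snr median signal-to-noise ratio (Inf for a noiseless curve whose
#'   sigma still carries the heuristic shape, scaled to snr = 100).
#' @param seed integer seed.
#' @return a \code{\link{scattering_curve}} with a \code{"truth"} attribute
#'   (rg, dmax, geometry, n_beads, radius).
#' @export
gen_saxs <- function(model, q, snr = 50, seed = NULL) {
  stopifnot(inherits(model, "bead_model"), all(q > 0),
            !is.unsorted(q, strictly = TRUE))
  if (!is.null(seed)) set.seed(seed)
  I <- debye_intensity(model, q)
  shape <- sqrt(pmax(I, 0) / q)
  shape[shape <= 0] <- min(shape[shape > 0])
  eff_snr <- if (is.finite(snr)) snr else 100
  sigma <- shape * stats::median(abs(I) / shape) / eff_snr
  noisy <- if (is.finite(snr)) I + stats::rnorm(length(q), sd = sigma) else I
  out <- scattering_curve(q, noisy, sigma)
  attr(out, "truth") <- list(rg = bead_rg(model), dmax = bead_dmax(model),
                             geometry = model$geometry,
                             n_beads = nrow(model$coords),
                             radius = model$radius, snr = snr, seed = seed)
  out
}

#' Define a two-channel cell-image scenario
#'
#' The rendered scene emulates a microtubule-bench field of view: a central
#' nucleus (bright in the nucleus channel), cytoplasm filling the rest of
#' the frame at a uniform baseline in the green and red channels, and
#' elongated Gaussian spots (microtubule clusters) whose per-spot channel
#' enrichments are drawn from a bivariate normal with correlation
#' \code{rho}. Optionally, bright nuclear aggregates and a poly-A FISH
#' channel are added for the aggregation scores. Pixel noise is
#' Poisson-Gaussian.
#'
#' @param size image side in pixels.
#' @param n_spots number of spots (placed on a jittered grid outside the
#'   nucleus so spots do not merge).
#' @param spot_sigma along/across Gaussian SDs in px (length 2); the
#'   across/along ratio sets the width-to-length ratio of detected spots.
#' @param enrichment_mean,enrichment_sd per-channel mean and SD of the true
#'   spot enrichments (spot mean / cytoplasm mean); enrichments are
#'   truncated below at 1.2 to keep every spot detectable.
#' @param rho correlation between the green and red enrichments, in [-1, 1].
#' @param baseline cytoplasm baseline intensity (counts).
#' @param noise_sd additive Gaussian read-noise SD on top of Poisson noise.
#' @param nucleus_radius radius of the nucleus disc in px.
#' @param n_aggregates number of nuclear aggregates (0 for none).
#' @param aggregate_radius,aggregate_contrast aggregate disc radius (px) and
#'   intensity contrast (aggregate = contrast x nuclear baseline) in the
#'   green channel.
#' @param fish_enrichment poly-A FISH enrichment of aggregates over the
#'   nucleus baseline in the FISH channel.
#' @param seed integer seed.
#' @return a list of class \code{image_scenario}.
#' @export
image_scenario <- function(size = 448L, n_spots = 120L,
                           spot_sigma = c(8, 1.6),
                           enrichment_mean = c(green = 2.5, red = 2.5),
                           enrichment_sd = c(green = 0.5, red = 0.5),
                           rho = 0.8, baseline = 100, noise_sd = 2,
                           nucleus_radius = 45L,
                           n_aggregates = 0L, aggregate_radius = 5L,
                           aggregate_contrast = 3, fish_enrichment = 2,
                           seed = 1L) {
  stopifnot(rho >= -1, rho <= 1, size > 0, length(spot_sigma) == 2L,
            all(spot_sigma > 0), baseline > 0, noise_sd >= 0)
  structure(as.list(environment()), class = "image_scenario")
}

disc_mask <- function(size, cx, cy, radius) {
  xs <- matrix(seq_len(size), size, size)
  ys <- matrix(seq_len(size), size, size, byrow = TRUE)
  (xs - cx)^2 + (ys - cy)^2 <= radius^2
}

## Render one elongated Gaussian (unit peak) into img around (cx, cy)
render_spot <- function(img, cx, cy, sigma, theta, amplitude) {
  ext <- ceiling(3 * max(sigma))
  size <- nrow(img)
  x0 <- max(1L, cx - ext); x1 <- min(size, cx + ext)
  y0 <- max(1L, cy - ext); y1 <- min(size, cy + ext)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(xs - cx, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - cy)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  g <- exp(-0.5 * ((u / sigma[1])^2 + (v / sigma[2])^2))
  img[xs, ys] <- img[xs, ys] + amplitude * g
  img
}

#' Generate a synthetic two-channel cell image with ground truth
#'
#' @param scenario an \code{\link{image_scenario}}.
#' @return a \code{\link{cell_image}} with channels \code{nucleus},
#'   \code{green}, \code{red} (and \code{fish} when aggregates are
#'   requested); ground truth (per-spot true enrichments and positions,
#'   aggregate geometry, rho) in the \code{"truth"} attribute.
#' @export
gen_images <- function(scenario) {
  stopifnot(inherits(scenario, "image_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  size <- sc$size
  cx0 <- cy0 <- (size + 1) / 2
  nucleus <- disc_mask(size, cx0, cy0, sc$nucleus_radius)

  ## jittered grid of candidate spot centres outside nucleus and margins
  pitch <- ceiling(6 * max(sc$spot_sigma) * 0.6) + 4L
  margin <- ceiling(3 * max(sc$spot_sigma)) + 2L
  gx <- seq(margin, size - margin, by = pitch)
  sites <- expand.grid(x = gx, y = gx)
  sites$x <- sites$x + sample(-2:2, nrow(sites), replace = TRUE)
  sites$y <- sites$y + sample(-2:2, nrow(sites), replace = TRUE)
  keep_dist <- sqrt((sites$x - cx0)^2 + (sites$y - cy0)^2) >
    sc$nucleus_radius + ceiling(3 * max(sc$spot_sigma))
  sites <- sites[keep_dist, ]
  if (nrow(sites) < sc$n_spots)
    stop("gen_images: not enough room for ", sc$n_spots, " spots")
  sites <- sites[sample.int(nrow(sites), sc$n_spots), ]

  ## bivariate-normal true enrichments, truncated below at 1.2
  mu <- sc$enrichment_mean; sd <- sc$enrichment_sd; rho <- sc$rho
  draw <- function(k) {
    z1 <- stats::rnorm(k); z2 <- stats::rnorm(k)
    g <- mu[1] + sd[1] * z1
    r <- mu[2] + sd[2] * (rho * z1 + sqrt(1 - rho^2) * z2)
    cbind(green = g, red = r)
  }
  enr <- draw(sc$n_spots)
  bad <- enr[, 1] < 1.2 | enr[, 2] < 1.2
  guard <- 0L
  while (any(bad) && guard < 100L) {
    guard <- guard + 1L
    enr[bad, ] <- draw(sum(bad))
    bad <- enr[, 1] < 1.2 | enr[, 2] < 1.2
  }
  theta <- stats::runif(sc$n_spots, 0, pi)

  b <- sc$baseline
  green <- matrix(b, size, size)
  red <- matrix(b, size, size)
  marker <- matrix(b, size, size)       # structural marker: same footprint,
  for (s in seq_len(sc$n_spots)) {      # brightness independent of enrichment
    green <- render_spot(green, sites$x[s], sites$y[s], sc$spot_sigma,
                         theta[s], (enr[s, 1] - 1) * b)
    red <- render_spot(red, sites$x[s], sites$y[s], sc$spot_sigma,
                       theta[s], (enr[s, 2] - 1) * b)
    marker <- render_spot(marker, sites$x[s], sites$y[s], sc$spot_sigma,
                          theta[s], 1.5 * b)
  }
  nuc_ch <- matrix(0.1 * b, size, size)
  nuc_ch[nucleus] <- 4 * b

  channels <- list(nucleus = nuc_ch, green = green, red = red,
                   marker = marker)
  agg_truth <- NULL
  if (sc$n_aggregates > 0L) {
    fish <- matrix(0.1 * b, size, size)
    fish[nucleus] <- b
    nuc_base <- 2 * b
    channels$green[nucleus] <- nuc_base
    rmax <- sc$nucleus_radius - sc$aggregate_radius - 3L
    ang <- 2 * pi * (seq_len(sc$n_aggregates) - 1) / sc$n_aggregates
    acx <- round(cx0 + 0.6 * rmax * cos(ang))
    acy <- round(cy0 + 0.6 * rmax * sin(ang))
    for (a in seq_len(sc$n_aggregates)) {
      m <- disc_mask(size, acx[a], acy[a], sc$aggregate_radius)
      channels$green[m] <- sc$aggregate_contrast * nuc_base
      fish[m] <- sc$fish_enrichment * b
    }
    channels$fish <- fish
    agg_truth <- data.frame(x = acx, y = acy,
                            radius = sc$aggregate_radius,
                            contrast = sc$aggregate_contrast,
                            fish_enrichment = sc$fish_enrichment)
  }

  ## noise_sd = 0 disables the whole Poisson-Gaussian noise model
  if (sc$noise_sd > 0) {
    for (nm in names(channels)) {
      ch <- channels[[nm]]
      noisy <- stats::rpois(length(ch), lambda = as.vector(ch)) +
        stats::rnorm(length(ch), sd = sc$noise_sd)
      channels[[nm]] <- matrix(pmax(noisy, 0), size, size)
    }
  }

  img <- cell_image(channels, metadata = list(seed = sc$seed))
  attr(img, "truth") <- list(
    spots = data.frame(x = sites$x, y = sites$y, theta = theta,
                       enr_green = enr[, 1], enr_red = enr[, 2]),
    rho = rho, baseline = b, nucleus_radius = sc$nucleus_radius,
    aggregates = agg_truth, seed = sc$seed)
  img
}

#' Write a generator's ground-truth sidecar as JSON
#'
#' @param x any generator output carrying a \code{"truth"} attribute.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(x, path) {
  truth <- attr(x, "truth")
  if (is.null(truth)) stop("write_truth_json: no truth attribute")
  truth <- rapply(truth, function(el) el, how = "replace")
  jsonlite::write_json(serialize_truth(truth), path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}

serialize_truth <- function(x) {
  if (inherits(x, "binding_model"))
    return(list(kind = x$kind, n = x$n, K = x$K, dH = x$dH))
  if (inherits(x, "titration_protocol"))
    return(list(V0 = x$V0, Mt0 = x$Mt0, Xs = x$Xs, dV = x$dV,
                temperature = x$temperature))
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, serialize_truth))
  x
}

#' Read a ground-truth sidecar written by \code{\link{write_truth_json}}
#'
#' @param path JSON file.
#' @return a list.
#' @export
read_truth_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
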