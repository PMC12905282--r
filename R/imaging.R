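#' Construct a multi-channel cell image
#'
#' @param channels named list of 2-D numeric matrices, all the same size,
#'   intensities >= 0. Conventional channel names: \code{nucleus} (DNA
#'   stain), \code{green}, \code{red}, optionally \code{fish}.
#' @param pixel_size pixel size in micrometres (optional).
#' @param metadata free-form list.
#' @return object of class \code{cell_image}.
#' @export
cell_image <- function(channels, pixel_size = NA_real_, metadata = list()) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("cell_image: all channels must share dimensions")
  if (any(vapply(channels, function(m) any(m < 0), logical(1))))
    stop("cell_image: intensities must be >= 0")
  structure(list(channels = channels, pixel_size = pixel_size,
                 metadata = metadata),
            class = "cell_image")
}

#' @export
print.cell_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("Cell image %dx%d px, channels: %s\n", d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

## Otsu threshold on a numeric vector (256-bin histogram)
otsu_threshold <- function(v) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- graphics::hist(v, breaks = seq(rng[1], rng[2], length.out = 257),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

#' Segment nucleus, cytoplasm and nuclear aggregates
#'
#' Nucleus: Otsu threshold on the nucleus-stain channel, holes filled.
#' Cytoplasm: a dilation band around the nucleus clipped to the frame,
#' minus the nucleus (for single-cell frames where the cell fills the field,
#' set \code{cytoplasm_radius = Inf} to use the whole non-nuclear frame).
#' Nuclear aggregates: white top-hat on the aggregate channel within the
#' nucleus, thresholded at \code{aggregate_k} times the in-nucleus median
#' absolute deviation above the median, then labelled.
#'
#' @param image a \code{\link{cell_image}}.
#' @param nucleus_channel channel name for the DNA stain.
#' @param cytoplasm_radius dilation radius (px) defining the cytoplasm band;
#'   Inf uses everything outside the nucleus.
#' @param aggregate_channel channel to segment aggregates in (NULL skips).
#' @param aggregate_tophat top-hat brush diameter in px (odd).
#' @param aggregate_k threshold in robust SD units above the nuclear median.
#' @return object of class \code{segmentation_masks}: logical \code{nucleus}
#'   and \code{cytoplasm}, integer label matrices \code{spots} (empty until
#'   \code{\link{detect_spots}}) and \code{aggregates}.
#' @export
segment_cell <- function(image, nucleus_channel = "nucleus",
                         cytoplasm_radius = Inf,
                         aggregate_channel = NULL,
                         aggregate_tophat = 15L, aggregate_k = 6) {
  stopifnot(inherits(image, "cell_image"))
  nuc_img <- image$channels[[nucleus_channel]]
  if (is.null(nuc_img)) stop("segment_cell: no channel '", nucleus_channel, "'")
  thr <- otsu_threshold(as.vector(nuc_img))
  nucleus <- nuc_img > thr
  nucleus <- EBImage::fillHull(EBImage::Image(nucleus * 1)) > 0
  nucleus <- matrix(as.logical(nucleus), nrow(nuc_img), ncol(nuc_img))

  if (is.infinite(cytoplasm_radius)) {
    cytoplasm <- !nucleus
  } else {
    band <- EBImage::dilate(EBImage::Image(nucleus * 1),
                            EBImage::makeBrush(2L * cytoplasm_radius + 1L,
                                               shape = "disc")) > 0
    cytoplasm <- matrix(as.logical(band), nrow(nuc_img), ncol(nuc_img)) & !nucleus
  }

  aggregates <- matrix(0L, nrow(nuc_img), ncol(nuc_img))
  if (!is.null(aggregate_channel)) {
    ach <- image$channels[[aggregate_channel]]
    if (is.null(ach)) stop("segment_cell: no channel '", aggregate_channel, "'")
    br <- EBImage::makeBrush(aggregate_tophat, shape = "disc")
    th <- EBImage::whiteTopHat(EBImage::Image(ach / max(ach)), br)
    th <- matrix(as.numeric(th), nrow(ach), ncol(ach)) * max(ach)
    vals <- th[nucleus]
    cut <- stats::median(vals) + aggregate_k * stats::mad(vals)
    agg_mask <- th > cut & nucleus
    lab <- EBImage::bwlabel(EBImage::Image(agg_mask * 1))
    aggregates <- matrix(as.integer(lab), nrow(ach), ncol(ach))
  }

  structure(list(nucleus = nucleus, cytoplasm = cytoplasm,
                 spots = matrix(0L, nrow(nuc_img), ncol(nuc_img)),
                 aggregates = aggregates),
            class = "segmentation_masks")
}

#' Detect microtubule-cluster spots in the cytoplasm
#'
#' Connected components of the chosen channel above an adaptive (Otsu)
#' intensity threshold computed over cytoplasm pixels. Each component is
#' measured: area (px^2), width-to-length ratio (minor/major principal-axis
#' length of the binary region), per-channel mean intensity and per-channel
#' enrichment (spot mean divided by the cytoplasm mean; cytoplasm pixels
#' belonging to any detected spot are excluded from the reference mean so
#' the baseline is not inflated by the spots themselves).
#'
#' @param image a \code{\link{cell_image}}.
#' @param channel channel used for detection.
#' @param masks a \code{\link{segmentation_masks}}.
#' @param enrich_channels channels for which to compute enrichment
#'   (default green and red where present).
#' @return list with \code{spots} (the measurements data frame: label, area,
#'   ratio, mean and enrichment per channel) and \code{masks} (the input
#'   masks with the \code{spots} label matrix filled in).
#' @export
detect_spots <- function(image, channel, masks,
                         enrich_channels = intersect(c("green", "red"),
                                                     names(image$channels))) {
  stopifnot(inherits(image, "cell_image"),
            inherits(masks, "segmentation_masks"))
  if (!any(masks$cytoplasm)) stop("detect_spots: empty cytoplasm mask")
  ch <- image$channels[[channel]]
  if (is.null(ch)) stop("detect_spots: no channel '", channel, "'")
  vals <- ch[masks$cytoplasm]
  thr <- otsu_threshold(vals)
  mask <- ch > thr & masks$cytoplasm
  if (!any(mask)) {
    masks$spots <- matrix(0L, nrow(ch), ncol(ch))
    return(list(spots = empty_spot_frame(enrich_channels), masks = masks))
  }
  lab_img <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labels <- matrix(as.integer(lab_img), nrow(ch), ncol(ch))
  nlab <- max(labels)
  areas <- tabulate(labels[labels > 0], nbins = nlab)
  mom <- EBImage::computeFeatures.moment(lab_img)
  major <- mom[, "m.majoraxis"]
  ecc <- mom[, "m.eccentricity"]
  minor <- major * sqrt(pmax(1 - ecc^2, 0))
  ratio <- pmin(pmax(minor / major, 1e-9), 1)

  cyto_ref <- masks$cytoplasm & labels == 0L
  df <- data.frame(label = seq_len(nlab), area = areas, ratio = ratio)
  for (cn in enrich_channels) {
    cimg <- image$channels[[cn]]
    cyto_mean <- mean(cimg[cyto_ref])
    if (!is.finite(cyto_mean) || cyto_mean <= 0)
      stop("detect_spots: degenerate cytoplasm mean in channel '", cn, "'")
    sums <- tapply(cimg[labels > 0], labels[labels > 0], mean)
    df[[paste0("mean_", cn)]] <- as.numeric(sums[as.character(df$label)])
    df[[paste0("enr_", cn)]] <- df[[paste0("mean_", cn)]] / cyto_mean
  }
  masks$spots <- labels
  list(spots = df, masks = masks)
}

empty_spot_frame <- function(enrich_channels) {
  df <- data.frame(label = integer(0), area = numeric(0), ratio = numeric(0))
  for (cn in enrich_channels) {
    df[[paste0("mean_", cn)]] <- numeric(0)
    df[[paste0("enr_", cn)]] <- numeric(0)
  }
  df
}

#' Filter spots by area and elongation
#'
#' Keeps spots with area strictly greater than \code{area_min}, strictly
#' smaller than \code{area_max}, and width-to-length ratio strictly smaller
#' than \code{ratio_max} (elongated, microtubule-like shapes). The defaults
#' are the standard tubular-spot gates (>20 px^2, <300 px^2, ratio <0.3).
#'
#' @param spots a spot-measurement data frame from \code{\link{detect_spots}}.
#' @param area_min,area_max area gates in px^2 (strict inequalities).
#' @param ratio_max width-to-length gate (strict).
#' @return the filtered data frame (a subset of the input rows).
#' @export
filter_spots <- function(spots, area_min = 20, area_max = 300,
                         ratio_max = 0.3) {
  keep <- spots$area > area_min & spots$area < area_max &
    spots$ratio < ratio_max
  spots[keep, , drop = FALSE]
}

#' Cytoplasm-normalised enrichment of one spot
#'
#' @param spot_mean mean spot intensity in a channel.
#' @param cytoplasm_mean mean cytoplasm intensity in the same channel (> 0).
#' @return spot_mean / cytoplasm_mean.
#' @export
enrichment <- function(spot_mean, cytoplasm_mean) {
  if (any(!is.finite(cytoplasm_mean)) || any(cytoplasm_mean <= 0))
    stop("enrichment: cytoplasm mean must be positive")
  spot_mean / cytoplasm_mean
}

#' Mixing score: R-squared of the two-channel enrichment regression
#'
#' Ordinary least squares of green enrichment on red enrichment across the
#' (filtered) spots pooled per well. An R-squared near 1 means the two
#' tethered proteins co-assemble on the same clusters (mix); near 0 means
#' they segregate.
#'
#' @param spots spot-measurement data frame with \code{enr_green} and
#'   \code{enr_red} columns.
#' @param min_spots minimum number of spots required.
#' @return object of class \code{mixing_score}: \code{r_squared},
#'   \code{slope}, \code{intercept}, \code{n}, \code{status}
#'   ("ok", "insufficient_spots" or "undefined").
#' @export
mixing_score <- function(spots, min_spots = 10L) {
  n <- nrow(spots)
  if (n < min_spots)
    return(structure(list(r_squared = NA_real_, slope = NA_real_,
                          intercept = NA_real_, n = n,
                          status = "insufficient_spots"),
                     class = "mixing_score"))
  x <- spots$enr_red; y <- spots$enr_green
  if (stats::var(x) == 0)
    return(structure(list(r_squared = NA_real_, slope = NA_real_,
                          intercept = NA_real_, n = n, status = "undefined"),
                     class = "mixing_score"))
  ## simple OLS in closed form; R2 = squared sample correlation
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (stats::var(y) == 0) 0 else stats::cor(x, y)^2
  structure(list(r_squared = r2, slope = slope, intercept = intercept,
                 n = n, status = "ok"),
            class = "mixing_score")
}

#' @export
print.mixing_score <- function(x, ...) {
  if (x$status != "ok")
    cat(sprintf("Mixing score: %s (n = %d)\n", x$status, x$n))
  else
    cat(sprintf("Mixing score: R2 = %.4f (slope %.3f, intercept %.3f, n = %d spots)\n",
                x$r_squared, x$slope, x$intercept, x$n))
  invisible(x)
}

#' Nuclear aggregate scores
#'
#' Relative intensity: sum over all aggregate pixels of (intensity minus the
#' local background, floored at 0) divided by the integrated intensity over
#' the whole nucleus. The local background of each aggregate is the median
#' intensity in a 2-px annulus around it (other aggregates excluded).
#' mRNA enrichment: mean FISH intensity over aggregate pixels divided by the
#' mean FISH intensity over the whole nucleus.
#'
#' @param image a \code{\link{cell_image}}.
#' @param masks \code{\link{segmentation_masks}} with a labelled
#'   \code{aggregates} matrix.
#' @param channel channel for the aggregate relative intensity.
#' @param fish_channel channel for the poly-A mRNA enrichment (NULL skips).
#' @param annulus_px local-background annulus width in px.
#' @return object of class \code{aggregate_score}: \code{relative_intensity},
#'   \code{mrna_enrichment} (NA when no FISH channel), \code{n_aggregates}.
#' @export
aggregate_scores <- function(image, masks, channel = "green",
                             fish_channel = NULL, annulus_px = 2L) {
  stopifnot(inherits(image, "cell_image"),
            inherits(masks, "segmentation_masks"))
  if (!any(masks$nucleus)) stop("aggregate_scores: empty nucleus mask")
  ch <- image$channels[[channel]]
  if (is.null(ch)) stop("aggregate_scores: no channel '", channel, "'")
  lab <- masks$aggregates
  nlab <- max(lab)
  nuc_total <- sum(ch[masks$nucleus])
  if (nlab == 0L)
    return(structure(list(relative_intensity = 0,
                          mrna_enrichment = NA_real_, n_aggregates = 0L),
                     class = "aggregate_score"))
  brush <- EBImage::makeBrush(2L * annulus_px + 1L, shape = "disc")
  agg_sum <- 0
  for (l in seq_len(nlab)) {
    m <- lab == l
    grown <- EBImage::dilate(EBImage::Image(m * 1), brush) > 0
    annulus <- matrix(as.logical(grown), nrow(ch), ncol(ch)) & lab == 0L
    bg <- stats::median(ch[annulus])
    agg_sum <- agg_sum + sum(pmax(ch[m] - bg, 0))
  }
  rel <- agg_sum / nuc_total
  mrna <- NA_real_
  if (!is.null(fish_channel)) {
    f <- image$channels[[fish_channel]]
    if (is.null(f)) stop("aggregate_scores: no channel '", fish_channel, "'")
    mrna <- mean(f[lab > 0]) / mean(f[masks$nucleus])
  }
  structure(list(relative_intensity = rel, mrna_enrichment = mrna,
                 n_aggregates = nlab),
            class = "aggregate_score")
}

#' @export
print.aggregate_score <- function(x, ...) {
  cat(sprintf("Aggregate score: relative intensity = %.4g over %d aggregate(s)",
              x$relative_intensity, x$n_aggregates))
  if (!is.na(x$mrna_enrichment))
    cat(sprintf(", poly-A mRNA enrichment = %.3f", x$mrna_enrichment))
  cat("\n")
  invisible(x)
}

#' Full mixing-score pipeline on one image
#'
#' segment -> detect -> filter -> pooled regression; the convenience path
#' used by the recovery studies.
#'
#' @param image a \code{\link{cell_image}}.
#' @param detection_channel channel for spot detection; defaults to a
#'   structural \code{marker} channel when the image has one (detection on a
#'   marker keeps the measured region independent of the per-spot
#'   fluorescence, avoiding brightness-dependent region bias), else green.
#' @param min_spots minimum spot count for the regression.
#' @param ... passed to \code{\link{filter_spots}}.
#' @return a \code{\link{mixing_score}} with the filtered measurements in
#'   attribute \code{"spots"}.
#' @export
mixing_pipeline <- function(image, detection_channel = NULL,
                            min_spots = 10L, ...) {
  if (is.null(detection_channel))
    detection_channel <- if ("marker" %in% names(image$channels))
      "marker" else "green"
  masks <- segment_cell(image)
  det <- detect_spots(image, detection_channel, masks)
  kept <- filter_spots(det$spots, ...)
  score <- mixing_score(kept, min_spots = min_spots)
  attr(score, "spots") <- kept
  score
}
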