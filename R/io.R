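#' Read / write ITC injection tables
#'
#' CSV dialect: header row with columns \code{injection_index},
#' \code{dV_uL}, and either \code{q_ucal} (per-injection heat in microcal)
#' or \code{q_kcal_per_mol} (heat normalised per mole of injectant);
#' optional \code{sigma} in the same unit as the heat column. The protocol
#' supplies concentrations so molar ratios can be reconstructed.
#'
#' @param path CSV file.
#' @param protocol the \code{\link{titration_protocol}} of the run.
#' @param dilution dilution convention for the molar-ratio reconstruction.
#' @return an \code{isotherm}.
#' @export
read_itc_csv <- function(path, protocol,
                         dilution = c("perfusion", "displaced")) {
  dilution <- match.arg(dilution)
  raw <- utils::read.csv(path, check.names = TRUE)
  need <- c("injection_index", "dV_uL")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("read_itc_csv: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path)
  if (anyNA(raw$injection_index) || anyNA(raw$dV_uL))
    stop("read_itc_csv: incomplete rows in ", path, " (truncated file?)")
  dV <- raw$dV_uL * 1e-6
  if ("q_ucal" %in% names(raw)) {
    q <- raw$q_ucal * 1e-9            # microcal -> kcal
    sig <- if ("sigma" %in% names(raw)) raw$sigma * 1e-9 else 0
  } else if ("q_kcal_per_mol" %in% names(raw)) {
    q <- raw$q_kcal_per_mol * protocol$Xs * dV
    sig <- if ("sigma" %in% names(raw)) raw$sigma * protocol$Xs * dV else 0
  } else stop("read_itc_csv: need a q_ucal or q_kcal_per_mol column in ", path)
  if (anyNA(q)) stop("read_itc_csv: missing heats in ", path)
  v <- cumsum(dV)
  conc <- cell_concentrations(protocol, v, dilution)
  new_isotherm(data.frame(
    injection = raw$injection_index, dV = dV, cum_volume = v,
    Mt = conc$Mt, Xt = conc$Xt,
    molar_ratio = ifelse(conc$Mt > 0, conc$Xt / conc$Mt, Inf),
    Q = NA_real_, q = q, q_per_mol = q / (protocol$Xs * dV),
    sigma = sig))
}

#' @rdname read_itc_csv
#' @param isotherm the isotherm to write.
#' @export
write_itc_csv <- function(isotherm, path) {
  df <- data.frame(injection_index = isotherm$injection,
                   dV_uL = isotherm$dV * 1e6,
                   q_ucal = isotherm$q * 1e9,
                   sigma = isotherm$sigma * 1e9)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write Sparky-style peak lists
#'
#' Tab- or whitespace-separated with a header line; columns
#' \code{Assignment} (e.g. "G37N-H"), \code{w1} (15N shift, ppm), \code{w2}
#' (1H shift, ppm) and optionally \code{height} and \code{status}. Rows
#' lacking a height get NA height, not an error.
#'
#' @param path input file.
#' @param condition condition label for the list.
#' @return a \code{\link{peak_list}}.
#' @export
read_peaklist <- function(path, condition = basename(path)) {
  raw <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE, fill = TRUE)
  need <- c("Assignment", "w1", "w2")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("read_peaklist: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path)
  m <- regmatches(raw$Assignment,
                  regexec("^([A-Za-z]{1,3})(\\d+)", raw$Assignment))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop("read_peaklist: unparseable assignment at line(s) ",
         paste(which(bad) + 1L, collapse = ", "), " in ", path)
  resname <- vapply(m, `[`, character(1), 2)
  resid <- as.integer(vapply(m, `[`, character(1), 3))
  if (anyNA(raw$w1) || anyNA(raw$w2))
    stop("read_peaklist: missing shifts in ", path, " (truncated file?)")
  height <- if ("height" %in% names(raw)) as.numeric(raw$height) else NA_real_
  status <- if ("status" %in% names(raw)) raw$status else "assigned"
  peak_list(residue_id = resid, residue_name = resname,
            deltaH = raw$w2, deltaN = raw$w1,
            height = height, status = status, condition = condition)
}

#' @rdname read_peaklist
#' @param peaks the \code{\link{peak_list}} to write.
#' @export
write_peaklist <- function(peaks, path) {
  nm <- ifelse(is.na(peaks$residue_name), "X", peaks$residue_name)
  df <- data.frame(Assignment = sprintf("%s%dN-H", nm, peaks$residue_id),
                   w1 = peaks$deltaN, w2 = peaks$deltaH,
                   height = peaks$height, status = peaks$status)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write 3-column SAXS curves
#'
#' Whitespace-separated q, I, sigma text, with '#' comment lines preserved
#' in the curve's \code{comments} field.
#'
#' @param path input file.
#' @return a \code{\link{scattering_curve}}.
#' @export
read_saxs_dat <- function(path) {
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines) | !nzchar(trimws(lines))
  comments <- lines[grepl("^\\s*#", lines)]
  body <- lines[!is_comment]
  if (!length(body)) stop("read_saxs_dat: no data rows in ", path)
  fields <- strsplit(trimws(body), "\\s+")
  ncol <- vapply(fields, length, integer(1))
  if (any(ncol < 2L))
    stop("read_saxs_dat: malformed row at data line ",
         which(ncol < 2L)[1], " in ", path)
  ## coercion failures surface as the explicit parse error below
  q <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 1)))
  I <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  sigma <- suppressWarnings(
    ifelse(ncol >= 3L,
           as.numeric(vapply(fields, function(f)
             if (length(f) >= 3L) f[3] else NA_character_,
             character(1))), NA_real_))
  if (anyNA(q) || anyNA(I))
    stop("read_saxs_dat: non-numeric q or I in ", path)
  if (is.unsorted(q, strictly = TRUE))
    stop("read_saxs_dat: q must be strictly increasing in ", path)
  scattering_curve(q, I, sigma, comments = comments)
}

#' @rdname read_saxs_dat
#' @param curve the \code{\link{scattering_curve}} to write.
#' @export
write_saxs_dat <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in curve$comments) writeLines(cm, con)
  writeLines(sprintf("%.8e %.8e %.8e", curve$q, curve$I, curve$sigma), con)
  invisible(path)
}

#' Read a directory (or file set) of numbered SEC-SAXS frames
#'
#' @param paths a directory containing .dat frames, or a character vector of
#'   frame files; frames are ordered by filename.
#' @return a \code{\link{sec_saxs_series}}.
#' @export
read_sec_series <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.dat$", full.names = TRUE)
  paths <- sort(paths)
  if (!length(paths)) stop("read_sec_series: no .dat frames found")
  sec_saxs_series(lapply(paths, read_saxs_dat))
}

#' Write a P(r) result as 2-column text plus a JSON sidecar
#'
#' @param pr a \code{\link{pair_distribution}}.
#' @param path output text file; the sidecar gets extension .json.
#' @export
write_pr <- function(pr, path) {
  con <- file(path, "w")
  writeLines("# r p(r)", con)
  writeLines(sprintf("%.6e %.6e", pr$r, pr$p), con)
  close(con)
  meta <- list(dmax = pr$dmax, rg = pr$rg, lambda = pr$lambda,
               back_chi2 = pr$back_chi2, positivity = pr$positivity)
  jsonlite::write_json(meta, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write multi-channel cell images as TIFF
#'
#' Multi-page 32-bit float TIFF with one page per channel; the channel map
#' names the pages.
#'
#' @param path TIFF file.
#' @param channel_map named integer vector mapping channel name -> page.
#' @return a \code{\link{cell_image}}.
#' @export
read_cell_tiff <- function(path, channel_map) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(channel_map > length(pages)))
    stop("read_cell_tiff: channel map refers to page beyond ",
         length(pages), " in ", path)
  channels <- lapply(channel_map, function(i) {
    m <- pages[[i]]
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m
  })
  names(channels) <- names(channel_map)
  cell_image(channels)
}

#' @rdname read_cell_tiff
#' @param image the \code{\link{cell_image}} to write. Intensities are
#'   rescaled to [0, 1] by the global maximum (stored nowhere: TIFF float
#'   pages keep relative structure, which is what the scores use).
#' @export
write_cell_tiff <- function(image, path) {
  mx <- max(vapply(image$channels, max, numeric(1)), 1)
  pages <- lapply(image$channels, function(m) m / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Default analysis configuration
#'
#' Every tolerance and threshold used by the analysis stages, at its
#' module-documented default. \code{run_config} reads a YAML file and
#' overlays it on these defaults; unknown keys are rejected.
#'
#' @return a nested list.
#' @export
default_config <- function() {
  list(
    itc = list(dilution = "perfusion", n_starts = 5L, exclude_first = FALSE),
    guinier = list(qmax_rg_limit = 1.3, min_points = 5L),
    vc = list(qmax = 0.3, calibration = "protein"),
    pr = list(n_r = 101L, positivity = TRUE,
              dmax_scan = list(lo_rg = 2, hi_rg = 5, step = 2)),
    frames = list(rg_tolerance = 0.05, min_run = 3L),
    spots = list(area_min = 20, area_max = 300, ratio_max = 0.3,
                 min_spots = 10L),
    segmentation = list(cytoplasm_radius = Inf, aggregate_tophat = 15L,
                        aggregate_k = 6, annulus_px = 2L),
    seed = 1L
  )
}

#' @rdname default_config
#' @param path YAML config file (optional; NULL returns the defaults).
#' @export
run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_strict <- function(base, over, where = "") {
    for (k in names(over)) {
      if (!k %in% names(base))
        stop("run_config: unknown key '", paste0(where, k), "'")
      if (is.list(base[[k]]) && is.list(over[[k]]))
        base[[k]] <- merge_strict(base[[k]], over[[k]],
                                  paste0(where, k, "."))
      else base[[k]] <- over[[k]]
    }
    base
  }
  merge_strict(cfg, user)
}

#' Write an ITC fit report (JSON + observed-vs-fitted CSV)
#'
#' @param fit an \code{itc_fit}.
#' @param json_path,csv_path output files (NULL to skip either).
#' @export
write_itc_report <- function(fit, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(fit, "itc_fit"))
  if (!is.null(json_path)) {
    report <- list(
      model = fit$kind, converged = fit$converged,
      estimates = fit$estimates,
      cooperativity_index = fit$cooperativity_index,
      rss = fit$rss, warnings = fit$warnings,
      thermodynamics = thermodynamics(fit))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null")
  }
  if (!is.null(csv_path)) {
    df <- data.frame(injection = fit$isotherm$injection,
                     molar_ratio = fit$isotherm$molar_ratio,
                     q_obs = fit$isotherm$q, q_fit = fit$fitted$q)
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(fit)
}

#' Write a CSP profile (CSV + JSON threshold sidecar)
#'
#' @param profile a \code{csp_profile}.
#' @param csv_path per-residue CSV; sidecar written next to it as .json.
#' @export
write_csp_report <- function(profile, csv_path) {
  stopifnot(inherits(profile, "csp_profile"))
  prof <- profile$profile
  prof$reason <- NA_character_
  exc <- profile$excluded
  if (nrow(exc)) {
    exc2 <- data.frame(residue_id = exc$residue_id, delta_delta = NA_real_,
                       flagged = NA, reason = exc$reason)
    prof <- rbind(prof, exc2)
    prof <- prof[order(prof$residue_id), ]
  }
  utils::write.csv(prof, csv_path, row.names = FALSE)
  jsonlite::write_json(list(threshold = profile$threshold,
                            robust = profile$robust,
                            n_matched = nrow(profile$profile)),
                       sub("\\.[^.]*$", ".json", csv_path),
                       auto_unbox = TRUE, digits = NA)
  invisible(profile)
}
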