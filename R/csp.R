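#' Construct a peak list
#'
#' An assigned-amide peak list for one experimental condition. Each residue
#' carries the proton and nitrogen chemical shifts (ppm), an intensity
#' (peak height) and a status: \code{"assigned"}, \code{"overlapped"},
#' \code{"unassigned"} or \code{"absent"} (the resonance is broadened beyond
#' detection). Only assigned peaks enter chemical-shift-perturbation
#' calculations; overlapped/unassigned residues are excluded with a reason.
#'
#' @param residue_id integer residue numbers (unique).
#' @param deltaH proton shift in ppm (NA allowed for non-assigned peaks).
#' @param deltaN nitrogen shift in ppm.
#' @param height peak height (>= 0), NA when not measured.
#' @param status character vector, one of assigned/overlapped/unassigned/absent.
#' @param residue_name optional residue one/three-letter names.
#' @param condition free-text condition label.
#' @return an object of class \code{peak_list} (a data frame).
#' @export
peak_list <- function(residue_id, deltaH, deltaN, height = NA_real_,
                      status = "assigned", residue_name = NA_character_,
                      condition = "") {
  residue_id <- as.integer(residue_id)
  if (anyDuplicated(residue_id)) stop("peak_list: residue_id must be unique")
  df <- data.frame(residue_id = residue_id,
                   residue_name = rep_len(residue_name, length(residue_id)),
                   deltaH = rep_len(as.numeric(deltaH), length(residue_id)),
                   deltaN = rep_len(as.numeric(deltaN), length(residue_id)),
                   height = rep_len(as.numeric(height), length(residue_id)),
                   status = rep_len(status, length(residue_id)))
  bad <- df$status == "assigned" & (!is.finite(df$deltaH) | !is.finite(df$deltaN))
  if (any(bad))
    stop("peak_list: assigned peaks need finite deltaH and deltaN (residues ",
         paste(df$residue_id[bad], collapse = ", "), ")")
  if (any(!is.na(df$height) & df$height < 0))
    stop("peak_list: heights must be >= 0")
  attr(df, "condition") <- condition
  class(df) <- c("peak_list", "data.frame")
  df
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("Peak list '%s': %d residues (%d assigned)\n",
              attr(x, "condition"), nrow(x), sum(x$status == "assigned")))
  print.data.frame(utils::head(as.data.frame(x), 5), digits = 4)
  if (nrow(x) > 5) cat(sprintf("  ... %d more residues\n", nrow(x) - 5L))
  invisible(x)
}

#' Combined amide chemical shift perturbation
#'
#' The weighted combined 1H/15N shift change between two states of the same
#' residue: dd = (0.5 [ (ddH)^2 + (0.14 ddN)^2 ])^0.5, with the 0.14 factor
#' compressing the wider nitrogen shift scale onto the proton scale.
#'
#' @param deltaH_a,deltaN_a shifts (ppm) in state a.
#' @param deltaH_b,deltaN_b shifts (ppm) in state b.
#' @return combined shift perturbation in ppm (vectorised).
#' @export
csp <- function(deltaH_a, deltaN_a, deltaH_b, deltaN_b) {
  ddH <- deltaH_a - deltaH_b
  ddN <- deltaN_a - deltaN_b
  sqrt(0.5 * (ddH^2 + (0.14 * ddN)^2))
}

#' Per-residue CSP profile with the 3xSD significance threshold
#'
#' Matches the two peak lists by residue id, computes the combined shift
#' perturbation for every residue assigned in both, and flags residues whose
#' perturbation exceeds three times the standard deviation of all matched
#' perturbations. Residues missing, overlapped or unassigned in either list
#' are reported as excluded with a reason.
#'
#' @param list_a,list_b \code{\link{peak_list}} objects for the two states.
#' @param robust use median/MAD in place of mean/SD for the threshold
#'   (default FALSE: plain standard deviation over all matched residues).
#' @return an object of class \code{csp_profile}: a list with a data frame
#'   \code{profile} (residue_id, delta_delta, flagged), the \code{threshold}
#'   (ppm) and a data frame \code{excluded} (residue_id, reason).
#' @export
csp_profile <- function(list_a, list_b, robust = FALSE) {
  stopifnot(inherits(list_a, "peak_list"), inherits(list_b, "peak_list"))
  ids <- union(list_a$residue_id, list_b$residue_id)
  a <- list_a[match(ids, list_a$residue_id), ]
  b <- list_b[match(ids, list_b$residue_id), ]
  reason <- rep(NA_character_, length(ids))
  miss_a <- is.na(a$residue_id) | a$status %in% c("absent")
  miss_b <- is.na(b$residue_id) | b$status %in% c("absent")
  bad_a <- !miss_a & a$status != "assigned"
  bad_b <- !miss_b & b$status != "assigned"
  reason[miss_a] <- "missing in list_a"
  reason[miss_b] <- ifelse(is.na(reason[miss_b]), "missing in list_b",
                           "missing in both")
  reason[bad_a] <- paste0(a$status[bad_a], " in list_a")
  reason[bad_b] <- ifelse(is.na(reason[bad_b]),
                          paste0(b$status[bad_b], " in list_b"), reason[bad_b])
  matched <- is.na(reason)
  if (sum(matched) < 3L)
    stop("csp_profile: fewer than 3 residues assigned in both lists")
  dd <- csp(a$deltaH[matched], a$deltaN[matched],
            b$deltaH[matched], b$deltaN[matched])
  threshold <- if (robust) 3 * stats::mad(dd) else 3 * stats::sd(dd)
  profile <- data.frame(residue_id = ids[matched], delta_delta = dd,
                        flagged = dd > threshold)
  profile <- profile[order(profile$residue_id), ]
  excluded <- data.frame(residue_id = ids[!matched], reason = reason[!matched])
  excluded <- excluded[order(excluded$residue_id), ]
  structure(list(profile = profile, threshold = threshold,
                 excluded = excluded, robust = robust),
            class = "csp_profile")
}

#' @export
print.csp_profile <- function(x, ...) {
  cat(sprintf("CSP profile: %d matched residues, threshold (3xSD) = %.4g ppm\n",
              nrow(x$profile), x$threshold))
  nf <- sum(x$profile$flagged)
  cat(sprintf("  %d residue(s) above threshold", nf))
  if (nf > 0 && nf <= 20)
    cat(": ", paste(x$profile$residue_id[x$profile$flagged], collapse = ", "))
  cat("\n")
  if (nrow(x$excluded))
    cat(sprintf("  %d excluded (missing/overlapped/unassigned)\n",
                nrow(x$excluded)))
  invisible(x)
}

#' @export
plot.csp_profile <- function(x, ...) {
  p <- x$profile
  graphics::plot(p$residue_id, p$delta_delta, type = "h",
                 xlab = "residue", ylab = expression(Delta * delta ~ "(ppm)"),
                 col = ifelse(p$flagged, 2, 1), ...)
  graphics::abline(h = x$threshold, lty = 3, col = 2)
  invisible(x)
}

#' Peak-height ratios between two conditions
#'
#' Per-residue height_after / height_before, the readout for exchange
#' broadening at an oligomerisation interface: residues whose peaks vanish
#' after a competition or binding event are flagged \code{"broadened"},
#' residues whose peaks come back (height_before = 0 or absent, measurable
#' after) are flagged \code{"reappeared"}.
#'
#' @param list_after,list_before \code{\link{peak_list}} objects.
#' @return a data frame: residue_id, height_before, height_after, ratio
#'   (NA when not finite-definable) and flag in
#'   \{ok, broadened, reappeared, omitted\}.
#' @export
peak_height_ratio <- function(list_after, list_before) {
  stopifnot(inherits(list_after, "peak_list"), inherits(list_before, "peak_list"))
  ids <- union(list_after$residue_id, list_before$residue_id)
  aft <- list_after[match(ids, list_after$residue_id), ]
  bef <- list_before[match(ids, list_before$residue_id), ]
  h_aft <- ifelse(is.na(aft$residue_id) | aft$status == "absent", 0, aft$height)
  h_bef <- ifelse(is.na(bef$residue_id) | bef$status == "absent", 0, bef$height)
  h_aft[is.na(h_aft)] <- 0
  h_bef[is.na(h_bef)] <- 0
  ratio <- rep(NA_real_, length(ids))
  flag <- rep("omitted", length(ids))
  both0 <- h_bef == 0 & h_aft == 0
  re <- h_bef == 0 & h_aft > 0
  br <- h_bef > 0 & h_aft == 0
  ok <- h_bef > 0 & h_aft > 0
  ratio[ok | br] <- h_aft[ok | br] / h_bef[ok | br]
  flag[ok] <- "ok"; flag[br] <- "broadened"; flag[re] <- "reappeared"
  out <- data.frame(residue_id = ids, height_before = h_bef,
                    height_after = h_aft, ratio = ratio, flag = flag)
  out[!both0, , drop = FALSE][order(out$residue_id[!both0]), ]
}
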