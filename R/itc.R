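#' Define an ITC titration protocol
#'
#' Describes the calorimeter experiment: cell volume, starting cell
#' (macromolecule) concentration, syringe (ligand) concentration, the
#' per-injection volumes, and temperature. All downstream heat-model
#' calculations take concentrations in molar, volumes in litres and
#' temperature in kelvin; heats are in kcal.
#'
#' @param cell_volume cell (active) volume V0 in litres.
#' @param cell_conc total macromolecule concentration in the cell at the
#'   start, in M.
#' @param syringe_conc ligand concentration in the syringe, in M.
#' @param injection_volumes numeric vector of injection volumes dVi in
#'   litres, one per injection.
#' @param temperature temperature in kelvin.
#' @return an object of class \code{titration_protocol}.
#' @examples
#' # 0.2 mL cell, 15 uM protein, 100 uM oligonucleotide, 37 x 1 uL
#' default_protocol()
#' @export
titration_protocol <- function(cell_volume, cell_conc, syringe_conc,
                               injection_volumes, temperature = 298.15) {
  stopifnot(is.numeric(cell_volume), length(cell_volume) == 1L,
            is.finite(cell_volume), cell_volume > 0,
            is.numeric(cell_conc), cell_conc >= 0,
            is.numeric(syringe_conc), syringe_conc >= 0,
            is.numeric(injection_volumes), length(injection_volumes) >= 1L,
            all(is.finite(injection_volumes)), all(injection_volumes > 0),
            is.numeric(temperature), temperature > 0)
  structure(list(V0 = cell_volume, Mt0 = cell_conc, Xs = syringe_conc,
                 dV = as.numeric(injection_volumes), temperature = temperature),
            class = "titration_protocol")
}

#' @export
print.titration_protocol <- function(x, ...) {
  cat("ITC titration protocol\n")
  cat(sprintf("  cell volume:        %.4g mL\n", x$V0 * 1e3))
  cat(sprintf("  cell concentration: %.4g uM\n", x$Mt0 * 1e6))
  cat(sprintf("  syringe ligand:     %.4g uM\n", x$Xs * 1e6))
  cat(sprintf("  injections:         %d (total %.3g uL)\n",
              length(x$dV), sum(x$dV) * 1e6))
  cat(sprintf("  temperature:        %.2f K\n", x$temperature))
  invisible(x)
}

#' The standard titration protocol used throughout this package
#'
#' A 0.2 mL cell with 15 uM macromolecule titrated with 100 uM ligand in
#' 37 injections of 1 uL, the typical configuration for a GT-repeat
#' oligonucleotide titrated into an RRM-containing protein.
#'
#' @param n_injections number of injections (default 37).
#' @return a \code{\link{titration_protocol}}.
#' @export
default_protocol <- function(n_injections = 37L) {
  titration_protocol(cell_volume = 0.2e-3, cell_conc = 15e-6,
                     syringe_conc = 100e-6,
                     injection_volumes = rep(1e-6, n_injections),
                     temperature = 298.15)
}

#' Binding-model constructors
#'
#' A binding model holds per-set stoichiometries n (sites per macromolecule
#' monomer), association constants K (1/M) and binding enthalpies dH
#' (kcal/mol). \code{one_set_model} describes a single class of independent
#' sites; \code{two_sets_model} two independent classes, the form used to
#' quantify cooperative two-monomer loading of one oligonucleotide.
#'
#' @param n,n1,n2 sites per macromolecule monomer (> 0).
#' @param K,K1,K2 association constants in 1/M (>= 0).
#' @param dH,dH1,dH2 binding enthalpies in kcal/mol.
#' @return an object of class \code{binding_model} with elements
#'   \code{kind}, \code{n}, \code{K}, \code{dH} (vectors over sets).
#' @export
one_set_model <- function(n, K, dH) {
  stopifnot(is.finite(n), n > 0, is.finite(K), K >= 0, is.finite(dH))
  structure(list(kind = "one_set", n = n, K = K, dH = dH),
            class = "binding_model")
}

#' @rdname one_set_model
#' @export
two_sets_model <- function(n1, n2, K1, K2, dH1, dH2) {
  stopifnot(is.finite(c(n1, n2)), n1 > 0, n2 > 0,
            is.finite(c(K1, K2)), K1 >= 0, K2 >= 0, is.finite(c(dH1, dH2)))
  structure(list(kind = "two_sets", n = c(n1, n2), K = c(K1, K2),
                 dH = c(dH1, dH2)),
            class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("Binding model (%s)\n", x$kind))
  for (s in seq_along(x$n))
    cat(sprintf("  set %d: n = %.4g, K = %.4g /M (KD = %.4g M), dH = %.4g kcal/mol\n",
                s, x$n[s], x$K[s], ifelse(x$K[s] > 0, 1 / x$K[s], Inf), x$dH[s]))
  invisible(x)
}

#' Free ligand concentration from the mass balance
#'
#' Solves Xt = X + Mt * sum_s n_s K_s X / (1 + K_s X) for the free ligand
#' concentration X in [0, Xt]. The left side is strictly increasing in X so
#' the root is unique; it is bracketed by bisection and polished by Newton
#' steps to a residual below 1e-12 * max(Xt, 1e-12).
#'
#' @param model a \code{\link{one_set_model}} or \code{\link{two_sets_model}}.
#' @param Mt total macromolecule concentration (M).
#' @param Xt total ligand concentration (M).
#' @return free ligand concentration X in M.
#' @export
free_ligand <- function(model, Mt, Xt) {
  if (any(!is.finite(Mt)) || any(!is.finite(Xt)) || any(Mt < 0) || any(Xt < 0))
    stop("free_ligand: Mt and Xt must be finite and non-negative")
  X <- free_ligand_vec(model, Mt, Xt)
  if (length(Mt) == 1L && length(Xt) == 1L) X[1] else X
}

## Vectorised mass-balance solve over injections: bisection bracket then
## Newton polish, all in vector arithmetic (the per-injection loop would
## dominate the fit cost otherwise).
free_ligand_vec <- function(model, Mt, Xt) {
  k <- max(length(Mt), length(Xt))
  Mt <- rep_len(Mt, k); Xt <- rep_len(Xt, k)
  n <- model$n; K <- model$K
  bound <- Mt > 0 & Xt > 0 & any(K > 0)
  X <- Xt                                  # free cases are exact already
  if (!any(bound)) return(X)
  bal <- function(x, mt, xt) {
    tot <- 0
    for (s in seq_along(n)) tot <- tot + n[s] * K[s] * x / (1 + K[s] * x)
    x + mt * tot - xt
  }
  mt <- Mt[bound]; xt <- Xt[bound]
  lo <- rep(0, sum(bound)); hi <- xt
  for (i in seq_len(40L)) {
    mid <- (lo + hi) / 2
    up <- bal(mid, mt, xt) > 0
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
  }
  x <- (lo + hi) / 2
  for (i in seq_len(6L)) {                 # Newton polish to machine precision
    slope <- 1
    for (s in seq_along(n)) slope <- slope + mt * n[s] * K[s] / (1 + K[s] * x)^2
    x <- x - bal(x, mt, xt) / slope
    x <- pmin(pmax(x, 0), xt)
  }
  X[bound] <- x
  X
}

#' Cumulative binding heat
#'
#' The cumulative heat after equilibration at total concentrations (Mt, Xt):
#' Q = Mt V0 sum_s n_s dH_s K_s X / (1 + K_s X), with X the free-ligand
#' solution of the mass balance. One-set and two-sets models differ only in
#' the number of terms in the sum.
#'
#' @inheritParams free_ligand
#' @param protocol a \code{\link{titration_protocol}} (supplies V0).
#' @return heat in kcal.
#' @export
cumulative_heat <- function(model, protocol, Mt, Xt) {
  X <- free_ligand_vec(model, Mt, Xt)
  k <- max(length(Mt), length(Xt))
  Mt <- rep_len(Mt, k)
  Q <- 0
  for (s in seq_along(model$n))
    Q <- Q + model$n[s] * model$dH[s] * model$K[s] * X / (1 + model$K[s] * X)
  out <- Mt * protocol$V0 * Q
  if (k == 1L) out[1] else out
}

## Concentrations in the cell after cumulative injected volume v.
## perfusion: continuous-overflow model, Mt = Mt0 exp(-v/V0);
## displaced: the stepwise displaced-volume bookkeeping used by
## instrument software, Mt = Mt0 (1 - v/2V0)/(1 + v/2V0).
cell_concentrations <- function(protocol, cumulative_volume,
                                dilution = c("perfusion", "displaced")) {
  dilution <- match.arg(dilution)
  v <- cumulative_volume; V0 <- protocol$V0
  if (dilution == "perfusion") {
    Mt <- protocol$Mt0 * exp(-v / V0)
    Xt <- protocol$Xs * (1 - exp(-v / V0))
  } else {
    Mt <- protocol$Mt0 * (1 - v / (2 * V0)) / (1 + v / (2 * V0))
    Xt <- protocol$Xs * (v / V0) / (1 + v / (2 * V0))
  }
  list(Mt = Mt, Xt = Xt)
}

#' Per-injection heats of a simulated titration
#'
#' Evaluates the cumulative heat at each injection (with injection-by-
#' injection dilution of both species) and converts to per-injection heats
#' with the displaced-volume correction
#' qi = Qi + dVi/V0 * (Qi + Qi-1)/2 - Qi-1.
#'
#' @inheritParams cumulative_heat
#' @param dilution how concentrations evolve across injections:
#'   \code{"perfusion"} (default; Mt_i = Mt0 exp(-v_i/V0)) or
#'   \code{"displaced"} (stepwise displaced-volume bookkeeping).
#' @return an object of class \code{isotherm}: a data frame with one row per
#'   injection and columns \code{injection}, \code{dV} (L),
#'   \code{cum_volume} (L), \code{Mt}, \code{Xt} (M), \code{molar_ratio},
#'   \code{Q} (cumulative heat, kcal), \code{q} (injection heat, kcal),
#'   \code{q_per_mol} (kcal per mol of injectant) and \code{sigma} (kcal).
#' @export
injection_heats <- function(model, protocol,
                            dilution = c("perfusion", "displaced")) {
  dilution <- match.arg(dilution)
  dV <- protocol$dV
  v <- cumsum(dV)
  conc <- cell_concentrations(protocol, v, dilution)
  Q <- cumulative_heat(model, protocol, conc$Mt, conc$Xt)
  q <- displaced_volume_correction(Q, dV, protocol$V0)
  ratio <- ifelse(conc$Mt > 0, conc$Xt / conc$Mt, Inf)
  new_isotherm(data.frame(
    injection = seq_along(dV), dV = dV, cum_volume = v,
    Mt = conc$Mt, Xt = conc$Xt, molar_ratio = ratio,
    Q = Q, q = q, q_per_mol = q / (protocol$Xs * dV),
    sigma = 0))
}

#' Displaced-volume correction of cumulative heats
#'
#' Converts a cumulative-heat sequence to per-injection heats,
#' qi = Qi + dVi/V0 * (Qi + Qi-1)/2 - Qi-1: part of the heat associated
#' with injection i leaves the active cell volume with the displaced
#' liquid, so the average of the bracketing cumulative heats, weighted by
#' the displaced fraction dVi/V0, is added back. With dVi = 0 this reduces
#' to the simple difference Qi - Qi-1.
#'
#' @param Q cumulative heats (kcal), one per injection (Q0 = 0 implied).
#' @param dV injection volumes (L), same length as Q.
#' @param V0 cell volume (L).
#' @return per-injection heats (kcal).
#' @export
displaced_volume_correction <- function(Q, dV, V0) {
  stopifnot(length(Q) == length(dV), V0 > 0, all(dV >= 0))
  Qprev <- c(0, Q[-length(Q)])
  Q + (dV / V0) * (Q + Qprev) / 2 - Qprev
}

new_isotherm <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("injection", "dV", "molar_ratio", "q") %in% names(df)))
  if (is.unsorted(df$molar_ratio)) stop("isotherm: molar_ratio must be non-decreasing")
  class(df) <- c("isotherm", "data.frame")
  df
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf("ITC isotherm: %d injections, molar ratio %.3g-%.3g\n",
              nrow(x), min(x$molar_ratio), max(x$molar_ratio)))
  print.data.frame(utils::head(as.data.frame(x), 5), digits = 4)
  if (nrow(x) > 5) cat(sprintf("  ... %d more injections\n", nrow(x) - 5L))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Fitting

## theta packs (log10 n, log10 K or -20 when K==0, dH) per set
theta_to_model <- function(theta, kind) {
  if (kind == "one_set")
    one_set_model(10^theta[1], 10^theta[2], theta[3])
  else
    two_sets_model(10^theta[1], 10^theta[2], 10^theta[3], 10^theta[4],
                   theta[5], theta[6])
}

model_to_theta <- function(model) {
  if (model$kind == "one_set")
    c(log10(model$n), log10(pmax(model$K, 1e-20)), model$dH)
  else
    c(log10(model$n), log10(pmax(model$K, 1e-20)), model$dH)
}

## Heuristic starting values from the shape of the isotherm:
## total stoichiometry from the molar ratio where the (per-mol) heat has
## dropped halfway from its initial plateau, dH from the first-plateau
## heat, K from an assumed mid-range Wiseman c.
itc_start_values <- function(isotherm, protocol, kind) {
  qpm <- isotherm$q_per_mol
  r <- isotherm$molar_ratio
  plateau <- stats::median(qpm[seq_len(min(4L, length(qpm)))])
  tail_q <- stats::median(qpm[seq(max(1L, length(qpm) - 3L), length(qpm))])
  half <- (plateau + tail_q) / 2
  past <- if (plateau < tail_q) which(qpm >= half) else which(qpm <= half)
  n_tot <- if (length(past)) r[past[1]] else stats::median(r)
  n_tot <- min(max(n_tot, 0.05), 10)
  dH0 <- plateau
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -5
  K0 <- 50 / (protocol$Mt0 * n_tot)    # Wiseman c ~ 50
  if (kind == "one_set") {
    list(base = c(log10(n_tot), log10(K0), dH0),
         spread = c(0.3, 1.5, 0))
  } else {
    list(base = c(log10(n_tot / 2), log10(n_tot / 2),
                  log10(K0 / 10), log10(K0 * 10), dH0, dH0),
         spread = c(0.3, 0.3, 1.5, 1.5, 0, 0))
  }
}

itc_residuals <- function(theta, kind, isotherm, protocol, weights, dilution,
                          skip) {
  model <- try(theta_to_model(theta, kind), silent = TRUE)
  if (inherits(model, "try-error")) return(rep(1e6, sum(!skip)))
  pred <- injection_heats(model, protocol, dilution)
  res <- (isotherm$q - pred$q) * weights
  res[!skip]
}

#' Fit a binding model to an ITC isotherm
#'
#' Weighted nonlinear least squares of the per-injection heat model
#' (cumulative heats from the one-set or two-sets equation, converted with
#' the displaced-volume correction) against observed heats. Multi-start
#' Levenberg-Marquardt (n, K on log10 scale) with heuristic initialisation
#' from the equivalence point, first-plateau heat and transition steepness.
#'
#' For two-sets fits the sets are relabelled after fitting so that set 1 is
#' the weaker site (larger KD); the independent-sites model is invariant
#' under set relabelling, so this convention makes the cooperativity index
#' KD1/KD2 >= 1 by construction.
#'
#' @param isotherm an \code{\link{injection_heats}}-style isotherm (observed
#'   heats in column \code{q}, kcal; optional per-injection \code{sigma}).
#' @param protocol the \code{\link{titration_protocol}} used.
#' @param model_kind \code{"one_set"} or \code{"two_sets"}.
#' @param init optional \code{binding_model} giving a starting point.
#' @param n_starts number of multi-start replicates (>= 5 recommended).
#' @param exclude_first drop the first injection from the fit (common
#'   instrument artifact); default FALSE.
#' @param dilution dilution convention, see \code{\link{injection_heats}}.
#' @return an object of class \code{itc_fit} with the point estimates,
#'   standard errors, derived thermodynamics (KD, dG, TdS per set at the
#'   protocol temperature), Wiseman c-values, the cooperativity index
#'   (two-sets only), residual sum of squares and a convergence flag.
#' @seealso \code{\link{cooperativity_index}}, \code{\link{thermodynamics}}
#' @export
fit_isotherm <- function(isotherm, protocol,
                         model_kind = c("one_set", "two_sets"),
                         init = NULL, n_starts = 5L, exclude_first = FALSE,
                         dilution = c("perfusion", "displaced")) {
  model_kind <- match.arg(model_kind)
  dilution <- match.arg(dilution)
  stopifnot(inherits(isotherm, "isotherm") || is.data.frame(isotherm))
  n_par <- if (model_kind == "one_set") 3L else 6L
  if (nrow(isotherm) < 2L * n_par)
    stop("fit_isotherm: need at least ", 2L * n_par, " injections")
  if (max(abs(isotherm$q)) < 1e-15)
    stop("fit_isotherm: no binding signal (all heats are zero)")

  sigma <- isotherm$sigma
  if (is.null(sigma) || all(sigma <= 0) || any(!is.finite(sigma)))
    sigma <- rep(1, nrow(isotherm))
  sigma[sigma <= 0] <- min(sigma[sigma > 0])
  weights <- 1 / sigma
  skip <- rep(FALSE, nrow(isotherm))
  if (exclude_first) skip[1] <- TRUE

  sv <- itc_start_values(isotherm, protocol, model_kind)
  starts <- list(sv$base)
  if (!is.null(init)) starts <- c(list(model_to_theta(init)), starts)
  set.seed_local <- function(k) sv$base + sv$spread * stats::rnorm(n_par) *
    (k / max(1, n_starts - 1))
  while (length(starts) < n_starts)
    starts[[length(starts) + 1L]] <- set.seed_local(length(starts))

  best <- NULL
  for (th0 in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = th0, fn = itc_residuals, kind = model_kind,
      isotherm = isotherm, protocol = protocol, weights = weights,
      dilution = dilution, skip = skip,
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-14, ptol = 1e-14, gtol = 0)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(structure(list(kind = model_kind, converged = FALSE,
                          status = "failed: no start converged"),
                     class = "itc_fit"))

  theta <- best$par
  ## covariance on the theta scale; delta method to the natural scale
  dof <- sum(!skip) - n_par
  cov_th <- try(solve(best$hessian) * best$deviance / max(dof, 1),
                silent = TRUE)
  se_th <- if (inherits(cov_th, "try-error")) rep(NA_real_, n_par) else
    sqrt(pmax(diag(cov_th), 0))

  model <- theta_to_model(theta, model_kind)
  nsets <- length(model$n)
  ln10 <- log(10)
  se_n <- model$n * ln10 * se_th[seq_len(nsets)]
  se_K <- model$K * ln10 * se_th[nsets + seq_len(nsets)]
  se_dH <- se_th[2L * nsets + seq_len(nsets)]

  ord <- seq_len(nsets)
  if (nsets == 2L) ord <- order(model$K)     # set 1 = weaker (larger KD)
  est <- data.frame(set = seq_len(nsets),
                    n = model$n[ord], se_n = se_n[ord],
                    K = model$K[ord], se_K = se_K[ord],
                    dH = model$dH[ord], se_dH = se_dH[ord])
  est$KD <- 1 / est$K
  Tk <- protocol$temperature
  est$dG <- -itc_gas_constant() * Tk * log(est$K)
  est$TdS <- est$dH - est$dG
  est$c_value <- est$K * protocol$Mt0 * est$n

  fitted_model <- if (nsets == 1L) one_set_model(est$n, est$K, est$dH) else
    two_sets_model(est$n[1], est$n[2], est$K[1], est$K[2], est$dH[1], est$dH[2])
  pred <- injection_heats(fitted_model, protocol, dilution)

  warn <- character(0)
  bad_c <- est$c_value < 1 | est$c_value > 1000
  if (any(bad_c))
    warn <- sprintf("Wiseman c outside [1, 1000] for set(s) %s: %s",
                    paste(which(bad_c), collapse = ","),
                    paste(signif(est$c_value[bad_c], 3), collapse = ", "))

  structure(list(
    kind = model_kind, estimates = est, model = fitted_model,
    cooperativity_index = if (nsets == 2L) est$KD[1] / est$KD[2] else NULL,
    rss = best$deviance, converged = best$info %in% 1:4,
    status = best$message, warnings = warn,
    protocol = protocol, dilution = dilution,
    isotherm = isotherm, fitted = pred, excluded_first = exclude_first),
    class = "itc_fit")
}

itc_gas_constant <- function() 1.987204e-3  # kcal / (mol K)

#' Cooperativity index of a two-sets ITC fit
#'
#' The ratio KD1/KD2 of the weaker to the tighter dissociation constant
#' (>= 1 by the set-ordering convention). Values much larger than 1 indicate
#' that the second macromolecule loads onto the ligand much more tightly
#' than the first, i.e. cooperative assembly; values near 1 indicate
#' independent loading.
#'
#' @param fit an \code{itc_fit} from a two-sets fit.
#' @return KD1/KD2, dimensionless.
#' @export
cooperativity_index <- function(fit) {
  stopifnot(inherits(fit, "itc_fit"))
  if (fit$kind != "two_sets")
    stop("cooperativity_index: requires a two-sets fit")
  if (any(fit$estimates$K <= 0))
    stop("cooperativity_index: both association constants must be positive")
  max(fit$estimates$KD) / min(fit$estimates$KD)
}

#' Binding thermodynamics from equilibrium parameters
#'
#' dG = -R T ln K and TdS = dH - dG per binding set, with
#' R = 1.987204e-3 kcal/(mol K).
#'
#' @param fit an \code{itc_fit}, or a \code{binding_model}.
#' @param temperature temperature in kelvin (defaults to the fit protocol's).
#' @return a data frame with one row per set: \code{K}, \code{KD},
#'   \code{dG}, \code{dH}, \code{TdS} (kcal/mol).
#' @export
thermodynamics <- function(fit, temperature = NULL) {
  if (inherits(fit, "itc_fit")) {
    if (is.null(temperature)) temperature <- fit$protocol$temperature
    K <- fit$estimates$K; dH <- fit$estimates$dH
  } else if (inherits(fit, "binding_model")) {
    if (is.null(temperature)) temperature <- 298.15
    K <- fit$K; dH <- fit$dH
  } else stop("thermodynamics: need an itc_fit or binding_model")
  if (any(K <= 0)) stop("thermodynamics: K must be positive")
  dG <- -itc_gas_constant() * temperature * log(K)
  data.frame(set = seq_along(K), K = K, KD = 1 / K, dG = dG, dH = dH,
             TdS = dH - dG)
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("ITC fit: %s model\n", x$kind))
  if (!isTRUE(x$converged)) cat("  ** did not converge:", x$status, "\n")
  if (is.null(x$estimates)) return(invisible(x))
  est <- x$estimates
  for (s in seq_len(nrow(est)))
    cat(sprintf("  set %d: n = %.3f (±%.3f)  KD = %.3g M  dH = %.3f kcal/mol  c = %.3g\n",
                s, est$n[s], est$se_n[s], est$KD[s], est$dH[s], est$c_value[s]))
  if (!is.null(x$cooperativity_index))
    cat(sprintf("  cooperativity index KD1/KD2 = %.3g\n", x$cooperativity_index))
  cat(sprintf("  RSS = %.3g, total n = %.3f\n", x$rss, sum(est$n)))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
summary.itc_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$estimates)) {
    cat("\nThermodynamics at", object$protocol$temperature, "K:\n")
    print(thermodynamics(object), digits = 4)
  }
  invisible(object)
}

#' @export
coef.itc_fit <- function(object, ...) {
  est <- object$estimates
  if (is.null(est)) return(numeric(0))
  out <- c(rbind(est$n, est$K, est$dH))
  names(out) <- as.vector(outer(c("n", "K", "dH"), est$set, paste0))
  out
}

#' @export
predict.itc_fit <- function(object, ...) object$fitted$q

#' @export
residuals.itc_fit <- function(object, ...) object$isotherm$q - object$fitted$q

#' @export
plot.itc_fit <- function(x, ...) {
  obs <- x$isotherm
  graphics::plot(obs$molar_ratio, obs$q_per_mol,
                 xlab = "molar ratio (ligand : macromolecule)",
                 ylab = "kcal per mol of injectant",
                 main = sprintf("ITC fit (%s)", x$kind), ...)
  graphics::lines(x$fitted$molar_ratio, x$fitted$q_per_mol, col = 2)
  invisible(x)
}

#' @export
simulate.itc_fit <- function(object, nsim = 1, seed = NULL, noise_sd = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim, gen_itc(object$model, object$protocol,
                                 noise_sd = noise_sd),
                   simplify = FALSE)
  if (nsim == 1L) out[[1]] else out
}
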