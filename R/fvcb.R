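# FvCB photosynthesis model: limitation-state assimilation, operating-point
# solution with mesophyll drawdown, and A-Ci curve fitting.

#' Rubisco kinetic constants
#'
#' Michaelis constants for carboxylation (`Kc`) and oxygenation (`Ko`) and the
#' oxygen mole fraction `O`, all at the reference leaf temperature. Defaults
#' are the widely used 25 degC mole-fraction set of the spreadsheet fitting
#' tools descending from Sharkey's calculator. No temperature-response
#' machinery is applied: gas exchange is assumed measured at `T_ref`.
#'
#' @param Kc Michaelis constant for CO2 (umol mol-1).
#' @param Ko Michaelis constant for O2 (mmol mol-1).
#' @param O Oxygen mole fraction (mmol mol-1).
#' @param T_ref Reference leaf temperature (degC), informational.
#' @return An object of class `kinetic_constants`.
#' @export
#' @examples
#' k <- kinetic_constants()
#' k$Kc * (1 + k$O / k$Ko)  # effective Michaelis term
kinetic_constants <- function(Kc = 404.9, Ko = 278.4, O = 210, T_ref = 25) {
  stopifnot(is.numeric(Kc), Kc > 0, is.numeric(Ko), Ko > 0,
            is.numeric(O), O > 0)
  structure(list(Kc = Kc, Ko = Ko, O = O, T_ref = T_ref),
            class = "kinetic_constants")
}

km_effective <- function(k) k$Kc * (1 + k$O / k$Ko)

#' FvCB parameter set
#'
#' Photosynthetic capacity parameters: maximum carboxylation rate `Vcmax`,
#' maximum electron transport rate `Jmax`, triose-phosphate-use rate `TPU`
#' (all umol m-2 s-1), day respiration `Rd`, mesophyll conductance `gm`
#' (mol CO2 m-2 s-1; `Inf` means no drawdown, i.e. Cc = Ci), and the CO2
#' photocompensation point `Gammastar` (umol mol-1). The defaults for `Rd`
#' (0.73) and `Gammastar` (38.18) are Laisk-method estimates for well-watered
#' walnut leaves; `Gammastar` is taken equal to the intercellular
#' photocompensation point.
#'
#' @param Vcmax,Jmax,TPU,Rd,gm,Gammastar Numeric scalars, see description.
#' @return An object of class `fvcb_params`.
#' @export
fvcb_params <- function(Vcmax, Jmax, TPU, Rd = 0.73, gm = Inf,
                        Gammastar = 38.18) {
  stopifnot(is.numeric(Vcmax), length(Vcmax) == 1, is.finite(Vcmax), Vcmax > 0,
            is.numeric(Jmax), length(Jmax) == 1, is.finite(Jmax), Jmax >= 0,
            is.numeric(TPU), length(TPU) == 1, is.finite(TPU), TPU > 0,
            is.numeric(Rd), length(Rd) == 1, is.finite(Rd), Rd >= 0,
            is.numeric(gm), length(gm) == 1, gm > 0,
            is.numeric(Gammastar), length(Gammastar) == 1,
            is.finite(Gammastar), Gammastar > 0)
  structure(list(Vcmax = Vcmax, Jmax = Jmax, TPU = TPU, Rd = Rd, gm = gm,
                 Gammastar = Gammastar),
            class = "fvcb_params")
}

#' A-Ci curve container
#'
#' Ordered gas-exchange observations for one leaflet. `data` must contain
#' columns `Ca`, `Ci`, `An` (umol mol-1, umol mol-1, umol CO2 m-2 s-1);
#' optional columns `PPFD`, `PhiPSII` and `T_leaf` are kept when present.
#'
#' @param data A data frame of observations.
#' @param replicate_id,accession_id Identifiers carried as attributes.
#' @param treatment One of `"well_watered"` or `"dehydrated"`.
#' @return A data frame of class `aci_curve`.
#' @export
aci_curve <- function(data, replicate_id = NA_character_,
                      accession_id = NA_character_,
                      treatment = c("well_watered", "dehydrated")) {
  treatment <- match.arg(treatment)
  stopifnot(is.data.frame(data), all(c("Ca", "Ci", "An") %in% names(data)))
  if (nrow(data) < 1) stop("an A-Ci curve needs at least one observation")
  if (any(!is.finite(data$Ci)) || any(data$Ci <= 0)) {
    stop("all Ci values must be positive and finite")
  }
  if (any(!is.finite(data$Ca)) || any(data$Ca <= 0)) {
    stop("all Ca values must be positive and finite")
  }
  keep <- intersect(c("Ca", "Ci", "An", "PPFD", "PhiPSII", "T_leaf"),
                    names(data))
  out <- as.data.frame(data[, keep, drop = FALSE])
  rownames(out) <- NULL
  structure(out,
            replicate_id = replicate_id, accession_id = accession_id,
            treatment = treatment,
            class = c("aci_curve", "data.frame"))
}

#' Rubisco-limited assimilation
#'
#' `An = Vcmax (Cc - Gammastar) / (Cc + Kc (1 + O/Ko)) - Rd`. Strictly
#' increasing in `Cc`, saturating at `Vcmax - Rd`.
#'
#' @param Cc Chloroplast CO2 mole fraction (umol mol-1), vectorised.
#' @param p An [fvcb_params()] object.
#' @param k A [kinetic_constants()] object.
#' @return Net assimilation (umol m-2 s-1).
#' @export
assimilation_rubisco <- function(Cc, p, k = kinetic_constants()) {
  if (any(Cc < 0)) stop("Cc must be non-negative")
  p$Vcmax * (Cc - p$Gammastar) / (Cc + km_effective(k)) - p$Rd
}

#' RuBP-regeneration-limited assimilation
#'
#' `An = J (Cc - Gammastar) / (4 Cc + 8 Gammastar) - Rd`, approaching
#' `J/4 - Rd` at saturating CO2.
#'
#' @param Cc Chloroplast CO2 mole fraction (umol mol-1), vectorised.
#' @param J Electron transport rate (umol m-2 s-1).
#' @param p An [fvcb_params()] object.
#' @return Net assimilation (umol m-2 s-1).
#' @export
assimilation_rubp <- function(Cc, J, p) {
  if (any(Cc < 0)) stop("Cc must be non-negative")
  if (any(J < 0)) stop("J must be non-negative")
  J * (Cc - p$Gammastar) / (4 * Cc + 8 * p$Gammastar) - p$Rd
}

#' TPU-limited assimilation
#'
#' The CO2-independent plateau `An = 3 TPU - Rd` (glycolate re-export set to
#' zero). By definition this is the CO2-saturated maximum assimilation rate.
#'
#' @param p An [fvcb_params()] object with `TPU > 0`.
#' @return Net assimilation (umol m-2 s-1), a scalar.
#' @export
assimilation_tpu <- function(p) {
  3 * p$TPU - p$Rd
}

#' Minimum-rule FvCB assimilation
#'
#' Net assimilation at a given chloroplast CO2 is the minimum of the Rubisco-,
#' RuBP-regeneration- and TPU-limited rates. Ties are resolved in the order
#' rubisco < rubp_regeneration < tpu.
#'
#' @param Cc Chloroplast CO2 mole fraction (umol mol-1), vectorised.
#' @param p An [fvcb_params()] object.
#' @param k A [kinetic_constants()] object.
#' @param J Electron transport rate; defaults to `p$Jmax` (saturating light).
#' @return A data frame with columns `An` and `state`.
#' @export
model_assimilation <- function(Cc, p, k = kinetic_constants(), J = p$Jmax) {
  a_c <- assimilation_rubisco(Cc, p, k)
  a_j <- assimilation_rubp(Cc, J, p)
  a_p <- rep(assimilation_tpu(p), length(Cc))
  m <- cbind(a_c, a_j, a_p)
  idx <- max.col(-m, ties.method = "first")
  data.frame(
    An = m[cbind(seq_along(Cc), idx)],
    state = c("rubisco", "rubp_regeneration", "tpu")[idx],
    stringsAsFactors = FALSE
  )
}

# Closed-form operating point for one hyperbolic branch
# An = a (Cc - G)/(e Cc + f) - Rd coupled with Cc = Ci - An/gm.
# Of the two quadratic roots the physical one lies on the increasing branch of
# the hyperbola, i.e. Cc > -f/e (the other root sits beyond the pole).
branch_operating_point <- function(Ci, a, e, f, Rd, G, gm) {
  if (!is.finite(gm)) {
    Cc <- Ci
  } else {
    qa <- -e / gm
    qb <- e * Ci + f - e * Rd / gm + a / gm
    qc <- Rd * (e * Ci + f) - a * (Ci - G)
    disc <- qb^2 - 4 * qa * qc
    if (any(disc < 0)) {
      stop("operating-point solve failed: no real chloroplast CO2 root")
    }
    s <- sqrt(disc)
    r1 <- (-qb + s) / (2 * qa)
    r2 <- (-qb - s) / (2 * qa)
    Cc1 <- Ci - r1 / gm
    Cc2 <- Ci - r2 / gm
    pole <- -f / e
    Cc <- ifelse(Cc1 > pole, Cc1, Cc2)
  }
  An <- a * (Cc - G) / (e * Cc + f) - Rd
  list(An = An, Cc = Cc)
}

#' Operating point of the coupled FvCB / diffusion system
#'
#' Solves the fixed point `An = model(Cc)` with `Cc = Ci - An/gm` in closed
#' (quadratic) form per limitation branch; the minimum rule is applied to the
#' branch solutions afterwards. With `gm = Inf` the drawdown vanishes and
#' `Cc = Ci` exactly.
#'
#' @param Ci Intercellular CO2 mole fraction (umol mol-1), vectorised.
#' @param p An [fvcb_params()] object.
#' @param k A [kinetic_constants()] object.
#' @param J Electron transport rate; defaults to `p$Jmax`.
#' @return A data frame with columns `An`, `Cc` and `state`.
#' @export
solve_operating_point <- function(Ci, p, k = kinetic_constants(), J = p$Jmax) {
  if (any(!is.finite(Ci)) || any(Ci <= 0)) stop("Ci must be positive")
  if (!(p$gm > 0)) stop("gm must be positive (Inf allowed)")
  rub <- branch_operating_point(Ci, p$Vcmax, 1, km_effective(k),
                                p$Rd, p$Gammastar, p$gm)
  rbp <- branch_operating_point(Ci, J, 4, 8 * p$Gammastar,
                                p$Rd, p$Gammastar, p$gm)
  an_p <- rep(assimilation_tpu(p), length(Ci))
  cc_p <- if (is.finite(p$gm)) Ci - an_p / p$gm else Ci
  m_an <- cbind(rub$An, rbp$An, an_p)
  m_cc <- cbind(rub$Cc, rbp$Cc, cc_p)
  idx <- max.col(-m_an, ties.method = "first")
  sel <- cbind(seq_along(Ci), idx)
  An <- m_an[sel]
  Cc <- m_cc[sel]
  if (any(Cc < -1e-9)) {
    stop("operating-point solve failed: chloroplast CO2 root below zero")
  }
  data.frame(An = An, Cc = pmax(Cc, 0),
             state = c("rubisco", "rubp_regeneration", "tpu")[idx],
             stringsAsFactors = FALSE)
}

# Predicted An for points assigned to fixed limitation blocks.
partition_predict <- function(Ci, labels, par, Km) {
  An <- numeric(length(Ci))
  i_c <- labels == "rubisco"
  i_j <- labels == "rubp_regeneration"
  i_p <- labels == "tpu"
  if (any(i_c)) {
    An[i_c] <- branch_operating_point(Ci[i_c], par[["Vcmax"]], 1, Km,
                                      par[["Rd"]], par[["Gammastar"]],
                                      par[["gm"]])$An
  }
  if (any(i_j)) {
    An[i_j] <- branch_operating_point(Ci[i_j], par[["Jmax"]], 4,
                                      8 * par[["Gammastar"]],
                                      par[["Rd"]], par[["Gammastar"]],
                                      par[["gm"]])$An
  }
  if (any(i_p)) {
    An[i_p] <- 3 * par[["TPU"]] - par[["Rd"]]
  }
  An
}

default_init <- function(Ci, An, Rd, G, Km) {
  tpu0 <- max((max(An) + Rd) / 3, 0.5)
  pick <- function(target) which.min(abs(Ci - target))
  i_lo <- pick(250)
  vc0 <- (An[i_lo] + Rd) * (Ci[i_lo] + Km) / max(Ci[i_lo] - G, 10)
  i_mid <- pick(600)
  j0 <- (An[i_mid] + Rd) * (4 * Ci[i_mid] + 8 * G) / max(Ci[i_mid] - G, 10)
  c(Vcmax = max(vc0, 5), Jmax = max(j0, 5), TPU = tpu0, gm = 0.2)
}

#' Fit the FvCB model to an A-Ci curve
#'
#' Minimises the sum of squared errors between observed assimilation and the
#' coupled operating-point predictions of [solve_operating_point()]. The
#' assignment of points to limitation states is found by exhaustive search
#' over ordered partitions of the Ci-sorted points (a Rubisco block from the
#' low-Ci end, then a RuBP-regeneration block, then an optional TPU block);
#' each partition is fitted by trust-region nonlinear least squares
#' ([minpack.lm::nls.lm]) on log-transformed parameters, the best partition is
#' refined from `n_starts` jittered starts, and the overall lowest SSE wins,
#' with ties broken by the lower `gm`.
#'
#' @param curve An [aci_curve()] (or data frame with `Ci`, `An`).
#' @param init Optional [fvcb_params()] starting values. Defaults to
#'   data-driven heuristics with `Rd = 0.73`, `Gammastar = 38.18`.
#' @param fixed Character vector of parameter names held at their `init`
#'   values; the default fixes the Laisk-derived `Rd` and `Gammastar`.
#' @param k A [kinetic_constants()] object.
#' @param n_starts Number of multistart fits for the winning partition.
#' @param seed Seed for the deterministic start jitter.
#' @return An object of class `aci_fit`: a list with elements `params`
#'   ([fvcb_params()]), `assignment` (per-point labels in Ci-sorted order,
#'   block boundaries, SSE) and `diagnostics` (SSE, residuals, fitted values,
#'   the sorted Ci, and the fluorescence-free "A-Ci method" `gm` estimate).
#' @export
fit_aci <- function(curve, init = NULL, fixed = c("Rd", "Gammastar"),
                    k = kinetic_constants(), n_starts = 3, seed = 1L) {
  df <- as.data.frame(curve)
  stopifnot(all(c("Ci", "An") %in% names(df)))
  ord <- order(df$Ci)
  Ci <- df$Ci[ord]
  An <- df$An[ord]
  n <- length(Ci)
  if (n < 5) {
    stop("insufficient data: at least 5 points are required to fit an A-Ci curve")
  }
  Km <- km_effective(k)
  Rd0 <- if (!is.null(init)) init$Rd else 0.73
  G0 <- if (!is.null(init)) init$Gammastar else 38.18
  start <- if (!is.null(init)) {
    c(Vcmax = init$Vcmax, Jmax = init$Jmax, TPU = init$TPU,
      gm = if (is.finite(init$gm)) init$gm else 0.2)
  } else {
    default_init(Ci, An, Rd0, G0, Km)
  }
  full0 <- c(start, Rd = Rd0, Gammastar = G0)
  all_names <- c("Vcmax", "Jmax", "TPU", "gm", "Rd", "Gammastar")
  fixed <- intersect(fixed, all_names)
  free <- setdiff(all_names, fixed)
  if (length(free) == 0) stop("no free parameters to fit")

  labels_for <- function(i, j) {
    c(rep("rubisco", i), rep("rubp_regeneration", j - i), rep("tpu", n - j))
  }
  fit_one <- function(labels, start_free) {
    resid_fn <- function(theta) {
      par <- full0
      par[free] <- exp(theta)
      pred <- tryCatch(partition_predict(Ci, labels, par, Km),
                       error = function(e) NULL)
      if (is.null(pred) || any(!is.finite(pred))) {
        return(rep(1e3, n))
      }
      An - pred
    }
    ft <- tryCatch(
      minpack.lm::nls.lm(
        par = log(start_free), fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                             ptol = 1e-13)
      ),
      error = function(e) NULL
    )
    if (is.null(ft)) return(NULL)
    par <- full0
    par[free] <- exp(coef(ft))
    # Score the candidate against the actual minimum-rule model, not the
    # partitioned prediction: a partition whose labels disagree with the
    # states its own parameters imply cannot win on an artefact of the
    # relaxation.
    params <- tryCatch(
      fvcb_params(Vcmax = par[["Vcmax"]], Jmax = par[["Jmax"]],
                  TPU = par[["TPU"]], Rd = par[["Rd"]], gm = par[["gm"]],
                  Gammastar = par[["Gammastar"]]),
      error = function(e) NULL)
    if (is.null(params)) return(NULL)
    op <- tryCatch(solve_operating_point(Ci, params, k),
                   error = function(e) NULL)
    if (is.null(op)) return(NULL)
    sse <- sum((An - op$An)^2)
    if (!is.finite(sse)) return(NULL)
    list(par = par, sse = sse, pred = op$An)
  }

  # Exhaustive ordered-partition search: Rubisco block of >= 2 points, then a
  # RuBP block of >= 1, then an optional TPU block.
  partitions <- list()
  for (i in 2:(n - 1)) {
    for (j in (i + 1):n) {
      partitions[[length(partitions) + 1]] <- c(i, j)
    }
  }
  start_free <- full0[free]
  best <- NULL
  best_part <- NULL
  for (pp in partitions) {
    labels <- labels_for(pp[1], pp[2])
    res <- fit_one(labels, start_free)
    if (is.null(res)) next
    if (is.null(best) || res$sse < best$sse - 1e-12 ||
        (abs(res$sse - best$sse) <= 1e-12 && res$par[["gm"]] < best$par[["gm"]])) {
      best <- res
      best_part <- pp
    }
  }
  if (is.null(best)) {
    stop("fit failure: no partition produced a converged fit")
  }

  # Multistart refinement of the winning partition against the Vcmax/gm ridge.
  labels <- labels_for(best_part[1], best_part[2])
  jitters <- with_seed(seed, {
    lapply(seq_len(max(n_starts - 1, 0)), function(i) {
      exp(rnorm(length(free), sd = 0.3))
    })
  })
  for (jt in jitters) {
    res <- fit_one(labels, setNames(start_free * jt, free))
    if (is.null(res)) next
    if (res$sse < best$sse - 1e-12 ||
        (abs(res$sse - best$sse) <= 1e-12 && res$par[["gm"]] < best$par[["gm"]])) {
      best <- res
    }
  }

  par <- best$par
  params <- fvcb_params(Vcmax = par[["Vcmax"]], Jmax = par[["Jmax"]],
                        TPU = par[["TPU"]], Rd = par[["Rd"]],
                        gm = par[["gm"]], Gammastar = par[["Gammastar"]])

  # Report the limitation states the fitted parameters imply under the
  # minimum rule, with an epsilon margin so that a later state claims a point
  # only when its branch is strictly lowest: a plateau that merely touches the
  # top point does not count as an observed TPU state.
  eps <- 1e-6
  an_c <- branch_operating_point(Ci, par[["Vcmax"]], 1, Km, par[["Rd"]],
                                 par[["Gammastar"]], par[["gm"]])$An
  an_j <- branch_operating_point(Ci, par[["Jmax"]], 4, 8 * par[["Gammastar"]],
                                 par[["Rd"]], par[["Gammastar"]],
                                 par[["gm"]])$An
  an_p <- rep(3 * par[["TPU"]] - par[["Rd"]], n)
  implied <- ifelse(an_c <= pmin(an_j, an_p) + eps, "rubisco",
                    ifelse(an_j <= an_p + eps, "rubp_regeneration", "tpu"))

  structure(
    list(
      params = params,
      assignment = list(labels = implied,
                        boundaries = best_part,
                        sse = best$sse),
      diagnostics = list(sse = best$sse,
                         residuals = An - best$pred,
                         fitted = best$pred,
                         Ci = Ci,
                         order = ord,
                         gm_aci = par[["gm"]],
                         fixed = fixed)
    ),
    class = "aci_fit"
  )
}

#' @export
print.aci_fit <- function(x, ...) {
  p <- x$params
  cat("FvCB A-Ci fit\n")
  cat(sprintf("  Vcmax = %.3f  Jmax = %.3f  TPU = %.3f (umol m-2 s-1)\n",
              p$Vcmax, p$Jmax, p$TPU))
  cat(sprintf("  gm = %.4f mol m-2 s-1   Rd = %.3f   Gammastar = %.2f\n",
              p$gm, p$Rd, p$Gammastar))
  cat(sprintf("  SSE = %.4g over %d points; blocks at %s\n",
              x$assignment$sse, length(x$assignment$labels),
              paste(x$assignment$boundaries, collapse = "/")))
  invisible(x)
}

#' CO2-saturated maximum assimilation rate
#'
#' `Amax = 3 TPU - Rd`, the plateau of the TPU-limited state. When the fitted
#' assignment contains no TPU-labelled points the estimate is flagged (the
#' plateau was never observed) and a warning is raised.
#'
#' @param fit An `aci_fit` object, or an [fvcb_params()] object.
#' @param assignment Optional assignment list when `fit` is a parameter set.
#' @return Amax (umol m-2 s-1) with attribute `flagged` (logical).
#' @export
amax <- function(fit, assignment = NULL) {
  if (inherits(fit, "aci_fit")) {
    params <- fit$params
    assignment <- fit$assignment
  } else {
    params <- fit
  }
  value <- assimilation_tpu(params)
  flagged <- FALSE
  if (!is.null(assignment) && !any(assignment$labels == "tpu")) {
    flagged <- TRUE
    warning("TPU plateau not represented in the fitted points; ",
            "Amax is an extrapolation", call. = FALSE)
  }
  structure(value, flagged = flagged)
}

#' Assimilation at a reference ambient CO2
#'
#' Linearly interpolates observed `An` against `Ca` at a reference ambient
#' partial pressure (default 40.4 Pa), converted to mole fraction at a fixed
#' total pressure of 101.325 kPa.
#'
#' @param curve An [aci_curve()] or data frame with `Ca` and `An`.
#' @param ca_ref Reference ambient CO2.
#' @param units Units of `ca_ref`: `"Pa"` (default) or `"umol/mol"`.
#' @param pressure_kPa Total pressure used for the Pa conversion.
#' @return Interpolated `An` (umol m-2 s-1).
#' @export
an_at_reference_ca <- function(curve, ca_ref = 40.4,
                               units = c("Pa", "umol/mol"),
                               pressure_kPa = 101.325) {
  units <- match.arg(units)
  df <- as.data.frame(curve)
  stopifnot(all(c("Ca", "An") %in% names(df)))
  ref <- if (units == "Pa") ca_ref / (pressure_kPa * 1000) * 1e6 else ca_ref
  if (ref < min(df$Ca) || ref > max(df$Ca)) {
    stop(sprintf(
      "reference Ca %.1f umol mol-1 is outside the observed range [%.1f, %.1f]",
      ref, min(df$Ca), max(df$Ca)))
  }
  approx(df$Ca, df$An, xout = ref, ties = mean)$y
}

#' Cuvette leak correction
#'
#' Applies the additive linear-in-gradient correction
#' `An_corr = An + k_leak (Ca - C_ambient)`, with `k_leak` estimated from an
#' empty-chamber calibration curve (see [estimate_leak()]).
#'
#' @param curve An [aci_curve()] or data frame with `Ca` and `An`.
#' @param k_leak Leak coefficient (umol m-2 s-1 per umol mol-1), `>= 0`.
#' @param c_ambient Ambient CO2 outside the chamber (umol mol-1).
#' @return The curve with corrected `An`; order and count preserved.
#' @export
leak_correct <- function(curve, k_leak, c_ambient = 400) {
  stopifnot(is.numeric(k_leak), length(k_leak) == 1, k_leak >= 0)
  df <- curve
  df$An <- df$An + k_leak * (df$Ca - c_ambient)
  df
}

#' Estimate the cuvette leak coefficient
#'
#' Regresses apparent flux in an empty chamber on the CO2 gradient
#' `(Ca - C_ambient)`; the leak coefficient is the negative of the slope
#' (apparent uptake grows with outward gradient), floored at zero.
#'
#' @param Ca Chamber CO2 setpoints (umol mol-1).
#' @param flux Apparent flux measured with no leaf (umol m-2 s-1).
#' @param c_ambient Ambient CO2 (umol mol-1).
#' @return `k_leak` (umol m-2 s-1 per umol mol-1).
#' @export
estimate_leak <- function(Ca, flux, c_ambient = 400) {
  stopifnot(length(Ca) == length(flux), length(Ca) >= 2)
  slope <- coef(lm(flux ~ I(Ca - c_ambient)))[[2]]
  max(-slope, 0)
}
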