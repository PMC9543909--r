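# Study-level statistics: intrinsic water-use efficiency, climate seasonality,
# percent change under dehydration, Bonferroni-controlled correlation
# matrices, and the gas-phase share of mesophyll conductance.

#' Intrinsic water-use efficiency
#'
#' `WUE_i = An / gs` (umol CO2 per mol H2O).
#'
#' @param An Net assimilation (umol m-2 s-1), vectorised.
#' @param gs Stomatal conductance (mol m-2 s-1), `> 0`.
#' @return `WUE_i` (umol mol-1).
#' @export
wue_i <- function(An, gs) {
  if (any(gs <= 0)) stop("gs must be positive")
  An / gs
}

#' Climate seasonality coefficient of variation
#'
#' `100 * SD / mean` of the 12 monthly values (n-1 SD). Temperature is used in
#' degC, matching the FAO-style convention; a near-zero mean makes the CV
#' meaningless and raises an error instead of returning a number.
#'
#' @param monthly Numeric vector of exactly 12 monthly means.
#' @return Seasonality CV (percent).
#' @export
seasonality_cv <- function(monthly) {
  if (length(monthly) != 12) stop("exactly 12 monthly values are required")
  m <- mean(monthly)
  if (abs(m) < 1e-9) stop("undefined CV: the monthly mean is zero")
  100 * sd(monthly) / m
}

#' Percent change under dehydration
#'
#' `100 * (dehydrated - well_watered) / well_watered`, signed.
#'
#' @param dehydrated,well_watered Numeric, vectorised; `well_watered != 0`.
#' @return Percent change.
#' @export
percent_change <- function(dehydrated, well_watered) {
  if (any(well_watered == 0)) stop("well-watered reference must be nonzero")
  100 * (dehydrated - well_watered) / well_watered
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise level in `(0, 1)`.
#' @param m Number of comparisons, `>= 1`.
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_alpha(0.05, 25)  # 0.002
bonferroni_alpha <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Gas-phase contribution to mesophyll conductance
#'
#' With the airspace and liquid-phase conductances in series, the share of the
#' total mesophyll resistance residing in the gas phase is
#' `100 * (1/g_IAS) / (1/gm) = 100 * gm / g_IAS` percent.
#'
#' @param g_ias Intercellular airspace conductance (mol m-2 s-1 bar-1).
#' @param gm Total mesophyll conductance (mol m-2 s-1), `0 < gm <= g_IAS`.
#' @return Contribution in percent, in `(0, 100]`.
#' @export
gias_contribution <- function(g_ias, gm) {
  if (any(gm <= 0)) stop("gm must be positive")
  if (any(gm > g_ias)) {
    stop("inconsistent conductances: gm exceeds g_IAS (series resistances)")
  }
  100 * gm / g_ias
}

apply_transform <- function(x, how) {
  switch(how,
         identity = x,
         log = {
           if (any(x <= 0)) stop("log transform requires positive values")
           log(x)
         },
         square = x^2,
         stop("unknown transform: ", how))
}

#' Pairwise Pearson correlation matrix
#'
#' Pearson correlation, R-squared and the two-sided p-value (t distribution,
#' n-2 df) for every pair of one variable from `vars_x` and one from `vars_y`
#' over the rows of `data` (typically accession means). Optional per-variable
#' log or square transforms are applied first.
#'
#' @param data A data frame holding all variables (one row per unit).
#' @param vars_x,vars_y Character vectors of column names.
#' @param transforms Optional named list mapping variable names to
#'   `"log"` or `"square"`.
#' @return A data frame with columns `x`, `y`, `r`, `r_squared`, `p`, `n`,
#'   `flag` (`"ok"`, `"zero_variance"` or `"insufficient_n"`).
#' @export
correlation_matrix <- function(data, vars_x, vars_y, transforms = NULL) {
  stopifnot(all(c(vars_x, vars_y) %in% names(data)))
  out <- list()
  for (vx in vars_x) {
    for (vy in vars_y) {
      x <- data[[vx]]
      y <- data[[vy]]
      if (!is.null(transforms)) {
        if (!is.null(transforms[[vx]])) x <- apply_transform(x, transforms[[vx]])
        if (!is.null(transforms[[vy]])) y <- apply_transform(y, transforms[[vy]])
      }
      cc <- complete.cases(x, y)
      x <- x[cc]; y <- y[cc]
      n <- length(x)
      row <- data.frame(x = vx, y = vy, r = NA_real_, r_squared = NA_real_,
                        p = NA_real_, n = n, flag = "ok",
                        stringsAsFactors = FALSE)
      if (n < 3) {
        row$flag <- "insufficient_n"
      } else if (var(x) == 0 || var(y) == 0) {
        row$flag <- "zero_variance"
      } else {
        ct <- cor.test(x, y, method = "pearson")
        row$r <- unname(ct$estimate)
        row$r_squared <- row$r^2
        row$p <- ct$p.value
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}

#' Dehydration response comparison across accessions
#'
#' For every accession and variable, computes the replicate-level percent
#' change under dehydration relative to the well-watered arm (replicates
#' paired by `replicate`), its mean and standard error, and tests every pair
#' of accessions for a different mean percent change with Welch two-sample
#' t-tests at the (Bonferroni-adjusted) threshold `alpha_adjusted`. The output
#' lists, per accession, the accessions it differs from — the layout of a
#' treatment-response table.
#'
#' @param traits Long data frame with columns `accession_id`, `treatment`
#'   (`"well_watered"` / `"dehydrated"`), `replicate`, and the variables.
#' @param variables Character vector of trait columns to compare.
#' @param alpha_adjusted Significance threshold for the pairwise tests.
#' @return A data frame with columns `accession_id`, `variable`, `mean_pct`,
#'   `se_pct`, `n`, `differs_from` (comma-separated accession ids, `""` when
#'   none, `NA` with a single replicate where the SE is undefined).
#' @export
dehydration_comparison <- function(traits, variables, alpha_adjusted = 0.002) {
  stopifnot(all(c("accession_id", "treatment", "replicate") %in% names(traits)),
            all(variables %in% names(traits)))
  accs <- sort(unique(traits$accession_id))
  out <- list()
  for (var in variables) {
    pct <- list()
    for (acc in accs) {
      ww <- traits[traits$accession_id == acc &
                     traits$treatment == "well_watered", ]
      dh <- traits[traits$accession_id == acc &
                     traits$treatment == "dehydrated", ]
      if (nrow(ww) == 0 || nrow(dh) == 0) {
        warning("accession ", acc, " lacks a treatment arm; excluded",
                call. = FALSE)
        next
      }
      mg <- merge(ww[, c("replicate", var)], dh[, c("replicate", var)],
                  by = "replicate", suffixes = c("_ww", "_dh"))
      pct[[acc]] <- percent_change(mg[[paste0(var, "_dh")]],
                                   mg[[paste0(var, "_ww")]])
    }
    used <- names(pct)
    for (acc in used) {
      v <- pct[[acc]]
      diffs <- character(0)
      if (length(v) >= 2 && sd(v) >= 0) {
        for (other in setdiff(used, acc)) {
          w <- pct[[other]]
          if (length(w) < 2) next
          if (sd(v) == 0 && sd(w) == 0) {
            different <- mean(v) != mean(w)
          } else {
            different <- t.test(v, w)$p.value < alpha_adjusted
          }
          if (different) diffs <- c(diffs, other)
        }
      }
      out[[length(out) + 1]] <- data.frame(
        accession_id = acc, variable = var,
        mean_pct = mean(v),
        se_pct = if (length(v) >= 2) sd(v) / sqrt(length(v)) else NA_real_,
        n = length(v),
        differs_from = if (length(v) >= 2) paste(diffs, collapse = ",")
                       else NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
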