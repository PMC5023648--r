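#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2 K n / (n - K - 1)`, where `K` counts every estimated
#' parameter including the error variance.
#'
#' @param loglik Maximized log-likelihood.
#' @param n Number of observations.
#' @param K Number of estimated parameters.
#' @return The AICc value.
#' @examples
#' aicc(0, 10, 1)    # 2.5
#' @export
aicc <- function(loglik, n, K) {
  check_number(loglik, "loglik")
  if (n <= K + 1) {
    stop_invalid("AICc undefined: need n > K + 1 (n = %d, K = %d)", n, K)
  }
  -2 * loglik + 2 * K * n / (n - K - 1)
}

#' Fit one version of the species--area relationship
#'
#' Ordinary least squares on one of three transforms of richness `S` against
#' band area `A`: untransformed (`S ~ A`), semi-log (`S ~ log A`) and
#' log--log (`log S ~ log A`, the power law `S = c A^z` whose slope is the
#' exponent `z`). Bands with zero richness cannot enter the log--log fit;
#' for comparability the same positive-richness, positive-area subset is used
#' for all three versions, and the number excluded is recorded. Natural
#' logarithms throughout. The Gaussian log-likelihood is evaluated at the ML
#' residual variance and AICc uses K = 3 (slope, intercept, variance).
#'
#' @param richness Per-band richness counts.
#' @param area Per-band areas (km^2).
#' @param version One of `"untransformed"`, `"semilog"`, `"loglog"`.
#' @return An object of class `species_area_fit` with elements `version`,
#'   `slope`, `slope_se`, `intercept`, `adj_r2`, `p_value`, `loglik`, `aicc`,
#'   `delta_aicc` (NA until [select_best_version()]), `n_used`, `n_dropped`.
#'   With fewer than 5 usable bands the AICc penalty is undefined and `aicc`
#'   is `NA`; such fits cannot enter version selection.
#' @export
fit_species_area <- function(richness, area,
                             version = c("untransformed", "semilog", "loglog")) {
  version <- match.arg(version)
  if (length(richness) != length(area)) {
    stop_invalid("richness and area must have equal length")
  }
  use <- is.finite(richness) & is.finite(area) & richness > 0 & area > 0
  if (!any(richness > 0, na.rm = TRUE)) stop_invalid("all-zero richness")
  n <- sum(use)
  if (n < 3) stop_invalid("need at least 3 usable bands, got %d", n)
  y <- switch(version,
              untransformed = richness[use],
              semilog = richness[use],
              loglog = log(richness[use]))
  x <- switch(version,
              untransformed = area[use],
              semilog = log(area[use]),
              loglog = log(area[use]))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ll <- as.numeric(stats::logLik(fit))
  p <- if (is.null(sm$fstatistic)) NA_real_ else {
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  }
  structure(
    list(version = version,
         slope = unname(stats::coef(fit)[2]),
         slope_se = unname(sm$coefficients[2, 2]),
         intercept = unname(stats::coef(fit)[1]),
         adj_r2 = sm$adj.r.squared,
         p_value = p,
         loglik = ll,
         aicc = if (n > 4) aicc(ll, n, 3L) else NA_real_,
         delta_aicc = NA_real_,
         n_used = n,
         n_dropped = sum(!use)),
    class = "species_area_fit"
  )
}

#' @export
print.species_area_fit <- function(x, ...) {
  lab <- if (x$version == "loglog") "z (power-law exponent)" else "slope"
  cat(sprintf("<species_area_fit> %s: %s = %.4f, intercept = %.4f\n",
              x$version, lab, x$slope, x$intercept))
  cat(sprintf("  adj R2 = %.4f, p = %.3g, AICc = %.2f%s, n = %d (%d dropped)\n",
              x$adj_r2, x$p_value, x$aicc,
              if (is.na(x$delta_aicc)) "" else sprintf(" (dAICc = %.2f)", x$delta_aicc),
              x$n_used, x$n_dropped))
  invisible(x)
}

#' @export
coef.species_area_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Select the best species--area version by AICc
#'
#' The minimum-AICc fit wins; any rival within 2 AICc units is flagged as
#' co-best (statistically indistinguishable support). All fits must use the
#' same band subset, otherwise their likelihoods are not comparable.
#'
#' @param fits A list of `species_area_fit` objects (typically the three
#'   versions).
#' @return The winning fit, with `delta_aicc` set to 0, a `co_best` character
#'   vector of rival versions with delta < 2, and an `all_fits` list whose
#'   elements carry their own `delta_aicc`.
#' @export
select_best_version <- function(fits) {
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, TRUE, "species_area_fit")))
  n_used <- vapply(fits, `[[`, 1L, "n_used")
  if (length(unique(n_used)) != 1L) {
    stop_invalid("fits use different band subsets (n_used = %s); AICc not comparable",
                 paste(n_used, collapse = ", "))
  }
  aiccs <- vapply(fits, `[[`, 1, "aicc")
  if (anyNA(aiccs)) {
    stop_invalid("AICc is undefined at n_used = %d (need n > K + 1 = 4)",
                 fits[[1]]$n_used)
  }
  deltas <- aiccs - min(aiccs)
  for (i in seq_along(fits)) fits[[i]]$delta_aicc <- deltas[i]
  best <- fits[[which.min(aiccs)]]
  rivals <- which(deltas < 2 & seq_along(fits) != which.min(aiccs))
  best$co_best <- vapply(fits[rivals], `[[`, "", "version")
  best$all_fits <- fits
  best
}

#' Method-1 area correction of richness
#'
#' Rescaled power-law correction `TRcor1 = 100 * TRobs / A^z`, with `z` the
#' fitted log--log species--area exponent. Bands with zero observed richness
#' get a corrected value of zero. Because the scale of the correction depends
#' on the area unit through the constant `c`, the unit is stamped into the
#' result.
#'
#' @param richness Per-band observed richness.
#' @param area Per-band areas (km^2).
#' @param z Power-law exponent.
#' @return A data frame with columns `trcor1`, `z_used`, `area_used`, plus an
#'   `area_unit` attribute.
#' @export
correct_method1 <- function(richness, area, z) {
  check_number(z, "z")
  if (length(richness) != length(area)) {
    stop_invalid("richness and area must have equal length")
  }
  if (any(richness > 0 & !(area > 0))) {
    stop_invalid("non-positive area in a band with positive richness")
  }
  trcor1 <- ifelse(richness > 0, 100 * richness / area^z, 0)
  structure(
    data.frame(trcor1 = trcor1, z_used = z, area_used = area),
    area_unit = "km2"
  )
}
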