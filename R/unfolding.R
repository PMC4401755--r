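#' Cosmic-ray continuum template
#'
#' No terrestrial gamma line exceeds 2.615 MeV, so bin 22 (3.0--3.2 MeV)
#' contains only the cosmic-ray secondary continuum. The template is flat in
#' pulse-height energy above 0.5 MeV with fixed shape, normalised so its bin
#' 22 content is 1; scaling it to the measured bin-22 counts gives the
#' cosmic contribution across all bins.
#'
#' @param bins Energy-bin scheme.
#' @return Length-22 numeric vector with bin 22 equal to 1.
#' @export
cosmic_template <- function(bins = energy_bins()) {
  ov <- pmax(0, pmin(bins$upper, 3.2) - pmax(bins$lower, 0.5))
  ov / ov[22]
}

#' Subtract the cosmic-ray contribution using bin 22
#'
#' The template is scaled so its bin-22 content equals the measured bin-22
#' counts and subtracted from all bins; bin 22 is exactly zero afterwards.
#' Negative results are clipped to zero and flagged. If the measured bin 22
#' is zero the spectrum is returned unchanged.
#'
#' @param spectrum A `bin_spectrum`.
#' @param template Cosmic shape from [cosmic_template()] (bin-22 content must
#'   be nonzero).
#' @return The corrected `bin_spectrum`, flag `"cosmic_subtracted"` added.
#' @export
subtract_cosmic <- function(spectrum, template = cosmic_template(spectrum$bins)) {
  stopifnot(inherits(spectrum, "bin_spectrum"))
  if (template[22] == 0) abort("cosmic template has zero bin-22 content")
  c22 <- spectrum$counts[22]
  if (c22 == 0) return(spectrum)
  shape <- template / template[22]
  corrected <- spectrum$counts - c22 * shape
  if (any(corrected < -1e-9)) spectrum$flags <- union(spectrum$flags, "negative_clipped")
  spectrum$var <- spectrum$var + shape^2 * spectrum$var[22]
  spectrum$counts <- pmax(0, corrected)
  spectrum$counts[22] <- 0
  spectrum$flags <- union(spectrum$flags, "cosmic_subtracted")
  spectrum
}

#' Subtract the photomultiplier 40K instrument background
#'
#' The potassium in photomultiplier-tube glass adds a fixed-rate pure-40K
#' component to every spectrum. Given the instrument background expressed as
#' count rates per bin (same bin scheme), its live-time-scaled counts are
#' subtracted elementwise; negatives are clipped and flagged.
#'
#' @param spectrum A `bin_spectrum`.
#' @param background_rate Length-22 vector of background count rates (cps).
#' @return The corrected `bin_spectrum`, flag `"pmt_subtracted"` added.
#' @export
subtract_pmt_background <- function(spectrum, background_rate) {
  stopifnot(inherits(spectrum, "bin_spectrum"), length(background_rate) == 22)
  corrected <- spectrum$counts - background_rate * spectrum$live_time
  if (any(corrected < -1e-9)) spectrum$flags <- union(spectrum$flags, "negative_clipped")
  spectrum$counts <- pmax(0, corrected)
  spectrum$flags <- union(spectrum$flags, "pmt_subtracted")
  spectrum
}

#' Unfold a binned count spectrum into incident flux
#'
#' Solves response x flux = count rate with a nonnegativity constraint
#' (non-negative least squares). Statistical errors are propagated linearly
#' from the Poisson variances of the raw bin counts through the
#' unconstrained inverse of the response matrix, which also supplies the
#' full flux covariance used downstream.
#'
#' @param spectrum A `bin_spectrum`, cosmic- and PMT-subtracted.
#' @param response A `response_matrix`.
#' @return Object of class `energy_spectrum`: `flux` (cm^-2 s^-1 per bin),
#'   `se`, `cov`, `residual_norm`, `condition`, `flags`.
#' @export
unfold <- function(spectrum, response) {
  stopifnot(inherits(spectrum, "bin_spectrum"),
            inherits(response, "response_matrix"))
  assert_same_bins(spectrum, response)
  m <- unclass(response)
  kappa <- response_condition(response)
  if (!is.finite(kappa) || kappa > 1e8) {
    abort(sprintf("response matrix ill-conditioned (condition estimate %.3g)", kappa))
  }
  rate <- spectrum$counts / spectrum$live_time
  ri <- solve(m)
  flux <- as.numeric(ri %*% rate)
  flags <- spectrum$flags
  if (min(flux) < -1e-9 * max(abs(flux), 1e-300)) {
    # active constraints: fall back to the non-negative least-squares solve
    sol <- tryCatch(pracma::lsqnonneg(m, rate), error = function(e) NULL)
    if (is.null(sol)) {
      flags <- union(flags, "nnls_fallback_clip")
      flux <- pmax(0, flux)
    } else flux <- sol$x
  } else flux <- pmax(0, flux)
  covm <- ri %*% diag(spectrum$var / spectrum$live_time^2) %*% t(ri)
  resid <- sqrt(sum((as.numeric(m %*% flux) - rate)^2))
  structure(list(flux = flux, se = sqrt(pmax(0, diag(covm))), cov = covm,
                 residual_norm = resid,
                 condition = kappa, bins = spectrum$bins,
                 edges = spectrum$edges, live_time = spectrum$live_time,
                 flags = flags),
            class = "energy_spectrum")
}

#' @export
tidy.energy_spectrum <- function(x, ...) {
  tibble(bin = 1:22, energy = x$bins$center, flux = x$flux, se = x$se)
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf("<energy_spectrum> integral flux %.3g cm^-2 s^-1, kerma %.1f nGy/h (condition %.1f)\n",
              sum(x$flux), kerma_from_flux(pmax(0, x$flux), x$bins), x$condition))
  invisible(x)
}

# key-bin groups of the 3x3 interference system
.GROUPS <- list(g14 = 14L, g16_18 = c(16L, 18L), g20 = 20L)

#' The 3 x 3 interference matrix of the key-bin groups
#'
#' Expected flux content of the three key-bin groups — {14} (40K 1.464 MeV),
#' {16, 18} (214Bi 1.765 + 2.205 MeV, pooled), {20} (208Tl 2.615 MeV) — per
#' unit activity concentration of each nuclide, taken from the unit flux
#' library. Nearly triangular: nothing terrestrial lies above the 208Tl bin,
#' and 40K contributes to its own bin only.
#'
#' @param library A `unit_flux_library`.
#' @return 3 x 3 matrix, rows = groups, columns = K40 / U238_series /
#'   Th232_series.
#' @export
interference_matrix <- function(library) {
  m <- vapply(.NUCLIDES, function(n) {
    vapply(.GROUPS, function(g) sum(library$flux[g, n]), numeric(1))
  }, numeric(3))
  dimnames(m) <- list(names(.GROUPS), .NUCLIDES)
  m
}

#' Estimate activity concentrations by successive approximation
#'
#' Fixed-point iteration on the three key-bin groups, in the order
#' Th -> U -> K exploiting the near-triangular interference: the
#' 232Th-series activity is set from the group-20 content; its library
#' contribution is stripped from groups {16+18} and {14}; the 238U-series
#' activity follows from the {16+18} residual, its contribution is stripped
#' from {14}; 40K from the final {14} residual. Iterated until every
#' activity changes by less than `tol` (relative) or 50 iterations.
#' Negative residual groups floor the activity at 0 with a flag.
#'
#' Air kerma components are activity x per-nuclide kerma coefficient;
#' statistical errors propagate the flux covariance through the linear
#' solve and are reported as percentages.
#'
#' @param spectrum An `energy_spectrum` from [unfold()].
#' @param library A `unit_flux_library`.
#' @param tol Relative convergence tolerance (default 1e-3, i.e. 0.1%).
#' @param surface,lat,lon Optional metadata carried into the result.
#' @return Object of class `activity_estimate` with fields `activity`,
#'   `activity_se`, `activity_pct_err` (per nuclide), `kerma` (per-nuclide
#'   nGy/h), `kerma_total` (with standard errors `kerma_se`,
#'   `kerma_total_se`), `contribution_pct` (integer percentages),
#'   `iterations`, `flags`. Use [tidy()] for the Table-1-style row.
#' @export
estimate_activities <- function(spectrum, library, tol = 1e-3,
                                surface = NA_character_,
                                lat = NA_real_, lon = NA_real_) {
  stopifnot(inherits(spectrum, "energy_spectrum"),
            inherits(library, "unit_flux_library"))
  if (any(spectrum$flux < 0)) abort("flux must be nonnegative")
  m3 <- interference_matrix(library)
  g_obs <- vapply(.GROUPS, function(g) sum(spectrum$flux[g]), numeric(1))

  a <- c(K40 = 0, U238_series = 0, Th232_series = 0)
  flags <- spectrum$flags
  converged <- FALSE
  for (it in 1:50) {
    a_old <- a
    r_th <- g_obs["g20"] - m3["g20", "K40"] * a["K40"] -
      m3["g20", "U238_series"] * a["U238_series"]
    a["Th232_series"] <- r_th / m3["g20", "Th232_series"]
    if (a["Th232_series"] < 0) { a["Th232_series"] <- 0; flags <- union(flags, "floored_Th232_series") }
    r_u <- g_obs["g16_18"] - m3["g16_18", "Th232_series"] * a["Th232_series"] -
      m3["g16_18", "K40"] * a["K40"]
    a["U238_series"] <- r_u / m3["g16_18", "U238_series"]
    if (a["U238_series"] < 0) { a["U238_series"] <- 0; flags <- union(flags, "floored_U238_series") }
    r_k <- g_obs["g14"] - m3["g14", "Th232_series"] * a["Th232_series"] -
      m3["g14", "U238_series"] * a["U238_series"]
    a["K40"] <- r_k / m3["g14", "K40"]
    if (a["K40"] < 0) { a["K40"] <- 0; flags <- union(flags, "floored_K40") }
    if (all(abs(a - a_old) <= tol * pmax(abs(a), 1e-12))) { converged <- TRUE; break }
  }
  if (!converged) {
    abort(paste0("successive approximation did not converge in 50 iterations; last activities: ",
                 paste(sprintf("%s=%.4g", names(a), a), collapse = ", ")))
  }

  # linear error propagation: group covariance from the flux covariance,
  # through the 3x3 solve (exact for the unfloored linear fixed point)
  agg <- matrix(0, 3, 22)
  for (i in seq_along(.GROUPS)) agg[i, .GROUPS[[i]]] <- 1
  cov_g <- agg %*% spectrum$cov %*% t(agg)
  m3i <- solve(m3)
  cov_a <- m3i %*% cov_g %*% t(m3i)
  a_se <- sqrt(pmax(0, diag(cov_a)))
  names(a_se) <- .NUCLIDES
  pct_err <- ifelse(a > 0, 100 * a_se / a, NA_real_)

  kerma <- a * library$kerma_coeff
  ktot <- sum(kerma)
  kerma_se <- a_se * library$kerma_coeff
  ktot_se <- sqrt(drop(t(library$kerma_coeff) %*% cov_a %*% library$kerma_coeff))
  contrib <- if (ktot > 0) round(100 * kerma / ktot) else kerma * NA_real_

  structure(list(activity = a, activity_se = a_se, activity_pct_err = pct_err,
                 kerma = kerma, kerma_se = kerma_se,
                 kerma_total = ktot, kerma_total_se = ktot_se,
                 contribution_pct = contrib, iterations = it,
                 surface = surface, lat = lat, lon = lon, flags = flags),
            class = "activity_estimate")
}

#' @export
print.activity_estimate <- function(x, ...) {
  cat(sprintf("<activity_estimate> K40 %.0f, U238 %.0f, Th232 %.0f Bq/kg; kerma %.0f nGy/h (%d/%d/%d %%)\n",
              x$activity[1], x$activity[2], x$activity[3], x$kerma_total,
              x$contribution_pct[1], x$contribution_pct[2], x$contribution_pct[3]))
  invisible(x)
}

#' @export
tidy.activity_estimate <- function(x, ...) {
  tibble(lat = x$lat, lon = x$lon,
         kerma_k40 = x$kerma[["K40"]], kerma_u238 = x$kerma[["U238_series"]],
         kerma_th232 = x$kerma[["Th232_series"]], kerma_total = x$kerma_total,
         pct_k40 = x$contribution_pct[["K40"]],
         pct_u238 = x$contribution_pct[["U238_series"]],
         pct_th232 = x$contribution_pct[["Th232_series"]],
         act_k40 = x$activity[["K40"]], act_k40_se = x$activity_se[["K40"]],
         act_u238 = x$activity[["U238_series"]], act_u238_se = x$activity_se[["U238_series"]],
         act_th232 = x$activity[["Th232_series"]], act_th232_se = x$activity_se[["Th232_series"]],
         surface = x$surface)
}

#' Total air kerma rate of an activity estimate
#'
#' Sum of the three per-nuclide kerma components.
#'
#' @param x An `activity_estimate`, or a numeric vector of per-nuclide kerma
#'   components (nGy/h).
#' @return Total air kerma rate in nGy/h.
#' @examples
#' kerma_total(c(40, 558, 1543))
#' @export
kerma_total <- function(x) {
  if (inherits(x, "activity_estimate")) return(sum(x$kerma))
  sum(as.numeric(x))
}
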