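#' Ground source model
#'
#' Homogeneous semi-infinite volume source: radionuclides mixed uniformly in
#' soil of fixed density, detector at fixed height in air. These are the
#' standard assumptions for converting terrestrial gamma flux to activity
#' concentration.
#'
#' @param density_g_cm3 Dry soil bulk density (g/cm^3).
#' @param height_cm Receptor height above the interface (cm).
#' @return Object of class `soil_model`.
#' @export
soil_model <- function(density_g_cm3 = 1.6, height_cm = 100) {
  stopifnot(density_g_cm3 > 0, height_cm >= 0)
  structure(list(density = density_g_cm3, height = height_cm),
            class = "soil_model")
}

#' Unit-activity flux library by 1-D Monte Carlo transport
#'
#' For each nuclide (40K, 238U-series, 232Th-series) the gamma-ray flux
#' density at the receptor height per unit activity concentration
#' (cm^-2 s^-1 per Bq/kg) is computed over the 22 energy bins, split into a
#' primary (uncollided) and a scattered component, together with the
#' per-nuclide air-kerma-rate coefficient (nGy/h per Bq/kg).
#'
#' Primary flux: each history samples an emission depth (exponential in soil
#' optical depth) and an upward direction cosine, and scores the attenuated
#' per-line flux estimator; histories are allocated to lines in proportion to
#' emission intensity. Scattered flux: a build-up treatment anchored to the
#' infinite-medium energy balance — at the air-soil interface the total air
#' kerma approaches half the equilibrium kerma of an infinite source medium,
#' so each line's scattered kerma is the analytic difference between that
#' limit and its primary kerma, scaled onto the Monte Carlo primary estimate
#' and distributed in energy below the line (flat in kerma per unit energy
#' down to 0.05 MeV, the down-scatter continuum).
#'
#' @param bins Energy-bin scheme.
#' @param lines Line library from [nuclide_lines()].
#' @param soil A [soil_model()].
#' @param histories Monte Carlo histories per nuclide.
#' @param seed Integer seed; the library is reproducible under it.
#' @return Object of class `unit_flux_library`: list with `flux`, `primary`,
#'   `scattered` (22 x 3 matrices, columns K40 / U238_series / Th232_series),
#'   `flux_se` (Monte Carlo standard errors of the primary component),
#'   `kerma_coeff` (named length-3 vector, nGy/h per Bq/kg), `bins`,
#'   `histories`, `seed`.
#' @examples
#' lib <- build_unit_flux_library(histories = 2e4, seed = 1)
#' lib$kerma_coeff
#' @export
build_unit_flux_library <- function(bins = energy_bins(),
                                    lines = nuclide_lines(),
                                    soil = soil_model(),
                                    histories = 1e6,
                                    seed = 1L) {
  if (nrow(lines) == 0) abort("empty line library")
  stopifnot(histories >= 1000)
  rho <- soil$density
  h <- soil$height

  primary <- scattered <- se2 <- matrix(0, 22, 3,
                                        dimnames = list(NULL, .NUCLIDES))
  with_local_seed(seed, {
    for (n in seq_along(.NUCLIDES)) {
      nl <- lines[lines$nuclide == .NUCLIDES[n], ]
      nhist <- pmax(100L, round(histories * nl$intensity / sum(nl$intensity)))
      for (l in seq_len(nrow(nl))) {
        e <- nl$energy[l]; p <- nl$intensity[l]
        mus <- mu_soil(e) * rho          # 1/cm in soil
        mua <- mu_air(e) * .AIR_DENSITY  # 1/cm in air
        s_v <- p * rho * 1e-3            # photons cm^-3 s^-1 per Bq/kg
        nh <- nhist[l]
        z <- rexp(nh, rate = mus)
        u <- runif(nh)
        w <- (s_v / (2 * mus)) * (1 / u) * exp(mus * z * (1 - 1 / u) - mua * h / u)
        phi_p <- mean(w)
        b <- bin_of_energy(e, bins)
        primary[b, n] <- primary[b, n] + phi_p
        se2[b, n] <- se2[b, n] + stats::var(w) / nh

        # scattered: interface kerma = half the infinite-medium kerma;
        # ratio total/primary kerma reduces to (mu/rho)_soil / (muen/rho)_air
        ratio <- mu_soil(e) / muen_air(e)
        k_p <- phi_p * e * muen_air(e) * .KERMA_PER_FLUX
        k_s <- max(0, k_p * (ratio - 1))
        if (e > 0.05 && k_s > 0) {
          frac <- interval_bin_overlap(0.05, e, bins)
          ks_b <- k_s * frac
          scattered[, n] <- scattered[, n] +
            ks_b / (bins$center * muen_air(bins$center) * .KERMA_PER_FLUX)
        }
      }
    }
  })

  flux <- primary + scattered
  kc <- vapply(1:3, function(n) {
    sum(flux[, n] * bins$center * muen_air(bins$center)) * .KERMA_PER_FLUX
  }, numeric(1))
  names(kc) <- .NUCLIDES

  structure(list(flux = flux, primary = primary, scattered = scattered,
                 flux_se = sqrt(se2), kerma_coeff = kc, bins = bins,
                 soil = soil, histories = histories, seed = seed,
                 edges = bin_edges(bins)),
            class = "unit_flux_library")
}

#' @export
tidy.unit_flux_library <- function(x, ...) {
  purrr::map_dfr(.NUCLIDES, function(n) {
    tibble(nuclide = n, bin = 1:22, energy = x$bins$center,
           primary = x$primary[, n], scattered = x$scattered[, n],
           flux = x$flux[, n])
  })
}

#' Air kerma rate from a binned flux spectrum
#'
#' Folds per-bin flux densities with the bin-centre photon energy and the
#' mass energy-absorption coefficient of air: sum over bins of
#' flux x E x muen/rho, expressed in nGy/h. Linear in the flux.
#'
#' @param flux Length-22 nonnegative vector of flux densities
#'   (cm^-2 s^-1 per bin), or an `energy_spectrum` from [unfold()].
#' @param bins Energy-bin scheme.
#' @return Air kerma rate in nGy/h.
#' @examples
#' kerma_from_flux(rep(0, 22))
#' @export
kerma_from_flux <- function(flux, bins = energy_bins()) {
  if (inherits(flux, "energy_spectrum")) flux <- flux$flux
  stopifnot(length(flux) == 22)
  if (any(flux < 0)) abort("negative flux bin; clip upstream before kerma folding")
  sum(flux * bins$center * muen_air(bins$center)) * .KERMA_PER_FLUX
}
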