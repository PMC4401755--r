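#' Gamma-line library for the terrestrial natural radionuclides
#'
#' Principal gamma lines and emission probabilities per parent decay for 40K
#' and for the 238U and 232Th decay series under secular equilibrium (the
#' unfolding treats each series as one unit, so every daughter line is
#' expressed per decay of the series parent; 208Tl lines carry the 35.94%
#' branching of the 232Th series at 212Bi). Energies in MeV; the values are
#' the standard tabulated natural-background line lists used in environmental
#' spectrometry (Beck-style compilations).
#'
#' @return Object of class `nuclide_lines`: tibble with columns `nuclide`
#'   (`"K40"`, `"U238_series"`, `"Th232_series"`), `energy` (MeV),
#'   `intensity` (photons per parent decay), `emitter` (daughter nuclide).
#' @examples
#' nuclide_lines() |> dplyr::count(nuclide, wt = energy * intensity)
#' @export
nuclide_lines <- function() {
  k40 <- tibble(nuclide = "K40", energy = 1.464, intensity = 0.1067,
                emitter = "K-40")

  u <- tibble(
    nuclide = "U238_series",
    energy = c(0.186, 0.242, 0.295, 0.352, 0.609, 0.665, 0.768, 0.806,
               0.934, 1.120, 1.155, 1.238, 1.281, 1.378, 1.401, 1.408,
               1.509, 1.661, 1.730, 1.765, 1.847, 2.119, 2.204, 2.448),
    intensity = c(0.0355, 0.0729, 0.1840, 0.3560, 0.4549, 0.0146, 0.0485,
                  0.0122, 0.0303, 0.1491, 0.0163, 0.0579, 0.0143, 0.0392,
                  0.0139, 0.0243, 0.0212, 0.0112, 0.0292, 0.1531, 0.0203,
                  0.0117, 0.0489, 0.0155),
    emitter = c("Ra-226", rep("Pb-214", 3), rep("Bi-214", 20))
  )

  th <- tibble(
    nuclide = "Th232_series",
    energy = c(0.129, 0.209, 0.239, 0.241, 0.270, 0.277, 0.300, 0.328,
               0.338, 0.409, 0.463, 0.511, 0.583, 0.727, 0.755, 0.772,
               0.795, 0.835, 0.861, 0.911, 0.965, 0.969, 1.588, 1.621,
               1.630, 2.615),
    intensity = c(0.0242, 0.0389, 0.4360, 0.0410, 0.0346, 0.0237, 0.0328,
                  0.0295, 0.1127, 0.0192, 0.0440, 0.0292, 0.3055, 0.0658,
                  0.0100, 0.0150, 0.0426, 0.0168, 0.0446, 0.2580, 0.0499,
                  0.1582, 0.0322, 0.0149, 0.0151, 0.3585),
    emitter = c("Ac-228", "Ac-228", "Pb-212", "Ra-224", "Ac-228", "Tl-208",
                "Pb-212", "Ac-228", "Ac-228", "Ac-228", "Ac-228", "Tl-208",
                "Tl-208", "Bi-212", "Ac-228", "Ac-228", "Ac-228", "Ac-228",
                "Tl-208", "Ac-228", "Ac-228", "Ac-228", "Ac-228", "Bi-212",
                "Ac-228", "Tl-208")
  )

  out <- bind_rows(k40, u, th)
  stopifnot(all(out$energy > 0 & out$energy <= 2.615),
            all(out$intensity > 0 & out$intensity <= 1))
  class(out) <- c("nuclide_lines", class(out))
  out
}

.NUCLIDES <- c("K40", "U238_series", "Th232_series")
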