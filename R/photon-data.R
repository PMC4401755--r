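# Photon interaction coefficients, 0.05--3 MeV, standard tabulated values
# (mass attenuation mu/rho and mass energy-absorption muen/rho, cm^2/g).
# Log-log interpolation between grid points; soil is a quartz-like dry soil.

.PHOTON_E <- c(0.05, 0.10, 0.15, 0.20, 0.30, 0.40, 0.50, 0.60,
               0.80, 1.00, 1.25, 1.50, 2.00, 3.00)

.MU_AIR <- c(0.2080, 0.1541, 0.1356, 0.1233, 0.1067, 0.0954, 0.0868,
             0.0804, 0.0706, 0.0636, 0.0568, 0.0517, 0.0445, 0.0358)

.MUEN_AIR <- c(0.0406, 0.0234, 0.0250, 0.0268, 0.0288, 0.0295, 0.0297,
               0.0295, 0.0289, 0.0278, 0.0266, 0.0254, 0.0234, 0.0205)

.MU_SOIL <- c(0.3150, 0.1670, 0.1398, 0.1250, 0.1073, 0.0955, 0.0868,
              0.0803, 0.0704, 0.0635, 0.0567, 0.0517, 0.0447, 0.0363)

.MU_NAI <- c(7.90, 1.670, 0.640, 0.360, 0.187, 0.133, 0.105,
             0.0926, 0.0774, 0.0684, 0.0611, 0.0563, 0.0506, 0.0456)

loglog_interp <- function(e, xs, ys) {
  e <- pmin(pmax(e, xs[1]), xs[length(xs)])
  exp(stats::approx(log(xs), log(ys), xout = log(e))$y)
}

mu_air <- function(e) loglog_interp(e, .PHOTON_E, .MU_AIR)
muen_air <- function(e) loglog_interp(e, .PHOTON_E, .MUEN_AIR)
mu_soil <- function(e) loglog_interp(e, .PHOTON_E, .MU_SOIL)
mu_nai <- function(e) loglog_interp(e, .PHOTON_E, .MU_NAI)

# Compton edge (MeV) for incident energy e
compton_edge <- function(e) 2 * e^2 / (0.511 + 2 * e)
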