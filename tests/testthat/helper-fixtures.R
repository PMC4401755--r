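# Shared fixtures, built once per test run. The flux library uses a reduced
# history count: its Monte Carlo standard errors are then well below the
# tolerances any test asserts against.
fx_bins <- energy_bins()
fx_lib <- build_unit_flux_library(fx_bins, histories = 5e4, seed = 1)
fx_rm <- build_response_matrix(fx_bins)

# reference Table-1 ratios: kerma component / activity from printed rows
fx_table1_coeff <- c(K40 = 0.0418, U238_series = 0.440, Th232_series = 0.650)

# an energy_spectrum wrapper for hand-made flux vectors (zero covariance)
as_energy_spectrum <- function(flux, bins = fx_bins) {
  structure(list(flux = flux, se = rep(0, 22), cov = matrix(0, 22, 22),
                 residual_norm = 0, condition = 1, bins = bins,
                 edges = bin_edges(bins), live_time = NA_real_,
                 flags = character()),
            class = "energy_spectrum")
}

# a bin_spectrum wrapper for hand-made count vectors
as_bin_spectrum <- function(counts, live_time = 1, var = counts,
                            bins = fx_bins) {
  structure(list(counts = counts, var = var, live_time = live_time,
                 dropped = 0, bins = bins, edges = bin_edges(bins),
                 flags = character()),
            class = "bin_spectrum")
}
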