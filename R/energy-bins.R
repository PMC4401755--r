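#' The 22-bin incident-energy scheme
#'
#' Natural terrestrial gamma spectrometry with a NaI(Tl) detector works on a
#' fixed partition of 0--3.2 MeV into 22 contiguous bins of width growing with
#' energy, arranged so that the analysis lines fall centrally in their own
#' bins: 1.464 MeV (40K) in bin 14, 1.765 and 2.205 MeV (214Bi) in bins 16 and
#' 18, 2.615 MeV (208Tl) in bin 20. Bin 22 (3.0--3.2 MeV) contains no
#' terrestrial lines and indexes the cosmic-ray continuum. Energies above
#' 3.2 MeV are not evaluated.
#'
#' Only the five anchored bins are fixed by the method; the remaining edges
#' are package constants chosen to tile \[0, 3.2\] MeV with monotonically
#' growing widths.
#'
#' @return An object of class `energy_bins`: integer-indexed tibble with
#'   columns `bin`, `lower`, `upper`, `center`, `width` (MeV), carrying the
#'   full edge vector as attribute `edges`.
#' @examples
#' energy_bins()
#' @export
energy_bins <- function() {
  edges <- c(0, 0.05, 0.10, 0.17, 0.25, 0.34, 0.44, 0.55, 0.67, 0.80,
             0.94, 1.08, 1.23, 1.39, 1.54, 1.69, 1.84, 2.10, 2.31, 2.51,
             2.72, 3.00, 3.20)
  out <- tibble(
    bin = seq_len(22L),
    lower = edges[-23],
    upper = edges[-1],
    center = (edges[-23] + edges[-1]) / 2,
    width = diff(edges)
  )
  attr(out, "edges") <- edges
  class(out) <- c("energy_bins", class(out))
  out
}

bin_edges <- function(bins) attr(bins, "edges")

# bin index containing energy e (MeV); NA outside [0, 3.2]
bin_of_energy <- function(e, bins = energy_bins()) {
  edges <- bin_edges(bins)
  idx <- findInterval(e, edges, rightmost.closed = TRUE)
  idx[e <= 0 | e > edges[length(edges)]] <- NA_integer_
  idx
}

# fraction of the interval [lo, hi] overlapping each bin (length-22 vector)
interval_bin_overlap <- function(lo, hi, bins = energy_bins()) {
  stopifnot(hi >= lo)
  ov <- pmax(0, pmin(bins$upper, hi) - pmax(bins$lower, lo))
  if (hi > lo) ov / (hi - lo) else as.numeric(bins$lower <= lo & bins$upper >= hi)
}

get_edges <- function(x) {
  if (inherits(x, "energy_bins")) return(bin_edges(x))
  if (is.list(x) && !is.null(x$edges)) return(x$edges)
  attr(x, "edges")
}

assert_same_bins <- function(a, b) {
  ea <- get_edges(a)
  eb <- get_edges(b)
  if (!isTRUE(all.equal(ea, eb))) {
    abort("bin structures differ between inputs", class = "carborne_bin_mismatch")
  }
  invisible(TRUE)
}
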