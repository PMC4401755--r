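#' Published spot measurements, Karunagappally Taluk (2013 survey)
#'
#' The 32 spot measurements (soil, grass and beach-sand surfaces) of the
#' 2013 car-borne survey of Karunagappally Taluk, Kerala: per-nuclide air
#' kerma rates, their integer percentage contributions, activity
#' concentrations with statistical errors, and the surface class, at 4-
#' decimal WGS-84 coordinates. Used throughout as the reference
#' decomposition table: its internal arithmetic (component sums, rounded
#' percentages, kerma-per-activity ratios) anchors the validation suite.
#'
#' @return Tibble with one row per spot: `panchayat`, `lat`, `lon`,
#'   `kerma_k40`, `kerma_u238`, `kerma_th232`, `kerma_total` (nGy/h),
#'   `pct_k40`, `pct_u238`, `pct_th232` (integer %), `act_*` / `act_*_err`
#'   (Bq/kg), `surface`.
#' @examples
#' kerala_spots() |> dplyr::count(surface)
#' @export
kerala_spots <- function() {
  path <- system.file("extdata", "karunagappally_spots.csv", package = "carborne")
  readr::read_csv(path, show_col_types = FALSE)
}

#' Published per-Panchayat annual effective doses (2013 survey)
#'
#' Regional annual effective dose summaries of the same survey: number of
#' mobile records, mean/maximum/minimum/median annual effective dose
#' (mSv/y, two significant figures) and the background radiation level
#' class of each of the 12 Panchayats.
#'
#' @return Tibble with columns `panchayat`, `n`, `mean_mSv_y`, `max_mSv_y`,
#'   `min_mSv_y`, `median_mSv_y`, `radiation_level`.
#' @export
kerala_regions <- function() {
  path <- system.file("extdata", "karunagappally_regions.csv", package = "carborne")
  readr::read_csv(path, show_col_types = FALSE)
}
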