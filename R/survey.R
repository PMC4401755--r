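#' Survey calibration constants
#'
#' The constants tying inside vehicle counts to outdoor dose: the car-body
#' shielding factor, the dose-rate conversion factor (air kerma per count
#' rate), the kerma-to-effective-dose conversion for adults, and the hours
#' in a year. Defaults are the survey-calibrated values 1.47 and
#' 0.00244 nGy/h/cpm with DCF 0.7 Sv/Gy and T 8760 h.
#'
#' @param shielding Outside/inside count-rate ratio (dimensionless, > 0).
#' @param conversion nGy/h per cpm (> 0).
#' @param dcf Sv/Gy (> 0).
#' @param hours_per_year Exposure hours per year (> 0).
#' @return Object of class `survey_constants`.
#' @export
survey_constants <- function(shielding = 1.47, conversion = 0.00244,
                             dcf = 0.7, hours_per_year = 8760) {
  vals <- c(shielding, conversion, dcf, hours_per_year)
  if (any(!is.finite(vals)) || any(vals <= 0)) abort("all survey constants must be > 0")
  structure(list(shielding = shielding, conversion = conversion,
                 dcf = dcf, hours_per_year = hours_per_year),
            class = "survey_constants")
}

ratio_fit <- function(data, yname, xname) {
  x <- data[[xname]]; y <- data[[yname]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) abort("at least 2 pairs are required for a through-origin fit")
  if (any(x < 0) || any(y < 0)) abort("count rates must be nonnegative")
  fit <- lm(y ~ 0 + x)
  est <- unname(stats::coef(fit)[1])
  se <- unname(sqrt(diag(suppressWarnings(stats::vcov(fit))))[1])
  structure(list(estimate = est, se = se, n = length(x),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 x = xname, y = yname, data = tibble(x = x, y = y)),
            class = "ratio_fit")
}

#' Fit the car-body shielding factor
#'
#' Through-origin least-squares slope of outside count rate on inside count
#' rate over paired measurements (34 calibration points in the reference
#' survey). Zero inside counts must imply zero outside counts physically,
#' hence no intercept.
#'
#' @param data Data frame of paired rates.
#' @param outside,inside Column names.
#' @return Object of class `ratio_fit` with `estimate`, `se`, `n`;
#'   [tidy()] / [glance()] methods available.
#' @export
fit_shielding_factor <- function(data, outside = "outside", inside = "inside") {
  ratio_fit(data, outside, inside)
}

#' Fit the dose-rate conversion factor
#'
#' Through-origin slope of spot air kerma rate (nGy/h, from unfolded
#' spectra) on total count rate (cpm) outside the vehicle.
#'
#' @param data Data frame of paired values.
#' @param kerma,cpm Column names.
#' @return A `ratio_fit`.
#' @export
fit_conversion_factor <- function(data, kerma = "kerma", cpm = "cpm") {
  ratio_fit(data, kerma, cpm)
}

#' @export
print.ratio_fit <- function(x, ...) {
  cat(sprintf("<ratio_fit> %s ~ 0 + %s: slope %.5g (se %.3g, n = %d)\n",
              x$y, x$x, x$estimate, x$se, x$n))
  invisible(x)
}

#' @export
tidy.ratio_fit <- function(x, ...) {
  tibble(term = paste0(x$y, "/", x$x), estimate = x$estimate,
         std.error = x$se)
}

#' @export
glance.ratio_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n)
}

#' Outdoor air kerma rate from inside vehicle counts
#'
#' The mobile-survey conversion: K_out = 2 N_in x shielding x conversion,
#' where N_in is the inside count over 30 s (doubled to counts per minute),
#' the shielding factor restores the unshielded rate and the conversion
#' factor maps cpm to nGy/h. With the default constants,
#' K_out = 2 N_in x 1.47 x 0.00244.
#'
#' @param data Data frame of survey points with a 30-s inside-count column.
#' @param constants A [survey_constants()].
#' @param counts Column name of the 30-s inside counts.
#' @return The input tibble with column `kerma_nGy_h` appended.
#' @examples
#' kerma_from_counts(tibble::tibble(counts = 10000))$kerma_nGy_h  # 71.736
#' @export
kerma_from_counts <- function(data, constants = survey_constants(),
                              counts = "counts") {
  n_in <- data[[counts]]
  if (any(n_in < 0, na.rm = TRUE)) abort("counts must be nonnegative")
  as_tibble(data) %>%
    mutate(kerma_nGy_h = 2 * n_in * constants$shielding * constants$conversion)
}

#' Annual effective dose from outdoor air kerma rate
#'
#' H (mSv/y) = K_out x DCF x T, with K_out in nGy/h, DCF = 0.7 Sv/Gy and
#' T = 8760 h/y; the nSv result is expressed in mSv. A conservative outdoor
#' estimate: no occupancy factor or building shielding is applied.
#'
#' @param data Data frame with a kerma column, or a bare numeric vector of
#'   kerma rates (nGy/h).
#' @param constants A [survey_constants()].
#' @param kerma Column name when `data` is a data frame.
#' @return The tibble with column `dose_mSv_y` appended, or a numeric
#'   vector for numeric input.
#' @examples
#' annual_effective_dose(2141)          # 13.13 -> reported as 13 mSv/y
#' signif(annual_effective_dose(2021), 2)
#' @export
annual_effective_dose <- function(data, constants = survey_constants(),
                                  kerma = "kerma_nGy_h") {
  if (is.numeric(data)) {
    if (any(data < 0, na.rm = TRUE)) abort("kerma must be >= 0")
    return(data * constants$dcf * constants$hours_per_year * 1e-6)
  }
  k <- data[[kerma]]
  if (any(k < 0, na.rm = TRUE)) abort("kerma must be >= 0")
  as_tibble(data) %>%
    mutate(dose_mSv_y = k * constants$dcf * constants$hours_per_year * 1e-6)
}

#' Per-region dose statistics
#'
#' Summarises survey points by region label: number of points, mean, median,
#' minimum and maximum annual dose (reported to 2 significant figures,
#' matching survey reporting practice), the coefficient of variation of the
#' kerma rate (percent), and the fraction of points above 1 mSv/y. The
#' overall fraction of points at or below 1 mSv/y is attached as attribute
#' `frac_at_or_below_1`.
#'
#' @param data Data frame of points with region labels, doses and kerma.
#' @param region,dose,kerma Column names.
#' @return Tibble with one row per region (empty regions are dropped with a
#'   warning), invariant min <= median <= max.
#' @export
summarize_regions <- function(data, region = "region", dose = "dose_mSv_y",
                              kerma = "kerma_nGy_h") {
  d <- as_tibble(data)
  if (any(is.na(d[[region]]))) {
    warn("points with missing region label omitted")
    d <- d[!is.na(d[[region]]), ]
  }
  out <- d %>%
    group_by(region = .data[[region]]) %>%
    summarise(
      n = dplyr::n(),
      mean_mSv_y = signif(mean(.data[[dose]]), 2),
      median_mSv_y = signif(median(.data[[dose]]), 2),
      min_mSv_y = signif(min(.data[[dose]]), 2),
      max_mSv_y = signif(max(.data[[dose]]), 2),
      cv_kerma_pct = 100 * sd(.data[[kerma]]) / mean(.data[[kerma]]),
      frac_above_1mSv = mean(.data[[dose]] > 1),
      .groups = "drop"
    )
  attr(out, "frac_at_or_below_1") <- mean(d[[dose]] <= 1)
  out
}

#' Grid survey points into a dose raster
#'
#' Fixed-size lon/lat cells; each occupied cell holds the mean kerma and
#' dose of its points, empty cells are retained with `NA` and flagged via
#' `n = 0`.
#'
#' @param data Survey points with `lon`, `lat`, kerma and dose columns.
#' @param cell_deg Cell size in degrees.
#' @param kerma,dose Column names (dose optional; skipped when absent).
#' @return Object of class `dose_raster`: tibble of cells with `lon`, `lat`
#'   centres, `n`, `kerma_mean` (and `dose_mean`).
#' @export
grid_dose_map <- function(data, cell_deg = 0.005, kerma = "kerma_nGy_h",
                          dose = "dose_mSv_y") {
  d <- as_tibble(data)
  if (nrow(d) < 1) abort("at least one point is required")
  ix <- floor(d$lon / cell_deg)
  iy <- floor(d$lat / cell_deg)
  d$._ix <- ix; d$._iy <- iy
  occ <- d %>%
    group_by(.data$._ix, .data$._iy) %>%
    summarise(n = dplyr::n(),
              kerma_mean = mean(.data[[kerma]]),
              dose_mean = if (dose %in% names(d)) mean(.data[[dose]]) else NA_real_,
              .groups = "drop")
  full <- tidyr::expand_grid(._ix = seq(min(ix), max(ix)),
                             ._iy = seq(min(iy), max(iy))) %>%
    left_join(occ, by = c("._ix", "._iy")) %>%
    mutate(n = tidyr::replace_na(.data$n, 0L),
           lon = (.data$._ix + 0.5) * cell_deg,
           lat = (.data$._iy + 0.5) * cell_deg) %>%
    select("lon", "lat", "n", "kerma_mean", "dose_mean")
  structure(full, cell_deg = cell_deg, class = c("dose_raster", class(full)))
}
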