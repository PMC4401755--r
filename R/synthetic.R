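#' Ground-truth scene for a spot measurement
#'
#' Everything the spectrum simulator needs to generate one spot measurement
#' with known truth: activity concentrations, instrument state and counting
#' conditions. Counting times of 300/600/900 s correspond to high/mid/low
#' radiation-level sites.
#'
#' @param activity Named vector of activity concentrations in Bq/kg for
#'   `K40`, `U238_series`, `Th232_series` (all >= 0).
#' @param surface One of `"soil"`, `"grass"`, `"sand"`.
#' @param cosmic_cps Cosmic count rate indexed by its bin-22 content (cps).
#'   The magnitude is a package assumption (typical sea-level NaI value).
#' @param pmt_cps Photomultiplier 40K contamination rate (cps), also an
#'   assumed instrument constant.
#' @param gain Channels per MeV.
#' @param offset Channel of 0 MeV.
#' @param resolution FWHM fraction at 0.662 MeV.
#' @param live_time Counting time in seconds.
#' @param seed Integer seed for the Poisson sampling.
#' @return Object of class `spot_scene`.
#' @export
spot_scene <- function(activity = c(K40 = 150, U238_series = 60, Th232_series = 100),
                       surface = c("soil", "grass", "sand"),
                       cosmic_cps = 2, pmt_cps = 1,
                       gain = 300, offset = 0, resolution = 0.07,
                       live_time = 300, seed = NULL) {
  surface <- match.arg(surface)
  a <- setNames(rep(0, 3), .NUCLIDES)
  a[names(activity)] <- activity
  if (any(a < 0)) abort("activities must be >= 0")
  if (live_time <= 0) abort("live time must be > 0")
  if (gain <= 0) abort("gain must be > 0")
  if (cosmic_cps < 0 || pmt_cps < 0) abort("background rates must be >= 0")
  structure(list(activity = a, surface = surface, cosmic_cps = cosmic_cps,
                 pmt_cps = pmt_cps, gain = gain, offset = offset,
                 resolution = resolution, live_time = live_time, seed = seed),
            class = "spot_scene")
}

# expected channel-level spectrum (counts) for given per-bin flux plus
# backgrounds, consistent in expectation with the 22x22 response matrix
expected_channel_spectrum <- function(scene, response, flux, channels = 1024) {
  edges <- attr(response, "edges")
  ch_e <- (seq_len(channels + 1) - 1 - scene$offset) / scene$gain
  ch_lo <- ch_e[-(channels + 1)]; ch_hi <- ch_e[-1]
  ch_w <- ch_hi - ch_lo
  peak_e <- attr(response, "peak_energy")
  peak_sig <- sigma_at(resolution_model(scene$resolution), peak_e)
  peak_mass <- attr(response, "peak_mass")
  cont_d <- attr(response, "cont_density")
  cont_edge <- attr(response, "cont_edge")

  mu <- numeric(channels)
  # PMT 40K rides on the response as extra flux in bin 14
  r14 <- sum(unclass(response)[, 14])
  phi <- flux
  phi[14] <- phi[14] + scene$pmt_cps / r14
  for (j in 1:22) {
    if (phi[j] <= 0) next
    # photopeak: Gaussian over channels, normalised on [0, 3.2] like the matrix
    gch <- diff(pnorm(ch_e, mean = peak_e[j], sd = peak_sig[j]))
    gch[ch_hi <= 0 | ch_lo >= 3.2] <- 0
    gch <- gch / sum(gch)
    # continuum: flat in energy up to the Compton edge
    cont <- pmax(0, pmin(ch_hi, cont_edge[j]) - pmax(ch_lo, 0)) * cont_d[j]
    mu <- mu + phi[j] * (peak_mass[j] * gch + cont)
  }
  # cosmic: flat in pulse-height energy on [0.5, 3.2], bin-22 content fixed
  cos_d <- scene$cosmic_cps / 0.2
  mu <- mu + cos_d * pmax(0, pmin(ch_hi, 3.2) - pmax(ch_lo, 0.5))
  mu * scene$live_time
}

#' Simulate a spot pulse-height spectrum
#'
#' Forward model of a spot measurement: the scene's activities are folded
#' with the unit flux library and the detector response; photopeaks are
#' placed in channel space at the scene's gain with its resolution, Compton
#' continua below the corresponding edges, plus the flat cosmic continuum
#' (anchored to the scene's bin-22 rate) and the photomultiplier 40K
#' component. Channel counts are Poisson-sampled under the scene seed; with
#' `poisson = FALSE` the expected (noise-free) spectrum is returned.
#'
#' @param scene A [spot_scene()].
#' @param response A `response_matrix` (same bin structure as the library).
#' @param library A `unit_flux_library`.
#' @param channels Number of MCA channels.
#' @param poisson Sample Poisson counting noise?
#' @return A `ph_spectrum`; the generating scene travels as attribute
#'   `scene` for test harnesses (never used by the analysis chain).
#' @export
simulate_spot_spectrum <- function(scene, response, library,
                                   channels = 1024, poisson = TRUE) {
  stopifnot(inherits(scene, "spot_scene"),
            inherits(response, "response_matrix"),
            inherits(library, "unit_flux_library"))
  assert_same_bins(response, library$bins)
  flux <- as.numeric(library$flux %*% scene$activity)
  mu <- expected_channel_spectrum(scene, response, flux, channels)
  counts <- if (poisson) {
    with_local_seed(scene$seed, rpois(channels, mu))
  } else round(mu)
  out <- ph_spectrum(counts, scene$live_time, gain_hint = scene$gain)
  attr(out, "scene") <- scene
  out
}

#' PMT background count-rate spectrum on the bin grid
#'
#' The instrument's photomultiplier 40K component expressed as count rates
#' per energy bin: the pure-40K response column scaled to the given total
#' rate. Used by [subtract_pmt_background()].
#'
#' @param response A `response_matrix`.
#' @param pmt_cps Total PMT 40K count rate (cps).
#' @return Length-22 vector of cps.
#' @export
pmt_background_rate <- function(response, pmt_cps) {
  col <- unclass(response)[, 14]
  pmt_cps * col / sum(col)
}

#' Process a spot spectrum into an activity estimate
#'
#' The full spot chain: individual energy calibration (Fourier smoothing +
#' two-peak location), rebinning to the 22-bin grid, cosmic subtraction via
#' bin 22, PMT 40K subtraction, response-matrix unfolding, and
#' successive-approximation activity estimation.
#'
#' @param spectrum A `ph_spectrum`.
#' @param response A `response_matrix`.
#' @param library A `unit_flux_library`.
#' @param pmt_cps Known instrument PMT 40K rate (cps).
#' @param nominal_gain Nominal gain seeding the peak search.
#' @param n_terms Fourier smoothing order.
#' @inheritParams estimate_activities
#' @return An `activity_estimate`.
#' @export
process_spot_spectrum <- function(spectrum, response, library, pmt_cps = 0,
                                  nominal_gain = 300, n_terms = 120,
                                  surface = NA_character_,
                                  lat = NA_real_, lon = NA_real_) {
  cal <- fit_energy_calibration(spectrum, nominal_gain = nominal_gain,
                                n_terms = n_terms)
  bs <- rebin_to_energy(spectrum, cal, library$bins)
  bs <- subtract_cosmic(bs)
  if (pmt_cps > 0) bs <- subtract_pmt_background(bs, pmt_background_rate(response, pmt_cps))
  es <- unfold(bs, response)
  estimate_activities(es, library, surface = surface, lat = lat, lon = lon)
}

#' Synthetic activity field on a lon/lat grid
#'
#' Smooth per-nuclide background plus Gaussian hotspots, emulating the
#' spatially localised thorium enrichment of monazite-bearing coastal sand
#' over an otherwise mild inland field.
#'
#' @param background Named per-nuclide background activities (Bq/kg).
#' @param hotspots Tibble with columns `lon`, `lat`, `radius_deg` and peak
#'   amplitudes `peak_k40`, `peak_u238`, `peak_th232` (Bq/kg added at the
#'   centre); may be empty.
#' @param lon_range,lat_range Field extent in decimal degrees (WGS-84).
#' @param nx,ny Grid dimensions.
#' @param smooth_sd Relative amplitude of the smooth seeded background
#'   variation (0 gives a constant background).
#' @param seed Integer seed.
#' @return Object of class `activity_field`: `lon`, `lat` vectors and one
#'   `nx x ny` matrix per nuclide.
#' @export
make_activity_field <- function(background = c(K40 = 150, U238_series = 60, Th232_series = 100),
                                hotspots = NULL,
                                lon_range = c(76.45, 76.62),
                                lat_range = c(8.93, 9.14),
                                nx = 60, ny = 60,
                                smooth_sd = 0, seed = NULL) {
  stopifnot(nx >= 2, ny >= 2)
  b <- setNames(rep(0, 3), .NUCLIDES)
  b[names(background)] <- background
  if (any(b < 0)) abort("background activities must be >= 0")
  lon <- seq(lon_range[1], lon_range[2], length.out = nx)
  lat <- seq(lat_range[1], lat_range[2], length.out = ny)
  grids <- with_local_seed(seed, {
    lapply(setNames(.NUCLIDES, .NUCLIDES), function(nuc) {
      g <- matrix(b[nuc], nx, ny)
      if (smooth_sd > 0 && b[nuc] > 0) {
        # low-order random Fourier modes give a smooth, seeded modulation
        px <- (lon - lon_range[1]) / diff(lon_range)
        py <- (lat - lat_range[1]) / diff(lat_range)
        mod <- matrix(0, nx, ny)
        for (k in 1:3) {
          amp <- rnorm(1, 0, smooth_sd / sqrt(3))
          phx <- runif(1, 0, 2 * pi); phy <- runif(1, 0, 2 * pi)
          mod <- mod + amp * outer(sin(2 * pi * k * px + phx),
                                   sin(2 * pi * k * py + phy))
        }
        g <- g * pmax(0.1, 1 + mod)
      }
      g
    })
  })
  if (!is.null(hotspots) && nrow(hotspots) > 0) {
    for (i in seq_len(nrow(hotspots))) {
      hs <- hotspots[i, ]
      d2 <- outer((lon - hs$lon)^2, (lat - hs$lat)^2, `+`)
      bump <- exp(-d2 / (2 * hs$radius_deg^2))
      grids$K40 <- grids$K40 + (hs$peak_k40 %||% 0) * bump
      grids$U238_series <- grids$U238_series + (hs$peak_u238 %||% 0) * bump
      grids$Th232_series <- grids$Th232_series + (hs$peak_th232 %||% 0) * bump
    }
  }
  structure(list(lon = lon, lat = lat, k40 = grids$K40,
                 u238 = grids$U238_series, th232 = grids$Th232_series,
                 hotspots = hotspots, background = b),
            class = "activity_field")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Coastal-strip preset field
#'
#' A ready-made heterogeneous field: mild inland background with smooth
#' variation, plus thorium-rich hotspots along the western (coastal) edge
#' with peak 232Th activities in the monazite-sand range.
#'
#' @param seed Integer seed.
#' @return An `activity_field` whose `hotspots` carry a `region` split:
#'   cells within the coastal strip (westernmost 25% of longitudes) vs
#'   inland.
#' @export
coastal_field <- function(seed = 42) {
  hs <- tibble(
    lon = c(76.465, 76.470, 76.468),
    lat = c(8.955, 9.000, 9.050),
    radius_deg = c(0.006, 0.005, 0.005),
    peak_k40 = c(800, 600, 500),
    peak_u238 = c(1100, 800, 600),
    peak_th232 = c(2200, 1500, 1200)
  )
  make_activity_field(hotspots = hs, smooth_sd = 0.15, seed = seed)
}

# per-cell kerma rate (nGy/h) matrix of a field under library coefficients
field_kerma <- function(field, kerma_coeff) {
  kerma_coeff[["K40"]] * field$k40 +
    kerma_coeff[["U238_series"]] * field$u238 +
    kerma_coeff[["Th232_series"]] * field$th232
}

#' @export
tidy.activity_field <- function(x, kerma_coeff = NULL, ...) {
  out <- tidyr::expand_grid(i = seq_along(x$lon), j = seq_along(x$lat)) %>%
    mutate(lon = x$lon[.data$i], lat = x$lat[.data$j],
           k40 = x$k40[cbind(.data$i, .data$j)],
           u238 = x$u238[cbind(.data$i, .data$j)],
           th232 = x$th232[cbind(.data$i, .data$j)])
  if (!is.null(kerma_coeff)) {
    km <- field_kerma(x, kerma_coeff)
    out$kerma <- km[cbind(out$i, out$j)]
  }
  out
}

# bilinear interpolation of a field matrix at (lon, lat) points
field_interp <- function(field, grid, lon, lat) {
  fx <- findInterval(lon, field$lon, all.inside = TRUE)
  fy <- findInterval(lat, field$lat, all.inside = TRUE)
  x1 <- field$lon[fx]; x2 <- field$lon[fx + 1]
  y1 <- field$lat[fy]; y2 <- field$lat[fy + 1]
  tx <- (lon - x1) / (x2 - x1); ty <- (lat - y1) / (y2 - y1)
  g <- function(i, j) grid[cbind(i, j)]
  (1 - tx) * (1 - ty) * g(fx, fy) + tx * (1 - ty) * g(fx + 1, fy) +
    (1 - tx) * ty * g(fx, fy + 1) + tx * ty * g(fx + 1, fy + 1)
}

#' Simulate a car-borne survey track
#'
#' Advances along the route polyline at constant speed, dropping a
#' measurement every `interval_s` seconds (333 m at 40 km/h and 30 s).
#' Distances use a local equirectangular projection, adequate at survey
#' scale. At each point the local per-nuclide activities give the true
#' outdoor kerma through the library coefficients; the expected inside
#' count over the interval is kerma / (shielding x conversion) x
#' interval/60, Poisson-sampled.
#'
#' @param field An `activity_field`.
#' @param route Tibble of polyline vertices (`lon`, `lat`), inside the field.
#' @param kerma_coeff Named per-nuclide kerma coefficients (nGy/h per
#'   Bq/kg), e.g. `lib$kerma_coeff`.
#' @param speed_kmh Vehicle speed.
#' @param interval_s Counting interval (s).
#' @param constants [survey_constants()] providing shielding and conversion
#'   factors.
#' @param start_time POSIXct of the first record.
#' @param seed Integer seed.
#' @return Tibble of survey points: `time`, `lon`, `lat`, `counts`
#'   (inside counts per interval), and the synthetic truth column
#'   `kerma_true` (nGy/h) for validation.
#' @export
simulate_survey_track <- function(field, route, kerma_coeff,
                                  speed_kmh = 40, interval_s = 30,
                                  constants = survey_constants(),
                                  start_time = as.POSIXct("2013-09-23 08:00:00", tz = "UTC"),
                                  seed = NULL) {
  stopifnot(inherits(field, "activity_field"), interval_s > 0, speed_kmh > 0)
  inx <- route$lon >= min(field$lon) & route$lon <= max(field$lon) &
    route$lat >= min(field$lat) & route$lat <= max(field$lat)
  if (!all(inx)) {
    abort(sprintf("route vertex %d (lon %.4f, lat %.4f) lies outside the field extent",
                  which(!inx)[1], route$lon[which(!inx)[1]], route$lat[which(!inx)[1]]))
  }
  lat0 <- mean(range(field$lat))
  mx <- 111320 * cos(lat0 * pi / 180)  # metres per degree lon
  my <- 110540                         # metres per degree lat
  x <- (route$lon - route$lon[1]) * mx
  y <- (route$lat - route$lat[1]) * my
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  cum <- c(0, cumsum(seg))
  step <- speed_kmh / 3.6 * interval_s
  s <- seq(0, cum[length(cum)], by = step)
  px <- stats::approx(cum, x, xout = s)$y
  py <- stats::approx(cum, y, xout = s)$y
  lon <- route$lon[1] + px / mx
  lat <- route$lat[1] + py / my

  kerma <- kerma_coeff[["K40"]] * field_interp(field, field$k40, lon, lat) +
    kerma_coeff[["U238_series"]] * field_interp(field, field$u238, lon, lat) +
    kerma_coeff[["Th232_series"]] * field_interp(field, field$th232, lon, lat)
  mu <- kerma / (constants$shielding * constants$conversion) * interval_s / 60
  counts <- with_local_seed(seed, rpois(length(mu), mu))
  tibble(time = start_time + seq_along(s) * interval_s - interval_s,
         lon = lon, lat = lat, counts = counts, kerma_true = kerma)
}

#' A default zig-zag survey route covering a field
#'
#' @param field An `activity_field`.
#' @param n_sweeps Number of north-south sweeps.
#' @param margin Fractional inset from the field edges.
#' @return Tibble of route vertices (`lon`, `lat`).
#' @export
field_route <- function(field, n_sweeps = 6, margin = 0.05) {
  lr <- range(field$lon); br <- range(field$lat)
  lons <- seq(lr[1] + margin * diff(lr), lr[2] - margin * diff(lr),
              length.out = n_sweeps)
  lats <- c(br[1] + margin * diff(br), br[2] - margin * diff(br))
  verts <- purrr::map_dfr(seq_along(lons), function(i) {
    la <- if (i %% 2 == 1) lats else rev(lats)
    tibble(lon = lons[i], lat = la)
  })
  verts
}
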