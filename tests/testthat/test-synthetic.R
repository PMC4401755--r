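test_that("an empty scene produces an all-zero spectrum", {
  sc <- spot_scene(activity = c(K40 = 0, U238_series = 0, Th232_series = 0),
                   cosmic_cps = 0, pmt_cps = 0, seed = 1)
  sp <- simulate_spot_spectrum(sc, fx_rm, fx_lib)
  expect_equal(sum(sp$counts), 0L)
})

test_that("a pure 40K scene deposits no counts above the 1.54 MeV channels beyond resolution tails", {
  sc <- spot_scene(activity = c(K40 = 1000, U238_series = 0, Th232_series = 0),
                   cosmic_cps = 0, pmt_cps = 0, live_time = 900, seed = 2)
  sp <- simulate_spot_spectrum(sc, fx_rm, fx_lib, poisson = FALSE)
  cutoff <- ceiling(300 * 1.54) + 15  # upper bin-14 edge plus ~3 sigma of tail
  expect_equal(sum(sp$counts[cutoff:1024]), 0)
  # photopeak cluster at gain x 1.464
  pk <- which.max(sp$counts[420:460]) + 419
  expect_lt(abs(pk - 300 * 1.464), 3)
  expect_gt(sum(sp$counts[1:420]), 0)  # Compton continuum present
})

test_that("the end-to-end chain recovers the reference sand activities within 3 sigma", {
  sc <- spot_scene(activity = c(K40 = 955, U238_series = 1269, Th232_series = 2374),
                   surface = "sand", live_time = 300, seed = 7)
  sp <- simulate_spot_spectrum(sc, fx_rm, fx_lib)
  est <- process_spot_spectrum(sp, fx_rm, fx_lib, pmt_cps = 1)
  z <- (est$activity - sc$activity) / est$activity_se
  expect_true(all(abs(z) < 3))
})

test_that("simulated counts are Poisson: replicate variance matches the mean", {
  sc <- spot_scene(activity = c(K40 = 400, U238_series = 150, Th232_series = 300),
                   live_time = 300, seed = NULL)
  mu <- carborne:::expected_channel_spectrum(
    sc, fx_rm, as.numeric(fx_lib$flux %*% sc$activity))
  set.seed(31)
  reps <- 60
  ch <- which(mu > 20)[seq(1, sum(mu > 20), length.out = 40)]
  x <- replicate(reps, {
    sp <- simulate_spot_spectrum(sc, fx_rm, fx_lib)
    sp$counts[ch]
  })
  # chi-square over replicates and channels: sum (x - mu)^2 / mu ~ chi2_{n}
  stat <- sum((x - mu[ch])^2 / mu[ch])
  n <- length(ch) * reps
  expect_gt(stat, qchisq(0.001, n))
  expect_lt(stat, qchisq(0.999, n))
})

test_that("identical seeds give identical spectra, different seeds differ", {
  sc1 <- spot_scene(seed = 123)
  sc2 <- spot_scene(seed = 123)
  sc3 <- spot_scene(seed = 124)
  expect_identical(simulate_spot_spectrum(sc1, fx_rm, fx_lib)$counts,
                   simulate_spot_spectrum(sc2, fx_rm, fx_lib)$counts)
  expect_false(identical(simulate_spot_spectrum(sc1, fx_rm, fx_lib)$counts,
                         simulate_spot_spectrum(sc3, fx_rm, fx_lib)$counts))
})

test_that("scene validation rejects impossible inputs", {
  expect_error(spot_scene(activity = c(K40 = -1)), ">= 0")
  expect_error(spot_scene(live_time = 0), "live time")
  expect_error(spot_scene(gain = -5), "gain")
})

test_that("a field without hotspots is constant; a hotspot peaks at its centre", {
  f <- make_activity_field(smooth_sd = 0)
  expect_equal(max(f$th232), min(f$th232))
  ctr_lon <- f$lon[20]; ctr_lat <- f$lat[25]  # centre on grid nodes
  hs <- tibble::tibble(lon = ctr_lon, lat = ctr_lat, radius_deg = 0.01,
                       peak_k40 = 0, peak_u238 = 0, peak_th232 = 1500)
  f2 <- make_activity_field(hotspots = hs, smooth_sd = 0)
  imax <- which(f2$th232 == max(f2$th232), arr.ind = TRUE)
  expect_equal(f2$lon[imax[1]], ctr_lon)
  expect_equal(f2$lat[imax[2]], ctr_lat)
  expect_equal(max(f2$th232), 100 + 1500)
  expect_error(make_activity_field(background = c(Th232_series = -5)), ">= 0")
})

test_that("the coastal preset concentrates kerma variability in the hotspot strip", {
  f <- coastal_field(seed = 42)
  km <- carborne:::field_kerma(f, fx_lib$kerma_coeff)
  coastal <- f$lon <= stats::quantile(f$lon, 0.25)
  cv <- function(x) 100 * sd(x) / mean(x)
  expect_gt(cv(as.numeric(km[coastal, ])), cv(as.numeric(km[!coastal, ])))
})

test_that("survey tracks have the right spacing and Poisson-consistent counts", {
  f <- make_activity_field(smooth_sd = 0)  # constant field
  route <- tibble::tibble(lon = c(76.46, 76.61), lat = c(9.0, 9.0))
  tr <- simulate_survey_track(f, route, fx_lib$kerma_coeff, speed_kmh = 40,
                              interval_s = 30, seed = 50)
  # consecutive points ~333 m apart
  d <- 111320 * cos(9 * pi / 180) * diff(tr$lon)
  expect_equal(mean(d), 40 / 3.6 * 30, tolerance = 0.01)

  # constant-field mean reconstructed kerma within 2 standard errors
  cst <- survey_constants()
  f100 <- make_activity_field(
    background = c(K40 = 0, U238_series = 0,
                   Th232_series = 100 / fx_lib$kerma_coeff[["Th232_series"]]),
    smooth_sd = 0)
  route2 <- field_route(f100, n_sweeps = 10)
  tr2 <- simulate_survey_track(f100, route2, fx_lib$kerma_coeff, seed = 51) |>
    kerma_from_counts(cst)
  expect_gt(nrow(tr2), 500)
  se <- sd(tr2$kerma_nGy_h) / sqrt(nrow(tr2))
  expect_lt(abs(mean(tr2$kerma_nGy_h) - 100), 2 * se + 1e-6)
})

test_that("a zero-activity field yields all-zero counts", {
  f <- make_activity_field(background = c(K40 = 0, U238_series = 0, Th232_series = 0),
                           smooth_sd = 0)
  route <- tibble::tibble(lon = c(76.46, 76.60), lat = c(9.0, 9.1))
  tr <- simulate_survey_track(f, route, fx_lib$kerma_coeff, seed = 1)
  expect_true(all(tr$counts == 0))
})

test_that("a route leaving the field names the offending vertex", {
  f <- make_activity_field()
  route <- tibble::tibble(lon = c(76.5, 77.5), lat = c(9.0, 9.0))
  expect_error(simulate_survey_track(f, route, fx_lib$kerma_coeff),
               "vertex 2")
})
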