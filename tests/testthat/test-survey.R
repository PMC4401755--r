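test_that("through-origin fits recover exact ratios", {
  inside <- c(100, 200, 400, 800)
  d <- tibble::tibble(inside = inside, outside = 1.47 * inside)
  expect_equal(fit_shielding_factor(d)$estimate, 1.47)
  expect_equal(fit_shielding_factor(tibble::tibble(inside = inside, outside = inside))$estimate, 1)
  cpm <- c(5000, 20000, 80000)
  d2 <- tibble::tibble(cpm = cpm, kerma = 0.00244 * cpm)
  expect_equal(fit_conversion_factor(d2)$estimate, 0.00244)
  d3 <- tibble::tibble(cpm = cpm, kerma = 0)
  expect_equal(fit_conversion_factor(d3)$estimate, 0)
  expect_error(fit_shielding_factor(tibble::tibble(inside = 1, outside = 2)),
               "at least 2")
})

test_that("noised factor fits recover truth within 3 standard errors at n = 34", {
  set.seed(17)
  for (r in c(1.3, 1.47, 1.8)) {
    mu_in <- runif(34, 500, 10000)
    d <- tibble::tibble(inside = rpois(34, mu_in), outside = rpois(34, r * mu_in))
    fit <- fit_shielding_factor(d)
    expect_lt(abs(fit$estimate - r), 3 * fit$se)
    expect_equal(fit$n, 34)
  }
})

test_that("tidy and glance expose the fit", {
  d <- tibble::tibble(inside = c(10, 20), outside = c(14.7, 29.4))
  fit <- fit_shielding_factor(d)
  expect_equal(tidy(fit)$estimate, 1.47)
  expect_equal(glance(fit)$nobs, 2)
})

test_that("count-to-kerma conversion follows K_out = 2 N_in x shielding x conversion", {
  expect_equal(kerma_from_counts(tibble::tibble(counts = 10000))$kerma_nGy_h, 71.736)
  expect_equal(kerma_from_counts(tibble::tibble(counts = 0))$kerma_nGy_h, 0)
  half <- survey_constants(conversion = 0.00244 / 2)
  expect_equal(kerma_from_counts(tibble::tibble(counts = 10000), half)$kerma_nGy_h,
               71.736 / 2)
  expect_error(kerma_from_counts(tibble::tibble(counts = -1)), "nonnegative")
})

test_that("annual effective dose applies DCF and exposure time with 2 s.f. reporting", {
  expect_equal(signif(annual_effective_dose(2141), 2), 13)
  expect_equal(signif(annual_effective_dose(2021), 2), 12)
  expect_equal(annual_effective_dose(0), 0)
  expect_equal(annual_effective_dose(2141), 2141 * 0.7 * 8760 * 1e-6)
  d <- annual_effective_dose(tibble::tibble(kerma_nGy_h = c(100, 200)))
  expect_equal(d$dose_mSv_y[2] / d$dose_mSv_y[1], 2)
})

test_that("doubling all counts doubles all doses (Eq 1 / Eq 2 linearity)", {
  d1 <- tibble::tibble(counts = c(100, 5000, 20000)) |>
    kerma_from_counts() |> annual_effective_dose()
  d2 <- tibble::tibble(counts = 2 * c(100, 5000, 20000)) |>
    kerma_from_counts() |> annual_effective_dose()
  expect_equal(d2$dose_mSv_y, 2 * d1$dose_mSv_y)
})

test_that("region summaries: single point collapses, constant region has zero CV, order-invariant", {
  one <- tibble::tibble(region = "a", dose_mSv_y = 1.23, kerma_nGy_h = 200)
  s <- summarize_regions(one)
  expect_equal(s$mean_mSv_y, s$median_mSv_y)
  expect_equal(s$min_mSv_y, s$max_mSv_y)

  const <- tibble::tibble(region = "c", dose_mSv_y = rep(0.5, 20),
                          kerma_nGy_h = rep(80, 20))
  expect_equal(summarize_regions(const)$cv_kerma_pct, 0)

  set.seed(2)
  pts <- tibble::tibble(region = sample(c("x", "y"), 200, TRUE),
                        kerma_nGy_h = rexp(200, 1 / 150)) |>
    annual_effective_dose(kerma = "kerma_nGy_h")
  a <- summarize_regions(pts)
  b <- summarize_regions(pts[sample(200), ])
  expect_equal(a, b, ignore_attr = TRUE)
  expect_true(all(a$min_mSv_y <= a$median_mSv_y & a$median_mSv_y <= a$max_mSv_y))
  # moments agree with direct recomputation at 2 s.f.
  xm <- pts |> dplyr::filter(region == "x")
  expect_equal(a$mean_mSv_y[a$region == "x"], signif(mean(xm$dose_mSv_y), 2))
  expect_equal(a$frac_above_1mSv[a$region == "x"], mean(xm$dose_mSv_y > 1))
})

test_that("gridding: one point occupies one cell; translation shifts the raster rigidly", {
  p <- tibble::tibble(lon = 76.5012, lat = 9.0031, kerma_nGy_h = 150,
                      dose_mSv_y = 0.9)
  r <- grid_dose_map(p)
  expect_equal(sum(r$n), 1L)
  expect_equal(r$kerma_mean[r$n == 1], 150)

  set.seed(6)
  pts <- tibble::tibble(lon = 76.5 + runif(50, 0, 0.05),
                        lat = 9.0 + runif(50, 0, 0.05),
                        kerma_nGy_h = runif(50, 50, 300),
                        dose_mSv_y = runif(50, 0.3, 2))
  r1 <- grid_dose_map(pts, cell_deg = 0.005)
  shift <- pts |> dplyr::mutate(lon = lon + 10 * 0.005, lat = lat + 4 * 0.005)
  r2 <- grid_dose_map(shift, cell_deg = 0.005)
  expect_equal(r2$kerma_mean, r1$kerma_mean)
  expect_equal(r2$lon, r1$lon + 10 * 0.005)
  expect_equal(r2$lat, r1$lat + 4 * 0.005)
})

test_that("the raster maximum falls within one cell of a synthetic hotspot", {
  f <- coastal_field(seed = 42)
  route <- field_route(f, n_sweeps = 18, margin = 0.02)  # sweep spacing < cell
  tr <- simulate_survey_track(f, route, fx_lib$kerma_coeff, seed = 9) |>
    kerma_from_counts() |> annual_effective_dose()
  r <- grid_dose_map(tr, cell_deg = 0.01)
  km <- carborne:::field_kerma(f, fx_lib$kerma_coeff)
  truth <- which(km == max(km), arr.ind = TRUE)
  tlon <- f$lon[truth[1]]; tlat <- f$lat[truth[2]]
  best <- r[which.max(r$kerma_mean), ]
  # cell centre within one cell of the true peak (centre offset <= 1.5 cell)
  expect_lt(abs(best$lon - tlon), 1.5 * 0.01)
  expect_lt(abs(best$lat - tlat), 1.5 * 0.01)
})

test_that("survey constants are validated", {
  expect_error(survey_constants(shielding = 0), "> 0")
  expect_error(survey_constants(conversion = -1), "> 0")
})
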