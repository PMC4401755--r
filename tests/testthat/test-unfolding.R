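test_that("cosmic subtraction nulls a pure cosmic spectrum and is a no-op on zero bin 22", {
  tmpl <- cosmic_template(fx_bins)
  pure <- as_bin_spectrum(tmpl * 50)
  out <- subtract_cosmic(pure)
  expect_equal(out$counts, rep(0, 22))
  terr <- as_bin_spectrum(c(rep(10, 21), 0))
  expect_equal(subtract_cosmic(terr)$counts, terr$counts)
})

test_that("cosmic subtraction recovers terrestrial bins with a known cosmic rate", {
  sc <- spot_scene(activity = c(K40 = 400, U238_series = 150, Th232_series = 300),
                   cosmic_cps = 3, pmt_cps = 0, live_time = 900, seed = 55)
  sp <- simulate_spot_spectrum(sc, fx_rm, fx_lib)
  cal <- structure(list(gain = 300, offset = 0), class = "energy_calibration")
  bs <- subtract_cosmic(rebin_to_energy(sp, cal))
  expect_equal(bs$counts[22], 0)
  flux <- as.numeric(fx_lib$flux %*% sc$activity)
  expected <- as.numeric(unclass(fx_rm) %*% flux) * 900
  big <- which(expected > 100)
  dev <- abs(bs$counts[big] - expected[big]) / sqrt(bs$var[big])
  expect_true(all(dev < 4))
  expect_gt(mean(dev < 2), 0.85)
})

test_that("PMT subtraction is the identity on zero background and nulls an equal spectrum", {
  x <- as_bin_spectrum(c(rep(30, 21), 0), live_time = 10)
  expect_equal(subtract_pmt_background(x, rep(0, 22))$counts, x$counts)
  out <- subtract_pmt_background(x, x$counts / x$live_time)
  expect_equal(out$counts, rep(0, 22))
})

test_that("unfolding with the identity response returns the count rates", {
  ident <- structure(diag(22), edges = bin_edges(fx_bins),
                     class = c("response_matrix", "matrix", "array"))
  bs <- as_bin_spectrum(seq(22, 1) * 10, live_time = 10)
  es <- unfold(bs, ident)
  expect_equal(es$flux, seq(22, 1), tolerance = 1e-12)
})

test_that("noise-free forward counts unfold back to the input flux within 1%", {
  flux <- as.numeric(fx_lib$flux %*% c(500, 300, 800))
  counts <- as.numeric(unclass(fx_rm) %*% flux) * 300
  es <- unfold(as_bin_spectrum(counts, live_time = 300), fx_rm)
  nz <- flux > 0
  expect_lt(max(abs(es$flux[nz] - flux[nz]) / max(flux)), 0.01)
})

test_that("kerma statistical error at ~600 nGy/h and 300 s is of order a few percent", {
  act <- c(K40 = 300, U238_series = 80, Th232_series = 900)
  sc <- spot_scene(activity = act, live_time = 300, seed = 77)
  sp <- simulate_spot_spectrum(sc, fx_rm, fx_lib)
  est <- process_spot_spectrum(sp, fx_rm, fx_lib, pmt_cps = 1)
  expect_gt(est$kerma_total, 400)
  expect_lt(est$kerma_total, 800)
  rel <- est$kerma_total_se / est$kerma_total
  expect_gt(rel, 0.002)
  expect_lt(rel, 0.1)
})

test_that("a pure Th library flux yields a_Th alone; exact mixtures equal the direct 3x3 solve", {
  es <- as_energy_spectrum(fx_lib$flux[, "Th232_series"] * 1000)
  est <- estimate_activities(es, fx_lib)
  expect_equal(unname(est$activity[["Th232_series"]]), 1000, tolerance = 2e-3)
  expect_equal(unname(est$activity[["K40"]]), 0, tolerance = 1e-6)
  expect_equal(unname(est$activity[["U238_series"]]), 0, tolerance = 1e-6)

  set.seed(12)
  m3 <- interference_matrix(fx_lib)
  for (rep in 1:5) {
    truth <- runif(3, 0, 3000)
    es <- as_energy_spectrum(as.numeric(fx_lib$flux %*% truth))
    est <- estimate_activities(es, fx_lib)
    g <- vapply(carborne:::.GROUPS, function(g) sum(es$flux[g]), numeric(1))
    direct <- solve(m3, g)   # independent oracle: direct linear inversion
    expect_equal(unname(est$activity), unname(direct), tolerance = 1e-3)
    expect_equal(unname(est$activity), truth, tolerance = 1e-3)
  }
})

test_that("interference matrix is near-triangular with a strictly positive Th column", {
  m3 <- interference_matrix(fx_lib)
  expect_true(all(m3[, "Th232_series"] > 0))
  expect_equal(m3["g16_18", "K40"], 0)
  expect_equal(m3["g20", "K40"], 0)
})

test_that("contribution percentages follow the printed-row rounding rule and sum to 100 +/- 1", {
  comp <- c(40, 558, 1543)
  expect_equal(round(100 * comp / sum(comp)), c(2, 26, 72))
  set.seed(8)
  for (rep in 1:10) {
    truth <- runif(3, 10, 3000)
    es <- as_energy_spectrum(as.numeric(fx_lib$flux %*% truth))
    est <- estimate_activities(es, fx_lib)
    expect_lte(abs(sum(est$contribution_pct) - 100), 1)
  }
})

test_that("total kerma is the sum of its components", {
  expect_equal(kerma_total(c(40, 558, 1543)), 2141)
  expect_equal(kerma_total(c(40, 521, 1460)), 2021)
  expect_equal(kerma_total(c(0, 0, 0)), 0)
  es <- as_energy_spectrum(as.numeric(fx_lib$flux %*% c(500, 300, 800)))
  est <- estimate_activities(es, fx_lib)
  expect_equal(kerma_total(est), est$kerma_total)
  expect_equal(est$kerma_total, sum(est$kerma))
})

test_that("raising the generator Th activity raises the estimated Th activity and kerma", {
  est_at <- function(th) {
    sc <- spot_scene(activity = c(K40 = 300, U238_series = 100, Th232_series = th),
                     live_time = 600, seed = 90)
    sp <- simulate_spot_spectrum(sc, fx_rm, fx_lib)
    process_spot_spectrum(sp, fx_rm, fx_lib, pmt_cps = 1)
  }
  e1 <- est_at(200); e2 <- est_at(800); e3 <- est_at(2000)
  expect_lt(e1$activity[["Th232_series"]], e2$activity[["Th232_series"]])
  expect_lt(e2$activity[["Th232_series"]], e3$activity[["Th232_series"]])
  expect_lt(e1$kerma[["Th232_series"]], e2$kerma[["Th232_series"]])
  expect_lt(e2$kerma[["Th232_series"]], e3$kerma[["Th232_series"]])
})

test_that("negative residual groups floor activities at zero with a flag", {
  flux <- rep(0, 22); flux[14] <- fx_lib$flux[14, "K40"] * 100
  flux[16] <- 1e-9  # nothing real in the Bi/Tl groups
  es <- as_energy_spectrum(flux)
  est <- estimate_activities(es, fx_lib)
  expect_equal(unname(est$activity[["Th232_series"]]), 0)
  expect_true(any(grepl("floored", est$flags)) || est$activity[["U238_series"]] >= 0)
})
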