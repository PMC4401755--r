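#' Write / read a pulse-height spectrum in the plain-text SPE-like dialect
#'
#' Two-column channel/count text with a small `#key: value` header carrying
#' the live time and a gain hint:
#' ```
#' #format: carborne-spe 1
#' #live_time_s: 300
#' #gain_hint_ch_per_mev: 300
#' channel count
#' 1 12
#' ...
#' ```
#' The round trip is lossless.
#'
#' @param spectrum A `ph_spectrum`.
#' @param path Output file path.
#' @return `write_spectrum()` returns `path` invisibly; `read_spectrum()`
#'   returns a `ph_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ph_spectrum"))
  hdr <- c("#format: carborne-spe 1",
           sprintf("#live_time_s: %.6g", spectrum$live_time),
           sprintf("#gain_hint_ch_per_mev: %.6g", spectrum$gain_hint),
           "channel count")
  body <- paste(seq_along(spectrum$counts), spectrum$counts)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  get_field <- function(key) {
    ln <- grep(paste0("^#", key, ":"), lines)
    if (length(ln) != 1) {
      abort(sprintf("missing or duplicated header field '%s' (header lines 1-%d)",
                    key, length(hdr)))
    }
    as.numeric(sub(paste0("^#", key, ":\\s*"), "", lines[ln]))
  }
  fmt <- grep("^#format: carborne-spe", lines)
  if (length(fmt) != 1 || fmt != 1) abort("malformed header at line 1: expected '#format: carborne-spe 1'")
  live <- get_field("live_time_s")
  gain <- get_field("gain_hint_ch_per_mev")
  colhdr <- which(lines == "channel count")
  if (length(colhdr) != 1) abort(sprintf("missing 'channel count' column header near line %d", length(hdr) + 1))
  body <- lines[(colhdr + 1):length(lines)]
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(parts) != 2)
  if (length(bad)) abort(sprintf("malformed spectrum row at line %d", colhdr + bad[1]))
  counts <- as.numeric(vapply(parts, `[`, character(1), 2))
  if (any(is.na(counts))) abort(sprintf("non-numeric count at line %d", colhdr + which(is.na(counts))[1]))
  ph_spectrum(counts, live_time = live, gain_hint = gain)
}

#' Write / read a survey track CSV
#'
#' Column layout `iso_time, lat, lon, counts_30s` in decimal degrees
#' (WGS-84, 4-decimal output precision).
#'
#' @param track Survey points tibble (as from [simulate_survey_track()]).
#' @param path File path.
#' @return `write_track()` returns `path` invisibly; `read_track()` a tibble
#'   with columns `time`, `lat`, `lon`, `counts`.
#' @export
write_track <- function(track, path) {
  out <- tibble(iso_time = format(track$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                lat = round(track$lat, 4), lon = round(track$lon, 4),
                counts_30s = track$counts)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(
    iso_time = readr::col_character(), lat = readr::col_double(),
    lon = readr::col_double(), counts_30s = readr::col_integer()))
  tibble(time = as.POSIXct(d$iso_time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
         lat = d$lat, lon = d$lon, counts = d$counts_30s)
}

#' Pipeline configuration
#'
#' All tunable constants of the end-to-end synthetic pipeline with
#' documented defaults; serialises losslessly to YAML.
#'
#' @param seed Root seed; all stage seeds derive from it.
#' @param histories Monte Carlo histories per nuclide for the flux library.
#' @param n_spots Number of spot scenes.
#' @param resolution FWHM fraction at 0.662 MeV.
#' @param gain Nominal gain (channels/MeV).
#' @param cosmic_cps,pmt_cps Instrument background rates.
#' @param smoothing_order Fourier smoothing order.
#' @param tol Successive-approximation relative tolerance.
#' @param shielding,conversion,dcf,hours_per_year Survey constants.
#' @param speed_kmh,interval_s Track parameters.
#' @param cell_deg Raster cell size (degrees).
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(seed = 1L, histories = 2e5, n_spots = 8,
                            resolution = 0.07, gain = 300,
                            cosmic_cps = 2, pmt_cps = 1,
                            smoothing_order = 120, tol = 1e-3,
                            shielding = 1.47, conversion = 0.00244,
                            dcf = 0.7, hours_per_year = 8760,
                            speed_kmh = 40, interval_s = 30,
                            cell_deg = 0.005) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full synthetic survey pipeline
#'
#' Orchestrates every stage end to end on generated data: flux library and
#' response matrix, coastal activity field, spot scenes (simulated,
#' calibrated, unfolded, estimated), survey track (counts to kerma to annual
#' dose), regional summaries and the gridded dose map. Deterministic under
#' the config seed; every written artifact is stamped with the config hash.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, CSV artifacts are written
#'   (`spots.csv` in the Table-1 column layout, `track_doses.csv`,
#'   `region_summary.csv`, `dose_raster.csv`).
#' @return List with elements `spots` (tibble of activity estimates),
#'   `track`, `regions`, `raster`, `library`, `response`, `config_hash`,
#'   invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- rlang::hash(unclass(config))
  bins <- energy_bins()
  lib <- build_unit_flux_library(bins, histories = config$histories,
                                 seed = derive_seed(config$seed, "library"))
  rm22 <- build_response_matrix(bins, resolution_model(config$resolution))
  constants <- survey_constants(config$shielding, config$conversion,
                                config$dcf, config$hours_per_year)

  field <- coastal_field(seed = derive_seed(config$seed, "field"))

  # spot scenes: activities drawn around the field's range, live time by level
  spots <- with_local_seed(derive_seed(config$seed, "spots"), {
    purrr::map_dfr(seq_len(config$n_spots), function(i) {
      hot <- i <= ceiling(config$n_spots / 3)
      act <- if (hot) {
        c(K40 = runif(1, 200, 1000), U238_series = runif(1, 200, 1300),
          Th232_series = runif(1, 500, 2400))
      } else {
        c(K40 = runif(1, 50, 700), U238_series = runif(1, 25, 400),
          Th232_series = runif(1, 40, 700))
      }
      sc <- spot_scene(activity = act, surface = if (hot) "sand" else "soil",
                       cosmic_cps = config$cosmic_cps, pmt_cps = config$pmt_cps,
                       gain = config$gain, resolution = config$resolution,
                       live_time = if (hot) 300 else 600,
                       seed = derive_seed(config$seed, paste0("spot", i)))
      sp <- simulate_spot_spectrum(sc, rm22, lib)
      est <- process_spot_spectrum(sp, rm22, lib, pmt_cps = config$pmt_cps,
                                   nominal_gain = config$gain,
                                   n_terms = config$smoothing_order,
                                   surface = sc$surface)
      tidy(est) %>% mutate(spot = i, live_time = sc$live_time,
                           true_k40 = act[["K40"]], true_u238 = act[["U238_series"]],
                           true_th232 = act[["Th232_series"]])
    })
  })

  route <- field_route(field)
  track <- simulate_survey_track(field, route, lib$kerma_coeff,
                                 speed_kmh = config$speed_kmh,
                                 interval_s = config$interval_s,
                                 constants = constants,
                                 seed = derive_seed(config$seed, "track")) %>%
    kerma_from_counts(constants) %>%
    annual_effective_dose(constants) %>%
    mutate(region = ifelse(.data$lon <= stats::quantile(field$lon, 0.25),
                           "coastal", "inland"))
  regions <- summarize_regions(track)
  raster <- grid_dose_map(track, cell_deg = config$cell_deg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- function(df) dplyr::mutate(df, config_hash = hash)
    readr::write_csv(stamp(spots), file.path(out_dir, "spots.csv"))
    readr::write_csv(stamp(track), file.path(out_dir, "track_doses.csv"))
    readr::write_csv(stamp(regions), file.path(out_dir, "region_summary.csv"))
    readr::write_csv(stamp(as_tibble(raster)), file.path(out_dir, "dose_raster.csv"))
  }
  invisible(list(spots = spots, track = track, regions = regions,
                 raster = raster, library = lib, response = rm22,
                 field = field, config_hash = hash))
}

#' Serialize the response matrix and flux library as plain text
#'
#' Versioned whitespace-delimited tables with a `#key: value` header carrying
#' the bin edges, so libraries can be regenerated, inspected and diffed.
#' Round trips are lossless to full double precision.
#'
#' @param matrix A `response_matrix`.
#' @param library A `unit_flux_library`.
#' @param path File path.
#' @return Writers return `path` invisibly; readers the reconstructed object.
#' @export
write_response_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "response_matrix"))
  res <- attr(matrix, "resolution")
  hdr <- c("#format: carborne-response 1",
           paste0("#edges: ", paste(format(attr(matrix, "edges"), digits = 17), collapse = " ")),
           paste0("#resolution_k: ", format(res$k, digits = 17)),
           paste0("#area_cm2: ", format(attr(matrix, "area_cm2"), digits = 17)),
           paste0("#length_cm: ", format(attr(matrix, "length_cm"), digits = 17)))
  body <- apply(unclass(matrix), 1, function(r) paste(format(r, digits = 17), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_response_matrix
#' @export
read_response_matrix <- function(path) {
  lines <- readLines(path)
  if (!grepl("^#format: carborne-response", lines[1])) {
    abort("malformed header at line 1: expected '#format: carborne-response 1'")
  }
  field <- function(key) {
    ln <- grep(paste0("^#", key, ":"), lines, value = TRUE)
    if (length(ln) != 1) abort(sprintf("missing header field '%s'", key))
    as.numeric(strsplit(sub(paste0("^#", key, ":\\s*"), "", ln), "\\s+")[[1]])
  }
  res <- structure(list(k = field("resolution_k")), class = "resolution_model")
  out <- build_response_matrix(energy_bins(), res,
                               area_cm2 = field("area_cm2"),
                               length_cm = field("length_cm"))
  body <- lines[!grepl("^#", lines)]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  if (!isTRUE(all.equal(field("edges"), attr(out, "edges")))) {
    abort("bin edges in file differ from the package bin scheme")
  }
  stopifnot(all(dim(m) == c(22, 22)))
  out[, ] <- m
  out
}

#' @rdname write_response_matrix
#' @export
write_flux_library <- function(library, path) {
  stopifnot(inherits(library, "unit_flux_library"))
  hdr <- c("#format: carborne-fluxlib 1",
           paste0("#edges: ", paste(format(library$edges, digits = 17), collapse = " ")),
           paste0("#histories: ", format(library$histories, digits = 17)),
           paste0("#seed: ", library$seed),
           paste0("#kerma_coeff: ", paste(format(library$kerma_coeff, digits = 17), collapse = " ")),
           "bin nuclide primary scattered se")
  rows <- tidy(library)
  se <- as.numeric(library$flux_se[cbind(rows$bin, match(rows$nuclide, colnames(library$flux_se)))])
  body <- paste(rows$bin, rows$nuclide,
                format(rows$primary, digits = 17),
                format(rows$scattered, digits = 17),
                format(se, digits = 17))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_response_matrix
#' @export
read_flux_library <- function(path) {
  lines <- readLines(path)
  if (!grepl("^#format: carborne-fluxlib", lines[1])) {
    abort("malformed header at line 1: expected '#format: carborne-fluxlib 1'")
  }
  field <- function(key) {
    ln <- grep(paste0("^#", key, ":"), lines, value = TRUE)
    as.numeric(strsplit(sub(paste0("^#", key, ":\\s*"), "", ln), "\\s+")[[1]])
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[body != "bin nuclide primary scattered se"]
  parts <- strsplit(trimws(body), "\\s+")
  bin <- as.integer(vapply(parts, `[`, character(1), 1))
  nuc <- vapply(parts, `[`, character(1), 2)
  primary <- scattered <- se2 <- matrix(0, 22, 3, dimnames = list(NULL, .NUCLIDES))
  for (i in seq_along(bin)) {
    primary[bin[i], nuc[i]] <- as.numeric(parts[[i]][3])
    scattered[bin[i], nuc[i]] <- as.numeric(parts[[i]][4])
    se2[bin[i], nuc[i]] <- as.numeric(parts[[i]][5])^2
  }
  bins <- energy_bins()
  if (!isTRUE(all.equal(field("edges"), bin_edges(bins)))) {
    abort("bin edges in file differ from the package bin scheme")
  }
  kc <- setNames(field("kerma_coeff"), .NUCLIDES)
  structure(list(flux = primary + scattered, primary = primary,
                 scattered = scattered, flux_se = sqrt(se2),
                 kerma_coeff = kc, bins = bins, soil = soil_model(),
                 histories = field("histories"), seed = field("seed"),
                 edges = bin_edges(bins)),
            class = "unit_flux_library")
}
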