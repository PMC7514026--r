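#' Benchmark synthetic-city specification
#'
#' The stock synthetic benchmark used by the package's end-to-end harness:
#' a 3 km x 3 km city rasterised at 60 x 60 cells, three crime-generating
#' POI classes (pubs/bars/inns, fast-food outlets, bus stops — the classic
#' night-time-economy trio) with weights 1, 0.6 and 0.4, plus twelve
#' zero-weight clutter classes with their own spatial structure, and 2000
#' crime incidents drawn from the exponential-kernel superposition density
#' at the conventional 75 m bandwidth. Parameter recovery on this city (do
#' the three generating classes survive select-10? does the sparse model
#' beat the alcohol-only baseline?) is the package's analysis-level check.
#'
#' @param seed integer seed for the generator.
#' @param n_cells_per_side grid resolution (default 60; 150 matches the
#'   full-resolution study geometry but is slower).
#' @param n_crimes number of incidents (default 2000).
#' @param n_clutter number of zero-weight clutter classes (default 12).
#' @return a [synthetic_city_spec()].
#' @export
benchmark_city_spec <- function(seed, n_cells_per_side = 60,
                                n_crimes = 2000, n_clutter = 12) {
  area <- study_area(0, 0, side = 3000, n_cells_per_side = n_cells_per_side)
  clutter_names <- c(
    "Clothing Stores", "Footwear Stores", "Cafes", "Car Parks", "Banks",
    "Pharmacies", "Hair and Beauty Services", "Bookmakers", "Supermarkets",
    "Hotels", "Charitable Organisations", "Cash Machines",
    "Counselling and Advice Services", "Nightclubs", "Restaurants",
    "Post Offices", "Dentists")[seq_len(n_clutter)]
  classes <- data.frame(
    class_name = c("Pubs, Bars and Inns", "Fast Food and Takeaway Outlets",
                   "Bus Stops", clutter_names),
    n_points = c(60, 70, 80, rep(50, length(clutter_names))),
    layout = c("clustered", "clustered", "clustered",
               rep("clustered", length(clutter_names))),
    stringsAsFactors = FALSE
  )
  synthetic_city_spec(
    area = area, classes = classes,
    true_weights = c("Pubs, Bars and Inns" = 1,
                     "Fast Food and Takeaway Outlets" = 0.6,
                     "Bus Stops" = 0.4),
    kernel = kernel_spec("exponential", area$kde_bandwidth),
    n_crimes = n_crimes, seed = seed
  )
}

RUN_MODES <- c("city", "combined", "sweep-alpha", "sweep-kernel",
               "sweep-bandwidth", "synth-benchmark", "anonymise-audit")

#' Validate a pipeline run configuration
#'
#' A run configuration is a plain named list (typically read from a YAML
#' key-value file, see [read_run_config()]) with fields:
#' \describe{
#'   \item{mode}{one of `city`, `combined`, `sweep-alpha`, `sweep-kernel`,
#'     `sweep-bandwidth`, `synth-benchmark`, `anonymise-audit`.}
#'   \item{out_dir}{output directory (created if absent).}
#'   \item{seed}{integer seed.}
#'   \item{crime_csv, poi_csv, crs, centre_x, centre_y}{inputs for `city`
#'     and the sweeps; `combined` instead takes `cities`, a list of such
#'     entries each with a `name`.}
#'   \item{side, n_cells_per_side, bandwidth_divisor}{study-area geometry
#'     (defaults 3000, 150, 40).}
#'   \item{kernel, bandwidth}{kernel shape and bandwidth (defaults
#'     exponential, side/divisor).}
#'   \item{K, n_repeats, k_select}{cross-validation design (defaults 2,
#'     100, 10).}
#'   \item{alcohol_classes}{baseline class name(s).}
#'   \item{alphas, kernels, bandwidths}{sweep grids for the sweep modes.}
#'   \item{strict_paper}{logical, see [cross_validate_city()].}
#' }
#' Validation failures are reported before any computation.
#'
#' @param config named list.
#' @return the validated config (with defaults filled in), class
#'   `run_config`.
#' @export
run_config <- function(config) {
  if (is.null(config$mode) || length(config$mode) != 1 ||
      !(config$mode %in% RUN_MODES)) {
    stop_poicrime("run_config: mode must be exactly one of: ",
                  paste(RUN_MODES, collapse = ", "),
                  class = "poicrime_config_error")
  }
  if (is.null(config$out_dir)) {
    stop_poicrime("run_config: out_dir is required",
                  class = "poicrime_config_error")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$side <- config$side %||% 3000
  config$n_cells_per_side <- config$n_cells_per_side %||% 150
  config$bandwidth_divisor <- config$bandwidth_divisor %||% 40
  ## note: [[ ]] avoids partial matching (config$bandwidth would match
  ## bandwidth_divisor, config$kernel would match a sweep's kernels list)
  config$kernel <- config[["kernel"]] %||% "exponential"
  config$bandwidth <- config[["bandwidth"]] %||%
    (config$side / config$bandwidth_divisor)
  config$K <- config$K %||% 2
  config$n_repeats <- config$n_repeats %||% 100
  config$k_select <- config$k_select %||% 10
  config$crs <- config$crs %||% "bng"
  config$alcohol_classes <- config$alcohol_classes %||% "Pubs, Bars and Inns"
  config$strict_paper <- isTRUE(config$strict_paper)
  needs_city_inputs <- config$mode %in%
    c("city", "sweep-alpha", "sweep-kernel", "sweep-bandwidth")
  if (needs_city_inputs) {
    for (fld in c("crime_csv", "poi_csv", "centre_x", "centre_y")) {
      if (is.null(config[[fld]])) {
        stop_poicrime("run_config: field '", fld, "' required for mode ",
                      config$mode, class = "poicrime_config_error")
      }
    }
    for (fld in c("crime_csv", "poi_csv")) {
      if (!file.exists(config[[fld]])) {
        stop_poicrime("run_config: file not found: ", config[[fld]],
                      class = "poicrime_config_error")
      }
    }
  }
  if (config$mode == "combined") {
    if (is.null(config$cities) || length(config$cities) < 2) {
      stop_poicrime("run_config: combined mode needs >= 2 cities",
                    class = "poicrime_config_error")
    }
    for (ct in config$cities) {
      for (fld in c("name", "crime_csv", "poi_csv", "centre_x", "centre_y")) {
        if (is.null(ct[[fld]])) {
          stop_poicrime("run_config: city entry missing field '", fld, "'",
                        class = "poicrime_config_error")
        }
      }
      if (!file.exists(ct$crime_csv) || !file.exists(ct$poi_csv)) {
        stop_poicrime("run_config: missing city input file for ", ct$name,
                      class = "poicrime_config_error")
      }
    }
  }
  structure(config, class = "run_config")
}

#' Read a run configuration from a YAML key-value file
#'
#' @param path YAML file; keys as documented in [run_config()].
#' @param overrides named list merged over the file's values.
#' @return validated `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  run_config(cfg)
}

load_city_bundle <- function(name, crime_csv, poi_csv, centre_x, centre_y,
                             config) {
  area <- study_area(centre_x, centre_y, side = config$side,
                     n_cells_per_side = config$n_cells_per_side,
                     bandwidth_divisor = config$bandwidth_divisor)
  pad <- config$bandwidth
  crimes_df <- read_crime_table(crime_csv, crs = config$crs)
  poi <- read_poi_table(poi_csv)
  sets <- poi_class_sets(poi$records)
  sets <- lapply(sets, window_points, area = area, pad = pad)
  crimes <- window_points(
    point_set(crimes_df$x, crimes_df$y, label = "crime"), area, pad)
  city_bundle(name, sets, crimes, area)
}

write_cv_csv <- function(res, path) {
  df <- data.frame(
    run = seq_along(res$proposed$per_run_r2),
    r2_proposed = res$proposed$per_run_r2,
    r2_baseline = res$baseline$per_run_r2,
    selected = vapply(res$proposed$per_run_selected,
                      paste, character(1), collapse = "; "))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Execute a configured pipeline run
#'
#' Validates the configuration, executes the corresponding module chain,
#' writes all output tables as headered CSV under `config$out_dir`, and
#' writes a `manifest.json` recording the mode, seed, parameter echo, input
#' file MD5 hashes, log notes (dropped records, empty-class columns), and
#' the MD5 of every artefact. Two runs with the same configuration and seed
#' produce byte-identical artefacts.
#'
#' @param config a [run_config()] (or a plain list, validated here).
#' @return the manifest, invisibly (list; also written as JSON).
#' @export
run_pipeline <- function(config) {
  config <- run_config(unclass(config))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  kernel <- kernel_spec(config$kernel, config$bandwidth)
  cvc <- cv_config(K = config$K, n_repeats = config$n_repeats,
                   seed = config$seed, k_select = config$k_select)
  artefacts <- character(0)
  notes <- character(0)
  emit <- function(name) {
    path <- file.path(config$out_dir, name)
    artefacts <<- c(artefacts, path)
    path
  }
  inputs <- character(0)

  if (config$mode %in% c("city", "sweep-alpha", "sweep-kernel",
                         "sweep-bandwidth")) {
    inputs <- c(config$crime_csv, config$poi_csv)
    bundle <- load_city_bundle(config$name %||% "city", config$crime_csv,
                               config$poi_csv, config$centre_x,
                               config$centre_y, config)
    notes <- c(notes, sprintf("classes=%d crimes=%d",
                              length(bundle$class_sets),
                              length(bundle$crimes)))
  }

  if (config$mode == "city") {
    res <- cross_validate_city(bundle, cvc, kernel,
                               alcohol_classes = config$alcohol_classes,
                               strict_paper = config$strict_paper)
    write_cv_csv(res, emit("cv_runs.csv"))
    utils::write.csv(data.frame(
      model = c("proposed", "baseline"),
      mean_r2 = c(res$proposed$mean_r2, res$baseline$mean_r2),
      sd_r2 = c(res$proposed$sd_r2, res$baseline$sd_r2)),
      emit("cv_summary.csv"), row.names = FALSE)
    utils::write.csv(count_selected_classes(res$proposed$per_run_selected),
                     emit("selected_classes.csv"), row.names = FALSE)
    ## full-data fit for the coefficient table
    basis <- suppressWarnings(build_basis(
      bundle$class_sets, bundle$area, kernel, rate = TRUE))
    y <- rate_values(suppressWarnings(
      estimate_density(bundle$crimes, bundle$area, kernel)))
    sel <- suppressWarnings(
      select_alpha_for_support(basis, y, k = cvc$k_select,
                               strict_paper = config$strict_paper))
    fit <- suppressWarnings(ols_refit(basis, y, sel$selected, sel$alpha))
    if (sel$fallback) notes <- c(notes, "alpha search used fallback path")
    write_model_fit_csv(fit, emit("model_fit.csv"))
  } else if (config$mode == "combined") {
    bundles <- lapply(config$cities, function(ct)
      load_city_bundle(ct$name, ct$crime_csv, ct$poi_csv, ct$centre_x,
                       ct$centre_y, config))
    inputs <- unlist(lapply(config$cities, function(ct)
      c(ct$crime_csv, ct$poi_csv)))
    loco <- leave_one_city_out(bundles, cvc, kernel)
    utils::write.csv(loco, emit("leave_one_city_out.csv"), row.names = FALSE)
    occ <- count_selected_classes(attr(loco, "fits"))
    utils::write.csv(occ, emit("selected_classes.csv"), row.names = FALSE)
  } else if (config$mode == "sweep-alpha") {
    alphas <- as.numeric(config$alphas %||%
                           c(0, 10^seq(-4, 0, length.out = 9)))
    tab <- alpha_sweep(bundle, alphas, cvc, kernel)
    utils::write.csv(tab, emit("alpha_sweep.csv"), row.names = FALSE)
  } else if (config$mode == "sweep-kernel") {
    kinds <- config$kernels %||% KERNEL_KINDS
    tab <- kernel_sweep(bundle, kinds, cvc, bandwidth = config$bandwidth)
    utils::write.csv(tab, emit("kernel_sweep.csv"), row.names = FALSE)
  } else if (config$mode == "sweep-bandwidth") {
    hs <- as.numeric(config$bandwidths %||%
                       (config$side / c(60, 50, 40, 30, 20)))
    tab <- bandwidth_sweep(bundle, hs, cvc, kind = config$kernel)
    utils::write.csv(tab, emit("bandwidth_sweep.csv"), row.names = FALSE)
  } else if (config$mode == "synth-benchmark") {
    spec <- benchmark_city_spec(config$seed,
                                n_cells_per_side =
                                  min(config$n_cells_per_side, 60))
    bundle <- generate_city(spec, "synthville")
    res <- cross_validate_city(bundle, cvc, kernel_spec(config$kernel,
                                                        config$bandwidth))
    write_cv_csv(res, emit("cv_runs.csv"))
    utils::write.csv(count_selected_classes(res$proposed$per_run_selected),
                     emit("selected_classes.csv"), row.names = FALSE)
    imp <- improvement_stats(res$baseline$mean_r2, res$proposed$mean_r2,
                             bundle$city_name)
    utils::write.csv(cbind(imp$per_city,
                           mean_improvement = imp$mean_improvement),
                     emit("improvement.csv"), row.names = FALSE)
  } else if (config$mode == "anonymise-audit") {
    spec <- benchmark_city_spec(config$seed,
                                n_cells_per_side =
                                  min(config$n_cells_per_side, 60))
    bundle <- generate_city(spec, "synthville", anonymise = TRUE)
    s <- displacement_summary(bundle$displacements)
    utils::write.csv(data.frame(statistic = c("mean", "median", "p90"),
                                metres = c(s$mean, s$median, s$p90)),
                     emit("displacement_summary.csv"), row.names = FALSE)
    utils::write.csv(s$bins, emit("displacement_histogram.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    mode = config$mode,
    seed = config$seed,
    strict_paper = config$strict_paper,
    parameters = list(
      side = config$side, n_cells_per_side = config$n_cells_per_side,
      bandwidth_divisor = config$bandwidth_divisor, kernel = config$kernel,
      bandwidth = config$bandwidth, K = config$K,
      n_repeats = config$n_repeats, k_select = config$k_select,
      alcohol_classes = config$alcohol_classes, crs = config$crs),
    inputs = lapply(stats::setNames(inputs, basename(inputs)), function(p)
      unname(tools::md5sum(p))),
    notes = notes,
    artefacts = lapply(stats::setNames(artefacts, basename(artefacts)),
                       function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Hour-by-weekday tabulation of timestamped crime records
#'
#' Descriptive only — no model stage consumes it. Open police extracts are
#' aggregated to the month and cannot be tabulated this way; the operation
#' therefore requires records that still carry an hour-resolution timestamp
#' (non-anonymised or synthetic data).
#'
#' @param records data.frame with a `timestamp` column (`POSIXct`, or
#'   strings parseable as `"%Y-%m-%d %H:%M"` / `"%Y-%m-%d %H:%M:%S"`).
#' @return 7 x 24 integer matrix; rows Monday..Sunday, columns hours 0-23.
#' @export
hourly_profile <- function(records) {
  if (!is.data.frame(records) || !("timestamp" %in% names(records))) {
    stop_poicrime("hourly_profile: records lack a 'timestamp' column; ",
                  "open police data is aggregated monthly and does not ",
                  "carry time of day — hour-resolution timestamps are only ",
                  "available for non-anonymised or synthetic inputs")
  }
  ts <- records$timestamp
  if (!inherits(ts, "POSIXt")) {
    ts <- as.POSIXct(as.character(ts), tz = "UTC",
                     tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"))
  }
  if (length(ts) && anyNA(ts)) {
    stop_poicrime("hourly_profile: unparseable timestamps present")
  }
  days <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
            "Saturday", "Sunday")
  out <- matrix(0L, nrow = 7, ncol = 24,
                dimnames = list(days, sprintf("%02d", 0:23)))
  if (length(ts)) {
    dow <- (as.POSIXlt(ts)$wday + 6L) %% 7L + 1L # Monday = 1
    hr <- as.POSIXlt(ts)$hour + 1L
    for (i in seq_along(ts)) out[dow[i], hr[i]] <- out[dow[i], hr[i]] + 1L
  }
  out
}
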