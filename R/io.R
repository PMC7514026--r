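#' Crime type used throughout the analysis
#'
#' Violent and sexual offences are the modelled category; robbery is a
#' separate source category and is excluded by default because it is
#' acquisitive rather than reactive in nature, so the default filter simply
#' does not include it.
#' @export
VIOLENCE_CRIME_TYPE <- "Violence and sexual offences"

CRIME_REQUIRED_COLS <- c("crime id", "month", "longitude", "latitude",
                         "crime type")
CRIME_OPTIONAL_COLS <- c("reported by", "falls within", "lsoa code",
                         "lsoa name", "last outcome category")

#' Read an open-police-data crime extract
#'
#' Reads a crime CSV in the open police data dialect (columns `Crime ID`,
#' `Month`, `Reported by`, `Falls within`, `Longitude`, `Latitude`,
#' `LSOA code`, `LSOA name`, `Crime type`, `Last outcome category`; header
#' matching is case-insensitive), keeps only the requested crime types,
#' projects WGS84 longitude/latitude to planar metres, and drops (and counts)
#' records with unparseable coordinates.
#'
#' @param path path to the CSV file.
#' @param crime_type_filter character vector of crime-type categories to
#'   retain (default: violence and sexual offences only, which excludes
#'   robbery — a separate source category).
#' @param crs coordinate system for the projection, see [lonlat_to_planar()].
#'   Use `"none"` when the longitude/latitude columns already hold planar
#'   metres (synthetic exports).
#' @return data.frame with columns `crime_id`, `month`, `reported_by`,
#'   `falls_within`, `x`, `y`, `lsoa_code`, `lsoa_name`, `crime_type`,
#'   `outcome`; attribute `n_dropped` counts records removed for unparseable
#'   coordinates.
#' @export
read_crime_table <- function(path, crime_type_filter = VIOLENCE_CRIME_TYPE,
                             crs = "bng") {
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  names(raw) <- tolower(trimws(names(raw)))
  missing_cols <- setdiff(CRIME_REQUIRED_COLS, names(raw))
  if (length(missing_cols)) {
    stop_poicrime("crime table schema error, missing columns: ",
                  paste(missing_cols, collapse = ", "),
                  class = "poicrime_schema_error")
  }
  if (nrow(raw) == 0L) {
    warning("read_crime_table: empty file ", path)
    out <- data.frame(crime_id = character(), month = character(),
                      reported_by = character(), falls_within = character(),
                      x = numeric(), y = numeric(),
                      lsoa_code = character(), lsoa_name = character(),
                      crime_type = character(), outcome = character())
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  opt <- function(col) {
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  lon <- suppressWarnings(as.numeric(raw[["longitude"]]))
  lat <- suppressWarnings(as.numeric(raw[["latitude"]]))
  ok <- is.finite(lon) & is.finite(lat)
  n_dropped <- sum(!ok)
  month <- raw[["month"]]
  bad_month <- ok & !grepl("^\\d{4}-\\d{2}$", month)
  if (any(bad_month)) {
    stop_poicrime("crime table: months not in YYYY-MM form: ",
                  paste(unique(month[bad_month]), collapse = ", "))
  }
  xy <- lonlat_to_planar(lon[ok], lat[ok], crs = crs)
  out <- data.frame(
    crime_id = raw[["crime id"]][ok],
    month = month[ok],
    reported_by = opt("reported by")[ok],
    falls_within = opt("falls within")[ok],
    x = xy$x, y = xy$y,
    lsoa_code = opt("lsoa code")[ok],
    lsoa_name = opt("lsoa name")[ok],
    crime_type = raw[["crime type"]][ok],
    outcome = opt("last outcome category")[ok],
    stringsAsFactors = FALSE
  )
  out <- out[out$crime_type %in% crime_type_filter, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Default column mapping for POI tables
#'
#' POI tables carry a point location in planar metres (Ordnance-Survey-style
#' easting/northing), a venue name, and a three-level class hierarchy
#' (class within category within group). The mapping can be overridden for
#' other column layouts.
#' @export
POI_DEFAULT_COLS <- c(x = "easting", y = "northing", name = "name",
                      class_name = "class", category = "category",
                      group = "group")

#' Read a classed point-of-interest table
#'
#' @param path path to the CSV file.
#' @param col_map named character vector mapping the internal field names
#'   (`x`, `y`, `name`, `class_name`, `category`, `group`) to the file's
#'   column names (matched case-insensitively); see [POI_DEFAULT_COLS].
#' @return list with `records` (data.frame with columns `x`, `y`, `name`,
#'   `class_name`, `category`, `group`; duplicate points retained) and
#'   `hierarchy` (distinct `(class_name, category, group)` rows). A class
#'   mapped to two different categories (or a category to two groups) raises
#'   a consistency error listing the offenders.
#' @export
read_poi_table <- function(path, col_map = POI_DEFAULT_COLS) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  names(raw) <- tolower(trimws(names(raw)))
  col_map <- stats::setNames(tolower(col_map), names(col_map))
  missing_cols <- setdiff(unname(col_map), names(raw))
  if (length(missing_cols)) {
    stop_poicrime("poi table schema error, missing columns: ",
                  paste(missing_cols, collapse = ", "),
                  class = "poicrime_schema_error")
  }
  empty <- list(
    records = data.frame(x = numeric(), y = numeric(), name = character(),
                         class_name = character(), category = character(),
                         group = character()),
    hierarchy = data.frame(class_name = character(), category = character(),
                           group = character()))
  if (nrow(raw) == 0L) return(empty)
  records <- data.frame(
    x = as.numeric(raw[[col_map[["x"]]]]),
    y = as.numeric(raw[[col_map[["y"]]]]),
    name = raw[[col_map[["name"]]]],
    class_name = raw[[col_map[["class_name"]]]],
    category = raw[[col_map[["category"]]]],
    group = raw[[col_map[["group"]]]],
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(records$class_name))) {
    stop_poicrime("poi table: empty class names")
  }
  hierarchy <- unique(records[c("class_name", "category", "group")])
  rownames(hierarchy) <- NULL
  dup_class <- unique(hierarchy$class_name[duplicated(hierarchy$class_name)])
  if (length(dup_class)) {
    stop_poicrime("poi hierarchy inconsistency: class(es) mapped to more ",
                  "than one (category, group): ",
                  paste(dup_class, collapse = ", "),
                  class = "poicrime_hierarchy_error")
  }
  cat_grp <- unique(hierarchy[c("category", "group")])
  dup_cat <- unique(cat_grp$category[duplicated(cat_grp$category)])
  if (length(dup_cat)) {
    stop_poicrime("poi hierarchy inconsistency: categor(ies) mapped to more ",
                  "than one group: ", paste(dup_cat, collapse = ", "),
                  class = "poicrime_hierarchy_error")
  }
  list(records = records, hierarchy = hierarchy)
}

#' Group POI records into per-class point sets
#'
#' @param records data.frame as returned by [read_poi_table()].
#' @param classes optional character vector fixing which classes (and their
#'   order) to return; defaults to the sorted distinct classes present.
#' @return named list of [point_set()]s.
#' @export
poi_class_sets <- function(records, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(records$class_name))
  out <- lapply(classes, function(cl) {
    sel <- records$class_name == cl
    point_set(records$x[sel], records$y[sel], label = cl)
  })
  stats::setNames(out, classes)
}

#' Write crime incidents in the open-police-data CSV dialect
#'
#' Inverse of [read_crime_table()]: planar coordinates are unprojected to
#' WGS84 longitude/latitude (unless `crs = "none"`), and standard column
#' names are emitted, so synthetic cities exercise the real input path
#' end-to-end.
#'
#' @param points a [point_set()] of crime incidents (planar metres).
#' @param path output CSV path.
#' @param month year-month string stamped on every record.
#' @param crime_type crime category stamped on every record.
#' @param reported_by reporting-force string.
#' @param crs see [planar_to_lonlat()].
#' @return `path`, invisibly.
#' @export
write_crime_csv <- function(points, path, month = "2024-06",
                            crime_type = VIOLENCE_CRIME_TYPE,
                            reported_by = "Synthetic Constabulary",
                            crs = "bng") {
  stopifnot(inherits(points, "point_set"))
  n <- length(points)
  ll <- planar_to_lonlat(points$x, points$y, crs = crs)
  df <- data.frame(
    `Crime ID` = sprintf("synth-%06d", seq_len(n)),
    `Month` = rep(month, n),
    `Reported by` = rep(reported_by, n),
    `Falls within` = rep(reported_by, n),
    `Longitude` = sprintf("%.10f", ll$lon),
    `Latitude` = sprintf("%.10f", ll$lat),
    `LSOA code` = rep("", n), `LSOA name` = rep("", n),
    `Crime type` = rep(crime_type, n),
    `Last outcome category` = rep("Under investigation", n),
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write POI point sets as a classed POI CSV
#'
#' @param class_sets named list of [point_set()]s (names are class names).
#' @param path output CSV path.
#' @param hierarchy optional data.frame `(class_name, category, group)`;
#'   classes absent from it get category `"Uncategorised"`, group `"Other"`.
#' @return `path`, invisibly.
#' @export
write_poi_csv <- function(class_sets, path, hierarchy = NULL) {
  rows <- lapply(class_sets, function(p) {
    n <- length(p)
    if (n == 0L) return(NULL)
    cat_ <- "Uncategorised"; grp <- "Other"
    if (!is.null(hierarchy)) {
      hit <- match(p$label, hierarchy$class_name)
      if (!is.na(hit)) {
        cat_ <- hierarchy$category[hit]; grp <- hierarchy$group[hit]
      }
    }
    data.frame(
      Name = sprintf("%s %d", p$label, seq_len(n)),
      Class = rep(p$label, n), Category = rep(cat_, n), Group = rep(grp, n),
      Easting = sprintf("%.6f", p$x), Northing = sprintf("%.6f", p$y),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(Name = character(), Class = character(),
                     Category = character(), Group = character(),
                     Easting = character(), Northing = character())
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a fitted sparse model as a (class, coefficient) CSV
#'
#' @param fit a `model_fit` (see [ols_refit()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_model_fit_csv <- function(fit, path) {
  stopifnot(inherits(fit, "model_fit"))
  df <- data.frame(
    class = c("(Intercept)", fit$selected_classes),
    coefficient = c(fit$intercept, unname(fit$ols_coefficients)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Bundled ten-city cross-validation benchmark
#'
#' Reference table of mean split-half cross-validation R^2 (with standard
#' deviations) for the alcohol-outlet-only baseline and the ten-class sparse
#' POI model over the central 3 km x 3 km of ten large UK cities, together
#' with the published per-city percentage improvements. Shipped so that the
#' improvement arithmetic ([improvement_stats()]) can be reproduced without
#' access to the licensed source data.
#'
#' @return data.frame with columns `city`, `baseline_mean`, `baseline_sd`,
#'   `model_mean`, `model_sd`, `improvement_pct`.
#' @export
uk_city_benchmark <- function() {
  path <- system.file("extdata", "uk_city_benchmark.csv",
                      package = "poicrime", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
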