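#' Specification of a synthetic city
#'
#' Defines the generative ground truth from which POI layouts and crime
#' incidents are drawn: a study area, a set of POI classes with abundances
#' and layout families, per-class crime weights, a kernel, and a seed. Crimes
#' are drawn from the superposition density
#' \deqn{C(x) \propto \sum_i w_i\, K(\|x - p_i\|),}
#' the sum running over all POIs, each carrying its class weight. The
#' generator exists so that every downstream stage (density estimation,
#' selection, cross-validation) is testable end-to-end with a known answer,
#' which licensed real-city data cannot provide.
#'
#' @param area a [study_area()].
#' @param classes data.frame with columns `class_name`, `n_points`, `layout`;
#'   `layout` is one of `"uniform"`, `"clustered"`, or
#'   `"collinear_with:<class>"` (the latter places each point within
#'   `collinear_offset` metres of a random point of the referenced class, so
#'   the two density maps are strongly correlated — emulating, e.g., clothing
#'   and footwear stores sharing shopping streets).
#' @param true_weights named non-negative numeric: crime weight per class
#'   (shared by all POIs of the class); classes absent from it get weight 0.
#' @param kernel a [kernel_spec()] (shape of the influence decay).
#' @param n_crimes number of crime incidents to draw.
#' @param seed base integer seed; every stage derives sub-seeds from it
#'   ([derive_seed()]).
#' @param n_clusters,cluster_sd clustered-layout parameters: number of
#'   cluster centres and the isotropic Gaussian scatter (metres) around them.
#' @param collinear_offset radius (metres) of the disc within which a
#'   collinear class scatters around its reference class.
#' @return object of class `synthetic_city_spec`.
#' @export
synthetic_city_spec <- function(area, classes, true_weights, kernel,
                                n_crimes, seed,
                                n_clusters = 5, cluster_sd = 150,
                                collinear_offset = 10) {
  stopifnot(inherits(area, "study_area"), inherits(kernel, "kernel_spec"),
            is.data.frame(classes),
            all(c("class_name", "n_points", "layout") %in% names(classes)),
            n_crimes >= 0)
  w <- stats::setNames(rep(0, nrow(classes)), classes$class_name)
  w[names(true_weights)] <- true_weights
  if (any(!is.finite(w)) || any(w < 0)) {
    stop_poicrime("synthetic_city_spec: weights must be finite and >= 0")
  }
  if (n_crimes > 0 && sum(w * classes$n_points) <= 0) {
    stop_poicrime("synthetic_city_spec: n_crimes > 0 requires at least one ",
                  "populated class with positive weight")
  }
  structure(list(
    area = area, classes = classes, true_weights = w, kernel = kernel,
    n_crimes = as.integer(n_crimes), seed = as.integer(seed),
    n_clusters = n_clusters, cluster_sd = cluster_sd,
    collinear_offset = collinear_offset
  ), class = "synthetic_city_spec")
}

## Uniform draw over the padded study square.
runif_area <- function(n, area, pad) {
  half <- area$side / 2 + pad
  list(x = stats::runif(n, area$centre_x - half, area$centre_x + half),
       y = stats::runif(n, area$centre_y - half, area$centre_y + half))
}

#' Generate the POI layout of a synthetic city
#'
#' Draws one [point_set()] per class, deterministically given the spec seed
#' (each class uses its own derived sub-stream, so adding a class does not
#' perturb the others). Layout families: `uniform` (i.i.d. over the padded
#' area), `clustered` (uniform cluster centres, Gaussian scatter), and
#' `collinear_with:<class>` (points within a small disc around random points
#' of an earlier class).
#'
#' @param spec a [synthetic_city_spec()].
#' @return named list of `point_set`s, in the order of `spec$classes`.
#' @export
generate_poi_layout <- function(spec) {
  stopifnot(inherits(spec, "synthetic_city_spec"))
  area <- spec$area
  pad <- spec$kernel$bandwidth
  half <- area$side / 2 + pad
  out <- list()
  for (i in seq_len(nrow(spec$classes))) {
    cl <- spec$classes$class_name[i]
    n <- spec$classes$n_points[i]
    layout <- spec$classes$layout[i]
    out[[cl]] <- with_seed(derive_seed(spec$seed, "layout", cl), {
      if (n == 0L) {
        point_set(label = cl)
      } else if (layout == "uniform") {
        p <- runif_area(n, area, pad)
        point_set(p$x, p$y, label = cl)
      } else if (layout == "clustered") {
        centres <- runif_area(spec$n_clusters, area, pad)
        ## scatter that lands outside the padded square is redrawn, so the
        ## class keeps exactly n points, all strictly interior (clamping
        ## would pile points onto the closed max edge, which the half-open
        ## window then drops)
        xs <- numeric(0); ys <- numeric(0)
        while (length(xs) < n) {
          m <- n - length(xs)
          pick <- sample.int(spec$n_clusters, m, replace = TRUE)
          x <- stats::rnorm(m, centres$x[pick], spec$cluster_sd)
          y <- stats::rnorm(m, centres$y[pick], spec$cluster_sd)
          inside <- x >= area$centre_x - half & x < area$centre_x + half &
            y >= area$centre_y - half & y < area$centre_y + half
          xs <- c(xs, x[inside]); ys <- c(ys, y[inside])
        }
        point_set(xs, ys, label = cl)
      } else if (startsWith(layout, "collinear_with:")) {
        ref <- sub("^collinear_with:", "", layout)
        if (is.null(out[[ref]]) || length(out[[ref]]) == 0L) {
          stop_poicrime("generate_poi_layout: class '", cl,
                        "' is collinear with undefined or empty class '",
                        ref, "'")
        }
        parent <- out[[ref]]
        xs <- numeric(0); ys <- numeric(0)
        while (length(xs) < n) { # redraw offsets leaving the padded square
          m <- n - length(xs)
          pick <- sample.int(length(parent), m, replace = TRUE)
          r <- spec$collinear_offset * sqrt(stats::runif(m))
          th <- stats::runif(m, 0, 2 * pi)
          x <- parent$x[pick] + r * cos(th)
          y <- parent$y[pick] + r * sin(th)
          inside <- x >= area$centre_x - half & x < area$centre_x + half &
            y >= area$centre_y - half & y < area$centre_y + half
          xs <- c(xs, x[inside]); ys <- c(ys, y[inside])
        }
        point_set(xs, ys, label = cl)
      } else {
        stop_poicrime("generate_poi_layout: unknown layout '", layout, "'")
      }
    })
  }
  out
}

#' Draw crime incidents from the superposition density
#'
#' Exact mixture sampling from the density proportional to
#' `sum_i w_i K(||x - p_i|| / h)`: a POI is selected with probability
#' proportional to its class weight, then an isotropic offset is added whose
#' radial law matches the planar kernel profile (closed-form inversion where
#' available, rejection sampling otherwise; see [sample_kernel_radius()]
#' internals). Draws landing outside the padded study square are resampled,
#' keeping the generative density consistent with the padded estimation
#' window. Deterministic given the spec seed.
#'
#' @param spec a [synthetic_city_spec()].
#' @param layout named list of `point_set`s from [generate_poi_layout()].
#' @return a `point_set` labelled `"crime"` with exactly `spec$n_crimes`
#'   points.
#' @export
sample_crimes <- function(spec, layout) {
  stopifnot(inherits(spec, "synthetic_city_spec"))
  w_class <- spec$true_weights
  poi_x <- numeric(0); poi_y <- numeric(0); poi_w <- numeric(0)
  for (cl in names(layout)) {
    p <- layout[[cl]]
    w <- if (cl %in% names(w_class)) w_class[[cl]] else 0
    if (w > 0 && length(p) > 0) {
      poi_x <- c(poi_x, p$x); poi_y <- c(poi_y, p$y)
      poi_w <- c(poi_w, rep(w, length(p)))
    }
  }
  if (spec$n_crimes > 0 && sum(poi_w) <= 0) {
    stop_poicrime("sample_crimes: all weights zero")
  }
  area <- spec$area
  pad <- spec$kernel$bandwidth
  half <- area$side / 2 + pad
  with_seed(derive_seed(spec$seed, "crimes"), {
    xs <- numeric(0); ys <- numeric(0)
    need <- spec$n_crimes
    while (need > 0) {
      pick <- sample.int(length(poi_w), need, replace = TRUE,
                         prob = poi_w / sum(poi_w))
      r <- sample_kernel_radius(spec$kernel, need)
      th <- stats::runif(need, 0, 2 * pi)
      x <- poi_x[pick] + r * cos(th)
      y <- poi_y[pick] + r * sin(th)
      inside <- x >= area$centre_x - half & x < area$centre_x + half &
        y >= area$centre_y - half & y < area$centre_y + half
      xs <- c(xs, x[inside]); ys <- c(ys, y[inside])
      need <- spec$n_crimes - length(xs)
    }
    point_set(xs, ys, label = "crime")
  })
}

#' Snap crimes to their nearest anonymisation targets
#'
#' Emulates the open-data privacy step: each incident is replaced by the
#' nearest of a fixed set of snap targets (POIs and/or road-centre points),
#' ties broken by lowest target index. The returned displacement distances
#' support quantisation-noise analysis ([displacement_summary()]).
#'
#' @param crimes a `point_set` of true incident locations.
#' @param snap_targets a non-empty `point_set` of snap targets.
#' @return list with `points` (snapped `point_set`, label preserved),
#'   `displacements` (numeric vector, metres, one per crime), and
#'   `target_index` (which target each crime snapped to).
#' @export
anonymise_crimes <- function(crimes, snap_targets) {
  stopifnot(inherits(crimes, "point_set"), inherits(snap_targets, "point_set"))
  if (length(snap_targets) == 0L) {
    stop_poicrime("anonymise_crimes: snap_targets is empty")
  }
  n <- length(crimes)
  idx <- integer(n); disp <- numeric(n)
  if (n > 0) {
    chunk <- 2048L
    for (start in seq(1L, n, by = chunk)) {
      sel <- start:min(n, start + chunk - 1L)
      d2 <- outer(crimes$x[sel], snap_targets$x, `-`)^2 +
        outer(crimes$y[sel], snap_targets$y, `-`)^2
      best <- max.col(-d2, ties.method = "first")
      idx[sel] <- best
      disp[sel] <- sqrt(d2[cbind(seq_along(sel), best)])
    }
  }
  list(
    points = point_set(snap_targets$x[idx], snap_targets$y[idx],
                       label = crimes$label),
    displacements = disp,
    target_index = idx
  )
}

#' Pool all POIs of a layout into one point set
#'
#' Convenience for building anonymisation snap targets from a generated
#' layout (optionally together with extra road-centre points).
#'
#' @param layout named list of `point_set`s.
#' @param extra optional additional `point_set` appended after the POIs.
#' @return a single `point_set` labelled `"snap_targets"`.
#' @export
pool_points <- function(layout, extra = NULL) {
  x <- unlist(lapply(layout, `[[`, "x"), use.names = FALSE)
  y <- unlist(lapply(layout, `[[`, "y"), use.names = FALSE)
  if (!is.null(extra)) {
    x <- c(x, extra$x); y <- c(y, extra$y)
  }
  point_set(x, y, label = "snap_targets")
}

#' Assemble a city bundle from a synthetic specification
#'
#' Runs the full generator: POI layout, crime sampling, and (optionally) the
#' anonymisation step with the POIs as snap targets. The result is a
#' `city_bundle`, the container consumed by the evaluation module.
#'
#' @param spec a [synthetic_city_spec()].
#' @param city_name name recorded in the bundle.
#' @param anonymise snap crimes to the nearest POI, as open police data does.
#' @return object of class `city_bundle`: `city_name`, `class_sets` (named
#'   list of `point_set`s), `crimes` (`point_set`), `area`, and — when
#'   `anonymise = TRUE` — `displacements` plus the unsnapped `true_crimes`.
#' @export
generate_city <- function(spec, city_name = "synthville", anonymise = FALSE) {
  layout <- generate_poi_layout(spec)
  crimes <- sample_crimes(spec, layout)
  bundle <- list(city_name = city_name, class_sets = layout,
                 crimes = crimes, area = spec$area,
                 true_weights = spec$true_weights)
  if (anonymise) {
    anon <- anonymise_crimes(crimes, pool_points(layout))
    bundle$true_crimes <- crimes
    bundle$crimes <- anon$points
    bundle$displacements <- anon$displacements
  }
  structure(bundle, class = "city_bundle")
}

#' @export
print.city_bundle <- function(x, ...) {
  cat(sprintf("city_bundle '%s': %d POI classes, %d crimes\n",
              x$city_name, length(x$class_sets), length(x$crimes)))
  invisible(x)
}
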