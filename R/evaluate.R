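#' Cross-validation configuration
#'
#' The default design mirrors the evaluation protocol for city-specific
#' models: 2-fold splits of the points themselves (half the POIs of every
#' class and half the crimes train, the other half tests), repeated 100
#' times with fresh random splits. `K = 2` keeps enough points in the test
#' half for a reliable density estimate.
#'
#' @param K number of folds (`>= 2`, default 2).
#' @param n_repeats number of independent re-splits (default 100).
#' @param seed base seed for the split sub-streams.
#' @param k_select number of POI classes the sparse model selects
#'   (default 10).
#' @return object of class `cv_config`.
#' @export
cv_config <- function(K = 2, n_repeats = 100, seed = 1, k_select = 10) {
  stopifnot(K >= 2, n_repeats >= 1, k_select >= 1)
  structure(list(K = as.integer(K), n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), k_select = as.integer(k_select)),
            class = "cv_config")
}

#' Assemble a city bundle from point data
#'
#' @param city_name city label.
#' @param class_sets named list of per-class [point_set()]s (names unique).
#' @param crimes crime [point_set()].
#' @param area the city's [study_area()].
#' @return object of class `city_bundle`.
#' @export
city_bundle <- function(city_name, class_sets, crimes, area) {
  nm <- vapply(class_sets, function(p) p$label, character(1))
  if (anyDuplicated(nm)) {
    stop_poicrime("city_bundle: duplicate class names")
  }
  structure(list(city_name = city_name,
                 class_sets = stats::setNames(class_sets, nm),
                 crimes = crimes, area = area),
            class = "city_bundle")
}

#' Partition point sets into K random near-equal parts
#'
#' Every point set is partitioned independently, uniformly at random, into
#' `K` parts whose sizes differ by at most one; the union of the parts
#' restores the input. Deterministic given `seed` (each set draws from its
#' own derived sub-stream, so the partition of one set does not depend on
#' the others).
#'
#' @param sets named list of [point_set()]s.
#' @param K number of parts.
#' @param seed integer seed.
#' @return list (same names as `sets`) of lists of `K` `point_set`s.
#' @export
split_points <- function(sets, K, seed) {
  stopifnot(K >= 2)
  out <- vector("list", length(sets))
  names(out) <- names(sets)
  for (i in seq_along(sets)) {
    p <- sets[[i]]
    n <- length(p)
    fold <- with_seed(derive_seed(seed, "split-set", p$label), {
      if (n == 0L) integer(0) else rep_len(seq_len(K), n)[sample.int(n)]
    })
    out[[i]] <- lapply(seq_len(K), function(f) {
      keep <- fold == f
      point_set(p$x[keep], p$y[keep], label = p$label)
    })
  }
  out
}

#' Coefficient of determination between density maps
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares about the mean of
#' the observed map; both maps are compared at the common grid samples. May
#' be negative (a model worse than the constant mean).
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return scalar R^2.
#' @export
r2_density <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop_poicrime("r2_density: length mismatch")
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0) stop_poicrime("r2_density: observed map has zero variance")
  1 - sum((observed - predicted)^2) / sst
}

## Internal cross-validation engine shared by cross_validate_city and the
## sweeps. `fitters` is a named list of functions(basis_train, y_train) ->
## list(predict = function(basis_test) numeric, selected = chr, support = int).
## Density scale: unless strict_paper, each half's KDE is put on the
## full-data incident-rate scale (values x point count x inverse sampling
## fraction) so train and test densities are directly comparable; strict
## mode uses the uncompensated per-point densities.
cv_engine <- function(bundle, cfg, kernel, fitters, strict_paper = FALSE) {
  area <- bundle$area
  pad <- kernel$bandwidth
  K <- cfg$K
  res <- lapply(fitters, function(f) {
    list(r2 = numeric(0), selected = list(), support = integer(0))
  })
  n_empty_columns <- 0L
  all_sets <- c(bundle$class_sets, list(.crime = bundle$crimes))
  for (rep_i in seq_len(cfg$n_repeats)) {
    parts <- split_points(all_sets, K, derive_seed(cfg$seed, "cv-split", rep_i))
    for (fold in seq_len(K)) {
      halves <- list(
        train = list(frac = (K - 1) / K,
                     pick = function(pp) do.call(rbind, lapply(
                       setdiff(seq_len(K), fold), function(f)
                         cbind(pp[[f]]$x, pp[[f]]$y)))),
        test = list(frac = 1 / K,
                    pick = function(pp) cbind(pp[[fold]]$x, pp[[fold]]$y)))
      mats <- lapply(halves, function(h) {
        sf <- if (strict_paper) 1 else 1 / h$frac
        class_sets <- lapply(names(bundle$class_sets), function(cl) {
          xy <- h$pick(parts[[cl]])
          window_points(point_set(xy[, 1], xy[, 2], label = cl), area, pad)
        })
        crime_xy <- h$pick(parts$.crime)
        crimes <- window_points(
          point_set(crime_xy[, 1], crime_xy[, 2], label = "crime"), area, pad)
        basis <- withCallingHandlers(
          build_basis(class_sets, area, kernel, scale_factor = sf,
                      rate = !strict_paper),
          warning = function(w) {
            n_empty_columns <<- n_empty_columns + 1L
            invokeRestart("muffleWarning")
          })
        cg <- suppressWarnings(
          estimate_density(crimes, area, kernel, scale_factor = sf))
        y <- if (strict_paper) flatten_density(cg) else rate_values(cg)
        list(basis = basis, y = y)
      })
      for (nm in names(fitters)) {
        ft <- fitters[[nm]](mats$train$basis, mats$train$y)
        r2 <- r2_density(ft$predict(mats$test$basis), mats$test$y)
        res[[nm]]$r2 <- c(res[[nm]]$r2, r2)
        res[[nm]]$selected <- c(res[[nm]]$selected, list(ft$selected))
        res[[nm]]$support <- c(res[[nm]]$support, ft$support)
      }
    }
  }
  lapply(res, function(r) {
    structure(list(
      per_run_r2 = r$r2,
      mean_r2 = mean(r$r2),
      sd_r2 = stats::sd(r$r2),
      per_run_selected = r$selected,
      per_run_support = r$support,
      K = K, n_repeats = cfg$n_repeats,
      n_empty_columns = n_empty_columns
    ), class = "cv_result")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: mean R^2 = %.4f (sd %.4f) over %d runs\n",
              x$mean_r2, x$sd_r2, length(x$per_run_r2)))
  invisible(x)
}

## Fitter: select-k LASSO + OLS refit. Falls back to an intercept-only
## (train-mean) predictor if the selection comes back empty.
fitter_sparse <- function(k_select, strict_paper = FALSE) {
  function(basis, y) {
    sel <- suppressWarnings(
      select_alpha_for_support(basis, y, k = k_select,
                               strict_paper = strict_paper))
    if (length(sel$selected) == 0L) {
      mu <- mean(y)
      return(list(predict = function(b) rep(mu, nrow(as_basis_matrix(b)$X)),
                  selected = character(0), support = 0L))
    }
    fit <- suppressWarnings(ols_refit(basis, y, sel$selected, sel$alpha))
    list(predict = function(b) predict_model(fit, b),
         selected = sel$selected, support = length(sel$selected))
  }
}

## Fitter: univariate alcohol-outlet baseline.
fitter_baseline <- function(alcohol_classes) {
  function(basis, y) {
    b <- as_basis_matrix(basis)
    idx <- match(alcohol_classes, b$classes)
    if (anyNA(idx)) {
      stop_poicrime("baseline: bundle lacks alcohol class(es): ",
                    paste(alcohol_classes[is.na(idx)], collapse = ", "))
    }
    fit <- baseline_fit(b$X[, idx, drop = FALSE], y,
                        label = paste(alcohol_classes, collapse = " + "))
    slope <- unname(fit$ols_coefficients)
    list(predict = function(bt) {
      bt <- as_basis_matrix(bt)
      rowSums(bt$X[, idx, drop = FALSE]) * slope + fit$intercept
    }, selected = alcohol_classes, support = 1L)
  }
}

#' Repeated split-half cross-validation of one city
#'
#' For every repeat and fold: densities are estimated from the training
#' part of each point set, the sparse model (penalty tuned for `k_select`
#' classes, then OLS-refit) and the alcohol-only baseline are fitted to the
#' training crime density, predictions are formed on the test-part basis and
#' scored (R^2) against the test-part crime density. Each half's density is
#' scaled to the full-data incident-rate scale unless `strict_paper`.
#'
#' @param bundle a [city_bundle()] (crime count should be at least `2 K`).
#' @param cfg a [cv_config()].
#' @param kernel a [kernel_spec()].
#' @param alcohol_classes class name(s) forming the baseline regressor.
#' @param strict_paper disable the sampling-fraction density compensation
#'   and bracket the penalty search on `[0, 1]`.
#' @return list with elements `proposed` and `baseline`, each a `cv_result`
#'   (`per_run_r2`, `mean_r2`, `sd_r2`, `per_run_selected`).
#' @export
cross_validate_city <- function(bundle, cfg, kernel,
                                alcohol_classes = "Pubs, Bars and Inns",
                                strict_paper = FALSE) {
  stopifnot(inherits(bundle, "city_bundle"), inherits(cfg, "cv_config"))
  if (length(bundle$crimes) < 2 * cfg$K) {
    stop_poicrime("cross_validate_city: too few crimes for K = ", cfg$K)
  }
  cv_engine(bundle, cfg, kernel,
            fitters = list(
              proposed = fitter_sparse(cfg$k_select, strict_paper),
              baseline = fitter_baseline(alcohol_classes)),
            strict_paper = strict_paper)
}

#' Leave-one-city-out evaluation of the combined model
#'
#' Builds, for each held-out city, a combined design from the remaining
#' cities: each city contributes its full-data flattened crime vector and
#' basis matrix rows, with class columns aligned by name over the union of
#' all cities' class vocabularies (a class absent from a city contributes a
#' zero column for that city's rows). The sparse model is fitted to the
#' combined data and scored on the held-out city's full-data basis and crime
#' density.
#'
#' @param bundles list of [city_bundle()]s (at least 2).
#' @param cfg a [cv_config()] (`k_select` is used; the split fields are not).
#' @param kernel a [kernel_spec()].
#' @return data.frame with columns `city` and `r2`; attribute `fits` holds
#'   the per-held-out-city `model_fit`s, attribute `classes` the aligned
#'   class vocabulary.
#' @export
leave_one_city_out <- function(bundles, cfg, kernel) {
  stopifnot(length(bundles) >= 2)
  classes <- sort(unique(unlist(lapply(bundles, function(b)
    names(b$class_sets)))))
  if (length(classes) == 0L) {
    stop_poicrime("leave_one_city_out: empty class vocabulary")
  }
  pad <- kernel$bandwidth
  per_city <- lapply(bundles, function(b) {
    sets <- lapply(classes, function(cl) {
      p <- b$class_sets[[cl]] %||% point_set(label = cl)
      window_points(p, b$area, pad)
    })
    basis <- suppressWarnings(
      build_basis(sets, b$area, kernel, rate = TRUE))
    cg <- suppressWarnings(
      estimate_density(window_points(b$crimes, b$area, pad), b$area, kernel))
    list(basis = basis, y = rate_values(cg))
  })
  names(per_city) <- vapply(bundles, `[[`, character(1), "city_name")
  fits <- list()
  r2 <- numeric(length(bundles))
  for (i in seq_along(bundles)) {
    train <- per_city[-i]
    X <- do.call(rbind, lapply(train, function(p) p$basis$matrix))
    colnames(X) <- classes
    y <- unlist(lapply(train, `[[`, "y"), use.names = FALSE)
    sel <- suppressWarnings(
      select_alpha_for_support(X, y, k = cfg$k_select))
    fit <- suppressWarnings(ols_refit(X, y, sel$selected, sel$alpha))
    fits[[names(per_city)[i]]] <- fit
    r2[i] <- r2_density(predict_model(fit, per_city[[i]]$basis),
                        per_city[[i]]$y)
  }
  out <- data.frame(city = names(per_city), r2 = r2,
                    stringsAsFactors = FALSE)
  attr(out, "fits") <- fits
  attr(out, "classes") <- classes
  out
}

#' Sweep the L1 penalty under the cross-validation design
#'
#' For each penalty value the model is a [lasso_fit()] at that fixed
#' penalty followed by an OLS refit on its support (intercept-only when the
#' support is empty), evaluated under the same split design as
#' [cross_validate_city()].
#'
#' @param bundle a [city_bundle()].
#' @param alphas numeric vector of penalty values.
#' @param cfg a [cv_config()].
#' @param kernel a [kernel_spec()].
#' @return data.frame with columns `alpha`, `mean_r2`, `sd_r2`,
#'   `mean_support`.
#' @export
alpha_sweep <- function(bundle, alphas, cfg, kernel) {
  fitters <- lapply(alphas, function(a) {
    force(a)
    function(basis, y) {
      lf <- lasso_fit(basis, y, a)
      sel <- names(lf$coefficients[lf$coefficients != 0])
      if (length(sel) == 0L) {
        mu <- mean(y)
        return(list(predict = function(b) rep(mu, nrow(as_basis_matrix(b)$X)),
                    selected = character(0), support = 0L))
      }
      fit <- suppressWarnings(ols_refit(basis, y, sel, a))
      list(predict = function(b) predict_model(fit, b),
           selected = sel, support = length(sel))
    }
  })
  names(fitters) <- sprintf("alpha_%d", seq_along(alphas))
  res <- cv_engine(bundle, cfg, kernel, fitters)
  data.frame(
    alpha = alphas,
    mean_r2 = vapply(res, `[[`, numeric(1), "mean_r2"),
    sd_r2 = vapply(res, `[[`, numeric(1), "sd_r2"),
    mean_support = vapply(res, function(r) mean(r$per_run_support),
                          numeric(1)),
    row.names = NULL
  )
}

#' Compare kernel shapes under the cross-validation design
#'
#' One full [cross_validate_city()]-style evaluation of the proposed model
#' per kernel shape, at a fixed bandwidth; the result is sorted by decreasing
#' mean R^2, so the first row is the best-performing kernel.
#'
#' @param bundle a [city_bundle()].
#' @param kinds kernel shapes to compare (default all six).
#' @param cfg a [cv_config()].
#' @param bandwidth bandwidth in metres shared by all kernels (default: the
#'   bundle area's `kde_bandwidth`).
#' @return data.frame with columns `kind`, `mean_r2`, `sd_r2`, sorted by
#'   decreasing `mean_r2`.
#' @export
kernel_sweep <- function(bundle, kinds = KERNEL_KINDS, cfg,
                         bandwidth = NULL) {
  bandwidth <- bandwidth %||% bundle$area$kde_bandwidth
  rows <- lapply(kinds, function(kind) {
    ks <- kernel_spec(kind, bandwidth)
    res <- cv_engine(bundle, cfg, ks,
                     fitters = list(proposed = fitter_sparse(cfg$k_select)))
    data.frame(kind = kind, mean_r2 = res$proposed$mean_r2,
               sd_r2 = res$proposed$sd_r2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_r2), ]
  rownames(out) <- NULL
  out
}

#' Sweep the KDE bandwidth under the cross-validation design
#'
#' Note that scores tend to improve as the bandwidth grows because larger
#' bandwidths smooth both maps, trading spatial resolution for agreement;
#' the bandwidth should be chosen for the intended resolution, not by
#' maximising this table.
#'
#' @param bundle a [city_bundle()].
#' @param bandwidths numeric vector of bandwidths (metres).
#' @param cfg a [cv_config()].
#' @param kind kernel shape (default `"exponential"`).
#' @return data.frame with columns `bandwidth`, `mean_r2`, `sd_r2`.
#' @export
bandwidth_sweep <- function(bundle, bandwidths, cfg, kind = "exponential") {
  rows <- lapply(bandwidths, function(h) {
    res <- cv_engine(bundle, cfg, kernel_spec(kind, h),
                     fitters = list(proposed = fitter_sparse(cfg$k_select)))
    data.frame(bandwidth = h, mean_r2 = res$proposed$mean_r2,
               sd_r2 = res$proposed$sd_r2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count how often each class enters the selected top-k
#'
#' Tallies, over a list of fitted city models, how many models selected each
#' POI class; sorted by decreasing count, ties broken alphabetically.
#'
#' @param city_fits list of `model_fit`s (or character vectors of selected
#'   class names).
#' @return data.frame with columns `class` and `count`.
#' @export
count_selected_classes <- function(city_fits) {
  sel <- lapply(city_fits, function(f) {
    if (inherits(f, "model_fit")) f$selected_classes else as.character(f)
  })
  if (length(sel) == 0L) {
    return(data.frame(class = character(), count = integer()))
  }
  tab <- table(unlist(lapply(sel, unique)))
  out <- data.frame(class = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$class), ]
  rownames(out) <- NULL
  out
}

#' Percentage improvement of the sparse model over the baseline
#'
#' Per-city improvement is `100 (model - baseline) / baseline`, truncated
#' toward zero to a whole percent (the convention of the published per-city
#' tables: 16.6% prints as 16%); the overall figures are means of these
#' whole-percent values, reported to one decimal. An explicit exclusion list
#' removes named outlier cities from the second mean.
#'
#' @param baseline_means,model_means aligned numeric vectors of mean R^2
#'   (baselines must be positive).
#' @param city_names aligned character vector.
#' @param exclude city names dropped from the exclusion-mean.
#' @return list with `per_city` (data.frame `city`, `improvement_pct`),
#'   `mean_improvement`, and `mean_improvement_excluding`.
#' @export
improvement_stats <- function(baseline_means, model_means, city_names,
                              exclude = character()) {
  if (length(baseline_means) != length(model_means) ||
      length(model_means) != length(city_names)) {
    stop_poicrime("improvement_stats: inputs not aligned")
  }
  if (any(baseline_means <= 0)) {
    stop_poicrime("improvement_stats: baseline means must be positive")
  }
  pct <- trunc(100 * (model_means - baseline_means) / baseline_means)
  keep <- !(city_names %in% exclude)
  list(
    per_city = data.frame(city = city_names, improvement_pct = pct,
                          stringsAsFactors = FALSE),
    mean_improvement = round(mean(pct), 1),
    mean_improvement_excluding = round(mean(pct[keep]), 1)
  )
}

#' Summarise anonymisation displacement distances
#'
#' Mean, median (mid-average convention for even counts), 90th percentile
#' (nearest-rank on the sorted list), and a fixed-width histogram of the
#' snap displacements, for quantisation-noise analysis.
#'
#' @param displacements numeric vector of displacement distances (metres).
#' @param bin_width histogram bin width in metres (default 5); bins are
#'   half-open `[lower, upper)`.
#' @return list with `mean`, `median`, `p90`, and `bins` (data.frame
#'   `lower`, `upper`, `count`).
#' @export
displacement_summary <- function(displacements, bin_width = 5) {
  d <- as.numeric(displacements)
  stopifnot(all(is.finite(d)), all(d >= 0))
  if (length(d) == 0L) {
    return(list(mean = NA_real_, median = NA_real_, p90 = NA_real_,
                bins = data.frame(lower = numeric(), upper = numeric(),
                                  count = integer())))
  }
  upper_lim <- max(bin_width, ceiling(max(d) / bin_width) * bin_width)
  breaks <- seq(0, upper_lim + bin_width, by = bin_width) # last bin catches max
  counts <- as.integer(table(cut(d, breaks, right = FALSE,
                                 include.lowest = FALSE)))
  list(
    mean = mean(d),
    median = stats::median(d),
    p90 = nearest_rank(d, 0.9),
    bins = data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
                      count = counts)
  )
}
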