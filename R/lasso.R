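## Sparse crime-density model: L1-penalised selection of POI classes.
##
## The crime density map y (flattened over the study grid) is modelled as a
## sparse linear combination of the basis-matrix columns (per-class POI
## density maps). The fit minimises
##     (1/2n) || y - B w ||_2^2 + alpha * || w ||_1
## after standardising the columns of B and centring y (the centring is
## equivalent to an unpenalised intercept: densities are non-negative with a
## positive mean, and without centring the L1 penalty would absorb it).
## Standardisation makes selection invariant to the scale of each column.
## Coordinate descent is delegated to glmnet with standardisation disabled,
## so the objective above is optimised exactly as written.

as_basis_matrix <- function(basis) {
  if (inherits(basis, "basis_matrix")) {
    list(X = basis$matrix, classes = basis$columns)
  } else {
    X <- as.matrix(basis)
    cls <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
    list(X = X, classes = cls)
  }
}

standardise_columns <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  constant <- !is.finite(scale) | scale <= 0
  scale[constant] <- 1 # constant columns: centred to zero, coefficient 0
  list(Xs = sweep(sweep(X, 2, center), 2, scale, `/`),
       center = center, scale = scale, constant = constant)
}

#' Smallest penalty with an all-zero solution
#'
#' For the standardised, centred problem the L1 path is empty at and above
#' `alpha_max = max_j |X_j' y| / n`; this is the natural upper end of the
#' penalty bracket used by [select_alpha_for_support()], valid regardless of
#' the data scale.
#'
#' @param basis a `basis_matrix` or numeric matrix.
#' @param y response vector (flattened crime density).
#' @return non-negative scalar.
#' @export
lasso_alpha_max <- function(basis, y) {
  b <- as_basis_matrix(basis)
  if (nrow(b$X) != length(y)) stop_poicrime("lasso_alpha_max: dimension mismatch")
  s <- standardise_columns(b$X)
  yc <- y - mean(y)
  max(abs(crossprod(s$Xs, yc))) / length(y)
}

#' L1-penalised (LASSO) fit of the crime-density model
#'
#' Minimises `(1/2n)||y - Bw||^2 + alpha ||w||_1` with standardised columns
#' and centred response (see the module notes above). Coefficients are
#' reported on the standardised scale (`coefficients`, the scale on which
#' selection operates) and back-transformed to the raw scale
#' (`coefficients_raw`, with `intercept`).
#'
#' @param basis a `basis_matrix` or numeric matrix (rows = grid samples).
#' @param y numeric response, same length as `nrow(basis)`.
#' @param alpha L1 penalty weight, `>= 0`. At 0 the fit is ordinary least
#'   squares; at or above [lasso_alpha_max()] every coefficient is zero.
#' @return object of class `lasso_fit`: `alpha`, `coefficients`,
#'   `coefficients_raw`, `intercept`, `n_nonzero`, `standardisation`.
#' @export
lasso_fit <- function(basis, y, alpha) {
  b <- as_basis_matrix(basis)
  X <- b$X
  if (nrow(X) != length(y)) stop_poicrime("lasso_fit: dimension mismatch")
  if (!all(is.finite(X)) || !all(is.finite(y)) || !is.finite(alpha) ||
      alpha < 0) {
    stop_poicrime("lasso_fit: non-finite inputs or negative alpha")
  }
  n <- length(y)
  s <- standardise_columns(X)
  yc <- y - mean(y)
  amax <- max(abs(crossprod(s$Xs, yc))) / n
  if (alpha >= amax * (1 - 1e-12)) {
    ## at or above alpha_max the all-zero vector satisfies the KKT
    ## conditions exactly; no descent needed
    coefs <- stats::setNames(rep(0, ncol(X)), b$classes)
  } else if (ncol(X) == 1L) {
    ## single-regressor case has a closed form (soft thresholding)
    z <- sum(s$Xs[, 1] * yc) / n
    d <- sum(s$Xs[, 1]^2) / n
    w <- if (d > 0) sign(z) * max(0, abs(z) - alpha) / d else 0
    coefs <- stats::setNames(w, b$classes)
  } else {
    ## decreasing penalty path down to the requested alpha (warm starts keep
    ## coordinate descent accurate at small penalties)
    lam_hi <- max(amax, alpha, .Machine$double.eps)
    path <- lam_hi * 0.7^(0:24)
    lambda <- sort(unique(c(path[path > alpha], alpha)), decreasing = TRUE)
    fit <- glmnet::glmnet(s$Xs, yc, family = "gaussian", alpha = 1,
                          lambda = lambda, standardize = FALSE,
                          intercept = FALSE, thresh = 1e-12, maxit = 1e6)
    j <- which(abs(fit$lambda - alpha) <= 1e-12 * max(1, alpha))
    j <- j[length(j)]
    coefs <- stats::setNames(as.numeric(fit$beta[, j]), b$classes)
  }
  coefs[s$constant] <- 0
  coefs_raw <- coefs / s$scale
  intercept <- mean(y) - sum(coefs_raw * s$center)
  structure(list(
    alpha = alpha,
    coefficients = coefs,
    coefficients_raw = coefs_raw,
    intercept = intercept,
    n_nonzero = sum(coefs != 0),
    standardisation = list(center = s$center, scale = s$scale,
                           y_center = mean(y))
  ), class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("lasso_fit: alpha = %.6g, %d non-zero of %d coefficients\n",
              x$alpha, x$n_nonzero, length(x$coefficients)))
  invisible(x)
}

#' Binary search for the penalty selecting a fixed number of classes
#'
#' Searches the penalty bracket `[0, alpha_max]` (see [lasso_alpha_max()])
#' by bisection for the largest `alpha` whose fit has exactly `k` non-zero
#' coefficients. The support size is piecewise constant and may skip `k`; in
#' that case the visited penalty with support size nearest to `k` (preferring
#' sizes above `k`) is used and the selection is truncated to the `k`
#' largest-magnitude standardised coefficients; this fallback is flagged in
#' the result.
#'
#' @param basis a `basis_matrix` or numeric matrix with at least `k`
#'   non-constant columns.
#' @param y response vector.
#' @param k target support size (default 10).
#' @param max_steps bisection step cap (default 60).
#' @param strict_paper if `TRUE`, bracket the search on `[0, 1]` instead of
#'   the data-driven `[0, alpha_max]` (only meaningful if the response is
#'   scaled so that `alpha_max <= 1`).
#' @return list with `alpha`, `fit` (the [lasso_fit()] at `alpha`),
#'   `selected` (character vector of `<= k` class names, ordered by
#'   decreasing coefficient magnitude), `fallback` (logical), and `visited`
#'   (data.frame of the visited `(alpha, n_nonzero)` path).
#' @export
select_alpha_for_support <- function(basis, y, k = 10, max_steps = 60,
                                     strict_paper = FALSE) {
  b <- as_basis_matrix(basis)
  s <- standardise_columns(b$X)
  if (sum(!s$constant) < k) {
    stop_poicrime("select_alpha_for_support: fewer than k = ", k,
                  " usable (non-constant) columns")
  }
  hi <- if (strict_paper) 1 else lasso_alpha_max(basis, y)
  lo <- 0
  visited_alpha <- numeric(0); visited_nnz <- integer(0)
  fits <- list()
  eval_at <- function(alpha) {
    fit <- lasso_fit(basis, y, alpha)
    visited_alpha <<- c(visited_alpha, alpha)
    visited_nnz <<- c(visited_nnz, fit$n_nonzero)
    fits[[length(fits) + 1L]] <<- fit
    fit
  }
  fit_lo <- eval_at(lo)
  fit_hi <- eval_at(hi)
  best_exact <- NULL
  note_exact <- function(fit) {
    if (fit$n_nonzero == k &&
        (is.null(best_exact) || fit$alpha > best_exact$alpha)) {
      best_exact <<- fit
    }
  }
  note_exact(fit_lo); note_exact(fit_hi)
  if (fit_hi$n_nonzero >= k) {
    lo <- hi # bracket degenerate; bisection below is a no-op
  }
  steps <- 2L
  while (steps < max_steps && (hi - lo) > 1e-12 * max(hi, 1)) {
    mid <- (lo + hi) / 2
    fit_mid <- eval_at(mid)
    note_exact(fit_mid)
    if (fit_mid$n_nonzero >= k) lo <- mid else hi <- mid
    steps <- steps + 1L
  }
  if (!is.null(best_exact)) {
    fit <- best_exact
    sel <- names(sort(abs(fit$coefficients[fit$coefficients != 0]),
                      decreasing = TRUE))
    return(list(alpha = fit$alpha, fit = fit, selected = sel,
                fallback = FALSE,
                visited = data.frame(alpha = visited_alpha,
                                     n_nonzero = visited_nnz)))
  }
  ## fallback: nearest support size, preferring sizes above k
  d <- abs(visited_nnz - k)
  pref <- order(d, visited_nnz <= k, -visited_alpha)
  pick <- pref[1]
  fit <- fits[[pick]]
  nz <- abs(fit$coefficients[fit$coefficients != 0])
  sel <- names(sort(nz, decreasing = TRUE))
  sel <- sel[seq_len(min(k, length(sel)))]
  warning("select_alpha_for_support: no visited penalty gave exactly ", k,
          " classes; truncated a support of ", fit$n_nonzero)
  list(alpha = fit$alpha, fit = fit, selected = sel, fallback = TRUE,
       visited = data.frame(alpha = visited_alpha, n_nonzero = visited_nnz))
}

#' Post-selection ordinary-least-squares refit
#'
#' Refits the selected classes by unpenalised least squares (with intercept)
#' on the raw, unstandardised columns: the penalty biases coefficients toward
#' zero, so the refit restores unbiased magnitudes on the selected support.
#' Rank deficiency is resolved by the minimum-norm solution, with a warning.
#'
#' @param basis a `basis_matrix` or numeric matrix.
#' @param y response vector.
#' @param selected character vector of class names to keep (non-empty).
#' @param alpha_used penalty that produced the selection (recorded only).
#' @return object of class `model_fit`: `selected_classes`,
#'   `ols_coefficients` (named), `intercept`, `alpha_used`, `r2_train`.
#' @export
ols_refit <- function(basis, y, selected, alpha_used = NA_real_) {
  b <- as_basis_matrix(basis)
  if (length(selected) == 0L) stop_poicrime("ols_refit: empty selection")
  idx <- match(selected, b$classes)
  if (anyNA(idx)) {
    stop_poicrime("ols_refit: unknown classes: ",
                  paste(selected[is.na(idx)], collapse = ", "))
  }
  X <- cbind(`(Intercept)` = 1, b$X[, idx, drop = FALSE])
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warning("ols_refit: rank-deficient design; using minimum-norm solution")
    beta <- as.numeric(MASS::ginv(X) %*% y)
  } else {
    beta <- qr.coef(qr_x, y)
  }
  fitted <- as.numeric(X %*% beta)
  sst <- sum((y - mean(y))^2)
  structure(list(
    selected_classes = selected,
    ols_coefficients = stats::setNames(beta[-1], selected),
    intercept = unname(beta[1]),
    alpha_used = alpha_used,
    r2_train = if (sst > 0) 1 - sum((y - fitted)^2) / sst else NA_real_
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit: %d classes, train R^2 = %.4f\n",
              length(x$selected_classes), x$r2_train))
  ord <- order(abs(x$ols_coefficients), decreasing = TRUE)
  for (i in ord) {
    cat(sprintf("  %-40s %12.6g\n", x$selected_classes[i],
                x$ols_coefficients[i]))
  }
  invisible(x)
}

#' Predict a crime-density map from a fitted sparse model
#'
#' @param fit a `model_fit`.
#' @param basis a `basis_matrix` or matrix containing (at least) the fitted
#'   classes as columns.
#' @return numeric vector of predicted density values, grid order.
#' @export
predict_model <- function(fit, basis) {
  stopifnot(inherits(fit, "model_fit"))
  b <- as_basis_matrix(basis)
  idx <- match(fit$selected_classes, b$classes)
  if (anyNA(idx)) {
    stop_poicrime("predict_model: basis lacks classes: ",
                  paste(fit$selected_classes[is.na(idx)], collapse = ", "))
  }
  as.numeric(b$X[, idx, drop = FALSE] %*% fit$ols_coefficients + fit$intercept)
}

#' Alcohol-outlet-only baseline regression
#'
#' Univariate ordinary least squares of the crime density on the density of
#' the configured alcohol-outlet class(es). When several class densities are
#' supplied they are summed into a single regressor (one combined outlet
#' density). This is the reference model that the sparse multi-class model is
#' compared against.
#'
#' @param alcohol_density numeric vector (flattened alcohol-outlet density),
#'   or matrix whose columns are summed.
#' @param y response vector (flattened crime density).
#' @param label class label recorded in the fit (default
#'   `"Pubs, Bars and Inns"`).
#' @return a `model_fit` with a single selected class.
#' @export
baseline_fit <- function(alcohol_density, y, label = "Pubs, Bars and Inns") {
  x <- if (is.matrix(alcohol_density)) rowSums(alcohol_density)
       else as.numeric(alcohol_density)
  if (length(x) != length(y)) stop_poicrime("baseline_fit: length mismatch")
  if (stats::sd(x) == 0) {
    stop_poicrime("baseline_fit: zero-variance alcohol regressor")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  beta <- fit$coefficients
  sst <- sum((y - mean(y))^2)
  structure(list(
    selected_classes = label,
    ols_coefficients = stats::setNames(beta[2], label),
    intercept = unname(beta[1]),
    alpha_used = NA_real_,
    r2_train = if (sst > 0) 1 - sum(fit$residuals^2) / sst else NA_real_
  ), class = "model_fit")
}
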