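make_spec <- function(classes, weights, kernel = kernel_spec("tophat", 75),
                      n_crimes = 100, seed = 42, area = NULL, ...) {
  synthetic_city_spec(area %||% study_area(0, 0, 3000, 30), classes,
                      weights, kernel, n_crimes, seed, ...)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("layout generation is deterministic and respects counts", {
  classes <- data.frame(
    class_name = c("A", "B", "C"), n_points = c(10, 0, 25),
    layout = c("uniform", "uniform", "clustered"))
  spec <- make_spec(classes, c(A = 1))
  l1 <- generate_poi_layout(spec)
  l2 <- generate_poi_layout(spec)
  expect_identical(l1, l2)
  expect_equal(vapply(l1, length, integer(1)), c(A = 10L, B = 0L, C = 25L))
  ## all points inside the padded square
  half <- 3000 / 2 + 75
  for (p in l1) {
    expect_true(all(abs(p$x) <= half & abs(p$y) <= half))
  }
})

test_that("collinear classes produce strongly correlated density maps", {
  classes <- data.frame(
    class_name = c("A", "B"), n_points = c(40, 40),
    layout = c("clustered", "collinear_with:A"))
  spec <- make_spec(classes, c(A = 1), kernel = kernel_spec("exponential", 75),
                    seed = 9, collinear_offset = 10)
  l <- generate_poi_layout(spec)
  a <- spec$area
  dA <- flatten_density(estimate_density(l$A, a, spec$kernel))
  dB <- flatten_density(estimate_density(l$B, a, spec$kernel))
  expect_gt(cor(dA, dB), 0.9)
})

test_that("collinearity with an undefined or empty class is an error", {
  classes <- data.frame(class_name = c("A", "B"), n_points = c(0, 5),
                        layout = c("uniform", "collinear_with:A"))
  expect_error(generate_poi_layout(make_spec(classes, c(B = 1))),
               "empty class")
  classes$layout[2] <- "collinear_with:Z"
  expect_error(generate_poi_layout(make_spec(classes, c(B = 1))),
               "undefined or empty")
})

test_that("crimes from a compact kernel stay within its support", {
  classes <- data.frame(class_name = "P", n_points = 1, layout = "uniform")
  spec <- make_spec(classes, c(P = 1), kernel = kernel_spec("tophat", 75),
                    n_crimes = 300, seed = 5)
  layout <- list(P = point_set(0, 0, "P"))
  cr <- sample_crimes(spec, layout)
  expect_equal(length(cr), 300)
  expect_true(all(sqrt(cr$x^2 + cr$y^2) <= 75))
  ## determinism
  cr2 <- sample_crimes(spec, layout)
  expect_identical(cr, cr2)
})

test_that("zero-weight classes attract no crimes", {
  classes <- data.frame(class_name = c("P", "Q"), n_points = c(1, 1),
                        layout = "uniform")
  spec <- make_spec(classes, c(P = 1, Q = 0),
                    kernel = kernel_spec("tophat", 75), n_crimes = 200)
  layout <- list(P = point_set(-500, 0, "P"), Q = point_set(500, 0, "Q"))
  cr <- sample_crimes(spec, layout)
  dP <- sqrt((cr$x + 500)^2 + cr$y^2)
  expect_true(all(dP <= 75)) # all within the only weighted POI's support
  ## all weights zero errors
  spec0 <- make_spec(classes, c(P = 1), n_crimes = 10)
  expect_error(sample_crimes(spec0, list(P = point_set(label = "P"),
                                         Q = point_set(0, 0, "Q"))),
               "weights zero")
})

test_that("exponential-kernel crime distances have mean 2h and the right law", {
  h <- 75
  classes <- data.frame(class_name = "P", n_points = 1, layout = "uniform")
  spec <- make_spec(classes, c(P = 1), kernel = kernel_spec("exponential", h),
                    n_crimes = 10000, seed = 12)
  layout <- list(P = point_set(0, 0, "P")) # centre: truncation negligible
  d <- with(sample_crimes(spec, layout), sqrt(x^2 + y^2))
  ## radial law r e^(-r/h): Gamma(shape 2, scale h), mean 2h, sd h sqrt(2)
  se <- h * sqrt(2) / sqrt(10000)
  expect_lt(abs(mean(d) - 2 * h), 3 * se)
  ks_dist <- max(abs(ecdf(d)(sort(d)) -
                       pgamma(sort(d), shape = 2, scale = h)))
  expect_lt(ks_dist, 0.02)
})

test_that("radial sampling matches the analytic law for every kernel", {
  h <- 50
  cdfs <- list(
    gaussian = function(r) 1 - exp(-r^2 / (2 * h^2)),
    tophat = function(r) pmin(1, (r / h)^2),
    epanechnikov = function(r) {
      u <- pmin(r / h, 1); 2 * u^2 - u^4
    },
    exponential = function(r) pgamma(r, shape = 2, scale = h),
    linear = function(r) {
      u <- pmin(r / h, 1); 3 * u^2 - 2 * u^3
    },
    cosine = function(r) {
      u <- pmin(r / h, 1)
      a <- pi / 2
      (cos(a * u) + a * u * sin(a * u) - 1) / (a * sin(a) + cos(a) - 1)
    })
  for (kind in KERNEL_KINDS) {
    d <- withr::with_seed(31, poicrime:::sample_kernel_radius(
      kernel_spec(kind, h), 5000))
    ks_dist <- max(abs(ecdf(d)(sort(d)) - cdfs[[kind]](sort(d))))
    expect_lt(ks_dist, 0.03)
  }
})

test_that("anonymisation snaps to the nearest target and reports displacements", {
  targets <- point_set(c(0, 100, 200), c(0, 0, 0), "snap")
  crimes <- point_set(c(0, 130, 260), c(0, 0, 40), "crime")
  out <- anonymise_crimes(crimes, targets)
  expect_equal(out$target_index, c(1L, 2L, 3L))
  expect_equal(out$displacements, c(0, 30, sqrt(60^2 + 40^2)))
  expect_equal(length(out$points), length(crimes)) # count preserved
  ## single target: everything maps there, displacement = original distance
  one <- anonymise_crimes(crimes, point_set(0, 0, "s"))
  expect_true(all(one$points$x == 0 & one$points$y == 0))
  expect_equal(one$displacements, sqrt(crimes$x^2 + crimes$y^2))
})

test_that("a 30 m lattice shift displaces every crime by exactly 30 m", {
  gx <- rep(seq(0, 400, by = 100), 5)
  gy <- rep(seq(0, 400, by = 100), each = 5)
  crimes <- point_set(gx, gy, "crime")
  targets <- point_set(gx + 30, gy, "snap")
  out <- anonymise_crimes(crimes, targets)
  expect_equal(out$displacements, rep(30, 25))
})

test_that("generated city bundles are reproducible end to end", {
  spec <- benchmark_city_spec(77, n_cells_per_side = 30, n_crimes = 200)
  b1 <- generate_city(spec, anonymise = TRUE)
  b2 <- generate_city(spec, anonymise = TRUE)
  expect_identical(b1, b2)
  expect_equal(length(b1$crimes), 200)
  expect_equal(length(b1$displacements), 200)
  ## snapped crimes all coincide with POIs
  pool <- pool_points(b1$class_sets)
  expect_true(all(b1$crimes$x %in% pool$x))
})
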