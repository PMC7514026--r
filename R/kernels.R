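#' Kernel specification for two-dimensional density estimation
#'
#' Six kernel shapes are supported; each models a different law for how the
#' influence of a point decays with Euclidean distance. All are normalised so
#' that the kernel integrates to 1 over the plane, making the resulting
#' density estimates proper two-dimensional densities.
#'
#' @param kind one of `"gaussian"`, `"tophat"`, `"epanechnikov"`,
#'   `"exponential"`, `"linear"` (triangular), `"cosine"`.
#' @param bandwidth spatial scale h in metres, `> 0`. The conventional choice
#'   here is the study-area side divided by 40 (75 m for a 3 km window).
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = "exponential", bandwidth = 75) {
  kind <- match.arg(kind, KERNEL_KINDS)
  stopifnot(is.finite(bandwidth), bandwidth > 0)
  structure(list(kind = kind, bandwidth = bandwidth), class = "kernel_spec")
}

#' @rdname kernel_spec
#' @export
KERNEL_KINDS <- c("gaussian", "tophat", "epanechnikov", "exponential",
                  "linear", "cosine")

## Unnormalised radial profiles k(u), u = distance / h, all with k(0) = 1.
kernel_shape <- function(kind, u) {
  switch(kind,
    gaussian     = exp(-u^2 / 2),
    tophat       = as.numeric(u <= 1),
    epanechnikov = pmax(0, 1 - u^2),
    exponential  = exp(-u),
    linear       = pmax(0, 1 - u),
    cosine       = ifelse(u <= 1, cos(pi * u / 2), 0),
    stop_poicrime("unknown kernel kind: ", kind)
  )
}

## Planar normalising constant c(h) such that the integral of c * k(|x|/h)
## over R^2 equals 1. With I = int_0^inf u k(u) du, c = 1 / (2 pi h^2 I).
## The radial moments I are closed-form:
##   gaussian 1; tophat 1/2; epanechnikov 1/4; exponential 1;
##   linear 1/6; cosine (2 pi - 4) / pi^2.
kernel_norm_const <- function(kind, h) {
  I <- switch(kind,
    gaussian     = 1,
    tophat       = 1 / 2,
    epanechnikov = 1 / 4,
    exponential  = 1,
    linear       = 1 / 6,
    cosine       = (2 * pi - 4) / pi^2,
    stop_poicrime("unknown kernel kind: ", kind)
  )
  1 / (2 * pi * h^2 * I)
}

#' Evaluate a normalised planar kernel profile
#'
#' Returns `c(h) * k(distance / h)` where the shape `k` is the radial profile
#' of the chosen kernel and `c(h)` normalises the planar integral to 1.
#' Units: metres^-2.
#'
#' @param spec a [kernel_spec()].
#' @param distance non-negative distance(s) in metres (vectorised).
#' @return non-negative kernel density value(s), metres^-2.
#' @examples
#' ks <- kernel_spec("gaussian", 75)
#' kernel_profile(ks, 75) / kernel_profile(ks, 0) # exp(-1/2)
#' @export
kernel_profile <- function(spec, distance) {
  stopifnot(inherits(spec, "kernel_spec"), all(distance >= 0))
  kernel_norm_const(spec$kind, spec$bandwidth) *
    kernel_shape(spec$kind, distance / spec$bandwidth)
}

## Effective support radius used to prune kernel evaluation. Compact kernels
## vanish beyond h exactly; for the non-compact shapes the radius is chosen
## so the dropped tail is below 1e-12 of the peak value (gaussian
## e^(-8^2/2) ~ 1e-14, exponential e^(-30) ~ 9e-14), i.e. truncation is
## invisible at double precision working tolerances.
kernel_cutoff <- function(spec) {
  switch(spec$kind,
         gaussian = 8 * spec$bandwidth,
         exponential = 30 * spec$bandwidth,
         spec$bandwidth)
}

## Draw n radial distances from the planar kernel density, i.e. from the
## radial law proportional to r * k(r / h). Closed-form inversions:
##   gaussian    -> Rayleigh(h)                (r = h sqrt(-2 log U))
##   exponential -> Gamma(shape 2, scale h)    (mean 2h)
##   tophat      -> r = h sqrt(U)              (uniform over the disc)
## Compact shapes without a convenient inverse (epanechnikov, linear, cosine)
## use rejection from the uniform-disc proposal with acceptance k(u) <= 1.
sample_kernel_radius <- function(spec, n) {
  h <- spec$bandwidth
  switch(spec$kind,
    gaussian    = h * sqrt(-2 * log(stats::runif(n))),
    exponential = stats::rgamma(n, shape = 2, scale = h),
    tophat      = h * sqrt(stats::runif(n)),
    {
      out <- numeric(0)
      while (length(out) < n) {
        m <- max(2L * (n - length(out)), 16L)
        r <- h * sqrt(stats::runif(m))
        keep <- stats::runif(m) < kernel_shape(spec$kind, r / h)
        out <- c(out, r[keep])
      }
      out[seq_len(n)]
    }
  )
}
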