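#' Bilateral filter parameters
#'
#' @param sigma_s spatial scale in pixels (> 0). The spatial kernel is
#'   `exp(-d^2 / sigma_s^2)` -- note there is no factor 2 in the denominator,
#'   unlike the textbook Gaussian; this matches the kernel convention used
#'   throughout this package.
#' @param sigma_r range (intensity) scale (> 0), on the \[0, 1\] scale.
#' @param radius kernel half-width in pixels; defaults to `ceiling(2 * sigma_s)`.
#' @return a `bilateral_params` object.
#' @export
bilateral_params <- function(sigma_s = 1.5, sigma_r = 0.1,
                             radius = ceiling(2 * sigma_s)) {
  if (!is.numeric(sigma_s) || sigma_s <= 0) stop("sigma_s must be > 0")
  if (!is.numeric(sigma_r) || sigma_r <= 0) stop("sigma_r must be > 0")
  radius <- as.integer(radius)
  if (radius < 1) stop("radius must be >= 1")
  structure(list(sigma_s = sigma_s, sigma_r = sigma_r, radius = radius),
            class = "bilateral_params")
}

# spatial kernel weights over the truncated (2r+1)^2 window, convention
# exp(-(dx^2+dy^2)/sigma_s^2); returned as a matrix indexed by (dy, dx)
spatial_kernel <- function(sigma_s, radius) {
  d <- seq(-radius, radius)
  exp(-outer(d^2, d^2, "+") / sigma_s^2)
}

# window accumulation shared by both filters: for each offset, `contrib(a, b)`
# returns the per-pixel weight matrix for source pixels shifted by (a, b);
# weights are renormalized per pixel over the in-bounds window, so every
# output is a convex combination of inputs (no padding).
window_filter <- function(x, radius, contrib) {
  h <- nrow(x); w <- ncol(x)
  num <- matrix(0, h, w); den <- matrix(0, h, w)
  for (a in -radius:radius) {
    if (a >= h || a <= -h) next  # offset larger than the image
    ro <- max(1, 1 - a):min(h, h - a)
    ri <- ro + a
    for (b in -radius:radius) {
      if (b >= w || b <= -w) next
      co <- max(1, 1 - b):min(w, w - b)
      ci <- co + b
      wt <- contrib(a, b, ro, co, ri, ci)
      num[ro, co] <- num[ro, co] + wt * x[ri, ci]
      den[ro, co] <- den[ro, co] + wt
    }
  }
  num / den
}

#' Gaussian smoothing with a truncated, renormalized kernel
#'
#' Weighted-average smoothing with spatial weights
#' `exp(-||p - q||^2 / sigma_s^2)`, truncated at `radius` and renormalized to
#' sum to one within the in-bounds window, so each output pixel is a convex
#' combination of input pixels (edges included, no padding).
#'
#' @param img an [image_patch()], matrix, or h x w x 3 array (filtered per
#'   channel).
#' @param sigma_s spatial scale (> 0), pixels.
#' @param radius kernel half-width; default `ceiling(2 * sigma_s)`.
#' @return filtered image of the same type and shape.
#' @export
gaussian_filter <- function(img, sigma_s = 1.5, radius = ceiling(2 * sigma_s)) {
  if (!is.numeric(sigma_s) || length(sigma_s) != 1 || sigma_s <= 0)
    stop("sigma_s must be a positive number")
  radius <- as.integer(radius)
  if (radius < 1) stop("radius must be >= 1")
  kern <- spatial_kernel(sigma_s, radius)
  map_pixels(img, function(x)
    window_filter(x, radius, function(a, b, ro, co, ri, ci)
      kern[a + radius + 1, b + radius + 1]))
}

#' Unnormalized bilateral kernel weight for one pixel pair
#'
#' The product of the spatial factor `exp(-||p - q||^2 / sigma_s^2)` and the
#' range factor `exp(-(Q_p - P_q)^2 / sigma_r^2)`, where `P` is the input
#' image and `Q` the guide. Normalization over the window happens in
#' [bilateral_filter()].
#'
#' @param p,q integer coordinate pairs (row, col).
#' @param P_q input-image intensity at `q`.
#' @param Q_p guide-image intensity at `p`.
#' @param params a [bilateral_params()] object.
#' @return weight in (0, 1].
#' @export
bilateral_weight <- function(p, q, P_q, Q_p, params = bilateral_params()) {
  stopifnot(inherits(params, "bilateral_params"))
  exp(-sum((p - q)^2) / params$sigma_s^2) *
    exp(-(Q_p - P_q)^2 / params$sigma_r^2)
}

#' Edge-preserving bilateral filter
#'
#' Per-pixel weighted average with weights from [bilateral_weight()],
#' renormalized to sum to one over the truncated window. With no guide image
#' the filter is self-guided (`guide = img`), the classic single-image
#' smoothing form; a guide of the same shape gives the joint/cross bilateral
#' form. Multi-channel inputs are filtered per channel against a grayscale
#' guide.
#'
#' @param img image to filter ([image_patch()], matrix or array).
#' @param guide optional guidance image of the same spatial shape.
#' @param params a [bilateral_params()] object.
#' @return filtered image of the same type and shape.
#' @export
bilateral_filter <- function(img, guide = NULL, params = bilateral_params()) {
  stopifnot(inherits(params, "bilateral_params"))
  gmat <- if (is.null(guide)) NULL else patch_gray(guide)
  r <- params$radius
  kern <- spatial_kernel(params$sigma_s, r)
  inv_sr2 <- 1 / params$sigma_r^2
  map_pixels(img, function(x) {
    g <- if (is.null(gmat)) x else gmat
    if (!identical(dim(g), dim(x)))
      stop("guide shape ", paste(dim(g), collapse = "x"),
           " does not match image shape ", paste(dim(x), collapse = "x"))
    window_filter(x, r, function(a, b, ro, co, ri, ci)
      kern[a + r + 1, b + r + 1] * exp(-(g[ro, co] - x[ri, ci])^2 * inv_sr2))
  })
}

#' Contrast enhancement
#'
#' Stretches patch contrast before feature extraction. `"clahe"`
#' (contrast-limited adaptive histogram equalization, the default -- robust to
#' stain variability across histology patches), `"histeq"` (global histogram
#' equalization) and `"minmax"` (affine stretch to full range) are available.
#' CLAHE and histogram equalization are delegated to \pkg{EBImage}; the CLAHE
#' clip limit is given as a fraction of tile pixels per histogram bin
#' (default 0.01 with 256 bins and 8 x 8 tiles).
#'
#' Constant images are returned unchanged by every method.
#'
#' @param img image in \[0, 1\] ([image_patch()], matrix or array).
#' @param method one of `"clahe"`, `"histeq"`, `"minmax"`.
#' @param clip_limit CLAHE clip limit (fraction scale, see above).
#' @param tiles number of CLAHE tiles along each axis.
#' @return enhanced image in \[0, 1\], same type and shape.
#' @export
enhance_contrast <- function(img, method = c("clahe", "histeq", "minmax"),
                             clip_limit = 0.01, tiles = 8) {
  method <- match.arg(method)
  map_pixels(img, function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(x)  # constant: nothing to enhance
    out <- switch(method,
      minmax = (x - rng[1]) / (rng[2] - rng[1]),
      histeq = {
        y <- EBImage::equalize(EBImage::Image(t(x)), range = c(0, 1),
                               levels = 256)
        t(EBImage::imageData(y))
      },
      clahe = {
        # pad by edge replication up to a tile multiple, enhance, crop back
        h <- nrow(x); w <- ncol(x)
        H <- tiles * ceiling(h / tiles); W <- tiles * ceiling(w / tiles)
        xp <- x[pmin(seq_len(H), h), pmin(seq_len(W), w), drop = FALSE]
        y <- EBImage::clahe(EBImage::Image(t(xp)), nx = tiles, ny = tiles,
                            bins = 256, limit = clip_limit * 256)
        t(EBImage::imageData(y))[seq_len(h), seq_len(w), drop = FALSE]
      })
    clip01(out)
  })
}

#' Full pre-processing step for one patch
#'
#' Normalizes, smooths (bilateral by default, pure Gaussian selectable) and
#' contrast-enhances a patch -- the pre-processing applied by the pipeline
#' before feature extraction.
#'
#' @param img input patch.
#' @param smoothing `"bilateral"` (self-guided, default) or `"gaussian"`.
#' @param params [bilateral_params()]; `sigma_s`/`radius` also drive the
#'   Gaussian option.
#' @param enhance contrast method passed to [enhance_contrast()], or
#'   `"none"`.
#' @return pre-processed image, same type.
#' @export
preprocess_patch <- function(img, smoothing = c("bilateral", "gaussian"),
                             params = bilateral_params(),
                             enhance = "clahe") {
  smoothing <- match.arg(smoothing)
  out <- if (smoothing == "bilateral") bilateral_filter(img, params = params)
         else gaussian_filter(img, params$sigma_s, params$radius)
  if (!identical(enhance, "none")) out <- enhance_contrast(out, enhance)
  out
}
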