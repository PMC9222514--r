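# Synthetic three-class data so every stage is testable fully offline.

# per-class texture parameters at full separability; VT = dense small dark
# nuclei on bright background, NVT = sparse low-contrast necrotic fragments,
# NT = smooth low-frequency stroma
texture_params <- function(patch_size) {
  area <- (patch_size / 128)^2
  list(
    VT  = list(background = 0.85, n_blobs = round(140 * area),
               r_min = 2,  r_max = 4,  intensity = 0.20, blur = 0.7),
    NVT = list(background = 0.70, n_blobs = round(28 * area),
               r_min = 4,  r_max = 9,  intensity = 0.45, blur = 1.6),
    NT  = list(background = 0.82, n_blobs = round(5 * area) + 1,
               r_min = 14, r_max = 30, intensity = 0.65, blur = 4.0))
}

draw_ellipses <- function(img, n, r_min, r_max, intensity, alpha = 0.85) {
  h <- nrow(img); w <- ncol(img)
  for (b in seq_len(n)) {
    cx <- stats::runif(1, 1, w); cy <- stats::runif(1, 1, h)
    ea <- stats::runif(1, r_min, r_max); eb <- stats::runif(1, r_min, r_max)
    th <- stats::runif(1, 0, pi)
    r <- max(ea, eb)
    xs <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
    ys <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
    dx <- outer(rep(1, length(ys)), xs - cx)
    dy <- outer(ys - cy, rep(1, length(xs)))
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    mask <- (u / ea)^2 + (v / eb)^2 <= 1
    blk <- img[ys, xs, drop = FALSE]
    blk[mask] <- blk[mask] * (1 - alpha) + intensity * alpha
    img[ys, xs] <- blk
  }
  img
}

#' Generate labeled synthetic histology-like patches
#'
#' Three textured classes emulating the benchmark's patch types: `VT` (dense
#' high-frequency field of small dark ellipses on a bright background),
#' `NVT` (sparse irregular low-contrast blobs), `NT` (smooth low-frequency
#' background). `separability` interpolates every class's texture parameters
#' between the common class-average set (0: all classes identically
#' distributed, so any classifier is at chance) and the fully distinct sets
#' (1). Gaussian pixel noise is added at `noise_sd` and values clipped to
#' \[0, 1\]. Output is bit-identical for a fixed spec and seed.
#'
#' @param n_per_class counts for VT, NVT, NT (default 345/263/536, mirroring
#'   the benchmark's class imbalance).
#' @param patch_size square patch side, >= 32.
#' @param separability real in \[0, 1\].
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param seed RNG seed.
#' @return list of [image_patch()] objects with labels and ids.
#' @export
generate_images <- function(n_per_class = c(VT = 345, NVT = 263, NT = 536),
                            patch_size = 128, separability = 1,
                            noise_sd = 0.05, seed = 1) {
  if (patch_size < 32) stop("patch_size must be >= 32")
  stopifnot(length(n_per_class) == 3, all(n_per_class >= 0),
            separability >= 0, separability <= 1, noise_sd >= 0)
  classes <- c("VT", "NVT", "NT")
  pars <- texture_params(patch_size)
  flds <- names(pars$VT)
  avg <- lapply(flds, function(f) mean(vapply(pars, `[[`, 0, f)))
  names(avg) <- flds
  blend <- lapply(pars, function(p) {
    out <- lapply(flds, function(f)
      (1 - separability) * avg[[f]] + separability * p[[f]])
    names(out) <- flds
    out
  })
  with_seed(seed, {
    patches <- list()
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      p <- blend[[cl]]
      nb <- max(1, round(p$n_blobs))
      for (i in seq_len(n_per_class[ci])) {
        img <- matrix(p$background, patch_size, patch_size)
        img <- draw_ellipses(img, nb, p$r_min, p$r_max, p$intensity)
        if (p$blur > 0.05)
          img <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(img)),
                                                     sigma = p$blur)))
        img <- clip01(img + stats::rnorm(length(img), 0, noise_sd))
        patches[[length(patches) + 1]] <-
          image_patch(img, label = cl, id = sprintf("%s_%04d", cl, i),
                      normalize = FALSE)
      }
    }
    patches
  })
}

#' Generate a labeled Gaussian-mixture feature table
#'
#' Stands in for extracted image features: one Gaussian per class with
#' pairwise class-mean distance `separation` (in units of the within-class
#' standard deviation), isotropic unit covariance or a random SPD covariance
#' with unit mean variance.
#'
#' @param n_per_class samples per class (length 3, classes VT/NVT/NT).
#' @param dim feature dimension (>= 2).
#' @param separation pairwise mean distance in within-class-sd units.
#' @param covariance `"isotropic"` or `"random_spd"`.
#' @param seed RNG seed.
#' @return list with `features` (matrix) and `labels` (factor).
#' @export
generate_features <- function(n_per_class = c(150, 150, 150), dim = 10,
                              separation = 6,
                              covariance = c("isotropic", "random_spd"),
                              seed = 1) {
  covariance <- match.arg(covariance)
  stopifnot(dim >= 2, separation >= 0, all(n_per_class >= 0))
  classes <- c("VT", "NVT", "NT")
  # equilateral triangle with side = separation, embedded in the first two dims
  mu <- rbind(c(0, 0), c(separation, 0),
              c(separation / 2, separation * sqrt(3) / 2))
  means <- cbind(mu, matrix(0, 3, dim - 2))
  with_seed(seed, {
    L <- if (covariance == "random_spd") {
      A <- matrix(stats::rnorm(dim * dim), dim)
      S <- tcrossprod(A) / dim
      S <- S / mean(diag(S))
      chol(S)
    } else diag(dim)
    n <- sum(n_per_class)
    X <- matrix(stats::rnorm(n * dim), n, dim) %*% L
    labs <- rep(classes, times = n_per_class)
    for (ci in 1:3) {
      idx <- which(labs == classes[ci])
      X[idx, ] <- sweep(X[idx, , drop = FALSE], 2, means[ci, ], "+")
    }
    list(features = X, labels = factor(labs, levels = classes))
  })
}

#' Preset split fractions
#'
#' @param preset `"80/20"` or `"70/30"`.
#' @return named fractions vector (`train`, `test`).
#' @export
split_preset <- function(preset = c("80/20", "70/30")) {
  preset <- match.arg(preset)
  if (preset == "80/20") c(train = 0.8, test = 0.2) else
    c(train = 0.7, test = 0.3)
}

#' Stratified dataset split
#'
#' Partitions sample indices into named subsets, stratified by class: within
#' each class, a seeded shuffle is cut so that every subset's per-class size
#' differs from the exact product by at most one sample.
#'
#' @param labels class label vector.
#' @param fractions named nonnegative fractions summing to 1.
#' @param seed RNG seed.
#' @return named list of disjoint integer index vectors covering all
#'   samples.
#' @export
split_dataset <- function(labels, fractions = split_preset("80/20"),
                          seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (is.null(names(fractions)) || any(names(fractions) == ""))
    stop("fractions must be named")
  labels <- as.character(labels)
  out <- stats::setNames(vector("list", length(fractions)), names(fractions))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      cuts <- round(cumsum(fractions) * length(idx))
      start <- 1
      for (j in seq_along(fractions)) {
        take <- if (cuts[j] >= start) idx[start:cuts[j]] else integer(0)
        out[[j]] <- c(out[[j]], take)
        start <- cuts[j] + 1
      }
    }
  })
  for (cl in unique(labels)) {
    for (j in seq_along(out))
      if (length(out[[j]]) > 0 && !cl %in% labels[out[[j]]])
        warning("class ", cl, " has 0 samples in split '",
                names(out)[j], "'")
  }
  lapply(out, sort)
}
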