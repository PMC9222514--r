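# internal helpers shared across modules

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
# Keeps every exported function deterministic without clobbering the session.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic fan-out of one global seed into per-stage seeds, so a stage
# can be rerun in isolation. Stays below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offs <- c(generate = 11L, split = 23L, filter = 37L, network = 53L,
            features = 71L, tune = 89L, train = 107L, evaluate = 131L)
  k <- if (is.character(stage)) {
    if (!stage %in% names(offs)) stop("unknown stage: ", stage)
    offs[[stage]]
  } else as.integer(stage)
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483629)
}

# preserves dim attributes (unlike pmin/pmax with a scalar first argument)
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Min-max scaler fitted on training data
#'
#' Fits per-column minimum and range on a training matrix so that features can
#' be mapped into \[0, 1\], the operating range required by the log-sigmoid
#' decoder of the sparse autoencoders. Constant columns map to 0.5.
#'
#' @param x numeric matrix, samples in rows.
#' @return an object of class `minmax_scaler`.
#' @seealso [apply_scaler()]
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  mins <- apply(x, 2, min)
  rngs <- apply(x, 2, max) - mins
  structure(list(min = mins, range = rngs), class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' @param scaler a `minmax_scaler` from [fit_scaler()].
#' @param x numeric matrix with the same columns as the training matrix.
#' @param clip clip the result into \[0, 1\] (out-of-range test samples).
#' @return scaled matrix.
#' @export
apply_scaler <- function(scaler, x, clip = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$min))
    stop("feature dimension mismatch: scaler has ", length(scaler$min),
         " columns, data has ", ncol(x))
  rng <- ifelse(scaler$range > 0, scaler$range, 1)
  out <- sweep(sweep(x, 2, scaler$min), 2, rng, "/")
  out[, scaler$range == 0] <- 0.5
  if (clip) out <- clip01(out)
  out
}
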