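# Independent brute-force oracles and reference data used across tests.

# direct double-loop bilateral filter (self-guided unless guide given)
brute_bilateral <- function(x, sigma_s, sigma_r, radius, guide = NULL) {
  if (is.null(guide)) guide <- x
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    num <- 0; den <- 0
    for (a in max(1, i - radius):min(h, i + radius)) {
      for (b in max(1, j - radius):min(w, j + radius)) {
        wt <- exp(-((i - a)^2 + (j - b)^2) / sigma_s^2) *
          exp(-(guide[i, j] - x[a, b])^2 / sigma_r^2)
        num <- num + wt * x[a, b]
        den <- den + wt
      }
    }
    out[i, j] <- num / den
  }
  out
}

# direct double-loop truncated renormalized Gaussian
brute_gaussian <- function(x, sigma_s, radius) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    num <- 0; den <- 0
    for (a in max(1, i - radius):min(h, i + radius)) {
      for (b in max(1, j - radius):min(w, j + radius)) {
        wt <- exp(-((i - a)^2 + (j - b)^2) / sigma_s^2)
        num <- num + wt * x[a, b]
        den <- den + wt
      }
    }
    out[i, j] <- num / den
  }
  out
}

# spreadsheet-style per-class metrics, written independently of the package
# implementation (explicit count arithmetic on the fraction scale)
ref_class_metrics <- function(cm) {
  cm <- unclass(cm)
  n <- sum(cm)
  t(sapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    tn <- n - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    fsc <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    num <- tp * tn - fp * fn
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    c(accuracy = (tp + tn) / n, precision = prec, recall = rec,
      f_score = fsc, mcc = if (den == 0) 0 else num / den,
      g_mean = sqrt(rec * spec))
  }))
}

# layer-by-layer spatial/channel shape calculator, independent of the
# forward implementation
shape_oracle <- function(spec) {
  s <- spec$input_size; ch <- spec$in_channels
  flat <- FALSE
  for (l in spec$layers) {
    if (l$kind == "conv") {
      s <- (s + 2 * l$pad - l$kernel_size) %/% l$stride + 1
      ch <- l$out_channels
    } else if (l$kind == "fire") {
      ch <- l$expand1_channels + l$expand3_channels
    } else if (l$kind == "maxpool") {
      s <- (s - l$size) %/% l$stride + 1
    } else if (l$kind == "gap") {
      flat <- TRUE
    } else if (l$kind == "classifier") {
      ch <- l$n_classes
    }
  }
  list(side = s, channels = ch, flat = flat)
}

# feature dimension at the tap point, by the same independent calculator
shape_oracle_feature_dim <- function(spec) {
  s <- spec$input_size; ch <- spec$in_channels
  for (nm in names(spec$layers)) {
    l <- spec$layers[[nm]]
    if (l$kind == "conv") {
      s <- (s + 2 * l$pad - l$kernel_size) %/% l$stride + 1
      ch <- l$out_channels
    } else if (l$kind == "fire") {
      ch <- l$expand1_channels + l$expand3_channels
    } else if (l$kind == "maxpool") {
      s <- (s - l$size) %/% l$stride + 1
    } else if (l$kind == "gap") {
      s <- 1
    } else if (l$kind == "classifier") {
      s <- 1; ch <- l$n_classes
    }
    if (nm == spec$tap_point) return(s * s * ch)
  }
  stop("tap point not found")
}

# equal-budget uniform random search baseline for the WDO benchmark
random_search <- function(objective, space, n_evals, seed) {
  D <- length(space$dims)
  set.seed(seed)
  best <- Inf
  for (i in seq_len(n_evals)) {
    x <- stats::runif(D, -1, 1)
    v <- objective(decode_position(space, x))
    if (v < best) best <- v
  }
  best
}

# small separable feature fixture shared by classifier tests
blob_fixture <- function(n = 50, dim = 8, separation = 6, seed = 3) {
  generate_features(rep(n, 3), dim = dim, separation = separation,
                    seed = seed)
}
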