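#' Rectified linear activation
#'
#' Elementwise `max(0, x)`.
#'
#' @param x numeric vector, matrix or array.
#' @return same shape.
#' @export
relu <- function(x) {
  x[x < 0] <- 0  # in place, preserving dim attributes
  x
}

#' Mean cross-entropy cost
#'
#' `-(1/m) * sum(x * log(a) + (1 - x) * log(1 - a))` over all entries, with
#' predictions clipped to `[1e-12, 1 - 1e-12]`. For one-hot targets and
#' per-class probability rows this is the standard classification cost.
#'
#' @param predicted probabilities in (0, 1), same shape as `target`.
#' @param target 0/1 (one-hot) values.
#' @param m number of training samples (defaults to `nrow(predicted)` for a
#'   matrix, else 1).
#' @return nonnegative cost.
#' @export
cross_entropy_cost <- function(predicted, target,
                               m = if (is.matrix(predicted))
                                 nrow(predicted) else 1) {
  if (!identical(dim(predicted), dim(target)) ||
      length(predicted) != length(target))
    stop("predicted and target shapes differ")
  a <- pmin(1 - 1e-12, pmax(1e-12, predicted))
  -sum(target * log(a) + (1 - target) * log(1 - a)) / m
}

# ---- layer specs ----

#' Convolutional network layer specs
#'
#' Building blocks of the feature-extractor network: plain convolutions
#' (kernel size restricted to 1 or 3 -- the architecture replaces 3x3 kernels
#' with 1x1 wherever possible, dividing the per-layer parameter count by 9),
#' fire modules (a 1x1 squeeze convolution feeding concatenated 1x1 and 3x3
#' expand branches), max pooling, global average pooling, and a single
#' softmax classifier head.
#'
#' @param out_channels,squeeze_channels,expand1_channels,expand3_channels
#'   positive channel counts; a fire module requires
#'   `squeeze < expand1 + expand3`.
#' @param kernel_size 1 or 3.
#' @param stride positive integer stride.
#' @param pad zero-padding width.
#' @param activation `"relu"` or `"none"`.
#' @param size pooling window.
#' @param n_classes number of output classes.
#' @param in_channels optional explicit input channel count (checked against
#'   the chain at build time).
#' @return a layer spec list.
#' @name layer_specs
NULL

#' @rdname layer_specs
#' @export
conv_spec <- function(out_channels, kernel_size = 3, stride = 1, pad = 0,
                      activation = c("relu", "none"), in_channels = NULL) {
  if (!kernel_size %in% c(1, 3)) stop("kernel_size must be 1 or 3")
  stopifnot(out_channels >= 1, stride >= 1, pad >= 0)
  list(kind = "conv", out_channels = as.integer(out_channels),
       kernel_size = as.integer(kernel_size), stride = as.integer(stride),
       pad = as.integer(pad), activation = match.arg(activation),
       in_channels = in_channels)
}

#' @rdname layer_specs
#' @export
fire_spec <- function(squeeze_channels, expand1_channels, expand3_channels) {
  stopifnot(squeeze_channels >= 1, expand1_channels >= 1,
            expand3_channels >= 1)
  if (squeeze_channels >= expand1_channels + expand3_channels)
    stop("fire module requires squeeze_channels < expand1 + expand3")
  list(kind = "fire", squeeze_channels = as.integer(squeeze_channels),
       expand1_channels = as.integer(expand1_channels),
       expand3_channels = as.integer(expand3_channels))
}

#' @rdname layer_specs
#' @export
maxpool_spec <- function(size = 3, stride = 2) {
  stopifnot(size >= 2, stride >= 1)
  list(kind = "maxpool", size = as.integer(size), stride = as.integer(stride))
}

#' @rdname layer_specs
#' @export
gap_spec <- function() list(kind = "gap")

#' @rdname layer_specs
#' @export
classifier_spec <- function(n_classes) {
  stopifnot(n_classes >= 2)
  list(kind = "classifier", n_classes = as.integer(n_classes))
}

#' Network specification
#'
#' An ordered, named list of layer specs plus input geometry, the tap point
#' whose activations form the feature vector, and exactly one classifier
#' head.
#'
#' @param layers named list of [layer_specs].
#' @param input_size square input side in pixels.
#' @param in_channels input channels (1 = grayscale).
#' @param tap_point name of the layer whose (flattened) activations are the
#'   extracted features.
#' @return a `network_spec` object.
#' @export
network_spec <- function(layers, input_size = 128, in_channels = 1,
                         tap_point = "gap") {
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("layers must be a fully named list")
  if (!tap_point %in% names(layers))
    stop("tap_point '", tap_point, "' does not name a layer")
  n_heads <- sum(vapply(layers, function(l) l$kind == "classifier", TRUE))
  if (n_heads != 1) stop("spec must contain exactly one classifier head")
  structure(list(layers = layers, input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 tap_point = tap_point),
            class = "network_spec")
}

#' Default SqueezeNet-v1.1-style specification
#'
#' Conv 3x3/2 then eight fire modules with interleaved max pooling, global
#' average pooling (the default feature tap, 512 channels at `width = 1`)
#' and a linear softmax head. `width` scales every channel count for
#' desk-scale runs.
#'
#' @param input_size square input side (default 128; use 227 for
#'   compatibility with externally trained weights).
#' @param in_channels input channels.
#' @param n_classes classifier classes.
#' @param width channel multiplier in (0, 1\].
#' @return a [network_spec()].
#' @export
squeezenet_spec <- function(input_size = 128, in_channels = 1, n_classes = 3,
                            width = 1) {
  s <- function(n) max(1L, as.integer(round(n * width)))
  network_spec(list(
    conv1 = conv_spec(s(64), kernel_size = 3, stride = 2),
    pool1 = maxpool_spec(),
    fire2 = fire_spec(s(16), s(64), s(64)),
    fire3 = fire_spec(s(16), s(64), s(64)),
    pool3 = maxpool_spec(),
    fire4 = fire_spec(s(32), s(128), s(128)),
    fire5 = fire_spec(s(32), s(128), s(128)),
    pool5 = maxpool_spec(),
    fire6 = fire_spec(s(48), s(192), s(192)),
    fire7 = fire_spec(s(48), s(192), s(192)),
    fire8 = fire_spec(s(64), s(256), s(256)),
    fire9 = fire_spec(s(64), s(256), s(256)),
    gap = gap_spec(),
    head = classifier_spec(n_classes)),
    input_size = input_size, in_channels = in_channels, tap_point = "gap")
}

he_init <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

#' Build (initialize) a network from a spec
#'
#' Deterministic He-normal initialization given `seed`; channel chaining is
#' validated (an explicit `in_channels` on a conv spec must match the chain).
#'
#' @param spec a [network_spec()].
#' @param seed RNG seed.
#' @return a `conv_network`: the spec plus initialized weights per layer.
#' @export
build_network <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  with_seed(seed, {
    cin <- spec$in_channels
    flat <- FALSE  # becomes TRUE after global pooling
    weights <- list()
    for (nm in names(spec$layers)) {
      l <- spec$layers[[nm]]
      weights[[nm]] <- switch(l$kind,
        conv = {
          if (flat) stop("conv layer '", nm, "' after global pooling")
          if (!is.null(l$in_channels) && l$in_channels != cin)
            stop("layer '", nm, "' expects ", l$in_channels,
                 " input channels but receives ", cin)
          w <- list(W = he_init(l$kernel_size, l$kernel_size, cin,
                                l$out_channels),
                    b = rep(0, l$out_channels))
          cin <- l$out_channels
          w
        },
        fire = {
          if (flat) stop("fire layer '", nm, "' after global pooling")
          w <- list(
            squeeze = list(W = he_init(1, 1, cin, l$squeeze_channels),
                           b = rep(0, l$squeeze_channels)),
            expand1 = list(W = he_init(1, 1, l$squeeze_channels,
                                       l$expand1_channels),
                           b = rep(0, l$expand1_channels)),
            expand3 = list(W = he_init(3, 3, l$squeeze_channels,
                                       l$expand3_channels),
                           b = rep(0, l$expand3_channels)))
          cin <- l$expand1_channels + l$expand3_channels
          w
        },
        maxpool = list(),
        gap = { flat <- TRUE; list() },
        classifier = {
          if (!flat) stop("classifier head requires global pooling first")
          list(W = matrix(stats::rnorm(l$n_classes * cin,
                                       0, sqrt(2 / cin)),
                          l$n_classes, cin),
               b = rep(0, l$n_classes))
        },
        stop("unknown layer kind: ", l$kind))
    }
    structure(list(spec = spec, weights = weights), class = "conv_network")
  })
}

#' @export
print.conv_network <- function(x, ...) {
  cat(sprintf("<conv_network: %d layers, input %dx%dx%d, %s parameters>\n",
              length(x$spec$layers), x$spec$input_size, x$spec$input_size,
              x$spec$in_channels,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Total trainable parameter count
#'
#' @param net a `conv_network`.
#' @return integer count of weight and bias entries.
#' @export
count_parameters <- function(net) {
  cnt <- function(w) if (is.list(w)) sum(vapply(w, cnt, 0)) else length(w)
  sum(vapply(net$weights, cnt, 0))
}

# zero-padded 2-D convolution via im2col; x is h x w x c, W is kh x kw x cin x cout
conv2d <- function(x, W, b, stride = 1, pad = 0) {
  kh <- dim(W)[1]; kw <- dim(W)[2]; cin <- dim(W)[3]; cout <- dim(W)[4]
  if (dim(x)[3] != cin)
    stop("channel mismatch: input has ", dim(x)[3], ", kernel expects ", cin)
  if (pad > 0) {
    xp <- array(0, dim(x) + c(2 * pad, 2 * pad, 0))
    xp[pad + seq_len(dim(x)[1]), pad + seq_len(dim(x)[2]), ] <- x
    x <- xp
  }
  h <- dim(x)[1]; w <- dim(x)[2]
  ho <- (h - kh) %/% stride + 1; wo <- (w - kw) %/% stride + 1
  if (ho < 1 || wo < 1) stop("input too small for kernel")
  if (kh == 1 && kw == 1) {
    xs <- x[seq(1, by = stride, length.out = ho),
            seq(1, by = stride, length.out = wo), , drop = FALSE]
    M <- matrix(xs, ho * wo, cin)
  } else {
    M <- matrix(0, ho * wo, kh * kw * cin)
    col <- 1L
    for (cc in seq_len(cin)) for (dx in 0:(kw - 1)) for (dy in 0:(kh - 1)) {
      M[, col] <- x[seq(1 + dy, by = stride, length.out = ho),
                    seq(1 + dx, by = stride, length.out = wo), cc]
      col <- col + 1L
    }
  }
  out <- sweep(M %*% matrix(W, kh * kw * cin, cout), 2, b, "+")
  array(out, c(ho, wo, cout))
}

maxpool2d <- function(x, size, stride) {
  h <- dim(x)[1]; w <- dim(x)[2]
  ho <- (h - size) %/% stride + 1; wo <- (w - size) %/% stride + 1
  if (ho < 1 || wo < 1) stop("input too small for pooling window")
  out <- array(-Inf, c(ho, wo, dim(x)[3]))
  for (dy in 0:(size - 1)) for (dx in 0:(size - 1))
    out <- pmax(out, x[seq(1 + dy, by = stride, length.out = ho),
                       seq(1 + dx, by = stride, length.out = wo), ,
                       drop = FALSE])
  out
}

# forward pass; returns list(tap = activations at tap_point, probs = softmax)
forward_network <- function(net, x, tap_point = net$spec$tap_point) {
  act <- x
  tap <- NULL
  for (nm in names(net$spec$layers)) {
    l <- net$spec$layers[[nm]]
    w <- net$weights[[nm]]
    act <- switch(l$kind,
      conv = {
        a <- conv2d(act, w$W, w$b, l$stride, l$pad)
        if (l$activation == "relu") relu(a) else a
      },
      fire = {
        sq <- relu(conv2d(act, w$squeeze$W, w$squeeze$b, 1, 0))
        e1 <- relu(conv2d(sq, w$expand1$W, w$expand1$b, 1, 0))
        e3 <- relu(conv2d(sq, w$expand3$W, w$expand3$b, 1, 1))
        out <- array(0, c(dim(e1)[1], dim(e1)[2], dim(e1)[3] + dim(e3)[3]))
        out[, , seq_len(dim(e1)[3])] <- e1
        out[, , dim(e1)[3] + seq_len(dim(e3)[3])] <- e3
        out
      },
      maxpool = maxpool2d(act, l$size, l$stride),
      gap = colMeans(matrix(act, prod(dim(act)[1:2]), dim(act)[3])),
      classifier = {
        z <- drop(w$W %*% as.numeric(act)) + w$b
        e <- exp(z - max(z))
        e / sum(e)
      })
    if (nm == tap_point) tap <- act
  }
  list(tap = as.numeric(tap), probs = act)
}

#' Extract a feature matrix from image patches
#'
#' Resizes every patch (bilinear) to the network input size, converts to the
#' network's channel count (channel mean for grayscale networks), runs the
#' frozen forward pass and flattens the activations at the tap point into one
#' row per image.
#'
#' @param images list of [image_patch()] objects (or plain matrices).
#' @param net a `conv_network` from [build_network()].
#' @param tap_point layer name; defaults to the spec's tap point.
#' @return samples x features numeric matrix with sample ids as row names and
#'   a `labels` attribute when the patches carry labels.
#' @export
extract_features <- function(images, net, tap_point = net$spec$tap_point) {
  if (!tap_point %in% names(net$spec$layers))
    stop("tap_point '", tap_point, "' does not name a layer")
  size <- net$spec$input_size
  rows <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    px <- if (net$spec$in_channels == 1) patch_gray(img)
          else if (inherits(img, "image_patch")) img$pixels else img
    if (min(dim(px)[1:2]) < 8)
      stop("image ", i, " is smaller than the 8-pixel minimum")
    if (!identical(dim(px)[1:2], c(size, size))) {
      eb <- if (length(dim(px)) == 3) EBImage::Image(aperm(px, c(2, 1, 3)),
                                                     colormode = "Color")
            else EBImage::Image(t(px))
      rz <- EBImage::imageData(EBImage::resize(eb, w = size, h = size))
      px <- if (length(dim(rz)) == 3) aperm(rz, c(2, 1, 3)) else t(rz)
    }
    x <- array(px, c(size, size, max(1, net$spec$in_channels)))
    forward_network(net, x, tap_point)$tap
  })
  dims <- lengths(rows)
  if (length(unique(dims)) != 1) stop("inconsistent feature dimensions")
  mat <- do.call(rbind, rows)
  ids <- vapply(seq_along(images), function(i) {
    id <- if (inherits(images[[i]], "image_patch")) images[[i]]$id else NULL
    if (is.null(id)) sprintf("sample_%04d", i) else id
  }, "")
  rownames(mat) <- ids
  labs <- vapply(images, function(p)
    if (inherits(p, "image_patch")) p$label else NA_character_, "")
  if (!all(is.na(labs))) attr(mat, "labels") <- labs
  mat
}

#' Export / import network weights
#'
#' `export_weights` returns the plain nested weight list; `import_weights`
#' installs a compatible container into a built network, checking every
#' layer's shapes and reporting the first offending layer by name. Use these
#' to load externally trained weights matching [squeezenet_spec()] shapes.
#'
#' @param net a `conv_network`.
#' @param weights nested list as produced by `export_weights`.
#' @return `export_weights`: nested list; `import_weights`: the network with
#'   imported weights.
#' @export
export_weights <- function(net) net$weights

#' @rdname export_weights
#' @export
import_weights <- function(net, weights) {
  check <- function(tmpl, w, path) {
    if (is.list(tmpl)) {
      if (!is.list(w) || !all(names(tmpl) %in% names(w)))
        stop("import error at layer '", path, "': missing component")
      for (nm in names(tmpl)) check(tmpl[[nm]], w[[nm]],
                                    paste(path, nm, sep = "/"))
    } else {
      dt <- dim(tmpl); dw <- dim(w)
      ok <- if (is.null(dt)) is.null(dw) && length(w) == length(tmpl)
            else identical(as.integer(dt), as.integer(dw))
      if (!ok)
        stop("import error at layer '", path, "': shape mismatch (expected ",
             paste(if (is.null(dt)) length(tmpl) else dt, collapse = "x"),
             ", got ", paste(if (is.null(dw)) length(w) else dw,
                             collapse = "x"), ")")
    }
  }
  for (nm in names(net$weights))
    check(net$weights[[nm]], weights[[nm]], nm)
  net$weights <- weights[names(net$weights)]
  net
}

#' Read / write a network spec as YAML
#'
#' @param spec a [network_spec()].
#' @param path file path.
#' @return `read_network_spec` returns a [network_spec()].
#' @export
write_network_spec <- function(spec, path) {
  yaml::write_yaml(list(input_size = spec$input_size,
                        in_channels = spec$in_channels,
                        tap_point = spec$tap_point,
                        layers = spec$layers), path)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  layers <- lapply(obj$layers, function(l) {
    l$kind <- as.character(l$kind)
    l
  })
  network_spec(layers, input_size = obj$input_size,
               in_channels = obj$in_channels, tap_point = obj$tap_point)
}
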