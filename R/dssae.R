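#' Log-sigmoid activation
#'
#' `1 / (1 + exp(-x))`, the coding activation of both the encoder and the
#' decoder. Saturates cleanly to 0/1 for large-magnitude inputs.
#'
#' @param x numeric vector, matrix or array.
#' @return same shape, values in (0, 1).
#' @export
logsig <- function(x) 1 / (1 + exp(-x))

#' Sparse autoencoder container
#'
#' One autoencoder layer: encoder `C = logsig(W_Y Y + B_Y)`, decoder
#' `Z = logsig(W_Z C + B_Z)`, with a Kullback-Leibler sparsity penalty pulling
#' mean code activations toward the sparsity proportion `rho` and an L2
#' penalty on both weight matrices.
#'
#' @param W_Y encoder weights, hidden x input.
#' @param B_Y encoder bias, length hidden.
#' @param W_Z decoder weights, input x hidden.
#' @param B_Z decoder bias, length input.
#' @param rho target sparsity proportion, strictly in (0, 1).
#' @param c_s sparsity regulation factor (>= 0).
#' @param c_w weight regulation factor (>= 0).
#' @return a `sparse_autoencoder` object.
#' @export
sparse_autoencoder <- function(W_Y, B_Y, W_Z, B_Z,
                               rho = 0.05, c_s = 1.0, c_w = 1e-4) {
  W_Y <- as.matrix(W_Y); W_Z <- as.matrix(W_Z)
  h <- nrow(W_Y); d <- ncol(W_Y)
  if (!identical(dim(W_Z), c(d, h)))
    stop("W_Z must be input x hidden (", d, " x ", h, ")")
  if (length(B_Y) != h || length(B_Z) != d) stop("bias length mismatch")
  if (!(rho > 0 && rho < 1)) stop("rho must be strictly inside (0, 1)")
  if (c_s < 0 || c_w < 0) stop("c_s and c_w must be >= 0")
  structure(list(W_Y = W_Y, B_Y = as.numeric(B_Y),
                 W_Z = W_Z, B_Z = as.numeric(B_Z),
                 rho = rho, c_s = c_s, c_w = c_w),
            class = "sparse_autoencoder")
}

sae_dims <- function(sae) c(input = ncol(sae$W_Y), hidden = nrow(sae$W_Y))

#' Encode samples to hidden codes
#'
#' @param sae a [sparse_autoencoder()].
#' @param Y numeric matrix, samples in rows (or a single vector).
#' @return code matrix, samples x hidden, entries in (0, 1).
#' @export
encode <- function(sae, Y) {
  Y <- rbind2d(Y)
  if (ncol(Y) != ncol(sae$W_Y))
    stop("input dim ", ncol(Y), " does not match encoder dim ", ncol(sae$W_Y))
  logsig(sweep(Y %*% t(sae$W_Y), 2, sae$B_Y, "+"))
}

#' Decode hidden codes to reconstructions
#'
#' @param sae a [sparse_autoencoder()].
#' @param C code matrix, samples x hidden.
#' @return reconstruction matrix, samples x input, entries in (0, 1).
#' @export
decode <- function(sae, C) {
  C <- rbind2d(C)
  if (ncol(C) != ncol(sae$W_Z))
    stop("code dim ", ncol(C), " does not match decoder dim ", ncol(sae$W_Z))
  logsig(sweep(C %*% t(sae$W_Z), 2, sae$B_Z, "+"))
}

rbind2d <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)

#' Kullback-Leibler sparsity penalty
#'
#' `sum_j [rho log(rho/rho_hat_j) + (1-rho) log((1-rho)/(1-rho_hat_j))]`,
#' where `rho_hat_j` is the mean activation of hidden unit j over the batch.
#' Activations are clipped to `[1e-8, 1 - 1e-8]` so dead or saturated units
#' cannot produce an infinite penalty.
#'
#' @param rho target sparsity proportion in (0, 1).
#' @param rho_hat vector of mean code activations.
#' @return nonnegative penalty; zero iff every `rho_hat_j == rho`.
#' @export
kl_sparsity <- function(rho, rho_hat) {
  if (!(rho > 0 && rho < 1)) stop("rho must be strictly inside (0, 1)")
  rh <- pmin(1 - 1e-8, pmax(1e-8, rho_hat))
  sum(rho * log(rho / rh) + (1 - rho) * log((1 - rho) / (1 - rh)))
}

#' L2 weight penalty of an autoencoder
#'
#' Half the summed squared entries of encoder and decoder weights,
#' `(1/2)(||W_Y||_F^2 + ||W_Z||_F^2)`. Biases are not penalized.
#'
#' @param sae a [sparse_autoencoder()].
#' @return nonnegative penalty.
#' @export
weight_reg <- function(sae) 0.5 * (sum(sae$W_Y^2) + sum(sae$W_Z^2))

#' Full sparse-autoencoder loss
#'
#' Mean squared reconstruction error plus the weighted sparsity and weight
#' penalties:
#' `(1/N) sum_n ||Z_n - Y_n||^2 + c_s * Gamma_s + c_w * Gamma_w`,
#' where `Gamma_s` is [kl_sparsity()] of the batch mean activations and
#' `Gamma_w` is [weight_reg()].
#'
#' @param sae a [sparse_autoencoder()].
#' @param Y samples x input matrix with entries in \[0, 1\].
#' @return nonnegative loss value.
#' @export
sae_loss <- function(sae, Y) {
  Y <- rbind2d(Y)
  if (nrow(Y) < 1) stop("empty batch")
  C <- encode(sae, Y)
  Z <- decode(sae, C)
  sum((Z - Y)^2) / nrow(Y) +
    sae$c_s * kl_sparsity(sae$rho, colMeans(C)) +
    sae$c_w * weight_reg(sae)
}

# ---- parameter packing and analytic gradient (internal) ----

sae_pack <- function(sae) c(sae$W_Y, sae$B_Y, sae$W_Z, sae$B_Z)

sae_unpack <- function(theta, d, h, rho, c_s, c_w) {
  i <- 0
  W_Y <- matrix(theta[i + seq_len(h * d)], h, d); i <- i + h * d
  B_Y <- theta[i + seq_len(h)]; i <- i + h
  W_Z <- matrix(theta[i + seq_len(d * h)], d, h); i <- i + d * h
  B_Z <- theta[i + seq_len(d)]
  sparse_autoencoder(W_Y, B_Y, W_Z, B_Z, rho, c_s, c_w)
}

# loss and gradient at packed parameters; Yt is input transposed (d x N)
sae_loss_grad <- function(theta, Yt, d, h, rho, c_s, c_w) {
  N <- ncol(Yt)
  i <- 0
  W_Y <- matrix(theta[i + seq_len(h * d)], h, d); i <- i + h * d
  B_Y <- theta[i + seq_len(h)]; i <- i + h
  W_Z <- matrix(theta[i + seq_len(d * h)], d, h); i <- i + d * h
  B_Z <- theta[i + seq_len(d)]
  C <- logsig(W_Y %*% Yt + B_Y)
  Z <- logsig(W_Z %*% C + B_Z)
  rho_hat <- pmin(1 - 1e-8, pmax(1e-8, rowMeans(C)))
  loss <- sum((Z - Yt)^2) / N +
    c_s * sum(rho * log(rho / rho_hat) +
              (1 - rho) * log((1 - rho) / (1 - rho_hat))) +
    c_w * 0.5 * (sum(W_Y^2) + sum(W_Z^2))
  d2 <- (2 / N) * (Z - Yt) * Z * (1 - Z)
  kl_d <- (c_s / N) * (-rho / rho_hat + (1 - rho) / (1 - rho_hat))
  dC <- crossprod(W_Z, d2) + kl_d
  d1 <- dC * C * (1 - C)
  grad <- c(tcrossprod(d1, Yt) + c_w * W_Y, rowSums(d1),
            tcrossprod(d2, C) + c_w * W_Z, rowSums(d2))
  list(value = loss, grad = grad)
}

# memoized fn/gr pair for scg_minimize (one forward/backward per theta)
make_fn_gr <- function(loss_grad) {
  last_theta <- NULL; last <- NULL
  eval_at <- function(theta) {
    if (is.null(last_theta) || !identical(theta, last_theta)) {
      last <<- loss_grad(theta)
      last_theta <<- theta
    }
    last
  }
  list(fn = function(theta) eval_at(theta)$value,
       gr = function(theta) eval_at(theta)$grad)
}

glorot_init <- function(h, d) {
  r <- sqrt(6 / (h + d))
  matrix(stats::runif(h * d, -r, r), h, d)
}

#' Train one sparse autoencoder by scaled conjugate gradient
#'
#' Full-batch scaled conjugate gradient on the [sae_loss()] objective with
#' seeded Glorot-uniform initialization. When `batch_size < nrow(Y)`, each
#' epoch cycles over seeded-shuffled mini-batches taking one conjugate step
#' per batch; with the default full batch, `epochs` caps the total number of
#' conjugate-gradient iterations.
#'
#' @param Y training matrix, samples x input, entries in \[0, 1\].
#' @param hidden number of hidden units.
#' @param rho,c_s,c_w sparsity proportion and regulation factors.
#' @param epochs iteration cap.
#' @param batch_size samples per batch; `Inf` (default) = full batch.
#' @param seed RNG seed for initialization and shuffling.
#' @return a trained [sparse_autoencoder()] with attribute `trace` (loss per
#'   accepted iteration).
#' @export
train_sae <- function(Y, hidden, rho = 0.05, c_s = 1.0, c_w = 1e-4,
                      epochs = 100, batch_size = Inf, seed = 1) {
  Y <- rbind2d(Y)
  if (nrow(Y) < 1) stop("empty batch")
  d <- ncol(Y); h <- as.integer(hidden)
  theta0 <- with_seed(seed, c(glorot_init(h, d), rep(0, h),
                              glorot_init(d, h), rep(0, d)))
  res <- fit_minibatch(theta0, function(idx) {
    Yt <- t(Y[idx, , drop = FALSE])
    make_fn_gr(function(th) sae_loss_grad(th, Yt, d, h, rho, c_s, c_w))
  }, N = nrow(Y), epochs = epochs, batch_size = batch_size, seed = seed)
  if (!is.finite(res$value))
    stop("non-finite loss during SAE training; trace: ",
         paste(utils::tail(res$trace, 5), collapse = ", "))
  sae <- sae_unpack(res$par, d, h, rho, c_s, c_w)
  attr(sae, "trace") <- res$trace
  sae
}

# shared full-batch / mini-batch driver around scg_minimize
fit_minibatch <- function(theta0, batch_fns, N, epochs, batch_size, seed) {
  if (batch_size >= N) {
    fg <- batch_fns(seq_len(N))
    return(scg_minimize(theta0, fg$fn, fg$gr, max_iter = epochs))
  }
  theta <- theta0
  trace <- numeric(0)
  value <- Inf
  with_seed(stage_seed(seed, 3L), {
    for (e in seq_len(epochs)) {
      ord <- sample.int(N)
      starts <- seq(1, N, by = batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1, N)]
        fg <- batch_fns(idx)
        res <- scg_minimize(theta, fg$fn, fg$gr, max_iter = 1)
        theta <- res$par
      }
      fg_all <- batch_fns(seq_len(N))
      value <- fg_all$fn(theta)
      trace <- c(trace, value)
    }
  })
  list(par = theta, value = value, trace = trace)
}

# ---- softmax head ----

softmax_rows <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# cross-entropy loss/grad for softmax head; Ct (h x N), Yk one-hot (K x N)
softmax_loss_grad <- function(theta, Ct, Yk, K, h, c_w) {
  N <- ncol(Ct)
  W <- matrix(theta[seq_len(K * h)], K, h)
  b <- theta[K * h + seq_len(K)]
  logits <- W %*% Ct + b
  logits <- sweep(logits, 2, apply(logits, 2, max))
  E <- exp(logits)
  P <- sweep(E, 2, colSums(E), "/")
  loss <- -sum(Yk * log(pmax(P, 1e-300))) / N + 0.5 * c_w * sum(W^2)
  dl <- (P - Yk) / N
  list(value = loss, grad = c(tcrossprod(dl, Ct) + c_w * W, rowSums(dl)))
}

#' Deep stacked sparse autoencoder classifier
#'
#' Greedy layer-wise training: autoencoder k is trained on the codes of
#' autoencoder k-1 (features are min-max scaled to \[0, 1\] first, scaler
#' fitted on this training set only), then a softmax output layer is trained
#' on the deepest codes with cross-entropy. All stages use the same scaled
#' conjugate gradient optimizer. An optional end-to-end fine-tuning pass
#' (plain gradient descent through the whole encoder stack at
#' `learning_rate`) is off by default.
#'
#' @param features numeric matrix, samples x features.
#' @param labels class labels (factor or character), one per row.
#' @param hidden_dims hidden-layer sizes of the stacked autoencoders
#'   (default four layers: 256, 128, 64, 32).
#' @param rho,c_s,c_w sparsity proportion and regulation factors shared by
#'   all layers.
#' @param epochs conjugate-gradient iteration cap per layer.
#' @param batch_size samples per batch (`Inf` = full batch).
#' @param learning_rate step size of the optional fine-tuning pass.
#' @param fine_tune number of end-to-end fine-tuning iterations (0 = off).
#' @param seed RNG seed.
#' @param class_names optional explicit class ordering.
#' @return a `dssae_model` with elements `saes`, `softmax_W`, `softmax_B`,
#'   `class_names`, `scaler`, `config` and `trace` (per-layer loss traces).
#' @export
train_dssae <- function(features, labels, hidden_dims = c(256, 128, 64, 32),
                        rho = 0.05, c_s = 1.0, c_w = 1e-4,
                        epochs = 100, batch_size = Inf, learning_rate = 0.01,
                        fine_tune = 0, seed = 1, class_names = NULL) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels))
    stop("label count ", length(labels), " does not match feature rows ",
         nrow(features))
  if (is.null(class_names)) class_names <- sort(unique(as.character(labels)))
  y <- factor(as.character(labels), levels = class_names)
  if (anyNA(y)) stop("labels outside class_names")
  scaler <- fit_scaler(features)
  X <- apply_scaler(scaler, features)
  dims <- c(ncol(X), hidden_dims)
  if (any(diff(dims) >= 0))
    warning("expansion layer: a hidden dim is >= its input dim (",
            paste(dims, collapse = " -> "), ")")
  saes <- vector("list", length(hidden_dims))
  code_scalers <- vector("list", length(hidden_dims))
  traces <- list()
  for (k in seq_along(hidden_dims)) {
    saes[[k]] <- train_sae(X, hidden_dims[k], rho = rho, c_s = c_s, c_w = c_w,
                           epochs = epochs, batch_size = batch_size,
                           seed = stage_seed(seed, 200L + k))
    traces[[paste0("sae", k)]] <- attr(saes[[k]], "trace")
    X <- encode(saes[[k]], X)
    # sparse codes concentrate near rho; restore full dynamic range before the
    # next layer so deeper autoencoders cannot satisfy their loss with a
    # constant code (scaler fitted on training codes only)
    code_scalers[[k]] <- fit_scaler(X)
    X <- apply_scaler(code_scalers[[k]], X)
  }
  # softmax head on the deepest codes
  K <- length(class_names); h <- ncol(X); N <- nrow(X)
  Yk <- t(stats::model.matrix(~ y - 1))  # K x N one-hot
  theta0 <- with_seed(stage_seed(seed, 299L), c(glorot_init(K, h), rep(0, K)))
  res <- fit_minibatch(theta0, function(idx)
    make_fn_gr(function(th) softmax_loss_grad(
      th, t(X[idx, , drop = FALSE]), Yk[, idx, drop = FALSE], K, h, c_w)),
    N = N, epochs = epochs, batch_size = batch_size, seed = seed)
  traces$softmax <- res$trace
  model <- structure(list(
    saes = saes, code_scalers = code_scalers,
    softmax_W = matrix(res$par[seq_len(K * h)], K, h),
    softmax_B = res$par[K * h + seq_len(K)],
    class_names = class_names, scaler = scaler,
    config = list(hidden_dims = hidden_dims, rho = rho, c_s = c_s, c_w = c_w,
                  epochs = epochs, batch_size = batch_size,
                  learning_rate = learning_rate, fine_tune = fine_tune,
                  seed = seed),
    trace = traces), class = "dssae_model")
  if (fine_tune > 0)
    model <- fine_tune_dssae(model, features, y, iters = fine_tune,
                             learning_rate = learning_rate)
  model
}

# end-to-end fine-tuning: plain gradient descent on the stack cross-entropy
fine_tune_dssae <- function(model, features, y, iters, learning_rate) {
  X0 <- apply_scaler(model$scaler, as.matrix(features))
  K <- length(model$class_names)
  Yk <- t(stats::model.matrix(~ y - 1))
  N <- nrow(X0)
  for (it in seq_len(iters)) {
    acts <- list(t(X0))  # column-major scaled activations per layer
    raw <- list()        # pre-rescale sigmoid outputs (for the derivative)
    for (k in seq_along(model$saes)) {
      C <- logsig(model$saes[[k]]$W_Y %*% acts[[k]] + model$saes[[k]]$B_Y)
      raw[[k]] <- C
      sc <- model$code_scalers[[k]]
      rg <- ifelse(sc$range > 0, sc$range, 1)
      acts[[k + 1]] <- clip01((C - sc$min) / rg)
    }
    top <- acts[[length(acts)]]
    logits <- model$softmax_W %*% top + model$softmax_B
    logits <- sweep(logits, 2, apply(logits, 2, max))
    E <- exp(logits); P <- sweep(E, 2, colSums(E), "/")
    dl <- (P - Yk) / N
    gW <- tcrossprod(dl, top); gb <- rowSums(dl)
    delta <- crossprod(model$softmax_W, dl)
    model$softmax_W <- model$softmax_W - learning_rate * gW
    model$softmax_B <- model$softmax_B - learning_rate * gb
    for (k in rev(seq_along(model$saes))) {
      sc <- model$code_scalers[[k]]
      rg <- ifelse(sc$range > 0, sc$range, 1)
      A <- raw[[k]]
      delta <- (delta / rg) * A * (1 - A)
      gWk <- tcrossprod(delta, acts[[k]])
      gbk <- rowSums(delta)
      delta <- crossprod(model$saes[[k]]$W_Y, delta)
      model$saes[[k]]$W_Y <- model$saes[[k]]$W_Y - learning_rate * gWk
      model$saes[[k]]$B_Y <- model$saes[[k]]$B_Y - learning_rate * gbk
    }
  }
  model
}

#' @export
print.dssae_model <- function(x, ...) {
  cat(sprintf("<dssae_model: %d -> %s -> %d classes (%s)>\n",
              length(x$scaler$min),
              paste(x$config$hidden_dims, collapse = " -> "),
              length(x$class_names), paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Predict classes or class probabilities
#'
#' Scales new features with the model's stored training scaler, propagates
#' through the encoder stack and the softmax head. Ties in the argmax are
#' broken toward the lowest class index.
#'
#' @param object a `dssae_model`.
#' @param newdata samples x features matrix.
#' @param type `"class"` (factor) or `"prob"` (samples x classes matrix).
#' @param ... unused.
#' @export
predict.dssae_model <- function(object, newdata, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  X <- apply_scaler(object$scaler, rbind2d(newdata))
  for (k in seq_along(object$saes))
    X <- apply_scaler(object$code_scalers[[k]], encode(object$saes[[k]], X))
  probs <- softmax_rows(sweep(X %*% t(object$softmax_W), 2,
                              object$softmax_B, "+"))
  colnames(probs) <- object$class_names
  if (type == "prob") return(probs)
  factor(object$class_names[max.col(probs, ties.method = "first")],
         levels = object$class_names)
}

#' Serialize / restore a DSSAE model as JSON
#'
#' Single-file JSON with a versioned schema: dimensions, hyperparameters,
#' class names and seed in the header, weights at full double precision.
#'
#' @param model a `dssae_model`.
#' @param path output file.
#' @return `load_dssae` returns the restored `dssae_model`.
#' @export
save_dssae <- function(model, path) {
  obj <- list(
    schema = "dssae-model/1",
    config = model$config,
    class_names = model$class_names,
    scaler = list(min = model$scaler$min, range = model$scaler$range),
    code_scalers = lapply(model$code_scalers, function(s)
      list(min = s$min, range = s$range)),
    saes = lapply(model$saes, function(s)
      list(W_Y = s$W_Y, B_Y = s$B_Y, W_Z = s$W_Z, B_Z = s$B_Z,
           rho = s$rho, c_s = s$c_s, c_w = s$c_w)),
    softmax_W = model$softmax_W, softmax_B = model$softmax_B)
  json <- jsonlite::serializeJSON(obj, digits = I(17))  # exact double round-trip
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_dssae
#' @export
load_dssae <- function(path) {
  obj <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  if (!identical(obj$schema, "dssae-model/1"))
    stop("unrecognized model schema: ", obj$schema)
  saes <- lapply(obj$saes, function(s)
    sparse_autoencoder(s$W_Y, s$B_Y, s$W_Z, s$B_Z, s$rho, s$c_s, s$c_w))
  structure(list(saes = saes,
                 code_scalers = lapply(obj$code_scalers, function(s)
                   structure(list(min = s$min, range = s$range),
                             class = "minmax_scaler")),
                 softmax_W = obj$softmax_W,
                 softmax_B = obj$softmax_B, class_names = obj$class_names,
                 scaler = structure(list(min = obj$scaler$min,
                                         range = obj$scaler$range),
                                    class = "minmax_scaler"),
                 config = obj$config, trace = NULL),
            class = "dssae_model")
}
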