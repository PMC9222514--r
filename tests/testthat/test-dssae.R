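test_that("log-sigmoid values and symmetry", {
  expect_equal(logsig(0), 0.5)
  expect_equal(logsig(2), 0.880797, tolerance = 1e-6)
  set.seed(30)
  x <- rnorm(50, sd = 3)
  expect_equal(logsig(x) + logsig(-x), rep(1, 50))
  expect_true(all(logsig(c(-1e3, 1e3)) == c(0, 1)))  # saturates cleanly
})

test_that("encode and decode follow the layer equations", {
  sae0 <- sparse_autoencoder(matrix(0, 3, 4), rep(0, 3),
                             matrix(0, 4, 3), rep(0, 4))
  Y <- matrix(runif(8), 2, 4)
  expect_true(all(encode(sae0, Y) == 0.5))
  expect_true(all(decode(sae0, matrix(0.3, 2, 3)) == 0.5))
  # hand-set 2x2 weights, one input
  sae <- sparse_autoencoder(matrix(c(1, -1, 0.5, 2), 2, 2),
                            c(0.1, -0.2),
                            matrix(c(0.3, 0.4, -0.1, 0.2), 2, 2),
                            c(0, 0.5))
  y <- c(0.2, 0.7)
  a <- c(1 * 0.2 + 0.5 * 0.7 + 0.1, -1 * 0.2 + 2 * 0.7 - 0.2)
  expect_equal(as.numeric(encode(sae, y)), 1 / (1 + exp(-a)))
  # batch encode equals stacked per-sample encodes
  Y2 <- matrix(runif(10), 5, 2)
  batch <- encode(sae, Y2)
  for (i in 1:5) expect_equal(batch[i, ], as.numeric(encode(sae, Y2[i, ])))
  # reconstruction dimension equals input dimension
  expect_equal(ncol(decode(sae, encode(sae, Y2))), 2)
  expect_error(encode(sae, matrix(0, 2, 3)), "dim")
})

test_that("KL sparsity penalty: closed form, additivity, convexity", {
  expect_equal(kl_sparsity(0.05, 0.05), 0)
  expect_equal(kl_sparsity(0.05, 0.2),
               0.05 * log(0.25) + 0.95 * log(0.95 / 0.8))
  rh <- c(0.1, 0.3, 0.6)
  expect_equal(kl_sparsity(0.2, rh),
               sum(vapply(rh, function(r) kl_sparsity(0.2, r), 0)))
  # nonnegative and convex along a grid in rho_hat
  grid <- seq(0.02, 0.98, by = 0.02)
  v <- vapply(grid, function(r) kl_sparsity(0.15, r), 0)
  expect_true(all(v >= 0))
  expect_true(all(diff(diff(v)) > -1e-10))
  expect_error(kl_sparsity(1.2, 0.5), "rho")
})

test_that("weight penalty: hand sum and quadratic homogeneity", {
  z <- sparse_autoencoder(matrix(0, 1, 2), 0, matrix(0, 2, 1), c(0, 0))
  expect_equal(weight_reg(z), 0)
  s <- sparse_autoencoder(matrix(c(1, 2), 1, 2), 0,
                          matrix(c(2, 1), 2, 1), c(0, 0))
  expect_equal(weight_reg(s), 5)
  s2 <- sparse_autoencoder(3 * s$W_Y, s$B_Y, 3 * s$W_Z, s$B_Z)
  expect_equal(weight_reg(s2), 9 * weight_reg(s))
})

test_that("sae loss composes reconstruction, sparsity and weight terms", {
  # zero parameters, all-0.5 input: reconstruction exact, KL at 0.5
  d <- 5
  sae0 <- sparse_autoencoder(matrix(0, 3, d), rep(0, 3),
                             matrix(0, d, 3), rep(0, d),
                             rho = 0.05, c_s = 1, c_w = 0)
  Y <- matrix(0.5, 1, d)
  expect_equal(sae_loss(sae0, Y), kl_sparsity(0.05, rep(0.5, 3)))
  # with penalties off and perfect reconstruction the loss is 0
  sae0$c_s <- 0
  expect_equal(sae_loss(sae0, Y), 0)
  expect_error(sae_loss(sae0, Y[0, , drop = FALSE]), "empty")
})

test_that("analytic gradient matches central finite differences", {
  set.seed(31)
  d <- 6; h <- 4; N <- 7
  for (rep in 1:3) {
    Y <- matrix(runif(N * d), N, d)
    theta <- rnorm(2 * d * h + d + h, sd = 0.6)
    an <- osteoDSSAE:::sae_loss_grad(theta, t(Y), d, h, 0.05, 1.0, 1e-4)
    eps <- 1e-6
    num <- vapply(seq_along(theta), function(i) {
      tp <- theta; tm <- theta
      tp[i] <- tp[i] + eps; tm[i] <- tm[i] - eps
      (osteoDSSAE:::sae_loss_grad(tp, t(Y), d, h, 0.05, 1.0, 1e-4)$value -
         osteoDSSAE:::sae_loss_grad(tm, t(Y), d, h, 0.05, 1.0, 1e-4)$value) /
        (2 * eps)
    }, 0)
    rel <- abs(num - an$grad) / pmax(1e-8, abs(num) + abs(an$grad))
    expect_lt(max(rel), 1e-5)
    # loss value agrees with the public sae_loss
    sae <- osteoDSSAE:::sae_unpack(theta, d, h, 0.05, 1.0, 1e-4)
    expect_equal(sae_loss(sae, Y), an$value)
  }
})

test_that("softmax head gradient matches finite differences", {
  set.seed(32)
  K <- 3; h <- 5; N <- 9
  X <- matrix(runif(N * h), N, h)
  y <- factor(sample(letters[1:K], N, TRUE), levels = letters[1:K])
  Yk <- t(stats::model.matrix(~ y - 1))
  theta <- rnorm(K * h + K, sd = 0.5)
  an <- osteoDSSAE:::softmax_loss_grad(theta, t(X), Yk, K, h, 1e-4)
  eps <- 1e-6
  num <- vapply(seq_along(theta), function(i) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + eps; tm[i] <- tm[i] - eps
    (osteoDSSAE:::softmax_loss_grad(tp, t(X), Yk, K, h, 1e-4)$value -
       osteoDSSAE:::softmax_loss_grad(tm, t(X), Yk, K, h, 1e-4)$value) /
      (2 * eps)
  }, 0)
  expect_lt(max(abs(num - an$grad) / pmax(1e-8, abs(num) + abs(an$grad))),
            1e-5)
})

test_that("training reduces reconstruction error on a 1-D manifold", {
  set.seed(33)
  t <- runif(60)
  Y <- cbind(0.2 + 0.6 * t, 0.8 - 0.6 * t)  # line segment in the unit box
  sae <- train_sae(Y, 1, c_s = 0, c_w = 0, epochs = 150, seed = 5)
  # the loss is (1/N) sum of squared errors over 2 dims: RMSE = sqrt(loss/2)
  init_rmse <- sqrt(attr(sae, "trace")[1] / 2)
  final_rmse <- sqrt(mean((decode(sae, encode(sae, Y)) - Y)^2))
  expect_lt(final_rmse, 0.1 * init_rmse)
  # same seed and data give identical weights
  sae2 <- train_sae(Y, 1, c_s = 0, c_w = 0, epochs = 150, seed = 5)
  expect_identical(sae$W_Y, sae2$W_Y)
  expect_identical(sae$B_Z, sae2$B_Z)
})

test_that("stronger sparsity pulls mean activations toward rho", {
  set.seed(34)
  Y <- matrix(runif(40 * 6), 40, 6)
  means <- vapply(c(0, 0.3, 1), function(cs) {
    sae <- train_sae(Y, 8, rho = 0.05, c_s = cs, c_w = 1e-4,
                     epochs = 120, seed = 9)
    mean(encode(sae, Y))
  }, 0)
  expect_true(all(diff(means) < 0))
  expect_lt(abs(means[3] - 0.05), abs(means[1] - 0.05))
})

test_that("an unregularized single-unit encoder aligns with the first PC", {
  set.seed(35)
  # anisotropic cloud kept in the sigmoid's near-linear regime
  t <- rnorm(200, 0, 0.12)
  n <- rnorm(200, 0, 0.015)
  dir <- c(1, 1) / sqrt(2)
  Y <- 0.5 + cbind(t * dir[1] - n * dir[2], t * dir[2] + n * dir[1])
  sae <- train_sae(Y, 1, c_s = 0, c_w = 0, epochs = 200, seed = 2)
  w <- as.numeric(sae$W_Y)
  pc1 <- prcomp(Y)$rotation[, 1]
  cosang <- abs(sum(w * pc1)) / sqrt(sum(w^2))
  expect_gt(cosang, 0.9)
})

test_that("stacked classifier separates Gaussian blobs and is consistent", {
  gf <- blob_fixture(n = 50, dim = 8, separation = 6, seed = 3)
  m <- suppressWarnings(train_dssae(gf$features, gf$labels,
                                    hidden_dims = c(32, 16, 8, 4),
                                    epochs = 120, fine_tune = 80,
                                    learning_rate = 0.5, seed = 2))
  pred <- predict(m, gf$features)
  expect_equal(error_rate(pred, gf$labels), 0)
  # probabilities sum to one
  pr <- predict(m, gf$features, type = "prob")
  expect_lt(max(abs(rowSums(pr) - 1)), 1e-9)
  # probabilities are invariant to duplicating a sample
  pr2 <- predict(m, gf$features[c(1, 1, 2), ], type = "prob")
  expect_equal(pr2[1, ], pr2[2, ])
  expect_equal(pr2[3, ], pr[2, ])
  # dimensional chaining of the stack
  dims <- vapply(m$saes, function(s) nrow(s$W_Y), 0L)
  expect_equal(dims, c(32L, 16L, 8L, 4L))
  for (k in 2:4)
    expect_equal(ncol(m$saes[[k]]$W_Y), nrow(m$saes[[k - 1]]$W_Y))
})

test_that("full-batch training is invariant to sample order", {
  gf <- blob_fixture(n = 15, dim = 5, separation = 5, seed = 8)
  perm <- sample(seq_along(gf$labels))
  m1 <- suppressWarnings(train_dssae(gf$features, gf$labels,
                                     hidden_dims = c(8, 4), epochs = 40,
                                     seed = 4))
  m2 <- suppressWarnings(train_dssae(gf$features[perm, ], gf$labels[perm],
                                     hidden_dims = c(8, 4), epochs = 40,
                                     seed = 4))
  p1 <- predict(m1, gf$features, type = "prob")
  p2 <- predict(m2, gf$features, type = "prob")
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("softmax predictions are shift invariant and ties deterministic", {
  gf <- blob_fixture(n = 10, dim = 4, separation = 4, seed = 12)
  m <- suppressWarnings(train_dssae(gf$features, gf$labels,
                                    hidden_dims = c(6, 3), epochs = 30,
                                    seed = 1))
  m2 <- m
  m2$softmax_B <- m$softmax_B + 5  # common shift of all logits
  expect_equal(predict(m, gf$features, type = "prob"),
               predict(m2, gf$features, type = "prob"))
  # tie broken toward the lowest class index
  m3 <- m
  m3$softmax_W[] <- 0; m3$softmax_B[] <- 0
  expect_true(all(predict(m3, gf$features) == m$class_names[1]))
})

test_that("model serialization round-trips exactly", {
  gf <- blob_fixture(n = 10, dim = 4, separation = 5, seed = 6)
  m <- suppressWarnings(train_dssae(gf$features, gf$labels,
                                    hidden_dims = c(6, 3), epochs = 30,
                                    seed = 3))
  f <- tempfile(fileext = ".json")
  save_dssae(m, f)
  m2 <- load_dssae(f)
  expect_identical(m$softmax_W, m2$softmax_W)
  expect_identical(m$saes[[1]]$W_Y, m2$saes[[1]]$W_Y)
  expect_identical(m$scaler$min, m2$scaler$min)
  expect_equal(predict(m, gf$features, type = "prob"),
               predict(m2, gf$features, type = "prob"))
  unlink(f)
})

test_that("training input contracts are enforced", {
  gf <- blob_fixture(n = 5, dim = 4, seed = 1)
  expect_error(train_dssae(gf$features, gf$labels[-1]), "label count")
  m <- suppressWarnings(train_dssae(gf$features, gf$labels,
                                    hidden_dims = c(4, 2), epochs = 10,
                                    seed = 1))
  expect_error(predict(m, gf$features[, 1:2]), "dimension mismatch")
  expect_warning(train_dssae(gf$features, gf$labels, hidden_dims = c(16, 2),
                             epochs = 5, seed = 1), "expansion")
})
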