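sphere_space <- function(D = 5) {
  do.call(search_space, lapply(seq_len(D), function(i)
    ss_continuous(paste0("x", i), -1, 1)))
}
sphere <- function(v) sum(unlist(v)^2)

test_that("error-rate fitness counts misclassifications as a percentage", {
  expect_equal(error_rate(rep("a", 50), rep("a", 50)), 0)
  pred <- c(rep("a", 95), rep("b", 5))
  expect_equal(error_rate(pred, rep("a", 100)), 5)
  set.seed(50)
  truth <- sample(c("a", "b", "c"), 40, TRUE)
  guess <- sample(c("a", "b", "c"), 40, TRUE)
  perm <- sample(40)
  expect_equal(error_rate(guess, truth), error_rate(guess[perm], truth[perm]))
  expect_error(error_rate(character(0), character(0)), "empty")
})

test_that("parcel ranking is lowest-pressure-first with index ties", {
  expect_equal(rank_parcels(c(3, 1, 2)), c(3L, 1L, 2L))
  expect_equal(rank_parcels(rep(2, 4)), 1:4)
  set.seed(51)
  r <- rank_parcels(runif(25))
  expect_setequal(r, 1:25)
  expect_warning(r2 <- rank_parcels(c(1, NaN, 0.5)), "non-finite")
  expect_equal(r2[2], 3L)
})

test_that("velocity update matches the hand-evaluated rank form", {
  cfg <- wdo_config(alpha = 0.4, g = 0.2, RT = 3, c = 0.4,
                    max_velocity = 0.3, seed = 1)
  # 1-D: the Coriolis surrogate uses the same dimension
  u <- update_velocity(x = 0.5, u = 0.1, k = 2, x_max = -0.2, cfg)
  # -0.2*0.5 + 0.6*0.1 + 0.5*3*(-0.7) - 0.4*0.1/2 = -1.11, clamped
  expect_equal(u, -0.3)
  cfg2 <- wdo_config(alpha = 0.4, g = 0.2, RT = 3, c = 0.4,
                     max_velocity = 10, seed = 1)
  expect_equal(update_velocity(0.5, 0.1, 2, -0.2, cfg2), -1.11)
  # rank-1 parcel feels no pressure-gradient pull
  u1 <- update_velocity(0.5, 0.1, 1, -0.2, cfg2)
  expect_equal(u1, -0.2 * 0.5 + 0.6 * 0.1 - 0.4 * 0.1)
  # with g = c = 0, alpha = 0, zero velocity and large rank the parcel heads
  # straight toward the leader scaled by RT
  cfg3 <- wdo_config(alpha = 0, g = 0, c = 0, RT = 3, max_velocity = 100,
                     seed = 1)
  x <- c(0.5, -0.4); xm <- c(-0.1, 0.3)
  u3 <- update_velocity(x, c(0, 0), k = 1e6, xm, cfg3)
  expect_equal(u3, 3 * (xm - x), tolerance = 1e-5)
  expect_error(update_velocity(0, 0, 0, 0, cfg), "rank")
})

test_that("position update applies unit time step and boundary handling", {
  cfg <- wdo_config(seed = 1)
  st <- update_position(c(0.2, -0.5), c(0, 0), cfg)
  expect_equal(st$x, c(0.2, -0.5))
  st2 <- update_position(0.9, 0.5, cfg)
  expect_equal(st2$x, 1)
  expect_equal(st2$u, 0)
  # positions stay inside the box under repeated random updates
  set.seed(52)
  x <- runif(3, -1, 1); u <- runif(3, -0.3, 0.3)
  for (i in 1:100) {
    st <- update_position(x, u, cfg)
    x <- st$x; u <- runif(3, -0.5, 0.5)
    expect_true(all(x >= -1 & x <= 1))
  }
  # reflecting boundary keeps the box too and negates velocity
  cfgr <- wdo_config(boundary = "reflect", seed = 1)
  st3 <- update_position(0.9, 0.5, cfgr)
  expect_equal(st3$x, 2 - 1.4)
  expect_equal(st3$u, -0.5)
})

test_that("search-space decode/encode round-trips on grid values", {
  sp <- search_space(
    ss_integer("epochs", list(20, 50, 100, 200)),
    ss_integer("batch_size", list(8, 16, 32, 64, Inf)),
    ss_continuous("learning_rate", 1e-4, 1e-1, transform = "log"),
    ss_continuous("c_s", 0, 1))
  for (v in list(list(epochs = 50, batch_size = Inf, learning_rate = 1e-3,
                      c_s = 0.25),
                 list(epochs = 200, batch_size = 8, learning_rate = 1e-1,
                      c_s = 1))) {
    dec <- decode_position(sp, encode_position(sp, v))
    expect_equal(dec$epochs, v$epochs)
    expect_equal(dec$batch_size, v$batch_size)
    expect_equal(dec$learning_rate, v$learning_rate, tolerance = 1e-12)
    expect_equal(dec$c_s, v$c_s)
  }
})

test_that("optimizer contracts: constant objective, monotone incumbent", {
  sp <- sphere_space(2)
  res <- wdo_optimize(function(v) 7, sp,
                      wdo_config(population = 5, iterations = 4, seed = 2))
  expect_equal(res$best_fitness, 7)
  expect_equal(res$history$best_fitness[1], 7)
  res2 <- wdo_optimize(sphere, sphere_space(3),
                       wdo_config(population = 8, iterations = 30, seed = 3))
  expect_true(all(diff(res2$history$best_fitness) <= 0))
  # reproducibility
  res3 <- wdo_optimize(sphere, sphere_space(3),
                       wdo_config(population = 8, iterations = 30, seed = 3))
  expect_identical(res2$best_x, res3$best_x)
})

test_that("optimizer converges on the 5-D sphere and beats random search", {
  bests <- c(); rs <- c()
  for (s in 1:10) {
    r <- wdo_optimize(sphere, sphere_space(5),
                      wdo_config(population = 20, iterations = 200,
                                 seed = s))
    bests <- c(bests, r$best_fitness)
    rs <- c(rs, random_search(sphere, sphere_space(5), 20 * 200, seed = s))
  }
  expect_lt(median(bests), 1e-2)
  expect_lt(median(bests), median(rs))
})

test_that("optimizer finds exhaustive optima on enumerable grids", {
  # 1-D grid of five points
  vals <- c(3, 1.2, 0.4, 2.5, 5)
  sp1 <- search_space(ss_integer("i", as.list(1:5)))
  f1 <- function(v) vals[v$i]
  exhaustive <- min(vals)
  hits <- vapply(1:10, function(s)
    wdo_optimize(f1, sp1, wdo_config(population = 4, iterations = 5,
                                     seed = s))$best_fitness, 0)
  expect_equal(median(hits), exhaustive)
  # 2-D grid (4 x 4 = 16 cells), budget >= 3x grid size
  sp2 <- search_space(ss_integer("a", as.list(0:3)),
                      ss_integer("b", as.list(0:3)))
  f2 <- function(v) (v$a - 2)^2 + (v$b - 1)^2 + 0.5
  hits2 <- vapply(1:10, function(s)
    wdo_optimize(f2, sp2, wdo_config(population = 8, iterations = 6,
                                     seed = s))$best_fitness, 0)
  expect_equal(median(hits2), 0.5)
})

test_that("removing the pressure-gradient term degrades convergence", {
  # a shifted sphere: the optimum is away from the origin, so the
  # gravitation term alone cannot find it and the rank-weighted pull toward
  # the leader has to do the work
  shifted <- function(v) sum((unlist(v) - 0.5)^2)
  with_rt <- vapply(1:6, function(s)
    wdo_optimize(shifted, sphere_space(5),
                 wdo_config(population = 15, iterations = 60,
                            seed = s))$best_fitness, 0)
  no_rt <- vapply(1:6, function(s)
    wdo_optimize(shifted, sphere_space(5),
                 wdo_config(population = 15, iterations = 60, RT = 1e-9,
                            seed = s))$best_fitness, 0)
  expect_lt(median(with_rt), median(no_rt))
})

test_that("failing objectives are assigned the worst fitness", {
  sp <- sphere_space(2)
  f <- function(v) if (v$x1 > 0) stop("boom") else sphere(v)
  warns <- character(0)
  res <- withCallingHandlers(
    wdo_optimize(f, sp, wdo_config(population = 4, iterations = 3,
                                   seed = 4)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_true(any(grepl("objective failed", warns)))
  expect_true(is.finite(res$best_fitness))
  expect_lte(res$best_fitness, 100)
})

test_that("hyperparameter tuning contracts hold on a tiny budget", {
  gf <- blob_fixture(n = 12, dim = 4, separation = 6, seed = 9)
  sp <- search_space(
    ss_integer("epochs", list(20, 40)),
    ss_integer("batch_size", list(Inf)),
    ss_continuous("learning_rate", 1e-3, 1e-1, transform = "log"))
  res <- suppressWarnings(tune_dssae(
    gf$features, gf$labels, space = sp,
    config = wdo_config(population = 2, iterations = 1, seed = 5),
    hidden_dims = c(6, 3)))
  expect_s3_class(res$model, "dssae_model")
  expect_named(res$best_hyperparameters,
               c("epochs", "batch_size", "learning_rate"))
  # identical seed, identical selection
  res2 <- suppressWarnings(tune_dssae(
    gf$features, gf$labels, space = sp,
    config = wdo_config(population = 2, iterations = 1, seed = 5),
    hidden_dims = c(6, 3)))
  expect_identical(res$best_hyperparameters, res2$best_hyperparameters)
  # mandatory dimensions enforced
  bad <- search_space(ss_continuous("learning_rate", 1e-3, 1e-1, "log"))
  expect_error(tune_dssae(gf$features, gf$labels, space = bad),
               "epochs")
})
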