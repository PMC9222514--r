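#' Classification error-rate fitness (percent)
#'
#' The objective minimized by the hyperparameter search:
#' `100 * misclassified / total`.
#'
#' @param predicted,actual equal-length label vectors.
#' @return percentage in \[0, 100\].
#' @export
error_rate <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("predicted and actual must have equal length")
  if (length(predicted) == 0) stop("empty input")
  100 * sum(as.character(predicted) != as.character(actual)) /
    length(predicted)
}

#' Wind Driven Optimization configuration
#'
#' Constants of the air-parcel velocity update: `alpha` friction, `g`
#' gravitation, `RT` pressure-gradient, `c` Coriolis, plus the elementwise
#' velocity clamp, population size and iteration budget. Values follow the
#' original WDO literature and are all tunable.
#'
#' @param population number of air parcels (>= 2).
#' @param alpha friction constant in \[0, 1).
#' @param g gravitation constant (>= 0).
#' @param RT pressure-gradient constant (> 0).
#' @param c Coriolis constant (>= 0).
#' @param max_velocity elementwise velocity clamp (> 0).
#' @param iterations number of evaluation/update rounds.
#' @param seed RNG seed.
#' @param boundary `"clip"` (clip position, zero the violating velocity
#'   component) or `"reflect"`.
#' @return a `wdo_config` object.
#' @export
wdo_config <- function(population = 20, alpha = 0.4, g = 0.2, RT = 3.0,
                       c = 0.4, max_velocity = 0.3, iterations = 50,
                       seed = 1, boundary = c("clip", "reflect")) {
  boundary <- match.arg(boundary)
  stopifnot(population >= 2, alpha >= 0, alpha < 1, g >= 0, RT > 0, c >= 0,
            max_velocity > 0, iterations >= 1)
  structure(list(population = as.integer(population), alpha = alpha, g = g,
                 RT = RT, c = c, max_velocity = max_velocity,
                 iterations = as.integer(iterations), seed = seed,
                 boundary = boundary),
            class = "wdo_config")
}

#' Rank air parcels by pressure
#'
#' Rank 1 is the lowest (best) pressure; ties are broken by parcel index.
#' Non-finite pressures are assigned the worst ranks with a warning.
#'
#' @param pressures numeric vector of fitness values.
#' @return integer ranks `k`, a permutation of `1..N`.
#' @export
rank_parcels <- function(pressures) {
  p <- pressures
  if (any(!is.finite(p))) {
    warning("non-finite pressure assigned worst rank")
    p[!is.finite(p)] <- Inf
  }
  rank(p, ties.method = "first")
}

#' Air-parcel velocity update
#'
#' Per dimension `d`:
#' `u_new[d] = -g*x[d] + (1-alpha)*u[d] + |1 - 1/k| * RT * (x_max[d] - x[d])
#'             - c * u[d'] / k`,
#' where `d'` is a uniformly chosen *other* dimension (the Coriolis
#' surrogate; `d' = d` in one dimension), followed by an elementwise clamp to
#' `[-max_velocity, max_velocity]`. The rank-1 parcel has no
#' pressure-gradient pull (`|1 - 1/1| = 0`).
#'
#' @param x current position vector in \[-1, 1\]^D.
#' @param u current velocity vector.
#' @param k parcel rank (1 = best).
#' @param x_max position of the rank-1 parcel.
#' @param config a [wdo_config()].
#' @return clamped new velocity vector.
#' @export
update_velocity <- function(x, u, k, x_max, config) {
  if (k < 1) stop("internal error: rank must be >= 1")
  D <- length(x)
  dprime <- if (D == 1) 1L else vapply(seq_len(D), function(d) {
    others <- setdiff(seq_len(D), d)
    others[sample.int(D - 1L, 1L)]
  }, integer(1))
  u_new <- -config$g * x + (1 - config$alpha) * u +
    abs(1 - 1 / k) * config$RT * (x_max - x) -
    config$c * u[dprime] / k
  pmin(config$max_velocity, pmax(-config$max_velocity, u_new))
}

#' Air-parcel position update
#'
#' `x_new = x + u_new` (unit time step), then boundary handling: by default
#' positions are clipped into \[-1, 1\] and the violating velocity component
#' is zeroed; `"reflect"` mirrors the position and negates that component.
#'
#' @param x current position.
#' @param u_new updated velocity.
#' @param config a [wdo_config()].
#' @return list with `x` (new position) and `u` (possibly modified velocity).
#' @export
update_position <- function(x, u_new, config) {
  xn <- x + u_new
  out <- xn < -1 | xn > 1
  if (config$boundary == "clip") {
    xn <- pmin(1, pmax(-1, xn))
    u_new[out] <- 0
  } else {
    xn[out] <- pmin(1, pmax(-1, 2 * sign(xn[out]) - xn[out]))
    u_new[out] <- -u_new[out]
  }
  list(x = xn, u = u_new)
}

# ---- search space ----

#' Hyperparameter search space
#'
#' Describes how the normalized WDO box \[-1, 1\]^D maps to native
#' hyperparameter units. Each dimension is one of [ss_continuous()]
#' (linear or log scale) or [ss_integer()] (finite value set, nearest-grid
#' decoding).
#'
#' @param ... dimension descriptors.
#' @return a `search_space` object.
#' @export
search_space <- function(...) {
  dims <- list(...)
  nm <- vapply(dims, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate dimension names")
  structure(list(dims = dims, names = nm), class = "search_space")
}

#' @param name dimension name.
#' @param lower,upper finite bounds (native units).
#' @param transform `"linear"` or `"log"` spacing.
#' @rdname search_space
#' @export
ss_continuous <- function(name, lower, upper, transform = c("linear", "log")) {
  transform <- match.arg(transform)
  stopifnot(is.finite(lower), is.finite(upper), lower < upper,
            transform == "linear" || lower > 0)
  list(kind = "continuous", name = name, lower = lower, upper = upper,
       transform = transform)
}

#' @param values finite set of allowed values (ordered).
#' @rdname search_space
#' @export
ss_integer <- function(name, values) {
  values <- as.list(values)
  vv <- unlist(values)
  stopifnot(length(vv) >= 1, is.numeric(vv), !anyNA(vv))
  list(kind = "integer", name = name, values = values)
}

#' Decode / encode between the normalized box and native units
#'
#' `decode_position` maps a point of \[-1, 1\]^D to a named list of native
#' values (nearest grid point for integer dimensions); `encode_position` is
#' its right inverse on grid values.
#'
#' @param space a [search_space()].
#' @param x numeric vector in \[-1, 1\]^D.
#' @return named list of native values.
#' @export
decode_position <- function(space, x) {
  stopifnot(length(x) == length(space$dims))
  out <- Map(function(dim, xi) {
    t <- (xi + 1) / 2
    if (dim$kind == "continuous") {
      if (dim$transform == "log")
        exp(log(dim$lower) + t * (log(dim$upper) - log(dim$lower)))
      else dim$lower + t * (dim$upper - dim$lower)
    } else {
      m <- length(dim$values)
      dim$values[[min(m, max(1, round(t * (m - 1)) + 1))]]
    }
  }, space$dims, as.list(x))
  names(out) <- space$names
  out
}

#' @param values named list of native values.
#' @rdname decode_position
#' @export
encode_position <- function(space, values) {
  vapply(space$dims, function(dim) {
    v <- values[[dim$name]]
    if (is.null(v)) stop("missing value for dimension ", dim$name)
    t <- if (dim$kind == "continuous") {
      if (dim$transform == "log")
        (log(v) - log(dim$lower)) / (log(dim$upper) - log(dim$lower))
      else (v - dim$lower) / (dim$upper - dim$lower)
    } else {
      i <- which(vapply(dim$values, identical, TRUE, v))
      if (length(i) == 0) i <- which.min(abs(unlist(dim$values) - v))
      (i[1] - 1) / max(1, length(dim$values) - 1)
    }
    2 * t - 1
  }, numeric(1))
}

#' Default DSSAE hyperparameter search space
#'
#' Epochs on a log-spaced integer grid 20..200, batch size in
#' {8, 16, 32, 64, full}, learning rate log-uniform on \[1e-4, 1e-1\].
#'
#' @return a [search_space()].
#' @export
default_search_space <- function() {
  epochs_grid <- unique(round(exp(seq(log(20), log(200), length.out = 10))))
  search_space(
    ss_integer("epochs", as.list(epochs_grid)),
    ss_integer("batch_size", list(8, 16, 32, 64, Inf)),
    ss_continuous("learning_rate", 1e-4, 1e-1, transform = "log"))
}

#' Wind Driven Optimization loop
#'
#' Minimizes `objective(decoded position)` over a [search_space()]. Air
#' parcels start uniformly in the normalized box; each round evaluates all
#' parcels, ranks them by pressure ([rank_parcels()]), then applies
#' [update_velocity()] and [update_position()]. An objective that throws is
#' assigned the worst fitness (100). Fully reproducible given
#' `config$seed`.
#'
#' @param objective function taking a named list of native values, returning
#'   a scalar fitness (lower is better).
#' @param space a [search_space()].
#' @param config a [wdo_config()].
#' @return list with `best_position` (named native values), `best_fitness`,
#'   `best_x` (normalized), and `history` (data frame: iteration,
#'   best_fitness, mean_fitness, one column per decoded dimension of the
#'   incumbent).
#' @export
wdo_optimize <- function(objective, space, config = wdo_config()) {
  D <- length(space$dims)
  N <- config$population
  with_seed(config$seed, {
    X <- matrix(stats::runif(N * D, -1, 1), N, D)
    U <- matrix(stats::runif(N * D, -config$max_velocity,
                             config$max_velocity), N, D)
    best_f <- Inf; best_x <- X[1, ]; hist_rows <- vector("list", 0)
    for (it in seq_len(config$iterations)) {
      press <- vapply(seq_len(N), function(i) {
        val <- tryCatch(objective(decode_position(space, X[i, ])),
                        error = function(e) {
                          warning("objective failed: ", conditionMessage(e))
                          100
                        })
        as.numeric(val)
      }, numeric(1))
      k <- rank_parcels(press)
      leader <- which(k == 1)
      if (press[leader] < best_f) {
        best_f <- press[leader]; best_x <- X[leader, ]
      }
      dec <- decode_position(space, best_x)
      hist_rows[[it]] <- data.frame(
        iteration = it, best_fitness = best_f,
        mean_fitness = mean(press[is.finite(press)]),
        lapply(dec, function(v) if (is.numeric(v)) v else as.character(v)))
      x_max <- X[leader, ]
      for (i in seq_len(N)) {
        u_new <- update_velocity(X[i, ], U[i, ], k[i], x_max, config)
        st <- update_position(X[i, ], u_new, config)
        X[i, ] <- st$x; U[i, ] <- st$u
      }
    }
    history <- do.call(rbind, hist_rows)
    list(best_position = decode_position(space, best_x),
         best_fitness = best_f, best_x = best_x, history = history)
  })
}

#' Tune DSSAE hyperparameters with WDO
#'
#' Splits the training data into an internal stratified 75/25
#' train/validation split; each parcel's pressure is the validation
#' [error_rate()] of a DSSAE trained with the decoded hyperparameters. The
#' best configuration is then retrained on the full training set. The search
#' space must contain the `epochs`, `batch_size` and `learning_rate`
#' dimensions; it may additionally tune `rho`, `c_s`, `c_w`.
#'
#' @param features samples x features matrix.
#' @param labels class labels.
#' @param space a [search_space()] (default [default_search_space()]).
#' @param config a [wdo_config()].
#' @param hidden_dims stacked-autoencoder layer sizes.
#' @param val_fraction internal validation fraction.
#' @param ... fixed arguments forwarded to [train_dssae()].
#' @return list with `model` (retrained on all data), `best_hyperparameters`,
#'   `best_fitness` (validation error %), and `history`.
#' @export
tune_dssae <- function(features, labels, space = default_search_space(),
                       config = wdo_config(), hidden_dims = c(256, 128, 64, 32),
                       val_fraction = 0.25, ...) {
  need <- c("epochs", "batch_size", "learning_rate")
  if (!all(need %in% space$names))
    stop("search space must include dimensions: ",
         paste(setdiff(need, space$names), collapse = ", "))
  features <- as.matrix(features)
  parts <- split_dataset(labels, c(train = 1 - val_fraction,
                                   validation = val_fraction),
                         seed = stage_seed(config$seed, "split"))
  tr <- parts$train; va <- parts$validation
  fixed <- list(...)
  objective <- function(hp) {
    args <- c(list(features = features[tr, , drop = FALSE],
                   labels = labels[tr], hidden_dims = hidden_dims,
                   seed = stage_seed(config$seed, "train")),
              hp, fixed)
    m <- do.call(train_dssae, args)
    error_rate(predict(m, features[va, , drop = FALSE]), labels[va])
  }
  res <- wdo_optimize(objective, space, config)
  final_args <- c(list(features = features, labels = labels,
                       hidden_dims = hidden_dims,
                       seed = stage_seed(config$seed, "train")),
                  res$best_position, fixed)
  list(model = do.call(train_dssae, final_args),
       best_hyperparameters = res$best_position,
       best_fitness = res$best_fitness, history = res$history)
}
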