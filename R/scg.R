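# Scaled conjugate gradient (Moller 1993), batch form. Used to train each
# sparse autoencoder layer and the softmax head.
#
# fn/gr take a parameter vector; returns list(par, value, trace) where trace
# is the loss after each accepted step.
scg_minimize <- function(par, fn, gr, max_iter = 100,
                         sigma0 = 1e-5, lambda0 = 1e-7, tol = 1e-10) {
  w <- par
  n <- length(w)
  lambda <- lambda0; lambda_bar <- 0
  f <- fn(w)
  if (!is.finite(f)) stop("non-finite loss at initialization")
  g <- gr(w)
  r <- -g
  p <- r
  success <- TRUE
  trace <- numeric(0)
  delta <- 0; norm_p2 <- sum(p^2)
  for (k in seq_len(max_iter)) {
    if (success) {
      norm_p2 <- sum(p^2)
      if (norm_p2 < 1e-300) break
      sigma <- sigma0 / sqrt(norm_p2)
      s <- (gr(w + sigma * p) - g) / sigma
      delta <- sum(p * s)
    }
    delta <- delta + (lambda - lambda_bar) * norm_p2
    if (delta <= 0) {  # make the Hessian approximation positive definite
      lambda_bar <- 2 * (lambda - delta / norm_p2)
      delta <- -delta + lambda * norm_p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    f_new <- fn(w + alpha * p)
    Delta <- if (is.finite(f_new)) 2 * delta * (f - f_new) / mu^2 else -1
    if (Delta >= 0) {  # accept step
      w <- w + alpha * p
      f_old <- f; f <- f_new
      g_new <- gr(w)
      r_new <- -g_new
      lambda_bar <- 0; success <- TRUE
      if (k %% n == 0) {
        p <- r_new  # restart in steepest-descent direction
      } else {
        beta <- (sum(r_new^2) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new; g <- g_new
      if (Delta >= 0.75) lambda <- lambda / 4
      trace <- c(trace, f)
      if (abs(f_old - f) < tol * (abs(f_old) + tol)) break
    } else {
      lambda_bar <- lambda; success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta * (1 - Delta) / norm_p2
    if (lambda > 1e100) break
  }
  list(par = w, value = f, trace = trace)
}
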