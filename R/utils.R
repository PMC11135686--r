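# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so seeded pipelines never perturb the
# global stream.
with_rng_seed <- function(seed, expr) {
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
  force(expr)
}

# Log-normal draws with arithmetic mean `mean` and coefficient of variation
# `cv` (sd/mean): sigma^2 = log(1 + cv^2), mu = log(mean) - sigma^2/2.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Levenberg-Marquardt least squares with forward-difference Jacobian.
# fn(x) returns the residual vector; x is unconstrained (callers work in
# log10-parameter space and clamp to box bounds via `lower`/`upper`).
lm_least_squares <- function(fn, x0, lower = NULL, upper = NULL,
                             max_iter = 200, ftol = 1e-12, xtol = 1e-10,
                             fd_step = 1e-6) {
  clamp <- function(x) {
    if (!is.null(lower)) x <- pmax(x, lower)
    if (!is.null(upper)) x <- pmin(x, upper)
    x
  }
  x <- clamp(x0)
  r <- fn(x)
  if (!all(is.finite(r))) return(list(par = x, rss = Inf, converged = FALSE,
                                      iter = 0L))
  rss <- sum(r^2)
  n <- length(x)
  lambda <- 1e-3
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- matrix(0, length(r), n)
    for (j in seq_len(n)) {
      h <- fd_step * max(abs(x[j]), 1)
      xj <- x; xj[j] <- xj[j] + h
      xj <- clamp(xj)
      hj <- xj[j] - x[j]
      if (hj == 0) { xj[j] <- x[j] - h; xj <- clamp(xj); hj <- xj[j] - x[j] }
      rj <- fn(xj)
      if (!all(is.finite(rj))) rj <- r        # frozen column on failure
      J[, j] <- (rj - r) / hj
    }
    g <- crossprod(J, r)
    A <- crossprod(J)
    improved <- FALSE
    for (k in 1:12) {
      step <- tryCatch(
        solve(A + lambda * diag(diag(A) + 1e-12, n), -g),
        error = function(e) NULL)
      if (!is.null(step)) {
        xn <- clamp(x + as.numeric(step))
        rn <- fn(xn)
        if (all(is.finite(rn)) && sum(rn^2) < rss) {
          drop_rel <- (rss - sum(rn^2)) / max(rss, 1e-300)
          dx <- max(abs(xn - x))
          x <- xn; r <- rn; rss <- sum(rn^2)
          lambda <- max(lambda / 3, 1e-12)
          improved <- TRUE
          if (drop_rel < ftol || dx < xtol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 5
    }
    if (!improved) { converged <- TRUE; break }
    if (converged) break
  }
  list(par = x, rss = rss, converged = converged, iter = iter)
}
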