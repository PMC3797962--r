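#' Covariance matrix adaptation evolution strategy
#'
#' Standard (mu/mu_w, lambda) CMA-ES with cumulative step-size adaptation,
#' rank-one and rank-mu covariance updates, used here as the episodic
#' policy-search engine: it samples candidate policy vectors from an adapted
#' multivariate Gaussian, ranks them by episode cost, and updates the search
#' distribution from the better half.  Only the initial step size needs
#' tuning.  Box bounds are handled by projection: the objective is evaluated
#' at the projected point with a quadratic penalty on the violation.
#'
#' @param fn Objective function of a numeric vector, returning a scalar
#'   cost (minimized).
#' @param x0 Initial mean vector (finite, within bounds).
#' @param sigma0 Initial step size (> 0).
#' @param budget Maximum number of objective evaluations.
#' @param lower,upper Optional per-coordinate box bounds.
#' @param lambda Population size; default `4 + floor(3 * log(n))`.
#' @param seed Optional integer seed for the sampling stream.
#' @param stop_value Stop early when the best cost falls at or below this.
#' @return List with `par` (best-so-far vector), `value` (its cost),
#'   `evaluations`, `restarts`, and `curve`, a data frame with one row per
#'   evaluation (`evaluation`, `current_cost`, `best_cost`); `best_cost` is
#'   non-increasing.
#' @export
cma_es <- function(fn, x0, sigma0, budget,
                   lower = NULL, upper = NULL, lambda = NULL,
                   seed = NULL, stop_value = -Inf) {
  stopifnot(sigma0 > 0, budget >= 0, all(is.finite(x0)))
  if (!is.null(seed)) set.seed(seed)
  n <- length(x0)
  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  lambda <- max(4L, as.integer(lambda))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)

  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  has_lo <- !is.null(lower); has_hi <- !is.null(upper)
  project <- function(x) {
    if (has_lo) x <- pmax(x, lower)
    if (has_hi) x <- pmin(x, upper)
    x
  }
  eval_pt <- function(x) {
    xp <- project(x)
    pen <- sum((x - xp)^2)
    fn(xp) + 1e4 * pen
  }

  init_state <- function(m) {
    list(m = m, sigma = sigma0, C = diag(n), ps = numeric(n),
         pc = numeric(n), eig = list(vectors = diag(n), values = rep(1, n)))
  }
  st <- init_state(project(x0))

  best_x <- project(x0)
  best_f <- Inf
  evals <- 0L
  restarts <- 0L
  cur_hist <- numeric(0); best_hist <- numeric(0)

  while (evals < budget && best_f > stop_value) {
    B <- st$eig$vectors
    Dg <- sqrt(pmax(st$eig$values, .Machine$double.eps))
    nb <- min(lambda, budget - evals)
    Z <- matrix(stats::rnorm(n * lambda), n, lambda)
    Y <- B %*% (Dg * Z)                       # C^{1/2} z
    X <- st$m + st$sigma * Y
    f <- rep(Inf, lambda)
    for (i in seq_len(nb)) {
      f[i] <- eval_pt(X[, i])
      evals <- evals + 1L
      if (f[i] < best_f) { best_f <- f[i]; best_x <- project(X[, i]) }
      cur_hist <- c(cur_hist, f[i]); best_hist <- c(best_hist, best_f)
    }
    if (nb < lambda) break
    ord <- order(f)
    sel <- ord[seq_len(mu)]
    yw <- Y[, sel, drop = FALSE] %*% w
    st$m <- st$m + st$sigma * as.vector(yw)

    # step-size path (uses C^{-1/2} y = B z)
    zw <- as.vector(B %*% (Z[, sel, drop = FALSE] %*% w))
    st$ps <- (1 - cs) * st$ps + sqrt(cs * (2 - cs) * mueff) * zw
    hsig <- sqrt(sum(st$ps^2)) /
      sqrt(1 - (1 - cs)^(2 * evals / lambda)) / chiN < 1.4 + 2 / (n + 1)
    st$pc <- (1 - cc) * st$pc +
      hsig * sqrt(cc * (2 - cc) * mueff) * as.vector(yw)

    Ysel <- Y[, sel, drop = FALSE]
    rank_mu <- Ysel %*% (w * t(Ysel))
    st$C <- (1 - c1 - cmu) * st$C +
      c1 * (st$pc %o% st$pc + (1 - hsig) * cc * (2 - cc) * st$C) +
      cmu * rank_mu
    st$C <- (st$C + t(st$C)) / 2
    st$sigma <- st$sigma * exp((cs / damps) * (sqrt(sum(st$ps^2)) / chiN - 1))

    eig <- eigen(st$C, symmetric = TRUE)
    degenerate <- !all(is.finite(eig$values)) ||
      max(eig$values) / max(min(eig$values), .Machine$double.xmin) > 1e14 ||
      st$sigma < 1e-12 || st$sigma > 1e7
    if (degenerate) {
      restarts <- restarts + 1L
      st <- init_state(best_x)
    } else {
      st$eig <- eig
    }
  }

  curve <- data.frame(evaluation = seq_along(cur_hist),
                      current_cost = cur_hist, best_cost = best_hist)
  list(par = best_x, value = best_f, evaluations = evals,
       restarts = restarts, curve = curve)
}
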