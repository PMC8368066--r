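# Approximate leave-one-out cross-validation via Pareto-smoothed importance
# sampling (PSIS-LOO), and Pseudo-BMA+ model weights from the Bayesian
# bootstrap over pointwise elpd differences.

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Generalized-Pareto fit to exceedances x > 0 by the Zhang & Stephens (2009)
# profile-posterior method, with the mild shape regularization toward 0.5
# used in PSIS. Returns shape k (xi) and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior <- 3
  m <- 30L + floor(sqrt(n))
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  jj <- seq_len(m)
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior * xstar)
  k_of <- vapply(theta, function(th) mean(log1p(-th * x)), numeric(1))
  # profile log-likelihood: l(theta) = n [log(-theta/k) - k - 1]
  l_theta <- n * (log(-theta / k_of) - k_of - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(l_theta - l_theta[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  k <- (n * k + prior * 0.5) / (n + prior) # regularized shape
  list(k = k, sigma = sigma)
}

# Generalized-Pareto quantile function (location 0).
gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smooth one vector of log importance weights (up to a constant).
# Returns the smoothed log weights and the fitted tail shape k.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5L || length(unique(lw)) < 5L) return(list(log_weights = lw, k = -Inf))
  ord <- order(lw)
  tail_idx <- ord[(S - M + 1L):S]
  cutoff <- lw[ord[S - M]]
  exceed <- exp(lw[tail_idx]) - exp(cutoff)
  if (all(exceed <= 0)) return(list(log_weights = lw, k = -Inf))
  fit <- gpd_fit(exceed)
  q <- gpd_quantile((seq_len(M) - 0.5) / M, fit$k, fit$sigma)
  smoothed <- log(q + exp(cutoff))
  # assign smoothed quantiles to the tail in rank order, truncate at max raw
  smoothed <- pmin(smoothed, 0)
  lw[tail_idx[order(lw[tail_idx])]] <- smoothed
  list(log_weights = lw, k = fit$k)
}

#' PSIS-LOO expected log predictive density
#'
#' Computes leave-one-out cross-validation from posterior draws by importance
#' sampling, stabilizing each observation's importance weights with a
#' generalized-Pareto fit to their tail (Pareto-smoothed importance
#' sampling). Tail shapes `k > 0.7` indicate unreliable pointwise estimates
#' and are flagged.
#'
#' @param loglik pointwise log-likelihood matrix (posterior draws x
#'   observations), e.g. the `loglik` element of a [fit_hierarchical()] fit.
#' @return a list of class `psis_loo`: `elpd_loo`, `se_elpd_loo`,
#'   `pointwise` (per-observation elpd), `pareto_k`, `n_high_k`.
#' @export
psis_loo <- function(loglik) {
  if (inherits(loglik, "hier_fit")) loglik <- loglik$loglik
  stopifnot(is.matrix(loglik), nrow(loglik) > 1L)
  N <- ncol(loglik)
  pointwise <- numeric(N)
  k <- numeric(N)
  for (i in seq_len(N)) {
    sm <- psis_smooth(-loglik[, i])
    lw <- sm$log_weights - logsumexp(sm$log_weights)
    pointwise[i] <- logsumexp(lw + loglik[, i])
    k[i] <- sm$k
  }
  n_high <- sum(k > 0.7)
  if (n_high > 0L) {
    warning(n_high, " observation(s) with Pareto k > 0.7; PSIS-LOO may be unreliable")
  }
  structure(list(elpd_loo = sum(pointwise),
                 se_elpd_loo = sqrt(N * stats::var(pointwise)),
                 pointwise = pointwise, pareto_k = k, n_high_k = n_high),
            class = "psis_loo")
}

#' @export
print.psis_loo <- function(x, ...) {
  cat(sprintf("<psis_loo> elpd_loo %.2f (se %.2f), %d/%d Pareto k > 0.7\n",
              x$elpd_loo, x$se_elpd_loo, x$n_high_k, length(x$pareto_k)))
  invisible(x)
}

#' Pseudo-BMA+ model weights
#'
#' Akaike-type weights over candidate models from their pointwise PSIS-LOO
#' elpd values, regularized by the Bayesian bootstrap: each bootstrap
#' replicate draws Dirichlet(1) observation weights, recomputes each model's
#' weighted total elpd, and softmax-normalizes across models; the reported
#' weight is the average over replicates. Weights sum to 1.
#'
#' @param loos list of [psis_loo()] objects fitted to the same data.
#' @param n_boot Bayesian-bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return named numeric vector of weights (names from `loos`).
#' @export
pseudo_bma_plus <- function(loos, n_boot = 1000L, seed = 1L) {
  stopifnot(length(loos) >= 2L)
  pw <- sapply(loos, function(l) l$pointwise)
  if (is.null(dim(pw))) stop("pointwise elpd vectors have mismatched lengths")
  n <- nrow(pw); K <- ncol(pw)
  w_acc <- matrix(0, n_boot, K)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      g <- stats::rgamma(n, 1)
      alpha <- g / sum(g)
      z <- n * as.numeric(t(pw) %*% alpha)
      w_acc[b, ] <- exp(z - max(z)) / sum(exp(z - max(z)))
    }
  })
  w <- colMeans(w_acc)
  names(w) <- names(loos)
  w / sum(w)
}

#' Compare hierarchical fits by PSIS-LOO and Pseudo-BMA+
#'
#' @param fits named list of [fit_hierarchical()] fits on identical data.
#' @param n_boot,seed passed to [pseudo_bma_plus()].
#' @return a list with `loos` (per model), `elpd` (named vector), and
#'   `weights` (Pseudo-BMA+ weights summing to 1).
#' @export
compare_models <- function(fits, n_boot = 1000L, seed = 1L) {
  stopifnot(length(fits) >= 2L)
  ys <- lapply(fits, function(f) f$y)
  for (k in seq_along(fits)[-1]) {
    if (!isTRUE(all.equal(ys[[1]], ys[[k]]))) {
      stop("models were not fitted to identical data")
    }
  }
  loos <- lapply(fits, psis_loo)
  if (is.null(names(loos))) names(loos) <- paste0("model", seq_along(loos))
  n_high_k <- vapply(loos, `[[`, numeric(1), "n_high_k")
  list(loos = loos,
       elpd = vapply(loos, `[[`, numeric(1), "elpd_loo"),
       weights = pseudo_bma_plus(loos, n_boot = n_boot, seed = seed),
       n_high_k = n_high_k,
       reliable = all(n_high_k == 0))
}
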