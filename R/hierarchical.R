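# Bayesian hierarchical regressions of above-baseline distances on genre or
# annotation layer, with crossed verb-level random intercepts and slopes.
# Backend: Gibbs sampling via JAGS (rjags).

#' Prior specification for the hierarchical regressions
#'
#' Weakly informative Student-t priors, location 0, 5 degrees of freedom:
#' scale 10 for the intercept and 2.5 for coefficients. Group-level standard
#' deviations and the residual standard deviation get half-Student-t(5)
#' priors with the scales given here.
#'
#' @param df degrees of freedom (default 5).
#' @param scale_intercept,scale_coefficient fixed-effect prior scales
#'   (defaults 10 and 2.5).
#' @param scale_sd,scale_sigma half-t scales for group-level and residual
#'   standard deviations (defaults 2.5).
#' @return a list of class `prior_spec`.
#' @export
prior_spec <- function(df = 5, scale_intercept = 10, scale_coefficient = 2.5,
                       scale_sd = 2.5, scale_sigma = 2.5) {
  stopifnot(df > 0, scale_intercept > 0, scale_coefficient > 0,
            scale_sd > 0, scale_sigma > 0)
  structure(list(df = df, scale_intercept = scale_intercept,
                 scale_coefficient = scale_coefficient,
                 scale_sd = scale_sd, scale_sigma = scale_sigma),
            class = "prior_spec")
}

jags_model_string <- function(L) {
  coef_prior <- if (L >= 2L)
    "  for (l in 2:L) { beta[l] ~ dt(0, pow(scale_coef, -2), df) }\n" else ""
  paste0("
model {
  for (i in 1:N) {
    mu[i] <- inprod(X[i, ], beta) + inprod(X[i, ], u_c[caus[i], ]) +
             inprod(X[i, ], u_n[noncaus[i], ])
    y[i] ~ dnorm(mu[i], prec)
  }
  prec <- 1 / (sigma^2 + tau^2)
  beta[1] ~ dt(0, pow(scale_int, -2), df)
", coef_prior, "
  # swept (finite-population) fixed effects over the verb sets in the data;
  # the raw beta / random-mean split is only prior-identified in a crossed
  # design and mixes slowly under Gibbs, while this sum is data-identified
  for (l in 1:L) {
    b_sweep[l] <- beta[l] + mean(u_c[, l]) + mean(u_n[, l])
  }
  for (l in 1:L) {
    sd_c[l] ~ dt(0, pow(scale_sd, -2), df) T(0, )
    sd_n[l] ~ dt(0, pow(scale_sd, -2), df) T(0, )
    for (j in 1:Jc) { u_c[j, l] ~ dnorm(0, pow(sd_c[l], -2)) }
    for (j in 1:Jn) { u_n[j, l] ~ dnorm(0, pow(sd_n[l], -2)) }
  }
  sigma ~ dt(0, pow(scale_sigma, -2), df) T(0, )
}
")
}

#' Fit the hierarchical discrimination regression
#'
#' Fits `response ~ predictor + (1 + predictor | caus) + (1 + predictor |
#' noncaus)` with a Gaussian likelihood: treatment-coded fixed effects
#' (reference level `cds` for genre, `raw` for layer, when present) and
#' crossed random intercepts and slopes for the individual causative and
#' non-causative verbs. Group-level effects are independent across
#' coefficients (diagonal covariance) with half-t(5) SD priors. Reported
#' fixed effects are the swept (finite-population) quantities
#' `beta + mean(u_caus) + mean(u_noncaus)`: in a crossed design the raw
#' split between the fixed effect and the random-effect means is identified
#' only through the prior, whereas the sum is data-identified, mixes well
#' under Gibbs sampling, and is the estimand of interest when the verb
#' lists are the whole population under study. An optional
#' known observation error `obs_error_sd` (e.g. the bootstrap SD of the
#' baseline) is added to the residual variance, giving the measurement-error
#' variant of the model.
#'
#' @param rows data.frame with columns `response`, the predictor column
#'   (`genre` or `layer`), `caus`, `noncaus`.
#' @param predictor `"genre"` or `"layer"`.
#' @param priors a [prior_spec()].
#' @param chains,iter,warmup MCMC settings: `chains` parallel chains of
#'   `warmup` adaptation+burn-in iterations followed by `iter` kept
#'   iterations each. Defaults 4 chains x (1000 + 1000).
#' @param seed integer seed; chain RNGs are derived deterministically.
#' @param obs_error_sd known Gaussian observation error SD of the response
#'   (default 0 = plain model).
#' @param intercept_only drop the predictor from the design (fixed intercept
#'   plus random verb intercepts only) — the comparison null model.
#' @param quiet suppress JAGS progress output.
#' @return an object of class `hier_fit`: `draws` (a [coda::mcmc.list] of the
#'   fixed effects and variance components), `fixed` (matrix of pooled
#'   fixed-effect draws), `loglik` (pooled draws x observations pointwise
#'   log-likelihood), `diagnostics` (split-chain R-hat and effective sample
#'   size per fixed effect), plus the design metadata.
#' @export
fit_hierarchical <- function(rows, predictor = c("genre", "layer"),
                             priors = prior_spec(), chains = 4L, iter = 1000L,
                             warmup = 1000L, seed = 1L, obs_error_sd = 0,
                             intercept_only = FALSE, quiet = TRUE) {
  predictor <- match.arg(predictor)
  stopifnot(is.data.frame(rows), all(c("response", "caus", "noncaus")
                                     %in% names(rows)))
  if (intercept_only) {
    levs <- character(0)
    X <- matrix(1, nrow(rows), 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    stopifnot(predictor %in% names(rows))
    ref <- if (predictor == "genre") "cds" else "raw"
    pv <- as.character(rows[[predictor]])
    levs <- unique(pv)
    if (length(levs) < 2L) stop("predictor '", predictor, "' needs >= 2 levels")
    if (ref %in% levs) levs <- c(ref, sort(setdiff(levs, ref))) else levs <- sort(levs)
    pv <- factor(pv, levels = levs)
    X <- stats::model.matrix(~pv)
    colnames(X) <- c("(Intercept)", paste0(predictor, levs[-1]))
  }
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  caus_lev <- sort(unique(as.character(rows$caus)))
  nonc_lev <- sort(unique(as.character(rows$noncaus)))
  dat <- list(
    y = as.numeric(rows$response), X = X, N = nrow(rows), L = ncol(X),
    caus = match(as.character(rows$caus), caus_lev), Jc = length(caus_lev),
    noncaus = match(as.character(rows$noncaus), nonc_lev), Jn = length(nonc_lev),
    df = priors$df, scale_int = priors$scale_intercept,
    scale_coef = priors$scale_coefficient, scale_sd = priors$scale_sd,
    scale_sigma = priors$scale_sigma, tau = obs_error_sd
  )
  inits <- lapply(seq_len(chains), function(k) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer((as.numeric(seed) * 1009 + 97 * k) %% 2147483629) + 1L)
  })
  run <- function() {
    jm <- rjags::jags.model(textConnection(jags_model_string(dat$L)), data = dat,
                            inits = inits, n.chains = chains, n.adapt = 0,
                            quiet = TRUE)
    invisible(utils::capture.output(stats::update(jm, n.iter = warmup)))
    rjags::coda.samples(jm, variable.names = c("beta", "b_sweep", "sigma",
                                               "sd_c", "sd_n", "u_c", "u_n"),
                        n.iter = iter)
  }
  samp <- if (quiet) suppressWarnings({
    invisible(utils::capture.output(out <- run())); out
  }) else run()

  pooled <- as.matrix(samp)
  # JAGS drops the index on length-1 vectors
  beta_cols <- if (ncol(X) == 1L) "beta" else paste0("beta[", seq_len(ncol(X)), "]")
  sweep_cols <- if (ncol(X) == 1L) "b_sweep" else
    paste0("b_sweep[", seq_len(ncol(X)), "]")
  fixed <- pooled[, sweep_cols, drop = FALSE]
  colnames(fixed) <- colnames(X)

  # pointwise log-likelihood, reconstructed from the draws
  S <- nrow(pooled)
  mu <- fixed %*% t(X)
  for (l in seq_len(ncol(X))) {
    uc <- pooled[, paste0("u_c[", dat$caus, ",", l, "]"), drop = FALSE]
    un <- pooled[, paste0("u_n[", dat$noncaus, ",", l, "]"), drop = FALSE]
    xl <- matrix(X[, l], S, dat$N, byrow = TRUE)
    mu <- mu + uc * xl + un * xl
  }
  sd_tot <- sqrt(pooled[, "sigma"]^2 + obs_error_sd^2)
  loglik <- stats::dnorm(matrix(dat$y, S, dat$N, byrow = TRUE), mu, sd_tot, log = TRUE)

  fixed_mcmc <- samp[, sweep_cols, drop = FALSE]
  rhat <- tryCatch(
    coda::gelman.diag(fixed_mcmc, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1],
    error = function(e) rep(NA_real_, ncol(X))
  )
  ess <- coda::effectiveSize(fixed_mcmc)
  structure(list(
    draws = samp, fixed = fixed, loglik = loglik,
    predictor = predictor, levels = levs, terms = colnames(X),
    caus_levels = caus_lev, noncaus_levels = nonc_lev,
    priors = priors, chains = chains, iter = iter, warmup = warmup,
    seed = as.integer(seed), obs_error_sd = obs_error_sd,
    y = dat$y, X = X,
    diagnostics = list(rhat = stats::setNames(as.numeric(rhat), colnames(X)),
                       ess = stats::setNames(as.numeric(ess), colnames(X)))
  ), class = "hier_fit")
}

#' Measurement-error variant of the hierarchical regression
#'
#' Treats the response as observed with known Gaussian error of SD
#' `baseline_sd` (the uncertainty of the subtracted baseline); with
#' `baseline_sd -> 0` this recovers [fit_hierarchical()].
#'
#' @inheritParams fit_hierarchical
#' @param baseline_sd known observation error SD (> 0).
#' @return a `hier_fit`.
#' @export
measurement_error_variant <- function(rows, baseline_sd,
                                      predictor = c("genre", "layer"), ...) {
  stopifnot(baseline_sd > 0)
  fit_hierarchical(rows, predictor = match.arg(predictor),
                   obs_error_sd = baseline_sd, ...)
}

#' @export
print.hier_fit <- function(x, ...) {
  cat(sprintf("<hier_fit> %s model, %d obs, %d chains x %d draws\n",
              x$predictor, length(x$y), x$chains, x$iter))
  print(summarize_posterior(x))
  invisible(x)
}

#' Summarize fixed-effect posteriors
#'
#' Posterior means, highest-posterior-density intervals at the requested
#' masses, the posterior probability of being above zero, and convergence
#' diagnostics for each fixed effect.
#'
#' @param fit a `hier_fit`, or a plain draws matrix (columns = parameters).
#' @param masses HPD interval masses (default 0.80 and 0.90).
#' @return a data.frame with one row per fixed effect: `mean`, `hpd_lo_<m>`
#'   and `hpd_hi_<m>` per mass, `prob_above_zero`, `rhat`, `ess`.
#' @export
summarize_posterior <- function(fit, masses = c(0.80, 0.90)) {
  if (inherits(fit, "hier_fit")) {
    draws <- fit$fixed
    diag_rhat <- fit$diagnostics$rhat
    diag_ess <- fit$diagnostics$ess
  } else {
    draws <- as.matrix(fit)
    diag_rhat <- rep(NA_real_, ncol(draws))
    diag_ess <- rep(NA_real_, ncol(draws))
  }
  if (nrow(draws) == 0L) stop("no posterior draws to summarize")
  out <- data.frame(term = colnames(draws), mean = colMeans(draws),
                    row.names = NULL)
  mc <- coda::as.mcmc(draws)
  for (m in masses) {
    hpd <- coda::HPDinterval(mc, prob = m)
    out[[sprintf("hpd_lo_%02d", round(100 * m))]] <- hpd[, "lower"]
    out[[sprintf("hpd_hi_%02d", round(100 * m))]] <- hpd[, "upper"]
  }
  out$prob_above_zero <- colMeans(draws > 0)
  out$rhat <- as.numeric(diag_rhat)
  out$ess <- as.numeric(diag_ess)
  out
}

#' Stack above-baseline tables into regression rows
#'
#' @param tables list of [above_baseline()] tables (each carrying `score`,
#'   `causative`, `noncausative`, `genre`, `layer`, `window` columns).
#' @return a data.frame with `response`, `genre`, `layer`, `caus`, `noncaus`,
#'   `window` — the input format of [fit_hierarchical()].
#' @export
discrimination_rows <- function(tables) {
  stacked <- do.call(rbind, lapply(tables, function(t) {
    data.frame(response = t$score, genre = t$genre, layer = t$layer,
               caus = t$causative, noncaus = t$noncausative, window = t$window)
  }))
  rownames(stacked) <- NULL
  stacked
}
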