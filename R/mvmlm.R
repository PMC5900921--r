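# Multivariate multilevel model for mixed Gaussian/probit performance
# dimensions, estimated by Gibbs sampling with data augmentation.
#
# Model, for patient i in provider j and dimension k = 1..K:
#   Ystar_ijk = alpha_k + X_ijk' beta_k + theta_jk + eps_ijk
#   theta_j ~ MVN(0, Sigma),  eps_i ~ MVN(0, Omega)
# Gaussian dimensions observe a monotone transform of Ystar; probit
# dimensions observe I(Ystar > 0) and have var(eps_k) fixed at 1.

#' Fit the multivariate multilevel performance model
#'
#' Estimates correlated provider-level random effects and correlated
#' patient-level errors over mixed Gaussian/probit outcome dimensions by a
#' Gibbs sampler: truncated-normal augmentation of the probit latents,
#' conditional-MVN imputation of missing outcome cells (missing at random
#' given covariates and the observed dimensions), conjugate normal updates
#' for the regression coefficients, per-provider conditional-MVN updates for
#' the random effects, and inverse-Wishart updates for both covariance
#' matrices, with the probit error variances identified at 1 by
#' parameter-expansion rescaling of each draw before storage.
#'
#' @param data patient-level data.frame with a `provider_id` column, one
#'   outcome column per dimension, and the covariate columns the dimension
#'   specs name. Binary outcomes must be coded 0/1 (`NA` allowed everywhere).
#' @param dimensions list of [dimension_spec] objects (a single spec gives a
#'   univariate fit).
#' @param iterations total MCMC iterations.
#' @param burn_in iterations discarded before storage.
#' @param thin storage interval.
#' @param seed RNG seed; identical data + settings + seed reproduce the fit
#'   draw for draw.
#' @param priors list with elements `coef_var` (prior variance of every
#'   regression coefficient, default `1e4`), `sigma_df`/`sigma_scale` and
#'   `omega_df`/`omega_scale` (inverse-Wishart degrees of freedom and scalar
#'   scale-matrix multiplier for the provider- and patient-level covariances;
#'   defaults `K + 2` with scales `0.01` and `1`).
#' @param mundlak optional character vector of covariate names whose
#'   provider means (computed on the estimation sample) are appended to every
#'   dimension's regressors to absorb covariate/random-effect correlation.
#' @param residual optional name of a first-stage selection residual column
#'   entered into every dimension (two-stage residual inclusion).
#' @param rhat_threshold convergence gate: the fit is flagged non-converged
#'   when any monitored scalar's split-Rhat exceeds this (default 1.05).
#' @param verbose print progress.
#' @return an object of class `mvmlm` with stored posterior draws of
#'   `alpha`, `beta`, `Sigma`, `Omega` and all provider effects `theta`,
#'   posterior-mean latent outcomes and fitted values, and convergence
#'   diagnostics (split-Rhat, effective sample size). Use [summary.mvmlm()],
#'   [provider_effects()], [perf_correlation()].
#' @examples
#' cfg <- synthetic_config(J = 10, n_j = 20, seed = 1)
#' coh <- simulate_cohort(cfg)
#' fit <- mvmlm(coh$patients, cfg$dimensions, iterations = 200,
#'              burn_in = 50, seed = 1)
#' fit
#' @export
mvmlm <- function(data, dimensions, iterations = 2000, burn_in = 500,
                  thin = 1, seed = 1L, priors = NULL,
                  mundlak = NULL, residual = NULL,
                  rhat_threshold = 1.05, verbose = FALSE) {
  dimensions <- check_dimensions(dimensions)
  K <- length(dimensions)
  nm <- dim_names(dimensions)
  fam <- dim_families(dimensions)
  if (!is.data.frame(data) || !nrow(data)) stopf("'data' must be non-empty")
  if (is.null(data$provider_id)) stopf("'data' needs a provider_id column")
  if (!is_count(iterations) || !is_count(burn_in, 0) || !is_count(thin))
    stopf("iterations, burn_in and thin must be positive integers")
  if (iterations <= burn_in) stopf("iterations must exceed burn_in")

  pr <- list(coef_var = 1e4, sigma_df = K + 2, sigma_scale = 0.01,
             omega_df = K + 2, omega_scale = 1)
  pr[names(priors)] <- priors

  prov <- factor(data$provider_id)
  provider <- as.integer(prov)
  J <- nlevels(prov)
  N <- nrow(data)
  n_j <- tabulate(provider, J)

  # latent-scale outcome matrix (NA = missing); probit kept as 0/1 indicator
  Y <- matrix(NA_real_, N, K, dimnames = list(NULL, nm))
  for (k in seq_len(K)) {
    col <- data[[nm[k]]]
    if (is.null(col)) stopf("outcome column '%s' not found", nm[k])
    if (all(is.na(col))) stopf("dimension '%s' is entirely missing", nm[k])
    if (fam[k] == "probit") {
      bad <- which(!is.na(col) & !(col %in% c(0, 1)))
      if (length(bad))
        stopf("binary outcome '%s' has non-0/1 value in row %d",
              nm[k], bad[1])
      Y[, k] <- col
    } else {
      Y[, k] <- dimensions[[k]]$trans(col)
    }
  }

  # per-dimension design matrices: intercept + covariates (+ mundlak, + 2SRI)
  extra <- character()
  if (!is.null(mundlak)) {
    miss <- setdiff(mundlak, names(data))
    if (length(miss)) stopf("mundlak covariates not found: %s",
                            paste(miss, collapse = ", "))
    for (v in mundlak) {
      data[[paste0("pm_", v)]] <- stats::ave(data[[v]], provider)
      extra <- c(extra, paste0("pm_", v))
    }
  }
  if (!is.null(residual)) {
    r <- data[[residual]]
    if (is.null(r)) stopf("residual column '%s' not found", residual)
    if (anyNA(r) || sd(r) == 0)
      stopf("residual column '%s' is degenerate (constant or missing)",
            residual)
    extra <- c(extra, residual)
  }
  Xl <- vector("list", K)
  for (k in seq_len(K)) {
    cv <- c(dimensions[[k]]$covariates, extra)
    miss <- setdiff(cv, names(data))
    if (length(miss)) stopf("covariates for '%s' not found: %s", nm[k],
                            paste(miss, collapse = ", "))
    X <- cbind(`(Intercept)` = 1,
               as.matrix(data[cv]))
    if (anyNA(X)) stopf("covariates for '%s' contain missing values", nm[k])
    Xl[[k]] <- X
  }

  res <- gibbs_mvmlm(Y, fam, Xl, provider, J, n_j, pr,
                     iterations, burn_in, thin, seed, verbose)

  # convergence diagnostics on scalar summaries
  diag_tab <- mvmlm_diagnostics(res, nm, fam)
  converged <- all(diag_tab$rhat < rhat_threshold, na.rm = TRUE)
  if (!converged)
    warnf("fit flagged non-converged: max split-Rhat %.3f (threshold %.2f)",
          max(diag_tab$rhat, na.rm = TRUE), rhat_threshold)

  structure(list(draws = res$draws, ystar_mean = res$ystar_mean,
                 fitted_mean = res$fitted_mean,
                 dimensions = dimensions, K = K, N = N, J = J,
                 provider_levels = levels(prov), n_j = n_j,
                 priors = pr, seed = seed,
                 settings = list(iterations = iterations, burn_in = burn_in,
                                 thin = thin),
                 mundlak = mundlak, residual = residual,
                 diagnostics = diag_tab, converged = converged,
                 rhat_threshold = rhat_threshold,
                 call = match.call()),
            class = "mvmlm")
}

# Core sampler. Y: N x K latent-scale matrix (probit columns hold 0/1/NA).
gibbs_mvmlm <- function(Y, fam, Xl, provider, J, n_j, pr,
                        iterations, burn_in, thin, seed, verbose = FALSE) {
  set.seed(seed)
  N <- nrow(Y); K <- ncol(Y)
  pb <- fam == "probit"
  miss <- is.na(Y)
  yobs1 <- !miss & Y == 1   # probit successes (only read for probit dims)

  # initial values
  Z <- Y
  for (k in seq_len(K)) {
    if (pb[k]) {
      Z[, k] <- ifelse(miss[, k], 0, ifelse(Y[, k] == 1, 0.5, -0.5))
    } else {
      Z[miss[, k], k] <- mean(Y[, k], na.rm = TRUE)
    }
  }
  p_k <- vapply(Xl, ncol, 0L)
  beta <- lapply(seq_len(K), function(k) {
    b <- rep(0, p_k[k]); b[1] <- mean(Z[, k]); b
  })
  XtX <- lapply(Xl, crossprod)
  M <- vapply(seq_len(K), function(k) drop(Xl[[k]] %*% beta[[k]]),
              numeric(N))
  # method-of-moments starting values for the provider effects and Sigma:
  # raw provider deviations of the latent proxy. Starting Sigma near zero
  # instead would put the chain in the funnel where small provider variances
  # and extreme correlations reinforce each other.
  R0 <- Z - M
  theta <- rowsum(R0, provider, reorder = TRUE) / n_j
  Sigma <- if (J > 1) cov(theta) else diag(0.1, K)
  Sigma <- Sigma + diag(0.05 * pmax(diag(Sigma), 0.01), K)  # keep PD
  theta_exp <- theta[provider, , drop = FALSE]
  Omega <- diag(pmax(apply(Z - M - theta_exp, 2, var), 0.1), K)
  diag(Omega)[pb] <- 1
  E <- Z - M - theta_exp

  S0_sig <- diag(pr$sigma_scale, K)
  S0_om <- diag(pr$omega_scale, K)
  v0 <- pr$coef_var

  n_store <- floor((iterations - burn_in) / thin)
  st <- list(alpha = matrix(NA_real_, n_store, K),
             beta = lapply(p_k, function(p) matrix(NA_real_, n_store, p)),
             Sigma = array(NA_real_, c(n_store, K, K)),
             Omega = array(NA_real_, c(n_store, K, K)),
             theta = array(NA_real_, c(n_store, J, K)))
  Zsum <- matrix(0, N, K); Fsum <- matrix(0, N, K)
  uniq_n <- sort(unique(n_j))
  s <- 0L

  for (it in seq_len(iterations)) {
    # conditional weights of each dim on the other dims' residuals
    cw <- lapply(seq_len(K), function(k) {
      if (K == 1) return(list(w = numeric(0), v = Omega[1, 1]))
      w <- solve(Omega[-k, -k, drop = FALSE], Omega[-k, k])
      list(w = w, v = max(Omega[k, k] - sum(Omega[k, -k] * w), 1e-10))
    })

    # (a) latent augmentation: probit cells truncated, missing cells free
    for (k in seq_len(K)) {
      w <- cw[[k]]$w; v <- cw[[k]]$v
      mu <- M[, k] + theta_exp[, k]
      if (K > 1) mu <- mu + drop(E[, -k, drop = FALSE] %*% w)
      if (pb[k]) {
        idx <- which(!miss[, k])
        Z[idx, k] <- rtnorm01(mu[idx], sqrt(v), yobs1[idx, k])
      }
      if (any(miss[, k])) {
        idx <- which(miss[, k])
        Z[idx, k] <- mu[idx] + sqrt(v) * rnorm(length(idx))
      }
      E[, k] <- Z[, k] - M[, k] - theta_exp[, k]
    }

    # (b) regression coefficients, dimension by dimension
    for (k in seq_len(K)) {
      w <- cw[[k]]$w; v <- cw[[k]]$v
      tgt <- Z[, k] - theta_exp[, k]
      if (K > 1) tgt <- tgt - drop(E[, -k, drop = FALSE] %*% w)
      prec <- XtX[[k]] / v + diag(1 / v0, p_k[k])
      U <- chol(prec)
      bhat <- backsolve(U, forwardsolve(t(U), crossprod(Xl[[k]], tgt) / v))
      beta[[k]] <- drop(bhat) + backsolve(U, rnorm(p_k[k]))
      M[, k] <- drop(Xl[[k]] %*% beta[[k]])
      E[, k] <- Z[, k] - M[, k] - theta_exp[, k]
    }

    # (c) provider effects
    R <- Z - M
    Srow <- rowsum(R, provider, reorder = TRUE)
    Oinv <- chol2inv(chol(Omega))
    Sinv <- chol2inv(chol(Sigma))
    A <- Srow %*% Oinv
    for (n in uniq_n) {
      js <- which(n_j == n)
      P <- Sinv + n * Oinv
      U <- chol(P)
      Ui <- backsolve(U, diag(K))
      mj <- A[js, , drop = FALSE] %*% (Ui %*% t(Ui))
      theta[js, ] <- mj +
        matrix(rnorm(length(js) * K), ncol = K) %*% t(Ui)
    }
    theta_exp <- theta[provider, , drop = FALSE]
    E <- R - theta_exp

    # (d) covariances
    Sigma <- riwish(pr$sigma_df + J, S0_sig + crossprod(theta))
    Omega <- riwish(pr$omega_df + N, S0_om + crossprod(E))

    if (it > burn_in && (it - burn_in) %% thin == 0) {
      # parameter expansion: the chain runs on the unidentified scale (probit
      # residual variances free under the inverse-Wishart); each stored draw
      # is rescaled to the identified scale (probit error variance = 1)
      s <- s + 1L
      d <- rep(1, K)
      if (any(pb)) d[pb] <- 1 / sqrt(diag(Omega)[pb])
      Om <- Omega * outer(d, d); diag(Om)[pb] <- 1
      st$alpha[s, ] <- vapply(beta, `[`, 0, 1) * d
      for (k in seq_len(K)) st$beta[[k]][s, ] <- beta[[k]] * d[k]
      st$Sigma[s, , ] <- Sigma * outer(d, d)
      st$Omega[s, , ] <- Om
      st$theta[s, , ] <- theta * rep(d, each = J)
      Zsum <- Zsum + Z * rep(d, each = N)
      Fsum <- Fsum + (M + theta_exp) * rep(d, each = N)
    }
    if (verbose && it %% 200 == 0)
      message(sprintf("iteration %d / %d", it, iterations))
  }

  for (k in seq_len(K)) colnames(st$beta[[k]]) <- colnames(Xl[[k]])
  list(draws = st, ystar_mean = Zsum / s, fitted_mean = Fsum / s)
}

# Split-Rhat / ESS table over the monitored scalars.
mvmlm_diagnostics <- function(res, nm, fam) {
  K <- length(nm)
  sc <- list()
  for (k in seq_len(K)) {
    sc[[paste0("alpha_", nm[k])]] <- res$draws$alpha[, k]
    sc[[paste0("tau_", nm[k])]] <- sqrt(res$draws$Sigma[, k, k])
    if (fam[k] == "gaussian")
      sc[[paste0("sigma_", nm[k])]] <- sqrt(res$draws$Omega[, k, k])
  }
  if (K > 1) {
    for (k in seq_len(K - 1)) for (l in (k + 1):K) {
      sc[[paste0("rho_theta_", nm[k], "_", nm[l])]] <-
        res$draws$Sigma[, k, l] /
        sqrt(res$draws$Sigma[, k, k] * res$draws$Sigma[, l, l])
      sc[[paste0("rho_eps_", nm[k], "_", nm[l])]] <-
        res$draws$Omega[, k, l] /
        sqrt(res$draws$Omega[, k, k] * res$draws$Omega[, l, l])
    }
  }
  data.frame(parameter = names(sc),
             rhat = vapply(sc, split_rhat, 0),
             ess = vapply(sc, ess, 0),
             row.names = NULL)
}

#' @export
print.mvmlm <- function(x, ...) {
  cat(sprintf("<mvmlm> %d dimensions (%s), %d providers, %d patients\n",
              x$K, paste(dim_names(x$dimensions), collapse = ", "),
              x$J, x$N))
  cat(sprintf("  %d stored draws (%d iterations, burn-in %d, thin %d)\n",
              nrow(x$draws$alpha), x$settings$iterations,
              x$settings$burn_in, x$settings$thin))
  cat(sprintf("  max split-Rhat %.3f -> %s\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}

#' Posterior summaries of a fitted performance model
#'
#' @param object an `mvmlm` fit.
#' @param probs quantiles reported for each parameter.
#' @param ... unused.
#' @return a `summary.mvmlm` object: a parameter table (posterior mean, SD,
#'   quantiles) covering intercepts, coefficients, provider-level SDs `tau`,
#'   residual SDs `sigma`, and both correlation matrices, plus diagnostics.
#' @export
summary.mvmlm <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  nm <- dim_names(object$dimensions)
  fam <- dim_families(object$dimensions)
  K <- object$K
  rows <- list()
  add <- function(name, draws)
    rows[[name]] <<- c(mean = mean(draws), sd = sd(draws),
                       quantile(draws, probs))
  for (k in seq_len(K)) {
    bk <- object$draws$beta[[k]]
    for (j in seq_len(ncol(bk)))
      add(paste0(nm[k], ":", colnames(bk)[j]), bk[, j])
    add(paste0("tau_", nm[k]), sqrt(object$draws$Sigma[, k, k]))
    if (fam[k] == "gaussian")
      add(paste0("sigma_", nm[k]), sqrt(object$draws$Omega[, k, k]))
  }
  if (K > 1) for (k in seq_len(K - 1)) for (l in (k + 1):K) {
    add(paste0("rho_theta_", nm[k], "_", nm[l]),
        object$draws$Sigma[, k, l] /
          sqrt(object$draws$Sigma[, k, k] * object$draws$Sigma[, l, l]))
    add(paste0("rho_eps_", nm[k], "_", nm[l]),
        object$draws$Omega[, k, l] /
          sqrt(object$draws$Omega[, k, k] * object$draws$Omega[, l, l]))
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, diagnostics = object$diagnostics,
                 converged = object$converged, K = K, J = object$J,
                 N = object$N),
            class = "summary.mvmlm")
}

#' @export
print.summary.mvmlm <- function(x, digits = 3, ...) {
  cat(sprintf("Multivariate multilevel fit: K = %d, J = %d providers, N = %d\n\n",
              x$K, x$J, x$N))
  print(round(x$table, digits))
  cat(sprintf("\nmax split-Rhat %.3f, min ESS %.0f -> %s\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE),
              if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}

#' @export
coef.mvmlm <- function(object, ...) {
  lapply(setNames(seq_len(object$K), dim_names(object$dimensions)),
         function(k) colMeans(object$draws$beta[[k]]))
}

#' Posterior-mean latent residuals
#'
#' Residuals on the latent scale: posterior mean of the augmented latent
#' outcome minus the posterior mean of `alpha + X beta + theta`.
#'
#' @param object an `mvmlm` fit.
#' @param ... unused.
#' @return an N x K matrix.
#' @export
residuals.mvmlm <- function(object, ...) {
  r <- object$ystar_mean - object$fitted_mean
  colnames(r) <- dim_names(object$dimensions)
  r
}

#' @export
fitted.mvmlm <- function(object, ...) {
  f <- object$fitted_mean
  colnames(f) <- dim_names(object$dimensions)
  f
}

#' Posterior-mean predictions on the latent scale
#'
#' @param object an `mvmlm` fit.
#' @param newdata data.frame with the model's covariate columns; if it has a
#'   `provider_id` matching an estimation-sample provider, that provider's
#'   posterior-mean effect is added.
#' @param ... unused.
#' @return matrix of latent-scale predictions (one column per dimension).
#' @export
predict.mvmlm <- function(object, newdata, ...) {
  nm <- dim_names(object$dimensions)
  out <- matrix(0, nrow(newdata), object$K, dimnames = list(NULL, nm))
  th <- apply(object$draws$theta, c(2, 3), mean)
  for (k in seq_len(object$K)) {
    b <- colMeans(object$draws$beta[[k]])
    cv <- names(b)[-1]
    miss <- setdiff(cv, names(newdata))
    if (length(miss)) stopf("newdata lacks covariates: %s",
                            paste(miss, collapse = ", "))
    X <- cbind(1, as.matrix(newdata[cv]))
    out[, k] <- drop(X %*% b)
  }
  if (!is.null(newdata$provider_id)) {
    idx <- match(as.character(newdata$provider_id), object$provider_levels)
    ok <- !is.na(idx)
    out[ok, ] <- out[ok, , drop = FALSE] + th[idx[ok], , drop = FALSE]
  }
  out
}

#' Simulate outcomes from the fitted model
#'
#' Posterior-predictive simulation at the estimation sample's covariates and
#' provider assignments: each replicate picks one stored posterior draw of
#' all parameters and provider effects, draws new patient-level errors from
#' that draw's `Omega`, and maps latent values to the observed scale.
#'
#' @param object an `mvmlm` fit.
#' @param nsim number of replicate datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return a list of `nsim` data.frames of simulated outcome columns.
#' @export
simulate.mvmlm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  nm <- dim_names(object$dimensions)
  ndraw <- nrow(object$draws$alpha)
  # rebuild each patient's fixed-effect part from the posterior-mean fitted
  # values minus that draw's provider effect is not available per draw, so we
  # use the posterior-mean linear predictor and per-draw theta/Omega.
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    d <- sample.int(ndraw, 1)
    Om <- object$draws$Omega[d, , ]
    eps <- rmvn(object$N, rep(0, object$K), matrix(Om, object$K))
    ystar <- object$fitted_mean + eps
    sim <- as.data.frame(observe_outcomes(ystar, object$dimensions,
                                          character()))
    names(sim) <- nm
    out[[s]] <- sim
  }
  out
}

#' Caterpillar plot of oriented provider effects
#'
#' Plots posterior means and 95% credible intervals of the provider effects
#' for one dimension, oriented so that up is better, sorted by posterior
#' mean.
#'
#' @param x an `mvmlm` fit.
#' @param dimension dimension name or index (default first).
#' @param ... passed to [graphics::plot()].
#' @export
plot.mvmlm <- function(x, dimension = 1, ...) {
  nm <- dim_names(x$dimensions)
  k <- if (is.character(dimension)) match(dimension, nm) else dimension
  if (is.na(k) || k < 1 || k > x$K) stopf("unknown dimension")
  o <- x$dimensions[[k]]$orientation
  dr <- x$draws$theta[, , k] * o
  m <- colMeans(dr)
  lo <- apply(dr, 2, quantile, 0.025)
  hi <- apply(dr, 2, quantile, 0.975)
  ord <- order(m)
  graphics::plot(seq_along(m), m[ord], ylim = range(lo, hi), pch = 16,
                 xlab = "provider (ranked)",
                 ylab = sprintf("oriented effect: %s", nm[k]), ...)
  graphics::segments(seq_along(m), lo[ord], seq_along(m), hi[ord],
                     col = "grey50")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Fit a univariate model for a single dimension
#'
#' Same engine with `K = 1`; used by the univariate arm of the
#' approach-comparison study.
#'
#' @param data patient table.
#' @param dimensions full dimension list.
#' @param dimension name or index of the dimension to fit.
#' @param ... passed to [mvmlm()].
#' @return an `mvmlm` fit with one dimension.
#' @export
fit_univariate <- function(data, dimensions, dimension, ...) {
  dimensions <- check_dimensions(dimensions)
  k <- if (is.character(dimension)) match(dimension, dim_names(dimensions))
       else dimension
  if (is.na(k)) stopf("unknown dimension '%s'", dimension)
  mvmlm(data, dimensions[k], ...)
}

#' Empirical Bayes provider-effect posteriors
#'
#' Per provider, the posterior mean `theta_hat` (a K-vector) and posterior
#' covariance `V` (K x K) of its random effect, computed from the stored
#' draws, together with the draws themselves. These are the inputs to the
#' dominance classification.
#'
#' @param fit an `mvmlm` fit.
#' @param force proceed even if the convergence gate failed.
#' @return an object of class `provider_effects`: a list with `provider_id`,
#'   `theta_hat` (J x K), `V` (K x K x J), `draws` (ndraw x J x K), `n_j`,
#'   dimension names and orientations.
#' @export
provider_effects <- function(fit, force = FALSE) {
  if (!inherits(fit, "mvmlm")) stopf("'fit' must be an mvmlm object")
  if (!fit$converged && !force)
    stopf("fit failed the convergence gate (split-Rhat >= %.2f); pass force = TRUE to override",
          fit$rhat_threshold)
  dr <- fit$draws$theta
  J <- fit$J; K <- fit$K
  theta_hat <- apply(dr, c(2, 3), mean)
  V <- array(NA_real_, c(K, K, J))
  for (j in seq_len(J)) V[, , j] <- cov(matrix(dr[, j, ], ncol = K))
  nm <- dim_names(fit$dimensions)
  colnames(theta_hat) <- nm
  structure(list(provider_id = fit$provider_levels,
                 theta_hat = theta_hat, V = V, draws = dr,
                 n_j = fit$n_j, dim_names = nm,
                 orientation = dim_orientations(fit$dimensions),
                 converged = fit$converged),
            class = "provider_effects")
}

#' @export
print.provider_effects <- function(x, ...) {
  cat(sprintf("<provider_effects> %d providers x %d dimensions (%s)\n",
              nrow(x$theta_hat), ncol(x$theta_hat),
              paste(x$dim_names, collapse = ", ")))
  invisible(x)
}

#' Posterior correlation matrix at a chosen level
#'
#' The provider level reports the correlation of the provider random effects
#' (from `Sigma` draws); the patient level reports the residual correlation
#' (from `Omega` draws). Posterior SDs and a flag for entries whose central
#' 95% interval excludes zero accompany the means.
#'
#' @param fit an `mvmlm` fit.
#' @param level `"provider"` or `"patient"`.
#' @return a list of class `perf_correlation` with `mean`, `sd` and
#'   `excludes_zero` matrices.
#' @export
perf_correlation <- function(fit, level = c("provider", "patient")) {
  level <- match.arg(level)
  arr <- if (level == "provider") fit$draws$Sigma else fit$draws$Omega
  K <- fit$K; nm <- dim_names(fit$dimensions)
  n <- dim(arr)[1]
  cors <- array(NA_real_, c(n, K, K))
  for (s in seq_len(n)) {
    m <- matrix(arr[s, , ], K)
    cors[s, , ] <- stats::cov2cor(m)
  }
  mn <- apply(cors, c(2, 3), mean)
  sdm <- apply(cors, c(2, 3), sd)
  lo <- apply(cors, c(2, 3), quantile, 0.025)
  hi <- apply(cors, c(2, 3), quantile, 0.975)
  ex <- lo > 0 | hi < 0
  diag(ex) <- FALSE
  dimnames(mn) <- dimnames(sdm) <- dimnames(ex) <- list(nm, nm)
  structure(list(mean = mn, sd = sdm, excludes_zero = ex, level = level),
            class = "perf_correlation")
}

#' @export
print.perf_correlation <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior %s-level correlation (mean):\n", x$level))
  print(round(x$mean, digits))
  cat("* = 95% credible interval excludes 0\n")
  marked <- ifelse(x$excludes_zero, "*", " ")
  print(noquote(marked))
  invisible(x)
}
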