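# Dominance classification of provider-effect posteriors against a benchmark.
#
# A provider dominates the benchmark when its (oriented) effect is positive
# on every dimension, is dominated when negative on every dimension, and is
# non-comparable otherwise. Posterior probabilities of the three states are
# orthant probabilities of the provider-effect posterior, estimated by
# simulation from MVN(theta_hat, V) (or by resampling the stored MCMC draws).

#' Define the performance benchmark
#'
#' The default (`conditional_mean`) benchmarks every provider against the
#' expected performance of a hypothetical provider of average performance,
#' i.e. `theta* = 0` on every dimension. An `absolute` benchmark supplies its
#' own `theta_star` on the latent scale.
#'
#' @param orientation K-vector of `+1`/`-1` (usually copied from the
#'   dimension specs): `+1` when a larger latent effect is better.
#' @param mode `"conditional_mean"` or `"absolute"`.
#' @param theta_star K-vector of latent-scale standards (used for
#'   `"absolute"`; zeros otherwise).
#' @return an object of class `benchmark`.
#' @export
benchmark <- function(orientation, mode = c("conditional_mean", "absolute"),
                      theta_star = NULL) {
  mode <- match.arg(mode)
  if (!all(orientation %in% c(-1, 1)))
    stopf("orientation entries must be +1 or -1")
  K <- length(orientation)
  if (mode == "conditional_mean") theta_star <- rep(0, K)
  theta_star <- rep_len(theta_star %||% 0, K)
  if (!all(is.finite(theta_star))) stopf("theta_star must be finite")
  structure(list(mode = mode, theta_star = theta_star,
                 orientation = orientation), class = "benchmark")
}

# Clip a posterior covariance to PSD if slightly indefinite; warn when the
# clip is material.
psd_chol <- function(V, tol = 1e-10) {
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (!is.null(L)) return(L)
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  warnf("singular posterior covariance: eigenvalues clipped at %.0e (min was %.3g)",
        tol, min(e$values))
  ev <- pmax(e$values, tol * max(abs(e$values), 1))
  chol(e$vectors %*% (ev * t(e$vectors)))
}

#' Posterior dominance probabilities for each provider
#'
#' For every provider, draws `S` samples of its effect vector, orients each
#' dimension so that positive means better than the benchmark, and estimates
#' `Pr(dominant)` as the fraction of draws with *all* components strictly
#' positive, `Pr(dominated)` with all strictly negative, and
#' `Pr(non-comparable)` as the complement, so the three sum to one by
#' construction. Per-dimension one-sided probabilities
#' `p_k = Phi(o_k (theta_hat_k - theta*_k) / sqrt(V_kk))` are reported for
#' the confidence-box comparisons, along with binomial Monte Carlo standard
#' errors.
#'
#' @param post a [provider_effects] object.
#' @param bench a [benchmark]; defaults to the conditional-mean benchmark
#'   with the orientations recorded in `post`.
#' @param S simulation draws per provider (>= 1000).
#' @param seed RNG seed.
#' @param method `"mvn"` samples from `MVN(theta_hat, V)` (the default);
#'   `"draws"` resamples the provider's retained MCMC draws.
#' @return a data.frame of class `dominance_result` with columns
#'   `provider_id`, `p_dominant`, `p_dominated`, `p_noncomparable`, their
#'   Monte Carlo SEs, and one `p_above_<dim>` column per dimension.
#' @examples
#' pe <- structure(list(provider_id = "a",
#'                      theta_hat = matrix(0, 1, 2), V = array(diag(2), c(2, 2, 1)),
#'                      n_j = 10, dim_names = c("x", "y"),
#'                      orientation = c(1, 1), converged = TRUE),
#'                 class = "provider_effects")
#' dominance(pe, S = 2000, seed = 1)
#' @export
dominance <- function(post, bench = NULL, S = 10000, seed = 1L,
                      method = c("mvn", "draws")) {
  method <- match.arg(method)
  if (!inherits(post, "provider_effects"))
    stopf("'post' must be a provider_effects object")
  if (!is_count(S, 1000)) stopf("S must be an integer >= 1000")
  bench <- bench %||% benchmark(post$orientation)
  K <- ncol(post$theta_hat)
  if (length(bench$orientation) != K)
    stopf("benchmark orientation length does not match K")
  set.seed(seed)
  J <- nrow(post$theta_hat)
  o <- bench$orientation
  res <- data.frame(provider_id = post$provider_id,
                    p_dominant = NA_real_, p_dominated = NA_real_,
                    p_noncomparable = NA_real_,
                    se_dominant = NA_real_, se_dominated = NA_real_)
  pk <- matrix(NA_real_, J, K,
               dimnames = list(NULL, paste0("p_above_", post$dim_names)))
  for (j in seq_len(J)) {
    mu <- post$theta_hat[j, ] - bench$theta_star
    V <- matrix(post$V[, , j], K)
    if (method == "mvn") {
      L <- psd_chol(V)
      Zs <- sweep(matrix(rnorm(S * K), S, K) %*% L, 2, mu, "+")
    } else {
      nd <- dim(post$draws)[1]
      Zs <- matrix(post$draws[sample.int(nd, S, replace = TRUE), j, ],
                   S, K)
      Zs <- sweep(Zs, 2, bench$theta_star, "-")
    }
    Zo <- sweep(Zs, 2, o, "*")
    pd <- mean(rowSums(Zo > 0) == K)   # strictly better on every dimension
    pl <- mean(rowSums(Zo < 0) == K)   # strictly worse on every dimension
    res$p_dominant[j] <- pd
    res$p_dominated[j] <- pl
    res$p_noncomparable[j] <- 1 - pd - pl
    res$se_dominant[j] <- sqrt(pd * (1 - pd) / S)
    res$se_dominated[j] <- sqrt(pl * (1 - pl) / S)
    pk[j, ] <- pnorm(o * mu / sqrt(pmax(diag(V), .Machine$double.eps)))
  }
  out <- cbind(res, pk)
  attr(out, "S") <- S
  attr(out, "K") <- K
  attr(out, "benchmark") <- bench
  class(out) <- c("dominance_result", "data.frame")
  out
}

#' @export
print.dominance_result <- function(x, digits = 3, ...) {
  cat(sprintf("<dominance_result> %d providers, S = %d draws\n",
              nrow(x), attr(x, "S")))
  print.data.frame(head(as.data.frame(x), 10), digits = digits)
  if (nrow(x) > 10) cat(sprintf("... %d more providers\n", nrow(x) - 10))
  invisible(x)
}

#' Deterministic multivariate-normal orthant probability
#'
#' Computes `P(sign_k * X_k > 0 for all k)` for `X ~ MVN(mean, cov)` by
#' deterministic numerical integration (Genz-style algorithm, absolute
#' tolerance about 1e-5 for `K <= 6`). Serves as the exact counterpart of
#' the simulation estimates in [dominance()].
#'
#' @param mean K-vector.
#' @param cov K x K positive semi-definite covariance.
#' @param signs K-vector of `+1`/`-1` choosing the orthant.
#' @return a single probability.
#' @examples
#' orthant_probability(c(0, 0), diag(2), c(1, 1))      # 0.25
#' @export
orthant_probability <- function(mean, cov, signs = rep(1, length(mean))) {
  K <- length(mean)
  if (K > 6) stopf("orthant_probability supports K <= 6")
  if (!all(signs %in% c(-1, 1))) stopf("signs must be +1/-1")
  cov <- matrix(cov, K)
  if (K == 1)
    return(unname(pnorm(signs[1] * mean[1] / sqrt(cov[1, 1]))))
  # flip axes so every constraint is "> 0"
  m <- signs * mean
  Vf <- cov * outer(signs, signs)
  # fixed RNG substream: Genz-Bretz quasi-Monte Carlo made reproducible
  if (exists(".Random.seed", envir = globalenv()))
    old <- get(".Random.seed", envir = globalenv())
  else { runif(1); old <- get(".Random.seed", envir = globalenv()) }
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(20170818L)
  p <- mvtnorm::pmvnorm(lower = rep(0, K), upper = rep(Inf, K), mean = m,
                        sigma = Vf,
                        algorithm = mvtnorm::GenzBretz(abseps = 1e-6,
                                                       maxpts = 100000L))
  as.numeric(p)
}

#' Threshold classification of dominance probabilities
#'
#' A provider is labelled `dominant` when `p_dominant >= threshold`,
#' `dominated` when `p_dominated >= threshold`, and `unclassified`
#' otherwise. For `threshold > 0.5` at most one rule can fire; at exactly
#' 0.5 both rules can only tie when each probability is exactly 0.5, in
#' which case `dominant` takes precedence (a measure-zero event under
#' simulation).
#'
#' @param result a [dominance()] result (or any data.frame with
#'   `p_dominant`/`p_dominated` columns).
#' @param threshold probability threshold in `[0.5, 1]`.
#' @return a factor with levels `dominant`, `dominated`, `unclassified`.
#' @export
classify <- function(result, threshold = 0.9) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0.5 || threshold > 1)
    stopf("threshold must lie in [0.5, 1]")
  lab <- ifelse(result$p_dominant >= threshold, "dominant",
                ifelse(result$p_dominated >= threshold, "dominated",
                       "unclassified"))
  factor(lab, levels = c("dominant", "dominated", "unclassified"))
}

#' Confidence-box classification from per-dimension probabilities
#'
#' The univariate/intermediate comparison rule: a provider is dominant
#' [dominated] when *all* per-dimension one-sided probabilities of exceeding
#' [falling short of] the benchmark reach the per-dimension cut. With the
#' Bonferroni correction the cut is `1 - (1 - threshold) / K`; without, it
#' is `threshold` itself. Comparisons use `>=` so boundary cases classify.
#'
#' @param post a [provider_effects] object (from a multivariate fit for the
#'   intermediate approach, or from [combine_univariate()] for the
#'   univariate approach).
#' @param threshold overall probability threshold in `[0.5, 1]`.
#' @param correction `"bonferroni"` or `"none"`.
#' @param bench optional [benchmark].
#' @return a factor with levels `dominant`, `dominated`, `unclassified`.
#' @export
box_classify <- function(post, threshold = 0.9,
                         correction = c("bonferroni", "none"),
                         bench = NULL) {
  correction <- match.arg(correction)
  if (threshold < 0.5 || threshold > 1)
    stopf("threshold must lie in [0.5, 1]")
  bench <- bench %||% benchmark(post$orientation)
  K <- ncol(post$theta_hat)
  cut <- if (correction == "bonferroni") 1 - (1 - threshold) / K
         else threshold
  J <- nrow(post$theta_hat)
  pk <- matrix(NA_real_, J, K)
  for (j in seq_len(J)) {
    mu <- post$theta_hat[j, ] - bench$theta_star
    vk <- diag(matrix(post$V[, , j], K))
    pk[j, ] <- pnorm(bench$orientation * mu / sqrt(pmax(vk, .Machine$double.eps)))
  }
  lab <- ifelse(rowSums(pk >= cut) == K, "dominant",
                ifelse(rowSums((1 - pk) >= cut) == K, "dominated",
                       "unclassified"))
  factor(lab, levels = c("dominant", "dominated", "unclassified"))
}

#' Combine univariate fits into one provider-effect posterior
#'
#' Stacks the provider effects of K separate univariate fits (same provider
#' set) into a single [provider_effects] object with a diagonal posterior
#' covariance, for use in the univariate arm of the approach comparison.
#'
#' @param fits list of univariate `mvmlm` fits, in dimension order.
#' @param force bypass the convergence gate of the individual fits.
#' @return a `provider_effects` object.
#' @export
combine_univariate <- function(fits, force = FALSE) {
  pes <- lapply(fits, provider_effects, force = force)
  ids <- pes[[1]]$provider_id
  for (p in pes) if (!identical(p$provider_id, ids))
    stopf("univariate fits cover different provider sets")
  K <- length(pes)
  J <- length(ids)
  theta_hat <- vapply(pes, function(p) p$theta_hat[, 1], numeric(J))
  V <- array(0, c(K, K, J))
  for (k in seq_len(K)) V[k, k, ] <- vapply(pes, function(p) p$V[1, 1, ],
                                            numeric(J))[, k]
  nd <- min(vapply(pes, function(p) dim(p$draws)[1], 0L))
  draws <- array(NA_real_, c(nd, J, K))
  for (k in seq_len(K)) draws[, , k] <- pes[[k]]$draws[seq_len(nd), , 1]
  nm <- vapply(pes, function(p) p$dim_names, "")
  structure(list(provider_id = ids, theta_hat = theta_hat, V = V,
                 draws = draws, n_j = pes[[1]]$n_j, dim_names = nm,
                 orientation = vapply(pes, function(p) p$orientation, 0),
                 converged = all(vapply(pes, function(p) p$converged, TRUE))),
            class = "provider_effects")
}

#' Compare univariate, intermediate and full multivariate classification
#'
#' Runs the three assessment strategies on one dataset: (1) separate
#' univariate fits with the Bonferroni confidence-box rule, (2) one
#' multivariate fit with the same box rule (correlation used in estimation,
#' ignored in the probability statements), and (3) the multivariate fit with
#' joint orthant probabilities. Emits counts of dominant/dominated providers
#' per threshold per approach.
#'
#' @param data patient table.
#' @param dimensions dimension list.
#' @param thresholds probability thresholds (default the 0.50/0.80/0.90/0.99
#'   grid).
#' @param S dominance simulation draws.
#' @param seed master seed (fits and simulation are sub-seeded from it).
#' @param correction box-rule correction.
#' @param force bypass convergence gates.
#' @param ... fitting arguments passed to [mvmlm()] / [fit_univariate()].
#' @return a data.frame of class `approach_comparison` with columns
#'   `threshold`, `approach`, `dominant`, `dominated`; the fitted objects
#'   are attached as attributes.
#' @export
compare_approaches <- function(data, dimensions, thresholds = c(0.5, 0.8, 0.9, 0.99),
                               S = 10000, seed = 1L,
                               correction = "bonferroni", force = FALSE, ...) {
  dimensions <- check_dimensions(dimensions)
  K <- length(dimensions)
  if (any(thresholds < 0.5 | thresholds > 1))
    stopf("thresholds must lie in [0.5, 1]")
  fit_mv <- mvmlm(data, dimensions, seed = derive_seed(seed, "fit"), ...)
  fits_uni <- lapply(seq_len(K), function(k)
    fit_univariate(data, dimensions, k,
                   seed = derive_seed(seed, "fit") + k, ...))
  pe_mv <- provider_effects(fit_mv, force = force)
  pe_uni <- combine_univariate(fits_uni, force = force)
  dom <- dominance(pe_mv, S = S, seed = derive_seed(seed, "assess"))

  rows <- list()
  for (t in thresholds) {
    lab_uni <- box_classify(pe_uni, t, correction)
    lab_int <- box_classify(pe_mv, t, correction)
    lab_full <- classify(dom, t)
    for (ap in c("univariate", "intermediate", "full")) {
      lab <- switch(ap, univariate = lab_uni, intermediate = lab_int,
                    full = lab_full)
      rows[[length(rows) + 1]] <-
        data.frame(threshold = t, approach = ap,
                   dominant = sum(lab == "dominant"),
                   dominated = sum(lab == "dominated"))
    }
  }
  out <- do.call(rbind, rows)
  out$approach <- factor(out$approach,
                         levels = c("univariate", "intermediate", "full"))
  attr(out, "fit") <- fit_mv
  attr(out, "univariate_fits") <- fits_uni
  attr(out, "dominance") <- dom
  attr(out, "pe_mv") <- pe_mv
  attr(out, "pe_uni") <- pe_uni
  class(out) <- c("approach_comparison", "data.frame")
  out
}

#' @export
print.approach_comparison <- function(x, ...) {
  cat("Dominant/dominated provider counts by approach and threshold:\n")
  print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Joint-ellipse and confidence-box coordinates for two dimensions
#'
#' Exports plain coordinates contrasting the joint credible ellipse of a
#' provider's effect on two dimensions with the rectangular "confidence box"
#' formed by independent (Bonferroni-adjusted) per-dimension intervals.
#'
#' @param post a [provider_effects] object.
#' @param provider provider id or index.
#' @param dims length-2 vector of dimension names or indices.
#' @param level coverage level (default 0.95).
#' @param correction `"bonferroni"` or `"none"` for the box.
#' @param n_points points on the ellipse outline.
#' @return a list with `ellipse` (n x 2 matrix), `box` (corner matrix) and
#'   `centre`.
#' @export
ellipse_box_coords <- function(post, provider = 1, dims = c(1, 2),
                               level = 0.95, correction = "bonferroni",
                               n_points = 181) {
  j <- if (is.character(provider)) match(provider, post$provider_id)
       else provider
  kk <- if (is.character(dims)) match(dims, post$dim_names) else dims
  mu <- post$theta_hat[j, kk]
  V <- matrix(post$V[, , j], ncol(post$theta_hat))[kk, kk]
  r <- sqrt(stats::qchisq(level, 2))
  ang <- seq(0, 2 * pi, length.out = n_points)
  circ <- cbind(cos(ang), sin(ang)) * r
  ell <- sweep(circ %*% chol(V), 2, mu, "+")
  a <- if (correction == "bonferroni") 1 - (1 - level) / 2 else level
  z <- qnorm(1 - (1 - a) / 2)
  hw <- z * sqrt(diag(V))
  box <- rbind(mu - hw, c(mu[1] + hw[1], mu[2] - hw[2]), mu + hw,
               c(mu[1] - hw[1], mu[2] + hw[2]), mu - hw)
  colnames(ell) <- colnames(box) <- post$dim_names[kk]
  list(ellipse = ell, box = box, centre = mu)
}
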