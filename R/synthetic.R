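# Synthetic cohort generator: patient-level data with the exact structure the
# estimator assumes (correlated provider effects, correlated mixed
# Gaussian/probit errors, configurable missingness, distance-driven provider
# choice with an unobserved severity confounder).

#' Configure the synthetic cohort generator
#'
#' Builds a validated generator configuration. With the default dimension set
#' (see [default_dimensions()]) all parameters default to a stylised
#' hip-replacement profiling setting: a skewed length of stay around 5.4 days
#' modelled on the log1p scale, an outcome score with mean 38.5 and residual
#' SD 9.2, and binary waiting/readmission indicators with marginal event
#' rates 0.17 and 0.05 (the probit intercepts are calibrated as
#' `qnorm(rate) * sqrt(1 + tau^2)` so the *marginal* rate matches after
#' integrating over providers). Provider- and patient-level correlation
#' matrices default to values typical of this setting (e.g. shorter stays
#' co-occurring with better outcome scores at provider level). For custom
#' dimension sets the defaults are neutral (`alpha = 0`, `beta = 0`,
#' `tau = 0.3`, `sigma = 1`, identity correlations, no missingness).
#'
#' @param J number of providers.
#' @param n_j patients per provider: a single count, or a length-2 range
#'   sampled uniformly per provider.
#' @param dimensions list of [dimension_spec] objects.
#' @param alpha numeric K-vector of latent-scale intercepts.
#' @param beta named list: per dimension, a named coefficient vector over that
#'   dimension's covariates (on the latent scale).
#' @param tau K-vector of provider random-effect SDs (latent scale), `>= 0`.
#' @param rho_theta K x K provider-level correlation matrix.
#' @param sigma K-vector of residual SDs; entries for probit dimensions are
#'   forced to 1 (probit identification).
#' @param rho_eps K x K patient-level correlation matrix.
#' @param missing_rates K-vector of missingness rates in `[0, 1]`.
#' @param missing_mechanism `"MCAR"` or `"MAR"` (missingness probability
#'   logistic in `mar_covariate`, with the intercept calibrated to hit the
#'   target rate).
#' @param mar_covariate covariate name driving MAR missingness.
#' @param mar_slope logistic slope on the (centred) MAR covariate.
#' @param covariate_model named list of functions `n -> numeric(n)` generating
#'   covariate columns; defaults provide `preop_score` (standard normal),
#'   `male` (Bernoulli 0.4) and `deprivation` (uniform on `[0, 0.24]`);
#'   unknown covariate names fall back to standard normals. Continuous
#'   covariates are mean-centred before use.
#' @param selection optional [selection_config()] block enabling endogenous
#'   provider choice.
#' @param theta_fixed optional J x K matrix of fixed provider effects
#'   (latent scale), overriding the MVN draw row-wise where non-`NA`; used
#'   to plant known dominant/dominated providers in power experiments.
#' @param top_code character vector of Gaussian dimension names whose
#'   *observed* values are top-coded at their empirical 99th percentile
#'   (default: none).
#' @param seed integer master seed (mandatory for reproducibility).
#' @return an object of class `synthetic_config`.
#' @seealso [simulate_cohort()], [apply_missingness()], [simulate_choice()]
#' @export
synthetic_config <- function(J = 100, n_j = 100,
                             dimensions = default_dimensions(),
                             alpha = NULL, beta = NULL, tau = NULL,
                             rho_theta = NULL, sigma = NULL, rho_eps = NULL,
                             missing_rates = NULL,
                             missing_mechanism = c("MCAR", "MAR"),
                             mar_covariate = "preop_score", mar_slope = 1,
                             covariate_model = NULL,
                             selection = NULL, top_code = character(),
                             theta_fixed = NULL, seed = 1L) {
  dimensions <- check_dimensions(dimensions)
  K <- length(dimensions)
  nm <- dim_names(dimensions)
  fam <- dim_families(dimensions)
  missing_mechanism <- match.arg(missing_mechanism)
  if (!is_count(J, 1)) stopf("J must be a positive integer")
  if (!(length(n_j) %in% 1:2) || any(n_j < 1) || any(n_j != floor(n_j)))
    stopf("n_j must be a positive count or a length-2 range")
  if (!is_count(seed, 0)) stopf("seed must be a non-negative integer")

  hip <- identical(unname(nm), c("los", "ohs", "wait18", "readm28"))
  if (is.null(tau))
    tau <- if (hip) c(los = 0.15, ohs = 1.5, wait18 = 0.3, readm28 = 0.3)
           else rep(0.3, K)
  tau <- rep_len(unname(tau), K)
  if (any(tau < 0)) stopf("tau must be non-negative")
  if (is.null(sigma))
    sigma <- if (hip) c(0.45, 9.2, 1, 1) else rep(1, K)
  sigma <- rep_len(unname(sigma), K)
  sigma[fam == "probit"] <- 1   # probit identification: residual variance 1
  if (any(sigma <= 0)) stopf("sigma must be positive")

  if (is.null(alpha)) {
    alpha <- if (hip)
      c(log1p(5.36), 38.5,
        qnorm(0.17) * sqrt(1 + tau[3]^2),   # marginal event rate 0.17
        qnorm(0.05) * sqrt(1 + tau[4]^2))   # marginal event rate 0.05
    else rep(0, K)
  }
  alpha <- rep_len(unname(alpha), K)

  if (is.null(beta)) {
    beta <- if (hip)
      list(los     = c(preop_score = -0.10, male = -0.02, deprivation = 0.30),
           ohs     = c(preop_score = 3.0, male = 0.5, deprivation = -5.0),
           wait18  = numeric(),
           readm28 = c(preop_score = -0.15, male = 0.10))
    else lapply(dimensions, function(d)
      setNames(rep(0, length(d$covariates)), d$covariates))
  }
  beta <- lapply(seq_len(K), function(k) {
    b <- beta[[nm[k]]] %||% beta[[k]] %||% numeric()
    cv <- dimensions[[k]]$covariates
    if (length(b) && is.null(names(b)) && length(b) == length(cv))
      names(b) <- cv
    miss <- setdiff(cv, names(b))
    b <- c(b[intersect(names(b), cv)], setNames(rep(0, length(miss)), miss))
    b[cv]
  })
  names(beta) <- nm

  default_rho <- function(lower, upper) {
    m <- diag(K)
    m[lower.tri(m)] <- lower
    m[upper.tri(m)] <- 0
    m <- m + t(m); diag(m) <- 1
    m
  }
  if (is.null(rho_theta))
    rho_theta <- if (hip)
      default_rho(c(-0.34, 0.26, 0.03, -0.31, -0.49, 0.16)) else diag(K)
  if (is.null(rho_eps)) {
    rho_eps <- if (hip) {
      m <- diag(K)
      m[upper.tri(m)] <- c(-0.13, 0.02, -0.02, 0.02, -0.07, 0.00)
      m + t(m) - diag(K)
    } else diag(K)
  }
  check_correlation_matrix(rho_theta, "rho_theta")
  check_correlation_matrix(rho_eps, "rho_eps")

  if (is.null(missing_rates))
    missing_rates <- if (hip) c(0.001, 0.152, 0.04, 0) else rep(0, K)
  missing_rates <- rep_len(unname(missing_rates), K)
  if (any(missing_rates < 0 | missing_rates > 1))
    stopf("missing_rates must lie in [0, 1]")

  if (!is.null(selection) && !inherits(selection, "selection_config"))
    stopf("'selection' must be built with selection_config()")
  if (!is.null(selection) && J < 2)
    stopf("selection requires at least 2 providers")
  bad <- setdiff(top_code, nm[fam == "gaussian"])
  if (length(bad))
    stopf("top_code names must be gaussian dimensions (offending: %s)",
          paste(bad, collapse = ", "))

  structure(list(J = as.integer(J), n_j = as.integer(n_j),
                 dimensions = dimensions, K = K,
                 alpha = alpha, beta = beta, tau = tau, sigma = sigma,
                 rho_theta = rho_theta, rho_eps = rho_eps,
                 missing_rates = missing_rates,
                 missing_mechanism = missing_mechanism,
                 mar_covariate = mar_covariate, mar_slope = mar_slope,
                 covariate_model = covariate_model,
                 selection = selection, top_code = top_code,
                 theta_fixed = theta_fixed, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Configure endogenous provider choice
#'
#' Providers are placed at fixed uniform sites on the unit square and each
#' patient at a uniform location; distance is Euclidean. A patient chooses a
#' provider by a conditional-logit draw with utility
#' `gamma[1]*d + gamma[2]*d^2 + gamma[3]*d^3 + closest*I(closest alternative)
#' + lambda * u_i * d`, where `u_i` is an unobserved standard-normal severity
#' confounder: `lambda > 0` makes sicker patients less deterred by distance,
#' so they travel further. The same `u_i` enters every latent outcome with
#' loading `delta[k]`, confounding naive provider-effect estimates.
#'
#' @param gamma distance polynomial coefficients (linear, squared, cubic).
#' @param closest utility bonus for the closest alternative.
#' @param lambda confounder-by-distance interaction strength; `0` disables
#'   confounding (choice then depends on distance only).
#' @param delta optional K-vector of confounder loadings on the latent
#'   outcomes; defaults to half a residual SD in the adverse direction of
#'   each dimension (`-orientation * 0.5 * sigma_k`).
#' @param geometry provider site layout: `"grid"` (regular lattice, so every
#'   provider faces comparable local competition and the first-stage
#'   residual's provider mean isolates the confounder) or `"random"`
#'   (uniform sites; choice-set competitiveness then varies across
#'   providers, a harder setting for the scalar-residual correction).
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(gamma = c(-8, 0, 0), closest = 0.5,
                             lambda = 16, delta = NULL,
                             geometry = c("grid", "random")) {
  gamma <- rep_len(gamma, 3)
  structure(list(gamma = gamma, closest = closest, lambda = lambda,
                 delta = delta, geometry = match.arg(geometry)),
            class = "selection_config")
}

# Built-in covariate generators for the default setting.
default_covariate_model <- function() {
  list(preop_score = function(n) rnorm(n),
       male        = function(n) rbinom(n, 1, 0.4),
       deprivation = function(n) runif(n, 0, 0.24))
}

# Assemble observed outcomes from latent values.
observe_outcomes <- function(ystar, dimensions, top_code) {
  K <- length(dimensions)
  out <- matrix(NA_real_, nrow(ystar), K,
                dimnames = list(NULL, dim_names(dimensions)))
  for (k in seq_len(K)) {
    d <- dimensions[[k]]
    if (d$family == "gaussian") {
      y <- d$inverse(ystar[, k])
      if (d$name %in% top_code) {
        cap <- quantile(y, 0.99, names = FALSE)
        y <- pmin(y, cap)
      }
      out[, k] <- y
    } else {
      out[, k] <- as.numeric(ystar[, k] > 0)
    }
  }
  out
}

#' Simulate a synthetic patient cohort
#'
#' Generates a complete patient-level dataset under the multivariate
#' multilevel model: for patient `i` in provider `j` and dimension `k`,
#' `Ystar_ijk = alpha_k + X_ijk' beta_k + theta_jk + eps_ijk`, with provider
#' effects `theta_j ~ MVN(0, diag(tau) rho_theta diag(tau))` and patient
#' errors `eps_i ~ MVN(0, diag(sigma) rho_eps diag(sigma))`. Gaussian
#' dimensions report the inverse transform of the latent value; probit
#' dimensions report `I(Ystar > 0)`. Continuous covariates are mean-centred.
#' The generating truth (provider effects, errors, linear predictors,
#' complete outcomes) is retained for parameter-recovery testing.
#'
#' Missingness and endogenous selection are *not* applied here; see
#' [apply_missingness()] and [simulate_choice()].
#'
#' @param config a [synthetic_config()].
#' @return an object of class `synthetic_cohort`: a list with elements
#'   `patients` (data.frame), `truth` (generating parameters, `theta`,
#'   complete outcomes), `dimensions` and `config`.
#' @examples
#' cfg <- synthetic_config(J = 5, n_j = 20, seed = 1)
#' coh <- simulate_cohort(cfg)
#' head(coh$patients)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stopf("'config' must be a synthetic_config")
  set.seed(derive_seed(config$seed, "simulate"))
  J <- config$J; K <- config$K; dims <- config$dimensions

  nj <- if (length(config$n_j) == 1) rep(config$n_j, J)
        else sample(config$n_j[1]:config$n_j[2], J, replace = TRUE)
  N <- sum(nj)
  provider <- rep(seq_len(J), nj)

  # covariates (continuous ones mean-centred before entering the model)
  covs <- unique(unlist(lapply(dims, `[[`, "covariates")))
  cm <- default_covariate_model()
  if (!is.null(config$covariate_model))
    cm[names(config$covariate_model)] <- config$covariate_model
  if (!length(covs)) {
    X <- as.data.frame(matrix(numeric(0), nrow = N, ncol = 0))
  } else
  X <- as.data.frame(setNames(lapply(covs, function(v) {
    gen <- cm[[v]] %||% function(n) rnorm(n)
    x <- gen(N)
    if (!all(x %in% c(0, 1))) x <- x - mean(x)
    x
  }), covs))

  Sigma <- diag(config$tau, K) %*% config$rho_theta %*% diag(config$tau, K)
  Omega <- diag(config$sigma, K) %*% config$rho_eps %*% diag(config$sigma, K)
  theta <- rmvn(J, rep(0, K), Sigma)
  if (!is.null(config$theta_fixed)) {
    tf <- config$theta_fixed
    theta[!is.na(tf)] <- tf[!is.na(tf)]
  }
  eps <- rmvn(N, rep(0, K), Omega)

  xb <- matrix(0, N, K)
  for (k in seq_len(K)) {
    b <- config$beta[[k]]
    if (length(b))
      xb[, k] <- as.matrix(X[names(b)]) %*% b
  }
  lin <- sweep(xb, 2, config$alpha, "+")
  ystar <- lin + theta[provider, , drop = FALSE] + eps
  obs <- observe_outcomes(ystar, dims, config$top_code)

  patients <- data.frame(patient_id = seq_len(N), provider_id = provider,
                         obs, X, check.names = FALSE)
  truth <- list(theta = theta, Sigma = Sigma, Omega = Omega,
                alpha = config$alpha, beta = config$beta,
                tau = config$tau, sigma = config$sigma,
                rho_theta = config$rho_theta, rho_eps = config$rho_eps,
                eps = eps, lin = lin, ystar = ystar,
                complete = obs, n_j = nj)
  structure(list(patients = patients, truth = truth,
                 dimensions = dims, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d providers, %d dimensions (%s)\n",
              nrow(x$patients), x$config$J, x$config$K,
              paste(dim_names(x$dimensions), collapse = ", ")))
  if (!is.null(x$truth$u)) cat("  endogenous provider choice applied\n")
  if (!is.null(x$truth$missing_mask)) cat("  missingness applied\n")
  invisible(x)
}

#' Mask outcome cells according to the configured missingness mechanism
#'
#' Under MCAR each outcome cell of dimension `k` is masked independently with
#' probability `missing_rates[k]`. Under MAR the masking probability is
#' logistic in the (centred) MAR covariate, with the intercept calibrated so
#' the expected rate matches `missing_rates[k]`; missingness then depends on
#' observed covariates but not on the masked outcome given them. Covariates
#' are never masked, and complete values are retained in `truth$complete`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param rates optional override of the configured per-dimension rates.
#' @return the cohort with outcome cells set to `NA` and the mask stored in
#'   `truth$missing_mask`.
#' @export
apply_missingness <- function(cohort, rates = NULL) {
  if (!inherits(cohort, "synthetic_cohort"))
    stopf("'cohort' must be a synthetic_cohort")
  cfg <- cohort$config
  rates <- rep_len(rates %||% cfg$missing_rates, cfg$K)
  if (any(rates < 0 | rates > 1)) stopf("missing rates must lie in [0, 1]")
  set.seed(derive_seed(cfg$seed, "missingness"))
  nm <- dim_names(cohort$dimensions)
  N <- nrow(cohort$patients)
  mask <- matrix(FALSE, N, cfg$K, dimnames = list(NULL, nm))
  for (k in seq_len(cfg$K)) {
    if (rates[k] == 0) next
    p <- if (cfg$missing_mechanism == "MCAR") rep(rates[k], N) else {
      x <- cohort$patients[[cfg$mar_covariate]]
      if (is.null(x)) stopf("MAR covariate '%s' not found", cfg$mar_covariate)
      x <- x - mean(x)
      a <- stats::uniroot(function(a) mean(stats::plogis(a + cfg$mar_slope * x)) - rates[k],
                          c(-30, 30))$root
      stats::plogis(a + cfg$mar_slope * x)
    }
    mask[, k] <- runif(N) < p
    cohort$patients[[nm[k]]][mask[, k]] <- NA
  }
  cohort$truth$missing_mask <- mask
  cohort
}

#' Re-assign providers by distance-driven choice with unobserved severity
#'
#' Implements the endogenous-selection layer of the generator (see
#' [selection_config()]): places providers and patients on the unit square,
#' draws each patient's provider from a conditional logit over the distance
#' polynomial, a closest-alternative bonus and a severity-by-distance
#' interaction, then rebuilds every outcome using the chosen provider's
#' effect and adds the severity confounder `delta_k * u_i` to each latent
#' dimension, so that naive estimation is biased when `lambda != 0`. Wide
#' per-provider distance columns `dist_<provider_id>` are appended.
#'
#' Call before [apply_missingness()].
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()] whose config
#'   includes a selection block.
#' @return the cohort with re-assigned `provider_id`, rebuilt outcomes,
#'   distance columns, and `u` (the confounder), provider/patient coordinates
#'   stored in `truth`.
#' @export
simulate_choice <- function(cohort) {
  if (!inherits(cohort, "synthetic_cohort"))
    stopf("'cohort' must be a synthetic_cohort")
  sel <- cohort$config$selection
  if (is.null(sel)) stopf("config has no selection block")
  if (!is.null(cohort$truth$missing_mask))
    stopf("apply selection before missingness")
  cfg <- cohort$config
  if (cfg$J < 2) stopf("selection requires at least 2 providers")
  set.seed(derive_seed(cfg$seed, "selection"))

  N <- nrow(cohort$patients); J <- cfg$J; K <- cfg$K
  sites <- if ((sel$geometry %||% "grid") == "grid") {
    # jittered lattice: enough site irregularity that remoteness (and hence
    # severity sorting) varies across providers, without the extreme local
    # density clumps of fully random sites
    m <- ceiling(sqrt(J))
    g <- seq(1 / (2 * m), 1 - 1 / (2 * m), length.out = m)
    s <- as.matrix(expand.grid(g, g))[seq_len(J), , drop = FALSE]
    s + matrix(runif(2 * J, -0.5 / m, 0.5 / m), J, 2)
  } else cbind(runif(J), runif(J))
  loc <- cbind(runif(N), runif(N))
  D <- sqrt(outer(loc[, 1], sites[, 1], "-")^2 +
            outer(loc[, 2], sites[, 2], "-")^2)
  closest <- D == matrix(apply(D, 1, min), N, J)
  u <- rnorm(N)

  util <- sel$gamma[1] * D + sel$gamma[2] * D^2 + sel$gamma[3] * D^3 +
    sel$closest * closest + sel$lambda * u * D
  util <- util - apply(util, 1, max)      # stabilise exp
  p <- exp(util); p <- p / rowSums(p)
  cum <- t(apply(p, 1, cumsum))
  provider <- max.col(cum >= runif(N), ties.method = "first")

  sigl <- ifelse(dim_families(cohort$dimensions) == "probit", 1, cfg$sigma)
  delta <- sel$delta %||% (-dim_orientations(cohort$dimensions) * 0.5 * sigl)
  delta <- rep_len(delta, K)

  ystar <- cohort$truth$lin + cohort$truth$theta[provider, , drop = FALSE] +
    cohort$truth$eps + outer(u, delta)
  obs <- observe_outcomes(ystar, cohort$dimensions, cfg$top_code)

  nm <- dim_names(cohort$dimensions)
  cohort$patients[, nm] <- obs
  cohort$patients$provider_id <- provider
  dist_cols <- as.data.frame(D)
  names(dist_cols) <- paste0("dist_", seq_len(J))
  cohort$patients <- cbind(cohort$patients, dist_cols)
  cohort$truth$ystar <- ystar
  cohort$truth$complete <- obs
  cohort$truth$u <- u
  cohort$truth$delta <- delta
  cohort$truth$sites <- sites
  cohort$truth$loc <- loc
  cohort$truth$n_j <- tabulate(provider, J)
  cohort
}
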