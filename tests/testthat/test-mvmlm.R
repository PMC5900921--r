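test_that("degenerate single-provider gaussian fit recovers mean and variance", {
  set.seed(1)
  y <- rnorm(400, mean = 2, sd = 1.5)
  data <- data.frame(provider_id = 1, y1 = y)
  dims <- list(dimension_spec("y1", "gaussian", "identity", 1, character()))
  fit <- quiet_fit(data, dims, iterations = 400, burn_in = 100, seed = 2)
  expect_lt(abs(mean(fit$draws$alpha) - mean(y)), 4 * sd(y) / sqrt(length(y)))
  expect_lt(abs(mean(fit$draws$Omega[, 1, 1]) - var(y)), 0.25)
})

test_that("gaussian-only fit matches the independent multilevel oracle", {
  dims <- gauss2_dims()
  rho <- matrix(c(1, 0.5, 0.5, 1), 2)
  cfg <- synthetic_config(J = 10, n_j = 20, dimensions = dims,
                          alpha = c(1, -1), tau = c(0.8, 0.8),
                          sigma = c(1, 1.5), rho_theta = rho,
                          rho_eps = diag(2), seed = 17)
  coh <- simulate_cohort(cfg)
  fit <- quiet_fit(coh$patients, dims, iterations = 1500, burn_in = 500,
                   seed = 3)
  s <- summary(fit)$table
  # dimension-wise oracle: REML via lme4 (independent implementation)
  for (k in 1:2) {
    nm <- c("y1", "y2")[k]
    d <- data.frame(y = coh$patients[[nm]], g = coh$patients$provider_id)
    lf <- lme4::lmer(y ~ (1 | g), data = d, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(lf))
    a_hat <- unname(lme4::fixef(lf)[1])
    expect_lt(abs(s[paste0(nm, ":(Intercept)"), "mean"] - a_hat),
              3 * s[paste0(nm, ":(Intercept)"), "sd"])
    expect_lt(abs(s[paste0("tau_", nm), "mean"] - vc$sdcor[1]),
              3 * s[paste0("tau_", nm), "sd"] + 0.05)
    expect_lt(abs(s[paste0("sigma_", nm), "mean"] - vc$sdcor[2]),
              3 * s[paste0("sigma_", nm), "sd"])
  }
  # provider-level covariance tracks the realised effects; the correlation
  # ratio itself is boundary-skewed at J = 10 and is tested at J = 100 in
  # the recovery experiment instead
  cv <- fit$draws$Sigma[, 1, 2]
  expect_lt(abs(mean(cv) - cov(coh$truth$theta)[1, 2]), 3 * sd(cv))
})

test_that("univariate probit fit marginalises back to the event rate", {
  dims <- list(dimension_spec("b1", "probit", orientation = 1,
                              covariates = character()))
  cfg <- synthetic_config(J = 60, n_j = 80, dimensions = dims,
                          alpha = qnorm(0.3) * sqrt(1 + 0.09), tau = 0.3,
                          rho_theta = diag(1), rho_eps = diag(1), seed = 19)
  coh <- simulate_cohort(cfg)
  fit <- quiet_fit(coh$patients, dims, iterations = 800, burn_in = 300,
                   seed = 4)
  # numeric-integration oracle: rate = E Phi(alpha + tau Z)
  a <- mean(fit$draws$alpha)
  tau_hat <- mean(sqrt(fit$draws$Sigma[, 1, 1]))
  rate_implied <- integrate(function(z) pnorm(a + tau_hat * z) * dnorm(z),
                            -8, 8)$value
  expect_lt(abs(rate_implied - mean(coh$patients$b1)), 0.02)
})

test_that("probit identification and PSD invariants hold in every stored draw", {
  coh <- small_cohort(J = 8, n_j = 15, seed = 23)
  fit <- quiet_fit(coh$patients, coh$dimensions, iterations = 300,
                   burn_in = 100, seed = 5)
  pb <- which(dim_families(coh$dimensions) == "probit")
  for (s in seq_len(nrow(fit$draws$alpha))) {
    Om <- fit$draws$Omega[s, , ]
    Sg <- fit$draws$Sigma[s, , ]
    expect_identical(unname(diag(Om)[pb]), rep(1, length(pb)))
    expect_gte(min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
    expect_gte(min(eigen(Sg, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
  pe <- provider_effects(fit, force = TRUE)
  for (j in 1:8)
    expect_gte(min(eigen(pe$V[, , j], only.values = TRUE)$values), -1e-10)
})

test_that("fits are draw-for-draw reproducible given the seed", {
  coh <- small_cohort(J = 6, n_j = 12, seed = 29)
  f1 <- quiet_fit(coh$patients, coh$dimensions, iterations = 150,
                  burn_in = 50, seed = 7)
  f2 <- quiet_fit(coh$patients, coh$dimensions, iterations = 150,
                  burn_in = 50, seed = 7)
  expect_identical(f1$draws, f2$draws)
  f3 <- quiet_fit(coh$patients, coh$dimensions, iterations = 150,
                  burn_in = 50, seed = 8)
  expect_false(identical(f1$draws$alpha, f3$draws$alpha))
})

test_that("input validation: binary values, missing dimensions, degenerate 2SRI column", {
  coh <- small_cohort(J = 5, n_j = 10, seed = 31)
  bad <- coh$patients
  bad$wait18[7] <- 2
  expect_error(quiet_fit(bad, coh$dimensions, iterations = 50, burn_in = 10),
               "wait18.*row 7")
  allna <- coh$patients
  allna$ohs <- NA_real_
  expect_error(quiet_fit(allna, coh$dimensions, iterations = 50, burn_in = 10),
               "entirely missing")
  cz <- coh$patients
  cz$sel_resid <- 0
  expect_error(quiet_fit(cz, coh$dimensions, residual = "sel_resid",
                         iterations = 50, burn_in = 10), "degenerate")
})

test_that("missing outcome cells are handled by augmentation", {
  cfg <- synthetic_config(J = 15, n_j = 40, seed = 37)
  coh <- apply_missingness(simulate_cohort(cfg))
  expect_true(anyNA(coh$patients$ohs))
  fit <- quiet_fit(coh$patients, cfg$dimensions, iterations = 200,
                   burn_in = 80, seed = 9)
  expect_false(anyNA(fit$draws$alpha))
  expect_false(anyNA(fit$ystar_mean))
})

test_that("Mundlak option appends provider-mean regressors to every dimension", {
  coh <- small_cohort(J = 8, n_j = 20, seed = 41)
  fit <- quiet_fit(coh$patients, coh$dimensions,
                   mundlak = c("preop_score", "deprivation"),
                   iterations = 120, burn_in = 40, seed = 10)
  for (k in 1:4) {
    cn <- colnames(fit$draws$beta[[k]])
    expect_true(all(c("pm_preop_score", "pm_deprivation") %in% cn))
  }
})

test_that("EB shrinkage: no between-provider variance means full shrinkage", {
  dims <- gauss2_dims()[1]
  cfg <- synthetic_config(J = 30, n_j = 30, dimensions = dims,
                          tau = 0, sigma = 1, rho_theta = diag(1),
                          rho_eps = diag(1), seed = 43)
  coh <- simulate_cohort(cfg)
  fit <- quiet_fit(coh$patients, dims, iterations = 500, burn_in = 200,
                   seed = 11)
  pe <- provider_effects(fit, force = TRUE)
  expect_lt(max(abs(pe$theta_hat)), 0.15)
})

test_that("EB means match the classical shrinkage closed form (balanced case)", {
  dims <- gauss2_dims()[1]
  cfg <- synthetic_config(J = 40, n_j = 25, dimensions = dims,
                          alpha = 0, tau = 0.7, sigma = 1,
                          rho_theta = diag(1), rho_eps = diag(1), seed = 47)
  coh <- simulate_cohort(cfg)
  fit <- quiet_fit(coh$patients, dims, iterations = 800, burn_in = 300,
                   seed = 12)
  pe <- provider_effects(fit, force = TRUE)
  tau2 <- mean(fit$draws$Sigma[, 1, 1])
  sig2 <- mean(fit$draws$Omega[, 1, 1])
  n <- 25
  lam <- tau2 / (tau2 + sig2 / n)
  ybar <- tapply(coh$patients$y1, coh$patients$provider_id, mean)
  a <- mean(fit$draws$alpha)
  target <- lam * (ybar - a)
  expect_gt(cor(pe$theta_hat[, 1], target), 0.999)
  expect_lt(max(abs(pe$theta_hat[, 1] - target)), 0.06)
})

test_that("doubling a provider's case load tightens its effect posterior", {
  dims <- gauss2_dims()[1]
  set.seed(53)
  y <- c(rnorm(60, 0.5), rnorm(30, 0.5), rnorm(200, 0))
  data <- data.frame(provider_id = rep(c(1, 2, 3), c(60, 30, 200)), y1 = y)
  fit <- quiet_fit(data, dims, iterations = 600, burn_in = 200, seed = 13)
  pe <- provider_effects(fit, force = TRUE)
  expect_lt(pe$V[1, 1, 1], pe$V[1, 1, 2])   # n=60 vs n=30, same deviation
})

test_that("univariate and multivariate effects agree in the independence limit", {
  dims <- gauss2_dims()
  cfg <- synthetic_config(J = 20, n_j = 30, dimensions = dims,
                          tau = c(0.6, 0.6), sigma = c(1, 1),
                          rho_theta = diag(2), rho_eps = diag(2), seed = 59)
  coh <- simulate_cohort(cfg)
  fmv <- quiet_fit(coh$patients, dims, iterations = 700, burn_in = 250,
                   seed = 14)
  fu <- suppressWarnings(fit_univariate(coh$patients, dims, "y1",
                                        iterations = 700, burn_in = 250,
                                        seed = 15))
  pe_m <- provider_effects(fmv, force = TRUE)
  pe_u <- provider_effects(fu, force = TRUE)
  expect_gt(cor(pe_m$theta_hat[, 1], pe_u$theta_hat[, 1]), 0.99)
  expect_lt(mean(abs(pe_m$theta_hat[, 1] - pe_u$theta_hat[, 1])), 0.05)
})

test_that("posterior correlation summaries are well-formed", {
  coh <- small_cohort(J = 10, n_j = 20, seed = 61)
  fit <- quiet_fit(coh$patients, coh$dimensions, iterations = 200,
                   burn_in = 80, seed = 16)
  for (lv in c("provider", "patient")) {
    pc <- perf_correlation(fit, lv)
    expect_equal(unname(diag(pc$mean)), rep(1, 4))
    expect_equal(pc$mean, t(pc$mean))
    expect_true(all(abs(pc$mean) <= 1))
    expect_false(any(diag(pc$excludes_zero)))
  }
})

test_that("fit methods (print, summary, coef, residuals, predict, simulate, plot) work", {
  coh <- small_cohort(J = 6, n_j = 15, seed = 67)
  fit <- quiet_fit(coh$patients, coh$dimensions, iterations = 150,
                   burn_in = 50, seed = 17)
  expect_output(print(fit), "mvmlm")
  s <- summary(fit)
  expect_output(print(s), "Multivariate multilevel fit")
  expect_named(coef(fit), c("los", "ohs", "wait18", "readm28"))
  r <- residuals(fit)
  expect_equal(dim(r), c(nrow(coh$patients), 4))
  expect_lt(max(abs(colMeans(r))), 0.5)
  p <- predict(fit, coh$patients[1:5, ])
  expect_equal(dim(p), c(5, 4))
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sim, 2)
  expect_true(all(sim[[1]]$wait18 %in% 0:1))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit, "ohs"))
  # convergence gate: unconverged fit refuses provider_effects unless forced
  short <- quiet_fit(coh$patients, coh$dimensions, iterations = 40,
                     burn_in = 10, seed = 18)
  if (!short$converged) expect_error(provider_effects(short), "convergence")
  expect_s3_class(provider_effects(short, force = TRUE), "provider_effects")
})
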