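test_that("configuration rejects invalid inputs with informative errors", {
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, 0.9, 0.9, 0.9, 1), 3)
  bad[1, 2] <- -0.9; bad[2, 1] <- -0.9   # indefinite
  dims3 <- list(dimension_spec("a", "gaussian"), dimension_spec("b", "gaussian"),
                dimension_spec("c", "gaussian"))
  expect_error(synthetic_config(dimensions = dims3, rho_theta = bad),
               "rho_theta")
  expect_error(synthetic_config(missing_rates = c(0, 0, 1.2, 0)), "missing_rates")
  expect_error(synthetic_config(tau = c(-1, 1, 1, 1)), "tau")
  expect_error(synthetic_config(J = 1, selection = selection_config()),
               "at least 2")
  expect_error(dimension_spec("x", orientation = 2), "orientation")
  expect_error(synthetic_config(top_code = "wait18"), "top_code")
})

test_that("with all structure switched off outcomes are standard normal / 0.5", {
  dims <- gauss2_dims()
  dims[[2]] <- dimension_spec("b1", "probit", orientation = 1,
                              covariates = character())
  cfg <- synthetic_config(J = 2, n_j = 10000, dimensions = dims,
                          alpha = c(0, 0), tau = c(0, 0), sigma = c(1, 1),
                          rho_theta = diag(2), rho_eps = diag(2), seed = 5)
  coh <- simulate_cohort(cfg)
  y <- coh$patients$y1
  expect_lt(abs(mean(y)), 3 / sqrt(length(y)))
  expect_lt(abs(sd(y) - 1), 0.02)
  expect_lt(abs(mean(coh$patients$b1) - 0.5), 3 * 0.5 / sqrt(length(y)))
})

test_that("provider-effect correlation matches the configured matrix", {
  # direct Monte-Carlo check on the generator's own theta draws
  dims <- gauss2_dims()
  rho <- matrix(c(1, 0.5, 0.5, 1), 2)
  cfg <- synthetic_config(J = 2000, n_j = 1, dimensions = dims,
                          tau = c(0.3, 0.3), sigma = c(1, 1),
                          rho_theta = rho, rho_eps = diag(2), seed = 7)
  coh <- simulate_cohort(cfg)
  expect_lt(abs(cor(coh$truth$theta)[1, 2] - 0.5), 0.03)
  expect_equal(dim(coh$truth$theta), c(2000, 2))
})

test_that("probit intercept calibration reproduces the marginal event rates", {
  # alpha = qnorm(rate) * sqrt(1 + tau^2) must marginalise back to the rate
  cfg <- synthetic_config(J = 400, n_j = 250, seed = 11)
  coh <- simulate_cohort(cfg)
  # 4 SEs including the provider-level clustering component
  se_rate <- function(p, tau, N, J)
    sqrt(p * (1 - p) / N + dnorm(qnorm(p))^2 * tau^2 / J)
  expect_lt(abs(mean(coh$patients$wait18) - 0.17),
            4 * se_rate(0.17, 0.3, 1e5, 400))
  expect_lt(abs(mean(coh$patients$readm28) - 0.05),
            4 * se_rate(0.05, 0.3, 1e5, 400))
})

test_that("latent moments and residual correlations match the configuration", {
  cfg <- synthetic_config(J = 200, n_j = 50, seed = 13)
  coh <- simulate_cohort(cfg)
  ys <- coh$truth$ystar
  K <- 4
  for (k in 1:K) {
    v_expect <- cfg$tau[k]^2 + cfg$sigma[k]^2
    v_obs <- var(ys[, k])
    se <- v_expect * sqrt(2 / nrow(ys)) * 3 + 0.05 * v_expect  # clustering slack
    expect_lt(abs(v_obs - v_expect), 3 * se + 0.1 * v_expect)
  }
  r_eps <- cor(coh$truth$eps)
  expect_lt(max(abs(r_eps - cfg$rho_eps)), 0.03)
})

test_that("generation is bit-reproducible given the seed", {
  c1 <- simulate_cohort(synthetic_config(J = 5, n_j = 10, seed = 42))
  c2 <- simulate_cohort(synthetic_config(J = 5, n_j = 10, seed = 42))
  c3 <- simulate_cohort(synthetic_config(J = 5, n_j = 10, seed = 43))
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$truth$theta, c2$truth$theta)
  expect_false(identical(c1$patients, c3$patients))
})

test_that("MCAR missingness hits the configured rate and nothing else", {
  cfg <- synthetic_config(J = 500, n_j = 200, seed = 3)
  coh <- simulate_cohort(cfg)
  complete <- coh$patients
  coh2 <- apply_missingness(coh)
  # the health-status dimension at its survey non-response rate
  expect_lt(abs(mean(is.na(coh2$patients$ohs)) - 0.152), 0.003)
  expect_equal(mean(is.na(coh2$patients$readm28)), 0)
  # non-masked cells unchanged; complete values retained in truth
  m <- coh2$truth$missing_mask[, "ohs"]
  expect_identical(coh2$patients$ohs[!m], complete$ohs[!m])
  expect_identical(coh2$truth$complete[, "ohs"], complete$ohs)
  # covariates never masked
  expect_false(anyNA(coh2$patients$preop_score))
  # zero rates leave the table untouched
  coh3 <- apply_missingness(coh, rates = rep(0, 4))
  expect_identical(coh3$patients, complete)
  expect_error(apply_missingness(coh, rates = c(0, 2, 0, 0)), "rates")
})

test_that("MAR missingness depends on the covariate but not the masked outcome", {
  cfg <- synthetic_config(J = 200, n_j = 100, seed = 9,
                          missing_mechanism = "MAR",
                          mar_covariate = "preop_score", mar_slope = 1.5)
  coh <- apply_missingness(simulate_cohort(cfg))
  m <- coh$truth$missing_mask[, "ohs"]
  expect_lt(abs(mean(m) - 0.152), 0.01)
  x <- coh$patients$preop_score
  y_true <- coh$truth$complete[, "ohs"]
  fit <- glm(m ~ x + y_true, family = binomial())
  z <- coef(summary(fit))[, "z value"]
  expect_gt(z["x"], 4)              # score test detects the driver
  expect_lt(abs(z["y_true"]), 3)    # no residual outcome dependence
})

test_that("top-coding caps the observed scale at the 99th percentile", {
  cfg <- synthetic_config(J = 50, n_j = 100, seed = 21, top_code = "los")
  coh <- simulate_cohort(cfg)
  raw <- coh$truth$ystar[, 1]
  expect_equal(max(coh$patients$los),
               unname(quantile(expm1(raw), 0.99)))
})

test_that("fixed provider effects override the random draw", {
  tf <- matrix(NA_real_, 10, 4); tf[1, ] <- c(1, 2, 3, 4)
  cfg <- synthetic_config(J = 10, n_j = 5, seed = 2, theta_fixed = tf)
  coh <- simulate_cohort(cfg)
  expect_equal(coh$truth$theta[1, ], c(1, 2, 3, 4))
})

test_that("distance-only choice ignores severity; confounded choice does not", {
  base <- function(lambda, seed) {
    cfg <- synthetic_config(J = 16, n_j = 80, seed = seed,
                            selection = selection_config(lambda = lambda))
    simulate_choice(simulate_cohort(cfg))
  }
  coh0 <- base(0, 31)
  # chosen-provider mean distance rank vs confounder: null under lambda = 0
  rank_of_choice <- function(coh) {
    D <- as.matrix(coh$patients[grep("^dist_", names(coh$patients))])
    idx <- cbind(seq_len(nrow(D)), coh$patients$provider_id)
    rowSums(D < D[idx])  # how many providers are closer than the chosen one
  }
  expect_lt(abs(cor(rank_of_choice(coh0), coh0$truth$u)),
            3 / sqrt(nrow(coh0$patients)))
  coh1 <- base(16, 31)
  expect_gt(cor(rank_of_choice(coh1), coh1$truth$u), 0.2)
  # strongly negative distance coefficient: most patients pick the closest
  cfg <- synthetic_config(J = 16, n_j = 80, seed = 33,
                          selection = selection_config(gamma = c(-40, 0, 0),
                                                       lambda = 0))
  coh <- simulate_choice(simulate_cohort(cfg))
  expect_gt(mean(rank_of_choice(coh) == 0), 0.8)
  # outcomes rebuilt with the chosen provider's effect plus confounder load
  expect_identical(dim(coh1$truth$ystar), dim(coh1$truth$lin))
})
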