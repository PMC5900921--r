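# Shared fixtures: everything is generated in code at test time.

quiet_fit <- function(...) suppressWarnings(mvmlm(...))

# Two plain gaussian dimensions with no covariates (oracle-friendly).
gauss2_dims <- function() list(
  dimension_spec("y1", "gaussian", "identity", +1, character()),
  dimension_spec("y2", "gaussian", "identity", +1, character())
)

# One gaussian + one probit dimension.
mixed2_dims <- function() list(
  dimension_spec("y1", "gaussian", "identity", +1, character()),
  dimension_spec("b1", "probit", orientation = +1, covariates = character())
)

# A small default-dimension cohort for smoke tests.
small_cohort <- function(J = 10, n_j = 20, seed = 1, ...) {
  simulate_cohort(synthetic_config(J = J, n_j = n_j, seed = seed, ...))
}

# Hand-rolled provider_effects object for dominance unit tests.
make_pe <- function(theta_hat, V, orientation = rep(1, ncol(theta_hat)),
                    draws = NULL) {
  J <- nrow(theta_hat); K <- ncol(theta_hat)
  if (length(dim(V)) == 2) V <- array(V, c(K, K, J))
  if (is.null(draws)) draws <- array(rnorm(50 * J * K), c(50, J, K))
  structure(list(provider_id = as.character(seq_len(J)),
                 theta_hat = theta_hat, V = V, draws = draws,
                 n_j = rep(10, J), dim_names = paste0("d", seq_len(K)),
                 orientation = orientation, converged = TRUE),
            class = "provider_effects")
}

# Independent brute-force conditional-logit log-likelihood (distance only).
clogit_loglik_brute <- function(b, choice) {
  ll <- 0
  for (pid in unique(choice$patient_id)) {
    rows <- choice[choice$patient_id == pid, ]
    eta <- b * rows$distance
    ll <- ll + eta[rows$chosen == 1] - log(sum(exp(eta)))
  }
  ll
}
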