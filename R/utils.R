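# Internal helpers shared across modules.

#' @importFrom stats rnorm runif qnorm pnorm pchisq quantile sd var cov cor
#'   coef rbinom rWishart setNames complete.cases as.formula
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a master seed
#'
#' Every stochastic stage of the pipeline (simulation, selection, fitting,
#' classification) is seeded with `derive_seed(master, stage)` so that stages
#' can be re-run in isolation while the whole run stays reproducible from a
#' single master seed. The derivation is `(master * 48271 + stage index) mod
#' (2^31 - 2) + 1`, a fixed linear map kept strictly inside the positive
#' 32-bit integer range.
#'
#' @param seed master seed (a single integer).
#' @param stage stage name, one of `"simulate"`, `"selection"`,
#'   `"missingness"`, `"fit"`, `"assess"`, `"compare"`.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage = c("simulate", "selection", "missingness",
                                        "fit", "assess", "compare")) {
  stage <- match.arg(stage)
  idx <- match(stage, c("simulate", "selection", "missingness",
                        "fit", "assess", "compare"))
  m <- 2147483646
  x <- ((as.numeric(seed) %% m) * 48271) %% m
  as.integer((x + idx) %% m + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == floor(x)
}

#' Check that a matrix is a valid correlation matrix
#'
#' Symmetric, unit diagonal, positive semi-definite (within a small numerical
#' tolerance on the smallest eigenvalue).
#'
#' @param m matrix to check.
#' @param name label used in the error message.
#' @param tol eigenvalue tolerance.
#' @return invisibly `TRUE`; stops with a diagnostic naming the offending
#'   matrix otherwise.
#' @keywords internal
check_correlation_matrix <- function(m, name = deparse(substitute(m)),
                                     tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stopf("'%s' must be a square matrix", name)
  if (max(abs(m - t(m))) > tol)
    stopf("'%s' is not symmetric", name)
  if (max(abs(diag(m) - 1)) > tol)
    stopf("'%s' does not have a unit diagonal", name)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol)
    stopf("'%s' is not positive semi-definite (min eigenvalue %.3g)",
          name, min(ev))
  invisible(TRUE)
}

# Draw one K-variate normal with mean m and *precision* P (upper chol U).
rmvn_prec <- function(m, U) {
  m + backsolve(U, rnorm(length(m)))
}

# Draw n rows from MVN(mean, cov); cov may be rank-deficient (eigen fallback).
rmvn <- function(n, mean, cov) {
  K <- length(mean)
  L <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(L)) {
    e <- eigen(cov, symmetric = TRUE)
    L <- t(e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0))))
  }
  matrix(rnorm(n * K), n, K) %*% L + rep(mean, each = n)
}

# Inverse-Wishart draw: X ~ IW(df, S)  <=>  X^{-1} ~ Wishart(df, S^{-1}).
riwish <- function(df, S) {
  W <- rWishart(1L, df, chol2inv(chol(S)))[, , 1L]
  chol2inv(chol(W))
}

# Truncated standard-normal-family draw, vectorised: N(mu, sd^2) truncated to
# (0, Inf) when lower = TRUE, (-Inf, 0] when lower = FALSE. Inverse-CDF with
# probability clamping; adequate for the |z| < ~8 regime these models live in.
rtnorm01 <- function(mu, sd, positive) {
  p0 <- pnorm(-mu / sd)           # P(draw <= 0)
  u <- runif(length(mu))
  p <- ifelse(positive, p0 + u * (1 - p0), u * p0)
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  mu + sd * qnorm(p)
}

# Split-Rhat (potential scale reduction on a single chain split in half).
split_rhat <- function(x) {
  n <- length(x)
  if (n < 4 || sd(x) == 0) return(1)
  h <- floor(n / 2)
  ch <- list(x[seq_len(h)], x[(n - h + 1):n])
  m <- vapply(ch, mean, 0); v <- vapply(ch, var, 0)
  W <- mean(v); B <- h * var(m)
  if (W <= 0) return(1)
  sqrt(((h - 1) / h * W + B / h) / W)
}

# Effective sample size via initial positive sequence of autocorrelations.
ess <- function(x) {
  n <- length(x)
  if (n < 4 || sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 2, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0.05) break
    s <- s + ac[k]
  }
  max(1, n / (1 + 2 * s))
}
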