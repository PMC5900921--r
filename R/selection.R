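# Two-stage residual inclusion for endogenous provider choice.
#
# Stage 1: a conditional logit of provider choice on alternative-specific
# distance features (distance, distance^2, distance^3, closest-alternative
# indicator), with low-volume providers removed from the choice set.
# Stage 2: the generalised first-stage residual r_i = 1 - phat_i(chosen) is
# entered as an extra regressor into every outcome dimension, and the K
# residual coefficients are tested jointly.

#' Build per-patient choice sets from wide distance columns
#'
#' Expands a patient table with `dist_<provider_id>` columns into long
#' choice-set form (one row per patient-alternative) with the distance
#' polynomial features and a closest-alternative indicator. Providers with
#' fewer than `min_patients` chosen patients are removed from every choice
#' set; patients whose chosen provider is removed are dropped and counted.
#'
#' @param data patient table with `patient_id`, `provider_id` and
#'   `dist_<id>` columns covering every provider.
#' @param min_patients volume floor for inclusion in the choice set
#'   (default 30; `0` disables the filter).
#' @return a data.frame of class `choice_data` with columns `patient_id`,
#'   `provider_id`, `distance`, `closest`, `chosen`; the number of dropped
#'   patients is in `attr(, "dropped")`.
#' @export
build_choice_set <- function(data, min_patients = 30) {
  if (is.null(data$patient_id) || is.null(data$provider_id))
    stopf("'data' needs patient_id and provider_id columns")
  dist_cols <- grep("^dist_", names(data), value = TRUE)
  if (!length(dist_cols)) stopf("no dist_<provider> columns found")
  ids <- sub("^dist_", "", dist_cols)
  if (!all(as.character(data$provider_id) %in% ids))
    stopf("some chosen providers have no distance column")
  D <- as.matrix(data[dist_cols])
  if (any(D < 0)) stopf("distances must be non-negative")

  vol <- table(factor(as.character(data$provider_id), levels = ids))
  keep <- names(vol)[vol >= min_patients]
  if (!length(keep)) stopf("volume floor leaves an empty choice set")
  drop_pat <- !(as.character(data$provider_id) %in% keep)
  dropped <- sum(drop_pat)
  if (dropped)
    message(sprintf("dropping %d patients whose provider falls below the %d-patient floor",
                    dropped, min_patients))
  data <- data[!drop_pat, , drop = FALSE]
  D <- D[!drop_pat, match(keep, ids), drop = FALSE]
  if (length(keep) < 2) stopf("fewer than 2 alternatives remain")

  n <- nrow(data); Jc <- length(keep)
  closest <- D == matrix(apply(D, 1, min), n, Jc)
  # break distance ties: exactly one closest alternative per patient
  first <- max.col(closest, ties.method = "first")
  closest[] <- FALSE
  closest[cbind(seq_len(n), first)] <- TRUE

  out <- data.frame(
    patient_id = rep(data$patient_id, each = Jc),
    provider_id = rep(keep, times = n),
    distance = as.vector(t(D)),
    closest = as.numeric(as.vector(t(closest))),
    chosen = as.numeric(rep(as.character(data$provider_id), each = Jc) ==
                          rep(keep, times = n)))
  attr(out, "dropped") <- dropped
  attr(out, "providers") <- keep
  class(out) <- c("choice_data", "data.frame")
  out
}

#' Fit the first-stage conditional logit of provider choice
#'
#' Maximum-likelihood conditional logit over the alternative-specific
#' features `distance`, `distance^2`, `distance^3` and the
#' closest-alternative indicator (features constant within a patient's
#' choice set drop out of the conditional likelihood). Estimation uses the
#' exact conditional likelihood for one chosen alternative per choice set.
#'
#' @param choice a [build_choice_set()] result.
#' @param features model features; any subset of
#'   `c("distance", "distance2", "distance3", "closest")`.
#' @return an object of class `choice_fit`: coefficients, log-likelihood,
#'   and the per-alternative predicted probabilities appended to the choice
#'   data (summing to one within each patient).
#' @export
fit_choice_model <- function(choice,
                             features = c("distance", "distance2",
                                          "distance3", "closest")) {
  if (!inherits(choice, "choice_data")) stopf("'choice' must be choice_data")
  features <- match.arg(features, several.ok = TRUE)
  ch <- as.data.frame(choice)
  ch$distance2 <- ch$distance^2
  ch$distance3 <- ch$distance^3
  nalt <- table(ch$patient_id)
  if (any(nalt < 2)) stopf("every patient needs at least 2 alternatives")
  # conditional logit = exact Cox partial likelihood with one chosen
  # alternative per stratum (survival::clogit builds the same call)
  ch$.t <- 1
  f <- as.formula(paste("survival::Surv(.t, chosen) ~",
                        paste(features, collapse = " + "),
                        "+ survival::strata(patient_id)"))
  fit <- survival::coxph(f, data = ch, method = "exact")
  cf <- coef(fit)
  if (anyNA(cf)) stopf("conditional logit did not converge (NA coefficients)")
  eta <- as.matrix(ch[features]) %*% cf
  grp <- factor(ch$patient_id, levels = unique(ch$patient_id))
  emax <- stats::ave(as.numeric(eta), grp, FUN = max)
  ex <- exp(eta - emax)
  denom <- stats::ave(as.numeric(ex), grp, FUN = sum)
  ch$prob <- as.numeric(ex) / denom
  ll <- sum(log(ch$prob[ch$chosen == 1]))
  structure(list(coefficients = cf, vcov = stats::vcov(fit),
                 loglik = ll, features = features, data = ch),
            class = "choice_fit")
}

#' @export
print.choice_fit <- function(x, digits = 4, ...) {
  cat("<choice_fit> conditional logit of provider choice\n")
  print(round(x$coefficients, digits))
  cat(sprintf("log-likelihood: %.3f (%d patients)\n", x$loglik,
              length(unique(x$data$patient_id))))
  invisible(x)
}

#' First-stage generalised residuals
#'
#' The scalar per-patient residual `r_i = 1 - phat_i(chosen alternative)`:
#' the probability mass the distance-only choice model assigns to
#' alternatives the patient did *not* choose. Patients whose choices the
#' instrument explains poorly receive large residuals; the residual proxies
#' the unobserved patient-level component of choice plus noise.
#'
#' @param fit a [fit_choice_model()] result.
#' @return a data.frame with `patient_id` and `sel_resid`.
#' @export
choice_residuals <- function(fit) {
  if (!inherits(fit, "choice_fit")) stopf("'fit' must be a choice_fit")
  ch <- fit$data[fit$data$chosen == 1, c("patient_id", "prob")]
  data.frame(patient_id = ch$patient_id, sel_resid = 1 - ch$prob)
}

#' Second-stage selection test and corrected fit
#'
#' Refits the multivariate multilevel model with the first-stage residual
#' entered into every dimension, and tests the K residual coefficients
#' jointly with a posterior Wald statistic: `m' V^{-1} m` for the posterior
#' mean `m` and posterior covariance `V` of the coefficients, referred to a
#' chi-square distribution on K degrees of freedom. A significant statistic
#' indicates selection bias; the corrected provider posteriors come from the
#' refitted model.
#'
#' @param data patient table (patients lacking a residual are dropped with a
#'   message).
#' @param dimensions dimension list.
#' @param residuals a [choice_residuals()] data.frame.
#' @param ... fitting arguments passed to [mvmlm()].
#' @return an object of class `selection_test`: residual coefficients
#'   (posterior means), their posterior covariance, `statistic`, `df`,
#'   `p.value`, and the corrected `fit`.
#' @export
selection_test <- function(data, dimensions, residuals, ...) {
  if (is.null(residuals$patient_id) || is.null(residuals$sel_resid))
    stopf("'residuals' needs patient_id and sel_resid columns")
  if (sd(residuals$sel_resid) == 0)
    stopf("degenerate residual column (no variation)")
  idx <- match(data$patient_id, residuals$patient_id)
  if (all(is.na(idx))) stopf("no patients match the residuals")
  if (anyNA(idx)) {
    message(sprintf("dropping %d patients without a first-stage residual",
                    sum(is.na(idx))))
    data <- data[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  data$sel_resid <- residuals$sel_resid[idx]
  fit <- mvmlm(data, dimensions, residual = "sel_resid", ...)
  K <- fit$K
  dr <- vapply(seq_len(K), function(k) {
    b <- fit$draws$beta[[k]]
    b[, colnames(b) == "sel_resid"]
  }, numeric(nrow(fit$draws$alpha)))
  m <- colMeans(dr)
  V <- cov(dr)
  stat <- drop(t(m) %*% solve(V, m))
  structure(list(coefficients = setNames(m, dim_names(fit$dimensions)),
                 vcov = V, statistic = stat, df = K,
                 p.value = pchisq(stat, K, lower.tail = FALSE),
                 fit = fit),
            class = "selection_test")
}

#' @export
print.selection_test <- function(x, digits = 3, ...) {
  cat("Joint test of first-stage residual coefficients (selection bias):\n")
  print(round(x$coefficients, digits))
  cat(sprintf("chi-square(%d) = %.2f, p = %.4g\n", x$df, x$statistic,
              x$p.value))
  invisible(x)
}
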