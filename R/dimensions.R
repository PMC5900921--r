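#' Define a performance dimension
#'
#' A performance dimension is one outcome column of the patient table together
#' with its measurement model: a Gaussian dimension is modelled on a
#' (possibly transformed) continuous latent scale, a probit dimension treats
#' the observed 0/1 outcome as the indicator that a latent Gaussian variable
#' exceeds zero. Each dimension carries its own risk-adjustment covariate set
#' (possibly empty, e.g. waiting time is deliberately not risk-adjusted) and
#' an orientation: `+1` when a higher value of the *latent* outcome is better
#' for patients, `-1` when it is worse (length of stay, waiting beyond target,
#' readmission).
#'
#' @param name column name of the outcome in the patient table.
#' @param family `"gaussian"` or `"probit"`.
#' @param transform for Gaussian dimensions, the map from observed to latent
#'   scale: `"identity"`, `"log1p"`, or `"custom"` (then supply `trans` and
#'   `inverse`). Probit dimensions take no transform.
#' @param orientation `+1` or `-1` (see above).
#' @param covariates character vector of covariate column names used for
#'   risk adjustment on this dimension; may be empty.
#' @param trans,inverse monotone transform and its inverse, used only when
#'   `transform = "custom"`.
#' @return an object of class `dimension_spec`.
#' @examples
#' dimension_spec("los", "gaussian", transform = "log1p", orientation = -1,
#'                covariates = c("preop_score", "male"))
#' @export
dimension_spec <- function(name, family = c("gaussian", "probit"),
                           transform = c("identity", "log1p", "custom"),
                           orientation = 1, covariates = character(),
                           trans = NULL, inverse = NULL) {
  family <- match.arg(family)
  if (!orientation %in% c(-1, 1))
    stopf("orientation for dimension '%s' must be +1 or -1", name)
  if (family == "probit") {
    transform <- "none"
    trans <- inverse <- NULL
  } else {
    transform <- match.arg(transform)
    if (transform == "identity") {
      trans <- identity; inverse <- identity
    } else if (transform == "log1p") {
      trans <- log1p; inverse <- expm1
    } else {
      if (!is.function(trans) || !is.function(inverse))
        stopf("custom transform for '%s' needs 'trans' and 'inverse' functions",
              name)
    }
  }
  structure(list(name = as.character(name), family = family,
                 transform = transform, orientation = orientation,
                 covariates = as.character(covariates),
                 trans = trans, inverse = inverse),
            class = "dimension_spec")
}

#' @export
print.dimension_spec <- function(x, ...) {
  cat(sprintf("<dimension> %s: %s%s, orientation %+d, covariates: %s\n",
              x$name, x$family,
              if (x$family == "gaussian") paste0(" (", x$transform, ")") else "",
              x$orientation,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Default four-dimensional performance specification
#'
#' The default dimension set mirrors a hip-replacement provider profiling
#' setting: a skewed continuous length of stay (log1p latent scale, lower is
#' better), a continuous patient-reported outcome score (identity scale,
#' higher is better), and two adverse binary indicators, waiting beyond the
#' 18-week target and 28-day emergency readmission (probit, lower is better).
#' Waiting time carries no risk adjustment; the other dimensions use the
#' generator's standard covariates.
#'
#' @return a list of four [dimension_spec] objects.
#' @export
default_dimensions <- function() {
  core <- c("preop_score", "male", "deprivation")
  list(
    dimension_spec("los",     "gaussian", "log1p",    -1, core),
    dimension_spec("ohs",     "gaussian", "identity", +1, core),
    dimension_spec("wait18",  "probit",   orientation = -1,
                   covariates = character()),
    dimension_spec("readm28", "probit",   orientation = -1,
                   covariates = c("preop_score", "male"))
  )
}

# Validate a list of dimension specs; returns it with names set.
check_dimensions <- function(dimensions) {
  if (inherits(dimensions, "dimension_spec")) dimensions <- list(dimensions)
  if (!length(dimensions)) stopf("at least one dimension is required")
  ok <- vapply(dimensions, inherits, TRUE, what = "dimension_spec")
  if (!all(ok)) stopf("'dimensions' must be a list of dimension_spec objects")
  nm <- vapply(dimensions, `[[`, "", "name")
  if (anyDuplicated(nm)) stopf("dimension names must be unique")
  names(dimensions) <- nm
  dimensions
}

dim_names <- function(dimensions) vapply(dimensions, `[[`, "", "name")
dim_families <- function(dimensions) vapply(dimensions, `[[`, "", "family")
dim_orientations <- function(dimensions)
  vapply(dimensions, `[[`, 0, "orientation")
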