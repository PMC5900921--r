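# Reading/writing patient tables, run configuration, and the end-to-end
# pipeline (simulate -> [selection] -> fit -> assess -> compare).

#' Read and validate a patient-level CSV
#'
#' Empty cells and `"NA"` are read as missing. Validation is column-level:
#' the provider column and every declared outcome column must exist, binary
#' outcomes may contain only 0/1/missing (violations are reported with row
#' and column), and covariates must be numeric and complete. Continuous
#' (non-0/1) covariates are mean-centred on load when `centre = TRUE`.
#'
#' @param path CSV path.
#' @param dimensions dimension list declaring outcomes and covariates.
#' @param centre mean-centre continuous covariates.
#' @return a validated data.frame.
#' @export
read_patient_table <- function(path, dimensions, centre = TRUE) {
  dimensions <- check_dimensions(dimensions)
  if (!file.exists(path)) stopf("file not found: %s", path)
  data <- utils::read.csv(path, na.strings = c("", "NA"),
                          check.names = FALSE)
  if (is.null(data$provider_id)) stopf("missing column: provider_id")
  if (is.null(data$patient_id)) data$patient_id <- seq_len(nrow(data))
  for (d in dimensions) {
    col <- data[[d$name]]
    if (is.null(col)) stopf("missing outcome column: %s", d$name)
    if (!is.numeric(col)) stopf("outcome column '%s' is not numeric", d$name)
    if (d$family == "probit") {
      bad <- which(!is.na(col) & !(col %in% c(0, 1)))
      if (length(bad))
        stopf("binary outcome '%s' has invalid value %s in row %d",
              d$name, format(col[bad[1]]), bad[1])
    }
  }
  covs <- unique(unlist(lapply(dimensions, `[[`, "covariates")))
  for (v in covs) {
    col <- data[[v]]
    if (is.null(col)) stopf("missing covariate column: %s", v)
    if (!is.numeric(col)) stopf("covariate column '%s' is not numeric", v)
    if (anyNA(col)) stopf("covariate column '%s' has missing values", v)
    if (centre && !all(col %in% c(0, 1)))
      data[[v]] <- col - mean(col)
  }
  data
}

#' Write a patient table as CSV (missing values as empty cells)
#'
#' @param data patient table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_patient_table <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Persist a synthetic cohort as plain text
#'
#' Writes `patients.csv` and `truth.json` (generating parameters and true
#' provider effects) into a directory.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_patient_table(cohort$patients, file.path(dir, "patients.csv"))
  tr <- cohort$truth
  truth <- list(theta = tr$theta, alpha = tr$alpha, beta = tr$beta,
                tau = tr$tau, sigma = tr$sigma,
                rho_theta = tr$rho_theta, rho_eps = tr$rho_eps,
                n_j = tr$n_j, seed = cohort$config$seed)
  if (!is.null(tr$u)) truth$latent_confounder <- tr$u
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a pipeline run configuration from YAML or JSON
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return a named list of settings for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Run the full assessment pipeline
#'
#' Executes simulate -> (selection correction) -> fit -> assess -> compare
#' as configured, and writes per-provider results, the counts table, fit
#' diagnostics and a run log into the output directory. Every stochastic
#' stage is sub-seeded from the single master seed (see [derive_seed()]),
#' so a rerun with the same configuration is byte-identical.
#'
#' @param config a named list (or a path readable by [read_run_config()])
#'   with entries: `out_dir` (required), `seed`, `J`, `n_j`, `iterations`,
#'   `burn_in`, `thin`, `S`, `thresholds`, `selection` (logical: simulate
#'   endogenous choice and apply the 2SRI correction), `min_patients`,
#'   `compare` (logical: run the three-approach comparison), `input`
#'   (optional CSV path to analyse instead of simulating; distance columns
#'   are then required when `selection` is on).
#' @return invisibly, a list with the fitted model, dominance results,
#'   counts, selection test (if run) and output file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- list(seed = 1L, J = 20, n_j = 30, iterations = 600, burn_in = 200,
              thin = 1, S = 10000, thresholds = c(0.5, 0.8, 0.9, 0.99),
              selection = FALSE, min_patients = 30, compare = TRUE,
              input = NULL, force = FALSE)
  cfg[names(config)] <- config
  if (is.null(cfg$out_dir)) stopf("config needs an out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run.log")
  log_line <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                     file = logf, append = TRUE)
  cat(sprintf("provdom run, master seed %d\n", cfg$seed), file = logf)
  log_line("R %s, provdom %s", getRversion(),
           as.character(utils::packageVersion("provdom")))

  dims <- default_dimensions()
  truth <- NULL
  if (is.null(cfg$input)) {
    scfg <- synthetic_config(
      J = cfg$J, n_j = cfg$n_j, seed = cfg$seed,
      selection = if (cfg$selection) selection_config() else NULL)
    coh <- simulate_cohort(scfg)
    if (cfg$selection) coh <- simulate_choice(coh)
    coh <- apply_missingness(coh)
    data <- coh$patients
    truth <- coh$truth
    write_patient_table(data, file.path(cfg$out_dir, "patients.csv"))
    log_line("simulated %d patients in %d providers (selection: %s)",
             nrow(data), cfg$J, cfg$selection)
  } else {
    data <- read_patient_table(cfg$input, dims)
    log_line("read %d patients from %s", nrow(data), cfg$input)
  }

  sel_test <- NULL
  fit_args <- list(iterations = cfg$iterations, burn_in = cfg$burn_in,
                   thin = cfg$thin)
  if (cfg$selection) {
    choice <- build_choice_set(data, min_patients = cfg$min_patients)
    cf <- fit_choice_model(choice)
    rs <- choice_residuals(cf)
    sel_test <- do.call(selection_test,
                        c(list(data, dims, rs,
                               seed = derive_seed(cfg$seed, "fit")),
                          fit_args))
    fit <- sel_test$fit
    log_line("selection test: chi-square(%d) = %.2f, p = %.4g",
             sel_test$df, sel_test$statistic, sel_test$p.value)
  } else {
    fit <- do.call(mvmlm, c(list(data, dims,
                                 seed = derive_seed(cfg$seed, "fit")),
                            fit_args))
  }
  log_line("fit: %d draws, max split-Rhat %.3f, converged: %s",
           nrow(fit$draws$alpha), max(fit$diagnostics$rhat, na.rm = TRUE),
           fit$converged)

  pe <- provider_effects(fit, force = cfg$force)
  dom <- dominance(pe, S = cfg$S, seed = derive_seed(cfg$seed, "assess"))
  res <- as.data.frame(dom)
  for (t in cfg$thresholds)
    res[[sprintf("label_%g", t)]] <- as.character(classify(dom, t))
  utils::write.csv(res, file.path(cfg$out_dir, "provider_results.csv"),
                   row.names = FALSE, na = "")

  counts <- NULL
  if (isTRUE(cfg$compare)) {
    comp <- do.call(compare_approaches,
                    c(list(data, dims, thresholds = cfg$thresholds,
                           S = cfg$S, seed = derive_seed(cfg$seed, "compare"),
                           force = cfg$force),
                      fit_args))
    counts <- as.data.frame(comp)
    jsonlite::write_json(counts, file.path(cfg$out_dir, "counts.json"),
                         digits = NA, pretty = TRUE)
    log_line("comparison written (thresholds: %s)",
             paste(cfg$thresholds, collapse = ", "))
  }
  jsonlite::write_json(
    list(diagnostics = fit$diagnostics, converged = fit$converged,
         seed = cfg$seed,
         selection = if (!is.null(sel_test))
           list(statistic = sel_test$statistic, df = sel_test$df,
                p.value = sel_test$p.value)),
    file.path(cfg$out_dir, "diagnostics.json"),
    digits = NA, auto_unbox = TRUE, pretty = TRUE)
  log_line("done")

  invisible(list(fit = fit, dominance = dom, counts = counts,
                 selection = sel_test, truth = truth,
                 files = file.path(cfg$out_dir,
                                   c("provider_results.csv",
                                     "diagnostics.json", "run.log"))))
}
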