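#' Margin of error for a sample proportion
#'
#' Normal-approximation half-width at maximum variance (p = 0.5):
#' `z * sqrt(0.25 / n)`, multiplied by the finite-population correction
#' `sqrt((N - n) / (N - 1))` when a population size `N` is supplied. This is
#' the convention under which a 442-respondent sample is representative
#' within 5% at 95% confidence, and an 81-respondent sample within about 9%
#' at 90% confidence.
#'
#' @param n Sample size (>= 1).
#' @param confidence Confidence level in (0, 1), default 0.95.
#' @param population Optional population size `N >= n`.
#' @return Margin of error as a proportion (e.g. 0.0466 for 4.66%).
#' @examples
#' margin_of_error(442, 0.95)  # ~0.047
#' margin_of_error(81, 0.90)   # ~0.091
#' @export
margin_of_error <- function(n, confidence = 0.95, population = NULL) {
  if (any(n < 1)) wc_abort("n must be >= 1", class = "wellcount_range_error")
  if (confidence <= 0 || confidence >= 1) {
    wc_abort("confidence must lie strictly between 0 and 1",
             class = "wellcount_range_error")
  }
  z <- stats::qnorm((1 + confidence) / 2)
  moe <- z * sqrt(0.25 / n)
  if (!is.null(population)) {
    if (any(n > population)) {
      wc_abort("sample size exceeds population size",
               class = "wellcount_range_error")
    }
    moe <- moe * sqrt((population - n) / (population - 1))
  }
  moe
}

#' Run the full scoring and reporting pipeline
#'
#' Executes recode -> profiles -> summary -> driver tables -> stratified
#' reports -> optional regression, writing CSV/JSON outputs and a manifest
#' to `out_dir`. The manifest records the configuration, seed and package
#' version (no timestamp), so a rerun with the same inputs is byte-identical.
#' On error, any partially written outputs are removed.
#'
#' @param raw Path to the raw survey CSV, or a data frame.
#' @param codebook_path Path to the codebook JSON/YAML, or a `wc_codebook`.
#' @param out_dir Output directory (created if needed).
#' @param stratifiers Covariate names to stratify by (those present are
#'   used; `income_group` is derived from `income_weekly` via
#'   [regroup_income()] when available).
#' @param fit_model Whether to fit the logistic maintenance model.
#' @param hope_cutoff Highly-positive hopefulness cutoff.
#' @param seed Seed recorded in the manifest and set before any stochastic
#'   step.
#' @return Invisibly, a list with `profiles`, `summary`, `drivers`,
#'   `reports`, `model` (or `NULL`) and the output `paths`.
#' @export
run_pipeline <- function(raw, codebook_path, out_dir,
                         stratifiers = c("gender", "age_band",
                                         "income_group", "region"),
                         fit_model = TRUE, hope_cutoff = 7, seed = 1L) {
  cb <- if (inherits(codebook_path, "wc_codebook")) codebook_path else
    load_codebook(codebook_path)
  raw_tbl <- if (is.data.frame(raw)) raw else
    readr::read_csv(raw, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw_tbl) == 0) {
    wc_abort("stage recode: the raw table has no rows",
             class = "wellcount_input_error")
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    written <<- c(written, path)
    if (grepl("\\.json$", name)) {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
    } else {
      readr::write_csv(obj, path, progress = FALSE)
    }
    path
  }

  set.seed(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      wc_abort(sprintf("stage %s: %s", name, conditionMessage(e)))
    })
  }

  ind <- stage("recode", recode(raw_tbl, cb))
  profiles <- stage("index", wellbeing_profiles(ind))
  summ <- stage("summarize", summarize_wellbeing(profiles))

  covs <- ind$covariates
  if ("income_weekly" %in% names(covs)) {
    inc <- regroup_income(covs$income_weekly)
    covs$income_group <- inc$group
    covs$no_income <- inc$no_income
  }

  drivers <- list(
    deprived = stage("drivers", driver_table(profiles, "deprived")),
    maintained = if (any(profiles$maintained == 1))
      driver_table(profiles, "maintained") else NULL
  )

  reports <- list()
  for (s in intersect(stratifiers, names(covs))) {
    reports[[s]] <- stage(paste0("report:", s),
                          stratified_rates(profiles, covs, s))
  }

  model <- NULL
  if (fit_model) {
    terms <- intersect(c("income_group", "hope_pre", "age_band", "gender"),
                       names(covs))
    model_data <- cbind(maintained = profiles$maintained,
                        as.data.frame(covs))
    model <- stage("fit", fit_maintenance_model(
      model_data, "maintained", terms,
      reference = list(income_group = "LOW", gender = "Man",
                       age_band = "18-24")))
  }

  paths <- character(0)
  paths["profiles"] <- emit(as.data.frame(profiles), "profiles.csv")
  paths["summary"] <- emit(summary_as_list(summ), "summary.json")
  paths["drivers_deprived"] <- emit(drivers$deprived, "drivers_deprived.csv")
  if (!is.null(drivers$maintained)) {
    paths["drivers_maintained"] <- emit(drivers$maintained,
                                        "drivers_maintained.csv")
  }
  for (s in names(reports)) {
    paths[paste0("report_", s)] <- emit(reports[[s]],
                                        sprintf("report_%s.csv", s))
  }
  if (!is.null(model)) {
    paths["model_terms"] <- emit(model$terms, "model_terms.csv")
    paths["model"] <- emit(
      list(nagelkerke = model$nagelkerke, accuracy = model$accuracy,
           n = model$n, loglik = model$loglik,
           loglik_null = model$loglik_null, separation = model$separation),
      "model.json")
  }
  manifest <- list(
    package = "wellcount",
    version = as.character(utils::packageVersion("wellcount")),
    seed = seed,
    hope_cutoff = hope_cutoff,
    stratifiers = as.list(intersect(stratifiers, names(covs))),
    fit_model = fit_model,
    n_respondents = nrow(raw_tbl),
    domains = as.list(names(ind$domains)),
    outputs = as.list(basename(paths))
  )
  paths["manifest"] <- emit(manifest, "manifest.json")

  ok <- TRUE
  invisible(list(profiles = profiles, summary = summ, drivers = drivers,
                 reports = reports, model = model, paths = paths))
}

# internal: plain-list form of a wc_summary for JSON serialization
summary_as_list <- function(s) {
  list(
    n_total = s$n_total, n_maintained = s$n_maintained,
    n_deprived = s$n_deprived,
    headcount_deprived = s$headcount_deprived,
    intensity_domains = if (is.na(s$intensity_domains)) NULL else
      s$intensity_domains,
    intensity_share = if (is.na(s$intensity_share)) NULL else
      s$intensity_share,
    adjusted_headcount = s$adjusted_headcount,
    censored_domain_deprivation = as.list(s$censored_domain_deprivation),
    uncensored_domain_deprivation = as.list(s$uncensored_domain_deprivation),
    D = s$D, k = s$k
  )
}
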