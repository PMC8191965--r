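#' Construct a variable recode rule
#'
#' A rule maps one raw survey column to a binary sufficiency indicator.
#' Four rule kinds are supported:
#' \describe{
#'   \item{category_set}{achievement iff the raw answer is in `achieving`.
#'     If `levels` is supplied, any non-missing answer outside `levels`
#'     is an error (strict vocabulary check).}
#'   \item{threshold_ge}{achievement iff the (numeric/ordinal) answer is
#'     greater than or equal to `cutoff`.}
#'   \item{threshold_le}{achievement iff the answer is less than or equal
#'     to `cutoff`.}
#'   \item{binary_passthrough}{the raw answer is already a 0/1 indicator.}
#' }
#'
#' Raw values matching `missing_codes` (or `NA`) are handled by
#' `missing_policy`: `"as_zero"` scores them as non-achievement so every
#' respondent is classified (the default, required for counting arithmetic
#' in which group sizes add up to the full sample); `"as_missing"`
#' propagates `NA` for sensitivity analysis.
#'
#' @param column Name of the raw column.
#' @param rule Rule kind, one of `"category_set"`, `"threshold_ge"`,
#'   `"threshold_le"`, `"binary_passthrough"`.
#' @param achieving Character vector of achieving categories (category_set).
#' @param cutoff Numeric cutoff (threshold rules).
#' @param levels Optional full category vocabulary (category_set).
#' @param missing_codes Raw values treated as missing.
#' @param missing_policy `"as_zero"` or `"as_missing"`.
#' @return A `wc_rule` list.
#' @export
variable_rule <- function(column,
                          rule = c("category_set", "threshold_ge",
                                   "threshold_le", "binary_passthrough"),
                          achieving = NULL, cutoff = NULL, levels = NULL,
                          missing_codes = character(),
                          missing_policy = c("as_zero", "as_missing")) {
  rule <- match.arg(rule)
  missing_policy <- match.arg(missing_policy)
  if (!is.character(column) || length(column) != 1L || !nzchar(column)) {
    wc_abort("`column` must be a single non-empty string",
             class = "wellcount_schema_error")
  }
  if (rule == "category_set" && (is.null(achieving) || length(achieving) == 0)) {
    wc_abort(sprintf("rule for column '%s': category_set requires `achieving`", column),
             class = "wellcount_schema_error")
  }
  if (rule %in% c("threshold_ge", "threshold_le") &&
      (is.null(cutoff) || !is.numeric(cutoff) || length(cutoff) != 1L)) {
    wc_abort(sprintf("rule for column '%s': threshold rules require a single numeric `cutoff`", column),
             class = "wellcount_schema_error")
  }
  structure(
    list(column = column, rule = rule,
         achieving = achieving, cutoff = cutoff, levels = levels,
         missing_codes = as.character(missing_codes),
         missing_policy = missing_policy),
    class = "wc_rule"
  )
}

#' Construct a domain specification
#'
#' @param name Domain name (unique within a codebook).
#' @param variables List of [variable_rule()] objects.
#' @param weight Positive domain weight; all-equal weights (the default)
#'   reproduce the unweighted counting rule.
#' @return A `wc_domain` list.
#' @export
domain_spec <- function(name, variables, weight = 1) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    wc_abort("domain `name` must be a single non-empty string",
             class = "wellcount_schema_error")
  }
  if (length(variables) < 1L) {
    wc_abort(sprintf("domain '%s' must contain at least one variable", name),
             class = "wellcount_schema_error")
  }
  if (!all(vapply(variables, inherits, logical(1), "wc_rule"))) {
    wc_abort(sprintf("domain '%s': all variables must be variable_rule objects", name),
             class = "wellcount_schema_error")
  }
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0) {
    wc_abort(sprintf("domain '%s': weight must be a positive number", name),
             class = "wellcount_schema_error")
  }
  structure(list(name = name, variables = variables, weight = weight),
            class = "wc_domain")
}

#' Construct a covariate specification
#'
#' @param name Covariate (raw column) name.
#' @param type `"categorical"`, `"ordinal"` or `"numeric"`.
#' @param levels Category labels (categorical/ordinal); order is kept.
#' @param missing_codes Raw values mapped to `NA`.
#' @return A `wc_covariate` list.
#' @export
covariate_spec <- function(name, type = c("categorical", "ordinal", "numeric"),
                           levels = NULL, missing_codes = character()) {
  type <- match.arg(type)
  if (type == "categorical" && is.null(levels)) {
    wc_abort(sprintf("covariate '%s': categorical covariates need `levels`", name),
             class = "wellcount_schema_error")
  }
  structure(list(name = name, type = type, levels = levels,
                 missing_codes = as.character(missing_codes)),
            class = "wc_covariate")
}

#' Construct and validate a codebook
#'
#' A codebook is the declarative mapping from raw survey columns to binary
#' sufficiency indicators grouped into domains, plus the demographic
#' covariates carried alongside. Invariants enforced: domain names unique,
#' each raw column assigned to exactly one domain, every domain non-empty,
#' weights positive.
#'
#' @param domains List of [domain_spec()] objects (order preserved).
#' @param covariates List of [covariate_spec()] objects.
#' @return A `wc_codebook` object.
#' @export
codebook <- function(domains, covariates = list()) {
  if (length(domains) < 1L) {
    wc_abort("a codebook needs at least one domain",
             class = "wellcount_schema_error")
  }
  if (!all(vapply(domains, inherits, logical(1), "wc_domain"))) {
    wc_abort("`domains` must be a list of domain_spec objects",
             class = "wellcount_schema_error")
  }
  dnames <- vapply(domains, `[[`, character(1), "name")
  if (anyDuplicated(dnames)) {
    wc_abort(sprintf("duplicate domain name: '%s'", dnames[duplicated(dnames)][1]),
             class = "wellcount_schema_error")
  }
  cols <- unlist(lapply(domains, function(d) {
    vapply(d$variables, `[[`, character(1), "column")
  }))
  if (anyDuplicated(cols)) {
    wc_abort(sprintf("column '%s' is assigned to more than one domain/variable",
                     cols[duplicated(cols)][1]),
             class = "wellcount_schema_error")
  }
  structure(
    list(domains = stats::setNames(domains, dnames), covariates = covariates),
    class = "wc_codebook"
  )
}

#' @export
print.wc_codebook <- function(x, ...) {
  m <- codebook_m(x)
  cat("<wc_codebook>", length(x$domains), "domains,",
      sum(m), "variables,", length(x$covariates), "covariates\n")
  for (d in names(m)) {
    cat(sprintf("  %-38s m = %d, threshold = %d, weight = %g\n",
                d, m[[d]], domain_threshold(m[[d]]), x$domains[[d]]$weight))
  }
  invisible(x)
}

#' Per-domain variable counts
#'
#' @param cb A `wc_codebook`.
#' @return Named integer vector of variable counts per domain (m_d).
#' @export
codebook_m <- function(cb) {
  vapply(cb$domains, function(d) length(d$variables), integer(1))
}

#' Read a codebook from JSON or YAML
#'
#' The on-disk schema has top-level keys `domains` and `covariates`. Each
#' domain has `name`, optional `weight`, and a list of `variables`; each
#' variable has `column`, `rule`, and the rule's parameters (`achieving`,
#' `cutoff`, `levels`, `missing_codes`, `missing_policy`). A shipped example
#' is at `system.file("extdata", "sa2020_codebook.json", package = "wellcount")`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated `wc_codebook`; domain order is preserved as listed.
#' @export
load_codebook <- function(path) {
  if (!file.exists(path)) {
    wc_abort(sprintf("codebook file not found: %s", path))
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  codebook_from_list(raw)
}

# internal: build a codebook from the parsed JSON/YAML list
codebook_from_list <- function(raw) {
  if (is.null(raw$domains)) {
    wc_abort("codebook must have a top-level `domains` key",
             class = "wellcount_schema_error")
  }
  known_rules <- c("category_set", "threshold_ge", "threshold_le",
                   "binary_passthrough")
  domains <- lapply(raw$domains, function(d) {
    vars <- lapply(d$variables, function(v) {
      if (is.null(v$rule) || !(v$rule %in% known_rules)) {
        wc_abort(sprintf("unknown rule_kind '%s' for column '%s'",
                         v$rule %||% "<missing>", v$column %||% "<missing>"),
                 class = "wellcount_schema_error")
      }
      variable_rule(
        column = v$column,
        rule = v$rule,
        achieving = unlist(v$achieving),
        cutoff = v$cutoff,
        levels = unlist(v$levels),
        missing_codes = unlist(v$missing_codes) %||% character(),
        missing_policy = v$missing_policy %||% "as_zero"
      )
    })
    domain_spec(name = d$name, variables = vars, weight = d$weight %||% 1)
  })
  covs <- lapply(raw$covariates %||% list(), function(cv) {
    covariate_spec(name = cv$name, type = cv$type %||% "categorical",
                   levels = unlist(cv$levels),
                   missing_codes = unlist(cv$missing_codes) %||% character())
  })
  codebook(domains, covs)
}

#' Write a codebook to JSON
#'
#' @param cb A `wc_codebook`.
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path) {
  as_plain <- list(
    domains = lapply(unname(cb$domains), function(d) {
      list(name = d$name, weight = d$weight,
           variables = lapply(d$variables, function(v) {
             out <- list(column = v$column, rule = v$rule)
             if (!is.null(v$achieving)) out$achieving <- as.list(v$achieving)
             if (!is.null(v$cutoff)) out$cutoff <- v$cutoff
             if (!is.null(v$levels)) out$levels <- as.list(v$levels)
             if (length(v$missing_codes)) out$missing_codes <- as.list(v$missing_codes)
             out$missing_policy <- v$missing_policy
             out
           }))
    }),
    covariates = lapply(cb$covariates, function(cv) {
      out <- list(name = cv$name, type = cv$type)
      if (!is.null(cv$levels)) out$levels <- as.list(cv$levels)
      if (length(cv$missing_codes)) out$missing_codes <- as.list(cv$missing_codes)
      out
    })
  )
  jsonlite::write_json(as_plain, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Default six-domain codebook (SA2020 reconstruction)
#'
#' A reconstruction of the six-domain, 56-question instrument used in the
#' 2020 South Australia wellbeing survey. Only the Ecology domain's variable
#' count (9) is published; the remaining counts are a documented
#' reconstruction from the questionnaire's structure and are labelled
#' synthetic: Psychological 9, Physical 8, Living standard 8, Community 8,
#' Governance 7, Ecology 9 (49 domain questions), plus 7 demographic and
#' hopefulness items. Domain questions are yes/no with "Yes" as achievement.
#'
#' @param missing_policy Missing-answer policy applied to every domain
#'   variable (`"as_zero"` default; see [variable_rule()]).
#' @return A `wc_codebook`.
#' @export
sa2020_codebook <- function(missing_policy = "as_zero") {
  mk_domain <- function(name, code, m) {
    domain_spec(name, lapply(seq_len(m), function(j) {
      variable_rule(sprintf("%s_q%d", code, j), "category_set",
                    achieving = "Yes", levels = c("Yes", "No"),
                    missing_codes = c("", "Prefer not to say"),
                    missing_policy = missing_policy)
    }))
  }
  domains <- list(
    mk_domain("Psychological and Emotional Health", "psych",      9),
    mk_domain("Physical Health",                    "physical",   8),
    mk_domain("Standard of Living",                 "living",     8),
    mk_domain("Family and Community Vitality",      "community",  8),
    mk_domain("Governance",                         "governance", 7),
    mk_domain("Ecological Diversity and Resilience","ecology",    9)
  )
  covariates <- list(
    covariate_spec("gender", "categorical",
                   levels = c("Man", "Woman", "Other/Not disclosed"),
                   missing_codes = ""),
    covariate_spec("age_band", "categorical",
                   levels = c("18-24", "25-34", "35-49", "50-64", "65+"),
                   missing_codes = ""),
    covariate_spec("region", "categorical",
                   levels = c("Greater Adelaide", "Regional South Australia"),
                   missing_codes = ""),
    covariate_spec("income_weekly", "numeric",
                   missing_codes = c("", "Prefer not to say")),
    covariate_spec("hope_pre", "ordinal", levels = as.character(1:8),
                   missing_codes = ""),
    covariate_spec("hope_during", "ordinal", levels = as.character(1:8),
                   missing_codes = "")
  )
  codebook(domains, covariates)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
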