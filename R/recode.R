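#' Recode a raw survey table into binary sufficiency indicators
#'
#' Applies every [variable_rule()] in the codebook to the raw table, producing
#' the respondents-by-variables achievement matrix (entries 0/1, or `NA`
#' under `missing_policy = "as_missing"`) grouped by domain, together with
#' the covariate table typed and aligned by respondent. No rows are dropped:
#' the indicator matrix always has one row per raw-table row.
#'
#' @param raw_table Data frame of raw answers, one row per respondent.
#'   A `respondent_id` column is used if present, otherwise row numbers.
#' @param cb A `wc_codebook`.
#' @return A `wc_indicators` object: list with `indicators` (tibble of 0/1
#'   columns), `domains` (named list mapping domain name to its columns),
#'   `m` (named variable counts), `covariates` (tibble), `respondent_id`.
#' @examples
#' cb <- codebook(list(domain_spec("D", list(
#'   variable_rule("q1", "category_set", achieving = "Yes")))))
#' recode(data.frame(q1 = c("Yes", "No")), cb)$indicators
#' @export
recode <- function(raw_table, cb) {
  stopifnot(inherits(cb, "wc_codebook"))
  raw_table <- as.data.frame(raw_table)
  all_cols <- unlist(lapply(cb$domains, function(d)
    vapply(d$variables, `[[`, character(1), "column")))
  missing_cols <- setdiff(all_cols, names(raw_table))
  if (length(missing_cols)) {
    wc_abort(sprintf("raw table is missing codebook column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             class = "wellcount_input_error")
  }

  ind_cols <- list()
  domains <- list()
  for (d in cb$domains) {
    cols <- character(0)
    for (v in d$variables) {
      ind_cols[[v$column]] <- apply_rule(raw_table[[v$column]], v)
      cols <- c(cols, v$column)
    }
    domains[[d$name]] <- cols
  }

  covs <- recode_covariates(raw_table, cb$covariates)

  rid <- if ("respondent_id" %in% names(raw_table)) {
    raw_table$respondent_id
  } else {
    seq_len(nrow(raw_table))
  }

  structure(
    list(indicators = tibble::as_tibble(ind_cols),
         domains = domains,
         m = codebook_m(cb),
         weights = vapply(cb$domains, `[[`, numeric(1), "weight"),
         covariates = covs,
         respondent_id = rid),
    class = "wc_indicators"
  )
}

#' @export
print.wc_indicators <- function(x, ...) {
  cat("<wc_indicators>", nrow(x$indicators), "respondents,",
      ncol(x$indicators), "variables in", length(x$domains), "domains\n")
  invisible(x)
}

# internal: apply one variable rule to a raw column -> integer 0/1/NA
apply_rule <- function(x, rule) {
  x_chr <- as.character(x)
  is_miss <- is.na(x) | x_chr %in% rule$missing_codes

  out <- switch(
    rule$rule,
    category_set = {
      if (!is.null(rule$levels)) {
        bad <- !is_miss & !(x_chr %in% rule$levels)
        if (any(bad)) {
          wc_abort(sprintf(
            "column '%s': raw category '%s' at row %d is outside the declared label set",
            rule$column, x_chr[which(bad)[1]], which(bad)[1]),
            class = "wellcount_input_error")
        }
      }
      as.integer(x_chr %in% rule$achieving)
    },
    threshold_ge = ,
    threshold_le = {
      xn <- suppressWarnings(as.numeric(x_chr))
      bad <- !is_miss & is.na(xn)
      if (any(bad)) {
        wc_abort(sprintf(
          "column '%s': non-numeric value '%s' at row %d under a threshold rule",
          rule$column, x_chr[which(bad)[1]], which(bad)[1]),
          class = "wellcount_input_error")
      }
      if (rule$rule == "threshold_ge") as.integer(xn >= rule$cutoff)
      else as.integer(xn <= rule$cutoff)
    },
    binary_passthrough = {
      xn <- suppressWarnings(as.numeric(x_chr))
      bad <- !is_miss & !(xn %in% c(0, 1))
      if (any(bad)) {
        wc_abort(sprintf(
          "column '%s': value '%s' at row %d is not a 0/1 indicator",
          rule$column, x_chr[which(bad)[1]], which(bad)[1]),
          class = "wellcount_input_error")
      }
      as.integer(xn)
    }
  )

  out[is_miss] <- if (rule$missing_policy == "as_zero") 0L else NA_integer_
  out
}

# internal: type and clean the covariate table
recode_covariates <- function(raw_table, cov_specs) {
  out <- list()
  for (cv in cov_specs) {
    if (!cv$name %in% names(raw_table)) next
    x <- raw_table[[cv$name]]
    x_chr <- as.character(x)
    x_chr[is.na(x) | x_chr %in% cv$missing_codes] <- NA
    out[[cv$name]] <- switch(
      cv$type,
      categorical = {
        bad <- !is.na(x_chr) & !(x_chr %in% cv$levels)
        if (any(bad)) {
          wc_abort(sprintf(
            "covariate '%s': value '%s' at row %d is outside the declared label set",
            cv$name, x_chr[which(bad)[1]], which(bad)[1]),
            class = "wellcount_input_error")
        }
        factor(x_chr, levels = cv$levels)
      },
      ordinal = {
        if (!is.null(cv$levels)) {
          bad <- !is.na(x_chr) & !(x_chr %in% cv$levels)
          if (any(bad)) {
            wc_abort(sprintf(
              "covariate '%s': value '%s' at row %d is outside the declared label set",
              cv$name, x_chr[which(bad)[1]], which(bad)[1]),
              class = "wellcount_input_error")
          }
          # numeric level labels (e.g. a 1-8 scale) come back as integers
          if (!anyNA(suppressWarnings(as.numeric(cv$levels)))) {
            as.integer(x_chr)
          } else {
            factor(x_chr, levels = cv$levels, ordered = TRUE)
          }
        } else {
          as.integer(x_chr)
        }
      },
      numeric = suppressWarnings(as.numeric(x_chr))
    )
  }
  tibble::as_tibble(out)
}

#' Recode a 1-8 hopefulness rating to a "highly positive" indicator
#'
#' Respondents rate positivity/hopefulness about life on a 1-8 scale
#' (1 = not positive/hopeful, 8 = very positive/hopeful). The indicator is 1
#' iff the rating is at or above `cutoff`. The scale never states which
#' points count as "highly positive"; the default cutoff of 7 takes the top
#' quarter of the scale and is configurable.
#'
#' @param value Integer vector of ratings in 1..8 (`NA` allowed).
#' @param cutoff Scale point at or above which the rating counts as highly
#'   positive (default 7).
#' @return Integer 0/1 vector (`NA` preserved).
#' @examples
#' recode_hopefulness(c(8, 7, 6, 1))  # 1 1 0 0
#' @export
recode_hopefulness <- function(value, cutoff = 7) {
  bad <- !is.na(value) & (value < 1 | value > 8 | value != as.integer(value))
  if (any(bad)) {
    wc_abort(sprintf("hopefulness value %s is outside the 1-8 scale",
                     value[which(bad)[1]]),
             class = "wellcount_range_error")
  }
  as.integer(value >= cutoff)
}

#' Regroup weekly income into low/high categories at $600
#'
#' Splits weekly income at the "$600 or less" boundary (inclusive), the
#' point that divides the survey sample into two nearly equal groups.
#' Respondents reporting no income are placed in the low group but flagged
#' separately, since that group (largely older, pension-supported
#' respondents) behaves differently from other low-income respondents.
#'
#' @param amount Weekly income: numeric, or character including declared
#'   no-income codes.
#' @param no_income_codes Raw values treated as "no income" (matched
#'   case-insensitively); a numeric 0 is also treated as no income.
#' @param missing_codes Raw values mapped to `NA`.
#' @return Tibble with columns `group` (factor `LOW`/`HIGH`) and
#'   `no_income` (logical).
#' @examples
#' regroup_income(c(600, 601, 0))
#' @export
regroup_income <- function(amount,
                           no_income_codes = c("no income", "nil"),
                           missing_codes = c("", "Prefer not to say")) {
  x_chr <- trimws(as.character(amount))
  is_miss <- is.na(amount) | x_chr %in% missing_codes
  is_noinc <- !is_miss & tolower(x_chr) %in% tolower(no_income_codes)
  xn <- suppressWarnings(as.numeric(x_chr))
  if (any(!is_miss & !is_noinc & is.na(xn))) {
    i <- which(!is_miss & !is_noinc & is.na(xn))[1]
    wc_abort(sprintf("income value '%s' at row %d is not numeric nor a declared code",
                     x_chr[i], i),
             class = "wellcount_input_error")
  }
  if (any(!is.na(xn) & xn < 0)) {
    wc_abort("negative income amount", class = "wellcount_range_error")
  }
  is_noinc <- is_noinc | (!is_miss & !is.na(xn) & xn == 0)
  group <- ifelse(is_miss, NA_character_,
                  ifelse(is_noinc | xn <= 600, "LOW", "HIGH"))
  tibble::tibble(
    group = factor(group, levels = c("LOW", "HIGH")),
    no_income = ifelse(is_miss, NA, is_noinc)
  )
}
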