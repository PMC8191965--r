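#' Classification rates stratified by a covariate
#'
#' Decomposes the maintained/deprived classification by a grouping covariate
#' (gender, age band, income group, region, ...). For each group it reports
#' the group size and the maintained/deprived percentage overall and per
#' domain. Respondents with a missing stratifier are excluded from the
#' denominator unless `na_label` names a group for them (as survey reports
#' sometimes carry an "Other/Unknown" column).
#'
#' @param profiles A `wc_profiles` tibble.
#' @param covariates Data frame of covariates, row-aligned with `profiles`.
#' @param stratifier Name of the covariate to stratify by.
#' @param na_label Optional label under which missing-stratifier respondents
#'   are reported as their own group; default `NULL` excludes them.
#' @return A tidy tibble (class `wc_subgroup_report`), one row per group and
#'   measure (`"overall"` first, then each domain) with columns `stratifier`,
#'   `group`, `n`, `measure`, `maintained_pct`, `deprived_pct`.
#' @export
stratified_rates <- function(profiles, covariates, stratifier,
                             na_label = NULL) {
  if (!stratifier %in% names(covariates)) {
    wc_abort(sprintf("unknown stratifier '%s'", stratifier))
  }
  if (nrow(covariates) != nrow(profiles)) {
    wc_abort("covariate table and profiles have different row counts",
             class = "wellcount_input_error")
  }
  g <- as.character(covariates[[stratifier]])
  if (!is.null(na_label)) g[is.na(g)] <- na_label
  keep <- !is.na(g)
  if (!any(keep)) {
    wc_abort(sprintf("stratifier '%s' has no non-missing groups", stratifier))
  }
  g <- g[keep]
  maintained <- profiles$maintained[keep]
  Z <- domain_sufficiency(profiles)[keep, , drop = FALSE]
  dnames <- attr(profiles, "domains")

  rows <- lapply(unique(g), function(grp) {
    sel <- g == grp
    n <- sum(sel)
    overall <- tibble::tibble(
      stratifier = stratifier, group = grp, n = n, measure = "overall",
      maintained_pct = 100 * mean(maintained[sel]),
      deprived_pct = 100 * mean(1 - maintained[sel]))
    per_dom <- tibble::tibble(
      stratifier = stratifier, group = grp, n = n, measure = dnames,
      maintained_pct = unname(100 * colMeans(Z[sel, , drop = FALSE])),
      deprived_pct = unname(100 * colMeans(1 - Z[sel, , drop = FALSE])))
    dplyr::bind_rows(overall, per_dom)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("wc_subgroup_report", class(out))
  out
}

#' Gap statistic between two group rates
#'
#' The point differential `a - b` in percentage points and the percent
#' difference `100 (a - b) / a` relative to the first group. In gender-gap
#' reporting the first group is the female rate, so a positive differential
#' indicates greater vulnerability of women; e.g. rates (98, 86) give a
#' 12-point gap and a 12.2 percent difference. The denominator convention
#' (first-listed group) matters: "percent difference" is ambiguous in
#' general, and the relative gap is not symmetric in its arguments.
#'
#' @param rate_a First group's rate, in percent (the denominator group).
#' @param rate_b Second group's rate, in percent.
#' @return Tibble with `rate_a`, `rate_b`, `point_differential`,
#'   `percent_difference` (`NA` when `rate_a` is 0).
#' @examples
#' gap_statistic(98, 86)
#' @export
gap_statistic <- function(rate_a, rate_b) {
  if (any(c(rate_a, rate_b) < 0 | c(rate_a, rate_b) > 100)) {
    wc_abort("rates must lie in [0, 100]", class = "wellcount_range_error")
  }
  pointd <- rate_a - rate_b
  pctd <- ifelse(rate_a == 0, NA_real_, 100 * pointd / rate_a)
  tibble::tibble(rate_a = rate_a, rate_b = rate_b,
                 point_differential = pointd,
                 percent_difference = pctd)
}

#' Multiple-response condition table
#'
#' Share of a group answering yes to each of several binary conditions.
#' Each respondent can satisfy several conditions, so no normalization is
#' applied across conditions and the percentages can total more than 100.
#'
#' @param conditions Data frame (or named list) of 0/1 condition columns.
#' @param mask Logical vector selecting the group (default: everyone).
#' @return Tibble with `condition` and `pct_yes`, in column order.
#' @examples
#' multiple_response_table(data.frame(a = c(1, 1, 1, 1), b = c(1, 0, 0, 0)))
#' @export
multiple_response_table <- function(conditions, mask = TRUE) {
  conditions <- tibble::as_tibble(conditions)
  mask <- rep_len(mask, nrow(conditions))
  if (!any(mask)) {
    wc_abort("the selected group is empty")
  }
  sub <- conditions[mask, , drop = FALSE]
  for (nm in names(sub)) check_binary(sub[[nm]], sprintf("condition '%s'", nm))
  tibble::tibble(condition = names(sub),
                 pct_yes = 100 * vapply(sub, mean, numeric(1), USE.NAMES = FALSE))
}

#' Change in the highly-positive hopefulness share between two waves
#'
#' Applies the same "highly positive" cutoff (see [recode_hopefulness()]) to
#' paired pre- and during-period 1-8 ratings and reports both shares and the
#' percentage-point fall.
#'
#' @param pre,during Paired integer ratings in 1..8, one entry per
#'   respondent in each wave.
#' @param cutoff Highly-positive cutoff, applied to both waves (default 7).
#' @return List with `share_pre`, `share_during` (percent) and
#'   `change_points` (`share_pre - share_during`, in percentage points).
#' @examples
#' hopefulness_shift(c(8, 8, 7, 2), c(8, 2, 2, 2))
#' @export
hopefulness_shift <- function(pre, during, cutoff = 7) {
  if (length(pre) != length(during)) {
    wc_abort("`pre` and `during` must be paired (same length)",
             class = "wellcount_input_error")
  }
  ok <- !is.na(pre) & !is.na(during)
  if (!any(ok)) wc_abort("no complete pre/during pairs")
  hp <- recode_hopefulness(pre[ok], cutoff)
  hd <- recode_hopefulness(during[ok], cutoff)
  share_pre <- 100 * mean(hp)
  share_during <- 100 * mean(hd)
  list(share_pre = share_pre, share_during = share_during,
       change_points = share_pre - share_during, n = sum(ok))
}
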