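#' Two-thirds sufficiency threshold
#'
#' The within-domain (and cross-domain) cutoff of the dual-cutoff counting
#' rule: the smallest integer t with t >= (2/3) m, i.e. `ceiling(2m/3)`.
#' With 9 variables the threshold is 6; with 6 domains the overall cutoff
#' is 4. The "strictly more than two-thirds" convention is deliberately not
#' used: it would give 7 for m = 9, contradicting the published rule that a
#' minimum score of 6 out of 9 achieves sufficiency.
#'
#' @param m Positive integer: number of variables (or domains).
#' @return Integer threshold(s).
#' @examples
#' domain_threshold(9)  # 6
#' domain_threshold(6)  # 4
#' @export
domain_threshold <- function(m) {
  if (any(is.na(m)) || any(m < 1) || any(m != as.integer(m))) {
    wc_abort("`m` must be a positive integer count",
             class = "wellcount_range_error")
  }
  as.integer(ceiling(2 * m / 3))
}

#' Score one domain for one respondent
#'
#' @param indicators Binary 0/1 vector, one entry per variable in the domain.
#' @return List with `raw` (achieved count) and `sufficiency` (1 iff
#'   `raw >= domain_threshold(length(indicators))`).
#' @examples
#' score_domain(c(1, 1, 1, 1, 1, 0, 0, 0, 0))  # raw 5, sufficiency 0
#' @export
score_domain <- function(indicators) {
  check_binary(indicators, "domain indicator")
  raw <- as.integer(sum(indicators))
  list(raw = raw,
       sufficiency = as.integer(raw >= domain_threshold(length(indicators))))
}

#' Classify overall wellbeing from domain sufficiency
#'
#' The second (cross-domain) cutoff: a respondent maintained overall
#' wellbeing iff they achieved sufficiency in at least `k` of the `D`
#' domains (default `k = ceiling(2D/3)`, the two-thirds rule, i.e. 4 of 6).
#'
#' @param domain_sufficiency Binary 0/1 vector of length D.
#' @param k Overall counting cutoff, `1 <= k <= D`.
#' @return List with `W` (composite wellbeing index, the count of sufficient
#'   domains), `maintained` (0/1), `c` (deprivation count, `D - W`).
#' @examples
#' classify_overall(c(1, 1, 1, 1, 0, 0))  # W 4, maintained 1, c 2
#' @export
classify_overall <- function(domain_sufficiency,
                             k = domain_threshold(length(domain_sufficiency))) {
  check_binary(domain_sufficiency, "domain sufficiency")
  D <- length(domain_sufficiency)
  if (k < 1 || k > D) {
    wc_abort(sprintf("overall cutoff k = %s out of range 1..%d", k, D),
             class = "wellcount_range_error")
  }
  W <- as.integer(sum(domain_sufficiency))
  list(W = W, maintained = as.integer(W >= k), c = as.integer(D - W))
}

#' Build per-respondent wellbeing profiles
#'
#' Applies [score_domain()] and [classify_overall()] across a recoded
#' indicator set, yielding one row per respondent with per-domain raw
#' scores (`score_*`), sufficiency indicators (`suff_*`), the composite
#' wellbeing index `W`, the `maintained` classification and the deprivation
#' count `c`. `NA` indicators (possible under `missing_policy =
#' "as_missing"`) are scored as non-achievement.
#'
#' Per-domain weights generalize the count: `W = sum(w_d z_d)` and the
#' cutoff `k` is then on the weight scale. With all weights equal to 1 and
#' `k = ceiling(2D/3)` this reduces to the plain counting rule.
#'
#' @param ind A `wc_indicators` object from [recode()].
#' @param k Overall cutoff; default `ceiling(2D/3)` when weights are all 1
#'   (must be given explicitly for unequal weights).
#' @param weights Optional named per-domain weights (default: codebook's,
#'   normally all 1).
#' @return A `wc_profiles` tibble with attributes `domains`, `k`, `weights`.
#' @export
wellbeing_profiles <- function(ind, k = NULL, weights = NULL) {
  stopifnot(inherits(ind, "wc_indicators"))
  dnames <- names(ind$domains)
  D <- length(dnames)
  w <- weights %||% ind$weights
  if (is.null(names(w))) names(w) <- dnames
  if (is.null(k)) {
    if (!all(w == w[[1]])) {
      wc_abort("an explicit `k` is required with unequal domain weights")
    }
    k <- domain_threshold(D) * w[[1]]
  }

  X <- as.matrix(ind$indicators)
  scores <- matrix(0L, nrow(X), D, dimnames = list(NULL, dnames))
  suff <- matrix(0L, nrow(X), D, dimnames = list(NULL, dnames))
  for (d in dnames) {
    cols <- ind$domains[[d]]
    s <- rowSums(X[, cols, drop = FALSE], na.rm = TRUE)
    scores[, d] <- as.integer(s)
    suff[, d] <- as.integer(s >= domain_threshold(length(cols)))
  }
  W <- as.vector(suff %*% w[dnames])
  out <- tibble::tibble(respondent_id = ind$respondent_id)
  for (d in dnames) out[[paste0("score_", d)]] <- scores[, d]
  for (d in dnames) out[[paste0("suff_", d)]] <- suff[, d]
  out$wellbeing_index <- W
  out$maintained <- as.integer(W >= k)
  out$deprivation_count <- sum(w) - W
  new_profiles(out, domains = dnames, k = k, weights = w[dnames])
}

# internal: tag a profiles tibble with its counting metadata
new_profiles <- function(df, domains, k, weights) {
  structure(df, domains = domains, k = k, weights = weights,
            class = c("wc_profiles", class(df)))
}

#' Extract the respondents-by-domains sufficiency matrix
#'
#' @param profiles A `wc_profiles` tibble.
#' @return Integer matrix, one column per domain, entries 0/1.
#' @export
domain_sufficiency <- function(profiles) {
  dnames <- attr(profiles, "domains")
  m <- as.matrix(as.data.frame(profiles)[paste0("suff_", dnames)])
  colnames(m) <- dnames
  storage.mode(m) <- "integer"
  m
}

#' Population-level counting indices
#'
#' Aggregates wellbeing profiles into the Alkire-Foster summary measures:
#' \describe{
#'   \item{H}{deprivation headcount ratio, the share classified as not able
#'     to maintain overall wellbeing.}
#'   \item{A_raw}{intensity in domain units: mean deprivation count among
#'     the deprived (absent when nobody is deprived).}
#'   \item{A}{intensity as a share, `A_raw / D`.}
#'   \item{M0}{adjusted headcount, `H * A`.}
#' }
#' plus censored (among the deprived) and uncensored (among everyone)
#' per-domain deprivation shares.
#'
#' Under the k-of-D identification rule every deprived respondent misses at
#' least `D - k + 1` domains, so `A_raw >= D - k + 1` (for k = 4 of D = 6:
#' at least 3).
#'
#' @param profiles A `wc_profiles` tibble (nonempty).
#' @return A `wc_summary` list.
#' @examples
#' summarize_wellbeing(sa2020_fixture())
#' @export
summarize_wellbeing <- function(profiles) {
  if (nrow(profiles) == 0) {
    wc_abort("cannot summarize an empty profile set")
  }
  dnames <- attr(profiles, "domains")
  D <- length(dnames)
  n <- nrow(profiles)
  deprived <- profiles$maintained == 0L
  n_dep <- sum(deprived)
  H <- n_dep / n
  A_raw <- if (n_dep > 0) mean(profiles$deprivation_count[deprived]) else NA_real_
  A <- A_raw / D
  M0 <- if (n_dep > 0) H * A else 0
  Z <- domain_sufficiency(profiles)
  censored <- if (n_dep > 0) colMeans(1 - Z[deprived, , drop = FALSE]) else
    stats::setNames(rep(NA_real_, D), dnames)
  uncensored <- colMeans(1 - Z)
  structure(
    list(n_total = n, n_maintained = n - n_dep, n_deprived = n_dep,
         headcount_deprived = H,
         intensity_domains = A_raw, intensity_share = A,
         adjusted_headcount = M0,
         censored_domain_deprivation = censored,
         uncensored_domain_deprivation = uncensored,
         D = D, k = attr(profiles, "k")),
    class = "wc_summary"
  )
}

#' @export
print.wc_summary <- function(x, ...) {
  cat("<wc_summary> n =", x$n_total, "\n")
  cat(sprintf("  maintained: %d (%.1f%%)   deprived: %d (%.1f%%)\n",
              x$n_maintained, 100 * (1 - x$headcount_deprived),
              x$n_deprived, 100 * x$headcount_deprived))
  if (!is.na(x$intensity_domains)) {
    cat(sprintf("  intensity A: %.1f of %d domains (share %.3f)   M0 = %.3f\n",
                x$intensity_domains, x$D, x$intensity_share,
                x$adjusted_headcount))
  }
  invisible(x)
}

#' Per-domain drivers of deprivation within a group
#'
#' For the deprived (or maintained) group, the percentage unable to maintain
#' wellbeing in each domain, sorted in descending order of expressed
#' dissatisfaction. These are multiple-response percentages: each respondent
#' can be deprived in several domains, so the column totals more than 100.
#'
#' @param profiles A `wc_profiles` tibble.
#' @param group `"deprived"` (default) or `"maintained"`.
#' @return Tibble with columns `domain`, `n`, `pct_deprived`, sorted
#'   descending by `pct_deprived`.
#' @export
driver_table <- function(profiles, group = c("deprived", "maintained")) {
  group <- match.arg(group)
  keep <- if (group == "deprived") profiles$maintained == 0L else
    profiles$maintained == 1L
  if (!any(keep)) {
    wc_abort(sprintf("the %s group is empty", group))
  }
  Z <- domain_sufficiency(profiles)[keep, , drop = FALSE]
  shares <- 100 * colMeans(1 - Z)
  tibble::tibble(domain = names(shares), n = sum(keep),
                 pct_deprived = unname(shares)) |>
    dplyr::arrange(dplyr::desc(.data$pct_deprived))
}
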