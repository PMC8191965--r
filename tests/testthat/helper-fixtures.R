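# Shared in-code fixtures for the test suite.

# a minimal two-variable, one-domain codebook over "Yes"/"No" answers
tiny_codebook <- function(missing_policy = "as_zero") {
  codebook(list(
    domain_spec("D1", list(
      variable_rule("q1", "category_set", achieving = "Yes",
                    levels = c("Yes", "No"), missing_codes = "",
                    missing_policy = missing_policy),
      variable_rule("q2", "category_set", achieving = "Yes",
                    levels = c("Yes", "No"), missing_codes = "",
                    missing_policy = missing_policy)
    ))
  ))
}

# random small indicator set: n respondents, D domains of m_d variables each
random_indicators <- function(n, m_per_domain, p = 0.5) {
  dnames <- paste0("dom", seq_along(m_per_domain))
  cols <- list()
  domains <- list()
  for (d in seq_along(m_per_domain)) {
    nm <- sprintf("%s_v%d", dnames[d], seq_len(m_per_domain[d]))
    for (j in seq_along(nm)) cols[[nm[j]]] <- rbinom(n, 1, p)
    domains[[dnames[d]]] <- nm
  }
  structure(
    list(indicators = tibble::as_tibble(cols),
         domains = domains,
         m = stats::setNames(as.integer(m_per_domain), dnames),
         weights = stats::setNames(rep(1, length(m_per_domain)), dnames),
         covariates = tibble::tibble(),
         respondent_id = seq_len(n)),
    class = "wc_indicators"
  )
}

# ------------------------------------------------------------------
# Independent brute-force oracle for the counting core: recomputes every
# quantity from first principles with explicit loops, sharing no code with
# the implementation under test.
# ------------------------------------------------------------------
oracle_threshold <- function(m) {
  t <- 1L
  while (t < 2 * m / 3) t <- t + 1L
  t
}

oracle_profiles <- function(ind, k = NULL) {
  X <- as.matrix(ind$indicators)
  D <- length(ind$domains)
  if (is.null(k)) k <- oracle_threshold(D)
  n <- nrow(X)
  out <- data.frame(W = integer(n), maintained = integer(n), c = integer(n))
  suff <- matrix(0L, n, D)
  for (i in seq_len(n)) {
    z <- integer(D)
    for (d in seq_len(D)) {
      cols <- ind$domains[[d]]
      s <- 0L
      for (cc in cols) s <- s + X[i, cc]
      z[d] <- if (s >= oracle_threshold(length(cols))) 1L else 0L
    }
    suff[i, ] <- z
    out$W[i] <- sum(z)
    out$maintained[i] <- if (sum(z) >= k) 1L else 0L
    out$c[i] <- D - sum(z)
  }
  list(table = out, suff = suff, k = k)
}

oracle_summary <- function(orc, D) {
  tab <- orc$table
  n <- nrow(tab)
  dep <- tab$maintained == 0L
  H <- sum(dep) / n
  A_raw <- if (any(dep)) sum(tab$c[dep]) / sum(dep) else NA_real_
  list(H = H, A_raw = A_raw, A = A_raw / D,
       M0 = if (any(dep)) H * A_raw / D else 0)
}

# hand-written logistic log-likelihood for the brute-force fit oracle
oracle_loglik <- function(beta, X, y) {
  eta <- as.vector(X %*% beta)
  sum(y * eta - log(1 + exp(eta)))
}
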