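test_that("two-thirds thresholds match the ceiling rule", {
  expect_identical(domain_threshold(9L), 6L)
  expect_identical(domain_threshold(6L), 4L)
  expect_identical(domain_threshold(1L), 1L)
  expect_identical(domain_threshold(7L), 5L)
  expect_error(domain_threshold(0), class = "wellcount_range_error")
})

test_that("domain scoring counts achievements against the threshold", {
  expect_equal(score_domain(rep(1, 9)), list(raw = 9L, sufficiency = 1L))
  expect_equal(score_domain(rep(0, 9)), list(raw = 0L, sufficiency = 0L))
  expect_equal(score_domain(c(1, 1, 1, 1, 1, 0, 0, 0, 0)),
               list(raw = 5L, sufficiency = 0L))  # 5 < threshold 6
  expect_error(score_domain(c(1, 2, 0)), class = "wellcount_type_error")
})

test_that("overall classification applies the k-of-D counting cutoff", {
  expect_equal(classify_overall(c(1, 1, 1, 1, 0, 0)),
               list(W = 4L, maintained = 1L, c = 2L))
  expect_equal(classify_overall(c(1, 1, 1, 0, 0, 0)),
               list(W = 3L, maintained = 0L, c = 3L))
  expect_equal(classify_overall(rep(1, 6)),
               list(W = 6L, maintained = 1L, c = 0L))
  expect_error(classify_overall(c(1, 0), k = 3),
               class = "wellcount_range_error")
})

test_that("counting core agrees with a brute-force oracle on random instances", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(1:12, 1)
    D <- sample(1:4, 1)
    m <- sample(1:5, D, replace = TRUE)
    ind <- random_indicators(n, m, p = runif(1, 0.2, 0.8))
    orc <- oracle_profiles(ind)
    pr <- wellbeing_profiles(ind)
    expect_equal(pr$wellbeing_index, orc$table$W)
    expect_equal(pr$maintained, orc$table$maintained)
    expect_equal(pr$deprivation_count, orc$table$c)
    expect_equal(unname(domain_sufficiency(pr)), orc$suff)

    s <- summarize_wellbeing(pr)
    os <- oracle_summary(orc, D)
    expect_equal(s$headcount_deprived, os$H)
    expect_equal(s$intensity_domains, os$A_raw)
    expect_equal(s$adjusted_headcount, os$M0)
  }
})

test_that("flipping an indicator 0 to 1 never hurts any wellbeing quantity", {
  set.seed(202)
  for (rep in 1:20) {
    ind <- random_indicators(sample(2:10, 1), sample(2:5, 3, replace = TRUE),
                             p = 0.5)
    X <- as.matrix(ind$indicators)
    zeros <- which(X == 0)
    if (!length(zeros)) next
    flip <- sample(zeros, 1)
    ind2 <- ind
    X2 <- X; X2[flip] <- 1L
    ind2$indicators <- tibble::as_tibble(as.data.frame(X2))

    p1 <- wellbeing_profiles(ind); p2 <- wellbeing_profiles(ind2)
    expect_true(all(p2$wellbeing_index >= p1$wellbeing_index))
    expect_true(all(p2$maintained >= p1$maintained))
    expect_true(all(p2$deprivation_count <= p1$deprivation_count))

    s1 <- summarize_wellbeing(p1); s2 <- summarize_wellbeing(p2)
    expect_lte(s2$headcount_deprived, s1$headcount_deprived)
    expect_lte(s2$adjusted_headcount, s1$adjusted_headcount)
  }
})

test_that("summary invariants hold and degenerate populations are exact", {
  # single respondent deprived in all six domains
  ind <- random_indicators(1, rep(3, 6), p = 0)
  s <- summarize_wellbeing(wellbeing_profiles(ind))
  expect_equal(s$headcount_deprived, 1)
  expect_equal(s$intensity_domains, 6)
  expect_equal(s$intensity_share, 1)
  expect_equal(s$adjusted_headcount, 1)

  # conservation and the deprivation-count bound under k = 4 of 6
  set.seed(303)
  ind <- random_indicators(200, rep(3, 6), p = 0.6)
  pr <- wellbeing_profiles(ind)
  s <- summarize_wellbeing(pr)
  expect_equal(s$n_maintained + s$n_deprived, s$n_total)
  dep_c <- pr$deprivation_count[pr$maintained == 0]
  expect_true(all(dep_c %in% 3:6))
  if (length(dep_c)) expect_gte(s$intensity_domains, 3)
  expect_lte(s$adjusted_headcount, s$headcount_deprived)
})

test_that("weighted counting reduces to the plain rule at equal weights", {
  set.seed(404)
  ind <- random_indicators(50, c(3, 4, 2, 5, 3, 4), p = 0.55)
  plain <- wellbeing_profiles(ind)
  halved <- wellbeing_profiles(ind,
                               weights = stats::setNames(rep(0.5, 6),
                                                         names(ind$domains)),
                               k = 2)  # 4-of-6 on the half-weight scale
  expect_equal(halved$maintained, plain$maintained)
  expect_equal(halved$wellbeing_index * 2, plain$wellbeing_index)
})

test_that("driver tables report multiple-response shares within a group", {
  # 4 respondents all deprived in domain P, half deprived in domain Q
  suff <- cbind(P = c(0, 0, 0, 0), Q = c(1, 1, 0, 0), R = c(1, 1, 1, 1))
  df <- tibble::tibble(respondent_id = 1:4,
                       suff_P = suff[, 1], suff_Q = suff[, 2],
                       suff_R = suff[, 3])
  df$wellbeing_index <- as.integer(rowSums(suff))
  df$maintained <- 0L  # treat all as the deprived group
  df$deprivation_count <- 3L - df$wellbeing_index
  pr <- structure(df, domains = c("P", "Q", "R"), k = 3,
                  weights = c(P = 1, Q = 1, R = 1),
                  class = c("wc_profiles", class(df)))
  dt <- driver_table(pr, "deprived")
  expect_equal(dt$pct_deprived[dt$domain == "P"], 100)
  expect_equal(dt$pct_deprived[dt$domain == "Q"], 50)
  expect_equal(dt$pct_deprived[dt$domain == "R"], 0)
  expect_equal(dt$pct_deprived, sort(dt$pct_deprived, decreasing = TRUE))
  expect_error(driver_table(pr, "maintained"))
})

test_that("reporting rounds half-up at the printed precision", {
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(as_pct(53, 81), 65.4)
  expect_equal(as_pct(310, 442), 70.1)
})
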