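test_that("stratified rates match hand counts on a toy population", {
  # group X = {maintained, maintained, deprived}, group Y = {deprived}
  ind <- random_indicators(4, c(1, 1, 1), p = 1)
  pr <- wellbeing_profiles(ind)
  pr$maintained <- c(1L, 1L, 0L, 0L)
  covs <- tibble::tibble(grp = c("X", "X", "X", "Y"))
  rep <- stratified_rates(pr, covs, "grp")
  ov <- rep[rep$measure == "overall", ]
  expect_equal(ov$maintained_pct[ov$group == "X"], 100 * 2 / 3,
               tolerance = 1e-12)
  expect_equal(ov$maintained_pct[ov$group == "Y"], 0)
  expect_equal(ov$n[ov$group == "X"], 3)
  # maintained% + deprived% = 100 within each group and measure
  expect_equal(rep$maintained_pct + rep$deprived_pct,
               rep_len(100, nrow(rep)))
  expect_error(stratified_rates(pr, covs, "nope"))
})

test_that("a single group reproduces the unstratified summary", {
  set.seed(11)
  ind <- random_indicators(60, rep(2, 6), p = 0.7)
  pr <- wellbeing_profiles(ind)
  s <- summarize_wellbeing(pr)
  rep <- stratified_rates(pr, tibble::tibble(g = rep("all", 60)), "g")
  ov <- rep[rep$measure == "overall", ]
  expect_equal(ov$deprived_pct / 100, s$headcount_deprived)
  expect_equal(ov$n, s$n_total)
})

test_that("missing stratifier values are excluded unless given a label", {
  ind <- random_indicators(5, c(1, 1, 1), p = 1)
  pr <- wellbeing_profiles(ind)
  covs <- tibble::tibble(g = c("a", "a", NA, "b", NA))
  rep <- stratified_rates(pr, covs, "g")
  expect_equal(sum(rep$n[rep$measure == "overall"]), 3)
  rep2 <- stratified_rates(pr, covs, "g", na_label = "Other")
  expect_equal(sum(rep2$n[rep2$measure == "overall"]), 5)
  expect_true("Other" %in% rep2$group)
})

test_that("headcounts decompose across any partition of the population", {
  set.seed(77)
  ind <- random_indicators(120, c(3, 2, 4, 3, 2, 3), p = 0.6)
  pr <- wellbeing_profiles(ind)
  H <- summarize_wellbeing(pr)$headcount_deprived
  for (rep_i in 1:5) {
    g <- sample(letters[1:sample(2:5, 1)], 120, replace = TRUE)
    tab <- stratified_rates(pr, tibble::tibble(g = g), "g")
    ov <- tab[tab$measure == "overall", ]
    expect_equal(sum(ov$n * ov$deprived_pct / 100) / sum(ov$n), H,
                 tolerance = 1e-12)
  }
})

test_that("gap statistics use the first group as the relative denominator", {
  g1 <- gap_statistic(98, 86)
  expect_equal(g1$point_differential, 12)
  expect_equal(round_half_up(g1$percent_difference, 1), 12.2)
  g2 <- gap_statistic(72, 61)
  expect_equal(g2$point_differential, 11)
  expect_equal(round_half_up(g2$percent_difference, 1), 15.3)
  expect_equal(gap_statistic(50, 50)$point_differential, 0)
  expect_equal(gap_statistic(50, 50)$percent_difference, 0)
  # antisymmetry of the point differential; undefined relative gap at 0
  expect_equal(gap_statistic(30, 70)$point_differential,
               -gap_statistic(70, 30)$point_differential)
  expect_true(is.na(gap_statistic(0, 10)$percent_difference))
  expect_error(gap_statistic(101, 5), class = "wellcount_range_error")
})

test_that("multiple-response tables keep per-condition shares unnormalized", {
  tab <- multiple_response_table(
    data.frame(c1 = c(1, 1, 1, 1), c2 = c(1, 0, 0, 0)))
  expect_equal(tab$pct_yes, c(100, 25))
  expect_equal(multiple_response_table(data.frame(z = c(0, 0)))$pct_yes, 0)
  # two all-yes conditions total 200%
  both <- multiple_response_table(data.frame(a = c(1, 1), b = c(1, 1)))
  expect_equal(sum(both$pct_yes), 200)
  # invariant to column order, all values in [0, 100]
  set.seed(5)
  cond <- data.frame(a = rbinom(30, 1, .4), b = rbinom(30, 1, .7),
                     c = rbinom(30, 1, .1))
  t1 <- multiple_response_table(cond)
  t2 <- multiple_response_table(cond[c("c", "a", "b")])
  expect_equal(t1$pct_yes[match(t2$condition, t1$condition)], t2$pct_yes)
  expect_true(all(t1$pct_yes >= 0 & t1$pct_yes <= 100))
  expect_error(multiple_response_table(cond, mask = rep(FALSE, 30)))
})

test_that("hopefulness shift reports both wave shares and the fall", {
  hs <- hopefulness_shift(c(8, 8, 7, 2), c(8, 2, 2, 2), cutoff = 7)
  expect_equal(hs$share_pre, 75)
  expect_equal(hs$share_during, 25)
  expect_equal(hs$change_points, 50)
  same <- hopefulness_shift(c(8, 3), c(8, 3))
  expect_equal(same$change_points, 0)
  low <- hopefulness_shift(c(2, 3), c(1, 2))
  expect_equal(c(low$share_pre, low$share_during, low$change_points),
               c(0, 0, 0))
  expect_error(hopefulness_shift(c(8, 7), c(8, 7, 6)),
               class = "wellcount_input_error")
})
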