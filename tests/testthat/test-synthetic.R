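test_that("generator config validates marginals and counts", {
  expect_error(generator_config(gender_marginal = c(a = 0.5, b = 0.4)),
               class = "wellcount_config_error")
  expect_error(generator_config(n = 0), class = "wellcount_config_error")
  cfg <- generator_config(n = 10, seed = 1)
  expect_s3_class(cfg, "wc_genconfig")
  expect_length(cfg$baselines, 6)
})

test_that("the same seed regenerates the table bit-for-bit", {
  a <- simulate_survey(generator_config(n = 150, seed = 99))
  b <- simulate_survey(generator_config(n = 150, seed = 99))
  expect_identical(a, b)
  c <- simulate_survey(generator_config(n = 150, seed = 100))
  expect_false(identical(a, c))
})

test_that("with effects off and baseline 0, single-variable achievement is ~50%", {
  cfg <- generator_config(
    n = 10000, seed = 7,
    m = c(solo = 1),
    domain_targets = c(solo = 0.5),
    effects = list(income_high = 0, hope_pre = 0, age = 0,
                   gender = c("Man" = 0, "Woman" = 0,
                              "Other/Not disclosed" = 0)),
    sigma_u = 0)
  expect_equal(unname(cfg$baselines), 0, tolerance = 1e-6)
  raw <- simulate_survey(cfg)
  share <- mean(raw$solo_q1 == "Yes")
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(share - 0.5), 3 * se)
})

test_that("empirical sufficiency converges to the calibrated baseline share", {
  # law of large numbers at a large n, effects off, latent on
  cfg <- generator_config(
    n = 20000, seed = 13,
    m = c(d1 = 5, d2 = 3),
    domain_targets = c(d1 = 0.7, d2 = 0.4),
    effects = list(income_high = 0, hope_pre = 0, age = 0,
                   gender = c("Man" = 0, "Woman" = 0,
                              "Other/Not disclosed" = 0)),
    sigma_u = 1)
  raw <- simulate_survey(cfg)
  for (d in c("d1", "d2")) {
    cols <- grep(paste0("^", d, "_q"), names(raw), value = TRUE)
    X <- vapply(raw[cols], function(x) as.integer(x == "Yes"),
                integer(nrow(raw)))
    suff <- rowSums(X) >= domain_threshold(length(cols))
    expect_equal(mean(suff), cfg$domain_targets[[d]], tolerance = 0.015)
  }
})

test_that("the default configuration reproduces the target sufficiency shares", {
  raw <- simulate_survey(generator_config(n = 5000, seed = 21))
  pr <- wellbeing_profiles(recode(raw, sa2020_codebook()))
  shares <- 100 * colMeans(domain_sufficiency(pr))
  targets <- 100 * generator_config(n = 10, seed = 1)$domain_targets
  expect_true(all(abs(shares - targets[names(shares)]) <= 5))
})

test_that("generated tables round-trip through the full pipeline", {
  raw <- simulate_survey(generator_config(n = 120, seed = 55,
                                          missing_rate = 0.03))
  ind <- recode(raw, sa2020_codebook())
  expect_equal(nrow(ind$indicators), 120)
  expect_true(all(as.matrix(ind$indicators) %in% c(0L, 1L)))  # as_zero policy
  pr <- wellbeing_profiles(ind)
  s <- summarize_wellbeing(pr)
  expect_equal(s$n_maintained + s$n_deprived, 120)
})

test_that("generated covariate marginals track their configuration", {
  raw <- simulate_survey(generator_config(n = 8000, seed = 77))
  expect_equal(mean(raw$gender == "Woman"), 0.748, tolerance = 0.02)
  expect_equal(mean(raw$region == "Greater Adelaide"), 0.76, tolerance = 0.02)
  expect_equal(mean(raw$region == ""), 0.10, tolerance = 0.02)
  inc <- regroup_income(raw$income_weekly)
  expect_equal(mean(inc$group == "LOW"), 0.5, tolerance = 0.03)
  # highly-positive hopefulness falls by about 28 points between waves
  hs <- hopefulness_shift(raw$hope_pre, raw$hope_during)
  expect_equal(hs$change_points, 28, tolerance = 3)
})

test_that("the deterministic fixture matches the published breakdown", {
  fx <- sa2020_fixture()
  expect_equal(nrow(fx), 579)
  dep <- fx[fx$maintained == 0, ]
  expect_equal(nrow(dep), 167)
  expect_equal(as.vector(table(dep$deprivation_count)[c("6", "5", "4", "3")]),
               c(4L, 16L, 61L, 86L))
  expect_equal(sum(fx$maintained), 412)
  # driver ordering matches the published ranking
  dt <- driver_table(fx, "deprived")
  expect_equal(dt$domain, c("Psychological and Emotional Health",
                            "Physical Health",
                            "Ecological Diversity and Resilience",
                            "Governance", "Standard of Living",
                            "Family and Community Vitality"))
  # fixture construction is deterministic
  expect_identical(fx, sa2020_fixture())
})
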