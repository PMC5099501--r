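test_that("pearson correlation matches the closed-form oracle", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4, 7.1, 0.3, 6.6, 5.0, 2.9)
  y <- c(2.0, 3.1, 2.8, 6.0, 3.9, 6.5, 1.1, 7.2, 4.6, 3.3)
  got <- pearson_cor(x, y)
  want <- pearson_oracle(x, y)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
  expect_equal(got$n, 10)

  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  set.seed(5)
  xx <- rnorm(10000)
  expect_lt(abs(pearson_cor(xx, sample(xx))$r), 0.05)
})

test_that("pearson handles affine invariance, antisymmetry and NA deletion", {
  set.seed(6)
  x <- rnorm(50); y <- 0.4 * x + rnorm(50)
  r0 <- pearson_cor(x, y)$r
  expect_equal(pearson_cor(3 * x + 2, 0.5 * y - 7)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_cor(x, -y)$r, -r0, tolerance = 1e-12)
  xna <- c(x, NA, 5); yna <- c(y, 3, NA)
  got <- pearson_cor(xna, yna)
  expect_equal(got$n, 50)
  expect_equal(got$r, r0, tolerance = 1e-12)
  expect_error(pearson_cor(rep(1, 10), rnorm(10)), "variance")
  expect_error(pearson_cor(1:2, 1:2), "3")
})

test_that("wilcoxon signed-rank matches exhaustive sign enumeration", {
  set.seed(7)
  for (i in 1:5) {
    d <- round(rnorm(8, 0.3, 1), 3)
    while (anyDuplicated(abs(d)) || any(d == 0)) d <- round(rnorm(8, 0.3, 1), 3)
    expect_equal(wilcoxon_signed_rank(d)$p_value, signrank_oracle_p(d),
                 tolerance = 1e-12)
  }
  # extreme one-sided configuration
  expect_lt(wilcoxon_signed_rank(seq(0.5, 10, length.out = 20))$p_value, 0.01)
  # antisymmetric differences put the statistic at its null center
  d <- c(1, -1, 2, -2, 3, -3, 4, -4)
  expect_equal(wilcoxon_signed_rank(d)$statistic, length(d) * (length(d) + 1) / 4)
  expect_error(wilcoxon_signed_rank(rep(0, 10)), "zero")
  expect_error(wilcoxon_signed_rank(c(1, 2, 3)), "6")
})

test_that("mann-whitney matches exhaustive rank-permutation enumeration", {
  set.seed(9)
  a <- round(rnorm(5, 1), 3); b <- round(rnorm(5), 3)
  expect_equal(mann_whitney(a, b)$p_value, ranksum_oracle_p(a, b),
               tolerance = 1e-12)
  # completely separated groups of size 10 and 10
  a10 <- 101:110; b10 <- 1:10
  expect_equal(mann_whitney(a10, b10)$p_value, ranksum_oracle_p(a10, b10),
               tolerance = 1e-12)
  # identical groups: no location shift
  g <- c(4, 8, 15, 16, 23, 42)
  expect_gt(mann_whitney(g, g)$p_value, 0.98)
  # minimal input runs on the exact path
  expect_no_error(mann_whitney(1, c(2, 3, 4, 5, 6)))
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("plan-type table reports means, paired and versus-rest tests", {
  set.seed(10)
  n <- 60
  types <- data.frame(
    category = rep(c("private", "private", "Medicaid", "Medicare", "Medicare"),
                   each = n),
    plan_type = rep(c("PPO", "HMO", "HMO", "PPO", "HMO"), each = n))
  satis <- rnorm(5 * n, 78, 5)
  agg <- data.frame(
    plan_id = seq_len(5 * n), state = "CA",
    category = types$category, plan_type = types$plan_type,
    n_members = 10,
    mean_rating = satis + 5 + rnorm(5 * n, 0, 2),  # planted paired shift
    OverallConsumerSatisfactionScore = satis)
  out <- plan_type_table(agg)
  expect_equal(nrow(out), 5)
  expect_equal(out$n_plans, rep(n, 5))
  expect_true(all(out$mean_patient_review > out$mean_consumer_satisfaction))
  expect_true(all(out$wilcoxon_paired_p < 0.05))

  # a lone plan type yields one warning and an NA row per missing type
  solo <- agg[agg$category == "Medicaid", ]
  ws <- capture_warnings(out1 <- plan_type_table(solo))
  expect_length(ws, 4)
  expect_match(ws, "no plans", all = TRUE)
  expect_equal(sum(!is.na(out1$mean_patient_review)), 1)
})

test_that("state-wise correlations stratify and respect min_plans", {
  set.seed(11)
  n <- 30
  agg <- data.frame(
    plan_id = seq_len(n), state = "CA", category = "private",
    plan_type = "HMO", n_members = 10,
    mean_rating = rnorm(n, 80, 4))
  agg$OverallConsumerSatisfactionScore <- 0.5 * agg$mean_rating + rnorm(n, 40, 2)
  out <- statewise_correlations(agg)
  expect_equal(nrow(out), 2)  # overall + CA
  expect_equal(out$r[out$stratum == "overall"], out$r[out$stratum == "CA"])

  two <- agg[1:2, ]; two$state <- "NY"
  out2 <- statewise_correlations(rbind(agg, two))
  expect_false("NY" %in% out2$stratum)
  expect_error(statewise_correlations(agg, min_plans = 2), "min_plans")

  bh <- statewise_correlations(agg, bh = TRUE)
  expect_true("p_adjusted" %in% names(bh))
})

test_that("condition correlations restrict members to mapped specialties", {
  cmap <- default_condition_map()
  expect_length(cmap, 6)
  set.seed(12)
  n_prov <- 240
  specialties <- rep(c("Pediatrics", "Endocrinology", "Oncology",
                       "Cardiologist", "Psychologist",
                       "Obstetrics and Gynecology"), each = 40)
  attrs <- data.frame(provider_id = sprintf("P%03d", seq_len(n_prov)),
                      state = "CA", specialty = specialties,
                      user_rating = rnorm(n_prov, 82, 8), n_reviews = 3,
                      castle_connolly = FALSE, num_referrals = 5,
                      hospital_score = 70, hospital_rank = 100,
                      relative_cost = 50, stringsAsFactors = FALSE)
  plans <- make_plan_table(30)
  for (col in unique(vapply(cmap, `[[`, "", "score_column")))
    plans[[col]] <- rnorm(30, 75, 6)
  membership <- data.frame(
    plan_id = sample(plans$plan_id, 3 * n_prov, replace = TRUE),
    provider_id = rep(attrs$provider_id, 3))
  out <- condition_correlations(attrs, membership, plans, cmap)
  expect_equal(sort(out$stratum), sort(names(cmap)))
  expect_true(all(abs(out$r) <= 1))
  expect_true(all(out$n >= 3))

  # a condition whose specialties no provider has is skipped with a warning
  attrs2 <- attrs[attrs$specialty != "Endocrinology", ]
  expect_warning(out2 <- condition_correlations(attrs2, membership, plans,
                                                cmap["Diabetes"]),
                 "Diabetes")
  expect_equal(nrow(out2), 0)
})

test_that("null type-I rates for all three tests are near nominal", {
  set.seed(13)
  B <- 400  # lighter version of the calibration run in the acceptance suite
  wp <- replicate(B, wilcoxon_signed_rank(rnorm(20))$p_value)
  mp <- replicate(B, mann_whitney(rnorm(15), rnorm(15))$p_value)
  pp <- replicate(B, pearson_cor(rnorm(20), rnorm(20))$p_value)
  for (rate in c(mean(wp < 0.05), mean(mp < 0.05), mean(pp < 0.05))) {
    expect_gt(rate, 0.02)
    expect_lt(rate, 0.08)
  }
})
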