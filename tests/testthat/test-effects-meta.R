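fourfold <- function(a, b, c, d, model = "dominant") {
  structure(list(a = a, b = b, c = c, d = d, model = model,
                 corrected = FALSE, study_id = "s"),
            class = "fourfold")
}

test_that("per-study log odds ratios match hand computation", {
  e <- study_log_or(fourfold(20, 80, 10, 90))
  expect_equal(e$or, 2.25)
  expect_equal(e$log_or, log(2.25), tolerance = 1e-12)
  expect_equal(e$se, sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90), tolerance = 1e-12)

  expect_equal(study_log_or(fourfold(10, 10, 10, 10))$log_or, 0)

  corr <- study_log_or(fourfold(0, 50, 10, 40))
  expect_true(corr$corrected)
  expect_equal(corr$or, (0.5 * 40.5) / (50.5 * 10.5), tolerance = 1e-12)

  # double-zero margins carry no information and are dropped
  expect_null(study_log_or(fourfold(0, 50, 0, 40)))
  expect_null(study_log_or(fourfold(10, 0, 40, 0)))
  expect_null(study_log_or(fourfold(0, 0, 10, 10)))
})

test_that("fixed-effect pooling is inverse-variance with the expected identities", {
  e <- study_log_or(fourfold(20, 80, 10, 90))
  pooled <- pool_fixed(list(e, e))
  expect_equal(pooled$or, 2.25)
  expect_equal(pooled$se, e$se / sqrt(2), tolerance = 1e-12)
  expect_equal(pooled$Q, 0)

  single <- pool_fixed(list(e))
  expect_equal(single$log_or, e$log_or)
  expect_equal(single$se, e$se)

  # convex combination and order invariance
  set.seed(11)
  for (i in 1:25) {
    eff <- random_effects(sample(2:8, 1))
    p <- pool_fixed(eff)
    th <- vapply(eff, `[[`, numeric(1), "log_or")
    expect_gte(p$log_or, min(th) - 1e-12)
    expect_lte(p$log_or, max(th) + 1e-12)
    p2 <- pool_fixed(rev(eff))
    expect_equal(p2$log_or, p$log_or, tolerance = 1e-14)
    expect_equal(p2$Q, p$Q, tolerance = 1e-12)
  }
  expect_error(pool_fixed(list()), "at least one")
})

test_that("DerSimonian-Laird pooling matches the hand formula and widens the CI", {
  eff <- list(make_effect(0, 0.2), make_effect(1, 0.2))
  rand <- pool_random_dl(eff)
  fix <- pool_fixed(eff)
  # Q = 12.5, tau2 = (12.5 - 1) / (50 - 25) = 0.46 by hand
  expect_equal(rand$Q, 12.5, tolerance = 1e-12)
  expect_equal(rand$tau2, 0.46, tolerance = 1e-12)
  expect_equal(rand$log_or, 0.5, tolerance = 1e-12)
  expect_gt(rand$ci_high - rand$ci_low, fix$ci_high - fix$ci_low)

  # homogeneous studies truncate tau2 at zero and collapse to fixed effect
  hom <- list(make_effect(0.5, 0.3), make_effect(0.5, 0.3), make_effect(0.5, 0.3))
  expect_equal(pool_random_dl(hom)$tau2, 0)
  expect_equal(pool_random_dl(hom)$log_or, pool_fixed(hom)$log_or)
  expect_error(pool_random_dl(hom[1]), "at least two")
})

test_that("DL pooling agrees with metafor on random instances to 1e-10", {
  skip_if_not_installed("metafor")
  set.seed(42)
  for (i in 1:100) {
    eff <- random_effects(sample(2:12, 1))
    th <- vapply(eff, `[[`, numeric(1), "log_or")
    se <- vapply(eff, `[[`, numeric(1), "se")
    ours <- pool_random_dl(eff)
    oracle <- metafor::rma(yi = th, sei = se, method = "DL")
    expect_equal(ours$log_or, as.numeric(oracle$beta), tolerance = 1e-10)
    expect_equal(ours$se, oracle$se, tolerance = 1e-10)
    expect_equal(ours$tau2, oracle$tau2, tolerance = 1e-10)
    expect_equal(ours$Q, oracle$QE, tolerance = 1e-10)
    # random-effects se never below fixed-effect se
    expect_gte(ours$se, pool_fixed(eff)$se - 1e-12)
  }
})

test_that("heterogeneity matches its defining formula and truncates correctly", {
  hom <- list(make_effect(0.3, 0.2), make_effect(0.3, 0.2), make_effect(0.3, 0.2))
  h <- heterogeneity(hom)
  expect_equal(h$Q, 0)
  expect_equal(h$I2, 0)
  expect_equal(h$I2_ci95[1], 0)

  set.seed(7)
  for (i in 1:50) {
    eff <- random_effects(sample(2:10, 1))
    h <- heterogeneity(eff)
    k <- length(eff)
    i2_oracle <- if (h$Q > 0) max(0, (h$Q - (k - 1)) / h$Q) * 100 else 0
    expect_equal(h$I2, i2_oracle, tolerance = 1e-12)
    expect_equal(h$Q_p, pchisq(h$Q, k - 1, lower.tail = FALSE), tolerance = 1e-12)
    expect_true(all(h$I2_ci95 >= 0 & h$I2_ci95 <= 100))
  }

  # Q exactly at its degrees of freedom sits on the truncation boundary
  th <- c(-0.5, 0.5)
  se <- c(1, 1) * sqrt(2 * 0.25 / 1) # makes Q = k - 1 = 1
  eff <- mapply(make_effect, th, se, SIMPLIFY = FALSE)
  expect_equal(heterogeneity(eff)$Q, 1, tolerance = 1e-12)
  expect_equal(heterogeneity(eff)$I2, 0)
})

test_that("the model switch follows the heterogeneity p-value strictly", {
  expect_equal(select_model(0.20), "fixed")
  expect_equal(select_model(0.01), "random")
  expect_equal(select_model(0.05), "fixed") # boundary keeps fixed
  expect_equal(select_model(NA_real_), "fixed")
})

test_that("Egger regression matches an OLS oracle on the transformed variables", {
  set.seed(99)
  for (i in 1:100) {
    eff <- random_effects(sample(3:12, 1))
    th <- vapply(eff, `[[`, numeric(1), "log_or")
    se <- vapply(eff, `[[`, numeric(1), "se")
    ours <- egger_test(eff)
    fit <- summary(lm(I(th / se) ~ I(1 / se)))
    expect_equal(ours$intercept, fit$coefficients[1, 1], tolerance = 1e-10)
    expect_equal(ours$intercept_se, fit$coefficients[1, 2], tolerance = 1e-10)
    expect_equal(ours$p_value, fit$coefficients[1, 4], tolerance = 1e-10)
  }
})

test_that("Egger handles symmetric and degenerate inputs", {
  sym <- list(make_effect(0.4, 0.2), make_effect(0.4, 0.2), make_effect(0.4, 0.2))
  e <- egger_test(sym)
  expect_equal(e$intercept, 0)
  expect_false(e$detected)

  two <- egger_test(list(make_effect(0, 0.1), make_effect(1, 0.4)))
  expect_false(two$evaluable)
  expect_false(two$detected)
})

test_that("meta_analyse is deterministic and flags insufficient studies", {
  d <- simulation_design(seed = 5)
  ds <- simulate_meta_dataset(d)
  r1 <- meta_analyse(ds, "rs_sim", "CD", "dominant")
  r2 <- meta_analyse(ds, "rs_sim", "CD", "dominant")
  expect_identical(r1$pooled$log_or, r2$pooled$log_or)
  expect_identical(r1$effects, r2$effects)
  expect_equal(r1$status, "ok")
  expect_equal(r1$k, 6)
  expect_equal(r1$n_cases, sum(d$n_cases))

  small <- ds
  small$records <- small$records[1, , drop = FALSE]
  r <- meta_analyse(small, "rs_sim", "CD", "dominant")
  expect_equal(r$status, "insufficient_studies")
  expect_equal(r$pooled$log_or, r$effects$log_or[1]) # k = 1 pools to itself
})

test_that("forest and funnel exports carry studies plus the pooled row", {
  ds <- simulate_meta_dataset(simulation_design(seed = 5))
  res <- meta_analyse(ds, "rs_sim", "CD", "dominant")
  fd <- forest_data(res)
  expect_equal(nrow(fd), res$k + 1)
  expect_equal(sum(fd$weight, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_equal(nrow(funnel_data(res)), res$k)
})
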