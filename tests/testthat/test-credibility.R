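test_that("BFDP reproduces printed synopsis values from OR and CI alone", {
  expect_lt(abs(bfdp_from_or_ci(8.64, 2.80, 26.69)$bfdp - 0.465), 0.01)
  expect_lt(abs(bfdp_from_or_ci(4.75, 2.43, 9.26)$bfdp - 0.017), 0.005)
  expect_lt(abs(bfdp_from_or_ci(0.97, 0.31, 3.04)$bfdp - 0.963), 0.01)
})

test_that("the approximate Bayes factor equals the normal density ratio", {
  set.seed(13)
  W <- bfdp_params()$prior_w
  for (i in 1:100) {
    or_ <- exp(rnorm(1, 0, 1))
    se <- runif(1, 0.05, 0.8)
    z <- qnorm(0.975)
    lo <- or_ * exp(-z * se)
    hi <- or_ * exp(z * se)
    r <- bfdp_from_or_ci(or_, lo, hi)
    theta <- log(or_)
    oracle <- dnorm(theta, 0, sqrt(r$V)) / dnorm(theta, 0, sqrt(r$V + W))
    expect_equal(r$ABF, oracle, tolerance = 1e-10)
  }
})

test_that("BFDP respects its null lower bound and monotonicity in |theta|", {
  r <- bfdp_from_or_ci(1.0, 0.5, 2.0)
  expect_gte(r$bfdp, 19 / 20) # theta = 0 floors at PO / (1 + PO)

  # strictly decreasing in |theta| at fixed V
  se <- 0.25
  z <- qnorm(0.975)
  ors <- exp(seq(0, 2, length.out = 15))
  b <- vapply(ors, function(o)
    bfdp_from_or_ci(o, o * exp(-z * se), o * exp(z * se))$bfdp, numeric(1))
  expect_true(all(diff(b) < 0))

  expect_error(bfdp_from_or_ci(-1, 0.5, 2))
  expect_error(bfdp_from_or_ci(1, 2, 0.5))
})

test_that("Venice grades follow the power / I2 / bias cutoffs and boundaries", {
  expect_equal(venice_grade(1.00, 46, FALSE)$as_string, "ABB")
  expect_equal(venice_grade(0.05, 0, FALSE)$as_string, "CAB")
  # declared boundary conventions
  expect_equal(venice_grade(0.80, 25, FALSE)$as_string, "AAB")
  expect_equal(venice_grade(0.50, 50, FALSE)$as_string, "BCB")
  expect_equal(venice_grade(0.49, 26, TRUE)$as_string, "CBC")
  # an egger_result can stand in for the bias flag
  eg <- structure(list(detected = TRUE), class = "egger_result")
  expect_equal(venice_grade(0.9, 10, eg)$bias, "C")
})

test_that("classification is existential over significant models with tier fallbacks", {
  pm <- data.frame(
    model = c("dominant", "recessive", "additive1", "additive2"),
    p = c(0.001, 0.2, 0.03, 0.6),
    bfdp = c(0.01, 0.5, 0.5, 0.9),
    power = c(0.95, 0.2, 0.6, 0.1),
    i2 = c(10, 0, 70, 0),
    eligible = TRUE, stringsAsFactors = FALSE
  )
  v <- classify_variant(pm)
  expect_equal(v$tier, "highly_credible")
  expect_equal(v$qualifying_model, "dominant")
  expect_equal(v$n_significant_models, 2L)

  # remove the witness: still significant twice, so less credible
  pm2 <- pm
  pm2$bfdp[1] <- 0.5
  expect_equal(classify_variant(pm2)$tier, "less_credible")

  # one significant model only
  pm3 <- pm
  pm3$p <- c(0.001, 0.2, 0.3, 0.6)
  expect_equal(classify_variant(pm3)$tier, "not_credible")

  # nothing significant
  pm4 <- pm
  pm4$p <- rep(0.5, 4)
  expect_equal(classify_variant(pm4)$tier, "not_credible")

  # ineligible models never contribute
  pm5 <- pm
  pm5$eligible <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(classify_variant(pm5)$n_significant_models, 2L)
  none <- classify_variant(transform(pm, eligible = FALSE))
  expect_equal(none$tier, "not_credible")
  expect_true(none$no_eligible_models)
})

test_that("classification is invariant to model order and idempotent", {
  pm <- data.frame(
    model = c("dominant", "recessive", "additive1", "additive2"),
    p = c(0.01, 0.02, 0.8, 0.04),
    bfdp = c(0.3, 0.1, 0.9, 0.15),
    power = c(0.9, 0.85, 0.1, 0.95),
    i2 = c(10, 20, 0, 55),
    eligible = TRUE, stringsAsFactors = FALSE
  )
  v1 <- classify_variant(pm)
  for (i in 1:5) {
    v2 <- classify_variant(pm[sample(nrow(pm)), ])
    expect_equal(v2$tier, v1$tier)
    expect_equal(v2$qualifying_model, v1$qualifying_model)
  }
  expect_equal(classify_variant(pm)$tier, v1$tier)
})

test_that("boundary conventions: p at alpha is not significant; I2 at 50 qualifies", {
  pm <- data.frame(
    model = c("dominant", "recessive"),
    p = c(0.05, 0.01), bfdp = c(0.01, 0.01), power = c(1, 1),
    i2 = c(0, 0), eligible = TRUE, stringsAsFactors = FALSE
  )
  expect_equal(classify_variant(pm)$n_significant_models, 1L)

  pm$p <- c(0.01, 0.02)
  pm$i2 <- c(50, 60)
  v <- classify_variant(pm)
  expect_equal(v$tier, "highly_credible")
  expect_equal(v$qualifying_model, "dominant") # I2 = 50 qualifies, 60 does not
})
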