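test_that("design matrix matches hand computation on a tiny village", {
  co <- hand_cohort()
  cont <- hand_contamination(0.5)
  doses <- default_reference_doses()
  d <- build_design(co, cont, doses)
  # only tomatoes consumed; only its DDT cell recorded (0.5 mg/kg, MPC 0.01)
  # X2: consumption weight on tomatoes = 1; mean over pesticide cells = 50
  expect_equal(d$pest_mpc_excess, rep(50, 3))
  # X3: EDIs (0.002, 0.0025, 0.0005) over ADI 0.01; the other pesticide
  # groups have no recorded concentrations, so their intakes are not
  # computable and are excluded from the mean rather than counted as zero
  expect_equal(d$pest_adi_excess, c(0.002, 0.0025, 0.0005) / 0.01)
  # X4: no heavy-metal concentrations recorded anywhere -> 0
  expect_equal(d$metal_mpc_excess, rep(0, 3))
  expect_equal(d$repair_score, rep(0, 3))
  expect_equal(d$smoking, c(0, 1, 0))
  expect_equal(d$age, c(40, 50, 60))

  # a fully unexposed never-smoker with functional genotypes has all-zero
  # risk predictors except age
  co0 <- co
  cont0 <- hand_contamination(0)
  d0 <- build_design(co0, cont0, doses)
  expect_equal(unname(as.matrix(d0[1, risk_predictors()])[1, -1]), rep(0, 8))

  # permuting individuals permutes rows only
  perm <- c(3, 1, 2)
  d_perm <- build_design(co[perm, ], cont, doses)
  expect_equal(d_perm$id, d$id[perm])
  expect_equal(d_perm$pest_adi_excess, d$pest_adi_excess[perm])

  # missing inputs are reported by individual id
  co_na <- co
  co_na$weight[2] <- NA
  expect_error(build_design(co_na, cont, doses), "H-2")
})

test_that("OLS fit matches the normal-equations oracle", {
  for (seed in 1:5) {
    d <- random_design(n = 151, seed = seed)
    set.seed(seed + 100)
    y <- 2 + as.matrix(d) %*% rnorm(9) + rnorm(151, 0, 1.5)
    fit <- fit_risk_model(d, drop(y))
    oracle <- ols_oracle(as.matrix(d), drop(y))
    expect_equal(unname(fit$coefficients), oracle$b, tolerance = 1e-8)
    expect_equal(unname(fit$se), oracle$se, tolerance = 1e-8)
    expect_equal(unname(fit$t), oracle$t, tolerance = 1e-8)
    expect_equal(fit$r2, oracle$r2, tolerance = 1e-10)
    expect_equal(fit$r2_adj, oracle$r2_adj, tolerance = 1e-10)
    # invariants: t = b / se exactly; adjusted R2 below R2
    expect_identical(fit$t, fit$coefficients / fit$se)
    expect_lte(fit$r2_adj, fit$r2)
  }
})

test_that("adjusted R-squared follows the printed formula at n = 151, m = 9", {
  d <- random_design(n = 151, seed = 42)
  set.seed(43)
  y <- as.matrix(d)[, 1] + rnorm(151, 0, 2)
  fit <- fit_risk_model(d, y)
  expect_equal(fit$r2_adj, 1 - (1 - fit$r2) * 150 / 141, tolerance = 1e-12)
  # worked value: R2 = 0.3 at these dimensions gives 0.2553 to 4 d.p.
  expect_equal(round(1 - (1 - 0.3) * 150 / 141, 4), 0.2553)
})

test_that("noiseless outcomes are recovered to full precision", {
  d <- random_design(n = 60, seed = 9)
  beta <- c(0.5, risk_weights("health")[-1])
  y <- drop(cbind(1, as.matrix(d)) %*% beta)
  fit <- suppressWarnings(fit_risk_model(d, y))
  expect_equal(unname(fit$coefficients), unname(beta), tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("rank deficiency is reported with the collinear column", {
  d <- random_design(n = 50, seed = 2)
  d$alcohol <- d$smoking
  set.seed(3)
  expect_error(fit_risk_model(d, rnorm(50)), "alcohol")
})

test_that("coefficient significance compares |t| with the fixed critical value", {
  fit <- structure(list(t = c(intercept = 1, x = 2.562, y = 1.905, z = 0)),
                   class = "risk_fit")
  expect_true(coefficient_significance(fit, 2.263)[["x"]])
  expect_false(coefficient_significance(fit, 2.693)[["y"]])
  expect_false(coefficient_significance(fit, 2.263)[["z"]])
  # negative t of the same magnitude is equally significant
  fit$t[["x"]] <- -2.562
  expect_true(coefficient_significance(fit, 2.263)[["x"]])
  expect_equal(unname(critical_values()), c(2.263, 2.693))
})

test_that("influence shares sum to the explained variability and respect orthogonality", {
  # orthogonal design: shares equal each predictor's marginal explained share
  set.seed(7)
  raw <- matrix(rnorm(200 * 9), 200, 9)
  X <- qr.Q(qr(scale(raw, scale = FALSE)))[, 1:9] # orthonormal, centered
  colnames(X) <- risk_predictors()
  y <- 3 * X[, 1] + 1 * X[, 2] + rnorm(200, 0, 0.5)
  fit <- fit_risk_model(as.data.frame(X), y)
  shares <- influence_shares(fit)
  expect_equal(sum(shares), 100 * fit$r2, tolerance = 1e-9)
  marginal <- vapply(seq_len(9), function(j) 100 * cor(y, X[, j])^2, numeric(1))
  expect_equal(unname(shares), marginal, tolerance = 1e-6)
  # a factor unrelated to y and to the other predictors gets ~no share
  expect_lt(shares[["antioxidant_score"]], 2)
})

test_that("published-coefficient prediction reproduces the printed equations", {
  zero <- rep(0, 9)
  expect_identical(predict_risk(zero, risk_weights("health")), 0.2975)
  expect_identical(predict_risk(zero, risk_weights("genetic")), 2.4756)
  x3 <- replace(zero, 3, 1)
  expect_equal(predict_risk(x3, risk_weights("health")), 0.2975 + 0.8601,
               tolerance = 1e-15)
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(9)
    w <- risk_weights(if (i %% 2 == 0) "health" else "genetic")
    hand <- w[1] + sum(w[-1] * x)
    expect_equal(predict_risk(x, w), unname(hand), tolerance = 1e-12)
  }
})

test_that("mean-threshold predictive ability counts concordant binarized pairs", {
  y <- c(0, 1, 2, 0, 3, 1)
  expect_equal(predictive_ability(y, y), 1)
  # anti-concordant and symmetric around the means
  s <- c(-1, 1, -2, 2, -3, 3)
  expect_equal(predictive_ability(s, -s), 0)
  # six-point hand count: labels s>(mean=0.5): F,T,F,T,F,T vs y>(mean=1):
  # F,F,T,T,F,F -> concordant at positions 1,4,5 -> 1/2
  s2 <- c(0, 1, 0, 1, 0, 1)
  y2 <- c(0, 1, 2, 2, 0, 1)
  expect_equal(predictive_ability(s2, y2), 0.5)
  # invariant under positive affine transforms of the scores
  set.seed(33)
  sc <- rnorm(40)
  yy <- rnorm(40)
  expect_equal(predictive_ability(3.2 * sc + 7, yy), predictive_ability(sc, yy))
  expect_warning(pa <- predictive_ability(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(pa))
})

test_that("alternative influence decomposition and robust errors are available", {
  d <- random_design(n = 100, seed = 12)
  set.seed(13)
  y <- drop(as.matrix(d) %*% c(2, 1, rep(0, 7)) + rnorm(100))
  fit <- fit_risk_model(d, y)
  seq_shares <- influence_shares(fit, method = "sequential")
  expect_equal(sum(seq_shares), 100 * fit$r2, tolerance = 1e-9)
  expect_true(all(seq_shares >= 0))
  fit_rob <- fit_risk_model(d, y, robust = TRUE)
  expect_equal(fit_rob$coefficients, fit$coefficients)
  expect_false(identical(fit_rob$se, fit$se))
  expect_identical(fit_rob$t, fit_rob$coefficients / fit_rob$se)
})
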