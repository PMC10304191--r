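test_that("daily intake is C * cons / bw, linear and additive over foods", {
  expect_equal(compute_edi(0, 0.3, 70), 0)
  expect_equal(compute_edi(0.5, 0.2, 70), 0.0014286, tolerance = 1e-4)
  expect_equal(compute_edi(0.5, 0.4, 70), 2 * compute_edi(0.5, 0.2, 70))
  expect_equal(compute_edi(1.0, 0.2, 70), 2 * compute_edi(0.5, 0.2, 70))
  # additivity over foods
  per_food <- compute_edi(c(0.5, 0.1, 0.3), c(0.2, 0.4, 0.1), 70)
  expect_equal(sum(per_food),
               compute_edi(0.5, 0.2, 70) + compute_edi(0.1, 0.4, 70) +
                 compute_edi(0.3, 0.1, 70))
  expect_error(compute_edi(0.5, 0.2, 0), "body_weight")
  expect_error(compute_edi(-0.5, 0.2, 70), ">= 0")
})

test_that("lifetime intake uses EF as a fraction of the year and reduces to the daily form", {
  # continuous lifetime exposure: ED = AT, EF = 365 days/year
  expect_equal(compute_edi_lifetime(0.5, 0.2, 365, 25550, 70, 25550),
               compute_edi(0.5, 0.2, 70))
  expect_equal(compute_edi_lifetime(1, 0.1, 365, 3650, 70, 25550),
               2.0408e-4, tolerance = 1e-4)
  expect_equal(compute_edi_lifetime(1, 0.1, 365, 0, 70, 25550), 0)
  expect_error(compute_edi_lifetime(1, 0.1, 365, 3650, 70, 0), "averaging_time")
})

test_that("short-term intake sums portion * highest residue over body weight", {
  foods <- c(a = 0.3)
  expect_equal(compute_esti(foods, c(a = 0.2), 60), 0.001)
  expect_equal(compute_esti(c(a = 0.3, b = 0.5), c(a = 0, b = 0), 60), 0)
  # a zero portion contributes nothing
  expect_equal(compute_esti(c(a = 0.3, b = 0), c(a = 0.2, b = 9), 60),
               compute_esti(c(a = 0.3), c(a = 0.2), 60))
  expect_error(compute_esti(c(a = 0.3, b = 0.1), c(a = 0.2), 60), "missing.*b")
  expect_error(compute_esti(foods, c(a = 0.2), 0), "> 0")
})

test_that("hazard indices implement the EDI/ADI family with the 1.0 threshold", {
  h <- hazard_indices(edi = 0.40, adi = 0.01)
  expect_equal(h$hi_ratio, 40)
  expect_true(h$hazardous)
  expect_equal(h$hi_pct, 4000)
  expect_equal(h$chq_pct, h$hi_pct)
  # boundary: exactly at the ADI is not flagged (strict > 1.0)
  hb <- hazard_indices(edi = 0.01, adi = 0.01)
  expect_equal(hb$hi_ratio, 1)
  expect_false(hb$hazardous)
  h0 <- hazard_indices(edi = 0, adi = 0.01, esti = 0, arfd = 0.1)
  expect_equal(unlist(h0[, c("hq", "hi_ratio", "hi_pct", "chq_pct", "ahq_pct")]),
               c(hq = 0, hi_ratio = 0, hi_pct = 0, chq_pct = 0, ahq_pct = 0))
  # acute index
  ha <- hazard_indices(edi = 0, adi = 0.01, esti = 0.05, arfd = 0.1)
  expect_equal(ha$ahq_pct, 50)
  # absent reference dose is not computable, never zero
  hna <- hazard_indices(edi = 0.4, adi = NA)
  expect_true(is.na(hna$hi_ratio) && is.na(hna$hi_pct))
  expect_false(hna$hazardous)
  expect_error(hazard_indices(0.4, adi = -1), "> 0")
})

test_that("MPC fold-excess flags strictly above 1 and respects missing limits", {
  expect_equal(mpc_excess(0.1, 0.1)$fold_excess, 1)
  expect_false(mpc_excess(0.1, 0.1)$excess)
  expect_equal(mpc_excess(0, 0.1)$fold_excess, 0)
  e <- mpc_excess(0.5, 0.1)
  expect_equal(e$fold_excess, 5)
  expect_true(e$excess)
  expect_true(is.na(mpc_excess(0.5, NA)$fold_excess))
  expect_error(mpc_excess(0.5, 0), "> 0")
})

test_that("per-individual and per-village exposures match hand computation", {
  co <- hand_cohort()
  cont <- hand_contamination(0.5)
  edi <- individual_edi(co, cont, groups = "DDT")
  # C * cons / bw per person: 0.5*0.2/50, 0.5*0.4/80, 0.5*0.1/100
  expect_equal(edi$DDT, c(0.002, 0.0025, 0.0005))
  ce <- cohort_exposure(co, cont, mode = "individual", groups = "DDT")
  expect_equal(ce$mean_edi, mean(c(0.002, 0.0025, 0.0005)))
  expect_equal(ce$sd_edi, sd(c(0.002, 0.0025, 0.0005)))

  # identical individuals -> zero spread
  co_same <- co
  co_same$weight <- 80
  co_same$cons_tomatoes <- 0.4
  ce_same <- cohort_exposure(co_same, cont, mode = "individual", groups = "DDT")
  expect_equal(ce_same$sd_edi, 0)
  expect_equal(ce_same$mean_edi, 0.5 * 0.4 / 80)

  # zero contamination everywhere -> zero intake
  ce0 <- cohort_exposure(co, hand_contamination(0), mode = "individual", groups = "DDT")
  expect_equal(ce0$mean_edi, 0)

  # scale property: k times the concentration scales every index by k
  k <- 3.7
  ce_k <- cohort_exposure(co, hand_contamination(0.5 * k), mode = "individual",
                          groups = "DDT")
  expect_equal(ce_k$mean_edi, k * ce$mean_edi, tolerance = 1e-12)
  hz <- hazard_indices(ce$mean_edi, adi = 0.001)
  hz_k <- hazard_indices(ce_k$mean_edi, adi = 0.001)
  expect_equal(hz_k$hi_ratio, k * hz$hi_ratio, tolerance = 1e-12)

  expect_error(cohort_exposure(co[0, ], cont), "empty")
})

test_that("cohort-norm mode uses standard consumption and village mean weight", {
  co <- hand_cohort()
  cont <- hand_contamination(0.5)
  norms <- setNames(rep(0, 7), food_items())
  norms["tomatoes"] <- 0.3
  ce <- cohort_exposure(co, cont, mode = "cohort-norm", norms = norms,
                        groups = "DDT")
  # mean weight (50+80+100)/3; only tomatoes contaminated
  expect_equal(ce$mean_edi, 0.5 * 0.3 / mean(c(50, 80, 100)))
  expect_error(cohort_exposure(co, cont, mode = "cohort-norm"), "norm")
})

test_that("missing concentration cells propagate as NA, never silent zero", {
  co <- hand_cohort()
  co$cons_meat <- 0.1 # consumes a food with no recorded concentration
  cont <- hand_contamination(0.5)
  edi <- individual_edi(co, cont, groups = "DDT")
  expect_true(all(is.na(edi$DDT)))
})
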