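# Shared fixtures built in code.

# Independent closed-form oracle for the Hardy-Weinberg Pearson chi-square:
# chi2 = n (4 n_AA n_BB - n_AB^2)^2 / ((2 n_AA + n_AB)^2 (2 n_BB + n_AB)^2).
# Algebraically identical to the three-cell observed-vs-expected sum but
# computed by a different route (integer arithmetic throughout).
hwe_chi2_oracle <- function(a, b, c) {
  n <- a + b + c
  n * (4 * a * c - b^2)^2 / ((2 * a + b)^2 * (2 * c + b)^2)
}

# Tiny three-person single-village cohort with hand-computable exposures.
# One contaminated food (tomatoes, DDT at 0.5 mg/kg); everyone consumes only
# tomatoes. All genotypes functional.
hand_cohort <- function() {
  panel <- variant_panel()
  d <- data.frame(
    id = c("H-1", "H-2", "H-3"),
    village = "Testville",
    sex = c("F", "M", "F"),
    age = c(40, 50, 60),
    weight = c(50, 80, 100),
    smoking = c(0L, 1L, 0L),
    alcohol = c(0L, 0L, 1L),
    stringsAsFactors = FALSE
  )
  for (f in food_items()) d[[paste0("cons_", f)]] <- 0
  d$cons_tomatoes <- c(0.2, 0.4, 0.1)
  for (j in seq_len(nrow(panel))) {
    d[[panel$rsid[j]]] <- if (panel$marker_model[j] == "codominant") 0L else "+"
  }
  d$questionnaire <- TRUE
  d
}

hand_contamination <- function(ddt_tomatoes = 0.5) {
  data.frame(
    village = "Testville",
    food = "tomatoes",
    group = "DDT",
    concentration = ddt_tomatoes,
    stringsAsFactors = FALSE
  )
}

# Small simulation configuration with fixed noise (skips calibration) for
# fast pipeline tests.
fast_config <- function(seed = 7L) {
  simulation_config(seed = seed, noise_sd_health = 40, noise_sd_genetic = 150)
}

# Normal-equations OLS oracle, independent of stats::lm: solves
# (X'X) b = X'y directly and derives classical SEs, R2 and adjusted R2.
ols_oracle <- function(X, y) {
  Xi <- cbind(1, X)
  n <- nrow(Xi)
  k <- ncol(Xi)
  xtx_inv <- solve(crossprod(Xi))
  b <- unname(drop(xtx_inv %*% crossprod(Xi, y)))
  resid <- y - drop(Xi %*% b)
  s2 <- sum(resid^2) / (n - k)
  se <- unname(sqrt(diag(xtx_inv) * s2))
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(b = b, se = se, t = b / se, r2 = r2,
       r2_adj = 1 - (1 - r2) * (n - 1) / (n - k))
}

# Random well-conditioned nine-predictor design shaped like the analysis set.
random_design <- function(n = 151, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 9), n, 9)
  colnames(X) <- risk_predictors()
  as.data.frame(X)
}
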