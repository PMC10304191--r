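#' Predictor names of the nine-factor risk model
#' @return Character vector of the nine predictor column names, in model order.
#' @export
risk_predictors <- function() {
  c("age", "pest_mpc_excess", "pest_adi_excess", "metal_mpc_excess",
    "repair_score", "detox_score", "antioxidant_score", "smoking", "alcohol")
}

design_matrix <- function(design) {
  as.matrix(design[, risk_predictors(), drop = FALSE])
}

# summary of per-(food,group) fold-excess cells into one number per food
summarise_cells <- function(fe_row, summary) {
  vals <- fe_row[!is.na(fe_row)]
  if (length(vals) == 0) return(0)
  switch(summary,
    mean = mean(vals),
    max = max(vals),
    count = sum(vals > 1)
  )
}

#' Build the nine-predictor design matrix
#'
#' Assembles, per individual: X1 age; X2 mean pesticide MPC fold-excess over
#' foods, weighted by the individual's consumption shares; X3 mean ADI
#' fold-excess of the individual's group-wise daily intakes over the
#' pesticide groups with an ADI; X4 the heavy-metal analogue of X2; X5-X7
#' the gene-cluster scores (DNA repair, detoxification, antioxidant defence);
#' X8 smoking; X9 alcohol. The original study states only that X2-X4 measure
#' "exceedance of permissible levels"; the consumption-weighted mean is this
#' package's default operationalisation, with `summary = "max"` or
#' `"count"` (number of limits exceeded) as alternatives.
#'
#' @param cohort Cohort data.frame (demographics, consumption, genotypes).
#' @param contamination Long-format contamination table.
#' @param doses Reference doses (needs `adi` and `mpc`).
#' @param panel Variant panel.
#' @param coding Genotype risk coding.
#' @param summary Within-food summary over contaminant groups.
#' @return data.frame: `id`, `village`, the nine predictors, plus any outcome
#'   columns present on the cohort (`health_latent`, `health_rank`,
#'   `genetic_latent`, `aberration_pct`).
#' @export
build_design <- function(cohort, contamination, doses, panel = variant_panel(),
                         coding = c("dominant", "additive"),
                         summary = c("mean", "max", "count")) {
  coding <- match.arg(coding)
  summary <- match.arg(summary)
  foods <- food_items()
  cons_cols <- paste0("cons_", foods)
  need <- c("id", "village", "age", "weight", "smoking", "alcohol", cons_cols)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- !stats::complete.cases(cohort[, need])
  if (any(bad)) {
    stop("missing predictor inputs for individual(s): ",
         paste(cohort$id[bad], collapse = ", "))
  }
  scores <- cluster_scores(cohort, panel, coding = coding)
  pest <- pesticide_groups()
  metals <- heavy_metal_groups()
  adi <- doses$adi[pest]
  edi <- individual_edi(cohort, contamination, groups = pest)
  mpc_mat <- matrix(NA_real_, length(foods), length(c(pest, metals)),
                    dimnames = list(foods, c(pest, metals)))
  idx <- cbind(match(doses$mpc$food, foods), match(doses$mpc$group, colnames(mpc_mat)))
  keep <- !is.na(idx[, 1]) & !is.na(idx[, 2])
  mpc_mat[idx[keep, , drop = FALSE]] <- doses$mpc$mpc[keep]

  x2 <- x3 <- x4 <- numeric(nrow(cohort))
  for (v in unique(cohort$village)) {
    cmat <- contamination_matrix(contamination, v, c(pest, metals))
    fe <- cmat / mpc_mat
    food_pest <- vapply(foods, function(f) summarise_cells(fe[f, pest], summary),
                        numeric(1))
    food_metal <- vapply(foods, function(f) summarise_cells(fe[f, metals], summary),
                         numeric(1))
    rows <- which(cohort$village == v)
    consumption <- as.matrix(cohort[rows, cons_cols, drop = FALSE])
    tot <- rowSums(consumption)
    w <- consumption / ifelse(tot > 0, tot, 1)
    x2[rows] <- drop(w %*% food_pest)
    x4[rows] <- drop(w %*% food_metal)
  }
  with_adi <- pest[!is.na(adi)]
  fe_adi <- sweep(as.matrix(edi[, with_adi, drop = FALSE]), 2,
                  adi[with_adi], "/")
  x3 <- apply(fe_adi, 1, function(r) summarise_cells(r, summary))

  out <- data.frame(
    id = cohort$id,
    village = cohort$village,
    age = cohort$age,
    pest_mpc_excess = x2,
    pest_adi_excess = x3,
    metal_mpc_excess = x4,
    repair_score = scores$repair_score,
    detox_score = scores$detox_score,
    antioxidant_score = scores$antioxidant_score,
    smoking = cohort$smoking,
    alcohol = cohort$alcohol,
    stringsAsFactors = FALSE
  )
  for (col in c("health_latent", "health_rank", "genetic_latent", "aberration_pct")) {
    if (col %in% names(cohort)) out[[col]] <- cohort[[col]]
  }
  out
}

#' Fit the multivariate linear risk model
#'
#' Ordinary least squares of an outcome on the nine risk predictors, with
#' classical homoskedastic standard errors, per-coefficient t-statistics
#' t_i = b_i / SE(b_i), the determination coefficient R^2, the adjusted
#' R^2 = 1 - (1 - R^2)(n - 1)/(n - m - 1), and the per-factor influence
#' decomposition of [influence_shares()].
#'
#' @param design Design data.frame from [build_design()] (or any data.frame
#'   containing the nine predictor columns).
#' @param outcome Outcome column name in `design`, or a numeric vector of
#'   length `nrow(design)`.
#' @param robust Use heteroskedasticity-consistent (HC1 sandwich) standard
#'   errors instead of the classical homoskedastic ones. Defaults off — the
#'   reference analysis uses classical errors.
#' @return Object of class `risk_fit`: `coefficients`, `se`, `t`, `r2`,
#'   `r2_adj`, `n`, `m`, `sigma`, `influence_pct` and the underlying `lm`
#'   fit.
#' @export
fit_risk_model <- function(design, outcome, robust = FALSE) {
  X <- design_matrix(design)
  y <- if (is.character(outcome)) {
    if (!outcome %in% names(design)) stop("no outcome column '", outcome, "'")
    design[[outcome]]
  } else {
    as.numeric(outcome)
  }
  if (length(y) != nrow(X)) stop("outcome length does not match design")
  n <- nrow(X)
  m <- ncol(X)
  if (n <= m + 1) stop("need n > m + 1 observations")
  dat <- data.frame(.y = y, X)
  fit <- stats::lm(.y ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  coefs <- stats::coef(fit)
  names(coefs) <- c("intercept", risk_predictors())
  if (robust) {
    # HC1 sandwich: (X'X)^-1 X' diag(e^2) X (X'X)^-1 * n/(n - k)
    Xi <- cbind(1, X)
    e <- stats::residuals(fit)
    xtx_inv <- solve(crossprod(Xi))
    meat <- crossprod(Xi * e)
    vc <- xtx_inv %*% meat %*% xtx_inv * n / (n - m - 1)
    se <- sqrt(diag(vc))
  } else {
    se <- sm$coefficients[, "Std. Error"]
  }
  names(se) <- names(coefs)
  tval <- coefs / se
  r2 <- sm$r.squared
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - m - 1)
  out <- structure(list(
    coefficients = coefs,
    se = se,
    t = tval,
    r2 = r2,
    r2_adj = r2_adj,
    n = n,
    m = m,
    sigma = sm$sigma,
    lm_fit = fit
  ), class = "risk_fit")
  out$influence_pct <- influence_shares(out)
  out
}

#' @export
print.risk_fit <- function(x, ...) {
  cat(sprintf("Nine-factor linear risk model (n = %d, m = %d)\n", x$n, x$m))
  tab <- data.frame(
    estimate = round(x$coefficients, 5),
    se = round(x$se, 5),
    t = round(x$t, 3)
  )
  print(tab)
  cat(sprintf("R^2 = %.4f, adjusted R^2 = %.4f\n", x$r2, x$r2_adj))
  invisible(x)
}

#' Per-coefficient significance against a fixed critical value
#'
#' A coefficient is declared significant when |t_i| exceeds the critical
#' value. The study's fixed critical values (2.263 for the health model,
#' 2.693 for the genetic model; see [critical_values()]) are supplied
#' constants, not recomputed Student quantiles.
#'
#' @param fit A `risk_fit`.
#' @param critical_value Positive scalar threshold.
#' @return Named logical vector over the coefficients.
#' @export
coefficient_significance <- function(fit, critical_value) {
  stopifnot(inherits(fit, "risk_fit"), critical_value > 0)
  abs(fit$t) > critical_value
}

#' Per-factor influence shares
#'
#' Decomposes the explained variability (100 * R^2 percent) over the nine
#' factors. The default uses squared semipartial correlations,
#' sr_i^2 = t_i^2 (1 - R^2)/(n - m - 1), rescaled so the shares sum exactly
#' to 100 * R^2; with mutually orthogonal predictors each share reduces to
#' the predictor's marginal 100 * r^2. The `"sequential"` alternative
#' rescales the Type I (sequential) sums of squares, which depends on the
#' predictor order. The decomposition method used for the original study is
#' not recorded; the semipartial default is this package's choice.
#'
#' @param fit A `risk_fit`.
#' @param method `"semipartial"` (default) or `"sequential"`.
#' @return Named numeric vector of shares (percent), summing to 100 * R^2.
#' @export
influence_shares <- function(fit, method = c("semipartial", "sequential")) {
  stopifnot(inherits(fit, "risk_fit"))
  method <- match.arg(method)
  if (method == "semipartial") {
    t_sl <- fit$t[risk_predictors()]
    raw <- t_sl^2 * (1 - fit$r2) / (fit$n - fit$m - 1)
  } else {
    ss <- stats::anova(fit$lm_fit)
    raw <- ss[risk_predictors(), "Sum Sq"]
    names(raw) <- risk_predictors()
  }
  total <- sum(raw)
  if (total == 0) raw * 0 else raw / total * 100 * fit$r2
}

#' Predict a risk score from a coefficient vector
#'
#' The linear score beta0 + beta . x, usable with the published coefficient
#' vectors ([risk_weights()]) or any fitted ones.
#'
#' @param x Numeric vector of the nine predictors (in [risk_predictors()]
#'   order), a matrix with nine columns, or a data.frame containing the nine
#'   predictor columns.
#' @param weights Length-10 coefficient vector, intercept first.
#' @return Numeric score(s).
#' @export
predict_risk <- function(x, weights) {
  if (length(weights) != 10) stop("weights must have length 10 (intercept + 9 slopes)")
  if (is.data.frame(x)) x <- design_matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 9) stop("x must supply nine predictor values")
    x <- matrix(x, nrow = 1)
  }
  unname(drop(weights[1] + x %*% weights[-1]))
}

#' Mean-threshold predictive ability
#'
#' Binarizes the predicted scores at their arithmetic mean and the observed
#' outcomes at theirs (above the mean = higher risk), and returns the
#' fraction of individuals with concordant labels. Undefined (returned as
#' `NA` with a warning) when either vector has zero variance.
#'
#' @param scores Predicted risk scores.
#' @param observed Observed outcome values, same length.
#' @return Proportion concordant in \[0, 1\], or `NA`.
#' @export
predictive_ability <- function(scores, observed) {
  if (length(scores) != length(observed)) stop("length mismatch")
  if (length(scores) < 2) stop("need at least two observations")
  if (stats::var(scores) == 0 || stats::var(observed) == 0) {
    warning("zero variance in scores or outcomes; predictive ability undefined")
    return(NA_real_)
  }
  mean((scores > mean(scores)) == (observed > mean(observed)))
}
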