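#' Food items covered by the dietary survey
#'
#' The seven food products analysed for pesticide and heavy-metal residues:
#' meat, cucumbers, tomatoes, peppers, apples, pears and milk. Milk is
#' consumed in L/day and treated as kg/day with density 1.
#'
#' @return Character vector of length 7.
#' @export
food_items <- function() {
  c("meat", "cucumbers", "tomatoes", "peppers", "apples", "pears", "milk")
}

#' Contaminant groups
#'
#' Detected organochlorine pesticides are pooled into six groups by chemical
#' structure (DDT, HCB, HCH, aldrin, endosulfan, heptachlor); eight heavy
#' metals are tracked individually.
#'
#' @return Character vectors naming the groups.
#' @export
pesticide_groups <- function() {
  c("DDT", "HCB", "HCH", "aldrin", "endosulfan", "heptachlor")
}

#' @rdname pesticide_groups
#' @export
heavy_metal_groups <- function() {
  c("Cu", "Zn", "Ni", "Co", "As", "Pb", "Cd", "Cr")
}

#' @rdname pesticide_groups
#' @export
contaminant_groups <- function() {
  data.frame(
    group = c(pesticide_groups(), heavy_metal_groups()),
    kind = rep(c("pesticide", "heavy_metal"), c(6L, 8L)),
    stringsAsFactors = FALSE
  )
}

#' Default variant panel
#'
#' The 21-marker susceptibility panel: 4 DNA-repair SNVs (XRCC3, XRCC1 x2,
#' XPD), 9 xenobiotic-detoxification markers (CYP1A1, CYP2B6, CYP2D6,
#' CYP2C19, GSTT1 and GSTM1 whole-gene deletions, GSTP1 x3) and 8
#' antioxidant-defence SNVs (SOD1 x2, NFE2L3, GPX4, GCLM, GCLC x3).
#' `risk_allele_freq` is the population frequency of the non-functional (risk)
#' allele used by the simulator; for the deletion markers it is the null-allele
#' frequency under the Hardy-Weinberg square-root estimator.
#'
#' @return A data.frame with columns `rsid`, `gene`, `cluster`
#'   (`repair`/`detox`/`antioxidant`), `marker_model`
#'   (`codominant`/`dominant_deletion`) and `risk_allele_freq`.
#' @export
variant_panel <- function() {
  p <- data.frame(
    rsid = c(
      "rs861539", "rs1799782", "rs25487", "rs13181",
      "rs17861084", "rs8192718", "rs186133763", "rs11592737",
      "GSTT1_del", "GSTM1_del", "rs1138272", "rs1695", "rs1871042",
      "rs138002121", "rs1041740", "rs2237329", "rs713041",
      "rs41303970", "rs12524550", "rs3799694", "rs524553"
    ),
    gene = c(
      "XRCC3", "XRCC1", "XRCC1", "XPD",
      "CYP1A1", "CYP2B6", "CYP2D6", "CYP2C19",
      "GSTT1", "GSTM1", "GSTP1", "GSTP1", "GSTP1",
      "SOD1", "SOD1", "NFE2L3", "GPX4",
      "GCLM", "GCLC", "GCLC", "GCLC"
    ),
    cluster = rep(c("repair", "detox", "antioxidant"), c(4L, 9L, 8L)),
    marker_model = "codominant",
    stringsAsFactors = FALSE
  )
  p$marker_model[p$rsid %in% c("GSTT1_del", "GSTM1_del")] <- "dominant_deletion"
  counts <- genotype_counts_table()
  freq <- vapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    if (r$marker_model == "codominant") {
      allele_freq_codominant(r$n_AA, r$n_AB, r$n_BB)[["pB"]]
    } else {
      allele_freq_dominant(r$n_positive, r$n_null)[["pMinus"]]
    }
  }, numeric(1))
  p$risk_allele_freq <- freq[match(p$rsid, counts$rsid)]
  p
}

#' Study genotype counts
#'
#' Per-variant genotype counts observed in the surveyed cohort (151
#' individuals genotyped for SNVs; deletion markers assayed on the larger
#' blood-donor set). Codominant markers carry `n_AA`/`n_AB`/`n_BB`
#' (A = ancestral, B = risk allele); deletion markers carry
#' `n_positive` (+/+ or +/-) and `n_null` (-/-).
#'
#' @return A data.frame with one row per panel variant.
#' @export
genotype_counts_table <- function() {
  path <- system.file("extdata", "genotype_counts.csv", package = "ocprisk")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "genotype_counts.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published risk-equation coefficients
#'
#' The two nine-factor linear risk equations proposed for this population.
#' Predictors: X1 age (years), X2 mean pesticide MPC fold-excess, X3 mean
#' pesticide ADI fold-excess of individual daily intakes, X4 mean heavy-metal
#' MPC fold-excess, X5-X7 gene-cluster scores (DNA repair, detoxification,
#' antioxidant defence), X8 smoking, X9 alcohol.
#'
#' @param model `"health"` (chronic-disease rank outcome) or `"genetic"`
#'   (chromosomal-aberration percentage outcome).
#' @return Named numeric vector of length 10: intercept plus nine slopes.
#' @export
risk_weights <- function(model = c("health", "genetic")) {
  model <- match.arg(model)
  nm <- c("intercept", "age", "pest_mpc_excess", "pest_adi_excess",
          "metal_mpc_excess", "repair_score", "detox_score",
          "antioxidant_score", "smoking", "alcohol")
  w <- switch(model,
    health  = c(0.2975, 0.0038, -0.0336, 0.8601, -0.282,
                0.09607, 0.5485, 0.2119, -0.3557, 0.1533),
    genetic = c(2.4756, -0.01415, 0.7166, -0.8569, -0.1146,
                1.1351, 0.2174, -0.7496, 0.9268, 0.2767)
  )
  names(w) <- nm
  w
}

#' Critical t-values used for coefficient significance
#'
#' The study's fixed critical values: 2.263 for the health model and 2.693
#' for the genetic model. They are treated as supplied constants (their
#' derivation is not recoverable) and can be overridden wherever used.
#'
#' @return Named numeric vector.
#' @export
critical_values <- function() {
  c(health = 2.263, genetic = 2.693)
}

# Reported whole-model anchors from the source study; used only as
# calibration targets for the simulator, never as expected outputs.
#' Calibration anchors for the simulator
#'
#' Whole-model summary values reported for the original cohort: determination
#' coefficients of the two fitted risk models and the predictive-ability
#' counts. The simulator calibrates its outcome noise so that refitting the
#' model on synthetic cohorts reproduces the determination coefficients on
#' average; none of these values is a reproducible target at the individual
#' level because the underlying data are not public.
#'
#' @return Named list.
#' @export
calibration_anchors <- function() {
  list(
    r2_health = 0.2474,
    r2_genetic = 0.1424,
    predictive_hits_health = 108L,
    predictive_hits_genetic = 104L,
    n_analysis = 151L,
    n_donors = 191L
  )
}
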