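#' Estimated daily intake of a contaminant
#'
#' EDI = C * Cons / Bw, in mg per kg body weight per day. Vectorised over all
#' arguments; summing per-food EDIs gives the contaminant-group total.
#'
#' @param concentration Mean contaminant concentration in the food, mg/kg.
#' @param consumption Daily consumption of the food, kg/day.
#' @param body_weight Body weight, kg (> 0).
#' @return EDI in mg/kg-bw/day.
#' @export
compute_edi <- function(concentration, consumption, body_weight) {
  if (any(body_weight <= 0, na.rm = TRUE)) stop("body_weight must be > 0")
  if (any(concentration < 0, na.rm = TRUE) || any(consumption < 0, na.rm = TRUE)) {
    stop("concentration and consumption must be >= 0")
  }
  concentration * consumption / body_weight
}

#' Lifetime-averaged estimated daily intake
#'
#' EDI = C * IR * (EF/365) * ED / (Bw * AT). The exposure frequency EF
#' (days/year) enters as the dimensionless fraction EF/365 so the result
#' keeps units of mg/kg-bw/day and is directly comparable to an ADI; with
#' EF = 365 and ED = AT this reduces to [compute_edi()].
#'
#' @param concentration Contaminant concentration, mg/kg.
#' @param ingestion_rate Food ingestion rate, kg/day.
#' @param exposure_frequency Days of exposure per year (default 365).
#' @param exposure_duration Exposure duration, days.
#' @param body_weight Body weight, kg (> 0).
#' @param averaging_time Averaging time, days (default 25550, i.e. 70 years,
#'   the carcinogenic-risk convention).
#' @return EDI in mg/kg-bw/day.
#' @export
compute_edi_lifetime <- function(concentration, ingestion_rate,
                                 exposure_frequency = 365,
                                 exposure_duration,
                                 body_weight,
                                 averaging_time = 25550) {
  if (any(averaging_time <= 0)) stop("averaging_time must be > 0")
  if (any(body_weight <= 0)) stop("body_weight must be > 0")
  concentration * ingestion_rate * (exposure_frequency / 365) *
    exposure_duration / (body_weight * averaging_time)
}

#' Estimated short-term intake
#'
#' ESTI = sum over foods of (full portion mass * highest residue level)
#' divided by the mean body weight: the single-sitting intake used for acute
#' risk against the ARfD.
#'
#' @param portions Named numeric vector: full-portion mass per food, kg.
#' @param highest_residue Named numeric vector: highest residue level (HR:P)
#'   per food, mg/kg; must cover every food in `portions`.
#' @param mean_body_weight Mean body weight, kg (> 0).
#' @return ESTI in mg/kg-bw/day.
#' @export
compute_esti <- function(portions, highest_residue, mean_body_weight) {
  if (mean_body_weight <= 0) stop("mean_body_weight must be > 0")
  foods <- names(portions)
  if (is.null(foods)) stop("portions must be a named vector")
  missing_hr <- setdiff(foods, names(highest_residue)[!is.na(highest_residue)])
  if (length(missing_hr) > 0) {
    stop("highest residue level missing for: ", paste(missing_hr, collapse = ", "))
  }
  sum(portions * highest_residue[foods]) / mean_body_weight
}

#' Hazard quotients and hazard indices
#'
#' Chronic indices compare the estimated daily intake with the acceptable
#' daily intake: HQ = HI_ratio = EDI/ADI, and the percentage forms
#' cHQ = HI_pct = 100 * EDI/ADI (the two chronic percentage definitions
#' coincide). The acute index compares the estimated short-term intake with
#' the acute reference dose: aHQ = 100 * ESTI/ARfD. A food/group is flagged
#' hazardous when HI_ratio exceeds 1.0 (strictly; at exactly 1.0 it is not
#' flagged). Indices whose reference dose is absent are returned as `NA`
#' (not computable), never as 0.
#'
#' @param edi Estimated daily intake, mg/kg-bw/day.
#' @param adi Acceptable daily intake, mg/kg-bw/day, or `NA` if none exists
#'   for the group.
#' @param esti Estimated short-term intake, mg/kg-bw/day (optional).
#' @param arfd Acute reference dose, mg/kg-bw/day, or `NA`.
#' @return data.frame with columns `hq`, `hi_ratio`, `hi_pct`, `chq_pct`,
#'   `ahq_pct` and logical `hazardous`.
#' @export
hazard_indices <- function(edi, adi = NA_real_, esti = NA_real_, arfd = NA_real_) {
  if (any(edi < 0, na.rm = TRUE)) stop("edi must be >= 0")
  if (any(adi <= 0, na.rm = TRUE) || any(arfd <= 0, na.rm = TRUE)) {
    stop("reference doses must be > 0 where present")
  }
  hq <- ifelse(is.na(adi), NA_real_, edi / adi)
  ahq <- ifelse(is.na(arfd) | is.na(esti), NA_real_, 100 * esti / arfd)
  data.frame(
    hq = hq,
    hi_ratio = hq,
    hi_pct = 100 * hq,
    chq_pct = 100 * hq,
    ahq_pct = ahq,
    hazardous = !is.na(hq) & hq > 1
  )
}

#' Maximum-permissible-concentration fold-excess
#'
#' @param concentration Measured concentration, mg/kg.
#' @param mpc Maximum permissible concentration, mg/kg (> 0), or `NA` when no
#'   limit is defined (result is `NA`, never 0).
#' @return data.frame with `fold_excess` = concentration/MPC and logical
#'   `excess` (strictly above 1).
#' @export
mpc_excess <- function(concentration, mpc) {
  if (any(concentration < 0, na.rm = TRUE)) stop("concentration must be >= 0")
  if (any(mpc <= 0, na.rm = TRUE)) stop("mpc must be > 0 where present")
  fold <- ifelse(is.na(mpc), NA_real_, concentration / mpc)
  data.frame(fold_excess = fold, excess = !is.na(fold) & fold > 1)
}

# Look up concentrations for one village as a (food x group) matrix.
contamination_matrix <- function(contamination, village = NULL,
                                 groups = contaminant_groups()$group) {
  if ("village" %in% names(contamination) && !is.null(village)) {
    contamination <- contamination[contamination$village == village, ]
  }
  m <- matrix(NA_real_, nrow = length(food_items()), ncol = length(groups),
              dimnames = list(food_items(), groups))
  idx <- cbind(match(contamination$food, food_items()),
               match(contamination$group, groups))
  keep <- !is.na(idx[, 1]) & !is.na(idx[, 2])
  m[idx[keep, , drop = FALSE]] <- contamination$concentration[keep]
  m
}

#' Per-individual estimated daily intake by contaminant group
#'
#' For each individual, sums C * cons / bw over the seven foods for every
#' contaminant group, using the individual's own consumption and body weight.
#' Missing concentration cells propagate as `NA` for the group (never
#' silently zero) unless every cell of the group is missing everywhere.
#'
#' @param cohort Cohort data.frame with `id`, `village`, `weight` and
#'   `cons_<food>` columns.
#' @param contamination Long-format contamination table with columns `food`,
#'   `group`, `concentration` and optionally `village`.
#' @param groups Contaminant groups to evaluate (default: all 14).
#' @return data.frame with `id`, `village` and one EDI column per group.
#' @export
individual_edi <- function(cohort, contamination,
                           groups = contaminant_groups()$group) {
  cons_cols <- paste0("cons_", food_items())
  missing <- setdiff(c("id", "village", "weight", cons_cols), names(cohort))
  if (length(missing) > 0) {
    stop("cohort lacks columns: ", paste(missing, collapse = ", "))
  }
  out <- cohort[, c("id", "village")]
  for (g in groups) out[[g]] <- NA_real_
  for (v in unique(cohort$village)) {
    cmat <- contamination_matrix(contamination, v, groups)
    rows <- which(cohort$village == v)
    consumption <- as.matrix(cohort[rows, cons_cols, drop = FALSE])
    for (g in groups) {
      # a missing concentration only matters for foods actually consumed
      terms <- sweep(consumption, 2, cmat[, g], "*")
      terms[consumption == 0] <- 0
      out[rows, g] <- rowSums(terms) / cohort$weight[rows]
    }
  }
  out
}

#' Per-village cohort exposure summary
#'
#' Mean and standard deviation of group-wise daily intakes per village.
#' In `"individual"` mode each surveyed person's own consumption and body
#' weight are used (the food-habits-aware summary); in `"cohort-norm"` mode a
#' single standard consumption norm per food and the village mean body weight
#' are used, and the spread reported is across the per-food intake
#' contributions.
#'
#' @param cohort Cohort data.frame.
#' @param contamination Long-format contamination table.
#' @param mode `"individual"` or `"cohort-norm"`.
#' @param norms Named numeric vector of standard daily consumption per food
#'   (kg/day), required in `"cohort-norm"` mode.
#' @param groups Contaminant groups to summarise (default: the six pesticide
#'   groups).
#' @return data.frame with `village`, `group`, `mean_edi`, `sd_edi`, `n`.
#' @export
cohort_exposure <- function(cohort, contamination,
                            mode = c("individual", "cohort-norm"),
                            norms = NULL,
                            groups = pesticide_groups()) {
  mode <- match.arg(mode)
  villages <- unique(cohort$village)
  if (length(villages) == 0 || nrow(cohort) == 0) stop("empty cohort")
  rows <- list()
  if (mode == "individual") {
    edi <- individual_edi(cohort, contamination, groups)
    for (v in villages) {
      sub <- edi[edi$village == v, , drop = FALSE]
      if (nrow(sub) == 0) stop("empty village: ", v)
      for (g in groups) {
        rows[[length(rows) + 1]] <- data.frame(
          village = v, group = g,
          mean_edi = mean(sub[[g]]),
          sd_edi = if (nrow(sub) > 1) stats::sd(sub[[g]]) else 0,
          n = nrow(sub), stringsAsFactors = FALSE
        )
      }
    }
  } else {
    if (is.null(norms)) stop("cohort-norm mode requires a consumption norm table")
    norms <- norms[food_items()]
    if (any(is.na(norms))) stop("norms must cover all seven foods")
    for (v in villages) {
      bw <- mean(cohort$weight[cohort$village == v])
      if (!is.finite(bw)) stop("empty village: ", v)
      cmat <- contamination_matrix(contamination, v, groups)
      for (g in groups) {
        contrib <- cmat[, g] * norms / bw
        contrib[norms == 0] <- 0
        rows[[length(rows) + 1]] <- data.frame(
          village = v, group = g,
          mean_edi = sum(contrib),
          sd_edi = stats::sd(contrib),
          n = sum(cohort$village == v), stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
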