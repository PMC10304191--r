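cohort_required_cols <- function() {
  c("id", "village", "sex", "age", "weight", "smoking", "alcohol",
    paste0("cons_", food_items()))
}

#' Write a cohort table to CSV
#'
#' Plain CSV with an explicit `NA` token, one row per individual, full
#' numeric precision (reports, not raw outputs, apply display rounding).
#' Round-trips losslessly through [read_cohort()].
#'
#' @param cohort Cohort data.frame.
#' @param path Output file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read and validate a cohort table
#'
#' Checks the schema (required demographic and consumption columns), types,
#' and row-level validity: body weight must be positive and numeric,
#' consumption non-negative; offending rows are reported by row number.
#'
#' @param path CSV file written by [write_cohort()] or following its schema.
#' @param panel Variant panel whose genotype columns, if present, are
#'   type-checked.
#' @return Cohort data.frame.
#' @export
read_cohort <- function(path, panel = variant_panel()) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  missing_cols <- setdiff(cohort_required_cols(), names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(cohort) == 0) {
    warning("cohort file is empty (header only)")
    return(cohort)
  }
  num_cols <- c("age", "weight", paste0("cons_", food_items()))
  for (col in num_cols) {
    if (!is.numeric(cohort[[col]])) {
      stop("column '", col, "' is not numeric")
    }
  }
  bad_weight <- which(is.na(cohort$weight) | cohort$weight <= 0)
  if (length(bad_weight) > 0) {
    stop("non-positive or missing body weight in row(s): ",
         paste(bad_weight, collapse = ", "))
  }
  cons <- as.matrix(cohort[, paste0("cons_", food_items())])
  bad_cons <- which(apply(cons, 1, function(r) any(is.na(r) | r < 0)))
  if (length(bad_cons) > 0) {
    stop("negative or missing consumption in row(s): ",
         paste(bad_cons, collapse = ", "))
  }
  for (rsid in intersect(panel$rsid, names(cohort))) {
    model <- panel$marker_model[panel$rsid == rsid]
    g <- cohort[[rsid]]
    if (model == "codominant") {
      if (!all(is.na(g) | g %in% c(0, 1, 2))) {
        stop("invalid genotype codes in column '", rsid, "'")
      }
    } else {
      if (!all(is.na(g) | g %in% c("+", "-"))) {
        stop("invalid deletion phenotype codes in column '", rsid, "'")
      }
    }
  }
  cohort
}

#' Read/write a long-format contamination table
#'
#' Columns: optional `village`, then `food`, `group`, `concentration`
#' (mg/kg); missing cells are explicit `NA`, never silently zero.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_contamination <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("food", "group", "concentration")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("contamination file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(x$concentration < 0, na.rm = TRUE)) stop("negative concentration")
  x
}

#' @rdname read_contamination
#' @param contamination Contamination data.frame.
#' @export
write_contamination <- function(contamination, path) {
  utils::write.csv(contamination, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a reference-dose table
#'
#' CSV with columns `group`, `adi` and optionally `arfd` (mg/kg-bw/day,
#' `NA` where no reference value exists). Groups not listed keep `NA`.
#' The remaining reference quantities (MPC table, exposure constants,
#' portion masses) are taken from `base` and can be overridden there.
#'
#' @param path CSV file path.
#' @param base Reference-dose list to fill in (default
#'   [default_reference_doses()]).
#' @return Reference-dose list, see [default_reference_doses()].
#' @export
read_reference_doses <- function(path, base = default_reference_doses()) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", "-"))
  if (!all(c("group", "adi") %in% names(x))) {
    stop("reference-dose file needs columns 'group' and 'adi'")
  }
  if (any(x$adi <= 0, na.rm = TRUE)) stop("ADI must be > 0 where present")
  doses <- base
  doses$adi[x$group] <- x$adi
  if ("arfd" %in% names(x)) {
    if (any(x$arfd <= 0, na.rm = TRUE)) stop("ARfD must be > 0 where present")
    doses$arfd[x$group] <- x$arfd
  }
  doses
}

#' Run the full risk-assessment pipeline
#'
#' Executes the enabled stages in dependency order — simulate (or load) the
#' cohort, per-village exposure and hazard tables, the genotype summary, the
#' two model fits and the predicted individual scores — writing every
#' intermediate table as CSV under `out_dir` plus a plain-text log. Identical
#' configuration and seed give byte-identical outputs.
#'
#' @param config An [simulation_config()] object.
#' @param out_dir Output directory (created if needed); `NULL` writes nothing.
#' @param stages Character subset of
#'   `c("simulate", "exposure", "genetics", "fit", "predict")`.
#' @param cohort Optional pre-built cohort (skips the simulate stage).
#' @return Invisible list: the risk report (`cohort`, `exposure_individual`,
#'   `exposure_norm`, `hazard`, `genetics`, `fit_health`, `fit_genetic`,
#'   `predictions`, `predictive_ability`).
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         stages = c("simulate", "exposure", "genetics",
                                    "fit", "predict"),
                         cohort = NULL) {
  stopifnot(inherits(config, "ocprisk_config"))
  all_stages <- c("simulate", "exposure", "genetics", "fit", "predict")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  deps <- list(fit = c("exposure", "genetics"), predict = "fit")
  for (s in intersect(names(deps), stages)) {
    lacking <- setdiff(deps[[s]], stages)
    if (length(lacking) > 0) {
      stop("stage '", s, "' requires stage(s): ", paste(lacking, collapse = ", "))
    }
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(obj, name) {
    if (!is.null(out_dir)) {
      utils::write.csv(obj, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE, na = "NA")
    }
  }
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("stages: %s", paste(stages, collapse = ",")))
  report <- list()

  if (is.null(cohort)) {
    if (!"simulate" %in% stages) stop("no cohort supplied and simulate stage disabled")
    cohort <- simulate_cohort(config)
    cohort <- simulate_outcomes(cohort, config)
  }
  report$cohort <- cohort
  log_lines <- c(log_lines, sprintf("cohort rows: %d", nrow(cohort)))
  emit(cohort, "cohort")
  analysis <- cohort[cohort$questionnaire %in% c(TRUE, NA), , drop = FALSE]

  if ("exposure" %in% stages) {
    report$exposure_individual <- cohort_exposure(
      analysis, config$contamination, mode = "individual")
    # regional norm: cohort-size-weighted mean of the village consumption means
    p <- config$profiles
    norms <- vapply(food_items(), function(f) {
      stats::weighted.mean(p[[paste0("cons_", f, "_mean")]], p$n_individuals)
    }, numeric(1))
    report$exposure_norm <- cohort_exposure(
      analysis, config$contamination, mode = "cohort-norm", norms = norms)
    hz <- report$exposure_individual
    adi <- config$doses$adi[hz$group]
    report$hazard <- cbind(hz, hazard_indices(hz$mean_edi, adi = adi))
    emit(report$exposure_individual, "exposure_individual")
    emit(report$exposure_norm, "exposure_norm")
    emit(report$hazard, "hazard")
  }

  if ("genetics" %in% stages) {
    report$genetics <- genotype_summary(tabulate_genotypes(analysis, config$panel))
    emit(report$genetics, "genetics_summary")
  }

  if ("fit" %in% stages) {
    design <- build_design(analysis, config$contamination, config$doses,
                           config$panel, coding = config$coding)
    report$design <- design
    report$fit_health <- fit_risk_model(design, "health_rank")
    report$fit_genetic <- fit_risk_model(design, "aberration_pct")
    coef_tab <- data.frame(
      term = names(report$fit_health$coefficients),
      health_estimate = unname(report$fit_health$coefficients),
      health_t = unname(report$fit_health$t),
      genetic_estimate = unname(report$fit_genetic$coefficients),
      genetic_t = unname(report$fit_genetic$t)
    )
    emit(design, "design")
    emit(coef_tab, "coefficients")
    log_lines <- c(log_lines,
                   sprintf("fit n: %d", report$fit_health$n),
                   sprintf("health R2: %.6f", report$fit_health$r2),
                   sprintf("genetic R2: %.6f", report$fit_genetic$r2))
  }

  if ("predict" %in% stages) {
    design <- report$design
    pred <- data.frame(
      id = design$id,
      health_score = predict_risk(design, report$fit_health$coefficients),
      genetic_score = predict_risk(design, report$fit_genetic$coefficients)
    )
    pred$health_high_risk <- pred$health_score > mean(pred$health_score)
    pred$genetic_high_risk <- pred$genetic_score > mean(pred$genetic_score)
    report$predictions <- pred
    report$predictive_ability <- c(
      health = predictive_ability(pred$health_score, design$health_rank),
      genetic = predictive_ability(pred$genetic_score, design$aberration_pct)
    )
    emit(pred, "predictions")
    log_lines <- c(log_lines,
                   sprintf("predictive ability health: %.4f",
                           report$predictive_ability[["health"]]),
                   sprintf("predictive ability genetic: %.4f",
                           report$predictive_ability[["genetic"]]))
  }

  if (!is.null(out_dir)) {
    writeLines(log_lines, file.path(out_dir, "log.txt"))
  }
  invisible(report)
}
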