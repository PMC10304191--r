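#' Allele frequencies from codominant genotype counts
#'
#' @param n_aa,n_ab,n_bb Non-negative integer genotype counts (A = ancestral
#'   allele, B = polymorphic/risk allele).
#' @return Named numeric vector `c(pA, pB)` with `pA + pB == 1`.
#' @export
allele_freq_codominant <- function(n_aa, n_ab, n_bb) {
  counts <- c(n_aa, n_ab, n_bb)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("genotype counts must be non-negative and non-missing")
  }
  n <- sum(counts)
  if (n == 0) stop("total genotype count is zero")
  pA <- (2 * n_aa + n_ab) / (2 * n)
  c(pA = pA, pB = 1 - pA)
}

#' Allele frequencies for a dominant deletion marker
#'
#' Whole-gene deletions (GSTT1, GSTM1) are assayed as a binary phenotype:
#' positive (+/+ or +/-) versus null (-/-). Under Hardy-Weinberg equilibrium
#' the null-allele frequency is estimated as the square root of the null
#' phenotype proportion.
#'
#' @param n_positive,n_null Non-negative phenotype counts.
#' @return Named numeric vector `c(pPlus, pMinus, null_phenotype_freq)`; the
#'   raw null-phenotype proportion is reported alongside because the two can
#'   legitimately disagree when HWE does not hold.
#' @export
allele_freq_dominant <- function(n_positive, n_null) {
  if (any(is.na(c(n_positive, n_null))) || n_positive < 0 || n_null < 0) {
    stop("phenotype counts must be non-negative and non-missing")
  }
  n <- n_positive + n_null
  if (n == 0) stop("total phenotype count is zero")
  q <- sqrt(n_null / n)
  c(pPlus = 1 - q, pMinus = q, null_phenotype_freq = n_null / n)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square comparing observed genotype counts with the
#' Hardy-Weinberg expectations n*p^2, 2npq, n*q^2 computed from the observed
#' allele frequencies, without continuity correction. The default reference
#' distribution uses 2 degrees of freedom, matching the convention of the
#' source survey (its printed p-values only reproduce at df = 2); the
#' conventional df = 1 is available via `df`.
#'
#' @param n_aa,n_ab,n_bb Genotype counts.
#' @param df Degrees of freedom for the reference chi-square (default 2).
#' @return A list with `chi2`, `df`, `p_value`, `allele_freqs` (`pA`, `pB`)
#'   and `expected` counts.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb, df = 2) {
  obs <- c(AA = n_aa, AB = n_ab, BB = n_bb)
  fr <- allele_freq_codominant(n_aa, n_ab, n_bb)
  n <- sum(obs)
  p <- fr[["pA"]]
  q <- fr[["pB"]]
  expected <- n * c(AA = p^2, AB = 2 * p * q, BB = q^2)
  if (any(expected == 0 & obs > 0)) {
    warning("expected count of zero with non-zero observed count; statistic is infinite")
    chi2 <- Inf
  } else {
    keep <- expected > 0
    chi2 <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  }
  list(
    chi2 = chi2,
    df = df,
    p_value = stats::pchisq(chi2, df = df, lower.tail = FALSE),
    allele_freqs = fr[c("pA", "pB")],
    expected = expected
  )
}

#' Sample-level genotyping quality control
#'
#' Samples with a call rate (fraction of successfully genotyped markers)
#' strictly below 98% are excluded.
#'
#' @param call_rate Numeric in \[0, 1\] (vectorised).
#' @return Logical: `TRUE` to keep, `FALSE` to drop.
#' @export
sample_qc <- function(call_rate) {
  if (any(is.na(call_rate)) || any(call_rate < 0 | call_rate > 1)) {
    stop("call_rate must be within [0, 1]")
  }
  call_rate >= 0.98
}

#' Per-variant risk score from a genotype call
#'
#' Scores a genotype 0 (fully functional protein, no risk) or 1 (at least one
#' non-functional allele present). The default dominant coding assigns 1 to
#' heterozygous carriers of codominant markers; the additive option scores
#' risk-allele dosage / 2 for sensitivity analysis. Deletion markers are
#' phenotype-only: 1 is assigned only to the null (-/-) call, since a
#' heterozygous deletion cannot be distinguished from +/+ by the assay.
#'
#' @param genotype For codominant markers, risk-allele copy number 0/1/2; for
#'   deletion markers the phenotype code `"+"` (positive) or `"-"` (null).
#' @param marker_model `"codominant"` or `"dominant_deletion"`.
#' @param coding `"dominant"` (default) or `"additive"`.
#' @return Numeric score in \[0, 1\]; `NA` input gives `NA`.
#' @export
genotype_score <- function(genotype, marker_model = c("codominant", "dominant_deletion"),
                           coding = c("dominant", "additive")) {
  marker_model <- match.arg(marker_model)
  coding <- match.arg(coding)
  if (length(genotype) != 1) {
    return(vapply(genotype, genotype_score, numeric(1),
                  marker_model = marker_model, coding = coding))
  }
  if (is.na(genotype)) return(NA_real_)
  if (marker_model == "codominant") {
    g <- suppressWarnings(as.numeric(genotype))
    if (is.na(g) || !g %in% c(0, 1, 2)) {
      stop("unknown codominant genotype code: ", genotype)
    }
    if (coding == "dominant") as.numeric(g >= 1) else g / 2
  } else {
    g <- as.character(genotype)
    if (!g %in% c("+", "-")) stop("unknown deletion phenotype code: ", genotype)
    as.numeric(g == "-")
  }
}

#' Gene-cluster susceptibility scores for a cohort
#'
#' For each individual, the per-cluster mean of per-variant 0/1 risk scores
#' over the non-missing panel variants of that cluster: `repair_score`,
#' `detox_score` and `antioxidant_score`, each in \[0, 1\].
#'
#' @param cohort Cohort data.frame with one genotype column per panel variant
#'   (named by `rsid`): 0/1/2 risk-allele copies for codominant markers,
#'   `"+"`/`"-"` for deletion markers.
#' @param panel Variant panel, see [variant_panel()].
#' @param coding Risk coding passed to [genotype_score()].
#' @return data.frame with `id`, the three cluster scores and per-cluster
#'   missing fractions.
#' @export
cluster_scores <- function(cohort, panel = variant_panel(),
                           coding = c("dominant", "additive")) {
  coding <- match.arg(coding)
  missing_cols <- setdiff(panel$rsid, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort lacks genotype columns: ", paste(missing_cols, collapse = ", "))
  }
  score_mat <- vapply(seq_len(nrow(panel)), function(j) {
    genotype_score(cohort[[panel$rsid[j]]],
                   marker_model = panel$marker_model[j], coding = coding)
  }, numeric(nrow(cohort)))
  if (nrow(cohort) == 1) score_mat <- matrix(score_mat, nrow = 1)
  out <- data.frame(id = cohort$id, stringsAsFactors = FALSE)
  for (cl in c("repair", "detox", "antioxidant")) {
    idx <- which(panel$cluster == cl)
    sub <- score_mat[, idx, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    if (any(n_obs == 0)) {
      stop("entire '", cl, "' cluster missing for individual(s): ",
           paste(cohort$id[n_obs == 0], collapse = ", "))
    }
    out[[paste0(cl, "_score")]] <- rowMeans(sub, na.rm = TRUE)
    out[[paste0(cl, "_missing_frac")]] <- 1 - n_obs / length(idx)
  }
  out
}

#' Genotype-table summary
#'
#' Computes, for each panel variant, the genotype counts, allele frequencies,
#' and (for codominant markers) the Hardy-Weinberg chi-square and p-value —
#' the machine-readable analogue of a population-genotyping summary table.
#' Frequencies and chi-square are additionally given rounded to 3 decimal
#' places as report columns; internal values keep full precision.
#'
#' @param counts data.frame shaped like [genotype_counts_table()].
#' @param df Degrees of freedom for the HWE test.
#' @return data.frame, one row per variant.
#' @export
genotype_summary <- function(counts = genotype_counts_table(), df = 2) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    if (r$marker_model == "codominant") {
      h <- hwe_test(r$n_AA, r$n_AB, r$n_BB, df = df)
      data.frame(
        rsid = r$rsid, gene = r$gene, cluster = r$cluster,
        marker_model = r$marker_model,
        n = r$n_AA + r$n_AB + r$n_BB,
        freq_A = h$allele_freqs[["pA"]], freq_B = h$allele_freqs[["pB"]],
        chi2 = h$chi2, p_value = h$p_value,
        stringsAsFactors = FALSE
      )
    } else {
      fr <- allele_freq_dominant(r$n_positive, r$n_null)
      data.frame(
        rsid = r$rsid, gene = r$gene, cluster = r$cluster,
        marker_model = r$marker_model,
        n = r$n_positive + r$n_null,
        freq_A = fr[["pPlus"]], freq_B = fr[["pMinus"]],
        chi2 = NA_real_, p_value = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  out$freq_A_report <- round(out$freq_A, 3)
  out$freq_B_report <- round(out$freq_B, 3)
  out$chi2_report <- round(out$chi2, 3)
  out
}

#' Tabulate genotype counts from a cohort table
#'
#' Counts genotype calls per panel variant from per-individual genotype
#' columns, producing a table shaped like [genotype_counts_table()] suitable
#' for [genotype_summary()].
#'
#' @param cohort Cohort data.frame with genotype columns named by `rsid`.
#' @param panel Variant panel.
#' @return data.frame of per-variant counts.
#' @export
tabulate_genotypes <- function(cohort, panel = variant_panel()) {
  rows <- lapply(seq_len(nrow(panel)), function(j) {
    rsid <- panel$rsid[j]
    g <- cohort[[rsid]]
    if (is.null(g)) stop("cohort lacks genotype column: ", rsid)
    if (panel$marker_model[j] == "codominant") {
      data.frame(
        rsid = rsid, gene = panel$gene[j], cluster = panel$cluster[j],
        marker_model = "codominant",
        n_AA = sum(g == 0, na.rm = TRUE),
        n_AB = sum(g == 1, na.rm = TRUE),
        n_BB = sum(g == 2, na.rm = TRUE),
        n_positive = NA_integer_, n_null = NA_integer_,
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(
        rsid = rsid, gene = panel$gene[j], cluster = panel$cluster[j],
        marker_model = "dominant_deletion",
        n_AA = NA_integer_, n_AB = NA_integer_, n_BB = NA_integer_,
        n_positive = sum(g == "+", na.rm = TRUE),
        n_null = sum(g == "-", na.rm = TRUE),
        stringsAsFactors = FALSE
      )
    }
  })
  do.call(rbind, rows)
}
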