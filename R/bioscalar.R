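#' Per-subject UP and DOWN signature scores
#'
#' Each signature gene is z-scored across all samples of the study, then
#' averaged within the UP and DOWN lists per subject. Standardization keeps
#' high-variance genes from dominating the mean and makes scores (and the
#' tertile cutoff downstream) comparable across studies; raw-scale averaging
#' is available with `standardize = FALSE`. Constant genes are dropped with
#' a warning.
#'
#' @param study an [ExpressionStudy-class].
#' @param upIDs,downIDs disjoint character vectors of signature gene ids;
#'   each must intersect the measured genes.
#' @param standardize z-score genes before averaging (default `TRUE`).
#' @return a [SignatureScores-class].
#' @export
signatureScores <- function(study, upIDs, downIDs, standardize = TRUE) {
  if (length(intersect(upIDs, downIDs)))
    stopf("input error: UP and DOWN lists must be disjoint")
  m <- assay(study)
  listMean <- function(ids, label) {
    present <- intersect(ids, rownames(m))
    if (!length(present))
      stopf("input error: no %s signature gene is measured in the study", label)
    sub <- m[present, , drop = FALSE]
    if (standardize) {
      sds <- apply(sub, 1, sd)
      if (any(sds == 0)) {
        warnf("%d constant %s gene(s) dropped", sum(sds == 0), label)
        sub <- sub[sds > 0, , drop = FALSE]
        if (!nrow(sub))
          stopf("input error: all %s signature genes are constant", label)
        sds <- sds[sds > 0]
      }
      sub <- (sub - rowMeans(sub)) / sds
    }
    list(score = colMeans(sub), n = nrow(sub))
  }
  up <- listMean(upIDs, "UP")
  dn <- listMean(downIDs, "DOWN")
  new("SignatureScores",
      sampleIDs = colnames(m),
      meanUP = unname(up$score),
      meanDOWN = unname(dn$score),
      group = groupLabels(study),
      nUp = as.integer(up$n),
      nDown = as.integer(dn$n))
}

#' Fit the coupling regression line on cases
#'
#' Least-squares regression of meanDOWN on meanUP restricted to case
#' subjects, with the Pearson correlation among cases and its two-sided
#' p-value. Controls are excluded from the fit (they are projected onto the
#' case line downstream for comparability).
#'
#' @param scores a [SignatureScores-class].
#' @return a [CouplingLine-class].
#' @export
fitCouplingLine <- function(scores) {
  case <- scores@group == "case"
  x <- scores@meanUP[case]
  y <- scores@meanDOWN[case]
  if (length(x) < 3)
    stopf("fit error: at least 3 cases are required")
  if (sd(x) == 0)
    stopf("fit error: meanUP is constant among cases")
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  if (sd(y) == 0) {
    r <- 0; pv <- 1
  } else {
    ct <- cor.test(x, y)
    r <- unname(ct$estimate); pv <- ct$p.value
  }
  new("CouplingLine", slope = slope, intercept = intercept,
      r = r, pValue = pv, nCases = as.integer(length(x)))
}

#' Project subjects onto the coupling line (the bioscalar)
#'
#' Each subject's (meanUP, meanDOWN) point is orthogonally projected onto
#' the coupling line; the bioscalar is the signed arc-length coordinate of
#' the projection measured from the line point nearest the origin, positive
#' in the direction of increasing meanUP. For a line through the origin this
#' is exactly the signed distance of the projected point from the origin.
#' All subjects (cases and controls) are projected.
#'
#' @param scores a [SignatureScores-class].
#' @param line a [CouplingLine-class], typically from [fitCouplingLine()].
#' @return a [BioscalarResult-class] with per-subject scalars; summary slots
#'   are filled by [summarizeBioscalar()].
#' @export
projectBioscalar <- function(scores, line) {
  validObject(line)
  b <- line@slope; a <- line@intercept
  # foot of the perpendicular from the origin, and unit direction of
  # increasing meanUP
  x0 <- -a * b / (1 + b^2)
  y0 <- a / (1 + b^2)
  ux <- 1 / sqrt(1 + b^2)
  uy <- b / sqrt(1 + b^2)
  s <- (scores@meanUP - x0) * ux + (scores@meanDOWN - y0) * uy
  new("BioscalarResult",
      sampleIDs = scores@sampleIDs,
      group = scores@group,
      bioscalar = unname(s),
      line = line,
      inflamed = rep(NA, length(s)))
}

#' Cohen's d standardized mean difference
#'
#' `(mean(cases) - mean(controls)) / pooledSD`, pooling with `n - 1` weights.
#'
#' @param caseValues,controlValues numeric vectors, at least 2 per group.
#' @return Cohen's d.
#' @export
cohensD <- function(caseValues, controlValues) {
  n1 <- length(caseValues); n2 <- length(controlValues)
  if (n1 < 2 || n2 < 2)
    stopf("input error: at least 2 values per group are required")
  sp2 <- ((n1 - 1) * var(caseValues) + (n2 - 1) * var(controlValues)) /
    (n1 + n2 - 2)
  if (sp2 <= 0)
    stopf("computation error: pooled standard deviation is zero")
  (mean(caseValues) - mean(controlValues)) / sqrt(sp2)
}

#' ROC area under the curve by the rank statistic
#'
#' The probability that a randomly chosen case outscores a randomly chosen
#' control, with ties counted one half (the Mann-Whitney identity).
#'
#' @param scores numeric vector.
#' @param labels case/control factor, or logical with `TRUE` = case.
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(scores, labels) {
  if (is.logical(labels)) case <- labels
  else case <- as.character(labels) == "case"
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 == 0 || n0 == 0)
    stopf("input error: both classes must be present")
  r <- rank(scores)
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Top-tertile subgroup classification
#'
#' The cutoff is the `ceiling(2n/3)`-th order statistic of the case scores
#' (nearest-rank convention); subjects strictly above it are flagged
#' "inflamed". Sensitivity is computed over the defining subgroup (the
#' top-tertile cases), and is therefore 1 by construction; specificity is
#' the fraction of controls at or below the cutoff.
#'
#' @param caseScores numeric vector of at least 3 case scores.
#' @param controlScores numeric vector of control scores.
#' @return list with `cutoff`, `inflamedCase` (logical per case),
#'   `sensitivity`, `specificity`.
#' @export
tertileClassify <- function(caseScores, controlScores) {
  n <- length(caseScores)
  if (n < 3)
    stopf("input error: at least 3 case scores are required")
  cutoff <- sort(caseScores)[ceiling(2 * n / 3)]
  inflamed <- caseScores > cutoff
  subgroup <- caseScores[inflamed]
  sens <- if (length(subgroup)) mean(subgroup > cutoff) else NA_real_
  spec <- if (length(controlScores)) mean(controlScores <= cutoff)
          else NA_real_
  list(cutoff = cutoff, inflamedCase = inflamed,
       sensitivity = sens, specificity = spec)
}

#' Fill the classification summaries of a bioscalar result
#'
#' Computes Cohen's d, the ROC AUC, the top-tertile cutoff with its
#' sensitivity/specificity, and the per-subject inflamed flags (score
#' strictly above the cutoff; ties classified non-inflamed).
#'
#' @param result a [BioscalarResult-class] from [projectBioscalar()].
#' @return the result with summary slots filled.
#' @export
summarizeBioscalar <- function(result) {
  case <- result@group == "case"
  cs <- result@bioscalar[case]
  ct <- result@bioscalar[!case]
  result@cohensD <- cohensD(cs, ct)
  result@auc <- rocAuc(result@bioscalar, case)
  tc <- tertileClassify(cs, ct)
  result@cutoff <- tc$cutoff
  result@sensitivity <- tc$sensitivity
  result@specificity <- tc$specificity
  result@inflamed <- result@bioscalar > tc$cutoff
  result
}
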