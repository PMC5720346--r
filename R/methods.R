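#' @describeIn accessors gene ids of an ExpressionStudy (rownames).
#' @export
setMethod("geneIDs", "ExpressionStudy", function(x) rownames(x))

#' @describeIn accessors case/control factor of an ExpressionStudy.
#' @export
setMethod("groupLabels", "ExpressionStudy", function(x) {
  factor(as.character(colData(x)$group), levels = c("control", "case"))
})

#' @describeIn accessors gene ids of a GeneStats object.
#' @export
setMethod("geneIDs", "GeneStats", function(x) x@geneIDs)

#' @describeIn accessors per-gene statistics as a data.frame (gene id, log2
#'   fold change, moderated t, total df, asymptotic p, permutation p).
#' @export
setMethod("statsTable", "GeneStats", function(x) {
  data.frame(geneID = x@geneIDs, logFC = x@logFC, t = x@t, df = x@df,
             pValue = x@pValue, pPerm = x@pPerm,
             stringsAsFactors = FALSE, row.names = NULL)
})

#' @describeIn accessors named vector of asymptotic p-values.
#' @export
setMethod("pValues", "GeneStats", function(x) setNames(x@pValue, x@geneIDs))

#' @describeIn accessors named vector of group log2 fold changes.
#' @export
setMethod("logFoldChanges", "GeneStats",
          function(x) setNames(x@logFC, x@geneIDs))

#' @describeIn accessors threshold grid of an OverlapProfile.
#' @export
setMethod("profileTable", "OverlapProfile", function(x) x@grid)

#' @describeIn accessors selected q2 threshold (`NA` if none).
#' @export
setMethod("q2Threshold", "OverlapProfile", function(x) x@q2)

#' @describeIn accessors q2 threshold a ConsensusSet was built at.
#' @export
setMethod("q2Threshold", "ConsensusSet", function(x) x@q2)

#' @describeIn accessors sign-concordant overexpressed genes.
#' @export
setMethod("upGenes", "ConsensusSet", function(x) x@up)

#' @describeIn accessors sign-concordant underexpressed genes.
#' @export
setMethod("downGenes", "ConsensusSet", function(x) x@down)

#' @describeIn accessors threshold-passing but sign-discordant genes.
#' @export
setMethod("discordantGenes", "ConsensusSet", function(x) x@discordant)

#' @describeIn accessors per-subject (meanUP, meanDOWN) as a data.frame.
#' @export
setMethod("signatureMeans", "SignatureScores", function(x) {
  data.frame(sampleID = x@sampleIDs, meanUP = x@meanUP, meanDOWN = x@meanDOWN,
             group = x@group, stringsAsFactors = FALSE, row.names = NULL)
})

#' @describeIn accessors group factor of SignatureScores.
#' @export
setMethod("groupLabels", "SignatureScores", function(x) x@group)

#' @describeIn accessors named per-subject bioscalar values.
#' @export
setMethod("bioscalars", "BioscalarResult",
          function(x) setNames(x@bioscalar, x@sampleIDs))

#' @describeIn accessors the CouplingLine a BioscalarResult was projected on.
#' @export
setMethod("couplingLine", "BioscalarResult", function(x) x@line)

#' @describeIn accessors restricted member lists of a GeneSetCollection.
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @describeIn accessors measurement universe of a GeneSetCollection.
#' @export
setMethod("universe", "GeneSetCollection", function(x) x@universe)

setMethod("show", "VariancePrior", function(object) {
  cat("VariancePrior: d0 =",
      if (is.infinite(object@d0)) "Inf" else format(object@d0, digits = 4),
      ", s0^2 =", format(object@s0Sq, digits = 4), "\n")
})

setMethod("show", "GeneStats", function(object) {
  cat("GeneStats for", length(object@geneIDs), "genes\n")
  cat("  moderated t with", format(object@df[1], digits = 4),
      "df; prior d0 =",
      if (is.infinite(object@prior@d0)) "Inf"
      else format(object@prior@d0, digits = 4), "\n")
  cat("  genes with p <= .05:", sum(object@pValue <= 0.05), "\n")
  if (!all(is.na(object@pPerm)))
    cat("  permutation p-values available\n")
})

setMethod("show", "OverlapProfile", function(object) {
  cat("OverlapProfile over", nrow(object@grid), "thresholds,",
      object@nGenes, "genes\n")
  if (is.na(object@q2)) {
    cat("  q2: not selected\n")
  } else {
    i <- which(object@grid$threshold == object@q2)[1]
    cat(sprintf("  q2 = %.4g (O11 = %d, E11 = %.2f, R = %.2f)\n",
                object@q2, object@grid$O11[i], object@grid$E11[i],
                object@grid$R[i]))
  }
})

setMethod("show", "ConsensusSet", function(object) {
  cat("ConsensusSet at q2 =", format(object@q2, digits = 4), "\n")
  cat("  UP:", length(object@up), " DOWN:", length(object@down),
      " discordant:", length(object@discordant), "\n")
})

setMethod("show", "CombinedTest", function(object) {
  cat("Fisher combination over", length(object@geneIDs), "genes\n")
  cat("  rejected at FDR", object@fdrLevel, ":", sum(object@rejected), "\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "terms over a universe of",
      length(object@universe), "genes\n")
})

setMethod("show", "SignatureScores", function(object) {
  cat("SignatureScores for", length(object@sampleIDs), "subjects (",
      sum(object@group == "case"), "cases );", object@nUp, "UP genes,",
      object@nDown, "DOWN genes\n")
})

setMethod("show", "CouplingLine", function(object) {
  cat(sprintf("CouplingLine (cases, n = %d): slope = %.4g, intercept = %.4g, r = %.3f\n",
              object@nCases, object@slope, object@intercept, object@r))
})

setMethod("show", "BioscalarResult", function(object) {
  cat("BioscalarResult for", length(object@sampleIDs), "subjects\n")
  if (!is.na(object@auc))
    cat(sprintf("  Cohen's d = %.3f, AUC = %.3f, tertile cutoff = %.3f, specificity = %.3f\n",
                object@cohensD, object@auc, object@cutoff,
                object@specificity))
})
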