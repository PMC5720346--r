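#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
NULL

#' ExpressionStudy: one case-control study
#'
#' An `ExpressionStudy` holds a normalized log2 expression matrix
#' (genes x samples) together with per-sample covariates, as a thin extension
#' of [SummarizedExperiment::SummarizedExperiment]. The `colData` must carry a
#' `group` column with both levels (`control` is the reference level, `case`
#' the contrast of interest); `batch`, `sex`, `age`, `anxiety` and optionally
#' `bmi` are the covariates the per-gene linear model can adjust for.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [ExpressionStudy()] for construction, [buildDesign()],
#'   [fitGeneModels()].
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  msg <- character()
  if (length(assays(object)) < 1L)
    return("an expression assay is required")
  m <- assay(object)
  if (anyNA(m))
    msg <- c(msg, "expression matrix contains missing values")
  if (is.null(rownames(object)))
    msg <- c(msg, "gene ids (rownames) are required")
  else if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be unique")
  if (is.null(colnames(object)))
    msg <- c(msg, "sample ids (colnames) are required")
  else if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  cd <- colData(object)
  if (!"group" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else {
    g <- as.character(cd$group)
    if (!all(g %in% c("case", "control")))
      msg <- c(msg, "group must be 'case' or 'control'")
    else if (length(unique(g)) < 2L)
      msg <- c(msg, "both group levels (case and control) must be present")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionStudy
#'
#' @param exprs numeric matrix of log2 expression, genes in rows (rownames =
#'   gene ids), samples in columns (colnames = sample ids). No missing values.
#' @param sampleData data.frame or DataFrame of per-sample covariates, one row
#'   per column of `exprs` (in the same order, or with rownames matching the
#'   sample ids). Must contain `group` with values `case`/`control`.
#' @param name optional study label stored in the object metadata.
#' @return an [ExpressionStudy-class] object.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' sd <- data.frame(group = c("case", "case", "case", "control", "control"))
#' ExpressionStudy(m, sd)
#' @export
ExpressionStudy <- function(exprs, sampleData, name = "study") {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  cd <- DataFrame(sampleData)
  if (!is.null(rownames(cd)) && !is.null(colnames(exprs)) &&
      !identical(rownames(cd), colnames(exprs))) {
    if (!all(colnames(exprs) %in% rownames(cd)))
      stopf("sample ids in the matrix and the sample table do not match")
    cd <- cd[colnames(exprs), , drop = FALSE]
  }
  if ("group" %in% colnames(cd))
    cd$group <- factor(as.character(cd$group), levels = c("control", "case"))
  for (col in c("batch", "sex", "anxiety"))
    if (col %in% colnames(cd)) cd[[col]] <- factor(as.character(cd[[col]]))
  se <- SummarizedExperiment(assays = list(exprs = exprs), colData = cd)
  out <- new("ExpressionStudy", se)
  metadata(out)$name <- name
  out
}

#' SimTruth: planted ground truth of a simulated study pair
#'
#' @slot sharedDE data.frame with columns `geneID`, `sign` (+1/-1) and
#'   `effect` (absolute log2 fold change) for genes differentially expressed
#'   in both studies with the same sign.
#' @slot specificDE list of two data.frames of the same shape, one per study,
#'   for study-specific DE genes (disjoint from the shared set).
#' @slot sigmaSq list of two named numeric vectors of true per-gene residual
#'   variances (log2 units squared).
#' @slot latentFactor list of two named numeric vectors: the per-case latent
#'   coupling factor values (controls are zero).
#' @slot coupling list with the per-study coupling loading `lambda` and the
#'   target case-level correlation `rhoTarget`.
#' @export
setClass("SimTruth", representation(
  sharedDE = "data.frame",
  specificDE = "list",
  sigmaSq = "list",
  latentFactor = "list",
  coupling = "list"
))

setValidity("SimTruth", function(object) {
  msg <- character()
  if (nrow(object@sharedDE) &&
      !all(object@sharedDE$sign %in% c(-1, 1)))
    msg <- c(msg, "shared DE signs must be +1 or -1")
  for (s in seq_along(object@specificDE)) {
    sp <- object@specificDE[[s]]
    if (nrow(sp) && length(intersect(sp$geneID, object@sharedDE$geneID)))
      msg <- c(msg, "shared and study-specific DE gene ids must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' GeneModelFits: per-gene ordinary least-squares fits
#'
#' One object summarizes the per-gene linear-model fits of a study against a
#' common design matrix: coefficient estimates, residual variances, the shared
#' residual degrees of freedom, and the unscaled variance of the group
#' coefficient (the group-column diagonal of \eqn{(X^T X)^{-1}}, identical for
#' all genes because the design is shared).
#'
#' @export
setClass("GeneModelFits", representation(
  geneIDs = "character",
  coefficients = "matrix",
  sigmaSq = "numeric",
  df = "numeric",
  unscaledGroupVar = "numeric",
  groupCoef = "character",
  design = "matrix"
))

#' VariancePrior: empirical-Bayes hyperparameters
#'
#' The hierarchical model for gene variances assumes
#' \eqn{\sigma_i^2 \sim s_0^2 d_0 / \chi^2_{d_0}} (a scaled inverse
#' chi-square); `d0` may be infinite, which collapses every posterior variance
#' to `s0Sq`.
#'
#' @slot d0 prior degrees of freedom (possibly `Inf`; the boundary value 0 is
#'   admitted as the no-shrinkage limit, where the moderated t reduces to the
#'   ordinary t).
#' @slot s0Sq prior variance (log2 units squared, > 0).
#' @export
setClass("VariancePrior", representation(d0 = "numeric", s0Sq = "numeric"))

setValidity("VariancePrior", function(object) {
  msg <- character()
  if (length(object@d0) != 1L || is.na(object@d0) || object@d0 < 0)
    msg <- c(msg, "d0 must be a single non-negative number (possibly Inf)")
  if (length(object@s0Sq) != 1L || is.na(object@s0Sq) || object@s0Sq <= 0)
    msg <- c(msg, "s0Sq must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' GeneStats: per-gene moderated statistics for one study
#'
#' @slot geneIDs gene identifiers.
#' @slot logFC group log2 fold change (case minus control).
#' @slot t moderated t-statistic.
#' @slot df total degrees of freedom (prior + residual).
#' @slot pValue two-sided asymptotic p-value, floored away from zero.
#' @slot pPerm optional permutation p-value (`NA` when not computed).
#' @slot prior the [VariancePrior-class] used for moderation.
#' @export
setClass("GeneStats", representation(
  geneIDs = "character",
  logFC = "numeric",
  t = "numeric",
  df = "numeric",
  pValue = "numeric",
  pPerm = "numeric",
  prior = "VariancePrior"
))

setValidity("GeneStats", function(object) {
  n <- length(object@geneIDs)
  msg <- character()
  if (length(object@logFC) != n || length(object@t) != n ||
      length(object@pValue) != n)
    msg <- c(msg, "per-gene slots must have one value per gene")
  if (any(object@pValue <= 0 | object@pValue > 1))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' OverlapProfile: observed/expected cross-study overlap along a threshold grid
#'
#' For each candidate p-value threshold `t` the profile records the per-study
#' significant counts `O1`, `O2`, the joint count `O11`, the chance-expected
#' joint count `E11 = O1 * O2 / N`, and the ratio `R = O11 / E11`.
#'
#' @slot grid data.frame with columns `threshold`, `O1`, `O2`, `O11`, `E11`,
#'   `R` (plus `Rlower`/`Rupper` when a resampling band was requested).
#' @slot nGenes total number of aligned genes `N`.
#' @slot q2 selected threshold (`NA` until [selectQ2()] finds one).
#' @slot ratioRule ratio rule used for selection (default 2).
#' @slot pMax upper end of the threshold range (default .05).
#' @export
setClass("OverlapProfile", representation(
  grid = "data.frame",
  nGenes = "integer",
  q2 = "numeric",
  ratioRule = "numeric",
  pMax = "numeric"
), prototype(q2 = NA_real_, ratioRule = 2, pMax = 0.05))

setValidity("OverlapProfile", function(object) {
  g <- object@grid
  need <- c("threshold", "O1", "O2", "O11", "E11", "R")
  if (!all(need %in% colnames(g)))
    return(paste("grid must have columns", paste(need, collapse = ", ")))
  if (any(g$O11 > pmin(g$O1, g$O2)))
    return("O11 cannot exceed min(O1, O2)")
  if (any(diff(g$O11) < 0) || any(diff(g$O1) < 0) || any(diff(g$O2) < 0))
    return("counts must be nondecreasing in the threshold")
  TRUE
})

#' ConsensusSet: replicated genes split by fold-change sign
#'
#' Genes significant in both studies at the selected threshold, partitioned
#' into sign-concordant UP (positive log2 fold change in both studies),
#' sign-concordant DOWN (negative in both), and discordant genes.
#'
#' @export
setClass("ConsensusSet", representation(
  up = "character",
  down = "character",
  discordant = "character",
  q2 = "numeric"
))

setValidity("ConsensusSet", function(object) {
  all3 <- c(object@up, object@down, object@discordant)
  if (anyDuplicated(all3))
    return("up, down and discordant lists must be disjoint")
  TRUE
})

#' CombinedTest: Fisher combination of two p-value vectors
#'
#' @slot geneIDs gene identifiers.
#' @slot statistic Fisher chi-square statistic `-2 (ln p1 + ln p2)`.
#' @slot pValue combined p from the upper tail of chi-square with 4 df.
#' @slot qValue Benjamini-Hochberg adjusted p-values.
#' @slot rejected logical flags at `fdrLevel`.
#' @slot fdrLevel FDR level used (default 0.10).
#' @export
setClass("CombinedTest", representation(
  geneIDs = "character",
  statistic = "numeric",
  pValue = "numeric",
  qValue = "numeric",
  rejected = "logical",
  fdrLevel = "numeric"
))

#' GeneSetCollection: gene sets restricted to a measurement universe
#'
#' @slot sets named list (term id -> character vector of member gene ids,
#'   already intersected with the universe).
#' @slot termNames named character vector of term descriptions.
#' @slot universe the measured gene universe.
#' @export
setClass("GeneSetCollection", representation(
  sets = "list",
  termNames = "character",
  universe = "character"
))

setValidity("GeneSetCollection", function(object) {
  if (anyDuplicated(names(object@sets)))
    return("term ids must be unique")
  ok <- vapply(object@sets, function(s) all(s %in% object@universe), logical(1))
  if (!all(ok))
    return("set members must be contained in the universe")
  TRUE
})

#' SignatureScores: per-subject mean UP and mean DOWN signature expression
#'
#' @export
setClass("SignatureScores", representation(
  sampleIDs = "character",
  meanUP = "numeric",
  meanDOWN = "numeric",
  group = "factor",
  nUp = "integer",
  nDown = "integer"
))

#' CouplingLine: regression of meanDOWN on meanUP among cases
#'
#' @slot slope,intercept least-squares fit on cases.
#' @slot r Pearson correlation among cases, with two-sided `pValue`.
#' @slot nCases number of cases used in the fit.
#' @export
setClass("CouplingLine", representation(
  slope = "numeric",
  intercept = "numeric",
  r = "numeric",
  pValue = "numeric",
  nCases = "integer"
))

setValidity("CouplingLine", function(object) {
  if (!is.finite(object@slope) || !is.finite(object@intercept))
    return("slope and intercept must be finite")
  if (is.finite(object@r) && abs(object@r) > 1 + 1e-12)
    return("|r| cannot exceed 1")
  TRUE
})

#' BioscalarResult: per-subject projection scores and classification summaries
#'
#' The bioscalar of a subject is the signed coordinate of the orthogonal
#' projection of their (meanUP, meanDOWN) point onto the coupling line,
#' measured from the line point nearest the origin, positive in the direction
#' of increasing meanUP. Summary slots are `NA` until filled by
#' [summarizeBioscalar()].
#'
#' @export
setClass("BioscalarResult", representation(
  sampleIDs = "character",
  group = "factor",
  bioscalar = "numeric",
  line = "CouplingLine",
  cohensD = "numeric",
  auc = "numeric",
  cutoff = "numeric",
  sensitivity = "numeric",
  specificity = "numeric",
  inflamed = "logical"
), prototype(cohensD = NA_real_, auc = NA_real_, cutoff = NA_real_,
             sensitivity = NA_real_, specificity = NA_real_))
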