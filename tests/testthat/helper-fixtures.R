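# Small fixtures built in code; no stored data.

# minimal valid study from a matrix and group labels
makeStudy <- function(m, group, ...) {
  extra <- list(...)
  sd <- data.frame(group = group, stringsAsFactors = FALSE)
  for (nm in names(extra)) sd[[nm]] <- extra[[nm]]
  rownames(sd) <- colnames(m)
  ExpressionStudy(m, sd)
}

# random study with full covariates (null unless delta given)
randomStudy <- function(nGenes = 50, nCase = 10, nCtrl = 10, seed = 1,
                        delta = NULL) {
  set.seed(seed)
  n <- nCase + nCtrl
  group <- rep(c("case", "control"), c(nCase, nCtrl))
  m <- matrix(rnorm(nGenes * n, 8, 0.5), nGenes, n,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("s%03d", seq_len(n))))
  if (!is.null(delta))
    m[seq_along(delta), group == "case"] <-
      m[seq_along(delta), group == "case"] + delta
  makeStudy(m, group,
            batch = sample(c("1", "2"), n, replace = TRUE),
            sex = sample(c("male", "female"), n, replace = TRUE),
            age = runif(n, 20, 65),
            anxiety = sample(c("0", "1"), n, replace = TRUE))
}

# fit + prior + moderated statistics in one go
studyStats <- function(study, covariates = c("batch", "sex", "age",
                                             "anxiety")) {
  design <- buildDesign(SummarizedExperiment::colData(study), covariates)
  fits <- fitGeneModels(study, design)
  moderatedStatistics(fits, estimateVariancePrior(fits))
}

# GeneStats stub from explicit p-values and fold changes
makeGeneStats <- function(p, lfc, ids = sprintf("g%03d", seq_along(p))) {
  new("GeneStats", geneIDs = ids, logFC = lfc,
      t = lfc, df = rep(10, length(p)), pValue = p,
      pPerm = rep(NA_real_, length(p)),
      prior = new("VariancePrior", d0 = 4, s0Sq = 1))
}

# SignatureScores stub from explicit coordinates
makeScores <- function(up, down, group) {
  new("SignatureScores", sampleIDs = sprintf("s%02d", seq_along(up)),
      meanUP = up, meanDOWN = down,
      group = factor(group, levels = c("control", "case")),
      nUp = 1L, nDown = 1L)
}

makeLine <- function(slope, intercept) {
  new("CouplingLine", slope = slope, intercept = intercept,
      r = NA_real_, pValue = NA_real_, nCases = 3L)
}
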