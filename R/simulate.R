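#' Configure the two-study simulator
#'
#' Defines the conditions of a paired case-control simulation: two whole-blood
#' style studies sharing a gene panel, with planted sign-concordant shared
#' differentially expressed (DE) genes, study-specific DE genes, hierarchical
#' gene variances, additive covariate effects (batch, sex, age, anxiety), and
#' a per-case latent factor coupling the mean expression of the planted UP
#' genes to that of the planted DOWN genes.
#'
#' Defaults reproduce the sampling frame of the two studies the package is
#' designed around: 113 cases / 57 controls and 94 cases / 100 controls on a
#' panel of 18,863 probes, with 200 shared DE genes of absolute log2 fold
#' change 0.8 (fraction overexpressed 90/165), a scaled inverse chi-square
#' variance prior with `d0 = 4`, `s0Sq = 0.25` log2-squared, and a target
#' case-level correlation of -0.8 between the mean UP and mean DOWN scores.
#'
#' @param nGenes number of genes on the shared panel.
#' @param study1,study2 named vectors `c(cases = , controls = )`.
#' @param nSharedDE number of DE genes shared (same sign) by both studies.
#' @param nSpecificDE length-2 vector: study-specific DE genes per study.
#' @param effectMean,effectSD distribution of absolute log2 effect sizes for
#'   DE genes (effects are `abs(rnorm(effectMean, effectSD))`).
#' @param fracUp fraction of shared DE genes overexpressed in cases.
#' @param d0,s0Sq variance prior: degrees of freedom (may be `Inf`) and scale.
#' @param covariateEffects named vector of coefficient scales (sd of per-gene
#'   Gaussian coefficient draws) for `batch`, `sex`, `age` (per year) and
#'   `anxiety`, in log2 units.
#' @param rhoTarget target correlation in `[-1, 0]` between case-level mean
#'   UP and mean DOWN signature scores.
#' @param tNoiseDF optional degrees of freedom for heavy-tailed (scaled
#'   Student-t) noise; `NULL` keeps Gaussian noise.
#' @param seed master integer seed; all stage substreams derive from it.
#' @return a validated list of class `SimConfig`.
#' @seealso [generateTwoStudies()]
#' @export
simConfig <- function(nGenes = 18863,
                      study1 = c(cases = 113, controls = 57),
                      study2 = c(cases = 94, controls = 100),
                      nSharedDE = 200,
                      nSpecificDE = c(100, 100),
                      effectMean = 0.8,
                      effectSD = 0,
                      fracUp = 90 / 165,
                      d0 = 4,
                      s0Sq = 0.25,
                      covariateEffects = c(batch = 0.1, sex = 0.1,
                                           age = 0.002, anxiety = 0.1),
                      rhoTarget = -0.8,
                      tNoiseDF = NULL,
                      seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes),
              study1 = study1, study2 = study2,
              nSharedDE = as.integer(nSharedDE),
              nSpecificDE = as.integer(nSpecificDE),
              effectMean = effectMean, effectSD = effectSD,
              fracUp = fracUp, d0 = d0, s0Sq = s0Sq,
              covariateEffects = covariateEffects,
              rhoTarget = rhoTarget, tNoiseDF = tNoiseDF,
              seed = as.integer(seed))
  validateSimConfig(cfg)
  class(cfg) <- "SimConfig"
  cfg
}

validateSimConfig <- function(cfg) {
  for (s in c("study1", "study2")) {
    sz <- cfg[[s]]
    if (!all(c("cases", "controls") %in% names(sz)))
      stopf("%s must be a named vector with 'cases' and 'controls'", s)
    if (any(sz < 2))
      stopf("%s must have at least 2 samples per group", s)
  }
  if (cfg$nGenes < 1) stopf("nGenes must be positive")
  if (cfg$nSharedDE < 0 || any(cfg$nSpecificDE < 0))
    stopf("DE gene counts must be non-negative")
  if (cfg$nSharedDE + sum(cfg$nSpecificDE) > cfg$nGenes)
    stopf("more DE genes than genes: %d shared + %d specific > %d",
          cfg$nSharedDE, sum(cfg$nSpecificDE), cfg$nGenes)
  if (cfg$rhoTarget < -1 || cfg$rhoTarget > 0)
    stopf("rhoTarget must lie in [-1, 0]")
  if (!is.infinite(cfg$d0) && cfg$d0 <= 0) stopf("d0 must be positive or Inf")
  if (cfg$s0Sq <= 0) stopf("s0Sq must be positive")
  if (cfg$fracUp < 0 || cfg$fracUp > 1) stopf("fracUp must be in [0, 1]")
  invisible(TRUE)
}

#' Sample gene-level residual variances
#'
#' Draws per-gene variances from the scaled inverse chi-square distribution
#' \eqn{\sigma^2 = d_0 s_0^2 / \chi^2_{d_0}} that the empirical-Bayes
#' moderated-t model assumes. With `d0 = Inf` the prior is degenerate and
#' every variance equals `s0Sq`.
#'
#' @param nGenes number of draws.
#' @param d0 prior degrees of freedom (> 0 or `Inf`).
#' @param s0Sq prior scale (> 0).
#' @param seed optional seed for determinism.
#' @return numeric vector of variances.
#' @export
sampleGeneVariances <- function(nGenes, d0, s0Sq, seed = NULL) {
  if (!is.infinite(d0) && d0 <= 0) stopf("d0 must be positive or Inf")
  if (s0Sq <= 0) stopf("s0Sq must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.infinite(d0)) return(rep(s0Sq, nGenes))
  d0 * s0Sq / rchisq(nGenes, df = d0)
}

# Solve for the latent-factor loading lambda so that the case-level
# correlation between mean UP and mean DOWN z-scored signature expression hits
# rhoTarget. Per-gene total variance (the z-scoring denominator) is
# s_g^2(lambda) = sigma_g^2 + covariate variance + group-shift variance
# + caseFrac * lambda^2; within cases the mean scores have noise variance
# P = sum(sigma_g^2 / s_g^2) / m^2 and coupling loading lambda * mean(1/s_g),
# giving a closed-form rho(lambda) that is solved by uniroot.
solveCouplingLambda <- function(rhoTarget, sigma2U, sigma2D,
                                extraVarU, extraVarD, caseFrac) {
  if (rhoTarget >= 0 || !length(sigma2U) || !length(sigma2D)) return(0)
  rho <- max(rhoTarget, -0.995)  # -1 is approached, never attained, with noise
  f <- caseFrac
  rhoAt <- function(lam) {
    sU <- sigma2U + extraVarU + f * lam^2
    sD <- sigma2D + extraVarD + f * lam^2
    cU <- lam * mean(1 / sqrt(sU))
    cD <- lam * mean(1 / sqrt(sD))
    pU <- sum(sigma2U / sU) / length(sigma2U)^2
    pD <- sum(sigma2D / sD) / length(sigma2D)^2
    -(cU * cD) / sqrt((pU + cU^2) * (pD + cD^2))
  }
  uniroot(function(l) rhoAt(l) - rho, lower = 1e-9, upper = 1e4,
          tol = 1e-10)$root
}

generateStudy <- function(cfg, studyIndex, de) {
  sizes <- cfg[[paste0("study", studyIndex)]]
  nCase <- as.integer(sizes[["cases"]])
  nCtrl <- as.integer(sizes[["controls"]])
  n <- nCase + nCtrl
  G <- cfg$nGenes
  ce <- cfg$covariateEffects

  set.seed(splitSeed(cfg$seed, 100L + studyIndex))
  group <- rep(c("case", "control"), c(nCase, nCtrl))
  batch <- sample(c("1", "2"), n, replace = TRUE)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  anxiety <- sample(c("0", "1"), n, replace = TRUE)
  age <- runif(n, 20, 65)

  sigma2 <- sampleGeneVariances(G, cfg$d0, cfg$s0Sq,
                                seed = splitSeed(cfg$seed, 200L + studyIndex))

  set.seed(splitSeed(cfg$seed, 300L + studyIndex))
  baseline <- runif(G, 4, 12)
  bBatch <- rnorm(G, 0, ce[["batch"]])
  bSex <- rnorm(G, 0, ce[["sex"]])
  bAge <- rnorm(G, 0, ce[["age"]])
  bAnx <- rnorm(G, 0, ce[["anxiety"]])

  delta <- numeric(G)
  if (nrow(de$shared))
    delta[de$shared$idx] <- de$shared$sign * de$shared$effect
  sp <- de$specific[[studyIndex]]
  if (nrow(sp)) delta[sp$idx] <- sp$sign * sp$effect

  caseInd <- as.numeric(group == "case")
  M <- matrix(baseline, G, n) +
    outer(bBatch, as.numeric(batch == "2")) +
    outer(bSex, as.numeric(sex == "female")) +
    outer(bAge, age) +
    outer(bAnx, as.numeric(anxiety == "1")) +
    outer(delta, caseInd)

  # latent coupling factor: per-case scalar, opposite-signed loadings on the
  # planted UP vs DOWN shared genes
  upIdx <- de$shared$idx[de$shared$sign > 0]
  dnIdx <- de$shared$idx[de$shared$sign < 0]
  f <- nCase / n
  extraVar <- bBatch^2 * 0.25 + bSex^2 * 0.25 + bAnx^2 * 0.25 +
    bAge^2 * (45^2 / 12) + f * (1 - f) * delta^2
  lambda <- solveCouplingLambda(cfg$rhoTarget, sigma2[upIdx], sigma2[dnIdx],
                                extraVar[upIdx], extraVar[dnIdx], f)
  latent <- numeric(n)
  if (lambda > 0) {
    latent[group == "case"] <- rnorm(nCase)
    if (length(upIdx))
      M[upIdx, ] <- M[upIdx, , drop = FALSE] +
        outer(rep(lambda, length(upIdx)), latent)
    if (length(dnIdx))
      M[dnIdx, ] <- M[dnIdx, , drop = FALSE] -
        outer(rep(lambda, length(dnIdx)), latent)
  }

  if (is.null(cfg$tNoiseDF)) {
    noise <- matrix(rnorm(G * n), G, n)
  } else {
    df <- cfg$tNoiseDF
    if (df <= 2) stopf("tNoiseDF must exceed 2")
    noise <- matrix(rt(G * n, df) / sqrt(df / (df - 2)), G, n)
  }
  M <- M + sqrt(sigma2) * noise  # row-wise recycling: gene-specific sd

  gids <- sprintf("gene%05d", seq_len(G))
  sids <- sprintf("S%d_%03d", studyIndex, seq_len(n))
  dimnames(M) <- list(gids, sids)
  meta <- data.frame(group = group, batch = batch, sex = sex, age = age,
                     anxiety = anxiety, row.names = sids,
                     stringsAsFactors = FALSE)
  study <- ExpressionStudy(M, meta, name = paste0("study", studyIndex))
  list(study = study,
       sigmaSq = setNames(sigma2, gids),
       latent = setNames(latent[group == "case"], sids[group == "case"]),
       lambda = lambda)
}

#' Generate a pair of case-control studies with known ground truth
#'
#' Expression is built as baseline + additive covariate effects + a group
#' effect for the planted DE genes (shared genes carry the same sign in both
#' studies) + a per-case latent coupling factor + Gaussian noise with
#' gene-specific variance drawn from the scaled inverse chi-square prior. The
#' latent loading is tuned analytically so the case-level correlation between
#' mean UP and mean DOWN z-scored expression approaches `rhoTarget`.
#'
#' @param config a [simConfig()] object.
#' @return a list with elements `study1`, `study2` ([ExpressionStudy-class])
#'   and `truth` ([SimTruth-class]).
#' @examples
#' cfg <- simConfig(nGenes = 300, study1 = c(cases = 10, controls = 10),
#'                  study2 = c(cases = 10, controls = 10), nSharedDE = 20,
#'                  nSpecificDE = c(5, 5), seed = 42)
#' sim <- generateTwoStudies(cfg)
#' sim$truth
#' @export
generateTwoStudies <- function(config) {
  if (!inherits(config, "SimConfig")) validateSimConfig(config)
  cfg <- config
  G <- cfg$nGenes
  gids <- sprintf("gene%05d", seq_len(G))

  set.seed(splitSeed(cfg$seed, 1L))
  nTot <- cfg$nSharedDE + sum(cfg$nSpecificDE)
  allIdx <- if (nTot) sample.int(G, nTot) else integer(0)
  sharedIdx <- head(allIdx, cfg$nSharedDE)
  spec1Idx <- allIdx[seq_len(cfg$nSpecificDE[1]) + cfg$nSharedDE]
  spec2Idx <- allIdx[seq_len(cfg$nSpecificDE[2]) + cfg$nSharedDE +
                       cfg$nSpecificDE[1]]
  drawDE <- function(idx, fracUp) {
    if (!length(idx))
      return(data.frame(idx = integer(0), geneID = character(0),
                        sign = numeric(0), effect = numeric(0)))
    sign <- ifelse(runif(length(idx)) < fracUp, 1, -1)
    effect <- abs(rnorm(length(idx), cfg$effectMean, cfg$effectSD))
    data.frame(idx = idx, geneID = gids[idx], sign = sign, effect = effect,
               stringsAsFactors = FALSE)
  }
  de <- list(shared = drawDE(sharedIdx, cfg$fracUp),
             specific = list(drawDE(spec1Idx, 0.5), drawDE(spec2Idx, 0.5)))

  g1 <- generateStudy(cfg, 1L, de)
  g2 <- generateStudy(cfg, 2L, de)

  truth <- new("SimTruth",
               sharedDE = de$shared[, c("geneID", "sign", "effect")],
               specificDE = list(study1 = de$specific[[1]][, c("geneID", "sign", "effect")],
                                 study2 = de$specific[[2]][, c("geneID", "sign", "effect")]),
               sigmaSq = list(study1 = g1$sigmaSq, study2 = g2$sigmaSq),
               latentFactor = list(study1 = g1$latent, study2 = g2$latent),
               coupling = list(lambda = c(study1 = g1$lambda,
                                          study2 = g2$lambda),
                               rhoTarget = cfg$rhoTarget))
  list(study1 = g1$study, study2 = g2$study, truth = truth)
}

#' Write a simulated study pair to plain-text files
#'
#' Writes per-study expression and metadata TSVs, the planted-truth tables and
#' the configuration (YAML) into an existing directory, and returns a manifest.
#' Nothing is written when the directory does not exist.
#'
#' @param sim result of [generateTwoStudies()].
#' @param config the [simConfig()] that produced it.
#' @param dir existing output directory.
#' @return data.frame manifest with columns `file` and `rows`.
#' @export
writeFixtureBundle <- function(sim, config, dir) {
  if (!dir.exists(dir))
    stopf("directory does not exist: %s", dir)
  files <- character(0); rows <- integer(0)
  emit <- function(df, name, rowNames = FALSE) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = rowNames, col.names = TRUE)
    files <<- c(files, name)
    rows <<- c(rows, nrow(df))
  }
  for (s in 1:2) {
    study <- sim[[paste0("study", s)]]
    m <- assay(study)
    em <- data.frame(geneID = rownames(m), as.data.frame(m),
                     check.names = FALSE, stringsAsFactors = FALSE)
    emit(em, sprintf("study%d_expression.tsv", s))
    md <- as.data.frame(colData(study))
    md <- data.frame(sampleID = rownames(md), md,
                     check.names = FALSE, stringsAsFactors = FALSE)
    emit(md, sprintf("study%d_metadata.tsv", s))
  }
  tr <- sim$truth
  tg <- rbind(
    if (nrow(tr@sharedDE)) cbind(tr@sharedDE, role = "shared"),
    if (nrow(tr@specificDE$study1)) cbind(tr@specificDE$study1,
                                          role = "specific1"),
    if (nrow(tr@specificDE$study2)) cbind(tr@specificDE$study2,
                                          role = "specific2"))
  if (is.null(tg))
    tg <- data.frame(geneID = character(0), sign = numeric(0),
                     effect = numeric(0), role = character(0))
  emit(tg, "truth_genes.tsv")
  lat <- do.call(rbind, lapply(names(tr@latentFactor), function(nm) {
    lf <- tr@latentFactor[[nm]]
    data.frame(study = nm, sampleID = names(lf), latent = unname(lf),
               stringsAsFactors = FALSE)
  }))
  emit(lat, "truth_latent.tsv")
  cfgPath <- file.path(dir, "config.yaml")
  cfgOut <- unclass(config)
  cfgOut <- cfgOut[!vapply(cfgOut, is.null, logical(1))]
  yaml::write_yaml(lapply(cfgOut, function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x), cfgPath)
  files <- c(files, "config.yaml")
  rows <- c(rows, NA_integer_)
  data.frame(file = files, rows = rows, stringsAsFactors = FALSE)
}
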