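test_that("design matrix has the expected columns and reference coding", {
  sd <- data.frame(group = rep(c("case", "control"), each = 4),
                   batch = rep(c("1", "2"), 4),
                   sex = rep(rep(c("male", "female"), each = 2), 2),
                   age = c(30, 41, 55, 28, 46, 33, 60, 25),
                   anxiety = c("0", "1", "1", "0", "1", "0", "0", "1"))
  X <- buildDesign(sd)
  expect_equal(ncol(X), 6)
  expect_identical(colnames(X),
                   c("(Intercept)", "groupcase", "batch2", "sexfemale",
                     "age", "anxiety1"))
  expect_true(all(X[, 1] == 1))
  expect_identical(attr(X, "groupCol"), "groupcase")

  # single-level factor dropped with a warning
  sd1 <- sd; sd1$batch <- "1"
  expect_warning(X1 <- buildDesign(sd1), "single level")
  expect_equal(ncol(X1), 5)

  # degenerate group: no contrast possible
  sdc <- sd; sdc$group <- "case"
  expect_error(buildDesign(sdc), "both group levels")

  expect_error(buildDesign(transform(sd, batch = "3")), "unknown level")
  expect_error(buildDesign(sd, covariates = c("batch", "bmi")),
               "not found")
})

test_that("per-gene OLS matches the normal-equations hand solution", {
  # 3 samples, 2 columns: X = [1 0; 1 1; 1 2], y = (1, 2, 2)
  m <- matrix(c(1, 2, 2), 1, 3,
              dimnames = list("g1", c("s1", "s2", "s3")))
  study <- makeStudy(m, c("control", "case", "case"))
  X <- cbind("(Intercept)" = rep(1, 3), groupcase = c(0, 1, 2))
  rownames(X) <- colnames(m)
  attr(X, "groupCol") <- "groupcase"
  fits <- fitGeneModels(study, X)
  # (X'X) beta = X'y solved by hand: beta = (7/6, 1/2); RSS = 1/6, d = 1
  expect_equal(unname(fits@coefficients[1, ]), c(7 / 6, 1 / 2),
               tolerance = 1e-12)
  expect_equal(fits@sigmaSq, 1 / 6, tolerance = 1e-12)
  expect_equal(fits@df, 1)
  # unscaled group variance = [(X'X)^-1]_22 = 1/2
  expect_equal(fits@unscaledGroupVar, 1 / 2, tolerance = 1e-12)
})

test_that("noiseless responses are recovered to machine precision", {
  study <- randomStudy(nGenes = 5, seed = 4)
  X <- buildDesign(SummarizedExperiment::colData(study))
  beta <- matrix(rnorm(5 * ncol(X)), 5, ncol(X))
  m <- beta %*% t(X)
  dimnames(m) <- dimnames(SummarizedExperiment::assay(study))
  noiseless <- makeStudy(m, as.character(groupLabels(study)),
                         batch = as.character(SummarizedExperiment::colData(study)$batch),
                         sex = as.character(SummarizedExperiment::colData(study)$sex),
                         age = SummarizedExperiment::colData(study)$age,
                         anxiety = as.character(SummarizedExperiment::colData(study)$anxiety))
  fits <- fitGeneModels(noiseless, X)
  expect_equal(unname(fits@coefficients), beta, tolerance = 1e-9)
  expect_true(all(fits@sigmaSq < 1e-18))
  expect_equal(fits@df, ncol(noiseless) - ncol(X))
})

test_that("variance prior estimation inverts the scaled-F moments", {
  # simulation oracle: true d0 = 4, s0^2 = 2, residual df d = 10
  set.seed(21)
  sigma2 <- sampleGeneVariances(20000, 4, 2)
  s2 <- sigma2 * rchisq(20000, 10) / 10
  fits <- new("GeneModelFits", geneIDs = as.character(seq_along(s2)),
              coefficients = matrix(0, length(s2), 1,
                                    dimnames = list(NULL, "groupcase")),
              sigmaSq = s2, df = 10, unscaledGroupVar = 0.1,
              groupCoef = "groupcase", design = matrix(0, 0, 0))
  pr <- estimateVariancePrior(fits)
  expect_lt(abs(pr@d0 - 4), 0.5)
  expect_lt(abs(pr@s0Sq - 2) / 2, 0.05)

  # identical variances: infinite prior at the common value
  fits@sigmaSq <- rep(0.7, 20000)
  pr2 <- estimateVariancePrior(fits)
  expect_true(is.infinite(pr2@d0))
  expect_equal(pr2@s0Sq, 0.7)

  fits@sigmaSq <- rep(0, 20000)
  expect_error(estimateVariancePrior(fits), "all residual variances")

  fits@sigmaSq <- c(0.5, 0.9, rep(0, 19998))
  expect_warning(estimateVariancePrior(fits), "low confidence")
})

test_that("moderated statistics follow the shrinkage formula", {
  fits <- new("GeneModelFits", geneIDs = c("g1", "g2"),
              coefficients = matrix(c(1, 0), 2, 1,
                                    dimnames = list(NULL, "groupcase")),
              sigmaSq = c(4, 4), df = 4, unscaledGroupVar = 0.25,
              groupCoef = "groupcase", design = matrix(0, 0, 0))
  # hand computation: s~2 = (4*1 + 4*4)/8 = 2.5, t = 1/sqrt(0.25*2.5)
  st <- moderatedStatistics(fits, new("VariancePrior", d0 = 4, s0Sq = 1))
  expect_equal(st@t[1], 1 / sqrt(0.625), tolerance = 1e-10)
  expect_equal(st@df[1], 8)
  expect_equal(st@pValue[1], 2 * pt(-1 / sqrt(0.625), 8), tolerance = 1e-12)
  # beta = 0 gives t = 0, p = 1
  expect_equal(st@t[2], 0)
  expect_equal(st@pValue[2], 1)
})

test_that("d0 = 0 reduces the moderated t to the ordinary t", {
  study <- randomStudy(nGenes = 30, seed = 8)
  X <- buildDesign(SummarizedExperiment::colData(study))
  fits <- fitGeneModels(study, X)
  st <- moderatedStatistics(fits, new("VariancePrior", d0 = 0, s0Sq = 1))
  tOrd <- fits@coefficients[, "groupcase"] /
    sqrt(fits@unscaledGroupVar * fits@sigmaSq)
  expect_equal(unname(st@t), unname(tOrd), tolerance = 1e-14)
  expect_equal(st@df[1], fits@df)
})

test_that("moderated pipeline agrees with the limma cross-check", {
  skip_if_not_installed("limma")
  study <- randomStudy(nGenes = 400, nCase = 15, nCtrl = 15, seed = 17)
  X <- buildDesign(SummarizedExperiment::colData(study))
  fits <- fitGeneModels(study, X)
  pr <- estimateVariancePrior(fits)
  st <- moderatedStatistics(fits, pr)
  lf <- limma::lmFit(SummarizedExperiment::assay(study), X)
  le <- limma::eBayes(lf)
  expect_equal(pr@d0, le$df.prior, tolerance = 1e-6)
  expect_equal(pr@s0Sq, le$s2.prior, tolerance = 1e-6)
  expect_equal(unname(st@t), unname(le$t[, "groupcase"]), tolerance = 1e-8)
  expect_equal(unname(st@pValue), unname(le$p.value[, "groupcase"]),
               tolerance = 1e-8)
})

test_that("results are invariant to gene and sample reordering", {
  study <- randomStudy(nGenes = 40, seed = 23)
  st <- studyStats(study)
  set.seed(1)
  gperm <- sample(nrow(study))
  sperm <- sample(ncol(study))
  shuffled <- study[gperm, sperm]
  st2 <- studyStats(shuffled)
  ord <- match(geneIDs(st), geneIDs(st2))
  expect_equal(pValues(st), pValues(st2)[ord], tolerance = 1e-12)
  expect_equal(logFoldChanges(st), logFoldChanges(st2)[ord],
               tolerance = 1e-12)
})

test_that("permutation p-values match exhaustive enumeration on a 2v2 toy", {
  m <- matrix(c(5.1, 3.2, 4.0, 2.5), 1, 4,
              dimnames = list("g1", paste0("s", 1:4)))
  study <- makeStudy(m, c("case", "case", "control", "control"))
  X <- cbind("(Intercept)" = rep(1, 4), groupcase = c(1, 1, 0, 0))
  rownames(X) <- colnames(m)
  attr(X, "groupCol") <- "groupcase"
  prior <- new("VariancePrior", d0 = 0, s0Sq = 1)
  # oracle: enumerate all C(4,2) = 6 relabelings with the pooled-variance t
  y <- m[1, ]
  tFor <- function(caseIdx) {
    g <- seq_len(4) %in% caseIdx
    unname(t.test(y[g], y[!g], var.equal = TRUE)$statistic)
  }
  combos <- combn(4, 2, simplify = FALSE)
  tAll <- vapply(combos, tFor, numeric(1))
  tObs <- tFor(c(1, 2))
  pExact <- mean(abs(tAll) >= abs(tObs) - 1e-12)
  pPkg <- permutationPvalues(study, X, prior = prior, exhaustive = TRUE)
  expect_equal(unname(pPkg), pExact, tolerance = 1e-12)
})

test_that("permutation p-values are floored at 1/(B+1) and match asymptotics", {
  # global-null generator data: hierarchical variances, so the moderated t
  # stays self-studentized and its permutation law tracks the asymptotic one
  cfg <- simConfig(nGenes = 300, study1 = c(cases = 20, controls = 20),
                   study2 = c(cases = 20, controls = 20),
                   nSharedDE = 0, nSpecificDE = c(0, 0), seed = 29)
  study <- generateTwoStudies(cfg)$study1
  X <- buildDesign(SummarizedExperiment::colData(study))
  fits <- fitGeneModels(study, X)
  pr <- estimateVariancePrior(fits)
  st <- moderatedStatistics(fits, pr)
  pPerm <- permutationPvalues(study, X, nPerm = 2000, seed = 5, prior = pr)
  expect_true(all(pPerm >= 1 / 2001))
  rms <- sqrt(mean((pPerm - pValues(st))^2))
  expect_lt(rms, 0.02)
})

test_that("permutation strata are validated", {
  study <- randomStudy(nGenes = 10, nCase = 4, nCtrl = 4, seed = 3)
  X <- buildDesign(SummarizedExperiment::colData(study))
  expect_error(permutationPvalues(study, X,
                                  strata = factor(seq_len(8))),
               "single sample")
  oneSided <- factor(c(1, 1, 1, 1, 2, 2, 2, 2))
  # stratum 1 holds only cases, stratum 2 only controls
  expect_error(permutationPvalues(study, X, strata = oneSided),
               "both group labels")
})

test_that("module eigengene matches closed-form PCA and detects shifts", {
  # identical genes: eigengene equals the standardized common profile
  set.seed(6)
  prof <- rnorm(20)
  m <- rbind(g1 = prof, g2 = prof, g3 = prof)
  colnames(m) <- paste0("s", 1:20)
  study <- makeStudy(m, rep(c("case", "control"), 10))
  eg <- moduleEigengene(study, c("g1", "g2", "g3"))
  expect_equal(unname(eg$eigengene),
               unname((prof - mean(prof)) / sd(prof)), tolerance = 1e-8)
  expect_equal(eg$varianceExplained, 1, tolerance = 1e-12)

  # 2-gene module: compare against a hand eigen-decomposition of the 2x2
  # correlation matrix (positively correlated pair, so the orientation
  # against the mean profile is well defined)
  set.seed(7)
  a <- rnorm(20)
  m2 <- rbind(a = a, b = 0.7 * a + rnorm(20, 0, 0.5))
  colnames(m2) <- paste0("s", 1:20)
  study2 <- makeStudy(m2, rep(c("case", "control"), 10))
  eg2 <- moduleEigengene(study2, c("a", "b"))
  Z <- t(scale(t(m2)))
  ev <- eigen(cor(t(Z)))
  scores <- as.numeric(t(Z) %*% ev$vectors[, 1])
  scores <- scores / sd(scores)
  if (cor(scores, colMeans(Z)) < 0) scores <- -scores
  expect_equal(unname(eg2$eigengene), scores, tolerance = 1e-8)

  # power: planted 1-sd shift at n = 100/100 is detected in >= 95% of seeds
  hits <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    grp <- rep(c("case", "control"), each = 100)
    base <- matrix(rnorm(5 * 200), 5, 200)
    base[, grp == "case"] <- base[, grp == "case"] + 1
    dimnames(base) <- list(paste0("g", 1:5), paste0("s", 1:200))
    moduleEigengene(makeStudy(base, grp), paste0("g", 1:5))$pValue < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  expect_error(moduleEigengene(study, "nope"), "none of the module genes")
  flat <- makeStudy(matrix(1, 2, 4, dimnames = list(c("x", "y"),
                                                    paste0("s", 1:4))),
                    c("case", "case", "control", "control"))
  expect_error(moduleEigengene(flat, c("x", "y")), "constant")
})
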