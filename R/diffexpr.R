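#' Build the per-gene model design matrix
#'
#' Treatment-coded design for the per-gene linear model: intercept, the
#' case/control contrast, and the requested covariates. Reference levels are
#' fixed (control, batch 1, male, anxiety 0) so the group coefficient is the
#' case-minus-control log2 fold change. Factor covariates observed at a
#' single level are dropped with a warning; the group contrast itself can
#' never be dropped.
#'
#' @param sampleData data.frame or DataFrame of per-sample covariates with a
#'   `group` column; typically `colData()` of an [ExpressionStudy-class].
#' @param covariates character vector of adjustment covariates; any of
#'   `"batch"`, `"sex"`, `"age"`, `"anxiety"`, `"bmi"`. Use
#'   `c("batch", "sex", "age")` for a model without the anxiety term, or add
#'   `"bmi"` for the body-mass-index sensitivity model.
#' @return numeric design matrix (samples x coefficients) of full column
#'   rank, with an attribute `"groupCol"` naming the group coefficient.
#' @export
buildDesign <- function(sampleData,
                        covariates = c("batch", "sex", "age", "anxiety")) {
  df <- as.data.frame(sampleData)
  if (!"group" %in% colnames(df))
    stopf("design error: 'group' column is required")
  g <- as.character(df$group)
  if (anyNA(g) || !all(g %in% c("case", "control")))
    stopf("design error: group must be 'case' or 'control' with no missing values")
  if (length(unique(g)) < 2L)
    stopf("design error: both group levels must be present, found only '%s'",
          unique(g))
  df$group <- factor(g, levels = c("control", "case"))

  refLevels <- list(batch = "1", sex = "male", anxiety = "0")
  kept <- character(0)
  for (cv in covariates) {
    if (!cv %in% colnames(df))
      stopf("design error: covariate '%s' not found in the sample table", cv)
    v <- df[[cv]]
    if (anyNA(v))
      stopf("design error: covariate '%s' has missing values", cv)
    if (cv %in% c("age", "bmi")) {
      df[[cv]] <- as.numeric(v)
      kept <- c(kept, cv)
      next
    }
    v <- as.character(v)
    ref <- refLevels[[cv]]
    known <- switch(cv, batch = c("1", "2"), sex = c("male", "female"),
                    anxiety = c("0", "1"), unique(v))
    if (!all(v %in% known))
      stopf("design error: unknown level '%s' for covariate '%s'",
            setdiff(v, known)[1], cv)
    lev <- unique(v)
    if (length(lev) < 2L) {
      warnf("covariate '%s' has a single level ('%s'); column dropped",
            cv, lev)
      next
    }
    df[[cv]] <- factor(v, levels = c(ref, setdiff(known, ref)))
    kept <- c(kept, cv)
  }
  fml <- stats::reformulate(c("group", kept))
  X <- model.matrix(fml, data = df)
  if (qr(X)$rank < ncol(X))
    stopf("design error: design matrix is rank deficient")
  rownames(X) <- rownames(df)
  attr(X, "groupCol") <- "groupcase"
  X
}

#' Fit per-gene ordinary least-squares models
#'
#' Fits the shared design to every gene by OLS. Residual variance is
#' `RSS / d` with `d = n - rank(X)` identical across genes; the unscaled
#' variance of the group coefficient is the group-column diagonal of
#' \eqn{(X^T X)^{-1}}.
#'
#' @param study an [ExpressionStudy-class].
#' @param design design matrix from [buildDesign()], rows aligned with the
#'   study samples.
#' @return a [GeneModelFits-class] object.
#' @export
fitGeneModels <- function(study, design) {
  Y <- assay(study)
  n <- ncol(Y)
  if (nrow(design) != n)
    stopf("design error: design has %d rows but the study has %d samples",
          nrow(design), n)
  if (!is.null(rownames(design)) &&
      !identical(rownames(design), colnames(Y)))
    stopf("design error: design rows do not align with study samples")
  p <- ncol(design)
  if (n <= p)
    stopf("design error: %d samples cannot support %d coefficients", n, p)
  fit <- lm.fit(design, t(Y))
  if (fit$rank < p)
    stopf("design error: design matrix is rank deficient")
  d <- n - fit$rank
  # lm.fit drops the matrix shape for a single-gene response
  coefs <- t(matrix(fit$coefficients, ncol = nrow(Y),
                    dimnames = list(colnames(design), rownames(Y))))
  res <- matrix(fit$residuals, ncol = nrow(Y))
  s2 <- colSums(res^2) / d
  gcol <- attr(design, "groupCol") %||% "groupcase"
  if (!gcol %in% colnames(design))
    stopf("design error: group column '%s' not present in the design", gcol)
  xtxinv <- chol2inv(chol(crossprod(design)))
  dimnames(xtxinv) <- list(colnames(design), colnames(design))
  new("GeneModelFits",
      geneIDs = rownames(Y),
      coefficients = coefs,
      sigmaSq = unname(s2),
      df = d,
      unscaledGroupVar = xtxinv[gcol, gcol],
      groupCoef = gcol,
      design = design)
}

#' Estimate the empirical-Bayes variance prior
#'
#' Method-of-moments fit of the scaled-F sampling model for the observed
#' residual variances, on the log scale: with
#' \eqn{s^2 \sim s_0^2 F(d, d_0)}, `log(s^2)` has mean
#' \eqn{\log s_0^2 + \psi(d/2) - \log(d/2) - \psi(d_0/2) + \log(d_0/2)} and
#' variance \eqn{\psi'(d/2) + \psi'(d_0/2)}. The trigamma relation is
#' inverted by bisection (tolerance 1e-8). When the excess variance of
#' `log(s^2)` is non-positive the prior degrees of freedom are flagged
#' infinite; finite solutions are capped at 1e6. Zero variances are excluded
#' from estimation (they are still shrunk downstream).
#'
#' @param fits a [GeneModelFits-class] object.
#' @return a [VariancePrior-class].
#' @export
estimateVariancePrior <- function(fits) {
  s2 <- fits@sigmaSq
  d <- fits@df
  pos <- s2 > 0
  if (!any(pos))
    stopf("estimation error: all residual variances are zero")
  if (sum(pos) < 2)
    stopf("estimation error: at least 2 genes with positive variance required")
  if (sum(pos) < 10)
    warnf("variance prior estimated from only %d genes; low confidence",
          sum(pos))
  e <- log(s2[pos]) - digamma(d / 2) + log(d / 2)
  if (var(e) == 0) {
    # degenerate data: all variances identical; the only consistent prior is
    # a point mass at the common value (shrinkage becomes a no-op)
    return(new("VariancePrior", d0 = Inf, s0Sq = s2[pos][1]))
  }
  excess <- var(e) - trigamma(d / 2)
  if (!is.finite(excess) || excess <= 0) {
    d0 <- Inf
    s0 <- exp(mean(e))
  } else {
    # trigamma is strictly decreasing; bisect for d0/2
    f <- function(x) trigamma(x) - excess
    root <- uniroot(f, lower = 1e-8, upper = 1e7, tol = 1e-8)$root
    d0 <- min(2 * root, 1e6)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  new("VariancePrior", d0 = d0, s0Sq = s0)
}

#' Moderated t-statistics and asymptotic p-values
#'
#' Shrinks each gene's residual variance toward the prior,
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d)}, forms the moderated
#' statistic \eqn{\tilde t = \hat\beta_{group} / \sqrt{c_g \tilde s^2}}, and
#' refers it to a t distribution with \eqn{d_0 + d} degrees of freedom
#' (standard normal in the infinite-prior limit). With `d0 = 0` the moderated
#' t reduces exactly to the ordinary t. Two-sided p-values are floored at the
#' smallest positive representable value.
#'
#' @param fits a [GeneModelFits-class].
#' @param prior a [VariancePrior-class], typically from
#'   [estimateVariancePrior()].
#' @return a [GeneStats-class] object.
#' @export
moderatedStatistics <- function(fits, prior) {
  validObject(prior)
  if (fits@unscaledGroupVar <= 0)
    stopf("internal error: unscaled group-coefficient variance must be positive")
  d0 <- prior@d0
  s0 <- prior@s0Sq
  d <- fits@df
  s2 <- fits@sigmaSq
  s2tilde <- if (is.infinite(d0)) rep(s0, length(s2))
             else (d0 * s0 + d * s2) / (d0 + d)
  beta <- fits@coefficients[, fits@groupCoef]
  se <- sqrt(fits@unscaledGroupVar * s2tilde)
  t <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  dfTot <- d0 + d
  p <- 2 * pt(-abs(t), df = dfTot)
  new("GeneStats",
      geneIDs = fits@geneIDs,
      logFC = unname(beta),
      t = unname(t),
      df = rep(dfTot, length(t)),
      pValue = unname(floorPValues(p)),
      pPerm = rep(NA_real_, length(t)),
      prior = prior)
}

# enumerate all distinct case-label placements across strata; returns a list
# of logical case-indicator vectors (the observed one excluded by the caller)
enumerateAssignments <- function(case, strata, limit = 10000L) {
  parts <- lapply(split(seq_along(case), strata), function(ix) {
    k <- sum(case[ix])
    utils::combn(ix, k, simplify = FALSE)
  })
  total <- prod(vapply(parts, length, numeric(1)))
  if (total > limit)
    stopf("exhaustive enumeration would need %.0f assignments; use Monte Carlo",
          total)
  grid <- expand.grid(lapply(parts, seq_along))
  lapply(seq_len(nrow(grid)), function(i) {
    ind <- rep(FALSE, length(case))
    for (j in seq_along(parts))
      ind[parts[[j]][[grid[i, j]]]] <- TRUE
    ind
  })
}

#' Permutation p-values for the moderated t
#'
#' Case/control labels are permuted within strata (by default the batch
#' factor, the largest nuisance variable), the group column of the design is
#' rebuilt, and the moderated t is recomputed with the same variance prior as
#' the observed analysis. The p-value is `(1 + B_exceed) / (1 + B)` with
#' `B_exceed` the number of permutations whose `|t*|` reaches the observed
#' `|t|`; the smallest attainable p is therefore `1 / (B + 1)`. With
#' `exhaustive = TRUE` all distinct within-stratum relabelings are enumerated
#' (the observed one playing the role of one permutation), which yields the
#' exact permutation p-value.
#'
#' @param study an [ExpressionStudy-class].
#' @param design design matrix from [buildDesign()].
#' @param nPerm number of random permutations (ignored when exhaustive).
#' @param seed RNG seed for the permutation draws.
#' @param prior optional [VariancePrior-class]; defaults to the prior
#'   estimated from the observed fits.
#' @param strata optional factor of permutation strata; defaults to `batch`
#'   from the study `colData` when present, otherwise a single stratum.
#' @param exhaustive enumerate all distinct relabelings instead of sampling.
#' @return named numeric vector of per-gene permutation p-values.
#' @export
permutationPvalues <- function(study, design, nPerm = 999L, seed = 1L,
                               prior = NULL, strata = NULL,
                               exhaustive = FALSE) {
  if (!exhaustive && nPerm < 1)
    stopf("nPerm must be at least 1")
  group <- groupLabels(study)
  case <- group == "case"
  cd <- colData(study)
  if (is.null(strata))
    strata <- if ("batch" %in% colnames(cd))
      factor(as.character(cd$batch)) else factor(rep(1L, ncol(study)))
  strata <- as.factor(strata)
  tab <- table(strata)
  if (any(tab < 2))
    stopf("configuration error: permutation stratum with a single sample")
  both <- tapply(case, strata, function(x) any(x) && any(!x))
  if (!all(both))
    stopf("configuration error: every permutation stratum must contain both group labels")

  gcol <- attr(design, "groupCol") %||% "groupcase"
  fits <- fitGeneModels(study, design)
  if (is.null(prior)) prior <- estimateVariancePrior(fits)
  tObs <- abs(moderatedStatistics(fits, prior)@t)

  Yt <- t(assay(study))
  n <- nrow(Yt)
  d <- n - ncol(design)
  d0 <- prior@d0; s0 <- prior@s0Sq
  tFor <- function(caseInd) {
    X <- design
    X[, gcol] <- as.numeric(caseInd)
    f <- lm.fit(X, Yt)
    if (f$rank < ncol(X)) return(NULL)  # degenerate permutation
    res <- matrix(f$residuals, nrow = n)
    s2 <- colSums(res^2) / d
    s2t <- if (is.infinite(d0)) rep(s0, length(s2))
           else (d0 * s0 + d * s2) / (d0 + d)
    cg <- chol2inv(chol(crossprod(X)))[match(gcol, colnames(X)),
                                       match(gcol, colnames(X))]
    beta <- matrix(f$coefficients, ncol = ncol(Yt))[match(gcol, colnames(X)), ]
    abs(beta) / sqrt(cg * s2t)
  }

  exceed <- numeric(length(tObs))
  # ties between |t*| and |t_obs| (e.g. sign-flipped relabelings) must count
  # as exceedances; compare with a tiny relative tolerance against float noise
  tRef <- tObs - 1e-12 * pmax(1, tObs)
  if (exhaustive) {
    assigns <- enumerateAssignments(case, strata)
    isObs <- vapply(assigns, function(a) all(a == case), logical(1))
    assigns <- assigns[!isObs]
    B <- length(assigns)
    for (a in assigns) {
      tp <- tFor(a)
      if (!is.null(tp)) exceed <- exceed + (tp >= tRef)
    }
  } else {
    set.seed(seed)
    B <- as.integer(nPerm)
    idxByStratum <- split(seq_len(n), strata)
    for (b in seq_len(B)) {
      perm <- case
      for (ix in idxByStratum) perm[ix] <- sample(case[ix])
      tp <- tFor(perm)
      if (is.null(tp)) exceed <- exceed + 1  # conservative for degenerate draws
      else exceed <- exceed + (tp >= tRef)
    }
  }
  setNames((1 + exceed) / (1 + B), rownames(assay(study)))
}

#' Module eigengene and case-control test
#'
#' Standardizes each gene of a module across samples, extracts first
#' principal-component scores scaled to unit variance, orients the eigengene
#' to correlate positively with the mean standardized expression of the
#' module, and tests for a case-control difference with a two-sided
#' two-sample (Welch) t-test.
#'
#' @param study an [ExpressionStudy-class].
#' @param moduleGenes character vector of gene ids (at least one must be
#'   present in the study).
#' @return list with `eigengene` (named, unit variance),
#'   `varianceExplained`, `pValue`, and `nGenes` used.
#' @export
moduleEigengene <- function(study, moduleGenes) {
  present <- intersect(moduleGenes, rownames(study))
  if (!length(present))
    stopf("none of the module genes are present in the study")
  Z <- assay(study)[present, , drop = FALSE]
  sds <- apply(Z, 1, sd)
  if (all(sds == 0))
    stopf("degenerate input: all module genes are constant")
  if (any(sds == 0)) {
    warnf("%d constant module gene(s) dropped", sum(sds == 0))
    Z <- Z[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  Z <- (Z - rowMeans(Z)) / sds
  sv <- svd(Z)
  scores <- sv$v[, 1] * sv$d[1]
  e <- scores / sd(scores)
  meanProfile <- colMeans(Z)
  orient <- cor(e, meanProfile)
  # two anti-correlated genes make the first PC orthogonal to the mean
  # profile; break the tie on the first gene of the module
  if (!is.finite(orient) || abs(orient) < 1e-8) orient <- cor(e, Z[1, ])
  if (orient < 0) e <- -e
  g <- groupLabels(study)
  pv <- t.test(e[g == "case"], e[g == "control"])$p.value
  list(eigengene = setNames(e, colnames(study)),
       varianceExplained = sv$d[1]^2 / sum(sv$d^2),
       pValue = pv,
       nGenes = nrow(Z))
}
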