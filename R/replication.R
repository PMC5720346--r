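#' Observed/expected cross-study overlap profile
#'
#' For every candidate threshold `t` the profile counts the genes significant
#' in study 1 (`O1 = #\{p1 <= t\}`), in study 2 (`O2`), and in both (`O11`),
#' and compares the joint count with its chance expectation under
#' independence, `E11 = O1 * O2 / N`. The ratio `R = O11 / E11` is the
#' replication signal: values near 1 are what coincidence produces, values of
#' 2 or more mean at least twice as many joint discoveries as chance expects.
#'
#' The default grid is the sorted union of all observed p-values at or below
#' `pMax` from both studies plus the endpoint `pMax` itself; the counts are
#' step functions that change only at observed values, so this grid is exact.
#'
#' @param p1,p2 aligned per-gene p-value vectors (same genes, same order;
#'   names are checked when present). Values must lie in (0, 1].
#' @param pMax upper end of the threshold range (default .05).
#' @param grid optional explicit threshold grid.
#' @param band if `TRUE`, attach a Monte-Carlo uncertainty band on `R`
#'   (2.5/97.5 percent quantiles) from Dirichlet resampling of the 2x2
#'   classification counts.
#' @param nBoot resamples for the band.
#' @param seed seed for the band resampling (local; the caller's RNG state is
#'   untouched).
#' @return an [OverlapProfile-class] object.
#' @export
overlapProfile <- function(p1, p2, pMax = 0.05, grid = NULL, band = FALSE,
                           nBoot = 2000L, seed = 1L) {
  if (!length(p1) || length(p1) != length(p2))
    stopf("input error: p-value vectors must be non-empty and equal length")
  if (!is.null(names(p1)) && !is.null(names(p2)) &&
      !identical(names(p1), names(p2)))
    stopf("input error: p-value vectors are not aligned on the same gene ids")
  if (any(p1 <= 0 | p1 > 1) || any(p2 <= 0 | p2 > 1))
    stopf("input error: p-values must lie in (0, 1]")
  N <- length(p1)
  if (is.null(grid))
    grid <- sort(unique(c(p1[p1 <= pMax], p2[p2 <= pMax], pMax)))
  else
    grid <- sort(unique(grid))
  O1 <- findInterval(grid, sort(p1))
  O2 <- findInterval(grid, sort(p2))
  O11 <- findInterval(grid, sort(pmax(p1, p2)))
  E11 <- O1 * O2 / N
  R <- ifelse(E11 == 0, ifelse(O11 == 0, 0, Inf), O11 / E11)
  tab <- data.frame(threshold = grid, O1 = O1, O2 = O2, O11 = O11,
                    E11 = E11, R = R)
  if (band) {
    qs <- withLocalSeed(seed, {
      t(vapply(seq_along(grid), function(i) {
        rs <- dirichletRatioSamples(O11[i], O1[i] - O11[i], O2[i] - O11[i],
                                    N - O1[i] - O2[i] + O11[i], nBoot)
        quantile(rs, c(0.025, 0.975), na.rm = TRUE)
      }, numeric(2)))
    })
    tab$Rlower <- qs[, 1]
    tab$Rupper <- qs[, 2]
  }
  new("OverlapProfile", grid = tab, nGenes = as.integer(N),
      q2 = NA_real_, ratioRule = 2, pMax = pMax)
}

# Dirichlet resampling of the 2x2 classification counts (n11, n10, n01, n00);
# returns samples of the overlap ratio R = pi11 / (pi1. * pi.1). Cells with a
# zero count stay at zero mass (rgamma with shape 0 is degenerate at 0).
dirichletRatioSamples <- function(n11, n10, n01, n00, B) {
  g11 <- rgamma(B, n11); g10 <- rgamma(B, n10)
  g01 <- rgamma(B, n01); g00 <- rgamma(B, n00)
  tot <- g11 + g10 + g01 + g00
  num <- g11 * tot
  den <- (g11 + g10) * (g11 + g01)
  ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
}

#' Select the replication threshold q2
#'
#' Finds the largest (most lenient) p-value threshold at or below `pMax` at
#' which the two studies share at least `ratioRule` times as many significant
#' genes as expected by chance. Two selection methods are available:
#'
#' * `"credible"` (default): the threshold qualifies when the posterior
#'   probability that the overlap ratio is at least `ratioRule` reaches
#'   `conf`, under Dirichlet resampling of the observed 2x2 counts. This
#'   guards the rule against the small-count instability of the raw ratio
#'   (a single coincidental joint gene at a tiny threshold makes
#'   `O11/E11 >= 2` with substantial probability under the null), and keeps
#'   the selection quiet on null data.
#' * `"point"`: the literal rule `R >= ratioRule` on the point estimate.
#'
#' @param profile an [OverlapProfile-class].
#' @param ratioRule required overlap ratio (default 2: "at least twice as
#'   many as expected by chance").
#' @param pMax largest admissible threshold (default .05).
#' @param method `"credible"` or `"point"`.
#' @param conf posterior probability required under the credible rule.
#' @param nBoot Dirichlet resamples per candidate threshold.
#' @param seed seed for the resampling (local RNG).
#' @return the selected threshold, or `NA` (with a message) when no
#'   threshold qualifies ("no replicated signal").
#' @export
selectQ2 <- function(profile, ratioRule = 2, pMax = 0.05,
                     method = c("credible", "point"), conf = 0.99,
                     nBoot = 2000L, seed = 1L) {
  method <- match.arg(method)
  g <- profile@grid
  cand <- which(g$threshold <= pMax & g$R >= ratioRule & g$O11 >= 1)
  if (!length(cand)) {
    message("no replicated signal: no threshold reaches the overlap-ratio rule")
    return(NA_real_)
  }
  if (method == "point")
    return(g$threshold[max(cand)])
  N <- profile@nGenes
  sel <- withLocalSeed(seed, {
    hit <- NA_real_
    for (i in rev(cand)) {
      rs <- dirichletRatioSamples(g$O11[i], g$O1[i] - g$O11[i],
                                  g$O2[i] - g$O11[i],
                                  N - g$O1[i] - g$O2[i] + g$O11[i], nBoot)
      if (mean(rs >= ratioRule) >= conf) { hit <- g$threshold[i]; break }
    }
    hit
  })
  if (is.na(sel))
    message("no replicated signal: overlap ratio never exceeds ",
            ratioRule, " with ", conf, " posterior probability")
  sel
}

#' Sign-concordant consensus gene set
#'
#' Genes significant in both studies at `q2` are partitioned by the sign of
#' their log2 fold changes: positive in both studies goes to UP, negative in
#' both to DOWN, anything else (including a fold change of exactly zero) is
#' discordant.
#'
#' @param stats1,stats2 [GeneStats-class] objects aligned on the same genes.
#' @param q2 replication threshold in (0, pMax].
#' @return a [ConsensusSet-class].
#' @export
consensusSet <- function(stats1, stats2, q2) {
  if (!identical(stats1@geneIDs, stats2@geneIDs))
    stopf("input error: gene statistics are not aligned on the same gene ids")
  if (is.na(q2) || q2 <= 0 || q2 > 0.05 + 1e-12)
    stopf("q2 must lie in (0, 0.05]")
  pass <- stats1@pValue <= q2 & stats2@pValue <= q2
  f1 <- stats1@logFC[pass]
  f2 <- stats2@logFC[pass]
  ids <- stats1@geneIDs[pass]
  up <- ids[f1 > 0 & f2 > 0]
  down <- ids[f1 < 0 & f2 < 0]
  disc <- setdiff(ids, c(up, down))
  new("ConsensusSet", up = up, down = down, discordant = disc, q2 = q2)
}

#' Fisher's combined probability test across two studies
#'
#' Per gene, \eqn{X^2 = -2(\ln p_1 + \ln p_2)} referred to the upper tail of
#' a chi-square distribution with 4 degrees of freedom. When `fdrLevel` is
#' given the combined p-values are also adjusted by Benjamini-Hochberg and
#' flagged at that level.
#'
#' @param p1,p2 aligned per-gene p-values in (0, 1]; exact zeros are an
#'   error (floor them first).
#' @param geneIDs optional ids (defaults to names of `p1`).
#' @param fdrLevel optional FDR level for rejection flags (e.g. 0.10).
#' @return a [CombinedTest-class].
#' @export
fisherCombine <- function(p1, p2, geneIDs = names(p1), fdrLevel = NA_real_) {
  if (!length(p1) || length(p1) != length(p2))
    stopf("input error: p-value vectors must be non-empty and equal length")
  if (any(p1 <= 0) || any(p2 <= 0))
    stopf("input error: p-values of zero are not admissible; floor them first")
  if (any(p1 > 1) || any(p2 > 1))
    stopf("input error: p-values must lie in (0, 1]")
  x2 <- -2 * (log(p1) + log(p2))
  p <- pchisq(x2, df = 4, lower.tail = FALSE)
  p <- floorPValues(p)
  if (is.null(geneIDs)) geneIDs <- as.character(seq_along(p1))
  if (!is.na(fdrLevel)) {
    fdr <- bhFdr(p, fdrLevel)
    q <- fdr$qValues; rej <- fdr$rejected
  } else {
    q <- rep(NA_real_, length(p)); rej <- rep(NA, length(p))
  }
  new("CombinedTest", geneIDs = unname(geneIDs), statistic = unname(x2),
      pValue = unname(p), qValue = unname(q), rejected = unname(rej),
      fdrLevel = fdrLevel)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' @param p vector of p-values in (0, 1].
#' @param level FDR level.
#' @return list with `qValues` (running-minimum adjusted p-values) and
#'   `rejected` (logical).
#' @export
bhFdr <- function(p, level = 0.05) {
  if (!length(p)) stopf("input error: empty p-value vector")
  if (any(p <= 0 | p > 1)) stopf("input error: p-values must lie in (0, 1]")
  q <- p.adjust(p, method = "BH")
  list(qValues = q, rejected = q <= level)
}

#' Expected chance overlap of two gene lists
#'
#' Mean of the hypergeometric intersection size of random lists of sizes
#' `nA` and `nB` drawn from a universe of `N` genes: `nA * nB / N`.
#'
#' @param nA,nB list sizes.
#' @param N universe size.
#' @return expected intersection size.
#' @examples
#' expectedOverlap(100, 100, 1000)  # 10
#' @export
expectedOverlap <- function(nA, nB, N) {
  if (N <= 0) stopf("input error: universe size must be positive")
  if (nA < 0 || nB < 0 || nA > N || nB > N)
    stopf("input error: list sizes must lie in [0, N]")
  nA * nB / N
}
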