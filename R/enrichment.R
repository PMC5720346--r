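#' Load gene sets from a GMT file
#'
#' Reads the tab-separated GMT dialect (term id, description, then member
#' genes) and restricts every set to the supplied measurement universe.
#' Duplicate members within a line are counted once; sets that are empty
#' after restriction are dropped with a warning.
#'
#' @param gmtPath path to the GMT file.
#' @param universe character vector of measured gene ids (the enrichment
#'   universe; typically the genes on the platform, not the genome).
#' @return a [GeneSetCollection-class].
#' @export
loadGeneSets <- function(gmtPath, universe) {
  if (!file.exists(gmtPath)) stopf("GMT file not found: %s", gmtPath)
  lines <- readLines(gmtPath)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stopf("parse error: GMT line %d has fewer than 3 tab-separated fields",
          bad[1])
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stopf("parse error: duplicated term id '%s'", ids[duplicated(ids)][1])
  descs <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  universe <- unique(universe)
  sets <- lapply(sets, intersect, universe)
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warnf("%d gene set(s) empty after restriction to the universe; dropped",
          sum(empty))
    sets <- sets[!empty]
    descs <- descs[!empty]
    ids <- ids[!empty]
  }
  new("GeneSetCollection", sets = sets,
      termNames = setNames(descs, ids), universe = universe)
}

#' Per-term Fisher's exact enrichment
#'
#' Classic independent-term enrichment: for each set the one-sided
#' hypergeometric upper-tail probability of observing at least the found
#' overlap between the query and the set, within the measurement universe.
#' Rows report `annotated` (set size in the universe), `found` (overlap with
#' the query), `expected` (`annotated * |query| / |universe|`), the Fisher
#' p-value, a Bonferroni-significance flag at `alpha` over the number of
#' terms, and a depletion flag (`found < expected`; flagged, never tested).
#' Rows are ranked by p-value.
#'
#' @param query character vector of gene ids; members outside the universe
#'   are trimmed with a warning.
#' @param collection a [GeneSetCollection-class].
#' @param alpha family-wise error level for the Bonferroni flag.
#' @return data.frame with columns `termID`, `termName`, `annotated`,
#'   `found`, `expected`, `pValue`, `bonferroni`, `depleted`.
#' @export
fisherEnrichment <- function(query, collection, alpha = 0.05) {
  uni <- collection@universe
  query <- unique(query)
  outside <- setdiff(query, uni)
  if (length(outside)) {
    warnf("%d query gene(s) outside the universe trimmed", length(outside))
    query <- intersect(query, uni)
  }
  if (!length(query))
    stopf("input error: query is empty after restriction to the universe")
  Nu <- length(uni)
  nq <- length(query)
  ann <- lengths(collection@sets)
  found <- vapply(collection@sets, function(s) length(intersect(s, query)),
                  integer(1))
  expected <- ann * nq / Nu
  p <- phyper(found - 1L, ann, Nu - ann, nq, lower.tail = FALSE)
  p <- floorPValues(pmin(p, 1))
  thr <- bonferroniThreshold(alpha, length(collection@sets))
  out <- data.frame(termID = names(collection@sets),
                    termName = unname(collection@termNames[names(collection@sets)]),
                    annotated = unname(ann),
                    found = unname(found),
                    expected = unname(expected),
                    pValue = unname(p),
                    bonferroni = unname(p <= thr),
                    depleted = unname(found < expected),
                    stringsAsFactors = FALSE)
  out[order(out$pValue, out$termID), , drop = FALSE]
}

#' Bonferroni per-test threshold
#'
#' @param alpha family-wise error level in (0, 1).
#' @param nTerms number of tests.
#' @return `alpha / nTerms`.
#' @examples
#' bonferroniThreshold(0.05, 10124)  # 4.94e-06
#' @export
bonferroniThreshold <- function(alpha, nTerms) {
  if (alpha <= 0 || alpha >= 1) stopf("input error: alpha must lie in (0, 1)")
  if (nTerms < 1) stopf("input error: nTerms must be at least 1")
  alpha / nTerms
}
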