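test_that("overlap counting equals a brute-force double loop", {
  set.seed(14)
  for (rep in 1:5) {
    N <- 50
    p1 <- setNames(runif(N)^2, sprintf("g%03d", 1:N))
    p2 <- setNames(runif(N)^2, names(p1))
    prof <- overlapProfile(p1, p2)
    g <- profileTable(prof)
    for (i in seq_len(nrow(g))) {
      t <- g$threshold[i]
      o1 <- sum(p1 <= t); o2 <- sum(p2 <= t)
      o11 <- sum(p1 <= t & p2 <= t)
      expect_identical(g$O1[i], o1)
      expect_identical(g$O2[i], o2)
      expect_identical(g$O11[i], o11)
      expect_equal(g$E11[i], o1 * o2 / N)
    }
  }
})

test_that("overlap profile handles saturated and disjoint lists", {
  # all p identical and tiny: lists saturate, R collapses to 1
  p <- setNames(rep(0.001, 10), paste0("g", 1:10))
  g <- profileTable(overlapProfile(p, p))
  at <- g[g$threshold >= 0.001, ]
  expect_true(all(at$O1 == 10 & at$O2 == 10 & at$O11 == 10))
  expect_true(all(at$E11 == 10 & at$R == 1))

  # significant genes disjoint between studies
  p1 <- setNames(c(rep(0.001, 5), rep(0.8, 5)), paste0("g", 1:10))
  p2 <- setNames(c(rep(0.8, 5), rep(0.001, 5)), paste0("g", 1:10))
  g2 <- profileTable(overlapProfile(p1, p2))
  expect_true(all(g2$O11 == 0))
  expect_true(all(g2$R == 0))

  expect_error(overlapProfile(numeric(0), numeric(0)), "non-empty")
  expect_error(overlapProfile(setNames(0.5, "a"), setNames(0.5, "b")),
               "aligned")
  expect_error(overlapProfile(c(0, 0.5), c(0.5, 0.5)), "\\(0, 1\\]")
})

test_that("q2 selection follows the ratio rule on constructed profiles", {
  grid <- data.frame(threshold = c(.01, .02, .03, .04),
                     O1 = c(100, 120, 200, 300), O2 = c(100, 120, 200, 300),
                     O11 = c(30, 36, 84, 162),
                     E11 = c(10, 14.4, 40, 90),
                     R = c(3.0, 2.5, 2.1, 1.8))
  prof <- new("OverlapProfile", grid = grid, nGenes = 1000L,
              q2 = NA_real_, ratioRule = 2, pMax = 0.05)
  expect_equal(selectQ2(prof, method = "point"), 0.03)

  # boundary: R = 2.0 exactly at t = .05 still qualifies ("at least twice")
  gb <- data.frame(threshold = .05, O1 = 100, O2 = 100, O11 = 20,
                   E11 = 10, R = 2.0)
  profB <- new("OverlapProfile", grid = gb, nGenes = 1000L,
               q2 = NA_real_, ratioRule = 2, pMax = 0.05)
  expect_equal(selectQ2(profB, method = "point"), 0.05)

  # R < 2 everywhere: null result with a "no replicated signal" notice
  gn <- transform(grid, R = c(1.5, 1.4, 1.2, 1.1))
  profN <- new("OverlapProfile", grid = gn, nGenes = 1000L,
               q2 = NA_real_, ratioRule = 2, pMax = 0.05)
  expect_message(qn <- selectQ2(profN, method = "point"),
                 "no replicated signal")
  expect_true(is.na(qn))

  # the credible rule agrees with the point rule when the ratio is decisive
  gd <- data.frame(threshold = c(.02, .03, .04),
                   O1 = c(200, 320, 400), O2 = c(200, 320, 400),
                   O11 = c(180, 300, 310),
                   E11 = c(40, 102.4, 160),
                   R = c(4.5, 2.93, 1.94))
  profD <- new("OverlapProfile", grid = gd, nGenes = 1000L,
               q2 = NA_real_, ratioRule = 2, pMax = 0.05)
  expect_equal(selectQ2(profD, method = "credible", seed = 2), 0.03)
  expect_equal(selectQ2(profD, method = "point"), 0.03)
  # on thin counts the credible rule is stricter than the point rule
  expect_true(selectQ2(prof, method = "credible", seed = 2) <= 0.03)
})

test_that("consensus sets partition threshold-passing genes by sign", {
  p1 <- c(.01, .01, .01, .01, .01, .5)
  p2 <- c(.02, .02, .02, .02, .02, .5)
  f1 <- c(1, -1, 1, 1, -1, 2)
  f2 <- c(1, -1, -1, 1, -1, 2)
  s1 <- makeGeneStats(p1, f1)
  s2 <- makeGeneStats(p2, f2)
  cs <- consensusSet(s1, s2, 0.025)
  expect_length(upGenes(cs), 2)
  expect_length(downGenes(cs), 2)
  expect_length(discordantGenes(cs), 1)

  # fold change exactly zero routes to discordant
  s1z <- makeGeneStats(c(.01, .01), c(0, 1))
  s2z <- makeGeneStats(c(.01, .01), c(1, 1))
  csz <- consensusSet(s1z, s2z, 0.02)
  expect_identical(discordantGenes(csz), "g001")
  expect_identical(upGenes(csz), "g002")

  expect_error(consensusSet(s1, makeGeneStats(p2, f2, ids = rev(s2@geneIDs)),
                            0.02), "aligned")
  expect_error(consensusSet(s1, s2, NA), "q2")
})

test_that("consensus recovers planted signs in simulation", {
  cfg <- simConfig(nGenes = 1200, study1 = c(cases = 60, controls = 60),
                   study2 = c(cases = 60, controls = 60),
                   nSharedDE = 100, nSpecificDE = c(0, 0), seed = 19)
  sim <- generateTwoStudies(cfg)
  s1 <- studyStats(sim$study1)
  s2 <- studyStats(sim$study2)
  cs <- consensusSet(s1, s2, 0.01)
  tr <- sim$truth@sharedDE
  recoveredUp <- intersect(upGenes(cs), tr$geneID)
  recoveredDown <- intersect(downGenes(cs), tr$geneID)
  expect_true(all(tr$sign[match(recoveredUp, tr$geneID)] == 1))
  expect_true(all(tr$sign[match(recoveredDown, tr$geneID)] == -1))
  expect_gt(length(recoveredUp) + length(recoveredDown), 80)
})

test_that("Fisher combination matches the chi-square(4) closed form", {
  ct <- fisherCombine(c(1, 0.1), c(1, 0.1))
  expect_equal(ct@statistic[1], 0)
  expect_equal(ct@pValue[1], 1)
  expect_equal(ct@statistic[2], -4 * log(0.1), tolerance = 1e-12)
  # survival function of chi-square(4): exp(-x/2) (1 + x/2)
  x <- ct@statistic[2]
  expect_equal(ct@pValue[2], exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  expect_equal(round(ct@pValue[2], 4), 0.0561)
  expect_equal(round(x, 4), 9.2103)

  # monotone nondecreasing in each input
  ps <- seq(0.01, 1, by = 0.01)
  combined <- fisherCombine(ps, rep(0.3, length(ps)))@pValue
  expect_true(all(diff(combined) >= -1e-15))

  expect_error(fisherCombine(c(0, .5), c(.5, .5)), "zero")
})

test_that("BH step-up matches hand enumeration", {
  r <- bhFdr(c(.005, .01, .03, .04), level = .05)
  expect_true(all(r$rejected))
  expect_equal(r$qValues, c(.02, .02, .04, .04))

  r1 <- bhFdr(rep(1, 5), level = .05)
  expect_false(any(r1$rejected))
  expect_true(all(r1$qValues == 1))

  r2 <- bhFdr(.04, level = .05)
  expect_true(r2$rejected)
  expect_equal(r2$qValues, .04)

  expect_error(bhFdr(numeric(0)), "empty")
})

test_that("expected chance overlap is the hypergeometric mean", {
  expect_equal(expectedOverlap(100, 100, 1000), 10)
  expect_equal(expectedOverlap(0, 50, 100), 0)
  expect_error(expectedOverlap(10, 200, 100), "\\[0, N\\]")

  # resampling oracle
  set.seed(33)
  draws <- replicate(10000, {
    length(intersect(sample(100, 20), sample(100, 30)))
  })
  expect_lt(abs(mean(draws) - expectedOverlap(20, 30, 100)), 0.08)
})

test_that("null studies rarely trigger q2 under the credible rule", {
  # two independent uniform p-value vectors; a handful of seeds here, the
  # full 50-seed calibration runs in the acceptance suite
  fired <- vapply(1:8, function(s) {
    set.seed(s)
    p1 <- setNames(runif(3000), sprintf("g%04d", 1:3000))
    p2 <- setNames(runif(3000), names(p1))
    prof <- overlapProfile(p1, p2)
    !is.na(suppressMessages(selectQ2(prof, seed = s)))
  }, logical(1))
  expect_lte(sum(fired), 1)
})
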