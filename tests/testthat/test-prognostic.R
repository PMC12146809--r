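test_that("FLIPI2 scoring counts adverse factors and names missing ones", {
  d <- data.frame(age = c(50, 65, 70), hb = c(13, 11, 13),
                  b2m_gt_uln = c(FALSE, FALSE, TRUE),
                  bm_involved = c(FALSE, TRUE, TRUE),
                  lodlin_gt6cm = c(FALSE, FALSE, TRUE))
  s <- flipi2Score(d)
  expect_equal(s$score, c(0, 3, 4))
  expect_equal(s$class, c("intermediate", "high", "high"))
  expect_error(flipi2Score(d[, -3]), "b2m_gt_uln")
  # exactly {age>60, BM+, Hb<12} is 3 of 5: high
  d3 <- data.frame(age_gt60 = TRUE, hb_lt12 = TRUE, b2m_gt_uln = FALSE,
                   bm_involved = TRUE, lodlin_gt6cm = FALSE)
  expect_equal(flipi2Score(d3)$class, "high")
})

test_that("classical FLIPI scoring spans 0 to 5", {
  d <- data.frame(age = c(40, 70), stage = c("II", "IV"),
                  hb = c(14, 10), ldh_gt_uln = c(FALSE, TRUE),
                  nodal_areas = c(2, 7))
  s <- flipiScore(d)
  expect_equal(s$score, c(0, 5))
  expect_equal(s$class, c("low-intermediate", "high"))
  expect_error(flipiScore(d[, -4]), "ldh_gt_uln")
})

test_that("FLIPI2 discriminates better than FLIPI when its factors drive risk", {
  # the simulated hazard works through FLIPI2-high, so FLIPI2 should win
  wins <- vapply(1:7, function(s) {
    co <- makeCohort(500, 1100 + s)
    cF2 <- concordanceHarrell(co$flipi2_score, co$pfs_time, co$pfs_event)$c
    cF1 <- concordanceHarrell(co$flipi_score, co$pfs_time, co$pfs_event)$c
    cF2 > cF1
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("combined risk grouping maps adverse-feature counts", {
  expect_equal(as.character(combinedRiskGroup(150, 180, "intermediate")),
               "low")
  expect_equal(as.character(combinedRiskGroup(400, 180, "intermediate")),
               "intermediate")
  expect_equal(as.character(combinedRiskGroup(150, 180, "high")),
               "intermediate")
  expect_equal(as.character(combinedRiskGroup(400, 180, "high")), "high")
  # partitions a cohort
  co <- makeCohort(300, 51)
  g <- combinedRiskGroup(co$tmtv, 180, co$flipi2_high)
  expect_equal(sum(table(g)), 300)
})

test_that("risk groups order hazards as expected in effect simulations", {
  ok <- vapply(1:6, function(s) {
    co <- makeCohort(700, 1200 + s)
    g <- combinedRiskGroup(co$tmtv, 180, co$flipi2_high)
    co$.int <- as.numeric(g == "intermediate")
    co$.high <- as.numeric(g == "high")
    m <- coxFit(co, c(".int", ".high"), "arm")
    hrInt <- m$table$hr[m$table$term == ".int"]
    hrHigh <- m$table$hr[m$table$term == ".high"]
    hrHigh > hrInt && hrInt > 1
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("univariable table recovers an injected effect and flags degenerates", {
  co <- makeCohort(600, 52)
  co$noise <- withr::with_seed(520, rbinom(nrow(co), 1, 0.5))
  co$allsame <- 1
  tab <- univariableTable(co, c("flipi2_high", "noise", "allsame"), "arm")
  expect_equal(nrow(tab), 3)
  # injected FLIPI2 effect (true HR 2.0) is covered by its CI
  r <- tab[tab$covariate == "flipi2_high", ]
  expect_true(r$lower < 2.0 && 2.0 < r$upper)
  # pure noise centered near 1
  rn <- tab[tab$covariate == "noise", ]
  expect_true(rn$lower < 1 && 1 < rn$upper)
  expect_match(tab$note[tab$covariate == "allsame"], "degenerate")
  # duplicated cohort halves as two strata reproduce the single-copy HR
  co2 <- rbind(transform(co, st = 1), transform(co, st = 2))
  t1 <- univariableTable(co, "flipi2_high")
  t2 <- univariableTable(co2, "flipi2_high", strata = "st")
  expect_equal(t2$hr, t1$hr, tolerance = 1e-8)
})

test_that("multivariable model reports TMTV in both forms", {
  co <- makeCohort(600, 53)
  mm <- multivariableModel(co, cut = 180)
  expect_true("tmtv_per500" %in% mm$continuous$table$term)
  expect_true("tmtv_hi" %in% mm$dichotomized$table$term)
  # adjusted dichotomized HR covers the injected conditional HR 1.6
  r <- mm$dichotomized$table[mm$dichotomized$table$term == "tmtv_hi", ]
  expect_true(r$lower < 1.6 && 1.6 < r$upper)
  expect_equal(mm$hrPer500$hr,
               exp(mm$continuous$table$coef[
                 mm$continuous$table$term == "tmtv_per500"]))
})

test_that("confounding attenuates the adjusted TMTV hazard ratio", {
  direction <- vapply(1:6, function(s) {
    co <- makeCohort(700, 1300 + s, factorLoading = 0.6)
    co$.hi <- as.numeric(co$tmtv > 180)
    uni <- coxFit(co, ".hi", "arm")$table$hr[1]
    adj <- coxFit(co, c(".hi", "flipi2_high"), "arm")$table$hr[1]
    adj < uni
  }, logical(1))
  expect_gt(mean(direction), 0.5)
})

test_that("POD24 analysis matches exhaustive hypergeometric enumeration", {
  # the published contingency table: 58/310 vs 42/354
  tab <- matrix(c(58, 310 - 58, 42, 354 - 42), 2, byrow = TRUE)
  pOracle <- oracleFisher(58, 252, 42, 312)
  expect_equal(fisher.test(tab)$p.value, pOracle, tolerance = 1e-9)
  expect_lt(pOracle, 0.05)  # same conclusion as the printed 0.017
  # small table equals enumeration
  expect_equal(fisher.test(matrix(c(3, 7, 1, 9), 2,
                                  byrow = TRUE))$p.value,
               oracleFisher(3, 7, 1, 9), tolerance = 1e-12)
  # identical proportions: p = 1 up to discreteness
  expect_equal(fisher.test(matrix(c(5, 45, 5, 45), 2))$p.value, 1)
  # random 2x2 tables with n <= 40 agree with the oracle
  set.seed(55)
  for (i in 1:40) {
    a <- rbinom(1, 10, 0.4); b <- rbinom(1, 10, 0.5)
    c0 <- rbinom(1, 10, 0.4); d0 <- rbinom(1, 10, 0.5)
    expect_equal(fisher.test(matrix(c(a, b, c0, d0), 2,
                                    byrow = TRUE))$p.value,
                 oracleFisher(a, b, c0, d0), tolerance = 1e-9)
  }
})

test_that("pod24 applies the evaluability rule and both tests", {
  co <- makeCohort(800, 56)
  p <- pod24(co, 180)
  # evaluability: event before 24 months or at least 24 months follow-up
  expected <- sum(co$pfs_time >= 24 | (co$pfs_event == 1 & co$pfs_time < 24))
  expect_equal(p$evaluable, expected)
  expect_equal(sum(p$table), expected)
  expect_equal(p$p, fisher.test(p$table)$p.value)
  pc <- pod24(co, 180, test = "chisq")
  expect_false(identical(p$p, pc$p))
  # high-TMTV group progresses early more often under the step hazard
  expect_gt(p$proportions[["high"]], p$proportions[["low"]])
  none <- data.frame(tmtv = c(100, 300), pfs_time = c(5, 9),
                     pfs_event = c(0, 0))
  expect_error(pod24(none, 180), "evaluable")
})

test_that("model comparison: redundant covariates add nothing", {
  co <- makeCohort(400, 57)
  co$dup <- co$flipi2_high
  mc <- modelComparison(co, "flipi2_high", "dup", "arm")
  expect_lt(abs(mc$deltaC), 1e-8)
  # an informative added covariate increases c in most replicates
  gains <- vapply(1:6, function(s) {
    cc <- makeCohort(500, 1400 + s)
    cc$.hi <- as.numeric(cc$tmtv > 180)
    modelComparison(cc, "flipi2_high", ".hi", "arm")$deltaC
  }, numeric(1))
  expect_gt(mean(gains > 0), 0.5)
})

test_that("bootstrap inclusion fraction behaves at the extremes", {
  co <- makeCohort(400, 58)
  b1 <- bif(co, 180, B = 1, seed = 3)
  expect_true(b1$lrtFraction %in% c(0, 1))
  b <- bif(co, 180, B = 12, seed = 4)
  expect_identical(bif(co, 180, B = 12, seed = 4)$lrtFraction,
                   b$lrtFraction)
  expect_true(b$lrtFraction >= 0 && b$lrtFraction <= 1)
  # a strong injected effect is almost always retained
  coS <- makeCohort(700, 59, logHr = list(tmtvStep = log(2)))
  bS <- bif(coS, 180, B = 200, seed = 5)
  expect_gt(bS$lrtFraction, 0.9)
  expect_gt(bS$aicFraction, 0.9)
})

test_that("Bland-Altman agreement has the documented conventions", {
  m <- simulateReaders(c(100, 200, 300), k = 2, cv = 0)
  ba <- blandAltman(m)
  expect_equal(ba$bias, 0)
  expect_equal(ba$cvPct, 0)
  # one reader exactly 10% above the other: bias is -10% of the mean scale
  x <- c(120, 250, 340, 180)
  m2 <- rbind(x, 1.10 * x)
  ba2 <- blandAltman(m2)
  expect_equal(ba2$bias, -0.10 * mean(x))
  expect_equal(ba2$pairs, 4)
  expect_error(blandAltman(m2[1, , drop = FALSE]), "two readers")
  # three readers pool all pairs
  ba3 <- blandAltman(rbind(x, x, x))
  expect_equal(ba3$pairs, 12)
  expect_equal(ba3$cvPct, 0)
})
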