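test_that("Kaplan-Meier estimate matches hand computation", {
  # censored at 1, event at 2, censored at 3: S(2) = 1 x (1 - 1/2) = 0.5
  d <- data.frame(pfs_time = c(1, 2, 3), pfs_event = c(0, 1, 0))
  km <- kmEstimate(d)
  expect_equal(survivalAt(km, 2), 0.5)
  expect_equal(survivalAt(km, 1.5), 1)    # before the first event
  expect_equal(survivalAt(km, 10), 0.5)   # carried forward
  # no events: S(t) = 1 everywhere
  km1 <- kmEstimate(data.frame(pfs_time = 1:5, pfs_event = rep(0, 5)))
  expect_equal(survivalAt(km1, c(1, 3, 99)), c(1, 1, 1))
  # all events at distinct times, n = 4: S after k-th event = (4 - k)/4
  km2 <- kmEstimate(data.frame(pfs_time = 1:4, pfs_event = rep(1, 4)))
  expect_equal(survivalAt(km2, 1:4), c(3, 2, 1, 0) / 4)
  expect_error(kmEstimate(data.frame(pfs_time = numeric(),
                                     pfs_event = numeric())), "empty")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(21)
  tt <- round(rexp(40, 0.1), 1) + 0.1
  d <- data.frame(pfs_time = tt, pfs_event = rep(1, 40))
  km <- kmEstimate(d)
  for (t0 in quantile(tt, c(0.2, 0.5, 0.8)))
    expect_equal(survivalAt(km, t0), mean(tt > t0))
})

test_that("log-rank test equals the hypergeometric oracle", {
  # duplicated data in two identical groups: statistic exactly 0
  d0 <- survFixture()
  dup <- rbind(transform(d0, g = "a"), transform(d0, g = "b"))
  expect_equal(logrankTest(dup, "g")$chisq, 0, tolerance = 1e-12)
  # hand-enumerable 6-subject fixture
  d <- data.frame(pfs_time = c(1, 2, 3, 4, 5, 6),
                  pfs_event = c(1, 1, 0, 1, 1, 1),
                  g = c("a", "b", "a", "b", "a", "b"))
  lr <- logrankTest(d, "g")
  expect_equal(lr$chisq, oracleLogrank(d$pfs_time, d$pfs_event, d$g),
               tolerance = 1e-10)
  expect_equal(lr$df, 1)
  # larger random fixture
  set.seed(5)
  d2 <- data.frame(pfs_time = sample(1:20, 30, TRUE),
                   pfs_event = rbinom(30, 1, 0.7),
                   g = sample(c("x", "y"), 30, TRUE))
  expect_equal(logrankTest(d2, "g")$chisq,
               oracleLogrank(d2$pfs_time, d2$pfs_event, d2$g),
               tolerance = 1e-10)
  # stratified with a single stratum equals unstratified
  d2$s <- "only"
  expect_equal(logrankTest(d2, "g", strata = "s")$chisq,
               logrankTest(d2, "g")$chisq)
  expect_error(logrankTest(transform(d2, g = "x"), "g"), "two groups")
})

test_that("Cox fit matches grid-search partial-likelihood maximization", {
  d <- data.frame(pfs_time = c(2, 4, 5, 7, 9, 11),
                  pfs_event = c(1, 1, 0, 1, 1, 1),
                  x = c(1, 0, 1, 1, 0, 0))
  fit <- coxFit(d, "x")
  bStar <- oracleCoxGrid(d$pfs_time, d$pfs_event, d$x)
  expect_equal(fit$table$coef[1], bStar, tolerance = 1e-4)
  # with ties (Efron handling)
  d2 <- data.frame(pfs_time = c(2, 2, 3, 3, 5, 8, 8, 9),
                   pfs_event = c(1, 1, 1, 0, 1, 1, 1, 0),
                   x = c(1, 0, 1, 1, 0, 1, 0, 0))
  expect_equal(coxFit(d2, "x")$table$coef[1],
               oracleCoxGrid(d2$pfs_time, d2$pfs_event, d2$x),
               tolerance = 1e-4)
  # reported quantities are internally consistent
  expect_equal(fit$table$hr, exp(fit$table$coef))
  expect_equal(fit$aic, -2 * fit$loglik + 2)
  # constant covariate carries no information and is flagged
  d$z <- 1
  expect_warning(fitZ <- coxFit(d, "z"), regexp = NA, class = NULL)
  expect_true("z" %in% fitZ$degenerate)
})

test_that("Cox estimates are shift-invariant and scale-equivariant", {
  co <- makeCohort(150, 31)
  f1 <- coxFit(co, "tmtv")
  f2 <- coxFit(transform(co, tmtv = tmtv + 1000), "tmtv")
  f3 <- coxFit(transform(co, tmtv = tmtv / 10), "tmtv")
  expect_equal(f1$table$coef, f2$table$coef, tolerance = 1e-6)
  expect_equal(10 * f1$table$coef, f3$table$coef, tolerance = 1e-6)
})

test_that("hazard ratio per increment transforms coefficient and CI", {
  co <- makeCohort(150, 32)
  fit <- coxFit(co, "tmtv")
  h <- hrPerIncrement(fit, "tmtv", 500)
  expect_equal(h$hr, exp(500 * fit$table$coef[1]))
  expect_equal(h$lower, exp(500 * (fit$table$coef[1] -
                                   qnorm(0.975) * fit$table$se[1])))
  # zero coefficient gives HR 1 for any increment
  fake <- fit; fake$table$coef[1] <- 0
  expect_equal(hrPerIncrement(fake, "tmtv", 500)$hr, 1)
})

test_that("restricted cubic spline basis has the restriction properties", {
  set.seed(8)
  x <- c(runif(300, 0, 100), -50, 200)
  kn <- rcsKnots(x, 5)
  expect_equal(length(kn), 5)
  b <- rcsBasis(x, kn)
  # k knots give k - 1 columns; k = 3 gives exactly 2
  expect_equal(ncol(b), 4)
  expect_equal(ncol(rcsBasis(x, rcsKnots(x, 3))), 2)
  # below the first knot the nonlinear columns vanish (exactly linear)
  below <- x < kn[1]
  expect_true(all(abs(b[below, -1]) == 0))
  # beyond the last knot every column is affine: zero second differences
  xs <- kn[5] + c(10, 20, 30)
  bb <- rcsBasis(xs, kn)
  for (j in seq_len(ncol(bb)))
    expect_lt(abs(bb[1, j] - 2 * bb[2, j] + bb[3, j]), 1e-8)
  # continuous second derivative at each interior knot: the numerical
  # jump across the knot is O(h) (it shrinks proportionally with the
  # step), whereas a discontinuous second derivative would leave an O(1)
  # jump independent of h
  jumpAt <- function(t0, h) {
    d2 <- function(z) (rcsBasis(z + h, kn) - 2 * rcsBasis(z, kn) +
                         rcsBasis(z - h, kn)) / h^2
    max(abs(d2(t0 + h) - d2(t0 - h)))
  }
  span <- diff(range(kn))
  d2scale <- max(abs((rcsBasis(kn[4] + 1, kn) - 2 * rcsBasis(kn[4], kn) +
                        rcsBasis(kn[4] - 1, kn))))
  for (t0 in kn[2:4]) {
    j1 <- jumpAt(t0, 1e-3 * span)
    j2 <- jumpAt(t0, 5e-4 * span)
    expect_lt(j1, 1e-2 * max(d2scale, 1e-6))  # tiny relative to curvature
    expect_lt(j2, 0.7 * j1 + 1e-12)           # shrinks with the step
  }
  # Harrell quantile placement for k = 5
  expect_equal(kn, unname(quantile(x, c(0.05, 0.275, 0.5, 0.725, 0.95))))
})

test_that("bootstrap knot selection reduces to in-sample AIC at B = 1", {
  co <- makeCohort(250, 33)
  ks <- selectKnotsBootstrap(co, "tmtv", kRange = 3:5, B = 1, seed = 1)
  direct <- vapply(3:5, function(k)
    coxRcsFitForTest(co, k), numeric(1))
  expect_equal(unname(ks$aicMean), direct, tolerance = 1e-8)
  expect_equal(ks$k, (3:5)[which.min(direct)])
  # deterministic per seed
  ks2 <- selectKnotsBootstrap(co, "tmtv", kRange = 3:4, B = 5, seed = 9)
  ks3 <- selectKnotsBootstrap(co, "tmtv", kRange = 3:4, B = 5, seed = 9)
  expect_identical(ks2$aicTrace, ks3$aicTrace)
})

test_that("concordance equals the all-pairs oracle and has sane bounds", {
  # scores equal to reversed event-time ranks: perfect concordance
  d <- data.frame(t = c(3, 1, 4, 2, 5), e = rep(1, 5))
  expect_equal(concordanceHarrell(-rank(d$t), d$t, d$e)$c, 1)
  # random scores on large data: near 0.5
  set.seed(13)
  n <- 400
  tt <- rexp(n); ee <- rbinom(n, 1, 0.7); ss <- rnorm(n)
  expect_equal(concordanceHarrell(ss, tt, ee)$c, 0.5, tolerance = 0.06)
  # n = 50 with censoring and tied scores: equals brute force
  set.seed(14)
  t2 <- sample(1:25, 50, TRUE); e2 <- rbinom(50, 1, 0.6)
  s2 <- sample(1:10, 50, TRUE)
  r <- concordanceHarrell(s2, t2, e2)
  expect_equal(r$c, oracleCindex(s2, t2, e2), tolerance = 1e-12)
  expect_true(r$lower <= r$c && r$c <= r$upper)
  # cross-check against the survival package on tie-free data
  t3 <- rexp(60); e3 <- rbinom(60, 1, 0.7); s3 <- rnorm(60)
  cs <- survival::concordance(survival::Surv(t3, e3) ~ s3, reverse = TRUE)
  expect_equal(concordanceHarrell(s3, t3, e3)$c, unname(cs$concordance),
               tolerance = 1e-10)
})

test_that("out-of-bag splits partition the indices at the expected rate", {
  sp <- bootstrapOobSplit(50, seed = 4)
  expect_length(sp$inBag, 50)
  expect_setequal(union(unique(sp$inBag), sp$outOfBag), 1:50)
  expect_length(intersect(unique(sp$inBag), sp$outOfBag), 0)
  expect_identical(sp, bootstrapOobSplit(50, seed = 4))
  # mean OOB fraction over many splits approaches 1 - 1/e
  fr <- vapply(1:400, function(s)
    length(bootstrapOobSplit(689, s)$outOfBag) / 689, numeric(1))
  expect_gt(mean(fr), 0.36)
  expect_lt(mean(fr), 0.375)
})

test_that("two-group log-rank equals the Cox score test at beta = 0", {
  co <- makeCohort(200, 35)
  co$hi <- as.numeric(co$tmtv > 180)
  lr <- logrankTest(co, "hi")
  ms <- maxstatCutpoint(co, grid = 180)
  expect_equal(ms$criterion, lr$chisq, tolerance = 1e-8)
})
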