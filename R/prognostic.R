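#' FLIPI2 score and risk class
#'
#' Counts the five FLIPI2 adverse factors: age > 60 years, hemoglobin
#' < 12 g/dL, beta-2-microglobulin above the upper limit of normal, bone
#' marrow involvement, and longest diameter of the largest involved node
#' > 6 cm. High risk is a score of 3 or more; scores 0-2 are classed
#' intermediate (a score of 0 is reported with its class even though such
#' patients fall outside the usual trial eligibility).
#'
#' @param data data.frame with columns \code{age} (or logical
#'   \code{age_gt60}), \code{hb} (or \code{hb_lt12}), \code{b2m_gt_uln},
#'   \code{bm_involved}, \code{lodlin_gt6cm}. A missing factor raises an
#'   error naming it.
#' @return data.frame(score, class) with class in
#'   \{"intermediate", "high"\}.
#' @export
flipi2Score <- function(data) {
  getFlag <- function(flag, raw, f) {
    if (flag %in% names(data)) as.logical(data[[flag]])
    else if (!is.null(raw) && raw %in% names(data)) f(data[[raw]])
    else stop("missing FLIPI2 factor: ", flag)
  }
  s <- getFlag("age_gt60", "age", function(a) a > 60) +
       getFlag("hb_lt12", "hb", function(h) h < 12) +
       getFlag("b2m_gt_uln", NULL, NULL) +
       getFlag("bm_involved", NULL, NULL) +
       getFlag("lodlin_gt6cm", NULL, NULL)
  if (any(is.na(s))) stop("FLIPI2 factors contain missing values")
  data.frame(score = as.integer(s),
             class = ifelse(s >= 3, "high", "intermediate"),
             stringsAsFactors = FALSE)
}

#' Classical FLIPI score and risk class
#'
#' Factors: age > 60, Ann Arbor stage III-IV, hemoglobin < 12 g/dL, LDH
#' above the upper limit of normal, more than 4 nodal areas. High risk is
#' 3 or more factors.
#'
#' @param data data.frame with columns \code{age}/\code{age_gt60},
#'   \code{stage} (II/III/IV) or logical \code{stage34}, \code{hb}/
#'   \code{hb_lt12}, \code{ldh_gt_uln}, \code{nodal_areas} or
#'   \code{nodal_gt4}.
#' @return data.frame(score, class).
#' @export
flipiScore <- function(data) {
  getFlag <- function(flag, raw, f) {
    if (flag %in% names(data)) as.logical(data[[flag]])
    else if (!is.null(raw) && raw %in% names(data)) f(data[[raw]])
    else stop("missing FLIPI factor: ", flag)
  }
  s <- getFlag("age_gt60", "age", function(a) a > 60) +
       getFlag("stage34", "stage", function(st) st %in% c("III", "IV")) +
       getFlag("hb_lt12", "hb", function(h) h < 12) +
       getFlag("ldh_gt_uln", NULL, NULL) +
       getFlag("nodal_gt4", "nodal_areas", function(x) x > 4)
  if (any(is.na(s))) stop("FLIPI factors contain missing values")
  data.frame(score = as.integer(s),
             class = ifelse(s >= 3, "high", "low-intermediate"),
             stringsAsFactors = FALSE)
}

#' Combined TMTV x FLIPI2 three-group risk classification
#'
#' Counts the two adverse features -- TMTV above the cutoff and high-risk
#' FLIPI2 -- and maps 0/1/2 to low / intermediate / high risk.
#'
#' @param tmtv numeric TMTV values (mL).
#' @param cut TMTV cutoff (mL).
#' @param flipi2High logical (or "high"/"intermediate") FLIPI2 class.
#' @return factor with levels low, intermediate, high.
#' @export
combinedRiskGroup <- function(tmtv, cut, flipi2High) {
  if (is.character(flipi2High)) flipi2High <- flipi2High == "high"
  adverse <- (tmtv > cut) + flipi2High
  factor(c("low", "intermediate", "high")[adverse + 1],
         levels = c("low", "intermediate", "high"))
}

#' Univariable Cox regression table
#'
#' One stratified Cox model per covariate, reported as n (\%), HR with 95\%
#' CI and p, in the layout of a trial prognostic-factor table. Degenerate
#' covariates (no variation) are flagged rather than dropped.
#'
#' @param data data.frame.
#' @param covariates character vector of binary/numeric covariate columns.
#' @param strata optional stratum column.
#' @param time,event column names.
#' @return data.frame, one row per covariate.
#' @export
univariableTable <- function(data, covariates, strata = NULL,
                             time = "pfs_time", event = "pfs_event") {
  rows <- lapply(covariates, function(cv) {
    x <- data[[cv]]
    npct <- if (is.logical(x) || all(x %in% c(0, 1)))
      sprintf("%d (%.0f)", sum(x), 100 * mean(x)) else ""
    if (length(unique(x)) < 2)
      return(data.frame(covariate = cv, n_pct = npct, hr = NA, lower = NA,
                        upper = NA, p = NA, note = "degenerate: no variation"))
    m <- tryCatch(coxFit(data, cv, strata, time, event),
                  error = function(e) NULL)
    if (is.null(m) || is.na(m$table$coef[1]))
      return(data.frame(covariate = cv, n_pct = npct, hr = NA, lower = NA,
                        upper = NA, p = NA, note = "fit failed"))
    r <- m$table[1, ]
    data.frame(covariate = cv, n_pct = npct, hr = r$hr, lower = r$lower,
               upper = r$upper, p = r$p, note = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multivariable PFS model with TMTV in both forms
#'
#' The adjusted stratified Cox model is fitted twice: with TMTV continuous
#' (hazard ratio reported per 500 mL increase) and with TMTV dichotomized
#' at the cutoff.
#'
#' @param data data.frame.
#' @param cut TMTV cutoff (mL) for the dichotomized form.
#' @param adjusters adjustment covariate columns (default FLIPI2 high, sex
#'   male, bendamustine regimen).
#' @param strata stratum column (default randomization arm).
#' @param time,event column names.
#' @return list(continuous = coxModelReport + per-500-mL HR,
#'   dichotomized = coxModelReport, cut).
#' @export
multivariableModel <- function(data, cut = 180,
                               adjusters = c("flipi2_high", "sex_male",
                                             "regimen_rb"),
                               strata = "arm",
                               time = "pfs_time", event = "pfs_event") {
  d <- data
  if (!"sex_male" %in% names(d) && "sex" %in% names(d))
    d$sex_male <- as.numeric(d$sex == "M")
  if (!"regimen_rb" %in% names(d) && "regimen" %in% names(d))
    d$regimen_rb <- as.numeric(d$regimen == "R-B")
  d$tmtv_per500 <- d$tmtv / 500
  d$tmtv_hi <- as.numeric(d$tmtv > cut)
  contFit <- coxFit(d, c("tmtv_per500", adjusters), strata, time, event)
  dichFit <- coxFit(d, c("tmtv_hi", adjusters), strata, time, event)
  list(continuous = contFit,
       hrPer500 = hrPerIncrement(contFit, "tmtv_per500", 1),
       dichotomized = dichFit, cut = cut)
}

#' Early progression (POD24) contingency analysis
#'
#' POD24 is a progression event within 24 months of the time origin.
#' Evaluable subjects have either an event before 24 months or at least 24
#' months of follow-up. The 2x2 table of TMTV group against POD24 is
#' tested with Fisher's exact test (two-sided) by default.
#'
#' @param data data.frame.
#' @param cut TMTV cutoff (mL).
#' @param window months defining early progression (default 24).
#' @param test \code{"fisher"} (default) or \code{"chisq"}.
#' @param var,time,event column names.
#' @return An object of class \code{pod24Result}: the 2x2 \code{table}
#'   (rows: TMTV group, cols: POD24), per-group proportions, p value,
#'   evaluable n.
#' @export
pod24 <- function(data, cut = 180, window = 24,
                  test = c("fisher", "chisq"), var = "tmtv",
                  time = "pfs_time", event = "pfs_event") {
  test <- match.arg(test)
  evaluable <- data[[time]] >= window |
    (data[[event]] == 1 & data[[time]] < window)
  d <- data[evaluable, , drop = FALSE]
  if (!nrow(d)) stop("no evaluable subjects for POD24")
  pod <- d[[event]] == 1 & d[[time]] <= window
  grp <- factor(d[[var]] > cut, levels = c(TRUE, FALSE),
                labels = c("high", "low"))
  tab <- table(grp, pod = factor(pod, levels = c(TRUE, FALSE),
                                 labels = c("POD24", "no POD24")))
  p <- if (test == "fisher") fisher.test(tab)$p.value
       else chisq.test(tab, correct = FALSE)$p.value
  structure(list(table = tab,
                 proportions = prop.table(tab, 1)[, "POD24"],
                 p = p, test = test, evaluable = nrow(d),
                 window = window, cut = cut),
            class = "pod24Result")
}

#' @export
print.pod24Result <- function(x, ...) {
  cat(sprintf(
    "POD24 (within %d months, cutoff %g mL): high %d/%d (%.0f%%) vs low %d/%d (%.0f%%), %s p = %.3g\n",
    x$window, x$cut,
    x$table["high", "POD24"], sum(x$table["high", ]),
    100 * x$proportions[["high"]],
    x$table["low", "POD24"], sum(x$table["low", ]),
    100 * x$proportions[["low"]], x$test, x$p))
  invisible(x)
}

#' Discrimination gain from adding a covariate (delta c-Harrell)
#'
#' Fits the base and the extended stratified Cox models, computes Harrell's
#' c with jackknife CIs for each model's linear predictor, their
#' difference, and the likelihood-ratio test of the added term.
#'
#' @param data data.frame.
#' @param base character vector of base-model covariates.
#' @param added covariate(s) added in the extended model.
#' @param strata optional stratum column.
#' @param time,event column names.
#' @return list(cBase, cFull (concordanceResult), deltaC, lrt =
#'   list(chisq, df, p), models).
#' @export
modelComparison <- function(data, base, added, strata = NULL,
                            time = "pfs_time", event = "pfs_event") {
  m0 <- coxFit(data, base, strata, time, event)
  m1 <- coxFit(data, c(base, added), strata, time, event)
  lp0 <- as.numeric(predict(m0$fit, type = "lp"))
  lp1 <- as.numeric(predict(m1$fit, type = "lp"))
  c0 <- concordanceHarrell(lp0, data[[time]], data[[event]])
  c1 <- concordanceHarrell(lp1, data[[time]], data[[event]])
  chisq <- 2 * (m1$loglik - m0$loglik)
  df <- nrow(m1$table) - nrow(m0$table)
  list(cBase = c0, cFull = c1, deltaC = c1$c - c0$c,
       lrt = list(chisq = chisq, df = df,
                  p = pchisq(chisq, df, lower.tail = FALSE)),
       models = list(base = m0, full = m1))
}

#' Bootstrap inclusion fraction of the TMTV term
#'
#' Across B with-replacement resamples, the FLIPI2-fixed model is fitted
#' with and without the dichotomized TMTV term; the fraction of resamples
#' in which TMTV is retained is reported under (a) a likelihood-ratio test
#' at p < 0.05 and (b) AIC selection (lower AIC with the term).
#'
#' @param data data.frame.
#' @param cut TMTV cutoff (mL).
#' @param B resamples.
#' @param seed integer seed.
#' @param fixed covariates kept in both models (default FLIPI2 high).
#' @param strata optional stratum column.
#' @param var,time,event column names.
#' @return An object of class \code{bifReport}: retention fractions and
#'   counts, B, failed resample count.
#' @export
bif <- function(data, cut = 180, B = 200, seed = 1L,
                fixed = "flipi2_high", strata = "arm", var = "tmtv",
                time = "pfs_time", event = "pfs_event") {
  stopifnot(B >= 1)
  n <- nrow(data)
  lrtKeep <- aicKeep <- rep(NA, B)
  withSeed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, replace = TRUE)
      d <- data[idx, , drop = FALSE]
      d$.hi <- as.numeric(d[[var]] > cut)
      res <- tryCatch({
        m0 <- coxFit(d, fixed, strata, time, event)
        m1 <- coxFit(d, c(fixed, ".hi"), strata, time, event)
        chisq <- 2 * (m1$loglik - m0$loglik)
        c(lrt = pchisq(chisq, 1, lower.tail = FALSE) < 0.05,
          aic = m1$aic < m0$aic)
      }, error = function(e) c(lrt = NA, aic = NA))
      lrtKeep[b] <- res["lrt"]; aicKeep[b] <- res["aic"]
    }
  })
  ok <- !is.na(lrtKeep)
  if (!any(ok)) stop("all bootstrap resamples failed")
  structure(list(B = B, failed = sum(!ok),
                 lrtFraction = mean(lrtKeep[ok]),
                 aicFraction = mean(aicKeep[ok]),
                 lrtCount = sum(lrtKeep[ok]), aicCount = sum(aicKeep[ok])),
            class = "bifReport")
}

#' @export
print.bifReport <- function(x, ...) {
  cat(sprintf(
    "Bootstrap inclusion fraction (B = %d, %d failed): LRT %d/%d (%.2f), AIC %d/%d (%.2f)\n",
    x$B, x$failed, x$lrtCount, x$B - x$failed, x$lrtFraction,
    x$aicCount, x$B - x$failed, x$aicFraction))
  invisible(x)
}

#' Bland-Altman inter-reader agreement
#'
#' Paired differences against means for each reader pair: mean bias and
#' limits of agreement (bias +/- 1.96 SD of the differences) on the
#' measurement scale, and a within-subject coefficient of variation
#' computed on the relative scale, CV\% = SD(d_i / m_i) / sqrt(2) x 100
#' with d_i the paired difference and m_i the pair mean. The relative form
#' is the appropriate convention for TMTV, whose measurement error is
#' multiplicative and whose values span orders of magnitude (an
#' absolute-difference CV would be dominated by the largest volumes); the
#' factor sqrt(2) converts the SD of a difference of two equally noisy
#' measurements to a per-measurement SD. With more than two readers all
#' pairs are pooled.
#'
#' @param readings reader-by-subject numeric matrix (>= 2 rows).
#' @return An object of class \code{blandAltmanResult}: bias, loa (length
#'   2), cvPct, pairs (number of paired measurements).
#' @export
blandAltman <- function(readings) {
  readings <- as.matrix(readings)
  if (nrow(readings) < 2) stop("at least two readers are required")
  cc <- colSums(is.na(readings)) == 0
  readings <- readings[, cc, drop = FALSE]
  if (ncol(readings) < 2) stop("fewer than two complete measurement pairs")
  prs <- utils::combn(nrow(readings), 2)
  diffs <- unlist(lapply(seq_len(ncol(prs)), function(j)
    readings[prs[1, j], ] - readings[prs[2, j], ]))
  means <- unlist(lapply(seq_len(ncol(prs)), function(j)
    (readings[prs[1, j], ] + readings[prs[2, j], ]) / 2))
  bias <- mean(diffs)
  sdd <- sd(diffs)
  if (!is.finite(sdd)) sdd <- 0
  rel <- diffs[means > 0] / means[means > 0]
  sdr <- if (length(rel) > 1) sd(rel) else 0
  if (!is.finite(sdr)) sdr <- 0
  structure(list(bias = bias,
                 loa = c(lower = bias - 1.96 * sdd, upper = bias + 1.96 * sdd),
                 cvPct = 100 * sdr / sqrt(2),
                 sdDiff = sdd, pairs = length(diffs)),
            class = "blandAltmanResult")
}

#' @export
print.blandAltmanResult <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: bias %.2f mL, LoA [%.2f, %.2f], CV %.2f%% (%d pairs)\n",
    x$bias, x$loa[1], x$loa[2], x$cvPct, x$pairs))
  invisible(x)
}
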