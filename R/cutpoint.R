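#' Candidate cutoff grid
#'
#' Unique observed marker values between two quantiles (default 10th-90th),
#' protecting the group sizes at the extremes.
#'
#' @param x marker values.
#' @param qlim lower/upper quantile limits.
#' @return Sorted numeric vector of candidate cutoffs.
#' @export
candidateGrid <- function(x, qlim = c(0.10, 0.90)) {
  q <- quantile(x, qlim, type = 7)
  sort(unique(x[x >= q[1] & x <= q[2]]))
}

.cutpointResult <- function(method, cutoff, criterion, grid, trace,
                            note = NULL) {
  structure(list(method = method, cutoff = cutoff, criterion = criterion,
                 grid = range(grid), trace = trace, note = note),
            class = "cutpointResult")
}

#' @export
print.cutpointResult <- function(x, ...) {
  cat(sprintf("Cutpoint (%s): %s mL (criterion %.4g)%s\n", x$method,
              if (is.na(x$cutoff)) "no cutpoint" else format(round(x$cutoff, 1)),
              x$criterion,
              if (!is.null(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Maximally selected (adjusted, stratified) log-rank cutoff
#'
#' For every candidate cutoff c the score statistic for the indicator
#' 1\{marker > c\} is computed from a stratified Cox model evaluated at the
#' null value of the indicator coefficient with the adjusters fixed at
#' their null-model estimates -- i.e. an adjusted log-rank-type statistic
#' that reduces exactly to the classical log-rank test when no adjusters
#' are given. The returned cutoff maximizes the statistic; ties go to the
#' smallest cutoff.
#'
#' @param data data.frame.
#' @param var marker column (default \code{"tmtv"}).
#' @param adjusters character vector of adjustment covariates (or NULL).
#' @param strata optional stratum column.
#' @param grid candidate cutoffs; default \code{\link{candidateGrid}} of
#'   the marker.
#' @param qlim quantile limits for the default grid.
#' @param time,event column names.
#' @return A \code{cutpointResult} with the per-candidate statistic trace.
#' @export
maxstatCutpoint <- function(data, var = "tmtv", adjusters = NULL,
                            strata = NULL, grid = NULL,
                            qlim = c(0.10, 0.90),
                            time = "pfs_time", event = "pfs_event") {
  if (is.null(grid)) grid <- candidateGrid(data[[var]], qlim)
  if (!length(grid)) stop("empty candidate grid")
  y <- survObj(data, time, event)
  beta0 <- numeric(0)
  if (length(adjusters)) {
    f0 <- as.formula(paste("y ~", coxRhs(adjusters, strata)))
    fit0 <- coxph(f0, data = data, ties = "efron")
    beta0 <- coef(fit0)
  }
  d <- data
  stat <- vapply(grid, function(cc) {
    d$.hi <- as.numeric(d[[var]] > cc)
    f <- as.formula(paste("y ~", coxRhs(c(".hi", adjusters), strata)))
    fit <- tryCatch(
      coxph(f, data = d, ties = "efron", init = c(0, beta0),
            control = coxph.control(iter.max = 0)),
      error = function(e) NULL, warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(fit)) NA_real_ else unname(fit$score)
  }, numeric(1))
  if (all(is.na(stat))) stop("no candidate produced a valid statistic")
  best <- which.max(stat)   # ties -> first = smallest cutoff
  .cutpointResult("maxstat", grid[best], stat[best], grid,
                  data.frame(cutoff = grid, statistic = stat))
}

#' Time-dependent ROC cutoff (Liu criterion, IPCW)
#'
#' Cumulative/dynamic sensitivity and specificity at a fixed horizon are
#' estimated with inverse-probability-of-censoring weights from the
#' Kaplan-Meier estimate of the censoring distribution: cases are subjects
#' with an event by the horizon (weighted by 1/G(T-)), controls are
#' subjects still at risk beyond it. The selected cutoff maximizes the
#' product sensitivity x specificity (the Liu criterion as operationalized
#' here); ties go to the smallest cutoff. With no censoring before the
#' horizon this reduces to the empirical binary-outcome ROC.
#'
#' @param data data.frame.
#' @param horizon months (default 36, i.e. the 3-year progression horizon).
#' @param var marker column.
#' @param grid candidate cutoffs (default as in
#'   \code{\link{maxstatCutpoint}}).
#' @param qlim quantile limits for the default grid.
#' @param time,event column names.
#' @return A \code{cutpointResult}; the trace holds sensitivity,
#'   specificity and their product per candidate.
#' @export
rocCutpointLiu <- function(data, horizon = 36, var = "tmtv", grid = NULL,
                           qlim = c(0.10, 0.90),
                           time = "pfs_time", event = "pfs_event") {
  tt <- data[[time]]; dd <- data[[event]]; x <- data[[var]]
  if (horizon >= max(tt)) stop("horizon beyond follow-up support")
  case <- tt <= horizon & dd == 1
  ctrl <- tt > horizon
  if (!any(case)) stop("no events before the horizon")
  cf <- survfit(Surv(tt, 1 - dd) ~ 1)
  G <- stats::stepfun(cf$time, c(1, cf$surv))
  wCase <- 1 / pmax(G(tt[case] - 1e-9), 1e-10)
  if (is.null(grid)) grid <- candidateGrid(x, qlim)
  if (!length(grid)) stop("empty candidate grid")
  xc <- x[case]; xk <- x[ctrl]
  sens <- vapply(grid, function(cc) sum(wCase[xc > cc]) / sum(wCase), numeric(1))
  spec <- vapply(grid, function(cc) mean(xk <= cc), numeric(1))
  crit <- sens * spec
  best <- which.max(crit)
  .cutpointResult("auc-roc-liu", grid[best], crit[best], grid,
                  data.frame(cutoff = grid, sensitivity = sens,
                             specificity = spec, criterion = crit))
}

#' Cutoff from the restricted-cubic-spline log-hazard curve
#'
#' Fits the adjusted stratified Cox model with an RCS expansion of the
#' marker and reads a cutoff off the fitted log hazard-ratio curve: the
#' smallest marker value above the cohort median at which the curve crosses
#' zero from below, located by bisection to 0.1 mL. The zero level is set
#' by the reference: \code{"meanRisk"} (default) centers the curve at the
#' cohort-average spline risk, so the crossing marks where predicted risk
#' exceeds the cohort average; \code{"median"} centers at the median
#' marker value (under a monotone fitted curve this crossing degenerates
#' to the reference itself, which is reported and flagged). If the curve
#' never crosses zero above the median, no cutpoint is reported.
#'
#' @param data data.frame.
#' @param var marker column.
#' @param adjusters,strata adjustment covariates and stratum column.
#' @param k number of spline knots (e.g. from
#'   \code{\link{selectKnotsBootstrap}}).
#' @param reference \code{"meanRisk"} or \code{"median"}.
#' @param time,event column names.
#' @return A \code{cutpointResult}; the trace holds the centered curve on
#'   the search grid.
#' @export
rcsCutpoint <- function(data, var = "tmtv", adjusters = NULL, strata = NULL,
                        k = 5, reference = c("meanRisk", "median"),
                        time = "pfs_time", event = "pfs_event") {
  reference <- match.arg(reference)
  fit <- coxRcsFit(data, var, k, adjusters, strata, time, event)
  x <- data[[var]]
  offset <- switch(reference,
                   median = fit$eval(median(x)),
                   meanRisk = mean(fit$eval(x)))
  f <- function(z) fit$eval(z) - offset
  from <- median(x)
  to <- quantile(x, 0.99, type = 7)
  gx <- seq(from, to, length.out = 2048)
  gy <- f(gx)
  trace <- data.frame(x = gx, logHr = gy)
  # first up-crossing of zero strictly above the median
  idx <- which(gy[-length(gy)] < 0 & gy[-1] >= 0)
  if (length(idx)) {
    lo <- gx[idx[1]]; hi <- gx[idx[1] + 1]
    while (hi - lo > 0.1) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    return(.cutpointResult("rcs", (lo + hi) / 2, f((lo + hi) / 2) + offset,
                           gx, trace))
  }
  if (all(gy >= 0)) {
    # monotone above the reference: crossing degenerates to the reference
    return(.cutpointResult("rcs", from, offset, gx, trace,
                           note = "degenerate: curve positive above reference; crossing at reference"))
  }
  .cutpointResult("rcs", NA_real_, NA_real_, gx, trace,
                  note = "no zero crossing in data support")
}

#' Pick the working cutoff among method candidates
#'
#' Each candidate (rounded to the nearest mL) is evaluated within the
#' reference treatment stratum by the log-rank statistic and the Cox hazard
#' ratio of the dichotomized marker; the winner is the candidate with the
#' largest log-rank statistic. The full evaluation table is returned so a
#' user can round the working cutoff (e.g. 181 to 180) deliberately.
#'
#' @param results list of \code{cutpointResult}s (or numeric cutoffs).
#' @param data data.frame.
#' @param referenceArm value of \code{armCol} defining the reference
#'   stratum (default \code{"standard"}).
#' @param armCol,var,time,event column names.
#' @return list(chosen, table, referenceArm).
#' @export
consensusCutoff <- function(results, data, referenceArm = "standard",
                            armCol = "arm", var = "tmtv",
                            time = "pfs_time", event = "pfs_event") {
  cand <- vapply(results, function(r)
    if (inherits(r, "cutpointResult")) r$cutoff else as.numeric(r), numeric(1))
  cand <- sort(unique(round(cand[!is.na(cand)])))
  if (!length(cand)) stop("no candidate cutoffs")
  ref <- data[data[[armCol]] == referenceArm, , drop = FALSE]
  if (!nrow(ref)) stop("reference arm not present: ", referenceArm)
  rows <- lapply(cand, function(cc) {
    d <- ref; d$.hi <- factor(d[[var]] > cc, levels = c(FALSE, TRUE))
    if (length(unique(d$.hi)) < 2)
      return(data.frame(cutoff = cc, chisq = NA, p = NA, hr = NA,
                        lower = NA, upper = NA))
    lr <- logrankTest(d, ".hi", time = time, event = event)
    d$.hiNum <- as.numeric(d[[var]] > cc)
    cx <- coxFit(d, ".hiNum", time = time, event = event)
    data.frame(cutoff = cc, chisq = lr$chisq, p = lr$p,
               hr = cx$table$hr[1], lower = cx$table$lower[1],
               upper = cx$table$upper[1])
  })
  tab <- do.call(rbind, rows)
  chosen <- tab$cutoff[which.max(tab$chisq)]
  list(chosen = chosen, table = tab, referenceArm = referenceArm)
}

#' Risk-band analysis around the working cutoff
#'
#' Splits subjects into three bands (at or below \code{low}, between, above
#' \code{high}), reports band occupancy, per-band Kaplan-Meier curves, and
#' hazard ratios against the lowest band (stratified, plus per treatment
#' arm). An empty band is reported, not fatal.
#'
#' @param data data.frame.
#' @param low,high band edges in mL (low < high).
#' @param armCol,var,time,event column names.
#' @return list(occupancy, km, hr, perArm, bands).
#' @export
bandAnalysis <- function(data, low = 180, high = 240, armCol = "arm",
                         var = "tmtv", time = "pfs_time",
                         event = "pfs_event") {
  stopifnot(low < high)
  band <- cut(data[[var]], c(-Inf, low, high, Inf),
              labels = c("low", "mid", "high"))
  occ <- as.numeric(table(band)) / length(band)
  names(occ) <- levels(band)
  km <- lapply(split(data, band), function(d)
    if (nrow(d)) kmEstimate(d, time, event) else NULL)
  hrTab <- function(d) {
    b <- cut(d[[var]], c(-Inf, low, high, Inf),
             labels = c("low", "mid", "high"))
    if (length(unique(b)) < 2 || !any(b == "low")) return(NULL)
    d$.mid <- as.numeric(b == "mid"); d$.high <- as.numeric(b == "high")
    cov <- c(".mid", ".high")[c(any(d$.mid == 1), any(d$.high == 1))]
    tryCatch(coxFit(d, cov, time = time, event = event)$table,
             error = function(e) NULL)
  }
  overall <- {
    d <- data
    d$.mid <- as.numeric(band == "mid"); d$.high <- as.numeric(band == "high")
    cov <- c(".mid", ".high")[c(any(d$.mid == 1), any(d$.high == 1))]
    if (length(cov))
      tryCatch(coxFit(d, cov, strata = if (armCol %in% names(d)) armCol,
                      time = time, event = event)$table,
               error = function(e) NULL)
  }
  perArm <- if (armCol %in% names(data))
    lapply(split(data, data[[armCol]]), hrTab) else NULL
  list(occupancy = occ, km = km, hr = overall, perArm = perArm,
       bands = c(low = low, high = high),
       emptyBands = names(occ)[occ == 0])
}

#' Out-of-bootstrap validation of a cutoff
#'
#' For each of B with-replacement resamples the cutoff is (optionally)
#' re-derived on the in-bag sample and then evaluated on the out-of-bag
#' records by a Cox fit of the dichotomized marker; the per-resample log
#' hazard ratios are pooled (mean, empirical 95\% interval). Resamples
#' whose out-of-bag set is degenerate (one marker group, or no events) are
#' skipped and counted.
#'
#' @param data data.frame.
#' @param cutoff cutoff in mL to validate.
#' @param B number of resamples.
#' @param seed integer seed.
#' @param rederive optional function(data) -> cutoff applied to each in-bag
#'   sample (e.g. wrapping \code{\link{maxstatCutpoint}}); NULL keeps
#'   \code{cutoff} fixed.
#' @param strata,var,time,event column names.
#' @return An object of class \code{oobValidation}: per-resample HRs,
#'   pooled HR with empirical 95\% interval, B, skipped count.
#' @export
oobValidate <- function(data, cutoff, B = 200, seed = 1L, rederive = NULL,
                        strata = NULL, var = "tmtv",
                        time = "pfs_time", event = "pfs_event") {
  stopifnot(B >= 1)
  n <- nrow(data)
  seeds <- childSeeds(seed, B)
  logHr <- rep(NA_real_, B)
  cuts <- rep(NA_real_, B)
  skipped <- 0L
  for (b in seq_len(B)) {
    sp <- bootstrapOobSplit(n, seeds[b])
    test <- data[sp$outOfBag, , drop = FALSE]
    cb <- if (is.null(rederive)) cutoff else
      tryCatch(rederive(data[sp$inBag, , drop = FALSE]),
               error = function(e) NA_real_)
    cuts[b] <- cb
    if (is.na(cb) || !nrow(test)) { skipped <- skipped + 1L; next }
    test$.hi <- as.numeric(test[[var]] > cb)
    if (length(unique(test$.hi)) < 2 || sum(test[[event]]) < 2) {
      skipped <- skipped + 1L; next
    }
    lh <- tryCatch(
      coxFit(test, ".hi", strata = strata, time = time,
             event = event)$table$coef[1],
      error = function(e) NA_real_)
    if (is.na(lh)) skipped <- skipped + 1L else logHr[b] <- lh
  }
  ok <- !is.na(logHr)
  if (!any(ok)) stop("every out-of-bag resample was degenerate")
  pooled <- mean(logHr[ok])
  ci <- quantile(logHr[ok], c(0.025, 0.975), type = 7)
  structure(list(hr = exp(pooled), lower = exp(ci[[1]]), upper = exp(ci[[2]]),
                 logHr = logHr[ok], cutoffs = cuts, B = B,
                 skipped = skipped, cutoff = cutoff),
            class = "oobValidation")
}

#' @export
print.oobValidation <- function(x, ...) {
  cat(sprintf(
    "OOB validation of cutoff %s mL: pooled HR %.2f (95%% interval %.2f-%.2f), B = %d (%d skipped)\n",
    format(x$cutoff), x$hr, x$lower, x$upper, x$B, x$skipped))
  invisible(x)
}

#' Side-by-side comparison with a previously published cutoff
#'
#' Runs the same univariable and multivariable dichotomized-marker models
#' at the working cutoff and at a historic cutoff (default 510 mL, derived
#' with the legacy 41\%-SUVmax segmentation), so their hazard ratios can be
#' compared on one table.
#'
#' @param data data.frame.
#' @param cutoff historic cutoff (mL).
#' @param workingCutoff the working cutoff (mL).
#' @param adjusters,strata multivariable specification.
#' @param var,time,event column names.
#' @return data.frame with one row per cutoff x model form.
#' @export
comparePublishedCutoff <- function(data, cutoff = 510, workingCutoff = 180,
                                   adjusters = c("flipi2_high"),
                                   strata = "arm", var = "tmtv",
                                   time = "pfs_time", event = "pfs_event") {
  oneCut <- function(cc) {
    d <- data; d$.hi <- as.numeric(d[[var]] > cc)
    if (length(unique(d$.hi)) < 2)
      return(data.frame(cutoff = cc, model = c("univariable", "multivariable"),
                        hr = NA, lower = NA, upper = NA, p = NA,
                        note = "degenerate: one group empty"))
    uni <- coxFit(d, ".hi", strata = strata, time = time, event = event)
    mul <- coxFit(d, c(".hi", adjusters), strata = strata,
                  time = time, event = event)
    pick <- function(m, lab) {
      r <- m$table[m$table$term == ".hi", ]
      data.frame(cutoff = cc, model = lab, hr = r$hr, lower = r$lower,
                 upper = r$upper, p = r$p, note = "")
    }
    rbind(pick(uni, "univariable"), pick(mul, "multivariable"))
  }
  out <- rbind(oneCut(workingCutoff), oneCut(cutoff))
  rownames(out) <- NULL
  out
}
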