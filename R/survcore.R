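#' @importFrom survival Surv coxph survfit survdiff strata coxph.control
NULL

# Build a Surv object from named columns.
survObj <- function(data, time = "pfs_time", event = "pfs_event") {
  if (!all(c(time, event) %in% names(data)))
    stop("columns not found: ", paste(setdiff(c(time, event), names(data)),
                                      collapse = ", "))
  if (any(data[[time]] <= 0)) stop("survival times must be positive")
  if (!all(data[[event]] %in% c(0, 1))) stop("event flags must be 0/1")
  Surv(data[[time]], data[[event]])
}

# Right-hand side of a Cox formula from covariate / strata names.
coxRhs <- function(covariates, strata = NULL) {
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  if (!is.null(strata) && length(strata))
    rhs <- paste(rhs, "+", paste0("strata(", strata, ")", collapse = " + "))
  rhs
}

#' Kaplan-Meier product-limit estimate
#'
#' @param data data.frame with time and event columns.
#' @param time,event column names (months; 1 = event).
#' @return An object of class \code{kmCurve}: event times, numbers at risk,
#'   event counts, survival estimates and Greenwood standard errors, with a
#'   \code{\link{survivalAt}} accessor.
#' @export
kmEstimate <- function(data, time = "pfs_time", event = "pfs_event") {
  if (!nrow(data)) stop("empty data")
  fit <- survfit(survObj(data, time, event) ~ 1, conf.type = "log-log")
  structure(list(time = fit$time, nRisk = fit$n.risk, nEvent = fit$n.event,
                 surv = fit$surv, stdErr = fit$std.err * fit$surv,
                 lower = fit$lower, upper = fit$upper, n = fit$n),
            class = "kmCurve")
}

#' @rdname kmEstimate
#' @param km a \code{kmCurve}.
#' @param at horizon(s) in months; the step-function value at the last
#'   event time at or before the horizon is returned (1 before the first
#'   event).
#' @return \code{survivalAt}: numeric survival probabilities.
#' @export
survivalAt <- function(km, at) {
  stopifnot(inherits(km, "kmCurve"))
  vapply(at, function(t0) {
    i <- which(km$time <= t0)
    if (!length(i)) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' @export
print.kmCurve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ", events =", sum(x$nEvent), "\n")
  invisible(x)
}

#' Log-rank test
#'
#' Observed-minus-expected statistic with hypergeometric variance, summed
#' over strata when a stratum column is given.
#'
#' @param data data.frame.
#' @param group column name of the group labels (>= 2 groups).
#' @param strata optional stratum column name.
#' @param time,event column names.
#' @return list(chisq, df, p).
#' @export
logrankTest <- function(data, group, strata = NULL,
                        time = "pfs_time", event = "pfs_event") {
  g <- data[[group]]
  if (length(unique(g)) < 2) stop("log-rank test needs at least two groups")
  rhs <- group
  if (!is.null(strata)) rhs <- paste(rhs, "+", paste0("strata(", strata, ")"))
  f <- as.formula(paste("survObj(data, time, event) ~", rhs))
  sd <- survdiff(f, data = data)
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Fit a (stratified) Cox proportional-hazards model
#'
#' Wraps a partial-likelihood fit with Efron tie handling and Newton
#' iterations, and reports coefficients as hazard ratios with Wald 95\% CIs
#' on the log scale, the log partial likelihood and AIC. Covariates that
#' carry no information (constant within strata) are reported as degenerate
#' rather than silently dropped.
#'
#' @param data data.frame.
#' @param covariates character vector of covariate column names.
#' @param strata optional stratum column name(s).
#' @param time,event column names.
#' @return An object of class \code{coxModelReport}: \code{table}
#'   (coef, se, hr, lower, upper, p per covariate), \code{loglik},
#'   \code{aic}, \code{n}, \code{nevent}, \code{degenerate},
#'   \code{converged}, and the underlying fit in \code{fit}.
#' @export
coxFit <- function(data, covariates, strata = NULL,
                   time = "pfs_time", event = "pfs_event") {
  y <- survObj(data, time, event)
  if (sum(data[[event]]) < length(covariates))
    stop("fewer events than covariates")
  f <- as.formula(paste("y ~", coxRhs(covariates, strata)))
  fit <- withCallingHandlers(
    coxph(f, data = data, ties = "efron",
          control = coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite", conditionMessage(w)))
        warning("possible monotone likelihood / non-convergence: ",
                conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  co <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  degenerate <- names(co)[is.na(co)]
  z <- co / se
  tab <- data.frame(
    term = names(co), coef = unname(co), se = unname(se),
    hr = exp(unname(co)),
    lower = exp(unname(co) - qnorm(0.975) * unname(se)),
    upper = exp(unname(co) + qnorm(0.975) * unname(se)),
    p = 2 * pnorm(-abs(unname(z))), stringsAsFactors = FALSE)
  ll <- fit$loglik[length(fit$loglik)]
  p <- sum(!is.na(co))
  structure(list(table = tab, loglik = ll, aic = -2 * ll + 2 * p,
                 n = fit$n, nevent = fit$nevent,
                 degenerate = degenerate,
                 converged = is.null(fit$info) || fit$iter < 100,
                 iter = fit$iter, fit = fit),
            class = "coxModelReport")
}

#' @export
print.coxModelReport <- function(x, ...) {
  cat("Cox PH model: n =", x$n, ", events =", x$nevent,
      ", logLik =", round(x$loglik, 2), ", AIC =", round(x$aic, 2), "\n")
  tb <- x$table
  tb$`HR (95% CI)` <- sprintf("%.2f (%.2f-%.2f)", tb$hr, tb$lower, tb$upper)
  print(tb[, c("term", "HR (95% CI)", "p")], row.names = FALSE)
  if (length(x$degenerate))
    cat("degenerate (no information):", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Hazard ratio for an increment of a continuous covariate
#'
#' For a continuous covariate with per-unit log hazard \eqn{\beta}, returns
#' \eqn{\exp(\delta\beta)} with the Wald CI transformed identically (e.g.
#' the hazard ratio per 500 mL increase of TMTV).
#'
#' @param model a \code{coxModelReport}.
#' @param covariate covariate name.
#' @param delta increment in the covariate's units.
#' @return list(hr, lower, upper, delta).
#' @export
hrPerIncrement <- function(model, covariate, delta) {
  stopifnot(inherits(model, "coxModelReport"))
  row <- model$table[model$table$term == covariate, ]
  if (!nrow(row)) stop("covariate not in model: ", covariate)
  list(hr = exp(delta * row$coef),
       lower = exp(delta * (row$coef - qnorm(0.975) * row$se)),
       upper = exp(delta * (row$coef + qnorm(0.975) * row$se)),
       delta = delta)
}

# Harrell's recommended knot placement quantiles by number of knots.
.rcsQuantiles <- list(
  `3` = c(0.10, 0.50, 0.90),
  `4` = c(0.05, 0.35, 0.65, 0.95),
  `5` = c(0.05, 0.275, 0.50, 0.725, 0.95),
  `6` = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
  `7` = c(0.025, 0.1833, 0.3417, 0.50, 0.6583, 0.8167, 0.975))

#' Restricted-cubic-spline knots at Harrell's quantiles
#'
#' @param x numeric data vector.
#' @param k number of knots (3 to 7).
#' @return Numeric vector of knot locations.
#' @export
rcsKnots <- function(x, k) {
  if (!k %in% 3:7) stop("k must be between 3 and 7")
  kn <- unname(quantile(x, .rcsQuantiles[[as.character(k)]], type = 7))
  if (length(unique(kn)) < k)
    stop("not enough distinct values to place ", k, " knots")
  kn
}

#' Restricted cubic spline basis (Harrell's truncated-power form)
#'
#' Produces the k-1 column basis (linear term plus k-2 restricted cubic
#' terms) that is exactly linear beyond the boundary knots and has
#' continuous first and second derivatives everywhere. Nonlinear terms are
#' scaled by the squared knot span for numerical balance.
#'
#' @param x numeric vector to expand.
#' @param knots knot locations, or a single integer k (3-7) to place knots
#'   at Harrell's quantiles of \code{x}.
#' @return Numeric matrix with \code{length(knots) - 1} columns and
#'   attribute \code{"knots"}; class \code{rcsBasis}.
#' @export
rcsBasis <- function(x, knots = 5) {
  if (length(knots) == 1 && knots == as.integer(knots))
    knots <- rcsKnots(x, knots)
  knots <- sort(knots)
  k <- length(knots)
  if (k < 3) stop("at least three knots are required")
  tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  cube <- function(u) pmax(u, 0)^3
  b <- matrix(0, length(x), k - 1)
  b[, 1] <- x
  for (j in seq_len(k - 2)) {
    b[, j + 1] <- (cube(x - knots[j]) -
                   cube(x - tk1) * (tk - knots[j]) / (tk - tk1) +
                   cube(x - tk)  * (tk1 - knots[j]) / (tk - tk1)) /
                  (tk - t1)^2
  }
  colnames(b) <- c("x", paste0("x'", seq_len(k - 2)))
  structure(b, knots = knots, class = c("rcsBasis", "matrix"))
}

#' Select the number of spline knots by bootstrap-averaged AIC
#'
#' For each bootstrap resample and each candidate number of knots k, an
#' adjusted stratified Cox model with a restricted-cubic-spline expansion of
#' the covariate is fitted and its AIC recorded; the selected k minimizes
#' the mean AIC across resamples. Resamples on which a fit fails are logged
#' and excluded for that k.
#'
#' @param data data.frame.
#' @param var continuous covariate column name (e.g. TMTV).
#' @param adjusters character vector of adjustment covariates.
#' @param strata optional stratum column.
#' @param kRange candidate knot counts (subset of 3:7).
#' @param B number of bootstrap resamples (B = 1 reduces to a single
#'   in-sample AIC comparison).
#' @param seed integer seed.
#' @param time,event column names.
#' @return list(k = selected knot count, aicMean = named mean-AIC vector,
#'   aicTrace = B x length(kRange) matrix, failures = failure counts).
#' @export
selectKnotsBootstrap <- function(data, var = "tmtv", adjusters = NULL,
                                 strata = NULL, kRange = 3:7, B = 100,
                                 seed = 1L, time = "pfs_time",
                                 event = "pfs_event") {
  stopifnot(B >= 1, all(kRange %in% 3:7))
  n <- nrow(data)
  aic <- matrix(NA_real_, B, length(kRange),
                dimnames = list(NULL, paste0("k", kRange)))
  withSeed(seed, {
    for (b in seq_len(B)) {
      idx <- if (B == 1) seq_len(n) else sample.int(n, replace = TRUE)
      d <- data[idx, , drop = FALSE]
      for (ki in seq_along(kRange)) {
        aic[b, ki] <- tryCatch({
          fit <- coxRcsFit(d, var, kRange[ki], adjusters, strata, time, event)
          fit$aic
        }, error = function(e) NA_real_)
      }
    }
  })
  fails <- colSums(is.na(aic))
  if (all(is.na(aic))) stop("all spline fits failed")
  aicMean <- colMeans(aic, na.rm = TRUE)
  kSel <- kRange[which.min(aicMean)]
  list(k = kSel, aicMean = aicMean, aicTrace = aic, failures = fails)
}

# Adjusted stratified Cox fit with an RCS expansion of `var`.
# Returns coef, knots, aic and an evaluator for the spline log-HR.
coxRcsFit <- function(data, var = "tmtv", k = 5, adjusters = NULL,
                      strata = NULL, time = "pfs_time",
                      event = "pfs_event", knots = NULL) {
  if (is.null(knots)) knots <- rcsKnots(data[[var]], k)
  bas <- rcsBasis(data[[var]], knots)
  d2 <- data
  bn <- paste0(".rcs", seq_len(ncol(bas)))
  for (j in seq_len(ncol(bas))) d2[[bn[j]]] <- bas[, j]
  rep <- coxFit(d2, c(bn, adjusters), strata, time, event)
  beta <- rep$table$coef[match(bn, rep$table$term)]
  if (any(is.na(beta))) stop("spline fit produced undetermined coefficients")
  list(report = rep, knots = knots, beta = beta, aic = rep$aic,
       eval = function(xnew) as.numeric(rcsBasis(xnew, knots)[, , drop = FALSE] %*% beta))
}

#' Harrell's concordance index with jackknife confidence interval
#'
#' Counts all usable pairs under right censoring (the member with the
#' shorter observed time must be an event; tied times are usable only when
#' exactly one member is censored at the tie). Higher scores must predict
#' earlier events. Tied scores count one half. The 95\% CI is
#' normal-theory with the leave-one-out jackknife variance.
#'
#' @param score numeric risk scores (higher = higher risk).
#' @param time,event observed times and 0/1 event flags.
#' @return An object of class \code{concordanceResult}: \code{c},
#'   \code{lower}, \code{upper}, \code{se}, \code{pairs} (usable pair
#'   count), \code{n}.
#' @export
concordanceHarrell <- function(score, time, event) {
  n <- length(score)
  stopifnot(length(time) == n, length(event) == n)
  ev <- event == 1
  lt <- outer(time, time, "<")
  te <- outer(time, time, "==")
  usable <- (lt & ev) | (te & outer(ev, !ev, "&"))   # i short+event vs j
  concM <- usable * (outer(score, score, ">") + 0.5 * outer(score, score, "=="))
  P <- sum(usable); C <- sum(concM)
  if (P == 0) stop("no usable pairs for concordance")
  cidx <- C / P
  Pi <- rowSums(usable) + colSums(usable)
  Ci <- rowSums(concM) + colSums(concM)
  cm <- ifelse(Pi < P, (C - Ci) / (P - Pi), cidx)
  jackVar <- (n - 1) / n * sum((cm - mean(cm))^2)
  se <- sqrt(jackVar)
  structure(list(c = cidx, se = se,
                 lower = max(0, cidx - qnorm(0.975) * se),
                 upper = min(1, cidx + qnorm(0.975) * se),
                 pairs = P, n = n),
            class = "concordanceResult")
}

#' @export
print.concordanceResult <- function(x, ...) {
  cat(sprintf("c-Harrell %.3f (95%% CI %.3f-%.3f), %d usable pairs, n = %d\n",
              x$c, x$lower, x$upper, x$pairs, x$n))
  invisible(x)
}

#' Bootstrap in-bag / out-of-bag split
#'
#' n draws with replacement form the in-bag multiset; the out-of-bag set is
#' its complement (expected fraction (1 - 1/n)^n, about 37\% for large n),
#' used as an internal test set for cutoff validation.
#'
#' @param n number of records.
#' @param seed integer seed.
#' @return list(inBag = integer multiset of size n, outOfBag = integer set).
#' @export
bootstrapOobSplit <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  withSeed(seed, {
    inBag <- sample.int(n, n, replace = TRUE)
    list(inBag = inBag, outOfBag = setdiff(seq_len(n), inBag))
  })
}
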