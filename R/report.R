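#' Run the full prognostic analysis pipeline
#'
#' Orchestrates the whole analysis on a cohort: TMTV distribution summary,
#' inter-reader agreement simulation, spline knot selection, cutoff
#' derivation by the three methods with consensus in the reference arm,
#' Kaplan-Meier and Cox modelling (univariable, multivariable with TMTV
#' continuous and dichotomized), early-progression (POD24) analysis, the
#' combined TMTV x FLIPI2 three-group model for PFS and OS, discrimination
#' gain (delta c-Harrell) and bootstrap inclusion fraction, band analysis,
#' and out-of-bootstrap validation of the chosen cutoff. Stage failures are
#' caught and reported with the stage name; a partial report is still
#' returned. The whole run is a deterministic function of (cohort, config,
#' seed).
#'
#' @param config list; recognized entries: \code{cohort} (data.frame) or
#'   \code{cohortSpec} (a \code{\link{cohortSpec}}; default spec if both
#'   absent), \code{seed} (default 1), \code{B} (bootstrap resamples for
#'   BIF and OOB validation, default 200), \code{knotB} (resamples for
#'   knot selection, default 40), \code{knotRange} (default 3:7),
#'   \code{horizon} (ROC horizon months, default 36), \code{band}
#'   (c(180, 240)), \code{publishedCutoff} (510), \code{readerCv} (0.05),
#'   \code{referenceArm} ("standard").
#' @return A nested list report (class \code{analysisReport}).
#' @seealso \code{\link{writeAnalysisReport}}
#' @export
runFullAnalysis <- function(config = list()) {
  cfg <- utils::modifyList(list(seed = 1L, B = 200L, knotB = 40L,
                                knotRange = 3:7, horizon = 36,
                                band = c(180, 240), publishedCutoff = 510,
                                readerCv = 0.05, referenceArm = "standard"),
                           config)
  seeds <- childSeeds(cfg$seed, 10)
  co <- if (!is.null(cfg[["cohort"]])) cfg[["cohort"]] else {
    spc <- if (!is.null(cfg[["cohortSpec"]])) cfg[["cohortSpec"]] else
      cohortSpec(seed = seeds[1])
    generateCohort(spc)
  }
  if (!"sex_male" %in% names(co) && "sex" %in% names(co))
    co$sex_male <- as.numeric(co$sex == "M")
  if (!"regimen_rb" %in% names(co) && "regimen" %in% names(co))
    co$regimen_rb <- as.numeric(co$regimen == "R-B")
  adj <- intersect(c("flipi2_high", "sex_male", "regimen_rb"), names(co))
  strat <- if ("arm" %in% names(co)) "arm" else NULL
  report <- list(seed = cfg$seed, n = nrow(co), errors = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cl <- conditionCall(e)
      report$errors[[name]] <<- paste0(
        conditionMessage(e),
        if (!is.null(cl)) paste0(" [in ", deparse(cl)[1], "]"))
      NULL
    })
  }

  report$tmtvSummary <- stage("tmtvSummary", {
    q <- quantile(co$tmtv, c(0.25, 0.5, 0.75), type = 7)
    list(n = nrow(co), median = q[[2]], q25 = q[[1]], q75 = q[[3]],
         fracAbove180 = mean(co$tmtv > 180))
  })

  report$readerAgreement <- stage("readerAgreement", {
    sub <- withSeed(seeds[2],
                    sample.int(nrow(co), max(2, round(0.2 * nrow(co)))))
    m <- simulateReaders(pmax(co$tmtv[sub], 1), k = 2, cv = cfg$readerCv,
                         seed = seeds[3])
    ba <- blandAltman(m)
    list(n = length(sub), cvPct = ba$cvPct, bias = ba$bias,
         loa = unname(ba$loa))
  })

  report$knotSelection <- stage("knotSelection", {
    ks <- selectKnotsBootstrap(co, "tmtv", adj, strat,
                               kRange = cfg$knotRange, B = cfg$knotB,
                               seed = seeds[4])
    list(k = ks$k, aicMean = as.list(ks$aicMean),
         failures = as.list(ks$failures))
  })
  kSel <- if (!is.null(report$knotSelection)) report$knotSelection$k else 5

  report$cutoffs <- stage("cutoffs", {
    ms <- maxstatCutpoint(co, "tmtv", adj, strat)
    liu <- rocCutpointLiu(co, horizon = cfg$horizon)
    rc <- rcsCutpoint(co, "tmtv", adj, strat, k = kSel)
    cons <- consensusCutoff(list(ms, liu, rc), co,
                            referenceArm = cfg$referenceArm)
    list(maxstat = ms$cutoff, liu = liu$cutoff, rcs = rc$cutoff,
         rcsNote = if (is.null(rc$note)) "" else rc$note,
         consensus = cons$chosen, consensusTable = cons$table)
  })
  cut <- if (!is.null(report$cutoffs)) report$cutoffs$consensus else 180

  report$survival <- stage("survival", {
    km <- kmEstimate(co)
    hi <- co[co$tmtv > cut, ]; lo <- co[co$tmtv <= cut, ]
    co$.hi <- as.numeric(co$tmtv > cut)
    uni <- coxFit(co, ".hi", strat)
    co$tmtv_per500 <- co$tmtv / 500
    cont <- coxFit(co, "tmtv_per500", strat)
    list(pfs5yr = survivalAt(km, 60),
         pfs5yrHigh = survivalAt(kmEstimate(hi), 60),
         pfs5yrLow = survivalAt(kmEstimate(lo), 60),
         events = sum(co$pfs_event),
         hrHigh = uni$table[1, c("hr", "lower", "upper", "p")],
         hrPer500 = hrPerIncrement(cont, "tmtv_per500", 1))
  })

  report$univariable <- stage("univariable", {
    co$.hi <- as.numeric(co$tmtv > cut)
    covs <- intersect(c(".hi", "age_gt60", "sex_male", "b2m_gt_uln",
                        "bm_involved", "lodlin_gt6cm", "hb_lt12",
                        "flipi2_high", "regimen_rb"), names(co))
    univariableTable(co, covs, strat)
  })

  report$multivariable <- stage("multivariable", {
    mm <- multivariableModel(co, cut, adj[adj != "tmtv"], strat)
    list(continuous = mm$continuous$table, hrPer500 = mm$hrPer500,
         dichotomized = mm$dichotomized$table)
  })

  report$pod24 <- stage("pod24", {
    p <- pod24(co, cut)
    list(table = as.list(as.data.frame(p$table)),
         propHigh = p$proportions[["high"]],
         propLow = p$proportions[["low"]], p = p$p,
         evaluable = p$evaluable)
  })

  report$combined <- stage("combined", {
    grp <- combinedRiskGroup(co$tmtv, cut, co$flipi2_high)
    co$.int <- as.numeric(grp == "intermediate")
    co$.high <- as.numeric(grp == "high")
    m <- coxFit(co, c(".int", ".high"), strat)
    km5 <- vapply(split(co, grp), function(d)
      survivalAt(kmEstimate(d), 60), numeric(1))
    dInt <- co[grp != "low", ]
    mHi <- coxFit(dInt, ".high", strat)
    list(sizes = as.list(table(grp)), pfs5yr = as.list(km5),
         hrIntermediate = m$table[m$table$term == ".int",
                                  c("hr", "lower", "upper", "p")],
         hrHigh = m$table[m$table$term == ".high",
                          c("hr", "lower", "upper", "p")],
         hrHighVsIntermediate = mHi$table[1, c("hr", "lower", "upper", "p")])
  })

  report$modelComparison <- stage("modelComparison", {
    co$.hi <- as.numeric(co$tmtv > cut)
    mc <- modelComparison(co, "flipi2_high", ".hi", strat)
    list(cFlipi2 = c(mc$cBase$c, mc$cBase$lower, mc$cBase$upper),
         cFlipi2Tmtv = c(mc$cFull$c, mc$cFull$lower, mc$cFull$upper),
         deltaC = mc$deltaC, lrtP = mc$lrt$p)
  })

  report$os <- if (all(c("os_time", "os_event") %in% names(co)))
    stage("os", {
      grp <- combinedRiskGroup(co$tmtv, cut, co$flipi2_high)
      co$.int <- as.numeric(grp == "intermediate")
      co$.high <- as.numeric(grp == "high")
      m <- coxFit(co, c(".int", ".high"), strat, time = "os_time",
                  event = "os_event")
      list(os5yr = survivalAt(kmEstimate(co, "os_time", "os_event"), 60),
           deaths = sum(co$os_event),
           hrIntermediate = m$table[m$table$term == ".int",
                                    c("hr", "lower", "upper", "p")],
           hrHigh = m$table[m$table$term == ".high",
                            c("hr", "lower", "upper", "p")])
    })
  else list(note = "OS columns absent; OS section skipped")

  report$band <- stage("band", {
    ba <- bandAnalysis(co, cfg$band[1], cfg$band[2])
    list(occupancy = as.list(ba$occupancy), empty = ba$emptyBands)
  })

  report$publishedCutoff <- stage("publishedCutoff", {
    comparePublishedCutoff(co, cfg$publishedCutoff, cut,
                           adjusters = intersect("flipi2_high", names(co)),
                           strata = strat)
  })

  report$bif <- stage("bif", {
    b <- bif(co, cut, B = cfg$B, seed = seeds[5], strata = strat)
    list(B = b$B, lrtFraction = b$lrtFraction,
         aicFraction = b$aicFraction, failed = b$failed)
  })

  report$oobValidation <- stage("oobValidation", {
    ov <- oobValidate(co, cut, B = cfg$B, seed = seeds[6], strata = strat)
    list(hr = ov$hr, lower = ov$lower, upper = ov$upper,
         B = ov$B, skipped = ov$skipped)
  })

  class(report) <- "analysisReport"
  report
}

#' Write an analysis report to JSON and markdown
#'
#' The JSON file is a faithful machine-readable dump (schema version
#' recorded); the markdown file is a human summary. Output depends only on
#' the report contents, so identical (cohort, config, seed) inputs yield
#' byte-identical files.
#'
#' @param report an \code{analysisReport} from \code{\link{runFullAnalysis}}.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return Invisibly, the paths written.
#' @export
writeAnalysisReport <- function(report, dir, prefix = "analysis") {
  stopifnot(inherits(report, "analysisReport"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonPath <- file.path(dir, paste0(prefix, ".json"))
  out <- unclass(report)
  out$schema <- "tmtv-analysis-report/1"
  jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = 10,
                       na = "null", dataframe = "rows")
  mdPath <- file.path(dir, paste0(prefix, ".md"))
  fmtHr <- function(r) sprintf("%.2f (%.2f-%.2f), p = %.3g",
                               r$hr, r$lower, r$upper, r$p)
  lines <- c(
    "# TMTV prognostic analysis report", "",
    sprintf("- n = %d, seed = %d", report$n, report$seed),
    if (!is.null(report$tmtvSummary)) sprintf(
      "- TMTV: median %.1f mL (IQR %.1f-%.1f), %.0f%% above 180 mL",
      report$tmtvSummary$median, report$tmtvSummary$q25,
      report$tmtvSummary$q75, 100 * report$tmtvSummary$fracAbove180),
    if (!is.null(report$readerAgreement)) sprintf(
      "- Inter-reader agreement (n = %d): CV %.1f%%",
      report$readerAgreement$n, report$readerAgreement$cvPct),
    if (!is.null(report$cutoffs)) sprintf(
      "- Cutoffs: maxstat %.0f, ROC-Liu %.0f, RCS %s; consensus %.0f mL",
      report$cutoffs$maxstat, report$cutoffs$liu,
      if (is.na(report$cutoffs$rcs)) "none" else
        sprintf("%.0f", report$cutoffs$rcs),
      report$cutoffs$consensus),
    if (!is.null(report$survival)) sprintf(
      "- 5-yr PFS %.0f%% overall (high %.0f%%, low %.0f%%); HR high vs low %s",
      100 * report$survival$pfs5yr, 100 * report$survival$pfs5yrHigh,
      100 * report$survival$pfs5yrLow, fmtHr(report$survival$hrHigh)),
    if (!is.null(report$pod24)) sprintf(
      "- POD24: %.0f%% vs %.0f%%, p = %.3g",
      100 * report$pod24$propHigh, 100 * report$pod24$propLow,
      report$pod24$p),
    if (!is.null(report$modelComparison)) sprintf(
      "- c-Harrell: FLIPI2 %.3f -> FLIPI2+TMTV %.3f (delta %.3f)",
      report$modelComparison$cFlipi2[1],
      report$modelComparison$cFlipi2Tmtv[1],
      report$modelComparison$deltaC),
    if (length(report$errors)) c("", "## Stage failures", "",
      sprintf("- %s: %s", names(report$errors), unlist(report$errors))),
    "")
  writeLines(lines, mdPath)
  invisible(c(jsonPath, mdPath))
}
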