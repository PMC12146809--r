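#' Specify a synthetic PET phantom
#'
#' A phantom is a voxel grid with a uniform background SUV, ellipsoidal
#' organs (liver, spleen, marrow, brain, bladder, heart) with diffuse or
#' focal uptake, and lesions (spheres or ellipsoids) tagged by site. Shapes
#' are voxelized by the center-in-shape rule, which makes every geometric
#' quantity exactly reproducible by brute-force enumeration of voxel
#' centers.
#'
#' @param grid integer(3), voxel counts per axis.
#' @param spacing numeric, voxel spacing in mm (length 1 or 3).
#' @param backgroundSuv uniform background SUV (dimensionless).
#' @param organs list of entries from \code{phantomOrgan()}.
#' @param lesions list of entries from \code{phantomLesion()}.
#' @param overlap \code{"error"} rejects specs in which two shapes with
#'   different SUV claim the same voxel; \code{"max"} resolves by max SUV.
#' @param blurFwhmMm optional isotropic Gaussian partial-volume blur
#'   (mm FWHM, 0 = off; blur is applied to the activity volume only, the
#'   truth always refers to the unblurred geometry).
#' @return A \code{phantomSpec} list, validated.
#' @export
phantomSpec <- function(grid, spacing, backgroundSuv = 1,
                        organs = list(), lesions = list(),
                        overlap = c("error", "max"), blurFwhmMm = 0) {
  overlap <- match.arg(overlap)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3, all(grid > 0), length(spacing) == 3,
            all(spacing > 0), backgroundSuv >= 0, blurFwhmMm >= 0)
  fieldOk <- function(sh) {
    all(is.finite(sh$center)) && all(sh$semi > 0) && sh$suv >= 0 &&
      all(sh$center - sh$semi >= 0) &&
      all(sh$center + sh$semi <= grid * spacing)
  }
  for (o in organs)
    if (!fieldOk(o)) stop("organ '", o$name, "' is invalid or does not fit the grid")
  for (l in lesions)
    if (!fieldOk(l)) stop("a lesion is invalid or does not fit inside the grid")
  structure(list(grid = grid, spacing = spacing,
                 backgroundSuv = backgroundSuv, organs = organs,
                 lesions = lesions, overlap = overlap,
                 blurFwhmMm = blurFwhmMm),
            class = "phantomSpec")
}

#' @rdname phantomSpec
#' @param name organ name, one of liver, spleen, marrow, brain, bladder,
#'   heart.
#' @param center,semi ellipsoid center and semi-axes in mm (semi of length 1
#'   gives a sphere).
#' @param suv uniform organ SUV.
#' @param pattern \code{"diffuse"} or \code{"focal"}; focal organs carry a
#'   list of \code{spots}, each a list with center, semi and suv, burned in
#'   on top of the organ baseline.
#' @param spots list of focal spots (see \code{pattern}).
#' @export
phantomOrgan <- function(name = c("liver", "spleen", "marrow", "brain",
                                  "bladder", "heart"),
                         center, semi, suv,
                         pattern = c("diffuse", "focal"), spots = list()) {
  name <- match.arg(name)
  pattern <- match.arg(pattern)
  if (length(semi) == 1) semi <- rep(semi, 3)
  list(name = name, center = center, semi = semi, suv = suv,
       pattern = pattern, spots = spots)
}

#' @rdname phantomSpec
#' @param site lesion site tag: nodal, extranodal, spleen or marrow.
#' @export
phantomLesion <- function(center, semi, suv,
                          site = c("nodal", "extranodal", "spleen", "marrow")) {
  site <- match.arg(site)
  if (length(semi) == 1) semi <- rep(semi, 3)
  list(center = center, semi = semi, suv = suv, site = site)
}

#' Generate a PET phantom with known ground truth
#'
#' Voxelizes the spec onto the grid (voxel center-in-shape rule), emits an
#' activity-concentration volume together with acquisition metadata chosen so
#' that \code{\link{toSUV}} recovers the specified SUVs voxel-wise, and a
#' \linkS4class{PhantomTruth} with exact per-lesion voxel counts, organ masks
#' and the true TMTV at the given threshold.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param seed integer seed (the default phantom is deterministic; the seed
#'   fixes any stochastic option and is recorded for provenance).
#' @param threshold SUV threshold defining which lesions count toward the
#'   true TMTV (default 4).
#' @return list with elements \code{activity} (\linkS4class{ActivityVolume}),
#'   \code{meta} (\linkS4class{AcquisitionMeta}), \code{truth}
#'   (\linkS4class{PhantomTruth}).
#' @examples
#' sp <- phantomSpec(c(32, 32, 32), 4, backgroundSuv = 1,
#'   lesions = list(phantomLesion(c(64, 64, 64), 16, suv = 6)))
#' ph <- generatePhantom(sp, seed = 1)
#' tmtv(ph$truth)
#' @export
generatePhantom <- function(spec, seed = 1L, threshold = 4.0) {
  stopifnot(inherits(spec, "phantomSpec"))
  dims <- spec$grid; sp <- spec$spacing
  suv <- array(spec$backgroundSuv, dims)
  owner <- array(0L, dims)          # 0 background, >0 shape id
  organMasks <- list()
  sid <- 0L
  paint <- function(mask, value, allowOverride = FALSE) {
    sid <<- sid + 1L
    clash <- mask & owner > 0L & abs(suv - value) > 1e-12
    if (any(clash) && !allowOverride) {
      if (spec$overlap == "error")
        stop("overlapping shapes with conflicting SUVs; set overlap = \"max\" to resolve")
      sel <- mask & (owner == 0L | value >= suv)
      suv[sel] <<- value; owner[sel] <<- sid
    } else {
      suv[mask] <<- value; owner[mask] <<- sid
    }
  }
  for (o in spec$organs) {
    m <- ellipsoidMask(dims, sp, o$center, o$semi)
    paint(m, o$suv)
    if (identical(o$pattern, "focal"))
      for (s in o$spots) {
        sm <- ellipsoidMask(dims, sp, s$center, s$semi)
        paint(sm & m, s$suv, allowOverride = TRUE)  # spots live inside their organ
      }
    organMasks[[o$name]] <- which(m)
  }
  lesTab <- data.frame(label = integer(), voxels = integer(),
                       volume_ml = numeric(), suv = numeric(),
                       site = character(), included = logical(),
                       stringsAsFactors = FALSE)
  vv <- prod(sp) / 1000
  for (i in seq_along(spec$lesions)) {
    l <- spec$lesions[[i]]
    m <- ellipsoidMask(dims, sp, l$center, l$semi)
    paint(m, l$suv)
    lesTab[i, c("label", "voxels", "volume_ml", "suv")] <-
      list(i, sum(m), sum(m) * vv, l$suv)
    lesTab$site[i] <- l$site
    lesTab$included[i] <- l$suv >= threshold
  }
  truth <- new("PhantomTruth", lesions = lesTab,
               tmtv = sum(lesTab$volume_ml[lesTab$included]),
               threshold = threshold, organMasks = organMasks,
               dim = dims, spacing = sp)
  # metadata chosen so that toSUV inverts exactly
  meta <- acquisitionMeta(350, as.POSIXct("2020-01-01 10:00:00", tz = "UTC"),
                          as.POSIXct("2020-01-01 11:00:00", tz = "UTC"),
                          bodyWeightKg = 70)
  act <- suv * (decayCorrectedDose(meta) / (meta@bodyWeightKg * 1000))
  if (spec$blurFwhmMm > 0)
    act <- withSeed(seed, gaussianBlur3d(act, sp, spec$blurFwhmMm))
  list(activity = activityVolume(act, sp), meta = meta, truth = truth)
}

#' Write a phantom to disk (NIfTI volume + JSON sidecars)
#'
#' @param phantom result of \code{\link{generatePhantom}}.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, the paths written.
#' @export
writePhantom <- function(phantom, dir, prefix = "phantom") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nii <- file.path(dir, paste0(prefix, ".nii"))
  writeVolume(phantom$activity, nii, meta = phantom$meta)
  tr <- phantom$truth
  jsonlite::write_json(list(
    threshold = tr@threshold, tmtv_ml = tr@tmtv,
    lesions = tr@lesions,
    organ_masks = lapply(tr@organMasks, as.integer),
    dim = tr@dim, spacing_mm = tr@spacing
  ), file.path(dir, paste0(prefix, "_truth.json")), digits = NA)
  invisible(c(nii, file.path(dir, paste0(prefix, "_truth.json"))))
}

#' Simulate multi-reader TMTV measurements
#'
#' Each reader's measurement is the true value times log-normal
#' multiplicative noise with the stated coefficient of variation
#' (\eqn{\sigma^2 = \log(1 + cv^2)}, median-unbiased), emulating
#' inter-reader variability in semi-automated TMTV delineation.
#'
#' @param trueTmtv numeric vector of true TMTV values (mL), all > 0.
#' @param k number of readers (>= 2).
#' @param cv multiplicative noise coefficient of variation (fraction >= 0).
#' @param seed integer seed.
#' @return A \code{k} x \code{length(trueTmtv)} matrix of reader
#'   measurements.
#' @export
simulateReaders <- function(trueTmtv, k = 2L, cv = 0.05, seed = 1L) {
  if (cv < 0) stop("cv must be non-negative")
  if (k < 2) stop("at least two readers are required")
  if (any(trueTmtv <= 0)) stop("true TMTV values must be positive")
  n <- length(trueTmtv)
  if (cv == 0)
    return(matrix(rep(trueTmtv, each = k), nrow = k,
                  dimnames = list(paste0("reader", seq_len(k)), NULL)))
  sigma <- sqrt(log(1 + cv^2))
  withSeed(seed, {
    noise <- matrix(exp(rnorm(k * n, 0, sigma)), nrow = k)
    m <- noise * matrix(rep(trueTmtv, each = k), nrow = k)
    dimnames(m) <- list(paste0("reader", seq_len(k)), NULL)
    m
  })
}
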