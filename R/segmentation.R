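#' Segmentation configuration
#'
#' @param method \code{"fixed-suv4"} (absolute SUV threshold, the
#'   standardized protocol) or \code{"pct41"} (legacy per-lesion 41\% of
#'   SUVmax).
#' @param threshold absolute SUV threshold, inclusive (default 4.0).
#' @param connectivity neighborhood for lesion individuation: 6 (faces),
#'   18 (faces+edges) or 26 (faces+edges+corners, default).
#' @param minLesionVolumeMl components smaller than this are dropped
#'   (default 0 = no filter).
#' @param exclusionOverlap fraction of a component's voxels inside the
#'   physiological-exclusion mask above which it is removed (default 0.5,
#'   i.e. majority overlap).
#' @param diffuseSpleenWholeOrgan when diffuse splenic involvement is
#'   detected, contribute the whole spleen anatomical volume (default TRUE)
#'   rather than only its thresholded voxels.
#' @return A \code{segmentationConfig} list.
#' @export
segmentationConfig <- function(method = c("fixed-suv4", "pct41"),
                               threshold = 4.0, connectivity = 26,
                               minLesionVolumeMl = 0,
                               exclusionOverlap = 0.5,
                               diffuseSpleenWholeOrgan = TRUE) {
  method <- match.arg(method)
  stopifnot(threshold > 0, connectivity %in% c(6, 18, 26),
            minLesionVolumeMl >= 0,
            exclusionOverlap >= 0, exclusionOverlap <= 1)
  structure(list(method = method, threshold = threshold,
                 connectivity = as.integer(connectivity),
                 minLesionVolumeMl = minLesionVolumeMl,
                 exclusionOverlap = exclusionOverlap,
                 diffuseSpleenWholeOrgan = diffuseSpleenWholeOrgan),
            class = "segmentationConfig")
}

#' Organ context for TMTV computation
#'
#' Voxel index sets (linear indices into the SUV array) steering the
#' protocol's organ rules: components majority-inside the exclusion mask are
#' discarded as physiological uptake; the liver VOI supplies the reference
#' background; spleen and marrow masks trigger their dedicated involvement
#' rules.
#'
#' @param exclusion integer indices of physiological-uptake voxels (brain,
#'   bladder, heart, ureters, ...).
#' @param liver integer indices of the liver reference VOI.
#' @param spleen,marrow integer indices of the organ masks.
#' @param marrowFocal either a logical vector of labels flagged focal by the
#'   operator, \code{"auto"} for the simulation heuristic (a marrow
#'   component is focal when its volume is below
#'   \code{marrowFocalFraction} of the marrow mask volume), or NULL (no
#'   marrow handled).
#' @param marrowFocalFraction heuristic fraction for \code{"auto"}
#'   (default 0.25).
#' @return An \code{organContext} list.
#' @export
organContext <- function(exclusion = integer(), liver = integer(),
                         spleen = integer(), marrow = integer(),
                         marrowFocal = "auto", marrowFocalFraction = 0.25) {
  structure(list(exclusion = as.integer(exclusion),
                 liver = as.integer(liver), spleen = as.integer(spleen),
                 marrow = as.integer(marrow), marrowFocal = marrowFocal,
                 marrowFocalFraction = marrowFocalFraction),
            class = "organContext")
}

#' Binary threshold mask
#'
#' @param suv a \linkS4class{SuvVolume}.
#' @param threshold inclusive SUV threshold: a voxel is foreground iff its
#'   SUV is greater than or equal to the threshold.
#' @return Logical 3-D array.
#' @export
thresholdMask <- function(suv, threshold = 4.0) {
  stopifnot(is(suv, "SuvVolume"), threshold > 0)
  suv@voxels >= threshold
}

# Neighbor offsets (voxel steps) for a connectivity scheme.
connectivityOffsets <- function(connectivity) {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  ord <- rowSums(abs(d))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3)
  d[keep, , drop = FALSE]
}

#' Label connected components of a 3-D mask
#'
#' Flood-fill labeling under 6-, 18- or 26-connectivity. Labels are assigned
#' in lexicographic order of each component's first voxel (column-major
#' linear index), so the labeling is deterministic regardless of traversal.
#'
#' @param mask logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of the same shape; 0 is background, components are
#'   numbered from 1.
#' @export
labelComponents <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3, connectivity %in% c(6, 18, 26))
  dims <- dim(mask)
  labels <- array(0L, dims)
  fg <- which(mask)                       # ascending linear indices
  if (!length(fg)) return(labels)
  off <- connectivityOffsets(connectivity)
  offLin <- off[, 1] + off[, 2] * dims[1] + off[, 3] * dims[1] * dims[2]
  coord <- arrayInd(fg, dims)
  # position of each foreground voxel in fg, 0 for background
  pos <- array(0L, dims); pos[fg] <- seq_along(fg)
  lab <- integer(length(fg))
  nextLabel <- 0L
  queue <- integer(length(fg))
  for (startPos in seq_along(fg)) {
    if (lab[startPos] != 0L) next
    nextLabel <- nextLabel + 1L
    lab[startPos] <- nextLabel
    queue[1] <- startPos; qlen <- 1L; qhead <- 1L
    while (qhead <= qlen) {
      cur <- queue[qhead]; qhead <- qhead + 1L
      cc <- coord[cur, ]
      for (k in seq_len(nrow(off))) {
        nc1 <- cc[1] + off[k, 1]
        if (nc1 < 1L || nc1 > dims[1]) next
        nc2 <- cc[2] + off[k, 2]
        if (nc2 < 1L || nc2 > dims[2]) next
        nc3 <- cc[3] + off[k, 3]
        if (nc3 < 1L || nc3 > dims[3]) next
        np <- pos[fg[cur] + offLin[k]]
        if (np != 0L && lab[np] == 0L) {
          lab[np] <- nextLabel
          qlen <- qlen + 1L; queue[qlen] <- np
        }
      }
    }
  }
  labels[fg] <- lab
  labels
}

#' Remove components overlapping the physiological-exclusion mask
#'
#' A component is discarded when the fraction of its voxels lying inside the
#' exclusion mask exceeds \code{overlapRule} (default: majority, > 0.5),
#' emulating the operator's removal of physiological uptake with a
#' deterministic criterion. Removals are reported for the audit trail.
#'
#' @param labeled integer label array from \code{\link{labelComponents}}.
#' @param exclusionIdx integer linear indices of the exclusion mask.
#' @param overlapRule overlap fraction above which a component is removed.
#' @return list(labels = filtered label array (removed components set to 0,
#'   labels unchanged otherwise), removed = data.frame(label, overlap)).
#' @export
applyExclusions <- function(labeled, exclusionIdx, overlapRule = 0.5) {
  if (any(exclusionIdx < 1 | exclusionIdx > length(labeled)))
    stop("exclusion mask indices fall outside the grid")
  if (!length(exclusionIdx))
    return(list(labels = labeled,
                removed = data.frame(label = integer(), overlap = numeric())))
  excl <- array(FALSE, dim(labeled)); excl[exclusionIdx] <- TRUE
  fg <- labeled > 0L
  tot <- tabulate(labeled[fg])
  inExcl <- tabulate(labeled[fg & excl], nbins = length(tot))
  frac <- ifelse(tot > 0, inExcl / tot, 0)
  drop <- which(frac > overlapRule)
  out <- labeled
  if (length(drop)) out[out %in% drop] <- 0L
  list(labels = out,
       removed = data.frame(label = drop, overlap = frac[drop]))
}

#' Mean liver SUV over a reference VOI
#'
#' @param suv a \linkS4class{SuvVolume}.
#' @param liverIdx integer linear indices of the liver VOI.
#' @return Arithmetic mean SUV over the VOI.
#' @export
liverReference <- function(suv, liverIdx) {
  stopifnot(is(suv, "SuvVolume"))
  if (!length(liverIdx)) stop("liver VOI is empty")
  if (any(liverIdx < 1 | liverIdx > length(suv@voxels)))
    stop("liver VOI indices fall outside the grid")
  mean(suv@voxels[liverIdx])
}

#' Spherical liver reference VOI builder
#'
#' Convenience for phantoms: a sphere of given diameter (default 3 cm)
#' centered in a supplied organ mask (at its centroid).
#'
#' @param suv a \linkS4class{SuvVolume} (for grid geometry).
#' @param organIdx linear indices of the liver mask.
#' @param diameterMm VOI diameter in mm.
#' @return Integer linear indices of the VOI.
#' @export
liverSphereVOI <- function(suv, organIdx, diameterMm = 30) {
  dims <- dim(suv@voxels); sp <- suv@spacing
  co <- arrayInd(organIdx, dims)
  centroid <- (colMeans(co) - 0.5) * sp
  which(ellipsoidMask(dims, sp, centroid, rep(diameterMm / 2, 3)))
}

#' Splenic involvement rule
#'
#' The spleen is involved if (a) at least one thresholded component lies
#' (majority of voxels) inside the spleen mask -- focal involvement -- or
#' (b) the mean spleen SUV strictly exceeds 150\% of the liver reference --
#' diffuse involvement. Diffuse involvement contributes the whole spleen
#' anatomical volume by default; focal involvement contributes the
#' thresholded components.
#'
#' @param suv a \linkS4class{SuvVolume}.
#' @param spleenIdx linear indices of the spleen mask (required).
#' @param liverRef mean liver SUV from \code{\link{liverReference}}.
#' @param labeled label array of thresholded components.
#' @param wholeOrganIfDiffuse contribute the full spleen mask for diffuse
#'   involvement (default TRUE); FALSE contributes thresholded spleen
#'   voxels only.
#' @return list(involved, mode = "none"/"focal"/"diffuse", contributionIdx
#'   = linear indices contributed, focalLabels = labels of spleen
#'   components).
#' @export
spleenRule <- function(suv, spleenIdx, liverRef, labeled,
                       wholeOrganIfDiffuse = TRUE) {
  if (!length(spleenIdx)) stop("spleen rule requested but spleen mask is missing")
  inSpleen <- array(FALSE, dim(labeled)); inSpleen[spleenIdx] <- TRUE
  fg <- labeled > 0L
  tot <- tabulate(labeled[fg])
  inside <- tabulate(labeled[fg & inSpleen], nbins = length(tot))
  focalLabels <- which(tot > 0 & inside / pmax(tot, 1) > 0.5)
  meanSpleen <- mean(suv@voxels[spleenIdx])
  diffuse <- meanSpleen > 1.5 * liverRef      # strict inequality
  if (diffuse) {
    idx <- if (wholeOrganIfDiffuse) spleenIdx else
      spleenIdx[labeled[spleenIdx] > 0L]
    list(involved = TRUE, mode = "diffuse", contributionIdx = idx,
         focalLabels = focalLabels, meanSpleenSuv = meanSpleen)
  } else if (length(focalLabels)) {
    idx <- which(array(labeled %in% focalLabels, dim(labeled)))
    list(involved = TRUE, mode = "focal", contributionIdx = idx,
         focalLabels = focalLabels, meanSpleenSuv = meanSpleen)
  } else {
    list(involved = FALSE, mode = "none", contributionIdx = integer(),
         focalLabels = integer(), meanSpleenSuv = meanSpleen)
  }
}

#' Bone-marrow involvement rule
#'
#' Marrow components contribute to TMTV only when flagged focal; diffuse
#' marrow uptake contributes nothing. Flags are per component: operator
#' supplied, or the simulation heuristic (\code{"auto"}: focal iff the
#' component is smaller than a set fraction of the marrow mask).
#'
#' @param labeled label array of thresholded components.
#' @param marrowIdx linear indices of the marrow mask.
#' @param focal \code{"auto"}, or an integer/logical selection of labels
#'   judged focal by the operator.
#' @param focalFraction heuristic fraction for \code{"auto"}.
#' @return list(marrowLabels, focalLabels, contributionIdx).
#' @export
marrowRule <- function(labeled, marrowIdx, focal = "auto",
                       focalFraction = 0.25) {
  if (!length(marrowIdx))
    return(list(marrowLabels = integer(), focalLabels = integer(),
                contributionIdx = integer()))
  inMarrow <- array(FALSE, dim(labeled)); inMarrow[marrowIdx] <- TRUE
  fg <- labeled > 0L
  tot <- tabulate(labeled[fg])
  inside <- tabulate(labeled[fg & inMarrow], nbins = length(tot))
  marrowLabels <- which(tot > 0 & inside / pmax(tot, 1) > 0.5)
  focalLabels <- if (identical(focal, "auto")) {
    marrowLabels[tot[marrowLabels] < focalFraction * length(marrowIdx)]
  } else if (is.logical(focal)) {
    intersect(marrowLabels, which(focal))
  } else intersect(marrowLabels, as.integer(focal))
  idx <- if (length(focalLabels))
    which(array(labeled %in% focalLabels, dim(labeled))) else integer()
  list(marrowLabels = marrowLabels, focalLabels = focalLabels,
       contributionIdx = idx)
}

# Build the per-lesion table for a set of retained-label voxels.
lesionTable <- function(labeled, suvArr, vv, siteOf = NULL) {
  labs <- sort(unique(labeled[labeled > 0L]))
  if (!length(labs))
    return(data.frame(label = integer(), voxels = integer(),
                      volume_ml = numeric(), suv_max = numeric(),
                      site = character(), stringsAsFactors = FALSE))
  cnt <- tabulate(labeled[labeled > 0L])[labs]
  smax <- vapply(labs, function(l) max(suvArr[labeled == l]), numeric(1))
  data.frame(label = labs, voxels = cnt, volume_ml = cnt * vv,
             suv_max = smax,
             site = if (is.null(siteOf)) rep("nodal", length(labs))
                    else siteOf[as.character(labs)],
             stringsAsFactors = FALSE)
}

#' Compute total metabolic tumor volume
#'
#' Full protocol: threshold the SUV volume at a fixed absolute SUV
#' (inclusive, default 4.0), individuate lesions as connected components,
#' remove physiological-uptake components via the exclusion mask, apply the
#' spleen rule (focal, or diffuse uptake above 150\% of the liver
#' background) and the marrow rule (focal uptake only), optionally drop
#' tiny components, and sum the retained lesion volumes. Every exclusion
#' and organ decision is recorded in the audit log.
#'
#' @param suv a \linkS4class{SuvVolume}.
#' @param config a \code{\link{segmentationConfig}}.
#' @param ctx an \code{\link{organContext}} (NULL = no organ handling).
#' @return A \linkS4class{TmtvResult}.
#' @examples
#' sp <- phantomSpec(c(32, 32, 32), 4,
#'   lesions = list(phantomLesion(c(64, 64, 64), 16, suv = 6)))
#' ph <- generatePhantom(sp)
#' res <- computeTMTV(toSUV(ph$activity, ph$meta))
#' tmtv(res) == tmtv(ph$truth)
#' @export
computeTMTV <- function(suv, config = segmentationConfig(), ctx = NULL) {
  stopifnot(is(suv, "SuvVolume"), inherits(config, "segmentationConfig"))
  if (config$method == "pct41")
    return(pct41Segment(suv, config = config, ctx = ctx))
  audit <- character()
  vv <- voxelVolume(suv)
  mask <- thresholdMask(suv, config$threshold)
  labeled <- labelComponents(mask, config$connectivity)
  audit <- c(audit, sprintf(
    "threshold SUV >= %g (inclusive), connectivity %d: %d component(s)",
    config$threshold, config$connectivity, max(labeled)))
  site <- setNames(rep("nodal", max(labeled)), seq_len(max(labeled)))
  retainedExtra <- integer()   # organ-contributed voxels outside components
  dropped <- data.frame(label = integer(), reason = character(),
                        stringsAsFactors = FALSE)
  if (!is.null(ctx)) {
    if (length(ctx$exclusion)) {
      ex <- applyExclusions(labeled, ctx$exclusion, config$exclusionOverlap)
      if (nrow(ex$removed)) {
        audit <- c(audit, sprintf(
          "excluded component %d (physiological overlap %.0f%%)",
          ex$removed$label, 100 * ex$removed$overlap))
        dropped <- rbind(dropped, data.frame(
          label = ex$removed$label,
          reason = sprintf("physiological overlap %.0f%%",
                           100 * ex$removed$overlap)))
      }
      labeled <- ex$labels
    }
    if (length(ctx$spleen)) {
      lr <- liverReference(suv, ctx$liver)
      sr <- spleenRule(suv, ctx$spleen, lr, labeled,
                       config$diffuseSpleenWholeOrgan)
      audit <- c(audit, sprintf(
        "spleen: mean SUV %.3f vs 1.5 x liver %.3f -> %s",
        sr$meanSpleenSuv, lr, sr$mode))
      if (sr$mode == "diffuse" && config$diffuseSpleenWholeOrgan) {
        # whole-organ volume replaces any thresholded spleen components
        if (length(sr$focalLabels)) {
          labeled[labeled %in% sr$focalLabels] <- 0L
          dropped <- rbind(dropped, data.frame(
            label = sr$focalLabels,
            reason = "absorbed into diffuse whole-spleen contribution"))
        }
        retainedExtra <- union(retainedExtra, sr$contributionIdx)
        audit <- c(audit, sprintf(
          "spleen: whole-organ contribution %.3f mL",
          length(sr$contributionIdx) * vv))
      } else if (length(sr$focalLabels)) {
        site[as.character(sr$focalLabels)] <- "spleen"
        audit <- c(audit, sprintf("spleen: focal component %d retained",
                                  sr$focalLabels))
      }
    }
    if (length(ctx$marrow)) {
      mr <- marrowRule(labeled, ctx$marrow, ctx$marrowFocal,
                       ctx$marrowFocalFraction)
      diffuseMarrow <- setdiff(mr$marrowLabels, mr$focalLabels)
      if (length(diffuseMarrow)) {
        labeled[labeled %in% diffuseMarrow] <- 0L
        audit <- c(audit, sprintf(
          "marrow: component %d diffuse, contributes 0 mL", diffuseMarrow))
        dropped <- rbind(dropped, data.frame(
          label = diffuseMarrow, reason = "diffuse marrow uptake"))
      }
      if (length(mr$focalLabels)) {
        site[as.character(mr$focalLabels)] <- "marrow"
        audit <- c(audit, sprintf("marrow: focal component %d retained",
                                  mr$focalLabels))
      }
    }
  }
  tab <- lesionTable(labeled, suv@voxels, vv, site)
  tab$retained <- rep(TRUE, nrow(tab))
  tab$reason <- rep("", nrow(tab))
  if (config$minLesionVolumeMl > 0) {
    small <- tab$volume_ml < config$minLesionVolumeMl
    if (any(small)) {
      audit <- c(audit, sprintf(
        "component %d below minimum lesion volume (%.3f mL)",
        tab$label[small], tab$volume_ml[small]))
      tab$retained[small] <- FALSE
      tab$reason[small] <- "below minimum lesion volume"
      labeled[labeled %in% tab$label[small]] <- 0L
    }
  }
  if (nrow(dropped)) {
    dtab <- data.frame(label = dropped$label, voxels = NA_integer_,
                       volume_ml = NA_real_, suv_max = NA_real_,
                       site = "excluded", retained = FALSE,
                       reason = dropped$reason, stringsAsFactors = FALSE)
    tab <- rbind(tab, dtab)
  }
  extraMl <- 0
  if (length(retainedExtra)) {
    # whole-spleen contribution enters as its own pseudo-lesion row
    newIdx <- setdiff(retainedExtra, which(labeled > 0L))
    extraMl <- length(newIdx) * vv
    tab <- rbind(tab, data.frame(
      label = max(c(0L, tab$label), na.rm = TRUE) + 1L,
      voxels = length(newIdx), volume_ml = extraMl,
      suv_max = max(suv@voxels[retainedExtra]),
      site = "spleen", retained = TRUE, reason = "diffuse spleen",
      stringsAsFactors = FALSE))
  }
  total <- sum(tab$volume_ml[tab$retained], na.rm = TRUE)
  gmax <- if (any(tab$retained)) max(tab$suv_max[tab$retained], na.rm = TRUE)
          else NA_real_
  new("TmtvResult", lesions = tab, tmtv = total, globalSuvMax = gmax,
      config = unclass(config), audit = audit, labelMap = labeled)
}

#' Legacy 41\%-of-SUVmax segmentation
#'
#' Detection pass at a seed threshold individuates candidate lesions; each
#' is then re-grown at its own threshold of 41\% of the component SUVmax
#' (the connected component of the per-lesion thresholded mask that contains
#' the component's peak voxel). Overlapping re-grown regions are merged so
#' no voxel is counted twice. Provided for comparison against the
#' fixed-threshold protocol (historic cutoffs were derived with this
#' method).
#'
#' @param suv a \linkS4class{SuvVolume}.
#' @param seedThreshold SUV threshold of the detection pass (default 2.5).
#' @param config a \code{\link{segmentationConfig}} (connectivity is used).
#' @param ctx optional \code{\link{organContext}}; only the exclusion mask
#'   is applied in this mode.
#' @return A \linkS4class{TmtvResult} with method \code{"pct41"}.
#' @export
pct41Segment <- function(suv, seedThreshold = 2.5,
                         config = segmentationConfig(method = "pct41"),
                         ctx = NULL) {
  stopifnot(is(suv, "SuvVolume"))
  vv <- voxelVolume(suv)
  audit <- sprintf("pct41: detection pass at SUV >= %g", seedThreshold)
  seeds <- labelComponents(thresholdMask(suv, seedThreshold),
                           config$connectivity)
  if (!is.null(ctx) && length(ctx$exclusion))
    seeds <- applyExclusions(seeds, ctx$exclusion,
                             config$exclusionOverlap)$labels
  out <- array(0L, dim(seeds))
  nextLab <- 0L
  for (l in seq_len(max(seeds))) {
    compIdx <- which(seeds == l)
    if (!length(compIdx)) next
    peak <- compIdx[which.max(suv@voxels[compIdx])]
    thr <- 0.41 * max(suv@voxels[compIdx])
    grown <- labelComponents(suv@voxels >= thr, config$connectivity)
    region <- which(grown == grown[peak])
    region <- region[out[region] == 0L]   # merge overlaps, count once
    if (!length(region)) next
    nextLab <- nextLab + 1L
    out[region] <- nextLab
    audit <- c(audit, sprintf(
      "lesion %d: SUVmax %.3f, threshold %.3f, %d voxel(s)",
      nextLab, max(suv@voxels[compIdx]), thr, length(region)))
  }
  tab <- lesionTable(out, suv@voxels, vv)
  tab$retained <- rep(TRUE, nrow(tab))
  tab$reason <- rep("", nrow(tab))
  total <- sum(tab$volume_ml)
  gmax <- if (nrow(tab)) max(tab$suv_max) else NA_real_
  cfg <- unclass(config); cfg$method <- "pct41"
  cfg$seedThreshold <- seedThreshold
  new("TmtvResult", lesions = tab, tmtv = total, globalSuvMax = gmax,
      config = cfg, audit = audit, labelMap = out)
}

#' Export a lesion table to CSV
#'
#' @param result a \linkS4class{TmtvResult}.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
writeLesionTable <- function(result, path) {
  stopifnot(is(result, "TmtvResult"))
  utils::write.csv(lesions(result), path, row.names = FALSE)
  invisible(path)
}
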