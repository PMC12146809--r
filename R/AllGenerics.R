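#' Accessors for PET volume and TMTV objects
#'
#' \code{spacing} returns the voxel spacing in mm; \code{voxelVolume} the
#' volume of one voxel in mL; \code{voxels} the raw 3-D array; \code{tmtv}
#' the total metabolic tumor volume in mL; \code{lesions} the per-lesion
#' table; \code{suvMax} the global SUVmax.
#'
#' @param x a \linkS4class{PetVolume}, \linkS4class{TmtvResult} or
#'   \linkS4class{PhantomTruth} object.
#' @return \code{spacing}: numeric(3) mm; \code{voxelVolume}: numeric scalar
#'   mL; \code{voxels}: 3-D array; \code{tmtv}: numeric scalar mL;
#'   \code{lesions}: data.frame; \code{suvMax}: numeric scalar.
#' @name accessors
#' @aliases spacing voxelVolume voxels tmtv lesions suvMax
NULL

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))
#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("tmtv", function(x) standardGeneric("tmtv"))
#' @rdname accessors
#' @export
setGeneric("lesions", function(x) standardGeneric("lesions"))
#' @rdname accessors
#' @export
setGeneric("suvMax", function(x) standardGeneric("suvMax"))

#' @rdname accessors
setMethod("spacing", "PetVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "PhantomTruth", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelVolume", "PetVolume", function(x) prod(x@spacing) / 1000)
#' @rdname accessors
setMethod("voxelVolume", "PhantomTruth", function(x) prod(x@spacing) / 1000)
#' @rdname accessors
setMethod("voxels", "PetVolume", function(x) x@voxels)
#' @rdname accessors
setMethod("tmtv", "TmtvResult", function(x) x@tmtv)
#' @rdname accessors
setMethod("tmtv", "PhantomTruth", function(x) x@tmtv)
#' @rdname accessors
setMethod("lesions", "TmtvResult", function(x) x@lesions)
#' @rdname accessors
setMethod("lesions", "PhantomTruth", function(x) x@lesions)
#' @rdname accessors
setMethod("suvMax", "SuvVolume", function(x) max(x@voxels))
#' @rdname accessors
setMethod("suvMax", "TmtvResult", function(x) x@globalSuvMax)

setMethod("show", "AcquisitionMeta", function(object) {
  dt <- as.numeric(object@scanTime) - as.numeric(object@injectionTime)
  cat("AcquisitionMeta:", object@injectedDoseMBq, "MBq,",
      object@bodyWeightKg, "kg, uptake", round(dt), "s, half-life",
      object@halfLifeS, "s\n")
})

setMethod("show", "ActivityVolume", function(object) {
  cat("ActivityVolume", paste(dim(object@voxels), collapse = " x "),
      "voxels,", paste(object@spacing, collapse = " x "), "mm, range [",
      signif(min(object@voxels), 4), ",", signif(max(object@voxels), 4),
      "] Bq/mL\n")
})

setMethod("show", "SuvVolume", function(object) {
  cat("SuvVolume", paste(dim(object@voxels), collapse = " x "),
      "voxels,", paste(object@spacing, collapse = " x "),
      "mm, SUVmax", signif(max(object@voxels), 4), "\n")
})

setMethod("show", "PhantomTruth", function(object) {
  cat("PhantomTruth:", nrow(object@lesions), "lesion(s), true TMTV",
      signif(object@tmtv, 6), "mL at SUV >=", object@threshold, "\n")
})

setMethod("show", "TmtvResult", function(object) {
  kept <- sum(object@lesions$retained)
  cat("TmtvResult (", object@config$method, "): TMTV ",
      signif(object@tmtv, 6), " mL, ", kept, " retained lesion(s)",
      if (nrow(object@lesions) > kept)
        paste0(" (", nrow(object@lesions) - kept, " excluded)"),
      ", global SUVmax ", signif(object@globalSuvMax, 4), "\n", sep = "")
})
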