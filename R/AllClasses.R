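#' @import methods
#' @importFrom stats quantile median qnorm pnorm rnorm runif rexp setNames
#'   approx uniroot sd var complete.cases anova pchisq fisher.test chisq.test
#'   as.formula coef vcov logLik
NULL

setOldClass(c("POSIXct", "POSIXt"))

#' Acquisition metadata for a PET scan
#'
#' Carries the quantities needed to convert an activity-concentration volume
#' to body-weight SUV: injected dose, injection and scan timestamps, isotope
#' half-life and patient body weight.
#'
#' @slot injectedDoseMBq injected activity in MBq at injection time.
#' @slot injectionTime,scanTime timestamps (\code{POSIXct}); the scan must not
#'   precede the injection.
#' @slot halfLifeS isotope half-life in seconds (default F-18, 6586.2 s).
#' @slot bodyWeightKg patient body weight in kg.
#' @exportClass AcquisitionMeta
setClass("AcquisitionMeta",
  representation(
    injectedDoseMBq = "numeric",
    injectionTime   = "POSIXct",
    scanTime        = "POSIXct",
    halfLifeS       = "numeric",
    bodyWeightKg    = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@injectedDoseMBq) != 1 || !is.finite(object@injectedDoseMBq) ||
        object@injectedDoseMBq <= 0)
      msg <- c(msg, "injectedDoseMBq must be a single positive number")
    if (length(object@bodyWeightKg) != 1 || !is.finite(object@bodyWeightKg) ||
        object@bodyWeightKg <= 0)
      msg <- c(msg, "bodyWeightKg must be a single positive number")
    if (length(object@halfLifeS) != 1 || !is.finite(object@halfLifeS) ||
        object@halfLifeS <= 0)
      msg <- c(msg, "halfLifeS must be a single positive number")
    if (length(object@scanTime) != 1 || length(object@injectionTime) != 1)
      msg <- c(msg, "timestamps must be single POSIXct values")
    else if (as.numeric(object@scanTime) < as.numeric(object@injectionTime))
      msg <- c(msg, "scanTime must not precede injectionTime")
    if (length(msg)) msg else TRUE
  }
)

#' Constructor for AcquisitionMeta
#'
#' @param injectedDoseMBq injected dose in MBq.
#' @param injectionTime,scanTime timestamps; character in ISO-8601 is accepted
#'   and parsed as UTC.
#' @param halfLifeS isotope half-life in seconds; default F-18.
#' @param bodyWeightKg body weight in kg.
#' @return An \linkS4class{AcquisitionMeta} object.
#' @examples
#' acquisitionMeta(350, "2020-01-01 10:00:00", "2020-01-01 11:00:00",
#'                 bodyWeightKg = 70)
#' @export
acquisitionMeta <- function(injectedDoseMBq, injectionTime, scanTime,
                            halfLifeS = 6586.2, bodyWeightKg) {
  toTime <- function(x) {
    if (inherits(x, "POSIXct")) return(x)
    out <- as.POSIXct(x, tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                     "%Y-%m-%d %H:%M:%OS",
                                     "%Y-%m-%d %H:%M",
                                     "%Y-%m-%d"))
    if (is.na(out)) stop("unparseable timestamp: ", x)
    out
  }
  new("AcquisitionMeta",
      injectedDoseMBq = as.numeric(injectedDoseMBq),
      injectionTime = toTime(injectionTime),
      scanTime = toTime(scanTime),
      halfLifeS = as.numeric(halfLifeS),
      bodyWeightKg = as.numeric(bodyWeightKg))
}

#' Voxel volumes on a regular 3-D grid
#'
#' \code{PetVolume} is the virtual parent of \linkS4class{ActivityVolume}
#' (activity concentration, Bq/mL) and \linkS4class{SuvVolume} (dimensionless
#' body-weight SUV). Both carry a 3-D numeric array and the voxel spacing in
#' mm per axis.
#'
#' @slot voxels 3-D numeric array of non-negative values.
#' @slot spacing numeric(3), voxel edge lengths in mm.
#' @aliases PetVolume-class ActivityVolume-class SuvVolume-class
#' @exportClass PetVolume
setClass("PetVolume",
  representation("VIRTUAL", voxels = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3)
      msg <- c(msg, "voxels must be a 3-D array")
    if (length(object@spacing) != 3 || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be three positive numbers (mm)")
    if (any(object@voxels < 0, na.rm = TRUE))
      msg <- c(msg, "voxel values must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

#' @exportClass ActivityVolume
setClass("ActivityVolume", contains = "PetVolume")

#' @exportClass SuvVolume
setClass("SuvVolume", contains = "PetVolume",
  representation(meta = "AcquisitionMeta"))

#' Construct an activity-concentration volume
#'
#' @param voxels 3-D array of activity concentration in Bq/mL.
#' @param spacing voxel spacing in mm per axis (length 1 or 3).
#' @return An \linkS4class{ActivityVolume}.
#' @export
activityVolume <- function(voxels, spacing) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  new("ActivityVolume", voxels = voxels, spacing = as.numeric(spacing))
}

#' Construct an SUV volume directly
#'
#' Normally produced by \code{\link{toSUV}}; this constructor supports
#' vendor images that are already SUV-scaled (passthrough mode).
#'
#' @param voxels 3-D array of dimensionless body-weight SUV.
#' @param spacing voxel spacing in mm per axis.
#' @param meta the \linkS4class{AcquisitionMeta} provenance.
#' @return A \linkS4class{SuvVolume}.
#' @export
suvVolume <- function(voxels, spacing, meta) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  new("SuvVolume", voxels = voxels, spacing = as.numeric(spacing), meta = meta)
}

#' Ground truth attached to a synthetic phantom
#'
#' Records, for every simulated lesion, its exact voxel count under the
#' center-in-shape voxelization rule, the corresponding volume in mL, and the
#' resulting true TMTV at the segmentation threshold; organ masks are stored
#' as linear voxel index sets.
#'
#' @slot lesions data.frame with one row per lesion: \code{label},
#'   \code{voxels}, \code{volume_ml}, \code{suv}, \code{site},
#'   \code{included} (counted in true TMTV, i.e. SUV at or above threshold).
#' @slot tmtv true total metabolic tumor volume in mL.
#' @slot threshold SUV threshold the truth refers to.
#' @slot organMasks named list of integer vectors (linear voxel indices).
#' @slot dim,spacing grid geometry.
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(lesions = "data.frame", tmtv = "numeric",
                 threshold = "numeric", organMasks = "list",
                 dim = "integer", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- c("label", "voxels", "volume_ml", "suv", "site", "included")
    if (!all(need %in% names(object@lesions)))
      msg <- c(msg, paste("lesions must have columns:", paste(need, collapse = ", ")))
    else {
      vv <- prod(object@spacing) / 1000
      if (nrow(object@lesions) &&
          max(abs(object@lesions$volume_ml - object@lesions$voxels * vv)) > 1e-9)
        msg <- c(msg, "lesion volume must equal voxel count x voxel volume")
      inc <- object@lesions$included
      if (abs(object@tmtv - sum(object@lesions$volume_ml[inc])) > 1e-9)
        msg <- c(msg, "tmtv must equal the sum of included lesion volumes")
    }
    if (length(msg)) msg else TRUE
  }
)

#' TMTV segmentation result
#'
#' Holds the per-lesion table (retained and excluded components), the total
#' metabolic tumor volume, the global SUVmax over retained lesions, a
#' snapshot of the configuration, an audit trail of exclusion and organ-rule
#' decisions, and the lesion label map.
#'
#' @slot lesions data.frame: \code{label}, \code{voxels}, \code{volume_ml},
#'   \code{suv_max}, \code{site}, \code{retained}, \code{reason}.
#' @slot tmtv total metabolic tumor volume (mL) of retained lesions.
#' @slot globalSuvMax maximum SUV over retained lesions (NA if none).
#' @slot config list snapshot of the \code{\link{segmentationConfig}} used.
#' @slot audit character log of decisions.
#' @slot labelMap integer array of retained-lesion labels (0 = background).
#' @exportClass TmtvResult
setClass("TmtvResult",
  representation(lesions = "data.frame", tmtv = "numeric",
                 globalSuvMax = "numeric", config = "list",
                 audit = "character", labelMap = "array"),
  validity = function(object) {
    msg <- character()
    if (object@tmtv < 0) msg <- c(msg, "tmtv must be non-negative")
    if (nrow(object@lesions)) {
      kept <- object@lesions$retained
      if (abs(object@tmtv - sum(object@lesions$volume_ml[kept])) > 1e-9)
        msg <- c(msg, "tmtv must equal the sum of retained lesion volumes")
    } else if (object@tmtv != 0) {
      msg <- c(msg, "tmtv must be 0 when there are no lesions")
    }
    if (length(msg)) msg else TRUE
  }
)
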