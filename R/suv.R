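#' Decay-corrected injected dose at scan time
#'
#' Applies radioactive decay over the uptake interval:
#' \eqn{D = D_0 \cdot 2^{-\Delta t / T_{1/2}}} with \eqn{\Delta t} the time
#' from injection to scan.
#'
#' @param meta an \linkS4class{AcquisitionMeta}.
#' @return Decay-corrected dose in Bq.
#' @examples
#' m <- acquisitionMeta(350, "2020-01-01 10:00:00", "2020-01-01 11:49:46.2",
#'                      bodyWeightKg = 70)
#' decayCorrectedDose(m)  # one half-life later: 175 MBq
#' @export
decayCorrectedDose <- function(meta) {
  stopifnot(is(meta, "AcquisitionMeta"))
  dt <- as.numeric(meta@scanTime) - as.numeric(meta@injectionTime)
  if (dt < 0) stop("scan time precedes injection time (negative uptake interval)")
  meta@injectedDoseMBq * 1e6 * 2^(-dt / meta@halfLifeS)
}

#' Convert activity concentration to body-weight SUV
#'
#' Voxel-wise \eqn{SUV = C \,[\mathrm{Bq/mL}] \times w\,[\mathrm{g}] / D\,[\mathrm{Bq}]}
#' with \eqn{D} the decay-corrected dose at scan time and \eqn{w} the body
#' weight. Only the body-weight SUV variant is provided.
#'
#' @param vol an \linkS4class{ActivityVolume}; with \code{passthrough=TRUE}
#'   a volume whose voxels are already SUV-scaled.
#' @param meta an \linkS4class{AcquisitionMeta}.
#' @param passthrough if TRUE the voxel values are taken as SUV as-is
#'   (vendor pre-scaled images); metadata is attached unchanged.
#' @return A \linkS4class{SuvVolume}.
#' @export
toSUV <- function(vol, meta, passthrough = FALSE) {
  stopifnot(is(vol, "PetVolume"), is(meta, "AcquisitionMeta"))
  if (passthrough)
    return(new("SuvVolume", voxels = vol@voxels, spacing = vol@spacing, meta = meta))
  d <- decayCorrectedDose(meta)
  if (d <= 0) stop("decay-corrected dose must be positive")
  w <- meta@bodyWeightKg * 1000  # g
  if (w <= 0) stop("body weight must be positive")
  new("SuvVolume", voxels = vol@voxels * (w / d), spacing = vol@spacing,
      meta = meta)
}

.metaFields <- c("injected_dose_MBq", "injection_time", "scan_time",
                 "half_life_s", "body_weight_kg")

#' Read and write PET volumes (NIfTI-1 + JSON sidecar)
#'
#' Volumes are stored as NIfTI-1 with the voxel spacing in the pixdim header
#' fields; acquisition metadata travels in a JSON sidecar with fields
#' \code{injected_dose_MBq}, \code{injection_time}, \code{scan_time}
#' (ISO-8601), \code{half_life_s}, \code{body_weight_kg}.
#'
#' @param path NIfTI file path (.nii or .nii.gz).
#' @param format only \code{"nifti"} is supported; a DICOM series reader is
#'   not provided.
#' @param metaPath optional sidecar JSON path; default replaces the NIfTI
#'   extension with \code{.json}. Missing mandatory fields raise an error
#'   naming them.
#' @param what class of volume to return, \code{"activity"} or \code{"suv"}.
#' @return \code{readVolume}: a list with elements \code{volume} and
#'   \code{meta} (NULL if no sidecar exists and \code{metaPath} not given).
#' @export
readVolume <- function(path, format = c("nifti", "dicom-series"),
                       metaPath = NULL, what = c("activity", "suv")) {
  format <- match.arg(format)
  what <- match.arg(what)
  if (format == "dicom-series")
    stop("DICOM series reading is not supported; convert to NIfTI-1 upstream")
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(img)
  sp <- as.numeric(sp)[seq_len(3)]
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  meta <- NULL
  if (is.null(metaPath)) {
    cand <- sub("\\.nii(\\.gz)?$", ".json", path)
    if (file.exists(cand)) metaPath <- cand
  }
  if (!is.null(metaPath)) {
    if (!file.exists(metaPath)) stop("metadata file not found: ", metaPath)
    j <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    missing <- setdiff(.metaFields, names(j))
    if (length(missing))
      stop("metadata is missing mandatory field(s): ",
           paste(missing, collapse = ", "))
    meta <- acquisitionMeta(j$injected_dose_MBq, j$injection_time,
                            j$scan_time, j$half_life_s, j$body_weight_kg)
  }
  vol <- if (what == "activity") activityVolume(arr, sp) else {
    if (is.null(meta)) stop("reading an SUV volume requires metadata")
    suvVolume(arr, sp, meta)
  }
  list(volume = vol, meta = meta)
}

#' @rdname readVolume
#' @param vol a \linkS4class{PetVolume} to write.
#' @param meta optional \linkS4class{AcquisitionMeta}; when given, the JSON
#'   sidecar is written next to the NIfTI file.
#' @return \code{writeVolume}: the NIfTI path, invisibly.
#' @export
writeVolume <- function(vol, path, meta = NULL, metaPath = NULL) {
  stopifnot(is(vol, "PetVolume"))
  img <- RNifti::asNifti(vol@voxels)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, path)
  if (!is.null(meta)) {
    if (is.null(metaPath)) metaPath <- sub("\\.nii(\\.gz)?$", ".json", path)
    fmt <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
    jsonlite::write_json(list(
      injected_dose_MBq = meta@injectedDoseMBq,
      injection_time = fmt(meta@injectionTime),
      scan_time = fmt(meta@scanTime),
      half_life_s = meta@halfLifeS,
      body_weight_kg = meta@bodyWeightKg
    ), metaPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
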