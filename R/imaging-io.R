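#' @include AllClasses.R frame-schedule.R
NULL

.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dynPET_error", "error", "condition")))
}

#' Construct a DynamicImage
#'
#' @param values 4-D numeric array (x, y, z, frame), kBq/mL.
#' @param spacing voxel spacing in mm, length-3.
#' @param sched a \code{\link{FrameSchedule}} matching dim 4.
#' @param units activity-concentration units; only "kBq/mL" is processed.
#' @return a validated \code{\link{DynamicImage}}.
#' @export
dynamicImage <- function(values, spacing, sched, units = "kBq/mL") {
  new("DynamicImage", values = values, spacing = as.numeric(spacing),
      schedule = sched, units = units)
}

#' Construct a VoiMask
#'
#' @param labels 3-D integer array of region labels (0 = background).
#' @param labelNames named integer vector or named list, organ -> label.
#' @return a validated \code{\link{VoiMask}}.
#' @export
voiMask <- function(labels, labelNames) {
  ln <- vapply(labelNames, as.integer, integer(1))
  storage.mode(labels) <- "integer"
  new("VoiMask", labels = labels, labelNames = ln)
}

#' Construct a ScanSession
#'
#' @param subjectId character identifier.
#' @param week imaging week (1--4).
#' @param injectedActivity MBq at scan start.
#' @param bodyWeight g.
#' @param glucosePre,glucosePost blood glucose, mmol/L (post may be NA).
#' @param route "iv" or "ip".
#' @param image,mask optional \code{DynamicImage} / \code{VoiMask}.
#' @param groundTruth list of simulator truth (phantoms only).
#' @return a validated \code{\link{ScanSession}}.
#' @export
scanSession <- function(subjectId, week, injectedActivity, bodyWeight,
                        glucosePre, glucosePost = NA_real_, route = "iv",
                        image = NULL, mask = NULL, groundTruth = list()) {
  new("ScanSession", subjectId = as.character(subjectId),
      week = as.integer(week), injectedActivity = as.numeric(injectedActivity),
      bodyWeight = as.numeric(bodyWeight), glucosePre = as.numeric(glucosePre),
      glucosePost = as.numeric(glucosePost), route = route, image = image,
      mask = mask, groundTruth = groundTruth)
}

# ---- dynamic image I/O -----------------------------------------------------

#' Read a 4-D dynamic volume with its frame-timing sidecar
#'
#' The volume is a 4-D NIfTI-1 file (fourth dimension = time); frame timing
#' comes from a JSON sidecar \code{{"frame_starts_s": [...],
#' "frame_durations_s": [...], "units": "kBq/mL"}} because NIfTI has no
#' standard frame-schedule field. Decay correction is assumed already
#' applied; the reader does not re-correct.
#'
#' @param volumePath path to the NIfTI volume.
#' @param sidecarPath path to the JSON sidecar.
#' @return a \code{\link{DynamicImage}}.
#' @export
readDynamicImage <- function(volumePath, sidecarPath) {
  nii <- RNifti::readNifti(volumePath)
  arr <- array(as.vector(nii), dim = dim(nii))
  if (length(dim(arr)) != 4L)
    .err(sprintf("expected a 4-D volume, got %d dimensions", length(dim(arr))),
         "dynPET_format_error")
  side <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  if (is.null(side$frame_starts_s) || is.null(side$frame_durations_s))
    .err("sidecar must contain frame_starts_s and frame_durations_s",
         "dynPET_format_error")
  if (length(side$frame_durations_s) != dim(arr)[4L])
    .err(sprintf("sidecar has %d frames but volume has %d time points",
                 length(side$frame_durations_s), dim(arr)[4L]),
         "dynPET_format_error")
  sched <- tryCatch(
    frameSchedule(side$frame_starts_s, side$frame_durations_s),
    error = function(e) .err(conditionMessage(e), "dynPET_validation_error"))
  units <- if (!is.null(side$units)) side$units else "kBq/mL"
  sp <- RNifti::pixdim(nii)[1:3]
  dynamicImage(arr, sp, sched, units)
}

#' Write a dynamic volume and its sidecar
#'
#' @param image a \code{\link{DynamicImage}}.
#' @param volumePath output NIfTI path.
#' @param sidecarPath output JSON sidecar path.
#' @return invisibly, the two paths.
#' @export
writeDynamicImage <- function(image, volumePath, sidecarPath) {
  nii <- RNifti::asNifti(image@values)
  RNifti::pixdim(nii) <- c(image@spacing, 1)
  RNifti::writeNifti(nii, volumePath)
  jsonlite::write_json(
    list(frame_starts_s = image@schedule@starts,
         frame_durations_s = image@schedule@durations,
         units = image@units),
    sidecarPath, auto_unbox = FALSE, digits = NA)
  invisible(c(volume = volumePath, sidecar = sidecarPath))
}

# ---- mask I/O --------------------------------------------------------------

#' Read a VOI label mask with its organ-name map
#'
#' @param maskPath integer-label NIfTI on the image grid.
#' @param namesPath JSON file mapping label values to organ names, e.g.
#'   \code{{"1": "tumor", "2": "liver"}}.
#' @return a \code{\link{VoiMask}}.
#' @export
readMaskSet <- function(maskPath, namesPath) {
  nii <- RNifti::readNifti(maskPath)
  arr <- array(as.vector(nii), dim = dim(nii))
  if (length(dim(arr)) != 3L)
    .err("mask must be a 3-D label volume", "dynPET_format_error")
  nm <- jsonlite::read_json(namesPath, simplifyVector = TRUE)
  labels <- as.integer(names(nm))
  if (any(is.na(labels)))
    .err("names file keys must be integer labels", "dynPET_format_error")
  ln <- stats::setNames(labels, unlist(nm))
  voiMask(round(arr), ln)
}

#' Write a VOI mask and its organ-name map
#'
#' @param mask a \code{\link{VoiMask}}.
#' @param maskPath output NIfTI path.
#' @param namesPath output JSON path.
#' @return invisibly, the two paths.
#' @export
writeMaskSet <- function(mask, maskPath, namesPath) {
  nii <- RNifti::asNifti(mask@labels, datatype = "int16")
  RNifti::writeNifti(nii, maskPath)
  nm <- as.list(names(mask@labelNames))
  names(nm) <- as.character(mask@labelNames)
  jsonlite::write_json(nm, namesPath, auto_unbox = TRUE)
  invisible(c(mask = maskPath, names = namesPath))
}

#' Check that a mask and an image share the voxel grid
#'
#' No resampling is ever performed; masks must match the image grid exactly.
#'
#' @param mask a \code{VoiMask}; \code{image} a \code{DynamicImage}.
#' @param image the image whose spatial grid is authoritative.
#' @return invisibly TRUE, or a grid-mismatch error.
#' @export
checkSameGrid <- function(mask, image) {
  if (!identical(dim(mask@labels), dim(image@values)[1:3]))
    .err(sprintf("mask grid %s does not match image grid %s",
                 paste(dim(mask@labels), collapse = "x"),
                 paste(dim(image@values)[1:3], collapse = "x")),
         "dynPET_grid_mismatch")
  invisible(TRUE)
}

.voiIndices <- function(mask, organ) {
  if (!organ %in% names(mask@labelNames))
    .err(sprintf("unknown organ '%s'; mask defines: %s", organ,
                 paste(names(mask@labelNames), collapse = ", ")),
         "dynPET_lookup_error")
  idx <- which(mask@labels == mask@labelNames[[organ]])
  if (length(idx) == 0L)
    .err(sprintf("VOI '%s' is empty on this grid", organ), "dynPET_empty_voi")
  idx
}

# ---- session manifests -----------------------------------------------------

#' Load a per-scan session manifest
#'
#' CSV with one row per scan and columns \code{subject_id, week,
#' injected_activity_mbq, body_weight_g, glucose_pre_mmol_l} and optionally
#' \code{glucose_post_mmol_l} and \code{route}. A missing post-scan glucose
#' is tolerated with a warning (the scan-average glucose then equals the
#' pre-scan value).
#'
#' @param manifestPath CSV path.
#' @return list of \code{\link{ScanSession}}, sorted by subject then week.
#' @export
loadSessionManifest <- function(manifestPath) {
  df <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  need <- c("subject_id", "week", "injected_activity_mbq", "body_weight_g",
            "glucose_pre_mmol_l")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .err(paste("manifest lacks columns:", paste(miss, collapse = ", ")),
         "dynPET_format_error")
  if (!"glucose_post_mmol_l" %in% names(df)) df$glucose_post_mmol_l <- NA_real_
  if (!"route" %in% names(df)) df$route <- "iv"
  df <- df[order(df$subject_id, df$week), , drop = FALSE]
  if (anyNA(df$glucose_post_mmol_l))
    warning(sprintf("%d session(s) lack a post-scan glucose; using the pre-scan value",
                    sum(is.na(df$glucose_post_mmol_l))))
  sessions <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(
      scanSession(df$subject_id[i], df$week[i], df$injected_activity_mbq[i],
                  df$body_weight_g[i], df$glucose_pre_mmol_l[i],
                  df$glucose_post_mmol_l[i], df$route[i]),
      error = function(e)
        .err(sprintf("manifest row %d (%s, week %s): %s", i, df$subject_id[i],
                     df$week[i], conditionMessage(e)),
             "dynPET_validation_error"))
  })
  sessions
}

# ---- tidy result tables ----------------------------------------------------

.tidyColumns <- c("subject", "week", "organ", "metric", "value", "units")

#' Write a tidy result table
#'
#' Flat rows (subject, week, organ, metric, value, units) in a stable column
#' order and deterministic row order (subject, week, organ, metric).
#'
#' @param records data.frame with at least the tidy columns.
#' @param outPath output CSV path.
#' @return invisibly, the ordered data.frame written.
#' @export
writeTidyResults <- function(records, outPath) {
  if (nrow(records) == 0L) {
    empty <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(.tidyColumns))),
      .tidyColumns)
    utils::write.csv(empty, outPath, row.names = FALSE)
    return(invisible(empty))
  }
  miss <- setdiff(.tidyColumns, names(records))
  if (length(miss))
    .err(paste("records lack columns:", paste(miss, collapse = ", ")),
         "dynPET_format_error")
  out <- records[.tidyColumns]
  out <- out[order(out$subject, out$week, out$organ, out$metric), , drop = FALSE]
  rownames(out) <- NULL
  disk <- out
  disk$value <- sprintf("%.17g", disk$value)  # full double precision roundtrip
  utils::write.csv(disk, outPath, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Read a tidy result table written by \code{writeTidyResults}
#' @param path CSV path.
#' @return data.frame with the tidy columns.
#' @export
readTidyResults <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(week = "integer", value = "numeric"))
}
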