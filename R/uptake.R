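#' @include AllClasses.R tac.R metabolic.R
NULL

#' Static uptake metrics of a VOI
#'
#' SUV_mean, SUV_max, their glucose-corrected counterparts
#' (SUVglu = SUV x Cglu, with Cglu the scan-average blood glucose) and the
#' VOI volume in mm^3 (voxel counting times voxel volume). For a dynamic
#' image the static value per voxel is the duration-weighted mean of the
#' frames whose mid-times fall inside \code{window} (default 45--60 min,
#' the uptake window of the static protocol); a single-frame selection can
#' be forced with \code{frames}.
#'
#' @param image a \code{\link{DynamicImage}}.
#' @param mask a \code{\link{VoiMask}} on the same grid.
#' @param organ VOI name.
#' @param session a \code{\link{ScanSession}} providing injected activity,
#'   body weight and glucose.
#' @param window length-2 numeric, minutes post-injection.
#' @param frames optional explicit frame indices (overrides \code{window}).
#' @return a list with elements \code{suv_mean, suv_max, suvglu_mean,
#'   suvglu_max, volume_mm3, cglu_mean, n_voxels}.
#' @export
staticUptakeMetrics <- function(image, mask, organ, session,
                                window = c(45, 60), frames = NULL) {
  checkSameGrid(mask, image)
  idx <- .voiIndices(mask, organ)
  mt <- midTimes(image)
  if (is.null(frames)) {
    frames <- which(mt >= window[1] & mt <= window[2])
    if (length(frames) == 0L)
      .err("no frames fall inside the static window", "dynPET_argument_error")
  }
  d <- dim(image@values)
  vm <- matrix(image@values, nrow = prod(d[1:3]))[idx, frames, drop = FALSE]
  w <- frameDurations(image@schedule)[frames]
  voxStatic <- as.vector(vm %*% (w / sum(w)))  # duration-weighted time-mean
  norm <- 1000 * session@injectedActivity / session@bodyWeight
  suv <- voxStatic / norm
  cglu <- averageBloodGlucose(session@glucosePre, session@glucosePost)
  voxVol <- prod(image@spacing)
  list(suv_mean = mean(suv), suv_max = max(suv),
       suvglu_mean = suvGlu(mean(suv), cglu),
       suvglu_max = suvGlu(max(suv), cglu),
       volume_mm3 = length(idx) * voxVol,
       cglu_mean = cglu, n_voxels = length(idx))
}

#' VOI volume in cubic millimetres
#'
#' Voxel counting times the voxel volume.
#'
#' @param mask a \code{\link{VoiMask}}.
#' @param organ VOI name.
#' @param spacing voxel spacing in mm (length 3).
#' @return volume in mm^3.
#' @export
voiVolume <- function(mask, organ, spacing) {
  length(.voiIndices(mask, organ)) * prod(spacing)
}
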