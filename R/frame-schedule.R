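#' @include AllClasses.R
NULL

#' Construct a frame schedule
#'
#' @param starts numeric frame start times in seconds from injection
#'   (first must be 0). May be omitted when \code{durations} is given, in
#'   which case contiguous starts are derived.
#' @param durations numeric frame durations in seconds.
#' @return a validated \code{\link{FrameSchedule}}.
#' @examples
#' frameSchedule(durations = c(10, 10, 20))
#' @export
frameSchedule <- function(starts = NULL, durations) {
  durations <- as.numeric(durations)
  if (is.null(starts))
    starts <- cumsum(c(0, durations[-length(durations)]))
  new("FrameSchedule", starts = as.numeric(starts), durations = durations)
}

#' The 23-frame, 60-minute acquisition schedule
#'
#' The dynamic whole-body mouse protocol: 8 x 5 s, 2 x 10 s, 2 x 30 s,
#' 3 x 60 s, 2 x 150 s, 2 x 300 s and 4 x 600 s, totalling exactly 3600 s.
#'
#' @return a \code{\link{FrameSchedule}} of 23 frames.
#' @examples
#' sum(frameDurations(mouseFrameSchedule()))  # 3600
#' @export
mouseFrameSchedule <- function() {
  frameSchedule(durations = c(rep(5, 8), rep(10, 2), rep(30, 2),
                              rep(60, 3), rep(150, 2), rep(300, 2),
                              rep(600, 4)))
}

#' Total scan duration in seconds
#' @param sched a \code{FrameSchedule}.
#' @return numeric, seconds.
#' @export
totalDuration <- function(sched) sum(sched@durations)

#' Voxel size from field of view and matrix size
#'
#' Plain acquisition-geometry arithmetic: voxel extent = FOV / matrix, per
#' axis. Used to reproduce printed MR voxel sizes from protocol tables.
#'
#' @param fov numeric field of view in mm (scalar or vector).
#' @param matrixSize integer matrix size along the same axes.
#' @return numeric voxel size(s) in mm, unrounded.
#' @examples
#' round(voxelSizeFromFov(76, 217), 2)  # 0.35
#' @export
voxelSizeFromFov <- function(fov, matrixSize) {
  stopifnot(length(fov) == length(matrixSize), all(fov > 0),
            all(matrixSize >= 1))
  fov / matrixSize
}
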