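#' @import methods
NULL

#' Frame mid-times in minutes
#'
#' Mid-frame reference times, \code{(start + duration/2) / 60}, the time grid
#' on which TACs, input functions and Patlak variables live.
#'
#' @param x a \code{FrameSchedule}, \code{DynamicImage},
#'   \code{TimeActivityCurve} or \code{InputFunction}.
#' @return numeric vector of minutes post-injection.
#' @export
setGeneric("midTimes", function(x) standardGeneric("midTimes"))

#' Number of time frames
#' @param x an object with a frame dimension.
#' @return integer count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame start times (seconds)
#' @param x a \code{FrameSchedule} or object carrying one.
#' @return numeric vector, seconds from injection.
#' @export
setGeneric("frameStarts", function(x) standardGeneric("frameStarts"))

#' Frame durations (seconds)
#' @param x a \code{FrameSchedule} or object carrying one.
#' @return numeric vector, seconds.
#' @export
setGeneric("frameDurations", function(x) standardGeneric("frameDurations"))

#' Acquisition schedule of an object
#' @param x a \code{DynamicImage} or phantom session.
#' @return a \code{FrameSchedule}.
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))

#' Voxel spacing in millimetres
#' @param x a \code{DynamicImage} or \code{VoiMask}.
#' @return numeric triple (dx, dy, dz) in mm.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Underlying numeric values of a container
#' @param x a \code{DynamicImage}, \code{TimeActivityCurve} or
#'   \code{InputFunction}.
#' @return the 4-D array (image), per-frame means (TAC) or plasma
#'   concentrations (input function).
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' Ground-truth net influx rate of a kinetic parameter set
#'
#' For the irreversible two-tissue model, \eqn{K_i = K_1 k_3 / (k_2 + k_3)};
#' zero when \eqn{k_3 = 0}.
#'
#' @param x a \code{KineticGroundTruth}.
#' @return Ki in mL·min^-1·mL^-1.
#' @export
setGeneric("trueKi", function(x) standardGeneric("trueKi"))
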