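#' LandmarkTrajectory: a time-ordered 33-landmark 3-D pose sequence
#'
#' Container for the pose-estimation output of one exercise recording:
#' for every frame, the x/y/z position and visibility of 33 anatomical
#' landmarks. Coordinates are either world coordinates (meters, origin at
#' the hip midpoint) or normalized image coordinates (x, y in [0,1]).
#' World coordinates are the default throughout the package because they
#' are invariant to where the subject stands in the image; image-space
#' trajectories are accepted but comparisons warn when they are used.
#'
#' @slot coords numeric array of dimension frames x 33 x 3 (x, y, z).
#' @slot visibility numeric matrix, frames x 33, each entry in [0, 1].
#' @slot frameIndex strictly increasing integer vector of frame counters.
#' @slot fps frames per second (positive scalar).
#' @slot space `"world"` or `"image"`.
#' @slot meta list of recording metadata (subject, exercise, repetition,
#'   role, ...). Values are scalar atomics.
#'
#' @seealso [LandmarkTrajectory()], [readTrajectory()], [landmarkSequence()]
#' @exportClass LandmarkTrajectory
setClass("LandmarkTrajectory",
    representation(
        coords     = "array",
        visibility = "matrix",
        frameIndex = "integer",
        fps        = "numeric",
        space      = "character",
        meta       = "list"
    )
)

setValidity("LandmarkTrajectory", function(object) {
    msg <- character()
    d <- dim(object@coords)
    if (length(d) != 3L || d[2] != .N_LANDMARKS || d[3] != 3L)
        msg <- c(msg, sprintf(
            "coords must be a frames x %d x 3 array, got dim [%s]",
            .N_LANDMARKS, paste(d, collapse = " x ")))
    if (!all(dim(object@visibility) == d[1:2]))
        msg <- c(msg, "visibility must be a frames x 33 matrix")
    if (anyNA(object@visibility) ||
        any(object@visibility < 0 | object@visibility > 1))
        msg <- c(msg, "visibility values must lie in [0, 1]")
    if (length(object@frameIndex) != d[1])
        msg <- c(msg, "frameIndex length must equal the number of frames")
    if (length(object@frameIndex) > 1L && any(diff(object@frameIndex) <= 0L))
        msg <- c(msg, "frame indices must be strictly increasing")
    if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
        msg <- c(msg, "fps must be a positive finite scalar")
    if (length(object@space) != 1L || !object@space %in% c("world", "image"))
        msg <- c(msg, "space must be \"world\" or \"image\"")
    if (object@space == "image" && d[1] > 0L) {
        xy <- object@coords[, , 1:2, drop = FALSE]
        if (any(xy < 0 | xy > 1, na.rm = TRUE))
            msg <- c(msg, "image-space x and y coordinates must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a LandmarkTrajectory
#'
#' @param coords frames x 33 x 3 numeric array of landmark positions.
#' @param visibility frames x 33 matrix in [0,1]; defaults to all 1.
#' @param fps frames per second.
#' @param space coordinate space, `"world"` (default) or `"image"`.
#' @param meta named list of recording metadata.
#' @param frameIndex integer frame counters; defaults to `0:(frames-1)`.
#' @return a validated [LandmarkTrajectory-class] object.
#' @examples
#' coords <- array(0, dim = c(5, 33, 3))
#' traj <- LandmarkTrajectory(coords, fps = 30)
#' nFrames(traj)
#' @export
LandmarkTrajectory <- function(coords, visibility = NULL, fps = 30,
                               space = c("world", "image"), meta = list(),
                               frameIndex = NULL) {
    space <- match.arg(space)
    coords <- as.array(coords)
    nf <- dim(coords)[1]
    if (is.null(visibility))
        visibility <- matrix(1, nrow = nf, ncol = .N_LANDMARKS)
    if (is.null(frameIndex))
        frameIndex <- seq_len(nf) - 1L
    new("LandmarkTrajectory",
        coords = coords, visibility = visibility,
        frameIndex = as.integer(frameIndex),
        fps = as.numeric(fps), space = space, meta = meta)
}

#' DtwResult: distance, warp path and cost matrix of one DTW alignment
#'
#' @slot distance non-negative accumulated DTW distance, the value of the
#'   final cell of the dynamic-programming matrix.
#' @slot path two-column integer matrix of aligned (i, j) index pairs,
#'   1-based, from (1, 1) to (|A|, |B|), monotone and continuous.
#' @slot costMatrix the |A| x |B| accumulated-cost matrix, or NULL when not
#'   retained.
#' @exportClass DtwResult
setClass("DtwResult",
    representation(distance = "numeric", path = "matrix", costMatrix = "ANY"))

setValidity("DtwResult", function(object) {
    msg <- character()
    if (length(object@distance) != 1L || object@distance < 0)
        msg <- c(msg, "distance must be a non-negative scalar")
    p <- object@path
    if (ncol(p) != 2L)
        msg <- c(msg, "path must have two columns")
    else if (nrow(p)) {
        if (any(p[1, ] != c(1L, 1L)))
            msg <- c(msg, "path must start at (1, 1)")
        if (nrow(p) > 1L) {
            st <- diff(p)
            if (any(st < 0L) || any(rowSums(st) < 1L) || any(st > 1L))
                msg <- c(msg, "path steps must increment i, j or both by 1")
        }
    }
    if (length(msg)) msg else TRUE
})

#' WilcoxonSignedRank: result of the paired signed-rank test
#'
#' @slot rPlus sum of ranks of positive differences.
#' @slot rMinus sum of ranks of negative differences.
#' @slot statistic `min(rPlus, rMinus)`, the tabled test statistic.
#' @slot pValue two-sided p-value.
#' @slot nEffective number of pairs contributing after zero handling.
#' @slot degenerate TRUE when all non-zero differences share one sign; the
#'   statistic is then 0 and the test carries little information.
#' @slot method `"exact"` or `"normal approximation"`.
#' @exportClass WilcoxonSignedRank
setClass("WilcoxonSignedRank",
    representation(
        rPlus = "numeric", rMinus = "numeric", statistic = "numeric",
        pValue = "numeric", nEffective = "integer",
        degenerate = "logical", method = "character"))

#' EvaluationReport: agreement between predicted and gold-standard scores
#'
#' @slot metrics data.frame with one row per (joint group x normalization
#'   method): MAE, RMSE, Pearson CC, Wilcoxon statistic and p-value, n.
#' @slot outlierLog data.frame logging every value removed by the outlier
#'   policy (subject, group).
#' @exportClass EvaluationReport
setClass("EvaluationReport",
    representation(metrics = "data.frame", outlierLog = "data.frame"))
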