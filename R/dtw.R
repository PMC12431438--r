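.as_seq_matrix <- function(x, arg = "sequence") {
    if (is.matrix(x)) {
        storage.mode(x) <- "double"
        return(x)
    }
    if (is.numeric(x))
        return(matrix(as.double(x), ncol = 1L))
    stop(arg, " must be a numeric vector or a points-in-rows matrix",
         call. = FALSE)
}

#' Distance between two points
#'
#' Element-wise distance used inside the DTW recursion: Euclidean (the
#' default, which performs best for movement comparison) or Manhattan.
#' Points may be scalars or coordinate triples; for scalars the Euclidean
#' distance reduces to the absolute difference.
#'
#' @param a,b numeric vectors of equal length (scalar or 3-D point).
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return non-negative scalar distance.
#' @examples
#' pointDistance(c(0, 0, 0), c(3, 4, 0))         # 5
#' pointDistance(c(0, 0, 0), c(1, 1, 1), "manhattan")  # 3
#' @export
pointDistance <- function(a, b, metric = c("euclidean", "manhattan")) {
    metric <- match.arg(metric)
    if (length(a) != length(b))
        stop("points have mixed dimensionality: ", length(a), " vs ",
             length(b), call. = FALSE)
    if (metric == "euclidean") sqrt(sum((a - b)^2)) else sum(abs(a - b))
}

#' Index-aligned Euclidean distance between equal-length sequences
#'
#' The rigid sequence distance sqrt(sum_i dist(A_i, B_i)^2): each element is
#' compared to the element at the same index, so a pure time shift between
#' otherwise identical sequences registers as a large distance. This is the
#' baseline that motivates DTW, which aligns indices before comparing.
#'
#' @param A,B numeric vectors, or matrices with points in rows; must have
#'   the same number of elements/rows.
#' @return non-negative scalar.
#' @examples
#' sequenceEuclidean(c(0, 1, 2, 3, 0, 0), c(0, 0, 1, 2, 3, 0))  # sqrt(12)
#' @export
sequenceEuclidean <- function(A, B) {
    A <- .as_seq_matrix(A, "A"); B <- .as_seq_matrix(B, "B")
    if (nrow(A) != nrow(B))
        stop("sequences must have equal length for index-aligned ",
             "Euclidean distance (got ", nrow(A), " and ", nrow(B), ")",
             call. = FALSE)
    if (ncol(A) != ncol(B))
        stop("sequences have mismatched point dimensionality", call. = FALSE)
    sqrt(sum(rowSums((A - B)^2)))
}

#' Dynamic time warping between two point sequences
#'
#' Computes the DTW distance by the standard dynamic program: the
#' accumulated cost D(i,j) = Dist(A_i, B_j) + min(D(i-1,j), D(i,j-1),
#' D(i-1,j-1)), filled from the first cell to D(|A|, |B|), whose value is
#' the reported distance. The optimal warp path -- monotone, continuous,
#' covering every index of both sequences -- is recovered by backtracking.
#' Sequences may be scalar series or rows of 3-D points; for multivariate
#' input the point metric acts on the whole coordinate triple at each
#' aligned pair (dependent DTW).
#'
#' @param A,B numeric vectors or points-in-rows matrices, length >= 1.
#' @param metric point metric, `"euclidean"` (default) or `"manhattan"`.
#' @param keepMatrix retain the accumulated-cost matrix in the result.
#' @param window optional Sakoe-Chiba band half-width (`|i - j| <= window`);
#'   `NULL` (default) leaves the alignment unconstrained.
#' @return a [DtwResult-class]: distance, warp path, optional cost matrix.
#' @examples
#' r <- dtw(c(0, 1, 2, 3, 0, 0), c(0, 0, 1, 2, 3, 0))
#' dtwDistance(r)   # 0: the shift is absorbed by the warp path
#' warpPath(r)
#' @export
dtw <- function(A, B, metric = c("euclidean", "manhattan"),
                keepMatrix = FALSE, window = NULL) {
    metric <- match.arg(metric)
    A <- .as_seq_matrix(A, "A"); B <- .as_seq_matrix(B, "B")
    if (nrow(A) < 1L || nrow(B) < 1L)
        stop("sequences must contain at least one point", call. = FALSE)
    res <- .dtw_cpp(A, B, metric = match(metric,
               c("euclidean", "manhattan")) - 1L,
               keep_matrix = keepMatrix,
               window = if (is.null(window)) -1L else as.integer(window))
    new("DtwResult", distance = res$distance, path = res$path,
        costMatrix = res$matrix)
}

#' DTW distance between one landmark's trajectories in two recordings
#'
#' Extracts the time-ordered (x, y, z) sequence of a single landmark from a
#' reference and a trial recording and returns the DTW distance between
#' them. By default the dependent multivariate formulation is used (the
#' point metric acts on the full coordinate triple); `type = "independent"`
#' instead runs one scalar DTW per axis and sums the three distances, as a
#' sensitivity analysis.
#'
#' @param ref,trial [LandmarkTrajectory-class] objects in the same
#'   coordinate space.
#' @param landmark landmark index in 0..32.
#' @param metric point metric passed to [dtw()].
#' @param type `"dependent"` (default) or `"independent"` multivariate
#'   handling.
#' @return non-negative DTW distance.
#' @export
landmarkDtw <- function(ref, trial, landmark,
                        metric = c("euclidean", "manhattan"),
                        type = c("dependent", "independent")) {
    metric <- match.arg(metric); type <- match.arg(type)
    .check_comparable(ref, trial)
    a <- landmarkSequence(ref, landmark)
    b <- landmarkSequence(trial, landmark)
    if (type == "dependent")
        return(dtwDistance(dtw(a, b, metric = metric)))
    sum(vapply(1:3, function(k)
        dtwDistance(dtw(a[, k], b[, k], metric = metric)), numeric(1)))
}

.check_comparable <- function(ref, trial) {
    stopifnot(is(ref, "LandmarkTrajectory"), is(trial, "LandmarkTrajectory"))
    if (coordSpace(ref) != coordSpace(trial))
        stop("trajectories are in different coordinate spaces (",
             coordSpace(ref), " vs ", coordSpace(trial), ")", call. = FALSE)
    if (coordSpace(ref) == "image")
        warning("comparing image-space trajectories: landmark positions ",
                "depend on where the subject stands in the image; ",
                "world coordinates are recommended", call. = FALSE)
    if (nFrames(ref) < 2L || nFrames(trial) < 2L)
        stop("trajectories must contain at least 2 frames for comparison",
             call. = FALSE)
    invisible(TRUE)
}
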