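#' @rdname LandmarkTrajectory-class
#' @param x,object a `LandmarkTrajectory`.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname LandmarkTrajectory-class
#' @export
setGeneric("framesPerSecond", function(x) standardGeneric("framesPerSecond"))

#' @rdname LandmarkTrajectory-class
#' @export
setGeneric("coordSpace", function(x) standardGeneric("coordSpace"))

#' @rdname LandmarkTrajectory-class
#' @export
setGeneric("trajMeta", function(x) standardGeneric("trajMeta"))

#' @rdname DtwResult-class
#' @param object a `DtwResult`.
#' @export
setGeneric("dtwDistance", function(object) standardGeneric("dtwDistance"))

#' @rdname DtwResult-class
#' @export
setGeneric("warpPath", function(object) standardGeneric("warpPath"))

#' @rdname DtwResult-class
#' @export
setGeneric("costMatrix", function(object) standardGeneric("costMatrix"))

setMethod("nFrames", "LandmarkTrajectory", function(x) dim(x@coords)[1])
setMethod("framesPerSecond", "LandmarkTrajectory", function(x) x@fps)
setMethod("coordSpace", "LandmarkTrajectory", function(x) x@space)
setMethod("trajMeta", "LandmarkTrajectory", function(x) x@meta)

setMethod("dtwDistance", "DtwResult", function(object) object@distance)
setMethod("warpPath", "DtwResult", function(object) object@path)
setMethod("costMatrix", "DtwResult", function(object) object@costMatrix)

setMethod("show", "LandmarkTrajectory", function(object) {
    m <- object@meta
    id <- if (!is.null(m$subject)) paste0(" [", m$subject,
        if (!is.null(m$repetition)) paste0("_", m$repetition), "]") else ""
    cat(sprintf(
        "LandmarkTrajectory%s: %d frames x %d landmarks, %s space, %.4g fps (%.2f s)\n",
        id, nFrames(object), .N_LANDMARKS, object@space, object@fps,
        nFrames(object) / object@fps))
    invisible(object)
})

setMethod("show", "DtwResult", function(object) {
    cat(sprintf("DtwResult: distance %.6g, warp path of %d pairs%s\n",
        object@distance, nrow(object@path),
        if (is.null(object@costMatrix)) "" else sprintf(
            ", %d x %d cost matrix retained",
            nrow(object@costMatrix), ncol(object@costMatrix))))
    invisible(object)
})

setMethod("show", "WilcoxonSignedRank", function(object) {
    cat(sprintf(
        "Wilcoxon signed-rank test (%s)\n  R+ = %.1f, R- = %.1f, R = %.1f, n = %d\n  two-sided p = %.4g%s\n",
        object@method, object@rPlus, object@rMinus, object@statistic,
        object@nEffective, object@pValue,
        if (object@degenerate)
            "\n  NOTE: all non-zero differences share one sign; the statistic is degenerate"
        else ""))
    invisible(object)
})

setMethod("show", "EvaluationReport", function(object) {
    cat("EvaluationReport\n")
    print(object@metrics, row.names = FALSE, digits = 4)
    if (nrow(object@outlierLog)) {
        cat("Outlier removals:\n")
        print(object@outlierLog, row.names = FALSE)
    }
    invisible(object)
})

#' @rdname EvaluationReport-class
#' @param object an `EvaluationReport`.
#' @export
setGeneric("reportMetrics", function(object) standardGeneric("reportMetrics"))

#' @rdname EvaluationReport-class
#' @export
setGeneric("outlierLog", function(object) standardGeneric("outlierLog"))

setMethod("reportMetrics", "EvaluationReport", function(object) object@metrics)
setMethod("outlierLog", "EvaluationReport", function(object) object@outlierLog)
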