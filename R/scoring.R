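#' Default joint groups for exercise assessment
#'
#' The clinician-defined grouping of pose landmarks used for assessment:
#' Head (landmarks 0 to 10), Trunk (11, 12, 23, 24) and Shoulder
#' (12, 14, 16). Landmark 12 belongs to both Trunk and Shoulder; overlap
#' between groups is permitted and its per-landmark DTW distance is
#' computed once and reused.
#'
#' @return named list of 0-based landmark index vectors.
#' @examples
#' defaultJointGroups()
#' @export
defaultJointGroups <- function() {
    list(Head = 0:10, Trunk = c(11L, 12L, 23L, 24L),
         Shoulder = c(12L, 14L, 16L))
}

.check_groups <- function(groups) {
    if (!is.list(groups) || is.null(names(groups)) ||
        any(!nzchar(names(groups))))
        stop("joint groups must be a named list of landmark index vectors",
             call. = FALSE)
    for (g in names(groups)) {
        idx <- groups[[g]]
        if (!length(idx))
            stop("joint group '", g, "' is empty", call. = FALSE)
        if (anyDuplicated(idx))
            stop("joint group '", g, "' has duplicated landmark indices",
                 call. = FALSE)
        if (any(idx < 0L | idx > .N_LANDMARKS - 1L))
            stop("joint group '", g, "' has landmark indices outside 0..",
                 .N_LANDMARKS - 1L, call. = FALSE)
    }
    invisible(TRUE)
}

#' Accumulated DTW distance of one joint group
#'
#' Sums the per-landmark DTW distances over all landmarks of one group:
#' the group's overall distance between a trial and the reference.
#'
#' @param ref,trial [LandmarkTrajectory-class] objects in the same space.
#' @param group integer vector of 0-based landmark indices.
#' @param metric point metric, see [dtw()].
#' @return non-negative accumulated distance.
#' @export
groupDistance <- function(ref, trial, group,
                          metric = c("euclidean", "manhattan")) {
    metric <- match.arg(metric)
    .check_groups(list(group = group))
    sum(vapply(group, function(k) landmarkDtw(ref, trial, k, metric = metric),
               numeric(1)))
}

#' Compare one trial recording to the reference
#'
#' Computes the accumulated DTW distance of every joint group between a
#' trial and the reference recording. Landmarks shared between groups are
#' aligned once and their distance reused in every group sum.
#'
#' @param ref,trial [LandmarkTrajectory-class] objects in the same space.
#' @param groups named list of 0-based landmark index vectors; defaults to
#'   [defaultJointGroups()].
#' @param metric point metric, see [dtw()].
#' @param id trial identifier of the form `ID<subject>_<rep>`; defaults to
#'   the trial's metadata.
#' @return one-row `data.frame`: `ID` plus one distance column per group.
#' @export
comparePair <- function(ref, trial, groups = defaultJointGroups(),
                        metric = c("euclidean", "manhattan"), id = NULL) {
    metric <- match.arg(metric)
    .check_groups(groups)
    .check_comparable(ref, trial)
    if (is.null(id)) {
        m <- trajMeta(trial)
        id <- if (!is.null(m$subject))
            paste0(m$subject,
                   if (!is.null(m$repetition)) paste0("_", m$repetition))
        else "trial"
    }
    needed <- sort(unique(unlist(groups)))
    per_lm <- vapply(needed, function(k)
        landmarkDtw(ref, trial, k, metric = metric), numeric(1))
    names(per_lm) <- as.character(needed)
    out <- data.frame(ID = id, stringsAsFactors = FALSE)
    for (g in names(groups))
        out[[g]] <- sum(per_lm[as.character(groups[[g]])])
    out
}

#' Compare every trial of a dataset directory to the reference
#'
#' Iterates over trajectory files named `ID<subject>_<rep>.(csv|json)` in a
#' directory, compares each to the reference with [comparePair()], and
#' returns the per-trial, per-group distance table (one row per trial,
#' ordered by subject then repetition). Unreadable trials are skipped with
#' a warning.
#'
#' @param datasetDir directory of trial trajectory files.
#' @param ref reference [LandmarkTrajectory-class].
#' @param groups,metric passed to [comparePair()].
#' @return `data.frame` of distances, `ID` plus one column per group.
#' @seealso [writeDistances()]
#' @export
batchCompare <- function(datasetDir, ref, groups = defaultJointGroups(),
                         metric = c("euclidean", "manhattan")) {
    metric <- match.arg(metric)
    files <- list.files(datasetDir,
        pattern = "^ID[0-9]+_[0-9]+\\.(csv|json)$", full.names = TRUE)
    if (!length(files)) {
        warning("no trial files matching ID<subject>_<rep> found in ",
                datasetDir, call. = FALSE)
        out <- data.frame(ID = character(0), stringsAsFactors = FALSE)
        for (g in names(groups)) out[[g]] <- numeric(0)
        return(out)
    }
    ids <- sub("\\.(csv|json)$", "", basename(files))
    parts <- do.call(rbind, strsplit(sub("^ID", "", ids), "_", fixed = TRUE))
    ord <- order(as.integer(parts[, 1]), as.integer(parts[, 2]))
    files <- files[ord]; ids <- ids[ord]
    rows <- vector("list", length(files))
    for (i in seq_along(files)) {
        rows[[i]] <- tryCatch(
            comparePair(ref, readTrajectory(files[i]), groups = groups,
                        metric = metric, id = ids[i]),
            error = function(e) {
                warning("skipping trial ", ids[i], ": ",
                        conditionMessage(e), call. = FALSE)
                NULL
            })
    }
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Normalization configuration for distance-to-score conversion
#'
#' Distances are converted to 0-100 movement-quality scores per joint
#' group, and the scale is inverted (score = 100 - scaled distance) so that
#' smaller distances mean higher quality. Min-max scaling uses `min = 0`
#' (an ideal performance has distance 0) and a per-group calibration
#' maximum -- explicitly the distance of "two very different" recordings,
#' or by default the batch maximum. Max-abs scaling divides by the maximum
#' absolute value and coincides with min-max when min = 0. Z-score
#' normalization standardizes by the per-group batch mean and population
#' standard deviation, then maps z onto the score scale by
#' `score = center - spread * z`.
#'
#' @param method `"minmax"`, `"maxabs"`, or `"zscore"`.
#' @param min minimum distance for min-max scaling (default 0).
#' @param max named vector/list of per-group calibration maxima, or `NULL`
#'   to use each group's batch maximum.
#' @param center,spread affine placing z-scores on the 0-100 scale.
#' @param clip clip scores into [0, 100] (default TRUE).
#' @return a `normConfig` list.
#' @export
normConfig <- function(method = c("minmax", "maxabs", "zscore"), min = 0,
                       max = NULL, center = 50, spread = 25, clip = TRUE) {
    structure(list(method = match.arg(method), min = min, max = max,
                   center = center, spread = spread, clip = clip),
              class = "normConfig")
}

#' Convert per-trial distances to 0-100 quality scores
#'
#' Applies the configured normalization independently to each joint-group
#' column of a distance table (distances of different groups are never
#' pooled) and inverts the scale so distance 0 maps to score 100.
#'
#' @param distances `data.frame` from [batchCompare()] (`ID` + group
#'   columns).
#' @param config a [normConfig()].
#' @return `data.frame` of per-trial scores with the calibration recorded
#'   in `attr(, "normalization")`.
#' @export
normalizeScores <- function(distances, config = normConfig()) {
    stopifnot(inherits(config, "normConfig"))
    groups <- setdiff(names(distances), "ID")
    out <- distances
    calib <- list(method = config$method, clip = config$clip)
    for (g in groups) {
        d <- distances[[g]]
        if (config$method %in% c("minmax", "maxabs")) {
            mx <- if (!is.null(config$max)) config$max[[g]] else
                if (config$method == "maxabs") max(abs(d)) else max(d)
            mn <- if (config$method == "maxabs") 0 else config$min
            if (!is.finite(mx) || mx <= mn)
                stop("invalid calibration for group '", g,
                     "': max (", mx, ") must exceed min (", mn, ")",
                     call. = FALSE)
            s <- 100 - 100 * (d - mn) / (mx - mn)
            calib[[g]] <- list(min = mn, max = mx)
        } else {
            mu <- mean(d)
            sigma <- sqrt(mean((d - mu)^2))
            if (sigma == 0)
                stop("z-score normalization undefined for group '", g,
                     "': zero spread", call. = FALSE)
            s <- config$center - config$spread * (d - mu) / sigma
            calib[[g]] <- list(mean = mu, sd = sigma,
                               center = config$center,
                               spread = config$spread)
        }
        out[[g]] <- if (config$clip) pmin(100, pmax(0, s)) else s
    }
    attr(out, "normalization") <- calib
    out
}

#' Average repetition scores into per-subject scores
#'
#' Collapses trial-level scores (`ID<subject>_<rep>`) to one row per
#' subject by the arithmetic mean over repetitions, per joint group.
#' Values removed by the outlier policy (`NA`) are excluded from the mean
#' of their group only.
#'
#' @param trialScores `data.frame` from [normalizeScores()].
#' @return `data.frame` with one row per subject (`ID<subject>`).
#' @export
aggregateSubjectScores <- function(trialScores) {
    if (!nrow(trialScores))
        stop("no trial scores to aggregate", call. = FALSE)
    if (any(!grepl("_", trialScores$ID)))
        stop("trial ids must have the form ID<subject>_<rep>; offending: ",
             paste(head(trialScores$ID[!grepl("_", trialScores$ID)], 3),
                   collapse = ", "), call. = FALSE)
    subj <- sub("_[^_]*$", "", trialScores$ID)
    groups <- setdiff(names(trialScores), "ID")
    usub <- unique(subj)
    out <- data.frame(ID = usub, stringsAsFactors = FALSE)
    for (g in groups)
        out[[g]] <- vapply(usub, function(s) {
            v <- trialScores[[g]][subj == s]
            if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
        }, numeric(1), USE.NAMES = FALSE)
    out
}

#' Angle at a vertex between two 3-D points
#'
#' The joint angle at `vertex` subtended by points `a` and `c`, from the
#' normalized dot product of the two arm vectors, in degrees in [0, 180].
#'
#' @param a,vertex,c numeric length-3 points.
#' @return angle in degrees.
#' @examples
#' jointAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
#' @export
jointAngle <- function(a, vertex, c) {
    u <- a - vertex; v <- c - vertex
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0)
        stop("joint angle undefined: an arm vector has zero length",
             call. = FALSE)
    cosang <- sum(u * v) / (nu * nv)
    acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Range of motion of an angle series
#'
#' The excursion (maximum minus minimum) of a joint-angle time series over
#' an exercise, in degrees.
#'
#' @param angles non-empty numeric vector of angles in degrees.
#' @return `max(angles) - min(angles)`.
#' @export
rangeOfMotion <- function(angles) {
    if (!length(angles) || all(is.na(angles)))
        stop("range of motion undefined for an empty angle series",
             call. = FALSE)
    max(angles, na.rm = TRUE) - min(angles, na.rm = TRUE)
}

#' Movement-quality index from guided and non-guided range of motion
#'
#' The percentage index `(1 - (ROM_GE - ROM_NGE) / ROM_GE) * 100`
#' comparing a subject's range of motion without guidance (`romNge`)
#' against the guided performance (`romGe`): 100 when the two are equal,
#' falling linearly as the non-guided excursion drops.
#'
#' @param romGe guided-exercise range of motion, degrees (> 0).
#' @param romNge non-guided range of motion, degrees.
#' @return index in percent.
#' @examples
#' movementQualityIndex(90, 72)  # 80
#' @export
movementQualityIndex <- function(romGe, romNge) {
    if (!is.finite(romGe) || romGe <= 0)
        stop("guided range of motion must be positive", call. = FALSE)
    (1 - (romGe - romNge) / romGe) * 100
}

#' Write / read a Table-3-style distances CSV
#'
#' Header `ID,<groups...>`, one row per trial (`ID01_1`, ...), distances
#' formatted with two decimals.
#'
#' @param distances `data.frame` of distances or scores.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDistances <- function(distances, path) {
    out <- distances
    for (g in setdiff(names(out), "ID"))
        out[[g]] <- ifelse(is.na(out[[g]]), "",
                           sprintf("%.2f", out[[g]]))
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeDistances
#' @export
readDistances <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!"ID" %in% names(df))
        stop("malformed distances/scores CSV (no ID column): ", path,
             call. = FALSE)
    df
}

#' @rdname writeDistances
#' @param scores `data.frame` of per-subject scores.
#' @export
writeScores <- function(scores, path) writeDistances(scores, path)
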