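.guess_format <- function(path, format) {
    if (format != "auto") return(format)
    if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
}

.meta_keys <- c("subject", "exercise", "repetition", "role")

#' Read a landmark trajectory from disk
#'
#' Two plain-text dialects are supported. The CSV dialect has a metadata
#' preamble of `# key=value` lines (at least `space` and `fps`) followed by
#' a header `frame,landmark,x,y,z,visibility` and one row per
#' (frame, landmark) pair -- 33 rows per frame, landmark indices 0..32.
#' The JSON dialect is an object with `space`, `fps`, `meta` and `frames`,
#' the latter a list of 33-element arrays of `{x, y, z, visibility}`
#' records.
#'
#' @param path file to read.
#' @param format `"csv"`, `"json"`, or `"auto"` (by file extension).
#' @return a validated [LandmarkTrajectory-class].
#' @seealso [writeTrajectory()]
#' @export
readTrajectory <- function(path, format = c("auto", "csv", "json")) {
    format <- .guess_format(path, match.arg(format))
    if (!file.exists(path))
        stop("trajectory file not found: ", path, call. = FALSE)
    if (format == "json") .read_traj_json(path) else .read_traj_csv(path)
}

.read_traj_csv <- function(path) {
    lines <- readLines(path)
    pre <- grepl("^#", lines)
    kv <- list()
    for (ln in sub("^#\\s*", "", lines[pre])) {
        parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
        if (length(parts) == 2L) kv[[trimws(parts[1])]] <- trimws(parts[2])
    }
    body <- lines[!pre & nzchar(lines)]
    if (length(body) < 2L)
        stop("malformed trajectory CSV (no data rows): ", path, call. = FALSE)
    df <- read.csv(text = body, stringsAsFactors = FALSE)
    need <- c("frame", "landmark", "x", "y", "z", "visibility")
    if (!all(need %in% names(df)))
        stop("malformed trajectory CSV ", path, ": expected columns ",
             paste(need, collapse = ","), call. = FALSE)
    frames <- unique(df$frame)
    if (is.unsorted(frames, strictly = TRUE))
        stop("parse error in ", path, ": frame indices not strictly ",
             "increasing", call. = FALSE)
    cnt <- table(df$frame)
    bad <- names(cnt)[cnt != .N_LANDMARKS]
    if (length(bad))
        stop("parse error in ", path, ": frame ", bad[1], " has ",
             cnt[bad[1]], " landmarks, expected ", .N_LANDMARKS,
             call. = FALSE)
    nf <- length(frames)
    df <- df[order(df$frame, df$landmark), ]
    if (!all(df$landmark == rep(0:(.N_LANDMARKS - 1L), nf)))
        stop("parse error in ", path, ": landmark indices of some frame ",
             "are not 0..", .N_LANDMARKS - 1L, call. = FALSE)
    coords <- array(NA_real_, dim = c(nf, .N_LANDMARKS, 3L))
    coords[, , 1] <- matrix(df$x, nrow = nf, byrow = TRUE)
    coords[, , 2] <- matrix(df$y, nrow = nf, byrow = TRUE)
    coords[, , 3] <- matrix(df$z, nrow = nf, byrow = TRUE)
    vis <- matrix(df$visibility, nrow = nf, byrow = TRUE)
    meta <- kv[setdiff(names(kv), c("space", "fps"))]
    LandmarkTrajectory(coords, vis,
        fps = as.numeric(kv$fps %||% 30),
        space = kv$space %||% "world",
        meta = meta, frameIndex = frames)
}

.read_traj_json <- function(path) {
    obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    fr <- obj$frames
    if (is.null(fr) || !length(fr))
        stop("malformed trajectory JSON (no frames): ", path, call. = FALSE)
    nf <- length(fr)
    coords <- array(NA_real_, dim = c(nf, .N_LANDMARKS, 3L))
    vis <- matrix(1, nrow = nf, ncol = .N_LANDMARKS)
    for (t in seq_len(nf)) {
        lm <- fr[[t]]
        if (length(lm) != .N_LANDMARKS)
            stop("parse error in ", path, ": frame ", t - 1L, " has ",
                 length(lm), " landmarks, expected ", .N_LANDMARKS,
                 call. = FALSE)
        for (k in seq_len(.N_LANDMARKS)) {
            p <- lm[[k]]
            coords[t, k, ] <- c(p$x, p$y, p$z)
            vis[t, k] <- p$visibility %||% 1
        }
    }
    LandmarkTrajectory(coords, vis,
        fps = as.numeric(obj$fps %||% 30),
        space = obj$space %||% "world",
        meta = lapply(obj$meta %||% list(), identity))
}

#' Write a landmark trajectory to disk
#'
#' Serializes a trajectory in either dialect accepted by
#' [readTrajectory()]; write followed by read reproduces the trajectory
#' (CSV coordinates are written with 6 decimal places, JSON at full
#' precision).
#'
#' @param traj a [LandmarkTrajectory-class].
#' @param path output file.
#' @param format `"csv"`, `"json"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path, format = c("auto", "csv", "json")) {
    stopifnot(is(traj, "LandmarkTrajectory"))
    validObject(traj)
    if (nFrames(traj) == 0L)
        stop("refusing to write an empty trajectory", call. = FALSE)
    format <- .guess_format(path, match.arg(format))
    if (format == "json") {
        frames <- lapply(seq_len(nFrames(traj)), function(t)
            lapply(seq_len(.N_LANDMARKS), function(k) list(
                x = traj@coords[t, k, 1], y = traj@coords[t, k, 2],
                z = traj@coords[t, k, 3],
                visibility = traj@visibility[t, k])))
        jsonlite::write_json(
            list(space = traj@space, fps = traj@fps, meta = traj@meta,
                 frames = frames),
            path, auto_unbox = TRUE, digits = NA)
    } else {
        con <- file(path, "w")
        on.exit(close(con))
        writeLines(sprintf("# space=%s", traj@space), con)
        writeLines(sprintf("# fps=%g", traj@fps), con)
        for (k in names(traj@meta))
            writeLines(sprintf("# %s=%s", k, traj@meta[[k]]), con)
        writeLines("frame,landmark,x,y,z,visibility", con)
        nf <- nFrames(traj)
        lm <- rep(0:(.N_LANDMARKS - 1L), nf)
        fr <- rep(traj@frameIndex, each = .N_LANDMARKS)
        x <- as.vector(t(traj@coords[, , 1, drop = FALSE][, , 1]))
        y <- as.vector(t(traj@coords[, , 2, drop = FALSE][, , 1]))
        z <- as.vector(t(traj@coords[, , 3, drop = FALSE][, , 1]))
        v <- as.vector(t(traj@visibility))
        writeLines(sprintf("%d,%d,%.6f,%.6f,%.6f,%.6f", fr, lm, x, y, z, v),
                   con)
    }
    invisible(path)
}

#' Extract one landmark's coordinate sequence
#'
#' Returns the time-ordered (x, y, z) positions of a single landmark -- the
#' per-landmark sequence that DTW consumes.
#'
#' @param traj a [LandmarkTrajectory-class].
#' @param landmark landmark index in 0..32.
#' @return numeric matrix, frames x 3.
#' @export
landmarkSequence <- function(traj, landmark) {
    stopifnot(is(traj, "LandmarkTrajectory"))
    if (length(landmark) != 1L || is.na(landmark) ||
        landmark < 0L || landmark > .N_LANDMARKS - 1L)
        stop("landmark index must be a single integer in 0..",
             .N_LANDMARKS - 1L, " (got ", landmark, ")", call. = FALSE)
    m <- traj@coords[, landmark + 1L, , drop = FALSE]
    dim(m) <- c(dim(traj@coords)[1], 3L)
    colnames(m) <- c("x", "y", "z")
    m
}

#' Estimate a trajectory from video frames through a pose backend
#'
#' The pose-estimation model itself is outside this package; it is accessed
#' through an adapter contract: a backend is any function that maps one
#' decoded video frame to a 33 x 4 numeric matrix (columns x, y, z,
#' visibility). `video` is either a list of already-decoded frames or a
#' file path together with a `reader` function that decodes it into such a
#' list. Frames on which the backend fails are dropped with a warning and
#' counted in the result's metadata.
#'
#' @param video list of decoded frames, or a file path when `reader` is
#'   given.
#' @param backend function(frame) -> 33 x 4 matrix (x, y, z, visibility).
#' @param space coordinate space the backend emits; world coordinates are
#'   the default and recommended choice.
#' @param fps frames per second of the source video.
#' @param reader optional function(path) -> list of decoded frames.
#' @param meta recording metadata list.
#' @return a [LandmarkTrajectory-class]; `trajMeta(x)$missingFrames` counts
#'   dropped frames.
#' @export
estimateTrajectory <- function(video, backend, space = c("world", "image"),
                               fps = 30, reader = NULL, meta = list()) {
    space <- match.arg(space)
    if (missing(backend) || is.null(backend))
        stop("no pose backend registered; supply a backend function or ",
             "use trajectory file input via readTrajectory()", call. = FALSE)
    if (is.character(video)) {
        if (is.null(reader))
            stop("a reader function is required to decode a video path",
                 call. = FALSE)
        video <- reader(video)
    }
    out <- vector("list", length(video))
    failed <- 0L
    for (t in seq_along(video)) {
        lm <- tryCatch(backend(video[[t]]), error = function(e) NULL)
        if (is.null(lm) || !is.matrix(lm) ||
            !all(dim(lm) == c(.N_LANDMARKS, 4L))) {
            failed <- failed + 1L
            next
        }
        out[[t]] <- lm
    }
    if (failed > 0L)
        warning("pose backend failed on ", failed, " of ", length(video),
                " frames; those frames were dropped", call. = FALSE)
    keep <- !vapply(out, is.null, logical(1))
    out <- out[keep]
    if (!length(out))
        stop("pose backend produced no valid frames", call. = FALSE)
    nf <- length(out)
    coords <- array(NA_real_, dim = c(nf, .N_LANDMARKS, 3L))
    vis <- matrix(1, nf, .N_LANDMARKS)
    for (t in seq_len(nf)) {
        coords[t, , ] <- out[[t]][, 1:3]
        vis[t, ] <- pmin(1, pmax(0, out[[t]][, 4]))
    }
    meta$missingFrames <- failed
    LandmarkTrajectory(coords, vis, fps = fps, space = space, meta = meta,
                       frameIndex = (seq_along(video)[keep]) - 1L)
}

#' Mark low-visibility landmark positions as missing
#'
#' Visibility is carried through the pipeline but not used by default; this
#' optional filter sets coordinates with visibility below a threshold to
#' `NA` for diagnostic use.
#'
#' @param traj a [LandmarkTrajectory-class].
#' @param threshold visibility cutoff in [0, 1].
#' @return the trajectory with sub-threshold positions replaced by `NA`.
#' @export
maskLowVisibility <- function(traj, threshold) {
    stopifnot(is(traj, "LandmarkTrajectory"),
              threshold >= 0, threshold <= 1)
    low <- traj@visibility < threshold
    for (k in 1:3) {
        sl <- traj@coords[, , k]
        sl[low] <- NA_real_
        traj@coords[, , k] <- sl
    }
    traj
}

`%||%` <- function(a, b) if (is.null(a)) b else a
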