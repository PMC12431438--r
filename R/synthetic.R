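# Resting 33-landmark pose in world coordinates (meters, origin at the hip
# midpoint; x right, y up, z toward camera -- the toolkit treats axis
# orientation as opaque). Rough standing-adult proportions.
.base_pose <- function() {
    p <- matrix(0, nrow = .N_LANDMARKS, ncol = 3)
    # face: nose 0, eyes 1-6, ears 7-8, mouth 9-10
    p[1, ] <- c(0.00, 0.62, 0.08)
    p[2:4, ] <- cbind(c(-0.02, -0.03, -0.04), 0.64, 0.07)
    p[5:7, ] <- cbind(c(0.02, 0.03, 0.04), 0.64, 0.07)
    p[8, ] <- c(-0.07, 0.62, 0.02)
    p[9, ] <- c(0.07, 0.62, 0.02)
    p[10, ] <- c(-0.02, 0.59, 0.07)
    p[11, ] <- c(0.02, 0.59, 0.07)
    # shoulders 11-12, elbows 13-14, wrists 15-16
    p[12, ] <- c(-0.16, 0.50, 0.00)
    p[13, ] <- c(0.16, 0.50, 0.00)
    p[14, ] <- c(-0.20, 0.24, 0.00)
    p[15, ] <- c(0.20, 0.24, 0.00)
    p[16, ] <- c(-0.22, 0.00, 0.02)
    p[17, ] <- c(0.22, 0.00, 0.02)
    # hands: pinky 17-18, index 19-20, thumb 21-22
    p[18, ] <- c(-0.23, -0.07, 0.02)
    p[19, ] <- c(0.23, -0.07, 0.02)
    p[20, ] <- c(-0.24, -0.08, 0.03)
    p[21, ] <- c(0.24, -0.08, 0.03)
    p[22, ] <- c(-0.22, -0.06, 0.04)
    p[23, ] <- c(0.22, -0.06, 0.04)
    # hips 23-24, knees 25-26, ankles 27-28
    p[24, ] <- c(-0.10, 0.00, 0.00)
    p[25, ] <- c(0.10, 0.00, 0.00)
    p[26, ] <- c(-0.11, -0.42, 0.01)
    p[27, ] <- c(0.11, -0.42, 0.01)
    p[28, ] <- c(-0.12, -0.82, 0.00)
    p[29, ] <- c(0.12, -0.82, 0.00)
    # heels 29-30, foot tips 31-32
    p[30, ] <- c(-0.12, -0.88, -0.03)
    p[31, ] <- c(0.12, -0.88, -0.03)
    p[32, ] <- c(-0.12, -0.86, 0.09)
    p[33, ] <- c(0.12, -0.86, 0.09)
    p
}

#' Parametric exercise template for synthetic recordings
#'
#' Defines a deterministic exercise as a resting pose plus a per-landmark
#' sinusoidal displacement `amplitude * sin(2*pi*frequency*t + phase)`
#' along each axis; landmarks without a motion entry stay at the base
#' pose. Two built-in templates emulate typical upper-body rehabilitation
#' movements: `"diagonal"` (an arm raise across the body, driving the
#' Shoulder group with smaller head and trunk involvement) and
#' `"rotation"` (a trunk rotation driving shoulders and hips in
#' counter-phase).
#'
#' @param name `"diagonal"`, `"rotation"`, or a custom label when
#'   `motion` is supplied.
#' @param duration exercise duration in seconds.
#' @param fps frames per second (the study's recordings run at ~30).
#' @param motion optional custom `data.frame` with columns `landmark`
#'   (0-based), `ax`, `ay`, `az` (amplitudes, meters), `freq` (Hz),
#'   `phase` (radians).
#' @param basePose optional 33 x 3 resting pose.
#' @return an `exerciseTemplate` list.
#' @export
exerciseTemplate <- function(name = c("diagonal", "rotation"), duration = 4,
                             fps = 30, motion = NULL, basePose = NULL) {
    if (!is.finite(duration) || duration <= 0)
        stop("duration must be positive", call. = FALSE)
    if (!is.finite(fps) || fps <= 0)
        stop("fps must be positive", call. = FALSE)
    if (is.null(motion)) {
        name <- match.arg(name)
        motion <- if (name == "diagonal") {
            # right-arm diagonal raise: wrist travels most, elbow half,
            # shoulder a little; hand landmarks follow the wrist; light
            # trunk sway and head bob.
            rbind(
                data.frame(landmark = 12L, ax = 0.02, ay = 0.03, az = 0.01,
                           freq = 0.5, phase = 0),
                data.frame(landmark = 14L, ax = 0.12, ay = 0.18, az = 0.05,
                           freq = 0.5, phase = 0),
                data.frame(landmark = c(16L, 18L, 20L, 22L),
                           ax = 0.25, ay = 0.35, az = 0.10,
                           freq = 0.5, phase = 0),
                data.frame(landmark = c(11L, 23L, 24L),
                           ax = 0.01, ay = 0.01, az = 0.005,
                           freq = 0.5, phase = 0),
                data.frame(landmark = 0:10, ax = 0.008, ay = 0.01,
                           az = 0.004, freq = 0.5, phase = 0))
        } else {
            # trunk rotation: shoulders and hips swing in z/x counter-phase
            rbind(
                data.frame(landmark = c(11L, 23L), ax = 0.04, ay = 0.005,
                           az = 0.12, freq = 0.5, phase = 0),
                data.frame(landmark = c(12L, 24L), ax = 0.04, ay = 0.005,
                           az = 0.12, freq = 0.5, phase = pi),
                data.frame(landmark = c(14L, 16L), ax = 0.06, ay = 0.01,
                           az = 0.15, freq = 0.5, phase = pi),
                data.frame(landmark = 0:10, ax = 0.02, ay = 0.004,
                           az = 0.05, freq = 0.5, phase = 0))
        }
    } else {
        name <- if (is.character(name)) name[1] else "custom"
    }
    structure(list(name = name, duration = duration, fps = fps,
                   motion = motion,
                   basePose = basePose %||% .base_pose()),
              class = "exerciseTemplate")
}

#' Perturbation specification for synthetic trials
#'
#' Describes how a trial deviates from the reference performance:
#' a multiplicative scaling of all motion amplitudes (1 = perfect,
#' smaller = reduced excursion), a leading idle period, a smooth monotone
#' time warp, and additive Gaussian coordinate noise. Identical seeds give
#' identical trials.
#'
#' @param amplitudeScale multiplicative factor on motion amplitudes
#'   (>= 0).
#' @param timeShift seconds of leading idle (first-frame pose repeated).
#' @param timeWarp strength in [0, 1) of a sinusoidal monotone
#'   reparameterization of time.
#' @param noiseSd standard deviation, in meters, of additive Gaussian
#'   noise on every coordinate.
#' @param seed integer seed for the noise draw.
#' @return a `perturbationSpec` list.
#' @export
perturbationSpec <- function(amplitudeScale = 1, timeShift = 0,
                             timeWarp = 0, noiseSd = 0, seed = 1L) {
    if (amplitudeScale < 0) stop("amplitudeScale must be >= 0",
                                 call. = FALSE)
    if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
    if (timeWarp < 0 || timeWarp >= 1)
        stop("timeWarp must lie in [0, 1)", call. = FALSE)
    structure(list(amplitudeScale = amplitudeScale, timeShift = timeShift,
                   timeWarp = timeWarp, noiseSd = noiseSd,
                   seed = as.integer(seed)),
              class = "perturbationSpec")
}

.template_coords <- function(template, times, amplitudeScale = 1) {
    nf <- length(times)
    coords <- array(rep(template$basePose, each = nf),
                    dim = c(nf, .N_LANDMARKS, 3))
    m <- template$motion
    amps <- as.matrix(m[, c("ax", "ay", "az")]) * amplitudeScale
    for (i in seq_len(nrow(m))) {
        s <- sin(2 * pi * m$freq[i] * times + m$phase[i])
        k <- m$landmark[i] + 1L
        for (ax in 1:3)
            coords[, k, ax] <- coords[, k, ax] + amps[i, ax] * s
    }
    coords
}

#' Generate the reference recording of an exercise template
#'
#' Deterministic world-space trajectory of `duration * fps` frames with
#' visibility 1 everywhere; stands in for the clinician-performed
#' reference video.
#'
#' @param template an [exerciseTemplate()].
#' @param meta metadata list stored on the trajectory.
#' @return a [LandmarkTrajectory-class].
#' @export
generateReference <- function(template,
                              meta = list(role = "reference")) {
    stopifnot(inherits(template, "exerciseTemplate"))
    nf <- round(template$duration * template$fps)
    times <- (seq_len(nf) - 1) / template$fps
    LandmarkTrajectory(.template_coords(template, times),
                       fps = template$fps, space = "world", meta = meta)
}

#' Generate one perturbed trial of an exercise template
#'
#' Applies, in order: amplitude scaling, a smooth monotone time warp,
#' a leading idle prefix (the first-frame pose repeated), and additive
#' Gaussian noise. With the identity perturbation the trial equals the
#' reference exactly.
#'
#' @param template an [exerciseTemplate()].
#' @param perturbation a [perturbationSpec()].
#' @param meta metadata list stored on the trajectory.
#' @return a [LandmarkTrajectory-class].
#' @export
generateTrial <- function(template, perturbation = perturbationSpec(),
                          meta = list(role = "trial")) {
    stopifnot(inherits(template, "exerciseTemplate"),
              inherits(perturbation, "perturbationSpec"))
    nf <- round(template$duration * template$fps)
    times <- (seq_len(nf) - 1) / template$fps
    if (perturbation$timeWarp > 0) {
        Tdur <- template$duration
        times <- times + perturbation$timeWarp * Tdur / (2 * pi) *
            sin(2 * pi * times / Tdur)
    }
    coords <- .template_coords(template, times,
                               perturbation$amplitudeScale)
    shift_frames <- round(perturbation$timeShift * template$fps)
    if (shift_frames > 0) {
        prefix <- coords[rep(1L, shift_frames), , , drop = FALSE]
        coords <- abind_frames(prefix, coords)
    }
    if (perturbation$noiseSd > 0) {
        old <- .Random.seed_save()
        on.exit(.Random.seed_restore(old))
        set.seed(perturbation$seed)
        coords <- coords + array(
            rnorm(length(coords), sd = perturbation$noiseSd),
            dim = dim(coords))
    }
    LandmarkTrajectory(coords, fps = template$fps, space = "world",
                       meta = meta)
}

abind_frames <- function(a, b) {
    out <- array(NA_real_, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2:3]))
    out[seq_len(dim(a)[1]), , ] <- a
    out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
    out
}

.Random.seed_save <- function()
    if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
.Random.seed_restore <- function(old) {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    invisible()
}

#' Generate a synthetic exercise cohort on disk
#'
#' Emulates the study design -- a cohort of subjects each repeating one
#' exercise several times, plus one clinician reference recording -- with
#' controlled, graded deviations so that every pipeline stage can be
#' exercised and parameter recovery can be tested. Writes one trajectory
#' file per trial (`ID<subject>_<rep>.csv`), the reference
#' (`reference.csv`), and `ground_truth.csv` recording each subject's
#' injected deviation and a synthetic gold score, a fixed decreasing
#' function of deviation: `gold = 100 * exp(-deviation / tau)`.
#'
#' @param template an [exerciseTemplate()].
#' @param outDir output directory (refused if non-empty unless
#'   `overwrite`).
#' @param nSubjects number of subjects (study design: 15).
#' @param reps repetitions per subject (study design: 3).
#' @param deviations per-subject deviation in [0, 1) applied as amplitude
#'   scale `1 - deviation`; defaults to an even grading from 0 to 0.6.
#' @param noiseSd Gaussian coordinate noise per trial, meters.
#' @param tau decay constant of the synthetic gold score (default 0.25).
#' @param seed master seed; per-trial seeds are derived from it
#'   deterministically.
#' @param overwrite allow writing into a non-empty directory.
#' @param format trajectory file format, `"csv"` or `"json"`.
#' @return invisibly, the ground-truth `data.frame`.
#' @export
generateCohort <- function(template, outDir, nSubjects = 15L, reps = 3L,
                           deviations = NULL, noiseSd = 0, tau = 0.25,
                           seed = 1L, overwrite = FALSE, format = "csv") {
    stopifnot(inherits(template, "exerciseTemplate"),
              nSubjects >= 1L, reps >= 1L)
    if (dir.exists(outDir) && length(list.files(outDir)) && !overwrite)
        stop("output directory ", outDir, " is not empty; use ",
             "overwrite = TRUE to replace it", call. = FALSE)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (is.null(deviations))
        deviations <- seq(0, 0.6, length.out = nSubjects)
    if (length(deviations) != nSubjects)
        stop("deviations must have one entry per subject", call. = FALSE)
    ref <- generateReference(template,
        meta = list(exercise = template$name, role = "reference"))
    writeTrajectory(ref, file.path(outDir, paste0("reference.", format)))
    gt <- data.frame(ID = sprintf("ID%02d", seq_len(nSubjects)),
                     deviation = deviations,
                     stringsAsFactors = FALSE)
    gold <- 100 * exp(-deviations / tau)
    gt$gold_Head <- gold; gt$gold_Trunk <- gold; gt$gold_Shoulder <- gold
    for (s in seq_len(nSubjects)) {
        for (r in seq_len(reps)) {
            trial_seed <- (as.integer(seed) * 10007L + s * 101L + r) %%
                .Machine$integer.max
            pert <- perturbationSpec(
                amplitudeScale = 1 - deviations[s],
                noiseSd = noiseSd, seed = trial_seed)
            tr <- generateTrial(template, pert,
                meta = list(subject = sprintf("ID%02d", s),
                            exercise = template$name,
                            repetition = r, role = "trial"))
            writeTrajectory(tr, file.path(outDir,
                sprintf("ID%02d_%d.%s", s, r, format)))
        }
    }
    write.csv(gt, file.path(outDir, "ground_truth.csv"),
              row.names = FALSE, quote = FALSE)
    invisible(gt)
}
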