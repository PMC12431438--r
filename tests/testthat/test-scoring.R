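test_that("default joint groups match the clinical grouping", {
    g <- defaultJointGroups()
    expect_named(g, c("Head", "Trunk", "Shoulder"))
    expect_identical(g$Head, 0:10)          # 11 landmarks
    expect_length(g$Head, 11L)
    expect_identical(g$Trunk, c(11L, 12L, 23L, 24L))
    expect_identical(g$Shoulder, c(12L, 14L, 16L))
    expect_true(12L %in% g$Trunk && 12L %in% g$Shoulder)  # overlap allowed
})

test_that("group distance is the sum of per-landmark DTW distances", {
    ref <- random_trajectory(nf = 10, seed = 21)
    trial <- random_trajectory(nf = 12, seed = 22)
    g <- c(4L, 16L)
    per <- vapply(g, function(k) landmarkDtw(ref, trial, k), numeric(1))
    expect_equal(groupDistance(ref, trial, g), sum(per))
    expect_equal(groupDistance(ref, ref, 0:10), 0)
    expect_error(groupDistance(ref, trial, integer(0)), "empty")
    expect_error(groupDistance(ref, trial, c(1L, 1L)), "duplicated")
    expect_error(groupDistance(ref, trial, 40L), "outside")
})

test_that("comparePair localizes an injected right-arm deviation", {
    tmpl <- small_template()
    ref <- generateReference(tmpl)
    trial <- generateTrial(tmpl, meta = list(subject = "ID01",
                                             repetition = 1))
    # deviation only in the right-arm landmarks (14, 16 and hand)
    for (k in c(14, 16, 18, 20, 22) + 1)
        trial@coords[, k, ] <- trial@coords[, k, ] +
            0.08 * sin(seq(0, 3 * pi, length.out = nFrames(trial)))
    rec <- comparePair(ref, trial)
    expect_identical(rec$ID, "ID01_1")
    expect_identical(names(rec), c("ID", "Head", "Trunk", "Shoulder"))
    expect_gt(rec$Shoulder, 1)
    expect_equal(rec$Head, 0, tolerance = 1e-9)
    expect_equal(rec$Trunk, 0, tolerance = 1e-9)

    same <- comparePair(ref, ref, id = "ID00_0")
    expect_true(all(as.numeric(same[1, -1]) == 0))
})

test_that("batch comparison walks a cohort deterministically", {
    td <- withr::local_tempdir()
    tmpl <- small_template()
    generateCohort(tmpl, td, nSubjects = 3, reps = 2, seed = 5,
                   deviations = c(0, 0.2, 0.4))
    ref <- readTrajectory(file.path(td, "reference.csv"))
    rec <- batchCompare(td, ref)
    expect_identical(nrow(rec), 6L)
    expect_identical(rec$ID[1:3], c("ID01_1", "ID01_2", "ID02_1"))
    # the zero-deviation subject reproduces the reference exactly
    expect_true(all(as.numeric(rec[rec$ID == "ID01_1", -1]) == 0))

    # unreadable trial: skipped with a warning, not silent
    writeLines("garbage", file.path(td, "ID09_1.csv"))
    expect_warning(rec2 <- batchCompare(td, ref), "skipping trial ID09_1")
    expect_identical(nrow(rec2), 6L)

    empty <- withr::local_tempdir()
    expect_warning(e <- batchCompare(empty, ref), "no trial files")
    expect_identical(nrow(e), 0L)
})

test_that("min-max scoring inverts and calibrates distances", {
    d <- data.frame(ID = c("ID01_1", "ID01_2", "ID02_1"),
                    Head = c(0, 50, 100), stringsAsFactors = FALSE)
    s <- normalizeScores(d, normConfig("minmax", max = list(Head = 100)))
    expect_equal(s$Head, c(100, 50, 0))
    # batch-max calibration gives the same here
    s2 <- normalizeScores(d, normConfig("minmax"))
    expect_equal(s2$Head, c(100, 50, 0))
    expect_identical(attr(s2, "normalization")$Head$max, 100)
    expect_error(
        normalizeScores(d, normConfig("minmax", max = list(Head = -1))),
        "Head")
})

test_that("max-abs equals min-max when the minimum is zero", {
    set.seed(8)
    d <- data.frame(ID = sprintf("ID%02d_1", 1:20),
                    Head = runif(20, 0, 300), Trunk = runif(20, 0, 80),
                    stringsAsFactors = FALSE)
    mm <- normalizeScores(d, normConfig("minmax", min = 0))
    ma <- normalizeScores(d, normConfig("maxabs"))
    expect_equal(mm$Head, ma$Head)
    expect_equal(mm$Trunk, ma$Trunk)
})

test_that("z-score mapping is affine and respects its configuration", {
    d <- data.frame(ID = sprintf("ID%02d_1", 1:10),
                    Head = c(3, 8, 1, 9, 4, 7, 2, 6, 5, 10),
                    stringsAsFactors = FALSE)
    s <- normalizeScores(d, normConfig("zscore", clip = FALSE))
    mu <- mean(d$Head); sigma <- sqrt(mean((d$Head - mu)^2))
    expect_equal(s$Head, 50 - 25 * (d$Head - mu) / sigma)
    expect_error(
        normalizeScores(data.frame(ID = "a_1", Head = c(2, 2),
                                   stringsAsFactors = FALSE),
                        normConfig("zscore")),
        "zero spread")
})

test_that("scores are monotone in distance and clipped to [0, 100]", {
    set.seed(13)
    for (method in c("minmax", "maxabs", "zscore")) {
        d <- data.frame(ID = sprintf("ID%02d_1", 1:15),
                        Head = sort(runif(15, 0, 200)),
                        stringsAsFactors = FALSE)
        s <- normalizeScores(d, normConfig(method))
        expect_true(all(diff(s$Head) <= 1e-12))
        expect_true(all(s$Head >= 0 & s$Head <= 100))
    }
})

test_that("repetition scores aggregate to per-subject means", {
    tr <- data.frame(ID = c("ID01_1", "ID01_2", "ID01_3", "ID02_1"),
                     Head = c(60, 70, 80, 55),
                     Trunk = c(90, NA, 70, 44),
                     stringsAsFactors = FALSE)
    ag <- aggregateSubjectScores(tr)
    expect_identical(ag$ID, c("ID01", "ID02"))
    expect_equal(ag$Head, c(70, 55))
    expect_equal(ag$Trunk, c(80, 44))   # NA rep excluded from its group
    expect_error(aggregateSubjectScores(
        data.frame(ID = "ID01", Head = 1, stringsAsFactors = FALSE)),
        "ID<subject>_<rep>")
})

test_that("joint angles, range of motion and the quality index compute", {
    expect_equal(jointAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
    expect_equal(jointAngle(c(2, 0, 0), c(0, 0, 0), c(5, 0, 0)), 0)
    expect_equal(jointAngle(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
    expect_error(jointAngle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
                 "zero length")

    expect_equal(rangeOfMotion(c(10, 50, 30)), 40)
    expect_equal(rangeOfMotion(rep(12, 5)), 0)
    expect_error(rangeOfMotion(numeric(0)), "empty")
    # dense sinusoid of amplitude A: excursion 2A up to sampling
    t <- seq(0, 2 * pi, length.out = 2000)
    expect_equal(rangeOfMotion(30 + 12 * sin(t)), 24, tolerance = 1e-4)

    expect_equal(movementQualityIndex(90, 90), 100)
    expect_equal(movementQualityIndex(90, 72), 80)
    expect_equal(movementQualityIndex(50, 0), 0)
    expect_error(movementQualityIndex(0, 10), "positive")
    # linear in the non-guided excursion, never exceeding 100
    nge <- seq(0, 90, by = 10)
    idx <- vapply(nge, function(v) movementQualityIndex(90, v), numeric(1))
    expect_equal(diff(idx), rep(idx[2] - idx[1], length(nge) - 1))
    expect_true(all(idx <= 100))
})

test_that("distance and score tables serialize with two decimals", {
    d <- data.frame(ID = c("ID01_1", "ID02_1"),
                    Head = c(220.634, 50.386), Trunk = c(1, NA),
                    stringsAsFactors = FALSE)
    f <- withr::local_tempfile(fileext = ".csv")
    writeDistances(d, f)
    lines <- readLines(f)
    expect_identical(lines[1], "ID,Head,Trunk")
    expect_identical(lines[2], "ID01_1,220.63,1.00")
    expect_identical(lines[3], "ID02_1,50.39,")
    back <- readDistances(f)
    expect_equal(back$Head, c(220.63, 50.39))

    g <- withr::local_tempfile(fileext = ".csv")
    writeLines("Head,Trunk", g)   # no ID column
    expect_error(readDistances(g), "ID column")
})
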