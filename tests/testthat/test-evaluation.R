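test_that("MAE and RMSE match hand-computed values", {
    y <- c(1, 2, 3); yhat <- c(2, 2, 2)
    expect_equal(maeScore(y, yhat), 2 / 3)
    expect_equal(rmseScore(y, yhat), sqrt(2 / 3))
    expect_equal(maeScore(y, y), 0)
    expect_equal(rmseScore(y, y), 0)
    # constant offset delta -> MAE = RMSE = delta
    expect_equal(maeScore(y, y + 3), 3)
    expect_equal(rmseScore(y, y + 3), 3)
    # single pair: both equal the absolute error
    expect_equal(maeScore(5, 9), 4)
    expect_equal(rmseScore(5, 9), 4)
    expect_error(maeScore(c(NA, NA), c(1, 2)), "no complete")
})

test_that("RMSE dominates MAE, with equality iff all errors equal", {
    set.seed(55)
    for (i in 1:200) {
        n <- sample(2:30, 1)
        y <- runif(n, 0, 100); yhat <- runif(n, 0, 100)
        expect_gte(rmseScore(y, yhat) + 1e-12, maeScore(y, yhat))
    }
    y <- c(10, 20, 30)
    expect_equal(rmseScore(y, y + c(5, -5, 5)), maeScore(y, y + c(5, -5, 5)))
})

test_that("Pearson correlation is affine-invariant and sign-aware", {
    set.seed(3)
    y <- runif(12, 0, 100); x <- y + rnorm(12, sd = 15)
    expect_equal(pearsonCC(y, 2 * y + 3), 1)
    expect_equal(pearsonCC(y, -y), -1)
    expect_equal(pearsonCC(y, 10 + 0.5 * x), pearsonCC(y, x))
    expect_equal(pearsonCC(y, -2 * x + 7), -pearsonCC(y, x))
    expect_warning(cc <- pearsonCC(y, rep(4, 12)), "constant")
    expect_true(is.na(cc))
})

test_that("min-max and z-score mappings of one distance set share a CC", {
    set.seed(91)
    d <- data.frame(ID = sprintf("ID%02d_1", 1:15),
                    Head = runif(15, 10, 400), stringsAsFactors = FALSE)
    gold <- runif(15, 0, 100)
    mm <- normalizeScores(d, normConfig("minmax", clip = FALSE))
    zs <- normalizeScores(d, normConfig("zscore", clip = FALSE))
    expect_equal(pearsonCC(gold, mm$Head), pearsonCC(gold, zs$Head))
})

test_that("signed-rank components reproduce hand rankings", {
    # differences predicted - actual = [1, -2, 3]
    w <- wilcoxonSignedRank(c(0, 2, 0), c(1, 0, 3))
    expect_equal(w@rPlus, 4)
    expect_equal(w@rMinus, 2)
    expect_equal(w@statistic, 2)
    expect_false(w@degenerate)

    # antisymmetric differences [-d, d] balance the rank sums
    w2 <- wilcoxonSignedRank(c(10, 10), c(7, 13))
    expect_equal(w2@rPlus, w2@rMinus)

    # all five predictions below actual: R = 0, degenerate, p = 2/2^5
    expect_warning(
        w3 <- wilcoxonSignedRank(c(50, 60, 70, 80, 90),
                                 c(45, 52, 61, 77, 83)),
        "one sign")
    expect_equal(w3@statistic, 0)
    expect_true(w3@degenerate)
    expect_equal(w3@pValue, 0.0625)

    # zero differences are dropped; all-zero input is undefined
    w4 <- wilcoxonSignedRank(c(1, 2, 3, 4), c(1, 3, 1, 6))
    expect_identical(w4@nEffective, 3L)
    expect_error(wilcoxonSignedRank(c(1, 2), c(1, 2)), "undefined")
})

test_that("exact p matches sign-assignment enumeration and wilcox.test", {
    set.seed(77)
    for (i in 1:40) {
        n <- sample(3:10, 1)
        d <- round(rnorm(n, sd = 5), 2)
        d[d == 0] <- 0.5
        w <- suppressWarnings(
            wilcoxonSignedRank(rep(0, n), d, mode = "exact"))
        expect_equal(w@pValue, enum_signed_rank_p(d), tolerance = 1e-12)
        expect_equal(w@rPlus + w@rMinus, n * (n + 1) / 2)
        if (!anyDuplicated(abs(d))) {
            ref <- suppressWarnings(
                stats::wilcox.test(d, exact = TRUE))
            expect_equal(w@pValue, unname(ref$p.value),
                         tolerance = 1e-12)
        }
    }
    # ties: average ranks keep the rank-sum identity
    wt <- wilcoxonSignedRank(rep(0, 4), c(1, -1, 2, -2))
    expect_equal(wt@rPlus + wt@rMinus, 10)
    expect_equal(wt@rPlus, wt@rMinus)
})

test_that("the normal approximation tracks the exact tie-free p", {
    set.seed(5150)
    for (i in 1:10) {
        d <- sample(1:200, 20) * sample(c(-1, 1), 20, replace = TRUE)
        pe <- wilcoxonSignedRank(rep(0, 20), d, mode = "exact")@pValue
        pn <- wilcoxonSignedRank(rep(0, 20), d, mode = "normal")@pValue
        expect_lt(abs(pe - pn), 0.01)
    }
    # auto switches to the approximation beyond 25 effective pairs
    d <- sample(1:500, 30) * sample(c(-1, 1), 30, replace = TRUE)
    expect_identical(wilcoxonSignedRank(rep(0, 30), d)@method,
                     "normal approximation")
})

test_that("pratt zero handling ranks zeros before discarding them", {
    w <- wilcoxonSignedRank(c(0, 0, 0), c(0, 2, -3),
                            zeroMethod = "pratt")
    # |d| = (0, 2, 3) -> ranks (1, 2, 3); zero's rank discarded
    expect_equal(w@rPlus, 2)
    expect_equal(w@rMinus, 3)
    expect_identical(w@nEffective, 2L)
})

test_that("the outlier policy removes single values, never subjects", {
    sc <- data.frame(ID = c("ID14", "ID15"),
                     Head = c(60, 70), Trunk = c(50, 55),
                     Shoulder = c(40, 45), stringsAsFactors = FALSE)
    out <- applyOutlierPolicy(sc, data.frame(subject = "ID15",
                                             group = "Head"))
    expect_true(is.na(out$Head[2]))
    expect_equal(out$Trunk[2], 55)      # other groups retained
    expect_equal(out$Shoulder[2], 45)
    expect_equal(out$Head[1], 60)
    log <- attr(out, "outlierLog")
    expect_identical(nrow(log), 1L)
    expect_identical(log$subject, "ID15")

    identity <- applyOutlierPolicy(sc, NULL)
    expect_equal(identity$Head, sc$Head)
    expect_error(applyOutlierPolicy(sc, data.frame(subject = "ID99",
                                                   group = "Head")),
                 "unknown subject")
    expect_error(applyOutlierPolicy(sc, data.frame(subject = "ID14",
                                                   group = "Arm")),
                 "unknown joint group")
})

test_that("evaluateScores builds a per-group agreement report", {
    set.seed(42)
    ids <- sprintf("ID%02d", 1:10)
    gold <- data.frame(ID = ids, Head = runif(10, 40, 100),
                       Trunk = runif(10, 40, 100), stringsAsFactors = FALSE)
    pred <- gold
    pred$Head <- pred$Head + rnorm(10, sd = 5)
    pred$Trunk <- pred$Trunk + rnorm(10, sd = 5)
    rep <- evaluateScores(pred, gold)
    m <- reportMetrics(rep)
    expect_identical(nrow(m), 2L)       # one row per group
    expect_identical(m$group, c("Head", "Trunk"))
    expect_true(all(m$RMSE >= m$MAE))
    expect_true(all(m$n == 10L))

    # predictions identical to gold: zero error, undefined test
    same <- evaluateScores(gold, gold)
    ms <- reportMetrics(same)
    expect_equal(ms$MAE, c(0, 0))
    expect_equal(ms$RMSE, c(0, 0))
    expect_true(all(is.na(ms$p)))

    # id mismatch is refused, listing the unmatched ids
    bad <- gold; bad$ID[1] <- "ID99"
    expect_error(evaluateScores(bad, gold), "ID99")

    # removing every value of a group leaves it undefined, not crashing
    spec <- data.frame(subject = ids, group = "Head",
                       stringsAsFactors = FALSE)
    r2 <- reportMetrics(evaluateScores(pred, gold, outliers = spec))
    expect_true(is.na(r2$MAE[r2$group == "Head"]))
    expect_false(is.na(r2$MAE[r2$group == "Trunk"]))
})

test_that("evaluation recovers the injected noise scale", {
    # gold scores plus Gaussian noise of sd sigma: MAE ~= sigma * sqrt(2/pi)
    set.seed(2718)
    sigma <- 6
    n <- 4000
    gold <- data.frame(ID = sprintf("ID%04d", 1:n),
                       Head = runif(n, 30, 70), stringsAsFactors = FALSE)
    pred <- gold
    pred$Head <- pred$Head + rnorm(n, sd = sigma)
    m <- reportMetrics(evaluateScores(pred, gold))
    expect_equal(m$MAE, sigma * sqrt(2 / pi), tolerance = 0.05)
    expect_equal(m$RMSE, sigma, tolerance = 0.05)
})
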