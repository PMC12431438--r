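#' Remove clinician-flagged outlier values from a score table
#'
#' Outliers in this setting are flagged per (subject, joint group), never
#' per subject: only the named group value is blanked (set `NA`) and every
#' other group value of the same subject is retained, so the remaining
#' groups can still be evaluated.
#'
#' @param scores per-subject score `data.frame` (`ID` + group columns).
#' @param outliers `data.frame` with columns `subject` and `group` (one row
#'   per value to remove), or `NULL` for no removal.
#' @return the filtered table; `attr(, "outlierLog")` lists every removal.
#' @export
applyOutlierPolicy <- function(scores, outliers = NULL) {
    log <- data.frame(subject = character(0), group = character(0),
                      value = numeric(0), stringsAsFactors = FALSE)
    if (!is.null(outliers) && nrow(outliers)) {
        for (i in seq_len(nrow(outliers))) {
            s <- outliers$subject[i]; g <- outliers$group[i]
            if (!s %in% scores$ID)
                stop("outlier spec references unknown subject '", s, "'",
                     call. = FALSE)
            if (!g %in% names(scores))
                stop("outlier spec references unknown joint group '", g,
                     "'", call. = FALSE)
            row <- which(scores$ID == s)
            log <- rbind(log, data.frame(subject = s, group = g,
                         value = scores[[g]][row],
                         stringsAsFactors = FALSE))
            scores[[g]][row] <- NA_real_
        }
    }
    attr(scores, "outlierLog") <- log
    scores
}

#' Mean absolute error between predicted and actual scores
#'
#' @param actual,predicted numeric vectors of equal length on the 0-100
#'   score scale; `NA` pairs are dropped.
#' @return mean of `|actual - predicted|`.
#' @export
maeScore <- function(actual, predicted) {
    p <- .paired(actual, predicted)
    mean(abs(p$y - p$yhat))
}

#' Root mean squared error between predicted and actual scores
#'
#' Always at least as large as the MAE on the same pairs; the gap grows
#' with the influence of large errors.
#'
#' @inheritParams maeScore
#' @return square root of the mean squared difference.
#' @export
rmseScore <- function(actual, predicted) {
    p <- .paired(actual, predicted)
    sqrt(mean((p$y - p$yhat)^2))
}

#' Pearson correlation between predicted and actual scores
#'
#' Invariant under positive affine transforms of either series (so any two
#' normalizations that are affine in the same distances yield the same
#' correlation magnitude); undefined and returned as `NA` with a warning
#' when either series is constant.
#'
#' @inheritParams maeScore
#' @return correlation in [-1, 1], or `NA` for constant input.
#' @export
pearsonCC <- function(actual, predicted) {
    p <- .paired(actual, predicted)
    if (length(p$y) < 2L) {
        warning("correlation undefined for fewer than 2 pairs",
                call. = FALSE)
        return(NA_real_)
    }
    if (sd(p$y) == 0 || sd(p$yhat) == 0) {
        warning("correlation undefined: a series is constant",
                call. = FALSE)
        return(NA_real_)
    }
    cor(p$y, p$yhat)
}

.paired <- function(actual, predicted) {
    if (length(actual) != length(predicted))
        stop("actual and predicted must have equal length", call. = FALSE)
    keep <- !(is.na(actual) | is.na(predicted))
    if (!any(keep))
        stop("no complete (actual, predicted) pairs", call. = FALSE)
    list(y = actual[keep], yhat = predicted[keep])
}

#' Wilcoxon signed-rank test for paired scores
#'
#' Paired non-parametric test of whether predicted and actual scores
#' differ systematically. Differences `d = predicted - actual` are formed;
#' zero differences are dropped (classical handling; `zeroMethod =
#' "pratt"` instead ranks them and then discards their ranks); absolute
#' differences are ranked ascending with average ranks on ties; the ranks
#' of the positive and negative differences are summed into R+ and R-,
#' and the statistic is `R = min(R-, R+)`. The two-sided p-value is exact
#' -- computed from the full null distribution of R+ over all sign
#' assignments of the observed rank multiset -- for up to 25 effective
#' pairs, and otherwise uses the normal approximation with tie and
#' continuity corrections. When every non-zero difference has the same
#' sign the statistic is necessarily 0 and the result is flagged
#' degenerate: the reported p then comes from the actual null
#' distribution, but carries little information.
#'
#' @param actual,predicted paired numeric vectors; `NA` pairs dropped.
#' @param mode `"auto"` (exact up to n = 25), `"exact"`, or `"normal"`.
#' @param zeroMethod `"drop"` (classical) or `"pratt"`.
#' @return a [WilcoxonSignedRank-class] object.
#' @examples
#' wilcoxonSignedRank(c(10, 20, 30), c(11, 18, 33))
#' @export
wilcoxonSignedRank <- function(actual, predicted,
                               mode = c("auto", "exact", "normal"),
                               zeroMethod = c("drop", "pratt")) {
    mode <- match.arg(mode); zeroMethod <- match.arg(zeroMethod)
    p <- .paired(actual, predicted)
    d <- p$yhat - p$y
    if (all(d == 0))
        stop("all paired differences are zero; the signed-rank test is ",
             "undefined", call. = FALSE)
    if (zeroMethod == "drop") {
        d <- d[d != 0]
        r <- rank(abs(d))
    } else {
        r_all <- rank(abs(d))
        keep <- d != 0
        r <- r_all[keep]
        d <- d[keep]
    }
    n <- length(d)
    rPlus <- sum(r[d > 0])
    rMinus <- sum(r[d < 0])
    stat <- min(rPlus, rMinus)
    degenerate <- (rPlus == 0 || rMinus == 0)
    if (degenerate)
        warning("all non-zero differences share one sign; the signed-rank ",
                "statistic is 0 and the test is not informative",
                call. = FALSE)
    if (mode == "auto") mode <- if (n <= 25L) "exact" else "normal"
    if (mode == "exact") {
        pv <- .signed_rank_exact_p(r, rPlus)
        method <- "exact"
    } else {
        pv <- .signed_rank_normal_p(r, rPlus)
        method <- "normal approximation"
    }
    new("WilcoxonSignedRank", rPlus = rPlus, rMinus = rMinus,
        statistic = stat, pValue = pv, nEffective = as.integer(n),
        degenerate = degenerate, method = method)
}

# Exact two-sided p for the signed-rank statistic with an arbitrary rank
# multiset (ties allowed). The null distribution of R+ is the distribution
# of the sum of a uniformly random subset of the ranks; it is built by
# convolution over the ranks, doubled so that average ranks (k + 1/2)
# index an integer count vector. p = min(1, 2 * min(P(R+ <= w), P(R+ >= w))).
.signed_rank_exact_p <- function(ranks, rPlus) {
    w <- as.integer(round(2 * ranks))
    total <- sum(w)
    counts <- numeric(total + 1L)   # counts[s + 1] = #subsets with sum s
    counts[1L] <- 1
    for (wi in w) {
        shifted <- c(numeric(wi), counts[seq_len(total + 1L - wi)])
        counts <- counts + shifted
    }
    counts <- counts / sum(counts)
    obs <- as.integer(round(2 * rPlus))
    lo <- sum(counts[seq_len(obs + 1L)])
    hi <- sum(counts[(obs + 1L):(total + 1L)])
    min(1, 2 * min(lo, hi))
}

# Normal approximation with tie-corrected variance and continuity
# correction 0.5 toward the mean.
.signed_rank_normal_p <- function(ranks, rPlus) {
    n <- length(ranks)
    mu <- n * (n + 1) / 4
    tie_tab <- table(ranks)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
        sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0)
        return(NA_real_)
    z <- (rPlus - mu - sign(rPlus - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
}

#' Evaluate predicted scores against a gold standard
#'
#' Joins per-subject predicted scores with gold-standard scores by subject
#' id, applies the per-value outlier policy, and reports MAE, RMSE,
#' Pearson correlation and the Wilcoxon signed-rank test per joint group
#' (one row per group and normalization label).
#'
#' @param predicted per-subject score `data.frame` (`ID` + group columns),
#'   e.g. from [aggregateSubjectScores()].
#' @param gold gold-standard `data.frame` in the same layout.
#' @param outliers outlier spec for [applyOutlierPolicy()], applied to the
#'   predicted scores (gold values of the removed pairs are dropped by the
#'   pairing itself).
#' @param method label recorded in the report's `method` column.
#' @return an [EvaluationReport-class].
#' @export
evaluateScores <- function(predicted, gold, outliers = NULL,
                           method = "minmax") {
    missing_ids <- setdiff(predicted$ID, gold$ID)
    extra_ids <- setdiff(gold$ID, predicted$ID)
    if (length(missing_ids) || length(extra_ids))
        stop("subject ids do not match; missing from gold: [",
             paste(missing_ids, collapse = ", "),
             "], missing from predictions: [",
             paste(extra_ids, collapse = ", "), "]", call. = FALSE)
    gold <- gold[match(predicted$ID, gold$ID), ]
    predicted <- applyOutlierPolicy(predicted, outliers)
    log <- attr(predicted, "outlierLog")
    groups <- intersect(setdiff(names(predicted), "ID"),
                        setdiff(names(gold), "ID"))
    if (!length(groups))
        stop("no joint-group columns shared between predictions and gold",
             call. = FALSE)
    rows <- lapply(groups, function(g) {
        y <- gold[[g]]; yhat <- predicted[[g]]
        ok <- !(is.na(y) | is.na(yhat))
        if (sum(ok) == 0)
            return(data.frame(group = g, method = method, n = 0L,
                MAE = NA_real_, RMSE = NA_real_, CC = NA_real_,
                W = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
        cc <- tryCatch(suppressWarnings(pearsonCC(y[ok], yhat[ok])),
                       error = function(e) NA_real_)
        wt <- tryCatch(suppressWarnings(
                  wilcoxonSignedRank(y[ok], yhat[ok])),
              error = function(e) NULL)
        data.frame(group = g, method = method, n = sum(ok),
            MAE = maeScore(y[ok], yhat[ok]),
            RMSE = rmseScore(y[ok], yhat[ok]),
            CC = cc,
            W = if (is.null(wt)) NA_real_ else wt@statistic,
            p = if (is.null(wt)) NA_real_ else wt@pValue,
            stringsAsFactors = FALSE)
    })
    new("EvaluationReport", metrics = do.call(rbind, rows),
        outlierLog = log)
}
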