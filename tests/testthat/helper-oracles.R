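# Independent oracles and fixture builders shared across the suite.

# Brute-force DTW: minimum accumulated cost over every monotone,
# continuous, boundary-complete warp path, found by exhaustive recursion
# (with a sound branch-and-bound cut: costs are non-negative). Only usable
# for short sequences; completely independent of the package's dynamic
# program.
brute_dtw <- function(A, B, metric = c("euclidean", "manhattan")) {
    metric <- match.arg(metric)
    if (!is.matrix(A)) A <- matrix(A, ncol = 1)
    if (!is.matrix(B)) B <- matrix(B, ncol = 1)
    pd <- function(i, j)
        if (metric == "euclidean") sqrt(sum((A[i, ] - B[j, ])^2))
        else sum(abs(A[i, ] - B[j, ]))
    n <- nrow(A); m <- nrow(B)
    best <- Inf
    rec <- function(i, j, acc) {
        acc <- acc + pd(i, j)
        if (acc > best) return(invisible())
        if (i == n && j == m) {
            best <<- min(best, acc)
            return(invisible())
        }
        if (i < n && j < m) rec(i + 1, j + 1, acc)
        if (i < n) rec(i + 1, j, acc)
        if (j < m) rec(i, j + 1, acc)
    }
    rec(1, 1, 0)
    best
}

# Exact two-sided signed-rank p by direct enumeration of all 2^n sign
# assignments of the observed rank multiset (n <= ~12).
enum_signed_rank_p <- function(d) {
    d <- d[d != 0]
    r <- rank(abs(d))
    n <- length(d)
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    rplus <- as.vector(signs %*% r)
    min(1, 2 * min(mean(rplus <= w_obs + 1e-9),
                   mean(rplus >= w_obs - 1e-9)))
}

# Random landmark trajectory with smooth per-landmark motion.
random_trajectory <- function(nf = 20, fps = 30, seed = 1,
                              space = "world") {
    set.seed(seed)
    coords <- array(rnorm(nf * 33 * 3, sd = 0.1), dim = c(nf, 33, 3))
    if (space == "image")
        coords[, , 1:2] <- plogis(coords[, , 1:2])
    LandmarkTrajectory(coords, fps = fps, space = space)
}

small_template <- function(name = "diagonal", duration = 2, fps = 20)
    exerciseTemplate(name, duration = duration, fps = fps)

# Prefix a trajectory coordinate array with k copies of its first frame.
abind_shift <- function(coords, k) {
    out <- array(NA_real_, dim = dim(coords) + c(k, 0, 0))
    out[seq_len(k), , ] <- coords[rep(1, k), , ]
    out[k + seq_len(dim(coords)[1]), , ] <- coords
    out
}

path_cost <- function(A, B, path, metric = "euclidean") {
    if (!is.matrix(A)) A <- matrix(A, ncol = 1)
    if (!is.matrix(B)) B <- matrix(B, ncol = 1)
    sum(vapply(seq_len(nrow(path)), function(k) {
        a <- A[path[k, 1], ]; b <- B[path[k, 2], ]
        if (metric == "euclidean") sqrt(sum((a - b)^2)) else sum(abs(a - b))
    }, numeric(1)))
}
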