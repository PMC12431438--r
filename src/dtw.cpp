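#include <Rcpp.h>
using namespace Rcpp;

// Point distance between row i of A and row j of B.
// metric: 0 = euclidean, 1 = manhattan. Sequences are stored row-major as
// n x d matrices (d = 1 for scalar series, 3 for landmark triples).
static inline double ptDist(const NumericMatrix &A, const NumericMatrix &B,
                            int i, int j, int metric) {
    const int d = A.ncol();
    double acc = 0.0;
    if (metric == 0) {
        for (int k = 0; k < d; ++k) {
            double diff = A(i, k) - B(j, k);
            acc += diff * diff;
        }
        return std::sqrt(acc);
    }
    for (int k = 0; k < d; ++k)
        acc += std::fabs(A(i, k) - B(j, k));
    return acc;
}

// Full O(|A|.|B|) DTW dynamic program with warp-path backtracking.
//
// The grid is defined over the sequence elements themselves: cell (1,1)
// holds Dist(A1, B1) and the first row/column accumulate along the edge,
// so the reported distance is the accumulated cost at (|A|, |B|).
// Ties in the predecessor minimum are broken diagonal, then vertical
// (i-1, j), then horizontal, giving deterministic paths; the distance is
// unaffected by the tie rule.
//
// window: Sakoe-Chiba band half-width (|i - j| <= window), or -1 for
// unconstrained alignment (the default used throughout the package).
// [[Rcpp::export(name = ".dtw_cpp")]]
List dtw_cpp(NumericMatrix A, NumericMatrix B, int metric = 0,
             bool keep_matrix = false, int window = -1) {
    const int n = A.nrow(), m = B.nrow();
    if (n < 1 || m < 1)
        stop("both sequences must contain at least one point");
    if (A.ncol() != B.ncol())
        stop("sequences have mismatched point dimensionality");
    const double INF = std::numeric_limits<double>::infinity();

    NumericMatrix D(n, m);
    std::fill(D.begin(), D.end(), INF);
    // 0 = diagonal, 1 = vertical (from i-1,j), 2 = horizontal (from i,j-1)
    IntegerMatrix from(n, m);

    for (int i = 0; i < n; ++i) {
        int jlo = 0, jhi = m - 1;
        if (window >= 0) {
            jlo = std::max(0, i - window);
            jhi = std::min(m - 1, i + window);
        }
        for (int j = jlo; j <= jhi; ++j) {
            double cost = ptDist(A, B, i, j, metric);
            if (i == 0 && j == 0) {
                D(i, j) = cost;
                from(i, j) = -1;
                continue;
            }
            double diag = (i > 0 && j > 0) ? D(i - 1, j - 1) : INF;
            double vert = (i > 0) ? D(i - 1, j) : INF;
            double horz = (j > 0) ? D(i, j - 1) : INF;
            double best = diag;
            int arg = 0;
            if (vert < best) { best = vert; arg = 1; }
            if (horz < best) { best = horz; arg = 2; }
            D(i, j) = cost + best;
            from(i, j) = arg;
        }
    }

    if (!R_FINITE(D(n - 1, m - 1)))
        stop("no warp path satisfies the window constraint");

    // Backtrack the argmin predecessors from (n, m) to (1, 1).
    std::vector<int> pi, pj;
    int i = n - 1, j = m - 1;
    while (true) {
        pi.push_back(i + 1);
        pj.push_back(j + 1);
        if (i == 0 && j == 0) break;
        switch (from(i, j)) {
        case 0: --i; --j; break;
        case 1: --i; break;
        default: --j; break;
        }
    }
    const int L = (int)pi.size();
    IntegerMatrix path(L, 2);
    for (int k = 0; k < L; ++k) {
        path(k, 0) = pi[L - 1 - k];
        path(k, 1) = pj[L - 1 - k];
    }

    return List::create(
        _["distance"] = D(n - 1, m - 1),
        _["path"] = path,
        _["matrix"] = keep_matrix ? (SEXP)D : R_NilValue);
}
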