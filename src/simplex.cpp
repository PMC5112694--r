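// Dense two-phase primal simplex used as the linear-programming kernel for
// flux balance analysis.  Solves the standard form
//
//     min c'x   s.t.  A x = b,  x >= 0
//
// with Bland's anti-cycling rule.  Problem sizes here are small (tens of
// rows/columns for the toy networks, low hundreds for genome-scale input),
// so a full dense tableau is simpler and fast enough; the biomass-coefficient
// fitting procedure calls this ~1e5 times, which is why it lives in C++.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Pivot until optimal over the first ncols_active columns.
// Returns 0 = optimal, 2 = unbounded, 3 = iteration limit.
int pivot_loop(mat& T, std::vector<int>& basis, const int ncols_active,
               const double tol, const int maxit) {
    const int m = static_cast<int>(T.n_rows) - 1;
    const int rhs = static_cast<int>(T.n_cols) - 1;
    for (int it = 0; it < maxit; ++it) {
        // Bland: entering column = smallest index with negative reduced cost.
        int enter = -1;
        for (int j = 0; j < ncols_active; ++j) {
            if (T(m, j) < -tol) { enter = j; break; }
        }
        if (enter < 0) return 0;
        // Ratio test; ties broken toward smallest basis index (Bland).
        int leave = -1;
        double best = datum::inf;
        for (int i = 0; i < m; ++i) {
            const double a = T(i, enter);
            if (a > tol) {
                const double r = T(i, rhs) / a;
                if (r < best - 1e-12 ||
                    (std::abs(r - best) <= 1e-12 &&
                     (leave < 0 || basis[i] < basis[leave]))) {
                    best = r;
                    leave = i;
                }
            }
        }
        if (leave < 0) return 2;
        const double p = T(leave, enter);
        T.row(leave) /= p;
        for (int i = 0; i <= m; ++i) {
            if (i == leave) continue;
            const double f = T(i, enter);
            if (f != 0.0) T.row(i) -= f * T.row(leave);
        }
        basis[leave] = enter;
    }
    return 3;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".Call_simplex_core")]]
Rcpp::List simplex_core(const arma::mat& A, const arma::vec& b,
                        const arma::vec& c, const double tol = 1e-9,
                        const int maxit = 100000) {
    int m = static_cast<int>(A.n_rows);
    const int n = static_cast<int>(A.n_cols);

    // Tableau: [A | I_m | rhs] with cost row appended; rows flipped so b >= 0.
    mat T(m + 1, n + m + 1, fill::zeros);
    for (int i = 0; i < m; ++i) {
        const double s = (b(i) < 0.0) ? -1.0 : 1.0;
        for (int j = 0; j < n; ++j) T(i, j) = s * A(i, j);
        T(i, n + i) = 1.0;
        T(i, n + m) = s * b(i);
    }

    std::vector<int> basis(m);
    for (int i = 0; i < m; ++i) basis[i] = n + i;

    // Phase 1: minimize sum of artificials.  Reduced cost row with the
    // artificial basis: subtract every constraint row from the cost row.
    for (int j = 0; j <= n + m; ++j) {
        double s = 0.0;
        for (int i = 0; i < m; ++i) s += T(i, j);
        T(m, j) = -s;
    }
    for (int i = 0; i < m; ++i) T(m, n + i) = 0.0;

    int status = pivot_loop(T, basis, n + m, tol, maxit);
    if (status == 3)
        return Rcpp::List::create(Rcpp::Named("status") = 3);
    const double phase1 = -T(m, n + m);
    if (phase1 > 1e-7)
        return Rcpp::List::create(Rcpp::Named("status") = 1);  // infeasible

    // Drive artificials out of the basis; rows that cannot pivot are
    // redundant (0 = 0) and are dropped.
    std::vector<int> drop;
    for (int i = 0; i < m; ++i) {
        if (basis[i] >= n) {
            int enter = -1;
            for (int j = 0; j < n; ++j) {
                if (std::abs(T(i, j)) > tol) { enter = j; break; }
            }
            if (enter < 0) {
                drop.push_back(i);
                continue;
            }
            const double p = T(i, enter);
            T.row(i) /= p;
            for (int k = 0; k <= m; ++k) {
                if (k == i) continue;
                const double f = T(k, enter);
                if (f != 0.0) T.row(k) -= f * T.row(i);
            }
            basis[i] = enter;
        }
    }
    if (!drop.empty()) {
        uvec keep(m + 1 - drop.size());
        int idx = 0;
        std::vector<int> nb;
        for (int i = 0; i < m; ++i) {
            if (std::find(drop.begin(), drop.end(), i) == drop.end()) {
                keep(idx++) = i;
                nb.push_back(basis[i]);
            }
        }
        keep(idx) = m;
        T = T.rows(keep);
        basis = nb;
        m = static_cast<int>(basis.size());
    }

    // Phase 2: reduced costs for the true objective.
    const int rhs = n + static_cast<int>(T.n_cols) - 1 - n;  // last column
    for (unsigned j = 0; j < T.n_cols; ++j) T(m, j) = 0.0;
    for (int j = 0; j < n; ++j) T(m, j) = c(j);
    for (int i = 0; i < m; ++i) {
        const double cb = c(basis[i]);
        if (cb != 0.0) T.row(m) -= cb * T.row(i);
    }
    (void)rhs;

    status = pivot_loop(T, basis, n, tol, maxit);
    if (status != 0)
        return Rcpp::List::create(Rcpp::Named("status") = status);

    vec x(n, fill::zeros);
    for (int i = 0; i < m; ++i)
        if (basis[i] < n) x(basis[i]) = T(i, T.n_cols - 1);
    const double obj = dot(c, x);
    return Rcpp::List::create(Rcpp::Named("status") = 0,
                              Rcpp::Named("x") = x,
                              Rcpp::Named("objective") = obj);
}
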