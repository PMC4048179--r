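// Coordinate-descent cores for the penalized multi-task regression family.
// All solvers work on precomputed Gram matrices (XtX, XtY) and minimize
//   0.5*||Y - X B||_F^2 + penalty(B)
// where 0.5*||Y - X B||_F^2 = 0.5*yty - <B, XtY> + 0.5*<B, XtX B>.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline double soft(double z, double t) {
    if (z > t) return z - t;
    if (z < -t) return z + t;
    return 0.0;
}

static double quad_loss(const mat& XtX, const mat& XtY, double yty,
                        const mat& B) {
    return 0.5 * yty - accu(B % XtY) + 0.5 * accu(B % (XtX * B));
}

// Row-block coordinate descent for
//   0.5*||Y - XB||^2 + sum_j lam1_j * ||b_j||_1
//                    + sum_j lam2_j * sum_g ||b_j[G_g]||_2
// (rows j of B; G_g disjoint column groups, default one group of all K).
// lam2 = 0 gives the plain (or SNP-weighted) lasso. The exact row update is
// the composition of the soft-threshold and the per-group shrinkage, valid
// because the row subproblem is isotropic and the groups are disjoint.
// [[Rcpp::export]]
Rcpp::List cpp_cd_l1l2(const arma::mat& XtX, const arma::mat& XtY, double yty,
                       const arma::vec& lam1, const arma::vec& lam2,
                       const Rcpp::List& colGroups,
                       arma::mat B, double tol, int maxit) {
    const int J = XtX.n_rows, K = XtY.n_cols;
    std::vector<uvec> G;
    if (colGroups.size() == 0) {
        G.push_back(regspace<uvec>(0, K - 1));
    } else {
        for (int g = 0; g < colGroups.size(); ++g)
            G.push_back(Rcpp::as<uvec>(colGroups[g]));
    }
    std::vector<double> trace;
    auto penalty = [&](const mat& M) {
        double p = 0.0;
        for (int j = 0; j < J; ++j) {
            p += lam1(j) * accu(abs(M.row(j)));
            if (lam2(j) > 0.0)
                for (size_t g = 0; g < G.size(); ++g)
                    p += lam2(j) * norm(M.submat(uvec{(uword)j}, G[g]), "fro");
        }
        return p;
    };
    double obj = quad_loss(XtX, XtY, yty, B) + penalty(B);
    trace.push_back(obj);
    bool converged = false;
    int it = 0;
    for (it = 1; it <= maxit; ++it) {
        for (int j = 0; j < J; ++j) {
            double a = XtX(j, j);
            if (a <= 0.0) { B.row(j).zeros(); continue; }
            rowvec z = XtY.row(j) - XtX.row(j) * B + a * B.row(j);
            rowvec u(K);
            for (int k = 0; k < K; ++k) u(k) = soft(z(k), lam1(j));
            if (lam2(j) > 0.0) {
                for (size_t g = 0; g < G.size(); ++g) {
                    double nrm = 0.0;
                    for (uword ii = 0; ii < G[g].n_elem; ++ii)
                        nrm += u(G[g](ii)) * u(G[g](ii));
                    nrm = std::sqrt(nrm);
                    double sc = (nrm <= lam2(j)) ? 0.0 : (1.0 - lam2(j) / nrm);
                    for (uword ii = 0; ii < G[g].n_elem; ++ii)
                        u(G[g](ii)) *= sc;
                }
            }
            B.row(j) = u / a;
        }
        double obj_new = quad_loss(XtX, XtY, yty, B) + penalty(B);
        trace.push_back(obj_new);
        double denom = std::max(std::abs(obj), 1e-12);
        if (std::abs(obj - obj_new) / denom < tol) { converged = true; obj = obj_new; break; }
        obj = obj_new;
    }
    return Rcpp::List::create(Rcpp::Named("B") = B,
                              Rcpp::Named("objective") = trace,
                              Rcpp::Named("converged") = converged,
                              Rcpp::Named("niter") = std::min(it, maxit));
}

// Graph-guided fused lasso (and its two-graph extension) by the variational
// (half-quadratic) reformulation: each fusion term w*|x|, with
// x = B(j,m) - s*B(j,l), is replaced by its smoothed version
// w*sqrt(x^2 + eps^2), which is majorized by w*(x^2 + d^2)/(2d) at
// d = sqrt(x_old^2 + eps^2). Given the d's the objective is quadratic plus
// the separable L1 term, and coordinate descent applies with exact
// soft-threshold steps (so L1 zeros are exact). Each outer cycle refreshes
// d and runs one full sweep; the recorded trace is the smoothed objective,
// which the MM structure makes non-increasing. The smoothed and exact
// objectives differ by at most eps * sum(w); the caller drives eps down by
// continuation with warm starts.
//
// colE_*: edges over columns of B (fusion across responses, applied per row).
// rowE_*: edges over rows of B (fusion across predictors, applied per column).
// [[Rcpp::export]]
Rcpp::List cpp_cd_gflasso(const arma::mat& XtX, const arma::mat& XtY,
                          double yty, double lam,
                          const arma::ivec& colE_a, const arma::ivec& colE_b,
                          const arma::vec& colE_w, const arma::vec& colE_s,
                          const arma::ivec& rowE_a, const arma::ivec& rowE_b,
                          const arma::vec& rowE_w, const arma::vec& rowE_s,
                          arma::mat B, double tol, int maxit, double eps) {
    const int J = XtX.n_rows, K = XtY.n_cols;
    const int nEc = colE_a.n_elem, nEr = rowE_a.n_elem;

    // adjacency: for each column k the incident column-edges, likewise rows
    std::vector<std::vector<std::pair<int,int> > > colAdj(K), rowAdj(J);
    for (int e = 0; e < nEc; ++e) {
        colAdj[colE_a(e)].push_back(std::make_pair(e, colE_b(e)));
        colAdj[colE_b(e)].push_back(std::make_pair(e, colE_a(e)));
    }
    for (int e = 0; e < nEr; ++e) {
        rowAdj[rowE_a(e)].push_back(std::make_pair(e, rowE_b(e)));
        rowAdj[rowE_b(e)].push_back(std::make_pair(e, rowE_a(e)));
    }

    mat Dc(J, std::max(nEc, 1));   // per (row, column-edge)
    mat Dr(std::max(nEr, 1), K);   // per (row-edge, column)

    // smoothed objective: fusion terms as w * sqrt(x^2 + eps^2)
    auto objective = [&](const mat& M) {
        double o = quad_loss(XtX, XtY, yty, M) + lam * accu(abs(M));
        for (int e = 0; e < nEc; ++e) {
            vec x = M.col(colE_a(e)) - colE_s(e) * M.col(colE_b(e));
            o += colE_w(e) * accu(sqrt(square(x) + eps * eps));
        }
        for (int e = 0; e < nEr; ++e) {
            rowvec x = M.row(rowE_a(e)) - rowE_s(e) * M.row(rowE_b(e));
            o += rowE_w(e) * accu(sqrt(square(x) + eps * eps));
        }
        return o;
    };

    std::vector<double> trace;
    double obj = objective(B);
    trace.push_back(obj);
    bool converged = false;
    int it = 0;
    for (it = 1; it <= maxit; ++it) {
        // refresh the variational terms at the current iterate
        for (int e = 0; e < nEc; ++e) {
            vec x = B.col(colE_a(e)) - colE_s(e) * B.col(colE_b(e));
            Dc.col(e) = sqrt(square(x) + eps * eps);
        }
        for (int e = 0; e < nEr; ++e) {
            rowvec x = B.row(rowE_a(e)) - rowE_s(e) * B.row(rowE_b(e));
            Dr.row(e) = sqrt(square(x) + eps * eps);
        }
        // one full coordinate sweep on the majorizing quadratic
        for (int k = 0; k < K; ++k) {
            for (int j = 0; j < J; ++j) {
                double a = XtX(j, j);
                if (a <= 0.0) { B(j, k) = 0.0; continue; }
                double z = XtY(j, k) - dot(XtX.row(j), B.col(k)) + a * B(j, k);
                for (size_t u = 0; u < colAdj[k].size(); ++u) {
                    int e = colAdj[k][u].first, l = colAdj[k][u].second;
                    double c = colE_w(e) / Dc(j, e);
                    a += c;
                    z += c * colE_s(e) * B(j, l);
                }
                for (size_t u = 0; u < rowAdj[j].size(); ++u) {
                    int e = rowAdj[j][u].first, i = rowAdj[j][u].second;
                    double c = rowE_w(e) / Dr(e, k);
                    a += c;
                    z += c * rowE_s(e) * B(i, k);
                }
                B(j, k) = soft(z, lam) / a;
            }
        }
        double obj_new = objective(B);
        trace.push_back(obj_new);
        double denom = std::max(std::abs(obj), 1e-12);
        if (std::abs(obj - obj_new) / denom < tol) { converged = true; obj = obj_new; break; }
        obj = obj_new;
    }
    return Rcpp::List::create(Rcpp::Named("B") = B,
                              Rcpp::Named("objective") = trace,
                              Rcpp::Named("converged") = converged,
                              Rcpp::Named("niter") = std::min(it, maxit));
}

// Root of h(t) = sum zt_i^2 / (d_i * t + w)^2 - 1 on t > 0 (the secular
// equation of the group update b = (Q + (w/t) I)^{-1} z with t = ||b||).
static double group_secular(const vec& zt, const vec& d, double w) {
    auto h = [&](double t) {
        double s = 0.0;
        for (uword i = 0; i < zt.n_elem; ++i) {
            double den = d(i) * t + w;
            s += zt(i) * zt(i) / (den * den);
        }
        return s - 1.0;
    };
    double lo = 0.0, hi = 1.0;
    int guard = 0;
    while (h(hi) > 0 && guard++ < 200) { lo = hi; hi *= 2.0; }
    for (int i = 0; i < 200; ++i) {
        double mid = 0.5 * (lo + hi);
        if (h(mid) > 0) lo = mid; else hi = mid;
        if ((hi - lo) / std::max(hi, 1e-300) < 1e-15) break;
    }
    return 0.5 * (lo + hi);
}

// Block coordinate descent for the group lasso
//   0.5*||Y - XB||^2 + sum_k sum_g w_g * ||B[G_g, k]||_2
// Groups partition the rows (predictors); the group update is exact via the
// eigendecomposition of X_g' X_g and the secular equation above.
// [[Rcpp::export]]
Rcpp::List cpp_bcd_grouplasso(const arma::mat& XtX, const arma::mat& XtY,
                              double yty, const Rcpp::List& groups,
                              const arma::vec& gw, arma::mat B,
                              double tol, int maxit) {
    const int K = XtY.n_cols;
    const int nG = groups.size();
    std::vector<uvec> G(nG);
    std::vector<mat> V(nG);
    std::vector<vec> D(nG);
    for (int g = 0; g < nG; ++g) {
        G[g] = Rcpp::as<uvec>(groups[g]);
        mat Q = XtX.submat(G[g], G[g]);
        vec eigval;
        mat eigvec;
        eig_sym(eigval, eigvec, Q);
        eigval = clamp(eigval, 0.0, datum::inf);
        V[g] = eigvec;
        D[g] = eigval;
    }
    auto penalty = [&](const mat& M) {
        double p = 0.0;
        for (int k = 0; k < K; ++k)
            for (int g = 0; g < nG; ++g)
                p += gw(g) * norm(M.submat(G[g], uvec{(uword)k}), "fro");
        return p;
    };
    std::vector<double> trace;
    double obj = quad_loss(XtX, XtY, yty, B) + penalty(B);
    trace.push_back(obj);
    bool converged = false;
    int it = 0;
    for (it = 1; it <= maxit; ++it) {
        for (int k = 0; k < K; ++k) {
            for (int g = 0; g < nG; ++g) {
                uvec col{(uword)k};
                vec z = XtY.submat(G[g], col) - XtX.rows(G[g]) * B.col(k)
                        + XtX.submat(G[g], G[g]) * B.submat(G[g], col);
                double w = gw(g);
                if (w <= 0.0) {
                    // unpenalized block: exact minimization (ridge-free)
                    B.submat(G[g], col) = solve(XtX.submat(G[g], G[g]) +
                                                1e-12 * eye(G[g].n_elem, G[g].n_elem), z);
                    continue;
                }
                if (norm(z, 2) <= w) {
                    B.submat(G[g], col).zeros();
                } else {
                    vec zt = V[g].t() * z;
                    double t = group_secular(zt, D[g], w);
                    vec b = V[g] * (zt % (t / (D[g] * t + w)));
                    B.submat(G[g], col) = b;
                }
            }
        }
        double obj_new = quad_loss(XtX, XtY, yty, B) + penalty(B);
        trace.push_back(obj_new);
        double denom = std::max(std::abs(obj), 1e-12);
        if (std::abs(obj - obj_new) / denom < tol) { converged = true; obj = obj_new; break; }
        obj = obj_new;
    }
    return Rcpp::List::create(Rcpp::Named("B") = B,
                              Rcpp::Named("objective") = trace,
                              Rcpp::Named("converged") = converged,
                              Rcpp::Named("niter") = std::min(it, maxit));
}
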