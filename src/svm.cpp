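#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin linear SVM dual on a
// precomputed kernel:
//
//   min_a  0.5 * sum_kl y_k y_l a_k a_l K_kl - sum_k a_k
//   s.t.   0 <= a_k <= C,  sum_k y_k a_k = 0
//
// Working in b_k = y_k a_k, the gradient is fhat_k - y_k with
// fhat_k = sum_l b_l K_kl, and the maximal violating pair is
//   i = argmax_{I_up} (y_k - fhat_k),  j = argmin_{I_low} (y_k - fhat_k).
// Each step moves mass t from b_j to b_i along the equality constraint.
// The bias solves f(x) = fhat(x) + b with b = (m + M) / 2 at convergence.
//
// idx maps the n active (training) rows onto the full kernel matrix, so a
// leave-one-out sweep reuses one kernel without copying submatrices.
static void smo_solve(const double *K, int ldK, const int *idx, int n,
                      const double *y, double C, double tol, int max_iter,
                      std::vector<double> &beta, double &b, double *fhat_out)
{
    beta.assign(n, 0.0);
    std::vector<double> fhat(n, 0.0);
    double m = 0.0, M = 0.0;

    std::vector<double> g(n);
    for (int iter = 0; iter < max_iter; ++iter) {
        int i = -1, j = -1;
        m = -HUGE_VAL;
        M = HUGE_VAL;
        for (int t = 0; t < n; ++t) {
            double a = y[t] * beta[t]; /* alpha_t */
            g[t] = y[t] - fhat[t];
            bool up = (y[t] > 0) ? (a < C) : (a > 0);
            bool lo = (y[t] > 0) ? (a > 0) : (a < C);
            if (up && g[t] > m) { m = g[t]; i = t; }
            if (lo && g[t] < M) M = g[t];
        }
        if (i < 0 || m - M < tol)
            break;

        /* second-order working-set selection for the partner index */
        const double *Ki = K + (size_t)ldK * idx[i];
        double Kii = Ki[idx[i]], best = 0.0;
        for (int t = 0; t < n; ++t) {
            double a = y[t] * beta[t];
            bool lo = (y[t] > 0) ? (a > 0) : (a < C);
            if (!lo || g[t] >= m)
                continue;
            double quad = Kii + K[(size_t)ldK * idx[t] + idx[t]]
                          - 2.0 * Ki[idx[t]];
            if (quad <= 1e-12)
                quad = 1e-12;
            double diff = m - g[t];
            double gain = -(diff * diff) / quad;
            if (gain < best) { best = gain; j = t; }
        }
        if (j < 0)
            break;

        const double *Kj = K + (size_t)ldK * idx[j];
        double quad = Kii + Kj[idx[j]] - 2.0 * Ki[idx[j]];
        if (quad <= 1e-12)
            quad = 1e-12;
        double t_step = (g[i] - g[j]) / quad;

        /* box caps: beta_i increases, beta_j decreases */
        double cap_i = (y[i] > 0) ? (C - y[i] * beta[i]) : (y[i] * beta[i]);
        double cap_j = (y[j] > 0) ? (y[j] * beta[j]) : (C - y[j] * beta[j]);
        double cap = cap_i < cap_j ? cap_i : cap_j;
        if (t_step > cap)
            t_step = cap;
        if (t_step <= 0)
            break;

        beta[i] += t_step;
        beta[j] -= t_step;
        for (int k = 0; k < n; ++k)
            fhat[k] += t_step * (Ki[idx[k]] - Kj[idx[k]]);
    }
    b = (std::isfinite(m) && std::isfinite(M)) ? 0.5 * (m + M) : 0.0;
    if (fhat_out)
        for (int k = 0; k < n; ++k)
            fhat_out[k] = fhat[k];
}

// [[Rcpp::export(name = ".svm_fit_kernel", rng = false)]]
List svm_fit_kernel(NumericMatrix K, NumericVector y, double C,
                    double tol = 1e-6, int max_iter = 1000000)
{
    int n = K.nrow();
    if (K.ncol() != n || y.size() != n)
        stop("kernel matrix and labels do not conform");
    std::vector<int> idx(n);
    for (int k = 0; k < n; ++k)
        idx[k] = k;
    std::vector<double> beta;
    double b = 0.0;
    std::vector<double> fhat(n);
    smo_solve(REAL(K), n, idx.data(), n, REAL(y), C, tol, max_iter,
              beta, b, fhat.data());
    NumericVector alpha(n), decision(n);
    for (int k = 0; k < n; ++k) {
        alpha[k] = y[k] * beta[k];
        decision[k] = fhat[k] + b;
    }
    return List::create(_["alpha"] = alpha, _["b"] = b,
                        _["decision"] = decision);
}

// Leave-one-out decision values: for each row i, train on all other rows
// and return the signed decision value of the held-out row.
// [[Rcpp::export(name = ".svm_loo_kernel", rng = false)]]
NumericVector svm_loo_kernel(NumericMatrix K, NumericVector y, double C,
                             double tol = 1e-6, int max_iter = 1000000)
{
    int n = K.nrow();
    if (K.ncol() != n || y.size() != n)
        stop("kernel matrix and labels do not conform");
    NumericVector out(n);
    std::vector<int> idx(n - 1);
    std::vector<double> ysub(n - 1), beta;
    const double *Kp = REAL(K);

    for (int i = 0; i < n; ++i) {
        int pos = 0;
        for (int k = 0; k < n; ++k) {
            if (k == i)
                continue;
            idx[pos] = k;
            ysub[pos] = y[k];
            ++pos;
        }
        double b = 0.0;
        smo_solve(Kp, n, idx.data(), n - 1, ysub.data(), C, tol, max_iter,
                  beta, b, NULL);
        double f = b;
        const double *Kcol = Kp + (size_t)n * i; /* column i = K(., i) */
        for (int k = 0; k < n - 1; ++k)
            f += beta[k] * Kcol[idx[k]];
        out[i] = f;
    }
    return out;
}
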