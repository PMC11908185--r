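#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for the finite hyperexponential mixture.
//
// Per iteration, in fixed draw order so runs are replayable from one seed:
//   1. z_n ~ Categorical(p), p_k proportional to pi_k * lambda_k * exp(-lambda_k t_n)
//      (log-space with per-event max shift: lambda_k * t_n can exceed 700)
//   2. Omega_k, T_k tallied from z
//   3. pi ~ Dirichlet(gamma + Omega) via normalized Gamma draws
//   4. lambda_k ~ Gamma(alpha_k + Omega_k, rate = beta_k + T_k)
// Uses the R RNG stream, so set.seed() on the R side fixes the chain.
//
// The per-event loops over the K components are branch-free and annotated
// for SIMD so the exp() calls vectorize; shifted log-weights are clamped
// at -700 (values below contribute < 1e-304 relative mass, i.e. exactly
// nothing at the resolution of the categorical draw, while staying clear
// of denormals).

// [[Rcpp::export]]
List gibbs_core(NumericVector t, int K, int n_iter, int burn_in, int thin,
                NumericVector alpha, NumericVector beta, NumericVector gamma,
                NumericVector pi0, NumericVector lambda0,
                bool store_z, bool verbose)
{
    const int n = t.size();
    const int w = (n_iter - burn_in) / thin;

    std::vector<double> pi(pi0.begin(), pi0.end());
    std::vector<double> lambda(lambda0.begin(), lambda0.end());
    std::vector<double> logc(K), a(K), p(K);
    std::vector<int> z(n);
    std::vector<int> Omega_k(K);
    std::vector<double> T_k(K);

    NumericMatrix pi_out(w, K), lambda_out(w, K);
    IntegerMatrix z_out(store_z ? w : 0, store_z ? n : 0);

    double* __restrict pa = a.data();
    double* __restrict pp = p.data();

    int kept = 0;
    for (int iter = 1; iter <= n_iter; ++iter) {
        if (iter % 1000 == 0) {
            checkUserInterrupt();
            if (verbose)
                Rcout << "iteration " << iter << "/" << n_iter << "\n";
        }

        for (int k = 0; k < K; ++k) {
            logc[k] = std::log(pi[k]) + std::log(lambda[k]);
            Omega_k[k] = 0;
            T_k[k] = 0.0;
        }
        const double* __restrict pl = lambda.data();
        const double* __restrict pc = logc.data();

        for (int i = 0; i < n; ++i) {
            const double ti = t[i];
            double amax = -1e308;
            #pragma omp simd reduction(max:amax)
            for (int k = 0; k < K; ++k) {
                pa[k] = pc[k] - pl[k] * ti;
                amax = amax > pa[k] ? amax : pa[k];
            }
            double total = 0.0;
            if (amax > -1e307) {
                #pragma omp simd reduction(+:total)
                for (int k = 0; k < K; ++k) {
                    double x = pa[k] - amax;
                    x = x < -700.0 ? -700.0 : x;
                    pp[k] = std::exp(x);
                    total += pp[k];
                }
            } else {
                // all components carry zero weight (degenerate state);
                // fall back to a uniform label rather than emit NaN
                for (int k = 0; k < K; ++k) pp[k] = 1.0;
                total = K;
            }
            const double u = unif_rand() * total;
            double cum = 0.0;
            int zk = K - 1;
            for (int k = 0; k < K; ++k) {
                cum += pp[k];
                if (u <= cum) { zk = k; break; }
            }
            z[i] = zk;
            Omega_k[zk] += 1;
            T_k[zk] += ti;
        }

        double gsum = 0.0;
        for (int k = 0; k < K; ++k) {
            pi[k] = R::rgamma(gamma[k] + Omega_k[k], 1.0);
            gsum += pi[k];
        }
        for (int k = 0; k < K; ++k) pi[k] /= gsum;

        for (int k = 0; k < K; ++k)
            lambda[k] = R::rgamma(alpha[k] + Omega_k[k],
                                  1.0 / (beta[k] + T_k[k]));

        if (iter > burn_in && (iter - burn_in) % thin == 0 && kept < w) {
            for (int k = 0; k < K; ++k) {
                pi_out(kept, k) = pi[k];
                lambda_out(kept, k) = lambda[k];
            }
            if (store_z)
                for (int i = 0; i < n; ++i)
                    z_out(kept, i) = z[i] + 1;
            ++kept;
        }
    }

    return List::create(_["pi"] = pi_out,
                        _["lambda"] = lambda_out,
                        _["z"] = z_out,
                        _["w"] = kept);
}

// Tally, per event n and final cluster k', how many kept samples map the
// event's indicator to k'. assign_map[i, k] gives the cluster (1..Kprime)
// of original component k in sample i, or 0 if weight-filtered.

// [[Rcpp::export]]
NumericMatrix membership_counts(IntegerMatrix z, IntegerMatrix assign_map,
                                int Kprime)
{
    const int w = z.nrow(), n = z.ncol();
    NumericMatrix counts(n, Kprime);
    for (int i = 0; i < w; ++i) {
        for (int j = 0; j < n; ++j) {
            const int cl = assign_map(i, z(i, j) - 1);
            if (cl > 0) counts(j, cl - 1) += 1.0;
        }
    }
    return counts;
}
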