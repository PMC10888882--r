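#include <Rcpp.h>
using namespace Rcpp;

// Two-state HMM with Poisson emissions on windowed counts.
// obs[w]  : private-variant count in window w
// ew[w]   : effective exposure of window w (weight * callable_bp/window_size);
//           ew <= 0 marks a masked window: no emission information, the chain
//           passes through on transitions alone.
// seq_start: 0-based indices where a new independent chain begins (chromosome
//           or haplotype boundaries); the chain is re-initialised from the
//           start distribution at each.

static inline double emis_log(int obs, double ew, double rate) {
    if (ew <= 0.0) return 0.0;              // masked: P(obs|state)=1
    double mu = rate * ew;
    if (mu <= 0.0) mu = 1e-300;
    return obs * std::log(mu) - mu - R::lgammafn(obs + 1.0);
}

// Scaled forward-backward. Returns per-window archaic-state posterior
// (state 1) and the log-likelihood; optionally accumulates EM statistics.
struct FBStats {
    double loglik;
    double gamma_obs[2];   // sum_w gamma_s(w) * obs_w   (ew>0 windows)
    double gamma_ew[2];    // sum_w gamma_s(w) * ew_w    (ew>0 windows)
    double xi[2][2];       // expected transition counts
    double start_gamma[2]; // sum of gamma at chain starts
    int n_chain;
};

static void fb_pass(const IntegerVector& obs, const NumericVector& ew,
                    const IntegerVector& seq_start,
                    const NumericVector& sp, const NumericMatrix& tr,
                    const NumericVector& rates,
                    NumericVector* post, FBStats* st) {
    int n = obs.size();
    int nseq = seq_start.size();
    st->loglik = 0.0;
    for (int s = 0; s < 2; ++s) {
        st->gamma_obs[s] = st->gamma_ew[s] = st->start_gamma[s] = 0.0;
        for (int t = 0; t < 2; ++t) st->xi[s][t] = 0.0;
    }
    st->n_chain = nseq;

    for (int q = 0; q < nseq; ++q) {
        int a = seq_start[q];
        int b = (q + 1 < nseq) ? seq_start[q + 1] : n;
        int m = b - a;
        if (m <= 0) continue;
        std::vector<double> alpha(2 * m), beta(2 * m), scale(m), el(2 * m);

        for (int w = 0; w < m; ++w)
            for (int s = 0; s < 2; ++s)
                el[2 * w + s] = std::exp(emis_log(obs[a + w], ew[a + w], rates[s]));

        // forward
        double c = 0.0;
        for (int s = 0; s < 2; ++s) { alpha[s] = sp[s] * el[s]; c += alpha[s]; }
        if (c <= 0.0) c = 1e-300;
        scale[0] = c;
        alpha[0] /= c; alpha[1] /= c;
        for (int w = 1; w < m; ++w) {
            c = 0.0;
            for (int s = 0; s < 2; ++s) {
                double acc = alpha[2 * (w - 1)] * tr(0, s) +
                             alpha[2 * (w - 1) + 1] * tr(1, s);
                alpha[2 * w + s] = acc * el[2 * w + s];
                c += alpha[2 * w + s];
            }
            if (c <= 0.0) c = 1e-300;
            scale[w] = c;
            alpha[2 * w] /= c; alpha[2 * w + 1] /= c;
        }
        // backward
        beta[2 * (m - 1)] = beta[2 * (m - 1) + 1] = 1.0;
        for (int w = m - 2; w >= 0; --w) {
            for (int s = 0; s < 2; ++s) {
                double acc = 0.0;
                for (int t = 0; t < 2; ++t)
                    acc += tr(s, t) * el[2 * (w + 1) + t] * beta[2 * (w + 1) + t];
                beta[2 * w + s] = acc / scale[w + 1];
            }
        }
        for (int w = 0; w < m; ++w) st->loglik += std::log(scale[w]);

        // posteriors and EM statistics
        for (int w = 0; w < m; ++w) {
            double g0 = alpha[2 * w] * beta[2 * w];
            double g1 = alpha[2 * w + 1] * beta[2 * w + 1];
            double z = g0 + g1;
            if (z <= 0.0) { g0 = g1 = 0.5; z = 1.0; }
            g0 /= z; g1 /= z;
            if (post) (*post)[a + w] = g1;
            if (ew[a + w] > 0.0) {
                st->gamma_obs[0] += g0 * obs[a + w];
                st->gamma_obs[1] += g1 * obs[a + w];
                st->gamma_ew[0] += g0 * ew[a + w];
                st->gamma_ew[1] += g1 * ew[a + w];
            }
            if (w == 0) { st->start_gamma[0] += g0; st->start_gamma[1] += g1; }
        }
        for (int w = 0; w < m - 1; ++w) {
            double denom = 0.0, x[2][2];
            for (int s = 0; s < 2; ++s)
                for (int t = 0; t < 2; ++t) {
                    x[s][t] = alpha[2 * w + s] * tr(s, t) *
                              el[2 * (w + 1) + t] * beta[2 * (w + 1) + t];
                    denom += x[s][t];
                }
            if (denom <= 0.0) continue;
            for (int s = 0; s < 2; ++s)
                for (int t = 0; t < 2; ++t)
                    st->xi[s][t] += x[s][t] / denom;
        }
    }
}

// [[Rcpp::export]]
List cpp_hmm_fb(IntegerVector obs, NumericVector ew, IntegerVector seq_start,
                NumericVector start_probs, NumericMatrix trans,
                NumericVector rates) {
    NumericVector post(obs.size());
    FBStats st;
    fb_pass(obs, ew, seq_start, start_probs, trans, rates, &post, &st);
    return List::create(_["posterior"] = post, _["loglik"] = st.loglik);
}

// [[Rcpp::export]]
List cpp_hmm_em(IntegerVector obs, NumericVector ew, IntegerVector seq_start,
                NumericVector start_probs, NumericMatrix trans,
                NumericVector rates, double tol, int max_iter,
                double rate_floor) {
    NumericVector sp = clone(start_probs), rt = clone(rates);
    NumericMatrix tr = clone(trans);
    std::vector<double> trace;
    FBStats st;
    double prev = R_NegInf;
    for (int it = 0; it < max_iter; ++it) {
        fb_pass(obs, ew, seq_start, sp, tr, rt, nullptr, &st);
        trace.push_back(st.loglik);
        // M-step
        for (int s = 0; s < 2; ++s) {
            double row = st.xi[s][0] + st.xi[s][1];
            if (row > 0.0) for (int t = 0; t < 2; ++t) tr(s, t) = st.xi[s][t] / row;
            if (st.gamma_ew[s] > 0.0) {
                rt[s] = st.gamma_obs[s] / st.gamma_ew[s];
                if (rt[s] < rate_floor) rt[s] = rate_floor;
            }
            sp[s] = st.start_gamma[s] / st.n_chain;
        }
        double zsp = sp[0] + sp[1];
        sp[0] /= zsp; sp[1] /= zsp;
        if (it > 0 && st.loglik - prev < tol) break;
        prev = st.loglik;
    }
    return List::create(_["start_probs"] = sp, _["trans"] = tr,
                        _["emit_rates"] = rt,
                        _["ll_trace"] = NumericVector(trace.begin(), trace.end()));
}
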