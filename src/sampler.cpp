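#include "rlddm_core.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Two-level hierarchical sampler.
//
// Subject-level parameters live on transformed scales (logit for alpha, log
// for strictly positive parameters, identity for the powers) and are modelled
// as Normal(mu_k, sigma_k) given the group level.  Group means get
// conjugate Gibbs updates under Normal(m0, s0) priors; group spreads get
// adaptive random-walk Metropolis on the log scale under half-Normal(tau)
// priors; subject parameters get per-coordinate adaptive random-walk
// Metropolis (Robbins-Monro step adaptation toward 0.44 acceptance during
// warm-up only, so the post-warm-up kernel is fixed and valid).
// ---------------------------------------------------------------------------

static inline double to_natural(double x, int trans) {
    if (trans == 0) return 1.0 / (1.0 + std::exp(-x));
    if (trans == 1) return std::exp(x);
    return x;
}

static inline double dnorm_log(double x, double m, double s) {
    double z = (x - m) / s;
    return -0.5 * z * z - std::log(s);
}

struct SubjStore {
    IntegerVector ty, tt, ch, use;
    NumericVector rt, re;
    SubjData d;
    double min_rt;
};

// [[Rcpp::export]]
List cpp_fit_mcmc(List subjects, IntegerVector slot, IntegerVector trans,
                  NumericVector m0, NumericVector s0, NumericVector tau,
                  bool drpow, bool bspow, int chains, int warmup, int iter,
                  int thin, double init_step, double seed) {
    const int S = subjects.size(), K = slot.size();
    std::vector<SubjStore> dat(S);
    for (int s = 0; s < S; ++s) {
        List sub = subjects[s];
        SubjStore &st = dat[s];
        st.ty = sub["type"]; st.tt = sub["tt"]; st.ch = sub["choice"];
        st.rt = sub["rt"]; st.re = sub["reinf"];
        st.d.n = st.ty.size();
        st.d.type = INTEGER(st.ty); st.d.tt = INTEGER(st.tt);
        st.d.choice = INTEGER(st.ch);
        st.d.rt = REAL(st.rt); st.d.reinf = REAL(st.re);
        st.d.use = nullptr;
        if (sub.containsElementNamed("use")) {
            st.use = sub["use"];
            if (st.use.size() == st.d.n) st.d.use = INTEGER(st.use);
        }
        double mr = R_PosInf;
        for (int i = 0; i < st.d.n; ++i)
            if (st.d.choice[i] >= 0 && st.d.rt[i] < mr) mr = st.d.rt[i];
        st.min_rt = mr;
    }
    int k_tnd = -1;
    for (int k = 0; k < K; ++k) if (slot[k] == 5) k_tnd = k;

    const double canon_default[6] = {0.5, 1.0, 1.0, 0.0, 0.0, 0.3};
    auto subj_loglik = [&](int s, const std::vector<double> &th) {
        double canon[6];
        for (int j = 0; j < 6; ++j) canon[j] = canon_default[j];
        for (int k = 0; k < K; ++k)
            canon[slot[k]] = to_natural(th[k], trans[k]);
        Pars P = make_pars(canon, drpow, bspow);
        return session_ll(dat[s].d, P);
    };

    const int kept = iter / thin, P_out = 2 * K + S * K;
    List out(chains);

    for (int c = 0; c < chains; ++c) {
        XRng rng = make_rng(seed, c);

        std::vector<double> mu(K), sig(K);
        std::vector<std::vector<double>> th(S, std::vector<double>(K));
        for (int k = 0; k < K; ++k) {
            mu[k] = m0[k] + 0.5 * s0[k] * rng.norm();
            sig[k] = 0.05 + std::fabs(0.3 * tau[k] * rng.norm());
        }
        for (int s = 0; s < S; ++s) {
            for (int k = 0; k < K; ++k) th[s][k] = mu[k] + sig[k] * rng.norm();
            if (k_tnd >= 0 && R_finite(dat[s].min_rt))
                th[s][k_tnd] = std::min(th[s][k_tnd],
                                        std::log(0.8 * dat[s].min_rt));
        }
        std::vector<double> ll(S);
        for (int s = 0; s < S; ++s) {
            ll[s] = subj_loglik(s, th[s]);
            int tries = 0;
            while (!std::isfinite(ll[s]) && tries++ < 200) {
                for (int k = 0; k < K; ++k)
                    th[s][k] = m0[k] + 0.1 * s0[k] * rng.norm();
                if (k_tnd >= 0 && R_finite(dat[s].min_rt))
                    th[s][k_tnd] = std::log(0.5 * dat[s].min_rt);
                ll[s] = subj_loglik(s, th[s]);
            }
            if (!std::isfinite(ll[s]))
                stop("could not find a finite-likelihood initialization for subject %d",
                     s + 1);
        }

        std::vector<std::vector<double>> lstep(S, std::vector<double>(K,
                                               std::log(init_step)));
        std::vector<double> hstep(K, std::log(0.3));
        std::vector<double> astep_mu(K, std::log(0.1));
        std::vector<double> astep_sig(K, std::log(0.1));
        NumericMatrix draws(kept, P_out);
        int row = 0;

        for (int it = 0; it < warmup + iter; ++it) {
            bool adapting = it < warmup;
            double gam = std::min(0.6, 3.0 / std::sqrt((double)it + 3.0));
            for (int s = 0; s < S; ++s) {
                std::vector<double> prop = th[s];
                for (int k = 0; k < K; ++k) {
                    double old = prop[k];
                    prop[k] = old + std::exp(lstep[s][k]) * rng.norm();
                    double lp = subj_loglik(s, prop);
                    double dpost = lp - ll[s] +
                        dnorm_log(prop[k], mu[k], sig[k]) -
                        dnorm_log(old, mu[k], sig[k]);
                    double acc;
                    if (std::isfinite(dpost) && std::log(rng.unif()) < dpost) {
                        th[s][k] = prop[k]; ll[s] = lp; acc = 1.0;
                    } else {
                        prop[k] = old; acc = 0.0;
                    }
                    if (adapting) lstep[s][k] += gam * (acc - 0.44);
                }
            }
            for (int k = 0; k < K; ++k) {
                // conjugate Gibbs for the group mean
                double sum = 0.0;
                for (int s = 0; s < S; ++s) sum += th[s][k];
                double prec = S / (sig[k] * sig[k]) + 1.0 / (s0[k] * s0[k]);
                double mean = (sum / (sig[k] * sig[k]) +
                               m0[k] / (s0[k] * s0[k])) / prec;
                mu[k] = mean + rng.norm() / std::sqrt(prec);
                // adaptive MH on log sigma, half-Normal(tau) prior
                double ssq = 0.0;
                for (int s = 0; s < S; ++s) {
                    double dth = th[s][k] - mu[k];
                    ssq += dth * dth;
                }
                auto lp_sig = [&](double sg) {
                    return -(double)S * std::log(sg) - ssq / (2.0 * sg * sg)
                           - sg * sg / (2.0 * tau[k] * tau[k])
                           + std::log(sg); // Jacobian of the log transform
                };
                double lsig = std::log(sig[k]);
                double lsigp = lsig + std::exp(hstep[k]) * rng.norm();
                double dpost = lp_sig(std::exp(lsigp)) - lp_sig(sig[k]);
                double acc = 0.0;
                if (std::isfinite(dpost) && std::log(rng.unif()) < dpost) {
                    sig[k] = std::exp(lsigp); acc = 1.0;
                }
                if (adapting) hstep[k] += gam * (acc - 0.44);
            }
            // Interweaved non-centered updates: move (mu_k, sigma_k) with
            // the subjects' standardized residuals held fixed, translating /
            // rescaling all subject values jointly.  This decouples the
            // hyperparameters from the subject level when the likelihood is
            // weak and is essential for adequate mixing of the group level.
            for (int k = 0; k < K; ++k) {
                // location move: th_s -> th_s + (mu' - mu)
                double dmu = std::exp(astep_mu[k]) * rng.norm();
                double mup = mu[k] + dmu;
                double dll = 0.0;
                std::vector<double> llp(S);
                std::vector<double> thp_k(S);
                for (int s = 0; s < S; ++s) {
                    std::vector<double> prop = th[s];
                    prop[k] += dmu;
                    thp_k[s] = prop[k];
                    llp[s] = subj_loglik(s, prop);
                    dll += llp[s] - ll[s];
                }
                double dpost = dll + dnorm_log(mup, m0[k], s0[k]) -
                               dnorm_log(mu[k], m0[k], s0[k]);
                double acc = 0.0;
                if (std::isfinite(dpost) && std::log(rng.unif()) < dpost) {
                    mu[k] = mup;
                    for (int s = 0; s < S; ++s) {
                        th[s][k] = thp_k[s]; ll[s] = llp[s];
                    }
                    acc = 1.0;
                }
                if (adapting) astep_mu[k] += gam * (acc - 0.35);
                // scale move: th_s -> mu + (sig'/sig) * (th_s - mu)
                double lsigp = std::log(sig[k]) +
                               std::exp(astep_sig[k]) * rng.norm();
                double sigp = std::exp(lsigp), ratio = sigp / sig[k];
                dll = 0.0;
                for (int s = 0; s < S; ++s) {
                    std::vector<double> prop = th[s];
                    prop[k] = mu[k] + ratio * (prop[k] - mu[k]);
                    thp_k[s] = prop[k];
                    llp[s] = subj_loglik(s, prop);
                    dll += llp[s] - ll[s];
                }
                dpost = dll - sigp * sigp / (2.0 * tau[k] * tau[k]) +
                        std::log(sigp) +
                        sig[k] * sig[k] / (2.0 * tau[k] * tau[k]) -
                        std::log(sig[k]);
                acc = 0.0;
                if (std::isfinite(dpost) && std::log(rng.unif()) < dpost) {
                    sig[k] = sigp;
                    for (int s = 0; s < S; ++s) {
                        th[s][k] = thp_k[s]; ll[s] = llp[s];
                    }
                    acc = 1.0;
                }
                if (adapting) astep_sig[k] += gam * (acc - 0.35);
            }
            if (!adapting && (it - warmup) % thin == 0 && row < kept) {
                int col = 0;
                for (int k = 0; k < K; ++k) draws(row, col++) = mu[k];
                for (int k = 0; k < K; ++k) draws(row, col++) = sig[k];
                for (int s = 0; s < S; ++s)
                    for (int k = 0; k < K; ++k)
                        draws(row, col++) = to_natural(th[s][k], trans[k]);
                ++row;
            }
            if (it % 256 == 0) Rcpp::checkUserInterrupt();
        }
        out[c] = draws;
    }
    return out;
}
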