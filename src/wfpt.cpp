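#include "rlddm_core.h"
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_wfpt_logd(NumericVector rt, double boundary, double t_nd,
                            double z_frac, double drift, bool upper,
                            double eps = 1e-10) {
    int n = rt.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i)
        out[i] = wfpt_log(rt[i] - t_nd, drift, boundary, z_frac, upper, eps);
    return out;
}

static SubjData as_subjdata(const List &s, IntegerVector &ty, IntegerVector &tt,
                            IntegerVector &ch, NumericVector &rt,
                            NumericVector &re, IntegerVector &use) {
    ty = s["type"]; tt = s["tt"]; ch = s["choice"]; rt = s["rt"]; re = s["reinf"];
    SubjData d;
    d.n = ty.size();
    d.type = INTEGER(ty); d.tt = INTEGER(tt); d.choice = INTEGER(ch);
    d.rt = REAL(rt); d.reinf = REAL(re);
    d.use = nullptr;
    if (s.containsElementNamed("use")) {
        use = s["use"];
        if (use.size() == d.n) d.use = INTEGER(use);
    }
    return d;
}

// [[Rcpp::export]]
NumericVector cpp_session_loglik(List subject, NumericVector canon,
                                 bool drpow, bool bspow, bool per_trial) {
    IntegerVector ty, tt, ch, use; NumericVector rt, re;
    SubjData d = as_subjdata(subject, ty, tt, ch, rt, re, use);
    Pars P = make_pars(REAL(canon), drpow, bspow);
    if (per_trial) {
        NumericVector out(d.n);
        session_ll(d, P, REAL(out));
        return out;
    }
    return NumericVector::create(session_ll(d, P));
}

// Per-trial log densities for a matrix of parameter draws (rows = draws,
// cols = canonical slots); used for held-out ELPD evaluation.
// [[Rcpp::export]]
NumericMatrix cpp_pointwise_loglik(List subject, NumericMatrix draws,
                                   bool drpow, bool bspow) {
    IntegerVector ty, tt, ch, use; NumericVector rt, re;
    SubjData d = as_subjdata(subject, ty, tt, ch, rt, re, use);
    int nd = draws.nrow();
    NumericMatrix out(nd, d.n);
    std::vector<double> buf(d.n);
    double canon[6];
    for (int j = 0; j < nd; ++j) {
        for (int k = 0; k < 6; ++k) canon[k] = draws(j, k);
        Pars P = make_pars(canon, drpow, bspow);
        session_ll(d, P, buf.data());
        for (int i = 0; i < d.n; ++i) out(j, i) = buf[i];
    }
    return out;
}

// Simulate one behavioural session on a schedule.  Outcomes follow the task
// contingencies: on reward trials the better option wins with probability
// good_prob (worse with 1 - good_prob); on loss trials the better option
// loses with 1 - good_prob (worse with good_prob); neutral trials pay 0.
// First-passage times exceeding the response window are censored as omitted.
// [[Rcpp::export]]
List cpp_sim_session(IntegerVector type, IntegerVector tt,
                     NumericVector good_prob, NumericVector canon,
                     bool drpow, bool bspow, double rt_max, double dt,
                     double seed) {
    int n = type.size();
    Pars P = make_pars(REAL(canon), drpow, bspow);
    XRng rng = make_rng(seed);
    IntegerVector choice(n);
    NumericVector rt(n), reinf(n);
    double Qu[3] = {0, 0, 0}, Ql[3] = {0, 0, 0};
    double tmax = rt_max - P.t_nd;
    for (int i = 0; i < n; ++i) {
        int ty = type[i], t = tt[i];
        double qdiff = (ty == 1) ? 0.4 : (Qu[ty] - Ql[ty]);
        double v = trial_drift(P, qdiff, t);
        double a = trial_boundary(P, t);
        FPT f = (tmax > 0.0)
                    ? sim_fpt_bridge(v, a, 0.5, tmax, dt, rng)
                    : FPT{0, 0.0};
        if (f.hit == 0) {
            choice[i] = -1; rt[i] = NA_REAL; reinf[i] = NA_REAL;
            continue;
        }
        int ch = f.hit == 1 ? 1 : 0;
        choice[i] = ch;
        rt[i] = f.t + P.t_nd;
        double r = 0.0;
        if (ty == 0) {          // reward trial
            double pw = ch == 1 ? good_prob[i] : 1.0 - good_prob[i];
            r = (rng.unif() < pw) ? 1.0 : 0.0;
        } else if (ty == 2) {   // loss trial
            double pl = ch == 1 ? 1.0 - good_prob[i] : good_prob[i];
            r = (rng.unif() < pl) ? -1.0 : 0.0;
        }
        reinf[i] = r;
        if (ty != 1) {
            if (ch == 1) Qu[ty] += P.alpha * (r - Qu[ty]);
            else         Ql[ty] += P.alpha * (r - Ql[ty]);
        }
    }
    return List::create(_["choice"] = choice, _["rt"] = rt,
                        _["reinf"] = reinf);
}

// Brute-force first-passage oracle: plain Euler-Maruyama paths with unit
// noise; returns one row per path (hit, decision time + t_nd).
// [[Rcpp::export]]
NumericMatrix cpp_oracle_fpt(double drift, double boundary, double z_frac,
                             double t_nd, int n_paths, double dt,
                             double t_max, double seed) {
    XRng rng = make_rng(seed);
    NumericMatrix out(n_paths, 2);
    for (int i = 0; i < n_paths; ++i) {
        FPT f = sim_fpt_euler(drift, boundary, z_frac, t_max, dt, rng);
        out(i, 0) = f.hit;
        out(i, 1) = f.hit == 0 ? NA_REAL : f.t + t_nd;
    }
    return out;
}

// Single first-passage draws with the bridge-corrected scheme (exposed for
// property tests of the behavioural simulator).
// [[Rcpp::export]]
NumericMatrix cpp_sim_fpt(double drift, double boundary, double z_frac,
                          int n_paths, double dt, double t_max, double seed) {
    XRng rng = make_rng(seed);
    NumericMatrix out(n_paths, 2);
    for (int i = 0; i < n_paths; ++i) {
        FPT f = sim_fpt_bridge(drift, boundary, z_frac, t_max, dt, rng);
        out(i, 0) = f.hit;
        out(i, 1) = f.hit == 0 ? NA_REAL : f.t;
    }
    return out;
}
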