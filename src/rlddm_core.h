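#ifndef RLDDM_CORE_H
#define RLDDM_CORE_H

#include <Rcpp.h>
#include <cmath>
#include <random>

// ---------------------------------------------------------------------------
// Wiener first passage time density (unit diffusion coefficient).
//
// wfpt_log_lower() evaluates the log joint density of absorption at the LOWER
// boundary at decision time t (response time minus non-decision time), for
// drift v, boundary separation a and relative starting point w (fraction of a
// measured from the lower boundary).  The density of the normalized process
// (a = 1, v = 0) is evaluated with the classic dual series: a small-time
// expansion over mirrored starting points and a large-time Fourier sine
// series, choosing whichever needs fewer terms for truncation error below
// `eps` (on the normalized density; absolute error after the 1/a^2 rescaling
// is smaller still for a >= 1).
// ---------------------------------------------------------------------------

inline double wfpt_log_norm(double tt, double w, double eps) {
    // log f(tt | v=0, a=1, w); tt is normalized time t/a^2
    double kl, ks;
    if (M_PI * tt * eps < 1.0) {
        kl = std::sqrt(-2.0 * std::log(M_PI * tt * eps) / (M_PI * M_PI * tt));
        kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
    } else {
        kl = 1.0 / (M_PI * std::sqrt(tt));
    }
    if (2.0 * std::sqrt(2.0 * M_PI * tt) * eps < 1.0) {
        ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * std::sqrt(2.0 * M_PI * tt) * eps));
        ks = std::max(ks, std::sqrt(tt) + 1.0);
    } else {
        ks = 2.0;
    }
    double p = 0.0;
    if (ks < kl) {                       // small-time expansion
        int K = (int)std::ceil(ks);
        int lo = -(int)std::floor((K - 1) / 2.0);
        int hi = (int)std::ceil((K - 1) / 2.0);
        for (int k = lo; k <= hi; ++k) {
            double u = w + 2.0 * k;
            p += u * std::exp(-u * u / (2.0 * tt));
        }
        p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
    } else {                             // large-time expansion
        int K = (int)std::ceil(kl);
        if (w == 0.5) {
            // sin(k*pi/2) vanishes for even k and alternates for odd k
            double sign = 1.0;
            for (int k = 1; k <= K; k += 2) {
                p += sign * k * std::exp(-k * k * M_PI * M_PI * tt / 2.0);
                sign = -sign;
            }
        } else {
            for (int k = 1; k <= K; ++k) {
                p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
                     std::sin(k * M_PI * w);
            }
        }
        p *= M_PI;
    }
    if (p <= 0.0 || !std::isfinite(p)) return -INFINITY;
    return std::log(p);
}

inline double wfpt_log_lower(double t, double v, double a, double w,
                             double eps = 1e-10) {
    if (!(t > 0.0) || !(a > 0.0) || !(w > 0.0) || !(w < 1.0)) return -INFINITY;
    double tt = t / (a * a);
    double lp = wfpt_log_norm(tt, w, eps);
    if (!std::isfinite(lp)) return -INFINITY;
    return lp - v * a * w - v * v * t / 2.0 - 2.0 * std::log(a);
}

// joint log density; upper-boundary density by reflection (v -> -v, w -> 1-w)
inline double wfpt_log(double t, double v, double a, double w, bool upper,
                       double eps = 1e-10) {
    return upper ? wfpt_log_lower(t, -v, a, 1.0 - w, eps)
                 : wfpt_log_lower(t, v, a, w, eps);
}

// ---------------------------------------------------------------------------
// Trial-level model structure shared by the likelihood and the simulators.
// Canonical parameter vector (natural scale), fixed slot order:
//   [0] alpha  learning rate
//   [1] nu     drift-rate scalar (set to 1 when a variant drops it)
//   [2] bnd    boundary separation (a, or baseline bb for power variants)
//   [3] bp     boundary-separation power
//   [4] p      drift-rate power
//   [5] t_nd   non-decision time (s)
// Variant flags: drpow replaces the constant drift scaling by (t/10)^p,
// bspow makes the boundary bb * (t/10)^bp; t is the 1-based within-type index.
// ---------------------------------------------------------------------------

struct Pars {
    double alpha, nu, bnd, bp, p, t_nd;
    bool drpow, bspow;
};

inline Pars make_pars(const double *c, bool drpow, bool bspow) {
    Pars P;
    P.alpha = c[0]; P.nu = c[1]; P.bnd = c[2];
    P.bp = c[3]; P.p = c[4]; P.t_nd = c[5];
    P.drpow = drpow; P.bspow = bspow;
    return P;
}

struct SubjData {
    int n;
    const int *type;     // 0 reward, 1 neutral, 2 loss
    const int *tt;       // within-type trial index, 1-based
    const int *choice;   // 1 upper/better, 0 lower/worse, -1 omitted
    const double *rt;    // seconds (NA when omitted)
    const double *reinf; // +1/0 reward, -1/0 loss, 0 neutral (NA when omitted)
    const int *use;      // likelihood mask (nullptr = all trials); masked
                         // trials still drive the value updates, so held-out
                         // outcomes remain part of the observed learning path
};

// log(t/10) for 1-based within-type indices (exp(b*logt) is cheaper than
// pow(t/10, b) and t never exceeds a session's per-type trial count)
inline double log_t10(int t) {
    static const int NT = 512;
    static double tab[NT + 1];
    static bool init = false;
    if (!init) {
        for (int i = 1; i <= NT; ++i) tab[i] = std::log(i / 10.0);
        init = true;
    }
    return (t >= 1 && t <= NT) ? tab[t] : std::log(t / 10.0);
}

inline double trial_drift(const Pars &P, double qdiff, int t) {
    double v = qdiff * P.nu;
    if (P.drpow) v *= std::exp(P.p * log_t10(t));
    return v;
}

inline double trial_boundary(const Pars &P, int t) {
    return P.bspow ? P.bnd * std::exp(P.bp * log_t10(t)) : P.bnd;
}

// Sequential replay of a session: value learning + WFPT log likelihood.
// Omitted trials contribute nothing and leave Q untouched; neutral trials use
// the fixed value difference 0.4 and are never updated.  If `per_trial` is
// non-null it receives each trial's log density (NA for omitted trials).
inline double session_ll(const SubjData &d, const Pars &P,
                         double *per_trial = nullptr) {
    double Qu[3] = {0.0, 0.0, 0.0}, Ql[3] = {0.0, 0.0, 0.0};
    double ll = 0.0;
    for (int i = 0; i < d.n; ++i) {
        int ty = d.type[i], t = d.tt[i], ch = d.choice[i];
        double qdiff = (ty == 1) ? 0.4 : (Qu[ty] - Ql[ty]);
        if (ch >= 0) {
            double v = trial_drift(P, qdiff, t);
            double a = trial_boundary(P, t);
            double l = wfpt_log(d.rt[i] - P.t_nd, v, a, 0.5, ch == 1);
            if (per_trial) per_trial[i] = l;
            if (!d.use || d.use[i]) ll += l;
            if (ty != 1 && std::isfinite(d.reinf[i])) {
                double r = d.reinf[i];
                if (ch == 1) Qu[ty] += P.alpha * (r - Qu[ty]);
                else         Ql[ty] += P.alpha * (r - Ql[ty]);
            }
        } else if (per_trial) {
            per_trial[i] = NA_REAL;
        }
        if (!per_trial && !std::isfinite(ll)) return -INFINITY;
    }
    return ll;
}

// ---------------------------------------------------------------------------
// First-passage simulation.
// sim_fpt_bridge: Euler scheme augmented with Brownian-bridge crossing
// probabilities within each step (removes the leading discretization bias),
// used by the behavioural simulator.  sim_fpt_euler: plain Euler-Maruyama,
// kept deliberately naive as an independent brute-force oracle.
// Returns hit (+1 upper, -1 lower, 0 censored) and the decision time.
// ---------------------------------------------------------------------------

struct FPT { int hit; double t; };

// xoshiro256+ with splitmix64 seeding and Marsaglia-polar normals: fast,
// fully deterministic and platform-independent (unlike the standard
// library's distribution objects)
struct XRng {
    std::uint64_t s[4];
    bool has_spare = false;
    double spare = 0.0;
    explicit XRng(std::uint64_t seed) {
        std::uint64_t x = seed;
        for (int i = 0; i < 4; ++i) {
            x += 0x9E3779B97F4A7C15ULL;
            std::uint64_t z = x;
            z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
            z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
            s[i] = z ^ (z >> 31);
        }
    }
    static inline std::uint64_t rotl(std::uint64_t x, int k) {
        return (x << k) | (x >> (64 - k));
    }
    inline std::uint64_t next() {
        std::uint64_t r = s[0] + s[3];
        std::uint64_t t = s[1] << 17;
        s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
        s[2] ^= t; s[3] = rotl(s[3], 45);
        return r;
    }
    inline double unif() {  // (0, 1)
        return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
    }
    inline double norm() {
        if (has_spare) { has_spare = false; return spare; }
        double u, v, q;
        do {
            u = 2.0 * unif() - 1.0;
            v = 2.0 * unif() - 1.0;
            q = u * u + v * v;
        } while (q >= 1.0 || q == 0.0);
        double f = std::sqrt(-2.0 * std::log(q) / q);
        spare = v * f; has_spare = true;
        return u * f;
    }
};

inline FPT sim_fpt_bridge(double v, double a, double w, double tmax,
                          double dt, XRng &rng) {
    double x = w * a, t = 0.0, sdt = std::sqrt(dt);
    while (t < tmax) {
        double xn = x + v * dt + sdt * rng.norm();
        t += dt;
        if (xn >= a) return {1, t};
        if (xn <= 0.0) return {-1, t};
        if (rng.unif() < std::exp(-2.0 * (a - x) * (a - xn) / dt))
            return {1, t};
        if (rng.unif() < std::exp(-2.0 * x * xn / dt)) return {-1, t};
        x = xn;
    }
    return {0, tmax};
}

inline FPT sim_fpt_euler(double v, double a, double w, double tmax,
                         double dt, XRng &rng) {
    double x = w * a, t = 0.0, sdt = std::sqrt(dt);
    while (t < tmax) {
        x += v * dt + sdt * rng.norm();
        t += dt;
        if (x >= a) return {1, t};
        if (x <= 0.0) return {-1, t};
    }
    return {0, tmax};
}

inline XRng make_rng(double seed, int stream = 0) {
    std::uint64_t s = (std::uint64_t)seed;
    s = s * 2654435761ULL + 0x9E3779B97F4A7C15ULL * (std::uint64_t)(stream + 1);
    return XRng(s);
}

#endif
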