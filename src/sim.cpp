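#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Portable RNG.
//
// mt19937_64 output is fully specified by the C++ standard, but the
// distribution adaptors (normal_distribution etc.) are not; all transforms
// are therefore implemented explicitly so that a given seed yields the same
// trajectory on any conforming compiler.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
    x += 0x9E3779B97F4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
}

struct RNG {
    std::mt19937_64 eng;
    explicit RNG(uint64_t seed) : eng(splitmix64(seed)) {}
    // uniform on (0, 1), 53-bit resolution, never exactly 0 or 1
    double unif() {
        return (static_cast<double>(eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
    }
    double expo(double rate) { return -std::log(unif()) / rate; }
    double norm() {
        double u1 = unif(), u2 = unif();
        return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
    }
    int binom_half(int n) {  // Binomial(n, 1/2)
        int k = 0;
        for (int i = 0; i < n; ++i) if (unif() < 0.5) ++k;
        return k;
    }
};

// per-cell stream: deterministic in (root seed, cell id), independent of the
// order in which cells of a colony are simulated
static inline uint64_t cell_stream(int rootSeed, int cellId) {
    return splitmix64(splitmix64(static_cast<uint64_t>(static_cast<uint32_t>(rootSeed)))
                      + static_cast<uint64_t>(static_cast<uint32_t>(cellId)));
}

// ---------------------------------------------------------------------------
// Level 1: transcriptional GRN (six species, Shea-Ackers production terms)
// species order throughout: R, T, G, P, X, N
// ---------------------------------------------------------------------------

static inline void grn_production(const double* s, const double* p,
                                  const double* kd, double* out) {
    const double R = s[0], T = s[1], G = s[2], P = s[3], N = s[5];
    out[0] = kd[0] * (p[0] * R + p[1] * N) / (1.0 + p[0] * R + p[1] * N);
    out[1] = kd[1] * (p[2] * T + p[3] * G + p[4] * N / (p[5] + P)) /
             (1.0 + p[2] * T + p[3] * G + p[4] * N + p[6] * P);
    out[2] = kd[2] * (p[7] * T + p[8] * N / (p[9] + P)) /
             (1.0 + p[7] * T + p[8] * N + p[10] * P);
    out[3] = kd[3] * (p[11] * P) / (1.0 + p[11] * P + p[12] * R * G * T);
    out[4] = kd[4] * 1.0 / (1.0 + p[13] * T + p[14] * G);
    out[5] = kd[5] * p[15] / (1.0 + N);
}

static inline void grn_degradation(const double* s, const double* g, double* out) {
    for (int i = 0; i < 5; ++i) out[i] = g[i] * s[i];
    out[5] = 0.0;  // Notch signal has no decay channel
}

// SSA over [t0, t1] with a knockdown-factor switch at `onset` (use onset
// outside the interval for a constant schedule). Records (t, state) rows into
// `rec` (stride 7) if non-null: initial state, every event, final stamp at t1.
static void grn_ssa(double* s, double t0, double t1,
                    const double* p, const double* g,
                    const double* kdPre, const double* kdPost, double onset,
                    RNG& rng, std::vector<double>* rec) {
    double t = t0;
    double prod[6], deg[6];
    if (rec) {
        rec->push_back(t);
        for (int i = 0; i < 6; ++i) rec->push_back(s[i]);
    }
    while (t < t1) {
        const double* kd = (t >= onset) ? kdPost : kdPre;
        double barrier = t1;
        if (t < onset && onset < t1) barrier = onset;
        grn_production(s, p, kd, prod);
        grn_degradation(s, g, deg);
        double a0 = 0.0;
        for (int i = 0; i < 6; ++i) a0 += prod[i] + deg[i];
        if (a0 <= 0.0) { t = barrier; continue; }
        double dt = rng.expo(a0);
        if (t + dt > barrier) { t = barrier; continue; }  // memoryless restart
        t += dt;
        double u = rng.unif() * a0;
        int sp = -1, dir = 0;
        double acc = 0.0;
        for (int i = 0; i < 6 && sp < 0; ++i) {
            acc += prod[i];
            if (u < acc) { sp = i; dir = +1; }
        }
        for (int i = 0; i < 6 && sp < 0; ++i) {
            acc += deg[i];
            if (u < acc) { sp = i; dir = -1; }
        }
        if (sp < 0) { sp = 5; dir = +1; }  // numerical edge: last channel
        s[sp] += dir;
        if (rec) {
            rec->push_back(t);
            for (int i = 0; i < 6; ++i) rec->push_back(s[i]);
        }
    }
    if (rec) {
        rec->push_back(t1);
        for (int i = 0; i < 6; ++i) rec->push_back(s[i]);
    }
}

// ---------------------------------------------------------------------------
// Level 2: epigenetic Bcl11b regulatory region (C, I, O site counts)
// nine transition channels of the three-state site model
// ---------------------------------------------------------------------------

// epi parameter order: k1, k2, k3, alpha, beta, gammaM, delta, epsilon
static const int CH_SRC[9] = {2, 1, 0, 1, 2, 1, 1, 0, 1};  // 0=C, 1=I, 2=O
static const int CH_DST[9] = {1, 0, 1, 2, 1, 0, 2, 1, 0};

// Attempt-rate scheme: each channel's weight is the rate at which the whole
// region attempts that transition; a uniformly chosen site must match the
// source state (acceptance probability source/S), and mediated channels
// additionally require a uniformly chosen mediator site to match
// (mediator/S). The effective propensity is therefore weight times the
// state fraction(s), NOT weight times the raw count — the region remodels
// on a slow (days) timescale regardless of the site total.
static inline double epi_propensities(const double* cio, double S,
                                      double X, double R, double N,
                                      const double* e, double* w) {
    const double fC = cio[0] / S, fI = cio[1] / S, fO = cio[2] / S;
    const double open_in = e[1] * N + e[2] * R;
    w[0] = e[0] * X * fO;      // O -> I   (X-driven closing)
    w[1] = e[0] * X * fI;      // I -> C
    w[2] = open_in * fC;       // C -> I   (Runx1/Notch-driven opening)
    w[3] = open_in * fI;       // I -> O
    w[4] = e[3] * fO * fC;     // O -> I   mediated by C
    w[5] = e[4] * fI * fC;     // I -> C   mediated by C
    w[6] = e[5] * fI * fO;     // I -> O   mediated by O
    w[7] = e[6] * fC * fO;     // C -> I   mediated by O
    w[8] = e[7] * fI * fI;     // I -> C   mediated by I
    double a0 = 0.0;
    for (int i = 0; i < 9; ++i) a0 += w[i];
    return a0;
}

// SSA over [t0, t1] with inputs (X, R, N) piecewise-constant from a GRN
// trajectory (stride 7: t, R, T, G, P, X, N). Records (t, C, I, O) rows if
// rec != null, up to maxRecord event rows (simulation always continues).
static long epi_ssa(double* cio, double S, const double* e,
                    const double* traj, size_t nrow,
                    double t0, double t1, RNG& rng,
                    std::vector<double>* rec, long maxRecord) {
    double t = t0;
    long nevents = 0;
    // locate first trajectory row applying at t0
    size_t idx = 0;
    while (idx + 1 < nrow && traj[7 * (idx + 1)] <= t0) ++idx;
    double w[9];
    if (rec) {
        rec->push_back(t); rec->push_back(cio[0]);
        rec->push_back(cio[1]); rec->push_back(cio[2]);
    }
    while (t < t1) {
        double tNext = (idx + 1 < nrow) ? traj[7 * (idx + 1)] : t1;
        if (tNext > t1) tNext = t1;
        const double X = traj[7 * idx + 5];
        const double R = traj[7 * idx + 1];
        const double N = traj[7 * idx + 6];
        double a0 = epi_propensities(cio, S, X, R, N, e, w);
        if (a0 <= 0.0) {
            t = tNext;
            if (idx + 1 < nrow && tNext < t1) ++idx;
            continue;
        }
        double dt = rng.expo(a0);
        if (t + dt > tNext) {  // input changes: restart draw (memoryless)
            t = tNext;
            if (idx + 1 < nrow && tNext < t1) ++idx;
            continue;
        }
        t += dt;
        double u = rng.unif() * a0;
        int ch = 8;
        double acc = 0.0;
        for (int i = 0; i < 9; ++i) {
            acc += w[i];
            if (u < acc) { ch = i; break; }
        }
        cio[CH_SRC[ch]] -= 1.0;
        cio[CH_DST[ch]] += 1.0;
        ++nevents;
        if (rec && nevents <= maxRecord) {
            rec->push_back(t); rec->push_back(cio[0]);
            rec->push_back(cio[1]); rec->push_back(cio[2]);
        }
    }
    if (rec) {
        rec->push_back(t1); rec->push_back(cio[0]);
        rec->push_back(cio[1]); rec->push_back(cio[2]);
    }
    return nevents;
}

// ---------------------------------------------------------------------------
// Level 3 primitives: division times, region inheritance
// ---------------------------------------------------------------------------

static inline double draw_division(int generation, const double* mu,
                                   const double* sd, RNG& rng) {
    int gi = generation < 4 ? generation : 4;
    double d;
    do { d = mu[gi] + sd[gi] * rng.norm(); } while (d <= 0.0);
    return d;
}

// X = 0 at division: all C -> I, each I -> I or O with probability 1/2 each,
// all O -> O; otherwise sites are copied verbatim.
static inline void inherit(double* cio, double motherX, RNG& rng) {
    if (motherX > 0.0) return;
    int I = static_cast<int>(cio[1]);
    int toO = rng.binom_half(I);
    double O = cio[2] + toO;
    double C = 0.0;
    double Inew = cio[0] + (I - toO);
    cio[0] = C; cio[1] = Inew; cio[2] = O;
}

// ---------------------------------------------------------------------------
// Exported interface
// ---------------------------------------------------------------------------

static NumericMatrix as_traj_matrix(const std::vector<double>& rec, int ncol,
                                    const CharacterVector& names) {
    size_t n = rec.size() / ncol;
    NumericMatrix m(n, ncol);
    for (size_t r = 0; r < n; ++r)
        for (int c = 0; c < ncol; ++c)
            m(r, c) = rec[r * ncol + c];
    colnames(m) = names;
    return m;
}

static const CharacterVector GRN_COLS =
    CharacterVector::create("time_h", "R", "T", "G", "P", "X", "N");
static const CharacterVector EPI_COLS =
    CharacterVector::create("time_h", "C", "I", "O");

// [[Rcpp::export]]
List grnPropensitiesCpp(NumericVector state, NumericVector p,
                        NumericVector gamma, NumericVector kd) {
    double prod[6], deg[6];
    grn_production(state.begin(), p.begin(), kd.begin(), prod);
    grn_degradation(state.begin(), gamma.begin(), deg);
    NumericVector pr(6), dg(6);
    for (int i = 0; i < 6; ++i) { pr[i] = prod[i]; dg[i] = deg[i]; }
    CharacterVector nm = CharacterVector::create("R", "T", "G", "P", "X", "N");
    pr.names() = nm; dg.names() = nm;
    return List::create(_["production"] = pr, _["degradation"] = dg);
}

// [[Rcpp::export]]
NumericMatrix simulateGRNCpp(NumericVector state0, double t0, double t1,
                             NumericVector p, NumericVector gamma,
                             NumericVector kdPre, NumericVector kdPost,
                             double onset, int seed) {
    double s[6];
    for (int i = 0; i < 6; ++i) s[i] = state0[i];
    RNG rng(splitmix64(static_cast<uint64_t>(static_cast<uint32_t>(seed))) ^ 0xA5A5A5A5ULL);
    std::vector<double> rec;
    grn_ssa(s, t0, t1, p.begin(), gamma.begin(), kdPre.begin(), kdPost.begin(),
            onset, rng, &rec);
    return as_traj_matrix(rec, 7, GRN_COLS);
}

// [[Rcpp::export]]
NumericVector epiChannelPropensitiesCpp(NumericVector region, double S,
                                        double X, double R, double N,
                                        NumericVector e) {
    double w[9];
    double cio[3] = {region[0], region[1], region[2]};
    epi_propensities(cio, S, X, R, N, e.begin(), w);
    NumericVector out(9);
    for (int i = 0; i < 9; ++i) out[i] = w[i];
    return out;
}

// [[Rcpp::export]]
List evolveRegionCpp(NumericVector region, NumericMatrix grnTraj,
                     double t0, double t1, NumericVector e, double S,
                     int seed, bool record, double maxRecord) {
    double cio[3] = {region[0], region[1], region[2]};
    RNG rng(splitmix64(static_cast<uint64_t>(static_cast<uint32_t>(seed))) ^ 0x5A5A5A5AULL);
    std::vector<double> rec;
    std::vector<double> traj(grnTraj.nrow() * 7);
    for (int r = 0; r < grnTraj.nrow(); ++r)
        for (int c = 0; c < 7; ++c) traj[r * 7 + c] = grnTraj(r, c);
    long nev = epi_ssa(cio, S, e.begin(), traj.data(), grnTraj.nrow(), t0, t1,
                       rng, record ? &rec : nullptr,
                       static_cast<long>(maxRecord));
    IntegerVector fin = IntegerVector::create(
        _["C"] = static_cast<int>(cio[0]),
        _["I"] = static_cast<int>(cio[1]),
        _["O"] = static_cast<int>(cio[2]));
    List out = List::create(_["final"] = fin, _["nEvents"] = static_cast<double>(nev));
    if (record) out["trajectory"] = as_traj_matrix(rec, 4, EPI_COLS);
    return out;
}

// [[Rcpp::export]]
IntegerVector inheritRegionCpp(NumericVector region, double motherX, int seed) {
    double cio[3] = {region[0], region[1], region[2]};
    RNG rng(splitmix64(static_cast<uint64_t>(static_cast<uint32_t>(seed))) ^ 0x3C3C3C3CULL);
    inherit(cio, motherX, rng);
    return IntegerVector::create(_["C"] = static_cast<int>(cio[0]),
                                 _["I"] = static_cast<int>(cio[1]),
                                 _["O"] = static_cast<int>(cio[2]));
}

// [[Rcpp::export]]
NumericVector drawDivisionTimesCpp(int generation, NumericVector mu,
                                   NumericVector sigma, int n, int seed) {
    RNG rng(splitmix64(static_cast<uint64_t>(static_cast<uint32_t>(seed))) ^ 0x77777777ULL);
    NumericVector out(n);
    for (int i = 0; i < n; ++i)
        out[i] = draw_division(generation, mu.begin(), sigma.begin(), rng);
    return out;
}

// Simulate one cell's full lifetime. RNG draw order within the cell's stream:
// region inheritance (non-root), division time, GRN SSA, epigenetic SSA.
// [[Rcpp::export]]
List simulateCellCpp(NumericVector state0, NumericVector motherRegion,
                     double motherX, bool isRoot, int generation,
                     double birth, double horizon,
                     NumericVector p, NumericVector gamma,
                     NumericVector kdPre, NumericVector kdPost, double kdOnset,
                     NumericVector e, double S,
                     NumericVector mu, NumericVector sigma,
                     int rootSeed, int cellId,
                     bool recordGrn, bool recordRegion) {
    RNG rng(cell_stream(rootSeed, cellId));
    double cio[3] = {motherRegion[0], motherRegion[1], motherRegion[2]};
    if (!isRoot) inherit(cio, motherX, rng);
    double tDiv = draw_division(generation, mu.begin(), sigma.begin(), rng);
    double tEnd = birth + tDiv;
    bool divided = true;
    if (tEnd > horizon) { tEnd = horizon; divided = false; }

    double s[6];
    for (int i = 0; i < 6; ++i) s[i] = state0[i];
    std::vector<double> grnRec;
    grn_ssa(s, birth, tEnd, p.begin(), gamma.begin(), kdPre.begin(),
            kdPost.begin(), kdOnset, rng, &grnRec);
    std::vector<double> epiRec;
    epi_ssa(cio, S, e.begin(), grnRec.data(), grnRec.size() / 7, birth, tEnd,
            rng, recordRegion ? &epiRec : nullptr, 2000000L);

    NumericVector fs(6);
    for (int i = 0; i < 6; ++i) fs[i] = s[i];
    fs.names() = CharacterVector::create("R", "T", "G", "P", "X", "N");
    IntegerVector fr = IntegerVector::create(
        _["C"] = static_cast<int>(cio[0]),
        _["I"] = static_cast<int>(cio[1]),
        _["O"] = static_cast<int>(cio[2]));
    List out = List::create(
        _["tDiv"] = tDiv,
        _["end"] = tEnd,
        _["divided"] = divided,
        _["finalState"] = fs,
        _["finalRegion"] = fr);
    if (recordGrn) out["grnTrajectory"] = as_traj_matrix(grnRec, 7, GRN_COLS);
    if (recordRegion) out["regionTrajectory"] = as_traj_matrix(epiRec, 4, EPI_COLS);
    return out;
}
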