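#include <Rcpp.h>
#include <cstring>
#include <cmath>
#include <limits>
#include <vector>
#include <string>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Substitution-matrix lookup: 256x256 table built from a scored matrix with
// single-character dimnames. Unknown characters must be filtered upstream.
// ---------------------------------------------------------------------------
struct SubTable {
    double tab[256][256];
    bool known[256];
    SubTable(const NumericMatrix& sub) {
        std::memset(known, 0, sizeof(known));
        for (int i = 0; i < 256; ++i)
            for (int j = 0; j < 256; ++j) tab[i][j] = NEG_INF;
        CharacterVector rn = rownames(sub), cn = colnames(sub);
        std::vector<unsigned char> ri(sub.nrow()), ci(sub.ncol());
        for (int i = 0; i < sub.nrow(); ++i) {
            ri[i] = (unsigned char) CHAR(STRING_ELT(rn, i))[0];
            known[ri[i]] = true;
        }
        for (int j = 0; j < sub.ncol(); ++j)
            ci[j] = (unsigned char) CHAR(STRING_ELT(cn, j))[0];
        for (int i = 0; i < sub.nrow(); ++i)
            for (int j = 0; j < sub.ncol(); ++j)
                tab[ri[i]][ci[j]] = sub(i, j);
    }
    inline double score(unsigned char a, unsigned char b) const {
        return tab[a][b];
    }
};

// gap of length L costs gap_open + L * gap_extend (Biostrings convention)

// ---------------------------------------------------------------------------
// Global (Needleman-Wunsch) alignment with affine gaps and deterministic
// traceback: at equal score prefer substitution, then gap in `a` (consume b),
// then gap in `b` (consume a).
// States: 0 = M (a_i ~ b_j), 1 = Y (gap in a, consumes b), 2 = X (gap in b).
// ---------------------------------------------------------------------------
struct NWResult {
    double score;
    std::string al_a, al_b;
};

static NWResult nw_core(const std::string& a, const std::string& b,
                        const SubTable& st, double go, double ge,
                        bool traceback) {
    const int n = (int) a.size(), m = (int) b.size();
    const double open1 = go + ge;  // cost of the first gapped position
    const int W = m + 1;
    std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
        Y((n + 1) * W, NEG_INF);
    std::vector<signed char> pM, pX, pY;
    if (traceback) {
        pM.assign((n + 1) * W, -1);
        pX.assign((n + 1) * W, -1);
        pY.assign((n + 1) * W, -1);
    }
    M[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
        Y[j] = -(go + ge * j);
        if (traceback) pY[j] = 1;
    }
    for (int i = 1; i <= n; ++i) {
        X[i * W] = -(go + ge * i);
        if (traceback) pX[i * W] = 2;
    }
    for (int i = 1; i <= n; ++i) {
        const unsigned char ca = (unsigned char) a[i - 1];
        for (int j = 1; j <= m; ++j) {
            const int ij = i * W + j, up = (i - 1) * W + j, lf = ij - 1,
                      dg = up - 1;
            // M: prefer M > Y > X on ties
            double best = M[dg];
            signed char pb = 0;
            if (Y[dg] > best) { best = Y[dg]; pb = 1; }
            if (X[dg] > best) { best = X[dg]; pb = 2; }
            M[ij] = best + st.score(ca, (unsigned char) b[j - 1]);
            if (traceback) pM[ij] = pb;
            // Y: gap in a (consume b_j), move left
            best = M[lf] - open1; pb = 0;
            if (Y[lf] - ge > best) { best = Y[lf] - ge; pb = 1; }
            if (X[lf] - open1 > best) { best = X[lf] - open1; pb = 2; }
            Y[ij] = best;
            if (traceback) pY[ij] = pb;
            // X: gap in b (consume a_i), move up
            best = M[up] - open1; pb = 0;
            if (Y[up] - open1 > best) { best = Y[up] - open1; pb = 1; }
            if (X[up] - ge > best) { best = X[up] - ge; pb = 2; }
            X[ij] = best;
            if (traceback) pX[ij] = pb;
        }
    }
    NWResult res;
    const int endc = n * W + m;
    int state = 0;
    res.score = M[endc];
    if (Y[endc] > res.score) { res.score = Y[endc]; state = 1; }
    if (X[endc] > res.score) { res.score = X[endc]; state = 2; }
    if (traceback) {
        std::string ra, rb;
        int i = n, j = m;
        while (i > 0 || j > 0) {
            const int ij = i * W + j;
            signed char prev;
            if (state == 0) {
                prev = pM[ij];
                ra.push_back(a[i - 1]);
                rb.push_back(b[j - 1]);
                --i; --j;
            } else if (state == 1) {
                prev = pY[ij];
                ra.push_back('-');
                rb.push_back(b[j - 1]);
                --j;
            } else {
                prev = pX[ij];
                ra.push_back(a[i - 1]);
                rb.push_back('-');
                --i;
            }
            state = prev;
        }
        res.al_a.assign(ra.rbegin(), ra.rend());
        res.al_b.assign(rb.rbegin(), rb.rend());
    }
    return res;
}

// identity over alignment columns, excluding terminal-gap overhangs
static double paai_from_alignment(const std::string& aa, const std::string& ab,
                                  int* ncols_out, int* nid_out) {
    const int L = (int) aa.size();
    int fa = -1, la = -1, fb = -1, lb = -1;
    for (int c = 0; c < L; ++c) {
        if (aa[c] != '-') { if (fa < 0) fa = c; la = c; }
        if (ab[c] != '-') { if (fb < 0) fb = c; lb = c; }
    }
    const int from = std::max(fa, fb), to = std::min(la, lb);
    int ncols = 0, nid = 0;
    for (int c = from; c <= to; ++c) {
        ++ncols;
        if (aa[c] == ab[c] && aa[c] != '-') ++nid;
    }
    if (ncols_out) *ncols_out = ncols;
    if (nid_out) *nid_out = nid;
    if (ncols == 0) return 0.0;
    return 100.0 * (double) nid / (double) ncols;
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, NumericMatrix sub,
                  double gap_open, double gap_extend) {
    SubTable st(sub);
    NWResult r = nw_core(a, b, st, gap_open, gap_extend, true);
    int ncols, nid;
    double pct = paai_from_alignment(r.al_a, r.al_b, &ncols, &nid);
    return List::create(_["score"] = r.score, _["aligned_a"] = r.al_a,
                        _["aligned_b"] = r.al_b, _["paai"] = pct,
                        _["aligned_cols"] = ncols, _["identical_cols"] = nid);
}

// [[Rcpp::export]]
NumericVector paai_vec_cpp(std::string query, CharacterVector refs,
                           NumericMatrix sub, double gap_open,
                           double gap_extend) {
    SubTable st(sub);
    NumericVector out(refs.size());
    for (int k = 0; k < refs.size(); ++k) {
        std::string r = as<std::string>(refs[k]);
        if (r == query) { out[k] = 100.0; continue; }
        NWResult res = nw_core(query, r, st, gap_open, gap_extend, true);
        out[k] = paai_from_alignment(res.al_a, res.al_b, NULL, NULL);
    }
    return out;
}

// [[Rcpp::export]]
NumericMatrix paai_matrix_cpp(CharacterVector seqs, NumericMatrix sub,
                              double gap_open, double gap_extend) {
    SubTable st(sub);
    const int n = seqs.size();
    NumericMatrix out(n, n);
    std::vector<std::string> s(n);
    for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
    for (int i = 0; i < n; ++i) {
        out(i, i) = 100.0;
        for (int j = i + 1; j < n; ++j) {
            double pct;
            if (s[i] == s[j]) {
                pct = 100.0;
            } else {
                NWResult r = nw_core(s[i], s[j], st, gap_open, gap_extend, true);
                pct = paai_from_alignment(r.al_a, r.al_b, NULL, NULL);
            }
            out(i, j) = pct;
            out(j, i) = pct;
        }
    }
    return out;
}

// ---------------------------------------------------------------------------
// Smith-Waterman local alignment score (affine gaps), for the all-vs-all
// similarity graph feeding Markov clustering.
// ---------------------------------------------------------------------------
static double sw_core(const std::string& a, const std::string& b,
                      const SubTable& st, double go, double ge) {
    const int n = (int) a.size(), m = (int) b.size();
    const double open1 = go + ge;
    std::vector<double> M(m + 1, 0.0), X(m + 1, NEG_INF), Y(m + 1, NEG_INF);
    double best = 0.0;
    for (int i = 1; i <= n; ++i) {
        double diagM = M[0], diagX = X[0], diagY = Y[0];
        M[0] = 0.0; X[0] = NEG_INF; Y[0] = NEG_INF;
        const unsigned char ca = (unsigned char) a[i - 1];
        for (int j = 1; j <= m; ++j) {
            const double sM = M[j], sX = X[j], sY = Y[j];
            double mm = std::max(std::max(diagM, diagX), diagY);
            if (mm < 0.0) mm = 0.0;  // local restart
            const double nm = mm + st.score(ca, (unsigned char) b[j - 1]);
            const double nx = std::max(std::max(sM - open1, sX - ge),
                                       sY - open1);
            const double ny = std::max(std::max(M[j - 1] - open1,
                                                Y[j - 1] - ge),
                                       X[j - 1] - open1);
            diagM = sM; diagX = sX; diagY = sY;
            M[j] = nm; X[j] = nx; Y[j] = ny;
            if (nm > best) best = nm;
        }
    }
    return best;
}

// [[Rcpp::export]]
double sw_score_cpp(std::string a, std::string b, NumericMatrix sub,
                    double gap_open, double gap_extend) {
    SubTable st(sub);
    return sw_core(a, b, st, gap_open, gap_extend);
}

// [[Rcpp::export]]
NumericMatrix sw_matrix_cpp(CharacterVector seqs, NumericMatrix sub,
                            double gap_open, double gap_extend) {
    SubTable st(sub);
    const int n = seqs.size();
    std::vector<std::string> s(n);
    for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
    NumericMatrix out(n, n);
    for (int i = 0; i < n; ++i) {
        out(i, i) = sw_core(s[i], s[i], st, gap_open, gap_extend);
        for (int j = i + 1; j < n; ++j) {
            double sc = sw_core(s[i], s[j], st, gap_open, gap_extend);
            out(i, j) = sc;
            out(j, i) = sc;
        }
    }
    return out;
}

// ---------------------------------------------------------------------------
// Profile-HMM dynamic programming (Plan7-style, global in model, local in
// sequence via free background-emitting flanks). All scores are log2-odds
// against the background, so flank emissions contribute exactly 0 bits.
//
// logtrans: (M+1) x 7 matrix, rows are nodes 0..M, columns
//   0 MM, 1 MI, 2 MD, 3 IM, 4 II, 5 DM, 6 DD  (log2 probabilities).
// Row 0 holds the begin transitions (B->M1 in MM, B->D1 in MD); row M holds
// the exits (M_M->E in MM, D_M->E in DM).
// logodds_match / logodds_ins: M x 20 log2(e/bg); query symbol -1 ('X')
// emits background (0 bits) in every state.
// ---------------------------------------------------------------------------
static inline double lse2(double x, double y) {
    if (x == NEG_INF) return y;
    if (y == NEG_INF) return x;
    double hi = x > y ? x : y, lo = x > y ? y : x;
    return hi + std::log2(1.0 + std::exp2(lo - hi));
}

// flat copies of the model matrices for tight inner loops
struct HmmFlat {
    int M;
    std::vector<double> em, ins;  // M x 20, row-major
    std::vector<double> tr;       // (M+1) x 7, row-major
    HmmFlat(const NumericMatrix& lm, const NumericMatrix& li,
            const NumericMatrix& lt)
        : M(lm.nrow()), em(lm.nrow() * 20), ins(lm.nrow() * 20),
          tr((lm.nrow() + 1) * 7) {
        for (int k = 0; k < M; ++k)
            for (int a = 0; a < 20; ++a) {
                em[k * 20 + a] = lm(k, a);
                ins[k * 20 + a] = li(k, a);
            }
        for (int k = 0; k <= M; ++k)
            for (int t = 0; t < 7; ++t) tr[k * 7 + t] = lt(k, t);
    }
};

// [[Rcpp::export]]
List hmm_viterbi_cpp(NumericMatrix logodds_match, NumericMatrix logodds_ins,
                     NumericMatrix logtrans, IntegerVector x, bool want_path) {
    const int M = logodds_match.nrow(), L = x.size();
    const int W = L + 1;
    HmmFlat H(logodds_match, logodds_ins, logtrans);
    std::vector<double> VM((M + 1) * W, NEG_INF), VI((M + 1) * W, NEG_INF),
        VD((M + 1) * W, NEG_INF);
    // pointers: 0 from M, 1 from I, 2 from D, 3 from begin/flank
    std::vector<signed char> pm, pi, pd;
    if (want_path) {
        pm.assign((M + 1) * W, -1);
        pi.assign((M + 1) * W, -1);
        pd.assign((M + 1) * W, -1);
    }
    const double t0MM = H.tr[0], t0MD = H.tr[2];
    for (int k = 1; k <= M; ++k) {
        const double tMM = H.tr[(k - 1) * 7 + 0], tMI1 = H.tr[k * 7 + 1],
                     tMD = H.tr[(k - 1) * 7 + 2], tIM = H.tr[(k - 1) * 7 + 3],
                     tII1 = H.tr[k * 7 + 4], tDM = H.tr[(k - 1) * 7 + 5],
                     tDD = H.tr[(k - 1) * 7 + 6];
        const double* emk = &H.em[(k - 1) * 20];
        const double* insk = &H.ins[(k - 1) * 20];
        const int base = k * W, pbase = base - W;
        for (int i = 0; i <= L; ++i) {
            const int ki = base + i, km1i = pbase + i;
            // D_k
            double best;
            signed char pb;
            if (k == 1) { best = t0MD; pb = 3; }
            else {
                const double fm = VM[km1i] + tMD;
                const double fd = VD[km1i] + tDD;
                if (fm >= fd) { best = fm; pb = 0; }
                else { best = fd; pb = 2; }
            }
            VD[ki] = best;
            if (want_path) pd[ki] = pb;
            if (i >= 1) {
                const int prev = km1i - 1;  // node k-1, position i-1
                const double eo = x[i - 1] >= 0 ? emk[x[i - 1]] : 0.0;
                if (k == 1) { best = t0MM; pb = 3; }
                else {
                    const double fm = VM[prev] + tMM;
                    const double fi = VI[prev] + tIM;
                    const double fd = VD[prev] + tDM;
                    best = fm; pb = 0;
                    if (fi > best) { best = fi; pb = 1; }
                    if (fd > best) { best = fd; pb = 2; }
                }
                VM[ki] = best + eo;
                if (want_path) pm[ki] = pb;
                // I_k
                const double ei = x[i - 1] >= 0 ? insk[x[i - 1]] : 0.0;
                const double gm = VM[ki - 1] + tMI1;
                const double gi = VI[ki - 1] + tII1;
                if (gm >= gi) { VI[ki] = gm + ei; if (want_path) pi[ki] = 0; }
                else { VI[ki] = gi + ei; if (want_path) pi[ki] = 1; }
            }
        }
    }
    double best = NEG_INF;
    int best_i = -1, best_state = -1;  // 0 = M_M, 2 = D_M
    for (int i = 0; i <= L; ++i) {
        const double em = VM[M * W + i] + H.tr[M * 7 + 0];
        const double ed = VD[M * W + i] + H.tr[M * 7 + 5];
        if (em > best) { best = em; best_i = i; best_state = 0; }
        if (ed > best) { best = ed; best_i = i; best_state = 2; }
    }
    List out = List::create(_["bits"] = best);
    if (want_path && best > NEG_INF) {
        std::vector<std::string> path;
        int k = M, i = best_i, state = best_state;
        while (true) {
            const int ki = k * W + i;
            signed char prev;
            char lab;
            if (state == 0) { lab = 'M'; prev = pm[ki]; }
            else if (state == 1) { lab = 'I'; prev = pi[ki]; }
            else { lab = 'D'; prev = pd[ki]; }
            path.push_back(std::string(1, lab) + std::to_string(k));
            if (prev == 3) break;
            if (state == 0) { --k; --i; }
            else if (state == 1) { --i; }
            else { --k; }
            state = prev;
        }
        CharacterVector pv(path.size());
        for (size_t q = 0; q < path.size(); ++q)
            pv[q] = path[path.size() - 1 - q];
        out["path"] = pv;
        out["seq_to"] = best_i;  // residues 1..seq_to consumed before C flank
    }
    return out;
}

// Viterbi bits only, flat model, reusable buffers
static double viterbi_bits_flat(const HmmFlat& H, const IntegerVector& x,
                                std::vector<double>& VM,
                                std::vector<double>& VI,
                                std::vector<double>& VD) {
    const int M = H.M, L = x.size(), W = L + 1;
    const size_t need = (size_t)(M + 1) * W;
    VM.assign(need, NEG_INF);
    VI.assign(need, NEG_INF);
    VD.assign(need, NEG_INF);
    const double t0MM = H.tr[0], t0MD = H.tr[2];
    for (int k = 1; k <= M; ++k) {
        const double tMM = H.tr[(k - 1) * 7 + 0], tMI1 = H.tr[k * 7 + 1],
                     tMD = H.tr[(k - 1) * 7 + 2], tIM = H.tr[(k - 1) * 7 + 3],
                     tII1 = H.tr[k * 7 + 4], tDM = H.tr[(k - 1) * 7 + 5],
                     tDD = H.tr[(k - 1) * 7 + 6];
        const double* emk = &H.em[(k - 1) * 20];
        const double* insk = &H.ins[(k - 1) * 20];
        const int base = k * W, pbase = base - W;
        for (int i = 0; i <= L; ++i) {
            const int ki = base + i, km1i = pbase + i;
            if (k == 1) VD[ki] = t0MD;
            else {
                const double fm = VM[km1i] + tMD, fd = VD[km1i] + tDD;
                VD[ki] = fm >= fd ? fm : fd;
            }
            if (i >= 1) {
                const int prev = km1i - 1;
                const double eo = x[i - 1] >= 0 ? emk[x[i - 1]] : 0.0;
                double best;
                if (k == 1) best = t0MM;
                else {
                    best = VM[prev] + tMM;
                    const double fi = VI[prev] + tIM, fd = VD[prev] + tDM;
                    if (fi > best) best = fi;
                    if (fd > best) best = fd;
                }
                VM[ki] = best + eo;
                const double ei = x[i - 1] >= 0 ? insk[x[i - 1]] : 0.0;
                const double gm = VM[ki - 1] + tMI1, gi = VI[ki - 1] + tII1;
                VI[ki] = (gm >= gi ? gm : gi) + ei;
            }
        }
    }
    double best = NEG_INF;
    for (int i = 0; i <= L; ++i) {
        const double em = VM[M * W + i] + H.tr[M * 7 + 0];
        const double ed = VD[M * W + i] + H.tr[M * 7 + 5];
        if (em > best) best = em;
        if (ed > best) best = ed;
    }
    return best;
}

// batch scan: bit-score matrix, proteins x profiles
// [[Rcpp::export]]
NumericMatrix hmm_scan_cpp(List profiles, List queries) {
    std::vector<HmmFlat> hm;
    hm.reserve(profiles.size());
    for (int j = 0; j < profiles.size(); ++j) {
        List p = profiles[j];
        hm.emplace_back(as<NumericMatrix>(p["lm"]),
                        as<NumericMatrix>(p["li"]),
                        as<NumericMatrix>(p["lt"]));
    }
    NumericMatrix out(queries.size(), profiles.size());
    std::vector<double> VM, VI, VD;
    for (int i = 0; i < queries.size(); ++i) {
        IntegerVector x = queries[i];
        for (size_t j = 0; j < hm.size(); ++j) {
            out(i, j) = viterbi_bits_flat(hm[j], x, VM, VI, VD);
        }
    }
    return out;
}

// [[Rcpp::export]]
double hmm_forward_cpp(NumericMatrix logodds_match, NumericMatrix logodds_ins,
                       NumericMatrix logtrans, IntegerVector x) {
    const int M = logodds_match.nrow(), L = x.size();
    const int W = L + 1;
    std::vector<double> FM((M + 1) * W, NEG_INF), FI((M + 1) * W, NEG_INF),
        FD((M + 1) * W, NEG_INF);
    HmmFlat H(logodds_match, logodds_ins, logtrans);
    const double t0MM = H.tr[0], t0MD = H.tr[2];
    for (int k = 1; k <= M; ++k) {
        const double tMM = H.tr[(k - 1) * 7 + 0], tMI1 = H.tr[k * 7 + 1],
                     tMD = H.tr[(k - 1) * 7 + 2], tIM = H.tr[(k - 1) * 7 + 3],
                     tII1 = H.tr[k * 7 + 4], tDM = H.tr[(k - 1) * 7 + 5],
                     tDD = H.tr[(k - 1) * 7 + 6];
        const double* emk = &H.em[(k - 1) * 20];
        const double* insk = &H.ins[(k - 1) * 20];
        const int base = k * W, pbase = base - W;
        for (int i = 0; i <= L; ++i) {
            const int ki = base + i, km1i = pbase + i;
            double v;
            if (k == 1) v = t0MD;
            else v = lse2(FM[km1i] + tMD, FD[km1i] + tDD);
            FD[ki] = v;
            if (i >= 1) {
                const int prev = km1i - 1;
                const double eo = x[i - 1] >= 0 ? emk[x[i - 1]] : 0.0;
                if (k == 1) v = t0MM;
                else v = lse2(lse2(FM[prev] + tMM, FI[prev] + tIM),
                              FD[prev] + tDM);
                FM[ki] = v + eo;
                const double ei = x[i - 1] >= 0 ? insk[x[i - 1]] : 0.0;
                FI[ki] = lse2(FM[ki - 1] + tMI1, FI[ki - 1] + tII1) + ei;
            }
        }
    }
    double tot = NEG_INF;
    for (int i = 0; i <= L; ++i) {
        tot = lse2(tot, FM[M * W + i] + H.tr[M * 7 + 0]);
        tot = lse2(tot, FD[M * W + i] + H.tr[M * 7 + 5]);
    }
    return tot;
}
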