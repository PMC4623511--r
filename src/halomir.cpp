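#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static const double INF = 1e9;
static const double EPS = 1e-6;

// base codes: A=0, C=1, G=2, U/T=3, other=-1
static inline int bcode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;
  }
}

// pair index 1..6 (AU,CG,GC,UA,GU,UG), 0 = not a pair
static inline int pidx(int a, int b) {
  if (a == 0 && b == 3) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 3 && b == 0) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

struct EnergyPar {
  double stack[7][7];       // [outer pair][inner pair], 1-based pair indices
  double hairpin[10];       // hairpin[n] for loop size n = 1..9
  double bulge[7];          // bulge[n] for n = 1..6
  double internal[7];       // internal[n] for total size n = 2..6
  double ml_a, ml_b, ml_c;  // multiloop offset, per-branch, per-unpaired
  double lxc;               // log extrapolation coefficient
  double asym_coef, asym_max;
  int max_loop, min_hairpin;
};

static EnergyPar read_par(List par) {
  EnergyPar p;
  NumericMatrix st = par["stack"];
  for (int i = 1; i <= 6; i++)
    for (int j = 1; j <= 6; j++) p.stack[i][j] = st(i - 1, j - 1);
  NumericVector h = par["hairpin"];
  for (int n = 1; n <= 9; n++) p.hairpin[n] = h[n - 1];
  NumericVector b = par["bulge"];
  for (int n = 1; n <= 6; n++) p.bulge[n] = b[n - 1];
  NumericVector in = par["internal"];
  for (int n = 1; n <= 6; n++) p.internal[n] = in[n - 1];
  p.ml_a = as<double>(par["ml_a"]);
  p.ml_b = as<double>(par["ml_b"]);
  p.ml_c = as<double>(par["ml_c"]);
  p.lxc = as<double>(par["lxc"]);
  p.asym_coef = as<double>(par["asym_coef"]);
  p.asym_max = as<double>(par["asym_max"]);
  p.max_loop = as<int>(par["max_loop"]);
  p.min_hairpin = as<int>(par["min_hairpin"]);
  return p;
}

static inline double eHairpin(const EnergyPar &p, int n) {
  if (n < p.min_hairpin) return INF;
  if (n <= 9) return p.hairpin[n];
  return p.hairpin[9] + p.lxc * std::log((double)n / 9.0);
}
static inline double eBulge(const EnergyPar &p, int n) {
  if (n > p.max_loop) return INF;
  if (n <= 6) return p.bulge[n];
  return p.bulge[6] + p.lxc * std::log((double)n / 6.0);
}
static inline double eInternal(const EnergyPar &p, int n1, int n2) {
  int n = n1 + n2;
  if (n > p.max_loop) return INF;
  double base = (n <= 6) ? p.internal[n] : p.internal[6] + p.lxc * std::log((double)n / 6.0);
  double asym = p.asym_coef * std::abs(n1 - n2);
  if (asym > p.asym_max) asym = p.asym_max;
  return base + asym;
}

// Minimum-free-energy folding by a Zuker-style dynamic program over the
// nearest-neighbor model defined by `par`: stacking energies on adjacent
// pairs, tabulated hairpin/bulge/internal loop penalties with logarithmic
// extrapolation, and a linear multiloop model. Optimal (and checked against
// exhaustive enumeration in the test suite) under this energy table.
// [[Rcpp::export]]
List fold_backend_cpp(std::string seq, List par) {
  EnergyPar P = read_par(par);
  int n = seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; i++) {
    s[i] = bcode(seq[i]);
    if (s[i] < 0 && seq[i] != 'N' && seq[i] != 'n')
      stop("invalid base in sequence: '%c'", seq[i]);
  }
  std::string db(n, '.');
  if (n < P.min_hairpin + 2)
    return List::create(_["structure"] = db, _["mfe"] = 0.0);

  std::vector<double> V((size_t)n * n, INF), WM((size_t)n * n, INF),
      WM2((size_t)n * n, INF);
  std::vector<double> W(n, 0.0);
#define IX(i, j) ((size_t)(i) * n + (j))

  for (int j = 0; j < n; j++) {
    for (int i = j - 1; i >= 0; i--) {
      int span = j - i - 1;
      int p = (s[i] >= 0 && s[j] >= 0) ? pidx(s[i], s[j]) : 0;
      double v = INF;
      if (p > 0 && span >= P.min_hairpin) {
        v = eHairpin(P, span);
        // interior loops (stack, bulge, internal), loop size capped
        int kmax = std::min(i + 1 + P.max_loop, j - 2);
        for (int k = i + 1; k <= kmax; k++) {
          int n1 = k - i - 1;
          int lmin = std::max(k + P.min_hairpin + 1, j - 1 - (P.max_loop - n1));
          for (int l = j - 1; l >= lmin; l--) {
            double vkl = V[IX(k, l)];
            if (vkl >= INF) continue;
            int n2 = j - l - 1;
            double e;
            if (n1 == 0 && n2 == 0) {
              int q = pidx(s[k], s[l]);
              e = P.stack[p][q] + vkl;
            } else if (n1 == 0 || n2 == 0) {
              e = eBulge(P, n1 + n2) + vkl;
            } else {
              e = eInternal(P, n1, n2) + vkl;
            }
            if (e < v) v = e;
          }
        }
        // multiloop closed by (i, j)
        if (span >= 2 * (P.min_hairpin + 2)) {
          double e = P.ml_a + P.ml_b + WM2[IX(i + 1, j - 1)];
          if (e < v) v = e;
        }
      }
      V[IX(i, j)] = v;

      // WM: >= 1 branch segment inside a multiloop
      double m = INF;
      if (v < INF) m = v + P.ml_b;
      if (i + 1 <= j && WM[IX(i + 1, j)] < INF)
        m = std::min(m, WM[IX(i + 1, j)] + P.ml_c);
      if (i <= j - 1 && WM[IX(i, j - 1)] < INF)
        m = std::min(m, WM[IX(i, j - 1)] + P.ml_c);
      double m2 = INF;
      for (int k = i + 1; k <= j; k++) {
        double a = WM[IX(i, k - 1)], b = WM[IX(k, j)];
        if (a < INF && b < INF) {
          if (a + b < m) m = a + b;
          if (a + b < m2) m2 = a + b;
        }
      }
      WM[IX(i, j)] = m;
      WM2[IX(i, j)] = m2;
    }
    // external segment ending at j
    double w = (j > 0) ? W[j - 1] : 0.0;
    for (int i = 0; i <= j; i++) {
      double vij = V[IX(i, j)];
      if (vij >= INF) continue;
      double cand = (i > 0 ? W[i - 1] : 0.0) + vij;
      if (cand < w) w = cand;
    }
    W[j] = w;
  }

  double mfe = W[n - 1];

  // traceback; prefers the unpaired option on ties so mfe == 0 yields all dots
  std::vector<std::array<int, 3>> stk; // {type, i, j}: 0=V, 1=WM, 2=WM2
  {
    int j = n - 1;
    while (j >= 0) {
      double wj = W[j], wprev = (j > 0) ? W[j - 1] : 0.0;
      if (std::fabs(wj - wprev) < EPS) { j--; continue; }
      bool found = false;
      for (int i = 0; i <= j && !found; i++) {
        double vij = V[IX(i, j)];
        if (vij >= INF) continue;
        if (std::fabs((i > 0 ? W[i - 1] : 0.0) + vij - wj) < EPS) {
          stk.push_back({0, i, j});
          j = i - 1;
          found = true;
        }
      }
      if (!found) stop("internal error: external traceback failed");
    }
  }
  while (!stk.empty()) {
    auto fr = stk.back();
    stk.pop_back();
    int i = fr[1], j = fr[2];
    if (fr[0] == 0) { // V
      db[i] = '(';
      db[j] = ')';
      double v = V[IX(i, j)];
      int span = j - i - 1, p = pidx(s[i], s[j]);
      if (std::fabs(v - eHairpin(P, span)) < EPS) continue;
      bool found = false;
      int kmax = std::min(i + 1 + P.max_loop, j - 2);
      for (int k = i + 1; k <= kmax && !found; k++) {
        int n1 = k - i - 1;
        int lmin = std::max(k + P.min_hairpin + 1, j - 1 - (P.max_loop - n1));
        for (int l = j - 1; l >= lmin && !found; l--) {
          double vkl = V[IX(k, l)];
          if (vkl >= INF) continue;
          int n2 = j - l - 1;
          double e;
          if (n1 == 0 && n2 == 0) e = P.stack[p][pidx(s[k], s[l])] + vkl;
          else if (n1 == 0 || n2 == 0) e = eBulge(P, n1 + n2) + vkl;
          else e = eInternal(P, n1, n2) + vkl;
          if (std::fabs(e - v) < EPS) {
            stk.push_back({0, k, l});
            found = true;
          }
        }
      }
      if (found) continue;
      if (span >= 2 * (P.min_hairpin + 2) &&
          std::fabs(P.ml_a + P.ml_b + WM2[IX(i + 1, j - 1)] - v) < EPS) {
        stk.push_back({2, i + 1, j - 1});
        continue;
      }
      stop("internal error: V traceback failed");
    } else if (fr[0] == 1) { // WM
      for (;;) {
        double m = WM[IX(i, j)];
        if (V[IX(i, j)] < INF && std::fabs(V[IX(i, j)] + P.ml_b - m) < EPS) {
          stk.push_back({0, i, j});
          break;
        }
        if (i + 1 <= j && WM[IX(i + 1, j)] < INF &&
            std::fabs(WM[IX(i + 1, j)] + P.ml_c - m) < EPS) { i++; continue; }
        if (i <= j - 1 && WM[IX(i, j - 1)] < INF &&
            std::fabs(WM[IX(i, j - 1)] + P.ml_c - m) < EPS) { j--; continue; }
        bool found = false;
        for (int k = i + 1; k <= j && !found; k++) {
          double a = WM[IX(i, k - 1)], b = WM[IX(k, j)];
          if (a < INF && b < INF && std::fabs(a + b - m) < EPS) {
            stk.push_back({1, i, k - 1});
            stk.push_back({1, k, j});
            found = true;
          }
        }
        if (!found) stop("internal error: WM traceback failed");
        break;
      }
    } else { // WM2
      double m2 = WM2[IX(i, j)];
      bool found = false;
      for (int k = i + 1; k <= j && !found; k++) {
        double a = WM[IX(i, k - 1)], b = WM[IX(k, j)];
        if (a < INF && b < INF && std::fabs(a + b - m2) < EPS) {
          stk.push_back({1, i, k - 1});
          stk.push_back({1, k, j});
          found = true;
        }
      }
      if (!found) stop("internal error: WM2 traceback failed");
    }
  }
#undef IX
  return List::create(_["structure"] = db, _["mfe"] = mfe);
}

static inline char comp_char(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'U': return 'A';
  default: return 'N';
  }
}

static std::string revcomp_str(const std::string &x) {
  std::string r(x.rbegin(), x.rend());
  for (auto &c : r) c = comp_char(c);
  return r;
}

// Ungapped all-placement scan of short tags over a set of chromosome
// sequences, both strands, Hamming distance <= max_mm. N never matches.
// Seeded by the pigeonhole principle: an alignment with <= max_mm
// mismatches of a tag split into max_mm + 1 disjoint seeds must carry at
// least one exact seed, so exact 5-mer index lookups of three seeds
// (tags are >= 15 nt) enumerate a superset of all placements, which are
// then verified by direct comparison.
// [[Rcpp::export]]
DataFrame map_scan_cpp(CharacterVector chroms, CharacterVector tags, int max_mm) {
  const int K = 5, NBUCKET = 1 << (2 * K); // 4^5 buckets
  std::vector<int> o_tag, o_chrom, o_start, o_mm;
  std::vector<std::string> o_strand;
  int nc = chroms.size(), nt = tags.size();
  std::vector<std::string> cs(nc);
  for (int c = 0; c < nc; c++) cs[c] = as<std::string>(chroms[c]);
  std::vector<std::string> fwd(nt), rev(nt);
  for (int t = 0; t < nt; t++) {
    fwd[t] = as<std::string>(tags[t]);
    rev[t] = revcomp_str(fwd[t]);
  }
  int n_seeds = max_mm + 1;

  std::vector<int> starts(NBUCKET + 1), posns;
  std::vector<int> code;
  std::vector<int> cand;
  for (int c = 0; c < nc; c++) {
    const std::string &g = cs[c];
    int L = g.size();
    code.assign(L, -1);
    for (int i = 0; i < L; i++) code[i] = bcode(g[i]) == 3 && (g[i] == 'U' || g[i] == 'u') ? -1 : bcode(g[i]);
    // exact K-mer index of this chromosome
    std::fill(starts.begin(), starts.end(), 0);
    auto kmer_at = [&](int i) {
      int v = 0;
      for (int k = 0; k < K; k++) {
        if (code[i + k] < 0) return -1;
        v = (v << 2) | code[i + k];
      }
      return v;
    };
    for (int i = 0; i + K <= L; i++) {
      int v = kmer_at(i);
      if (v >= 0) starts[v + 1]++;
    }
    for (int b = 0; b < NBUCKET; b++) starts[b + 1] += starts[b];
    posns.assign(starts[NBUCKET], 0);
    std::vector<int> fill(starts.begin(), starts.end() - 1);
    for (int i = 0; i + K <= L; i++) {
      int v = kmer_at(i);
      if (v >= 0) posns[fill[v]++] = i;
    }
    for (int t = 0; t < nt; t++) {
      int lt = fwd[t].size();
      if (lt > L) continue;
      for (int strand = 0; strand < 2; strand++) {
        const std::string &pat = strand == 0 ? fwd[t] : rev[t];
        cand.clear();
        bool fallback = lt < n_seeds * K; // too short for disjoint seeds
        for (int s = 0; !fallback && s < n_seeds; s++) {
          int off = (int)((long)s * lt / n_seeds);
          if (off + K > lt) off = lt - K;
          int v = 0;
          bool ok = true;
          for (int k = 0; k < K; k++) {
            int b = bcode(pat[off + k]);
            if (b < 0 || pat[off + k] == 'U' || pat[off + k] == 'u') { ok = false; break; }
            v = (v << 2) | b;
          }
          if (!ok) { fallback = true; break; } // seed with N: scan directly
          for (int u = starts[v]; u < starts[v + 1]; u++) {
            int pos = posns[u] - off;
            if (pos >= 0 && pos + lt <= L) cand.push_back(pos);
          }
        }
        if (fallback) {
          cand.clear();
          for (int pos = 0; pos + lt <= L; pos++) cand.push_back(pos);
        } else {
          std::sort(cand.begin(), cand.end());
          cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
        }
        for (int pos : cand) {
          int mm = 0;
          for (int k = 0; k < lt; k++) {
            char gb = g[pos + k], tb = pat[k];
            // match only when equal and a concrete base (N never matches)
            if (!(gb == tb && (gb == 'A' || gb == 'C' || gb == 'G' || gb == 'T'))) {
              if (++mm > max_mm) break;
            }
          }
          if (mm <= max_mm) {
            o_tag.push_back(t + 1);
            o_chrom.push_back(c + 1);
            o_start.push_back(pos);
            o_strand.push_back(strand == 0 ? "+" : "-");
            o_mm.push_back(mm);
          }
        }
      }
    }
  }
  DataFrame out = DataFrame::create(_["tag"] = o_tag, _["chrom"] = o_chrom,
                                    _["start"] = o_start, _["strand"] = o_strand,
                                    _["mismatches"] = o_mm,
                                    _["stringsAsFactors"] = false);
  return out;
}

// Match tags against short mature reference sequences allowing end shifts of
// up to max_shift nt at either end and up to max_mm mismatches in the
// overlap. Returns the best reference per tag (0 = no match).
// [[Rcpp::export]]
DataFrame match_mature_cpp(CharacterVector tags, CharacterVector refs,
                           int max_mm, int max_shift) {
  int nt = tags.size(), nr = refs.size();
  std::vector<std::string> rs(nr);
  for (int r = 0; r < nr; r++) rs[r] = as<std::string>(refs[r]);
  IntegerVector best_ref(nt, 0), best_mm(nt, NA_INTEGER), best_shift(nt, NA_INTEGER);
  for (int t = 0; t < nt; t++) {
    std::string tg = as<std::string>(tags[t]);
    int lt = tg.size();
    int bmm = max_mm + 1, bsh = 2 * max_shift + 1, bref = 0;
    for (int r = 0; r < nr; r++) {
      const std::string &rf = rs[r];
      int lr = rf.size();
      for (int o = -max_shift; o <= max_shift; o++) {
        // tag position i aligns to ref position i + o (0-based)
        int end_shift = (o + lt) - lr;
        if (end_shift < -max_shift || end_shift > max_shift) continue;
        int lo = std::max(0, -o), hi = std::min(lt, lr - o);
        if (hi - lo < lt - 2 * max_shift) continue;
        int mm = 0;
        for (int i = lo; i < hi; i++)
          if (tg[i] != rf[i + o]) mm++;
        int sh = std::abs(o) + std::abs(end_shift);
        if (mm <= max_mm && (mm < bmm || (mm == bmm && sh < bsh))) {
          bmm = mm; bsh = sh; bref = r + 1;
        }
      }
    }
    if (bref > 0) {
      best_ref[t] = bref;
      best_mm[t] = bmm;
      best_shift[t] = bsh;
    }
  }
  return DataFrame::create(_["tag"] = seq_len(nt), _["ref"] = best_ref,
                           _["mm"] = best_mm, _["shift"] = best_shift);
}

// penalty for one miRNA:target base pair in a duplex (bases in RNA space)
static inline double pair_cost(char m, char t, double wobble, double mismatch) {
  int a = bcode(m), b = bcode(t);
  if (a < 0 || b < 0) return mismatch;
  if (pidx(a, b) >= 1 && pidx(a, b) <= 4) return 0.0; // Watson-Crick
  if (pidx(a, b) >= 5) return wobble;                 // G:U
  return mismatch;
}

// Global alignment of a miRNA (5'->3') against a candidate target window.
// The window is supplied 5'->3' in transcript orientation; pairing is
// antiparallel, so the window is reversed internally. Penalties are doubled
// at miRNA seed positions. Returns the expectation score, per-column
// classification and the window coordinate paired to each miRNA position.
// [[Rcpp::export]]
List nw_duplex_cpp(std::string mirna, std::string window, double wobble,
                   double mismatch, double gap, int seed_lo, int seed_hi,
                   double seed_mult) {
  int m = mirna.size(), w = window.size();
  std::string tw(window.rbegin(), window.rend()); // pairing order
  auto mult = [&](int i) { return (i >= seed_lo && i <= seed_hi) ? seed_mult : 1.0; };
  std::vector<double> D((m + 1) * (w + 1), 0.0);
#define DX(i, j) D[(size_t)(i) * (w + 1) + (j)]
  for (int i = 1; i <= m; i++) DX(i, 0) = DX(i - 1, 0) + gap * mult(i);
  for (int j = 1; j <= w; j++) DX(0, j) = DX(0, j - 1) + gap * mult(1);
  for (int i = 1; i <= m; i++) {
    for (int j = 1; j <= w; j++) {
      double diag = DX(i - 1, j - 1) + pair_cost(mirna[i - 1], tw[j - 1], wobble, mismatch) * mult(i);
      double up = DX(i - 1, j) + gap * mult(i);
      double left = DX(i, j - 1) + gap * mult(std::min(i + 1, m));
      DX(i, j) = std::min(diag, std::min(up, left));
    }
  }
  double score = DX(m, w);
  // traceback (prefer diagonal)
  IntegerVector pair_of(m, 0); // window coordinate (1-based, 5'->3') per miRNA pos
  std::vector<int> col_m, col_t; // 0 = gap
  std::vector<std::string> col_type;
  int i = m, j = w;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        std::fabs(DX(i, j) - (DX(i - 1, j - 1) +
                              pair_cost(mirna[i - 1], tw[j - 1], wobble, mismatch) * mult(i))) < 1e-9) {
      double c = pair_cost(mirna[i - 1], tw[j - 1], wobble, mismatch);
      col_m.push_back(i);
      col_t.push_back(w - j + 1); // back to transcript orientation (1-based)
      col_type.push_back(c == 0.0 ? "match" : (c == wobble && c != mismatch ? "wobble" : "mismatch"));
      pair_of[i - 1] = w - j + 1;
      i--; j--;
    } else if (i > 0 && std::fabs(DX(i, j) - (DX(i - 1, j) + gap * mult(i))) < 1e-9) {
      col_m.push_back(i); col_t.push_back(0); col_type.push_back("gap_target");
      i--;
    } else {
      col_m.push_back(0); col_t.push_back(w - j + 1); col_type.push_back("gap_mirna");
      j--;
    }
  }
  std::reverse(col_m.begin(), col_m.end());
  std::reverse(col_t.begin(), col_t.end());
  std::reverse(col_type.begin(), col_type.end());
#undef DX
  return List::create(_["score"] = score, _["pair_of"] = pair_of,
                      _["col_mirna"] = wrap(col_m), _["col_target"] = wrap(col_t),
                      _["col_type"] = wrap(col_type));
}

// Score every window of lengths len(mirna) + (-len_delta .. +len_delta)
// along a transcript; returns windows with score <= cutoff.
// [[Rcpp::export]]
DataFrame scan_windows_cpp(std::string mirna, std::string transcript,
                           double cutoff, int len_delta, double wobble,
                           double mismatch, double gap, int seed_lo,
                           int seed_hi, double seed_mult) {
  int m = mirna.size(), L = transcript.size();
  std::vector<int> o_start, o_len;
  std::vector<double> o_score;
  auto mult = [&](int i) { return (i >= seed_lo && i <= seed_hi) ? seed_mult : 1.0; };
  std::vector<double> D;
  for (int wl = m - len_delta; wl <= m + len_delta; wl++) {
    if (wl < 1 || wl > L) continue;
    D.assign((size_t)(m + 1) * (wl + 1), 0.0);
    for (int s = 0; s + wl <= L; s++) {
      std::string tw(transcript.rbegin() + (L - s - wl), transcript.rbegin() + (L - s));
#define DX(i, j) D[(size_t)(i) * (wl + 1) + (j)]
      for (int i = 1; i <= m; i++) DX(i, 0) = DX(i - 1, 0) + gap * mult(i);
      for (int j = 1; j <= wl; j++) DX(0, j) = DX(0, j - 1) + gap * mult(1);
      for (int i = 1; i <= m; i++) {
        for (int j = 1; j <= wl; j++) {
          double diag = DX(i - 1, j - 1) + pair_cost(mirna[i - 1], tw[j - 1], wobble, mismatch) * mult(i);
          double up = DX(i - 1, j) + gap * mult(i);
          double left = DX(i, j - 1) + gap * mult(std::min(i + 1, m));
          DX(i, j) = std::min(diag, std::min(up, left));
        }
      }
      if (DX(m, wl) <= cutoff + 1e-9) {
        o_start.push_back(s);
        o_len.push_back(wl);
        o_score.push_back(DX(m, wl));
      }
#undef DX
    }
  }
  return DataFrame::create(_["start"] = o_start, _["len"] = o_len,
                           _["score"] = o_score);
}
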