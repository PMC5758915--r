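// Partition function, base-pair probabilities and stochastic traceback for
// a simplified nearest-neighbor model of RNA secondary structure.
//
// Energy model (must stay in lockstep with structureEnergy() in R/energy.R):
//   hairpin(i,j)              : hp[j-i-1]
//   stacked inner pair        : stack[pt(i,j)][pt(i+1,j-1)]
//                               + bonus[i]+bonus[j]+bonus[i+1]+bonus[j-1]
//   other single inner pair   : il[(k-i-1)+(j-l-1)]
//   multibranch loop          : a + b*(branches) + c*(unpaired), with the
//                               closing pair counted as a branch
//   exterior loop             : 0
// Per-nucleotide pseudo-free-energy bonuses enter only through base-pair
// stacks, once per stack membership. Long doubles keep the Boltzmann sums
// in range without rescaling for sequences up to several hundred nt.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef long double ld;

static inline int pairType(int a, int b) {
  // bases A=0 C=1 G=2 U=3; pair codes AU UA GC CG GU UG -> 0..5
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

namespace {

struct Engine {
  int N, minH;
  std::vector<int> s;
  const NumericMatrix& stack;
  const NumericVector& hp;   // hp[L] = hairpin penalty for size L
  const NumericVector& il;   // il[L] = internal/bulge penalty for size L
  double a, b, c;            // multibranch offset / per-branch / per-unpaired
  const NumericVector& bonus;
  double kT;

  std::vector<std::vector<ld> > V, WM, Vh;
  std::vector<ld> Wl, Wr;

  Engine(const IntegerVector& seq, const NumericMatrix& stack_,
         const NumericVector& hp_, const NumericVector& il_,
         const NumericVector& mb, int minH_, const NumericVector& bonus_,
         double kT_)
    : N(seq.size()), minH(minH_), s(seq.begin(), seq.end()), stack(stack_),
      hp(hp_), il(il_), a(mb[0]), b(mb[1]), c(mb[2]), bonus(bonus_), kT(kT_) {}

  inline ld B(double e) const { return expl((ld)(-e / kT)); }
  inline ld Bc(int len) const { return expl((ld)(-c * len / kT)); }
  inline int pt(int i, int j) const { return pairType(s[i], s[j]); }
  inline double stackE(int i, int j) const {
    // stack formed by (i,j) over (i+1,j-1), with bonuses of all 4 positions
    return stack(pt(i, j), pt(i + 1, j - 1)) +
      bonus[i] + bonus[j] + bonus[i + 1] + bonus[j - 1];
  }
  inline ld wmAt(int i, int j) const { return (i > j) ? (ld)0 : WM[i][j]; }
  inline ld Mu(int i, int j) const {  // >= 0 multibranch branches in [i,j]
    return (i > j) ? (ld)1 : WM[i][j] + Bc(j - i + 1);
  }

  void inside() {
    V.assign(N, std::vector<ld>(N, 0.0L));
    WM.assign(N, std::vector<ld>(N, 0.0L));
    for (int d = 1; d < N; ++d) {
      for (int i = 0; i + d < N; ++i) {
        int j = i + d;
        if (d > minH && pt(i, j) >= 0) {
          ld v = B(hp(j - i - 1));
          for (int k = i + 1; k < j; ++k) {
            for (int l = k + minH + 1; l < j; ++l) {
              if (V[k][l] <= 0) continue;
              if (k == i + 1 && l == j - 1)
                v += B(stackE(i, j)) * V[k][l];
              else
                v += B(il((k - i - 1) + (j - l - 1))) * V[k][l];
            }
          }
          // multibranch: (h,l) is the rightmost branch, WM holds the rest
          for (int h = i + 2; h < j; ++h) {
            if (WM[i + 1][h - 1] <= 0) continue;
            for (int l = h + minH + 1; l < j; ++l) {
              if (V[h][l] <= 0) continue;
              v += B(a + 2 * b) * Bc(j - 1 - l) * WM[i + 1][h - 1] * V[h][l];
            }
          }
          V[i][j] = v;
        }
        // WM over [i,j]: >= 1 branch, conditioned on position i
        ld wm = (i < j) ? Bc(1) * WM[i + 1][j] : (ld)0;
        for (int l = i + minH + 1; l <= j; ++l) {
          if (V[i][l] <= 0) continue;
          wm += V[i][l] * B(b) * (Bc(j - l) + wmAt(l + 1, j));
        }
        WM[i][j] = wm;
      }
    }
    Wl.assign(N + 1, 1.0L);
    for (int t = 1; t <= N; ++t) {
      ld w = Wl[t - 1];
      int j = t - 1;
      for (int i = 0; i < j - minH; ++i)
        if (V[i][j] > 0) w += Wl[i] * V[i][j];
      Wl[t] = w;
    }
    Wr.assign(N + 1, 1.0L);
    for (int t = N - 1; t >= 0; --t) {
      ld w = Wr[t + 1];
      for (int j = t + minH + 1; j < N; ++j)
        if (V[t][j] > 0) w += V[t][j] * Wr[j + 1];
      Wr[t] = w;
    }
  }

  void outside() {
    Vh.assign(N, std::vector<ld>(N, 0.0L));
    for (int d = N - 1; d > minH; --d) {
      for (int i = 0; i + d < N; ++i) {
        int j = i + d;
        if (V[i][j] <= 0) continue;
        ld vh = Wl[i] * Wr[j + 1];
        if (i >= 1 && j + 1 < N && V[i - 1][j + 1] > 0)
          vh += Vh[i - 1][j + 1] * B(stackE(i - 1, j + 1));
        for (int p = 0; p < i; ++p) {
          for (int q = j + 1; q < N; ++q) {
            if (V[p][q] <= 0 || Vh[p][q] <= 0) continue;
            int sz = (i - p - 1) + (q - j - 1);
            if (sz > 0)  // internal loop / bulge around (i,j)
              vh += Vh[p][q] * B(il(sz));
            // multibranch closed by (p,q) with (i,j) one of >= 2 branches
            ld fill = Mu(p + 1, i - 1) * Mu(j + 1, q - 1) -
              Bc(i - p - 1) * Bc(q - j - 1);
            if (fill > 0)
              vh += Vh[p][q] * B(a + 2 * b) * fill;
          }
        }
        Vh[i][j] = vh;
      }
    }
  }

  // ---- stochastic traceback ------------------------------------------

  void traceV(int i, int j, std::vector<int>& partner) {
    partner[i] = j + 1;  // record 1-based
    partner[j] = i + 1;
    ld u = (ld)unif_rand() * V[i][j];
    ld acc = B(hp(j - i - 1));
    if (u <= acc) return;
    for (int k = i + 1; k < j; ++k) {
      for (int l = k + minH + 1; l < j; ++l) {
        if (V[k][l] <= 0) continue;
        if (k == i + 1 && l == j - 1) acc += B(stackE(i, j)) * V[k][l];
        else acc += B(il((k - i - 1) + (j - l - 1))) * V[k][l];
        if (u <= acc) { traceV(k, l, partner); return; }
      }
    }
    for (int h = i + 2; h < j; ++h) {
      if (WM[i + 1][h - 1] <= 0) continue;
      for (int l = h + minH + 1; l < j; ++l) {
        if (V[h][l] <= 0) continue;
        acc += B(a + 2 * b) * Bc(j - 1 - l) * WM[i + 1][h - 1] * V[h][l];
        if (u <= acc) {
          traceWM(i + 1, h - 1, partner);
          traceV(h, l, partner);
          return;
        }
      }
    }
    // numerical remainder: fall back to the hairpin term
  }

  void traceWM(int i, int j, std::vector<int>& partner) {
    ld u = (ld)unif_rand() * WM[i][j];
    ld acc = (i < j) ? Bc(1) * WM[i + 1][j] : (ld)0;
    if (u <= acc) { traceWM(i + 1, j, partner); return; }
    for (int l = i + minH + 1; l <= j; ++l) {
      if (V[i][l] <= 0) continue;
      acc += V[i][l] * B(b) * Bc(j - l);
      if (u <= acc) { traceV(i, l, partner); return; }
      if (l + 1 <= j && WM[l + 1][j] > 0) {
        acc += V[i][l] * B(b) * WM[l + 1][j];
        if (u <= acc) {
          traceV(i, l, partner);
          traceWM(l + 1, j, partner);
          return;
        }
      }
    }
    if (i < j) traceWM(i + 1, j, partner);  // numerical remainder
  }

  void sampleOne(std::vector<int>& partner) {
    std::fill(partner.begin(), partner.end(), 0);
    int t = 0;
    while (t < N) {
      ld u = (ld)unif_rand() * Wr[t];
      if (u <= Wr[t + 1]) { ++t; continue; }
      ld acc = Wr[t + 1];
      bool placed = false;
      for (int j = t + minH + 1; j < N; ++j) {
        if (V[t][j] <= 0) continue;
        acc += V[t][j] * Wr[j + 1];
        if (u <= acc) {
          traceV(t, j, partner);
          t = j + 1;
          placed = true;
          break;
        }
      }
      if (!placed) ++t;  // numerical remainder
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".foldEngine")]]
List foldEngine(IntegerVector seq, NumericMatrix stack, NumericVector hp,
                NumericVector il, NumericVector mb, int minHairpin,
                NumericVector bonus, double kT, int nSamples) {
  int N = seq.size();
  if (N < minHairpin + 2)
    stop("sequence too short for the minimum hairpin size");
  Engine eng(seq, stack, hp, il, mb, minHairpin, bonus, kT);
  eng.inside();
  eng.outside();

  ld Z = eng.Wr[0];
  NumericMatrix P(N, N);
  for (int i = 0; i < N; ++i)
    for (int j = i + minHairpin + 1; j < N; ++j)
      if (eng.V[i][j] > 0)
        P(i, j) = (double)(eng.V[i][j] * eng.Vh[i][j] / Z);

  IntegerMatrix samples(std::max(nSamples, 0), N);
  if (nSamples > 0) {
    GetRNGstate();
    std::vector<int> partner(N);
    for (int r = 0; r < nSamples; ++r) {
      eng.sampleOne(partner);
      for (int i = 0; i < N; ++i) samples(r, i) = partner[i];
    }
    PutRNGstate();
  }
  return List::create(_["P"] = P, _["lnZ"] = (double)logl(Z),
                      _["samples"] = samples);
}
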