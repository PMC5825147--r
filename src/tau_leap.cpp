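#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Locate the channel hit by a uniform draw on [0, W) via binary search on
// the cumulative weight vector.
static inline int pick_channel(const std::vector<double> &cum, double u) {
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (u < cum[mid]) hi = mid; else lo = mid + 1;
  }
  return lo;
}

// Tau-leaping pure birth process: N_i <- N_i + k_i with
// k_i ~ Poisson(r * N_i * tau), iterated until the total population reaches
// n_crit (or t_max of simulated time has elapsed). The joint draw of the
// k_i is realized as K ~ Poisson(r * n * tau) events distributed over clones
// proportionally to N_i, which is distributionally identical to independent
// per-clone Poisson draws.
// [[Rcpp::export]]
List cpp_tau_leap_grow(NumericVector sizes, double r, double tau,
                       double n_crit, double t_max) {
  int C = sizes.size();
  std::vector<double> N(sizes.begin(), sizes.end());
  double n = 0.0;
  for (int i = 0; i < C; ++i) n += N[i];
  double t = 0.0;
  long steps = 0;
  std::vector<double> cum(C);

  while (n < n_crit && t < t_max) {
    if (r <= 0.0 || n <= 0.0) break; // nothing can ever happen
    double K = R::rpois(r * n * tau);
    if (K > 0.5) {
      double acc = 0.0;
      for (int i = 0; i < C; ++i) { acc += N[i]; cum[i] = acc; }
      int Ki = (int)K;
      for (int e = 0; e < Ki; ++e) {
        double u = unif_rand() * acc;
        N[pick_channel(cum, u)] += 1.0;
      }
      n += K;
    }
    t += tau;
    ++steps;
  }
  return List::create(_["sizes"] = NumericVector(N.begin(), N.end()),
                      _["elapsed"] = t, _["steps"] = (double)steps);
}

// Tau-leaping engine for the cancer stem cell model. State per clone i:
// N_CSC[i] and N_DC[i, m] for ages m = 0..M. Channels per clone:
//   CSC division (propensity rcsc * X_i * N_CSC); the division mode is
//     thinned per event into symmetric (p1: +1 CSC), asymmetric (p2: +1 DC0)
//     or symmetric commitment (p3: -1 CSC, +2 DC0);
//   DC division for m < M (rdc * X_i * N_DCm): -1 DCm, +2 DC(m+1);
//   DC death at age M (rdc * X_i * N_DCM): -1 DCM.
// Per leap, counts for channels that remove cells are clamped to the count
// available at the start of the leap so no species goes negative.
// [[Rcpp::export]]
List cpp_csc_tau_leap(NumericVector csc, NumericMatrix dc, NumericVector x,
                      double p1, double p2, double p3,
                      double rcsc, double rdc, double tau,
                      double n_crit, double t_max) {
  int C = csc.size();
  int A = dc.ncol();        // age classes 0..M  (A = M + 1)
  int nch = A + 1;          // channels per clone: CSC division + A DC classes
  std::vector<double> S(csc.begin(), csc.end());
  std::vector<double> D(C * A);
  for (int i = 0; i < C; ++i)
    for (int m = 0; m < A; ++m) D[i * A + m] = dc(i, m);

  double n = 0.0;
  for (int i = 0; i < C; ++i) n += S[i];
  for (size_t j = 0; j < D.size(); ++j) n += D[j];

  double t = 0.0;
  long steps = 0;
  bool stalled = false;
  std::vector<double> cum(C * nch);
  std::vector<double> k1(C), k2(C), k3(C), kdc(C * A);

  while (n < n_crit && n > 0.0 && t < t_max) {
    // cumulative propensities, channel layout: clone-major
    double acc = 0.0;
    for (int i = 0; i < C; ++i) {
      double xi = x[i];
      acc += rcsc * xi * S[i];
      cum[i * nch] = acc;
      for (int m = 0; m < A; ++m) {
        acc += rdc * xi * D[i * A + m];
        cum[i * nch + 1 + m] = acc;
      }
    }
    if (acc <= 0.0) { stalled = n > 0.0; break; }

    double K = R::rpois(acc * tau);
    if (K > 0.5) {
      std::fill(k1.begin(), k1.end(), 0.0);
      std::fill(k2.begin(), k2.end(), 0.0);
      std::fill(k3.begin(), k3.end(), 0.0);
      std::fill(kdc.begin(), kdc.end(), 0.0);
      int Ki = (int)K;
      for (int e = 0; e < Ki; ++e) {
        int ch = pick_channel(cum, unif_rand() * acc);
        int i = ch / nch, off = ch % nch;
        if (off == 0) {
          double u = unif_rand();
          if (u < p1) k1[i] += 1.0;
          else if (u < p1 + p2) k2[i] += 1.0;
          else k3[i] += 1.0;
        } else {
          kdc[i * A + (off - 1)] += 1.0;
        }
      }
      // apply with clamping against start-of-leap counts
      for (int i = 0; i < C; ++i) {
        double *d = &D[i * A];
        double k3c = std::min(k3[i], S[i]);
        double delta = k1[i] + k2[i] + k3c;
        S[i] += k1[i] - k3c;
        double carry = k2[i] + 2.0 * k3c; // cells arriving in DC age 0
        for (int m = 0; m < A; ++m) {
          double kc = std::min(kdc[i * A + m], d[m]);
          double newd = d[m] - kc + carry;
          if (m < A - 1) {       // division into next age class
            carry = 2.0 * kc;
            delta += kc;
          } else {               // death at maximum age
            carry = 0.0;
            delta -= kc;
          }
          d[m] = newd;
        }
        n += delta;
      }
    }
    t += tau;
    ++steps;
  }

  NumericMatrix dcout(C, A);
  for (int i = 0; i < C; ++i)
    for (int m = 0; m < A; ++m) dcout(i, m) = D[i * A + m];
  return List::create(_["csc"] = NumericVector(S.begin(), S.end()),
                      _["dc"] = dcout,
                      _["elapsed"] = t, _["steps"] = (double)steps,
                      _["extinct"] = (n <= 0.0), _["stalled"] = stalled,
                      _["n"] = n);
}
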