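#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Deterministic tie perturbation: unit i (0-based, within its layer) has its
// drive lowered by (i + 1) * TIE_EPS, so equal drives resolve to the lowest
// index. TIE_EPS is far below any meaningful drive difference.
static const double TIE_EPS = 1e-9;

static double kwta_threshold_impl(const double *d, int n, int k) {
  if (k <= 0) {
    double mx = d[0] - TIE_EPS;
    for (int i = 1; i < n; ++i) {
      double v = d[i] - (i + 1) * TIE_EPS;
      if (v > mx) mx = v;
    }
    return mx + 1.0;
  }
  if (k >= n) {
    double mn = d[0] - TIE_EPS;
    for (int i = 1; i < n; ++i) {
      double v = d[i] - (i + 1) * TIE_EPS;
      if (v < mn) mn = v;
    }
    return mn - 1.0;
  }
  static thread_local std::vector<double> v;
  v.resize(n);
  for (int i = 0; i < n; ++i) v[i] = d[i] - (i + 1) * TIE_EPS;
  std::nth_element(v.begin(), v.begin() + (k - 1), v.end(),
                   std::greater<double>());
  double kth = v[k - 1];
  std::nth_element(v.begin() + k, v.begin() + k, v.end(),
                   std::greater<double>());
  double k1th = v[k];
  return 0.5 * (kth + k1th);
}

//' @noRd
// [[Rcpp::export]]
double cpp_kwta_threshold(NumericVector drives, int k) {
  int n = drives.size();
  if (k < 0 || k > n) stop("k must be between 0 and length(drives)");
  if (n == 0) stop("empty drive vector");
  return kwta_threshold_impl(drives.begin(), n, k);
}

// Synchronous two-phase settling. Weight matrices are receiver x sender.
// Layers are laid out in one concatenated activation vector via `offsets`
// (0-based). `pscale` is rel_weight / k_active(source). Sub-threshold units
// transmit zero activity; winners take logistic(gain * (drive - theta)).
// Activations relax toward their target with under-relaxation `step`.
//' @noRd
// [[Rcpp::export]]
List cpp_settle(List weights, IntegerVector psrc, IntegerVector ptgt,
                NumericVector pscale, IntegerVector offsets,
                IntegerVector sizes, IntegerVector kvec,
                LogicalVector clamped, NumericVector acts0, double gain,
                int max_cycles, double tol, double step) {
  int n_lay = sizes.size();
  int n_proj = psrc.size();
  int total = acts0.size();
  NumericVector acts = clone(acts0);
  // `drive` is the instantaneous accumulation; `idrive` the time-integrated
  // net input actually fed to the inhibition/activation step
  std::vector<double> drive(total), idrive(total, 0.0);
  bool have_idrive = false;

  // keep raw pointers to the weight matrices (receiver x sender, col-major:
  // column i holds all targets of sender i)
  std::vector<const double *> wptr(n_proj);
  std::vector<int> wrows(n_proj);
  for (int p = 0; p < n_proj; ++p) {
    NumericMatrix W = weights[p];
    wptr[p] = W.begin();
    wrows[p] = W.nrow();
  }

  // contributions from clamped senders never change within a settle;
  // accumulate them once
  std::vector<double> cdrive(total, 0.0);
  for (int p = 0; p < n_proj; ++p) {
    int s = psrc[p], t = ptgt[p];
    if (clamped[t] || !clamped[s]) continue;
    int off_s = offsets[s], off_t = offsets[t];
    int ns = sizes[s], nt = sizes[t];
    double sc = pscale[p];
    const double *W = wptr[p];
    double *dr = &cdrive[off_t];
    for (int i = 0; i < ns; ++i) {
      double a = acts[off_s + i];
      if (a <= 0.0) continue;
      double as = a * sc;
      const double *col = W + (std::size_t)i * nt;
      for (int j = 0; j < nt; ++j) dr[j] += as * col[j];
    }
  }

  int cycle = 0;
  bool converged = false;
  double maxdiff = 0.0;
  for (cycle = 1; cycle <= max_cycles; ++cycle) {
    drive = cdrive;
    for (int p = 0; p < n_proj; ++p) {
      int s = psrc[p], t = ptgt[p];
      if (clamped[t] || clamped[s]) continue;
      int off_s = offsets[s], off_t = offsets[t];
      int ns = sizes[s], nt = sizes[t];
      double sc = pscale[p];
      const double *W = wptr[p];
      double *dr = &drive[off_t];
      for (int i = 0; i < ns; ++i) {
        double a = acts[off_s + i];
        if (a <= 0.0) continue;
        double as = a * sc;
        const double *col = W + (std::size_t)i * nt;
        for (int j = 0; j < nt; ++j) dr[j] += as * col[j];
      }
    }

    // integrate net input with the same under-relaxation as activations
    if (!have_idrive) {
      idrive = drive;
      have_idrive = true;
    } else {
      for (int u = 0; u < total; ++u)
        idrive[u] += step * (drive[u] - idrive[u]);
    }

    maxdiff = 0.0;
    for (int l = 0; l < n_lay; ++l) {
      if (clamped[l]) continue;
      int off = offsets[l], n = sizes[l], k = kvec[l];
      double theta = kwta_threshold_impl(&idrive[off], n, k);
      double msum = 0.0;
      int mcount = 0;
      for (int j = 0; j < n; ++j) {
        double v = idrive[off + j] - (j + 1) * TIE_EPS;
        if (v > theta) {
          msum += v - theta;
          ++mcount;
        }
      }
      // normalize margins by the mean winner margin so activations are
      // O(1) whatever the layer's drive scale
      double denom = (mcount > 0) ? msum / mcount : 1.0;
      if (denom <= 0.0) denom = 1.0;
      for (int j = 0; j < n; ++j) {
        double dp = idrive[off + j] - (j + 1) * TIE_EPS;
        // winners take a saturating function of their normalized
        // suprathreshold margin; zero exactly at threshold keeps the map
        // continuous across the winner boundary, and sub-threshold units
        // transmit nothing
        double target = 0.0;
        if (dp > theta) target = std::tanh(gain * (dp - theta) / denom);
        double a = acts[off + j];
        double na = a + step * (target - a);
        if (na < 1e-8) na = 0.0;
        double df = std::fabs(na - a);
        if (df > maxdiff) maxdiff = df;
        acts[off + j] = na;
      }
    }
    if (maxdiff < tol) {
      converged = true;
      break;
    }
  }
  if (!converged) cycle = max_cycles;

  return List::create(_["acts"] = acts, _["cycles"] = cycle,
                      _["converged"] = converged, _["max_change"] = maxdiff);
}

// Contrastive Hebbian update with a small Hebbian mix and soft weight
// bounding, applied in place. W is receiver x sender; x are sender-phase
// activations, y receiver-phase activations.
//' @noRd
// [[Rcpp::export]]
void cpp_chl_update(NumericMatrix W, NumericVector xm, NumericVector xp,
                    NumericVector ym, NumericVector yp, double rate,
                    double lambda, bool soft) {
  int nt = W.nrow(), ns = W.ncol();
  if (xm.size() != ns || xp.size() != ns || ym.size() != nt ||
      yp.size() != nt)
    stop("phase vector lengths do not match weight dimensions");
  // receivers silent in both phases contribute nothing
  std::vector<int> act_j;
  act_j.reserve(nt);
  for (int j = 0; j < nt; ++j)
    if (yp[j] > 0.0 || ym[j] > 0.0) act_j.push_back(j);
  if (act_j.empty()) return;

  double *w = W.begin();
  for (int i = 0; i < ns; ++i) {
    double xpi = xp[i], xmi = xm[i];
    double *col = w + (std::size_t)i * nt;
    for (std::size_t a = 0; a < act_j.size(); ++a) {
      int j = act_j[a];
      double wij = col[j];
      double raw = (1.0 - lambda) * (xpi * yp[j] - xmi * ym[j]) +
                   lambda * yp[j] * (xpi - wij);
      if (soft) raw *= (raw > 0.0) ? (1.0 - wij) : wij;
      double nw = wij + rate * raw;
      if (nw < 0.0) nw = 0.0;
      if (nw > 1.0) nw = 1.0;
      col[j] = nw;
    }
  }
}
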