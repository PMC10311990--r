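#include <Rcpp.h>
using namespace Rcpp;

// Spike rasters arrive as event lists (neuron id per spike, global bin per
// spike). The hot loops below work on a CSR-style index: ptr[b]..ptr[b+1]-1
// delimit the neurons spiking in global bin b (trial-major bin order).

// [[Rcpp::export]]
List bin_events_cpp(IntegerVector gbin, IntegerVector neuron, int n_bins) {
  int ne = gbin.size();
  std::vector<int> cnt(n_bins + 1, 0);
  for (int e = 0; e < ne; ++e) {
    int g = gbin[e];
    if (g < 1 || g > n_bins) stop("event bin out of range");
    cnt[g]++;
  }
  for (int b = 1; b <= n_bins; ++b) cnt[b] += cnt[b - 1];
  IntegerVector idx(ne);
  std::vector<int> fill(n_bins, 0);
  for (int e = 0; e < ne; ++e) {
    int g = gbin[e];
    idx[cnt[g - 1] + fill[g - 1]++] = neuron[e];
  }
  IntegerVector ptr(n_bins + 1);
  for (int b = 0; b <= n_bins; ++b) ptr[b] = cnt[b];
  return List::create(_["ptr"] = ptr, _["idx"] = idx);
}

// Memoryless threshold unit: V = sum_i x_i w_i per bin, spike iff V > threshold
// (strict). Empty bins give V = 0.
// [[Rcpp::export]]
IntegerVector threshold_forward_cpp(IntegerVector ptr, IntegerVector idx,
                                    NumericVector w, double threshold) {
  int nb = ptr.size() - 1;
  IntegerVector y(nb);
  for (int b = 0; b < nb; ++b) {
    double V = 0.0;
    for (int e = ptr[b]; e < ptr[b + 1]; ++e) V += w[idx[e] - 1];
    y[b] = (V > threshold) ? 1 : 0;
  }
  return y;
}

// Leaky integrate-and-fire: explicit Euler
//   V <- V + dt * (-(V - Ve) + Ipost * (sum_i w_i x_i) * Rm) / tau
// with strict threshold crossing and reset, membrane state reset to Ve at
// every trial boundary.
// [[Rcpp::export]]
List lif_forward_cpp(IntegerVector ptr, IntegerVector idx, NumericVector w,
                     int bins_per_trial, double Ve, double Rm, double tau,
                     double dt, double Ipost, double Vt, double Vreset,
                     bool return_potential) {
  int nb = ptr.size() - 1;
  IntegerVector y(nb);
  NumericVector Vout(return_potential ? nb : 0);
  double V = Ve;
  for (int b = 0; b < nb; ++b) {
    if (b % bins_per_trial == 0) V = Ve;
    double I = 0.0;
    for (int e = ptr[b]; e < ptr[b + 1]; ++e) I += w[idx[e] - 1];
    V += dt * (-(V - Ve) + Ipost * I * Rm) / tau;
    if (V > Vt) {
      y[b] = 1;
      V = Vreset;
    }
    if (return_potential) Vout[b] = V;
  }
  return List::create(_["spikes"] = y, _["potential"] = Vout);
}

// Online perceptron training: one pass visits every bin in chronological
// order (trials in given order), predicts with the current weights through
// the forward model, then applies w_i += lr * (y - y') * x_i. For the
// memoryless threshold model empty bins can be skipped: V = 0 <= threshold
// so y' = 0, and x = 0 makes the update vanish; bins with y == 1 and no
// input still count as errors (precomputed once).
// model: 0 = threshold unit, 1 = leaky integrate-and-fire.
// [[Rcpp::export]]
List perceptron_train_cpp(IntegerVector ptr, IntegerVector idx,
                          IntegerVector y, NumericVector w0, double lr,
                          int n_iter, int model, double threshold,
                          int bins_per_trial, double Ve, double Rm,
                          double tau, double dt, double Ipost, double Vt,
                          double Vreset,
                          Nullable<NumericVector> w_true_) {
  NumericVector w = clone(w0);
  int nb = ptr.size() - 1;
  int nw = w.size();
  bool has_true = w_true_.isNotNull();
  NumericVector wt;
  if (has_true) {
    wt = NumericVector(w_true_.get());
    if (wt.size() != nw) stop("w_true length mismatch");
  }
  NumericVector rmse(n_iter, NA_REAL);
  NumericVector errrate(n_iter);

  long long empty_pos = 0;
  if (model == 0) {
    for (int b = 0; b < nb; ++b)
      if (ptr[b + 1] == ptr[b] && y[b] == 1) ++empty_pos;
  }

  for (int it = 0; it < n_iter; ++it) {
    long long nerr = (model == 0) ? empty_pos : 0;
    double V = Ve;
    for (int b = 0; b < nb; ++b) {
      int s = ptr[b], eend = ptr[b + 1];
      int yp;
      if (model == 0) {
        if (s == eend) continue;
        double Vb = 0.0;
        for (int e = s; e < eend; ++e) Vb += w[idx[e] - 1];
        yp = (Vb > threshold) ? 1 : 0;
      } else {
        if (b % bins_per_trial == 0) V = Ve;
        double I = 0.0;
        for (int e = s; e < eend; ++e) I += w[idx[e] - 1];
        V += dt * (-(V - Ve) + Ipost * I * Rm) / tau;
        if (V > Vt) {
          yp = 1;
          V = Vreset;
        } else {
          yp = 0;
        }
      }
      int diff = y[b] - yp;
      if (diff != 0) {
        ++nerr;
        double d = lr * diff;
        for (int e = s; e < eend; ++e) w[idx[e] - 1] += d;
      }
    }
    errrate[it] = (double)nerr / (double)nb;
    if (has_true) {
      double ss = 0.0;
      for (int i = 0; i < nw; ++i) {
        double dd = w[i] - wt[i];
        ss += dd * dd;
      }
      rmse[it] = std::sqrt(ss / nw);
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = w, _["error_rate"] = errrate,
                      _["rmse"] = rmse);
}
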