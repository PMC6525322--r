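#include <Rcpp.h>
using namespace Rcpp;

// Variant codes (kept in sync with variant_code() on the R side):
// 0 = full, 1 = facilitation_only, 2 = no_c_to_f_plasticity,
// 3 = no_conjunctive_layer

// Baseline-rectified logistic: logistic in shape, but phi(0) == 0 exactly so
// a silent network with zero input is a true fixed point.
static inline double phi(double x, double gain, double threshold) {
  double base = 1.0 / (1.0 + std::exp(gain * threshold));
  double raw = 1.0 / (1.0 + std::exp(-gain * (x - threshold)));
  double v = (raw - base) / (1.0 - base);
  return v > 0.0 ? v : 0.0;
}

static inline double clip01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

// Renormalize each row of W (nr x nc) to euclidean norm w_norm.
static void normalize_rows(NumericMatrix W, double w_norm) {
  int nr = W.nrow(), nc = W.ncol();
  for (int r = 0; r < nr; ++r) {
    double ss = 0.0;
    for (int j = 0; j < nc; ++j) ss += W(r, j) * W(r, j);
    if (ss > 0.0) {
      double s = w_norm / std::sqrt(ss);
      for (int j = 0; j < nc; ++j) W(r, j) *= s;
    }
  }
}

// Run n_steps of rate dynamics + continuous plasticity with constant external
// input. Mutates copies of the state vectors/matrices and returns the updated
// state together with the visited rates.
// [[Rcpp::export]]
List run_epoch_cpp(List state, NumericVector i_ext, int n_steps, List params,
                   bool plastic = true, bool record = true) {
  NumericVector f = clone(as<NumericVector>(state["f"]));
  NumericVector c = clone(as<NumericVector>(state["c"]));
  NumericMatrix W_fc = clone(as<NumericMatrix>(state["W_fc"]));
  NumericMatrix W_cf = clone(as<NumericMatrix>(state["W_cf"]));
  NumericMatrix W_ff = clone(as<NumericMatrix>(state["W_ff"]));
  NumericVector u_f = clone(as<NumericVector>(state["u_f"]));
  NumericVector u_c = clone(as<NumericVector>(state["u_c"]));
  int t = as<int>(state["t"]);

  const int n_dims = as<int>(params["n_dims"]);
  const int n_feat = as<int>(params["n_feat_per_dim"]);
  const int n_f = n_dims * n_feat;
  const int n_c = as<int>(params["n_conj"]);
  const double tau = as<double>(params["tau"]);
  const double beta_f = as<double>(params["beta_f"]);
  const double beta_c = as<double>(params["beta_c"]);
  const double eta = as<double>(params["eta"]);
  const double w_norm = as<double>(params["w_norm"]);
  const double sigma = as<double>(params["noise_sigma"]);
  const double gain = as<double>(params["gain"]);
  const double threshold = as<double>(params["threshold"]);
  const int variant = as<int>(params["variant_code"]);
  const double facil_U = as<double>(params["facil_U"]);
  const double facil_tau = as<double>(params["facil_tau"]);

  if (i_ext.size() != n_f) stop("external input has length %d, expected %d",
                                (int)i_ext.size(), n_f);
  if (f.size() != n_f || c.size() != n_c)
    stop("state dimensions do not match params");

  NumericMatrix trace_f(record ? n_steps : 0, n_f);
  NumericMatrix trace_c(record ? n_steps : 0, n_c);

  std::vector<double> drive_f(n_f), drive_c(n_c), dimsum(n_dims);

  RNGScope scope;

  for (int s = 0; s < n_steps; ++s) {
    // --- recurrent drive onto features ---
    if (variant == 3) {
      for (int i = 0; i < n_f; ++i) {
        double acc = 0.0;
        for (int k = 0; k < n_f; ++k) acc += W_ff(i, k) * f[k];
        drive_f[i] = acc;
      }
    } else if (variant == 1) {
      // facilitation-gated transmission: efficacy is the presynaptic
      // facilitation variable itself (shared across postsynaptic targets)
      for (int i = 0; i < n_f; ++i) {
        double acc = 0.0;
        for (int j = 0; j < n_c; ++j) acc += W_cf(i, j) * u_c[j] * c[j];
        drive_f[i] = acc;
      }
    } else {
      for (int i = 0; i < n_f; ++i) {
        double acc = 0.0;
        for (int j = 0; j < n_c; ++j) acc += W_cf(i, j) * c[j];
        drive_f[i] = acc;
      }
    }

    // within-dimension lateral inhibition among features
    for (int d = 0; d < n_dims; ++d) {
      double acc = 0.0;
      for (int k = 0; k < n_feat; ++k) acc += f[d * n_feat + k];
      dimsum[d] = acc;
    }
    for (int i = 0; i < n_f; ++i) {
      int d = i / n_feat;
      drive_f[i] += i_ext[i] - beta_f * (dimsum[d] - f[i]);
      if (sigma > 0.0) drive_f[i] += R::rnorm(0.0, sigma);
    }

    // --- drive onto conjunctive units ---
    if (variant != 3) {
      double csum = 0.0;
      for (int j = 0; j < n_c; ++j) csum += c[j];
      for (int j = 0; j < n_c; ++j) {
        double acc = 0.0;
        if (variant == 1) {
          for (int i = 0; i < n_f; ++i) acc += W_fc(j, i) * u_f[i] * f[i];
        } else {
          for (int i = 0; i < n_f; ++i) acc += W_fc(j, i) * f[i];
        }
        drive_c[j] = acc - beta_c * (csum - c[j]);
        if (sigma > 0.0) drive_c[j] += R::rnorm(0.0, sigma);
      }
    }

    // --- leaky relaxation toward nonlinearity of drive, then clip ---
    for (int i = 0; i < n_f; ++i) {
      f[i] = clip01(f[i] + (phi(drive_f[i], gain, threshold) - f[i]) / tau);
      if (!std::isfinite(f[i]))
        stop("non-finite feature rate at step t=%d", t + 1);
    }
    if (variant != 3) {
      for (int j = 0; j < n_c; ++j) {
        c[j] = clip01(c[j] + (phi(drive_c[j], gain, threshold) - c[j]) / tau);
        if (!std::isfinite(c[j]))
          stop("non-finite conjunctive rate at step t=%d", t + 1);
      }
    }
    ++t;

    // --- continuous plasticity (all epochs, including blanks) ---
    if (plastic) {
      if ((variant == 0 || variant == 2) && eta > 0.0) {
        for (int j = 0; j < n_c; ++j)
          for (int i = 0; i < n_f; ++i)
            W_fc(j, i) += eta * c[j] * f[i];
        normalize_rows(W_fc, w_norm);
        if (variant == 0) {
          for (int i = 0; i < n_f; ++i)
            for (int j = 0; j < n_c; ++j)
              W_cf(i, j) += eta * f[i] * c[j];
          normalize_rows(W_cf, w_norm);
        }
      } else if (variant == 3 && eta > 0.0) {
        for (int i = 0; i < n_f; ++i)
          for (int k = 0; k < n_f; ++k)
            if (i != k) W_ff(i, k) += eta * f[i] * f[k];
        normalize_rows(W_ff, w_norm);
      } else if (variant == 1) {
        // presynaptic short-term facilitation, shared across postsynaptic
        // targets (no Hebbian term)
        for (int i = 0; i < n_f; ++i)
          u_f[i] += facil_U * (1.0 - u_f[i]) * f[i] - u_f[i] / facil_tau;
        for (int j = 0; j < n_c; ++j)
          u_c[j] += facil_U * (1.0 - u_c[j]) * c[j] - u_c[j] / facil_tau;
      }
    }

    if (record) {
      for (int i = 0; i < n_f; ++i) trace_f(s, i) = f[i];
      for (int j = 0; j < n_c; ++j) trace_c(s, j) = c[j];
    }
  }

  List out_state = List::create(
    _["f"] = f, _["c"] = c, _["W_fc"] = W_fc, _["W_cf"] = W_cf,
    _["W_ff"] = W_ff, _["u_f"] = u_f, _["u_c"] = u_c, _["t"] = t);
  out_state.attr("class") = CharacterVector::create("wm_state");
  return List::create(_["state"] = out_state, _["trace_f"] = trace_f,
                      _["trace_c"] = trace_c);
}
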