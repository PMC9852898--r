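#include <Rcpp.h>
using namespace Rcpp;

// Density of the first-passage time of a unit-diffusion Wiener process at the
// LOWER of two absorbing boundaries {0, 1}, started at relative position w,
// zero drift, expressed in normalized time u = t / alpha^2. Two equivalent
// series expansions are available; per evaluation the one needing fewer terms
// for truncation error < eps is used (small-time vs large-time form).
static double wfpt_scaled(double u, double w, double eps) {
  if (u <= 0.0) return 0.0;

  // terms required by each expansion
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * u * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * eps) / (M_PI * M_PI * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }

  double p = 0.0;
  if (ks < kl) {                         // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -((K - 1) / 2);
    int hi = (K - 1) / 2 + ((K - 1) % 2);
    for (int k = lo; k <= hi; ++k) {
      double z = w + 2.0 * k;
      p += z * std::exp(-z * z / (2.0 * u));
    }
    p /= std::sqrt(2.0 * M_PI * u * u * u);
  } else {                               // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) *
           std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return p;
}

// First-passage-time density of the drift-diffusion process with boundary
// separation alpha, non-decision time tau, relative start beta, drift delta,
// unit diffusion. `upper = true` gives the density of hits at the upper
// boundary (the healthy choice); internally evaluated via reflection
// (w -> 1 - beta, v -> -delta) of the lower-boundary form.
// [[Rcpp::export]]
NumericVector dwiener_cpp(NumericVector t, double alpha, double tau,
                          double beta, double delta, bool upper,
                          bool give_log, double eps = 1e-10) {
  int n = t.size();
  NumericVector out(n);
  double w = upper ? 1.0 - beta : beta;
  double v = upper ? -delta : delta;
  double a2 = alpha * alpha;
  for (int i = 0; i < n; ++i) {
    double tt = t[i] - tau;
    if (!R_finite(tt) || tt <= 0.0) {
      out[i] = give_log ? R_NegInf : 0.0;
      continue;
    }
    double u = tt / a2;
    double p = wfpt_scaled(u, w, eps);
    if (p <= 0.0) {
      out[i] = give_log ? R_NegInf : 0.0;
    } else if (give_log) {
      out[i] = std::log(p) - std::log(a2) - v * alpha * w - v * v * tt / 2.0;
    } else {
      out[i] = p / a2 * std::exp(-v * alpha * w - v * v * tt / 2.0);
    }
  }
  return out;
}

// Euler-Maruyama simulation of the same process. Within-step boundary
// crossings are detected with the Brownian-bridge crossing probability, which
// removes the leading O(sqrt(dt)) bias of naive endpoint checking. Decision
// times exceeding tmax are returned as NA (caller decides the policy).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List rwiener_cpp(int n, double alpha, double tau, double beta, double delta,
                 double dt = 1e-3, double tmax = 60.0) {
  NumericVector rt(n);
  LogicalVector up(n);
  double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = beta * alpha;
    double tdec = 0.0;
    int hit = 0; // 0 none, 1 upper, -1 lower
    while (tdec < tmax) {
      double xn = x + delta * dt + sdt * norm_rand();
      tdec += dt;
      if (xn >= alpha) { hit = 1; }
      else if (xn <= 0.0) { hit = -1; }
      else {
        // bridge crossing probabilities for either boundary within the step
        double pu = std::exp(-2.0 * (alpha - x) * (alpha - xn) / dt);
        double pl = std::exp(-2.0 * x * xn / dt);
        double uu = unif_rand();
        if (uu < pu) hit = 1;
        else if (uu < pu + pl) hit = -1;
      }
      if (hit != 0) break;
      x = xn;
    }
    if (hit == 0) {
      rt[i] = NA_REAL;
      up[i] = NA_LOGICAL;
    } else {
      rt[i] = tau + tdec;
      up[i] = (hit == 1);
    }
  }
  return List::create(_["rt"] = rt, _["upper"] = up);
}

// Joint negative log-likelihood of (rt, boundary) pairs; kept in C++ because
// the optimizer calls it thousands of times per fit.
// [[Rcpp::export]]
double wiener_negloglik_cpp(NumericVector rt, LogicalVector upper,
                            double alpha, double tau, double beta,
                            double delta, double eps = 1e-10) {
  int n = rt.size();
  double nll = 0.0;
  double w_up = 1.0 - beta, v_up = -delta;
  double a2 = alpha * alpha;
  for (int i = 0; i < n; ++i) {
    double tt = rt[i] - tau;
    if (tt <= 0.0) return 1e10; // guarded -Inf log-likelihood
    double w = upper[i] ? w_up : beta;
    double v = upper[i] ? v_up : delta;
    double p = wfpt_scaled(tt / a2, w, eps);
    if (p <= 0.0 || !R_finite(p)) return 1e10;
    nll -= std::log(p) - std::log(a2) - v * alpha * w - v * v * tt / 2.0;
  }
  if (!R_finite(nll)) return 1e10;
  return nll;
}
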