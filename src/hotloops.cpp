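#include <Rcpp.h>
using namespace Rcpp;

// Simulate an order-1 Markov chain of DNA codes (A=1, C=2, G=3, T=4).
// `init` is the initial base distribution, `trans` a 4x4 row-stochastic
// transition matrix. Uses R's RNG, so results follow set.seed().
// [[Rcpp::export]]
IntegerVector markov_sim_cpp(int n, NumericVector init, NumericMatrix trans) {
  IntegerVector out(n);
  if (n <= 0) return out;
  double u = R::runif(0.0, 1.0);
  int s = 3;
  double acc = 0.0;
  for (int b = 0; b < 4; b++) {
    acc += init[b];
    if (u <= acc) { s = b; break; }
  }
  out[0] = s + 1;
  for (int i = 1; i < n; i++) {
    u = R::runif(0.0, 1.0);
    acc = 0.0;
    int t = 3;
    for (int b = 0; b < 4; b++) {
      acc += trans(s, b);
      if (u <= acc) { t = b; break; }
    }
    s = t;
    out[i] = s + 1;
  }
  return out;
}

// Sum log-PWM scores over all windows. `emb` is (n_windows x w) of base
// codes 1..5 (5 = N); `logpwm` is (w x 5) with column 5 a large negative
// sentinel so windows containing N are effectively excluded.
// [[Rcpp::export]]
NumericVector score_windows_cpp(IntegerMatrix emb, NumericMatrix logpwm) {
  int n = emb.nrow(), w = emb.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double s = 0.0;
    for (int j = 0; j < w; j++) {
      s += logpwm(j, emb(i, j) - 1);
    }
    out[i] = s;
  }
  return out;
}

// One ZOOPS Gibbs chain: initialise sites at random, then `iterations`
// sweeps; in each sweep every sequence's site is resampled from the
// posterior over all windows on both strands plus the no-site option.
// embF/embR: per-sequence (np x w) window code matrices (codes 1..5);
// bgF/bgR: per-sequence background log-probabilities per window.
// Returns the final site assignment (pos = 0 means no site; strand 1 =
// forward, 2 = reverse). Uses R's RNG throughout.
// [[Rcpp::export]]
List gibbs_chain_cpp(List embF, List embR, List bgF, List bgR, int w,
                     int iterations, double site_prior, NumericVector pseudo,
                     bool both_strands) {
  int n = embF.size();
  IntegerVector pos(n, 0), strand(n, 0);
  std::vector<double> counts(w * 4, 0.0);
  int nsites = 0;

  std::vector<IntegerMatrix> eF(n), eR(n);
  std::vector<NumericVector> bF(n), bR(n);
  std::vector<int> np(n);
  for (int i = 0; i < n; i++) {
    eF[i] = as<IntegerMatrix>(embF[i]);
    bF[i] = as<NumericVector>(bgF[i]);
    np[i] = eF[i].nrow();
    if (both_strands) {
      eR[i] = as<IntegerMatrix>(embR[i]);
      bR[i] = as<NumericVector>(bgR[i]);
    }
  }

  auto add_site = [&](int i, int p, int s, double sign) {
    IntegerMatrix &e = (s == 1) ? eF[i] : eR[i];
    for (int j = 0; j < w; j++) {
      int b = e(p - 1, j);
      if (b <= 4) counts[j * 4 + (b - 1)] += sign;
    }
  };

  // init: site with probability site_prior, uniform position/strand
  for (int i = 0; i < n; i++) {
    if (unif_rand() > site_prior) continue;
    int s = (both_strands && unif_rand() < 0.5) ? 2 : 1;
    int p = (int)(unif_rand() * np[i]) + 1;
    if (p > np[i]) p = np[i];
    // reject windows containing N
    IntegerMatrix &e = (s == 1) ? eF[i] : eR[i];
    bool hasN = false;
    for (int j = 0; j < w; j++) if (e(p - 1, j) > 4) { hasN = true; break; }
    if (hasN) continue;
    pos[i] = p; strand[i] = s;
    add_site(i, p, s, 1.0);
    nsites++;
  }

  std::vector<double> logpwm(w * 5);
  std::vector<double> llr;
  for (int it = 0; it < iterations; it++) {
    for (int i = 0; i < n; i++) {
      if (pos[i] > 0) {
        add_site(i, pos[i], strand[i], -1.0);
        nsites--;
      }
      double denom = (double)nsites + 1.0;
      for (int j = 0; j < w; j++) {
        for (int b = 0; b < 4; b++) {
          logpwm[j * 5 + b] = std::log((counts[j * 4 + b] + pseudo[b]) / denom);
        }
        logpwm[j * 5 + 4] = -1e9;
      }
      int nopt = both_strands ? 2 * np[i] : np[i];
      llr.resize(nopt);
      double m = 0.0;
      for (int p = 0; p < np[i]; p++) {
        double s = 0.0;
        for (int j = 0; j < w; j++) s += logpwm[j * 5 + (eF[i](p, j) - 1)];
        llr[p] = s - bF[i][p];
        if (llr[p] > m) m = llr[p];
      }
      if (both_strands) {
        for (int p = 0; p < np[i]; p++) {
          double s = 0.0;
          for (int j = 0; j < w; j++) s += logpwm[j * 5 + (eR[i](p, j) - 1)];
          llr[np[i] + p] = s - bR[i][p];
          if (llr[np[i] + p] > m) m = llr[np[i] + p];
        }
      }
      double wnone = std::exp(-m) * (1.0 - site_prior);
      double total = wnone;
      for (int p = 0; p < nopt; p++) {
        llr[p] = std::exp(llr[p] - m) * site_prior / nopt;
        total += llr[p];
      }
      double u = unif_rand() * total;
      int picked = 0; // 0 = no site
      double acc = wnone;
      if (u > acc) {
        for (int p = 0; p < nopt; p++) {
          acc += llr[p];
          if (u <= acc) { picked = p + 1; break; }
        }
        if (picked == 0) picked = nopt; // numerical tail
      }
      if (picked == 0) {
        pos[i] = 0; strand[i] = 0;
      } else {
        int s = (picked <= np[i]) ? 1 : 2;
        int p = (picked <= np[i]) ? picked : picked - np[i];
        pos[i] = p; strand[i] = s;
        add_site(i, p, s, 1.0);
        nsites++;
      }
    }
  }
  return List::create(_["pos"] = pos, _["strand"] = strand,
                      _["nsites"] = nsites);
}
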