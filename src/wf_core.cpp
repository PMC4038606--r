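#include <Rcpp.h>
using namespace Rcpp;

// Forward Wright-Fisher loop over independent sites.
//
// sizes:     haploid population size (2N) per generation, length T+1; sizes[0]
//            is the (empty) founding generation, transitions t = 1..T produce
//            generation t at size sizes[t].
// muL_*:     per-chromosome, per-generation mutation rate over the synonymous /
//            nonsynonymous target (already rescaled by lambda).
// shape, scale: gamma parameters of |s| for new nonsynonymous mutations
//            (scale already rescaled by lambda); neutral_ns forces s = 0.
// snapshot_at: sorted transition indices (1..T) after which the segregating
//            set is recorded.
//
// RNG calls are made in exactly the order of the reference R engine
// (wf_engine_r): one rbinom per site in storage order, then rpois (syn),
// rpois (ns) and one rgamma per new nonsynonymous site, so the two engines
// are stream-identical under a common seed.
//
// [[Rcpp::export]]
List wf_core_cpp(IntegerVector sizes, double muL_syn, double muL_ns,
                 double shape, double scale, bool neutral_ns,
                 IntegerVector snapshot_at) {
  const int T = sizes.size() - 1;
  std::vector<double> s;
  std::vector<int> cnt, org;
  std::vector<int> kl;  // 0 = synonymous, 1 = nonsynonymous
  s.reserve(4096); cnt.reserve(4096); org.reserve(4096); kl.reserve(4096);

  int n_fixed_syn = 0, n_fixed_ns = 0;
  List snaps(snapshot_at.size());
  int next_snap = 0;

  RNGScope scope;
  for (int t = 1; t <= T; ++t) {
    const int twoN_cur = sizes[t - 1];
    const int twoN_next = sizes[t];

    // Selection (genic, deterministic) then binomial drift; compact in place.
    size_t j = 0;
    const size_t n = s.size();
    for (size_t i = 0; i < n; ++i) {
      const double p = (double) cnt[i] / (double) twoN_cur;
      double pstar;
      if (s[i] <= -1.0) {
        pstar = 0.0;  // lethal
      } else {
        pstar = p * (1.0 + s[i]) / (1.0 + p * s[i]);
      }
      const int c = (int) R::rbinom((double) twoN_next, pstar);
      if (c <= 0) continue;
      if (c >= twoN_next) {  // fixed: drop from the segregating set
        if (kl[i] == 0) ++n_fixed_syn; else ++n_fixed_ns;
        continue;
      }
      s[j] = s[i]; cnt[j] = c; org[j] = org[i]; kl[j] = kl[i];
      ++j;
    }
    s.resize(j); cnt.resize(j); org.resize(j); kl.resize(j);

    // Mutational influx: Poisson(2N * mu * L) new single-copy mutations
    // among the offspring generation's 2N chromosomes (infinite-sites
    // convention: a mutation first drifts in the generation after the one
    // in which it arose).
    const int k_syn = (int) R::rpois((double) twoN_next * muL_syn);
    const int k_ns  = (int) R::rpois((double) twoN_next * muL_ns);
    if (twoN_next > 1) {
      for (int i = 0; i < k_syn; ++i) {
        s.push_back(0.0); cnt.push_back(1); org.push_back(t); kl.push_back(0);
      }
      for (int i = 0; i < k_ns; ++i) {
        double si = neutral_ns ? 0.0 : -R::rgamma(shape, scale);
        s.push_back(si); cnt.push_back(1); org.push_back(t); kl.push_back(1);
      }
    }

    if (next_snap < snapshot_at.size() && snapshot_at[next_snap] == t) {
      snaps[next_snap] = DataFrame::create(
        _["s"] = NumericVector(s.begin(), s.end()),
        _["klass"] = IntegerVector(kl.begin(), kl.end()),
        _["count"] = IntegerVector(cnt.begin(), cnt.end()),
        _["origin"] = IntegerVector(org.begin(), org.end()));
      ++next_snap;
    }
  }

  return List::create(_["snapshots"] = snaps,
                      _["n_fixed_syn"] = n_fixed_syn,
                      _["n_fixed_ns"] = n_fixed_ns);
}
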