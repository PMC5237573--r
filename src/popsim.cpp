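#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Forward Wright-Fisher simulator with an infinite-sites mutation model.
// A haplotype is the sorted vector of its derived-mutation positions
// (Morgan scale, continuous on [0, genetic_length)); positions double as
// mutation identities, which is exact under infinite sites.

typedef std::vector<double> Hap;

static void make_gamete(const Hap &h1, const Hap &h2, double gen_len,
                        double u_gamete, Hap &out, std::vector<double> &cxbuf) {
  out.clear();
  int ncx = (int)R::rpois(gen_len);
  if (ncx == 0) {
    out = (unif_rand() < 0.5) ? h1 : h2;
  } else {
    cxbuf.clear();
    for (int i = 0; i < ncx; i++) cxbuf.push_back(unif_rand() * gen_len);
    std::sort(cxbuf.begin(), cxbuf.end());
    cxbuf.push_back(gen_len + 1.0); // sentinel closes the last segment
    bool use1 = unif_rand() < 0.5;
    double lo = 0.0;
    for (size_t k = 0; k < cxbuf.size(); k++) {
      double hi = cxbuf[k];
      const Hap &src = use1 ? h1 : h2;
      Hap::const_iterator it_lo = std::lower_bound(src.begin(), src.end(), lo);
      Hap::const_iterator it_hi = std::lower_bound(src.begin(), src.end(), hi);
      out.insert(out.end(), it_lo, it_hi);
      use1 = !use1;
      lo = hi;
    }
  }
  if (u_gamete > 0) {
    int nmut = (int)R::rpois(u_gamete);
    for (int i = 0; i < nmut; i++) {
      double pos = unif_rand() * gen_len;
      out.insert(std::upper_bound(out.begin(), out.end(), pos), pos);
    }
  }
}

// Remove mutations fixed in the whole breeding population; they no longer
// segregate and only inflate the haplotype lists. Removed positions are
// recorded so downstream code can distinguish fixation from loss.
static void prune_fixed(std::vector<Hap> &pop, std::vector<double> &fixed_log) {
  if (pop.empty()) return;
  Hap common = pop[0], tmp;
  for (size_t i = 1; i < pop.size() && !common.empty(); ++i) {
    tmp.clear();
    std::set_intersection(common.begin(), common.end(), pop[i].begin(),
                          pop[i].end(), std::back_inserter(tmp));
    common.swap(tmp);
  }
  if (common.empty()) return;
  fixed_log.insert(fixed_log.end(), common.begin(), common.end());
  for (size_t i = 0; i < pop.size(); ++i) {
    tmp.clear();
    std::set_difference(pop[i].begin(), pop[i].end(), common.begin(),
                        common.end(), std::back_inserter(tmp));
    pop[i].swap(tmp);
  }
}

static void reproduce(const std::vector<Hap> &cur, int n_offspring,
                      double gen_len, double u_gamete, std::vector<Hap> &nxt,
                      std::vector<double> &cxbuf) {
  int n_par = (int)cur.size() / 2;
  nxt.resize(2 * (size_t)n_offspring);
  for (int i = 0; i < n_offspring; i++) {
    int p1 = (int)(unif_rand() * n_par);
    if (p1 == n_par) p1--;
    int p2 = (int)(unif_rand() * n_par);
    if (p2 == n_par) p2--;
    make_gamete(cur[2 * p1], cur[2 * p1 + 1], gen_len, u_gamete, nxt[2 * i], cxbuf);
    make_gamete(cur[2 * p2], cur[2 * p2 + 1], gen_len, u_gamete, nxt[2 * i + 1], cxbuf);
  }
}

// [[Rcpp::export]]
List simulate_population_cpp(IntegerVector ne_schedule, int final_n,
                             double mutation_rate, double physical_length,
                             double genetic_length,
                             Nullable<List> init_haplotypes = R_NilValue,
                             int prune_every = 25) {
  double u_gamete = mutation_rate * physical_length;
  int n_gen = ne_schedule.size();
  std::vector<Hap> cur, nxt;
  std::vector<double> cxbuf, fixed_log;

  if (init_haplotypes.isNotNull()) {
    List init(init_haplotypes);
    cur.resize(init.size());
    for (int i = 0; i < init.size(); i++) {
      NumericVector h = init[i];
      cur[i].assign(h.begin(), h.end());
      std::sort(cur[i].begin(), cur[i].end());
    }
  } else {
    cur.assign(2 * (size_t)ne_schedule[0], Hap());
  }

  for (int g = 1; g < n_gen; g++) {
    reproduce(cur, ne_schedule[g], genetic_length, u_gamete, nxt, cxbuf);
    cur.swap(nxt);
    if (prune_every > 0 && g % prune_every == 0) prune_fixed(cur, fixed_log);
  }
  // expand the final breeding population into the genotyped sample
  reproduce(cur, final_n, genetic_length, u_gamete, nxt, cxbuf);
  cur.swap(nxt);

  // collect segregating sites over the 2 * final_n sampled haplotypes
  size_t n_hap = cur.size();
  std::vector<double> all;
  size_t tot = 0;
  for (size_t i = 0; i < n_hap; i++) tot += cur[i].size();
  all.reserve(tot);
  for (size_t i = 0; i < n_hap; i++)
    all.insert(all.end(), cur[i].begin(), cur[i].end());
  std::sort(all.begin(), all.end());

  std::vector<double> pos;
  std::vector<int> cnt;
  size_t i = 0;
  while (i < all.size()) {
    size_t j = i;
    while (j < all.size() && all[j] == all[i]) j++;
    size_t c = j - i;
    if (c < n_hap) { // segregating (fixed sites dropped)
      pos.push_back(all[i]);
      cnt.push_back((int)c);
    } else {
      fixed_log.push_back(all[i]);
    }
    i = j;
  }

  int S = (int)pos.size();
  RawMatrix haps((int)n_hap, S);
  for (size_t h = 0; h < n_hap; h++) {
    const Hap &hap = cur[h];
    for (size_t m = 0; m < hap.size(); m++) {
      std::vector<double>::iterator it =
          std::lower_bound(pos.begin(), pos.end(), hap[m]);
      if (it != pos.end() && *it == hap[m])
        haps((int)h, (int)(it - pos.begin())) = 1;
    }
  }

  std::sort(fixed_log.begin(), fixed_log.end());
  return List::create(
      _["haplotypes"] = haps,
      _["positions_morgan"] = NumericVector(pos.begin(), pos.end()),
      _["counts"] = IntegerVector(cnt.begin(), cnt.end()),
      _["fixed_positions_morgan"] =
          NumericVector(fixed_log.begin(), fixed_log.end()));
}

// Genotype dosages (0/1/2 copies of the derived allele) for selected sites.
// `cols` is 1-based.
// [[Rcpp::export]]
IntegerMatrix genotypes_from_haps(RawMatrix haps, IntegerVector cols) {
  int n = haps.nrow() / 2, k = cols.size();
  IntegerMatrix g(n, k);
  for (int j = 0; j < k; j++) {
    int c = cols[j] - 1;
    for (int i = 0; i < n; i++)
      g(i, j) = (int)haps(2 * i, c) + (int)haps(2 * i + 1, c);
  }
  return g;
}
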