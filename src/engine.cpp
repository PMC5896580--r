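// Life-cycle engine for cytoplasmic genomes in diploid hosts.
//
// State is a class-count representation: genomes are identified only by
// their substitution counts (alpha, kappa), cells by the copy number of each
// class they hold.  The population is stored cell-major as N rows of S
// slots (S = capacity >= K live classes, so mutation can append classes
// without restructuring), which keeps every per-cell pass contiguous in
// memory.  All randomness comes from R's RNG so that set.seed() in R fully
// determines a run.

#include <Rcpp.h>
#include <map>
#include <set>
#include <vector>
#include <utility>
#include <cmath>

using namespace Rcpp;

// Zero-truncated Binomial(l, mu): number of new substitutions on a genome
// known to carry at least one, sampled by inversion over k = 1, 2, ...
static int rtruncbinom(int l, double mu) {
  double p0 = std::pow(1.0 - mu, (double)l);
  double denom = 1.0 - p0;
  if (denom <= 0.0) return 1;
  double u = unif_rand() * denom;
  double pk = (double)l * mu * std::pow(1.0 - mu, (double)(l - 1)); // P(k = 1)
  double cum = pk;
  int k = 1;
  while (u > cum && k < l) {
    pk *= ((double)(l - k) / (double)(k + 1)) * (mu / (1.0 - mu));
    k += 1;
    cum += pk;
  }
  return k;
}

// q^m by squaring (m is a copy number, at most a few hundred)
static inline double ipow(double q, int m) {
  double r = 1.0;
  while (m) {
    if (m & 1) r *= q;
    q *= q;
    m >>= 1;
  }
  return r;
}

// Binomial(m, p) by inversion from zero; one uniform per draw.  For
// p > 1/2 the complement is sampled so the scan length stays O(m * min(p,
// 1-p)).  Reciprocals of the small k in play are tabulated once.
static double recip_tab[4096];
static struct RecipInit {
  RecipInit() {
    recip_tab[0] = 0.0;
    for (int k = 1; k < 4096; ++k) recip_tab[k] = 1.0 / (double)k;
  }
} recip_init;

static inline double recip(int k) {
  return k < 4096 ? recip_tab[k] : 1.0 / (double)k;
}

static int rbinom_inv(int m, double p) {
  double q = 1.0 - p, u = unif_rand();
  double pmf = ipow(q, m), cdf = pmf, r = p / q;
  int k = 0;
  while (u > cdf && k < m) {
    ++k;
    pmf *= r * (double)(m - k + 1) * recip(k);
    cdf += pmf;
  }
  return k;
}

static inline int rbinom_small(int m, double p) {
  if (m <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return m;
  if (m <= 3) {  // a handful of Bernoulli trials is cheaper than inversion
    int k = 0;
    for (int t = 0; t < m; ++t) k += unif_rand() < p;
    return k;
  }
  if (p > 0.5) return m - rbinom_inv(m, 1.0 - p);
  return rbinom_inv(m, p);
}

struct FitnessPars {
  double s_b, s_d, theta_b, theta_d, X;
};

static inline double beneficial_factor(double x, const FitnessPars &fp) {
  double u = x >= fp.X ? 1.0 : x / fp.X;
  return (1.0 - fp.s_b) + fp.s_b * std::pow(u, fp.theta_b);
}

static inline double deleterious_factor(double y, const FitnessPars &fp) {
  double v = y >= fp.X ? 1.0 : y / fp.X;
  return 1.0 - fp.s_d * std::pow(v, fp.theta_d);
}

static inline double cell_fitness(double x, double y, const FitnessPars &fp) {
  double w = beneficial_factor(x, fp) + deleterious_factor(y, fp) - 1.0;
  return w > 0.0 ? w : 0.0;
}

struct Engine {
  // configuration
  int N, n, b, l, gamma_target, max_generations;
  double mu_b, mu_d;
  FitnessPars fp;
  bool uniparental, stop_on_gamma;

  // state: counts[j * S + c] is cell j's copy number of class c
  int K, S;
  std::vector<int> alpha, kappa;
  std::vector<int> counts;
  std::map<std::pair<int, int>, int> cls_index;
  int generation;

  // scratch
  std::vector<double> w, xb, xk;
  std::vector<int> newcounts;

  // trajectory accumulators
  std::vector<int> rec_gen, rec_min_a, rec_min_k, rec_max_a, rec_max_k,
      rec_nclasses;
  std::vector<double> rec_mean_a, rec_mean_k, rec_within_va, rec_within_vk,
      rec_between_wvar, rec_mean_w, rec_mean_cell_classes;
  std::vector<int> cf_gen, cf_alpha, cf_kappa;
  std::vector<double> cf_count;

  inline int &cnt(int cell, int cls) { return counts[(size_t)cell * S + cls]; }

  void grow_capacity(int new_S) {
    std::vector<int> nc((size_t)N * new_S, 0);
    for (int j = 0; j < N; ++j)
      std::copy(counts.begin() + (size_t)j * S,
                counts.begin() + (size_t)j * S + K,
                nc.begin() + (size_t)j * new_S);
    counts.swap(nc);
    S = new_S;
  }

  int class_id(int a, int k) {
    std::pair<int, int> key(a, k);
    std::map<std::pair<int, int>, int>::iterator it = cls_index.find(key);
    if (it != cls_index.end()) return it->second;
    if (K == S) grow_capacity(S + 64);
    // slots beyond the live classes may hold stale values (the stage
    // buffers are recycled without zeroing): clear the new class's column
    for (int j = 0; j < N; ++j) counts[(size_t)j * S + K] = 0;
    alpha.push_back(a);
    kappa.push_back(k);
    cls_index[key] = K;
    return K++;
  }

  // --- stage 1: mutation -------------------------------------------------
  void collect_hits(double mu, bool beneficial,
                    std::map<long long, std::pair<int, int> > &pending) {
    if (mu <= 0.0) return;
    long long G = (long long)N * n;
    double p1 = 1.0 - std::pow(1.0 - mu, (double)l);
    int M = (int)R::rbinom((double)G, p1);
    std::set<long long> chosen;
    while ((int)chosen.size() < M) {
      long long idx = (long long)(unif_rand() * (double)G);
      if (idx >= G) continue;
      if (!chosen.insert(idx).second) continue;
      int k = rtruncbinom(l, mu);
      std::pair<int, int> &pr = pending[idx];
      if (beneficial) pr.first += k; else pr.second += k;
    }
  }

  void mutate() {
    std::map<long long, std::pair<int, int> > pending;
    collect_hits(mu_b, true, pending);
    collect_hits(mu_d, false, pending);
    if (pending.empty()) return;
    // Resolve genome slots against the pre-mutation state.  Map keys are
    // sorted (cell-major, position ascending) so one cumulative walk per
    // cell suffices.
    std::vector<int> res_cell, res_cls, res_da, res_dk;
    int cur_cell = -1, walk_cls = 0, cum = 0;
    for (std::map<long long, std::pair<int, int> >::iterator it =
             pending.begin();
         it != pending.end(); ++it) {
      int cell = (int)(it->first / n);
      int pos = (int)(it->first % n);
      if (cell != cur_cell) { cur_cell = cell; walk_cls = 0; cum = 0; }
      while (walk_cls < K && cum + cnt(cell, walk_cls) <= pos) {
        cum += cnt(cell, walk_cls);
        ++walk_cls;
      }
      res_cell.push_back(cell);
      res_cls.push_back(walk_cls);
      res_da.push_back(it->second.first);
      res_dk.push_back(it->second.second);
    }
    for (size_t i = 0; i < res_cell.size(); ++i) {
      int cls = res_cls[i], cell = res_cell[i];
      cnt(cell, cls) -= 1;
      int nc = class_id(alpha[cls] + res_da[i], kappa[cls] + res_dk[i]);
      cnt(cell, nc) += 1;
    }
  }

  // --- per-cell substitution loads ---------------------------------------
  void loads() {
    xb.assign(N, 0.0);
    xk.assign(N, 0.0);
    for (int j = 0; j < N; ++j) {
      const int *row = &counts[(size_t)j * S];
      double a = 0.0, kk = 0.0;
      for (int c = 0; c < K; ++c) {
        int m = row[c];
        if (m) { a += (double)m * alpha[c]; kk += (double)m * kappa[c]; }
      }
      xb[j] = a;
      xk[j] = kk;
    }
  }

  // --- stage 2: selection on hosts ---------------------------------------
  void select() {
    loads();
    w.resize(N);
    double tot = 0.0;
    for (int j = 0; j < N; ++j) {
      w[j] = cell_fitness(xb[j], xk[j], fp);
      tot += w[j];
    }
    if (tot <= 0.0)
      stop("population extinct: all cell fitness values are zero at generation %d",
           generation);
    std::vector<double> cum(N);
    double acc = 0.0;
    for (int j = 0; j < N; ++j) { acc += w[j]; cum[j] = acc; }
    newcounts.resize((size_t)N * S);  // only the K live slots are copied;
                                      // stale tails are never read
    for (int j = 0; j < N; ++j) {
      double r = unif_rand() * tot;
      int lo = 0, hi = N - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cum[mid] < r) lo = mid + 1; else hi = mid;
      }
      std::copy(counts.begin() + (size_t)lo * S,
                counts.begin() + (size_t)lo * S + K,
                newcounts.begin() + (size_t)j * S);
    }
    counts.swap(newcounts);
  }

  // --- stages 3-4: gametogenesis, mating, repopulation --------------------
  // A gamete is a small (class, count) list of b copies sampled with
  // replacement from the parent's n copies.  Sampling ndraw copies with
  // replacement gives multinomial class counts, drawn exactly through the
  // conditional-binomial chain (one inversion-sampled binomial per class).
  typedef std::vector<std::pair<int, int> > Pack;

  void draw_pack(const Pack &nz, int total, int ndraw, Pack &out) {
    out.clear();
    if (nz.size() == 1) { out.push_back(std::make_pair(nz[0].first, ndraw)); return; }
    int rem = ndraw, left = total;
    for (size_t i = 0; i < nz.size() && rem > 0; ++i) {
      int k = (nz[i].second == left) ? rem
              : rbinom_small(rem, (double)nz[i].second / (double)left);
      if (k) out.push_back(std::make_pair(nz[i].first, k));
      rem -= k;
      left -= nz[i].second;
    }
  }

  std::vector<Pack> gamA, gama;  // reused across generations

  void reproduce() {
    if ((int)gamA.size() != N) { gamA.resize(N); gama.resize(N); }
    Pack nz;
    for (int j = 0; j < N; ++j) {
      nz.clear();
      const int *row = &counts[(size_t)j * S];
      for (int c = 0; c < K; ++c)
        if (row[c]) nz.push_back(std::make_pair(c, row[c]));
      // visiting classes in descending copy number lets the conditional
      // chain exhaust its trials early (any order is exact)
      if (nz.size() > 2)
        for (size_t i = 1; i < nz.size(); ++i) {
          std::pair<int, int> v = nz[i];
          size_t q = i;
          while (q > 0 && nz[q - 1].second < v.second) {
            nz[q] = nz[q - 1];
            --q;
          }
          nz[q] = v;
        }
      draw_pack(nz, n, b, gamA[j]);
      // under uniparental inheritance the a-gamete's cytoplasmic content
      // is never transmitted, so drawing it would have no observable
      // effect; skip the draw
      if (!uniparental) draw_pack(nz, n, b, gama[j]);
    }
    // random bipartite pairing of A-gametes with a-gametes
    std::vector<int> perm(N);
    for (int j = 0; j < N; ++j) perm[j] = j;
    for (int j = N - 1; j > 0; --j) {
      int i = (int)(unif_rand() * (double)(j + 1));
      if (i > j) i = j;
      std::swap(perm[j], perm[i]);
    }
    newcounts.resize((size_t)N * S);
    for (int j = 0; j < N; ++j) {
      const Pack &pA = gamA[j];
      const Pack *pa = uniparental ? 0 : &gama[perm[j]];
      int *row = &newcounts[(size_t)j * S];
      std::fill(row, row + K, 0);
      if (pA.size() == 1 &&
          (uniparental ||
           (pa->size() == 1 && (*pa)[0].first == pA[0].first))) {
        row[pA[0].first] = n;
        continue;
      }
      // multinomial chain straight over the gamete entries; repeated class
      // ids across the two gametes are fine (counts aggregate)
      int rem = n, left = uniparental ? b : 2 * b;
      for (int part = 0; part < 2 && rem > 0; ++part) {
        const Pack *pk = part == 0 ? &pA : pa;
        if (!pk) break;
        for (size_t i = 0; i < pk->size() && rem > 0; ++i) {
          int m = (*pk)[i].second;
          int k = (m == left) ? rem
                  : rbinom_small(rem, (double)m / (double)left);
          if (k) row[(*pk)[i].first] += k;
          rem -= k;
          left -= m;
        }
      }
    }
    counts.swap(newcounts);
  }

  // --- housekeeping -------------------------------------------------------
  // drop empty classes and record the generation in one pass over the state
  void compact_and_record() {
    std::vector<long long> tot(K, 0);
    double wva = 0.0, wvk = 0.0, mcls = 0.0, mw = 0.0, m2w = 0.0;
    for (int j = 0; j < N; ++j) {
      const int *row = &counts[(size_t)j * S];
      double sa = 0.0, sk = 0.0, sa2 = 0.0, sk2 = 0.0;
      int ncls = 0;
      for (int c = 0; c < K; ++c) {
        int m = row[c];
        if (!m) continue;
        tot[c] += m;
        ++ncls;
        sa += (double)m * alpha[c];
        sk += (double)m * kappa[c];
        sa2 += (double)m * alpha[c] * alpha[c];
        sk2 += (double)m * kappa[c] * kappa[c];
      }
      double ma = sa / n, mk = sk / n;
      wva += sa2 / n - ma * ma;
      wvk += sk2 / n - mk * mk;
      mcls += ncls;
      double wj = cell_fitness(sa, sk, fp);
      mw += wj;
      m2w += wj * wj;
    }
    wva /= N; wvk /= N; mcls /= N; mw /= N; m2w /= N;

    // lazy compaction: rebuild only once enough classes have died (or the
    // slack is exhausted); dead classes cost one skipped test per cell
    int live = 0;
    for (int c = 0; c < K; ++c)
      if (tot[c] > 0) ++live;
    if (K - live >= 8 || K + 8 > S) {
      int newK = live;
      int newS = newK + 64;
      newcounts.resize((size_t)N * newS);
      std::vector<int> keep;
      for (int c = 0; c < K; ++c)
        if (tot[c] > 0) keep.push_back(c);
      std::vector<int> na(newK), nk(newK);
      std::map<std::pair<int, int>, int> nidx;
      for (int i = 0; i < newK; ++i) {
        na[i] = alpha[keep[i]];
        nk[i] = kappa[keep[i]];
        nidx[std::make_pair(na[i], nk[i])] = i;
      }
      for (int j = 0; j < N; ++j) {
        const int *row = &counts[(size_t)j * S];
        int *nrow = &newcounts[(size_t)j * newS];
        for (int i = 0; i < newK; ++i) nrow[i] = row[keep[i]];
      }
      alpha.swap(na);
      kappa.swap(nk);
      counts.swap(newcounts);
      cls_index.swap(nidx);
      K = newK;
      S = newS;
      std::vector<long long> nt(newK);
      for (int i = 0; i < newK; ++i) nt[i] = tot[keep[i]];
      tot.swap(nt);
    }

    // population-level summaries over the live classes
    long long G = (long long)N * n;
    double mean_a = 0.0, mean_k = 0.0;
    int min_a = -1, min_k = -1, max_a = 0, max_k = 0, nlive = 0;
    for (int c = 0; c < K; ++c) {
      if (tot[c] <= 0) continue;
      ++nlive;
      mean_a += (double)tot[c] * alpha[c];
      mean_k += (double)tot[c] * kappa[c];
      if (min_a < 0 || alpha[c] < min_a) min_a = alpha[c];
      if (min_k < 0 || kappa[c] < min_k) min_k = kappa[c];
      if (alpha[c] > max_a) max_a = alpha[c];
      if (kappa[c] > max_k) max_k = kappa[c];
      cf_gen.push_back(generation);
      cf_alpha.push_back(alpha[c]);
      cf_kappa.push_back(kappa[c]);
      cf_count.push_back((double)tot[c]);
    }
    min_alpha_live = min_a;
    rec_gen.push_back(generation);
    rec_mean_a.push_back(mean_a / (double)G);
    rec_mean_k.push_back(mean_k / (double)G);
    rec_min_a.push_back(min_a);
    rec_min_k.push_back(min_k);
    rec_max_a.push_back(max_a);
    rec_max_k.push_back(max_k);
    rec_nclasses.push_back(nlive);
    rec_within_va.push_back(wva);
    rec_within_vk.push_back(wvk);
    rec_mean_cell_classes.push_back(mcls);
    rec_between_wvar.push_back(m2w - mw * mw);
    rec_mean_w.push_back(mw);
  }

  int min_alpha_live;

  bool gamma_reached() { return min_alpha_live >= gamma_target; }

  void step() {
    mutate();
    select();
    reproduce();
    generation += 1;
  }
};

// [[Rcpp::export]]
List cpp_run_cytoplasmic(int N, int n, int b, int l, double mu_b, double mu_d,
                         double s_b, double s_d, double theta_b,
                         double theta_d, double X, bool uniparental,
                         bool stop_on_gamma, int gamma, int max_generations,
                         Nullable<List> initial_state) {
  Engine e;
  e.N = N; e.n = n; e.b = b; e.l = l;
  e.mu_b = mu_b; e.mu_d = mu_d;
  e.fp.s_b = s_b; e.fp.s_d = s_d;
  e.fp.theta_b = theta_b; e.fp.theta_d = theta_d;
  e.fp.X = X;
  e.uniparental = uniparental;
  e.stop_on_gamma = stop_on_gamma;
  e.gamma_target = gamma;
  e.max_generations = max_generations;
  e.generation = 0;

  if (initial_state.isNotNull()) {
    List init(initial_state);
    IntegerVector ia = init["alpha"], ik = init["kappa"];
    IntegerMatrix im = init["counts"]; // K x N (class by cell)
    e.K = ia.size();
    if (im.nrow() != e.K || im.ncol() != N)
      stop("initial_state counts must be a K x N matrix");
    e.S = e.K + 64;
    e.alpha.assign(ia.begin(), ia.end());
    e.kappa.assign(ik.begin(), ik.end());
    e.counts.assign((size_t)N * e.S, 0);
    for (int c = 0; c < e.K; ++c) {
      e.cls_index[std::make_pair(e.alpha[c], e.kappa[c])] = c;
      for (int j = 0; j < N; ++j) e.cnt(j, c) = im(c, j);
    }
  } else {
    e.K = 1;
    e.S = 65;
    e.alpha.assign(1, 0);
    e.kappa.assign(1, 0);
    e.counts.assign((size_t)N * e.S, 0);
    for (int j = 0; j < N; ++j) e.cnt(j, 0) = n;
    e.cls_index[std::make_pair(0, 0)] = 0;
  }

  RNGScope scope;
  e.compact_and_record(); // generation 0
  bool truncated = false;
  std::string reason = "max_generations";
  if (e.stop_on_gamma && e.gamma_reached()) {
    reason = "all_genomes_reach_gamma";
  } else {
    while (true) {
      e.step();
      e.compact_and_record();
      if (e.stop_on_gamma && e.gamma_reached()) {
        reason = "all_genomes_reach_gamma";
        break;
      }
      if (e.generation >= e.max_generations) {
        truncated = e.stop_on_gamma;
        break;
      }
      if (e.generation % 512 == 0) Rcpp::checkUserInterrupt();
    }
  }

  // export only classes still present somewhere in the population
  std::vector<long long> ftot(e.K, 0);
  for (int j = 0; j < N; ++j)
    for (int c = 0; c < e.K; ++c) ftot[c] += e.cnt(j, c);
  std::vector<int> fkeep;
  for (int c = 0; c < e.K; ++c)
    if (ftot[c] > 0) fkeep.push_back(c);
  IntegerMatrix fin((int)fkeep.size(), N);
  IntegerVector falpha((int)fkeep.size()), fkappa((int)fkeep.size());
  for (size_t i = 0; i < fkeep.size(); ++i) {
    falpha[i] = e.alpha[fkeep[i]];
    fkappa[i] = e.kappa[fkeep[i]];
    for (int j = 0; j < N; ++j) fin((int)i, j) = e.cnt(j, fkeep[i]);
  }

  return List::create(
      _["summary"] = List::create(
          _["generation"] = wrap(e.rec_gen), _["mean_alpha"] = wrap(e.rec_mean_a),
          _["mean_kappa"] = wrap(e.rec_mean_k), _["min_alpha"] = wrap(e.rec_min_a),
          _["min_kappa"] = wrap(e.rec_min_k), _["max_alpha"] = wrap(e.rec_max_a),
          _["max_kappa"] = wrap(e.rec_max_k),
          _["n_classes"] = wrap(e.rec_nclasses),
          _["within_cell_var_alpha"] = wrap(e.rec_within_va),
          _["within_cell_var_kappa"] = wrap(e.rec_within_vk),
          _["mean_cell_classes"] = wrap(e.rec_mean_cell_classes),
          _["between_cell_fitness_var"] = wrap(e.rec_between_wvar),
          _["mean_fitness"] = wrap(e.rec_mean_w)),
      _["class_freq"] = List::create(
          _["generation"] = wrap(e.cf_gen), _["alpha"] = wrap(e.cf_alpha),
          _["kappa"] = wrap(e.cf_kappa), _["count"] = wrap(e.cf_count)),
      _["stop_generation"] = e.generation, _["stop_reason"] = reason,
      _["truncated"] = truncated,
      _["final_state"] = List::create(_["alpha"] = falpha,
                                      _["kappa"] = fkappa,
                                      _["counts"] = fin));
}
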