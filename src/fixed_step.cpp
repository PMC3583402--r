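// Naive fixed-step reference simulator: the chromosome is walked one
// nucleotide per tick (dt = 1/v seconds). Deliberately simple and
// independent of the event-driven engine; used to validate it on small
// genomes. Supports promoters, protein-factor sites and head-on
// collisions; G-quadruplex sites are not implemented here.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct Pol {
  long pos;      // current position, 0-based
  int dir;       // +1 heavy, -1 light
  long dist;     // nucleotides traveled
  bool circled;  // already counted as a circling polymerase
  bool alive;
};

// circular interval overlap: [a, a+alen) vs [b, b+blen), a,b in [0,L)
static inline bool circ_overlap(long a, long alen, long b, long blen, long L) {
  long off = ((b - a) % L + L) % L;
  return off < alen || off + blen > L;
}

// [[Rcpp::export(name = ".fixed_step_cpp")]]
List fixed_step_cpp(double L_, double v, double t_end, double run_up,
                    IntegerVector prom_tss, IntegerVector prom_dir,
                    NumericVector prom_lambda,
                    IntegerVector prom_fp_start, IntegerVector prom_fp_len,
                    IntegerVector fs_start, IntegerVector fs_len,
                    NumericVector fs_p, NumericVector fs_q,
                    NumericVector fs_lambda,
                    IntegerVector gene_entry, IntegerVector gene_span,
                    IntegerVector gene_dir, int footprint) {
  const long L = (long)L_;
  const double dt = 1.0 / v;
  const long n_ticks = (long)std::ceil(t_end * v - 1e-9);
  const int n_pr = prom_tss.size(), n_fs = fs_start.size(),
            n_g = gene_entry.size();

  std::vector<double> pr_prob(n_pr), fs_prob(n_fs);
  for (int i = 0; i < n_pr; ++i) pr_prob[i] = 1.0 - std::exp(-prom_lambda[i] * dt);
  for (int j = 0; j < n_fs; ++j) fs_prob[j] = 1.0 - std::exp(-fs_lambda[j] * dt);

  std::vector<bool> fs_bound(n_fs, false);
  std::vector<Pol> pols;
  std::vector<std::vector<long> > d_entry; // per pol per gene, set at birth

  long bindings = 0, terminations = 0, collisions = 0;
  long circ_h = 0, circ_l = 0;
  IntegerVector gene_counts(n_g);
  IntegerVector stops_h(n_fs), stops_l(n_fs), passes_h(n_fs), passes_l(n_fs);

  RNGScope scope;

  for (long tick = 0; tick < n_ticks; ++tick) {
    const double t = (tick + 1) * dt;
    const bool win = (t > run_up) && (t <= t_end + 1e-12);

    // factor binding attempts
    for (int j = 0; j < n_fs; ++j) {
      if (fs_prob[j] <= 0.0 || unif_rand() >= fs_prob[j]) continue;
      if (fs_bound[j]) continue;
      bool free_ = true;
      for (size_t k = 0; k < pols.size() && free_; ++k) {
        if (!pols[k].alive) continue;
        long lo = pols[k].dir > 0 ? pols[k].pos - (footprint - 2)
                                  : pols[k].pos - 1;
        lo = ((lo % L) + L) % L;
        if (circ_overlap(fs_start[j], fs_len[j], lo, footprint, L))
          free_ = false;
      }
      if (free_) fs_bound[j] = true;
    }

    // promoter binding attempts
    for (int i = 0; i < n_pr; ++i) {
      if (pr_prob[i] <= 0.0 || unif_rand() >= pr_prob[i]) continue;
      bool free_ = true;
      for (size_t k = 0; k < pols.size() && free_; ++k) {
        if (!pols[k].alive) continue;
        long lo = pols[k].dir > 0 ? pols[k].pos - (footprint - 2)
                                  : pols[k].pos - 1;
        lo = ((lo % L) + L) % L;
        if (circ_overlap(prom_fp_start[i], prom_fp_len[i], lo, footprint, L))
          free_ = false;
      }
      for (int j = 0; j < n_fs && free_; ++j)
        if (fs_bound[j] &&
            circ_overlap(prom_fp_start[i], prom_fp_len[i], fs_start[j],
                         fs_len[j], L))
          free_ = false;
      if (!free_) continue;
      Pol p; p.pos = prom_tss[i]; p.dir = prom_dir[i]; p.dist = 0;
      p.circled = false; p.alive = true;
      pols.push_back(p);
      std::vector<long> de(n_g);
      for (int g = 0; g < n_g; ++g)
        de[g] = (((long)(gene_entry[g] - p.pos) * p.dir) % L + L) % L;
      d_entry.push_back(de);
      ++bindings;
    }

    // move polymerases one nucleotide each
    for (size_t k = 0; k < pols.size(); ++k) {
      if (!pols[k].alive) continue;
      pols[k].pos = ((pols[k].pos + pols[k].dir) % L + L) % L;
      pols[k].dist += 1;

      // full circle completed?
      if (!pols[k].circled && pols[k].dist >= L) {
        pols[k].circled = true;
        if (win) { if (pols[k].dir > 0) ++circ_h; else ++circ_l; }
      }

      // gene covers complete when dist == d_entry + span (+ m*L)
      for (int g = 0; g < n_g; ++g) {
        if (gene_dir[g] != pols[k].dir) continue;
        long c0 = d_entry[k][g] + gene_span[g];
        if (pols[k].dist >= c0 && (pols[k].dist - c0) % L == 0 && win)
          ++gene_counts[g];
      }

      // bound terminator at this position?
      bool died = false;
      for (int j = 0; j < n_fs && !died; ++j) {
        if (!fs_bound[j]) continue;
        long edge = pols[k].dir > 0 ? fs_start[j]
                                    : (fs_start[j] + fs_len[j]) % L;
        if (pols[k].pos != edge) continue;
        double pp = pols[k].dir > 0 ? fs_p[j] : fs_q[j];
        if (unif_rand() < pp) {
          fs_bound[j] = false;
          if (win) { if (pols[k].dir > 0) ++passes_h[j]; else ++passes_l[j]; }
        } else {
          if (win) { if (pols[k].dir > 0) ++stops_h[j]; else ++stops_l[j]; }
          pols[k].alive = false; ++terminations; died = true;
        }
      }
      if (died) continue;

      // head-on collision: same nucleotide as an opposing polymerase
      for (size_t m = 0; m < pols.size(); ++m) {
        if (m == k || !pols[m].alive || pols[m].dir == pols[k].dir) continue;
        if (pols[m].pos == pols[k].pos) {
          pols[k].alive = false; pols[m].alive = false;
          terminations += 2;
          if (win) ++collisions;
          break;
        }
      }
    }
  }

  long active = 0;
  for (size_t k = 0; k < pols.size(); ++k) if (pols[k].alive) ++active;

  return List::create(
    _["gene_counts"] = gene_counts,
    _["stops_heavy"] = stops_h, _["stops_light"] = stops_l,
    _["passes_heavy"] = passes_h, _["passes_light"] = passes_l,
    _["circling"] = IntegerVector::create(_["heavy"] = circ_h,
                                          _["light"] = circ_l),
    _["collisions"] = (double)collisions,
    _["bindings"] = (double)bindings,
    _["terminations"] = (double)terminations,
    _["active_at_end"] = (double)active);
}
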