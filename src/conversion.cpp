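#include <Rcpp.h>
#include <R_ext/Random.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Simulation kernel. State is tracked only at ancestrally heterologous
// columns: conversions copy existing states between copies, so monomorphic
// columns can never change and carry no information for observability.
//
// Each region is a list(anc = integer matrix [n_copies x n_het states],
// het = integer vector of 1-based full-alignment columns (sorted),
// ncol = alignment length, spacer = logical). A spacer is encoded as one
// pseudo-column holding allele ids; spacer conversions always cover it.
//
// The size sampler is a list(region = 1-based region index per template
// event, lo, hi = floored integer size range per template).

struct Region {
  IntegerMatrix anc;            // n_copies x m
  std::vector<int> het;         // full coords, sorted (size m)
  int ncol;
  bool spacer;
  int m() const { return (int)het.size(); }
};

static std::vector<Region> parse_regions(List regions) {
  std::vector<Region> out;
  for (int i = 0; i < regions.size(); ++i) {
    List r = regions[i];
    Region reg;
    reg.anc = as<IntegerMatrix>(r["anc"]);
    IntegerVector h = r["het"];
    reg.het.assign(h.begin(), h.end());
    reg.ncol = as<int>(r["ncol"]);
    reg.spacer = as<bool>(r["spacer"]);
    if (reg.anc.nrow() > 64)
      stop("more than 64 copies not supported");
    if ((int)reg.het.size() != reg.anc.ncol())
      stop("het index does not match state matrix");
    out.push_back(reg);
  }
  return out;
}

static inline int unif_idx(int n) {
  return (int)R_unif_index((double)n);
}

// Minimum number of conversion events explaining row `cur` of one recipient
// against the ancestral matrix, by greedy left-to-right partition of changed
// columns. A donor is compatible with an event iff its ancestral state equals
// the evolved state at every heterologous column spanned by the event
// (unchanged spanned columns included). Compatibility is antitone in the
// span, so the greedy maximal extension attains the minimum.
static int greedy_min_events(const IntegerMatrix& anc, const int* cur,
                             int rec, int n, int m) {
  int count = 0;
  bool active = false;
  uint64_t confirmed = 0, pending = 0;
  for (int j = 0; j < m; ++j) {
    bool changed = cur[j] != anc(rec, j);
    if (!active) {
      if (!changed) continue;
      uint64_t cand = 0;
      for (int d = 0; d < n; ++d)
        if (d != rec && anc(d, j) == cur[j]) cand |= (uint64_t)1 << d;
      if (cand == 0) stop("novel allele error: no compatible donor");
      active = true;
      confirmed = pending = cand;
    } else {
      uint64_t match = 0;
      for (int d = 0; d < n; ++d)
        if (d != rec && anc(d, j) == cur[j]) match |= (uint64_t)1 << d;
      if (changed) {
        uint64_t x = pending & match;
        if (x) {
          confirmed = pending = x;
        } else {
          ++count;                           // close previous event
          uint64_t cand = match;
          if (cand == 0) stop("novel allele error: no compatible donor");
          confirmed = pending = cand;
        }
      } else {
        pending &= match;                     // provisional span filter
      }
    }
  }
  if (active) ++count;
  (void)confirmed;
  return count;
}

// [[Rcpp::export]]
IntegerVector cpp_count_min_events(IntegerMatrix anc, IntegerMatrix fin) {
  if (anc.nrow() != fin.nrow() || anc.ncol() != fin.ncol())
    stop("shape mismatch");
  int n = anc.nrow(), m = anc.ncol();
  if (n > 64) stop("more than 64 copies not supported");
  IntegerVector out(n);
  std::vector<int> row(m);
  for (int r = 0; r < n; ++r) {
    for (int j = 0; j < m; ++j) row[j] = fin(r, j);
    out[r] = greedy_min_events(anc, row.data(), r, n, m);
  }
  return out;
}

struct Sampler {
  std::vector<int> region, lo, hi;
  int size() const { return (int)region.size(); }
};

static Sampler parse_sampler(List sampler) {
  Sampler s;
  IntegerVector reg = sampler["region"], lo = sampler["lo"], hi = sampler["hi"];
  s.region.assign(reg.begin(), reg.end());
  s.lo.assign(lo.begin(), lo.end());
  s.hi.assign(hi.begin(), hi.end());
  if (s.size() == 0) stop("empty size sampler");
  return s;
}

struct Conv { int reg, rec, don, start, end; };

// RNG draw order per event: template, size, start, recipient, donor.
static Conv draw_conversion(const Sampler& s, const std::vector<Region>& regs) {
  Conv c;
  int t = unif_idx(s.size());
  c.reg = s.region[t] - 1;
  const Region& reg = regs[c.reg];
  int size;
  if (reg.spacer) {
    size = reg.ncol;
  } else {
    size = s.lo[t] + unif_idx(s.hi[t] - s.lo[t] + 1);
    if (size > reg.ncol) size = reg.ncol;
  }
  c.start = 1 + unif_idx(reg.ncol - size + 1);
  c.end = c.start + size - 1;
  int n = reg.anc.nrow();
  c.rec = unif_idx(n);
  c.don = unif_idx(n - 1);
  if (c.don >= c.rec) ++c.don;
  return c;
}

// apply to a row-major buffer (n_copies x m), donor contributes its CURRENT
// (possibly previously converted) states
static void apply_conv(const Region& reg, std::vector<int>& buf, const Conv& c) {
  int m = reg.m();
  if (m == 0) return;
  const std::vector<int>& het = reg.het;
  int k = (int)(std::lower_bound(het.begin(), het.end(), c.start) - het.begin());
  for (; k < m && het[k] <= c.end; ++k)
    buf[(size_t)c.rec * m + k] = buf[(size_t)c.don * m + k];
}

static void reset_buf(const Region& reg, std::vector<int>& buf) {
  int n = reg.anc.nrow(), m = reg.m();
  buf.resize((size_t)n * m);
  for (int r = 0; r < n; ++r)
    for (int j = 0; j < m; ++j)
      buf[(size_t)r * m + j] = reg.anc(r, j);
}

static int count_region(const Region& reg, const std::vector<int>& buf) {
  int n = reg.anc.nrow(), m = reg.m(), tot = 0;
  if (m == 0) return 0;
  for (int r = 0; r < n; ++r)
    tot += greedy_min_events(reg.anc, buf.data() + (size_t)r * m, r, n, m);
  return tot;
}

// Replicate totals of observable (minimum reconstructable) conversions.
// Per replicate: for each of n_lineages lineages draw N ~ Poisson(lambda),
// sample and apply N conversions sequentially, then sum the per-recipient
// greedy minimum event counts over all regions and lineages.
// [[Rcpp::export]]
IntegerVector cpp_replicate_totals(double lambda, int n_lineages,
                                   int n_replicates, List regions,
                                   List sampler) {
  std::vector<Region> regs = parse_regions(regions);
  Sampler smp = parse_sampler(sampler);
  int R = regs.size();
  std::vector<std::vector<int>> buf(R);
  IntegerVector totals(n_replicates);
  RNGScope scope;
  for (int rep = 0; rep < n_replicates; ++rep) {
    int total = 0;
    for (int lin = 0; lin < n_lineages; ++lin) {
      int nev = (int)R::rpois(lambda);
      if (nev > 0) {
        for (int i = 0; i < R; ++i) reset_buf(regs[i], buf[i]);
        for (int e = 0; e < nev; ++e) {
          Conv c = draw_conversion(smp, regs);
          apply_conv(regs[c.reg], buf[c.reg], c);
        }
        for (int i = 0; i < R; ++i) total += count_region(regs[i], buf[i]);
      }
    }
    totals[rep] = total;
  }
  return totals;
}

// Conditional resampling: keep drawing conversions (each assigned to a
// uniformly random lineage) until the total observable count over all
// lineages equals `target`, then tabulate observable events by recipient
// operon and changed heterologous column. After a draw only the touched
// (lineage, region, recipient) parsimony count can change, so counts are
// updated incrementally.
// [[Rcpp::export]]
List cpp_conditional_resample(int target, int n_lineages, int n_replicates,
                              List regions, List sampler, int max_draws) {
  std::vector<Region> regs = parse_regions(regions);
  Sampler smp = parse_sampler(sampler);
  int R = regs.size();
  int n_copies = regs.empty() ? 0 : regs[0].anc.nrow();
  for (int i = 0; i < R; ++i)
    if (regs[i].anc.nrow() != n_copies) stop("regions disagree on copy number");
  int m_all = 0;
  for (int i = 0; i < R; ++i) m_all += regs[i].m();

  IntegerMatrix operon_counts(n_replicates, n_copies);
  IntegerMatrix site_counts(n_replicates, m_all);
  IntegerVector draws_used(n_replicates);

  // per lineage x region working buffers and per (lineage, region, recipient)
  // minimum-event counts
  std::vector<std::vector<std::vector<int>>> buf(n_lineages,
      std::vector<std::vector<int>>(R));
  std::vector<std::vector<std::vector<int>>> cnt(n_lineages,
      std::vector<std::vector<int>>(R));

  RNGScope scope;
  for (int rep = 0; rep < n_replicates; ++rep) {
    int total = 0;
    for (int lin = 0; lin < n_lineages; ++lin)
      for (int i = 0; i < R; ++i) {
        reset_buf(regs[i], buf[lin][i]);
        cnt[lin][i].assign(n_copies, 0);
      }
    int d = 0;
    while (total != target) {
      if (d >= max_draws)
        stop("conditional resampling did not reach the target count within %d draws",
             max_draws);
      int lin = unif_idx(n_lineages);
      Conv c = draw_conversion(smp, regs);
      const Region& reg = regs[c.reg];
      apply_conv(reg, buf[lin][c.reg], c);
      int m = reg.m();
      int newc = (m == 0) ? 0 :
        greedy_min_events(reg.anc,
                          buf[lin][c.reg].data() + (size_t)c.rec * m,
                          c.rec, n_copies, m);
      total += newc - cnt[lin][c.reg][c.rec];
      cnt[lin][c.reg][c.rec] = newc;
      ++d;
      if (total > target) {
        // a draw can raise the observable count by more than one (a new
        // event can split an existing one), so the walk can skip past the
        // target; once above it the drift is upward, so restart the
        // replicate rather than waiting for a reverting draw
        for (int l2 = 0; l2 < n_lineages; ++l2)
          for (int i = 0; i < R; ++i) {
            reset_buf(regs[i], buf[l2][i]);
            cnt[l2][i].assign(n_copies, 0);
          }
        total = 0;
      }
    }
    draws_used[rep] = d;
    // tabulate: operon = recipient of each observable event; site = each
    // changed heterologous column (each changed column belongs to exactly
    // one inferred event of its recipient)
    for (int lin = 0; lin < n_lineages; ++lin) {
      int off = 0;
      for (int i = 0; i < R; ++i) {
        const Region& reg = regs[i];
        int m = reg.m();
        for (int r = 0; r < n_copies; ++r) {
          operon_counts(rep, r) += cnt[lin][i][r];
          const int* row = buf[lin][i].data() + (size_t)r * m;
          for (int j = 0; j < m; ++j)
            if (row[j] != reg.anc(r, j)) site_counts(rep, off + j) += 1;
        }
        off += m;
      }
    }
  }
  return List::create(_["operon"] = operon_counts,
                      _["site"] = site_counts,
                      _["draws"] = draws_used);
}
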