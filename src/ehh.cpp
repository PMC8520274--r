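#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Extended haplotype homozygosity walker.
//
// Haplotypes sharing the core allele start in one group; walking outward,
// groups split on each marker's allele and haplotypes hitting a missing call
// are dropped from that marker onward. EHH at a marker is
// sum_g C(|g|, 2) / C(n_carriers_at_core, 2); singleton groups are pruned
// (they can never pair again), which keeps the walk cheap once the decay
// has collapsed.

static inline double pairs(double k) { return k * (k - 1.0) / 2.0; }

// One refinement step at marker x; returns the new numerator.
static double split_groups(std::vector<std::vector<int>> &groups,
                           const int *col) {
  std::vector<std::vector<int>> next;
  double num = 0.0;
  for (std::vector<std::vector<int>>::iterator g = groups.begin();
       g != groups.end(); ++g) {
    std::vector<int> g0, g1;
    for (size_t j = 0; j < g->size(); ++j) {
      int a = col[(*g)[j]];
      if (a == NA_INTEGER) continue;
      if (a == 0) g0.push_back((*g)[j]); else g1.push_back((*g)[j]);
    }
    if (g0.size() >= 2) { num += pairs((double)g0.size()); next.push_back(g0); }
    if (g1.size() >= 2) { num += pairs((double)g1.size()); next.push_back(g1); }
  }
  groups.swap(next);
  return num;
}

// Trapezoidal iHH for one side of the decay. Truncates at the last marker
// with EHH >= cutoff (the segment crossing below the cutoff is excluded)
// and at the near edge of any inter-marker gap > max_gap.
static double ihh_side(const IntegerMatrix &hap, const NumericVector &pos,
                       const std::vector<int> &carriers, int core, int dir,
                       double cutoff, double max_gap) {
  int m = hap.ncol();
  double denom = pairs((double)carriers.size());
  if (denom <= 0) return 0.0;
  std::vector<std::vector<int>> groups;
  groups.push_back(carriers);
  double ehh_prev = 1.0, pos_prev = pos[core], area = 0.0;
  for (int x = core + dir; x >= 0 && x < m; x += dir) {
    double gap = std::abs(pos[x] - pos_prev);
    if (gap > max_gap) break;
    double num = split_groups(groups, &hap(0, x));
    double ehh = num / denom;
    if (ehh < cutoff) break;
    area += 0.5 * (ehh_prev + ehh) * gap;
    ehh_prev = ehh;
    pos_prev = pos[x];
    if (groups.empty()) break;  // EHH is 0 from here on; only reachable if cutoff <= 0
  }
  return area;
}

// Full EHH decay for one core SNP and allele, both directions, no
// truncation. Returns marker indices (1-based) and EHH values ordered by
// position, including the core (EHH = 1).
// [[Rcpp::export]]
List cpp_ehh_decay(IntegerMatrix hap, NumericVector pos, int core1,
                   int allele) {
  int nh = hap.nrow(), m = hap.ncol(), core = core1 - 1;
  std::vector<int> carriers;
  for (int i = 0; i < nh; ++i) {
    int a = hap(i, core);
    if (a != NA_INTEGER && a == allele) carriers.push_back(i);
  }
  if (carriers.size() < 2)
    stop("EHH undefined: fewer than 2 haplotypes carry the core allele");
  double denom = pairs((double)carriers.size());

  std::vector<int> idx;
  std::vector<double> val;
  for (int dir = -1; dir <= 1; dir += 2) {
    std::vector<std::vector<int>> groups;
    groups.push_back(carriers);
    bool dead = false;
    for (int x = core + dir; x >= 0 && x < m; x += dir) {
      double ehh = 0.0;
      if (!dead) {
        double num = split_groups(groups, &hap(0, x));
        ehh = num / denom;
        if (groups.empty()) dead = true;
      }
      idx.push_back(x + 1);
      val.push_back(ehh);
    }
  }
  idx.push_back(core + 1);
  val.push_back(1.0);
  return List::create(_["index"] = wrap(idx), _["ehh"] = wrap(val));
}

// Per-SNP integrated EHH for ancestral and derived core alleles.
// anc: per-SNP ancestral allele (0/1); eligible: per-SNP flag.
// Returns an m x 2 matrix (ihh_a, ihh_d); NA when the SNP is ineligible or
// an allele has fewer than 2 carriers.
// [[Rcpp::export]]
NumericMatrix cpp_ihh_scan(IntegerMatrix hap, NumericVector pos,
                           IntegerVector anc, LogicalVector eligible,
                           double cutoff, double max_gap) {
  int nh = hap.nrow(), m = hap.ncol();
  NumericMatrix out(m, 2);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int s = 0; s < m; ++s) {
    if (s % 256 == 0) checkUserInterrupt();
    if (!eligible[s]) continue;
    int a_anc = anc[s];
    std::vector<int> ca, cd;
    const int *col = &hap(0, s);
    for (int i = 0; i < nh; ++i) {
      int a = col[i];
      if (a == NA_INTEGER) continue;
      if (a == a_anc) ca.push_back(i); else cd.push_back(i);
    }
    if (ca.size() >= 2) {
      out(s, 0) = ihh_side(hap, pos, ca, s, -1, cutoff, max_gap) +
                  ihh_side(hap, pos, ca, s, +1, cutoff, max_gap);
    }
    if (cd.size() >= 2) {
      out(s, 1) = ihh_side(hap, pos, cd, s, -1, cutoff, max_gap) +
                  ihh_side(hap, pos, cd, s, +1, cutoff, max_gap);
    }
  }
  colnames(out) = CharacterVector::create("ihh_a", "ihh_d");
  return out;
}
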