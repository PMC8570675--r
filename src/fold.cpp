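#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Per-pair energies (kcal/mol): GC -3.0, AU -2.0, GU -1.0. T treated as U,
// N never pairs. Minimum hairpin loop of 3 unpaired nt.
static inline double pair_energy(char a, char b) {
  if (a == 'T') a = 'U';
  if (b == 'T') b = 'U';
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
  return 1.0; // sentinel: not pairable
}

static const int MIN_LOOP = 3;

// [[Rcpp::export(name = ".fold_dp")]]
List fold_dp(std::string seq) {
  int n = seq.size();
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'U' && c != 'T' && c != 'N')
      stop("invalid character '%s' in sequence", std::string(1, c).c_str());
  }
  // E[i][j]: minimum energy of subsequence [i, j], 0-based inclusive.
  std::vector<std::vector<double>> E(n, std::vector<double>(n, 0.0));
  // choice[i][j]: -1 => j unpaired; k >= 0 => (k, j) paired.
  std::vector<std::vector<int>> choice(n, std::vector<int>(n, -1));

  for (int span = MIN_LOOP + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double unpaired = E[i][j - 1];
      double best_paired = 1e18;
      int pick = -1;
      for (int k = i; k <= j - MIN_LOOP - 1; ++k) {
        double e = pair_energy(seq[k], seq[j]);
        if (e > 0) continue;
        double cand = e + (k > i ? E[i][k - 1] : 0.0) + E[k + 1][j - 1];
        if (cand < best_paired) { // strict: ties keep the 5'-most partner
          best_paired = cand;
          pick = k;
        }
      }
      // ties between pairing and not pairing j resolve toward pairing,
      // which extends stems and keeps the traceback deterministic
      if (pick >= 0 && best_paired <= unpaired) {
        E[i][j] = best_paired;
        choice[i][j] = pick;
      } else {
        E[i][j] = unpaired;
        choice[i][j] = -1;
      }
    }
  }

  // iterative traceback
  std::vector<int> pairs(n, -1);
  std::vector<std::pair<int, int>> stack;
  if (n > 0) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < MIN_LOOP + 1) continue;
    int k = choice[i][j];
    if (k < 0) {
      stack.push_back(std::make_pair(i, j - 1));
    } else {
      pairs[k] = j;
      pairs[j] = k;
      if (k > i) stack.push_back(std::make_pair(i, k - 1));
      stack.push_back(std::make_pair(k + 1, j - 1));
    }
  }

  IntegerVector pv(n);
  for (int i = 0; i < n; ++i) pv[i] = pairs[i] + 1; // 1-based, 0 = unpaired
  double energy = (n > 0) ? E[0][n - 1] : 0.0;
  return List::create(_["pairs"] = pv, _["energy"] = energy);
}

// Mismatch counts of `read` placed ungapped at every offset of `ref`
// (0-based offsets 0 .. nref - nread). U and T are equivalent.
// [[Rcpp::export(name = ".mismatch_scan")]]
IntegerVector mismatch_scan(std::string read, std::string ref) {
  int nr = read.size(), nf = ref.size();
  if (nr == 0 || nr > nf) return IntegerVector(0);
  for (int i = 0; i < nr; ++i) if (read[i] == 'T') read[i] = 'U';
  for (int i = 0; i < nf; ++i) if (ref[i] == 'T') ref[i] = 'U';
  int noff = nf - nr + 1;
  IntegerVector out(noff);
  for (int off = 0; off < noff; ++off) {
    int mm = 0;
    for (int i = 0; i < nr; ++i) mm += (read[i] != ref[off + i]);
    out[off] = mm;
  }
  return out;
}

static int adapter_scan_one(std::string read, std::string adapter,
                            int max_mm, int min_overlap) {
  int nr = read.size(), na = adapter.size();
  for (int i = 0; i < nr; ++i) if (read[i] == 'T') read[i] = 'U';
  for (int i = 0; i < na; ++i) if (adapter[i] == 'T') adapter[i] = 'U';
  for (int i = 0; i + min_overlap <= nr; ++i) {
    int cmp = std::min(na, nr - i);
    if (cmp < min_overlap) break;
    int mm = 0;
    for (int k = 0; k < cmp && mm <= max_mm; ++k)
      mm += (read[i + k] != adapter[k]);
    if (mm <= max_mm) return i; // insert length (0 => adapter dimer)
  }
  return -1;
}

// [[Rcpp::export(name = ".adapter_scan")]]
int adapter_scan(std::string read, std::string adapter, int max_mm,
                 int min_overlap) {
  return adapter_scan_one(read, adapter, max_mm, min_overlap);
}

// [[Rcpp::export(name = ".adapter_scan_many")]]
IntegerVector adapter_scan_many(CharacterVector reads, std::string adapter,
                                int max_mm, int min_overlap) {
  int n = reads.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = adapter_scan_one(as<std::string>(reads[i]), adapter, max_mm,
                              min_overlap);
  return out;
}
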