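#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) of a read against a haplotype window.
// Read-end soft clips are free (score 0 per clipped base), so the optimum is
// the local-alignment optimum; every cell attaining the maximum score is
// traced back, which yields ALL score-tied placements -- in particular the
// U - u + 1 equivalent placements of a read lying wholly inside a pure
// repeat tract.  'N' in either sequence scores as a mismatch always.

static inline int subst(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export(name = ".cpp_align_read")]]
List cpp_align_read(std::string read, std::string hap,
                    int match, int mismatch, int gap_open, int gap_extend,
                    bool score_only = false, int max_placements = 10000) {
  const int m = (int)read.size();
  const int n = (int)hap.size();
  if (m == 0) stop("empty read");
  if (n == 0) stop("empty haplotype");

  const int NEG = -1000000000;
  // H: best score of alignment ending at (i,j); E: gap in read (deletion,
  // consumes hap); F: gap in hap (insertion, consumes read).
  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> E((size_t)(m + 1) * (n + 1), NEG);
  std::vector<int> F((size_t)(m + 1) * (n + 1), NEG);
  auto idx = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  int best = 0;
  for (int i = 1; i <= m; ++i) {
    const char rc = read[i - 1];
    for (int j = 1; j <= n; ++j) {
      int e = std::max(H[idx(i, j - 1)] + gap_open + gap_extend,
                       E[idx(i, j - 1)] + gap_extend);
      int f = std::max(H[idx(i - 1, j)] + gap_open + gap_extend,
                       F[idx(i - 1, j)] + gap_extend);
      int h = H[idx(i - 1, j - 1)] + subst(rc, hap[j - 1], match, mismatch);
      h = std::max(std::max(h, e), f);
      if (h < 0) h = 0;
      E[idx(i, j)] = e;
      F[idx(i, j)] = f;
      H[idx(i, j)] = h;
      if (h > best) best = h;
    }
  }

  if (score_only || best == 0) {
    return List::create(_["score"] = best, _["starts"] = IntegerVector(0),
                        _["ends"] = IntegerVector(0),
                        _["cigars"] = CharacterVector(0),
                        _["truncated"] = false);
  }

  // Collect all maximum cells, column-major order so placements come out
  // sorted by end coordinate; dedup later by (start, cigar).
  std::vector<std::pair<int, int> > cells;
  bool truncated = false;
  for (int j = 1; j <= n && !truncated; ++j)
    for (int i = 1; i <= m; ++i)
      if (H[idx(i, j)] == best) {
        cells.push_back(std::make_pair(i, j));
        if ((int)cells.size() >= max_placements) { truncated = true; break; }
      }

  std::vector<int> starts, ends;
  std::vector<std::string> cigars;
  for (size_t c = 0; c < cells.size(); ++c) {
    int i = cells[c].first, j = cells[c].second;
    // traceback; ops collected reversed.  Deterministic preference:
    // diagonal > deletion (E) > insertion (F).
    std::string rev_ops;
    int state = 0; // 0 = H, 1 = E, 2 = F
    while (i > 0 && j > 0) {
      if (state == 0) {
        int h = H[idx(i, j)];
        if (h == 0) break;
        int diag = H[idx(i - 1, j - 1)] + subst(read[i - 1], hap[j - 1], match, mismatch);
        if (h == diag) {
          rev_ops.push_back(read[i - 1] == hap[j - 1] && read[i - 1] != 'N' &&
                            hap[j - 1] != 'N' ? '=' : 'X');
          --i; --j;
        } else if (h == E[idx(i, j)]) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) {
        rev_ops.push_back('D');
        if (E[idx(i, j)] == E[idx(i, j - 1)] + gap_extend) { --j; }
        else { --j; state = 0; }
      } else {
        rev_ops.push_back('I');
        if (F[idx(i, j)] == F[idx(i - 1, j)] + gap_extend) { --i; }
        else { --i; state = 0; }
      }
    }
    int read_start = i;          // clipped prefix length
    int hap_start = j;           // 0-based start on hap
    int iend = cells[c].first;   // read bases consumed
    // run-length encode, with soft clips at read ends
    std::string cig;
    auto emit = [&cig](int len, char op) {
      if (len > 0) { cig += std::to_string(len); cig.push_back(op); }
    };
    emit(read_start, 'S');
    int run = 0; char cur = 0;
    for (int k = (int)rev_ops.size() - 1; k >= 0; --k) {
      char op = rev_ops[k];
      if (op == cur) ++run;
      else { emit(run, cur); cur = op; run = 1; }
    }
    emit(run, cur);
    emit(m - iend, 'S');
    starts.push_back(hap_start);
    ends.push_back(cells[c].second);
    cigars.push_back(cig);
  }

  // dedup identical placements (same start + cigar), preserve order; then
  // sort by (start, end) for the deterministic-order contract.
  std::vector<size_t> keep;
  for (size_t a = 0; a < starts.size(); ++a) {
    bool dup = false;
    for (size_t b = 0; b < keep.size(); ++b) {
      size_t o = keep[b];
      if (starts[o] == starts[a] && cigars[o] == cigars[a]) { dup = true; break; }
    }
    if (!dup) keep.push_back(a);
  }
  std::sort(keep.begin(), keep.end(), [&](size_t a, size_t b) {
    if (starts[a] != starts[b]) return starts[a] < starts[b];
    return ends[a] < ends[b];
  });

  IntegerVector out_start(keep.size()), out_end(keep.size());
  CharacterVector out_cig(keep.size());
  for (size_t k = 0; k < keep.size(); ++k) {
    out_start[k] = starts[keep[k]];
    out_end[k] = ends[keep[k]];
    out_cig[k] = cigars[keep[k]];
  }
  return List::create(_["score"] = best, _["starts"] = out_start,
                      _["ends"] = out_end, _["cigars"] = out_cig,
                      _["truncated"] = truncated);
}
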