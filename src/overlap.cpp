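#include <Rcpp.h>
using namespace Rcpp;

// Gap-free dovetail/containment overlap scan between two sequences.
//
// Every relative offset of b against a is evaluated; the overlap region is
// the intersection of the two sequences at that offset. 'N' never counts as
// a match (it still counts toward the overlap length). A candidate must
// have length >= min_overlap and identity >= min_identity; the best
// candidate maximises score = matches - mismatch_penalty * mismatches,
// ties broken by longer length, then smaller offset (deterministic).
//
// Returns a List(found, offset, a_start, b_start, length, matches, score)
// with 0-based a_start/b_start. offset is the shift of b relative to a
// (negative: b starts before a).
// [[Rcpp::export]]
List cpp_best_overlap(std::string a, std::string b, int min_overlap,
                      double min_identity, double mismatch_penalty) {
  int la = a.size(), lb = b.size();
  bool found = false;
  double best_score = 0;
  int best_len = -1, best_d = 0, best_m = 0;
  for (int d = -(lb - min_overlap); d <= la - min_overlap; ++d) {
    int astart = d > 0 ? d : 0;
    int bstart = d < 0 ? -d : 0;
    int len = std::min(la - astart, lb - bstart);
    if (len < min_overlap) continue;
    int need = (int)std::ceil(min_identity * len - 1e-9);
    int m = 0;
    bool viable = true;
    for (int k = 0; k < len; ++k) {
      char ca = a[astart + k], cb = b[bstart + k];
      if (ca == cb && ca != 'N') ++m;
      if (m + (len - 1 - k) < need) { viable = false; break; }
    }
    if (!viable || m < need) continue;
    double score = m - mismatch_penalty * (len - m);
    bool better = false;
    if (!found || score > best_score + 1e-9) {
      better = true;
    } else if (score > best_score - 1e-9) {
      if (len > best_len || (len == best_len && d < best_d)) better = true;
    }
    if (better) {
      found = true;
      best_score = score; best_len = len; best_d = d; best_m = m;
    }
  }
  if (!found) return List::create(Named("found") = false);
  int astart = best_d > 0 ? best_d : 0;
  int bstart = best_d < 0 ? -best_d : 0;
  return List::create(
    Named("found") = true,
    Named("offset") = best_d,
    Named("a_start") = astart,
    Named("b_start") = bstart,
    Named("length") = best_len,
    Named("matches") = best_m,
    Named("score") = best_score);
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

// Both-orientation wrapper around the overlap scan: evaluates b forward
// and reverse-complemented and returns the better hit with orientation
// "+" or "-" (ties: higher score, then longer overlap, then forward).
// [[Rcpp::export]]
List cpp_best_overlap_both(std::string a, std::string b, int min_overlap,
                           double min_identity, double mismatch_penalty) {
  List fwd = cpp_best_overlap(a, b, min_overlap, min_identity,
                              mismatch_penalty);
  List rev = cpp_best_overlap(a, revcomp(b), min_overlap, min_identity,
                              mismatch_penalty);
  bool ff = as<bool>(fwd["found"]), rf = as<bool>(rev["found"]);
  if (!ff && !rf) return List::create(Named("found") = false);
  bool useRev = false;
  if (rf && !ff) {
    useRev = true;
  } else if (ff && rf) {
    double fs = as<double>(fwd["score"]), rs = as<double>(rev["score"]);
    int fl = as<int>(fwd["length"]), rl = as<int>(rev["length"]);
    if (rs > fs + 1e-9 || (rs > fs - 1e-9 && rl > fl)) useRev = true;
  }
  List out = useRev ? rev : fwd;
  out["orientation"] = useRev ? "-" : "+";
  return out;
}

// Global alignment of two residue strings with cost 0 for a match, 1 for a
// mismatch and 1 per gap position. Returns c(cost, alignment_length) where
// alignment_length is the maximum length over all minimum-cost alignments
// (a deterministic normaliser for the p-distance-like value cost/length).
// [[Rcpp::export]]
NumericVector cpp_align_dist(std::string a, std::string b) {
  int n = a.size(), m = b.size();
  std::vector<int> D((n + 1) * (m + 1)), L((n + 1) * (m + 1));
  int w = m + 1;
  D[0] = 0; L[0] = 0;
  for (int i = 1; i <= n; ++i) { D[i * w] = i; L[i * w] = i; }
  for (int j = 1; j <= m; ++j) { D[j] = j; L[j] = j; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int sub = D[(i - 1) * w + (j - 1)] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = D[(i - 1) * w + j] + 1;
      int ins = D[i * w + (j - 1)] + 1;
      int best = std::min(sub, std::min(del, ins));
      int len = -1;
      if (sub == best) len = std::max(len, L[(i - 1) * w + (j - 1)] + 1);
      if (del == best) len = std::max(len, L[(i - 1) * w + j] + 1);
      if (ins == best) len = std::max(len, L[i * w + (j - 1)] + 1);
      D[i * w + j] = best;
      L[i * w + j] = len;
    }
  }
  return NumericVector::create(D[n * w + m], L[n * w + m]);
}
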