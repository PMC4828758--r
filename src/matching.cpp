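#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// All ungapped alignments of `tag` in `genome` (forward orientation of the
// given strings) with <= max_mm substitutions. Returns 0-based starts and
// per-hit mismatch positions (1-based in the tag).
static void scan_one(const std::string& tag, const std::string& subject,
                     int max_mm, std::vector<int>& starts,
                     std::vector<std::vector<int> >& mmpos) {
  int lt = tag.size(), ls = subject.size();
  for (int off = 0; off + lt <= ls; ++off) {
    int mm = 0;
    for (int k = 0; k < lt; ++k) {
      if (subject[off + k] != tag[k] && ++mm > max_mm) break;
    }
    if (mm <= max_mm) {
      starts.push_back(off);
      std::vector<int> pos;
      for (int k = 0; k < lt; ++k)
        if (subject[off + k] != tag[k]) pos.push_back(k + 1);
      mmpos.push_back(pos);
    }
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': r[i] = 'T'; break;
      case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break;
      case 'T': r[i] = 'A'; break;
      case 'U': r[i] = 'A'; break;
    }
  }
  return r;
}

// [[Rcpp::export]]
List genome_scan_cpp(std::string tag, std::string genome, int max_mm) {
  std::vector<int> starts_f, starts_r;
  std::vector<std::vector<int> > mm_f, mm_r;
  scan_one(tag, genome, max_mm, starts_f, mm_f);
  std::string rc = revcomp(tag);
  scan_one(rc, genome, max_mm, starts_r, mm_r);
  int lt = tag.size();
  int nf = starts_f.size(), nr = starts_r.size();
  IntegerVector start(nf + nr), nmm(nf + nr);
  CharacterVector strand(nf + nr), mmstr(nf + nr);
  for (int i = 0; i < nf; ++i) {
    start[i] = starts_f[i];
    strand[i] = "+";
    nmm[i] = mm_f[i].size();
    std::string s;
    for (size_t k = 0; k < mm_f[i].size(); ++k) {
      if (k) s += ",";
      s += std::to_string(mm_f[i][k]);
    }
    mmstr[i] = s;
  }
  for (int i = 0; i < nr; ++i) {
    start[nf + i] = starts_r[i];
    strand[nf + i] = "-";
    nmm[nf + i] = mm_r[i].size();
    // mismatch positions reported in tag orientation
    std::string s;
    std::vector<int> pos;
    for (size_t k = 0; k < mm_r[i].size(); ++k)
      pos.push_back(lt - mm_r[i][k] + 1);
    std::sort(pos.begin(), pos.end());
    for (size_t k = 0; k < pos.size(); ++k) {
      if (k) s += ",";
      s += std::to_string(pos[k]);
    }
    mmstr[nf + i] = s;
  }
  return List::create(_["start"] = start, _["strand"] = strand,
                      _["n_mismatches"] = nmm,
                      _["mismatch_positions"] = mmstr);
}

// Best containment hit of `tag` in a set of references: fewest mismatches,
// ties by reference order then smallest offset. Returns (ref index 1-based,
// n_mismatches, offset 0-based) or ref index 0 when there is no hit.
// [[Rcpp::export]]
IntegerVector ref_scan_cpp(std::string tag, CharacterVector refs,
                           int max_mm) {
  int best_ref = 0, best_mm = max_mm + 1, best_off = -1;
  int lt = tag.size();
  for (int r = 0; r < refs.size(); ++r) {
    std::string ref = as<std::string>(refs[r]);
    int ls = ref.size();
    if (ls < lt) continue;
    for (int off = 0; off + lt <= ls; ++off) {
      int mm = 0;
      for (int k = 0; k < lt; ++k)
        if (ref[off + k] != tag[k] && ++mm >= best_mm) break;
      if (mm < best_mm) {
        best_mm = mm;
        best_ref = r + 1;
        best_off = off;
        if (mm == 0) break;
      }
    }
    if (best_mm == 0) break;
  }
  if (best_ref == 0 || best_mm > max_mm)
    return IntegerVector::create(0, -1, -1);
  return IntegerVector::create(best_ref, best_mm, best_off);
}
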