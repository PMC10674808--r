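#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive Hamming-distance matcher for short reads against a small
// reference.  Every offset on both strands is scanned; the minimum
// mismatch count and its best placement (plus strand first, then
// smallest position) are reported.  'N' never matches anything.

static inline char rc_base(char c) {
  switch (c) {
    case 'A': return 'U';
    case 'U': return 'A';
    case 'G': return 'C';
    case 'C': return 'G';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = rc_base(out[i]);
  return out;
}

// scan one strand; returns best mismatch count (or max_mm + 1) and the
// smallest position achieving it (1-based)
static void scan_strand(const std::string& target, const std::string& read,
                        int max_mm, int& best_mm, int& best_pos) {
  const int n = (int) target.size(), m = (int) read.size();
  best_mm = max_mm + 1;
  best_pos = -1;
  for (int off = 0; off + m <= n; ++off) {
    int mm = 0;
    for (int k = 0; k < m; ++k) {
      char t = target[off + k], r = read[k];
      if (t != r || t == 'N') {
        if (++mm >= best_mm) break;
      }
    }
    if (mm < best_mm) {
      best_mm = mm;
      best_pos = off + 1;
      if (best_mm == 0) return;
    }
  }
}

// [[Rcpp::export(name = ".map_read_cpp")]]
List map_read_cpp(std::string target, std::string read, int max_mm) {
  int mm_p, pos_p, mm_m, pos_m;
  scan_strand(target, read, max_mm, mm_p, pos_p);
  std::string rc = revcomp(read);
  scan_strand(target, rc, max_mm, mm_m, pos_m);
  bool mapped = std::min(mm_p, mm_m) <= max_mm;
  int mm, pos;
  char strand;
  if (mm_p <= mm_m) {          // plus strand wins ties
    mm = mm_p; pos = pos_p; strand = '+';
  } else {
    mm = mm_m; pos = pos_m; strand = '-';
  }
  return List::create(_["mapped"] = mapped,
                      _["position"] = mapped ? pos : NA_INTEGER,
                      _["strand"] = mapped ? std::string(1, strand) : "",
                      _["mismatches"] = mapped ? mm : NA_INTEGER);
}

// [[Rcpp::export(name = ".map_reads_cpp")]]
DataFrame map_reads_cpp(std::string target, CharacterVector reads,
                        int max_mm) {
  const int n = reads.size();
  LogicalVector mapped(n);
  IntegerVector position(n), mismatches(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    std::string read = as<std::string>(reads[i]);
    int mm_p, pos_p, mm_m, pos_m;
    scan_strand(target, read, max_mm, mm_p, pos_p);
    std::string rc = revcomp(read);
    scan_strand(target, rc, max_mm, mm_m, pos_m);
    int mm, pos;
    char st;
    if (mm_p <= mm_m) { mm = mm_p; pos = pos_p; st = '+'; }
    else              { mm = mm_m; pos = pos_m; st = '-'; }
    if (mm <= max_mm) {
      mapped[i] = true; position[i] = pos; mismatches[i] = mm;
      strand[i] = std::string(1, st);
    } else {
      mapped[i] = false; position[i] = NA_INTEGER;
      mismatches[i] = NA_INTEGER; strand[i] = NA_STRING;
    }
  }
  return DataFrame::create(_["mapped"] = mapped, _["position"] = position,
                           _["strand"] = strand,
                           _["mismatches"] = mismatches,
                           _["stringsAsFactors"] = false);
}
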