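#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static inline char complement(char b) {
  switch (b) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = complement(out[i]);
  return out;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}

// Trim terminal bases with quality < threshold (Phred+33) from both ends.
// Returns kept flag plus trimmed sequence/quality strings.
// [[Rcpp::export(name = ".trim_batch_cpp")]]
List trim_batch_cpp(CharacterVector seqs, CharacterVector quals,
                    int q_threshold, int min_len) {
  int n = seqs.size();
  CharacterVector seq_out(n), qual_out(n);
  LogicalVector keep(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    if (s.size() != q.size()) stop("sequence/quality length mismatch at record %d", i + 1);
    int L = (int)s.size();
    int lo = 0, hi = L - 1;
    while (lo < L && (int)q[lo] - 33 < q_threshold) ++lo;
    while (hi >= lo && (int)q[hi] - 33 < q_threshold) --hi;
    int len = hi - lo + 1;
    if (lo > hi || len < min_len) {
      keep[i] = false; seq_out[i] = ""; qual_out[i] = "";
    } else {
      keep[i] = true;
      seq_out[i] = s.substr(lo, len);
      qual_out[i] = q.substr(lo, len);
    }
  }
  return List::create(_["keep"] = keep, _["sequence"] = seq_out, _["quality"] = qual_out);
}

// Merge read pairs by the best ungapped overlap (r2 reverse-complemented here).
// Candidate overlaps o in [min_overlap, min(L1, L2)] compare the last o bases of
// r1 with the first o bases of revcomp(r2); candidates with mismatch fraction
// above max_mismatch_frac are rejected. Among the rest the overlap maximising
// matches wins (ties: fewer mismatches, then the smaller overlap — evaluated in
// ascending order so behaviour is deterministic). Consensus takes the higher
// quality base; consensus quality is the max of the two.
// [[Rcpp::export(name = ".merge_batch_cpp")]]
List merge_batch_cpp(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     int min_overlap, double max_mismatch_frac) {
  int n = seq1.size();
  CharacterVector seq_out(n), qual_out(n);
  LogicalVector merged(n);
  IntegerVector overlap_out(n);
  for (int i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(seq1[i]);
    std::string q1 = as<std::string>(qual1[i]);
    std::string s2 = revcomp(as<std::string>(seq2[i]));
    std::string q2 = as<std::string>(qual2[i]);
    std::reverse(q2.begin(), q2.end());
    int L1 = (int)s1.size(), L2 = (int)s2.size();
    int omax = std::min(L1, L2);
    int best_o = -1, best_match = -1, best_mm = 0;
    for (int o = min_overlap; o <= omax; ++o) {
      int mm = 0;
      int mm_budget = (int)(max_mismatch_frac * o);
      const char* a = s1.data() + (L1 - o);
      const char* b = s2.data();
      for (int k = 0; k < o; ++k) {
        if (a[k] != b[k] && ++mm > mm_budget) break;
      }
      if (mm > mm_budget) continue;
      int match = o - mm;
      if (match > best_match || (match == best_match && mm < best_mm)) {
        best_match = match; best_mm = mm; best_o = o;
      }
    }
    if (best_o < 0) {
      merged[i] = false; seq_out[i] = ""; qual_out[i] = ""; overlap_out[i] = NA_INTEGER;
      continue;
    }
    int o = best_o;
    std::string ms = s1.substr(0, L1 - o);
    std::string mq = q1.substr(0, L1 - o);
    for (int k = 0; k < o; ++k) {
      char c1 = s1[L1 - o + k], c2 = s2[k];
      char qa = q1[L1 - o + k], qb = q2[k];
      ms += (qa >= qb) ? c1 : c2;
      mq += std::max(qa, qb);
    }
    ms += s2.substr(o);
    mq += q2.substr(o);
    merged[i] = true; seq_out[i] = ms; qual_out[i] = mq; overlap_out[i] = o;
  }
  return List::create(_["merged"] = merged, _["sequence"] = seq_out,
                      _["quality"] = qual_out, _["overlap"] = overlap_out);
}

// Best ungapped identity over nesting shifts: slide the shorter sequence along
// the longer (no overhangs), identity = matches / shorter length. A fast lower
// bound on the global-alignment identity for gap-free homologs.
// [[Rcpp::export(name = ".ungapped_identity_cpp")]]
double ungapped_identity_cpp(std::string a, std::string b) {
  if (a.size() < b.size()) std::swap(a, b);
  int La = (int)a.size(), Lb = (int)b.size();
  if (Lb == 0) return 0.0;
  int best = 0;
  for (int off = 0; off <= La - Lb; ++off) {
    int m = 0;
    const char* pa = a.data() + off;
    for (int k = 0; k < Lb; ++k) if (pa[k] == b[k]) ++m;
    if (m > best) best = m;
  }
  return (double)best / Lb;
}

// Greedy centroid clustering with the bounded-shift ungapped identity.
// Each sequence joins the first centroid with identity >= threshold, else
// founds a cluster. For founders, the first centroid falling in
// [threshold - band, threshold) is reported so the caller can re-examine the
// decision with an exact alignment.
// [[Rcpp::export(name = ".greedy_cluster_cpp")]]
List greedy_cluster_cpp(CharacterVector seqs, double threshold, double band) {
  int n = seqs.size();
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  IntegerVector cluster(n);
  std::vector<int> centroids;
  IntegerVector band_centroid(n, 0);
  NumericVector band_u(n, 0.0);
  for (int i = 0; i < n; ++i) {
    int assigned = 0;
    int first_band = 0; double first_band_u = 0.0;
    for (size_t c = 0; c < centroids.size(); ++c) {
      const std::string& a0 = ss[i];
      const std::string& b0 = ss[centroids[c]];
      const std::string& a = (a0.size() >= b0.size()) ? a0 : b0;
      const std::string& b = (a0.size() >= b0.size()) ? b0 : a0;
      int La = (int)a.size(), Lb = (int)b.size();
      int best = 0;
      int mm_budget = Lb - (int)std::ceil((threshold - band) * Lb);
      for (int off = 0; off <= La - Lb; ++off) {
        int mm = 0;
        const char* pa = a.data() + off;
        for (int k = 0; k < Lb; ++k) {
          if (pa[k] != b[k] && ++mm > mm_budget) break;
        }
        if (mm <= mm_budget && Lb - mm > best) best = Lb - mm;
      }
      double u = (double)best / Lb;
      if (u >= threshold) { assigned = (int)c + 1; break; }
      if (u >= threshold - band && first_band == 0) {
        first_band = (int)c + 1; first_band_u = u;
      }
    }
    if (assigned > 0) {
      cluster[i] = assigned;
    } else {
      centroids.push_back(i);
      cluster[i] = (int)centroids.size();
      band_centroid[i] = first_band;
      band_u[i] = first_band_u;
    }
  }
  IntegerVector cidx(centroids.size());
  for (size_t c = 0; c < centroids.size(); ++c) cidx[c] = centroids[c] + 1;
  return List::create(_["cluster"] = cluster, _["centroid_idx"] = cidx,
                      _["band_centroid"] = band_centroid, _["band_u"] = band_u);
}

// Per-position match indicator of two equal-length strings (for bimera scans).
// [[Rcpp::export(name = ".match_positions_cpp")]]
LogicalVector match_positions_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("sequences must have equal length");
  int L = (int)a.size();
  LogicalVector out(L);
  for (int i = 0; i < L; ++i) out[i] = a[i] == b[i];
  return out;
}

// Substitution errors at a fixed per-base rate; positions drawn with R's RNG.
// [[Rcpp::export(name = ".mutate_batch_cpp")]]
CharacterVector mutate_batch_cpp(CharacterVector seqs, double error_rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int L = (int)s.size();
    int k = (int)R::rbinom((double)L, error_rate);
    if (k > 0) {
      for (int e = 0; e < k; ++e) {
        int pos = (int)(R::unif_rand() * L);
        if (pos >= L) pos = L - 1;
        char cur = s[pos];
        char nb = cur;
        while (nb == cur) nb = bases[(int)(R::unif_rand() * 4) % 4];
        s[pos] = nb;
      }
    }
    out[i] = s;
  }
  return out;
}
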