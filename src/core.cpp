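#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// 3' tail trimming: drop bases from the end while the terminal base's
// Phred score is below `floor`. Qualities are phred+33 encoded strings.
// [[Rcpp::export]]
List cpp_trim_tails(CharacterVector seqs, CharacterVector quals, int floor_phred) {
  int n = seqs.size();
  CharacterVector out_s(n), out_q(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    size_t len = s.size();
    while (len > 0 && (int)q[len - 1] - 33 < floor_phred) --len;
    out_s[i] = s.substr(0, len);
    out_q[i] = q.substr(0, len);
  }
  return List::create(_["seq"] = out_s, _["qual"] = out_q);
}

// Pair merging. s2/q2 must already be the reverse complement of the raw R2
// (qualities reversed accordingly). For overlap o (s1 tail vs s2 head):
//   merged = s1[0, n1) + s2[o, n2)
// The admissible offset maximises matching bases subject to o >= min_overlap
// and mismatch fraction <= max_mismatch_frac; ties go to the larger overlap.
// At overlap disagreements the higher-quality base wins (tie -> R1 base);
// at agreements the quality is the max of the two.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector s1v, CharacterVector q1v,
                     CharacterVector s2v, CharacterVector q2v,
                     int min_overlap, double max_mismatch_frac) {
  int n = s1v.size();
  CharacterVector out_s(n), out_q(n);
  LogicalVector ok(n);
  IntegerVector ovl(n);
  for (int i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(s1v[i]), q1 = as<std::string>(q1v[i]);
    std::string s2 = as<std::string>(s2v[i]), q2 = as<std::string>(q2v[i]);
    int n1 = s1.size(), n2 = s2.size();
    int max_o = std::min(n1, n2);
    int best_o = -1, best_m = -1;
    for (int o = min_overlap; o <= max_o; ++o) {
      int m = 0;
      const char *p1 = s1.data() + (n1 - o), *p2 = s2.data();
      for (int k = 0; k < o; ++k) if (p1[k] == p2[k]) ++m;
      if ((double)(o - m) / o > max_mismatch_frac) continue;
      if (m > best_m || (m == best_m && o > best_o)) { best_m = m; best_o = o; }
    }
    if (best_o < 0) { ok[i] = false; out_s[i] = NA_STRING; out_q[i] = NA_STRING; ovl[i] = NA_INTEGER; continue; }
    int o = best_o;
    std::string ms = s1;
    std::string mq = q1;
    // resolve the overlap region in place
    for (int k = 0; k < o; ++k) {
      int i1 = n1 - o + k;
      char b1 = s1[i1], b2 = s2[k];
      char c1 = q1[i1], c2 = q2[k];
      if (b1 == b2) {
        mq[i1] = std::max(c1, c2);
      } else if (c2 > c1) {
        ms[i1] = b2;
        mq[i1] = c2;
      } // else keep R1 base (covers tie)
    }
    ms += s2.substr(o);
    mq += q2.substr(o);
    ok[i] = true; out_s[i] = ms; out_q[i] = mq; ovl[i] = o;
  }
  return List::create(_["seq"] = out_s, _["qual"] = out_q,
                      _["accepted"] = ok, _["overlap"] = ovl);
}

// Anchored mismatch counts of each primer against the prefix (at_start) or
// suffix of each sequence. Sequence shorter than the primer -> NA.
// [[Rcpp::export]]
IntegerMatrix cpp_anchored_mismatches(CharacterVector seqs, CharacterVector primers,
                                      bool at_start) {
  int n = seqs.size(), m = primers.size();
  std::vector<std::string> ps(m);
  for (int j = 0; j < m; ++j) ps[j] = as<std::string>(primers[j]);
  IntegerMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (int j = 0; j < m; ++j) {
      int np = ps[j].size();
      if ((int)s.size() < np) { out(i, j) = NA_INTEGER; continue; }
      const char *a = at_start ? s.data() : s.data() + (s.size() - np);
      int mm = 0;
      for (int k = 0; k < np; ++k) if (a[k] != ps[j][k]) ++mm;
      out(i, j) = mm;
    }
  }
  return out;
}

static inline int hamming_full(const std::string &a, const std::string &b) {
  // full-length divergence: mismatches over the shorter length plus the
  // length difference
  size_t n = std::min(a.size(), b.size());
  int d = (int)(std::max(a.size(), b.size()) - n);
  for (size_t k = 0; k < n; ++k) if (a[k] != b[k]) ++d;
  return d;
}

// De novo bimera flagging on a sample's distinct sequences.
// A candidate is flagged when some breakpoint b (>= margin bases from both
// ends) splits it into a left-anchored prefix matching parent A and a
// right-anchored suffix matching parent B, each with <= max_mm_per_side
// mismatches, where both parents are unflagged sequences with abundance
// >= min_fold x the candidate's, differ from each other by >= min_parent_div
// bases and from the candidate by >= min_candidate_div bases, AND the
// two-parent model explains the candidate strictly better than either
// parent alone (model mismatches < divergence from each parent). The last
// condition keeps error variants of an abundant template from decomposing
// into (true parent, anything): amplicons share identical primer termini, so
// a breakpoint inside a primer region never beats the single-parent model.
// [[Rcpp::export]]
LogicalVector cpp_flag_bimeras(CharacterVector seqs, IntegerVector counts,
                               double min_fold, int max_mm_per_side, int margin,
                               int min_parent_div, int min_candidate_div) {
  int n = seqs.size();
  std::vector<std::string> sq(n);
  for (int i = 0; i < n; ++i) sq[i] = as<std::string>(seqs[i]);
  // process in decreasing abundance so parents are settled before candidates
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) { return counts[a] > counts[b]; });
  LogicalVector flagged(n, false);
  int M = max_mm_per_side;
  for (int oi = 0; oi < n; ++oi) {
    int c = ord[oi];
    int Lc = sq[c].size();
    if (Lc < 2 * margin) continue;
    // eligible parents and their divergence from the candidate
    std::vector<int> par, cdiv;
    for (int oj = 0; oj < oi; ++oj) {
      int p = ord[oj];
      if (flagged[p]) continue;
      if ((double)counts[p] < min_fold * (double)counts[c]) continue;
      int d = hamming_full(sq[c], sq[p]);
      if (d >= min_candidate_div) { par.push_back(p); cdiv.push_back(d); }
    }
    if (par.size() < 2) continue;
    int np = par.size();
    // reachL[j][m]: largest b such that candidate[0,b) matches parent j's
    // prefix with exactly <= m mismatches; reachR[j][m]: right-anchored twin
    std::vector<std::vector<int>> reachL(np, std::vector<int>(M + 1, 0)),
                                  reachR(np, std::vector<int>(M + 1, 0));
    for (int j = 0; j < np; ++j) {
      const std::string &a = sq[par[j]];
      int La = a.size();
      int lim = std::min(Lc, La), mm = 0;
      for (int k = 0; k < lim; ++k) {
        if (sq[c][k] != a[k] && ++mm > M) break;
        for (int m = mm; m <= M; ++m) reachL[j][m] = k + 1;
      }
      mm = 0;
      for (int k = 0; k < lim; ++k) {
        if (sq[c][Lc - 1 - k] != a[La - 1 - k] && ++mm > M) break;
        for (int m = mm; m <= M; ++m) reachR[j][m] = k + 1;
      }
    }
    bool hit = false;
    for (int ja = 0; ja < np && !hit; ++ja) {
      for (int jb = 0; jb < np; ++jb) {
        if (ja == jb) continue;
        // smallest model mismatch total over admissible breakpoints
        int best = -1;
        for (int ma = 0; ma <= M; ++ma) for (int mb = 0; mb <= M; ++mb) {
          int hi = std::min(Lc - margin, reachL[ja][ma]);
          int lo = std::max(margin, Lc - reachR[jb][mb]);
          if (lo <= hi && (best < 0 || ma + mb < best)) best = ma + mb;
        }
        if (best < 0) continue;
        if (best >= cdiv[ja] || best >= cdiv[jb]) continue;
        if (hamming_full(sq[par[ja]], sq[par[jb]]) < min_parent_div) continue;
        hit = true; break;
      }
    }
    if (hit) flagged[c] = true;
  }
  return flagged;
}

// Ungapped reference search. Identity (%) of query vs reference = matching
// bases at offset 0 over min(len) / query length x 100. Per query, the best
// identity is tracked per species; returns the top species, its identity and
// aligned length, and the best identity among the other species.
// [[Rcpp::export]]
DataFrame cpp_top2_search(CharacterVector queries, CharacterVector refs,
                          IntegerVector ref_species, int n_species) {
  int nq = queries.size(), nr = refs.size();
  std::vector<std::string> rf(nr);
  for (int j = 0; j < nr; ++j) rf[j] = as<std::string>(refs[j]);
  IntegerVector top_sp(nq), sec_sp(nq), aln(nq);
  NumericVector top_id(nq), sec_id(nq);
  std::vector<double> best(n_species);
  std::vector<int> balign(n_species);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    int lq = q.size();
    std::fill(best.begin(), best.end(), -1.0);
    std::fill(balign.begin(), balign.end(), 0);
    for (int j = 0; j < nr; ++j) {
      int lr = rf[j].size();
      int ov = std::min(lq, lr), m = 0;
      for (int k = 0; k < ov; ++k) if (q[k] == rf[j][k]) ++m;
      double ident = 100.0 * (double)m / (double)lq;
      int sp = ref_species[j] - 1;
      if (ident > best[sp]) { best[sp] = ident; balign[sp] = ov; }
    }
    int b1 = -1, b2 = -1;
    for (int s = 0; s < n_species; ++s) {
      if (best[s] < 0) continue;
      if (b1 < 0 || best[s] > best[b1]) { b2 = b1; b1 = s; }
      else if (b2 < 0 || best[s] > best[b2]) { b2 = s; }
    }
    top_sp[i] = b1 + 1;
    top_id[i] = b1 >= 0 ? best[b1] : NA_REAL;
    aln[i] = b1 >= 0 ? balign[b1] : NA_INTEGER;
    sec_sp[i] = b2 >= 0 ? b2 + 1 : NA_INTEGER;
    sec_id[i] = b2 >= 0 ? best[b2] : NA_REAL;
  }
  return DataFrame::create(_["top_species"] = top_sp, _["top_identity"] = top_id,
                           _["aligned_length"] = aln,
                           _["second_species"] = sec_sp, _["second_identity"] = sec_id);
}

// Apply n_err[i] random substitutions to seqs[i] (positions and replacement
// bases drawn from R's RNG so runs are reproducible under set.seed()).
// [[Rcpp::export]]
CharacterVector cpp_apply_substitutions(CharacterVector seqs, IntegerVector n_err) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int ne = n_err[i];
    for (int e = 0; e < ne; ++e) {
      int pos = (int)(unif_rand() * s.size());
      if (pos >= (int)s.size()) pos = s.size() - 1;
      char old = s[pos], nb = old;
      while (nb == old) nb = bases[(int)(unif_rand() * 4) % 4];
      s[pos] = nb;
    }
    out[i] = s;
  }
  return out;
}

// Phred integer matrix (reads x positions) -> phred+33 strings.
// [[Rcpp::export]]
CharacterVector cpp_quals_to_strings(IntegerMatrix q) {
  int n = q.nrow(), m = q.ncol();
  CharacterVector out(n);
  std::string s(m, ' ');
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) s[j] = (char)(q(i, j) + 33);
    out[i] = s;
  }
  return out;
}

// Hamming distance between two equal-role strings (helper for tests/curation)
// [[Rcpp::export]]
IntegerVector cpp_pairwise_hamming(CharacterVector a, CharacterVector b) {
  int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = hamming_full(as<std::string>(a[i]), as<std::string>(b[i]));
  return out;
}
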