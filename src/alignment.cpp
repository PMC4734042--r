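// Desk-scale alignment kernels: match-maximising identity for greedy
// clustering, banded affine Smith-Waterman for translated homology search,
// and the seeded search driver that emits BLAST-tabular rows.
#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const int NEG = -1000000;

// ---------------------------------------------------------------------------
// Identity between two proteins: number of identical residues in the
// alignment that maximises identical residues (gaps free, end gaps on the
// longer sequence free), divided by the shorter sequence length. With free
// gaps this is the longest common subsequence.
static int lcs_length(const std::string& a, const std::string& b) {
  const int na = (int)a.size(), nb = (int)b.size();
  std::vector<int> prev(nb + 1, 0), cur(nb + 1, 0);
  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      if (a[i - 1] == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[nb];
}

// [[Rcpp::export]]
double cpp_pairwise_identity(std::string a, std::string b) {
  if (a.empty() || b.empty()) stop("empty sequence");
  int shorter = std::min((int)a.size(), (int)b.size());
  return 100.0 * lcs_length(a, b) / shorter;
}

// ---------------------------------------------------------------------------
// Greedy incremental clustering (CD-HIT style). `seqs` must already be
// ordered (longest first, id tie-break done in R). Returns 1-based index of
// the representative sequence for each input. Optional 4-mer prefilter skips
// pairs sharing no 4-mer; at cut-offs >= 50% this cannot change results for
// family-structured inputs, and equivalence is asserted in the test suite.
// [[Rcpp::export]]
IntegerVector cpp_cluster_greedy(std::vector<std::string> seqs, double cutoff,
                                 bool prefilter) {
  const int n = (int)seqs.size();
  IntegerVector rep(n);
  std::vector<int> reps;  // indices of representatives, in founding order
  std::vector<std::vector<uint32_t>> kmers(n);
  if (prefilter) {
    for (int i = 0; i < n; ++i) {
      const std::string& s = seqs[i];
      std::vector<uint32_t>& v = kmers[i];
      for (int p = 0; p + 4 <= (int)s.size(); ++p) {
        uint32_t code = 0;
        for (int q = 0; q < 4; ++q) code = code * 128u + (uint8_t)s[p + q];
        v.push_back(code);
      }
      std::sort(v.begin(), v.end());
      v.erase(std::unique(v.begin(), v.end()), v.end());
    }
  }
  for (int i = 0; i < n; ++i) {
    int found = -1;
    for (int r : reps) {
      if (prefilter) {
        // any shared 4-mer?
        const std::vector<uint32_t>&x = kmers[i], &y = kmers[r];
        bool shared = false;
        size_t a = 0, b = 0;
        while (a < x.size() && b < y.size()) {
          if (x[a] == y[b]) { shared = true; break; }
          if (x[a] < y[b]) ++a; else ++b;
        }
        if (!shared) continue;
      }
      int shorter = std::min((int)seqs[i].size(), (int)seqs[r].size());
      if (100.0 * lcs_length(seqs[i], seqs[r]) / shorter >= cutoff) {
        found = r;
        break;
      }
    }
    rep[i] = (found < 0 ? i : found) + 1;
    if (found < 0) reps.push_back(i);
  }
  return rep;
}

// ---------------------------------------------------------------------------
// Translation, standard genetic code. The 64-entry codon table (ACGT-major
// order) is supplied from R (derived from Biostrings::GENETIC_CODE) so there
// is a single source of truth for the code.
static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static std::string translate_frame(const std::string& dna, int off,
                                   const std::string& codon_table) {
  std::string pep;
  const int n = (int)dna.size();
  pep.reserve((n - off) / 3);
  for (int p = off; p + 3 <= n; p += 3) {
    int a = base_idx(dna[p]), b = base_idx(dna[p + 1]), c = base_idx(dna[p + 2]);
    pep.push_back((a < 0 || b < 0 || c < 0) ? 'X' : codon_table[a * 16 + b * 4 + c]);
  }
  return pep;
}

static std::string revcomp(const std::string& dna) {
  std::string rc(dna.rbegin(), dna.rend());
  for (char& c : rc) {
    switch (c) {
      case 'A': c = 'T'; break; case 'C': c = 'G'; break;
      case 'G': c = 'C'; break; case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  return rc;
}

// [[Rcpp::export]]
List cpp_six_frames(std::string dna, std::string codon_table) {
  std::string rc = revcomp(dna);
  List out(6);
  for (int f = 0; f < 3; ++f) {
    out[f] = translate_frame(dna, f, codon_table);
    out[3 + f] = translate_frame(rc, f, codon_table);
  }
  out.attr("names") =
      CharacterVector::create("+1", "+2", "+3", "-1", "-2", "-3");
  return out;
}

// ---------------------------------------------------------------------------
// Banded affine-gap Smith-Waterman with full traceback. Gap of length L
// costs gap_open + L * gap_ext. Band restricts the diagonal d = i - j
// (1-based query pos minus subject pos) to [dlo, dhi].
struct SWResult {
  int score = 0, matches = 0, mismatches = 0, gap_open_count = 0, aln_len = 0;
  int qstart = 0, qend = 0, sstart = 0, send = 0;
};

static SWResult sw_banded(const std::string& q, const std::string& s,
                          const int* sub, const int* cmap, int gap_open,
                          int gap_ext, int dlo, int dhi) {
  const int m = (int)q.size(), n = (int)s.size();
  const int W = n + 1;
  static thread_local std::vector<int> H, E, F;
  static thread_local std::vector<int8_t> tH, tE, tF;
  size_t sz = (size_t)(m + 1) * W;
  H.assign(sz, 0); E.assign(sz, NEG); F.assign(sz, NEG);
  tH.assign(sz, 0); tE.assign(sz, 0); tF.assign(sz, 0);
  const int go = gap_open + gap_ext, ge = gap_ext;
  SWResult best;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i - dhi), jhi = std::min(n, i - dlo);
    const int ci = cmap[(uint8_t)q[i - 1]];
    for (int j = jlo; j <= jhi; ++j) {
      size_t k = (size_t)i * W + j;
      // E: gap in query (consume subject)
      int eo = H[k - 1] - go, ee = E[k - 1] - ge;
      E[k] = std::max(eo, ee);
      tE[k] = (int8_t)(eo >= ee ? 1 : 0);
      // F: gap in subject (consume query)
      int fo = H[k - W] - go, fe = F[k - W] - ge;
      F[k] = std::max(fo, fe);
      tF[k] = (int8_t)(fo >= fe ? 1 : 0);
      int sc = sub[ci * 32 + cmap[(uint8_t)s[j - 1]]];
      int diag = H[k - W - 1] + sc;
      int h = 0; int8_t t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (E[k] > h) { h = E[k]; t = 2; }
      if (F[k] > h) { h = F[k]; t = 3; }
      H[k] = h; tH[k] = t;
      if (h > best.score) { best.score = h; bi = i; bj = j; }
    }
  }
  if (best.score <= 0) return best;
  // traceback
  int i = bi, j = bj, state = 0;  // 0=H, 1=E, 2=F
  best.qend = bi; best.send = bj;
  while (true) {
    size_t k = (size_t)i * W + j;
    if (state == 0) {
      int8_t t = tH[k];
      if (t == 0) break;
      if (t == 1) {
        ++best.aln_len;
        if (q[i - 1] == s[j - 1]) ++best.matches; else ++best.mismatches;
        best.qstart = i; best.sstart = j;
        --i; --j;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++best.aln_len;
      if (tE[k] == 1) { ++best.gap_open_count; state = 0; }
      --j;
    } else {
      ++best.aln_len;
      if (tF[k] == 1) { ++best.gap_open_count; state = 0; }
      --i;
    }
    if (i == 0 || j == 0) {
      // alignment is local; H traceback stops before hitting an edge, and E/F
      // chains always re-enter H first, so this is only a safety net
      break;
    }
  }
  return best;
}

// Score-only banded SW with rolling rows: no traceback storage, so it is
// several times faster. Used as a first pass; the full DP is re-run only on
// pairs that clear the reporting floor.
static int sw_banded_score(const std::string& q, const std::string& s,
                           const int* sub, const int* cmap, int gap_open,
                           int gap_ext, int dlo, int dhi) {
  const int m = (int)q.size(), n = (int)s.size();
  static thread_local std::vector<int> H0, H1, E0, E1, F1;
  H0.assign(n + 1, 0); H1.assign(n + 1, 0);
  E0.assign(n + 1, NEG); E1.assign(n + 1, NEG); F1.assign(n + 1, NEG);
  const int go = gap_open + gap_ext, ge = gap_ext;
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i - dhi), jhi = std::min(n, i - dlo);
    const int* srow = sub + cmap[(uint8_t)q[i - 1]] * 32;
    // stale values left of this row's band must read as outside-the-band
    if (jlo >= 2 && jlo - 1 <= n) { H1[jlo - 1] = 0; E1[jlo - 1] = NEG; }
    for (int j = jlo; j <= jhi; ++j) {
      int e = std::max(H1[j - 1] - go, E1[j - 1] - ge);
      int f = std::max(H0[j] - go, F1[j] - ge);
      int h = H0[j - 1] + srow[cmap[(uint8_t)s[j - 1]]];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      E1[j] = e; F1[j] = f; H1[j] = h;
      if (h > best) best = h;
    }
    if (jhi >= 0 && jhi < n) {
      H1[jhi + 1] = 0; E1[jhi + 1] = NEG; F1[jhi + 1] = NEG;
    }
    std::swap(H0, H1); std::swap(E0, E1);
  }
  return best;
}

// Exhaustive variant exposed for oracle-style use from R.
// [[Rcpp::export]]
List cpp_smith_waterman(std::string query, std::string subject,
                        IntegerMatrix submat, std::string sub_alphabet,
                        int gap_open, int gap_ext) {
  std::vector<int> sub(32 * 32, NEG);
  std::vector<int> cmap(256, -1);
  int na = (int)sub_alphabet.size();
  for (int i = 0; i < na; ++i) cmap[(uint8_t)sub_alphabet[i]] = i;
  // unknown residues behave like X
  int xi = cmap[(uint8_t)'X'];
  std::vector<int> cm(256, xi);
  for (int i = 0; i < 256; ++i) if (cmap[i] >= 0) cm[i] = cmap[i];
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < na; ++j) {
      int v = submat(i, j);
      // stop codons are hard barriers: never inside a reported alignment
      if (sub_alphabet[i] == '*' || sub_alphabet[j] == '*') v = NEG;
      sub[i * 32 + j] = v;
    }
  SWResult r = sw_banded(query, subject, sub.data(), cm.data(), gap_open,
                         gap_ext, -(int)subject.size(), (int)query.size());
  return List::create(
      _["score"] = r.score, _["matches"] = r.matches,
      _["mismatches"] = r.mismatches, _["gap_openings"] = r.gap_open_count,
      _["aln_len"] = r.aln_len, _["q_start"] = r.qstart, _["q_end"] = r.qend,
      _["s_start"] = r.sstart, _["s_end"] = r.send);
}

// ---------------------------------------------------------------------------
// Seeded translated (or protein-protein) search against representative
// sequences. For each (query, subject) the best local alignment over frames
// is reported as one tabular row. exhaustive=true skips seeding and runs the
// full dynamic program on every pair (the oracle search used to build truth
// annotations).
// [[Rcpp::export]]
DataFrame cpp_search(std::vector<std::string> read_ids,
                     std::vector<std::string> read_seqs,
                     std::vector<std::string> subj_ids,
                     std::vector<std::string> subj_seqs,
                     IntegerMatrix submat, std::string sub_alphabet,
                     std::string codon_table, bool query_is_protein,
                     int gap_open, int gap_ext, int seed_len, bool exhaustive,
                     int band_width, double lambda, double logK, double min_bit,
                     double db_residues) {
  const int nq = (int)read_ids.size(), ns = (int)subj_ids.size();
  if (ns == 0) stop("empty database");
  // substitution lookup
  std::vector<int> sub(32 * 32, NEG);
  std::vector<int> cmraw(256, -1);
  int na = (int)sub_alphabet.size();
  for (int i = 0; i < na; ++i) cmraw[(uint8_t)sub_alphabet[i]] = i;
  int xi = cmraw[(uint8_t)'X'];
  std::vector<int> cm(256, xi);
  for (int i = 0; i < 256; ++i) if (cmraw[i] >= 0) cm[i] = cmraw[i];
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < na; ++j) {
      int v = submat(i, j);
      if (sub_alphabet[i] == '*' || sub_alphabet[j] == '*') v = NEG;
      sub[i * 32 + j] = v;
    }
  // frames per query
  const int nframes = query_is_protein ? 1 : 6;
  std::vector<std::vector<std::string>> frames(nq);
  for (int i = 0; i < nq; ++i) {
    if (query_is_protein) {
      frames[i].push_back(read_seqs[i]);
    } else {
      std::string rc = revcomp(read_seqs[i]);
      for (int f = 0; f < 3; ++f) frames[i].push_back(translate_frame(read_seqs[i], f, codon_table));
      for (int f = 0; f < 3; ++f) frames[i].push_back(translate_frame(rc, f, codon_table));
    }
  }
  auto seed_ok = [](const std::string& s, int p, int k) {
    for (int q = 0; q < k; ++q)
      if (s[p + q] == 'X' || s[p + q] == '*') return false;
    return true;
  };
  auto encode = [&](const std::string& s, int p, int k) {
    uint64_t code = 0;
    for (int q = 0; q < k; ++q) code = code * 32u + (uint64_t)cm[(uint8_t)s[p + q]];
    return code;
  };
  std::vector<std::string> out_q, out_s;
  std::vector<double> out_pid, out_ev, out_bit;
  std::vector<int> out_len, out_mm, out_go, out_qs, out_qe, out_ss, out_se,
      out_frame;
  const double ln2 = std::log(2.0);
  for (int si = 0; si < ns; ++si) {
    const std::string& S = subj_seqs[si];
    std::unordered_map<uint64_t, std::vector<int>> idx;
    if (!exhaustive) {
      for (int p = 0; p + seed_len <= (int)S.size(); ++p)
        if (seed_ok(S, p, seed_len))
          idx[encode(S, p, seed_len)].push_back(p + 1);  // 1-based
    }
    for (int qi = 0; qi < nq; ++qi) {
      int best_score = 0, best_frame = -1, best_dlo = 0, best_dhi = 0;
      for (int f = 0; f < nframes; ++f) {
        const std::string& P = frames[qi][f];
        if ((int)P.size() < (exhaustive ? 1 : seed_len)) continue;
        int dlo, dhi;
        if (exhaustive) {
          dlo = -(int)S.size(); dhi = (int)P.size();
        } else {
          int mind = 0, maxd = 0; bool any = false;
          for (int p = 0; p + seed_len <= (int)P.size(); ++p) {
            if (!seed_ok(P, p, seed_len)) continue;
            auto it = idx.find(encode(P, p, seed_len));
            if (it == idx.end()) continue;
            for (int sp : it->second) {
              int d = (p + 1) - sp;
              if (!any) { mind = maxd = d; any = true; }
              else { mind = std::min(mind, d); maxd = std::max(maxd, d); }
            }
          }
          if (!any) continue;
          dlo = mind - band_width; dhi = maxd + band_width;
        }
        int sc = sw_banded_score(P, S, sub.data(), cm.data(), gap_open,
                                 gap_ext, dlo, dhi);
        if (sc > best_score) {
          best_score = sc; best_frame = f; best_dlo = dlo; best_dhi = dhi;
        }
      }
      if (best_frame < 0 || best_score <= 0) continue;
      int mlen = (int)frames[qi][best_frame].size();
      double bit = (lambda * best_score - logK) / ln2;
      if (bit < min_bit) continue;
      // full DP with traceback only for reported pairs
      SWResult best = sw_banded(frames[qi][best_frame], S, sub.data(),
                                cm.data(), gap_open, gap_ext, best_dlo,
                                best_dhi);
      bit = (lambda * best.score - logK) / ln2;  // identical by construction
      double ev = (double)mlen * db_residues * std::pow(2.0, -bit);
      // query coordinates: nucleotide positions on the read for translated
      // search (minus-strand frames give qstart > qend), else residues
      int qs = best.qstart, qe = best.qend;
      if (!query_is_protein) {
        int off = best_frame % 3;  // 0,1,2 within strand
        int L = (int)read_seqs[qi].size();
        int nt_s = 3 * (best.qstart - 1) + off + 1;
        int nt_e = 3 * best.qend + off;
        if (best_frame < 3) { qs = nt_s; qe = nt_e; }
        else { qs = L - nt_s + 1; qe = L - nt_e + 1; }
      }
      out_q.push_back(read_ids[qi]); out_s.push_back(subj_ids[si]);
      out_pid.push_back(100.0 * best.matches / best.aln_len);
      out_len.push_back(best.aln_len); out_mm.push_back(best.mismatches);
      out_go.push_back(best.gap_open_count);
      out_qs.push_back(qs); out_qe.push_back(qe);
      out_ss.push_back(best.sstart); out_se.push_back(best.send);
      out_ev.push_back(ev); out_bit.push_back(bit);
      out_frame.push_back(best_frame < 3 ? best_frame + 1 : -(best_frame - 2));
    }
  }
  return DataFrame::create(
      _["query_id"] = out_q, _["subject_id"] = out_s,
      _["pct_identity"] = out_pid, _["aln_length"] = out_len,
      _["mismatches"] = out_mm, _["gap_openings"] = out_go,
      _["q_start"] = out_qs, _["q_end"] = out_qe, _["s_start"] = out_ss,
      _["s_end"] = out_se, _["evalue"] = out_ev, _["bit_score"] = out_bit,
      _["frame"] = out_frame, _["stringsAsFactors"] = false);
}
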