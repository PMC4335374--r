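// Core sequence routines: banded affine-gap semi-global alignment with
// deterministic tie-breaking and left-aligned indels, pileup accumulation,
// per-read window checks around variant sites, indel-event extraction, and
// per-base error injection for the read simulator.
//
// Alignment model: free end gaps on both sequences (overlap alignment),
// gap(k) = gap_open + k * gap_extend, charged once per gap plus per base.
// Ties: diagonal (match/mismatch) preferred over a gap, deletion (ref gap
// consuming reference) over insertion; indels are left-normalized afterwards.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

static const int NEG = -100000000;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'N': return 'N'; default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3; default: return -1;
  }
}

struct AlnResult {
  int score = NEG;
  int read_start = 0, read_end = 0;   // aligned read interval [start, end)
  int ref_start = 0, ref_end = 0;     // aligned reference interval
  std::string cigar;                  // runs of S = X I D
  int n_match = 0, n_col = 0;         // matches / aligned columns
  bool ok = false;
};

// ---- cigar helpers ----------------------------------------------------

struct Run { char op; int len; };

static std::vector<Run> parse_cigar(const std::string& cg) {
  std::vector<Run> runs;
  int len = 0;
  for (char c : cg) {
    if (c >= '0' && c <= '9') {
      len = len * 10 + (c - '0');
    } else {
      runs.push_back({c, len});
      len = 0;
    }
  }
  return runs;
}

static std::string encode_runs(const std::vector<Run>& runs) {
  std::string out;
  char buf[16];
  for (const auto& r : runs) {
    if (r.len <= 0) continue;
    snprintf(buf, sizeof(buf), "%d%c", r.len, r.op);
    out += buf;
  }
  return out;
}

// ---- core banded DP ---------------------------------------------------

// read vs ref, band on d = j - i in [dlo, dhi]
static AlnResult align_core(const std::string& read, const std::string& ref,
                            int match, int mismatch, int gap_open, int gap_extend,
                            int dlo, int dhi) {
  const int m = (int)read.size(), n = (int)ref.size();
  dlo = std::max(dlo, -m);
  dhi = std::min(dhi, n);
  if (dlo > dhi) { dlo = std::min(0, n - m); dhi = std::max(0, n - m); }
  const int W = dhi - dlo + 1;
  const int ge = gap_extend, go = gap_open + gap_extend;  // cost of first gap base

  // cell k (k = j - i - dlo, 0..W-1) lives at slot k + 1; slots 0 and W + 1
  // are permanent NEG sentinels so neighbour access never branches
  std::vector<int> Hprev(W + 2, NEG), Fprev(W + 2, NEG);
  std::vector<int> Hcur(W + 2, NEG), Fcur(W + 2, NEG);
  std::vector<uint8_t> bt((size_t)(m + 1) * W, 3);  // 3 = START

  for (int k = 0; k < W; ++k) {
    int j = 0 + dlo + k;
    if (j >= 0 && j <= n) Hprev[k + 1] = 0;
  }
  int best = NEG, bi = 0, bj = 0;
  if (dhi >= n) { best = 0; bi = 0; bj = n; }  // empty alignment end at (0, n)

  const char* R = read.c_str();
  const char* Q = ref.c_str();
  for (int i = 1; i <= m; ++i) {
    std::fill(Hcur.begin(), Hcur.end(), NEG);
    const int off = i + dlo;
    int jlo = std::max(0, off), jhi = std::min(n, off + W - 1);
    uint8_t* bti = &bt[(size_t)i * W];
    const char ri = R[i - 1];
    int E = NEG;
    if (jlo == 0) {  // free leading read gap
      Hcur[1 - off] = 0;
      jlo = 1;
    }
    int* __restrict hc = Hcur.data();
    int* __restrict fc = Fcur.data();
    const int* __restrict hp = Hprev.data();
    const int* __restrict fp = Fprev.data();
    const int slo = jlo - off + 1, shi = jhi - off + 1;
    // pass 1: diagonal and vertical-gap states (no intra-row dependency)
    for (int s = slo; s <= shi; ++s) {
      const int f_open = hp[s + 1] + go;
      const int f_ext = fp[s + 1] + ge;
      const int fx = f_ext >= f_open;
      const int F = fx ? f_ext : f_open;
      fc[s] = F;
      const int diag = hp[s] + (ri == Q[s + off - 2] ? match : mismatch);
      const int d = diag >= F;
      hc[s] = d ? diag : F;
      bti[s - 1] = (uint8_t)((d ? 0 : 2) | (fx << 3));
    }
    // pass 2: horizontal-gap (E) correction; priority diag >= E >= F on ties
    for (int s = slo; s <= shi; ++s) {
      const int e_open = hc[s - 1] + go;
      const int e_ext = E + ge;
      const int ex = e_ext >= e_open;
      E = ex ? e_ext : e_open;
      const int h = hc[s];
      if (E > h || (E == h && (bti[s - 1] & 3) == 2)) {
        hc[s] = E;
        bti[s - 1] = (uint8_t)(1 | (ex << 2) | (bti[s - 1] & 8));
      } else {
        bti[s - 1] |= (uint8_t)(ex << 2);
      }
    }
    if (i == m) {
      for (int j = jlo; j <= jhi; ++j)
        if (hc[j - off + 1] > best) { best = hc[j - off + 1]; bi = m; bj = j; }
    } else if (jhi == n && hc[n - off + 1] > best) {
      best = hc[n - off + 1]; bi = i; bj = n;
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  AlnResult res;
  if (best <= NEG / 2) return res;
  res.score = best;

  // traceback (ops collected in reverse)
  std::vector<char> cols;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    uint8_t b = bt[(size_t)i * W + (j - i - dlo)];
    uint8_t src = b & 3;
    if (src == 3) break;  // free-start cell
    if (src == 0) {
      cols.push_back(read[i - 1] == ref[j - 1] ? '=' : 'X');
      --i; --j;
    } else if (src == 1) {  // deletion run (consumes ref), walk left in E
      while (j > 0) {
        bool ext = (bt[(size_t)i * W + (j - i - dlo)] & 4) != 0;
        cols.push_back('D');
        --j;
        if (!ext) break;  // the gap opened at this cell; resume in H
      }
    } else {  // insertion run (consumes read), walk up in F
      while (i > 0) {
        bool ext = (bt[(size_t)i * W + (j - i - dlo)] & 8) != 0;
        cols.push_back('I');
        --i;
        if (!ext) break;
      }
    }
  }
  std::reverse(cols.begin(), cols.end());
  res.read_start = i; res.read_end = bi;
  res.ref_start = j;  res.ref_end = bj;

  // ---- leftmost gap placement ----
  // slide each indel block left across aligned columns while the swap is
  // score-neutral: the displaced column must keep its match/mismatch status
  // (for an insertion block starting at read position ri with preceding
  // aligned column (read ri-1, ref fj-1), the shifted column aligns
  // read[ri+L-1] to ref[fj-1])
  {
    int rpos = res.read_start, fpos = res.ref_start;
    size_t a = 0;
    const size_t nc = cols.size();
    while (a < nc) {
      char op = cols[a];
      size_t b2 = a;
      while (b2 < nc && cols[b2] == op) ++b2;
      int L = (int)(b2 - a);
      if (op == 'I') {
        size_t aa = a; int ri0 = rpos, fj0 = fpos;
        while (aa > 0 && (cols[aa - 1] == '=' || cols[aa - 1] == 'X') &&
               ri0 > 0 && fj0 > 0 &&
               (read[ri0 + L - 1] == ref[fj0 - 1]) == (read[ri0 - 1] == ref[fj0 - 1])) {
          cols[b2 - 1] = cols[aa - 1]; cols[aa - 1] = 'I';
          --aa; --b2; --ri0; --fj0;
        }
        rpos += L;
      } else if (op == 'D') {
        size_t aa = a; int ri0 = rpos, fj0 = fpos;
        while (aa > 0 && (cols[aa - 1] == '=' || cols[aa - 1] == 'X') &&
               ri0 > 0 && fj0 > 0 &&
               (ref[fj0 + L - 1] == read[ri0 - 1]) == (ref[fj0 - 1] == read[ri0 - 1])) {
          cols[b2 - 1] = cols[aa - 1]; cols[aa - 1] = 'D';
          --aa; --b2; --ri0; --fj0;
        }
        fpos += L;
      } else {
        rpos += L; fpos += L;
      }
      a = b2;
    }
    // recompute = / X after shifting (a shifted gap may move an X context)
    rpos = res.read_start; fpos = res.ref_start;
    for (size_t c = 0; c < nc; ++c) {
      switch (cols[c]) {
        case '=': case 'X':
          cols[c] = (read[rpos] == ref[fpos]) ? '=' : 'X';
          ++rpos; ++fpos; break;
        case 'I': ++rpos; break;
        case 'D': ++fpos; break;
      }
    }
  }

  // run-length encode with soft clips
  std::vector<Run> runs;
  if (res.read_start > 0) runs.push_back({'S', res.read_start});
  for (size_t c = 0; c < cols.size();) {
    size_t e = c;
    while (e < cols.size() && cols[e] == cols[c]) ++e;
    runs.push_back({cols[c], (int)(e - c)});
    c = e;
  }
  if (res.read_end < m) runs.push_back({'S', m - res.read_end});
  // merge adjacent same-op runs created by normalization
  std::vector<Run> merged;
  for (const auto& r : runs) {
    if (!merged.empty() && merged.back().op == r.op) merged.back().len += r.len;
    else merged.push_back(r);
  }
  res.cigar = encode_runs(merged);
  for (const auto& r : merged) {
    if (r.op == '=') { res.n_match += r.len; res.n_col += r.len; }
    else if (r.op == 'X' || r.op == 'I' || r.op == 'D') res.n_col += r.len;
  }
  res.ok = true;
  return res;
}

// ---- k-mer orientation vote -------------------------------------------

static const int KMER = 13;

static std::vector<uint32_t> ref_kmer_set(const std::string& ref) {
  std::vector<uint32_t> set;
  if ((int)ref.size() < KMER) return set;
  for (size_t p = 0; p + KMER <= ref.size(); ++p) {
    uint32_t h = 0; bool ok = true;
    for (int t = 0; t < KMER; ++t) {
      int b = base_code(ref[p + t]);
      if (b < 0) { ok = false; break; }
      h = (h << 2) | b;
    }
    if (ok) set.push_back(h);
  }
  std::sort(set.begin(), set.end());
  set.erase(std::unique(set.begin(), set.end()), set.end());
  return set;
}

static inline bool kmer_in(const std::vector<uint32_t>& set, uint32_t h) {
  return std::binary_search(set.begin(), set.end(), h);
}

// returns (fwd hits, rev hits) over up to `nprobe` sampled k-mers
static void orient_vote(const std::string& read, const std::vector<uint32_t>& set,
                        int nprobe, int& fwd, int& rev) {
  fwd = rev = 0;
  const int m = (int)read.size();
  if (m < KMER) return;
  const int span = m - KMER;
  for (int t = 0; t < nprobe; ++t) {
    int p = (int)((int64_t)span * t / std::max(1, nprobe - 1));
    uint32_t hf = 0, hr = 0; bool ok = true;
    for (int q = 0; q < KMER; ++q) {
      int b = base_code(read[p + q]);
      if (b < 0) { ok = false; break; }
      hf = (hf << 2) | b;
      hr = (hr << 2) | (3 - base_code(read[p + KMER - 1 - q]));
    }
    if (!ok) continue;
    if (kmer_in(set, hf)) ++fwd;
    if (kmer_in(set, hr)) ++rev;
  }
}

// ---- exported: batch alignment ----------------------------------------

// [[Rcpp::export]]
List cpp_align_batch(CharacterVector reads, std::string ref,
                     int match, int mismatch, int gap_open, int gap_extend,
                     int band_pad, bool banded, double min_identity,
                     double rescue_identity) {
  const int nr = reads.size();
  const int n = (int)ref.size();
  std::vector<uint32_t> kset = ref_kmer_set(ref);

  LogicalVector mapped(nr);
  CharacterVector strand(nr), cigar(nr), aln_seq(nr);
  IntegerVector score(nr), ref_start(nr), ref_end(nr), n_match(nr), n_col(nr);
  NumericVector identity(nr);

  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int m = (int)fwd.size();
    auto run = [&](const std::string& q, bool full) {
      int delta = n - (int)q.size();
      int dlo, dhi;
      if (banded && !full) {
        dlo = std::min(0, delta) - band_pad;
        dhi = std::max(0, delta) + band_pad;
      } else {
        dlo = -(int)q.size(); dhi = n;
      }
      return align_core(q, ref, match, mismatch, gap_open, gap_extend, dlo, dhi);
    };
    int vf = 0, vr = 0;
    orient_vote(fwd, kset, 48, vf, vr);
    std::string rev = (vr >= vf || m < KMER) ? revcomp(fwd) : std::string();

    AlnResult best; char best_strand = '+'; std::string best_seq;
    auto consider = [&](const AlnResult& a, char s, const std::string& q) {
      if (a.ok && a.score > best.score) { best = a; best_strand = s; best_seq = q; }
    };
    if (vf > vr) {
      consider(run(fwd, false), '+', fwd);
      double id0 = best.ok && best.n_col ? (double)best.n_match / best.n_col : 0.0;
      if (id0 < rescue_identity) {
        if (rev.empty()) rev = revcomp(fwd);
        consider(run(rev, false), '-', rev);
      }
    } else if (vr > vf) {
      consider(run(rev, false), '-', rev);
      double id0 = best.ok && best.n_col ? (double)best.n_match / best.n_col : 0.0;
      if (id0 < rescue_identity) consider(run(fwd, false), '+', fwd);
    } else {
      consider(run(fwd, false), '+', fwd);
      if (rev.empty()) rev = revcomp(fwd);
      consider(run(rev, false), '-', rev);
    }
    double id = best.ok && best.n_col ? (double)best.n_match / best.n_col : 0.0;
    if (banded && (!best.ok || id < rescue_identity)) {
      // rescue with an exhaustive pass on the better orientation
      AlnResult full = run(best_strand == '+' ? fwd : (rev.empty() ? revcomp(fwd) : rev), true);
      if (full.ok && full.score > best.score) {
        best = full;
        best_seq = best_strand == '+' ? fwd : (rev.empty() ? revcomp(fwd) : rev);
      }
      id = best.ok && best.n_col ? (double)best.n_match / best.n_col : 0.0;
    }
    mapped[r] = best.ok && id >= min_identity;
    strand[r] = std::string(1, best_strand);
    score[r] = best.ok ? best.score : NA_INTEGER;
    ref_start[r] = best.ok ? best.ref_start : NA_INTEGER;
    ref_end[r] = best.ok ? best.ref_end : NA_INTEGER;
    if (best.ok) cigar[r] = best.cigar; else cigar[r] = NA_STRING;
    identity[r] = best.ok ? id : NA_REAL;
    n_match[r] = best.n_match; n_col[r] = best.n_col;
    if (best.ok) aln_seq[r] = best_seq; else aln_seq[r] = NA_STRING;
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["mapped"] = mapped, _["strand"] = strand, _["score"] = score,
    _["ref_start"] = ref_start, _["ref_end"] = ref_end, _["cigar"] = cigar,
    _["identity"] = identity, _["n_match"] = n_match, _["n_col"] = n_col,
    _["aln_seq"] = aln_seq);
}

// single-pair exhaustive alignment (used by oracles / small problems)
// [[Rcpp::export]]
List cpp_align_pair(std::string read, std::string ref,
                    int match, int mismatch, int gap_open, int gap_extend) {
  AlnResult a = align_core(read, ref, match, mismatch, gap_open, gap_extend,
                           -(int)read.size(), (int)ref.size());
  return List::create(
    _["score"] = a.ok ? a.score : NA_INTEGER,
    _["ref_start"] = a.ref_start, _["ref_end"] = a.ref_end,
    _["cigar"] = a.cigar, _["n_match"] = a.n_match, _["n_col"] = a.n_col);
}

// ---- exported: pileup --------------------------------------------------

// Base observations within `mask_w` reference bases of an indel in the same
// read are skipped: score-tied alignments can couple an indel error with a
// neighbouring substitution and deterministically park the mismatch at a
// fixed offset, which at high coverage shows up as a systematic artefact
// allele. Deletion columns themselves are always tallied in the del row.
// [[Rcpp::export]]
List cpp_pileup(CharacterVector aln_seq, CharacterVector cigar,
                IntegerVector ref_start, int ref_len, int mask_w) {
  IntegerMatrix counts(5, ref_len);  // rows A C G T del
  std::map<std::pair<int, std::string>, int> ins;
  std::vector<uint8_t> mask(ref_len, 0);
  const int nr = aln_seq.size();
  for (int r = 0; r < nr; ++r) {
    if (cigar[r] == NA_STRING) continue;
    std::string q = as<std::string>(aln_seq[r]);
    std::vector<Run> runs = parse_cigar(as<std::string>(cigar[r]));
    int i = 0, j = ref_start[r];
    int span_lo = ref_len, span_hi = 0;
    if (mask_w > 0) {
      int jj = j;
      for (const auto& rn : runs) {
        if (rn.op == 'I' || rn.op == 'D') {
          int lo = std::max(0, jj - mask_w);
          int hi = std::min(ref_len, jj + (rn.op == 'D' ? rn.len : 0) + mask_w);
          for (int p = lo; p < hi; ++p) mask[p] = 1;
          span_lo = std::min(span_lo, lo);
          span_hi = std::max(span_hi, hi);
        }
        if (rn.op == '=' || rn.op == 'X' || rn.op == 'D') jj += rn.len;
      }
    }
    for (const auto& rn : runs) {
      switch (rn.op) {
        case 'S': i += rn.len; break;
        case '=': case 'X':
          for (int t = 0; t < rn.len; ++t, ++i, ++j) {
            int b = base_code(q[i]);
            if (b >= 0 && j >= 0 && j < ref_len && !mask[j]) ++counts(b, j);
          }
          break;
        case 'I':
          if (j >= 0 && j <= ref_len) ++ins[{j, q.substr(i, rn.len)}];
          i += rn.len;
          break;
        case 'D':
          for (int t = 0; t < rn.len; ++t, ++j)
            if (j >= 0 && j < ref_len) ++counts(4, j);
          break;
      }
    }
    if (span_lo < span_hi)
      std::fill(mask.begin() + span_lo, mask.begin() + span_hi, 0);
  }
  const int ni = (int)ins.size();
  IntegerVector ipos(ni), icount(ni);
  CharacterVector iseq(ni);
  int t = 0;
  for (const auto& kv : ins) {
    ipos[t] = kv.first.first; iseq[t] = kv.first.second; icount[t] = kv.second; ++t;
  }
  return List::create(
    _["counts"] = counts,
    _["ins_pos"] = ipos, _["ins_seq"] = iseq, _["ins_count"] = icount);
}

// ---- exported: per-read window status around variant sites ------------

// status: 0 = ref allele with clean flanks, 1 = alt allele with clean
// flanks, 2 = excluded (flank mismatch/indel, uncovered window, del or
// third allele at the site)
// [[Rcpp::export]]
IntegerMatrix cpp_window_status(CharacterVector aln_seq, CharacterVector cigar,
                                IntegerVector ref_start, int ref_len,
                                IntegerVector var_pos, CharacterVector var_ref,
                                CharacterVector var_alt, int w) {
  const int nr = aln_seq.size(), nv = var_pos.size();
  IntegerMatrix status(nr, nv);
  std::vector<int> wlo(nv), whi(nv);  // clipped inclusive window bounds
  std::vector<char> vref(nv), valt(nv);
  for (int v = 0; v < nv; ++v) {
    wlo[v] = std::max(0, var_pos[v] - w);
    whi[v] = std::min(ref_len - 1, var_pos[v] + w);
    vref[v] = as<std::string>(var_ref[v])[0];
    valt[v] = as<std::string>(var_alt[v])[0];
  }
  for (int r = 0; r < nr; ++r) {
    if (cigar[r] == NA_STRING) {
      for (int v = 0; v < nv; ++v) status(r, v) = 2;
      continue;
    }
    std::string q = as<std::string>(aln_seq[r]);
    std::vector<Run> runs = parse_cigar(as<std::string>(cigar[r]));
    std::vector<char> site(nv, 0);      // base observed at the site, 'D' = deletion
    std::vector<bool> dirty(nv, false); // flank mismatch or indel in window
    int i = 0, j = ref_start[r];
    int jend = j;
    for (const auto& rn : runs) {
      switch (rn.op) {
        case 'S': i += rn.len; break;
        case '=':
          for (int v = 0; v < nv; ++v)
            if (var_pos[v] >= j && var_pos[v] < j + rn.len) site[v] = vref[v];
          i += rn.len; j += rn.len; break;
        case 'X':
          for (int t = 0; t < rn.len; ++t, ++i, ++j) {
            for (int v = 0; v < nv; ++v) {
              if (j == var_pos[v]) site[v] = q[i];
              else if (j >= wlo[v] && j <= whi[v]) dirty[v] = true;
            }
          }
          break;
        case 'I':
          for (int v = 0; v < nv; ++v)
            if (j > wlo[v] && j <= whi[v]) dirty[v] = true;
          i += rn.len; break;
        case 'D':
          for (int t = 0; t < rn.len; ++t, ++j) {
            for (int v = 0; v < nv; ++v) {
              if (j == var_pos[v]) site[v] = 'D';
              else if (j >= wlo[v] && j <= whi[v]) dirty[v] = true;
            }
          }
          break;
      }
      jend = j;
    }
    for (int v = 0; v < nv; ++v) {
      bool covered = ref_start[r] <= wlo[v] && jend >= whi[v] + 1;
      int st;
      if (!covered || dirty[v] || site[v] == 0 || site[v] == 'D') st = 2;
      else if (site[v] == valt[v]) st = 1;
      else if (site[v] == vref[v]) st = 0;
      else st = 2;
      status(r, v) = st;
    }
  }
  return status;
}

// ---- exported: indel events >= min_len --------------------------------

// [[Rcpp::export]]
DataFrame cpp_events(CharacterVector aln_seq, CharacterVector cigar,
                     IntegerVector ref_start, int min_len) {
  std::vector<int> read_idx, pos, len;
  std::vector<std::string> kind, seq;
  const int nr = aln_seq.size();
  for (int r = 0; r < nr; ++r) {
    if (cigar[r] == NA_STRING) continue;
    std::string q = as<std::string>(aln_seq[r]);
    std::vector<Run> runs = parse_cigar(as<std::string>(cigar[r]));
    int i = 0, j = ref_start[r];
    for (const auto& rn : runs) {
      switch (rn.op) {
        case 'S': i += rn.len; break;
        case '=': case 'X': i += rn.len; j += rn.len; break;
        case 'I':
          if (rn.len >= min_len) {
            read_idx.push_back(r + 1); kind.push_back("insertion");
            pos.push_back(j); len.push_back(rn.len);
            seq.push_back(q.substr(i, rn.len));
          }
          i += rn.len; break;
        case 'D':
          if (rn.len >= min_len) {
            read_idx.push_back(r + 1); kind.push_back("deletion");
            pos.push_back(j); len.push_back(rn.len);
            seq.push_back("");
          }
          j += rn.len; break;
      }
    }
  }
  return DataFrame::create(
    _["read_idx"] = read_idx, _["kind"] = kind, _["position"] = pos,
    _["length"] = len, _["seq"] = seq, _["stringsAsFactors"] = false);
}

// ---- exported: per-base error injection for the simulator -------------

// templates: clone template sequences; per read, tpl_a (1-based), and for
// chimeric reads tpl_b (1-based, 0 = none) with a switch at `breakpoint`
// (prefix [0, b) from A, suffix [b, ...) from B). Errors are i.i.d. per
// base: deletion, substitution (uniform over the three other bases), then
// a single-base insertion after the base. Uses R's RNG stream.
// [[Rcpp::export]]
CharacterVector cpp_simulate_reads(CharacterVector templates, IntegerVector tpl_a,
                                   IntegerVector tpl_b, IntegerVector breakpoint,
                                   LogicalVector rc,
                                   double sub_rate, double ins_rate, double del_rate) {
  const int nt = templates.size(), nr = tpl_a.size();
  std::vector<std::string> tpl(nt);
  for (int t = 0; t < nt; ++t) tpl[t] = as<std::string>(templates[t]);
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(nr);
  std::string mol, read;
  for (int r = 0; r < nr; ++r) {
    const std::string& A = tpl[tpl_a[r] - 1];
    if (tpl_b[r] > 0) {
      const std::string& B = tpl[tpl_b[r] - 1];
      int b = breakpoint[r];
      mol = A.substr(0, std::min((size_t)b, A.size()));
      if ((size_t)b < B.size()) mol += B.substr(b);
    } else {
      mol = A;
    }
    read.clear();
    read.reserve(mol.size() + 64);
    for (size_t p = 0; p < mol.size(); ++p) {
      double u = unif_rand();
      if (u < del_rate) {
        // base dropped
      } else if (u < del_rate + sub_rate) {
        int b0 = base_code(mol[p]);
        int alt = (int)(unif_rand() * 3.0);
        if (alt > 2) alt = 2;
        // pick among the three other bases
        int bnew = (b0 + 1 + alt) & 3;
        read.push_back(b0 < 0 ? 'N' : BASES[bnew]);
      } else {
        read.push_back(mol[p]);
      }
      if (unif_rand() < ins_rate) {
        int b = (int)(unif_rand() * 4.0);
        if (b > 3) b = 3;
        read.push_back(BASES[b]);
      }
    }
    if (rc[r]) read = revcomp(read);
    out[r] = read;
    if (r % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) out[i] = revcomp(as<std::string>(x[i]));
  return out;
}
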