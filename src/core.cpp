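#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Sequence encoding helpers
// ---------------------------------------------------------------------------

static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

// minimal nonnegative number parsers (avoid libc strtol/strtod so the
// binary stays portable across glibc versions)
static long parse_long(const std::string& s) {
  long v = 0;
  for (char c : s) {
    if (c < '0' || c > '9') break;
    v = v * 10 + (c - '0');
  }
  return v;
}

static double parse_double_int(const std::string& s) {
  return (double)parse_long(s);
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

// ---------------------------------------------------------------------------
// Seed index: hash of every k-mer position in the reference
// ---------------------------------------------------------------------------

struct SeedIndex {
  int k;
  std::vector<std::string> contigs;
  std::vector<std::string> names;
  // packed position: (contig << 32) | 0-based offset
  std::unordered_map<uint64_t, std::vector<uint64_t> > table;
  size_t n_positions = 0, n_multi = 0;
};

static bool kmer_at(const std::string& s, size_t i, int k, uint64_t& key) {
  uint64_t v = 0;
  for (int j = 0; j < k; ++j) {
    int e = enc(s[i + j]);
    if (e > 3) return false;
    v = (v << 2) | (uint64_t)e;
  }
  key = v;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k) {
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  for (int c = 0; c < seqs.size(); ++c) {
    idx->contigs.push_back(as<std::string>(seqs[c]));
    idx->names.push_back(as<std::string>(names[c]));
  }
  for (size_t c = 0; c < idx->contigs.size(); ++c) {
    const std::string& s = idx->contigs[c];
    if ((int)s.size() < k) continue;
    for (size_t i = 0; i + k <= s.size(); ++i) {
      uint64_t key;
      if (!kmer_at(s, i, k, key)) continue;
      idx->table[key].push_back(((uint64_t)c << 32) | (uint64_t)i);
      idx->n_positions++;
    }
  }
  for (auto& kv : idx->table) if (kv.second.size() > 1) idx->n_multi += kv.second.size();
  XPtr<SeedIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
bool cpp_ptr_valid(SEXP xp) {
  return R_ExternalPtrAddr(xp) != NULL;
}

// [[Rcpp::export]]
List cpp_index_stats(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  return List::create(_["n_positions"] = (double)idx->n_positions,
                      _["n_multi"] = (double)idx->n_multi,
                      _["n_kmers"] = (double)idx->table.size(),
                      _["k"] = idx->k);
}

// [[Rcpp::export]]
IntegerVector cpp_kmer_hits(SEXP xp, std::string kmer) {
  XPtr<SeedIndex> idx(xp);
  uint64_t key;
  std::vector<int> out;
  if ((int)kmer.size() == idx->k && kmer_at(kmer, 0, idx->k, key)) {
    auto it = idx->table.find(key);
    if (it != idx->table.end())
      for (auto p : it->second) out.push_back((int)(p & 0xffffffffULL) + 1);
  }
  return wrap(out);
}

// ---------------------------------------------------------------------------
// Glocal affine-gap aligner (query global, reference window local)
// match +1, mismatch -2, gap open -4, gap extend -1 (open includes first base)
// ---------------------------------------------------------------------------

struct AlnResult {
  int score = INT32_MIN / 4;
  int ref_start = 0;  // 0-based offset into window where alignment begins
  std::string cigar;
  int nm = 0;
};

static const int MATCH = 1, MISMATCH = -2, GAP_OPEN = -5, GAP_EXT = -1;
// GAP_OPEN here is the cost of the first gap base (-4 open + -1 extend)

static AlnResult glocal_align(const std::string& q, const std::string& w) {
  int n = q.size(), m = w.size();
  const int NEG = INT32_MIN / 4;
  // DP over query rows; M/Ix(gap in ref: insertion in query)/Iy(gap in query: deletion)
  std::vector<std::vector<int> > M(n + 1, std::vector<int>(m + 1, NEG));
  std::vector<std::vector<int> > X(n + 1, std::vector<int>(m + 1, NEG)); // gap in window (I)
  std::vector<std::vector<int> > Y(n + 1, std::vector<int>(m + 1, NEG)); // gap in query (D)
  for (int j = 0; j <= m; ++j) M[0][j] = 0; // free start anywhere in window
  for (int i = 1; i <= n; ++i) {
    X[i][0] = std::max(M[i - 1][0] + GAP_OPEN, X[i - 1][0] + GAP_EXT);
    for (int j = 1; j <= m; ++j) {
      int s = (enc(q[i - 1]) == enc(w[j - 1]) && enc(q[i - 1]) < 4) ? MATCH : MISMATCH;
      int best = std::max(std::max(M[i - 1][j - 1], X[i - 1][j - 1]), Y[i - 1][j - 1]);
      M[i][j] = best + s;
      X[i][j] = std::max(std::max(M[i - 1][j] + GAP_OPEN, X[i - 1][j] + GAP_EXT),
                         Y[i - 1][j] + GAP_OPEN);
      Y[i][j] = std::max(std::max(M[i][j - 1] + GAP_OPEN, Y[i][j - 1] + GAP_EXT),
                         X[i][j - 1] + GAP_OPEN);
    }
  }
  // best end: query fully consumed, any window position
  AlnResult res;
  int bj = 0, bstate = 0;
  for (int j = 0; j <= m; ++j) {
    for (int st = 0; st < 2; ++st) {
      int v = st == 0 ? M[n][j] : X[n][j];
      if (v > res.score) { res.score = v; bj = j; bstate = st; }
    }
  }
  // traceback
  std::vector<char> ops;
  int i = n, j = bj, st = bstate, nm = 0;
  while (i > 0) {
    if (st == 0) { // M
      int s = (enc(q[i - 1]) == enc(w[j - 1]) && enc(q[i - 1]) < 4) ? MATCH : MISMATCH;
      if (s == MISMATCH) nm++;
      int prev = M[i][j] - s;
      ops.push_back('M');
      if (M[i - 1][j - 1] == prev) st = 0;
      else if (X[i - 1][j - 1] == prev) st = 1;
      else st = 2;
      i--; j--;
    } else if (st == 1) { // X: query base consumed, no ref (insertion)
      ops.push_back('I'); nm++;
      if (j >= 0 && M[i - 1][j] + GAP_OPEN == X[i][j]) st = 0;
      else if (X[i - 1][j] + GAP_EXT == X[i][j]) st = 1;
      else st = 2;
      i--;
    } else { // Y: ref base consumed, no query (deletion)
      ops.push_back('D'); nm++;
      if (M[i][j - 1] + GAP_OPEN == Y[i][j]) st = 0;
      else if (Y[i][j - 1] + GAP_EXT == Y[i][j]) st = 2;
      else st = 1;
      j--;
    }
  }
  res.ref_start = j;
  // build cigar string (ops reversed)
  std::string cg;
  int run = 0; char cur = 0;
  for (auto it = ops.rbegin(); it != ops.rend(); ++it) {
    if (*it == cur) run++;
    else {
      if (run) cg += std::to_string(run) + cur;
      cur = *it; run = 1;
    }
  }
  if (run) cg += std::to_string(run) + cur;
  res.cigar = cg;
  res.nm = nm;
  return res;
}

// ---------------------------------------------------------------------------
// Read mapping: seed-and-vote candidate loci, ungapped check, glocal fallback,
// split detection for junction-spanning reads
// ---------------------------------------------------------------------------

struct Cand { int contig; long start; int votes; };

static int ungapped_mismatches(const std::string& r, const std::string& ref, long start) {
  int m = 0;
  long L = r.size(), R = ref.size();
  for (long i = 0; i < L; ++i) {
    long p = start + i;
    if (p < 0 || p >= R || enc(r[i]) != enc(ref[p]) || enc(r[i]) > 3) m++;
  }
  return m;
}

// longest prefix of r matching ref at start with <= max_mm mismatches,
// trimmed back to end on a match
static int prefix_run(const std::string& r, const std::string& ref, long start, int max_mm) {
  long L = r.size(), R = ref.size();
  int mm = 0; long last_match = -1;
  for (long i = 0; i < L; ++i) {
    long p = start + i;
    bool ok = (p >= 0 && p < R && enc(r[i]) == enc(ref[p]) && enc(r[i]) < 4);
    if (ok) last_match = i;
    else { mm++; if (mm > max_mm) break; }
  }
  return (int)(last_match + 1);
}

static int suffix_run(const std::string& r, const std::string& ref, long end_excl, int max_mm) {
  // aligns r's suffix so that r[L-1] sits at ref[end_excl-1]
  long L = r.size(), R = ref.size();
  int mm = 0; long first_match = L;
  for (long i = L - 1; i >= 0; --i) {
    long p = end_excl - (L - i);
    bool ok = (p >= 0 && p < R && enc(r[i]) == enc(ref[p]) && enc(r[i]) < 4);
    if (ok) first_match = i;
    else { mm++; if (mm > max_mm) break; }
  }
  return (int)(L - first_match);
}

// [[Rcpp::export]]
List cpp_map_reads(SEXP xp, CharacterVector reads, int seed_step = 25,
                   int max_candidates = 12, double min_score_frac = 0.30,
                   double split_trigger_frac = 0.75, int min_split_part = 30) {
  XPtr<SeedIndex> idx(xp);
  int k = idx->k;
  int nseq = reads.size();
  IntegerVector out_contig(nseq, NA_INTEGER), out_pos(nseq, NA_INTEGER);
  CharacterVector out_strand(nseq), out_cigar(nseq), out_seq(nseq);
  IntegerVector out_score(nseq, NA_INTEGER), out_nm(nseq, NA_INTEGER);
  LogicalVector out_split(nseq, false), out_amb(nseq, false), out_mapped(nseq, false);
  IntegerVector sp_contig(nseq, NA_INTEGER), sp_pos(nseq, NA_INTEGER), sp_len(nseq, NA_INTEGER);
  IntegerVector tie_contig(nseq, NA_INTEGER), tie_pos(nseq, NA_INTEGER);

  for (int ri = 0; ri < nseq; ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    int L = fwd.size();
    if (L < k) continue;
    std::string rev = revcomp(fwd);

    struct Scored {
      int contig; long start; int strand; int score; int nm;
      std::string cigar; bool gapped;
    };
    std::vector<Scored> scored;
    std::vector<Cand> cands_by_strand[2];

    for (int st = 0; st < 2; ++st) {
      const std::string& r = st == 0 ? fwd : rev;
      std::map<std::pair<int, long>, int> votes;
      std::vector<int> offs;
      for (int o = 0; o + k <= L; o += seed_step) offs.push_back(o);
      if (offs.empty() || offs.back() != L - k) offs.push_back(L - k);
      for (int o : offs) {
        uint64_t key;
        if (!kmer_at(r, o, k, key)) continue;
        auto it = idx->table.find(key);
        if (it == idx->table.end()) continue;
        if (it->second.size() > 200) continue; // repeat k-mer
        for (auto p : it->second) {
          int c = (int)(p >> 32);
          long pos = (long)(p & 0xffffffffULL);
          votes[std::make_pair(c, pos - o)]++;
        }
      }
      std::vector<Cand> cands;
      for (auto& kv : votes)
        cands.push_back({kv.first.first, kv.first.second, kv.second});
      std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
        if (a.votes != b.votes) return a.votes > b.votes;
        if (a.contig != b.contig) return a.contig < b.contig;
        return a.start < b.start;
      });
      if ((int)cands.size() > max_candidates) cands.resize(max_candidates);
      cands_by_strand[st] = cands;
      for (auto& cd : cands) {
        const std::string& ref = idx->contigs[cd.contig];
        int mm = ungapped_mismatches(r, ref, cd.start);
        int sc = L - 3 * mm;
        scored.push_back({cd.contig, cd.start, st, sc, mm,
                          std::to_string(L) + "M", false});
      }
    }

    if (scored.empty()) continue;
    std::sort(scored.begin(), scored.end(), [](const Scored& a, const Scored& b) {
      if (a.score != b.score) return a.score > b.score;
      if (a.contig != b.contig) return a.contig < b.contig;
      if (a.start != b.start) return a.start < b.start;
      return a.strand < b.strand;
    });

    Scored best = scored[0];
    // gapped rescue for imperfect best hits
    if (best.nm > std::max(2, (int)(0.04 * L))) {
      int ntry = std::min((int)scored.size(), 3);
      for (int t = 0; t < ntry; ++t) {
        const Scored& cd = scored[t];
        const std::string& ref = idx->contigs[cd.contig];
        long w0 = std::max(0L, cd.start - 25);
        long w1 = std::min((long)ref.size(), cd.start + L + 25);
        if (w1 - w0 < L / 2) continue;
        const std::string& r = cd.strand == 0 ? fwd : rev;
        AlnResult ar = glocal_align(r, ref.substr(w0, w1 - w0));
        if (ar.score > best.score) {
          best = {cd.contig, w0 + ar.ref_start, cd.strand, ar.score, ar.nm,
                  ar.cigar, true};
        }
      }
    }

    // split-read detection: triggered when the best alignment is poor OR
    // carries more than a couple of mismatches -- at a junction between
    // homeologous loci the full-length alignment can look acceptable
    // (~15% mismatches on one side) yet a split explains the read better
    bool made_split = false;
    if (best.nm > 2 || best.score < split_trigger_frac * L) {
      int bp_len = 0, bs_len = 0;
      int bp_c = -1, bs_c = -1; long bp_s = 0, bs_e = 0; int bp_st = -1, bs_st = -1;
      for (int st = 0; st < 2; ++st) {
        const std::string& r = st == 0 ? fwd : rev;
        for (auto& cd : cands_by_strand[st]) {
          const std::string& ref = idx->contigs[cd.contig];
          int pl = prefix_run(r, ref, cd.start, 0);
          if (pl > bp_len || (pl == bp_len && bp_c >= 0 &&
              (cd.contig < bp_c || (cd.contig == bp_c && cd.start < bp_s)))) {
            if (pl >= bp_len) { bp_len = pl; bp_c = cd.contig; bp_s = cd.start; bp_st = st; }
          }
          int sl = suffix_run(r, ref, cd.start + L, 0);
          if (sl > bs_len || (sl == bs_len && bs_c >= 0 &&
              (cd.contig < bs_c || (cd.contig == bs_c && cd.start < bs_e)))) {
            if (sl >= bs_len) { bs_len = sl; bs_c = cd.contig; bs_e = cd.start + L; bs_st = st; }
          }
        }
      }
      // small diagonal shifts on the same contig are short indels, better
      // represented by a gapped alignment than a split
      bool distinct = (bp_c != bs_c) ||
        (std::labs((bs_e - L) - bp_s) > 40);
      if (bp_len >= min_split_part && bs_len >= min_split_part &&
          bp_len + bs_len >= L && bp_st == bs_st && bp_st >= 0 && distinct &&
          bp_len + bs_len > best.score) {
        // primary: prefix segment; secondary: suffix segment
        out_contig[ri] = bp_c + 1;
        out_pos[ri] = (int)bp_s + 1;
        out_strand[ri] = bp_st == 0 ? "+" : "-";
        out_cigar[ri] = std::to_string(bp_len) + "M" +
          std::to_string(L - bp_len) + "S";
        out_seq[ri] = bp_st == 0 ? fwd : rev;
        out_score[ri] = bp_len + bs_len;
        out_nm[ri] = 0;
        out_split[ri] = true;
        out_mapped[ri] = true;
        sp_contig[ri] = bs_c + 1;
        sp_pos[ri] = (int)(bs_e - bs_len) + 1;
        sp_len[ri] = bs_len;
        made_split = true;
      }
    }

    if (!made_split) {
      if (best.score < min_score_frac * L) continue; // unmapped
      // clamp: convert out-of-contig overhangs to soft clips
      const std::string& ref = idx->contigs[best.contig];
      long start = best.start;
      std::string cigar = best.cigar;
      if (!best.gapped) {
        int lead = 0, trail = 0;
        if (start < 0) { lead = (int)(-start); start = 0; }
        long over = best.start + L - (long)ref.size();
        if (over > 0) trail = (int)over;
        if (lead + trail >= L) continue;
        cigar = "";
        if (lead) cigar += std::to_string(lead) + "S";
        cigar += std::to_string(L - lead - trail) + "M";
        if (trail) cigar += std::to_string(trail) + "S";
      }
      out_contig[ri] = best.contig + 1;
      out_pos[ri] = (int)start + 1;
      out_strand[ri] = best.strand == 0 ? "+" : "-";
      out_cigar[ri] = cigar;
      out_seq[ri] = best.strand == 0 ? fwd : rev;
      out_score[ri] = best.score;
      out_nm[ri] = best.nm;
      out_mapped[ri] = true;
      // tie detection among ungapped-scored candidates at distinct loci
      for (size_t t = 1; t < scored.size(); ++t) {
        if (scored[t].score != scored[0].score) break;
        if (scored[t].contig != scored[0].contig ||
            std::labs(scored[t].start - scored[0].start) > 3) {
          out_amb[ri] = true;
          tie_contig[ri] = scored[t].contig + 1;
          tie_pos[ri] = (int)scored[t].start + 1;
          break;
        }
      }
    }
  }

  return List::create(
    _["contig"] = out_contig, _["pos"] = out_pos, _["strand"] = out_strand,
    _["cigar"] = out_cigar, _["seq"] = out_seq, _["score"] = out_score,
    _["nm"] = out_nm, _["is_split"] = out_split, _["ambiguous"] = out_amb,
    _["mapped"] = out_mapped, _["split_contig"] = sp_contig,
    _["split_pos"] = sp_pos, _["split_len"] = sp_len,
    _["tie_contig"] = tie_contig, _["tie_pos"] = tie_pos);
}

// ---------------------------------------------------------------------------
// Pileup: per-position base counts and gapped-alignment indel evidence
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_pileup(IntegerVector contig_idx, IntegerVector pos,
                CharacterVector cigar, CharacterVector seq,
                IntegerVector contig_lens) {
  int ncontig = contig_lens.size();
  std::vector<IntegerMatrix> counts;
  for (int c = 0; c < ncontig; ++c)
    counts.push_back(IntegerMatrix(4, contig_lens[c]));
  // indel evidence keyed by contig:pos_before:alt description
  std::map<std::string, int> indels;

  int n = contig_idx.size();
  for (int i = 0; i < n; ++i) {
    if (contig_idx[i] == NA_INTEGER) continue;
    int c = contig_idx[i] - 1;
    long rp = pos[i] - 1; // ref cursor 0-based
    long qp = 0;
    std::string cg = as<std::string>(cigar[i]);
    std::string sq = as<std::string>(seq[i]);
    long clen = contig_lens[c];
    size_t ci = 0;
    while (ci < cg.size()) {
      long num = 0;
      while (ci < cg.size() && isdigit(cg[ci])) { num = num * 10 + (cg[ci] - '0'); ci++; }
      char op = cg[ci++];
      if (op == 'M') {
        for (long j = 0; j < num; ++j) {
          long p = rp + j;
          if (p >= 0 && p < clen && qp + j < (long)sq.size()) {
            int e = enc(sq[qp + j]);
            if (e < 4) counts[c](e, p)++;
          }
        }
        rp += num; qp += num;
      } else if (op == 'I') {
        std::string ins = sq.substr(qp, num);
        indels["I\t" + std::to_string(c + 1) + "\t" + std::to_string(rp) + "\t" + ins]++;
        qp += num;
      } else if (op == 'D') {
        indels["D\t" + std::to_string(c + 1) + "\t" + std::to_string(rp) + "\t" +
          std::to_string(num)]++;
        rp += num;
      } else if (op == 'S') {
        qp += num;
      } else if (op == 'H') {
        // nothing
      } else if (op == 'N') {
        rp += num;
      }
    }
  }

  List cl(ncontig);
  for (int c = 0; c < ncontig; ++c) cl[c] = counts[c];
  std::vector<std::string> ikind, ialt;
  std::vector<int> icontig; std::vector<double> ipos; std::vector<int> icount;
  for (auto& kv : indels) {
    std::string s = kv.first;
    size_t p1 = s.find('\t'), p2 = s.find('\t', p1 + 1), p3 = s.find('\t', p2 + 1);
    ikind.push_back(s.substr(0, p1));
    icontig.push_back((int)parse_long(s.substr(p1 + 1, p2 - p1 - 1)));
    ipos.push_back(parse_double_int(s.substr(p2 + 1, p3 - p2 - 1)));
    ialt.push_back(s.substr(p3 + 1));
    icount.push_back(kv.second);
  }
  return List::create(_["counts"] = cl,
                      _["indel_kind"] = wrap(ikind),
                      _["indel_contig"] = wrap(icontig),
                      _["indel_pos_before"] = wrap(ipos),
                      _["indel_alt"] = wrap(ialt),
                      _["indel_count"] = wrap(icount));
}

// ---------------------------------------------------------------------------
// Greedy overlap-layout-consensus local assembler
// ---------------------------------------------------------------------------

static bool overlap_ok(const std::string& a, const std::string& b, size_t olen,
                       double min_ident, size_t& mism_out) {
  // suffix of a (length olen) vs prefix of b
  size_t mism = 0, maxm = (size_t)std::floor((1.0 - min_ident) * olen);
  size_t off = a.size() - olen;
  for (size_t i = 0; i < olen; ++i) {
    if (enc(a[off + i]) != enc(b[i]) || enc(a[off + i]) > 3) {
      if (++mism > maxm) return false;
    }
  }
  mism_out = mism;
  return true;
}

// [[Rcpp::export]]
CharacterVector cpp_assemble(CharacterVector reads_in, int min_overlap = 30,
                             double min_identity = 0.95, int min_contig = 200) {
  // use reads and reverse complements, deduplicated, lexicographically sorted
  std::vector<std::string> pool;
  for (int i = 0; i < reads_in.size(); ++i) {
    std::string s = as<std::string>(reads_in[i]);
    pool.push_back(s);
    pool.push_back(revcomp(s));
  }
  std::sort(pool.begin(), pool.end());
  pool.erase(std::unique(pool.begin(), pool.end()), pool.end());
  int n = pool.size();
  if (n == 0) return CharacterVector(0);

  // index: 16-mer prefix seeds of each read
  const int SK = 16;
  std::unordered_map<uint64_t, std::vector<int> > pref;
  for (int i = 0; i < n; ++i) {
    if ((int)pool[i].size() < SK) continue;
    uint64_t key;
    if (kmer_at(pool[i], 0, SK, key)) pref[key].push_back(i);
  }

  std::vector<bool> used(n, false);
  std::vector<std::string> contigs;

  for (int s0 = 0; s0 < n; ++s0) {
    if (used[s0]) continue;
    std::string contig = pool[s0];
    used[s0] = true;
    // mark the revcomp twin as used too
    {
      std::string rc = revcomp(pool[s0]);
      auto it = std::lower_bound(pool.begin(), pool.end(), rc);
      if (it != pool.end() && *it == rc) used[it - pool.begin()] = true;
    }
    for (int dir = 0; dir < 2; ++dir) {
      // dir 0: extend right; dir 1: operate on revcomp to extend original left
      if (dir == 1) contig = revcomp(contig);
      bool extended = true;
      while (extended) {
        extended = false;
        // candidate reads whose prefix seed occurs in the contig tail;
        // perfect overlaps are preferred over merely-tolerated ones so
        // that near-identical homeologous haplotypes cannot hijack the
        // extension while an exact continuation exists
        long tail0 = std::max(0L, (long)contig.size() - 400);
        int best_read = -1; size_t best_ov = 0; size_t best_mism = SIZE_MAX;
        for (long p = tail0; p + SK <= (long)contig.size(); ++p) {
          uint64_t key;
          if (!kmer_at(contig, p, SK, key)) continue;
          auto it = pref.find(key);
          if (it == pref.end()) continue;
          size_t olen = contig.size() - p;
          for (int rid : it->second) {
            if (used[rid]) continue;
            const std::string& r = pool[rid];
            if (r.size() <= olen) continue;            // no extension
            if (olen < (size_t)min_overlap) continue;
            size_t mism = 0;
            if (!overlap_ok(contig, r, olen, min_identity, mism)) continue;
            bool better = false;
            bool cur_perfect = mism == 0, best_perfect = best_mism == 0;
            if (cur_perfect != best_perfect) better = cur_perfect;
            else if (olen != best_ov) better = olen > best_ov;
            else if (best_read >= 0 && r < pool[best_read]) better = true;
            if (better) {
              best_ov = olen; best_read = rid; best_mism = mism;
            }
          }
        }
        if (best_read >= 0) {
          const std::string& r = pool[best_read];
          contig += r.substr(best_ov);
          used[best_read] = true;
          std::string rc = revcomp(r);
          auto it = std::lower_bound(pool.begin(), pool.end(), rc);
          if (it != pool.end() && *it == rc) used[it - pool.begin()] = true;
          extended = true;
        }
      }
      if (dir == 1) contig = revcomp(contig); // restore orientation
    }
    // absorb reads contained in the contig (exact substring, both strands)
    for (int i = 0; i < n; ++i) {
      if (used[i]) continue;
      if (contig.find(pool[i]) != std::string::npos) used[i] = true;
    }
    if ((int)contig.size() >= min_contig) contigs.push_back(contig);
  }
  // canonical orientation: lexicographic min of contig / revcomp, sorted by
  // decreasing length then sequence for determinism
  for (auto& c : contigs) {
    std::string rc = revcomp(c);
    if (rc < c) c = rc;
  }
  std::sort(contigs.begin(), contigs.end(), [](const std::string& a, const std::string& b) {
    if (a.size() != b.size()) return a.size() > b.size();
    return a < b;
  });
  return wrap(contigs);
}

// ---------------------------------------------------------------------------
// Exhaustive maximal identical run scan used by breakpoint-interval location
// (also serves as the brute-force oracle in tests)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_identical_runs(CharacterVector aligned1, CharacterVector aligned2) {
  std::string a = as<std::string>(aligned1[0]);
  std::string b = as<std::string>(aligned2[0]);
  int n = a.size();
  std::vector<int> rs, re, o1s, o1e, o2s, o2e;
  int p1 = 0, p2 = 0; // 1-based coords consumed so far
  int i = 0;
  while (i < n) {
    bool eq = (a[i] != '-' && b[i] != '-' && enc(a[i]) == enc(b[i]) && enc(a[i]) < 4);
    if (eq) {
      int s = i, s1 = p1 + 1, s2 = p2 + 1;
      while (i < n && a[i] != '-' && b[i] != '-' && enc(a[i]) == enc(b[i]) && enc(a[i]) < 4) {
        p1++; p2++; i++;
      }
      rs.push_back(s + 1); re.push_back(i);
      o1s.push_back(s1); o1e.push_back(p1);
      o2s.push_back(s2); o2e.push_back(p2);
    } else {
      if (a[i] != '-') p1++;
      if (b[i] != '-') p2++;
      i++;
    }
  }
  return List::create(_["col_start"] = wrap(rs), _["col_end"] = wrap(re),
                      _["orf1_start"] = wrap(o1s), _["orf1_end"] = wrap(o1e),
                      _["orf2_start"] = wrap(o2s), _["orf2_end"] = wrap(o2e));
}
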