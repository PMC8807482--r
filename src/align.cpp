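// Banded Smith-Waterman (Gotoh affine gaps) germline segment alignment.
//
// The band is centred on the best k-mer seed diagonal between read and
// segment; with no seed (or band_width <= 0) the full DP matrix is used.
// Coordinates are 0-based half-open throughout. A gap of length L costs
// gap_open + L * gap_extend.

#include <Rcpp.h>
#include <climits>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;

struct Aln {
  int score = 0;
  int r_start = 0, r_end = 0;  // read span, half-open
  int g_start = 0, g_end = 0;  // germline span, half-open
  std::string cigar;           // ops over =,X,I,D (I: extra read base)
  std::vector<int> sub_read;   // mismatch positions in read coords
  std::vector<int> sub_g;      // mismatch positions in germline coords
  bool has_indel = false;
  bool valid = false;
};

static inline int nt_code(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; }
  return -1;
}

// k-mer position index of one germline segment, built once per batch
struct SegIndex {
  int k = 0, m = 0;
  std::unordered_map<uint64_t, std::vector<int>> pos;
};

static SegIndex build_seg_index(const std::string& seg, int k) {
  SegIndex idx;
  idx.k = k;
  idx.m = (int)seg.size();
  uint64_t key = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int j = 0; j < idx.m; ++j) {
    int c = nt_code(seg[j]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) idx.pos[key].push_back(j - k + 1);
  }
  return idx;
}

// rolling k-mer codes of a read: one entry per start position, -1 when the
// window contains a non-ACGT character
static std::vector<int64_t> read_kmers(const std::string& read, int k) {
  int n = (int)read.size();
  std::vector<int64_t> out(std::max(0, n - k + 1), -1);
  uint64_t key = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = nt_code(read[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) out[i - k + 1] = (int64_t)key;
  }
  return out;
}

// best seed diagonal (g_pos - r_pos); returns false if no k-mer is shared
static bool seed_diagonal_indexed(const std::vector<int64_t>& kmers,
                                  const SegIndex& idx, int& center) {
  if (idx.m < idx.k || kmers.empty()) return false;
  std::unordered_map<int, int> diag_count;
  int best_d = 0, best_n = 0;
  for (int r0 = 0; r0 < (int)kmers.size(); ++r0) {
    if (kmers[r0] < 0) continue;
    auto it = idx.pos.find((uint64_t)kmers[r0]);
    if (it == idx.pos.end()) continue;
    for (int j0 : it->second) {
      int d = j0 - r0;
      int cnt = ++diag_count[d];
      if (cnt > best_n || (cnt == best_n && d < best_d)) {
        best_n = cnt; best_d = d;
      }
    }
  }
  if (best_n == 0) return false;
  center = best_d;
  return true;
}

static bool seed_diagonal(const std::string& read, const std::string& seg,
                          int k, int& center) {
  SegIndex idx = build_seg_index(seg, k);
  return seed_diagonal_indexed(read_kmers(read, k), idx, center);
}

static Aln gotoh_core(const std::string& read, const std::string& seg,
                      int match, int mismatch, int gap_open, int gap_extend,
                      int center, int band, bool do_traceback) {
  int n = (int)read.size(), m = (int)seg.size();
  Aln out;
  if (n == 0 || m == 0) return out;
  int gopen = gap_open + gap_extend;  // first gap base

  // grow-only scratch buffers; cells are initialized per band window, so
  // stale content outside the window is never read
  static std::vector<int> M, X /*gap in seg: read insertion*/,
                          Y /*gap in read: segment deletion*/;
  static std::vector<signed char> tM, tX, tY;
  size_t need = (size_t)(n + 1) * (m + 1);
  if (M.size() < need) {
    M.resize(need); X.resize(need); Y.resize(need);
    tM.resize(need); tX.resize(need); tY.resize(need);
  }
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  // local alignments start inside cells (prev = 0 below), never from the
  // borders, so every initialized cell starts as unreachable
  {
    int jlo0 = std::max(0, 1 + center - band - 1);
    int jhi0 = std::min(m, 1 + center + band);
    for (int j = jlo0; j <= jhi0; ++j) {
      M[at(0, j)] = NEG; X[at(0, j)] = NEG; Y[at(0, j)] = NEG;
    }
  }

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i + center - band);
    int jhi = std::min(m, i + center + band);
    if (jlo > jhi) continue;
    // seal the window edges of this row for the rows below
    M[at(i, jlo - 1)] = NEG; X[at(i, jlo - 1)] = NEG; Y[at(i, jlo - 1)] = NEG;
    if (jhi < m) {
      M[at(i, jhi + 1)] = NEG; X[at(i, jhi + 1)] = NEG; Y[at(i, jhi + 1)] = NEG;
    }
    for (int j = jlo; j <= jhi; ++j) {
      // gap states
      int x1 = (M[at(i - 1, j)] > NEG) ? M[at(i - 1, j)] - gopen : NEG;
      int x2 = (X[at(i - 1, j)] > NEG) ? X[at(i - 1, j)] - gap_extend : NEG;
      if (x1 >= x2) { X[at(i, j)] = x1; tX[at(i, j)] = 1; }
      else          { X[at(i, j)] = x2; tX[at(i, j)] = 2; }

      int y1 = (M[at(i, j - 1)] > NEG) ? M[at(i, j - 1)] - gopen : NEG;
      int y2 = (Y[at(i, j - 1)] > NEG) ? Y[at(i, j - 1)] - gap_extend : NEG;
      if (y1 >= y2) { Y[at(i, j)] = y1; tY[at(i, j)] = 1; }
      else          { Y[at(i, j)] = y2; tY[at(i, j)] = 2; }

      int s = (read[i - 1] == seg[j - 1]) ? match : mismatch;
      int dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)],
          dY = Y[at(i - 1, j - 1)];
      // strict > keeps zero-scoring prefixes out of the local alignment
      int prev = 0; signed char tb = 0;          // 0: local start
      if (dM > NEG && dM > prev) { prev = dM; tb = 1; }
      if (dX > NEG && dX > prev) { prev = dX; tb = 2; }
      if (dY > NEG && dY > prev) { prev = dY; tb = 3; }
      int v = prev + s;
      if (v < 0) { v = 0; tb = 0; }
      M[at(i, j)] = v; tM[at(i, j)] = tb;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }

  out.score = best;
  if (best <= 0) return out;
  out.valid = true;
  if (!do_traceback) {
    // end coordinates still reported so aligned-length tie-breaks work
    out.r_end = bi; out.g_end = bj;
    return out;
  }

  // traceback from the best M cell
  std::string ops;
  int i = bi, j = bj, state = 0;  // 0 = M
  while (true) {
    if (state == 0) {
      signed char tb = tM[at(i, j)];
      bool mm = read[i - 1] != seg[j - 1];
      ops.push_back(mm ? 'X' : '=');
      if (mm) { out.sub_read.push_back(i - 1); out.sub_g.push_back(j - 1); }
      --i; --j;
      if (tb == 0) break;
      state = (tb == 1) ? 0 : (tb == 2 ? 1 : 2);
    } else if (state == 1) {   // X: read insertion
      signed char tb = tX[at(i, j)];
      ops.push_back('I');
      --i;
      state = (tb == 1) ? 0 : 1;
    } else {                   // Y: germline deletion
      signed char tb = tY[at(i, j)];
      ops.push_back('D');
      --j;
      state = (tb == 1) ? 0 : 2;
    }
  }
  out.r_start = i; out.r_end = bi;
  out.g_start = j; out.g_end = bj;
  std::reverse(ops.begin(), ops.end());
  std::reverse(out.sub_read.begin(), out.sub_read.end());
  std::reverse(out.sub_g.begin(), out.sub_g.end());
  out.has_indel = ops.find('I') != std::string::npos ||
                  ops.find('D') != std::string::npos;

  // run-length encode the op string
  std::string cig;
  size_t p = 0;
  while (p < ops.size()) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cig += std::to_string(q - p); cig.push_back(ops[p]);
    p = q;
  }
  out.cigar = cig;
  return out;
}

// seed-then-band driver: band around the best shared-k-mer diagonal, full
// dynamic programming when banding is disabled or no seed exists
static Aln gotoh_local(const std::string& read, const std::string& seg,
                       int match, int mismatch, int gap_open, int gap_extend,
                       int band_width, int seed_k,
                       bool do_traceback = true) {
  int n = (int)read.size(), m = (int)seg.size();
  int center = 0, band = n + m;  // effectively unbanded
  if (band_width > 0) {
    int c;
    if (seed_diagonal(read, seg, seed_k, c)) { center = c; band = band_width; }
  }
  return gotoh_core(read, seg, match, mismatch, gap_open, gap_extend,
                    center, band, do_traceback);
}

// upper bound on the local-alignment score of a pair sharing no k-mer:
// every k aligned columns contain at least one mismatch (gaps only lower
// the score further under this scheme)
static int seedless_score_bound(int n, int m, int k, int match, int mismatch) {
  int L = std::min(n, m);
  int forced = L / k;
  return match * (L - forced) + mismatch * forced;
}

// does the alignment contain an indel op touching germline window [lo, hi)?
// (indel columns outside the window are junction-side alignment artifacts,
// not segment indels)
static bool indel_in_window(const Aln& a, int lo, int hi) {
  if (!a.valid || !a.has_indel) return false;
  int j = a.g_start;
  size_t p = 0;
  while (p < a.cigar.size()) {
    size_t q = p;
    while (q < a.cigar.size() && isdigit(a.cigar[q])) ++q;
    int len = std::stoi(a.cigar.substr(p, q - p));
    char op = a.cigar[q];
    if (op == '=' || op == 'X') {
      j += len;
    } else if (op == 'I') {
      if (j >= lo && j < hi) return true;  // insertion sits before germline j
    } else {  // D consumes germline [j, j+len)
      if (j < hi && j + len > lo) return true;
      j += len;
    }
    p = q + 1;
  }
  return false;
}

// map a germline position to the read position aligned to it; -1 if the
// position is outside the aligned span or falls in a deletion
static int map_germline_pos(const Aln& a, int g_pos) {
  if (!a.valid || g_pos < a.g_start || g_pos >= a.g_end) return -1;
  int i = a.r_start, j = a.g_start;
  size_t p = 0;
  while (p < a.cigar.size()) {
    size_t q = p;
    while (q < a.cigar.size() && isdigit(a.cigar[q])) ++q;
    int len = std::stoi(a.cigar.substr(p, q - p));
    char op = a.cigar[q];
    for (int t = 0; t < len; ++t) {
      if (op == '=' || op == 'X') {
        if (j == g_pos) return i;
        ++i; ++j;
      } else if (op == 'I') {
        ++i;
      } else {  // D
        if (j == g_pos) return -1;
        ++j;
      }
    }
    p = q + 1;
  }
  return -1;
}

static List aln_to_list(const Aln& a) {
  return List::create(
    _["score"] = a.score, _["valid"] = a.valid,
    _["read_start"] = a.r_start, _["read_end"] = a.r_end,
    _["germline_start"] = a.g_start, _["germline_end"] = a.g_end,
    _["cigar"] = a.cigar,
    _["substitution_read_pos"] = IntegerVector(a.sub_read.begin(), a.sub_read.end()),
    _["substitution_germline_pos"] = IntegerVector(a.sub_g.begin(), a.sub_g.end()),
    _["has_indel"] = a.has_indel);
}

// [[Rcpp::export]]
List cpp_align_segment(std::string read, std::string segment,
                       int match, int mismatch, int gap_open, int gap_extend,
                       int band_width, int seed_k) {
  Aln a = gotoh_local(read, segment, match, mismatch, gap_open, gap_extend,
                      band_width, seed_k);
  return aln_to_list(a);
}

// [[Rcpp::export]]
int cpp_map_germline_pos(std::string read, std::string segment,
                         int match, int mismatch, int gap_open, int gap_extend,
                         int band_width, int seed_k, int g_pos) {
  Aln a = gotoh_local(read, segment, match, mismatch, gap_open, gap_extend,
                      band_width, seed_k);
  return map_germline_pos(a, g_pos);
}

// pick the best segment: score, then longer aligned read span, then
// lexicographically smaller name
static int best_segment(const std::string& read,
                        const std::vector<std::string>& seqs,
                        const CharacterVector& names,
                        const std::vector<SegIndex>& idxs,
                        int match, int mismatch, int gap_open, int gap_extend,
                        int band_width, int seed_k, Aln& best_aln) {
  // Score-only sweep: seeded segments first (banded, cheap); seedless
  // segments only get the full matrix when their score bound could still
  // beat the seeded front-runner. Traceback only the (rarely tied) winners.
  int n_seg = (int)seqs.size();
  std::vector<int> scores(n_seg, 0), centers(n_seg, 0), bands(n_seg, 0);
  std::vector<bool> seeded(n_seg, false), scored(n_seg, false);
  std::vector<int64_t> kmers;
  if (band_width > 0) kmers = read_kmers(read, seed_k);
  int top = 0;
  for (int s = 0; s < n_seg; ++s) {
    int c;
    bands[s] = (int)read.size() + (int)seqs[s].size();
    if (band_width > 0 && seed_diagonal_indexed(kmers, idxs[s], c)) {
      seeded[s] = true; centers[s] = c; bands[s] = band_width;
      Aln a = gotoh_core(read, seqs[s], match, mismatch, gap_open, gap_extend,
                         c, band_width, /*do_traceback=*/false);
      if (a.valid) scores[s] = a.score;
      scored[s] = true;
      if (scores[s] > top) top = scores[s];
    }
  }
  for (int s = 0; s < n_seg; ++s) {
    if (scored[s]) continue;
    int bound = seedless_score_bound((int)read.size(), (int)seqs[s].size(),
                                     seed_k, match, mismatch);
    if (bound <= top && top > 0) continue;  // cannot become the best call
    Aln a = gotoh_core(read, seqs[s], match, mismatch, gap_open, gap_extend,
                       0, bands[s], /*do_traceback=*/false);
    if (a.valid) scores[s] = a.score;
    scored[s] = true;
    if (scores[s] > top) top = scores[s];
  }
  if (top <= 0) return -1;

  int best_idx = -1;
  for (int s = 0; s < n_seg; ++s) {
    if (!scored[s] || scores[s] != top) continue;
    Aln a = gotoh_core(read, seqs[s], match, mismatch, gap_open, gap_extend,
                       seeded[s] ? centers[s] : 0, bands[s],
                       /*do_traceback=*/true);
    bool take = false;
    if (best_idx < 0) take = true;
    else {
      int la = a.r_end - a.r_start, lb = best_aln.r_end - best_aln.r_start;
      if (la != lb) take = la > lb;
      else take = std::string(names[s]) < std::string(names[best_idx]);
    }
    if (take) { best_aln = a; best_idx = s; }
  }
  return best_idx;
}

// fail codes: 0 none, 1 no_v, 2 no_j, 3 anchor_unmapped, 4 unproductive_cdr3
// (finalised in R), 5 short_read, 6 indel
// [[Rcpp::export]]
List cpp_annotate_batch(CharacterVector reads,
                        CharacterVector v_names, CharacterVector v_seqs,
                        IntegerVector v_anchors,
                        CharacterVector j_names, CharacterVector j_seqs,
                        IntegerVector j_anchors,
                        int match, int mismatch, int gap_open, int gap_extend,
                        int band_width, int seed_k,
                        int min_overlap, int v_min_len, int j_min_len) {
  int n = reads.size();
  std::vector<std::string> vs(v_seqs.size()), js(j_seqs.size());
  for (int i = 0; i < v_seqs.size(); ++i) vs[i] = as<std::string>(v_seqs[i]);
  for (int i = 0; i < j_seqs.size(); ++i) js[i] = as<std::string>(j_seqs[i]);

  std::vector<SegIndex> v_idx, j_idx;
  for (const auto& s : vs) v_idx.push_back(build_seg_index(s, seed_k));
  for (const auto& s : js) j_idx.push_back(build_seg_index(s, seed_k));

  CharacterVector v_call(n, NA_STRING), j_call(n, NA_STRING);
  IntegerVector v_score(n, NA_INTEGER), j_score(n, NA_INTEGER);
  IntegerVector v_sub(n, NA_INTEGER), v_alen(n, NA_INTEGER);
  IntegerVector cdr3_start(n, NA_INTEGER), cdr3_end(n, NA_INTEGER);
  IntegerVector vdj_start(n, NA_INTEGER), vdj_end(n, NA_INTEGER);
  IntegerVector fail(n, 0);

  for (int r = 0; r < n; ++r) {
    std::string read = as<std::string>(reads[r]);
    if ((int)read.size() < min_overlap) { fail[r] = 5; continue; }

    Aln va;
    int vi = best_segment(read, vs, v_names, v_idx, match, mismatch, gap_open,
                          gap_extend, band_width, seed_k, va);
    if (vi < 0 || va.g_end - va.g_start < v_min_len) { fail[r] = 1; continue; }
    v_call[r] = v_names[vi];
    v_score[r] = va.score;
    // substitutions within the V span up to the end of the anchor codon:
    // junction columns beyond the anchor belong to the CDR3, not the V count
    int cut = v_anchors[vi] + 3;
    int nsub = 0;
    for (int p : va.sub_g) if (p < cut) ++nsub;
    v_sub[r] = nsub;
    int win_end = std::min(va.g_end, cut);
    v_alen[r] = std::max(0, win_end - va.g_start);
    vdj_start[r] = va.r_start;

    Aln ja;
    int ji = best_segment(read, js, j_names, j_idx, match, mismatch, gap_open,
                          gap_extend, band_width, seed_k, ja);
    if (ji < 0 || ja.g_end - ja.g_start < j_min_len) { fail[r] = 2; continue; }
    j_call[r] = j_names[ji];
    j_score[r] = ja.score;
    vdj_end[r] = ja.r_end;

    if (indel_in_window(va, 0, v_anchors[vi] + 3) ||
        indel_in_window(ja, j_anchors[ji], (int)js[ji].size())) {
      fail[r] = 6; continue;
    }

    int rv = map_germline_pos(va, v_anchors[vi]);
    int rj = map_germline_pos(ja, j_anchors[ji]);
    if (rv < 0 || rj < 0 || rv + 3 > (int)read.size() ||
        rj + 3 > (int)read.size()) { fail[r] = 3; continue; }
    if (rj + 3 <= rv) { fail[r] = 4; continue; }
    cdr3_start[r] = rv;
    cdr3_end[r] = rj + 3;
  }

  return List::create(
    _["v_call"] = v_call, _["j_call"] = j_call,
    _["v_score"] = v_score, _["j_score"] = j_score,
    _["v_mutation_count"] = v_sub, _["v_aligned_length"] = v_alen,
    _["cdr3_start"] = cdr3_start, _["cdr3_end"] = cdr3_end,
    _["vdj_start"] = vdj_start, _["vdj_end"] = vdj_end,
    _["fail_code"] = fail);
}
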