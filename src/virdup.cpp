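#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// 2-bit base encoding; anything but ACGT breaks a k-mer.
static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

struct IndexHolder {
  KmerIndex idx;
  int k;
  int len;
};

static void finalize_index(IndexHolder* p) { delete p; }

// Build a hash index of all exact k-mers of `seq` (positions 1-based).
// k must be <= 31 so a k-mer fits in 62 bits.
// [[Rcpp::export]]
SEXP kmer_index_cpp(std::string seq, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  IndexHolder* h = new IndexHolder();
  h->k = k;
  h->len = (int)seq.size();
  const uint64_t mask = (k == 31) ? ~0ULL >> 2 : ((1ULL << (2 * k)) - 1);
  uint64_t key = 0;
  int run = 0;  // valid bases accumulated
  for (int i = 0; i < (int)seq.size(); ++i) {
    int b = base2bit(seq[i]);
    if (b < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (++run >= k) h->idx[key].push_back(i - k + 2);  // 1-based start
  }
  XPtr<IndexHolder> ptr(h, true);
  return ptr;
}

// All (read_pos, ref_pos) anchor pairs of exact k-mer matches of `read`
// against an indexed reference, skipping reference k-mers occurring more
// than max_hits times. 1-based coordinates.
// [[Rcpp::export]]
IntegerMatrix kmer_anchors_cpp(SEXP index, std::string read, int max_hits) {
  XPtr<IndexHolder> ptr(index);
  const int k = ptr->k;
  const uint64_t mask = (k == 31) ? ~0ULL >> 2 : ((1ULL << (2 * k)) - 1);
  std::vector<int> rp, fp;
  uint64_t key = 0;
  int run = 0;
  for (int i = 0; i < (int)read.size(); ++i) {
    int b = base2bit(read[i]);
    if (b < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (++run < k) continue;
    KmerIndex::const_iterator it = ptr->idx.find(key);
    if (it == ptr->idx.end()) continue;
    const std::vector<int>& hits = it->second;
    if ((int)hits.size() > max_hits) continue;
    for (size_t j = 0; j < hits.size(); ++j) {
      rp.push_back(i - k + 2);
      fp.push_back(hits[j]);
    }
  }
  IntegerMatrix out((int)rp.size(), 2);
  for (int i = 0; i < (int)rp.size(); ++i) {
    out(i, 0) = rp[i];
    out(i, 1) = fp[i];
  }
  colnames(out) = CharacterVector::create("read_pos", "ref_pos");
  return out;
}

// Greedy partition of anchors (sorted by read_pos, then ref_pos) into
// colinear blocks: an anchor joins the open block whose tail it extends with
// 1 <= d_read <= max_gap, 1 <= d_ref <= max_gap and |diagonal shift| <=
// diag_tol (smallest shift wins). Returns 1-based block id per anchor.
// [[Rcpp::export]]
IntegerVector partition_blocks_cpp(IntegerVector read_pos, IntegerVector ref_pos,
                                   int max_gap, int diag_tol) {
  int n = read_pos.size();
  IntegerVector out(n);
  struct Block { int last_read, last_ref, id; bool open; };
  std::vector<Block> blocks;
  int next_id = 1;
  for (int i = 0; i < n; ++i) {
    int rp = read_pos[i], fp = ref_pos[i];
    int best = -1, best_dd = diag_tol + 1;
    for (int b = 0; b < (int)blocks.size(); ++b) {
      if (!blocks[b].open) continue;
      if (rp - blocks[b].last_read > max_gap) { blocks[b].open = false; continue; }
      int dread = rp - blocks[b].last_read;
      int dref  = fp - blocks[b].last_ref;
      if (dread < 1 || dref < 1 || dref > max_gap) continue;
      int dd = dread - dref; if (dd < 0) dd = -dd;
      if (dd < best_dd) { best_dd = dd; best = b; }
    }
    if (best >= 0) {
      blocks[best].last_read = rp;
      blocks[best].last_ref = fp;
      out[i] = blocks[best].id;
    } else {
      Block nb; nb.last_read = rp; nb.last_ref = fp; nb.id = next_id++; nb.open = true;
      blocks.push_back(nb);
      out[i] = nb.id;
    }
  }
  return out;
}

// Banded global (Needleman-Wunsch) alignment of a against b with linear gap
// penalty. The band is centred on the (0,0)-(la,lb) diagonal; callers must
// pass band >= |la - lb| plus slack. Returns the score, match/gap column
// counts and the per-column coordinates (0 where a row/column is gapped).
// [[Rcpp::export]]
List band_align_cpp(std::string a, std::string b, int band,
                    int match, int mismatch, int gap) {
  const int la = (int)a.size(), lb = (int)b.size();
  const long NEG = -1000000000L;
  if (band < std::abs(la - lb)) band = std::abs(la - lb);
  const int W = 2 * band + 1;

  std::vector<long> prev((size_t)W, NEG), cur((size_t)W, NEG);
  std::vector<signed char> tb((size_t)(la + 1) * W, 0);  // 1 diag, 2 up(a), 3 left(b)

  // centre column for row i
  #define CENTER(i) ((la == 0) ? 0 : (int)(((long long)(i) * lb) / la))

  int c0 = CENTER(0);
  for (int j = std::max(0, c0 - band); j <= std::min(lb, c0 + band); ++j) {
    prev[(size_t)(j - c0 + band)] = (long)j * gap;
    if (j > 0) tb[(size_t)(j - c0 + band)] = 3;
  }
  for (int i = 1; i <= la; ++i) {
    int ci = CENTER(i), cp = CENTER(i - 1);
    int lo = std::max(0, ci - band), hi = std::min(lb, ci + band);
    std::fill(cur.begin(), cur.end(), NEG);
    for (int j = lo; j <= hi; ++j) {
      long best = NEG; signed char dir = 0;
      // diagonal from (i-1, j-1)
      if (j >= 1) {
        int off = j - 1 - cp + band;
        if (off >= 0 && off < W && prev[(size_t)off] > NEG) {
          long s = prev[(size_t)off] + ((a[i - 1] == b[j - 1]) ? match : mismatch);
          if (s > best) { best = s; dir = 1; }
        }
      }
      // up from (i-1, j): gap in b
      {
        int off = j - cp + band;
        if (off >= 0 && off < W && prev[(size_t)off] > NEG) {
          long s = prev[(size_t)off] + gap;
          if (s > best) { best = s; dir = 2; }
        }
      }
      // left from (i, j-1): gap in a
      if (j >= 1) {
        int off = j - 1 - ci + band;
        if (off >= 0 && off < W && cur[(size_t)off] > NEG) {
          long s = cur[(size_t)off] + gap;
          if (s > best) { best = s; dir = 3; }
        }
      }
      cur[(size_t)(j - ci + band)] = best;
      tb[(size_t)i * W + (j - ci + band)] = dir;
    }
    std::swap(prev, cur);
  }

  int cl = CENTER(la);
  long score = prev[(size_t)(lb - cl + band)];

  // traceback
  std::vector<int> apos, bpos;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    signed char dir = tb[(size_t)i * W + (j - CENTER(i) + band)];
    if (dir == 1) { apos.push_back(i); bpos.push_back(j); --i; --j; }
    else if (dir == 2) { apos.push_back(i); bpos.push_back(0); --i; }
    else if (dir == 3) { apos.push_back(0); bpos.push_back(j); --j; }
    else break;  // band edge pathology; should not occur with adequate band
  }
  const int ncol = (int)apos.size();
  IntegerVector A(ncol), B(ncol);
  int n_match = 0, n_mm = 0, n_gap = 0;
  for (int c = 0; c < ncol; ++c) {
    int ai = apos[ncol - 1 - c], bj = bpos[ncol - 1 - c];
    A[c] = ai; B[c] = bj;
    if (ai == 0 || bj == 0) ++n_gap;
    else if (a[ai - 1] == b[bj - 1]) ++n_match;
    else ++n_mm;
  }
  #undef CENTER
  return List::create(_["score"] = (double)score,
                      _["n_match"] = n_match,
                      _["n_mismatch"] = n_mm,
                      _["n_gap"] = n_gap,
                      _["n_cols"] = ncol,
                      _["a_pos"] = A,
                      _["b_pos"] = B);
}
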