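#include <Rcpp.h>
using namespace Rcpp;

// Gotoh local alignment of a position-specific score profile against a
// subject sequence, affine gaps costing open + ext * length.
//
// prof: L x 21 integer score matrix (21st column = X, constant -1)
// cons: length-L consensus residue codes (1..21), identity bookkeeping
// subj: subject residue codes (1..21)
//
// Deterministic tie-breaks: cell states prefer diagonal (match) over up
// (gap in subject) over left (gap in profile); the best cell is the
// first strict maximum in row-major scan order, giving the leftmost
// maximal alignment.
//
// [[Rcpp::export]]
List sw_profile_cpp(const IntegerMatrix& prof, const IntegerVector& cons,
                    const IntegerVector& subj, int gap_open, int gap_ext) {
  const int L = prof.nrow();
  const int n = subj.size();
  const int NEG = -1000000000;
  const int open_cost = gap_open + gap_ext;

  // DP rows (previous and current) for M, Ix (up), Iy (left)
  std::vector<int> Mprev(n + 1, 0), Mcur(n + 1, 0);
  std::vector<int> Xprev(n + 1, NEG), Xcur(n + 1, NEG);
  std::vector<int> Yprev(n + 1, NEG), Ycur(n + 1, NEG);

  // traceback: tbM 0=start,1=from M,2=from Ix,3=from Iy (all diagonal)
  //            tbX 1=open(from M above),0=extend; tbY likewise (left)
  std::vector<unsigned char> tbM((size_t)(L + 1) * (n + 1), 0);
  std::vector<unsigned char> tbX((size_t)(L + 1) * (n + 1), 0);
  std::vector<unsigned char> tbY((size_t)(L + 1) * (n + 1), 0);

  int best = 0, bi = 0, bj = 0;

  for (int i = 1; i <= L; ++i) {
    Mcur[0] = 0; Xcur[0] = NEG; Ycur[0] = NEG;
    const size_t row = (size_t)i * (n + 1);
    for (int j = 1; j <= n; ++j) {
      // gap states first (depend on previous row / current row left)
      int x_open = Mprev[j] - open_cost;
      int x_ext  = Xprev[j] - gap_ext;
      if (x_open >= x_ext) { Xcur[j] = x_open; tbX[row + j] = 1; }
      else                 { Xcur[j] = x_ext;  tbX[row + j] = 0; }

      int y_open = Mcur[j - 1] - open_cost;
      int y_ext  = Ycur[j - 1] - gap_ext;
      if (y_open >= y_ext) { Ycur[j] = y_open; tbY[row + j] = 1; }
      else                 { Ycur[j] = y_ext;  tbY[row + j] = 0; }

      // match state: restartable local alignment
      int dm = Mprev[j - 1], dx = Xprev[j - 1], dy = Yprev[j - 1];
      int pre = 0; unsigned char from = 0;
      if (dm >= dx && dm >= dy) { if (dm > 0) { pre = dm; from = 1; } }
      else if (dx >= dy)        { if (dx > 0) { pre = dx; from = 2; } }
      else                      { if (dy > 0) { pre = dy; from = 3; } }
      int s = prof(i - 1, subj[j - 1] - 1);
      Mcur[j] = pre + s;
      tbM[row + j] = from;
      if (Mcur[j] > best) { best = Mcur[j]; bi = i; bj = j; }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  if (best <= 0) {
    return List::create(_["score"] = 0, _["q_pos"] = IntegerVector(0),
                        _["s_pos"] = IntegerVector(0),
                        _["align_len"] = 0, _["nident"] = 0,
                        _["mismatches"] = 0, _["gap_opens"] = 0);
  }

  // traceback from (bi, bj) in state M
  std::vector<int> qp, sp;
  int i = bi, j = bj, state = 1; // 1=M, 2=Ix, 3=Iy
  int align_len = 0, nident = 0, mism = 0, gapopens = 0;
  while (state != 0) {
    const size_t row = (size_t)i * (n + 1);
    if (state == 1) {
      qp.push_back(i); sp.push_back(j);
      ++align_len;
      if (cons[i - 1] == subj[j - 1]) ++nident; else ++mism;
      state = tbM[row + j];
      --i; --j;
      if (state == 0) break;
    } else if (state == 2) {
      ++align_len;
      unsigned char t = tbX[row + j];
      if (t == 1) { ++gapopens; state = 1; } // opened from M
      --i;
    } else {
      ++align_len;
      unsigned char t = tbY[row + j];
      if (t == 1) { ++gapopens; state = 1; }
      --j;
    }
  }
  std::reverse(qp.begin(), qp.end());
  std::reverse(sp.begin(), sp.end());

  return List::create(_["score"] = best,
                      _["q_pos"] = wrap(qp), _["s_pos"] = wrap(sp),
                      _["align_len"] = align_len, _["nident"] = nident,
                      _["mismatches"] = mism, _["gap_opens"] = gapopens);
}

// Score-only batch scan of a profile against many subjects; returns the
// best local score per subject. Used by search_proteome before the
// per-hit traceback pass.
// [[Rcpp::export]]
IntegerVector sw_profile_scores_cpp(const IntegerMatrix& prof,
                                    const List& subjects,
                                    int gap_open, int gap_ext) {
  const int L = prof.nrow();
  const int NEG = -1000000000;
  const int open_cost = gap_open + gap_ext;
  const int nsub = subjects.size();
  IntegerVector out(nsub);

  for (int k = 0; k < nsub; ++k) {
    IntegerVector subj = subjects[k];
    const int n = subj.size();
    std::vector<int> Mprev(n + 1, 0), Mcur(n + 1, 0);
    std::vector<int> Xprev(n + 1, NEG), Xcur(n + 1, NEG);
    std::vector<int> Yprev(n + 1, NEG), Ycur(n + 1, NEG);
    int best = 0;
    for (int i = 1; i <= L; ++i) {
      Mcur[0] = 0; Xcur[0] = NEG; Ycur[0] = NEG;
      for (int j = 1; j <= n; ++j) {
        int x = std::max(Mprev[j] - open_cost, Xprev[j] - gap_ext);
        int y = std::max(Mcur[j - 1] - open_cost, Ycur[j - 1] - gap_ext);
        Xcur[j] = x; Ycur[j] = y;
        int pre = std::max(0, std::max(Mprev[j - 1],
                     std::max(Xprev[j - 1], Yprev[j - 1])));
        Mcur[j] = pre + prof(i - 1, subj[j - 1] - 1);
        if (Mcur[j] > best) best = Mcur[j];
      }
      std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
    }
    out[k] = best;
  }
  return out;
}
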