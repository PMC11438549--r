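#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap Smith-Waterman over a substitution matrix.
//
// Gap cost convention: a gap of length L costs open + L * extend (the first
// gapped position pays open + extend). Local alignment: cell values are
// clamped so any alignment may start anywhere; score 0 means "no alignment".
//
// Alongside the score DP we track, per cell and per state, the number of
// identical aligned residue pairs on a best-scoring path into that cell.
// Ties between equal-score predecessors are broken toward the larger match
// count, so the reported match count is the maximum attainable over all
// optimal local alignments reachable by the DP recurrences.

namespace {

const double NEG_INF = -1e30;

struct AlnResult {
  double score;
  int matches;
};

// Full three-state DP kept in matrices; peptides are short (<= ~50 residues)
// so the O(nm) memory is negligible.
AlnResult sw_align_full(const std::vector<int>& a, const std::vector<int>& b,
                        const NumericMatrix& sub, double open, double ext) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return {0.0, 0};
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  std::vector<int> cM((n + 1) * W, 0), cX((n + 1) * W, 0), cY((n + 1) * W, 0);

  double best = 0.0;
  int best_matches = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int id = i * W + j, di = (i - 1) * W + (j - 1),
                up = (i - 1) * W + j, lf = i * W + (j - 1);
      const double s = sub(a[i - 1], b[j - 1]);
      const int is_match = (a[i - 1] == b[j - 1]) ? 1 : 0;

      double dbest = 0.0;  // fresh start of a local alignment
      int dcnt = 0;
      const double cand[3] = {M[di], X[di], Y[di]};
      const int ccnt[3] = {cM[di], cX[di], cY[di]};
      for (int t = 0; t < 3; ++t)
        if (cand[t] > dbest || (cand[t] == dbest && ccnt[t] > dcnt)) {
          dbest = cand[t]; dcnt = ccnt[t];
        }
      M[id] = dbest + s;
      cM[id] = dcnt + is_match;

      const double xcand[3] = {M[up] - (open + ext), X[up] - ext,
                               Y[up] - (open + ext)};
      const int xcnt[3] = {cM[up], cX[up], cY[up]};
      double xb = NEG_INF; int xc = 0;
      for (int t = 0; t < 3; ++t)
        if (xcand[t] > xb || (xcand[t] == xb && xcnt[t] > xc)) {
          xb = xcand[t]; xc = xcnt[t];
        }
      X[id] = xb; cX[id] = xc;

      const double ycand[3] = {M[lf] - (open + ext), Y[lf] - ext,
                               X[lf] - (open + ext)};
      const int ycnt[3] = {cM[lf], cY[lf], cX[lf]};
      double yb = NEG_INF; int yc = 0;
      for (int t = 0; t < 3; ++t)
        if (ycand[t] > yb || (ycand[t] == yb && ycnt[t] > yc)) {
          yb = ycand[t]; yc = ycnt[t];
        }
      Y[id] = yb; cY[id] = yc;

      if (M[id] > best || (M[id] == best && cM[id] > best_matches)) {
        best = M[id]; best_matches = cM[id];
      }
    }
  }
  if (best <= 0.0) return {0.0, 0};
  return {best, best_matches};
}

std::vector<int> encode_seq(const std::string& s,
                            const std::vector<int>& lut) {
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int code = lut[static_cast<unsigned char>(s[i])];
    if (code < 0) stop("residue '%c' not in the alignment alphabet", s[i]);
    out[i] = code;
  }
  return out;
}

}  // namespace

//' @useDynLib peptideml, .registration = TRUE
//' @importFrom Rcpp sourceCpp

// [[Rcpp::export(name = ".sw_align_pairs")]]
List sw_align_pairs(CharacterVector seq_a, CharacterVector seq_b,
                    NumericMatrix sub, std::string alphabet,
                    double gap_open, double gap_extend) {
  if (seq_a.size() != seq_b.size()) stop("seq_a and seq_b lengths differ");
  if (sub.nrow() != (int)alphabet.size() || sub.ncol() != (int)alphabet.size())
    stop("substitution matrix does not match alphabet size");
  std::vector<int> lut(256, -1);
  for (size_t i = 0; i < alphabet.size(); ++i)
    lut[static_cast<unsigned char>(alphabet[i])] = i;

  const int np = seq_a.size();
  NumericVector score(np), identity(np);
  IntegerVector matches(np);
  for (int p = 0; p < np; ++p) {
    std::string sa = as<std::string>(seq_a[p]);
    std::string sb = as<std::string>(seq_b[p]);
    std::vector<int> ea = encode_seq(sa, lut), eb = encode_seq(sb, lut);
    AlnResult r = sw_align_full(ea, eb, sub, gap_open, gap_extend);
    score[p] = r.score;
    matches[p] = r.matches;
    size_t denom = std::max(sa.size(), sb.size());
    identity[p] = denom == 0 ? 0.0 : (double)r.matches / (double)denom;
  }
  return List::create(_["score"] = score, _["matches"] = matches,
                      _["identity"] = identity);
}
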