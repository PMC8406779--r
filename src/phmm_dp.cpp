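#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Local (Smith-Waterman-style) alignment of a sequence to a nucleotide
// profile HMM, in log-odds space (nats). Entry is free into any match
// column, exit is free from any match column; flanking sequence and the
// empty alignment contribute 0. State layout per column j: M_j, I_j
// (between M_j and M_{j+1}), D_j. Legal moves: M->{M,I,D}, I->{I,M},
// D->{D,M}.
//
// lom: n x 4 match emission log-odds (A,C,G,T); loi: length-4 insert
// emission log-odds; ltm: (n-1) x 3 log transitions out of M_j
// (M->M, M->I, M->D); lti: (n-1) x 2 out of I_j (I->M, I->I);
// ltd: (n-1) x 2 out of D_j (D->M, D->D). seq: 0..3 = A,C,G,T; 4 = N
// (scores 0 everywhere).

static const double NEG = -1e18;

// [[Rcpp::export]]
List phmm_viterbi_cpp(NumericMatrix lom, NumericVector loi,
                      NumericMatrix ltm, NumericMatrix lti,
                      NumericMatrix ltd, IntegerVector seq) {
  int n = lom.nrow();
  int L = seq.size();
  NumericMatrix VM(L + 1, n + 1), VI(L + 1, n + 1), VD(L + 1, n + 1);
  IntegerMatrix PM(L + 1, n + 1), PI(L + 1, n + 1), PD(L + 1, n + 1);
  std::fill(VM.begin(), VM.end(), NEG);
  std::fill(VI.begin(), VI.end(), NEG);
  std::fill(VD.begin(), VD.end(), NEG);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= L; i++) {
    int x = seq[i - 1];
    for (int j = 1; j <= n; j++) {
      double em = (x < 4) ? lom(j - 1, x) : 0.0;
      // match: free entry (0) or continuation from column j-1
      double s = 0.0;
      int p = 0;
      if (j > 1 && i > 1) {
        double c = VM(i - 1, j - 1) + ltm(j - 2, 0);
        if (c > s) { s = c; p = 1; }
        c = VI(i - 1, j - 1) + lti(j - 2, 0);
        if (c > s) { s = c; p = 2; }
        c = VD(i - 1, j - 1) + ltd(j - 2, 0);
        if (c > s) { s = c; p = 3; }
      }
      VM(i, j) = em + s;
      PM(i, j) = p;
      // insert I_j exists only between columns (j < n)
      if (j < n && i > 1) {
        double ei = (x < 4) ? loi[x] : 0.0;
        double cM = VM(i - 1, j) + ltm(j - 1, 1);
        double cI = VI(i - 1, j) + lti(j - 1, 1);
        if (cM >= cI) { VI(i, j) = ei + cM; PI(i, j) = 1; }
        else          { VI(i, j) = ei + cI; PI(i, j) = 2; }
      }
      // delete: consumes no residue, advances along j within row i
      if (j > 1) {
        double cM = VM(i, j - 1) + ltm(j - 2, 2);
        double cD = VD(i, j - 1) + ltd(j - 2, 1);
        if (cM >= cD) { VD(i, j) = cM; PD(i, j) = 1; }
        else          { VD(i, j) = cD; PD(i, j) = 3; }
      }
      if (VM(i, j) > best) { best = VM(i, j); bi = i; bj = j; }
    }
  }

  if (bi == 0) {
    return List::create(_["score"] = 0.0, _["seq_start"] = NA_INTEGER,
                        _["seq_end"] = NA_INTEGER,
                        _["model_start"] = NA_INTEGER,
                        _["model_end"] = NA_INTEGER,
                        _["path"] = "", _["col_of_pos"] = IntegerVector(0));
  }

  // traceback from (bi, bj) in state M
  std::string path;
  std::vector<int> cols;  // model column per consumed residue (0 = insert)
  int i = bi, j = bj, st = 0;  // st: 0=M, 1=I, 2=D
  int si = bi, sj = bj;
  for (;;) {
    if (st == 0) {
      path.push_back('M');
      cols.push_back(j);
      si = i; sj = j;
      int p = PM(i, j);
      if (p == 0) break;
      st = (p == 1) ? 0 : (p == 2) ? 1 : 2;
      i--; j--;
    } else if (st == 1) {
      path.push_back('I');
      cols.push_back(0);
      st = (PI(i, j) == 1) ? 0 : 1;
      i--;
    } else {
      path.push_back('D');
      st = (PD(i, j) == 1) ? 0 : 2;
      j--;
    }
  }
  std::reverse(path.begin(), path.end());
  std::reverse(cols.begin(), cols.end());
  return List::create(_["score"] = best, _["seq_start"] = si,
                      _["seq_end"] = bi, _["model_start"] = sj,
                      _["model_end"] = bj, _["path"] = path,
                      _["col_of_pos"] = wrap(cols));
}

static inline double lse2(double a, double b) {
  if (a <= NEG / 2) return b;
  if (b <= NEG / 2) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// Total log-odds over all local paths (same path space as Viterbi),
// including the empty alignment with odds 1.
// [[Rcpp::export]]
double phmm_forward_cpp(NumericMatrix lom, NumericVector loi,
                        NumericMatrix ltm, NumericMatrix lti,
                        NumericMatrix ltd, IntegerVector seq) {
  int n = lom.nrow();
  int L = seq.size();
  NumericMatrix FM(L + 1, n + 1), FI(L + 1, n + 1), FD(L + 1, n + 1);
  std::fill(FM.begin(), FM.end(), NEG);
  std::fill(FI.begin(), FI.end(), NEG);
  std::fill(FD.begin(), FD.end(), NEG);

  double mx = 0.0;  // running max of terminal scores (empty path = 0)
  for (int i = 1; i <= L; i++) {
    int x = seq[i - 1];
    for (int j = 1; j <= n; j++) {
      double em = (x < 4) ? lom(j - 1, x) : 0.0;
      double s = 0.0;  // free entry, odds 1
      if (j > 1 && i > 1) {
        s = lse2(s, FM(i - 1, j - 1) + ltm(j - 2, 0));
        s = lse2(s, FI(i - 1, j - 1) + lti(j - 2, 0));
        s = lse2(s, FD(i - 1, j - 1) + ltd(j - 2, 0));
      }
      FM(i, j) = em + s;
      if (j < n && i > 1) {
        double ei = (x < 4) ? loi[x] : 0.0;
        FI(i, j) = ei + lse2(FM(i - 1, j) + ltm(j - 1, 1),
                             FI(i - 1, j) + lti(j - 1, 1));
      }
      if (j > 1) {
        FD(i, j) = lse2(FM(i, j - 1) + ltm(j - 2, 2),
                        FD(i, j - 1) + ltd(j - 2, 1));
      }
      if (FM(i, j) > mx) mx = FM(i, j);
    }
  }
  // logsumexp over the empty path (0) and exit from every M cell
  double tot = std::exp(0.0 - mx);
  for (int i = 1; i <= L; i++)
    for (int j = 1; j <= n; j++)
      if (FM(i, j) > NEG / 2) tot += std::exp(FM(i, j) - mx);
  return mx + std::log(tot);
}
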