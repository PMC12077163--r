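#include <Rcpp.h>
using namespace Rcpp;

// Global-in-profile, global-in-sequence affine-gap alignment of one
// sequence against a position-specific log-odds profile (bits).
//
// States: M consumes one residue and one column; D consumes a column
// (deletion); I consumes a residue (insertion). A gap of length k costs
// gap_open + (k - 1) * gap_extend; insert and delete share one penalty
// set. Insert emissions and unknown residues (code < 0, i.e. X) score 0.
// Ties are broken deterministically with preference M > D > I.
//
// seq: 0-based residue codes into the profile's row order; -1 for X.
// [[Rcpp::export(name = ".align_dp")]]
List align_dp(NumericMatrix logodds, IntegerVector seq,
              double gap_open, double gap_extend) {
  const int M = logodds.ncol();
  const int n = seq.size();
  const double NEG = -std::numeric_limits<double>::infinity();

  // (n+1) x (M+1) per state, row-major index i * (M + 1) + j
  std::vector<double> Sm((n + 1) * (M + 1), NEG);
  std::vector<double> Sd((n + 1) * (M + 1), NEG);
  std::vector<double> Si((n + 1) * (M + 1), NEG);
  std::vector<char> Pm((n + 1) * (M + 1), 0);
  std::vector<char> Pd((n + 1) * (M + 1), 0);
  std::vector<char> Pi((n + 1) * (M + 1), 0);
  auto at = [M](int i, int j) { return i * (M + 1) + j; };

  for (int j = 1; j <= M; ++j) {
    Sd[at(0, j)] = -gap_open - (j - 1) * gap_extend;
    Pd[at(0, j)] = (j == 1) ? 'S' : 'D';
  }
  for (int i = 1; i <= n; ++i) {
    Si[at(i, 0)] = -gap_open - (i - 1) * gap_extend;
    Pi[at(i, 0)] = (i == 1) ? 'S' : 'I';
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= M; ++j) {
      const int code = seq[i - 1];
      const double emit = (code < 0) ? 0.0 : logodds(code, j - 1);
      // match: predecessor at (i-1, j-1), preference M > D > I, start ok
      {
        double prev;
        char p;
        if (i == 1 && j == 1) {
          prev = 0.0;
          p = 'S';
        } else {
          prev = Sm[at(i - 1, j - 1)];
          p = 'M';
          if (Sd[at(i - 1, j - 1)] > prev) {
            prev = Sd[at(i - 1, j - 1)];
            p = 'D';
          }
          if (Si[at(i - 1, j - 1)] > prev) {
            prev = Si[at(i - 1, j - 1)];
            p = 'I';
          }
        }
        if (prev > NEG) {
          Sm[at(i, j)] = prev + emit;
          Pm[at(i, j)] = p;
        }
      }
      // delete: from (i, j-1)
      {
        double best = Sm[at(i, j - 1)] - gap_open;
        char p = 'M';
        if (Sd[at(i, j - 1)] - gap_extend > best) {
          best = Sd[at(i, j - 1)] - gap_extend;
          p = 'D';
        }
        if (Si[at(i, j - 1)] - gap_open > best) {
          best = Si[at(i, j - 1)] - gap_open;
          p = 'I';
        }
        if (best > NEG) {
          Sd[at(i, j)] = best;
          Pd[at(i, j)] = p;
        }
      }
      // insert: from (i-1, j)
      {
        double best = Sm[at(i - 1, j)] - gap_open;
        char p = 'M';
        if (Sd[at(i - 1, j)] - gap_open > best) {
          best = Sd[at(i - 1, j)] - gap_open;
          p = 'D';
        }
        if (Si[at(i - 1, j)] - gap_extend > best) {
          best = Si[at(i - 1, j)] - gap_extend;
          p = 'I';
        }
        if (best > NEG) {
          Si[at(i, j)] = best;
          Pi[at(i, j)] = p;
        }
      }
    }
  }

  double score = Sm[at(n, M)];
  char state = 'M';
  if (Sd[at(n, M)] > score) {
    score = Sd[at(n, M)];
    state = 'D';
  }
  if (Si[at(n, M)] > score) {
    score = Si[at(n, M)];
    state = 'I';
  }

  // traceback
  std::string rev;
  int i = n, j = M;
  while (!(i == 0 && j == 0)) {
    rev.push_back(state);
    char prev;
    if (state == 'M') {
      prev = Pm[at(i, j)];
      --i;
      --j;
    } else if (state == 'D') {
      prev = Pd[at(i, j)];
      --j;
    } else {
      prev = Pi[at(i, j)];
      --i;
    }
    if (prev == 'S') break;
    state = prev;
  }
  std::string states(rev.rbegin(), rev.rend());
  return List::create(_["score"] = score, _["states"] = states);
}
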