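// Affine-gap pairwise alignment (Gotoh) with a global pattern and a local
// subject: leading and trailing unaligned subject is free, the whole
// pattern must align. Mirrors the "global-local" mode used for indel
// recovery in primer-anchored amplicon reads: match +1, mismatch -2, gap
// of length L costs open + L * ext.
//
// Problem sizes are tiny (reads ~100 bases against windows ~150 bases),
// but thousands of reads per library make an R-level implementation the
// pipeline bottleneck; this is the one hot loop the package compiles.

#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

static const double NEG = -1e18;

// [[Rcpp::export]]
List gotoh_global_local(CharacterVector patterns, std::string subject,
                        double match = 1.0, double mismatch = -2.0,
                        double gap_open = 5.0, double gap_ext = 0.5) {
  const int n = subject.size();
  const int np = patterns.size();
  CharacterVector pat_g(np), sub_g(np);
  IntegerVector sub_start(np);
  NumericVector score_out(np);

  const double first_gap = gap_open + gap_ext;

  for (int q = 0; q < np; ++q) {
    std::string pat = as<std::string>(patterns[q]);
    const int m = pat.size();

    // H = best, X = gap in subject (pattern char vs '-'),
    // Y = gap in pattern ('-' vs subject char)
    std::vector<double> Hp(n + 1), Xp(n + 1), Yp(n + 1);
    std::vector<double> Hc(n + 1), Xc(n + 1), Yc(n + 1);
    // traceback: 0 diag, 1 up (X), 2 left (Y); per matrix whether the
    // previous state continued the gap
    std::vector<unsigned char> tbH((m + 1) * (n + 1));
    std::vector<unsigned char> tbX((m + 1) * (n + 1));
    std::vector<unsigned char> tbY((m + 1) * (n + 1));

    for (int j = 0; j <= n; ++j) { Hp[j] = 0.0; Xp[j] = NEG; Yp[j] = NEG; }

    for (int i = 1; i <= m; ++i) {
      Hc[0] = -(gap_open + gap_ext * i);      // pattern prefix vs nothing
      Xc[0] = Hc[0];
      Yc[0] = NEG;
      for (int j = 1; j <= n; ++j) {
        const double s = (pat[i - 1] == subject[j - 1]) ? match : mismatch;
        const double dM = Hp[j - 1] + s;

        const double x_open = Hp[j] - first_gap;
        const double x_ext = Xp[j] - gap_ext;
        if (x_open >= x_ext) { Xc[j] = x_open; tbX[i * (n + 1) + j] = 0; }
        else { Xc[j] = x_ext; tbX[i * (n + 1) + j] = 1; }

        const double y_open = Hc[j - 1] - first_gap;
        const double y_ext = Yc[j - 1] - gap_ext;
        if (y_open >= y_ext) { Yc[j] = y_open; tbY[i * (n + 1) + j] = 0; }
        else { Yc[j] = y_ext; tbY[i * (n + 1) + j] = 1; }

        double best = dM; unsigned char move = 0;
        if (Xc[j] > best) { best = Xc[j]; move = 1; }
        if (Yc[j] > best) { best = Yc[j]; move = 2; }
        Hc[j] = best; tbH[i * (n + 1) + j] = move;
      }
      std::swap(Hp, Hc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    }

    // free trailing subject: best over the last pattern row
    int jbest = 0; double best = NEG;
    for (int j = 0; j <= n; ++j)
      if (Hp[j] > best) { best = Hp[j]; jbest = j; }

    // second pass to rebuild traceback (row-wise storage already kept)
    // walk back from (m, jbest)
    std::string ap, as_;
    int i = m, j = jbest;
    int state = 0; // 0 = H, 1 = X, 2 = Y
    while (i > 0) {
      if (state == 0) {
        unsigned char mv = tbH[i * (n + 1) + j];
        if (mv == 0) {
          if (j == 0) { // came from pattern-vs-nothing prefix
            ap.push_back(pat[i - 1]); as_.push_back('-'); --i; continue;
          }
          ap.push_back(pat[i - 1]); as_.push_back(subject[j - 1]);
          --i; --j;
        } else state = mv;
      } else if (state == 1) {
        unsigned char cont = tbX[i * (n + 1) + j];
        ap.push_back(pat[i - 1]); as_.push_back('-');
        --i;
        state = cont ? 1 : 0;
      } else {
        unsigned char cont = tbY[i * (n + 1) + j];
        ap.push_back('-'); as_.push_back(subject[j - 1]);
        --j;
        state = cont ? 2 : 0;
      }
    }
    std::reverse(ap.begin(), ap.end());
    std::reverse(as_.begin(), as_.end());
    pat_g[q] = ap; sub_g[q] = as_;
    sub_start[q] = j + 1;   // 1-based subject position where alignment begins
    score_out[q] = best;
  }
  return List::create(_["pattern"] = pat_g, _["subject"] = sub_g,
                      _["subject_start"] = sub_start, _["score"] = score_out);
}
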