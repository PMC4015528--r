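#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Alignment alphabet: A,C,G,T compare literally. 'N' on either side never
// matches, and the read-side placeholder '?' (the collapsed allele site)
// never matches, so every placement that covers the placeholder pays at
// least one mismatch.
static inline bool is_wild(char c) { return c == 'N' || c == '?'; }
static inline bool base_mismatch(char rd, char rf) {
  return is_wild(rd) || is_wild(rf) || rd != rf;
}

static std::string runlen_cigar(const std::vector<char>& ops) {
  std::string out;
  size_t i = 0;
  while (i < ops.size()) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    out += std::to_string(j - i);
    out += ops[i];
    i = j;
  }
  return out;
}

// Hamming mismatch counts of `read` placed at each 1-based `start` in `ref`.
// Counting stops at cap+1 (callers only need to know a placement exceeded
// the budget). Out-of-range starts give NA.
// [[Rcpp::export]]
IntegerVector C_mismatch_counts(std::string ref, std::string read,
                                IntegerVector starts, int cap) {
  const int m = (int)read.size();
  const int L = (int)ref.size();
  IntegerVector out(starts.size());
  for (R_xlen_t s = 0; s < starts.size(); ++s) {
    int st = starts[s] - 1;
    if (st < 0 || st + m > L) { out[s] = NA_INTEGER; continue; }
    int mm = 0;
    for (int j = 0; j < m; ++j) {
      if (base_mismatch(read[j], ref[st + j])) {
        if (++mm > cap) break;
      }
    }
    out[s] = mm;
  }
  return out;
}

// Exhaustive forward-strand Hamming scan: every 1-based start where the
// mismatch count is <= max_mm. Early exit per offset keeps this usable as
// a generation-time brute-force check on megabase references.
// [[Rcpp::export]]
List C_scan_hamming(std::string ref, std::string read, int max_mm) {
  const int m = (int)read.size();
  const int L = (int)ref.size();
  std::vector<int> starts, counts;
  for (int st = 0; st + m <= L; ++st) {
    int mm = 0;
    bool ok = true;
    for (int j = 0; j < m; ++j) {
      if (base_mismatch(read[j], ref[st + j])) {
        if (++mm > max_mm) { ok = false; break; }
      }
    }
    if (ok) { starts.push_back(st + 1); counts.push_back(mm); }
  }
  return List::create(_["start"] = wrap(starts), _["mismatches"] = wrap(counts));
}

// Semi-global unit-cost alignment: the read is aligned end-to-end, the
// reference window has free leading/trailing bases. Returns a minimum
// edit path (mismatch = insertion = deletion = 1) with two tie-break
// layers encoded as epsilon costs (UNIT dominates both): the placeholder
// column is kept on a reference base rather than inside an insertion run
// (its coordinate is undefined there), and gap runs are kept contiguous
// (split gaps are co-optimal under unit costs but scatter indels through
// the CIGAR and can shift the SNP coordinate in repeats). Traceback is
// deterministic: M over D over I, leftmost end column on ties.
// ref_start/ref_end are 1-based within `window`.
// [[Rcpp::export]]
List C_glocal_align(std::string read, std::string window) {
  const int m = (int)read.size();
  const int n = (int)window.size();
  if (m == 0 || n == 0) stop("empty sequence in gapped alignment");
  // epsilon-layered costs: unit edit = 1024, placeholder-as-M rebate 16,
  // gap-open surcharge 1 (run counts and rebates never reach 1024, so
  // the unit-cost optimum is preserved exactly)
  const int UNIT = 1024, SUBQ = 1024 - 16, OPEN = 1024 + 1, EXT = 1024;
  const int INF = INT_MAX / 4;
  std::vector<std::vector<int>> B(m + 1, std::vector<int>(n + 1, 0));
  std::vector<std::vector<int>> Dg(m + 1, std::vector<int>(n + 1, INF));
  std::vector<std::vector<int>> Ig(m + 1, std::vector<int>(n + 1, INF));
  std::vector<std::vector<unsigned char>> tbB(m + 1, std::vector<unsigned char>(n + 1, 0));
  std::vector<std::vector<unsigned char>> tbD(m + 1, std::vector<unsigned char>(n + 1, 0));
  std::vector<std::vector<unsigned char>> tbI(m + 1, std::vector<unsigned char>(n + 1, 0));
  // tbB: 0 start row, 1 diag, 2 via Dg, 3 via Ig; tbD/tbI: 1 open, 2 extend
  for (int i = 1; i <= m; ++i) {
    Ig[i][0] = OPEN + (i - 1) * EXT;
    B[i][0] = Ig[i][0];
    tbB[i][0] = 3;
    tbI[i][0] = (i == 1) ? 1 : 2;
    for (int j = 1; j <= n; ++j) {
      int opn = B[i][j - 1] == INF ? INF : B[i][j - 1] + OPEN;
      int ext = Dg[i][j - 1] == INF ? INF : Dg[i][j - 1] + EXT;
      if (opn <= ext) { Dg[i][j] = opn; tbD[i][j] = 1; }
      else            { Dg[i][j] = ext; tbD[i][j] = 2; }
      opn = B[i - 1][j] == INF ? INF : B[i - 1][j] + OPEN;
      ext = Ig[i - 1][j] == INF ? INF : Ig[i - 1][j] + EXT;
      if (opn <= ext) { Ig[i][j] = opn; tbI[i][j] = 1; }
      else            { Ig[i][j] = ext; tbI[i][j] = 2; }
      int sub = read[i - 1] == '?' ? SUBQ :
                (base_mismatch(read[i - 1], window[j - 1]) ? UNIT : 0);
      int best = B[i - 1][j - 1] + sub;
      unsigned char t = 1;
      if (Dg[i][j] < best) { best = Dg[i][j]; t = 2; }
      if (Ig[i][j] < best) { best = Ig[i][j]; t = 3; }
      B[i][j] = best;
      tbB[i][j] = t;
    }
  }
  int bestj = 0, bestc = B[m][0];
  for (int j = 1; j <= n; ++j)
    if (B[m][j] < bestc) { bestc = B[m][j]; bestj = j; }

  std::vector<char> ops;
  int i = m, j = bestj, state = 0; // 0 = B, 1 = Dg, 2 = Ig
  int nmm = 0, nins = 0, ndel = 0;
  while (i > 0 || state != 0) {
    if (state == 0) {
      unsigned char t = tbB[i][j];
      if (i == 0) break;
      if (t == 1) {
        ops.push_back('M');
        if (read[i - 1] == '?' || base_mismatch(read[i - 1], window[j - 1]))
          ++nmm;
        --i; --j;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      unsigned char t = tbD[i][j];
      ops.push_back('D'); ++ndel;
      --j;
      if (t == 1) state = 0;
    } else {
      unsigned char t = tbI[i][j];
      ops.push_back('I'); ++nins;
      --i;
      if (t == 1) state = 0;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(
    _["cost"] = nmm + nins + ndel, _["mismatches"] = nmm,
    _["insertions"] = nins, _["deletions"] = ndel,
    _["cigar"] = runlen_cigar(ops),
    _["ref_start"] = j + 1, _["ref_end"] = bestj);
}

// Local (Smith-Waterman) alignment with affine gaps under the Gotoh
// recurrence: a length-g gap costs gap_open + gap_extend * (g - 1).
// With gapless = true only diagonal moves are allowed. Traceback is
// deterministic: best cell is the first maximal cell in row-major order;
// within a cell, diagonal is preferred over a reference gap (D) over a
// read gap (I), and gap states prefer closing (opening move) first.
// As in the semi-global aligner, epsilon-layered internal scores break
// ties among co-optimal alignments: scores are scaled by 16, the
// placeholder-as-M column earns an 8-point rebate over a regular
// mismatch (keeping the SNP column on a reference base), and each gap
// opening carries a 1-point surcharge (keeping gap runs contiguous).
// The epsilon layer never outweighs a true score difference; the
// reported score is recomputed on the caller's scheme.
// [[Rcpp::export]]
List C_sw_align(std::string read, std::string window, int match,
                int mismatch_pen, int gap_open, int gap_extend,
                bool gapless) {
  const int m = (int)read.size();
  const int n = (int)window.size();
  if (m == 0 || n == 0) stop("empty sequence in local alignment");
  const int NEG = INT_MIN / 4;
  const int MATCH2 = 16 * match;
  const int MISM2 = 16 * mismatch_pen;
  const int OPEN2 = 16 * gap_open + 1;
  const int EXT2 = 16 * gap_extend;
  std::vector<std::vector<int>> H(m + 1, std::vector<int>(n + 1, 0));
  std::vector<std::vector<int>> Dg(m + 1, std::vector<int>(n + 1, NEG));
  std::vector<std::vector<int>> Ig(m + 1, std::vector<int>(n + 1, NEG));
  // tbH: 0 stop, 1 diag, 2 via Dg, 3 via Ig; tbD/tbI: 1 opened, 2 extended
  std::vector<std::vector<unsigned char>> tbH(m + 1, std::vector<unsigned char>(n + 1, 0));
  std::vector<std::vector<unsigned char>> tbD(m + 1, std::vector<unsigned char>(n + 1, 0));
  std::vector<std::vector<unsigned char>> tbI(m + 1, std::vector<unsigned char>(n + 1, 0));

  int bi = 0, bj = 0, bscore = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      if (!gapless) {
        int opn = H[i][j - 1] - OPEN2;
        int ext = Dg[i][j - 1] - EXT2;
        if (opn >= ext) { Dg[i][j] = opn; tbD[i][j] = 1; }
        else            { Dg[i][j] = ext; tbD[i][j] = 2; }
        opn = H[i - 1][j] - OPEN2;
        ext = Ig[i - 1][j] - EXT2;
        if (opn >= ext) { Ig[i][j] = opn; tbI[i][j] = 1; }
        else            { Ig[i][j] = ext; tbI[i][j] = 2; }
      }
      int s = read[i - 1] == '?' ? -(MISM2 - 8) :
              (base_mismatch(read[i - 1], window[j - 1]) ? -MISM2 : MATCH2);
      int best = 0; unsigned char t = 0;
      int diag = H[i - 1][j - 1] + s;
      if (diag > best) { best = diag; t = 1; }
      if (!gapless) {
        if (Dg[i][j] > best) { best = Dg[i][j]; t = 2; }
        if (Ig[i][j] > best) { best = Ig[i][j]; t = 3; }
      }
      H[i][j] = best; tbH[i][j] = t;
      if (best > bscore) { bscore = best; bi = i; bj = j; }
    }
  }
  if (bscore <= 0) {
    return List::create(_["score"] = 0, _["cigar"] = "",
                        _["read_start"] = 0, _["read_end"] = 0,
                        _["ref_start"] = 0, _["ref_end"] = 0,
                        _["matches"] = 0, _["mismatches"] = 0,
                        _["insertions"] = 0, _["deletions"] = 0);
  }

  std::vector<char> ops;
  int i = bi, j = bj, state = 0; // 0 = H, 1 = Dg, 2 = Ig
  int nmat = 0, nmm = 0, nins = 0, ndel = 0;
  for (;;) {
    if (state == 0) {
      unsigned char t = tbH[i][j];
      if (t == 0) break;
      if (t == 1) {
        ops.push_back('M');
        if (base_mismatch(read[i - 1], window[j - 1])) ++nmm; else ++nmat;
        --i; --j;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      unsigned char t = tbD[i][j];
      ops.push_back('D'); ++ndel;
      --j;
      if (t == 1) state = 0;
    } else {
      unsigned char t = tbI[i][j];
      ops.push_back('I'); ++nins;
      --i;
      if (t == 1) state = 0;
    }
  }
  std::reverse(ops.begin(), ops.end());
  // score on the caller's scheme: each gap run costs open + ext*(len-1)
  int score = match * nmat - mismatch_pen * nmm;
  size_t t = 0;
  while (t < ops.size()) {
    size_t u = t;
    while (u < ops.size() && ops[u] == ops[t]) ++u;
    if (ops[t] == 'D' || ops[t] == 'I')
      score -= gap_open + gap_extend * ((int)(u - t) - 1);
    t = u;
  }
  return List::create(
    _["score"] = score, _["cigar"] = runlen_cigar(ops),
    _["read_start"] = i + 1, _["read_end"] = bi,
    _["ref_start"] = j + 1, _["ref_end"] = bj,
    _["matches"] = nmat, _["mismatches"] = nmm,
    _["insertions"] = nins, _["deletions"] = ndel);
}
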