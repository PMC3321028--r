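// Dynamic-programming kernels: profile-HMM Viterbi, profile-profile
// Needleman-Wunsch, frameshift-aware protein-to-DNA alignment, and the
// e-PCR primer scan. All coordinates returned to R are 1-based inclusive.
#include <Rcpp.h>
#include <array>
#include <cfloat>
using namespace Rcpp;

static const double NEG_INF = -1e30;

// Local (flank-free) Viterbi over a profile HMM.
// emit: M x 20 match log2-odds. trans: M x 7 log2 probabilities with columns
// (MM, MI, MD, IM, II, DM, DD); row j holds transitions out of position j
// (rows 1..M-1 used). seq: integer residues 0..19, -1 for unknown (scores 0).
// entry: log2 entry probability added when a path starts at any match state.
// Paths start and end in a match state; unaligned flanks are free.
// [[Rcpp::export(name = ".cpp_viterbi")]]
List cpp_viterbi(NumericMatrix emit, NumericMatrix trans, IntegerVector seq,
                 double entry) {
  const int M = emit.nrow();
  const int L = seq.size();
  // DP matrices (j = 1..M rows 0..M-1; i = 1..L cols 0..L-1)
  NumericMatrix VM(M, L), VI(M, L), VD(M, L);
  IntegerMatrix PM(M, L), PI(M, L), PD(M, L); // traceback codes
  std::fill(VM.begin(), VM.end(), NEG_INF);
  std::fill(VI.begin(), VI.end(), NEG_INF);
  std::fill(VD.begin(), VD.end(), NEG_INF);

  double best = NEG_INF;
  int bj = -1, bi = -1;
  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < M; ++j) {
      const int a = seq[i];
      const double e = (a >= 0) ? emit(j, a) : 0.0;
      // match state
      double v = entry; int p = 0; // 0 = begin
      if (j > 0 && i > 0) {
        double cand = VM(j - 1, i - 1) + trans(j - 1, 0);
        if (cand > v) { v = cand; p = 1; }
        cand = VI(j - 1, i - 1) + trans(j - 1, 3);
        if (cand > v) { v = cand; p = 2; }
        cand = VD(j - 1, i - 1) + trans(j - 1, 5);
        if (cand > v) { v = cand; p = 3; }
      }
      VM(j, i) = e + v; PM(j, i) = p;
      if (VM(j, i) > best) { best = VM(j, i); bj = j; bi = i; }
      // insert state (emits at background: 0 log-odds)
      if (i > 0) {
        double vi = VM(j, i - 1) + trans(j, 1); int pi_ = 1;
        double cand = VI(j, i - 1) + trans(j, 4);
        if (cand > vi) { vi = cand; pi_ = 2; }
        VI(j, i) = vi; PI(j, i) = pi_;
      }
      // delete state
      if (j > 0) {
        double vd = VM(j - 1, i) + trans(j - 1, 2); int pd = 1;
        double cand = VD(j - 1, i) + trans(j - 1, 6);
        if (cand > vd) { vd = cand; pd = 3; }
        VD(j, i) = vd; PD(j, i) = pd;
      }
    }
  }
  if (bj < 0)
    return List::create(_["score"] = NA_REAL);

  // traceback from (bj, bi) in match state
  std::vector<int> st_type, st_j, st_i;
  int j = bj, i = bi, type = 0; // 0=M,1=I,2=D
  while (true) {
    st_type.push_back(type); st_j.push_back(j + 1);
    st_i.push_back(type == 2 ? NA_INTEGER : i + 1);
    int p;
    if (type == 0) p = PM(j, i);
    else if (type == 1) p = PI(j, i);
    else p = PD(j, i);
    if (type == 0) {
      if (p == 0) break;           // begin
      if (p == 1) { --j; --i; type = 0; }
      else if (p == 2) { --j; --i; type = 1; }
      else { --j; --i; type = 2; }
    } else if (type == 1) {
      if (p == 1) { --i; type = 0; } else { --i; type = 1; }
    } else { // delete
      if (p == 1) { --j; type = 0; } else { --j; type = 2; }
    }
  }
  std::reverse(st_type.begin(), st_type.end());
  std::reverse(st_j.begin(), st_j.end());
  std::reverse(st_i.begin(), st_i.end());
  int nmatch = 0;
  for (size_t k = 0; k < st_type.size(); ++k) if (st_type[k] == 0) ++nmatch;
  return List::create(
    _["score"] = best,
    _["t_start"] = st_i.front(), _["t_end"] = bi + 1,
    _["m_start"] = st_j.front(), _["m_end"] = bj + 1,
    _["n_match"] = nmatch,
    _["path_state"] = IntegerVector(st_type.begin(), st_type.end()),
    _["path_model"] = IntegerVector(st_j.begin(), st_j.end()),
    _["path_seq"] = IntegerVector(st_i.begin(), st_i.end()));
}

// Global profile-profile Needleman-Wunsch with affine gaps (end gaps
// penalized). prof1/prof2: 20 x L frequency matrices. sub: 20x20 score
// matrix. Returns column maps (index into source profile, or NA for gap).
// [[Rcpp::export(name = ".cpp_nw_profile")]]
List cpp_nw_profile(NumericMatrix prof1, NumericMatrix prof2,
                    NumericMatrix sub, double gap_open, double gap_ext) {
  const int L1 = prof1.ncol(), L2 = prof2.ncol();
  // column-column scores
  NumericMatrix cs(L1, L2);
  // prof' * sub * prof: do t(prof1) %*% sub first
  NumericMatrix tmp(L1, 20);
  for (int i = 0; i < L1; ++i)
    for (int b = 0; b < 20; ++b) {
      double s = 0;
      for (int a = 0; a < 20; ++a) s += prof1(a, i) * sub(a, b);
      tmp(i, b) = s;
    }
  for (int i = 0; i < L1; ++i)
    for (int j = 0; j < L2; ++j) {
      double s = 0;
      for (int b = 0; b < 20; ++b) s += tmp(i, b) * prof2(b, j);
      cs(i, j) = s;
    }

  NumericMatrix Mm(L1 + 1, L2 + 1), Xx(L1 + 1, L2 + 1), Yy(L1 + 1, L2 + 1);
  IntegerMatrix PMm(L1 + 1, L2 + 1), PXx(L1 + 1, L2 + 1), PYy(L1 + 1, L2 + 1);
  Mm(0, 0) = 0; Xx(0, 0) = NEG_INF; Yy(0, 0) = NEG_INF;
  for (int i = 1; i <= L1; ++i) {
    Mm(i, 0) = NEG_INF; Yy(i, 0) = NEG_INF;
    Xx(i, 0) = -gap_open - gap_ext * (i - 1); PXx(i, 0) = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= L2; ++j) {
    Mm(0, j) = NEG_INF; Xx(0, j) = NEG_INF;
    Yy(0, j) = -gap_open - gap_ext * (j - 1); PYy(0, j) = (j == 1) ? 1 : 3;
  }
  for (int i = 1; i <= L1; ++i)
    for (int j = 1; j <= L2; ++j) {
      // M: diagonal
      double v = Mm(i - 1, j - 1); int p = 1;
      if (Xx(i - 1, j - 1) > v) { v = Xx(i - 1, j - 1); p = 2; }
      if (Yy(i - 1, j - 1) > v) { v = Yy(i - 1, j - 1); p = 3; }
      Mm(i, j) = v + cs(i - 1, j - 1); PMm(i, j) = p;
      // X: gap in prof2 (consume prof1 column i)
      v = Mm(i - 1, j) - gap_open; p = 1;
      if (Xx(i - 1, j) - gap_ext > v) { v = Xx(i - 1, j) - gap_ext; p = 2; }
      Xx(i, j) = v; PXx(i, j) = p;
      // Y: gap in prof1
      v = Mm(i, j - 1) - gap_open; p = 1;
      if (Yy(i, j - 1) - gap_ext > v) { v = Yy(i, j - 1) - gap_ext; p = 3; }
      Yy(i, j) = v; PYy(i, j) = p;
    }
  double score = Mm(L1, L2); int state = 1;
  if (Xx(L1, L2) > score) { score = Xx(L1, L2); state = 2; }
  if (Yy(L1, L2) > score) { score = Yy(L1, L2); state = 3; }

  std::vector<int> map1, map2;
  int i = L1, j = L2;
  while (i > 0 || j > 0) {
    if (state == 1) {
      int p = PMm(i, j);
      map1.push_back(i); map2.push_back(j); --i; --j; state = p;
    } else if (state == 2) {
      int p = PXx(i, j);
      map1.push_back(i); map2.push_back(NA_INTEGER); --i; state = p;
    } else {
      int p = PYy(i, j);
      map1.push_back(NA_INTEGER); map2.push_back(j); --j; state = p;
    }
  }
  std::reverse(map1.begin(), map1.end());
  std::reverse(map2.begin(), map2.end());
  return List::create(_["score"] = score,
                      _["map1"] = IntegerVector(map1.begin(), map1.end()),
                      _["map2"] = IntegerVector(map2.begin(), map2.end()));
}

// Frameshift-aware local alignment of a reference protein to DNA.
// prot: integer residues 0..19. dna: integer bases 0..3 (A,C,G,T).
// sub: 20x20 protein score matrix. codon_aa: length-64 map from codon index
// (16*b1 + 4*b2 + b3) to amino-acid index 0..19, or -1 for stop.
// Match moves consume one reference residue and 3 (in frame), 2 or 4
// (frameshift, penalty fs) DNA bases; affine gaps consume whole codons or
// whole residues. Stop codons inside the alignment score stop_score and are
// reported as events.
// [[Rcpp::export(name = ".cpp_fs_align")]]
List cpp_fs_align(IntegerVector prot, IntegerVector dna, NumericMatrix sub,
                  IntegerVector codon_aa, double gap_open, double gap_ext,
                  double fs, double stop_score) {
  const int P = prot.size(), D = dna.size();
  NumericMatrix Mm(P + 1, D + 1), GA(P + 1, D + 1), GB(P + 1, D + 1);
  IntegerMatrix PMv(P + 1, D + 1), PGA(P + 1, D + 1), PGB(P + 1, D + 1);
  std::fill(GA.begin(), GA.end(), NEG_INF);
  std::fill(GB.begin(), GB.end(), NEG_INF);
  std::fill(Mm.begin(), Mm.end(), NEG_INF);
  for (int j = 0; j <= D; ++j) Mm(0, j) = NEG_INF;

  // codon score of codon ending at dna position j (1-based), length len
  auto codon_score = [&](int i, int j, int len) -> double {
    // use the last 3 bases when len >= 3, pad concept: for len 2 use the two
    // bases + wildcard averaged? Keep deterministic: for len 2 and 4 the
    // translated codon is taken from the last 3 consumed bases (len 4) or is
    // scored as the reference-vs-unknown floor (len 2).
    if (len == 2) return -1.0; // partial codon: weak neutral score
    int b1 = dna[j - 3], b2 = dna[j - 2], b3 = dna[j - 1];
    int aa = codon_aa[16 * b1 + 4 * b2 + b3];
    if (aa < 0) return stop_score;
    return sub(prot[i - 1], aa);
  };

  double best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= P; ++i) {
    for (int j = 1; j <= D; ++j) {
      // match in frame
      double v = NEG_INF; int p = 0;
      if (j >= 3) {
        double base = 0; int pp = 0; // local start
        if (Mm(i - 1, j - 3) > base) { base = Mm(i - 1, j - 3); pp = 1; }
        if (GA(i - 1, j - 3) > base) { base = GA(i - 1, j - 3); pp = 2; }
        if (GB(i - 1, j - 3) > base) { base = GB(i - 1, j - 3); pp = 3; }
        v = base + codon_score(i, j, 3); p = pp;
      }
      if (j >= 2 && Mm(i - 1, j - 2) - fs + codon_score(i, j, 2) > v) {
        v = Mm(i - 1, j - 2) - fs + codon_score(i, j, 2); p = 4;
      }
      if (j >= 4 && Mm(i - 1, j - 4) - fs + codon_score(i, j, 3) > v) {
        v = Mm(i - 1, j - 4) - fs + codon_score(i, j, 3); p = 5;
      }
      Mm(i, j) = v; PMv(i, j) = p;
      if (v > best) { best = v; bi = i; bj = j; }
      // GA: unmatched dna codon
      if (j >= 3) {
        double va = Mm(i, j - 3) - gap_open; int pa = 1;
        if (GA(i, j - 3) - gap_ext > va) { va = GA(i, j - 3) - gap_ext; pa = 2; }
        GA(i, j) = va; PGA(i, j) = pa;
      }
      // GB: unmatched reference residue
      double vb = Mm(i - 1, j) - gap_open; int pb = 1;
      if (GB(i - 1, j) - gap_ext > vb) { vb = GB(i - 1, j) - gap_ext; pb = 2; }
      GB(i, j) = vb; PGB(i, j) = pb;
    }
  }
  if (bi == 0)
    return List::create(_["score"] = 0.0, _["ref_start"] = NA_INTEGER,
                        _["ref_end"] = NA_INTEGER, _["dna_start"] = NA_INTEGER,
                        _["dna_end"] = NA_INTEGER,
                        _["events"] = IntegerMatrix(0, 3),
                        _["frames"] = IntegerMatrix(0, 3));

  // traceback
  std::vector<int> ev_kind, ev_dna, ev_ref; // kind 1 = frameshift, 2 = stop
  int i = bi, j = bj, state = 1; // 1=M, 2=GA, 3=GB
  int ref_start = bi, dna_start = bj;
  while (i > 0 && j > 0) {
    if (state == 1) {
      int p = PMv(i, j);
      int len = (p == 4) ? 2 : (p == 5) ? 4 : 3;
      if (p == 4 || p == 5) { ev_kind.push_back(1); ev_dna.push_back(j); ev_ref.push_back(i); }
      if (len >= 3) {
        int b1 = dna[j - 3], b2 = dna[j - 2], b3 = dna[j - 1];
        if (codon_aa[16 * b1 + 4 * b2 + b3] < 0) {
          ev_kind.push_back(2); ev_dna.push_back(j); ev_ref.push_back(i);
        }
      }
      ref_start = i; dna_start = j - len + 1;
      if (p == 0) { --i; j -= len; break; }
      if (p == 1 || p == 4 || p == 5) { --i; j -= len; state = 1; }
      else if (p == 2) { --i; j -= len; state = 2; }
      else { --i; j -= len; state = 3; }
    } else if (state == 2) {
      int p = PGA(i, j); j -= 3; state = (p == 1) ? 1 : 2;
    } else {
      int p = PGB(i, j); --i; state = (p == 1) ? 1 : 3;
    }
  }
  std::reverse(ev_kind.begin(), ev_kind.end());
  std::reverse(ev_dna.begin(), ev_dna.end());
  std::reverse(ev_ref.begin(), ev_ref.end());
  IntegerMatrix events(ev_kind.size(), 3);
  for (size_t k = 0; k < ev_kind.size(); ++k) {
    events(k, 0) = ev_kind[k]; events(k, 1) = ev_dna[k]; events(k, 2) = ev_ref[k];
  }
  return List::create(_["score"] = best, _["ref_start"] = ref_start,
                      _["ref_end"] = bi, _["dna_start"] = dna_start,
                      _["dna_end"] = bj, _["events"] = events);
}

// e-PCR primer binding scan. primer/tmpl: integer bases 0..3.
// Semi-global DP: the whole primer must align, with its first and last base
// paired to template bases (gaps strictly internal, as in primer
// hybridization); template position is free. Substitutions and indels are
// bounded separately; alignments are canonical (a primer-gap may not
// directly follow a template-gap or vice versa, so an indel pair cannot
// impersonate a substitution). Returns one row per admissible end position:
// (end, start, n_sub, n_gap), minimizing substitutions then gaps at each
// end position.
// [[Rcpp::export(name = ".cpp_epcr_scan")]]
IntegerMatrix cpp_epcr_scan(IntegerVector primer, IntegerVector tmpl,
                            int max_mm, int max_gaps) {
  const int Lp = primer.size(), Lt = tmpl.size();
  const int G = max_gaps + 1;
  const int BIG = 1000000;
  const int NS = 3; // 0 = match/sub, 1 = primer gap (template skipped),
                    // 2 = template gap (primer base skipped)
  // dp[i][g][s] over template positions, rolled over j; start[] carries the
  // template start position of the minimizing path
  auto mk = [&]() {
    return std::vector<std::vector<std::array<int, NS>>>(
        Lp + 1, std::vector<std::array<int, NS>>(G, {BIG, BIG, BIG}));
  };
  auto cur = mk(), prev = mk(), scur = mk(), sprev = mk();
  std::vector<std::array<int, 4>> out; // end, start, sub, gap

  // j = 0 column: nothing aligned yet (leading primer skips not allowed)
  for (int g = 0; g < G; ++g) {
    prev[0][g] = {BIG, BIG, BIG}; sprev[0][g] = {1, 1, 1};
    if (g == 0) prev[0][0][0] = 0;
  }
  for (int i = 1; i <= Lp; ++i)
    for (int g = 0; g < G; ++g) {
      prev[i][g] = {BIG, BIG, BIG}; sprev[i][g] = {1, 1, 1};
    }

  for (int j = 1; j <= Lt; ++j) {
    for (int g = 0; g < G; ++g) {
      cur[0][g] = {BIG, BIG, BIG}; scur[0][g] = {j + 1, j + 1, j + 1};
      if (g == 0) cur[0][g][0] = 0; // fresh start after template position j
    }
    for (int i = 1; i <= Lp; ++i) {
      for (int g = 0; g < G; ++g) {
        int mm = (primer[i - 1] == tmpl[j - 1]) ? 0 : 1;
        // state 0: consume (i, j) as match/sub from any previous state
        int bestv = BIG, bests = -1;
        for (int s = 0; s < NS; ++s) {
          int v = prev[i - 1][g][s];
          if (v < bestv) { bestv = v; bests = sprev[i - 1][g][s]; }
        }
        cur[i][g][0] = (bestv >= BIG) ? BIG : bestv + mm;
        scur[i][g][0] = bests;
        // state 1: primer gap (skip template base j); not after state 2
        int v1 = BIG, s1 = -1;
        if (g > 0) {
          if (prev[i][g - 1][0] < v1) { v1 = prev[i][g - 1][0]; s1 = sprev[i][g - 1][0]; }
          if (prev[i][g - 1][1] < v1) { v1 = prev[i][g - 1][1]; s1 = sprev[i][g - 1][1]; }
        }
        cur[i][g][1] = v1; scur[i][g][1] = s1;
        // state 2: template gap (skip primer base i); not after state 1,
        // and never on the first or last primer base
        int v2 = BIG, s2 = -1;
        if (g > 0 && i > 1 && i < Lp) {
          if (cur[i - 1][g - 1][0] < v2) { v2 = cur[i - 1][g - 1][0]; s2 = scur[i - 1][g - 1][0]; }
          if (cur[i - 1][g - 1][2] < v2) { v2 = cur[i - 1][g - 1][2]; s2 = scur[i - 1][g - 1][2]; }
        }
        cur[i][g][2] = v2; scur[i][g][2] = s2;
      }
    }
    // admissible end at j? The last primer base must pair with template
    // base j (state 0 only). Report the explanation with the fewest gaps.
    int bs = BIG, bg = -1, bstart = -1;
    for (int g = 0; g < G; ++g) {
      if (cur[Lp][g][0] <= max_mm) {
        bs = cur[Lp][g][0]; bg = g; bstart = scur[Lp][g][0];
        break;
      }
    }
    if (bg >= 0) out.push_back({j, bstart, bs, bg});
    std::swap(cur, prev); std::swap(scur, sprev);
  }
  IntegerMatrix res(out.size(), 4);
  for (size_t k = 0; k < out.size(); ++k)
    for (int c = 0; c < 4; ++c) res(k, c) = out[k][c];
  colnames(res) = CharacterVector::create("end", "start", "n_sub", "n_gap");
  return res;
}
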