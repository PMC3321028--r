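# Independent oracles used by the tests: brute-force path enumeration for the
# profile-HMM Viterbi, exhaustive move enumeration for the frameshift
# aligner, connected components for cluster chaining, and a plain-R DP for
# the e-PCR binding decision. These deliberately re-derive each quantity from
# first principles rather than calling the implementation under test.

# --- tiny profile HMM construction -----------------------------------------

toy_msa <- function(rows) tibble::tibble(id = paste0("s", seq_along(rows)),
                                         seq = rows)

# --- exhaustive Viterbi oracle ----------------------------------------------

# Enumerate every legal state path (start and end in a match state, local
# flanks free) and return the maximum total log2-odds score.
enumerate_viterbi <- function(hmm, protein) {
  s <- nlrscan:::aa_to_int(protein)
  L <- length(s)
  M <- hmm$M
  emit <- function(j, i) {
    if (is.na(s[i])) 0 else hmm$emit_lo[j, s[i]]
  }
  tr <- hmm$trans_lo
  best <- -Inf
  # walk(state, j, i, score): state consumed up to residue i, model pos j
  walk <- function(state, j, i, score) {
    if (state == "M" && score > best) best <<- unname(score)
    # transitions out of position j exist only for j < M
    if (j < M) {
      if (state == "M") {
        if (i < L) walk("M", j + 1, i + 1, score + tr[j, "MM"] + emit(j + 1, i + 1))
        if (i < L) walk("I", j, i + 1, score + tr[j, "MI"])
        walk("D", j + 1, i, score + tr[j, "MD"])
      } else if (state == "I") {
        if (i < L) walk("M", j + 1, i + 1, score + tr[j, "IM"] + emit(j + 1, i + 1))
        if (i < L) walk("I", j, i + 1, score + tr[j, "II"])
      } else { # D
        if (i < L) walk("M", j + 1, i + 1, score + tr[j, "DM"] + emit(j + 1, i + 1))
        walk("D", j + 1, i, score + tr[j, "DD"])
      }
    } else if (state == "I" && i < L) {
      walk("I", j, i + 1, score + tr[j, "II"])
      if (FALSE) NULL
    }
  }
  entry <- log2(1 / M)
  for (i0 in seq_len(L)) {
    for (j0 in seq_len(M)) {
      walk("M", j0, i0, entry + emit(j0, i0))
    }
  }
  best
}

# --- exhaustive frameshift-alignment oracle ---------------------------------

# DFS over the same move set as align_protein_to_dna (local start/end, match
# consuming 3/2/4 bases, affine codon/residue gaps), maximizing total score.
# Exponential; only for very small inputs.
enumerate_fs_align <- function(protein, dna, gap_open = 11, gap_extend = 1,
                               fs = 12, stop_score = -8) {
  prot <- nlrscan:::aa_to_int(protein)
  d <- nlrscan:::dna_to_int(dna)
  P <- length(prot); D <- length(d)
  sub <- nlrscan:::blosum62_matrix()
  ct <- nlrscan:::codon_table()
  codon_score <- function(i, j, len) {
    if (len == 2) return(-1)
    aa <- ct[16 * (d[j - 2] - 1) + 4 * (d[j - 1] - 1) + (d[j] - 1) + 1]
    if (aa < 0) stop_score else sub[prot[i], aa + 1]
  }
  best <- 0
  walk <- function(i, j, state, score) {
    if (state == "M" && score > best) best <<- score
    if (i < P) {
      if (j + 3 <= D) {
        walk(i + 1, j + 3, "M", score + codon_score(i + 1, j + 3, 3))
      }
      if (state == "M") {
        if (j + 2 <= D) walk(i + 1, j + 2, "M", score - fs + codon_score(i + 1, j + 2, 2))
        if (j + 4 <= D) walk(i + 1, j + 4, "M", score - fs + codon_score(i + 1, j + 4, 3))
      }
      # gap in dna consumption (unmatched reference residue)
      if (state == "M") walk(i + 1, j, "GB", score - gap_open)
      if (state == "GB") walk(i + 1, j, "GB", score - gap_extend)
    }
    if (j + 3 <= D) {
      if (state == "M") walk(i, j + 3, "GA", score - gap_open)
      if (state == "GA") walk(i, j + 3, "GA", score - gap_extend)
    }
  }
  for (i0 in 0:(P - 1)) {
    for (j0 in 0:D) {
      if (j0 + 3 <= D) {
        walk(i0 + 1, j0 + 3, "M", codon_score(i0 + 1, j0 + 3, 3))
      }
    }
  }
  best
}

# --- connected-components cluster oracle ------------------------------------

brute_clusters <- function(chrom, starts, max_gap) {
  n <- length(starts)
  adj <- abs(outer(starts, starts, "-")) <= max_gap &
    outer(chrom, chrom, "==")
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# --- plain-R e-PCR binding oracle -------------------------------------------

# Minimum substitutions to align the full primer ending at template position
# `end`, using at most `max_gaps` indels; NA when no alignment satisfies both
# bounds.
brute_epcr_ends <- function(primer, template, max_mm, max_gaps) {
  p <- strsplit(primer, "")[[1]]
  t <- strsplit(template, "")[[1]]
  Lp <- length(p); Lt <- length(t)
  ok <- logical(Lt)
  for (end in seq_len(Lt)) {
    # DP over suffix alignment ending exactly at `end`; canonical alignments
    # (state 1 = match/sub, 2 = primer gap, 3 = template gap; 2 and 3 may
    # not follow each other)
    win_lo <- max(1, end - Lp - max_gaps + 1)
    tt <- t[win_lo:end]
    n <- length(tt)
    dp <- array(Inf, dim = c(Lp + 1, n + 1, max_gaps + 1, 3))
    dp[1, , 1, 1] <- 0 # alignment may start after any template prefix
    for (i in 1:Lp) {
      for (j in 1:n) {
        for (g in 0:max_gaps) {
          # match/sub from any state
          dp[i + 1, j + 1, g + 1, 1] <-
            min(dp[i, j, g + 1, ]) + (p[i] != tt[j])
          if (g > 0) {
            # primer gap (skip template base): not after a template gap
            dp[i + 1, j + 1, g + 1, 2] <-
              min(dp[i + 1, j, g, c(1, 2)])
            # template gap (skip primer base): not after a primer gap and
            # never on the first or last primer base
            if (i > 1 && i < Lp) {
              dp[i + 1, j + 1, g + 1, 3] <-
                min(dp[i, j + 1, g, c(1, 3)])
            }
          }
        }
      }
    }
    # the last primer base must pair with the template base at `end`
    ok[end] <- any(dp[Lp + 1, n + 1, , 1] <= max_mm)
  }
  which(ok)
}

# small deterministic protein set with a planted motif
planted_motif_set <- function(n = 20, len = 60, motif = "WHKDEWYA",
                              seed = 11) {
  nlrscan:::with_seed(seed, {
    purrr::map_chr(seq_len(n), function(i) {
      bg <- nlrscan:::random_protein(len)
      pos <- sample.int(len - nchar(motif) + 1, 1)
      paste0(substr(bg, 1, pos - 1), motif,
             substr(bg, pos + nchar(motif), len))
    })
  })
}
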