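# Shared alphabets, background frequencies, and small numeric helpers.

#' Amino-acid alphabet used throughout the package
#' @keywords internal
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Robinson & Robinson background amino-acid frequencies, in AA_ALPHABET20
# order. Used as the null emission model for log-odds scoring and E-value
# calibration.
ROBINSON_BG <- c(
  A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
  G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
  M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
  S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216)

#' Convert an amino-acid string to integer codes
#'
#' @param x character scalar. Unknown residues (X etc.) become `NA`.
#' @return integer vector, 1-based indices into [AA_ALPHABET20].
#' @keywords internal
aa_to_int <- function(x) {
  match(strsplit(toupper(x), "")[[1]], AA_ALPHABET20)
}

#' @keywords internal
dna_to_int <- function(x) {
  match(strsplit(toupper(x), "")[[1]], c("A", "C", "G", "T"))
}

# BLOSUM62 restricted to the 20 standard residues, in AA_ALPHABET20 order.
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62[AA_ALPHABET20, AA_ALPHABET20]
    }
    cache
  }
})

# 64-entry codon -> amino-acid index map (0-based aa index, -1 = stop),
# codon index = 16*b1 + 4*b2 + b3 with bases A,C,G,T = 0..3.
codon_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bases <- c("A", "C", "G", "T")
      codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
      # outer() fills first argument fastest; rebuild in b1-major order
      idx <- expand.grid(b3 = 0:3, b2 = 0:3, b1 = 0:3)
      codons <- paste0(bases[idx$b1 + 1], bases[idx$b2 + 1], bases[idx$b3 + 1])
      aa <- Biostrings::GENETIC_CODE[codons]
      out <- match(aa, AA_ALPHABET20) - 1L
      out[aa == "*"] <- -1L
      cache <<- out
    }
    cache
  }
})

# codon index -> residue character (including "*"), aligned with codon_table()
codon_chars <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ct <- codon_table()
      aa <- AA_ALPHABET20[pmax(ct, 0L) + 1L]
      aa[ct < 0L] <- "*"
      cache <<- aa
    }
    cache
  }
})

#' Translate a DNA coding sequence
#'
#' Standard nuclear genetic code; trailing partial codons are dropped,
#' internal stop codons translate to `*`, and codons containing ambiguous
#' bases translate to `X`.
#'
#' @param dna character scalar of A/C/G/T (case-insensitive).
#' @return character scalar amino-acid sequence.
#' @export
translate_cds <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  b <- dna_to_int(substr(dna, 1L, 3L * n)) - 1L
  dim(b) <- c(3L, n)
  idx <- 16L * b[1, ] + 4L * b[2, ] + b[3, ] + 1L
  aa <- codon_chars()[idx]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' @keywords internal
revcomp <- function(dna) {
  rawToChar(rev(charToRaw(chartr("ACGTacgtN", "TGCAtgcaN", dna))))
}

#' Round half away from zero
#'
#' `base::round()` rounds half to even; summary tables in this package round
#' half up, matching how the percentages in published NLR surveys are printed.
#'
#' @param x numeric. @param digits integer.
#' @return numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * k) %% 2147483629
}

random_protein <- function(n, bg = ROBINSON_BG) {
  paste(sample(AA_ALPHABET20, n, replace = TRUE, prob = bg), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Mutate a protein: substitute each residue with rate `rate`, never touching
# positions in `protect` (integer positions).
mutate_protein <- function(x, rate, protect = integer()) {
  ch <- strsplit(x, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  hit <- setdiff(hit, protect)
  if (length(hit)) {
    repl <- sample(AA_ALPHABET20, length(hit), replace = TRUE, prob = ROBINSON_BG)
    ch[hit] <- repl
  }
  paste(ch, collapse = "")
}

codons_by_aa <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc), gc)
    }
    cache
  }
})

# Back-translate a protein to a CDS, sampling synonymous codons uniformly.
# Appends a stop codon.
backtranslate <- function(protein) {
  by_aa <- codons_by_aa()
  ch <- strsplit(protein, "")[[1]]
  opts <- by_aa[ch]
  lens <- lengths(opts)
  pick <- ceiling(stats::runif(length(ch)) * lens)
  codons <- mapply(`[`, opts, pick)
  stop_c <- by_aa[["*"]][sample.int(3L, 1L)]
  paste0(paste(codons, collapse = ""), stop_c)
}

# Shared k-mer similarity between two protein strings (used to shortlist
# alignment references).
kmer_share <- function(a, b, k = 4) {
  if (nchar(a) < k || nchar(b) < k) return(0)
  ka <- substring(a, seq_len(nchar(a) - k + 1), seq_len(nchar(a) - k + 1) + k - 1)
  kb <- substring(b, seq_len(nchar(b) - k + 1), seq_len(nchar(b) - k + 1) + k - 1)
  length(intersect(ka, kb)) / min(length(unique(ka)), length(unique(kb)))
}
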