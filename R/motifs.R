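# Canonical motif set used by both the synthetic-genome generator and the
# packaged detection models. The NBS (NB-ARC) block carries the four strictly
# ordered motifs of plant R proteins -- P-loop, kinase-2, kinase-3a and GLPL --
# embedded in conserved core segments (C*) and lineage-divergent segments (V*).
# Three lineage variants are modelled: two CC-lineage signatures (the CC(I) /
# CC(II) split seen in NLR phylogenies) and one TIR-lineage signature. The
# kinase-2 motif ends in W for the CC lineages and D for the TIR lineage, the
# classical NBS signature discriminator.

NLR_MOTIF <- list(
  ploop  = "GMGGVGKTTLAQ",
  k2_cc  = "KRYLIVLDDVW",
  k2_tir = "KRYLIVLDDVD",
  k3a    = "GSRIIVTSRN",
  glpl   = "GLPLALKV",
  v0     = "CTLESAIGPL",
  v1_cc1 = "IFAKRTHGIGTAPSAKENDLWSAVD",
  v1_cc2 = "NLGLAVPKSGKFDNPFIYWDQGQRS",
  v1_tir = "MDGLHKKDWRALMSTLLGLESSSLL",
  c1     = "IVDVQYDAWLGAIMMSWQEH",
  c2     = "CMTDVSHLKSIRIRARSA",
  c3     = "VALAAAQVRTLNEQIMSVNV",
  v2_cc1 = "VAIDEQASVTESLTFPKLQD",
  v2_cc2 = "ISLGRATADTALGVKFSGCK",
  v2_tir = "DNGSDQTMLCNQTACLTKRP",
  c4     = "GDEIFAQPGATKAKY",
  tir    = paste0("STGAWVLLSQPPNKFCVVNMVKVSCELEFEMFLDPAFAEGKDLIYDENPTPID",
                  "GQPQIAYPLRVVERKSAALLAL"),
  cc     = strrep("LEELQKA", 5),
  lrr    = "LSGLDLSNNKLSGPIPSSLGN",
  kinase = paste0("GSGSFGKVYK", "QRSETPNAAEAYLAHEIQ", "HRDLKPENLL",
                  "FEKQDHSLTLGHNLHPLGFCNPEAQ", "DFGLARE",
                  "TDKVRFPDFLFSFDIMSLGD", "GTPEYMAPEV",
                  "KSGITRFKVSHLTADLESLLGIWSP"))

#' NBS (NB-ARC) domain consensus for one lineage signature
#'
#' @param subtype `"cc1"`, `"cc2"` or `"tir"`.
#' @return list with `seq` (consensus string) and `offsets`, a tibble of the
#'   four motif spans (1-based, inclusive) within the domain.
#' @export
nbs_consensus <- function(subtype = c("cc1", "cc2", "tir")) {
  subtype <- match.arg(subtype)
  m <- NLR_MOTIF
  v1 <- m[[paste0("v1_", subtype)]]
  v2 <- m[[paste0("v2_", subtype)]]
  k2 <- if (subtype == "tir") m$k2_tir else m$k2_cc
  parts <- c(m$v0, m$ploop, v1, m$c1, k2, m$c2, m$k3a, m$c3, v2, m$glpl, m$c4)
  lens <- nchar(parts)
  starts <- cumsum(c(1, lens[-length(lens)]))
  ends <- starts + lens - 1
  offsets <- tibble::tibble(
    motif = c("ploop", "kinase2", "kinase3a", "glpl"),
    start = starts[c(2, 5, 7, 10)],
    end = ends[c(2, 5, 7, 10)])
  list(seq = paste(parts, collapse = ""), offsets = offsets)
}

# Positions within the NBS consensus that are held invariant by the noise
# model (the four motifs; these are the most conserved residues of real
# NB-ARC domains).
nbs_protected_positions <- function(subtype) {
  off <- nbs_consensus(subtype)$offsets
  unlist(Map(seq.int, off$start, off$end))
}

# --- position-specific scoring matrices -------------------------------------

#' Construct a PSSM
#'
#' @param probs W x 20 matrix of per-position residue probabilities (columns
#'   in [AA_ALPHABET20] order).
#' @param threshold bit-score threshold for [scan_pssm()].
#' @param name optional motif name.
#' @return object of class `nlr_pssm` (log2-odds versus the packaged
#'   background).
#' @export
new_pssm <- function(probs, threshold, name = "motif") {
  stopifnot(ncol(probs) == 20, nrow(probs) >= 3, all(is.finite(probs)))
  probs <- probs / rowSums(probs)
  lo <- log2(sweep(probs, 2, ROBINSON_BG, "/"))
  colnames(lo) <- AA_ALPHABET20
  structure(list(log_odds = lo, width = nrow(probs), threshold = threshold,
                 name = name),
            class = "nlr_pssm")
}

#' @export
print.nlr_pssm <- function(x, ...) {
  cat(sprintf("<nlr_pssm '%s'> width %d, threshold %.1f bits\n",
              x$name, x$width, x$threshold))
  invisible(x)
}

#' PSSM from a consensus sequence
#'
#' Each column puts probability `conservation` on the consensus residue and
#' spreads the rest over the background. The default threshold is half the
#' maximum attainable score, which separates noisy consensus copies from
#' background sequence by a wide margin for motifs of width >= 8.
#'
#' @param consensus amino-acid string (or character vector of equally likely
#'   variants, e.g. the two kinase-2 lineage forms).
#' @param conservation probability mass on the consensus residue.
#' @param threshold_frac threshold as a fraction of the maximum score.
#' @param name motif name.
#' @return `nlr_pssm`.
#' @export
pssm_from_consensus <- function(consensus, conservation = 0.9,
                                threshold_frac = 0.5, name = "motif") {
  w <- nchar(consensus[[1]])
  stopifnot(all(nchar(consensus) == w))
  probs <- matrix(0, w, 20)
  for (cs in consensus) {
    idx <- aa_to_int(cs)
    p <- matrix(rep(ROBINSON_BG * (1 - conservation), each = w), w, 20)
    p[cbind(seq_len(w), idx)] <- p[cbind(seq_len(w), idx)] + conservation
    probs <- probs + p / length(consensus)
  }
  pssm <- new_pssm(probs, threshold = 0, name = name)
  maxs <- sum(apply(pssm$log_odds, 1, max))
  pssm$threshold <- threshold_frac * maxs
  pssm
}

# The packaged motif PSSMs used by the domain-architecture module.
packaged_pssms <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- NLR_MOTIF
      cache <<- list(
        tir = pssm_from_consensus(m$tir, name = "TIR"),
        lrr = pssm_from_consensus(m$lrr, name = "LRR"),
        ploop = pssm_from_consensus(m$ploop, threshold_frac = 0.6, name = "PLOOP"),
        kinase2 = pssm_from_consensus(c(m$k2_cc, m$k2_tir),
                                      threshold_frac = 0.55, name = "KINASE2"),
        kinase3a = pssm_from_consensus(m$k3a, threshold_frac = 0.6, name = "KINASE3A"),
        glpl = pssm_from_consensus(m$glpl, threshold_frac = 0.6, name = "GLPL"))
    }
    cache
  }
})

# --- coiled-coil heptad propensity table ------------------------------------

# Log-odds-style propensities for the seven heptad positions (a..g);
# hydrophobic residues favoured at a/d, charged/polar at e/g, mild
# preferences elsewhere. Lupas-style sliding-window scoring uses the best of
# the seven phases.
heptad_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tab <- matrix(-0.4, 20, 7, dimnames = list(AA_ALPHABET20, letters[1:7]))
      for (p in c("a", "d")) {
        tab[, p] <- -1.2
        tab[c("L", "I", "V", "M", "F", "A"), p] <- c(2.2, 1.8, 1.4, 1.2, 0.8, 0.6)
      }
      for (p in c("e", "g")) {
        tab[, p] <- -0.6
        tab[c("E", "K", "Q", "R", "D", "A"), p] <- c(1.2, 1.2, 0.9, 0.9, 0.4, 0.3)
      }
      for (p in c("b", "c", "f")) {
        tab[, p] <- -0.4
        tab[c("E", "K", "A", "Q", "R", "S", "L", "D", "N"), p] <-
          c(0.6, 0.6, 0.5, 0.5, 0.4, 0.3, 0.2, 0.2, 0.1)
      }
      cache <<- tab
    }
    cache
  }
})

# --- packaged seed alignments and reference proteins ------------------------

#' Path to a packaged data file
#' @param file file name under `extdata/`.
#' @return absolute path.
#' @export
nlr_extdata <- function(file) {
  path <- system.file("extdata", file, package = "nlrscan", mustWork = FALSE)
  if (!nzchar(path)) stop("packaged file not found: ", file)
  path
}

#' Packaged seed alignment
#'
#' Stockholm seed alignments shipped with the package: `"nbarc"` (the NB-ARC
#' domain across the three lineage signatures), `"kinase"` (protein-kinase
#' exclusion model), `"nbs_cc"` and `"nbs_tir"` (lineage sub-profiles used by
#' the NBS-signature classifier). All rows are synthetic sequences sampled
#' around the packaged consensus set.
#'
#' @param which seed name.
#' @return tibble with columns `id`, `seq` (aligned rows).
#' @export
seed_alignment <- function(which = c("nbarc", "kinase", "nbs_cc", "nbs_tir")) {
  which <- match.arg(which)
  read_stockholm(nlr_extdata(paste0(which, "_seed.sto")))
}

#' Packaged reference R-protein set
#'
#' Synthetic stand-in for a curated resistance-protein database: one
#' full-length reference per NLR architecture template plus non-NLR
#' stress-response references. Used by [screen_nbs_derived()] in place of a
#' live database search.
#'
#' @return tibble as returned by [read_fasta()].
#' @export
reference_r_proteins <- function() {
  read_fasta(nlr_extdata("reference_r_proteins.fasta"))
}
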