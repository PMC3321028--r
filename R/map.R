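# Physical mapping: anchoring scaffold genes to pseudomolecules, cluster and
# singleton detection, flanking-window construction, ORF extraction, and the
# reference-set homology screen that recovers NBS-derived genes.

#' Anchor scaffold genes to chromosome coordinates
#'
#' Forward-placed scaffolds shift coordinates by the scaffold offset;
#' reverse-placed scaffolds mirror them (`chr_start = offset +
#' (scaffold_length - end + 1)`) and flip the strand. Genes on scaffolds
#' absent from the anchor table are returned with `chromosome = NA`.
#'
#' @param genes tibble with `gene_id`, `seqid`, `start`, `end`, `strand`
#'   (1-based inclusive scaffold coordinates); extra columns are carried
#'   through.
#' @param anchor_table tibble from [read_anchor_table()].
#' @return the input with `chromosome`, `chr_start`, `chr_end`, `chr_strand`
#'   added.
#' @export
anchor_genes <- function(genes, anchor_table) {
  at <- anchor_table[match(genes$seqid, anchor_table$scaffold_id), ]
  bad <- !is.na(at$scaffold_id) & genes$end > at$scaffold_length
  if (any(bad)) {
    stop("gene extends past scaffold length: ", genes$gene_id[bad][1])
  }
  fwd <- !is.na(at$orientation) & at$orientation == "+"
  rev <- !is.na(at$orientation) & at$orientation == "-"
  chr_start <- ifelse(fwd, at$chromosome_offset + genes$start,
                      ifelse(rev, at$chromosome_offset +
                               (at$scaffold_length - genes$end + 1), NA))
  chr_end <- ifelse(fwd, at$chromosome_offset + genes$end,
                    ifelse(rev, at$chromosome_offset +
                             (at$scaffold_length - genes$start + 1), NA))
  flip <- c(`+` = "-", `-` = "+")
  dplyr::mutate(genes,
                chromosome = at$chromosome,
                chr_start = as.numeric(chr_start),
                chr_end = as.numeric(chr_end),
                chr_strand = ifelse(fwd, genes$strand,
                                    ifelse(rev, flip[genes$strand], NA)))
}

#' Detect physical gene clusters by single-linkage chaining
#'
#' Consecutive genes on a chromosome whose start-to-start distance is at most
#' `max_gap` join one cluster; clusters have at least two members. Cluster
#' composition is `simple_CNL` / `simple_TNL` when every member belongs to
#' one lineage, otherwise `mixed`.
#'
#' @param anchored tibble from [anchor_genes()] (rows with `chromosome` NA
#'   are ignored); an architecture `code` column, when present, drives the
#'   composition label.
#' @param max_gap chaining distance in bp.
#' @return list with `clusters` (one row per cluster) and `genes` (input rows
#'   with `cluster_id`, `is_singleton`).
#' @export
detect_clusters <- function(anchored, max_gap = 100000) {
  g <- dplyr::filter(anchored, !is.na(.data$chromosome))
  g <- dplyr::arrange(g, .data$chromosome, .data$chr_start, .data$gene_id)
  g$cluster_id <- NA_character_
  clusters <- tibble::tibble()
  cl_n <- 0
  for (chr in unique(g$chromosome)) {
    idx <- which(g$chromosome == chr)
    if (!length(idx)) next
    starts <- g$chr_start[idx]
    brk <- c(0, cumsum(diff(starts) > max_gap))
    for (b in unique(brk)) {
      mem <- idx[brk == b]
      if (length(mem) < 2) next
      cl_n <- cl_n + 1
      cid <- sprintf("cluster_%03d", cl_n)
      g$cluster_id[mem] <- cid
      comp <- "mixed"
      if ("code" %in% names(g)) {
        lin <- dplyr::case_when(
          g$code[mem] %in% c("CNL", "CN", "NL_CC", "N_CC") ~ "CNL",
          g$code[mem] %in% c("TNL", "TN", "NL_TIR", "N_TIR") ~ "TNL",
          TRUE ~ "other")
        comp <- if (all(lin == "CNL")) "simple_CNL"
        else if (all(lin == "TNL")) "simple_TNL" else "mixed"
      }
      clusters <- dplyr::bind_rows(clusters, tibble::tibble(
        cluster_id = cid, chromosome = chr,
        members = list(g$gene_id[mem]), n = length(mem),
        span_start = min(g$chr_start[mem]), span_end = max(g$chr_end[mem]),
        composition = comp))
    }
  }
  g$is_singleton <- is.na(g$cluster_id)
  out_genes <- dplyr::left_join(
    anchored, dplyr::select(g, "gene_id", "cluster_id", "is_singleton"),
    by = "gene_id")
  list(clusters = clusters, genes = out_genes)
}

#' Chain clusters into super-clusters
#'
#' Clusters on the same chromosome whose spans lie within `max_gap` of each
#' other are reported as one super-cluster.
#'
#' @param clusters cluster tibble from [detect_clusters()].
#' @param max_gap span-to-span distance in bp.
#' @return tibble of super-clusters (`chromosome`, member cluster ids, span).
#' @export
super_clusters <- function(clusters, max_gap = 500000) {
  if (!nrow(clusters)) return(tibble::tibble())
  cl <- dplyr::arrange(clusters, .data$chromosome, .data$span_start)
  out <- tibble::tibble()
  n <- 0
  for (chr in unique(cl$chromosome)) {
    idx <- which(cl$chromosome == chr)
    gap <- cl$span_start[idx][-1] - cl$span_end[idx][-length(idx)]
    brk <- c(0, cumsum(gap > max_gap))
    for (b in unique(brk)) {
      mem <- idx[brk == b]
      if (length(mem) < 2) next
      n <- n + 1
      out <- dplyr::bind_rows(out, tibble::tibble(
        super_cluster_id = sprintf("super_%02d", n), chromosome = chr,
        clusters = list(cl$cluster_id[mem]),
        n_clusters = length(mem), n_genes = sum(cl$n[mem]),
        span_start = min(cl$span_start[mem]),
        span_end = max(cl$span_end[mem])))
    }
  }
  out
}

#' Find "alone" genes
#'
#' A gene is alone when its nearest NBS gene on the same chromosome is
#' strictly farther than `min_dist`, or when it is the only NBS gene on its
#' chromosome.
#'
#' @param anchored anchored gene tibble.
#' @param min_dist distance threshold in bp.
#' @return input rows that qualify.
#' @export
find_singletons <- function(anchored, min_dist = 3e6) {
  g <- dplyr::filter(anchored, !is.na(.data$chromosome))
  alone <- vapply(seq_len(nrow(g)), function(i) {
    same <- setdiff(which(g$chromosome == g$chromosome[i]), i)
    length(same) == 0 ||
      min(abs(g$chr_start[same] - g$chr_start[i])) > min_dist
  }, logical(1))
  g[alone, ]
}

#' Flanking windows around scaffold NBS genes
#'
#' Scaffolds with fewer than two NBS genes produce no window; exactly two
#' produce one `flank_small` window around the NBS span; three or more widen
#' it to `flank_large`. Windows are clipped to scaffold bounds.
#'
#' @param scaffold_genes tibble with `gene_id`, `seqid`, `start`, `end`.
#' @param nbs_ids gene ids tagged as NBS genes.
#' @param scaffold_lengths named vector of scaffold lengths.
#' @param flank_small,flank_large window half-widths in bp.
#' @return tibble with `seqid`, `start`, `end`, `n_nbs`, `nbs_ids`.
#' @export
flanking_windows <- function(scaffold_genes, nbs_ids, scaffold_lengths,
                             flank_small = 100000, flank_large = 200000) {
  nbs <- dplyr::filter(scaffold_genes, .data$gene_id %in% nbs_ids)
  out <- nbs %>%
    dplyr::group_by(.data$seqid) %>%
    dplyr::summarise(n_nbs = dplyr::n(),
                     span_start = min(.data$start),
                     span_end = max(.data$end),
                     nbs_ids = list(.data$gene_id), .groups = "drop") %>%
    dplyr::filter(.data$n_nbs >= 2)
  if (!nrow(out)) {
    return(tibble::tibble(seqid = character(), start = numeric(),
                          end = numeric(), n_nbs = integer(),
                          nbs_ids = list()))
  }
  flank <- ifelse(out$n_nbs >= 3, flank_large, flank_small)
  dplyr::transmute(out, seqid = .data$seqid,
                   start = pmax(1, .data$span_start - flank),
                   end = pmin(unname(scaffold_lengths[.data$seqid]),
                              .data$span_end + flank),
                   n_nbs = .data$n_nbs, nbs_ids = .data$nbs_ids)
}

#' Extract ORFs from a DNA segment
#'
#' ATG-to-stop open reading frames of at least `min_codons` codons, all six
#' frames. Coordinates refer to the supplied segment, 1-based inclusive on
#' the forward strand.
#'
#' @param dna character scalar.
#' @param min_codons minimum ORF length in codons (including the start,
#'   excluding the stop).
#' @return tibble with `start`, `end`, `strand`, `protein`.
#' @export
extract_orfs <- function(dna, min_codons = 80) {
  L <- nchar(dna)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else revcomp(dna)
    for (frame in 0:2) {
      sub <- substr(s, frame + 1, L)
      aa <- translate_cds(sub)
      if (nchar(aa) == 0) next
      m <- gregexpr(sprintf("M[^*]{%d,}", min_codons - 1), aa)[[1]]
      if (m[1] == -1) next
      for (k in seq_along(m)) {
        a0 <- m[k]
        alen <- attr(m, "match.length")[k]
        nt_start <- frame + (a0 - 1) * 3 + 1
        nt_end <- frame + (a0 - 1 + alen) * 3
        if (strand == "+") {
          st <- nt_start; en <- nt_end
        } else {
          st <- L - nt_end + 1; en <- L - nt_start + 1
        }
        out <- c(out, list(tibble::tibble(
          start = st, end = en, strand = strand,
          protein = substr(aa, a0, a0 + alen - 1))))
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), protein = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$end, .data$strand)
}

# Karlin-Altschul E-value for a gapped BLOSUM62 local alignment score
# (published constants lambda = 0.267, K = 0.041).
sw_evalue <- function(score, m, n) {
  0.041 * m * n * exp(-0.267 * score)
}

#' Screen window ORFs against the reference R-protein set
#'
#' Each ORF is aligned (Smith-Waterman, BLOSUM62) against the packaged
#' reference proteins. ORFs homologous to an NLR reference are typed by their
#' NBS-model coverage: zero coverage gives `"nbs_derived"` (an NLR relic that
#' lost the NBS domain), coverage below the partial threshold gives
#' `"partial_nbs"`; ORFs homologous only to non-NLR stress references are
#' `"resistance_like"`.
#'
#' @param window_orfs tibble with at least `protein` (plus any coordinate
#'   columns, carried through).
#' @param references tibble (`id`, `description`, `seq`); descriptions
#'   starting with `"NLR"` mark NLR references.
#' @param nbs_hmm calibrated NBS profile HMM used for coverage.
#' @param max_evalue,min_identity,min_ref_coverage homology cutoffs.
#' @param partial_threshold NBS coverage below which a hit is partial.
#' @param relaxed_evalue E-value threshold for counting NBS-model coverage.
#' @return input tibble with `call` (`nbs_derived`, `partial_nbs`,
#'   `resistance_like` or `none`), `best_ref`, `ref_identity`,
#'   `ref_coverage`, `nbs_coverage`.
#' @export
screen_nbs_derived <- function(window_orfs, references, nbs_hmm,
                               max_evalue = 1e-5, min_identity = 30,
                               min_ref_coverage = 0.5,
                               partial_threshold = 0.5,
                               relaxed_evalue = 1e-2) {
  n <- nrow(window_orfs)
  call <- rep("none", n)
  best_ref <- rep(NA_character_, n)
  ident <- rep(NA_real_, n)
  refcov <- rep(NA_real_, n)
  nbscov <- rep(0, n)
  is_nlr_ref <- startsWith(references$description, "NLR")
  sub <- blosum62_matrix()
  for (i in seq_len(n)) {
    p <- window_orfs$protein[i]
    # k-mer prefilter keeps the quadratic alignments affordable
    shares <- vapply(references$seq, function(r) kmer_share(p, r), numeric(1),
                     USE.NAMES = FALSE)
    cand <- which(shares > 0.02)
    if (!length(cand)) next
    best <- NULL
    for (j in cand) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(p), Biostrings::AAString(references$seq[j]),
        type = "local", substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1)
      sc <- Biostrings::score(al)
      ev <- sw_evalue(sc, nchar(p), nchar(references$seq[j]))
      pid <- Biostrings::pid(al)
      cov <- Biostrings::nchar(Biostrings::subject(al)) /
        nchar(references$seq[j])
      if (ev <= max_evalue && pid >= min_identity && cov >= min_ref_coverage) {
        if (is.null(best) || sc > best$sc) {
          best <- list(sc = sc, j = j, pid = pid, cov = cov)
        }
      }
    }
    if (is.null(best)) next
    best_ref[i] <- references$id[best$j]
    ident[i] <- best$pid
    refcov[i] <- best$cov
    if (is_nlr_ref[best$j]) {
      v <- suppressWarnings(viterbi(nbs_hmm, p))
      ev <- hmm_evalue(nbs_hmm, v$score, max(n, 1))
      cov <- if (ev <= relaxed_evalue) v$n_match / nbs_hmm$M else 0
      nbscov[i] <- cov
      call[i] <- if (cov == 0) "nbs_derived"
      else if (cov < partial_threshold) "partial_nbs"
      else "none" # a full NBS gene; handled by the HMM stage, not this screen
    } else {
      call[i] <- "resistance_like"
    }
  }
  dplyr::mutate(window_orfs, call = call, best_ref = best_ref,
                ref_identity = ident, ref_coverage = refcov,
                nbs_coverage = nbscov)
}

#' Per-chromosome, per-bin gene counts (distribution track)
#'
#' @param anchored anchored gene tibble.
#' @param bin bin width in bp.
#' @return tibble with `chromosome`, `bin_start`, `n`.
#' @export
chromosome_distribution <- function(anchored, bin = 1e6) {
  anchored %>%
    dplyr::filter(!is.na(.data$chromosome)) %>%
    dplyr::mutate(bin_start = floor(.data$chr_start / bin) * bin) %>%
    dplyr::count(.data$chromosome, .data$bin_start, name = "n")
}
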