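# Frameshift-aware pseudogene analysis: a candidate gene's DNA is aligned to
# intact reference proteins with a dynamic program over (protein position x
# DNA position x frame); frame switches and in-frame stop codons become
# recorded events, and the disabling lesion is classified from the event set
# and the aligned reference coverage.

#' Frameshift-aware alignment of a reference protein to DNA
#'
#' Local alignment in which each reference residue consumes three DNA bases
#' in frame, or two/four bases across a frameshift (penalty
#' `frameshift_penalty`); codon matches are scored with BLOSUM62 on the
#' translated codon, stop codons score `stop_score` and are recorded as
#' events; gaps are affine and consume whole codons or whole residues.
#'
#' @param reference_protein amino-acid string.
#' @param dna DNA string (at least one codon).
#' @param gap_open,gap_extend affine gap penalties.
#' @param frameshift_penalty cost of a frame switch.
#' @param stop_score score of an in-frame stop codon (mismatch floor).
#' @return list with `score`, `ref_start`/`ref_end`, `dna_start`/`dna_end`
#'   (1-based inclusive), `events` (tibble of `kind` in
#'   frameshift/premature_stop, `dna_pos`, `codon`, `ref_pos`) and
#'   `ref_coverage` (aligned fraction of the reference).
#' @export
align_protein_to_dna <- function(reference_protein, dna, gap_open = 11,
                                 gap_extend = 1, frameshift_penalty = 12,
                                 stop_score = -8) {
  stopifnot(nchar(dna) >= 3)
  prot <- aa_to_int(reference_protein)
  prot[is.na(prot)] <- 1L
  d <- dna_to_int(dna)
  d[is.na(d)] <- 1L
  res <- .cpp_fs_align(prot - 1L, d - 1L, blosum62_matrix(), codon_table(),
                       gap_open, gap_extend, frameshift_penalty, stop_score)
  ev <- res$events
  events <- tibble::tibble(
    kind = c("frameshift", "premature_stop")[ev[, 1]],
    dna_pos = ev[, 2],
    codon = ceiling(ev[, 2] / 3),
    ref_pos = ev[, 3])
  cov <- if (is.na(res$ref_start)) 0 else
    (res$ref_end - res$ref_start + 1) / nchar(reference_protein)
  list(score = res$score, ref_start = res$ref_start, ref_end = res$ref_end,
       dna_start = res$dna_start, dna_end = res$dna_end,
       events = events, ref_coverage = cov)
}

#' Classify the disabling lesion of a candidate gene
#'
#' The gene's (spliced) DNA is aligned against a shortlist of intact
#' reference proteins (ranked by shared k-mers, ties by reference id); the
#' best-scoring alignment is interpreted with the cause priority
#' scaffold-end > premature stop > frameshift > partial deletion > intact.
#' A scaffold-end call requires the gene to lie within `scaffold_end_margin`
#' of a scaffold terminus with the alignment truncated on that side.
#'
#' @param gene_id candidate id.
#' @param gene_dna spliced CDS DNA of the candidate.
#' @param reference_set tibble (`id`, `seq`) of intact reference proteins
#'   (the candidate itself is excluded by id).
#' @param coverage_threshold reference coverage below which a clean
#'   alignment is called a partial deletion.
#' @param max_refs alignments performed (k-mer shortlist size).
#' @param gene_scaffold_pos optional list with `start`, `end`,
#'   `scaffold_length`, `strand` for the scaffold-end rule.
#' @param scaffold_end_margin bp from a scaffold terminus that counts as
#'   truncated-by-assembly.
#' @param frameshift_penalty passed to [align_protein_to_dna()].
#' @return one-row tibble: `gene_id`, `cause`, `breakpoint_codon`,
#'   `reference`, `score`, `ref_coverage`, `n_events`.
#' @export
call_pseudogene <- function(gene_id, gene_dna, reference_set,
                            coverage_threshold = 0.8, max_refs = 3,
                            gene_scaffold_pos = NULL,
                            scaffold_end_margin = 500,
                            frameshift_penalty = 12) {
  refs <- dplyr::filter(reference_set, .data$id != gene_id)
  if (!nrow(refs)) {
    return(tibble::tibble(gene_id = gene_id, cause = "unclassifiable",
                          breakpoint_codon = NA_integer_,
                          reference = NA_character_, score = NA_real_,
                          ref_coverage = NA_real_, n_events = NA_integer_))
  }
  gene_aa <- sub("\\*.*$", "", translate_cds(gene_dna))
  shares <- vapply(refs$seq, function(r) kmer_share(gene_aa, r), numeric(1),
                   USE.NAMES = FALSE)
  ord <- order(-shares, refs$id)
  short <- ord[seq_len(min(max_refs, length(ord)))]
  best <- NULL
  for (j in short) {
    al <- align_protein_to_dna(refs$seq[j], gene_dna,
                               frameshift_penalty = frameshift_penalty)
    al$reference <- refs$id[j]
    if (is.null(best) || al$score > best$score ||
        (al$score == best$score && al$reference < best$reference)) {
      best <- al
    }
  }
  ev <- best$events
  # scaffold-end: physical truncation by the assembly edge
  cause <- NULL
  breakpoint <- NA_integer_
  if (!is.null(gene_scaffold_pos)) {
    gp <- gene_scaffold_pos
    near_end <- gp$scaffold_length - gp$end <= scaffold_end_margin
    near_start <- gp$start <= scaffold_end_margin
    # which gene side the scaffold terminus truncates (3' side for a + gene
    # at the right edge or a - gene at the left edge)
    trunc_3p <- (near_end && gp$strand == "+") || (near_start && gp$strand == "-")
    ref_len <- nchar(refs$seq[match(best$reference, refs$id)])
    truncated <- !is.na(best$ref_end) && best$ref_end < ref_len - 5
    if (trunc_3p && truncated && best$ref_coverage < coverage_threshold) {
      cause <- "scaffold_end"
      breakpoint <- ceiling(best$dna_end / 3) + 1L
    }
  }
  if (is.null(cause)) {
    stops <- ev[ev$kind == "premature_stop", ]
    shifts <- ev[ev$kind == "frameshift", ]
    if (nrow(stops)) {
      cause <- "premature_stop"
      breakpoint <- stops$codon[1]
    } else if (nrow(shifts)) {
      cause <- "frameshift"
      breakpoint <- shifts$codon[1]
    } else if (best$ref_coverage < coverage_threshold) {
      cause <- "deletion_partial"
      breakpoint <- ceiling(best$dna_end / 3) + 1L
    } else {
      cause <- "intact"
    }
  }
  tibble::tibble(gene_id = gene_id, cause = cause,
                 breakpoint_codon = as.integer(breakpoint),
                 reference = best$reference, score = best$score,
                 ref_coverage = best$ref_coverage, n_events = nrow(ev))
}

#' Pseudogene calls for a set of candidates
#'
#' @param candidates tibble with `gene_id`, `dna` and optionally `start`,
#'   `end`, `strand`, `scaffold_length` (for the scaffold-end rule).
#' @param reference_set intact reference proteins (`id`, `seq`).
#' @inheritParams call_pseudogene
#' @return tibble of per-gene calls.
#' @export
call_pseudogenes <- function(candidates, reference_set,
                             coverage_threshold = 0.8, max_refs = 3,
                             frameshift_penalty = 12) {
  rows <- purrr::map(seq_len(nrow(candidates)), function(i) {
    pos <- NULL
    if (all(c("start", "end", "strand", "scaffold_length") %in%
            names(candidates))) {
      pos <- list(start = candidates$start[i], end = candidates$end[i],
                  strand = candidates$strand[i],
                  scaffold_length = candidates$scaffold_length[i])
    }
    call_pseudogene(candidates$gene_id[i], candidates$dna[i], reference_set,
                    coverage_threshold = coverage_threshold,
                    max_refs = max_refs, gene_scaffold_pos = pos,
                    frameshift_penalty = frameshift_penalty)
  })
  dplyr::bind_rows(rows)
}
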