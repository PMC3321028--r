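# Pipeline orchestration and the summary tables: architecture counts with
# lineage subtotals, the per-chromosome pseudogene distribution, derived
# percentages, and the in-silico PCR primer screen.

#' Pipeline configuration
#'
#' Houses every numeric threshold of the pipeline. Defaults are the
#' published operating points: strict/relaxed HMM E-values 1e-60 / 1e-2,
#' coiled-coil probability 0.9 with a 0.025 validation margin, 100 kb cluster
#' chaining, 100/200 kb flanking windows, 3 Mb singleton distance, 500
#' bootstrap replicates, and up to three mismatches plus three gaps per
#' e-PCR primer.
#'
#' @param strict_evalue,relaxed_evalue HMM search thresholds
#'   (`strict_evalue < relaxed_evalue`).
#' @param cc_prob_threshold,cc_validation_cutoff coiled-coil thresholds.
#' @param cluster_max_gap,flank_small,flank_large,singleton_min_dist bp.
#' @param bootstrap_replicates NJ bootstrap replicates.
#' @param partial_nbs_threshold NBS coverage below which a gene is PARTIAL.
#' @param epcr_max_mismatch,epcr_max_gaps per-primer e-PCR tolerances.
#' @param coverage_threshold reference coverage for pseudogene calling.
#' @param frameshift_penalty frame-switch cost in the pseudogene aligner.
#' @param n_null,null_length E-value calibration sample.
#' @param seed RNG seed for every stochastic step.
#' @return `nlr_pipeline_config` list.
#' @export
pipeline_config <- function(strict_evalue = 1e-60, relaxed_evalue = 1e-2,
                            cc_prob_threshold = 0.9,
                            cc_validation_cutoff = 0.025,
                            cluster_max_gap = 100000,
                            flank_small = 100000, flank_large = 200000,
                            singleton_min_dist = 3e6,
                            bootstrap_replicates = 500,
                            partial_nbs_threshold = 0.5,
                            epcr_max_mismatch = 3, epcr_max_gaps = 3,
                            coverage_threshold = 0.8,
                            frameshift_penalty = 12,
                            n_null = 1000, null_length = 350, seed = 1) {
  cfg <- list(strict_evalue = strict_evalue, relaxed_evalue = relaxed_evalue,
              cc_prob_threshold = cc_prob_threshold,
              cc_validation_cutoff = cc_validation_cutoff,
              cluster_max_gap = cluster_max_gap, flank_small = flank_small,
              flank_large = flank_large,
              singleton_min_dist = singleton_min_dist,
              bootstrap_replicates = bootstrap_replicates,
              partial_nbs_threshold = partial_nbs_threshold,
              epcr_max_mismatch = epcr_max_mismatch,
              epcr_max_gaps = epcr_max_gaps,
              coverage_threshold = coverage_threshold,
              frameshift_penalty = frameshift_penalty,
              n_null = n_null, null_length = null_length, seed = seed)
  num <- unlist(cfg[c("cc_prob_threshold", "cluster_max_gap", "flank_small",
                      "flank_large", "singleton_min_dist",
                      "bootstrap_replicates", "partial_nbs_threshold")])
  if (any(num <= 0)) stop("thresholds must be positive")
  if (!(strict_evalue < relaxed_evalue)) {
    stop("strict_evalue must be smaller than relaxed_evalue")
  }
  structure(cfg, class = "nlr_pipeline_config")
}

#' Run the full annotation pipeline
#'
#' Stages, in order: seed-model calibration, two-pass species refinement and
#' relaxed search, kinase exclusion, domain scans and architecture
#' classification, anchoring, cluster/singleton detection, flanking-window
#' ORF recovery of NBS-derived genes, pseudogene cause calling, and the
#' NBS-domain NJ phylogeny with bootstrap and clade labels.
#'
#' @param genome_dir directory containing `genome.fasta`, `genes.gff3`,
#'   `proteins.fasta` and `anchor.tsv` (as written by [generate_genome()]).
#' @param config [pipeline_config()].
#' @param out_dir optional directory for the result files (`arch_table.tsv`,
#'   `pseudo_table.tsv`, `clusters.bed`, `tree.nwk`, `candidates.tsv`,
#'   `nbs_derived.tsv`, `run.log`).
#' @return `nlr_pipeline` result bundle.
#' @export
run_pipeline <- function(genome_dir, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "nlr_pipeline_config"))
  paths <- list(genome = file.path(genome_dir, "genome.fasta"),
                gff = file.path(genome_dir, "genes.gff3"),
                proteins = file.path(genome_dir, "proteins.fasta"),
                anchor = file.path(genome_dir, "anchor.tsv"))
  missing <- !vapply(paths, file.exists, logical(1))
  if (any(missing)) {
    stop("missing input file(s): ",
         paste(unlist(paths)[missing], collapse = ", "))
  }
  log_lines <- c(sprintf("nlrscan pipeline, seed %d", config$seed),
                 sprintf("thresholds: %s",
                         paste(sprintf("%s=%g", names(unclass(config))[-18],
                                       unlist(unclass(config))[-18]),
                               collapse = " ")))

  genome <- read_fasta(paths$genome, alphabet = "dna")
  models <- read_gff3(paths$gff)
  proteins <- read_fasta(paths$proteins)
  anchor <- read_anchor_table(paths$anchor)
  scaffold_len <- stats::setNames(nchar(genome$seq), genome$id)

  # ---- stage 1-3: HMM search with refinement -------------------------------
  nbs_seed <- build_profile(seed_alignment("nbarc"), name = "NB-ARC")
  nbs_seed <- calibrate_evalue(nbs_seed, n_null = config$n_null,
                               null_length = config$null_length,
                               seed = derive_seed(config$seed, 11))
  kinase <- build_profile(seed_alignment("kinase"), name = "kinase")
  kinase <- calibrate_evalue(kinase, n_null = config$n_null,
                             null_length = config$null_length,
                             seed = derive_seed(config$seed, 12))
  refined <- refine_species_model(proteins, nbs_seed,
                                  strict = config$strict_evalue,
                                  relaxed = config$relaxed_evalue,
                                  seed = derive_seed(config$seed, 13))
  species <- refined$species_hmm
  log_lines <- c(log_lines,
                 sprintf("strict hits: %d; relaxed candidates: %d",
                         nrow(refined$stage1_hits), nrow(refined$hits)))

  # ---- stage 4: kinase exclusion ------------------------------------------
  kept <- kinase_filter(refined$hits, proteins, kinase)
  log_lines <- c(log_lines, sprintf("after kinase filter: %d", nrow(kept)))

  # ---- stage 5: domain architecture ---------------------------------------
  cand_prot <- proteins[match(kept$target_id, proteins$id), ]
  arch <- classify_architectures(cand_prot, coverage = kept, config = config)

  # map proteins to gene models
  gid <- models$gene_id[match(kept$target_id, models$protein_id)]
  span <- purrr::map(match(kept$target_id, models$protein_id), function(i) {
    range(models$cds[[i]])
  })
  candidates <- tibble::tibble(
    gene_id = gid, protein_id = kept$target_id,
    seqid = models$seqid[match(gid, models$gene_id)],
    start = vapply(span, min, 1), end = vapply(span, max, 1),
    strand = models$strand[match(gid, models$gene_id)],
    bits = kept$bits, evalue = kept$evalue, coverage = kept$coverage) %>%
    dplyr::left_join(dplyr::rename(arch, protein_id = "id"),
                     by = "protein_id")

  # ---- stage 6: anchoring, clusters, singletons ---------------------------
  anchored <- anchor_genes(candidates, anchor)
  cl <- detect_clusters(anchored, max_gap = config$cluster_max_gap)
  anchored <- cl$genes
  alone <- find_singletons(anchored, min_dist = config$singleton_min_dist)
  supers <- super_clusters(cl$clusters)

  # ---- stage 7: flanking windows and NBS-derived screen -------------------
  windows <- flanking_windows(
    dplyr::select(anchored, "gene_id", "seqid", "start", "end"),
    nbs_ids = anchored$gene_id, scaffold_lengths = scaffold_len,
    flank_small = config$flank_small, flank_large = config$flank_large)
  refs <- reference_r_proteins()
  orfs <- purrr::map(seq_len(nrow(windows)), function(w) {
    seg <- substr(genome$seq[genome$id == windows$seqid[w]],
                  windows$start[w], windows$end[w])
    o <- extract_orfs(seg, min_codons = 80)
    if (!nrow(o)) return(o)
    o$start <- o$start + windows$start[w] - 1
    o$end <- o$end + windows$start[w] - 1
    o$seqid <- windows$seqid[w]
    # drop ORFs overlapping annotated gene models on this scaffold
    g <- models[models$seqid == windows$seqid[w], ]
    gs <- vapply(g$cds, min, 1); ge <- vapply(g$cds, max, 1)
    keep <- vapply(seq_len(nrow(o)), function(k)
      !any(o$start[k] <= ge & o$end[k] >= gs), logical(1))
    o[keep, ]
  })
  orfs <- dplyr::bind_rows(orfs)
  nbs_derived <- if (nrow(orfs)) {
    screen_nbs_derived(orfs, refs, species,
                       partial_threshold = config$partial_nbs_threshold,
                       relaxed_evalue = config$relaxed_evalue)
  } else {
    dplyr::mutate(orfs, call = character(0))
  }
  nbs_derived <- dplyr::filter(nbs_derived, .data$call != "none")

  # ---- stage 8: pseudogene calls ------------------------------------------
  cand_dna <- vapply(seq_len(nrow(candidates)), function(i) {
    m <- models[models$protein_id == candidates$protein_id[i], ]
    spliced_cds(m, genome$seq[genome$id == m$seqid])
  }, character(1))
  pg_input <- dplyr::mutate(candidates, dna = cand_dna,
                            scaffold_length = scaffold_len[.data$seqid])
  reference_set <- intact_reference_set(candidates, cand_dna, refs)
  pg <- call_pseudogenes(
    dplyr::select(pg_input, "gene_id", "dna", "start", "end", "strand",
                  "scaffold_length"),
    reference_set, coverage_threshold = config$coverage_threshold,
    frameshift_penalty = config$frameshift_penalty)
  candidates <- dplyr::left_join(candidates, pg, by = "gene_id") %>%
    dplyr::mutate(pseudogene = !.data$cause %in% c("intact", "unclassifiable"))
  anchored <- dplyr::left_join(
    anchored, dplyr::select(pg, "gene_id", "cause"), by = "gene_id") %>%
    dplyr::mutate(pseudogene = !.data$cause %in% c("intact", "unclassifiable"))

  # ---- stage 9: phylogeny -------------------------------------------------
  phylo <- NULL
  clades <- NULL
  nbs_dom <- purrr::map_chr(seq_len(nrow(cand_prot)), function(i) {
    sd <- find_nbs_subdomains(cand_prot$seq[i])
    extract_nbs_domain(cand_prot$seq[i], sd)
  })
  keep <- !is.na(nbs_dom)
  if (sum(keep) >= 2) {
    ref_leaves <- c(ref_CC_I = nbs_consensus("cc1")$seq,
                    ref_CC_II = nbs_consensus("cc2")$seq,
                    ref_TIR = nbs_consensus("tir")$seq)
    aln_in <- tibble::tibble(
      id = c(cand_prot$id[keep], names(ref_leaves)),
      seq = c(nbs_dom[keep], unname(ref_leaves)))
    msa <- progressive_align(aln_in)
    msa <- trim_alignment_ends(msa)
    phylo <- bootstrap_support(msa, replicates = config$bootstrap_replicates,
                               seed = derive_seed(config$seed, 14))
    clades <- assign_clades(phylo, c(ref_CC_I = "CC_I", ref_CC_II = "CC_II",
                                     ref_TIR = "TIR"))
  }

  # ---- tables --------------------------------------------------------------
  arch_table <- architecture_summary(candidates)
  pseudo_table <- pseudogene_summary(anchored)

  result <- structure(list(
    config = config, proteins = proteins,
    seed_hmm = nbs_seed, species_hmm = species, kinase_hmm = kinase,
    stage1_hits = refined$stage1_hits, hits = refined$hits,
    candidates = candidates, anchored = anchored,
    clusters = cl$clusters, super_clusters = supers, alone = alone,
    windows = windows, nbs_derived = nbs_derived,
    tree = phylo, clades = clades,
    arch_table = arch_table, pseudo_table = pseudo_table,
    log = log_lines), class = "nlr_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(arch_table, file.path(out_dir, "arch_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pseudo_table, file.path(out_dir, "pseudo_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      dplyr::select(candidates, -dplyr::any_of(c("offsets"))),
      file.path(out_dir, "candidates.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(cl$clusters)) {
      write_bed(dplyr::transmute(cl$clusters, seqid = .data$chromosome,
                                 start = .data$span_start,
                                 end = .data$span_end,
                                 name = .data$cluster_id),
                file.path(out_dir, "clusters.bed"))
    }
    if (nrow(nbs_derived)) {
      utils::write.table(nbs_derived, file.path(out_dir, "nbs_derived.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(phylo)) write_newick(phylo, file.path(out_dir, "tree.nwk"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  result
}

# Intact alignment references: candidates whose CDS is in frame, stop-free
# and near full class length, plus the packaged full-length NLR references.
intact_reference_set <- function(candidates, cand_dna, packaged_refs) {
  prot <- sub("\\*$", "", vapply(cand_dna, translate_cds, character(1),
                                 USE.NAMES = FALSE))
  nlr_refs <- packaged_refs[startsWith(packaged_refs$description, "NLR"), ]
  ok <- vapply(seq_along(cand_dna), function(i) {
    if (nchar(cand_dna[i]) %% 3 != 0) return(FALSE)
    if (grepl("\\*", prot[i])) return(FALSE)
    shares <- vapply(nlr_refs$seq, function(r) kmer_share(prot[i], r),
                     numeric(1), USE.NAMES = FALSE)
    tpl_len <- nchar(nlr_refs$seq[which.max(shares)])
    nchar(prot[i]) >= 0.92 * tpl_len
  }, logical(1))
  dplyr::bind_rows(
    tibble::tibble(id = candidates$gene_id[ok], seq = prot[ok]),
    tibble::tibble(id = nlr_refs$id, seq = nlr_refs$seq))
}

#' @export
print.nlr_pipeline <- function(x, ...) {
  cat(sprintf(paste0("<nlr_pipeline> %d candidates (%d pseudogenes), ",
                     "%d clusters, %d NBS-derived calls\n"),
              nrow(x$candidates), sum(x$candidates$pseudogene, na.rm = TRUE),
              nrow(x$clusters), nrow(x$nbs_derived)))
  invisible(x)
}

#' Architecture count table with lineage subtotals
#'
#' @param records tibble with a `code` column (one row per gene).
#' @return tibble with one row per code, the CNL-type and TNL-type subtotals,
#'   the grand total, and the partial-NBS count.
#' @export
architecture_summary <- function(records) {
  cnl_codes <- c("CNL", "CN", "NL_CC", "N_CC")
  tnl_codes <- c("TNL", "TN", "NL_TIR", "N_TIR")
  cnt <- function(code) sum(records$code == code, na.rm = TRUE)
  counts <- vapply(c(cnl_codes, tnl_codes), cnt, integer(1))
  tibble::tibble(
    row = c(cnl_codes, "Total CNL type", tnl_codes, "Total TNL type",
            "Total", "Partial NBS genes"),
    count = unname(c(counts[cnl_codes], sum(counts[cnl_codes]),
                     counts[tnl_codes], sum(counts[tnl_codes]),
                     sum(counts), cnt("PARTIAL"))))
}

#' Per-chromosome pseudogene distribution table
#'
#' One row per chromosome plus a `-` row for unanchored genes and a `Total`
#' row; percentages are rounded half-up to two decimals.
#'
#' @param records tibble with `chromosome` (NA = unanchored) and `pseudogene`
#'   (logical).
#' @return tibble with `chromosome`, `total_genes`, `n_pseudogenes`,
#'   `percent`.
#' @export
pseudogene_summary <- function(records) {
  chr <- ifelse(is.na(records$chromosome), "-", records$chromosome)
  lv <- c(sort(unique(chr[chr != "-"])), if ("-" %in% chr) "-")
  rows <- purrr::map(lv, function(cc) {
    sel <- chr == cc
    tibble::tibble(chromosome = cc, total_genes = sum(sel),
                   n_pseudogenes = sum(records$pseudogene[sel], na.rm = TRUE))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_rows(out, tibble::tibble(
    chromosome = "Total", total_genes = nrow(records),
    n_pseudogenes = sum(records$pseudogene, na.rm = TRUE)))
  dplyr::mutate(out, percent = ifelse(.data$total_genes > 0,
                                      round_half_up(100 * .data$n_pseudogenes /
                                                      .data$total_genes, 2), 0))
}

#' Derived percentage at quoted precision
#'
#' @param numerator,denominator positive counts.
#' @param digits decimal places (rounded half-up).
#' @return numeric percentage.
#' @export
ratio_report <- function(numerator, denominator, digits = 1) {
  if (any(denominator == 0)) stop("zero denominator")
  round_half_up(100 * numerator / denominator, digits)
}

# Collapse near-duplicate binding ends at one physical site: admissible end
# positions closer than max_gaps + 2 describe the same hybridization; keep
# the fewest substitutions, then fewest gaps.
collapse_sites <- function(hits, max_gaps) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits[, "end"])
  hits <- hits[ord, , drop = FALSE]
  grp <- cumsum(c(1, diff(hits[, "end"]) > max_gaps + 1))
  keep <- vapply(split(seq_len(nrow(hits)), grp), function(idx) {
    h <- hits[idx, , drop = FALSE]
    idx[order(h[, "n_gap"], h[, "n_sub"], h[, "end"])[1]]
  }, integer(1))
  hits[sort(keep), , drop = FALSE]
}

#' Primer pairs of the alternative-splicing screen
#'
#' The three published primer pairs (Red, Black, Orange) used to probe a
#' TMV-resistance-gene homolog.
#'
#' @return tibble with `name`, `forward`, `reverse`.
#' @export
tmv_primers <- function() {
  tibble::tibble(
    name = c("Red", "Black", "Orange"),
    forward = c("TAATTGTATTCACGGAAGATTATGGA",
                "CTGCTGAAATACAGAATCTCATTGAT",
                "AGAATCTATTGAAGGGCTTGTTCTT"),
    reverse = c("TCAAGAACTACAAGATTTTCATGAGG",
                "ATTTGTTACTTTGTTCAGTGATCTGC",
                "GTCAATATTCACGGGGTCACTC"))
}

#' In-silico PCR primer screen
#'
#' Approximate primer matching with at most `max_mismatch` substitutions and
#' `max_gaps` indels per primer (counted separately): the forward primer on
#' the plus strand and the reverse-complemented reverse primer downstream
#' within `max_amplicon` define a predicted amplicon.
#'
#' @param primer_pairs tibble (`name`, `forward`, `reverse`), sequences 5'-3'.
#' @param templates tibble (`id`, `seq`) of DNA templates.
#' @param max_mismatch,max_gaps per-primer tolerances.
#' @param max_amplicon maximum product length (bp).
#' @return tibble: `primer`, `template`, `start`, `end`, `length`,
#'   `fwd_mismatch`, `fwd_gaps`, `rev_mismatch`, `rev_gaps`.
#' @export
epcr_screen <- function(primer_pairs, templates, max_mismatch = 3,
                        max_gaps = 3, max_amplicon = 5000) {
  stopifnot(all(nchar(primer_pairs$forward) >= 15),
            all(nchar(primer_pairs$reverse) >= 15),
            all(grepl("^[ACGT]+$", primer_pairs$forward)),
            all(grepl("^[ACGT]+$", primer_pairs$reverse)))
  out <- list()
  for (t in seq_len(nrow(templates))) {
    tmpl <- dna_to_int(templates$seq[t]) - 1L
    tmpl[is.na(tmpl)] <- 0L
    for (p in seq_len(nrow(primer_pairs))) {
      fwd <- dna_to_int(primer_pairs$forward[p]) - 1L
      rev <- dna_to_int(revcomp(primer_pairs$reverse[p])) - 1L
      fh <- collapse_sites(.cpp_epcr_scan(fwd, tmpl, max_mismatch, max_gaps),
                           max_gaps)
      rh <- collapse_sites(.cpp_epcr_scan(rev, tmpl, max_mismatch, max_gaps),
                           max_gaps)
      if (!nrow(fh) || !nrow(rh)) next
      for (i in seq_len(nrow(fh))) {
        ok <- rh[, "start"] > fh[i, "end"] &
          rh[, "end"] - fh[i, "start"] + 1 <= max_amplicon
        for (j in which(ok)) {
          out <- c(out, list(tibble::tibble(
            primer = primer_pairs$name[p], template = templates$id[t],
            start = unname(fh[i, "start"]), end = unname(rh[j, "end"]),
            length = unname(rh[j, "end"] - fh[i, "start"] + 1),
            fwd_mismatch = unname(fh[i, "n_sub"]),
            fwd_gaps = unname(fh[i, "n_gap"]),
            rev_mismatch = unname(rh[j, "n_sub"]),
            rev_gaps = unname(rh[j, "n_gap"]))))
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(primer = character(), template = character(),
                          start = integer(), end = integer(),
                          length = integer(), fwd_mismatch = integer(),
                          fwd_gaps = integer(), rev_mismatch = integer(),
                          rev_gaps = integer()))
  }
  dplyr::bind_rows(out)
}
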