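# Synthetic genomes with planted NLR truth. The generator emulates the
# structure of a draft plant genome as used for NLR surveys: pseudomolecules
# assembled from anchored scaffolds (plus deliberately unanchored scaffolds),
# NLR genes of all eight architecture codes arranged in physical clusters and
# singletons, pseudogenized copies with known lesions, NBS-derived and
# stress-response gene relics near clusters, protein-kinase decoys sharing
# the P-loop, and random background genes.

NLR_CLASS_CODES <- c("CNL", "CN", "NL_CC", "N_CC", "TNL", "TN", "NL_TIR", "N_TIR")

class_has <- function(code) {
  list(cc = code %in% c("CNL", "CN"),
       tir = code %in% c("TNL", "TN"),
       lrr = code %in% c("CNL", "NL_CC", "TNL", "NL_TIR"),
       lineage = if (code %in% c("TNL", "TN", "NL_TIR", "N_TIR")) "tir" else "cc")
}

# Class-level template pads, fixed by construction (deterministic).
class_pads <- local({
  cache <- list()
  function(code) {
    if (is.null(cache[[code]])) {
      k <- match(code, NLR_CLASS_CODES)
      cache[[code]] <<- with_seed(91820 + k, list(
        pad_a = random_protein(7), pad_b = random_protein(12),
        pad_n = random_protein(25), pad_c = random_protein(10),
        pad_d = random_protein(8), pad_e = random_protein(30),
        tail = random_protein(450)))
    }
    cache[[code]]
  }
})

# Assemble the class template and track absolute domain offsets.
build_nlr_template <- function(class_code, subtype = NULL, nrep = 8) {
  stopifnot(class_code %in% NLR_CLASS_CODES)
  h <- class_has(class_code)
  if (is.null(subtype)) subtype <- if (h$lineage == "tir") "tir" else "cc1"
  pads <- class_pads(class_code)
  nbs <- nbs_consensus(subtype)

  parts <- list(M = "M")
  if (h$cc) {
    parts <- c(parts, list(pad_a = pads$pad_a, cc = NLR_MOTIF$cc,
                           pad_b = pads$pad_b))
  } else if (h$tir) {
    parts <- c(parts, list(pad_a = pads$pad_a, tir = NLR_MOTIF$tir,
                           pad_b = pads$pad_b))
  } else {
    parts <- c(parts, list(pad_n = pads$pad_n))
  }
  parts <- c(parts, list(nbs = nbs$seq))
  if (h$lrr) {
    parts <- c(parts, list(pad_c = pads$pad_c,
                           lrr = strrep(NLR_MOTIF$lrr, nrep),
                           pad_d = pads$pad_d))
  } else {
    parts <- c(parts, list(pad_e = pads$pad_e))
  }
  lens <- vapply(parts, nchar, integer(1))
  offs <- cumsum(c(1L, lens))[seq_along(parts)]
  names(offs) <- names(parts)
  nbs_start <- offs[["nbs"]]
  nbs_end <- nbs_start + nchar(nbs$seq) - 1L
  target_len <- ceiling(2.6 * nbs_end) + 40L
  tail_len <- max(target_len - sum(lens), 60L)
  parts <- c(parts, list(tail = substr(pads$tail, 1, tail_len)))
  full_seq <- paste(unlist(parts), collapse = "")

  motifs <- nbs$offsets
  motifs$start <- motifs$start + nbs_start - 1L
  motifs$end <- motifs$end + nbs_start - 1L
  dom <- tibble::tibble(
    motif = c("cc", "tir", "lrr"),
    start = c(if (h$cc) offs[["cc"]] else NA_integer_,
              if (h$tir) offs[["tir"]] else NA_integer_,
              if (h$lrr) offs[["lrr"]] else NA_integer_),
    end = c(if (h$cc) offs[["cc"]] + 34L else NA_integer_,
            if (h$tir) offs[["tir"]] + nchar(NLR_MOTIF$tir) - 1L else NA_integer_,
            if (h$lrr) offs[["lrr"]] + nrep * nchar(NLR_MOTIF$lrr) - 1L
            else NA_integer_))
  offsets <- dplyr::bind_rows(motifs, dom[!is.na(dom$start), ])
  protected <- unlist(Map(seq.int, motifs$start, motifs$end))
  if (h$cc) protected <- c(protected, seq.int(offs[["cc"]], offs[["cc"]] + 34L))
  list(seq = full_seq, offsets = offsets, protected = protected,
       nbs_start = nbs_start, nbs_end = nbs_end, subtype = subtype,
       nrep = if (h$lrr) nrep else 0L)
}

#' Generate one synthetic NLR protein
#'
#' Builds the class template (domains in their strictly ordered arrangement)
#' and applies neutral substitution noise outside the invariant motif blocks
#' (the four NBS motifs and the coiled-coil heptads). Consumes the current
#' RNG stream.
#'
#' @param class_code one of the eight architecture codes.
#' @param subtype NBS lineage signature (`"cc1"`, `"cc2"`, `"tir"`; default
#'   matches the class lineage).
#' @param nrep LRR repeat count for LRR-bearing classes.
#' @param noise substitution rate outside protected positions.
#' @return list with `record` (tibble `id`,`seq`) and `truth` (tibble of
#'   domain offsets plus class metadata).
#' @export
generate_nlr_protein <- function(class_code, subtype = NULL, nrep = NULL,
                                 noise = 0.05) {
  if (!class_code %in% NLR_CLASS_CODES) {
    stop("unknown architecture code: ", class_code)
  }
  if (is.null(nrep)) nrep <- sample(4:12, 1)
  tpl <- build_nlr_template(class_code, subtype, nrep)
  seq <- mutate_protein(tpl$seq, noise, protect = tpl$protected)
  list(record = tibble::tibble(id = paste0("nlr_", class_code), seq = seq),
       truth = tibble::tibble(class_code = class_code, subtype = tpl$subtype,
                              nrep = tpl$nrep, length = nchar(seq),
                              nbs_start = tpl$nbs_start, nbs_end = tpl$nbs_end,
                              offsets = list(tpl$offsets)))
}

#' Plant a pseudogenizing lesion into an intact CDS
#'
#' @param cds_dna intact coding sequence (length divisible by 3, no internal
#'   stop codon, terminal stop allowed).
#' @param cause one of `"none"`, `"premature_stop"`, `"frameshift"`,
#'   `"deletion_partial"` (`"scaffold_end"` is only meaningful during genome
#'   assembly and raises an error here).
#' @param codon_range optional integer range restricting where the lesion may
#'   fall (1-based codons); defaults to any internal codon.
#' @return list with `dna`, `cause`, `breakpoint_codon` (NA when
#'   `cause = "none"`).
#' @export
plant_pseudogene <- function(cds_dna, cause, codon_range = NULL) {
  n <- nchar(cds_dna)
  stopifnot(n %% 3 == 0)
  ncod <- n %/% 3
  aa <- translate_cds(cds_dna)
  if (grepl("\\*", substr(aa, 1, ncod - 1))) stop("CDS has an internal stop")
  if (cause == "none") {
    return(list(dna = cds_dna, cause = "none", breakpoint_codon = NA_integer_))
  }
  if (cause == "scaffold_end") {
    stop("cause 'scaffold_end' requires genome assembly context")
  }
  rng <- if (is.null(codon_range)) c(2L, ncod - 2L) else as.integer(codon_range)
  if (cause == "premature_stop") {
    codon <- sample(seq(rng[1], rng[2]), 1)
    stopc <- sample(c("TAA", "TGA", "TAG"), 1)
    dna <- paste0(substr(cds_dna, 1, (codon - 1) * 3), stopc,
                  substr(cds_dna, codon * 3 + 1, n))
    return(list(dna = dna, cause = cause, breakpoint_codon = codon))
  }
  if (cause == "frameshift") {
    codon <- sample(seq(rng[1], rng[2]), 1)
    pos <- (codon - 1) * 3 + sample(1:3, 1)
    if (stats::runif(1) < 0.5) {
      dna <- paste0(substr(cds_dna, 1, pos), sample(c("A", "C", "G", "T"), 1),
                    substr(cds_dna, pos + 1, n))
    } else {
      dna <- paste0(substr(cds_dna, 1, pos - 1), substr(cds_dna, pos + 1, n))
    }
    return(list(dna = dna, cause = cause, breakpoint_codon = codon))
  }
  if (cause == "deletion_partial") {
    min_keep <- if (is.null(codon_range)) 2L else as.integer(codon_range[1])
    f_max <- min(0.6, 1 - min_keep / ncod)
    f <- stats::runif(1, 0.2, max(f_max, 0.21))
    keep <- floor(ncod * (1 - f))
    dna <- substr(cds_dna, 1, keep * 3)
    return(list(dna = dna, cause = cause, breakpoint_codon = keep + 1L))
  }
  stop("unknown pseudogene cause: ", cause)
}

#' Study-condition specification for the synthetic genome
#'
#' Defaults define the packaged study conditions: 60 NLR genes spanning all
#' eight architecture codes at roughly the CNL/TNL proportions seen in
#' Solanaceae surveys, 40% pseudogenized with a premature-stop-and-frameshift
#' dominated cause mix, 40 protein-kinase decoys, 200 background genes,
#' clusters of 2-8 genes on anchored scaffolds, and about 16% of NLRs on
#' unanchored scaffolds.
#'
#' @param class_counts named integer vector over the eight codes.
#' @param cluster_sizes sizes of the anchored clusters.
#' @param unanchored_clusters cluster sizes planted on unanchored scaffolds.
#' @param unanchored_singles singleton NLRs on unanchored scaffolds.
#' @param n_chromosomes,chromosome_length,scaffolds_per_chromosome genome
#'   shape (lengths in bp).
#' @param cluster_gap_range start-to-start gap range (bp) within clusters.
#' @param pseudogene_fraction fraction of NLR genes carrying a lesion.
#' @param cause_mix proportions over the four lesion causes (sums to 1).
#' @param n_kinase_decoys,n_background_genes decoy/background gene counts.
#' @param n_nbs_derived,n_partial_nbs,n_stress_like unannotated relic ORFs
#'   planted near clusters.
#' @param founder_noise,gene_noise substitution rates applied at the founder
#'   and gene level outside protected motif blocks.
#' @param seed RNG seed; equal specs and seeds give byte-identical output.
#' @return `nlr_synthetic_spec` list.
#' @export
synthetic_spec <- function(
    class_counts = c(CNL = 9, CN = 4, NL_CC = 23, N_CC = 15,
                     TNL = 4, TN = 2, NL_TIR = 2, N_TIR = 1),
    cluster_sizes = c(8, 6, 5, 5, 4, 3, 3, 2, 2),
    unanchored_clusters = c(4, 3),
    unanchored_singles = 3,
    n_chromosomes = 5,
    chromosome_length = 2.4e6,
    scaffolds_per_chromosome = 5,
    cluster_gap_range = c(8000, 30000),
    pseudogene_fraction = 0.4,
    cause_mix = c(premature_stop = 0.4, frameshift = 0.4,
                  deletion_partial = 0.15, scaffold_end = 0.05),
    n_kinase_decoys = 40,
    n_background_genes = 200,
    n_nbs_derived = 4,
    n_partial_nbs = 2,
    n_stress_like = 3,
    founder_noise = 0.05,
    gene_noise = 0.02,
    seed = 7) {
  stopifnot(all(names(class_counts) %in% NLR_CLASS_CODES),
            all(class_counts >= 0),
            pseudogene_fraction >= 0, pseudogene_fraction <= 1,
            abs(sum(cause_mix) - 1) < 1e-9,
            n_kinase_decoys >= 0, n_background_genes >= 0)
  total <- sum(class_counts)
  n_unanch <- sum(unanchored_clusters) + unanchored_singles
  n_clustered <- sum(cluster_sizes)
  if (total > 0 && total < n_clustered + n_unanch) {
    stop("class_counts too small for the cluster plan")
  }
  structure(list(
    class_counts = class_counts, cluster_sizes = cluster_sizes,
    unanchored_clusters = unanchored_clusters,
    unanchored_singles = unanchored_singles,
    n_chromosomes = n_chromosomes, chromosome_length = chromosome_length,
    scaffolds_per_chromosome = scaffolds_per_chromosome,
    cluster_gap_range = cluster_gap_range,
    pseudogene_fraction = pseudogene_fraction, cause_mix = cause_mix,
    n_kinase_decoys = n_kinase_decoys,
    n_background_genes = n_background_genes,
    n_nbs_derived = n_nbs_derived, n_partial_nbs = n_partial_nbs,
    n_stress_like = n_stress_like,
    founder_noise = founder_noise, gene_noise = gene_noise, seed = seed),
    class = "nlr_synthetic_spec")
}

# largest-remainder apportionment of n into proportions p (ties broken in
# declaration order)
apportion <- function(n, p) {
  q <- n * p / sum(p)
  f <- floor(q)
  rem <- n - sum(f)
  if (rem > 0) {
    ord <- order(-(q - f), seq_along(q))
    f[ord[seq_len(rem)]] <- f[ord[seq_len(rem)]] + 1
  }
  as.integer(f)
}

#' Generate a synthetic genome bundle
#'
#' Writes `genome.fasta` (scaffolds), `genes.gff3`, `proteins.fasta`
#' (annotation-style predicted proteins: translations up to the first stop),
#' `anchor.tsv` and `truth.tsv` into `out_dir`, all deterministically from
#' `spec$seed`.
#'
#' @param spec [synthetic_spec()].
#' @param out_dir output directory (created if needed).
#' @return `nlr_genome` list with file paths and the `truth` tibble.
#' @export
generate_genome <- function(spec = synthetic_spec(), out_dir = tempfile("genome")) {
  stopifnot(inherits(spec, "nlr_synthetic_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- with_seed(spec$seed, generate_genome_impl(spec, out_dir))
  res
}

generate_genome_impl <- function(spec, out_dir) {
  scaf_len <- round(spec$chromosome_length / spec$scaffolds_per_chromosome)
  # ---- scaffold plan ----
  scaffolds <- tibble::tibble()
  for (ch in seq_len(spec$n_chromosomes)) {
    for (k in seq_len(spec$scaffolds_per_chromosome)) {
      scaffolds <- dplyr::bind_rows(scaffolds, tibble::tibble(
        scaffold_id = sprintf("scaffold_%02d_%02d", ch, k),
        chromosome = sprintf("chr%02d", ch),
        chromosome_offset = (k - 1) * scaf_len,
        orientation = if (k == spec$scaffolds_per_chromosome) "-" else "+",
        scaffold_length = scaf_len, anchored = TRUE))
    }
  }
  un_lens <- c(rep(300000, length(spec$unanchored_clusters)),
               if (spec$unanchored_singles > 0) 200000 else NULL)
  for (u in seq_along(un_lens)) {
    scaffolds <- dplyr::bind_rows(scaffolds, tibble::tibble(
      scaffold_id = sprintf("scaffold_un_%02d", u), chromosome = NA_character_,
      chromosome_offset = NA_real_, orientation = "+",
      scaffold_length = un_lens[u], anchored = FALSE))
  }

  # ---- gene roster ----
  codes <- rep(names(spec$class_counts), spec$class_counts)
  n_nlr <- length(codes)
  genes <- tibble::tibble(
    gene_id = sprintf("gene%04d", seq_len(n_nlr)),
    class_code = sample(codes))
  # lineage subtypes: CC-lineage founders split between cc1 and cc2
  founders <- list()
  founder_key <- character(n_nlr)
  for (i in seq_len(n_nlr)) {
    code <- genes$class_code[i]
    h <- class_has(code)
    subtype <- if (h$lineage == "tir") "tir"
    else if (code %in% c("CNL", "NL_CC") && i %% 2 == 0) "cc2" else "cc1"
    key <- paste0(code, ".", subtype)
    if (is.null(founders[[key]])) {
      nrep <- sample(4:12, 1)
      tpl <- build_nlr_template(code, subtype, nrep)
      fseq <- mutate_protein(tpl$seq, spec$founder_noise, protect = tpl$protected)
      founders[[key]] <- c(tpl, list(founder_seq = fseq))
    }
    founder_key[i] <- key
  }
  genes$subtype <- sub("^.*\\.", "", founder_key)
  genes$protein <- vapply(seq_len(n_nlr), function(i) {
    f <- founders[[founder_key[i]]]
    mutate_protein(f$founder_seq, spec$gene_noise, protect = f$protected)
  }, character(1))
  genes$nbs_start <- vapply(founder_key, function(k) founders[[k]]$nbs_start, 1L)
  genes$nbs_end <- vapply(founder_key, function(k) founders[[k]]$nbs_end, 1L)
  genes$offsets <- purrr::map(founder_key, function(k) founders[[k]]$offsets)

  # ---- unit plan: clusters, unanchored units, singletons ----
  n_unanch <- sum(spec$unanchored_clusters) + spec$unanchored_singles
  n_clustered <- sum(spec$cluster_sizes)
  n_single <- n_nlr - n_clustered - n_unanch
  stopifnot(n_single >= 0)
  perm <- sample.int(n_nlr)
  take <- function(n) {
    out <- perm[seq_len(n)]; perm <<- perm[-seq_len(n)]; out
  }
  units <- list()
  for (s in spec$cluster_sizes) {
    units <- c(units, list(list(type = "cluster", members = take(s),
                                anchored = TRUE)))
  }
  for (s in spec$unanchored_clusters) {
    units <- c(units, list(list(type = "cluster", members = take(s),
                                anchored = FALSE)))
  }
  if (spec$unanchored_singles > 0) {
    units <- c(units, list(list(type = "spread", members = take(spec$unanchored_singles),
                                anchored = FALSE)))
  }
  for (i in seq_len(n_single)) {
    units <- c(units, list(list(type = "single", members = take(1),
                                anchored = TRUE)))
  }

  # ---- pseudogene plan ----
  n_pseudo <- floor(n_nlr * spec$pseudogene_fraction + 0.5)
  causes <- rep(names(spec$cause_mix), apportion(n_pseudo, spec$cause_mix))
  pseudo_idx <- sort(sample.int(n_nlr, n_pseudo))
  genes$cause <- "none"
  genes$cause[pseudo_idx] <- sample(causes)
  # the scaffold-end lesion must sit on a gene of its own anchored singleton
  anch_singles <- unlist(purrr::map(units, function(u)
    if (u$type == "single" && u$anchored) u$members else NULL))
  se_idx <- which(genes$cause == "scaffold_end")
  for (i in se_idx) {
    if (!(i %in% anch_singles)) {
      j <- anch_singles[!(anch_singles %in% se_idx)][1]
      if (is.na(j)) { genes$cause[i] <- "premature_stop"; next }
      tmp <- genes$cause[j]; genes$cause[j] <- "scaffold_end"; genes$cause[i] <- tmp
      se_idx <- which(genes$cause == "scaffold_end")
    }
  }

  # ---- scaffold assignment of units ----
  anch_scafs <- scaffolds$scaffold_id[scaffolds$anchored]
  # reserve the last chromosome for a lone singleton when possible
  last_chr <- sprintf("chr%02d", spec$n_chromosomes)
  reserve <- scaffolds$scaffold_id[scaffolds$anchored &
                                     scaffolds$chromosome == last_chr]
  main_scafs <- setdiff(anch_scafs, reserve)
  un_scafs <- scaffolds$scaffold_id[!scaffolds$anchored]
  anchored_units <- which(vapply(units, function(u) u$anchored, TRUE))
  unanch_units <- which(!vapply(units, function(u) u$anchored, TRUE))
  lone_unit <- NA_integer_
  singles <- which(vapply(units, function(u) u$type == "single" && u$anchored, TRUE))
  # keep the scaffold-end gene's unit off the reserved chromosome
  se_units <- which(vapply(units, function(u)
    any(genes$cause[u$members] == "scaffold_end"), TRUE))
  lone_cand <- setdiff(singles, se_units)
  if (length(reserve) && length(lone_cand)) lone_unit <- lone_cand[1]
  assign_tbl <- tibble::tibble(unit = integer(), scaffold_id = character())
  rest <- setdiff(anchored_units, lone_unit)
  if (length(rest) > length(main_scafs)) stop("requested genes exceed genome space")
  assign_tbl <- dplyr::bind_rows(
    assign_tbl,
    tibble::tibble(unit = rest, scaffold_id = main_scafs[seq_along(rest)]),
    if (!is.na(lone_unit)) tibble::tibble(unit = lone_unit, scaffold_id = reserve[1]),
    tibble::tibble(unit = unanch_units, scaffold_id = un_scafs[seq_along(unanch_units)]))

  # ---- place NLR genes on scaffolds ----
  placements <- tibble::tibble()
  genes$cluster_id <- NA_character_
  cl_counter <- 0
  for (r in seq_len(nrow(assign_tbl))) {
    u <- units[[assign_tbl$unit[r]]]
    sid <- assign_tbl$scaffold_id[r]
    slen <- scaffolds$scaffold_length[scaffolds$scaffold_id == sid]
    m <- u$members
    # anchored scaffolds keep wide margins so units on neighbouring
    # scaffolds can never chain across the pseudomolecule junction
    margin <- if (u$anchored) 120000 else 30000
    if (u$type == "cluster") {
      cl_counter <- cl_counter + 1
      cid <- sprintf("cluster%02d", cl_counter)
      genes$cluster_id[m] <- cid
      gaps <- if (length(m) > 1)
        round(stats::runif(length(m) - 1, spec$cluster_gap_range[1],
                           spec$cluster_gap_range[2])) else numeric(0)
      starts <- cumsum(c(0, gaps))
      hi <- slen - max(starts) - margin
      if (hi <= margin) stop("requested genes exceed genome space")
      starts <- round(stats::runif(1, margin, hi)) + starts
    } else if (u$type == "spread") {
      starts <- round(seq(20000, slen - 20000, length.out = length(m)))
    } else {
      starts <- round(stats::runif(1, margin, slen - margin))
    }
    placements <- dplyr::bind_rows(placements, tibble::tibble(
      gene = m, scaffold_id = sid, planned_start = round(starts)))
  }
  genes$scaffold_id <- NA_character_
  genes$planned_start <- NA_real_
  if (nrow(placements)) {
    genes$scaffold_id[placements$gene] <- placements$scaffold_id
    genes$planned_start[placements$gene] <- placements$planned_start
  }

  # ---- lesions, CDS and final coordinates ----
  genes$strand <- sample(c("+", "-"), n_nlr, replace = TRUE)
  genes$breakpoint <- NA_integer_
  genes$dna <- NA_character_
  for (i in seq_len(n_nlr)) {
    cds <- backtranslate(genes$protein[i])
    ncod <- nchar(cds) %/% 3
    rng <- c(genes$nbs_end[i] + 15L, ncod - 30L)
    cause <- genes$cause[i]
    if (cause %in% c("none", "scaffold_end")) {
      genes$dna[i] <- cds
    } else {
      lesion <- plant_pseudogene(cds, cause, codon_range = rng)
      genes$dna[i] <- lesion$dna
      genes$breakpoint[i] <- lesion$breakpoint_codon
    }
  }
  # scaffold-end genes: truncate and pin to the scaffold terminus
  for (i in which(genes$cause == "scaffold_end")) {
    ncod <- nchar(genes$dna[i]) %/% 3
    cut <- sample(seq(genes$nbs_end[i] + 20L, ncod - 30L), 1)
    genes$dna[i] <- substr(genes$dna[i], 1, cut * 3)
    genes$breakpoint[i] <- cut + 1L
    genes$strand[i] <- "+"
    slen <- scaffolds$scaffold_length[scaffolds$scaffold_id == genes$scaffold_id[i]]
    genes$planned_start[i] <- slen - nchar(genes$dna[i]) + 1
  }
  genes$start <- as.integer(genes$planned_start)
  genes$end <- as.integer(genes$start + nchar(genes$dna) - 1L)
  genes$role <- "nlr"

  # ---- decoys and background genes ----
  extra <- tibble::tibble()
  if (spec$n_kinase_decoys > 0) {
    kin_tpl <- with_seed(55901, paste0("M", NLR_MOTIF$ploop,
                                       random_protein(20), NLR_MOTIF$kinase,
                                       random_protein(160)))
    extra <- dplyr::bind_rows(extra, tibble::tibble(
      gene_id = sprintf("kin%04d", seq_len(spec$n_kinase_decoys)),
      protein = vapply(seq_len(spec$n_kinase_decoys), function(i)
        mutate_protein(kin_tpl, spec$founder_noise,
                       protect = seq(2, 13)), character(1)),
      role = "kinase_decoy"))
  }
  if (spec$n_background_genes > 0) {
    extra <- dplyr::bind_rows(extra, tibble::tibble(
      gene_id = sprintf("bgd%04d", seq_len(spec$n_background_genes)),
      protein = vapply(seq_len(spec$n_background_genes), function(i)
        paste0("M", random_protein(round(stats::runif(1, 180, 320)))),
        character(1)),
      role = "background"))
  }
  if (nrow(extra)) {
    extra$dna <- vapply(extra$protein, backtranslate, character(1),
                        USE.NAMES = FALSE)
    extra$strand <- sample(c("+", "-"), nrow(extra), replace = TRUE)
  }

  # ---- occupancy bookkeeping ----
  occupied <- list()
  for (sid in scaffolds$scaffold_id) occupied[[sid]] <- matrix(numeric(0), 0, 2)
  note <- function(sid, s, e) {
    occupied[[sid]] <<- rbind(occupied[[sid]], c(s - 3000, e + 3000))
  }
  is_free <- function(sid, s, e) {
    occ <- occupied[[sid]]
    !nrow(occ) || all(e < occ[, 1] | s > occ[, 2])
  }
  for (i in seq_len(n_nlr)) note(genes$scaffold_id[i], genes$start[i], genes$end[i])

  # ---- relic ORFs near clusters (unannotated) ----
  relics <- tibble::tibble()
  clusters_anch <- assign_tbl$unit[vapply(assign_tbl$unit, function(k)
    units[[k]]$type == "cluster", TRUE)]
  relic_specs <- c(rep("nbs_derived", spec$n_nbs_derived),
                   rep("partial_nbs", spec$n_partial_nbs),
                   rep("stress_like", spec$n_stress_like))
  stress_tpl <- with_seed(77121, paste0("M", random_protein(260)))
  if (length(relic_specs) && length(clusters_anch)) {
    host_units <- sample(clusters_anch, length(relic_specs), replace = TRUE)
    for (k in seq_along(relic_specs)) {
      kind <- relic_specs[k]
      uidx <- host_units[k]
      sid <- assign_tbl$scaffold_id[assign_tbl$unit == uidx]
      m <- units[[uidx]]$members
      tpl <- build_nlr_template("CNL", "cc1", nrep = 8)
      prot <- if (kind == "nbs_derived") {
        paste0(substr(tpl$seq, 1, tpl$nbs_start - 1),
               substr(tpl$seq, tpl$nbs_end + 1, nchar(tpl$seq)))
      } else if (kind == "partial_nbs") {
        paste0(substr(tpl$seq, 1, tpl$nbs_start + 49),
               substr(tpl$seq, tpl$nbs_end + 1, nchar(tpl$seq)))
      } else {
        stress_tpl
      }
      prot <- mutate_protein(prot, 0.03)
      prot <- paste0("M", sub("^M", "", prot))
      dna <- backtranslate(prot)
      span <- range(genes$start[m])
      pos <- NA_integer_
      for (try in 1:100) {
        cand <- round(span[1] + stats::runif(1, -50000, -8000))
        if (cand > 1000 && is_free(sid, cand, cand + nchar(dna) - 1)) {
          pos <- cand; break
        }
      }
      if (is.na(pos)) stop("requested genes exceed genome space")
      note(sid, pos, pos + nchar(dna) - 1)
      relics <- dplyr::bind_rows(relics, tibble::tibble(
        gene_id = sprintf("relic%02d", k), role = kind, scaffold_id = sid,
        start = pos, protein = prot, dna = dna, strand = "+"))
    }
    relics$end <- relics$start + nchar(relics$dna) - 1L
  }
  if (nrow(extra)) {
    extra$scaffold_id <- NA_character_
    extra$start <- NA_integer_
    for (i in seq_len(nrow(extra))) {
      len <- nchar(extra$dna[i])
      for (try in 1:200) {
        sid <- sample(scaffolds$scaffold_id, 1)
        slen <- scaffolds$scaffold_length[scaffolds$scaffold_id == sid]
        pos <- round(stats::runif(1, 1000, slen - len - 1000))
        if (is_free(sid, pos, pos + len - 1)) {
          extra$scaffold_id[i] <- sid
          extra$start[i] <- pos
          note(sid, pos, pos + len - 1)
          break
        }
      }
      if (is.na(extra$start[i])) stop("requested genes exceed genome space")
    }
    extra$end <- extra$start + nchar(extra$dna) - 1L
  }

  # ---- assemble scaffold sequences ----
  seqs <- stats::setNames(vector("list", nrow(scaffolds)), scaffolds$scaffold_id)
  for (r in seq_len(nrow(scaffolds))) {
    seqs[[r]] <- random_dna(scaffolds$scaffold_length[r])
  }
  insert <- function(sid, s, dna, strand) {
    d <- if (strand == "-") revcomp(dna) else dna
    x <- seqs[[sid]]
    substr(x, s, s + nchar(d) - 1) <- d
    seqs[[sid]] <<- x
  }
  for (i in seq_len(n_nlr)) {
    insert(genes$scaffold_id[i], genes$start[i], genes$dna[i], genes$strand[i])
  }
  if (nrow(extra)) for (i in seq_len(nrow(extra)))
    insert(extra$scaffold_id[i], extra$start[i], extra$dna[i], extra$strand[i])
  if (nrow(relics)) for (i in seq_len(nrow(relics)))
    insert(relics$scaffold_id[i], relics$start[i], relics$dna[i], relics$strand[i])

  # ---- annotation-style predicted proteins ----
  predicted <- function(dna) {
    aa <- translate_cds(dna)
    sub("\\*.*$", "", aa)
  }
  annotated <- dplyr::bind_rows(
    dplyr::transmute(genes, gene_id = .data$gene_id, seqid = .data$scaffold_id,
                     start = .data$start, end = .data$end,
                     strand = .data$strand, dna = .data$dna,
                     role = .data$role),
    if (nrow(extra)) dplyr::transmute(extra, gene_id = .data$gene_id,
                                      seqid = .data$scaffold_id,
                                      start = .data$start, end = .data$end,
                                      strand = .data$strand, dna = .data$dna,
                                      role = .data$role))
  annotated$protein_id <- paste0(annotated$gene_id, ".p1")
  annotated$protein <- vapply(annotated$dna, predicted, character(1),
                              USE.NAMES = FALSE)

  # ---- write outputs ----
  paths <- list(
    genome = file.path(out_dir, "genome.fasta"),
    gff = file.path(out_dir, "genes.gff3"),
    proteins = file.path(out_dir, "proteins.fasta"),
    anchor = file.path(out_dir, "anchor.tsv"),
    truth = file.path(out_dir, "truth.tsv"))
  write_fasta(tibble::tibble(id = scaffolds$scaffold_id, seq = unlist(seqs)),
              paths$genome)
  models <- tibble::tibble(
    gene_id = annotated$gene_id,
    mrna_id = paste0(annotated$gene_id, ".m1"),
    protein_id = annotated$protein_id,
    seqid = annotated$seqid, strand = annotated$strand,
    exons = purrr::map2(annotated$start, annotated$end,
                        function(s, e) cbind(start = s, end = e)),
    cds = purrr::map2(annotated$start, annotated$end,
                      function(s, e) cbind(start = s, end = e)))
  write_gff3(models, paths$gff)
  write_fasta(tibble::tibble(id = annotated$protein_id,
                             description = annotated$gene_id,
                             seq = annotated$protein), paths$proteins)
  anchor <- scaffolds[scaffolds$anchored,
                      c("scaffold_id", "chromosome", "chromosome_offset",
                        "orientation", "scaffold_length")]
  write_anchor_table(anchor, paths$anchor)

  truth <- dplyr::bind_rows(
    tibble::tibble(
      gene_id = genes$gene_id, role = "nlr", class_code = genes$class_code,
      subtype = genes$subtype, scaffold_id = genes$scaffold_id,
      start = genes$start, end = genes$end, strand = genes$strand,
      cluster_id = genes$cluster_id, cause = genes$cause,
      breakpoint_codon = genes$breakpoint,
      nbs_start = genes$nbs_start, nbs_end = genes$nbs_end,
      protein_id = paste0(genes$gene_id, ".p1")),
    if (nrow(extra)) tibble::tibble(
      gene_id = extra$gene_id, role = extra$role, class_code = NA_character_,
      subtype = NA_character_, scaffold_id = extra$scaffold_id,
      start = extra$start, end = extra$end, strand = extra$strand,
      cluster_id = NA_character_, cause = NA_character_,
      breakpoint_codon = NA_integer_, nbs_start = NA_integer_,
      nbs_end = NA_integer_, protein_id = paste0(extra$gene_id, ".p1")),
    if (nrow(relics)) tibble::tibble(
      gene_id = relics$gene_id, role = relics$role, class_code = NA_character_,
      subtype = NA_character_, scaffold_id = relics$scaffold_id,
      start = relics$start, end = relics$end, strand = relics$strand,
      cluster_id = NA_character_, cause = NA_character_,
      breakpoint_codon = NA_integer_, nbs_start = NA_integer_,
      nbs_end = NA_integer_, protein_id = NA_character_))
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  structure(list(dir = out_dir, paths = paths, truth = truth, spec = spec),
            class = "nlr_genome")
}

#' @export
print.nlr_genome <- function(x, ...) {
  cat(sprintf("<nlr_genome> %s\n  %d truth records (%d NLR genes)\n",
              x$dir, nrow(x$truth), sum(x$truth$role == "nlr")))
  invisible(x)
}
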