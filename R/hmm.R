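# Profile hidden Markov models of protein domains: construction from a seed
# alignment, local Viterbi search, empirical Gumbel E-value calibration, the
# two-pass species-specific refinement, and the protein-kinase exclusion
# filter.

#' Build a profile HMM from a multiple alignment
#'
#' Columns whose gap fraction is at most `match_gap_threshold` become match
#' states. Emissions and transitions are estimated by maximum likelihood with
#' Laplace pseudocounts; the background is the packaged Robinson-Robinson
#' frequency set. Model structure is Plan7-like (match/insert/delete, no
#' insert-delete transitions) with uniform local entry over match states.
#'
#' @param msa tibble with columns `id`, `seq` (aligned rows, `-` gaps) or a
#'   character vector of aligned rows.
#' @param match_gap_threshold maximum gap fraction for a match column.
#' @param pseudocount Laplace pseudocount added to emission and transition
#'   counts.
#' @param name model name.
#' @return object of class `nlr_profile_hmm` with fields `M`, `emit`
#'   (match-emission probabilities), `emit_lo`/`trans_lo` (log2 scores),
#'   `bg`, and `calibration` (`NULL` until [calibrate_evalue()]).
#' @export
build_profile <- function(msa, match_gap_threshold = 0.5, pseudocount = 1,
                          name = "profile") {
  seqs <- if (is.data.frame(msa)) msa$seq else msa
  if (length(seqs) < 1) stop("empty alignment")
  if (length(unique(nchar(seqs))) != 1) stop("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  gapf <- colMeans(mat == "-" | mat == ".")
  match_cols <- which(gapf <= match_gap_threshold)
  M <- length(match_cols)
  if (M < 2) stop("fewer than 2 match columns; all columns gapped?")

  # emissions
  emit <- matrix(pseudocount, M, 20, dimnames = list(NULL, AA_ALPHABET20))
  for (k in seq_len(M)) {
    col <- mat[, match_cols[k]]
    cnt <- table(factor(col[col %in% AA_ALPHABET20], levels = AA_ALPHABET20))
    emit[k, ] <- emit[k, ] + as.numeric(cnt)
  }
  emit <- emit / rowSums(emit)

  # transitions: walk each row through its M/I/D state sequence
  trans_counts <- matrix(pseudocount, M, 7,
                         dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                                 "DM", "DD")))
  is_match_col <- seq_len(ncol(mat)) %in% match_cols
  pos_of_col <- cumsum(is_match_col) # model position at/before each column
  for (r in seq_len(nrow(mat))) {
    prev_state <- "B"; prev_pos <- 0L
    for (cidx in seq_len(ncol(mat))) {
      res <- mat[r, cidx]
      if (is_match_col[cidx]) {
        state <- if (res == "-" || res == ".") "D" else "M"
        pos <- pos_of_col[cidx]
      } else {
        if (res == "-" || res == ".") next
        state <- "I"; pos <- pos_of_col[cidx]
      }
      key <- paste0(prev_state, state)
      if (key %in% colnames(trans_counts) && prev_pos >= 1 && prev_pos < M) {
        trans_counts[prev_pos, key] <- trans_counts[prev_pos, key] + 1
      }
      prev_state <- state; prev_pos <- pos
    }
  }
  norm <- function(cols) {
    tt <- trans_counts[, cols, drop = FALSE]
    tt / pmax(rowSums(tt), .Machine$double.eps)
  }
  trans <- cbind(norm(c("MM", "MI", "MD")), norm(c("IM", "II")),
                 norm(c("DM", "DD")))
  trans <- trans[, c("MM", "MI", "MD", "IM", "II", "DM", "DD")]

  hmm <- structure(list(
    M = M, emit = emit,
    emit_lo = log2(sweep(emit, 2, ROBINSON_BG, "/")),
    trans_lo = log2(trans),
    bg = ROBINSON_BG, name = name, calibration = NULL,
    consensus = paste(AA_ALPHABET20[apply(emit, 1, which.max)], collapse = "")),
    class = "nlr_profile_hmm")
  hmm
}

#' @export
print.nlr_profile_hmm <- function(x, ...) {
  cat(sprintf("<nlr_profile_hmm '%s'> M = %d match states, %s\n", x$name, x$M,
              if (is.null(x$calibration)) "uncalibrated"
              else sprintf("Gumbel(mu = %.2f, lambda = %.3f)",
                           x$calibration$mu, x$calibration$lambda)))
  invisible(x)
}

#' Local Viterbi alignment of a protein to a profile HMM
#'
#' Smith-Waterman-style local profile alignment: the path starts and ends in
#' a match state, unaligned flanks are free, and the bit score is the log2
#' odds of the best path against the background model. Residues outside the
#' 20-letter alphabet are scored as background (zero log-odds).
#'
#' @param hmm `nlr_profile_hmm`.
#' @param protein amino-acid string.
#' @return list with `score` (bits), `t_start`/`t_end` (envelope on the
#'   protein, 1-based inclusive), `m_start`/`m_end` (model envelope),
#'   `n_match`, and `path` (tibble of state/model/seq indices).
#' @export
viterbi <- function(hmm, protein) {
  stopifnot(inherits(hmm, "nlr_profile_hmm"), nchar(protein) >= 1)
  seq_int <- aa_to_int(protein)
  if (anyNA(seq_int)) {
    warning("residues outside the amino-acid alphabet scored as background")
  }
  seq0 <- ifelse(is.na(seq_int), -1L, seq_int - 1L)
  res <- .cpp_viterbi(hmm$emit_lo, hmm$trans_lo, as.integer(seq0),
                      entry = log2(1 / hmm$M))
  res$path <- tibble::tibble(
    state = c("M", "I", "D")[res$path_state + 1L],
    model = res$path_model, seq = res$path_seq)
  res$path_state <- res$path_model <- res$path_seq <- NULL
  res
}

#' Calibrate E-values for a profile HMM
#'
#' Fits a Gumbel (type-I extreme value) distribution by maximum likelihood to
#' the local Viterbi bit scores of i.i.d. background sequences. E-values are
#' then `n_targets * P(S >= s)` under the fitted null.
#'
#' @param hmm `nlr_profile_hmm`.
#' @param n_null number of null sequences.
#' @param null_length length of each null sequence.
#' @param seed RNG seed (calibration is deterministic given the seed).
#' @return the HMM with its `calibration` field set (`mu`, `lambda`,
#'   `n_null`, `null_length`, `seed`).
#' @export
calibrate_evalue <- function(hmm, n_null = 1000, null_length = 350, seed = 1) {
  scores <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      s <- random_protein(null_length)
      viterbi(hmm, s)$score
    }, numeric(1))
  })
  if (stats::sd(scores) < 1e-9) stop("degenerate null score distribution")
  fit <- fit_gumbel(scores)
  hmm$calibration <- list(mu = fit$mu, lambda = fit$lambda, n_null = n_null,
                          null_length = null_length, seed = seed)
  hmm
}

# Maximum-likelihood Gumbel fit (location mu, scale 1/lambda).
fit_gumbel <- function(x) {
  lam0 <- pi / (stats::sd(x) * sqrt(6))
  mu0 <- mean(x) - 0.5772156649 / lam0
  nll <- function(p) {
    lam <- exp(p[2])
    z <- lam * (x - p[1])
    -sum(log(lam) - z - exp(-z))
  }
  opt <- stats::optim(c(mu0, log(lam0)), nll, method = "Nelder-Mead")
  list(mu = opt$par[1], lambda = exp(opt$par[2]))
}

#' Gumbel tail probability and E-value
#'
#' @param hmm calibrated `nlr_profile_hmm`.
#' @param score bit score(s).
#' @param n_targets database size the E-value refers to.
#' @return numeric E-value(s): `n_targets * P(S >= score)`.
#' @export
hmm_evalue <- function(hmm, score, n_targets) {
  cal <- hmm$calibration
  if (is.null(cal)) stop("model is not calibrated; run calibrate_evalue()")
  p <- -expm1(-exp(-cal$lambda * (score - cal$mu)))
  n_targets * p
}

#' Search a proteome with a calibrated profile HMM
#'
#' @param hmm calibrated `nlr_profile_hmm`.
#' @param proteins tibble with `id`, `seq` (as from [read_fasta()]).
#' @param evalue_threshold report hits with E-value at or below this.
#' @param n_targets database size for the E-value (defaults to
#'   `nrow(proteins)`).
#' @return tibble of hits sorted by E-value (ties by `target_id`):
#'   `target_id`, `bits`, `evalue`, envelope columns and `nbs_coverage`
#'   (matched fraction of model length).
#' @export
search_proteome <- function(hmm, proteins, evalue_threshold = 1e-2,
                            n_targets = nrow(proteins)) {
  if (nrow(proteins) == 0) {
    return(tibble::tibble(target_id = character(), bits = numeric(),
                          evalue = numeric(), t_start = integer(),
                          t_end = integer(), m_start = integer(),
                          m_end = integer(), coverage = numeric()))
  }
  hits <- purrr::map(seq_len(nrow(proteins)), function(i) {
    v <- suppressWarnings(viterbi(hmm, proteins$seq[i]))
    tibble::tibble(target_id = proteins$id[i], bits = v$score,
                   evalue = hmm_evalue(hmm, v$score, n_targets),
                   t_start = v$t_start, t_end = v$t_end,
                   m_start = v$m_start, m_end = v$m_end,
                   coverage = v$n_match / hmm$M)
  })
  out <- dplyr::bind_rows(hits)
  out <- dplyr::filter(out, .data$evalue <= evalue_threshold)
  dplyr::arrange(out, .data$evalue, .data$target_id)
}

#' Two-pass species-specific model refinement
#'
#' Stage 1 searches the proteome with the seed model at the strict threshold;
#' stage 2 aligns the envelope regions of the strict hits and rebuilds a
#' species-specific model (recalibrated); stage 3 re-searches the full
#' proteome with the species model at the relaxed threshold.
#'
#' @param proteins proteome tibble (`id`, `seq`).
#' @param seed_hmm calibrated seed model.
#' @param strict,relaxed E-value thresholds for the two passes.
#' @param seed RNG seed for the recalibration.
#' @return list with `species_hmm`, `hits` (stage-3 candidates) and
#'   `stage1_hits`.
#' @export
refine_species_model <- function(proteins, seed_hmm, strict = 1e-60,
                                 relaxed = 1e-2, seed = 1) {
  stopifnot(strict < relaxed)
  stage1 <- search_proteome(seed_hmm, proteins, strict)
  if (nrow(stage1) < 2) {
    warning("fewer than 2 strict hits; falling back to the seed model")
    return(list(species_hmm = seed_hmm,
                hits = search_proteome(seed_hmm, proteins, relaxed),
                stage1_hits = stage1))
  }
  env <- stage1 %>%
    dplyr::left_join(proteins, by = c(target_id = "id")) %>%
    dplyr::mutate(domain = substr(.data$seq, .data$t_start, .data$t_end))
  msa <- progressive_align(tibble::tibble(id = env$target_id, seq = env$domain))
  species <- build_profile(msa, name = paste0(seed_hmm$name, "-species"))
  species <- calibrate_evalue(species,
                              n_null = seed_hmm$calibration$n_null,
                              null_length = seed_hmm$calibration$null_length,
                              seed = derive_seed(seed, 1))
  list(species_hmm = species,
       hits = search_proteome(species, proteins, relaxed),
       stage1_hits = stage1)
}

#' Exclude protein-kinase false positives
#'
#' NB-ARC and protein-kinase domains share the P-loop; candidates scoring
#' higher against the kinase model than against the NBS model are removed.
#'
#' @param candidate_hits hit tibble from [search_proteome()] (NBS bits in
#'   `bits`).
#' @param proteins proteome tibble.
#' @param kinase_hmm calibrated kinase model.
#' @return retained hits with an added `kinase_bits` column.
#' @export
kinase_filter <- function(candidate_hits, proteins, kinase_hmm) {
  if (nrow(candidate_hits) == 0) {
    return(dplyr::mutate(candidate_hits, kinase_bits = numeric(0)))
  }
  seqs <- proteins$seq[match(candidate_hits$target_id, proteins$id)]
  kb <- vapply(seqs, function(s) suppressWarnings(viterbi(kinase_hmm, s)$score),
               numeric(1), USE.NAMES = FALSE)
  out <- dplyr::mutate(candidate_hits, kinase_bits = kb)
  dplyr::filter(out, .data$kinase_bits <= .data$bits)
}

# --- model serialization (versioned TSV sections) ---------------------------

#' Write / read a profile HMM in the package's TSV format
#'
#' Plain-text serialization with sections `HEADER`, `EMIT-M`, `TRANS` and
#' `CALIB`.
#'
#' @param hmm `nlr_profile_hmm`. @param path file path.
#' @return `path` (write) or the model (read).
#' @export
write_profile_hmm <- function(hmm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#nlrscan-profile\tv1",
               sprintf("HEADER\tname=%s\tM=%d", hmm$name, hmm$M)), con)
  writeLines("EMIT-M", con)
  utils::write.table(format(hmm$emit, digits = 10), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines("TRANS", con)
  utils::write.table(format(2^hmm$trans_lo, digits = 10), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(hmm$calibration)) {
    writeLines(sprintf("CALIB\tmu=%.8g\tlambda=%.8g\tn_null=%d\tnull_length=%d\tseed=%d",
                       hmm$calibration$mu, hmm$calibration$lambda,
                       hmm$calibration$n_null, hmm$calibration$null_length,
                       as.integer(hmm$calibration$seed)), con)
  }
  invisible(path)
}

#' @rdname write_profile_hmm
#' @export
read_profile_hmm <- function(path) {
  lines <- readLines(path)
  stopifnot(startsWith(lines[1], "#nlrscan-profile"))
  hdr <- strsplit(lines[2], "\t")[[1]]
  name <- sub("^name=", "", hdr[2])
  M <- as.integer(sub("^M=", "", hdr[3]))
  iE <- which(lines == "EMIT-M"); iT <- which(lines == "TRANS")
  emit <- as.matrix(utils::read.delim(text = lines[(iE + 1):(iE + 1 + M)]))
  trans <- as.matrix(utils::read.delim(text = lines[(iT + 1):(iT + 1 + M)]))
  hmm <- structure(list(
    M = M, emit = emit,
    emit_lo = log2(sweep(emit, 2, ROBINSON_BG, "/")),
    trans_lo = log2(trans), bg = ROBINSON_BG, name = name,
    calibration = NULL,
    consensus = paste(AA_ALPHABET20[apply(emit, 1, which.max)], collapse = "")),
    class = "nlr_profile_hmm")
  iC <- which(startsWith(lines, "CALIB"))
  if (length(iC)) {
    kv <- strsplit(lines[iC], "\t")[[1]][-1]
    vals <- stats::setNames(as.numeric(sub("^[a-z_]+=", "", kv)),
                            sub("=.*$", "", kv))
    hmm$calibration <- as.list(vals)
  }
  hmm
}
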