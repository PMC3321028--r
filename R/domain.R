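# Domain-architecture classification: PSSM window scans (TIR, LRR, NBS
# subdomains), coiled-coil heptad scoring, the kinase-2 NBS signature, the
# eight-way architecture call, and EM motif discovery.

#' Scan a protein with a PSSM
#'
#' Scores every window and reports non-overlapping hits at or above the PSSM
#' threshold, selected greedily by score (ties to the leftmost window).
#'
#' @param protein amino-acid string.
#' @param pssm `nlr_pssm`.
#' @return tibble with `kind`, `start`, `end` (1-based inclusive), `score`.
#' @export
scan_pssm <- function(protein, pssm) {
  W <- pssm$width
  L <- nchar(protein)
  empty <- tibble::tibble(kind = character(), start = integer(),
                          end = integer(), score = numeric())
  if (L < W) return(empty)
  s <- aa_to_int(protein)
  n <- L - W + 1
  scores <- numeric(n)
  for (w in seq_len(W)) {
    res <- s[w:(w + n - 1)]
    add <- pssm$log_odds[w, ]
    contrib <- ifelse(is.na(res), 0, add[res])
    scores <- scores + contrib
  }
  cand <- which(scores >= pssm$threshold)
  if (!length(cand)) return(empty)
  ord <- cand[order(-scores[cand], cand)]
  taken <- logical(L)
  keep <- integer()
  for (p in ord) {
    if (!any(taken[p:(p + W - 1)])) {
      keep <- c(keep, p)
      taken[p:(p + W - 1)] <- TRUE
    }
  }
  keep <- sort(keep)
  tibble::tibble(kind = pssm$name, start = keep, end = keep + W - 1L,
                 score = scores[keep])
}

#' Coiled-coil detection by heptad sliding-window scoring
#'
#' Each window of `window` residues is scored under the packaged heptad
#' propensity table at its best of the seven register phases; the score maps
#' to a probability through a logistic, each residue takes the maximum
#' probability over covering windows, and maximal runs at or above
#' `prob_threshold` are reported as coiled-coil segments. Segments whose peak
#' probability also clears `1 - validation_cutoff` carry `validated = TRUE`
#' (the two published-threshold semantics collapse onto one probability
#' scale).
#'
#' @param protein amino-acid string.
#' @param window window length (residues).
#' @param prob_threshold per-residue probability threshold.
#' @param validation_cutoff secondary margin; a segment is validated when its
#'   peak probability is at least `1 - validation_cutoff`.
#' @return tibble with `kind = "CC"`, `start`, `end`, `score` (peak
#'   probability) and `validated`.
#' @export
coiled_coil_scan <- function(protein, window = 28, prob_threshold = 0.9,
                             validation_cutoff = 0.025) {
  L <- nchar(protein)
  empty <- tibble::tibble(kind = character(), start = integer(),
                          end = integer(), score = numeric(),
                          validated = logical())
  if (L < window) return(empty)
  tab <- heptad_table()
  s <- aa_to_int(protein)
  n <- L - window + 1
  best <- rep(-Inf, n)
  for (phase in 0:6) {
    cls <- ((seq_len(L) - 1 + phase) %% 7) + 1
    per <- ifelse(is.na(s), -0.4, tab[cbind(s, cls)])
    cs <- c(0, cumsum(per))
    wscore <- cs[(window + 1):(L + 1)] - cs[1:n]
    best <- pmax(best, wscore)
  }
  wprob <- stats::plogis((best - 18) / 1.5)
  rp <- rep(0, L)
  # per-residue probability: max over covering windows
  for (off in seq_len(window)) {
    idx <- seq_len(n) + off - 1
    rp[idx] <- pmax(rp[idx], wprob)
  }
  above <- rp >= prob_threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- which(r$values)
  tibble::tibble(kind = "CC", start = as.integer(starts[seg]),
                 end = as.integer(ends[seg]),
                 score = vapply(seg, function(k)
                   max(rp[starts[k]:ends[k]]), numeric(1))) %>%
    dplyr::mutate(validated = .data$score >= 1 - validation_cutoff)
}

#' Locate the ordered NBS subdomain motifs
#'
#' Scans the P-loop, kinase-2, kinase-3a and GLPL PSSMs and selects the
#' highest-total-score combination of at most one hit per motif that respects
#' the canonical order P-loop < kinase-2 < kinase-3a < GLPL without overlap.
#'
#' @param protein amino-acid string.
#' @param pssms named list of PSSMs (default: packaged set).
#' @return list with `hits` (ordered tibble) and `complete` (all four
#'   present).
#' @export
find_nbs_subdomains <- function(protein, pssms = packaged_pssms()) {
  order_names <- c("ploop", "kinase2", "kinase3a", "glpl")
  cand <- purrr::map(order_names, function(nm) {
    h <- scan_pssm(protein, pssms[[nm]])
    h <- dplyr::slice_max(h, .data$score, n = 6, with_ties = FALSE)
    dplyr::arrange(h, .data$start)
  })
  # exhaustive selection over (absent + candidates) per motif, maximizing
  # total score subject to ordered non-overlapping placement
  grid <- expand.grid(purrr::map(cand, function(h) 0:nrow(h)))
  best_sel <- rep(0L, 4); best_score <- -Inf
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    prev_end <- 0L; total <- 0; ok <- TRUE
    for (m in 1:4) {
      k <- idx[m]
      if (k == 0L) next
      if (cand[[m]]$start[k] <= prev_end) { ok <- FALSE; break }
      prev_end <- cand[[m]]$end[k]
      total <- total + cand[[m]]$score[k]
    }
    if (ok && total > best_score) { best_score <- total; best_sel <- idx }
  }
  best <- dplyr::bind_rows(purrr::map2(cand, best_sel, function(h, k) {
    if (k == 0L) h[0, ] else h[k, ]
  }))
  list(hits = best, complete = all(c("PLOOP", "KINASE2", "KINASE3A", "GLPL")
                                   %in% best$kind))
}

# Packaged lineage sub-profiles (built lazily from the shipped seed
# alignments).
packaged_subprofiles <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(
        cc = build_profile(seed_alignment("nbs_cc"), name = "NBS-CC"),
        tir = build_profile(seed_alignment("nbs_tir"), name = "NBS-TIR"))
    }
    cache
  }
})

#' NBS signature typing (CC lineage versus TIR lineage)
#'
#' Primary rule: the terminal residue of the kinase-2 motif (tryptophan for
#' the CC lineage, aspartate for the TIR lineage). Fallback and consistency
#' check: local Viterbi scores against the two packaged lineage sub-profiles.
#'
#' @param protein amino-acid string.
#' @param subdomain_hits result of [find_nbs_subdomains()].
#' @param cc_sub_hmm,tir_sub_hmm lineage sub-profiles (default packaged).
#' @return list with `type` (`"CC_type"`, `"TIR_type"` or `"undetermined"`),
#'   `kinase2_terminal`, `cc_score`, `tir_score`.
#' @export
classify_signature <- function(protein, subdomain_hits,
                               cc_sub_hmm = packaged_subprofiles()$cc,
                               tir_sub_hmm = packaged_subprofiles()$tir) {
  hits <- subdomain_hits$hits
  k2 <- hits[hits$kind == "KINASE2", ]
  terminal <- if (nrow(k2) == 1) substr(protein, k2$end, k2$end) else NA_character_
  cc_s <- suppressWarnings(viterbi(cc_sub_hmm, protein)$score)
  tir_s <- suppressWarnings(viterbi(tir_sub_hmm, protein)$score)
  type <- if (!is.na(terminal) && terminal == "W") "CC_type"
  else if (!is.na(terminal) && terminal == "D") "TIR_type"
  else if (cc_s > tir_s) "CC_type"
  else if (tir_s > cc_s) "TIR_type"
  else "undetermined"
  list(type = type, kinase2_terminal = terminal,
       cc_score = cc_s, tir_score = tir_s)
}

#' Assign one of the eight architecture codes
#'
#' TIR present takes the TIR branch (TNL/TN by LRR presence); otherwise CC
#' present takes the CNL branch (CNL/CN); proteins with neither N-terminal
#' domain are typed by their NBS signature subscript (NL_CC/N_CC or
#' NL_TIR/N_TIR). NBS model coverage below `partial_threshold` yields
#' `PARTIAL`. Proteins carrying both CC and TIR resolve to the TIR branch
#' with `conflict = TRUE`.
#'
#' @param domain_hits tibble of domain hits (`kind` in CC/TIR/LRR, plus the
#'   subdomain motifs).
#' @param signature result of [classify_signature()].
#' @param nbs_coverage matched fraction of the NBS model length.
#' @param partial_threshold coverage below which the call is `PARTIAL`.
#' @param min_lrr_hits LRR repeats required to call the LRR domain present.
#' @return tibble row: `code`, `cc`, `tir`, `lrr`, `signature`,
#'   `nbs_coverage`, `conflict`.
#' @export
assign_architecture <- function(domain_hits, signature, nbs_coverage,
                                partial_threshold = 0.5, min_lrr_hits = 2) {
  cc <- any(domain_hits$kind == "CC")
  tir <- any(domain_hits$kind == "TIR")
  lrr <- sum(domain_hits$kind == "LRR") >= min_lrr_hits
  conflict <- cc && tir
  code <- if (nbs_coverage < partial_threshold) {
    "PARTIAL"
  } else if (tir) {
    if (lrr) "TNL" else "TN"
  } else if (cc) {
    if (lrr) "CNL" else "CN"
  } else if (signature$type == "TIR_type") {
    if (lrr) "NL_TIR" else "N_TIR"
  } else {
    if (lrr) "NL_CC" else "N_CC"
  }
  tibble::tibble(code = code, cc = cc, tir = tir, lrr = lrr,
                 signature = signature$type, nbs_coverage = nbs_coverage,
                 conflict = conflict)
}

#' Full architecture classification of candidate proteins
#'
#' Convenience wrapper running the coiled-coil, TIR, LRR and NBS-subdomain
#' scans plus signature typing for each candidate, then
#' [assign_architecture()].
#'
#' @param proteins tibble (`id`, `seq`).
#' @param coverage named vector or tibble mapping protein id to NBS model
#'   coverage (from the HMM search); missing ids default to 1.
#' @param config optional [pipeline_config()] for thresholds.
#' @return tibble, one row per protein: id, architecture call columns and
#'   motif offsets (`ploop_start`, `glpl_end`).
#' @export
classify_architectures <- function(proteins, coverage = NULL, config = pipeline_config()) {
  pssms <- packaged_pssms()
  subs <- packaged_subprofiles()
  cov_of <- function(id) {
    if (is.null(coverage)) return(1)
    if (is.data.frame(coverage)) {
      i <- match(id, coverage$target_id)
      return(ifelse(is.na(i), 1, coverage$coverage[i]))
    }
    v <- coverage[id]
    ifelse(is.na(v), 1, v)
  }
  rows <- purrr::map(seq_len(nrow(proteins)), function(i) {
    p <- proteins$seq[i]
    cc <- coiled_coil_scan(p, prob_threshold = config$cc_prob_threshold,
                           validation_cutoff = config$cc_validation_cutoff)
    tirh <- scan_pssm(p, pssms$tir)
    lrrh <- scan_pssm(p, pssms$lrr)
    sd <- find_nbs_subdomains(p, pssms)
    sig <- classify_signature(p, sd, subs$cc, subs$tir)
    hits <- dplyr::bind_rows(
      if (nrow(cc)) dplyr::select(cc, "kind", "start", "end", "score"),
      tirh, lrrh, sd$hits)
    call <- assign_architecture(hits, sig, cov_of(proteins$id[i]),
                                partial_threshold = config$partial_nbs_threshold)
    pl <- sd$hits[sd$hits$kind == "PLOOP", ]
    gl <- sd$hits[sd$hits$kind == "GLPL", ]
    dplyr::mutate(call, id = proteins$id[i],
                  nbs_complete = sd$complete,
                  ploop_start = if (nrow(pl)) pl$start[1] else NA_integer_,
                  glpl_end = if (nrow(gl)) gl$end[1] else NA_integer_,
                  .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' EM motif discovery (one occurrence per sequence)
#'
#' MEME-style expectation maximization under the OOPS model: every sequence
#' contains exactly one motif occurrence at an unknown position. The best of
#' `n_starts` random initializations by log-likelihood is returned;
#' deterministic under a fixed seed. The EM log-likelihood is non-decreasing
#' across iterations.
#'
#' @param proteins character vector (or tibble with `seq`) of at least 5
#'   sequences, each at least `width` long.
#' @param width motif width.
#' @param n_starts random restarts.
#' @param seed RNG seed.
#' @return `nlr_pssm` with attributes `consensus`, `loglik` and
#'   `loglik_trace`.
#' @export
em_discover_motif <- function(proteins, width, n_starts = 10, seed = 1) {
  seqs <- if (is.data.frame(proteins)) proteins$seq else proteins
  if (length(seqs) < 5) stop("need at least 5 sequences")
  if (any(nchar(seqs) < width)) stop("width exceeds the shortest sequence")
  ints <- purrr::map(seqs, function(s) {
    v <- aa_to_int(s)
    v[is.na(v)] <- sample.int(20, sum(is.na(v)), replace = TRUE, prob = ROBINSON_BG)
    v
  })
  lbg <- log(ROBINSON_BG)

  run_em <- function(theta) {
    prev_ll <- -Inf
    trace <- numeric()
    for (iter in 1:200) {
      lth <- log(theta)
      counts <- matrix(0, width, 20)
      ll <- 0
      for (v in ints) {
        n <- length(v) - width + 1
        lw <- numeric(n)
        for (w in seq_len(width)) {
          res <- v[w:(w + n - 1)]
          lw <- lw + lth[w, ][res] - lbg[res]
        }
        m <- max(lw)
        z <- exp(lw - m)
        ll <- ll + m + log(sum(z)) - log(n) + sum(lbg[v])
        z <- z / sum(z)
        for (w in seq_len(width)) {
          res <- v[w:(w + n - 1)]
          agg <- rowsum(z, group = res)
          counts[w, as.integer(rownames(agg))] <-
            counts[w, as.integer(rownames(agg))] + agg[, 1]
        }
      }
      trace <- c(trace, ll)
      theta <- counts + matrix(rep(ROBINSON_BG, each = width), width, 20) * 0.5
      theta <- theta / rowSums(theta)
      if (is.finite(prev_ll) && ll - prev_ll < 1e-8) break
      prev_ll <- ll
    }
    list(theta = theta, ll = ll, trace = trace)
  }

  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      si <- sample.int(length(ints), 1)
      p0 <- sample.int(length(ints[[si]]) - width + 1, 1)
      win <- ints[[si]][p0:(p0 + width - 1)]
      theta <- matrix(rep(ROBINSON_BG * 0.3, each = width), width, 20)
      theta[cbind(seq_len(width), win)] <- theta[cbind(seq_len(width), win)] + 0.7
      theta <- theta / rowSums(theta)
      fit <- run_em(theta)
      if (is.null(best) || fit$ll > best$ll) best <- fit
    }
  })
  colnames(best$theta) <- AA_ALPHABET20
  pssm <- new_pssm(best$theta, threshold = 0, name = sprintf("EM-w%d", width))
  pssm$threshold <- 0.5 * sum(apply(pssm$log_odds, 1, max))
  attr(pssm, "consensus") <- paste(AA_ALPHABET20[apply(best$theta, 1, which.max)],
                                   collapse = "")
  attr(pssm, "loglik") <- best$ll
  attr(pssm, "loglik_trace") <- best$trace
  pssm
}
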