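# broom-style tidiers for the fitted objects.

#' Tidy a profile HMM
#'
#' @param x `nlr_profile_hmm`.
#' @param ... unused.
#' @return tibble with one row per match state: `position`, `consensus`
#'   residue and its emission probability, and the information content
#'   (bits) of the emission distribution.
#' @export
tidy.nlr_profile_hmm <- function(x, ...) {
  best <- apply(x$emit, 1, which.max)
  info <- vapply(seq_len(x$M), function(j) {
    p <- x$emit[j, ]
    sum(p * log2(p / x$bg))
  }, numeric(1))
  tibble::tibble(position = seq_len(x$M),
                 consensus = AA_ALPHABET20[best],
                 p_consensus = x$emit[cbind(seq_len(x$M), best)],
                 information = info)
}

#' @rdname tidy.nlr_profile_hmm
#' @export
glance.nlr_profile_hmm <- function(x, ...) {
  tibble::tibble(name = x$name, n_match_states = x$M,
                 calibrated = !is.null(x$calibration),
                 mu = x$calibration$mu %||% NA_real_,
                 lambda = x$calibration$lambda %||% NA_real_)
}

#' Tidy a pipeline result
#'
#' @param x `nlr_pipeline`.
#' @param ... unused.
#' @return the per-gene candidate tibble (architecture, position, cluster
#'   membership, pseudogene call).
#' @export
tidy.nlr_pipeline <- function(x, ...) {
  dplyr::select(x$anchored, dplyr::any_of(c(
    "gene_id", "protein_id", "code", "signature", "nbs_coverage",
    "chromosome", "chr_start", "chr_end", "cluster_id", "is_singleton",
    "cause", "pseudogene", "evalue", "bits")))
}

#' @rdname tidy.nlr_pipeline
#' @export
glance.nlr_pipeline <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$candidates),
    n_pseudogenes = sum(x$candidates$pseudogene, na.rm = TRUE),
    n_clusters = nrow(x$clusters),
    n_clustered = if (nrow(x$clusters)) sum(x$clusters$n) else 0L,
    n_anchored = sum(!is.na(x$anchored$chromosome)),
    n_nbs_derived = sum(x$nbs_derived$call == "nbs_derived"),
    n_partial_nbs = sum(x$nbs_derived$call == "partial_nbs"),
    n_resistance_like = sum(x$nbs_derived$call == "resistance_like"))
}

#' Tidy a synthetic genome bundle
#'
#' @param x `nlr_genome`.
#' @param ... unused.
#' @return the planted-truth tibble.
#' @export
tidy.nlr_genome <- function(x, ...) x$truth
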