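# ggplot2 views of the main result types.

#' Chromosome map of anchored NLR genes
#'
#' One horizontal track per chromosome with gene positions colored by
#' lineage (CNL-type green, TNL-type red, PARTIAL yellow), the usual way NLR
#' distributions are drawn.
#'
#' @param anchored anchored gene tibble (needs `chromosome`, `chr_start`,
#'   and optionally `code`).
#' @return a ggplot.
#' @export
plot_gene_map <- function(anchored) {
  df <- dplyr::filter(anchored, !is.na(.data$chromosome))
  df$lineage <- dplyr::case_when(
    df$code %in% c("CNL", "CN", "NL_CC", "N_CC") ~ "CNL-type",
    df$code %in% c("TNL", "TN", "NL_TIR", "N_TIR") ~ "TNL-type",
    TRUE ~ "partial")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chr_start / 1e6,
                                   y = .data$chromosome)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$lineage), shape = 124,
                        size = 6) +
    ggplot2::scale_colour_manual(values = c(`CNL-type` = "#1b9e77",
                                            `TNL-type` = "#d95f02",
                                            partial = "#e6ab02")) +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Architecture count bar chart
#'
#' @param arch_table tibble from [architecture_summary()].
#' @return a ggplot.
#' @export
plot_architecture_counts <- function(arch_table) {
  df <- dplyr::filter(arch_table, !grepl("^Total|^Partial", .data$row))
  df$row <- factor(df$row, levels = df$row)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$row, y = .data$count)) +
    ggplot2::geom_col(fill = "#386cb0") +
    ggplot2::labs(x = "architecture code", y = "genes") +
    ggplot2::theme_minimal()
}

#' @rdname plot_gene_map
#' @param object `nlr_pipeline`.
#' @param ... unused.
#' @export
autoplot.nlr_pipeline <- function(object, ...) {
  plot_gene_map(object$anchored)
}

#' Coiled-coil probability profile
#'
#' @param protein amino-acid string.
#' @inheritParams coiled_coil_scan
#' @return a ggplot of the per-residue coil probability.
#' @export
plot_coiled_coil <- function(protein, window = 28, prob_threshold = 0.9) {
  L <- nchar(protein)
  tab <- heptad_table()
  s <- aa_to_int(protein)
  n <- L - window + 1
  stopifnot(n >= 1)
  best <- rep(-Inf, n)
  for (phase in 0:6) {
    cls <- ((seq_len(L) - 1 + phase) %% 7) + 1
    per <- ifelse(is.na(s), -0.4, tab[cbind(s, cls)])
    cs <- c(0, cumsum(per))
    best <- pmax(best, cs[(window + 1):(L + 1)] - cs[1:n])
  }
  wprob <- stats::plogis((best - 18) / 1.5)
  rp <- rep(0, L)
  for (off in seq_len(window)) {
    idx <- seq_len(n) + off - 1
    rp[idx] <- pmax(rp[idx], wprob)
  }
  ggplot2::ggplot(tibble::tibble(position = seq_len(L), probability = rp),
                  ggplot2::aes(.data$position, .data$probability)) +
    ggplot2::geom_line(colour = "#386cb0") +
    ggplot2::geom_hline(yintercept = prob_threshold, linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
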