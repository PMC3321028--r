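# NBS-domain phylogeny: P-loop-anchored domain extraction, guide-tree
# progressive alignment, distance matrices, neighbor joining with the
# standard Saitou-Nei update, column-resampling bootstrap, and clade
# assignment against labelled reference leaves.

#' Extract the NBS domain anchored at the P-loop
#'
#' The domain runs from the P-loop start to the GLPL end plus `tail`
#' residues, clipped to the protein; proteins lacking a P-loop or GLPL hit
#' are excluded (returned as `NA`).
#'
#' @param protein amino-acid string.
#' @param subdomain_hits result of [find_nbs_subdomains()].
#' @param tail residues kept past the GLPL motif.
#' @return character scalar or `NA` when excluded.
#' @export
extract_nbs_domain <- function(protein, subdomain_hits, tail = 30) {
  hits <- subdomain_hits$hits
  pl <- hits[hits$kind == "PLOOP", ]
  gl <- hits[hits$kind == "GLPL", ]
  if (nrow(pl) != 1 || nrow(gl) != 1) return(NA_character_)
  substr(protein, pl$start, min(gl$end + tail, nchar(protein)))
}

# shared 3-mer guide distance
kmer3_dist <- function(seqs) {
  n <- length(seqs)
  km <- purrr::map(seqs, function(s) {
    if (nchar(s) < 3) return(character(0))
    unique(substring(s, 1:(nchar(s) - 2), 3:nchar(s)))
  })
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- min(length(km[[i]]), length(km[[j]]))
      share <- if (denom == 0) 0 else
        length(intersect(km[[i]], km[[j]])) / denom
      d[i, j] <- d[j, i] <- 1 - share
    }
  }
  d
}

seq_to_profile <- function(rows) {
  # rows: character matrix (rows x columns) with "-" gaps
  L <- ncol(rows)
  prof <- matrix(0, 20, L)
  for (i in seq_len(nrow(rows))) {
    idx <- match(rows[i, ], AA_ALPHABET20)
    ok <- which(!is.na(idx))
    prof[cbind(idx[ok], ok)] <- prof[cbind(idx[ok], ok)] + 1
  }
  prof / nrow(rows)
}

#' Progressive multiple sequence alignment
#'
#' UPGMA guide tree on shared 3-mer distances, then profile-profile
#' Needleman-Wunsch merges with affine gaps (BLOSUM62 expected column
#' scores). Deterministic. For two sequences the result is the optimal
#' global pairwise alignment.
#'
#' @param sequences tibble (`id`, `seq`) or character vector.
#' @param gap_open,gap_extend affine gap penalties (a length-k gap costs
#'   `gap_open + (k - 1) * gap_extend`).
#' @return tibble (`id`, `seq`) of aligned rows in input order, with
#'   attribute `"score"` (final merge score).
#' @export
progressive_align <- function(sequences, gap_open = 10, gap_extend = 0.5) {
  if (is.character(sequences)) {
    sequences <- tibble::tibble(
      id = paste0("seq", seq_along(sequences)), seq = sequences)
  }
  n <- nrow(sequences)
  if (n == 1) {
    out <- sequences
    attr(out, "score") <- 0
    return(out)
  }
  sub <- blosum62_matrix()
  d <- kmer3_dist(sequences$seq)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # alignment state per active cluster: character matrix + row ids
  state <- purrr::map(seq_len(n), function(i) {
    list(rows = matrix(strsplit(sequences$seq[i], "")[[1]], nrow = 1),
         ids = sequences$id[i])
  })
  merged <- vector("list", nrow(hc$merge))
  score <- 0
  for (k in seq_len(nrow(hc$merge))) {
    pick <- function(v) if (v < 0) state[[-v]] else merged[[v]]
    a <- pick(hc$merge[k, 1]); b <- pick(hc$merge[k, 2])
    pa <- seq_to_profile(a$rows); pb <- seq_to_profile(b$rows)
    al <- .cpp_nw_profile(pa, pb, sub, gap_open, gap_extend)
    score <- al$score
    expand <- function(rows, map) {
      out <- matrix("-", nrow(rows), length(map))
      ok <- !is.na(map)
      out[, ok] <- rows[, map[ok], drop = FALSE]
      out
    }
    merged[[k]] <- list(rows = rbind(expand(a$rows, al$map1),
                                     expand(b$rows, al$map2)),
                        ids = c(a$ids, b$ids))
  }
  fin <- merged[[nrow(hc$merge)]]
  seqs <- apply(fin$rows, 1, paste, collapse = "")
  out <- tibble::tibble(id = fin$ids, seq = seqs)
  out <- out[match(sequences$id, out$id), ]
  attr(out, "score") <- score
  out
}

#' Trim poorly aligned alignment ends
#'
#' Removes leading and trailing columns whose gap fraction exceeds
#' `max_gap_fraction` (the automated counterpart of manual end curation).
#'
#' @param msa tibble (`id`, `seq`).
#' @param max_gap_fraction columns above this at either end are dropped.
#' @return trimmed MSA tibble.
#' @export
trim_alignment_ends <- function(msa, max_gap_fraction = 0.8) {
  mat <- do.call(rbind, strsplit(msa$seq, ""))
  gapf <- colMeans(mat == "-")
  keep <- which(gapf <= max_gap_fraction)
  if (!length(keep)) return(msa[0, ])
  cols <- seq(min(keep), max(keep))
  dplyr::mutate(msa, seq = apply(mat[, cols, drop = FALSE], 1, paste,
                                 collapse = ""))
}

#' Pairwise distance matrix from an alignment
#'
#' Pairwise-deletion p-distance, optionally Poisson-corrected
#' (`-ln(1 - p)`).
#'
#' @param msa tibble (`id`, `seq`) with at least 2 rows.
#' @param model `"p"` or `"poisson"`.
#' @return symmetric numeric matrix with taxon dimnames.
#' @export
distance_matrix <- function(msa, model = c("p", "poisson")) {
  model <- match.arg(model)
  stopifnot(nrow(msa) >= 2)
  mat <- do.call(rbind, strsplit(msa$seq, ""))
  n <- nrow(mat)
  ok <- (mat != "-" & mat != ".") * 1
  comparable <- tcrossprod(ok)
  if (any(comparable[upper.tri(comparable)] == 0)) {
    w <- which(comparable == 0 & upper.tri(comparable), arr.ind = TRUE)[1, ]
    stop(sprintf("no comparable columns between %s and %s",
                 msa$id[w[1]], msa$id[w[2]]))
  }
  matches <- matrix(0, n, n)
  for (a in unique(as.vector(mat))) {
    if (a %in% c("-", ".")) next
    ia <- (mat == a) * 1
    matches <- matches + tcrossprod(ia)
  }
  p <- 1 - matches / comparable
  diag(p) <- 0
  D <- if (model == "p") p else -log(pmax(1 - p, 1e-12))
  dimnames(D) <- list(msa$id, msa$id)
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration: each step joins the pair minimizing the Q
#' criterion (ties broken by the lexicographically smallest taxon-label
#' pair); branch lengths follow the standard two-point formulas, with
#' negative estimates clamped to zero and counted in the `"n_clamped"`
#' attribute. The `"joins"` attribute records the chosen pair per step.
#'
#' @param dm symmetric distance matrix with taxon dimnames (n >= 3).
#' @return unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) >= 3, all(is.finite(dm)))
  labels <- rownames(dm)
  D <- dm
  # active node bookkeeping: newick fragment + representative (smallest leaf)
  frag <- labels
  rep_lab <- labels
  joins <- list()
  n_clamped <- 0
  quote_lab <- function(x) {
    ifelse(grepl("[[:space:](),:;]", x), paste0("'", x, "'"), x)
  }
  frag <- quote_lab(frag)
  while (nrow(D) > 3) {
    n <- nrow(D)
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, "+")
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    qmin <- min(Q)
    ties <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    keys <- apply(ties, 1, function(ij) {
      k <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(k, collapse = "\r")
    })
    pick <- which.min(match(keys, sort(keys)))
    i <- min(ties[pick, ]); j <- max(ties[pick, ])
    joins <- c(joins, list(sort(c(rep_lab[i], rep_lab[j]))))
    bi <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { n_clamped <- n_clamped + 1; bi <- 0 }
    if (bj < 0) { n_clamped <- n_clamped + 1; bj <- 0 }
    newf <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], bi, frag[j], bj)
    newd <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    frag <- c(frag[keep], newf)
    rep_lab <- c(rep_lab[keep], min(rep_lab[c(i, j)]))
    D <- D2
  }
  # final three-point join
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  bl <- c(b1, b2, b3)
  n_clamped <- n_clamped + sum(bl < 0)
  bl <- pmax(bl, 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], bl[1], frag[2], bl[2], frag[3], bl[3])
  tree <- ape::read.tree(text = nwk)
  attr(tree, "joins") <- joins
  attr(tree, "n_clamped") <- n_clamped
  tree
}

#' Bootstrap supports for the NJ tree
#'
#' Columns are resampled with replacement `replicates` times; the support of
#' each internal edge of the full-data tree is the percentage of replicate
#' trees containing that bipartition. Taxa are put in canonical (sorted id)
#' order first, so supports do not depend on input order.
#'
#' @param msa tibble (`id`, `seq`).
#' @param replicates bootstrap replicates.
#' @param seed RNG seed.
#' @param model distance model (see [distance_matrix()]).
#' @return the full-data `ape::phylo` tree with `node.label` set to supports
#'   (0-100; root label empty).
#' @export
bootstrap_support <- function(msa, replicates = 500, seed = 1, model = "p") {
  msa <- dplyr::arrange(msa, .data$id)
  L <- nchar(msa$seq[1])
  stopifnot(L >= 2)
  mat <- do.call(rbind, strsplit(msa$seq, ""))
  full <- nj_tree(distance_matrix(msa, model))
  reps <- with_seed(seed, {
    purrr::map(seq_len(replicates), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      m2 <- dplyr::mutate(msa, seq = apply(mat[, cols, drop = FALSE], 1,
                                           paste, collapse = ""))
      nj_tree(distance_matrix(m2, model))
    })
  })
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / replicates)
  lab <- as.character(support)
  lab[1] <- "" # root of the stored (arbitrarily rooted) representation
  full$node.label <- lab
  attr(full, "support") <- support
  full
}

#' Assign leaves to reference-labelled clades
#'
#' Every unlabelled leaf takes the label of its smallest enclosing clade
#' (any bipartition side containing the leaf) that contains at least one
#' reference leaf; if that clade's references carry more than one label the
#' leaf is `unassigned`.
#'
#' @param tree `ape::phylo`.
#' @param reference_labels named character vector: reference leaf ->
#'   clade label (e.g. `CC_I`, `CC_II`, `TIR`).
#' @return tibble with `leaf`, `clade`.
#' @export
assign_clades <- function(tree, reference_labels) {
  tips <- tree$tip.label
  if (!any(names(reference_labels) %in% tips)) {
    stop("no reference leaves present in the tree")
  }
  refs <- reference_labels[names(reference_labels) %in% tips]
  n <- length(tips)
  # all clades: descendant tip sets of internal nodes, plus complements
  desc <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (!length(kids)) return(node)
    unlist(purrr::map(kids, desc))
  }
  clades <- list()
  for (node in (n + 1):(n + tree$Nnode)) {
    below <- desc(node)
    clades <- c(clades, list(below), list(setdiff(seq_len(n), below)))
  }
  clades <- clades[vapply(clades, function(x) length(x) > 0 && length(x) < n,
                          TRUE)]
  sizes <- vapply(clades, length, integer(1))
  ord <- order(sizes)
  out <- vapply(seq_len(n), function(i) {
    tip <- tips[i]
    if (tip %in% names(refs)) return(unname(refs[tip]))
    for (k in ord) {
      cl <- clades[[k]]
      if (!(i %in% cl)) next
      labs <- unique(refs[intersect(tips[cl], names(refs))])
      if (length(labs) == 0) next
      return(if (length(labs) == 1) unname(labs) else "unassigned")
    }
    "unassigned"
  }, character(1))
  tibble::tibble(leaf = tips, clade = out)
}
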