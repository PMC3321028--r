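# Domain extraction, progressive alignment, distances, neighbor joining,
# bootstrap and clade assignment.

test_that("NBS extraction is P-loop anchored with a clipped GLPL tail", {
  hits <- list(hits = tibble::tibble(
    kind = c("PLOOP", "KINASE2", "KINASE3A", "GLPL"),
    start = c(161, 230, 260, 413), end = c(172, 240, 269, 420),
    score = 10))
  prot <- strrep("A", 900)
  expect_equal(extract_nbs_domain(prot, hits),
               substr(prot, 161, 450))
  # clipping at the protein end
  short <- strrep("A", 430)
  expect_equal(nchar(extract_nbs_domain(short, hits)), 430 - 161 + 1)
  # missing P-loop -> excluded
  no_pl <- list(hits = hits$hits[-1, ])
  expect_true(is.na(extract_nbs_domain(prot, no_pl)))
})

test_that("progressive alignment of two sequences equals the pairwise DP", {
  set.seed(81)
  for (r in 1:6) {
    a <- nlrscan:::random_protein(sample(30:60, 1))
    b <- nlrscan:::random_protein(sample(30:60, 1))
    ours <- progressive_align(c(a, b), gap_open = 10, gap_extend = 0.5)
    # Biostrings scores a length-k gap as opening + k*extension; ours as
    # opening + (k-1)*extension, so shift the opening to compare
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 9.5, gapExtension = 0.5)
    expect_equal(attr(ours, "score"), Biostrings::score(ref),
                 tolerance = 1e-6)
  }
})

test_that("identical sequences align gap-free; a planted deletion is one gap", {
  msa <- progressive_align(rep("MKVDEWYALLR", 4))
  expect_true(all(!grepl("-", msa$seq)))

  set.seed(82)
  base <- nlrscan:::random_protein(60)
  fam <- c(base,
           nlrscan:::mutate_protein(base, 0.03),
           paste0(substr(base, 1, 29), substr(base, 33, 60)),
           nlrscan:::mutate_protein(base, 0.03))
  msa2 <- progressive_align(fam)
  # the deleted row shows exactly one gap run of length 3
  gaps <- gregexpr("-+", msa2$seq[3])[[1]]
  expect_equal(length(gaps), 1)
  expect_equal(attr(gaps, "match.length"), 3)
  # ungapping returns the input (MSA invariant)
  expect_equal(gsub("-", "", msa2$seq[3]), fam[3])
})

test_that("p and Poisson distances match hand counts and stay symmetric", {
  msa <- tibble::tibble(id = c("a", "b"),
                        seq = c(strrep("A", 100),
                                paste0(strrep("A", 97), "CCC")))
  D <- distance_matrix(msa, "p")
  expect_equal(D["a", "b"], 0.03)
  Dp <- distance_matrix(msa, "poisson")
  expect_equal(Dp["a", "b"], -log(0.97))
  expect_equal(unname(distance_matrix(tibble::tibble(
    id = c("x", "y"), seq = c("AAAA", "AAAA")), "p")["x", "y"]), 0)

  set.seed(83)
  rows <- replicate(6, paste(sample(c(nlrscan:::AA_ALPHABET20, "-"), 50,
                                    TRUE), collapse = ""))
  D2 <- distance_matrix(tibble::tibble(id = letters[1:6], seq = rows))
  expect_equal(D2, t(D2))
  expect_true(all(diag(D2) == 0))

  no_overlap <- tibble::tibble(id = c("a", "b"),
                               seq = c("AA--", "--CC"))
  expect_error(distance_matrix(no_overlap), "a and b")
})

test_that("NJ solves the three-taxon case in closed form", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (5 + 9 - 10) / 2)
  expect_equal(unname(bl["b"]), (5 + 10 - 9) / 2)
  expect_equal(unname(bl["c"]), (9 + 10 - 5) / 2)
})

test_that("NJ recovers random additive trees and matches ape::nj", {
  set.seed(84)
  for (n in c(5, 6, 8)) {
    for (r in 1:4) {
      true_tree <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
      D <- ape::cophenetic.phylo(true_tree)
      D <- D[sort(rownames(D)), sort(colnames(D))]
      ours <- nj_tree(D)
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(ours),
                                             ape::unroot(true_tree))), 0)
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(ours),
                                             ape::unroot(ape::nj(D)))), 0)
      # branch lengths reproduce the additive metric
      expect_equal(ape::cophenetic.phylo(ours)[rownames(D), colnames(D)], D,
                   tolerance = 1e-9)
    }
  }
})

test_that("each NJ join is the brute-force Q minimum", {
  set.seed(85)
  for (r in 1:5) {
    n <- 7
    lab <- paste0("t", 1:n)
    M <- matrix(stats::runif(n * n, 0.1, 2), n, n)
    D <- (M + t(M)) / 2
    diag(D) <- 0
    dimnames(D) <- list(lab, lab)
    tr <- nj_tree(D)
    joins <- attr(tr, "joins")
    # independent first-step oracle
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    w <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    expect_setequal(joins[[1]], lab[w])
  }
})

test_that("negative NJ branch estimates are clamped and flagged", {
  D <- matrix(c(0, 1, 6, 1, 0, 6.5, 6, 6.5, 0) / 2, 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  # violate additivity hard enough for a negative leaf branch
  D["a", "b"] <- D["b", "a"] <- 0.05
  D["a", "c"] <- D["c", "a"] <- 3
  D["b", "c"] <- D["c", "b"] <- 2.6
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "n_clamped"), 1)
})

test_that("bootstrap gives near-unit support to separated clades", {
  set.seed(86)
  base1 <- nlrscan:::random_protein(120)
  base2 <- nlrscan:::random_protein(120)
  rows <- c(purrr::map_chr(1:5, function(i) nlrscan:::mutate_protein(base1, 0.02)),
            purrr::map_chr(1:5, function(i) nlrscan:::mutate_protein(base2, 0.02)))
  msa <- tibble::tibble(id = sprintf("s%02d", 1:10), seq = rows)
  t0 <- Sys.time()
  tr <- bootstrap_support(msa, replicates = 100, seed = 4)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_lt(elapsed, 60)
  # the clade bipartition s01-s05 | s06-s10 must be strongly supported
  part <- ape::prop.part(tr)
  labs <- attr(part, "labels")
  sizes <- vapply(part, length, integer(1))
  support <- attr(tr, "support")
  grp1 <- sort(labs[part[[which(sizes == 5)[1]]]])
  expect_true(identical(grp1, sprintf("s%02d", 1:5)) ||
                identical(grp1, sprintf("s%02d", 6:10)))
  expect_gte(support[which(sizes == 5)[1]], 95)
  # determinism under the seed
  tr2 <- bootstrap_support(msa, replicates = 100, seed = 4)
  expect_identical(attr(tr2, "support"), attr(tr, "support"))
  # taxon input order must not matter
  tr3 <- bootstrap_support(msa[sample.int(10), ], replicates = 100, seed = 4)
  expect_identical(attr(tr3, "support"), attr(tr, "support"))
})

test_that("clade labels propagate from pure reference clades only", {
  txt <- "(((r1:0.1,x1:0.1):0.1,(r2:0.1,x2:0.1):0.1):0.3,((r3:0.1,x3:0.1):0.3,x4:0.4):0.1);"
  tr <- ape::read.tree(text = txt)
  refs <- c(r1 = "CC_I", r2 = "CC_I", r3 = "TIR")
  got <- assign_clades(tr, refs)
  lab <- stats::setNames(got$clade, got$leaf)
  expect_equal(unname(lab["x1"]), "CC_I")
  expect_equal(unname(lab["x2"]), "CC_I")
  expect_equal(unname(lab["x3"]), "TIR")
  expect_equal(unname(lab["r1"]), "CC_I") # references keep their own label
  expect_error(assign_clades(tr, c(zz = "CC_I")), "reference")
})

test_that("a leaf whose every enclosing labelled clade is mixed is unassigned", {
  txt <- "((r1:0.1,r2:0.1):0.1,(x1:0.1,r3:0.1):0.1);"
  tr <- ape::read.tree(text = txt)
  refs <- c(r1 = "CC_I", r2 = "CC_II", r3 = "TIR")
  got <- assign_clades(tr, refs)
  expect_equal(got$clade[got$leaf == "x1"], "TIR") # smallest pure clade wins
  # now make every enclosing labelled clade mixed: each bipartition side
  # containing x1 and a reference holds references of both labels
  txt2 <- "((x1:0.1,(r1:0.1,r2:0.1):0.1):0.1,(r3:0.1,r4:0.1):0.1);"
  tr2 <- ape::read.tree(text = txt2)
  refs2 <- c(r1 = "CC_I", r2 = "CC_II", r3 = "CC_I", r4 = "CC_II")
  got2 <- assign_clades(tr2, refs2)
  expect_equal(got2$clade[got2$leaf == "x1"], "unassigned")
})

test_that("end trimming drops ragged high-gap columns only", {
  msa <- tibble::tibble(id = c("a", "b", "c", "d", "e"),
                        seq = c("M-KVD-", "--KVD-", "--KVDE", "--KVD-",
                                "--KVD-"))
  tr <- trim_alignment_ends(msa, max_gap_fraction = 0.7)
  expect_equal(tr$seq[1], "KVD")
})
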