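# Anchoring arithmetic, cluster chaining, flanking windows, ORF extraction
# and the NBS-derived screen.

mk_anchor <- function(...) tibble::tibble(...)

test_that("anchoring follows the forward and mirrored reverse formulas", {
  at <- mk_anchor(scaffold_id = c("fw", "rv"), chromosome = "chr01",
                  chromosome_offset = c(0, 10000),
                  orientation = c("+", "-"),
                  scaffold_length = c(5000, 1000))
  genes <- tibble::tibble(gene_id = c("a", "b"), seqid = c("fw", "rv"),
                          start = c(100, 101), end = c(400, 400),
                          strand = c("+", "+"))
  got <- anchor_genes(genes, at)
  # forward at offset 0: unchanged
  expect_equal(got$chr_start[1], 100)
  expect_equal(got$chr_end[1], 400)
  expect_equal(got$chr_strand[1], "+")
  # reverse placement: gene [101,400] on a 1000 bp scaffold at offset 10000
  expect_equal(got$chr_start[2], 10000 + (1000 - 400 + 1))
  expect_equal(got$chr_end[2], 10000 + (1000 - 101 + 1))
  expect_equal(got$chr_strand[2], "-")

  # missing scaffold -> unanchored
  genes2 <- tibble::tibble(gene_id = "c", seqid = "nowhere", start = 1,
                           end = 10, strand = "+")
  got2 <- anchor_genes(genes2, at)
  expect_true(is.na(got2$chromosome))

  # extending past the scaffold is an error
  bad <- tibble::tibble(gene_id = "d", seqid = "rv", start = 900, end = 1100,
                        strand = "+")
  expect_error(anchor_genes(bad, at), "past scaffold")
})

test_that("cluster chaining matches the worked example and labels singletons", {
  at <- mk_anchor(scaffold_id = "s", chromosome = "chr01",
                  chromosome_offset = 0, orientation = "+",
                  scaffold_length = 1e6)
  genes <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"), seqid = "s",
                          start = c(1, 50001, 140001, 400001),
                          end = c(1, 50001, 140001, 400001) + 100,
                          strand = "+",
                          code = c("CNL", "CNL", "CN", "TNL"))
  cl <- detect_clusters(anchor_genes(genes, at), max_gap = 100000)
  expect_equal(nrow(cl$clusters), 1)
  expect_setequal(cl$clusters$members[[1]], c("g1", "g2", "g3"))
  expect_equal(cl$clusters$composition, "simple_CNL")
  expect_true(cl$genes$is_singleton[cl$genes$gene_id == "g4"])

  # a lone gene on a chromosome is a singleton, no cluster
  single <- detect_clusters(anchor_genes(genes[1, ], at))
  expect_equal(nrow(single$clusters), 0)
  expect_true(all(single$genes$is_singleton))
})

test_that("chaining equals brute-force connected components on random data", {
  set.seed(15)
  for (r in 1:10) {
    n <- sample(10:50, 1)
    chrom <- sample(paste0("chr0", 1:3), n, replace = TRUE)
    starts <- sample.int(2e6, n)
    genes <- tibble::tibble(gene_id = sprintf("g%03d", 1:n),
                            chromosome = chrom, chr_start = starts,
                            chr_end = starts + 100)
    cl <- detect_clusters(genes, max_gap = 100000)
    comp <- brute_clusters(chrom, starts, 100000)
    # same partition: group sizes per component
    got <- cl$genes$cluster_id
    got[is.na(got)] <- paste0("single_", seq_len(sum(is.na(got))))
    expect_equal(length(unique(paste(comp, got))), length(unique(comp)))
    # order invariance
    perm <- sample.int(n)
    cl2 <- detect_clusters(genes[perm, ], max_gap = 100000)
    expect_equal(sum(cl2$genes$is_singleton), sum(cl$genes$is_singleton))
    expect_equal(nrow(cl2$clusters), nrow(cl$clusters))
  }
})

test_that("cluster members plus singletons partition the anchored genes", {
  g <- generate_genome(synthetic_spec(seed = 3), withr::local_tempdir())
  nlr <- g$truth[g$truth$role == "nlr", ]
  anchored <- anchor_genes(
    tibble::tibble(gene_id = nlr$gene_id, seqid = nlr$scaffold_id,
                   start = nlr$start, end = nlr$end, strand = nlr$strand),
    read_anchor_table(g$paths$anchor))
  cl <- detect_clusters(anchored)
  anch <- cl$genes[!is.na(cl$genes$chromosome), ]
  in_clusters <- unlist(cl$clusters$members)
  singles <- anch$gene_id[anch$is_singleton]
  expect_setequal(c(in_clusters, singles), anch$gene_id)
  expect_equal(length(intersect(in_clusters, singles)), 0)
})

test_that("alone genes obey the strict 3 Mb rule", {
  genes <- tibble::tibble(
    gene_id = c("a", "b", "c", "d", "e"),
    chromosome = c("chr01", "chr01", "chr02", "chr02", "chr03"),
    chr_start = c(1e6, 5e6, 1e6, 1e6 + 3e6, 2e6),
    chr_end = c(1e6, 5e6, 1e6, 1e6 + 3e6, 2e6) + 1000)
  alone <- find_singletons(genes, min_dist = 3e6)
  # a,b are 4 Mb apart -> both alone; c,d exactly 3 Mb -> not alone (strict >)
  # e is its chromosome's only gene -> alone
  expect_setequal(alone$gene_id, c("a", "b", "e"))
  close_pair <- genes[1:2, ]
  close_pair$chr_start <- c(1e6, 1e6 + 1000)
  expect_equal(nrow(find_singletons(close_pair)), 0)
})

test_that("flanking windows follow the 2-NBS/100kb and 3-NBS/200kb rules", {
  sl <- c(s2 = 1e6, s3 = 1e6, s1 = 1e6, s0 = 1e6)
  genes <- tibble::tibble(
    gene_id = sprintf("g%d", 1:7),
    seqid = c("s0", "s2", "s2", "s3", "s3", "s3", "s1"),
    start = c(5e5, 4e5, 5e5, 3e5, 4e5, 5e5, 19000),
    end = c(5e5, 4e5, 5e5, 3e5, 4e5, 5e5, 19000) + 2000)
  w <- flanking_windows(genes, nbs_ids = genes$gene_id, scaffold_lengths = sl)
  expect_setequal(w$seqid, c("s2", "s3"))
  w2 <- w[w$seqid == "s2", ]
  expect_equal(w2$start, 4e5 - 1e5)
  expect_equal(w2$end, 5e5 + 2000 + 1e5)
  w3 <- w[w$seqid == "s3", ]
  expect_equal(w3$start, 3e5 - 2e5)
  expect_equal(w3$end, 5e5 + 2000 + 2e5)

  # clipping at the scaffold boundary
  two_near_end <- tibble::tibble(gene_id = c("x", "y"), seqid = "s1",
                                 start = c(19000, 60000),
                                 end = c(21000, 62000))
  wc <- flanking_windows(two_near_end, c("x", "y"), sl)
  expect_equal(wc$start, 1)
  expect_equal(wc$end, 162000)
})

test_that("ORF extraction finds planted ORFs on both strands", {
  set.seed(16)
  prot <- paste0("M", nlrscan:::random_protein(100))
  orf_dna <- nlrscan:::backtranslate(prot)
  bg1 <- nlrscan:::random_dna(500)
  bg2 <- nlrscan:::random_dna(400)
  tmpl <- paste0(bg1, orf_dna, bg2, nlrscan:::revcomp(orf_dna),
                 nlrscan:::random_dna(100))
  orfs <- extract_orfs(tmpl, min_codons = 80)
  # the planted ORF may gain an upstream in-frame extension from the random
  # background, so test containment plus the stop-codon boundary
  hit_f <- orfs[orfs$strand == "+" & grepl(prot, orfs$protein, fixed = TRUE), ]
  expect_equal(nrow(hit_f), 1)
  expect_equal(hit_f$end, 500 + nchar(orf_dna) - 3) # last sense codon
  rc_start <- 500 + nchar(orf_dna) + 400 + 1
  hit_r <- orfs[orfs$strand == "-" & grepl(prot, orfs$protein, fixed = TRUE), ]
  expect_equal(nrow(hit_r), 1)
  expect_equal(hit_r$start, rc_start + 3) # stop codon at the low end
})

test_that("the reference screen types NBS-derived, partial and stress ORFs", {
  refs <- reference_r_proteins()
  hmm <- calibrate_evalue(build_profile(seed_alignment("nbarc")),
                          n_null = 400, seed = 9)
  tpl <- nlrscan:::build_nlr_template("CNL", "cc1", nrep = 8)
  derived <- paste0(substr(tpl$seq, 1, tpl$nbs_start - 1),
                    substr(tpl$seq, tpl$nbs_end + 1, nchar(tpl$seq)))
  partial <- paste0(substr(tpl$seq, 1, tpl$nbs_start + 49),
                    substr(tpl$seq, tpl$nbs_end + 1, nchar(tpl$seq)))
  stress <- nlrscan:::with_seed(77121, paste0("M", nlrscan:::random_protein(260)))
  rand <- nlrscan:::with_seed(5, nlrscan:::random_protein(200))
  orfs <- tibble::tibble(
    orf = c("derived", "partial", "stress", "rand"),
    protein = c(derived, partial, stress, rand))
  got <- screen_nbs_derived(orfs, refs, hmm)
  expect_equal(got$call, c("nbs_derived", "partial_nbs", "resistance_like",
                           "none"))
  expect_equal(got$nbs_coverage[1], 0)
  expect_gt(got$nbs_coverage[2], 0)
  expect_lt(got$nbs_coverage[2], 0.5)
})
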