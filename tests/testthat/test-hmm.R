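# Profile-HMM construction, Viterbi search, calibration and the refinement /
# kinase-exclusion pathway.

test_that("build_profile estimates emissions with Laplace pseudocounts", {
  # column {A, A} with pseudocount 1: P(A) = (2+1)/(2+20) = 3/22
  hmm <- build_profile(toy_msa(c("AC", "AC")), pseudocount = 1)
  expect_equal(hmm$M, 2)
  expect_equal(unname(hmm$emit[1, "A"]), 3 / 22)
  expect_equal(unname(hmm$emit[1, "C"]), 1 / 22)
  expect_equal(unname(rowSums(hmm$emit)), rep(1, 2), tolerance = 1e-12)

  # zero pseudocount on identical ungapped rows: point masses
  hmm0 <- build_profile(toy_msa(rep("MKV", 3)), pseudocount = 0)
  expect_equal(unname(hmm0$emit[1, "M"]), 1)
  expect_equal(unname(hmm0$emit[2, "K"]), 1)
  expect_equal(sum(hmm0$emit[1, ] > 0), 1)
})

test_that("gappy columns are dropped from the match states", {
  # column 2 has gap fraction 0.75 > 0.5 -> excluded, M decremented
  hmm <- build_profile(toy_msa(c("A-C", "A-C", "A-C", "AWC")))
  expect_equal(hmm$M, 2)
  expect_error(build_profile(toy_msa(c("--", "--"))), "match columns")
  expect_error(build_profile(toy_msa(character(0))), "empty")
})

test_that("model is invariant to row order and distributions renormalize", {
  rows <- c("MKVD", "MKVE", "MRVD", "MKWD")
  h1 <- build_profile(toy_msa(rows))
  h2 <- build_profile(toy_msa(rev(rows)))
  expect_equal(h1$emit, h2$emit)
  expect_equal(h1$trans_lo, h2$trans_lo)
  expect_equal(unname(rowSums(h1$emit)), rep(1, h1$M), tolerance = 1e-12)
  expect_equal(unname(rowSums(2^h1$trans_lo[, c("MM", "MI", "MD")])),
               rep(1, h1$M), tolerance = 1e-12)
})

test_that("Viterbi equals exhaustive path enumeration on tiny models", {
  set.seed(41)
  for (rep in 1:12) {
    m_len <- sample(2:3, 1)
    rows <- replicate(3, nlrscan:::random_protein(m_len))
    hmm <- build_profile(toy_msa(rows))
    protein <- nlrscan:::random_protein(sample(2:5, 1))
    got <- viterbi(hmm, protein)$score
    want <- enumerate_viterbi(hmm, protein)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("the consensus of a zero-pseudocount profile takes the all-match path", {
  rows <- rep("MKVDEW", 3)
  hmm <- build_profile(toy_msa(rows), pseudocount = 0)
  v <- viterbi(hmm, "MKVDEW")
  expect_equal(v$n_match, hmm$M)
  expect_equal(v$t_start, 1)
  expect_equal(v$t_end, 6)
  want <- sum(hmm$emit_lo[cbind(1:6, nlrscan:::aa_to_int("MKVDEW"))]) +
    log2(1 / hmm$M)
  expect_equal(v$score, want, tolerance = 1e-9)
})

test_that("a planted NB-ARC protein outscores its shuffle, 100/100 seeds", {
  hmm <- build_profile(seed_alignment("nbarc"))
  cons <- nbs_consensus("cc1")$seq
  wins <- vapply(1:100, function(s) {
    nlrscan:::with_seed(s, {
      planted <- paste0(nlrscan:::random_protein(40),
                        nlrscan:::mutate_protein(cons, 0.1),
                        nlrscan:::random_protein(40))
      shuffled <- paste(sample(strsplit(planted, "")[[1]]), collapse = "")
      viterbi(hmm, planted)$score > viterbi(hmm, shuffled)$score
    })
  }, logical(1))
  expect_true(all(wins))
})

test_that("calibration fixes a Gumbel tail that matches the empirical null", {
  hmm <- build_profile(seed_alignment("nbarc"))
  hmm <- calibrate_evalue(hmm, n_null = 1000, null_length = 350, seed = 5)
  expect_gt(hmm$calibration$lambda, 0)
  # empirical fraction of null scores with P <= 0.01 is near 0.01
  scores <- nlrscan:::with_seed(99, vapply(1:1000, function(i)
    viterbi(hmm, nlrscan:::random_protein(350))$score, numeric(1)))
  pvals <- -expm1(-exp(-hmm$calibration$lambda *
                         (scores - hmm$calibration$mu)))
  frac <- mean(pvals <= 0.01)
  expect_gte(frac, 0.005)
  expect_lte(frac, 0.02)
})

test_that("E-values scale linearly with database size and are monotone", {
  hmm <- build_profile(seed_alignment("nbarc"))
  hmm <- calibrate_evalue(hmm, n_null = 300, null_length = 200, seed = 5)
  e1 <- hmm_evalue(hmm, 40, n_targets = 100)
  e2 <- hmm_evalue(hmm, 40, n_targets = 200)
  expect_equal(e2, 2 * e1)
  # the score needed for E = 1e-60 exceeds the score for E = 1e-2
  sc <- seq(0, 2000, by = 0.5)
  ev <- hmm_evalue(hmm, sc, 100)
  expect_gt(min(sc[ev <= 1e-60]), min(sc[ev <= 1e-2]))
})

test_that("search results nest across thresholds and sort deterministically", {
  nlr <- nlrscan:::with_seed(8, purrr::map_chr(1:6, function(i)
    generate_nlr_protein(sample(c("CNL", "TNL", "N_CC"), 1))$record$seq))
  bg <- nlrscan:::with_seed(9, purrr::map_chr(1:30, function(i)
    nlrscan:::random_protein(300)))
  prots <- tibble::tibble(id = sprintf("p%02d", 1:36), seq = c(nlr, bg))
  hmm <- calibrate_evalue(build_profile(seed_alignment("nbarc")),
                          n_null = 500, seed = 3)
  hits_loose <- search_proteome(hmm, prots, 1e-2)
  hits_strict <- search_proteome(hmm, prots, 1e-60)
  expect_true(all(hits_strict$target_id %in% hits_loose$target_id))
  expect_true(all(prots$id[1:6] %in% hits_loose$target_id))
  expect_false(any(prots$id[7:36] %in% hits_loose$target_id))
  expect_equal(hits_loose$evalue, sort(hits_loose$evalue))
  expect_equal(nrow(search_proteome(hmm, prots[0, ], 1e-2)), 0)
})

test_that("two-pass refinement keeps planted NBS and supersets the strict set", {
  set.seed(10)
  nlr <- purrr::map_chr(1:12, function(i)
    generate_nlr_protein(sample(c("CNL", "TNL", "NL_CC"), 1))$record$seq)
  kin_tpl <- nlrscan:::with_seed(55901, paste0(
    "M", nlrscan:::NLR_MOTIF$ploop, nlrscan:::random_protein(20),
    nlrscan:::NLR_MOTIF$kinase, nlrscan:::random_protein(160)))
  kin <- purrr::map_chr(1:8, function(i)
    nlrscan:::mutate_protein(kin_tpl, 0.05, protect = 2:13))
  bg <- purrr::map_chr(1:40, function(i) nlrscan:::random_protein(300))
  prots <- tibble::tibble(id = sprintf("p%02d", seq_len(60)),
                          seq = c(nlr, kin, bg))
  seed_hmm <- calibrate_evalue(build_profile(seed_alignment("nbarc")),
                               n_null = 500, seed = 3)
  expect_error(refine_species_model(prots, seed_hmm, strict = 1e-2,
                                    relaxed = 1e-60), "strict")
  ref <- refine_species_model(prots, seed_hmm, seed = 4)
  # planted recall before kinase filtering
  expect_true(all(prots$id[1:12] %in% ref$hits$target_id))
  # stage-3 superset of stage-1
  expect_true(all(ref$stage1_hits$target_id %in% ref$hits$target_id))
  # no random background present
  expect_false(any(prots$id[21:60] %in% ref$hits$target_id))

  # kinase filter removes the decoys and equals the brute-force comparison
  kin_hmm <- calibrate_evalue(build_profile(seed_alignment("kinase")),
                              n_null = 500, seed = 6)
  kept <- kinase_filter(ref$hits, prots, kin_hmm)
  expect_true(all(prots$id[1:12] %in% kept$target_id))
  expect_false(any(prots$id[13:20] %in% kept$target_id))
  brute_removed <- vapply(seq_len(nrow(ref$hits)), function(i) {
    s <- prots$seq[match(ref$hits$target_id[i], prots$id)]
    viterbi(kin_hmm, s)$score > ref$hits$bits[i]
  }, logical(1))
  expect_setequal(kept$target_id, ref$hits$target_id[!brute_removed])
})

test_that("profile serialization round trips scores and calibration", {
  hmm <- calibrate_evalue(build_profile(seed_alignment("nbs_tir"),
                                        name = "tirsub"),
                          n_null = 200, null_length = 150, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_hmm(hmm, f)
  back <- read_profile_hmm(f)
  expect_equal(back$M, hmm$M)
  expect_equal(back$emit, hmm$emit, tolerance = 1e-8)
  expect_equal(back$calibration$lambda, hmm$calibration$lambda,
               tolerance = 1e-6)
  p <- nlrscan:::with_seed(1, nlrscan:::random_protein(120))
  expect_equal(viterbi(back, p)$score, viterbi(hmm, p)$score,
               tolerance = 1e-6)
})
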