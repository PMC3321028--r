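# Domain scans, signature typing, the eight-way architecture call, and EM
# motif discovery.

test_that("scan_pssm hits equal brute-force window scores", {
  pssms <- nlrscan:::packaged_pssms()
  tir <- pssms$tir
  prot <- nlrscan:::with_seed(3, paste0(
    nlrscan:::random_protein(5), nlrscan:::NLR_MOTIF$tir,
    nlrscan:::random_protein(40)))
  hits <- scan_pssm(prot, tir)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 6L)
  # brute-force window score oracle
  s <- nlrscan:::aa_to_int(prot)
  W <- tir$width
  brute <- vapply(seq_len(nchar(prot) - W + 1), function(p) {
    sum(tir$log_odds[cbind(seq_len(W), s[p:(p + W - 1)])])
  }, numeric(1))
  expect_equal(hits$score, max(brute), tolerance = 1e-9)
  expect_equal(hits$start, which.max(brute))

  # homopolymer protein yields nothing
  expect_equal(nrow(scan_pssm(strrep("P", 200), tir)), 0)
})

test_that("scan_pssm brute-force equivalence holds for random PSSMs", {
  set.seed(12)
  for (r in 1:8) {
    W <- sample(3:8, 1)
    probs <- matrix(stats::rgamma(W * 20, 0.4), W, 20)
    pssm <- new_pssm(probs / rowSums(probs), threshold = -Inf)
    prot <- nlrscan:::random_protein(40)
    s <- nlrscan:::aa_to_int(prot)
    brute <- vapply(seq_len(40 - W + 1), function(p)
      sum(pssm$log_odds[cbind(seq_len(W), s[p:(p + W - 1)])]), numeric(1))
    hits <- scan_pssm(prot, pssm)
    # every reported hit score matches its brute-force window score
    expect_equal(hits$score, brute[hits$start], tolerance = 1e-9)
    expect_equal(max(hits$score), max(brute), tolerance = 1e-9)
  }
})

test_that("threshold at the maximum window score keeps only argmax windows", {
  pssm <- nlrscan:::packaged_pssms()$glpl
  prot <- nlrscan:::with_seed(5, paste0(nlrscan:::random_protein(20),
                                        nlrscan:::NLR_MOTIF$glpl,
                                        nlrscan:::random_protein(20)))
  all_hits <- scan_pssm(prot, new_pssm(2^pssm$log_odds *
                                         rep(nlrscan:::ROBINSON_BG, each = pssm$width),
                                       threshold = -Inf))
  pssm2 <- pssm
  pssm2$threshold <- max(all_hits$score)
  at_max <- scan_pssm(prot, pssm2)
  expect_equal(nrow(at_max), 1)
  expect_equal(at_max$score, max(all_hits$score))
})

test_that("coiled-coil scan finds an ideal heptad block at any phase", {
  for (shift in 0:6) {
    cc <- substr(strrep("LEELQKA", 7), shift + 1, shift + 35)
    prot <- nlrscan:::with_seed(30 + shift, paste0(
      nlrscan:::random_protein(10), cc, nlrscan:::random_protein(30)))
    seg <- coiled_coil_scan(prot)
    expect_equal(nrow(seg), 1)
    # segment overlaps the planted block [11, 45]
    expect_lt(seg$start, 46)
    expect_gt(seg$end, 10)
    expect_true(seg$validated)
  }
  expect_equal(nrow(coiled_coil_scan(strrep("P", 100))), 0)
})

test_that("one window of the ideal heptad scores as the hand formula says", {
  tab <- nlrscan:::heptad_table()
  block <- strrep("LEELQKA", 4) # exactly 28 residues, phase 0
  res <- nlrscan:::aa_to_int(block)
  cls <- ((seq_len(28) - 1) %% 7) + 1
  hand <- sum(tab[cbind(res, cls)])
  # 4 heptads x (L@a + E@b + E@c + L@d + Q@e + K@f + A@g)
  expect_equal(hand, 4 * (2.2 + 0.6 + 0.6 + 2.2 + 0.9 + 0.6 + 0.3))
  expect_gt(stats::plogis((hand - 18) / 1.5), 0.99)
})

test_that("NBS subdomains are found in order with completeness flagged", {
  set.seed(44)
  p <- generate_nlr_protein("CNL")
  prot <- p$record$seq
  off <- p$truth$offsets[[1]]
  sd <- find_nbs_subdomains(prot)
  expect_true(sd$complete)
  expect_equal(sd$hits$kind, c("PLOOP", "KINASE2", "KINASE3A", "GLPL"))
  for (m in c("ploop", "kinase2", "kinase3a", "glpl")) {
    want <- off$start[off$motif == m]
    got <- sd$hits$start[tolower(sd$hits$kind) == m]
    expect_equal(got, want)
  }

  # remove the GLPL: three hits, not complete
  glpl_start <- off$start[off$motif == "glpl"]
  broken <- paste0(substr(prot, 1, glpl_start - 1),
                   strrep("P", 8),
                   substr(prot, glpl_start + 8, nchar(prot)))
  sd2 <- find_nbs_subdomains(broken)
  expect_false(sd2$complete)
  expect_equal(nrow(sd2$hits), 3)
})

test_that("ordered-subset selection equals exhaustive search when order breaks", {
  # plant GLPL before the P-loop: the selector must drop the cheaper motif
  m <- nlrscan:::NLR_MOTIF
  prot <- nlrscan:::with_seed(7, paste0(
    nlrscan:::random_protein(10), m$glpl, nlrscan:::random_protein(10),
    m$ploop, nlrscan:::random_protein(10), m$k2_cc,
    nlrscan:::random_protein(10), m$k3a, nlrscan:::random_protein(10)))
  sd <- find_nbs_subdomains(prot)
  pssms <- nlrscan:::packaged_pssms()
  # exhaustive oracle over all single-hit combinations
  cand <- purrr::map(c("ploop", "kinase2", "kinase3a", "glpl"), function(nm)
    scan_pssm(prot, pssms[[nm]]))
  combos <- expand.grid(purrr::map(cand, function(h) 0:nrow(h)))
  best <- -Inf
  for (r in seq_len(nrow(combos))) {
    sel <- purrr::map2(cand, as.integer(combos[r, ]),
                       function(h, k) if (k) h[k, ] else h[0, ])
    sel <- dplyr::bind_rows(sel)
    if (nrow(sel) > 1 &&
        (any(diff(sel$start) <= 0) ||
         any(sel$start[-1] <= sel$end[-nrow(sel)]))) next
    best <- max(best, sum(sel$score))
  }
  expect_equal(sum(sd$hits$score), best, tolerance = 1e-9)
  expect_false(sd$complete)
})

test_that("the kinase-2 terminal residue decides the NBS signature", {
  set.seed(51)
  cc_prot <- generate_nlr_protein("N_CC")$record$seq
  tir_prot <- generate_nlr_protein("N_TIR")$record$seq
  sig_cc <- classify_signature(cc_prot, find_nbs_subdomains(cc_prot))
  sig_tir <- classify_signature(tir_prot, find_nbs_subdomains(tir_prot))
  expect_equal(sig_cc$type, "CC_type")
  expect_equal(sig_cc$kinase2_terminal, "W")
  expect_equal(sig_tir$type, "TIR_type")
  expect_equal(sig_tir$kinase2_terminal, "D")
  # sub-profile fallback agrees
  expect_gt(sig_cc$cc_score, sig_cc$tir_score)
  expect_gt(sig_tir$tir_score, sig_tir$cc_score)
})

test_that("signature is undetermined without kinase-2 and with tied scores", {
  empty_hits <- list(hits = tibble::tibble(kind = character(),
                                           start = integer(),
                                           end = integer(), score = numeric()))
  same <- build_profile(seed_alignment("nbs_cc"))
  sig <- classify_signature(strrep("A", 60), empty_hits, same, same)
  expect_equal(sig$type, "undetermined")
})

test_that("all eight architecture codes are reachable and pure", {
  sig_cc <- list(type = "CC_type")
  sig_tir <- list(type = "TIR_type")
  hit <- function(kind, n = 1) tibble::tibble(
    kind = rep(kind, n), start = seq(1, by = 40, length.out = n),
    end = seq(30, by = 40, length.out = n), score = 10)
  cases <- list(
    list(dplyr::bind_rows(hit("CC"), hit("LRR", 3)), sig_cc, "CNL"),
    list(hit("CC"), sig_cc, "CN"),
    list(hit("LRR", 3), sig_cc, "NL_CC"),
    list(hit("CC", 0), sig_cc, "N_CC"),
    list(dplyr::bind_rows(hit("TIR"), hit("LRR", 3)), sig_tir, "TNL"),
    list(hit("TIR"), sig_tir, "TN"),
    list(hit("LRR", 3), sig_tir, "NL_TIR"),
    list(hit("TIR", 0), sig_tir, "N_TIR"))
  for (cs in cases) {
    call <- assign_architecture(cs[[1]], cs[[2]], nbs_coverage = 1)
    expect_equal(call$code, cs[[3]])
    # purity: same hits, same code
    expect_equal(assign_architecture(cs[[1]], cs[[2]], 1)$code, cs[[3]])
  }
  # low coverage always yields PARTIAL
  expect_equal(assign_architecture(cases[[1]][[1]], sig_cc, 0.3)$code,
               "PARTIAL")
  # CC + TIR conflict resolves to the TIR branch and is flagged
  both <- dplyr::bind_rows(hit("CC"), hit("TIR"), hit("LRR", 3))
  call <- assign_architecture(both, sig_cc, 1)
  expect_equal(call$code, "TNL")
  expect_true(call$conflict)
})

test_that("synthetic proteins of every class classify to their truth code", {
  set.seed(77)
  for (code in nlrscan:::NLR_CLASS_CODES) {
    for (r in 1:3) {
      prot <- generate_nlr_protein(code)$record$seq
      got <- classify_architectures(tibble::tibble(id = "x", seq = prot))
      expect_equal(got$code, code)
    }
  }
  expect_error(generate_nlr_protein("XXX"), "unknown")
})

test_that("EM motif discovery recovers a planted motif", {
  seqs <- planted_motif_set(n = 20, len = 60, motif = "WHKDEWYA")
  pssm <- em_discover_motif(seqs, width = 8, n_starts = 10, seed = 2)
  expect_equal(attr(pssm, "consensus"), "WHKDEWYA")
  # EM log-likelihood is non-decreasing
  trace <- attr(pssm, "loglik_trace")
  expect_true(all(diff(trace) >= -1e-6))
  # determinism
  pssm2 <- em_discover_motif(seqs, width = 8, n_starts = 10, seed = 2)
  expect_equal(attr(pssm2, "loglik"), attr(pssm, "loglik"))
})

test_that("EM on identical sequences converges to near-unit columns", {
  seqs <- rep("MKVDEWYALLRRSTG", 6)
  pssm <- em_discover_motif(seqs, width = 6, n_starts = 4, seed = 3)
  probs <- 2^pssm$log_odds * rep(nlrscan:::ROBINSON_BG, each = pssm$width)
  expect_true(all(apply(probs, 1, max) > 0.9))
  expect_error(em_discover_motif(seqs, width = 50), "width")
  expect_error(em_discover_motif(seqs[1:3], width = 6), "at least 5")
})
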