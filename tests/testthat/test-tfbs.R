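test_that("expected_match_count has the right closed-form corners", {
  # d = l: every window matches
  expect_equal(expected_match_count("ACG", 10, 3), 8)
  # single position, exact match, uniform DNA
  expect_equal(expected_match_count("A", 1, 0), 0.25)
  # frozen from exhaustive averaging over all 16 two-letter windows:
  # P(h <= 1) = (1 + 2*3/4... ) = 7/16 per window
  expect_equal(expected_match_count("AC", 2, 1), 7 / 16)
})

test_that("expected_match_count equals exhaustive window averaging", {
  set.seed(83)
  for (i in 1:6) {
    l <- sample(2:4, 1); d <- sample(0:2, 1)
    motif <- random_string(l)
    all <- r_all_lmers(l)
    p_hit <- mean(vapply(all, function(w) r_hamming(w, motif) <= d,
                         logical(1)))
    m <- sample(l:20, 1)
    expect_equal(expected_match_count(motif, m, d), (m - l + 1) * p_hit)
  }
})

test_that("expected_match_count respects non-uniform backgrounds", {
  bg <- c(A = 0.7, C = 0.1, G = 0.1, T = 0.1)
  # exact-match probability of "AA" is 0.49 per window
  expect_equal(expected_match_count("AA", 2, 0, background = bg), 0.49)
  # exhaustive check at l = 2, d = 1
  all <- r_all_lmers(2)
  pz <- vapply(strsplit(all, ""), function(ch) prod(bg[ch]), numeric(1))
  want <- sum(pz[vapply(all, r_hamming, numeric(1), b = "AC") <= 1])
  expect_equal(expected_match_count("AC", 2, 1, background = bg), want)
})

test_that("expected_match_count agrees with Monte-Carlo within 3 SE", {
  set.seed(87)
  for (d in 0:2) {
    motif <- random_string(6)
    nrep <- 100000
    wins <- matrix(sample(DNA, 6 * nrep, replace = TRUE), ncol = 6)
    mot <- strsplit(motif, "")[[1]]
    hits <- rowSums(t(t(wins) != mot)) <= d
    p_hat <- mean(hits)
    se <- sqrt(p_hat * (1 - p_hat) / nrep)
    p_dp <- expected_match_count(motif, 6, d)
    expect_lt(abs(p_dp - p_hat), 3 * se + 1e-12)
  }
})

test_that("sequence specificity is additive across sequences", {
  seqs1 <- seq_set("ACGTACGTAC")
  seqs2 <- seq_set(c("ACGTACGTAC", "ACGTACGTAC"))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  s1 <- sequence_specificity(seqs1, "ACGT", 1, background = bg)
  s2 <- sequence_specificity(seqs2, "ACGT", 1, background = bg)
  expect_equal(s2, 2 * s1)
  expect_equal(s1, log(expected_match_count("ACGT", 10, 1, background = bg)))
  # d = l: score is sum log (m_i - l + 1)
  expect_equal(sequence_specificity(seqs2, "ACGT", 4, background = bg),
               2 * log(7))
})

test_that("phase I finds planted motifs within its grid and stops at first d", {
  inst <- generate_planted_instance(n = 6, m = 60, l = 7, d = 1, q = 6,
                                    seed = 303)
  cand <- phase1_select(inst$seqs, l_min = 6, l_max = 8,
                        d_max = function(l) 2, time_budget = 60)
  expect_true(inst$motif %in% cand$motif)
  found_at <- cand[cand$motif == inst$motif, ]
  expect_lte(found_at$d[1], 1)
  expect_equal(cand, dplyr::arrange(cand, score, motif))

  # exact common l-mer: found at d = 0 and the d loop stops there
  seqs <- seq_set(c("TTTACGGGAAC", "CCTACGGGATT", "GGTACGGGACT"))
  cand0 <- phase1_select(seqs, l_min = 7, l_max = 7,
                         d_max = function(l) 2, time_budget = 60)
  expect_true("TACGGGA" %in% cand0$motif)
  expect_true(all(cand0$d == 0))

  # zero budget: clean empty result
  expect_equal(nrow(phase1_select(inst$seqs, l_min = 6, l_max = 8,
                                  time_budget = 0)), 0)
})

test_that("phase II reports exactly the planted coordinates at d_site = 0", {
  inst <- generate_planted_instance(n = 5, m = 50, l = 6, d = 0, q = 5,
                                    seed = 404)
  cand <- tibble::tibble(motif = inst$motif, l = 6L, d = 0L, score = -10)
  sites <- phase2_sites(inst$seqs, cand, k_top = 1, d_site = 0)
  # every plant is reported
  found <- paste(sites$id, sites$start)
  planted <- paste(inst$plants$id, inst$plants$offset)
  expect_true(all(planted %in% found))
  # and every reported site is an exact motif occurrence
  expect_true(all(sites$distance == 0))
  expect_true(all(sites$site == inst$motif))
  expect_equal(sites$end, sites$start + 6L)
})

test_that("phase II ordering, k_top and empty input behave as documented", {
  seqs <- seq_set(c("AAACGTTT", "CCACGTGG"))
  cand <- tibble::tibble(motif = c("CCCC", "ACGT", "TTTT"),
                         l = 4L, d = c(1L, 1L, 1L),
                         score = c(5, -2, -2))
  sites <- phase2_sites(seqs, cand, k_top = 2)
  # ties broken lexicographically: ACGT before TTTT; CCCC dropped by k_top
  expect_false("CCCC" %in% sites$motif)
  expect_true(all(sites$motif %in% c("ACGT", "TTTT")))
  # k_top larger than candidate count uses everything
  sites_all <- phase2_sites(seqs, cand, k_top = 10)
  expect_true("CCCC" %in% sites_all$motif ||
              !any(grepl("CCCC", seqs$seq)))
  # empty candidates give an empty, well-typed frame
  empty <- phase2_sites(seqs, cand[0, ])
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("id", "start", "end", "site", "distance", "motif",
                        "score"))
  # determinism
  expect_identical(sites, phase2_sites(seqs, cand, k_top = 2))
})

test_that("planted motif ranks first by specificity among same-(l,d) candidates", {
  # replicated seeded planted datasets: the planted motif should out-rank
  # spurious candidates found at the planted (l, d) in nearly all replicates
  set.seed(91)
  wins <- 0L
  total <- 20L
  for (i in seq_len(total)) {
    inst <- generate_planted_instance(n = 8, m = 80, l = 8, d = 1, q = 8,
                                      seed = 7000 + i)
    fit <- pms_search(inst$seqs, 8, 1, 8, algorithm = "qpms7",
                      evidence = FALSE)
    sc <- vapply(fit$motifs$motif, function(mm)
      sequence_specificity(inst$seqs, mm, 1), numeric(1))
    best <- fit$motifs$motif[order(sc, fit$motifs$motif)][1]
    if (identical(best, inst$motif)) wins <- wins + 1L
  }
  expect_gte(wins / total, 0.9)
})
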