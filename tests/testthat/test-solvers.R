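test_that("brute force matches the definition-direct oracle", {
  toy <- seq_set(c("ACGTA", "TACGT", "CCGTT"))
  got <- tidy(pms_search(toy, 3, 1, 3, algorithm = "brute"))
  expect_true("ACG" %in% got$motif)
  expect_equal(got$motif, r_motif_search(c("ACGTA", "TACGT", "CCGTT"), 3, 1, 3))
  # (l, d=l-? ) degenerate: d = l - 1 over tiny strings is near-everything
  set.seed(41)
  for (i in 1:10) {
    strings <- vapply(1:3, function(j) random_string(10), character(1))
    l <- sample(2:4, 1); d <- sample(0:(l - 1), 1); q <- sample(1:3, 1)
    got <- tidy(pms_search(seq_set(strings), l, d, q, algorithm = "brute",
                           evidence = FALSE))$motif
    expect_equal(got, r_motif_search(strings, l, d, q))
  }
})

test_that("full and union-of-balls candidate generation agree", {
  set.seed(43)
  for (i in 1:8) {
    seqs <- random_seq_set(4, 25)
    l <- sample(4:6, 1); d <- sample(1:2, 1); q <- sample(2:4, 1)
    full <- tidy(pms_search(seqs, l, d, q, algorithm = "brute",
                            brute_mode = "full", evidence = FALSE))$motif
    un <- tidy(pms_search(seqs, l, d, q, algorithm = "brute",
                          brute_mode = "union", evidence = FALSE))$motif
    expect_identical(full, un)
  }
})

test_that("brute force refuses oversized full enumeration", {
  seqs <- random_seq_set(3, 30)
  expect_error(
    pms_search(seqs, 12, 2, 3, algorithm = "brute", brute_mode = "full",
               brute_cap = 1e4),
    "cap"
  )
})

test_that("all engines return identical motif sets, filter on and off", {
  set.seed(47)
  for (i in 1:25) {
    n <- sample(4:7, 1)
    seqs <- random_seq_set(n, sample(20:45, 1))
    l <- sample(5:8, 1); d <- sample(1:2, 1)
    q <- sample(c(n, n - 1, n - 2), 1)
    for (filt in c(FALSE, TRUE)) {
      res <- all_engine_motifs(seqs, l, d, q, filter = filt)
      expect_identical(res$prune, res$brute, info = paste("i =", i))
      expect_identical(res$pruneI, res$brute, info = paste("i =", i))
      expect_identical(res$seven, res$brute, info = paste("i =", i))
    }
  }
})

test_that("engines agree on protein instances", {
  set.seed(53)
  for (i in 1:6) {
    n <- sample(4:5, 1)
    seqs <- random_seq_set(n, sample(15:25, 1), symbols = PROTEIN)
    l <- sample(3:4, 1); d <- 1
    q <- sample(c(n, n - 1), 1)
    res <- all_engine_motifs(seqs, l, d, q)
    expect_identical(res$prune, res$brute)
    expect_identical(res$pruneI, res$brute)
    expect_identical(res$seven, res$brute)
  }
})

test_that("d = 0 reduces to exact common l-mers", {
  seqs <- seq_set(c("AACGTT", "CCACGG", "TTACGA"))
  for (a in c("brute", "qpmsprune", "qpmspruneI", "qpms7")) {
    got <- tidy(pms_search(seqs, 3, 0, 3, algorithm = a, evidence = FALSE))
    expect_equal(got$motif, "ACG", info = a)
  }
})

test_that("q = n = 2 qPMS7 equals the intersection of window ball unions", {
  set.seed(59)
  for (i in 1:6) {
    seqs <- random_seq_set(2, 15)
    l <- 4; d <- sample(1:2, 1)
    got <- tidy(pms_search(seqs, l, d, 2, algorithm = "qpms7",
                           evidence = FALSE))$motif
    balls <- lapply(seqs$seq, function(s) {
      unique(unlist(lapply(r_windows(s, l), r_ball, d = d)))
    })
    expect_identical(got, sort(intersect(balls[[1]], balls[[2]])))
  }
})

test_that("monotonicity: motif sets grow as d rises or q falls", {
  set.seed(61)
  for (i in 1:8) {
    n <- sample(4:6, 1)
    seqs <- random_seq_set(n, sample(20:35, 1))
    l <- sample(4:6, 1); d <- 1; q <- sample(3:n, 1)
    base <- tidy(pms_search(seqs, l, d, q, algorithm = "qpms7",
                            evidence = FALSE))$motif
    up_d <- tidy(pms_search(seqs, l, d + 1, q, algorithm = "qpms7",
                            evidence = FALSE))$motif
    dn_q <- tidy(pms_search(seqs, l, d, q - 1, algorithm = "qpms7",
                            evidence = FALSE))$motif
    expect_true(all(base %in% up_d))
    expect_true(all(base %in% dn_q))
  }
})

test_that("surviving lists change work, never results", {
  set.seed(67)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    seqs <- random_seq_set(n, sample(25:40, 1))
    l <- sample(5:7, 1); d <- sample(1:2, 1); q <- sample((n - 1):n, 1)
    plain <- pms_search(seqs, l, d, q, algorithm = "qpmsprune",
                        evidence = FALSE)
    lists <- pms_search(seqs, l, d, q, algorithm = "qpmspruneI",
                        evidence = FALSE)
    expect_identical(lists$motifs$motif, plain$motifs$motif)
    expect_lte(lists$stats$distance_updates, plain$stats$distance_updates)
    expect_lte(lists$stats$nodes_visited, plain$stats$nodes_visited)
  }
})

test_that("preprocess_filter keeps exactly the 2d-supported windows", {
  seqs <- seq_set(c("AAA", "AAC"))
  keep <- preprocess_filter(seqs, l = 3, d = 0, q = 2)
  expect_equal(keep[[1]], integer(0))  # "AAA" has no exact partner
  expect_equal(keep[[2]], integer(0))
  # 2d >= l removes nothing
  seqs2 <- random_seq_set(4, 20)
  keep2 <- preprocess_filter(seqs2, l = 4, d = 2, q = 4)
  expect_true(all(vapply(keep2, length, integer(1)) == 20 - 4 + 1))
  # planted occurrences always survive the filter
  set.seed(71)
  inst <- generate_planted_instance(n = 6, m = 40, l = 6, d = 1, q = 6,
                                    seed = 404)
  keep3 <- preprocess_filter(inst$seqs, l = 6, d = 1, q = 6)
  for (r in seq_len(nrow(inst$plants))) {
    expect_true(inst$plants$offset[r] %in% keep3[[inst$plants$seq_index[r]]])
  }
})

test_that("planted motifs are always recovered at quorum", {
  set.seed(73)
  for (i in 1:5) {
    n <- sample(5:7, 1); q <- sample(3:n, 1)
    inst <- generate_planted_instance(n = n, m = 30, l = 5, d = 1, q = q,
                                      seed = 1000 + i)
    for (a in c("brute", "qpmsprune", "qpmspruneI", "qpms7")) {
      got <- tidy(pms_search(inst$seqs, 5, 1, q, algorithm = a,
                             evidence = FALSE))$motif
      expect_true(inst$motif %in% got, info = paste(a, "i =", i))
    }
  }
})

test_that("reports carry consistent support and evidence", {
  toy <- seq_set(c("ACGTA", "TACGT", "CCGTT"))
  fit <- pms_search(toy, 3, 1, 3, algorithm = "brute")
  expect_true(all(fit$motifs$support >= 3))
  ev <- fit$evidence[fit$evidence$motif == "ACG", ]
  expect_equal(ev$distance, c(0L, 0L, 1L))  # ACG exact in seq1 and seq2
  rep <- assemble_report(toy, "ACG", d = 1, q = 3)
  expect_equal(rep$distance, c(0L, 0L, 1L))
  expect_equal(rep$offsets[[1]], 0L)
  expect_equal(rep$offsets[[2]], 1L)
  expect_equal(attr(rep, "support"), 3L)
  # quorum contract violation
  expect_error(assemble_report(toy, "AAA", d = 0, q = 2),
               class = "qpms_param_error")
})

test_that("parameter validation raises classed errors", {
  toy <- random_seq_set(3, 10)
  expect_error(pms_search(toy, 4, 4, 3), class = "qpms_param_error")
  expect_error(pms_search(toy, 4, 1, 5), class = "qpms_param_error")
  expect_error(pms_search(toy, 11, 1, 3), class = "qpms_param_error")
  expect_error(pms_search(toy, 4, 1, 1, algorithm = "qpms7"),
               class = "qpms_param_error")
})

test_that("qPMS7 handles q < n via the extended pivot-pair range", {
  # q = n - 2 exercises r2 up to n - q + 2 = 4 pivot sequences
  set.seed(79)
  for (i in 1:6) {
    seqs <- random_seq_set(6, 25)
    got <- all_engine_motifs(seqs, 5, 1, 4)
    expect_identical(got$seven, got$brute)
  }
})
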