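test_that("ball_size matches the closed form and brute enumeration", {
  expect_equal(ball_size(3, 0, 4), 1)
  expect_equal(ball_size(2, 2, 4), 16)
  expect_equal(ball_size(3, 1, 4), 10)  # frozen from brute force over 64 3-mers
  expect_error(ball_size(3, 4, 4), class = "qpms_param_error")
  set.seed(3)
  for (i in 1:10) {
    l <- sample(2:5, 1); d <- sample(0:l, 1)
    expect_equal(ball_size(l, d, 4), length(r_ball(random_string(l), d)))
  }
})

test_that("enumerate_ball yields each member exactly once", {
  expect_equal(enumerate_ball("AC", 0), "AC")
  b <- enumerate_ball("AC", 1)
  expect_length(b, 7)
  expect_setequal(b, c("AC", "CC", "GC", "TC", "AA", "AG", "AT"))
  expect_setequal(enumerate_ball("GG", 2), r_all_lmers(2))  # d = l: whole space
  set.seed(5)
  for (i in 1:10) {
    l <- sample(2:6, 1); d <- sample(0:min(l, 3), 1)
    x <- random_string(l)
    b <- enumerate_ball(x, d)
    expect_equal(anyDuplicated(b), 0L)
    expect_setequal(b, r_ball(x, d))
  }
})

test_that("mutation-tree traversal mirrors the ball with depth = distance", {
  res <- dfs_mutation_tree("AA", 1)
  expect_equal(res$nodes, 7L)
  expect_equal(res$members,
               c("AA", "CA", "GA", "TA", "AC", "AG", "AT"))
  expect_equal(dfs_mutation_tree("ACGT", 0)$nodes, 1L)
  set.seed(9)
  for (i in 1:5) {
    l <- sample(2:5, 1); d <- sample(0:l, 1)
    x <- random_string(l)
    res <- dfs_mutation_tree(x, d)
    expect_equal(res$nodes, ball_size(l, d, 4))
    expect_equal(sort(res$members), sort(enumerate_ball(x, d)))
    expect_equal(anyDuplicated(res$members), 0L)
  }
})

test_that("visitor enter/leave calls are properly nested with correct depths", {
  events <- list()
  dfs_mutation_tree("ACG", 2, visitor = function(t, p, depth, event) {
    events[[length(events) + 1L]] <<- list(t = t, p = p, depth = depth,
                                           event = event)
  })
  stack <- character()
  for (e in events) {
    expect_equal(e$depth, r_hamming(e$t, "ACG"))
    if (e$event == "enter") {
      stack <- c(stack, e$t)
    } else {
      expect_equal(e$t, stack[length(stack)])
      stack <- stack[-length(stack)]
    }
  }
  expect_length(stack, 0)
})

test_that("min_descendant_distance equals the brute-force subtree minimum", {
  expect_equal(min_descendant_distance("AAAA", 0, 0, "AAAA", 2), 0L)
  expect_equal(min_descendant_distance("AAAA", 0, 0, "TTTT", 2), 2L)
  set.seed(17)
  for (i in 1:8) {
    l <- sample(3:5, 1); d <- sample(1:min(l, 3), 1)
    x <- random_string(l)
    y <- random_string(l)
    nodes <- quorumotif:::cpp_ball_nodes(
      quorumotif:::encode_lmer(x, motif_alphabet("dna")), d, 4L)
    # walk every node; brute-force its descendant set from the member list
    members <- apply(nodes$members, 1, function(cc)
      paste(DNA[cc + 1], collapse = ""))
    for (k in seq_along(members)) {
      t <- members[k]; p <- nodes$p[k]; depth <- nodes$depth[k]
      # descendants of (t,p): members agreeing with t on positions 1..p
      pref <- function(z) substr(z, 1, p)
      desc <- members[vapply(members, function(z) {
        pref(z) == pref(t) && r_hamming(z, x) >= depth
      }, logical(1))]
      # refine: true descendants also agree with x beyond p wherever t does...
      # exact definition: z is in the subtree iff z == t on 1..p and
      # h(prefix) == depth (all its mutations at <= p are exactly t's)
      desc <- desc[vapply(desc, function(z) {
        sum(strsplit(pref(z), "")[[1]] != strsplit(substr(x, 1, p), "")[[1]]) == depth
      }, logical(1))]
      want <- min(vapply(desc, r_hamming, numeric(1), a = y))
      expect_equal(min_descendant_distance(t, p, depth, y, d), as.integer(want))
    }
  }
})

test_that("two-ball intersection is governed by center distance vs radii sum", {
  expect_true(two_ball_nonempty("ACG", "ACG", 0, 0))
  expect_false(two_ball_nonempty("AAA", "TTT", 1, 1))
  expect_true(two_ball_nonempty("AAT", "ATT", 0, 1))
  set.seed(19)
  for (i in 1:20) {
    l <- sample(2:4, 1)
    c1 <- random_string(l); c2 <- random_string(l)
    r1 <- sample(0:l, 1); r2 <- sample(0:l, 1)
    want <- length(intersect(r_ball(c1, r1), r_ball(c2, r2))) > 0
    expect_equal(two_ball_nonempty(c1, c2, r1, r2), want)
  }
})

test_that("three-ball feasibility agrees with exhaustive search (DNA)", {
  expect_true(three_ball_nonempty("AA", "AA", "AA", 0, 0, 0))
  expect_false(three_ball_nonempty("AA", "CC", "AC", 0, 0, 2))
  expect_true(three_ball_nonempty("AAAA", "TTTT", "AATT", 2, 2, 2))
  set.seed(23)
  for (i in 1:12) {
    L <- sample(2:4, 1)
    c1 <- random_string(L); c2 <- random_string(L); c3 <- random_string(L)
    cube <- r_three_ball_cube(c1, c2, c3)
    for (r1 in 0:L) for (r2 in 0:L) for (r3 in 0:L) {
      expect_equal(three_ball_nonempty(c1, c2, c3, r1, r2, r3),
                   cube[r1 + 1, r2 + 1, r3 + 1],
                   info = paste(c1, c2, c3, r1, r2, r3))
    }
  }
})

test_that("three-ball feasibility is exact on protein and binary alphabets", {
  set.seed(29)
  for (i in 1:4) {
    L <- 3
    syms <- PROTEIN
    c1 <- random_string(L, syms); c2 <- random_string(L, syms)
    c3 <- random_string(L, syms)
    cube <- r_three_ball_cube(c1, c2, c3, syms)
    for (r1 in 0:L) for (r2 in 0:L) for (r3 in 0:L) {
      expect_equal(three_ball_nonempty(c1, c2, c3, r1, r2, r3,
                                       alphabet = "protein"),
                   cube[r1 + 1, r2 + 1, r3 + 1])
    }
  }
  bin <- motif_alphabet(c("0", "1"))
  for (i in 1:4) {
    L <- 4
    syms <- c("0", "1")
    c1 <- random_string(L, syms); c2 <- random_string(L, syms)
    c3 <- random_string(L, syms)
    cube <- r_three_ball_cube(c1, c2, c3, syms)
    for (r1 in 0:L) for (r2 in 0:L) for (r3 in 0:L) {
      expect_equal(three_ball_nonempty(c1, c2, c3, r1, r2, r3, alphabet = bin),
                   cube[r1 + 1, r2 + 1, r3 + 1])
    }
  }
})

test_that("three-ball reduces to two-ball when the third radius is L", {
  set.seed(31)
  for (i in 1:20) {
    L <- sample(2:5, 1)
    c1 <- random_string(L); c2 <- random_string(L); c3 <- random_string(L)
    r1 <- sample(0:L, 1); r2 <- sample(0:L, 1)
    expect_equal(three_ball_nonempty(c1, c2, c3, r1, r2, L),
                 two_ball_nonempty(c1, c2, r1, r2))
  }
})

test_that("compiled exhaustive ball verification passes for small word sizes", {
  for (l in 1:5) {
    res <- ball_exhaustive_check(l, 4)
    expect_true(res$ok, info = paste("l =", l, res$message))
    expect_equal(res$centers, 4^l)
  }
})
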