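#' Size of a Hamming ball
#'
#' Number of l-mers within Hamming distance `d` of any fixed center over an
#' alphabet of `sigma` characters: `sum_{i=0..d} choose(l, i) * (sigma-1)^i`.
#' Depends only on `(l, d, sigma)`.
#'
#' @param l Word length.
#' @param d Radius, `0 <= d <= l`.
#' @param sigma Alphabet size, `>= 2`.
#' @return A double (exact for all sizes representable without rounding).
#' @examples
#' ball_size(3, 1, 4) # 10
#' @export
ball_size <- function(l, d, sigma) {
  if (d < 0 || d > l || sigma < 2) {
    abort("need 0 <= d <= l and sigma >= 2", class = "qpms_param_error")
  }
  i <- 0:d
  sum(choose(l, i) * (sigma - 1)^i)
}

#' Enumerate a Hamming ball
#'
#' All l-mers within distance `d` of the center `x`, each exactly once, in
#' the depth-first order of the mutation tree (center first; children mutate
#' a position to the right of their parent's last mutation, in increasing
#' position then alphabet order).
#'
#' @param x Center l-mer.
#' @param d Radius.
#' @param alphabet Alphabet of `x`.
#' @return Character vector of `ball_size(l, d, sigma)` l-mers.
#' @examples
#' enumerate_ball("AC", 1)
#' @export
enumerate_ball <- function(x, d, alphabet = "dna") {
  alphabet <- motif_alphabet(alphabet)
  xc <- encode_lmer(x, alphabet)
  if (d < 0 || d > length(xc)) {
    abort("need 0 <= d <= l", class = "qpms_param_error")
  }
  nodes <- cpp_ball_nodes(xc, as.integer(d), alphabet$size)
  decode_matrix(nodes$members, alphabet)
}

#' Depth-first traversal of the mutation tree
#'
#' The mutation tree of a center `x` enumerates its d-neighborhood: each node
#' is `(t, p)` where `t` agrees with `x` at every position beyond `p` (the
#' last mutated position, 1-based; 0 at the root) and the node's depth equals
#' its distance to `x`. Children mutate one position `p' > p` to each
#' character other than `x[p']`, provided the depth allows it. The traversal
#' is implemented in plain R so it can host arbitrary visitor callbacks; the
#' search engines use a compiled equivalent.
#'
#' @inheritParams enumerate_ball
#' @param visitor Optional function called as `visitor(t, p, depth, event)`
#'   with `event` `"enter"` or `"leave"`; calls are properly nested.
#' @return A list of traversal statistics: `nodes`, `max_depth`, and
#'   `members` (the visited l-mers in preorder).
#' @export
dfs_mutation_tree <- function(x, d, visitor = NULL, alphabet = "dna") {
  alphabet <- motif_alphabet(alphabet)
  xc <- encode_lmer(x, alphabet)
  l <- length(xc)
  if (d < 0 || d > l) abort("need 0 <= d <= l", class = "qpms_param_error")
  sigma <- alphabet$size
  env <- new.env(parent = emptyenv())
  env$nodes <- 0L
  env$max_depth <- 0L
  env$members <- character(ball_size(l, d, sigma))
  t <- xc
  recurse <- function(p, depth) {
    env$nodes <- env$nodes + 1L
    env$max_depth <- max(env$max_depth, depth)
    env$members[env$nodes] <- decode_lmer(t, alphabet)
    if (!is.null(visitor)) visitor(decode_lmer(t, alphabet), p, depth, "enter")
    if (depth < d) {
      for (pp in seq_len(l)[seq_len(l) > p]) {
        for (c in seq_len(sigma) - 1L) {
          if (c == xc[pp]) next
          t[pp] <<- c
          recurse(pp, depth + 1L)
          t[pp] <<- xc[pp]
        }
      }
    }
    if (!is.null(visitor)) visitor(decode_lmer(t, alphabet), p, depth, "leave")
  }
  recurse(0L, 0L)
  list(nodes = env$nodes, max_depth = env$max_depth, members = env$members)
}

#' Minimum distance from any descendant of a tree node to a target l-mer
#'
#' For a node `(t, p)` at depth `depth` in the mutation tree of some pivot,
#' descendants can alter only positions beyond `p`, in at most `d - depth`
#' places. The minimum of `hamming(t', y)` over all descendants `t'`
#' (including the node itself) is therefore
#' `a + max(0, b - (d - depth))`, with `a` the mismatches of `t` and `y` over
#' positions `1..p` and `b` over positions `p+1..l`. A window `y` is ignored
#' (dropped from the surviving list) at a node exactly when this exceeds `d`.
#'
#' @param t Node l-mer.
#' @param p Last mutated position (1-based; 0 = root).
#' @param depth Node depth (= distance of `t` to the pivot).
#' @param y Target l-mer.
#' @param d Search radius.
#' @param alphabet Alphabet.
#' @return Integer minimum achievable distance.
#' @export
min_descendant_distance <- function(t, p, depth, y, d, alphabet = "dna") {
  alphabet <- motif_alphabet(alphabet)
  tc <- encode_lmer(t, alphabet)
  yc <- encode_lmer(y, alphabet)
  if (length(tc) != length(yc)) {
    abort("t and y must have equal length", class = "qpms_param_error")
  }
  l <- length(tc)
  if (p < 0 || p > l) abort("need 0 <= p <= l", class = "qpms_param_error")
  mism <- tc != yc
  a <- if (p > 0) sum(mism[seq_len(p)]) else 0L
  b <- sum(mism) - a
  as.integer(a + max(0L, b - (d - depth)))
}

#' Do two Hamming balls intersect?
#'
#' Balls `B_r1(c1)` and `B_r2(c2)` over the same alphabet intersect iff
#' `hamming(c1, c2) <= r1 + r2`.
#'
#' @param c1,c2 Center l-mers (equal length).
#' @param r1,r2 Radii.
#' @param alphabet Alphabet.
#' @return Logical.
#' @export
two_ball_nonempty <- function(c1, c2, r1, r2, alphabet = "dna") {
  hamming_dist(c1, c2) <= r1 + r2
}

#' Is the intersection of three Hamming balls non-empty?
#'
#' Decides exactly whether some string `z` satisfies `hamming(z, ci) <= ri`
#' for all three balls, by dynamic programming over positions: the state
#' tracks mismatches to `c1` and `c2` accumulated so far while minimizing
#' mismatches to `c3`; per-position choices are to copy one of the column's
#' characters or (alphabet permitting) any character distinct from all of
#' them. This is the feasibility test behind the qPMS7 surviving-window rule.
#'
#' @param c1,c2,c3 Center strings of equal length.
#' @param r1,r2,r3 Radii (negative radius means the ball is empty).
#' @param alphabet Alphabet.
#' @return Logical.
#' @examples
#' three_ball_nonempty("AAAA", "TTTT", "AATT", 2, 2, 2)
#' @export
three_ball_nonempty <- function(c1, c2, c3, r1, r2, r3, alphabet = "dna") {
  alphabet <- motif_alphabet(alphabet)
  e1 <- encode_lmer(c1, alphabet)
  e2 <- encode_lmer(c2, alphabet)
  e3 <- encode_lmer(c3, alphabet)
  if (length(e1) != length(e2) || length(e1) != length(e3)) {
    abort("centers must have equal length", class = "qpms_param_error")
  }
  cpp_three_ball_nonempty(e1, e2, e3, as.integer(r1), as.integer(r2),
                          as.integer(r3), alphabet$size)
}

# exhaustive compiled self-check of the ball/tree machinery over every center
# of length l (used by the test suite; exported for reproducibility)
#' Exhaustive verification of ball enumeration
#'
#' Enumerates, for every center of length `l` over an alphabet of size
#' `sigma` and every radius `d <= l`, the full Hamming ball via the mutation
#' tree, and verifies the member count against the closed form, uniqueness of
#' members, ball membership, and that node depth equals distance to the
#' center.
#'
#' @param l Word length (kept small; the check is exponential by design).
#' @param sigma Alphabet size.
#' @return List with `ok`, `centers`, `nodes`.
#' @export
ball_exhaustive_check <- function(l, sigma = 4L) {
  cpp_ball_exhaustive_check(as.integer(l), as.integer(sigma))
}
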