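# Independent brute-force oracles used across the suite.  They enumerate the
# full joint outcome space of small designs and never call the package's
# restricted-support or conditional-model code paths.

# Enumerate every stage-1 outcome vector of a design.
enum_x_grid <- function(design) {
  as.matrix(expand.grid(lapply(design$n1, function(n) 0:n)))
}

# Exhaustive conditional expectation E[Y/n2 | selected M, pooled z1, all
# other stage-1 counts, selection event], for every reachable conditioning
# class.  Returns a data frame keyed by (M, z1, other-counts) with the
# oracle value and one representative (x, y) outcome.
enum_umvcue_oracle <- function(design, S) {
  xs <- enum_x_grid(design)
  acc <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(xs))) {
    x <- as.integer(xs[r, ])
    sel <- select_classifier(x, design)
    if (!sel$continued) next
    px <- prod(stats::dbinom(x, design$n1, S))
    if (px == 0) next
    for (y in 0:design$n2) {
      p <- px * stats::dbinom(y, design$n2, S[sel$M])
      if (p == 0) next
      key <- paste(sel$M, x[sel$M] + y,
                   paste(x[-sel$M], collapse = ","), sep = "|")
      cur <- acc[[key]]
      if (is.null(cur)) cur <- list(p = 0, py = 0, x = x, y = y)
      cur$p <- cur$p + p
      cur$py <- cur$py + p * y
      acc[[key]] <- cur
    }
  }
  keys <- ls(acc)
  data.frame(
    key = keys,
    oracle = vapply(keys, function(k) {
      acc[[k]]$py / acc[[k]]$p / design$n2
    }, numeric(1)),
    x = I(lapply(keys, function(k) acc[[k]]$x)),
    y = vapply(keys, function(k) acc[[k]]$y, numeric(1)),
    row.names = NULL)
}

# Exhaustive conditional pmf of Z1 = X_M + Y given the selection event and
# the other classifiers' observed stage-1 counts, at sensitivity s for the
# selected classifier.
enum_z1_pmf_oracle <- function(design, M, x_rest, s) {
  n1M <- design$n1[M]
  n2 <- design$n2
  probs <- numeric(n1M + n2 + 1)   # index z1 + 1
  for (xM in 0:n1M) {
    x <- integer(design$K)
    x[-M] <- x_rest
    x[M] <- xM
    sel <- select_classifier(x, design)
    if (!sel$continued || sel$M != M) next
    pxm <- stats::dbinom(xM, n1M, s)
    for (y in 0:n2) {
      probs[xM + y + 1] <- probs[xM + y + 1] +
        pxm * stats::dbinom(y, n2, s)
    }
  }
  probs / sum(probs)
}

# A representative grid of small designs whose outcome spaces are
# exhaustively enumerable: covers K = 1, 2, 3, equal and unequal stage-1
# sizes, zero and positive cut-offs.
small_design_grid <- function() {
  list(
    two_stage_design(n1 = 4, c = 0, n2 = 4),
    two_stage_design(n1 = 5, c = 2, n2 = 4),
    two_stage_design(n1 = c(5, 5), c = c(0, 0), n2 = 5),
    two_stage_design(n1 = c(5, 5), c = c(3, 3), n2 = 5),
    two_stage_design(n1 = c(6, 4), c = c(2, 1), n2 = 5),
    two_stage_design(n1 = c(4, 6), c = c(0, 3), n2 = 6),
    two_stage_design(n1 = c(4, 4, 4), c = c(0, 0, 0), n2 = 4),
    two_stage_design(n1 = c(5, 4, 3), c = c(2, 2, 1), n2 = 4))
}
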