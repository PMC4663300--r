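# Independent oracles used to freeze expected values.

# Closed form of the two-cluster c-means objective at m = 2, derived by
# hand from the membership update: with d1 = (v1-x)^2, d2 = (v2-x)^2,
#   u1 = d2/(d1+d2), u2 = d1/(d1+d2),
#   u1^2 d1 + u2^2 d2 = d1 d2 / (d1 + d2).
# A pixel on a center contributes 0 (the 0/0 case).
oracle_pair_objective <- function(x, v1, v2) {
  d1 <- (v1 - x)^2
  d2 <- (v2 - x)^2
  term <- d1 * d2 / (d1 + d2)
  sum(term[is.finite(term)])
}

# Brute-force global minimum over all center pairs on a regular grid.
brute_force_min_j <- function(x, res = 0.5) {
  g <- seq(0, 255, by = res)
  best <- Inf
  for (v1 in g) {
    d1 <- (v1 - x)^2
    d2 <- outer(g, x, "-")^2
    num <- sweep(d2, 2, d1, "*")
    den <- sweep(d2, 2, d1, "+")
    term <- num / den
    term[den == 0] <- 0
    best <- min(best, min(rowSums(term)))
  }
  best
}

# Literal transcription of the membership update, kept separate from the
# package's vectorized implementation.
oracle_membership_column <- function(xj, centers, m) {
  d <- abs(centers - xj)
  if (any(d == 0)) {
    u <- numeric(length(centers))
    u[which(d == 0)[1]] <- 1
    return(u)
  }
  sapply(seq_along(centers), function(i)
    1 / sum((d[i] / d)^(2 / (m - 1))))
}

random_tiny_image <- function(n_px, seed) {
  withr_seed <- seed # simple deterministic draw without touching withr
  set.seed(withr_seed)
  matrix(sample(0:255, n_px, replace = TRUE), 1, n_px)
}
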