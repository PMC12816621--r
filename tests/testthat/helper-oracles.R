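# Independent oracles, deliberately naive: each re-derives a quantity by
# brute force or closed form, never by calling the code path under test.

# mean pairwise Euclidean distance by explicit double loop
oracle_mean_pairwise_dist <- function(cent) {
  n <- nrow(cent)
  d <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- c(d, sqrt(sum((cent[i, ] - cent[j, ])^2)))
    }
  }
  mean(d)
}

# centroid statistic recomputed from scratch for a label vector
oracle_het_stat <- function(xy, labels) {
  groups <- unique(labels)
  cent <- t(vapply(groups, function(g) {
    colMeans(xy[labels == g, , drop = FALSE])
  }, numeric(ncol(xy))))
  oracle_mean_pairwise_dist(cent)
}

# exact permutation p by enumerating every distinct two-group labeling
# (uniform shuffling of a label multiset makes each arrangement equally
# likely); feasible for <= 8 cells
oracle_exact_perm_p <- function(xy, labels) {
  stopifnot(length(unique(labels)) == 2, length(labels) <= 8)
  obs <- oracle_het_stat(xy, labels)
  lv <- unique(labels)
  nA <- sum(labels == lv[1])
  combos <- utils::combn(length(labels), nA)
  stats <- apply(combos, 2, function(idx) {
    lab <- rep(lv[2], length(labels))
    lab[idx] <- lv[1]
    oracle_het_stat(xy, lab)
  })
  mean(stats >= obs)
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables with the same margins whose
# probability does not exceed the observed table's
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(support, function(a) {
    choose(r1, a) * choose(n - r1, c1 - a) / choose(n, c1)
  }, 0)
  p_obs <- probs[match(tab[1, 1], support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# BH step-up by the textbook recipe: p * n / rank, then running minimum
# from the largest p downward
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# two-group log-rank chi-square from the observed-minus-expected tally at
# each distinct event time
oracle_logrank_chisq <- function(time1, event1, time2, event2) {
  times <- sort(unique(c(time1[event1 == 1], time2[event2 == 1])))
  O1 <- E1 <- V <- 0
  for (t in times) {
    n1 <- sum(time1 >= t); n2 <- sum(time2 >= t)
    d1 <- sum(time1 == t & event1 == 1)
    d2 <- sum(time2 == t & event2 == 1)
    n <- n1 + n2; d <- d1 + d2
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# tertile assignment by sorting and cutting at the linear-interpolation
# 1/3 and 2/3 quantiles, written independently of the package's rule
oracle_tertiles <- function(scores) {
  s <- sort(scores)
  n <- length(s)
  interp_q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  q1 <- interp_q(1 / 3); q2 <- interp_q(2 / 3)
  ifelse(scores <= q1, "Low", ifelse(scores <= q2, "Intermediate", "High"))
}

# small helpers for building fixtures in code
toy_cells <- function(coords, patients) {
  cell_table(sprintf("c%02d", seq_len(nrow(coords))), patients, coords)
}

toy_expr <- function(values, genes, samples) {
  expression_matrix(matrix(values, nrow = length(genes),
                           dimnames = list(genes, samples)))
}
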