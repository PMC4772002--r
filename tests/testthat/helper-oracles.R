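# Independent reference implementations used as oracles. These deliberately
# take the slow, literal route and never share code with the package.

# quadratic-time BH step-up: adj_i = min over j with p_j >= p_i of p_j * m / rank_j
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  for (i in (m - 1):1) {
    if (m > 1) ranked[i] <- min(ranked[i], ranked[i + 1])
  }
  out <- numeric(m)
  out[o] <- pmin(ranked, 1)
  out
}

# brute-force NB conditional exact test: enumerate every split of the total,
# computing group-sum pmfs from first principles by convolving per-replicate
# NB pmfs (not the aggregate-NB shortcut for equal size factors).
nb_exact_reference <- function(k_a, k_b, sf_a = rep(1, length(k_a)),
                               sf_b = rep(1, length(k_b)), alpha = 0) {
  total <- sum(k_a) + sum(k_b)
  q <- total / (sum(sf_a) + sum(sf_b))
  group_pmf <- function(sf) {
    # distribution of the group sum on 0..total by repeated convolution
    pmf <- c(1, rep(0, total))
    for (s in sf) {
      one <- if (alpha == 0) dpois(0:total, lambda = s * q)
             else dnbinom(0:total, mu = s * q, size = 1 / alpha)
      new <- rep(0, total + 1)
      for (v in 0:total) {
        if (pmf[v + 1] > 0)
          new[(v:total) + 1] <- new[(v:total) + 1] + pmf[v + 1] * one[0:(total - v) + 1]
      }
      pmf <- new
    }
    pmf
  }
  pa <- group_pmf(sf_a)
  pb <- group_pmf(sf_b)
  pr <- sapply(0:total, function(a) pa[a + 1] * pb[total - a + 1])
  p_obs <- pr[sum(k_a) + 1]
  sum(pr[pr <= p_obs * (1 + 1e-8)]) / sum(pr)
}

# exhaustive central hypergeometric upper tail by combinatorial counting
hyper_upper_reference <- function(k, N, K, n) {
  kk <- max(k, max(0, n - (N - K))):min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# O(n^3) average-linkage agglomeration returning sorted merge heights
average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}

random_count_matrix <- function(n_genes, n_samples, lambda = 50, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  count_matrix(m)
}
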