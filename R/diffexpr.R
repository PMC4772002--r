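#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over genes (restricted to
#' genes with nonzero counts in every sample) of the ratio of the count to the
#' gene's geometric mean across samples. This is the standard normalization of
#' the negative-binomial count-based DE family.
#'
#' @param m A `CountMatrix`.
#' @return Named positive numeric vector of per-sample size factors.
#' @export
size_factors_median_ratio <- function(m) {
  stopifnot(inherits(m, "CountMatrix"))
  x <- unclass(m)
  keep <- rowSums(x == 0) == 0
  if (!any(keep))
    stop("no gene has nonzero counts in every sample; pre-filter the matrix ",
         "or supply more deeply sequenced samples")
  lx <- log(x[keep, , drop = FALSE])
  geo <- rowMeans(lx)
  sf <- apply(lx, 2, function(col) stats::median(exp(col - geo)))
  names(sf) <- colnames(m)
  sf
}

#' Per-gene dispersion estimation with a parametric trend floor
#'
#' Method-of-moments dispersion on normalized counts, pooled within groups.
#' For normalized count x = k/s with NB(mu*s, alpha) raw counts,
#' Var(x) ~ mu * mean(1/s) + alpha * mu^2, so the raw estimate is
#' `(pooled within-group variance - mu * mean(1/s)) / mu^2`, floored at 0.
#' A parametric mean-dispersion trend `alpha(mu) = a0 + a1/mu` is then fit by
#' least squares over genes and each gene receives
#' `max(own estimate, trend value)` - a conservative sharing rule.
#'
#' @param m A `CountMatrix`.
#' @param groups Character or factor of length `ncol(m)` assigning samples to
#'   conditions (replicate groups).
#' @param size_factors Named per-sample size factors; computed from `m` when
#'   `NULL`.
#' @return A data.frame with columns `gene_id`, `alpha` (final shared value),
#'   `alpha_gene` (floored per-gene moments estimate) and `method`.
#' @export
estimate_dispersion <- function(m, groups, size_factors = NULL) {
  stopifnot(inherits(m, "CountMatrix"))
  if (length(groups) != ncol(m))
    stop("`groups` must have one entry per sample")
  if (is.null(size_factors)) size_factors <- size_factors_median_ratio(m)
  sf <- size_factors[colnames(m)]
  if (anyNA(sf)) stop("size factors missing for some samples")
  groups <- as.character(groups)
  tab <- table(groups)
  method <- "per-gene moments + trend floor"
  if (all(tab < 2)) {
    warning("no group has replicates; falling back to blind pooled dispersion ",
            "estimation across all samples")
    groups <- rep("all", ncol(m))
    tab <- table(groups)
    method <- "blind pooled + trend floor"
  }
  x <- sweep(unclass(m), 2, sf, "/")  # normalized counts
  use <- names(tab)[tab >= 2]
  # pooled within-group mean and variance over replicated groups
  mu <- rowMeans(x)
  ss <- 0; df <- 0
  xi <- 0  # shot-noise correction: average 1/s over replicated samples
  nrep <- 0
  for (g in use) {
    idx <- which(groups == g)
    xg <- x[, idx, drop = FALSE]
    mg <- rowMeans(xg)
    ss <- ss + rowSums((xg - mg)^2)
    df <- df + length(idx) - 1
    xi <- xi + sum(1 / sf[idx])
    nrep <- nrep + length(idx)
  }
  v <- ss / df
  xi <- xi / nrep
  raw <- (v - mu * xi) / mu^2
  raw[!is.finite(raw)] <- 0
  alpha_gene <- pmax(raw, 0)
  # parametric trend alpha(mu) = a0 + a1/mu on the unfloored estimates
  ok <- is.finite(raw) & mu > 0
  trend <- rep(0, length(mu))
  if (sum(ok) >= 3 && stats::var(1 / mu[ok]) > 0) {
    fit <- stats::lm.fit(cbind(1, 1 / mu[ok]), raw[ok])
    co <- fit$coefficients
    trend <- pmax(co[1] + co[2] / mu, 0)
    trend[!is.finite(trend)] <- 0
  }
  data.frame(gene_id = rownames(m),
             alpha = pmax(alpha_gene, trend),
             alpha_gene = alpha_gene,
             method = method,
             stringsAsFactors = FALSE)
}

#' Negative-binomial conditional exact test for two groups of counts
#'
#' Tests equality of the (normalized) mean between two groups by conditioning
#' on the pooled total T. Each group's summed count is modelled as a single
#' negative binomial (the aggregate of i.i.d. NB replicates at common
#' dispersion `alpha`): group A has mean `sA * q` and size `sA^2/(alpha *
#' sum(sfA^2))` where `sA = sum(sfA)` and `q = T/(sA+sB)`; `alpha = 0` is the
#' Poisson limit. The two-sided p-value sums, over all splits (a, T-a) of the
#' total, the probabilities no larger than that of the observed split,
#' normalized by the total probability of all splits.
#'
#' @param k_a,k_b Integer count vectors for the two groups (replicates).
#' @param sf_a,sf_b Size factors for the samples of each group (default 1).
#' @param alpha NB dispersion (variance = mu + alpha mu^2); `>= 0`.
#' @return p-value in (0, 1]. An all-zero input returns 1 with attribute
#'   `flag = "all-zero"`.
#' @export
nb_exact_test <- function(k_a, k_b, sf_a = rep(1, length(k_a)),
                          sf_b = rep(1, length(k_b)), alpha = 0) {
  if (alpha < 0) stop("alpha must be >= 0")
  ka <- sum(k_a); kb <- sum(k_b)
  total <- ka + kb
  if (total == 0) {
    p <- 1
    attr(p, "flag") <- "all-zero"
    return(p)
  }
  sA <- sum(sf_a); sB <- sum(sf_b)
  q <- total / (sA + sB)
  a <- 0:total
  pa <- nb_group_pmf(a, s = sA, s2 = sum(sf_a^2), q = q, alpha = alpha)
  pb <- nb_group_pmf(total - a, s = sB, s2 = sum(sf_b^2), q = q, alpha = alpha)
  pr <- pa * pb
  tot <- sum(pr)
  if (tot <= 0) return(1)
  p_obs <- pr[ka + 1]
  p <- sum(pr[pr <= p_obs * (1 + 1e-8)]) / tot
  min(max(p, .Machine$double.xmin), 1)
}

# pmf of a group's summed count: NB with mean s*q and aggregate size
# s^2/(alpha*s2); Poisson in the alpha -> 0 limit
nb_group_pmf <- function(k, s, s2, q, alpha) {
  mu <- s * q
  if (alpha == 0) return(stats::dpois(k, lambda = mu))
  stats::dnbinom(k, mu = mu, size = s^2 / (alpha * s2))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper over the standard step-up FDR adjustment: monotone,
#' capped at 1, order-preserving under the same ranks.
#'
#' @param p Numeric vector of p-values in \[0, 1\]; `NaN`/`NA` rejected.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p)) stop("NA/NaN p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential expression for one two-group comparison
#'
#' @param m A `CountMatrix` (may contain more samples than used).
#' @param samples_a,samples_b Sample ids of the two groups; the test direction
#'   is B relative to A (`call = "up"` means B higher).
#' @param size_factors Per-sample size factors covering both groups.
#' @param alpha Named per-gene dispersion vector.
#' @param threshold BH-adjusted significance threshold (default 0.05).
#' @return A `DEResult` data.frame: `gene_id`, `mean_a`, `mean_b`,
#'   `log2_fold_change`, `p_value`, `p_adjusted`, `call`.
#' @export
de_test <- function(m, samples_a, samples_b, size_factors, alpha,
                    threshold = 0.05) {
  stopifnot(inherits(m, "CountMatrix"))
  ka <- unclass(m)[, samples_a, drop = FALSE]
  kb <- unclass(m)[, samples_b, drop = FALSE]
  sfa <- size_factors[samples_a]
  sfb <- size_factors[samples_b]
  al <- alpha[rownames(m)]
  pv <- vapply(seq_len(nrow(m)), function(i) {
    as.numeric(nb_exact_test(ka[i, ], kb[i, ], sfa, sfb, al[i]))
  }, numeric(1))
  mean_a <- rowMeans(sweep(ka, 2, sfa, "/"))
  mean_b <- rowMeans(sweep(kb, 2, sfb, "/"))
  padj <- bh_adjust(pv)
  call <- rep("ns", nrow(m))
  sig <- padj < threshold
  call[sig & mean_b > mean_a] <- "up"
  call[sig & mean_b < mean_a] <- "down"
  # a significant p with exactly equal means carries no direction; keep ns
  data.frame(gene_id = rownames(m), mean_a = mean_a, mean_b = mean_b,
             log2_fold_change = log2(mean_b / mean_a),
             p_value = pv, p_adjusted = padj, call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' The three pairwise DE comparisons of one parent-parent-hybrid trio
#'
#' Runs hybrid vs maternal, hybrid vs paternal and maternal vs paternal
#' comparisons (the "second member" of each pair is the one whose direction
#' the call reports: `fm` up means F1 above the maternal parent). BH
#' correction is applied within each comparison separately. Size factors are
#' computed once from the full matrix; dispersions are estimated across the
#' trio's three replicate groups and shared by all three comparisons.
#'
#' @param m A `CountMatrix` containing the trio's samples.
#' @param d A [trio_design()].
#' @param threshold BH-adjusted significance threshold (default 0.05).
#' @param size_factors Optional precomputed size factors.
#' @return List with elements `fm` (F1 vs maternal), `fp` (F1 vs paternal),
#'   `mp` (paternal vs maternal) - each a `DEResult` data.frame - plus
#'   `dispersion` and `size_factors`.
#' @export
pairwise_trio_de <- function(m, d, threshold = 0.05, size_factors = NULL) {
  stopifnot(inherits(m, "CountMatrix"), inherits(d, "TrioDesign"))
  check_design_in_matrix(m, d)
  if (is.null(size_factors)) size_factors <- size_factors_median_ratio(m)
  sub <- count_matrix(unclass(m)[, trio_samples(d), drop = FALSE])
  groups <- c(rep("maternal", length(d$maternal_samples)),
              rep("paternal", length(d$paternal_samples)),
              rep("hybrid", length(d$hybrid_samples)))
  disp <- estimate_dispersion(sub, groups, size_factors)
  al <- stats::setNames(disp$alpha, disp$gene_id)
  list(
    fm = de_test(m, d$maternal_samples, d$hybrid_samples, size_factors, al, threshold),
    fp = de_test(m, d$paternal_samples, d$hybrid_samples, size_factors, al, threshold),
    mp = de_test(m, d$maternal_samples, d$paternal_samples, size_factors, al, threshold),
    dispersion = disp,
    size_factors = size_factors
  )
}
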