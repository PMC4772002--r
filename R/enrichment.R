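#' Fit a gene-length probability weighting function
#'
#' Long genes accumulate more reads and are more likely to be called
#' differentially expressed at a given expression level; enrichment tests
#' that ignore this over-report categories of long genes. The probability
#' weighting function (PWF) estimates P(DE | length) by binning genes into
#' `n_bins` equal-occupancy length bins, computing the per-bin DE fraction,
#' and smoothing with isotonic (pool-adjacent-violators) regression so the
#' fit is monotone nondecreasing in length.
#'
#' @param de_flags Named 0/1 (or logical) vector over the background genes.
#' @param lengths Named numeric vector of gene lengths (bp), covering the
#'   same genes.
#' @param n_bins Number of length bins (default 40; reduced when there are
#'   fewer distinct lengths).
#' @param eps Weights are clipped to `(eps, 1 - eps)` (default 1e-4).
#' @return Named numeric vector: per-gene selection weight in (0, 1), with
#'   attribute `bins` (the fitted per-bin values).
#' @export
fit_pwf <- function(de_flags, lengths, n_bins = 40, eps = 1e-4) {
  genes <- names(de_flags)
  if (is.null(genes)) stop("de_flags must be named by gene id")
  miss <- setdiff(genes, names(lengths))
  if (length(miss)) stop("missing length for gene '", miss[1], "'")
  de <- as.numeric(de_flags) > 0
  if (!any(de)) stop("no DE genes; enrichment is undefined")
  L <- lengths[genes]
  if (length(unique(L)) < 2) {
    w <- rep(mean(de), length(genes))
    names(w) <- genes
    attr(w, "bins") <- mean(de)
    return(pmin(pmax(w, eps), 1 - eps))
  }
  nb <- min(n_bins, length(unique(L)))
  # equal-occupancy bins in length rank order
  ord <- rank(L, ties.method = "first")
  bin <- ceiling(ord / length(L) * nb)
  bin_frac <- tapply(de, bin, mean)
  bin_len <- tapply(L, bin, mean)
  o <- order(bin_len)
  iso <- stats::isoreg(bin_len[o], bin_frac[o])
  fitted <- stats::setNames(iso$yf, names(bin_frac)[o])
  w <- fitted[as.character(bin)]
  names(w) <- genes
  w <- pmin(pmax(w, eps), 1 - eps)
  attr(w, "bins") <- fitted
  w
}

#' Wallenius noncentral hypergeometric pmf
#'
#' Probability of drawing `k` "in-term" genes when `n` genes are sampled
#' without replacement from a background of `N` genes of which `K` are in
#' the term, each in-term gene weighted `odds` relative to the rest
#' (biased-urn model of length-biased DE selection). Evaluated by the exact
#' integral representation
#' `P(k) = C(K,k) C(N-K,n-k) * Integral_0^1 (1-t^(odds/D))^k (1-t^(1/D))^(n-k) dt`
#' with `D = odds (K-k) + (N-K-(n-k))`, computed on the log scale with
#' adaptive quadrature and renormalized over the support.
#'
#' @param k Integer vector of in-term draw counts.
#' @param N,K,n Background size, term size, number of draws.
#' @param odds Weight of in-term genes relative to the rest (> 0).
#' @return Numeric vector of probabilities summing to 1 over the support.
#' @export
dwallenius <- function(k, N, K, n, odds = 1) {
  if (odds <= 0) stop("odds must be positive")
  if (K > N || n > N) stop("require K <= N and n <= N")
  support <- max(0, n - (N - K)):min(n, K)
  logp <- vapply(support, wallenius_log_kernel, numeric(1),
                 N = N, K = K, n = n, w = odds)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  out <- numeric(length(k))
  idx <- match(k, support)
  out[!is.na(idx)] <- p[idx[!is.na(idx)]]
  out
}

# log of the unnormalized Wallenius pmf kernel at one support point
wallenius_log_kernel <- function(x, N, K, n, w) {
  D <- w * (K - x) + (N - K - (n - x))
  if (D <= 0) {
    # everything is sampled; a single-point distribution
    return(0)
  }
  f <- function(t) {
    r <- x * log1p(-t^(w / D)) + (n - x) * log1p(-t^(1 / D))
    ifelse(is.finite(r), exp(r), 0)
  }
  I <- stats::integrate(f, 0, 1, rel.tol = 1e-12, abs.tol = 0,
                        subdivisions = 2000L, stop.on.error = FALSE)
  val <- max(I$value, .Machine$double.xmin)
  lchoose(K, x) + lchoose(N - K, n - x) + log(val)
}

#' Wallenius upper-tail over-representation p-value
#'
#' `P(X >= k)` under [dwallenius()]; with `odds = 1` this reduces exactly to
#' the central hypergeometric tail.
#'
#' @inheritParams dwallenius
#' @return Upper-tail probability.
#' @export
pwallenius_upper <- function(k, N, K, n, odds = 1) {
  if (k <= max(0, n - (N - K))) return(1)
  support <- max(0, n - (N - K)):min(n, K)
  p <- dwallenius(support, N, K, n, odds)
  sum(p[support >= k])
}

#' Length-bias-aware enrichment of one term (Wallenius test)
#'
#' Over-representation of `term_genes` among `de_genes` against `background`,
#' with the selection bias summarized by the PWF: the odds weight is the mean
#' PWF value inside the term divided by the mean outside.
#'
#' @param term_genes Character vector (subset of background).
#' @param de_genes Character vector (subset of background).
#' @param background Character vector of all testable genes.
#' @param pwf Named weight vector from [fit_pwf()] (uniform weights when
#'   `NULL`, reducing to the central hypergeometric).
#' @param term_id Optional identifier carried into the result.
#' @return One-row data.frame: `term_id`, `k`, `n`, `K`, `N`, `odds`,
#'   `p_value`.
#' @export
wallenius_enrichment <- function(term_genes, de_genes, background, pwf = NULL,
                                 term_id = NA_character_) {
  background <- unique(background)
  if (!length(background)) stop("background is empty")
  if (length(setdiff(term_genes, background)))
    stop("term contains genes outside the background")
  if (length(setdiff(de_genes, background)))
    stop("DE set contains genes outside the background")
  term_genes <- unique(term_genes); de_genes <- unique(de_genes)
  N <- length(background); K <- length(term_genes); n <- length(de_genes)
  k <- length(intersect(term_genes, de_genes))
  odds <- 1
  if (!is.null(pwf) && K > 0 && K < N) {
    w_in <- mean(pwf[term_genes])
    w_out <- mean(pwf[setdiff(background, term_genes)])
    odds <- w_in / w_out
  }
  p <- if (K == 0 || k == 0) 1 else pwallenius_upper(k, N, K, n, odds)
  data.frame(term_id = term_id, k = k, n = n, K = K, N = N, odds = odds,
             p_value = p, stringsAsFactors = FALSE)
}

#' Central hypergeometric over-representation of one term
#'
#' The classical one-sided Fisher/hypergeometric upper-tail test (no length
#' bias), as used for pathway over-representation.
#'
#' @inheritParams wallenius_enrichment
#' @return One-row data.frame as in [wallenius_enrichment()] (`odds = 1`).
#' @export
hypergeom_enrichment <- function(term_genes, de_genes, background,
                                 term_id = NA_character_) {
  background <- unique(background)
  if (!length(background)) stop("background is empty")
  if (length(setdiff(term_genes, background)))
    stop("term contains genes outside the background")
  if (length(setdiff(de_genes, background)))
    stop("DE set contains genes outside the background")
  term_genes <- unique(term_genes); de_genes <- unique(de_genes)
  N <- length(background); K <- length(term_genes); n <- length(de_genes)
  k <- length(intersect(term_genes, de_genes))
  p <- if (K == 0 || k == 0) 1 else
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(term_id = term_id, k = k, n = n, K = K, N = N, odds = 1,
             p_value = p, stringsAsFactors = FALSE)
}

#' Test every term of an annotation map
#'
#' @param annotation Named list term -> gene ids (as from
#'   [read_annotation_map()]).
#' @param de_genes,background Gene-id vectors.
#' @param pwf Optional PWF; when supplied the Wallenius test is used,
#'   otherwise the central hypergeometric.
#' @param threshold Passed to [adjust_terms()].
#' @return Data.frame of per-term results with BH-adjusted p-values and
#'   significance flags.
#' @export
enrich_terms <- function(annotation, de_genes, background, pwf = NULL,
                         threshold = 0.05) {
  rows <- lapply(names(annotation), function(tid) {
    genes <- intersect(annotation[[tid]], background)
    if (is.null(pwf))
      hypergeom_enrichment(genes, de_genes, background, term_id = tid)
    else
      wallenius_enrichment(genes, de_genes, background, pwf, term_id = tid)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(term_id = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), odds = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  adjust_terms(res, threshold = threshold)
}

#' BH-adjust a table of term results and flag significance
#'
#' Adjustment is applied across all tested terms of one ontology; the
#' threshold on the corrected p-value defaults to 0.05 and is configurable.
#'
#' @param results Data.frame with a `p_value` column.
#' @param threshold Adjusted-p significance cutoff.
#' @return The table with `p_adjusted` and logical `flag` columns appended,
#'   ordered by p-value.
#' @export
adjust_terms <- function(results, threshold = 0.05) {
  results$p_adjusted <- bh_adjust(results$p_value)
  results$flag <- results$p_adjusted < threshold
  results[order(results$p_value, results$term_id), , drop = FALSE]
}
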