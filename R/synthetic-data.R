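#' Specification of a synthetic trio experiment
#'
#' Defines the ground-truth structure of a simulated parent-parent-hybrid
#' RNA-seq experiment: how many genes, the mixture over the twelve expression
#' classes plus `nonDEG`, the baseline expression level, the fold change
#' separating differing levels, the negative-binomial dispersion
#' (variance = mu + alpha mu^2), the replicate count per line, and the range
#' of per-sample library size factors.
#'
#' @param n_genes Number of genes (> 0).
#' @param classes Named numeric vector of proportions over labels from
#'   `c(as.character(1:12), "nonDEG")`; must sum to 1 (tolerance 1e-9).
#' @param base_mean Expected normalized count at the reference level (> 0).
#' @param fold_change Ratio between differing levels (> 1).
#' @param dispersion NB dispersion alpha (>= 0; 0 is the Poisson limit).
#' @param n_reps Replicates per line (>= 1; >= 2 for a testable design).
#' @param size_factor_range Length-2 positive range for sample size factors.
#' @param seed Integer seed; one seed drives the whole experiment, with
#'   per-gene substreams derived deterministically so results do not depend
#'   on gene order.
#' @return A `TruthSpec` list.
#' @export
truth_spec <- function(n_genes,
                       classes = c(nonDEG = 1),
                       base_mean = 200,
                       fold_change = 4,
                       dispersion = 0.01,
                       n_reps = 2,
                       size_factor_range = c(0.7, 1.4),
                       seed = 1L) {
  if (n_genes < 1) stop("n_genes must be positive")
  allowed <- c(as.character(1:12), "nonDEG")
  bad <- setdiff(names(classes), allowed)
  if (length(bad)) stop("unknown class label '", bad[1], "'")
  if (is.null(names(classes)) || any(names(classes) == ""))
    stop("class proportions must be named")
  if (any(classes < 0))
    stop("negative proportion for class '", names(classes)[classes < 0][1], "'")
  if (abs(sum(classes) - 1) > 1e-9)
    stop("class proportions must sum to 1 (got ", format(sum(classes)), ")")
  if (base_mean <= 0) stop("base_mean must be positive")
  if (fold_change <= 1) stop("fold_change must exceed 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (length(size_factor_range) != 2 || any(size_factor_range <= 0) ||
      size_factor_range[1] > size_factor_range[2])
    stop("size_factor_range must be an increasing pair of positive reals")
  structure(list(n_genes = as.integer(n_genes), classes = classes,
                 base_mean = base_mean, fold_change = fold_change,
                 dispersion = dispersion, n_reps = as.integer(n_reps),
                 size_factor_range = as.numeric(size_factor_range),
                 seed = as.integer(seed)),
            class = "TruthSpec")
}

# true (maternal, hybrid, paternal) normalized means for one class label.
# b = base level, f = fold change. Geometry: additive hybrids sit at the
# parental mid-point; ELD hybrids at one parent's level; transgressive-up at
# f * max(parents); transgressive-down at min(parents) / f.
class_true_means <- function(label, b, f) {
  hi <- b * f
  switch(label,
    "nonDEG" = c(b, b, b),
    "1"  = c(b, (b + hi) / 2, hi),
    "12" = c(hi, (b + hi) / 2, b),
    "2"  = c(b, hi, hi),
    "11" = c(hi, b, b),
    "4"  = c(hi, hi, b),
    "9"  = c(b, b, hi),
    "3"  = c(b, hi * f, hi),
    "7"  = c(b, hi, b),
    "10" = c(hi, hi * f, b),
    "6"  = c(b, b / f, hi),
    "8"  = c(b, b / f, b),
    "5"  = c(hi, b / f, b),
    stop("unknown class label '", label, "'")
  )
}

# deterministic per-gene substream seed below 2^31
gene_sub_seed <- function(seed, idx, stream = 0L) {
  as.integer((as.double(seed) * 48271 + as.double(idx) * 104729 +
                as.double(stream) * 7919) %% 2147483629)
}

# largest-remainder apportionment of n genes over class proportions
apportion_classes <- function(classes, n) {
  raw <- classes * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Simulate one parent-parent-hybrid count matrix with known truth
#'
#' Draws per-gene class labels according to the spec's mixture, constructs
#' the class-determined true normalized means (see the geometry in
#' [truth_spec()]), draws per-sample size factors uniformly in
#' `size_factor_range`, and samples counts from
#' `NB(mean = size_factor * true mean, dispersion = alpha)` (Poisson when
#' `alpha = 0`). Identical spec and seed give identical output.
#'
#' @param spec A [truth_spec()].
#' @param cross_id Identifier used for lines and samples (default `"X1"`).
#' @param truth Optional `SyntheticTruth` from a previous call: reuse its
#'   class labels and means (same genes) and only redraw size factors and
#'   counts, so several crosses can share one gene-level ground truth.
#' @return List with `counts` (a [count_matrix()]), `design` (a
#'   [trio_design()]) and `truth` (a `SyntheticTruth` data.frame with
#'   `gene_id`, `class`, `mu_m`, `mu_f1`, `mu_p`, plus a `size_factors`
#'   attribute).
#' @export
simulate_trio_counts <- function(spec, cross_id = "X1", truth = NULL) {
  stopifnot(inherits(spec, "TruthSpec"))
  n <- spec$n_genes
  gene_ids <- sprintf("g%04d", seq_len(n))
  if (is.null(truth)) {
    counts_per_class <- apportion_classes(spec$classes, n)
    labels <- rep(names(counts_per_class), counts_per_class)
    set.seed(gene_sub_seed(spec$seed, 0L, 1L))
    labels <- sample(labels)
    mus <- t(vapply(labels, class_true_means, numeric(3),
                    b = spec$base_mean, f = spec$fold_change))
    truth <- data.frame(gene_id = gene_ids, class = labels,
                        mu_m = mus[, 1], mu_f1 = mus[, 2], mu_p = mus[, 3],
                        row.names = NULL, stringsAsFactors = FALSE)
  } else {
    if (!identical(truth$gene_id, gene_ids))
      stop("supplied truth does not match this spec's gene universe")
  }
  r <- spec$n_reps
  roles <- c("maternal", "paternal", "hybrid")
  lines <- stats::setNames(paste0(cross_id, "_", c("mat", "pat", "f1")), roles)
  sample_ids <- unname(unlist(lapply(lines, function(l) paste0(l, "_", seq_len(r)))))
  cross_seed <- gene_sub_seed(spec$seed, 0L,
                              2L + utf8_stream_offset(cross_id))
  set.seed(cross_seed)
  sf <- stats::runif(3 * r, spec$size_factor_range[1], spec$size_factor_range[2])
  names(sf) <- sample_ids
  # per-sample true mean rows: maternal reps, paternal reps, hybrid reps
  mu_per_sample <- cbind(matrix(rep(truth$mu_m, r), ncol = r),
                         matrix(rep(truth$mu_p, r), ncol = r),
                         matrix(rep(truth$mu_f1, r), ncol = r))
  counts <- matrix(0L, nrow = n, ncol = 3 * r,
                   dimnames = list(gene_ids, sample_ids))
  for (i in seq_len(n)) {
    set.seed(gene_sub_seed(cross_seed, i))
    mu <- mu_per_sample[i, ] * sf
    counts[i, ] <- if (spec$dispersion == 0) {
      stats::rpois(length(mu), lambda = mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion)
    }
  }
  design <- trio_design(cross_id,
                        maternal_samples = sample_ids[seq_len(r)],
                        paternal_samples = sample_ids[r + seq_len(r)],
                        hybrid_samples  = sample_ids[2 * r + seq_len(r)])
  attr(truth, "size_factors") <- sf
  list(counts = count_matrix(counts), design = design, truth = truth)
}

utf8_stream_offset <- function(id) {
  sum(utf8ToInt(id) * seq_along(utf8ToInt(id))) %% 100003L
}

#' Simulate several crosses sharing one gene-level ground truth
#'
#' Mirrors a multi-cross design in which the same genes carry the same
#' expression-class truth in every cross (as when crosses share parental
#' lines); counts and size factors are redrawn independently per cross.
#'
#' @param spec A [truth_spec()].
#' @param n_crosses Number of crosses (default 3).
#' @return List of per-cross results as from [simulate_trio_counts()], named
#'   `X1`, `X2`, ...
#' @export
simulate_heterosis_experiment <- function(spec, n_crosses = 3) {
  first <- simulate_trio_counts(spec, cross_id = "X1")
  out <- vector("list", n_crosses)
  out[[1]] <- first
  for (k in seq_len(n_crosses)[-1]) {
    out[[k]] <- simulate_trio_counts(spec, cross_id = paste0("X", k),
                                     truth = first$truth)
  }
  names(out) <- paste0("X", seq_len(n_crosses))
  out
}

#' Simulate body-weight samples for two parents and their hybrid
#'
#' Normal phenotype samples for a mid-parent heterosis analysis.
#'
#' @param mu_m,mu_p,mu_f1 True means (maternal, paternal, F1).
#' @param sd Common within-line standard deviation (> 0).
#' @param n Individuals per line (>= 2).
#' @param seed Integer seed.
#' @return List of numeric vectors `maternal`, `paternal`, `hybrid`.
#' @export
simulate_body_weights <- function(mu_m, mu_p, mu_f1, sd, n, seed = 1L) {
  if (n < 2) stop("n must be >= 2 (standard error undefined otherwise)")
  if (sd <= 0) stop("sd must be positive")
  set.seed(as.integer(seed))
  list(maternal = stats::rnorm(n, mu_m, sd),
       paternal = stats::rnorm(n, mu_p, sd),
       hybrid = stats::rnorm(n, mu_f1, sd))
}

#' Summarize a simulated phenotype sample into a line summary
#'
#' @param line_id Line identifier.
#' @param x Numeric sample vector.
#' @return A [phenotype_summary()].
#' @export
summarize_sample <- function(line_id, x) {
  phenotype_summary(line_id, mean(x), stats::sd(x) / sqrt(length(x)), length(x))
}

#' Generate a reproducible gene-length table and term-to-gene map
#'
#' Stands in for category/pathway databases in tests and demos: gene lengths
#' uniform over `length_range`, each term annotating `genes_per_term` genes
#' sampled without replacement.
#'
#' @param n_genes Number of genes.
#' @param n_terms Number of terms (0 allowed).
#' @param genes_per_term Genes per term (<= n_genes).
#' @param length_range Increasing positive pair of lengths in bp.
#' @param seed Integer seed.
#' @param gene_ids Optional gene ids (defaults to `g0001`...).
#' @return List with `lengths` (named vector) and `annotation` (named list
#'   term -> gene ids).
#' @export
make_annotation_fixture <- function(n_genes, n_terms, genes_per_term,
                                    length_range = c(300, 6000), seed = 1L,
                                    gene_ids = NULL) {
  if (genes_per_term > n_genes) stop("genes_per_term cannot exceed n_genes")
  if (genes_per_term < 1 && n_terms > 0) stop("genes_per_term must be >= 1")
  if (length(length_range) != 2 || any(length_range <= 0) ||
      length_range[1] > length_range[2])
    stop("length_range must be an increasing pair of positive lengths")
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(n_genes))
  set.seed(as.integer(seed))
  lengths <- stats::setNames(
    round(stats::runif(n_genes, length_range[1], length_range[2])), gene_ids)
  annotation <- list()
  if (n_terms > 0) {
    annotation <- lapply(seq_len(n_terms), function(t)
      sort(sample(gene_ids, genes_per_term)))
    names(annotation) <- sprintf("T%03d", seq_len(n_terms))
  } else {
    annotation <- structure(list(), names = character(0))
  }
  list(lengths = lengths, annotation = annotation)
}

#' Write the tabular outputs of a simulated experiment
#'
#' Emits the pipeline's plain-text formats: counts TSV, sample sheet TSV
#' (`sample_id line role cross`), and truth TSV
#' (`gene_id class mu_m mu_f1 mu_p`).
#'
#' @param sim Result of [simulate_trio_counts()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulated_trio <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cid <- sim$design$cross_id
  paths <- c(counts = file.path(dir, paste0(cid, "_counts.tsv")),
             samples = file.path(dir, paste0(cid, "_samples.tsv")),
             truth = file.path(dir, paste0(cid, "_truth.tsv")))
  write_counts(sim$counts, paths["counts"])
  d <- sim$design
  sheet <- data.frame(
    sample_id = trio_samples(d),
    line = sub("_[0-9]+$", "", trio_samples(d)),
    role = c(rep("maternal", length(d$maternal_samples)),
             rep("paternal", length(d$paternal_samples)),
             rep("hybrid", length(d$hybrid_samples))),
    cross = cid, stringsAsFactors = FALSE)
  write_tsv(sheet, paths["samples"])
  write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}

#' Map a true expression class to its recovery category
#'
#' The category a perfect pipeline should assign to a gene simulated from a
#' given class, at the coarse (ELD merged to parent-of-origin) level.
#'
#' @param class Character vector of class labels (`"1"`..`"12"`, `"nonDEG"`).
#' @return Character vector of coarse categories.
#' @export
true_coarse_category <- function(class) {
  full <- c(CLASS_CATEGORY, nonDEG = "nonDEG")
  coarse_category(unname(full[as.character(class)]))
}
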