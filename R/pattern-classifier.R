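#' Expression classes and categories
#'
#' The twelve expression classes partition differentially expressed genes by
#' the relative levels of maternal parent, F1 hybrid, and paternal parent:
#' additive (1, 12: hybrid between two differing parents), expression-level
#' dominance toward the paternal (2 high, 11 low) or maternal (4 high, 9 low)
#' parent, and transgressive up- (3, 7, 10) or down-regulation (5, 6, 8).
#' @name expression-classes
#' @keywords internal
NULL

CLASS_CATEGORY <- c(
  "1" = "additive", "12" = "additive",
  "2" = "ELD-paternal-high", "11" = "ELD-paternal-low",
  "4" = "ELD-maternal-high", "9" = "ELD-maternal-low",
  "3" = "transgressive-up", "7" = "transgressive-up", "10" = "transgressive-up",
  "5" = "transgressive-down", "6" = "transgressive-down", "8" = "transgressive-down"
)

DOMINANCE_CLASSES <- c("2", "4", "9", "11")

#' Collapse a fine category to its coarse family
#'
#' Maps the ELD high/low subdivisions to `ELD-paternal` / `ELD-maternal`;
#' other categories pass through.
#' @param category Character vector of categories.
#' @return Character vector of coarse categories.
#' @export
coarse_category <- function(category) {
  sub("^(ELD-(maternal|paternal))-(high|low)$", "\\1", category)
}

#' Genes excluded for missing reads in a whole line
#'
#' A gene with no reads in any replicate of at least one line of the trio is
#' set aside before classification (its within-line mean is not estimable).
#' With `rule = "any_zero"` a single zero sample suffices to exclude.
#'
#' @param m A `CountMatrix`.
#' @param d A [trio_design()].
#' @param rule `"all_reps_zero"` (default) or `"any_zero"`.
#' @return Character vector of excluded gene ids.
#' @export
exclude_zero_genes <- function(m, d, rule = c("all_reps_zero", "any_zero")) {
  rule <- match.arg(rule)
  stopifnot(inherits(m, "CountMatrix"))
  check_design_in_matrix(m, d)
  x <- unclass(m)
  line_sets <- list(d$maternal_samples, d$paternal_samples, d$hybrid_samples)
  excl <- Reduce(`|`, lapply(line_sets, function(ss) {
    xs <- x[, ss, drop = FALSE]
    if (rule == "all_reps_zero") rowSums(xs) == 0 else rowSums(xs == 0) > 0
  }))
  rownames(m)[excl]
}

#' Classify one gene from its trio of pairwise calls and means
#'
#' Decision table over the calls `c_fm` (F1 vs maternal), `c_fp` (F1 vs
#' paternal) and `c_mp` (paternal vs maternal), each in
#' `{"up", "down", "ns"}`, plus the normalized means:
#' all `ns` -> nonDEG; both hybrid-parent calls `up` -> transgressive up
#' (class 3/7/10 by parent order); both `down` -> transgressive down
#' (6/8/5); `c_fp = ns` with the other two significant -> ELD toward the
#' paternal parent (2 high / 11 low); `c_fm = ns` symmetric -> ELD toward
#' the maternal parent (4 high / 9 low); all three significant with the
#' hybrid strictly between the parents -> additive (1 if maternal lower,
#' 12 if maternal higher); anything else -> conflicting. Total and
#' deterministic over all call/ordering combinations.
#'
#' @param c_fm,c_fp,c_mp Calls (direction of the second member of each pair).
#' @param mu_m,mu_f,mu_p Normalized means of maternal, hybrid, paternal.
#' @return List with `class_id` (character: `"1"`..`"12"`, `"nonDEG"`,
#'   `"conflicting"`) and `category`.
#' @export
classify_gene <- function(c_fm, c_fp, c_mp, mu_m, mu_f, mu_p) {
  calls <- c(c_fm, c_fp, c_mp)
  if (!all(calls %in% c("up", "down", "ns")))
    stop("calls must be 'up', 'down' or 'ns'")
  cls <-
    if (all(calls == "ns")) "nonDEG"
    else if (c_fm == "up" && c_fp == "up") {
      switch(c_mp, up = "3", ns = "7", down = "10")
    } else if (c_fm == "down" && c_fp == "down") {
      switch(c_mp, up = "6", ns = "8", down = "5")
    } else if (c_fp == "ns" && c_fm != "ns" && c_mp != "ns") {
      if (c_mp == "up") "2" else "11"          # paternal above/below maternal
    } else if (c_fm == "ns" && c_fp != "ns" && c_mp != "ns") {
      if (c_mp == "down") "4" else "9"         # maternal above/below paternal
    } else if (all(calls != "ns") &&
               mu_f > min(mu_m, mu_p) && mu_f < max(mu_m, mu_p)) {
      if (mu_m < mu_p) "1" else "12"
    } else "conflicting"
  category <- if (cls %in% names(CLASS_CATEGORY)) unname(CLASS_CATEGORY[cls]) else cls
  list(class_id = cls, category = category)
}

#' Classify all genes of one cross
#'
#' Applies [classify_gene()] to every gene using the three DE tables of the
#' cross, after setting aside zero-read genes. The DEG set is defined as the
#' genes significant in at least one of the three comparisons, minus the
#' excluded genes; category proportions are reported over the DEG set.
#'
#' @param de List as returned by [pairwise_trio_de()] (elements `fm`, `fp`,
#'   `mp`).
#' @param m A `CountMatrix`.
#' @param d A [trio_design()].
#' @param zero_rule Passed to [exclude_zero_genes()].
#' @return A `PatternClassification` list: `table` (per-gene data.frame with
#'   class, category, means and calls), `proportions` (named vector over
#'   DEG categories, NULL when no DEGs), `n_deg`, `excluded`.
#' @export
classify_all <- function(de, m, d, zero_rule = "all_reps_zero") {
  for (nm in c("fm", "fp", "mp")) {
    if (!identical(de[[nm]]$gene_id, rownames(m)))
      stop("DE table '", nm, "' does not match the count matrix gene universe")
  }
  excluded <- exclude_zero_genes(m, d, zero_rule)
  n <- nrow(m)
  cls <- character(n); cat_ <- character(n)
  for (i in seq_len(n)) {
    r <- classify_gene(de$fm$call[i], de$fp$call[i], de$mp$call[i],
                       de$fm$mean_a[i], de$fm$mean_b[i], de$fp$mean_a[i])
    cls[i] <- r$class_id; cat_[i] <- r$category
  }
  is_excl <- rownames(m) %in% excluded
  cls[is_excl] <- "excluded"; cat_[is_excl] <- "excluded"
  tab <- data.frame(gene_id = rownames(m), class = cls, category = cat_,
                    mu_m = de$fm$mean_a, mu_f1 = de$fm$mean_b,
                    mu_p = de$fp$mean_a,
                    c_fm = de$fm$call, c_fp = de$fp$call, c_mp = de$mp$call,
                    row.names = NULL, stringsAsFactors = FALSE)
  sig_any <- de$fm$call != "ns" | de$fp$call != "ns" | de$mp$call != "ns"
  deg <- tab$gene_id[sig_any & !is_excl]
  props <- NULL
  if (length(deg)) {
    pc <- table(tab$category[tab$gene_id %in% deg])
    props <- as.numeric(pc) / length(deg)
    names(props) <- names(pc)
  }
  structure(list(table = tab, proportions = props, n_deg = length(deg),
                 deg_genes = deg, excluded = excluded, cross_id = d$cross_id),
            class = "PatternClassification")
}

#' @export
print.PatternClassification <- function(x, ...) {
  cat(sprintf("PatternClassification '%s': %d genes, %d DEGs, %d excluded\n",
              x$cross_id, nrow(x$table), x$n_deg, length(x$excluded)))
  if (!is.null(x$proportions)) {
    for (nm in names(sort(x$proportions, decreasing = TRUE)))
      cat(sprintf("  %-22s %6.2f%%\n", nm, 100 * x$proportions[nm]))
  }
  invisible(x)
}

#' Venn partition of two DEG sets
#'
#' @param set_a,set_b Character vectors (gene ids).
#' @return Named integer vector `c(only_a, both, only_b)`.
#' @export
venn_counts <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  both <- length(intersect(set_a, set_b))
  c(only_a = length(set_a) - both, both = both, only_b = length(set_b) - both)
}

#' Dominance DEGs common to all crosses
#'
#' Genes falling in a dominance class (2, 4, 9 or 11) in every supplied
#' classification.
#'
#' @param classifications List of `PatternClassification` objects (>= 1).
#' @return Character vector of gene ids.
#' @export
common_dominance_set <- function(classifications) {
  if (!length(classifications)) stop("at least one classification required")
  sets <- lapply(classifications, function(cl) {
    cl$table$gene_id[cl$table$class %in% DOMINANCE_CLASSES]
  })
  Reduce(intersect, sets)
}

#' Hierarchical clustering of samples by expression correlation
#'
#' Average-linkage agglomerative clustering on the distance
#' `1 - Pearson correlation` between sample columns. Samples are ordered by
#' id before clustering so that leaf order is deterministic.
#'
#' @param e Numeric expression matrix (genes x samples), e.g. RPKM from
#'   [compute_rpkm()].
#' @return An object of class `hclust`.
#' @export
hier_cluster <- function(e) {
  if (ncol(e) < 2) stop("need at least two samples")
  e <- e[, order(colnames(e)), drop = FALSE]
  sds <- apply(e, 2, stats::sd)
  if (any(sds == 0))
    stop("constant expression in sample(s): ",
         paste(colnames(e)[sds == 0], collapse = ", "),
         " - correlation undefined")
  d <- stats::as.dist(1 - stats::cor(e))
  stats::hclust(d, method = "average")
}
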