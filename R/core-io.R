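#' Construct a count matrix container
#'
#' A `CountMatrix` is an integer gene x sample matrix with unique gene and
#' sample identifiers, the raw-count substrate for every downstream stage.
#'
#' @param counts Integer matrix (genes in rows, samples in columns) with
#'   rownames (gene ids) and colnames (sample ids).
#' @return A `CountMatrix` object (an integer matrix with class attribute).
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id: ", rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ", colnames(counts)[duplicated(colnames(counts))][1])
  if (anyNA(counts)) stop("NA counts are not allowed")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("non-integer counts are not allowed")
  storage.mode(counts) <- "integer"
  structure(counts, class = c("CountMatrix", class(matrix())))
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Assignment of samples to the three members of one cross
#'
#' @param cross_id Identifier of the cross.
#' @param maternal_samples,paternal_samples,hybrid_samples Character vectors
#'   of sample ids; the three sets must be nonempty and pairwise disjoint.
#' @return A `TrioDesign` object.
#' @export
trio_design <- function(cross_id, maternal_samples, paternal_samples, hybrid_samples) {
  sets <- list(maternal = maternal_samples, paternal = paternal_samples,
               hybrid = hybrid_samples)
  for (role in names(sets)) {
    if (length(sets[[role]]) < 1)
      stop("cross ", cross_id, ": no ", role, " samples")
  }
  all_ids <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("cross ", cross_id, ": sample '", all_ids[duplicated(all_ids)][1],
         "' assigned to more than one role")
  structure(list(cross_id = cross_id,
                 maternal_samples = as.character(maternal_samples),
                 paternal_samples = as.character(paternal_samples),
                 hybrid_samples = as.character(hybrid_samples)),
            class = "TrioDesign")
}

#' @export
print.TrioDesign <- function(x, ...) {
  cat(sprintf("TrioDesign '%s': %d maternal, %d paternal, %d hybrid samples\n",
              x$cross_id, length(x$maternal_samples),
              length(x$paternal_samples), length(x$hybrid_samples)))
  invisible(x)
}

trio_samples <- function(d) {
  c(d$maternal_samples, d$paternal_samples, d$hybrid_samples)
}

check_design_in_matrix <- function(m, d) {
  missing <- setdiff(trio_samples(d), colnames(m))
  if (length(missing))
    stop("cross ", d$cross_id, ": sample(s) not in count matrix: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Read a gene x sample count matrix from TSV
#'
#' Expects a header row whose first column is `gene_id`; remaining columns are
#' sample counts. Plain or gzip-compressed files are accepted. Malformed input
#' (duplicate ids, negative, missing or non-integer entries, ragged rows) is
#' rejected rather than coerced.
#'
#' @param path Path to a TSV file.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop(path, ": expected a gene_id column plus >=1 sample column")
  gene_ids <- df[[1]]
  if (anyDuplicated(gene_ids))
    stop(path, ": duplicate gene id '", gene_ids[duplicated(gene_ids)][1], "'")
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(path, ": non-numeric count for gene '", gene_ids[bad[1]],
         "', sample '", colnames(df)[-1][bad[2]], "'")
  }
  if (any(num < 0) || any(num != round(num))) {
    bad <- which(num < 0 | num != round(num), arr.ind = TRUE)[1, ]
    stop(path, ": counts must be nonnegative integers (gene '",
         gene_ids[bad[1]], "', sample '", colnames(df)[-1][bad[2]], "')")
  }
  dimnames(num) <- list(gene_ids, colnames(df)[-1])
  count_matrix(num)
}

#' Write a count matrix to TSV
#'
#' Writes the exact format [read_counts()] reads back (round-trip identity):
#' UTF-8 TSV, header `gene_id` then sample ids, no quoting.
#'
#' @param m A `CountMatrix`.
#' @param path Output path (`.gz` suffix writes gzip).
#' @export
write_counts <- function(m, path) {
  stopifnot(inherits(m, "CountMatrix"))
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Compute RPKM expression values
#'
#' RPKM (reads per kilobase of gene model per million mapped reads) for count
#' `C_ij`, gene length `L_i` (bp) and per-sample total `N_j`:
#' `RPKM_ij = C_ij * 1e9 / (N_j * L_i)`.
#'
#' @param m A `CountMatrix`.
#' @param lengths Named numeric vector of gene lengths in bp (must cover all
#'   genes in `m`; all positive).
#' @param totals Named numeric vector of per-sample total mapped reads. When
#'   `NULL` (default) the column sums of `m` stand in for the library totals.
#' @return A numeric matrix of RPKM values with attributes `lengths` and
#'   `totals` recording the provenance.
#' @export
compute_rpkm <- function(m, lengths, totals = NULL) {
  stopifnot(inherits(m, "CountMatrix"))
  missing_len <- setdiff(rownames(m), names(lengths))
  if (length(missing_len))
    stop("missing gene length for: ", paste(utils::head(missing_len, 3), collapse = ", "))
  L <- lengths[rownames(m)]
  if (any(L <= 0)) stop("non-positive length for gene '",
                        rownames(m)[which(L <= 0)[1]], "'")
  if (is.null(totals)) {
    N <- colSums(m)
    names(N) <- colnames(m)
  } else {
    missing_tot <- setdiff(colnames(m), names(totals))
    if (length(missing_tot))
      stop("missing library total for sample: ", missing_tot[1])
    N <- totals[colnames(m)]
  }
  if (any(N <= 0)) stop("non-positive library total for sample '",
                        colnames(m)[which(N <= 0)[1]], "'")
  rpkm <- sweep(sweep(unclass(m) * 1e9, 2, N, "/"), 1, L, "/")
  attr(rpkm, "lengths") <- L
  attr(rpkm, "totals") <- N
  rpkm
}

#' Read a sample sheet into trio designs
#'
#' The sheet is a TSV with columns `sample_id`, `line`, `role`, `cross`;
#' `role` is one of `maternal`, `paternal`, `hybrid`. A sample may serve in
#' several crosses (shared parental lines) but only one role per cross.
#'
#' @param path Path to the sample-sheet TSV.
#' @return A named list of [trio_design()] objects, one per cross, in order
#'   of first appearance.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character")
  required <- c("sample_id", "line", "role", "cross")
  miss <- setdiff(required, colnames(df))
  if (length(miss)) stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  bad_role <- setdiff(unique(df$role), c("maternal", "paternal", "hybrid"))
  if (length(bad_role)) stop(path, ": unknown role '", bad_role[1], "'")
  crosses <- unique(df$cross)
  designs <- lapply(crosses, function(cr) {
    sub <- df[df$cross == cr, , drop = FALSE]
    if (anyDuplicated(sub$sample_id))
      stop(path, ": cross '", cr, "': sample '",
           sub$sample_id[duplicated(sub$sample_id)][1],
           "' assigned two roles")
    trio_design(cr,
                maternal_samples = sub$sample_id[sub$role == "maternal"],
                paternal_samples = sub$sample_id[sub$role == "paternal"],
                hybrid_samples  = sub$sample_id[sub$role == "hybrid"])
  })
  names(designs) <- crosses
  designs
}

#' Read a gene-length table
#'
#' @param path TSV with columns `gene_id`, `length_bp`.
#' @return Named numeric vector of lengths (bp).
#' @export
read_gene_lengths <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = c("character", "numeric"))
  miss <- setdiff(c("gene_id", "length_bp"), colnames(df))
  if (length(miss)) stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop(path, ": duplicate gene id '", df$gene_id[duplicated(df$gene_id)][1], "'")
  if (any(!is.finite(df$length_bp)) || any(df$length_bp <= 0))
    stop(path, ": lengths must be positive")
  stats::setNames(df$length_bp, df$gene_id)
}

#' Read a term-to-gene annotation map
#'
#' @param path Two-column TSV `term_id`, `gene_id` (one row per assignment).
#' @return Named list mapping each term id to a character vector of gene ids.
#' @export
read_annotation_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character")
  miss <- setdiff(c("term_id", "gene_id"), colnames(df))
  if (length(miss)) stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(structure(list(), names = character(0)))
  split(df$gene_id, factor(df$term_id, levels = unique(df$term_id)))
}
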