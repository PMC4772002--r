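#' Summary of one line's phenotype
#'
#' @param line_id Line identifier.
#' @param mean Trait mean (e.g. body weight in micrograms).
#' @param se Standard error of the mean (>= 0).
#' @param n Number of individuals measured.
#' @return A `PhenotypeSummary` list.
#' @export
phenotype_summary <- function(line_id, mean, se = 0, n = 1L) {
  if (se < 0) stop("se must be >= 0")
  if (se > 0 && n < 2) stop("a positive SE requires n >= 2")
  structure(list(line_id = line_id, mean = mean, se = se, n = as.integer(n)),
            class = "PhenotypeSummary")
}

#' Mid-parent value
#'
#' Arithmetic mean of the two parental line means.
#'
#' @param p1,p2 [phenotype_summary()] objects (or bare numbers).
#' @return Numeric MPV.
#' @export
mid_parent_value <- function(p1, p2) {
  (pheno_mean(p1) + pheno_mean(p2)) / 2
}

pheno_mean <- function(x) if (inherits(x, "PhenotypeSummary")) x$mean else as.numeric(x)

#' Decimal half-up rounding
#'
#' Rounds the way printed tables do: halves go up in decimal, so 98.135
#' becomes 98.14. Base `round()` operates on the binary representation
#' (98.135 is stored slightly below the half) and rounds half to even, which
#' cannot reproduce such printed values.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Rate of heterosis
#'
#' Percent deviation of the F1 mean from the mid-parent value:
#' `RH = 100 * (F1 - MPV) / MPV`. Some published tables compute RH from the
#' MPV rounded to two decimals; `round_mpv = TRUE` reproduces that behavior.
#'
#' @param f1,p1,p2 [phenotype_summary()] objects (or bare means).
#' @param round_mpv Round MPV to 2 dp before forming the ratio.
#' @return RH in percent (full precision; round for display).
#' @export
heterosis_rate <- function(f1, p1, p2, round_mpv = FALSE) {
  mpv <- mid_parent_value(p1, p2)
  if (round_mpv) mpv <- round_half_up(mpv, 2)
  if (mpv == 0) stop("mid-parent value is zero; heterosis rate undefined")
  100 * (pheno_mean(f1) - mpv) / mpv
}

#' Significance of F1 deviation from the mid-parent value
#'
#' Normal-approximation contrast of the F1 mean against the mid-parent value
#' using independent line SEs:
#' `z = (F1 - MPV) / sqrt(SE_F1^2 + (SE_P1^2 + SE_P2^2)/4)`, with a
#' two-sided normal p-value and marks `**` (p < 0.01), `*` (p < 0.05), `ns`.
#'
#' @param f1,p1,p2 [phenotype_summary()] objects with SEs.
#' @return List with `statistic`, `p_value`, `mark`, `mpv`.
#' @export
mpv_significance_test <- function(f1, p1, p2) {
  stopifnot(inherits(f1, "PhenotypeSummary"), inherits(p1, "PhenotypeSummary"),
            inherits(p2, "PhenotypeSummary"))
  se2 <- f1$se^2 + (p1$se^2 + p2$se^2) / 4
  if (se2 == 0) stop("all standard errors are zero; test undefined")
  mpv <- mid_parent_value(p1, p2)
  z <- (f1$mean - mpv) / sqrt(se2)
  p <- 2 * stats::pnorm(-abs(z))
  mark <- if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
  list(statistic = z, p_value = p, mark = mark, mpv = mpv)
}

#' Heterosis statistics for one cross
#'
#' Convenience wrapper combining [mid_parent_value()], [heterosis_rate()] and
#' [mpv_significance_test()].
#'
#' @param cross_id Cross identifier.
#' @param f1,p1,p2 [phenotype_summary()] objects (F1, father, mother).
#' @param round_mpv Passed to [heterosis_rate()].
#' @return A `HeterosisResult` data.frame row.
#' @export
heterosis_result <- function(cross_id, f1, p1, p2, round_mpv = FALSE) {
  tst <- mpv_significance_test(f1, p1, p2)
  data.frame(cross_id = cross_id,
             f1_mean = f1$mean, p1_mean = p1$mean, p2_mean = p2$mean,
             mpv = tst$mpv,
             rh_percent = heterosis_rate(f1, p1, p2, round_mpv = round_mpv),
             statistic = tst$statistic, p_value = tst$p_value,
             mark = tst$mark, row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a phenotype summary table
#'
#' @param path TSV with columns `line_id`, `mean`, `se`, `n`.
#' @return Named list of [phenotype_summary()] objects.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "")
  miss <- setdiff(c("line_id", "mean", "se", "n"), colnames(df))
  if (length(miss)) stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    phenotype_summary(df$line_id[i], df$mean[i], df$se[i], df$n[i]))
  names(out) <- df$line_id
  out
}

#' Delta-delta-Ct relative expression
#'
#' qPCR fold change: `2^-ddCt` with
#' `ddCt = (Ct_target,test - Ct_ref,test) - (Ct_target,ctrl - Ct_ref,ctrl)`.
#'
#' @param ct_target_test,ct_ref_test Target and reference-gene Ct in the test
#'   sample.
#' @param ct_target_ctrl,ct_ref_ctrl The same in the control sample.
#' @return Fold change of the target in test relative to control.
#' @export
ddct_relative_expression <- function(ct_target_test, ct_ref_test,
                                     ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
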