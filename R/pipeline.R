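#' Validate a pipeline configuration
#'
#' A configuration either names real input files (`inputs:` with `counts`,
#' `samples`, `lengths`, `annotation`, optionally `phenotypes` +
#' `phenotype_crosses`) or a simulation block (`simulate:` with the
#' [truth_spec()] fields plus `n_crosses` and optional phenotype means) -
#' never both. Thresholds (`padj`, `enrichment`), the zero-exclusion rule,
#' the RH rounding flag and the seed are surfaced at the top level.
#'
#' @param cfg A named list, or the path to a YAML file holding one.
#' @return The validated config list (with defaults filled in).
#' @export
pipeline_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1) {
    if (!file.exists(cfg)) stop("config file not found: ", cfg)
    cfg <- yaml::read_yaml(cfg)
  }
  if (!is.list(cfg)) stop("config must be a list or a YAML file path")
  has_real <- !is.null(cfg$inputs)
  has_sim <- !is.null(cfg$simulate)
  if (has_real == has_sim)
    stop("config must contain exactly one of `inputs` or `simulate`")
  cfg$padj <- cfg$padj %||% 0.05
  cfg$enrichment_threshold <- cfg$enrichment_threshold %||% 0.05
  cfg$zero_rule <- cfg$zero_rule %||% "all_reps_zero"
  cfg$round_mpv <- isTRUE(cfg$round_mpv)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  for (th in c("padj", "enrichment_threshold")) {
    if (cfg[[th]] <= 0 || cfg[[th]] >= 1)
      stop("`", th, "` must lie in (0, 1)")
  }
  if (has_real) {
    need <- c("counts", "samples", "lengths", "annotation")
    miss <- setdiff(need, names(cfg$inputs))
    if (length(miss))
      stop("inputs block missing: ", paste(miss, collapse = ", "))
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full heterosis analysis pipeline
#'
#' Stages: load or simulate trio count data; per-cross normalization, trio
#' differential expression, and expression-pattern classification; Venn
#' partition of the two hybrid-vs-parent DEG sets per cross; dominance genes
#' common to all crosses; length-bias-aware enrichment of that common set;
#' RPKM + sample clustering; phenotype heterosis statistics when phenotype
#' data are configured. All outputs are plain TSV/JSON in `out_dir`, plus a
#' `manifest.json` with the config hash, seed and per-stage row counts.
#' Identical config and seed give byte-identical outputs.
#'
#' @param cfg Config list or YAML path (see [pipeline_config()]).
#' @param out_dir Output directory (created; must be empty or absent).
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg, out_dir) {
  cfg <- pipeline_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[hetvig] ", sprintf(...))

  manifest <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                   stages = list())

  # ---- stage: inputs -------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    log_stage("simulating %d crosses", cfg$simulate$n_crosses %||% 3)
    sp <- cfg$simulate
    spec <- truth_spec(
      n_genes = sp$n_genes %||% 1200,
      classes = unlist(sp$classes %||%
                         stats::setNames(rep(1 / 13, 13), c(as.character(1:12), "nonDEG"))),
      base_mean = sp$base_mean %||% 200,
      fold_change = sp$fold_change %||% 4,
      dispersion = sp$dispersion %||% 0.01,
      n_reps = sp$n_reps %||% 2,
      size_factor_range = unlist(sp$size_factor_range %||% c(0.7, 1.4)),
      seed = cfg$seed)
    sims <- simulate_heterosis_experiment(spec, n_crosses = sp$n_crosses %||% 3)
    for (s in sims) write_simulated_trio(s, file.path(out_dir, "inputs"))
    counts_list <- lapply(sims, `[[`, "counts")
    designs <- lapply(sims, `[[`, "design")
    truth <- sims[[1]]$truth
    fx <- make_annotation_fixture(spec$n_genes,
                                  n_terms = sp$n_terms %||% 30,
                                  genes_per_term = sp$genes_per_term %||% 40,
                                  seed = cfg$seed,
                                  gene_ids = rownames(counts_list[[1]]))
    lengths <- fx$lengths; annotation <- fx$annotation
    phenotypes <- NULL
    if (!is.null(sp$phenotype)) {
      ph <- sp$phenotype
      bw <- simulate_body_weights(ph$mu_m, ph$mu_p, ph$mu_f1,
                                  sd = ph$sd %||% 10, n = ph$n %||% 200,
                                  seed = cfg$seed)
      phenotypes <- list(list(cross_id = "X1",
                              f1 = summarize_sample("f1", bw$hybrid),
                              p1 = summarize_sample("pat", bw$paternal),
                              p2 = summarize_sample("mat", bw$maternal)))
    }
  } else {
    log_stage("reading inputs")
    m <- read_counts(cfg$inputs$counts)
    designs <- read_sample_sheet(cfg$inputs$samples)
    counts_list <- stats::setNames(
      rep(list(m), length(designs)), names(designs))
    truth <- NULL
    lengths <- read_gene_lengths(cfg$inputs$lengths)
    annotation <- read_annotation_map(cfg$inputs$annotation)
    phenotypes <- NULL
    if (!is.null(cfg$inputs$phenotypes)) {
      ph <- read_phenotypes(cfg$inputs$phenotypes)
      phenotypes <- lapply(cfg$inputs$phenotype_crosses, function(pc)
        list(cross_id = pc$cross_id, f1 = ph[[pc$f1]],
             p1 = ph[[pc$father]], p2 = ph[[pc$mother]]))
    }
  }
  manifest$stages$inputs <- list(n_crosses = length(designs),
                                 n_genes = nrow(counts_list[[1]]))

  # ---- stage: DE + classification per cross --------------------------------
  classifications <- list()
  venns <- list()
  for (cid in names(designs)) {
    log_stage("cross %s: differential expression", cid)
    m <- counts_list[[cid]]
    d <- designs[[cid]]
    de <- pairwise_trio_de(m, d, threshold = cfg$padj)
    for (cmp in c("fm", "fp", "mp"))
      write_tsv(de[[cmp]], file.path(out_dir, sprintf("de_%s_%s.tsv", cid, cmp)))
    cl <- classify_all(de, m, d, zero_rule = cfg$zero_rule)
    write_tsv(cl$table, file.path(out_dir, sprintf("classes_%s.tsv", cid)))
    classifications[[cid]] <- cl
    deg_fm <- de$fm$gene_id[de$fm$call != "ns"]
    deg_fp <- de$fp$gene_id[de$fp$call != "ns"]
    venns[[cid]] <- venn_counts(deg_fm, deg_fp)
  }
  summary_json <- list(
    crosses = lapply(classifications, function(cl)
      list(n_deg = cl$n_deg, n_excluded = length(cl$excluded),
           proportions = as.list(cl$proportions))),
    venn = lapply(venns, as.list))
  manifest$stages$classification <-
    lapply(classifications, function(cl) cl$n_deg)

  # ---- stage: cross-wise set algebra ---------------------------------------
  common_dom <- common_dominance_set(classifications)
  summary_json$common_dominance <- list(n = length(common_dom),
                                        genes = common_dom)
  manifest$stages$common_dominance <- length(common_dom)

  # ---- stage: enrichment ---------------------------------------------------
  background <- rownames(counts_list[[1]])
  enr <- NULL
  if (length(common_dom) && length(annotation)) {
    log_stage("enrichment of %d common dominance genes", length(common_dom))
    de_flags <- stats::setNames(as.integer(background %in% common_dom), background)
    pwf <- fit_pwf(de_flags, lengths)
    enr <- enrich_terms(annotation, common_dom, background, pwf,
                        threshold = cfg$enrichment_threshold)
    write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    manifest$stages$enrichment <- sum(enr$flag)
  }

  # ---- stage: clustering ---------------------------------------------------
  m1 <- counts_list[[1]]
  rpkm <- compute_rpkm(m1, lengths)
  hc <- tryCatch(hier_cluster(rpkm), error = function(e) NULL)
  if (!is.null(hc)) {
    summary_json$cluster_leaf_order <- hc$labels[hc$order]
  }

  # ---- stage: phenotype ----------------------------------------------------
  if (!is.null(phenotypes)) {
    log_stage("phenotype heterosis statistics")
    het <- do.call(rbind, lapply(phenotypes, function(pc)
      heterosis_result(pc$cross_id, pc$f1, pc$p1, pc$p2,
                       round_mpv = cfg$round_mpv)))
    write_tsv(het, file.path(out_dir, "heterosis.tsv"))
    summary_json$heterosis <- lapply(seq_len(nrow(het)), function(i)
      as.list(het[i, ]))
    manifest$stages$phenotype <- nrow(het)
  }

  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(classifications = classifications, venns = venns,
                 common_dominance = common_dom, enrichment = enr,
                 truth = truth, manifest = manifest))
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Summarize a completed pipeline run
#'
#' Reads the run directory's machine outputs and renders a plain-text report
#' whose numbers are taken from (and therefore consistent with) those files:
#' per-cross DEG counts and category proportions, Venn partitions, the common
#' dominance set size, flagged enrichment terms, and heterosis statistics.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @return Character vector of report lines (invisibly also written to
#'   `report.txt` in the run directory).
#' @export
summarize_run <- function(run_dir) {
  sj <- file.path(run_dir, "summary.json")
  if (!file.exists(sj)) stop("missing file: ", sj)
  s <- jsonlite::read_json(sj)
  lines <- c("hetvig run summary", "==================")
  for (cid in names(s$crosses)) {
    cr <- s$crosses[[cid]]
    lines <- c(lines, sprintf("cross %s: %d DEGs (%d genes excluded)",
                              cid, cr$n_deg, cr$n_excluded))
    if (cr$n_deg == 0) {
      lines <- c(lines, "  zero DEGs; no category proportions")
    } else {
      dom <- sum(unlist(cr$proportions[grepl("^ELD", names(cr$proportions))]))
      lines <- c(lines, sprintf("  dominance (ELD) share of DEGs: %.2f%%", 100 * dom))
      for (nm in names(cr$proportions))
        lines <- c(lines, sprintf("    %-22s %6.2f%%", nm,
                                  100 * cr$proportions[[nm]]))
    }
    v <- s$venn[[cid]]
    if (!is.null(v))
      lines <- c(lines, sprintf("  Venn (F1-vs-mat | both | F1-vs-pat): %d | %d | %d",
                                v$only_a, v$both, v$only_b))
  }
  lines <- c(lines, sprintf("dominance DEGs common to all crosses: %d",
                            s$common_dominance$n))
  ef <- file.path(run_dir, "enrichment.tsv")
  if (file.exists(ef)) {
    enr <- utils::read.delim(ef)
    lines <- c(lines, sprintf("enriched terms (adjusted p below threshold): %d of %d",
                              sum(enr$flag), nrow(enr)))
  }
  if (!is.null(s$heterosis)) {
    for (h in s$heterosis)
      lines <- c(lines, sprintf("heterosis %s: MPV %.2f, RH %.2f%% (%s)",
                                h$cross_id, h$mpv, h$rh_percent, h$mark))
  }
  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(lines)
}
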