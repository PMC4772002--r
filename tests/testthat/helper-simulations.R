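# Shared simulation fixtures, computed once per test run and cached.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

all_class_spec <- function(n_genes = 1200, fold_change = 4, dispersion = 0.01,
                           n_reps = 3, seed = 1) {
  truth_spec(n_genes = n_genes,
             classes = setNames(rep(1 / 13, 13), c(as.character(1:12), "nonDEG")),
             base_mean = 200, fold_change = fold_change,
             dispersion = dispersion, n_reps = n_reps, seed = seed)
}

# the study-condition recovery run: all 12 classes + nonDEG, fold change 4,
# dispersion 0.01, 3 replicates, 1200 genes
recovery_run <- function() {
  cached("recovery", {
    spec <- all_class_spec()
    sim <- simulate_trio_counts(spec)
    de <- pairwise_trio_de(sim$counts, sim$design)
    cl <- classify_all(de, sim$counts, sim$design)
    list(spec = spec, sim = sim, de = de, cl = cl)
  })
}

# null run: every gene nonDEG, for false-call-rate checks
null_run <- function() {
  cached("null", {
    spec <- truth_spec(n_genes = 2000, classes = c(nonDEG = 1),
                       base_mean = 200, fold_change = 4,
                       dispersion = 0.01, n_reps = 3, seed = 11)
    sim <- simulate_trio_counts(spec)
    de <- pairwise_trio_de(sim$counts, sim$design)
    list(spec = spec, sim = sim, de = de)
  })
}
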