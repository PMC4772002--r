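# enumerate every call combination with mean orderings that realize it
call_levels <- c("up", "down", "ns")

# means consistent with a call triple: construct mu values compatible with
# each call's direction (ns -> equal), covering betweenness variants
consistent_means <- function(c_fm, c_fp, c_mp) {
  # base maternal level 10; paternal from c_mp; hybrid from c_fm if
  # informative, else from c_fp, else equal to both
  mu_m <- 10
  mu_p <- switch(c_mp, up = 20, down = 5, ns = 10)
  mu_f <- if (c_fm == "up") mu_m + 7
          else if (c_fm == "down") mu_m - 4
          else if (c_fp == "up") mu_p + 7
          else if (c_fp == "down") mu_p - 4
          else mu_m
  c(mu_m = mu_m, mu_f = mu_f, mu_p = mu_p)
}

test_that("classification is total, single-valued, and category-consistent", {
  combos <- expand.grid(c_fm = call_levels, c_fp = call_levels,
                        c_mp = call_levels, stringsAsFactors = FALSE)
  class_sets <- list(additive = c("1", "12"),
                     `ELD-paternal-high` = "2", `ELD-paternal-low` = "11",
                     `ELD-maternal-high` = "4", `ELD-maternal-low` = "9",
                     `transgressive-up` = c("3", "7", "10"),
                     `transgressive-down` = c("5", "6", "8"))
  seen <- character(0)
  for (i in seq_len(nrow(combos))) {
    cm <- combos[i, ]
    # sweep several mean orderings, not only the consistent one
    for (mu in list(consistent_means(cm$c_fm, cm$c_fp, cm$c_mp),
                    c(mu_m = 1, mu_f = 2, mu_p = 3),
                    c(mu_m = 3, mu_f = 2, mu_p = 1),
                    c(mu_m = 2, mu_f = 9, mu_p = 2))) {
      r <- classify_gene(cm$c_fm, cm$c_fp, cm$c_mp, mu[1], mu[2], mu[3])
      expect_length(r$class_id, 1)
      expect_true(r$class_id %in% c(as.character(1:12), "nonDEG", "conflicting"))
      if (r$class_id %in% as.character(1:12)) {
        expect_true(r$class_id %in% class_sets[[r$category]])
      } else {
        expect_identical(r$category, r$class_id)
      }
      seen <- union(seen, r$class_id)
    }
  }
  # the sweep exercises every class at least once
  expect_setequal(seen, c(as.character(1:12), "nonDEG", "conflicting"))
})

test_that("pinned class facts hold", {
  # hybrid indistinguishable from the (lower) father while parents differ
  r <- classify_gene("down", "ns", "down", mu_m = 20, mu_f = 5, mu_p = 5)
  expect_identical(r$class_id, "11")
  expect_identical(r$category, "ELD-paternal-low")
  # all non-significant -> nonDEG
  r <- classify_gene("ns", "ns", "ns", 1, 1, 1)
  expect_identical(r$class_id, "nonDEG")
  # additive: all significant, hybrid strictly between
  r <- classify_gene("up", "down", "up", mu_m = 5, mu_f = 10, mu_p = 20)
  expect_identical(r$class_id, "1")
  r <- classify_gene("down", "up", "down", mu_m = 20, mu_f = 10, mu_p = 5)
  expect_identical(r$class_id, "12")
  # transgressive above both parents, parents equal
  r <- classify_gene("up", "up", "ns", 5, 30, 5)
  expect_identical(r$class_id, "7")
})

test_that("reciprocal-cross symmetry maps classes as expected", {
  swap_map <- c("1" = "12", "12" = "1", "2" = "4", "4" = "2",
                "11" = "9", "9" = "11", "3" = "10", "10" = "3",
                "6" = "5", "5" = "6", "7" = "7", "8" = "8",
                nonDEG = "nonDEG", conflicting = "conflicting")
  flip <- c(up = "down", down = "up", ns = "ns")
  combos <- expand.grid(c_fm = call_levels, c_fp = call_levels,
                        c_mp = call_levels, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    cm <- combos[i, ]
    mu <- consistent_means(cm$c_fm, cm$c_fp, cm$c_mp)
    orig <- classify_gene(cm$c_fm, cm$c_fp, cm$c_mp, mu[1], mu[2], mu[3])
    # exchange maternal and paternal roles
    swapped <- classify_gene(cm$c_fp, cm$c_fm, unname(flip[cm$c_mp]),
                             mu[3], mu[2], mu[1])
    expect_identical(swapped$class_id, unname(swap_map[orig$class_id]))
  }
})

test_that("zero-read exclusion follows the whole-line rule", {
  x <- matrix(5L, nrow = 4, ncol = 6,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  x["g1", ] <- 0L                      # zero everywhere -> excluded
  x["g2", c("s5")] <- 0L               # one hybrid replicate zero -> kept
  x["g3", c("s3", "s4")] <- 0L         # whole paternal line zero -> excluded
  m <- count_matrix(x)
  d <- trio_design("X", paste0("s", 1:2), paste0("s", 3:4), paste0("s", 5:6))
  expect_setequal(exclude_zero_genes(m, d), c("g1", "g3"))
  expect_setequal(exclude_zero_genes(m, d, rule = "any_zero"),
                  c("g1", "g2", "g3"))
})

test_that("planted all-zero-in-one-line genes are exactly the excluded set", {
  run <- recovery_run()
  m0 <- unclass(run$sim$counts)
  set.seed(3)
  planted <- sample(rownames(m0), 5)
  m0[planted, run$sim$design$paternal_samples] <- 0L
  # ensure no other gene qualifies by construction: give every other gene a
  # positive count in each line
  others <- setdiff(rownames(m0), planted)
  for (ss in list(run$sim$design$maternal_samples,
                  run$sim$design$paternal_samples,
                  run$sim$design$hybrid_samples)) {
    zero_rows <- others[rowSums(m0[others, ss, drop = FALSE]) == 0]
    m0[zero_rows, ss[1]] <- 1L
  }
  excl <- exclude_zero_genes(count_matrix(m0), run$sim$design)
  expect_setequal(excl, planted)
})

test_that("classify_all recovers planted categories and sane proportions", {
  run <- recovery_run()
  cl <- run$cl
  expect_s3_class(cl, "PatternClassification")
  expect_equal(sum(cl$proportions), 1, tolerance = 1e-12)
  truth_cat <- true_coarse_category(run$sim$truth$class)
  pred_cat <- coarse_category(cl$table$category)
  # per-category confusion-matrix diagonal
  for (categ in unique(truth_cat)) {
    idx <- truth_cat == categ
    expect_gte(mean(pred_cat[idx] == categ), 0.8)
  }
})

test_that("ELD-only simulations approach pure dominance as effects grow", {
  spec <- truth_spec(n_genes = 300,
                     classes = c("2" = 0.25, "4" = 0.25, "9" = 0.25, "11" = 0.25),
                     base_mean = 200, fold_change = 8, dispersion = 0.001,
                     n_reps = 3, seed = 9)
  sim <- simulate_trio_counts(spec)
  de <- pairwise_trio_de(sim$counts, sim$design, threshold = 0.001)
  cl <- classify_all(de, sim$counts, sim$design)
  dom <- sum(cl$proportions[grepl("^ELD", names(cl$proportions))])
  expect_gte(dom, 0.95)
})

test_that("empty DEG sets are flagged rather than summarized", {
  x <- matrix(50L, nrow = 10, ncol = 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  m <- count_matrix(x)
  d <- trio_design("X", paste0("s", 1:2), paste0("s", 3:4), paste0("s", 5:6))
  de <- pairwise_trio_de(m, d)
  cl <- classify_all(de, m, d)
  expect_equal(cl$n_deg, 0)
  expect_null(cl$proportions)
})

test_that("venn counts equal brute-force set algebra", {
  expect_equal(venn_counts(letters[1:10], letters[1:10]),
               c(only_a = 0, both = 10, only_b = 0))
  expect_equal(venn_counts(letters[1:3], letters[4:7]),
               c(only_a = 3, both = 0, only_b = 4))
  set.seed(81)
  for (i in 1:10) {
    a <- sample(sprintf("g%03d", 1:100), sample(5:60, 1))
    b <- sample(sprintf("g%03d", 1:100), sample(5:60, 1))
    v <- venn_counts(a, b)
    expect_equal(unname(v),
                 c(length(setdiff(a, b)), length(intersect(a, b)),
                   length(setdiff(b, a))))
    expect_equal(v[["only_a"]] + v[["both"]], length(unique(a)))
  }
})

test_that("the common dominance set is the planted intersection", {
  # fabricate three classifications with controlled dominance membership
  mk <- function(dom_genes, all_genes) {
    tab <- data.frame(gene_id = all_genes,
                      class = ifelse(all_genes %in% dom_genes, "9", "nonDEG"),
                      stringsAsFactors = FALSE)
    structure(list(table = tab, cross_id = "x"),
              class = "PatternClassification")
  }
  genes <- sprintf("g%03d", 1:200)
  set.seed(91)
  core <- sample(genes, 40)
  cls <- lapply(1:3, function(i) mk(union(core, sample(genes, 30)), genes))
  expect_setequal(common_dominance_set(cls), Reduce(
    intersect, lapply(cls, function(cl) cl$table$gene_id[cl$table$class == "9"])))
  expect_true(all(core %in% common_dominance_set(cls)))
  # a gene dominant in only 2 of 3 crosses is excluded
  two_of_three <- setdiff(common_dominance_set(cls[1:2]), core)
  if (length(two_of_three)) {
    missing_in_3 <- setdiff(two_of_three,
                            cls[[3]]$table$gene_id[cls[[3]]$table$class == "9"])
    expect_false(any(missing_in_3 %in% common_dominance_set(cls)))
  }
  # single classification -> its own dominance set
  expect_setequal(common_dominance_set(cls[1]),
                  cls[[1]]$table$gene_id[cls[[1]]$table$class == "9"])
})

test_that("average-linkage sample clustering matches a cubic-time oracle", {
  set.seed(101)
  e <- matrix(rnorm(200 * 6), ncol = 6,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:6)))
  hc <- hier_cluster(e)
  d <- as.dist(1 - cor(e))
  expect_equal(sort(hc$height), average_linkage_heights(d), tolerance = 1e-10)

  # identical samples merge first at height ~0
  e2 <- cbind(e, s7 = e[, "s1"])
  hc2 <- hier_cluster(e2)
  expect_lt(min(hc2$height), 1e-12)
  first <- hc2$merge[1, ]
  expect_setequal(hc2$labels[-first], c("s1", "s7"))

  # constant sample rejected
  e3 <- e; e3[, 2] <- 1
  expect_error(hier_cluster(e3), "constant")
})

test_that("forced topology: identical pair merges before the outlier joins", {
  g <- 50
  set.seed(111)
  base <- rnorm(g)
  e <- cbind(a = base + 10, b = base + 10, c = -base + 10)
  rownames(e) <- sprintf("g%02d", 1:g)
  hc <- hier_cluster(e)
  expect_setequal(hc$labels[-hc$merge[1, ]], c("a", "b"))
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
})
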