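test_that("window signal matches a brute-force interval sum", {
  ann <- tiny_annotation()
  set.seed(11)
  df <- do.call(rbind, lapply(ann$gene_id, function(g)
    ends_at_offsets(ann, g, sample(-150:150, 30),
                    counts = sample(1:5, 30, replace = TRUE),
                    anchor = "start")))
  df <- aggregate(count ~ seq_id + pos + strand, df, sum)
  tab <- make_ends(df)
  ws <- window_signal(tab, ann, window = c(-100, 100))
  for (gi in seq_len(nrow(ann))) {
    g <- as.data.frame(ann)[gi, ]
    tot <- 0
    for (ri in seq_len(nrow(df))) {
      r <- df[ri, ]
      if (r$seq_id != g$seq_id || r$strand != g$strand) next
      off <- if (g$strand == "+") r$pos - g$cds_start else g$cds_start - r$pos
      if (off >= -100 && off < 100) tot <- tot + r$count
    }
    expect_equal(unname(ws[g$gene_id]), tot)
  }
})

test_that("window signal boundary cases behave as documented", {
  ann <- tiny_annotation()
  empty <- make_ends(data.frame(seq_id = "chrA", pos = 5000L, strand = "+",
                                count = 3))
  expect_equal(unname(window_signal(empty, ann)["gplus"]), 0)
  at_start <- make_ends(ends_at_offsets(ann, "gplus", 0, counts = 7,
                                        anchor = "start"))
  expect_equal(unname(window_signal(at_start, ann)["gplus"]), 7)
})

test_that("the pseudocounted ratio is stable and scale-invariant", {
  expect_equal(signal_ratio(5, 5), 1)
  expect_equal(signal_ratio(2000, 1000), (2000.5) / (1000.5))
  expect_equal(signal_ratio(0, 0), 1)
  # joint rescaling of both strains (with the pseudocount on the same
  # scale) leaves the ratios exactly unchanged
  set.seed(2)
  wt <- runif(50, 0, 100); mut <- runif(50, 0, 100)
  r1 <- signal_ratio(mut, wt, pseudocount = 0.5)
  r2 <- signal_ratio(mut * 3, wt * 3, pseudocount = 1.5)
  expect_equal(r1, r2)
  # with a fixed pseudocount the ranking is still essentially preserved
  r3 <- signal_ratio(mut * 3, wt * 3, pseudocount = 0.5)
  expect_gt(cor(r1, r3, method = "spearman"), 0.999)
})

test_that("the decile partition is an exact equal-sized partition", {
  set.seed(5)
  r <- setNames(runif(5100), sprintf("g%04d", 1:5100))
  asg <- decile_partition(r, k = 10)
  expect_equal(nrow(asg), 5100)
  expect_equal(unname(table(asg$cluster)), rep(510L, 10), ignore_attr = TRUE)
  expect_equal(sum(asg$kdis), 1020)
  expect_false(anyDuplicated(asg$gene_id) > 0)
  # cluster 1 holds the highest ratios
  expect_true(min(asg$ratio[asg$cluster == 1]) >=
                max(asg$ratio[asg$cluster == 2]))
  # remainder goes to the first clusters, sizes differ by at most one
  asg2 <- decile_partition(setNames(runif(103), paste0("x", 1:103)), k = 10)
  sizes <- as.integer(table(asg2$cluster))
  expect_true(max(sizes) - min(sizes) <= 1)
  expect_equal(sizes[1:3], c(11L, 11L, 11L))
})

test_that("partition edge cases: singletons, ties, too few genes", {
  r <- setNames(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1), letters[1:10])
  asg <- decile_partition(r, k = 10)
  expect_equal(asg$cluster, 1:10)
  expect_equal(asg$gene_id, letters[1:10])
  # ties broken stably by gene id
  tied <- setNames(rep(1, 4), c("d", "b", "a", "c"))
  asg_t <- decile_partition(tied, k = 2)
  expect_equal(asg_t$gene_id, c("a", "b", "c", "d"))
  expect_error(decile_partition(setNames(1:5, letters[1:5]), k = 10), "fewer")
})

test_that("hypergeometric overlap matches exhaustive enumeration (universe <= 20)", {
  universe <- sprintf("u%02d", 1:20)
  set_a <- universe[1:5]
  for (ov_target in 0:5) {
    set_b <- c(head(set_a, ov_target), head(universe[6:20], 5 - ov_target))
    res <- overlap_test(set_a, set_b, universe)
    expect_equal(res$overlap, ov_target)
    draws <- combn(20, 5)
    in_a <- seq_len(20) %in% match(set_a, universe)
    p_enum <- mean(apply(draws, 2, function(d) sum(in_a[d])) >= ov_target)
    expect_equal(res$p_value, p_enum, tolerance = 1e-12)
  }
})

test_that("overlap test degenerate cases", {
  u <- sprintf("u%03d", 1:500)
  disjoint <- overlap_test(u[1:5], u[6:10], u)
  expect_gt(disjoint$p_value, 0.9)
  same <- overlap_test(u[1:5], u[1:5], u)
  expect_lt(same$p_value, 1e-10)
  expect_error(overlap_test("a", "a", character()), "empty universe")
  expect_error(overlap_test("zz", "a", u), "subsets")
})

test_that("group comparisons attach the conventional significance tiers", {
  set.seed(3)
  vals <- setNames(c(rnorm(40), rnorm(40), rnorm(40) + 10),
                   sprintf("g%03d", 1:120))
  groups <- rep(c("a", "b", "c"), each = 40)
  out <- group_compare(vals, groups)
  expect_equal(nrow(out), 3)
  ab <- out[out$group_a == "a" & out$group_b == "b", ]
  expect_equal(ab$tier, "ns")
  ac <- out[out$group_a == "a" & out$group_b == "c", ]
  expect_equal(ac$tier, "****")
  # list-of-gene-sets interface agrees with the factor interface
  out2 <- group_compare(vals, list(a = names(vals)[1:40],
                                   b = names(vals)[41:80],
                                   c = names(vals)[81:120]))
  expect_equal(out2$p_value, out$p_value)
})

test_that("abundance normalization removes a planted depth confound", {
  ann <- tiny_annotation()
  shape <- c(-30L, 0L, 12L, 48L)
  df_lo <- ends_at_offsets(ann, "gplus", shape, counts = 2, anchor = "start")
  df_hi <- ends_at_offsets(ann, "gminus", shape, counts = 20, anchor = "start")
  tab <- make_ends(rbind(df_lo, df_hi), normalized = TRUE)
  ab <- c(gplus = 2, gminus = 20)
  pr <- expression_normalized_profile(tab, ann, c("gplus", "gminus"), ab,
                                      flank_up = 60, flank_down = 60)
  per_gene_lo <- expression_normalized_profile(tab, ann, "gplus",
                                               ab, flank_up = 60,
                                               flank_down = 60)
  # both genes contribute the identical normalized shape
  expect_equal(pr$values, per_gene_lo$values)
  # abundance of one removes nothing when all abundances are 1
  pr1 <- expression_normalized_profile(tab, ann, c("gplus", "gminus"),
                                       c(gplus = 1, gminus = 1),
                                       flank_up = 60, flank_down = 60)
  plain <- anchored_profile(tab, ann, "start", 60, 60,
                            gene_set = c("gplus", "gminus"), value = "mean")
  expect_equal(pr1$values, plain$values)
  expect_warning(
    expression_normalized_profile(tab, ann, c("gplus", "gminus"),
                                  c(gplus = 1), flank_up = 10,
                                  flank_down = 10),
    "dropped")
})

test_that("cluster metagenes conserve the all-genes profile", {
  ann <- generate_annotation(60, seed = 17)
  sim <- simulate_library(ann, decay_regime("wt"), depth = 3e4, seed = 2)
  rp <- rpm_normalize(sim$ends)
  r <- setNames(runif(60), ann$gene_id)
  asg <- decile_partition(r, k = 3)
  cm <- cluster_metagenes(list(wt = rp), ann, asg, flank_up = 40,
                          flank_down = 40, n_bins = 10)
  # weighted mean of per-cluster start profiles = all-genes mean profile
  sizes <- as.integer(table(asg$cluster))
  weighted <- Reduce(`+`, lapply(1:3, function(cl)
    cm$wt[[paste0("cluster", cl)]]$start$values * sizes[cl])) / 60
  all_genes <- anchored_profile(rp, ann, "start", 40, 40, value = "mean")
  expect_equal(weighted, all_genes$values)
})

test_that("planted import-sensitive genes show elevated 5' signal in top clusters", {
  ann <- generate_annotation(200, seed = 18)
  wt <- simulate_library(ann, decay_regime("wt"), kdis_fraction = 0.2,
                         depth = 2e5, seed = 51)
  planted <- wt$truth$gene_id[wt$truth$kdis_flag]
  mut <- simulate_library(ann, decay_regime("dnls12"), kdis_fraction = 0.2,
                          kdis_genes = planted, depth = 2e5, seed = 52)
  asg <- kdis_classify(wt$ends, mut$ends, ann)
  expect_gte(mean(planted %in% asg$gene_id[asg$kdis]), 0.8)
  cm <- cluster_metagenes(list(mut = rpm_normalize(mut$ends)), ann, asg,
                          flank_up = 100, flank_down = 50, n_bins = 10)
  top <- mean(cm$mut$cluster1$start$values)
  mid <- mean(cm$mut$cluster5$start$values)
  expect_gt(top, mid)
})

test_that("identical strains give ratios near one everywhere", {
  ann <- generate_annotation(80, seed = 20)
  sim <- simulate_library(ann, decay_regime("wt"), depth = 1e5, seed = 61)
  asg <- kdis_classify(sim$ends, sim$ends, ann)
  expect_true(all(abs(asg$ratio - 1) < 1e-12))
})
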