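test_that("rpm normalization scales to one million and preserves ratios", {
  tab <- make_ends(data.frame(seq_id = "c", pos = c(10L, 20L), strand = "+",
                              count = c(2, 998)))
  rp <- rpm_normalize(tab)
  expect_equal(rp$counts$count[rp$counts$pos == 10], 2000)   # 2/1000 reads
  expect_equal(sum(rp$counts$count), 1e6)
  expect_equal(rp$counts$count[1] / rp$counts$count[2],
               tab$counts$count[1] / tab$counts$count[2])
  # a library already at one million reads maps to itself
  tab2 <- make_ends(data.frame(seq_id = "c", pos = 1:2, strand = "+",
                               count = c(4e5, 6e5)))
  expect_equal(rpm_normalize(tab2)$counts$count, c(4e5, 6e5))
  empty <- five_prime_end_table(data.frame(seq_id = character(),
                                           pos = integer(),
                                           strand = character(),
                                           count = numeric()))
  expect_error(rpm_normalize(empty), "empty")
})

test_that("a single end at the start codon lands at offset zero", {
  ann <- tiny_annotation()
  for (g in c("gplus", "gminus")) {
    tab <- make_ends(ends_at_offsets(ann, g, 0, anchor = "start"))
    pr <- anchored_profile(tab, ann, "start", 50, 50, gene_set = g)
    expect_equal(pr$values[pr$positions == 0], 1)
    expect_equal(sum(pr$values), 1)
  }
})

test_that("anchored profiles match a brute-force per-read oracle", {
  ann <- tiny_annotation()
  set.seed(99)
  df <- do.call(rbind, lapply(ann$gene_id, function(g)
    ends_at_offsets(ann, g, sample(-60:260, 40, replace = TRUE),
                    counts = sample(1:4, 40, replace = TRUE),
                    anchor = "start")))
  df <- aggregate(count ~ seq_id + pos + strand, df, sum)
  tab <- make_ends(df)
  for (anch in c("start", "stop")) {
    pr <- anchored_profile(tab, ann, anch, 80, 80)
    oracle <- brute_anchored(df, as.data.frame(ann),
                             if (anch == "start") "cds_start" else "cds_end",
                             80, 80)
    expect_equal(pr$positions, oracle$positions)
    expect_equal(pr$values, oracle$values)
  }
})

test_that("profiles are equivariant under strand mirroring", {
  # one gene on +, its mirror image on -, reads mirrored likewise
  ann <- genome_annotation(data.frame(
    gene_id = c("fw", "rc"), seq_id = c("cF", "cR"), strand = c("+", "-"),
    tss = c(100L, 900L), cds_start = c(150L, 850L),
    cds_end = c(450L, 550L), term = c(500L, 500L)))
  offsets <- c(-20L, 0L, 3L, 17L, 100L)
  tab <- make_ends(rbind(ends_at_offsets(ann, "fw", offsets, anchor = "start"),
                         ends_at_offsets(ann, "rc", offsets, anchor = "start")))
  p_fw <- anchored_profile(tab, ann, "start", 30, 120, gene_set = "fw")
  p_rc <- anchored_profile(tab, ann, "start", 30, 120, gene_set = "rc")
  expect_equal(p_fw$values, p_rc$values)
})

test_that("gene-body profile reduces to the resampled coverage when genes agree", {
  # three identical + strand genes, same CDS length, same relative coverage
  ann <- genome_annotation(data.frame(
    gene_id = paste0("g", 1:3), seq_id = "c", strand = "+",
    tss = c(100L, 1100L, 2100L), cds_start = c(150L, 1150L, 2150L),
    cds_end = c(240L, 1240L, 2240L), term = c(300L, 1300L, 2300L)))
  cov <- rep(0, 93)            # CDS incl. stop = 90 + 3
  cov[c(1, 10, 50, 93)] <- c(5, 2, 7, 1)
  df <- do.call(rbind, lapply(ann$gene_id, function(g)
    ends_at_offsets(ann, g, which(cov > 0) - 1L, counts = cov[cov > 0],
                    anchor = "start")))
  tab <- make_ends(df)
  pr <- genebody_profile(tab, ann, n_bins = 31, flank_up = 10,
                         flank_down = 10, trim_extreme = 0)
  body <- pr$values[pr$region == "body"]
  # expected: mass-preserving resampling of the common coverage (93 -> 31)
  cum <- c(0, cumsum(cov))
  expected <- diff(approx(0:93, cum, xout = 93 * (0:31) / 31)$y)
  expect_equal(body, expected)
  expect_equal(sum(body), sum(cov))
})

test_that("the robustness trim excludes extreme genes, matching an explicit oracle", {
  n <- 40
  ann <- genome_annotation(data.frame(
    gene_id = sprintf("g%02d", 1:n), seq_id = "c", strand = "+",
    tss = seq(1L, by = 1000L, length.out = n),
    cds_start = seq(101L, by = 1000L, length.out = n),
    cds_end = seq(401L, by = 1000L, length.out = n),
    term = seq(600L, by = 1000L, length.out = n)))
  set.seed(7)
  base <- lapply(seq_len(n), function(i) {
    k <- if (i == 1) 4000 else sample(5:20, 1)     # gene 1 is the outlier
    ends_at_offsets(ann, ann$gene_id[i], sample(0:302, 10), counts = k / 10,
                    anchor = "start")
  })
  tab <- make_ends(do.call(rbind, base))
  trimmed <- genebody_profile(tab, ann, n_bins = 20, flank_up = 0,
                              flank_down = 0, trim_extreme = 0.05)
  plain <- genebody_profile(tab, ann, n_bins = 20, flank_up = 0,
                            flank_down = 0, trim_extreme = 0)
  # oracle: per-bin matrix, explicit trimmed mean (drop floor(t*n/2) per side)
  per_gene <- vapply(seq_len(n), function(i) {
    v <- numeric(303)
    h <- base[[i]]
    off <- if (ann$strand[i] == "+") h$pos - ann$cds_start[i] else
      ann$cds_start[i] - h$pos
    for (j in seq_along(off)) v[off[j] + 1] <- v[off[j] + 1] + h$count[j]
    cum <- c(0, cumsum(v))
    diff(approx(0:303, cum, xout = 303 * (0:20) / 20)$y)
  }, numeric(20))
  oracle_trim <- apply(per_gene, 1, function(x) {
    k <- floor(0.05 * n / 2)
    mean(sort(x)[(k + 1):(n - k)])
  })
  expect_equal(trimmed$values, oracle_trim)
  expect_equal(plain$values, rowMeans(per_gene))
  # the outlier gene dominates the plain mean but not the trimmed one
  outlier_bins <- per_gene[, 1] > 100
  expect_true(all(trimmed$values[outlier_bins] < plain$values[outlier_bins]))
  expect_true(all(trimmed$values >= apply(per_gene, 1, min) - 1e-9 &
                    trimmed$values <= apply(per_gene, 1, max) + 1e-9))
})

test_that("genes shorter than the bin count are resampled, not dropped", {
  ann <- tiny_annotation()   # gsmall has a 33-nt body
  tab <- make_ends(ends_at_offsets(ann, "gsmall", c(0, 15, 30),
                                   anchor = "start"))
  pr <- genebody_profile(tab, ann, n_bins = 50, flank_up = 0, flank_down = 0,
                         gene_set = "gsmall", trim_extreme = 0)
  expect_equal(length(pr$values), 50)
  expect_equal(sum(pr$values), 3)
})

test_that("profile containers enforce their invariants", {
  expect_error(metagene_profile("start", c(1, 1, 2), c(0, 0, 0), 1),
               "strictly increasing")
  expect_error(metagene_profile("start", 1:3, c(0, 0), 1), "equal length")
  expect_error(anchored_profile(make_ends(data.frame(
    seq_id = "c", pos = 1L, strand = "+", count = 1)),
    tiny_annotation(), "start", gene_set = character()), "empty gene_set")
})
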