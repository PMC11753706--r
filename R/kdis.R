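#' Start-codon window signal per gene
#'
#' Sums sense-strand 5'P signal in a transcript-axis window around the
#' first nt of the start codon, by default the 200-nt region `[-100, +100)`.
#' This is the quantity whose mutant/WT ratio defines the KDIS ranking:
#' genes whose degradation intermediates pile up just upstream of the AUG
#' when the exonuclease cannot reach the nucleus score high.
#'
#' @param table a [five_prime_end_table()], normally rpm-normalized.
#' @param ann a [genome_annotation()].
#' @param gene_set optional subset of genes; default all.
#' @param window half-open window `[window[1], window[2])` in nt relative
#'   to the first nt of the start codon.
#' @return named numeric vector of window signals (0 where no ends fall in
#'   the window), in annotation order.
#' @export
window_signal <- function(table, ann, gene_set = NULL,
                          window = c(-100L, 100L)) {
  .assert(length(window) == 2 && window[1] < window[2],
          "window must be c(lo, hi) with lo < hi")
  genes <- .ann_subset(ann, gene_set)
  reg <- .anchor_regions(genes, genes$cds_start,
                         as.integer(window[1]), as.integer(window[2]) - 1L)
  hits <- .ends_in_regions(table, reg)
  out <- setNames(numeric(nrow(genes)), genes$gene_id)
  if (nrow(hits) > 0) {
    agg <- hits[, .(value = sum(count)), by = gene_id]
    out[agg$gene_id] <- agg$value
  }
  out
}

#' Pseudocounted mutant/WT signal ratio
#'
#' `(mut + pseudocount) / (wt + pseudocount)`; the pseudocount (in rpm
#' units) keeps zero-signal genes defined and equal to 1 when both strains
#' are empty. The ratio is invariant to a joint rescaling of both strains.
#'
#' @param mut,wt window signals (same genes, same order).
#' @param pseudocount positive pseudocount, default 0.5 rpm.
#' @return numeric vector of ratios.
#' @export
signal_ratio <- function(mut, wt, pseudocount = 0.5) {
  .assert(pseudocount > 0, "pseudocount must be > 0")
  .assert(length(mut) == length(wt), "mut and wt must have equal length")
  (mut + pseudocount) / (wt + pseudocount)
}

#' Equal-sized ratio deciles and the KDIS call
#'
#' Sorts genes by ratio from highest to lowest (stable tie-break on
#' gene id) and splits them into `k` contiguous clusters of equal size
#' (any remainder goes to the first clusters, so sizes differ by at most
#' 1). Cluster 1 holds the highest ratios; genes in clusters 1-2 are
#' called KDIS. A 1-D k-means alternative is available for comparison, but
#' the rank-based equal-size partition is the normative method.
#'
#' @param ratios named numeric vector of per-gene ratios (names = gene
#'   ids); needs at least `k` genes.
#' @param k number of clusters (default 10).
#' @param method `"rank"` (default) or `"kmeans"`.
#' @return data.table with `gene_id`, `ratio`, `cluster` (1..k) and `kdis`
#'   (`cluster <= 2`), ordered by descending ratio.
#' @export
decile_partition <- function(ratios, k = 10L, method = c("rank", "kmeans")) {
  method <- match.arg(method)
  .assert(!is.null(names(ratios)) && !anyDuplicated(names(ratios)),
          "ratios must be named by unique gene ids")
  n <- length(ratios)
  k <- as.integer(k)
  .assert(n >= k, "fewer genes than clusters")
  ord <- order(-ratios, names(ratios))
  if (method == "rank") {
    sizes <- rep(n %/% k, k)
    r <- n %% k
    if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
    cl <- rep(seq_len(k), times = sizes)
  } else {
    km <- kmeans(ratios, centers = k, nstart = 10)
    rank_of <- rank(-km$centers[, 1], ties.method = "first")
    cl_raw <- rank_of[km$cluster]
    cl <- cl_raw[ord]
  }
  data.table::data.table(gene_id = names(ratios)[ord],
                         ratio = unname(ratios[ord]),
                         cluster = as.integer(cl),
                         kdis = cl <= 2L)
}

#' One-step KDIS classification from two libraries
#'
#' Convenience wrapper: rpm-normalizes the wild-type and mutant libraries,
#' computes their start-codon [window_signal()]s, forms the pseudocounted
#' [signal_ratio()] and partitions genes with [decile_partition()].
#'
#' @param wt,mut [five_prime_end_table()]s for the wild-type and mutant.
#' @param ann a [genome_annotation()]; only its genes are analyzed (genes
#'   with incomplete TSS/termination annotation should already have been
#'   excluded when the annotation was built).
#' @param window window around the start codon, as in [window_signal()].
#' @param pseudocount ratio pseudocount in rpm.
#' @param k number of clusters.
#' @param method partition method, see [decile_partition()].
#' @return the [decile_partition()] table with extra columns
#'   `window_signal_wt` and `window_signal_mut` (rpm).
#' @export
kdis_classify <- function(wt, mut, ann, window = c(-100L, 100L),
                          pseudocount = 0.5, k = 10L,
                          method = c("rank", "kmeans")) {
  sw <- window_signal(rpm_normalize(wt), ann, window = window)
  sm <- window_signal(rpm_normalize(mut), ann, window = window)
  r <- setNames(signal_ratio(sm, sw, pseudocount), names(sw))
  out <- decile_partition(r, k = k, method = match.arg(method))
  out[, `:=`(window_signal_wt = sw[gene_id],
             window_signal_mut = sm[gene_id])]
  out[]
}

#' Per-cluster metagene profiles
#'
#' For each strain library and each cluster of an assignment, computes a
#' start-anchored profile and a length-normalized gene-body profile, the
#' per-cluster view that reveals which clusters drive a global profile
#' change. Empty clusters are skipped with a warning.
#'
#' @param tables named list of rpm-normalized [five_prime_end_table()]s
#'   (one per strain).
#' @param ann a [genome_annotation()].
#' @param assignment a [decile_partition()] table.
#' @param flank_up,flank_down,n_bins,trim_extreme profile parameters, see
#'   [anchored_profile()] and [genebody_profile()].
#' @return nested list: `result[[strain]][[paste0("cluster", i)]]` is a
#'   list with elements `start` and `genebody`.
#' @export
cluster_metagenes <- function(tables, ann, assignment,
                              flank_up = 100L, flank_down = 100L,
                              n_bins = 50L, trim_extreme = 0.05) {
  .assert(is.list(tables) && !is.null(names(tables)),
          "tables must be a named list of FivePrimeEndTables")
  clusters <- sort(unique(assignment$cluster))
  lapply(tables, function(tab) {
    out <- list()
    for (cl in clusters) {
      gs <- assignment$gene_id[assignment$cluster == cl]
      gs <- intersect(gs, ann$gene_id)
      if (length(gs) == 0L) {
        warning("cluster ", cl, " is empty; skipped", call. = FALSE)
        next
      }
      out[[paste0("cluster", cl)]] <- list(
        start = anchored_profile(tab, ann, "start", flank_up, flank_down,
                                 gene_set = gs, value = "mean"),
        genebody = genebody_profile(tab, ann, n_bins, flank_up, flank_down,
                                    trim_extreme, gene_set = gs))
    }
    out
  })
}

#' Abundance-normalized metagene profile
#'
#' Divides each gene's anchored coverage vector by its mRNA abundance
#' before averaging, removing expression-level differences between gene
#' groups so that profile shape comparisons are not confounded by depth.
#'
#' @param table an rpm-normalized [five_prime_end_table()].
#' @param ann a [genome_annotation()].
#' @param gene_set character vector of genes to average.
#' @param abundance named positive numeric vector of per-gene mRNA
#'   abundances; genes of `gene_set` missing here are dropped with a
#'   warning.
#' @param anchor,flank_up,flank_down as in [anchored_profile()].
#' @return a [metagene_profile()] (per-gene mean of normalized vectors).
#' @export
expression_normalized_profile <- function(table, ann, gene_set, abundance,
                                          anchor = "start",
                                          flank_up = 100L, flank_down = 100L) {
  .assert(!is.null(names(abundance)), "abundance must be named by gene id")
  miss <- setdiff(gene_set, names(abundance))
  if (length(miss) > 0) {
    warning(length(miss), " gene(s) without abundance dropped", call. = FALSE)
    gene_set <- setdiff(gene_set, miss)
  }
  .assert(length(gene_set) > 0, "no genes left after abundance matching")
  ab <- abundance[gene_set]
  .assert(all(is.finite(ab)) && all(ab > 0), "abundances must be positive")
  m <- .gene_offset_matrix(table, ann, gene_set, anchor, flank_up, flank_down)
  m <- m / ab
  metagene_profile(anchor, seq.int(-flank_up, flank_down), colMeans(m),
                   length(gene_set), value_mode = "mean")
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail hypergeometric probability of observing at least the actual
#' overlap between two gene sets drawn from a common universe.
#'
#' @param set_a,set_b character vectors of gene ids, subsets of `universe`.
#' @param universe character vector of all eligible gene ids (nonempty).
#' @return list with `overlap`, `expected`, `p_value`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  .assert(length(universe) > 0, "empty universe")
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  .assert(all(set_a %in% universe) && all(set_b %in% universe),
          "sets must be subsets of the universe")
  n_u <- length(universe)
  ov <- length(intersect(set_a, set_b))
  p <- phyper(ov - 1, length(set_a), n_u - length(set_a), length(set_b),
              lower.tail = FALSE)
  list(overlap = ov,
       expected = length(set_a) * length(set_b) / n_u,
       p_value = p)
}

.significance_tier <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE)
}

#' Pairwise rank-sum comparisons across gene groups
#'
#' Runs [compare_fpi()] between every pair of groups of a per-gene metric
#' and attaches the conventional significance tiers
#' (`ns` p >= 0.05, `*` < 0.05, `**` < 0.01, `***` < 0.001,
#' `****` < 0.0001).
#'
#' @param values named numeric vector of per-gene values.
#' @param groups either a factor/character vector aligned with `values`,
#'   or a named list of gene-id vectors.
#' @return data.table with one row per group pair: medians, W statistic,
#'   p value and tier label.
#' @export
group_compare <- function(values, groups) {
  if (is.list(groups)) {
    .assert(!is.null(names(groups)), "group list must be named")
    vals <- lapply(groups, function(g) values[intersect(g, names(values))])
  } else {
    .assert(length(groups) == length(values),
            "groups must align with values")
    vals <- split(values, groups)
  }
  lv <- names(vals)
  .assert(length(lv) >= 2, "need at least two groups")
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  out <- data.table::rbindlist(lapply(pairs, function(p) {
    cmp <- compare_fpi(vals[[p[1]]], vals[[p[2]]])
    data.table::data.table(group_a = p[1], group_b = p[2],
                           n_a = cmp$n_a, n_b = cmp$n_b,
                           median_a = cmp$median_a, median_b = cmp$median_b,
                           statistic = cmp$statistic, p_value = cmp$p_value)
  }))
  out[, tier := as.character(.significance_tier(p_value))]
  out[]
}
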