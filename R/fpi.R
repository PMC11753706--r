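#' Per-gene codon-frame counts of 5'P ends
#'
#' Assigns every sense-strand 5'P end inside the CDS (stop codon excluded)
#' to a codon frame, `frame = (offset from the first nt of the start codon)
#' mod 3`, and tallies the three frames per gene. A wild-type cotranslational
#' decay pattern concentrates ends in one preferred frame because the
#' exonuclease halts at a fixed distance behind each ribosome.
#'
#' @param table a [five_prime_end_table()] (raw counts are customary here,
#'   but rpm values are accepted).
#' @param ann a [genome_annotation()].
#' @param gene_set optional subset of genes; default all. Zero-count genes
#'   are retained with all-zero frames.
#' @return data.table with columns `gene_id`, `F0`, `F1`, `F2`, `f_total`
#'   and `preferred_frame` (argmax of the frame counts; ties resolved to
#'   the lowest frame index).
#' @export
frame_counts <- function(table, ann, gene_set = NULL) {
  genes <- .ann_subset(ann, gene_set)
  cdsl <- .cds_len(genes)
  reg <- .anchor_regions(genes, genes$cds_start, 0L, cdsl - 1L)
  hits <- .ends_in_regions(table, reg)
  out <- data.table::data.table(gene_id = genes$gene_id,
                                F0 = 0, F1 = 0, F2 = 0)
  if (nrow(hits) > 0) {
    hits[, frame := offset %% 3L]
    agg <- hits[, .(value = sum(count)), by = .(gene_id, frame)]
    for (f in 0:2) {
      a <- agg[frame == f]
      col <- paste0("F", f)
      out[match(a$gene_id, out$gene_id), (col) := a$value]
    }
  }
  fc <- as.matrix(out[, .(F0, F1, F2)])
  out[, f_total := rowSums(fc)]
  out[, preferred_frame := max.col(fc, ties.method = "first") - 1L]
  out[]
}

#' Frame protection index (FPI)
#'
#' The FPI of a gene is `log2(2 * F_preferred / (F_total - F_preferred))`
#' over its three codon-frame counts: 0 when the frames are uniform
#' (`F_pref = F_total/3`), positive when one frame is protected, i.e. when
#' 5'P ends track the ribosome. A pseudocount added to every frame keeps
#' the statistic finite when all ends fall in one frame or the gene is
#' empty; genes with fewer than `min_reads` raw in-CDS ends are flagged
#' missing (`NA`) so they can be excluded from group statistics.
#'
#' @param stats output of [frame_counts()], or a bare numeric length-3
#'   vector of frame counts (returns a single FPI value; `min_reads` is
#'   ignored for the vector form).
#' @param pseudocount value added to each of the three frame counts
#'   (default 1).
#' @param min_reads minimum raw `f_total` for a gene to receive an FPI
#'   (default 10).
#' @return the `stats` table with an `fpi` column, or a single number.
#' @examples
#' fpi(c(10, 10, 10), pseudocount = 0)  # uniform -> 0
#' fpi(c(20, 5, 5), pseudocount = 0)    # log2(40/10) = 2
#' @export
fpi <- function(stats, pseudocount = 1, min_reads = 10) {
  .assert(pseudocount >= 0, "pseudocount must be >= 0")
  fpi1 <- function(fc) {
    fc <- fc + pseudocount
    fp <- max(fc)
    log2(2 * fp / (sum(fc) - fp))
  }
  if (is.numeric(stats) && length(stats) == 3L) return(fpi1(stats))
  .assert(is.data.frame(stats) && all(c("F0", "F1", "F2") %in% names(stats)),
          "stats must come from frame_counts() or be a length-3 vector")
  out <- data.table::as.data.table(stats)
  fc <- as.matrix(out[, c("F0", "F1", "F2")]) + pseudocount
  fp <- apply(fc, 1, max)
  v <- log2(2 * fp / (rowSums(fc) - fp))
  v[out$f_total < min_reads] <- NA_real_
  out$fpi <- v
  out[]
}

#' Relative recovery of cotranslational decay capacity
#'
#' Places a mutant strain's FPI on the scale spanned by the exonuclease
#' null (0) and the wild type (1):
#' `(fpi_mut - fpi_null) / (fpi_wt - fpi_null)`.
#'
#' @param fpi_wt,fpi_mut,fpi_null strain-level FPI values (e.g. per-gene
#'   medians); `fpi_wt` must differ from `fpi_null`.
#' @return recovery fraction (0 = no better than the null, 1 = wild type).
#' @examples
#' fpi_recovery(1.00, 0.87, 0.79)  # ~0.381
#' @export
fpi_recovery <- function(fpi_wt, fpi_mut, fpi_null) {
  .assert(is.finite(fpi_wt) && is.finite(fpi_mut) && is.finite(fpi_null),
          "FPI inputs must be finite")
  .assert(fpi_wt != fpi_null,
          "recovery undefined when fpi_wt equals fpi_null")
  (fpi_mut - fpi_null) / (fpi_wt - fpi_null)
}

#' Two-group rank-sum comparison of per-gene values
#'
#' Unpaired two-sided Wilcoxon rank-sum test between two groups of per-gene
#' statistics (FPI values, lengths, expression ratios...), with medians and
#' the median difference reported alongside. Missing values are dropped;
#' fully tied input returns p = 1 with a warning.
#'
#' @param group_a,group_b numeric vectors (>= 3 non-missing values each).
#' @return list with `statistic` (W), `p_value`, `median_a`, `median_b`,
#'   `median_diff`, `n_a`, `n_b`.
#' @export
compare_fpi <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  .assert(length(a) >= 3 && length(b) >= 3,
          "each group needs at least 3 non-missing values")
  if (length(unique(c(a, b))) == 1L) {
    warning("all values tied; p set to 1", call. = FALSE)
    return(list(statistic = length(a) * length(b) / 2, p_value = 1,
                median_a = median(a), median_b = median(b),
                median_diff = 0, n_a = length(a), n_b = length(b)))
  }
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_a = median(a), median_b = median(b),
       median_diff = median(a) - median(b),
       n_a = length(a), n_b = length(b))
}
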