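#' Metagene profile container
#'
#' @param anchor `"start"`, `"stop"` or `"genebody"`.
#' @param positions strictly increasing offsets: nt for start/stop anchors;
#'   for gene-body profiles, upstream flank nt (negative), CDS bin midpoints
#'   as fractions in (0,1), and downstream flank nt (>= 1).
#' @param values nonnegative profile values aligned with `positions`.
#' @param n_genes number of genes contributing.
#' @param value_mode `"sum"` (summed rpm across genes) or `"mean"`
#'   (per-gene mean); the two conventions differ only in y-axis scale.
#' @param region optional character vector tagging each position
#'   (`upstream`/`body`/`downstream`) for gene-body profiles.
#' @return list of the above, class `MetageneProfile`.
#' @export
metagene_profile <- function(anchor, positions, values, n_genes,
                             value_mode = "sum", region = NULL) {
  .assert(length(positions) == length(values),
          "positions and values must have equal length")
  .assert(all(diff(positions) > 0), "positions must be strictly increasing")
  .assert(all(values >= -1e-9), "profile values must be nonnegative")
  structure(list(anchor = anchor, positions = unname(positions),
                 values = unname(pmax(values, 0)), n_genes = n_genes,
                 value_mode = value_mode, region = region),
            class = "MetageneProfile")
}

#' @export
print.MetageneProfile <- function(x, ...) {
  cat("MetageneProfile (", x$anchor, " anchor, ", x$value_mode, "): ",
      length(x$positions), " positions over ", x$n_genes, " genes; argmax at ",
      format(x$positions[which.max(x$values)]), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.MetageneProfile <- function(x, ...) {
  df <- data.frame(position = x$positions, value = x$values)
  if (!is.null(x$region)) df$region <- x$region
  df
}

#' @export
plot.MetageneProfile <- function(x, ...) {
  graphics::plot(x$positions, x$values, type = "h",
                 xlab = paste0("offset from ", x$anchor),
                 ylab = paste0(x$value_mode, " 5'P signal"), ...)
  invisible(x)
}

#' Start/stop-anchored metagene profile
#'
#' Accumulates sense-strand 5'P end signal per nt offset relative to the
#' first nt of the start codon (`anchor = "start"`) or of the stop codon
#' (`anchor = "stop"`), across genes. Offset 0 is the anchor nucleotide;
#' offsets on minus-strand genes are mirrored so the profile is
#' strand-equivariant. Reads are taken by genomic window only — overlapping
#' neighbours are not masked.
#'
#' @param table a [five_prime_end_table()] (typically [rpm_normalize()]d).
#' @param ann a [genome_annotation()].
#' @param anchor `"start"` or `"stop"`.
#' @param flank_up,flank_down nonnegative flank widths in nt (offsets
#'   `-flank_up .. +flank_down`).
#' @param gene_set optional character vector of genes; default all.
#' @param value `"sum"` (sum of rpm over genes) or `"mean"` (divided by the
#'   number of genes).
#' @return a [metagene_profile()].
#' @export
anchored_profile <- function(table, ann, anchor = c("start", "stop"),
                             flank_up = 100L, flank_down = 100L,
                             gene_set = NULL, value = c("sum", "mean")) {
  anchor <- match.arg(anchor)
  value <- match.arg(value)
  .assert(flank_up >= 0 && flank_down >= 0, "flanks must be >= 0")
  genes <- .ann_subset(ann, gene_set)
  .assert(nrow(genes) > 0, "empty gene_set")
  a <- if (anchor == "start") genes$cds_start else genes$cds_end
  reg <- .anchor_regions(genes, a, -as.integer(flank_up),
                         as.integer(flank_down))
  hits <- .ends_in_regions(table, reg)
  offs <- seq.int(-flank_up, flank_down)
  vals <- numeric(length(offs))
  if (nrow(hits) > 0) {
    agg <- hits[, .(value = sum(count)), by = offset]
    vals[match(agg$offset, offs)] <- agg$value
  }
  if (value == "mean") vals <- vals / nrow(genes)
  metagene_profile(anchor, offs, vals, nrow(genes), value_mode = value)
}

# linear interpolation of the cumulative count vector: mass-preserving,
# monotone resampling of a per-nt coverage vector to n_bins bins
.resample_bins <- function(v, n_bins) {
  L <- length(v)
  cum <- c(0, cumsum(v))
  diff(approx(0:L, cum, xout = L * (0:n_bins) / n_bins)$y)
}

#' Length-normalized gene-body metagene with robust trimming
#'
#' Each gene's coding-region coverage (CDS including the stop codon) is
#' resampled to `n_bins` bins by monotone interpolation of its cumulative
#' count vector — a mass-preserving stand-in for spline-based length
#' normalization that cannot go negative. Flanks stay in natural nt units.
#' Per position, genes are averaged after discarding the `trim_extreme`
#' fraction of the most extreme values (half highest, half lowest), the
#' robustness filter that keeps a few outlier genes from dominating the
#' profile.
#'
#' @inheritParams anchored_profile
#' @param n_bins number of CDS bins (>= 10).
#' @param trim_extreme total fraction of per-position values to discard
#'   (`0 <= trim_extreme < 0.5`); 0 gives the plain mean.
#' @return a [metagene_profile()] with `anchor = "genebody"`.
#' @export
genebody_profile <- function(table, ann, n_bins = 100L,
                             flank_up = 100L, flank_down = 100L,
                             trim_extreme = 0.05, gene_set = NULL) {
  .assert(n_bins >= 10, "n_bins must be >= 10")
  .assert(trim_extreme >= 0 && trim_extreme < 0.5,
          "trim_extreme must be in [0, 0.5)")
  genes <- .ann_subset(ann, gene_set)
  .assert(nrow(genes) > 0, "empty gene_set")
  n_bins <- as.integer(n_bins)
  flank_up <- as.integer(flank_up)
  flank_down <- as.integer(flank_down)
  body_len <- .cds_len(genes) + 3L          # CDS incl. stop codon

  reg <- .anchor_regions(genes, genes$cds_start, -flank_up,
                         body_len + flank_down - 1L)
  # per-gene windows differ in length: rebuild hi per gene
  hits <- .ends_in_regions(table, reg)
  bygene <- split(hits, factor(hits$gene_id, levels = genes$gene_id))

  n_pos <- flank_up + n_bins + flank_down
  mat <- matrix(0, nrow = nrow(genes), ncol = n_pos)
  for (gi in seq_len(nrow(genes))) {
    h <- bygene[[gi]]
    Lg <- body_len[gi]
    full <- numeric(flank_up + Lg + flank_down)
    if (!is.null(h) && nrow(h) > 0) {
      h <- h[offset >= -flank_up & offset < Lg + flank_down]
      if (nrow(h) > 0) {
        acc <- rowsum(h$count, h$offset + flank_up + 1L)
        full[as.integer(rownames(acc))] <- acc[, 1]
      }
    }
    up <- full[seq_len(flank_up)]
    body <- full[flank_up + seq_len(Lg)]
    down <- full[flank_up + Lg + seq_len(flank_down)]
    mat[gi, ] <- c(up, .resample_bins(body, n_bins), down)
  }

  vals <- apply(mat, 2, .trimmed_mean, trim = trim_extreme)
  positions <- c(if (flank_up > 0) seq.int(-flank_up, -1L),
                 (seq_len(n_bins) - 0.5) / n_bins,
                 if (flank_down > 0) seq_len(flank_down))
  region <- c(rep("upstream", flank_up), rep("body", n_bins),
              rep("downstream", flank_down))
  metagene_profile("genebody", positions, vals, nrow(genes),
                   value_mode = "mean", region = region)
}

# per-gene offset matrix around an anchor (rows = genes, cols = offsets)
.gene_offset_matrix <- function(table, ann, gene_set, anchor = "start",
                                flank_up = 100L, flank_down = 100L) {
  genes <- .ann_subset(ann, gene_set)
  a <- if (anchor == "start") genes$cds_start else genes$cds_end
  reg <- .anchor_regions(genes, a, -as.integer(flank_up),
                         as.integer(flank_down))
  hits <- .ends_in_regions(table, reg)
  offs <- seq.int(-flank_up, flank_down)
  m <- matrix(0, nrow = nrow(genes), ncol = length(offs),
              dimnames = list(genes$gene_id, offs))
  if (nrow(hits) > 0) {
    agg <- hits[, .(value = sum(count)), by = .(gene_id, offset)]
    m[cbind(match(agg$gene_id, genes$gene_id),
            match(agg$offset, offs))] <- agg$value
  }
  m
}
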