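# Hand-built fixtures with coordinates small enough to verify on paper.

# Three genes: two on +, one on -, all CDS lengths multiples of 3.
tiny_annotation <- function() {
  genome_annotation(data.frame(
    gene_id = c("gplus", "gminus", "gsmall"),
    seq_id = c("chrA", "chrA", "chrB"),
    strand = c("+", "-", "+"),
    tss = c(1000L, 3000L, 500L),
    cds_start = c(1050L, 2950L, 520L),
    cds_end = c(1350L, 2650L, 550L),   # CDS lengths 300, 300, 30 (excl. stop)
    term = c(1500L, 2500L, 600L),
    expression_weight = c(1, 1, 1)))
}

# end table from a compact spec: data.frame(seq_id, pos, strand, count)
make_ends <- function(df, library_id = "test", normalized = FALSE) {
  five_prime_end_table(df, library_id = library_id, normalized = normalized)
}

# place ends at transcript-axis offsets relative to a gene anchor
ends_at_offsets <- function(ann, gene_id, offsets, counts = 1,
                            anchor = c("start", "stop", "tss")) {
  anchor <- match.arg(anchor)
  adf <- as.data.frame(ann)
  g <- adf[adf$gene_id == gene_id, ]
  a <- switch(anchor, start = g$cds_start, stop = g$cds_end, tss = g$tss)
  pos <- if (g$strand == "+") a + offsets else a - offsets
  data.frame(seq_id = g$seq_id, pos = pos, strand = g$strand,
             count = rep_len(counts, length(offsets)))
}

# brute-force oracle: per-offset sum of sense 5'P signal around an anchor,
# computed read-by-read without the package's join machinery
brute_anchored <- function(counts_df, ann, anchor_col, flank_up, flank_down) {
  offs <- seq.int(-flank_up, flank_down)
  vals <- numeric(length(offs))
  for (gi in seq_len(nrow(ann))) {
    g <- ann[gi, ]
    a <- g[[anchor_col]]
    for (ri in seq_len(nrow(counts_df))) {
      r <- counts_df[ri, ]
      if (r$seq_id != g$seq_id || r$strand != g$strand) next
      off <- if (g$strand == "+") r$pos - a else a - r$pos
      if (off >= -flank_up && off <= flank_down) {
        vals[off + flank_up + 1] <- vals[off + flank_up + 1] + r$count
      }
    }
  }
  list(positions = offs, values = vals)
}
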