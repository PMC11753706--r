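#' Single-nucleotide 5'P end-count table
#'
#' A `FivePrimeEndTable` stores, per library, the number of 5'-monophosphate
#' read ends observed at each (sequence, position, strand). A "5'P end" is a
#' single nucleotide: the 5'-most aligned base of a read (on the minus
#' strand, the highest genomic coordinate).
#'
#' @param counts data.frame/data.table with columns `seq_id`, `pos`
#'   (1-based nt), `strand` and `count` (nonnegative; numeric after rpm
#'   normalization).
#' @param library_id library label.
#' @param normalized logical; `TRUE` once counts are in rpm units.
#' @return list with elements `library_id`, `counts` (keyed data.table),
#'   `total` (sum of counts) and `normalized`, of class `FivePrimeEndTable`.
#' @export
five_prime_end_table <- function(counts, library_id = "library",
                                 normalized = FALSE) {
  dt <- data.table::as.data.table(counts)
  req <- c("seq_id", "pos", "strand", "count")
  .assert(all(req %in% names(dt)),
          paste("end table must have columns:", paste(req, collapse = ", ")))
  .assert(all(dt$strand %in% c("+", "-")), "strand must be '+' or '-'")
  .assert(all(is.finite(dt$count)) && all(dt$count >= 0),
          "counts must be finite and nonnegative")
  dt <- dt[count > 0, .(count = sum(count)), by = .(seq_id, pos, strand)]
  data.table::setkey(dt, seq_id, pos, strand)
  structure(list(library_id = library_id, counts = dt[],
                 total = sum(dt$count), normalized = isTRUE(normalized)),
            class = "FivePrimeEndTable")
}

#' @export
print.FivePrimeEndTable <- function(x, ...) {
  cat("FivePrimeEndTable '", x$library_id, "': ",
      nrow(x$counts), " positions, total ",
      format(x$total, big.mark = ","),
      if (x$normalized) " rpm" else " reads", "\n", sep = "")
  invisible(x)
}

#' Reads-per-million normalization
#'
#' Scales every end count by `10^6 / total` so that the library sums to one
#' million, the standard library-size (rpm) normalization. Ratios between
#' positions are unchanged.
#'
#' @param table a [five_prime_end_table()].
#' @return the table with rpm-scaled counts and `normalized = TRUE`.
#' @export
rpm_normalize <- function(table) {
  .assert(inherits(table, "FivePrimeEndTable"), "not a FivePrimeEndTable")
  .assert(table$total > 0, "cannot rpm-normalize an empty library")
  if (table$normalized) return(table)
  dt <- data.table::copy(table$counts)
  dt[, count := count * 1e6 / table$total]
  out <- five_prime_end_table(dt, table$library_id, normalized = TRUE)
  attr(out, "raw_total") <- table$total
  out
}

# sense-strand ends falling in per-gene windows ---------------------------
#
# regions: data.table(gene_id, seq_id, strand, lo, hi, anchor) with
# lo <= hi genomic bounds (inclusive). Returns (gene_id, offset, count)
# where offset is the transcript-axis distance from `anchor`.
.ends_in_regions <- function(table, regions) {
  ends <- data.table::copy(table$counts)
  if (nrow(ends) == 0L) {
    return(data.table::data.table(gene_id = character(),
                                  offset = integer(), count = numeric()))
  }
  ends[, `:=`(start = pos, end = pos)]
  reg <- data.table::as.data.table(regions)
  data.table::setkey(reg, seq_id, strand, lo, hi)
  hits <- data.table::foverlaps(
    ends, reg,
    by.x = c("seq_id", "strand", "start", "end"),
    by.y = c("seq_id", "strand", "lo", "hi"),
    nomatch = NULL)
  hits[, offset := .tx_offset(pos, anchor, strand)]
  hits[, .(gene_id, offset, count)]
}

# per-gene windows around a genomic anchor, covering transcript-axis
# offsets off_lo..off_hi (inclusive)
.anchor_regions <- function(ann, anchor_pos, off_lo, off_hi) {
  plus <- ann$strand == "+"
  data.table::data.table(
    gene_id = ann$gene_id, seq_id = ann$seq_id, strand = ann$strand,
    lo = as.integer(ifelse(plus, anchor_pos + off_lo, anchor_pos - off_hi)),
    hi = as.integer(ifelse(plus, anchor_pos + off_hi, anchor_pos - off_lo)),
    anchor = as.integer(anchor_pos))
}
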