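#' Gene-model annotation table
#'
#' A `GenomeAnnotation` is a `data.table` with one row per gene and the
#' coordinate anchors every downstream stage uses. All coordinates are
#' 1-based genomic nucleotide positions; on the minus strand the anchors run
#' numerically downhill so that the transcript-oriented ordering
#' `tss <= cds_start < cds_end <= term` always holds once positions are
#' projected on the transcript axis.
#'
#' Columns:
#' \describe{
#'   \item{gene_id}{unique gene identifier}
#'   \item{seq_id}{sequence (chromosome) name}
#'   \item{strand}{`"+"` or `"-"`}
#'   \item{tss}{transcription start site (first transcribed nt)}
#'   \item{cds_start}{first nt of the start codon}
#'   \item{cds_end}{first nt of the stop codon}
#'   \item{term}{last transcribed nt (termination site)}
#'   \item{expression_weight}{positive relative expression weight}
#' }
#'
#' The coding-frame arithmetic requires the CDS length excluding the stop
#' codon, `|cds_end - cds_start|`, to be a positive multiple of 3.
#'
#' @param genes data.frame with the columns above (`expression_weight`
#'   optional, defaults to 1).
#' @return A validated `GenomeAnnotation` (also a `data.table`). Genes
#'   failing validation are dropped; their ids and reasons are kept in the
#'   `"dropped"` attribute and reported via a message.
#' @export
genome_annotation <- function(genes) {
  dt <- data.table::as.data.table(genes)
  req <- c("gene_id", "seq_id", "strand", "tss", "cds_start", "cds_end", "term")
  .assert(all(req %in% names(dt)),
          paste("annotation must have columns:", paste(req, collapse = ", ")))
  if (!"expression_weight" %in% names(dt)) dt[, expression_weight := 1]
  dt[, gene_id := as.character(gene_id)]
  dt[, seq_id := as.character(seq_id)]
  dt[, strand := as.character(strand)]
  .assert(!anyDuplicated(dt$gene_id), "gene_ids must be unique")

  reason <- rep(NA_character_, nrow(dt))
  bad_strand <- !dt$strand %in% c("+", "-")
  reason[bad_strand] <- "invalid strand"
  o_cs <- .tx_offset(dt$cds_start, dt$tss, dt$strand)
  o_ce <- .tx_offset(dt$cds_end, dt$tss, dt$strand)
  o_tm <- .tx_offset(dt$term, dt$tss, dt$strand)
  bad_order <- !(o_cs >= 0 & o_ce > o_cs & o_tm >= o_ce)
  reason[is.na(reason) & bad_order] <- "anchors not ordered tss<=cds_start<cds_end<=term"
  cdsl <- abs(dt$cds_end - dt$cds_start)
  bad_frame <- cdsl <= 0 | cdsl %% 3L != 0L
  reason[is.na(reason) & bad_frame] <- "CDS length not a positive multiple of 3"
  bad_w <- !is.finite(dt$expression_weight) | dt$expression_weight <= 0
  reason[is.na(reason) & bad_w] <- "non-positive expression_weight"

  dropped <- data.table::data.table(gene_id = dt$gene_id[!is.na(reason)],
                                    reason = reason[!is.na(reason)])
  if (nrow(dropped) > 0L) {
    message(nrow(dropped), " gene(s) dropped during annotation validation (",
            paste(unique(dropped$reason), collapse = "; "), ")")
  }
  ann <- dt[is.na(reason)]
  .assert(nrow(ann) >= 1L, "no valid genes left after validation")
  data.table::setattr(ann, "dropped", dropped)
  data.table::setattr(ann, "class",
                      c("GenomeAnnotation", class(data.table::data.table())))
  ann[]
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", nrow(x), "genes on",
      length(unique(x$seq_id)), "sequence(s)\n")
  NextMethod()
}

# derived per-gene quantities --------------------------------------------

.utr5_len <- function(ann) abs(ann$cds_start - ann$tss)
.cds_len  <- function(ann) abs(ann$cds_end - ann$cds_start)   # excludes stop
.tx_len   <- function(ann) abs(ann$term - ann$tss) + 1L

# subset the annotation to an optional gene set, preserving class
.ann_subset <- function(ann, gene_set = NULL) {
  if (is.null(gene_set)) return(ann)
  missing <- setdiff(gene_set, ann$gene_id)
  .assert(length(missing) == 0L,
          paste("genes not in annotation:", paste(head(missing, 5), collapse = ", ")))
  out <- ann[match(gene_set, ann$gene_id)]
  data.table::setattr(out, "class", class(ann))
  out
}

#' Generate a synthetic yeast-like annotation
#'
#' Lays out `n_genes` non-overlapping gene models on synthetic chromosomes,
#' with log-normal 5'UTR, CDS and 3'UTR length distributions chosen to mimic
#' a compact yeast-like transcriptome (median 5'UTR ~45 nt, capped at 120 nt;
#' median CDS ~1200 nt; median 3'UTR ~120 nt) and a log-normal expression
#' weight spanning a broad dynamic range. Strands alternate so that every
#' downstream stage is exercised on both orientations.
#'
#' @param n_genes number of genes (>= 1).
#' @param seed integer seed; the output is deterministic given the seed.
#' @param utr5_meanlog,utr5_sdlog log-normal parameters of the 5'UTR length.
#' @param utr5_range inclusive clamp for 5'UTR lengths (nt).
#' @param cds_codons_meanlog,cds_codons_sdlog log-normal parameters for the
#'   CDS length in codons (stop codon added separately).
#' @param cds_codons_range inclusive clamp for CDS codon counts.
#' @param utr3_meanlog,utr3_sdlog,utr3_range as above, for the 3'UTR.
#' @param expr_sdlog sd(log) of the expression weights.
#' @param intergenic gap in nt between consecutive genes.
#' @param genes_per_seq genes per synthetic chromosome.
#' @return A [genome_annotation()] of `n_genes` genes.
#' @examples
#' ann <- generate_annotation(50, seed = 1)
#' all(abs(ann$cds_end - ann$cds_start) %% 3 == 0)
#' @export
generate_annotation <- function(n_genes, seed,
                                utr5_meanlog = log(45), utr5_sdlog = 0.55,
                                utr5_range = c(10L, 120L),
                                cds_codons_meanlog = log(400),
                                cds_codons_sdlog = 0.45,
                                cds_codons_range = c(40L, 2000L),
                                utr3_meanlog = log(120), utr3_sdlog = 0.5,
                                utr3_range = c(20L, 400L),
                                expr_sdlog = 1,
                                intergenic = 200L,
                                genes_per_seq = 500L) {
  .assert(is.numeric(n_genes) && n_genes >= 1, "n_genes must be >= 1")
  .assert(all(c(utr5_sdlog, cds_codons_sdlog, utr3_sdlog, expr_sdlog) >= 0) &&
            intergenic >= 0 && genes_per_seq >= 1,
          "invalid distribution parameters")
  n_genes <- as.integer(n_genes)
  withr::with_seed(seed, {
    clamp <- function(x, r) pmin(pmax(as.integer(round(x)), r[1]), r[2])
    utr5 <- clamp(rlnorm(n_genes, utr5_meanlog, utr5_sdlog), utr5_range)
    codons <- clamp(rlnorm(n_genes, cds_codons_meanlog, cds_codons_sdlog),
                    cds_codons_range)
    cdsl <- 3L * codons                      # excludes the stop codon
    utr3 <- clamp(rlnorm(n_genes, utr3_meanlog, utr3_sdlog), utr3_range)
    txl <- utr5 + cdsl + 3L + utr3
    w <- rlnorm(n_genes, 0, expr_sdlog)
    strand <- rep(c("+", "-"), length.out = n_genes)

    seq_idx <- ((seq_len(n_genes) - 1L) %/% as.integer(genes_per_seq)) + 1L
    seq_id <- sprintf("synth_chr%02d", seq_idx)
    # sequential layout, restarting the cursor on each chromosome
    gstart <- integer(n_genes)
    cursor <- 1L
    for (i in seq_len(n_genes)) {
      if (i > 1L && seq_idx[i] != seq_idx[i - 1L]) cursor <- 1L
      gstart[i] <- cursor
      cursor <- cursor + txl[i] + as.integer(intergenic)
    }
    gend <- gstart + txl - 1L

    plus <- strand == "+"
    tss <- ifelse(plus, gstart, gend)
    cds_start <- ifelse(plus, tss + utr5, tss - utr5)
    cds_end <- ifelse(plus, cds_start + cdsl, cds_start - cdsl)
    term <- ifelse(plus, gend, gstart)

    genome_annotation(data.table::data.table(
      gene_id = sprintf("SYNG%05d", seq_len(n_genes)),
      seq_id = seq_id, strand = strand,
      tss = as.integer(tss), cds_start = as.integer(cds_start),
      cds_end = as.integer(cds_end), term = as.integer(term),
      expression_weight = w))
  })
}
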