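#' Write a 5'P end table as BED6
#'
#' Each (sequence, position, strand) becomes a 1-nt BED interval with the
#' end count in the score field. Coordinates are converted to the BED
#' 0-based half-open convention by `rtracklayer`.
#'
#' @param table a [five_prime_end_table()]; must be nonempty.
#' @param path output file path (`.bed`).
#' @return `path`, invisibly.
#' @export
write_library <- function(table, path) {
  .assert(inherits(table, "FivePrimeEndTable"), "not a FivePrimeEndTable")
  .assert(nrow(table$counts) > 0, "refusing to write an empty end table")
  dt <- table$counts
  gr <- GenomicRanges::GRanges(
    seqnames = dt$seq_id,
    ranges = IRanges::IRanges(start = dt$pos, width = 1L),
    strand = dt$strand,
    score = dt$count)
  names(gr) <- rep(table$library_id, length(gr))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write an annotation as GFF3
#'
#' Emits gene, mRNA and CDS features per gene. The CDS feature spans the
#' coding region *including* the stop codon (SGD-style), so its width is
#' `cds_len + 3`; the internal `cds_end` anchor (first nt of the stop codon)
#' is recovered on reading. `expression_weight` is carried as a gene
#' attribute so the round trip is lossless.
#'
#' @param ann a [genome_annotation()].
#' @param path output file path (`.gff3`).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  .assert(inherits(ann, "GenomeAnnotation"), "not a GenomeAnnotation")
  plus <- ann$strand == "+"
  g_lo <- pmin(ann$tss, ann$term)
  g_hi <- pmax(ann$tss, ann$term)
  # CDS incl. stop codon on the genomic axis
  stop_last <- ifelse(plus, ann$cds_end + 2L, ann$cds_end - 2L)
  c_lo <- pmin(ann$cds_start, stop_last)
  c_hi <- pmax(ann$cds_start, stop_last)
  mk <- function(lo, hi, type, id, parent) {
    gr <- GenomicRanges::GRanges(ann$seq_id,
                                 IRanges::IRanges(lo, hi), ann$strand)
    gr$source <- "fivePdecay"
    gr$type <- type
    gr$ID <- id
    if (!is.null(parent)) gr$Parent <- parent
    gr
  }
  genes <- mk(g_lo, g_hi, "gene", ann$gene_id, NULL)
  genes$expression_weight <- ann$expression_weight
  mrna <- mk(g_lo, g_hi, "mRNA", paste0(ann$gene_id, "_mRNA"), ann$gene_id)
  cds <- mk(c_lo, c_hi, "CDS", paste0(ann$gene_id, "_CDS"),
            paste0(ann$gene_id, "_mRNA"))
  all <- suppressWarnings(c(genes, mrna, cds))
  ord <- order(as.character(GenomicRanges::seqnames(all)),
               GenomicRanges::start(all),
               match(all$type, c("gene", "mRNA", "CDS")))
  rtracklayer::export(all[ord], path, format = "GFF3")
  invisible(path)
}

.first_chr <- function(x) {
  # Parent comes back as a CharacterList from GFF3
  if (is.null(x)) return(NULL)
  if (methods::is(x, "List")) {
    vapply(x, function(e) if (length(e)) as.character(e[[1]]) else NA_character_,
           character(1))
  } else as.character(x)
}

#' Read a transcript annotation from GFF3/GTF
#'
#' Parses gene and CDS features (resolving CDS -> mRNA -> gene parentage
#' where mRNA/transcript features are present, or `gene_id` attributes in
#' GTF). The gene extent provides the TSS and termination site; the CDS
#' feature is taken to include the stop codon. Genes are validated with the
#' [genome_annotation()] rules; genes lacking a CDS, with a multi-segment
#' CDS, or with a CDS width that is not a multiple of 3 are excluded and
#' counted in the `"dropped"` attribute, with a warning.
#'
#' @param path GFF3 or GTF file.
#' @return a [genome_annotation()].
#' @export
read_annotation <- function(path) {
  .assert(file.exists(path), paste("annotation file not found:", path))
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("failed to parse annotation '",
                                          path, "': ", conditionMessage(e),
                                          call. = FALSE))
  type <- as.character(gr$type)
  m <- S4Vectors::mcols(gr)
  pick_id <- function(sel) {
    id <- NULL
    for (col in c("ID", "gene_id", "Name")) {
      if (col %in% names(m)) {
        v <- .first_chr(m[[col]][sel])
        if (is.null(id)) id <- v else id[is.na(id)] <- v[is.na(id)]
      }
    }
    id
  }

  gsel <- which(type == "gene")
  .assert(length(gsel) > 0, "no gene features found")
  gid <- pick_id(gsel)
  gdt <- data.table::data.table(
    gene_id = gid,
    seq_id = as.character(GenomicRanges::seqnames(gr)[gsel]),
    strand = as.character(GenomicRanges::strand(gr)[gsel]),
    lo = GenomicRanges::start(gr)[gsel],
    hi = GenomicRanges::end(gr)[gsel],
    expression_weight = if ("expression_weight" %in% names(m)) {
      suppressWarnings(as.numeric(.first_chr(m$expression_weight[gsel])))
    } else NA_real_)

  # transcript id -> gene id map (mRNA/transcript features)
  tsel <- which(type %in% c("mRNA", "transcript"))
  tx2gene <- character()
  if (length(tsel) > 0 && "Parent" %in% names(m)) {
    tx2gene <- setNames(.first_chr(m$Parent[tsel]), pick_id(tsel))
  }

  csel <- which(type == "CDS")
  .assert(length(csel) > 0, "no CDS features found")
  parent <- if ("Parent" %in% names(m)) .first_chr(m$Parent[csel]) else
    rep(NA_character_, length(csel))
  cgene <- if ("gene_id" %in% names(m)) .first_chr(m$gene_id[csel]) else
    rep(NA_character_, length(csel))
  via_tx <- !is.na(parent) & parent %in% names(tx2gene)
  cgene[is.na(cgene) & via_tx] <- tx2gene[parent[is.na(cgene) & via_tx]]
  direct <- is.na(cgene) & !is.na(parent) & parent %in% gdt$gene_id
  cgene[direct] <- parent[direct]
  cdt <- data.table::data.table(
    gene_id = cgene,
    c_lo = GenomicRanges::start(gr)[csel],
    c_hi = GenomicRanges::end(gr)[csel])
  cdt <- cdt[!is.na(gene_id),
             .(c_lo = min(c_lo), c_hi = max(c_hi), n_seg = .N), by = gene_id]

  ann <- merge(gdt, cdt, by = "gene_id", all.x = TRUE)
  drop_reason <- rep(NA_character_, nrow(ann))
  drop_reason[is.na(ann$c_lo)] <- "no CDS feature"
  drop_reason[is.na(drop_reason) & ann$n_seg > 1] <- "multi-segment CDS"
  w <- ann$c_hi - ann$c_lo + 1L
  drop_reason[is.na(drop_reason) & (w %% 3L != 0L | w < 6L)] <-
    "CDS width not a positive multiple of 3 (incl. stop)"
  pre_drop <- data.table::data.table(
    gene_id = ann$gene_id[!is.na(drop_reason)],
    reason = drop_reason[!is.na(drop_reason)])
  if (nrow(pre_drop) > 0L) {
    warning(nrow(pre_drop), " gene(s) excluded while reading '",
            basename(path), "' (",
            paste(unique(pre_drop$reason), collapse = "; "), ")",
            call. = FALSE)
  }
  ann <- ann[is.na(drop_reason)]
  .assert(nrow(ann) > 0, "no usable genes in annotation")

  plus <- ann$strand == "+"
  out <- genome_annotation(data.table::data.table(
    gene_id = ann$gene_id, seq_id = ann$seq_id, strand = ann$strand,
    tss = as.integer(ifelse(plus, ann$lo, ann$hi)),
    cds_start = as.integer(ifelse(plus, ann$c_lo, ann$c_hi)),
    cds_end = as.integer(ifelse(plus, ann$c_hi - 2L, ann$c_lo + 2L)),
    term = as.integer(ifelse(plus, ann$hi, ann$lo)),
    expression_weight = data.table::fifelse(is.na(ann$expression_weight), 1,
                                            ann$expression_weight)))
  attr(out, "dropped") <- rbind(pre_drop, attr(out, "dropped"))
  out
}

#' Read 5'P end positions from BED or BAM
#'
#' In `five_prime_point` mode each record is collapsed to its 5'-most base
#' (interval start on the plus strand, interval end on the minus strand); in
#' `full_read` mode one count is spread over every covered base ("physical
#' coverage"). For width-1 BED records carrying a positive numeric score,
#' the score is interpreted as a pre-aggregated end count (the format
#' [write_library()] emits); any other record contributes 1. Records with
#' unknown strand are skipped with a warning.
#'
#' @param path `.bed` (via rtracklayer) or `.bam` (via GenomicAlignments,
#'   if installed) file.
#' @param mode `"five_prime_point"` (default) or `"full_read"`.
#' @param library_id library label (default: file name).
#' @return a [five_prime_end_table()].
#' @export
read_ends <- function(path, mode = c("five_prime_point", "full_read"),
                      library_id = NULL) {
  mode <- match.arg(mode)
  .assert(file.exists(path), paste("end file not found:", path))
  if (is.null(library_id)) {
    library_id <- sub("\\.(bed|bam)$", "", basename(path), ignore.case = TRUE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "bam") {
    .assert(requireNamespace("GenomicAlignments", quietly = TRUE),
            "reading BAM requires the GenomicAlignments package")
    gr <- GenomicRanges::granges(GenomicAlignments::readGAlignments(path))
    w <- rep(1, length(gr))
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    sc <- gr$score
    w <- rep(1, length(gr))
    if (!is.null(sc)) {
      use <- GenomicRanges::width(gr) == 1L & !is.na(sc) & sc > 0
      w[use] <- sc[use]
    }
  }
  strand <- as.character(GenomicRanges::strand(gr))
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    warning(sum(bad), " record(s) with unknown strand skipped", call. = FALSE)
    gr <- gr[!bad]; w <- w[!bad]; strand <- strand[!bad]
  }
  .assert(length(gr) > 0, "no stranded records in input")

  if (mode == "five_prime_point") {
    pos <- ifelse(strand == "+", GenomicRanges::start(gr),
                  GenomicRanges::end(gr))
    dt <- data.table::data.table(
      seq_id = as.character(GenomicRanges::seqnames(gr)),
      pos = as.integer(pos), strand = strand, count = w)
    dt <- dt[, .(count = sum(count)), by = .(seq_id, pos, strand)]
  } else {
    dt <- data.table::rbindlist(lapply(c("+", "-"), function(s) {
      sel <- strand == s
      if (!any(sel)) return(NULL)
      cov <- GenomicRanges::coverage(gr[sel], weight = w[sel])
      data.table::rbindlist(lapply(names(cov), function(sq) {
        r <- cov[[sq]]
        rl <- S4Vectors::runLength(r)
        rv <- S4Vectors::runValue(r)
        ends_ <- cumsum(rl)
        starts_ <- ends_ - rl + 1L
        keep <- rv > 0
        if (!any(keep)) return(NULL)
        data.table::data.table(
          seq_id = sq,
          pos = as.integer(unlist(mapply(seq.int, starts_[keep], ends_[keep],
                                         SIMPLIFY = FALSE))),
          strand = s,
          count = rep(rv[keep], rl[keep]))
      }))
    }))
  }
  five_prime_end_table(dt, library_id = library_id)
}
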