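#' Decay regime parameters for the degradome simulator
#'
#' A `DecayRegime` bundles the parameters of the generative model for one
#' strain class:
#'
#' * `wt` — functional cytoplasmic and nuclear 5'->3' exonuclease: most
#'   decapped molecules are cotranslationally trimmed, giving strong 3-nt
#'   periodicity in the preferred frame and a pronounced pause peak upstream
#'   of the stop codon.
#' * `dnls12` — exonuclease excluded from the nucleus (NLS-disrupted):
#'   trimming is partially impaired and a designated import-sensitive (KDIS)
#'   gene subset additionally accumulates decapped-but-untrimmed 5' ends
#'   near the TSS.
#' * `null` — exonuclease deletion: no cotranslational trimming; ends pile
#'   up at the TSS and the residual periodic background (endonucleolytic in
#'   origin) is frame-displaced by `bg_frame_shift` nt.
#'
#' @param name one of `"wt"`, `"dnls12"`, `"null"`.
#' @param trim_coupling probability in `[0,1]` that a decapped molecule is
#'   cotranslationally trimmed to a ribosome-coupled end.
#' @param frame_bias length-3 simplex: frame preference of ribosome-coupled
#'   ends (frame 0 = in frame with the start codon).
#' @param stop_pause_weight nonnegative excess mass at the stop-pause
#'   position; among coupled ends, a fraction
#'   `stop_pause_weight / (1 + stop_pause_weight)` is placed exactly at the
#'   pause offset.
#' @param tss_accum fraction in `[0,1]` of ends left untrimmed at the 5' end
#'   of the transcript (applies to KDIS-flagged genes, or to all genes under
#'   the `null` regime).
#' @param bg_frame_shift integer nt displacement of the periodic background.
#' @param noise_rate fraction of ends placed uniformly over the transcript.
#' @return list of validated parameters, class `DecayRegime`.
#' @export
decay_regime <- function(name = c("wt", "dnls12", "null"),
                         trim_coupling = NULL, frame_bias = NULL,
                         stop_pause_weight = NULL, tss_accum = NULL,
                         bg_frame_shift = NULL, noise_rate = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    wt = list(trim_coupling = 0.90, frame_bias = c(0.60, 0.22, 0.18),
              stop_pause_weight = 0.25, tss_accum = 0.00,
              bg_frame_shift = 0L, noise_rate = 0.10),
    dnls12 = list(trim_coupling = 0.80, frame_bias = c(0.52, 0.26, 0.22),
                  stop_pause_weight = 0.18, tss_accum = 0.75,
                  bg_frame_shift = 0L, noise_rate = 0.12),
    null = list(trim_coupling = 0.00, frame_bias = c(0.55, 0.25, 0.20),
                stop_pause_weight = 0.00, tss_accum = 0.60,
                bg_frame_shift = -1L, noise_rate = 0.35))
  r <- defaults
  for (p in names(defaults)) {
    v <- get(p)
    if (!is.null(v)) r[[p]] <- v
  }
  r$name <- name
  .assert(length(r$frame_bias) == 3 && all(r$frame_bias >= 0) &&
            abs(sum(r$frame_bias) - 1) < 1e-8,
          "frame_bias must be a length-3 simplex")
  .assert(r$trim_coupling >= 0 && r$trim_coupling <= 1,
          "trim_coupling must be in [0,1]")
  .assert(r$tss_accum >= 0 && r$tss_accum <= 1, "tss_accum must be in [0,1]")
  .assert(r$stop_pause_weight >= 0, "stop_pause_weight must be >= 0")
  .assert(r$noise_rate >= 0 && r$noise_rate <= 1,
          "noise_rate must be in [0,1]")
  r$bg_frame_shift <- as.integer(r$bg_frame_shift)
  structure(r, class = "DecayRegime")
}

#' Simulate a 5'P degradome library
#'
#' Draws `depth` single-nucleotide 5'P ends from a per-gene mixture model.
#' Reads are allocated to genes with probability proportional to
#' `expression_weight`. Each molecule is then, in order:
#'
#' 1. left untrimmed near the TSS with probability `tss_accum` (for
#'    KDIS-flagged genes, or all genes under the `null` regime); the offset
#'    from the TSS is geometric with rate `tss_decay`, clamped to the 5'UTR;
#' 2. otherwise uniform background over the transcript with probability
#'    `noise_rate`;
#' 3. otherwise ribosome-coupled with probability `trim_coupling`: placed at
#'    the stop-pause position (`stop_pause_offset` nt from the first nt of
#'    the stop codon) with probability
#'    `stop_pause_weight/(1+stop_pause_weight)`, else in a frame drawn from
#'    `frame_bias` at a uniform codon of the CDS;
#' 4. otherwise endonucleolytic background: periodic like (3) but with every
#'    frame displaced by `bg_frame_shift` nt (mod 3) and no stop pause.
#'
#' @param ann a [genome_annotation()].
#' @param regime a [decay_regime()].
#' @param kdis_fraction fraction of genes flagged as import-sensitive
#'   (KDIS); exactly `round(kdis_fraction * n_genes)` genes are flagged.
#' @param depth number of ends to draw (>= 1).
#' @param stop_pause_offset nt offset of the ribosome stop-pause peak
#'   relative to the first nt of the stop codon (default -17).
#' @param tss_decay geometric rate of the TSS-proximal offset distribution.
#' @param kdis_genes optional character vector fixing the flagged genes
#'   (overrides the random draw; its length must match the fraction).
#' @param seed integer seed; output is bit-identical given the seed.
#' @return list with elements `ends` (a [five_prime_end_table()]), `truth`
#'   (data.table `gene_id`, `kdis_flag`), `regime`, `depth`.
#' @export
simulate_library <- function(ann, regime, kdis_fraction = 0, depth,
                             stop_pause_offset = -17L, tss_decay = 0.08,
                             kdis_genes = NULL, seed) {
  .assert(inherits(ann, "GenomeAnnotation"), "ann must be a GenomeAnnotation")
  .assert(inherits(regime, "DecayRegime"), "regime must be a DecayRegime")
  .assert(is.numeric(depth) && depth >= 1, "empty library: depth must be >= 1")
  .assert(kdis_fraction >= 0 && kdis_fraction <= 1,
          "kdis_fraction must be in [0,1]")
  depth <- as.integer(depth)
  n <- nrow(ann)
  utr5 <- .utr5_len(ann)
  cdsl <- .cds_len(ann)
  txl <- .tx_len(ann)

  withr::with_seed(seed, {
    n_k <- round(kdis_fraction * n)
    if (is.null(kdis_genes)) {
      kdis_genes <- if (n_k > 0) sample(ann$gene_id, n_k) else character()
    } else {
      .assert(all(kdis_genes %in% ann$gene_id) && length(kdis_genes) == n_k,
              "kdis_genes must be round(kdis_fraction*n) annotated genes")
    }
    kflag <- ann$gene_id %in% kdis_genes
    elig <- if (identical(regime$name, "null")) rep(TRUE, n) else kflag

    g <- sample.int(n, depth, replace = TRUE, prob = ann$expression_weight)
    is_tss <- runif(depth) < regime$tss_accum * elig[g]
    rest <- !is_tss
    is_noise <- rest & runif(depth) < regime$noise_rate
    rest <- rest & !is_noise
    is_coupled <- rest & runif(depth) < regime$trim_coupling
    is_bg <- rest & !is_coupled
    sp <- regime$stop_pause_weight
    is_stop <- is_coupled & runif(depth) < sp / (1 + sp)
    is_per <- is_coupled & !is_stop

    txpos <- integer(depth)
    i <- which(is_tss)
    if (length(i)) {
      off <- rgeom(length(i), tss_decay)
      txpos[i] <- pmin(off, pmax(utr5[g[i]] - 1L, 0L))
    }
    i <- which(is_noise)
    if (length(i)) txpos[i] <- as.integer(floor(runif(length(i)) * txl[g[i]]))
    i <- which(is_stop)
    if (length(i)) {
      txpos[i] <- utr5[g[i]] + pmax(cdsl[g[i]] + as.integer(stop_pause_offset), 0L)
    }
    periodic <- function(i, shift) {
      f <- (sample.int(3L, length(i), replace = TRUE,
                       prob = regime$frame_bias) - 1L + shift) %% 3L
      codon <- as.integer(floor(runif(length(i)) * (cdsl[g[i]] %/% 3L)))
      utr5[g[i]] + 3L * codon + f
    }
    i <- which(is_per)
    if (length(i)) txpos[i] <- periodic(i, 0L)
    i <- which(is_bg)
    if (length(i)) txpos[i] <- periodic(i, regime$bg_frame_shift)

    pos <- as.integer(ifelse(ann$strand[g] == "+",
                             ann$tss[g] + txpos, ann$tss[g] - txpos))
    dt <- data.table::data.table(seq_id = ann$seq_id[g], pos = pos,
                                 strand = ann$strand[g])
    dt <- dt[, .(count = .N), by = .(seq_id, pos, strand)]
    ends <- five_prime_end_table(dt, library_id = regime$name)
    truth <- data.table::data.table(gene_id = ann$gene_id, kdis_flag = kflag)
    list(ends = ends, truth = truth, regime = regime$name, depth = depth)
  })
}

#' Simulate a strain-by-gene relative-expression matrix with planted classes
#'
#' Builds a `StrainFeatureMatrix` (see [build_strain_matrix()]) in which
#' strains carrying a binary feature (e.g. loss of cytoplasmic 5'->3' decay)
#' share a common log2(mutant/WT) expression shift of magnitude `effect`
#' over the genes, while feature-negative strains sit at zero; independent
#' Gaussian noise of sd `noise` is added everywhere. Optional `n_nd` strains
#' are drawn from the positive class but labelled `"nd"` (not determined).
#'
#' @param n_yes,n_no,n_nd strains per class.
#' @param n_genes number of genes.
#' @param effect scale of the class-specific gene effect (log2 units).
#' @param noise per-entry Gaussian noise sd (log2 units).
#' @param metrics metric names to populate (each gets the same class
#'   structure with independent noise).
#' @param feature name of the binary feature.
#' @param seed integer seed.
#' @return a `StrainFeatureMatrix` with a `features` table of
#'   `"yes"`/`"no"`/`"nd"` labels.
#' @export
simulate_strain_matrix <- function(n_yes = 4, n_no = 4, n_nd = 0,
                                   n_genes = 200, effect = 3, noise = 0.3,
                                   metrics = c("HL", "RA", "SR"),
                                   feature = "decay_5to3", seed = 1) {
  .assert(n_yes >= 1 && n_no >= 1, "need at least one strain per class")
  withr::with_seed(seed, {
    strains <- c(sprintf("yes_%d", seq_len(n_yes)),
                 sprintf("no_%d", seq_len(n_no)),
                 if (n_nd > 0) sprintf("nd_%d", seq_len(n_nd)))
    labels <- c(rep("yes", n_yes), rep("no", n_no), rep("nd", n_nd))
    positive <- labels == "yes" | labels == "nd"   # nd drawn from positives
    genes <- sprintf("G%04d", seq_len(n_genes))
    values <- lapply(setNames(metrics, metrics), function(m) {
      shift <- rnorm(n_genes) * effect
      v <- outer(as.numeric(positive), shift) +
        matrix(rnorm(length(strains) * n_genes, sd = noise),
               nrow = length(strains))
      dimnames(v) <- list(strains, genes)
      v
    })
    features <- data.table::data.table(strain = strains)
    features[[feature]] <- labels
    structure(list(values = values, strains = strains, genes = genes,
                   features = features, dropped = 0L),
              class = "StrainFeatureMatrix")
  })
}
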