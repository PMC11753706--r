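#' Strain-by-gene relative expression matrix
#'
#' Builds log2(mutant/WT) matrices for a set of strains and metrics
#' (typically mRNA half-life HL, mRNA amount RA and synthesis rate SR from
#' genomic run-on experiments), restricted to genes with complete positive
#' values in every strain and the reference (complete-case).
#'
#' @param strain_tables named list of data.frames, one per strain, each with
#'   a `gene_id` column and one numeric column per metric.
#' @param wt reference data.frame of the same shape.
#' @param metrics metric column names to use (default `HL`, `RA`, `SR`).
#' @param features optional data.frame with a `strain` column and one
#'   `"yes"/"no"/"nd"` column per binary strain feature.
#' @return list with `values` (named list of strain x gene matrices),
#'   `strains`, `genes`, `features`, `dropped` (genes lost to
#'   complete-casing), class `StrainFeatureMatrix`.
#' @export
build_strain_matrix <- function(strain_tables, wt,
                                metrics = c("HL", "RA", "SR"),
                                features = NULL) {
  .assert(is.list(strain_tables) && !is.null(names(strain_tables)),
          "strain_tables must be a named list")
  .assert("gene_id" %in% names(wt), "wt needs a gene_id column")
  ok_genes <- function(df) {
    .assert(all(c("gene_id", metrics) %in% names(df)),
            "each table needs gene_id and all metric columns")
    m <- as.matrix(df[, metrics, drop = FALSE])
    df$gene_id[rowSums(!is.finite(m) | m <= 0) == 0]
  }
  genes <- Reduce(intersect, c(lapply(strain_tables, ok_genes),
                               list(ok_genes(wt))))
  .assert(length(genes) > 0, "no genes shared by all strains and the reference")
  if (length(genes) < 50) {
    warning("only ", length(genes), " genes shared with the reference",
            call. = FALSE)
  }
  n_all <- length(unique(unlist(c(lapply(strain_tables, `[[`, "gene_id"),
                                  list(wt$gene_id)))))
  dropped <- n_all - length(genes)
  if (dropped > 0) message(dropped, " gene(s) dropped by complete-casing")

  wt_idx <- match(genes, wt$gene_id)
  values <- lapply(setNames(metrics, metrics), function(met) {
    m <- t(vapply(strain_tables, function(df) {
      log2(df[[met]][match(genes, df$gene_id)] / wt[[met]][wt_idx])
    }, numeric(length(genes))))
    dimnames(m) <- list(names(strain_tables), genes)
    m
  })
  structure(list(values = values, strains = names(strain_tables),
                 genes = genes, features = features, dropped = dropped),
            class = "StrainFeatureMatrix")
}

#' @export
print.StrainFeatureMatrix <- function(x, ...) {
  cat("StrainFeatureMatrix:", length(x$strains), "strains x",
      length(x$genes), "genes;", length(x$values), "metric(s):",
      paste(names(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' PCA of strain-level relative expression
#'
#' Column-centered singular value decomposition of a strains x genes
#' matrix of one metric. Component signs are fixed so that the
#' largest-magnitude loading of each component is positive, making the
#' result deterministic. Variables are not scaled to unit variance by
#' default.
#'
#' @param x a `StrainFeatureMatrix` or a plain strains x genes matrix.
#' @param metric which metric of a `StrainFeatureMatrix` to analyze.
#' @param n_dims number of components to keep (default 4); if the matrix
#'   rank supports fewer, the available ones are returned with a warning.
#' @param scale. scale variables to unit variance before the SVD.
#' @return list with `scores` (strains x dims), `loadings` (genes x dims),
#'   `explained` (variance fractions, non-increasing), `center`, `n_dims`,
#'   `metric`; class `PCAResult`.
#' @export
strain_pca <- function(x, metric = NULL, n_dims = 4L, scale. = FALSE) {
  if (inherits(x, "StrainFeatureMatrix")) {
    if (is.null(metric)) metric <- names(x$values)[1]
    m <- x$values[[metric]]
    .assert(!is.null(m), paste("unknown metric:", metric))
  } else {
    m <- as.matrix(x)
    if (is.null(metric)) metric <- "matrix"
  }
  .assert(nrow(m) >= 2 && ncol(m) >= 2, "need at least 2 strains and 2 genes")
  pc <- prcomp(m, center = TRUE, scale. = scale.)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  d <- min(as.integer(n_dims), rank, nrow(m) - 1L)
  if (d < n_dims) {
    warning("rank supports only ", d, " component(s); returning those",
            call. = FALSE)
  }
  scores <- pc$x[, seq_len(d), drop = FALSE]
  loadings <- pc$rotation[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 center = pc$center, n_dims = d, metric = metric),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat("PCAResult (", x$metric, "): ", nrow(x$scores), " strains, ",
      x$n_dims, " dims; explained: ",
      paste(sprintf("%.1f%%", 100 * x$explained[seq_len(x$n_dims)]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Class separation of a binary strain feature in a PCA plane
#'
#' Quantifies how well two feature classes ("yes"/"no") separate in the
#' plane of a chosen pair of principal components: the score is the
#' distance between the two class centroids divided by the mean distance
#' of classified strains to their own centroid. Strains labelled `"nd"`
#' are excluded from the score but assigned to the nearest centroid.
#'
#' @param result a [strain_pca()] result.
#' @param features data.frame with a `strain` column and the feature
#'   column (`"yes"/"no"/"nd"` values), covering the scored strains.
#' @param feature feature column name.
#' @param dim_pair length-2 integer vector of component indices
#'   (default `c(1, 2)`).
#' @param threshold score above which the plane is labelled separated
#'   (default 2).
#' @return list with `feature`, `dim_pair`, `score`, `separated`,
#'   `centroids` (2 x 2 matrix), `nd_assignment` (named character).
#' @export
feature_separation <- function(result, features, feature,
                               dim_pair = c(1L, 2L), threshold = 2) {
  .assert(inherits(result, "PCAResult"), "result must come from strain_pca()")
  .assert(all(dim_pair >= 1 & dim_pair <= result$n_dims),
          "dim_pair outside the available components")
  .assert(feature %in% names(features), paste("unknown feature:", feature))
  lab <- setNames(as.character(features[[feature]]), features$strain)
  strains <- rownames(result$scores)
  .assert(all(strains %in% names(lab)), "features must cover all strains")
  lab <- lab[strains]
  pts <- result$scores[, dim_pair, drop = FALSE]
  yes <- pts[lab == "yes", , drop = FALSE]
  no <- pts[lab == "no", , drop = FALSE]
  .assert(nrow(yes) >= 1 && nrow(no) >= 1,
          "feature needs at least one strain in each class")
  c_yes <- colMeans(yes)
  c_no <- colMeans(no)
  between <- sqrt(sum((c_yes - c_no)^2))
  d_within <- c(sqrt(rowSums((yes - rep(c_yes, each = nrow(yes)))^2)),
                sqrt(rowSums((no - rep(c_no, each = nrow(no)))^2)))
  within <- mean(d_within)
  score <- if (within > 0) between / within else if (between > 0) Inf else 0
  nd <- which(lab == "nd")
  nd_assignment <- character(0)
  if (length(nd) > 0) {
    p <- pts[nd, , drop = FALSE]
    d_yes <- sqrt(rowSums((p - rep(c_yes, each = nrow(p)))^2))
    d_no <- sqrt(rowSums((p - rep(c_no, each = nrow(p)))^2))
    nd_assignment <- setNames(ifelse(d_yes <= d_no, "yes", "no"),
                              strains[nd])
  }
  list(feature = feature, dim_pair = dim_pair, score = score,
       separated = is.infinite(score) || score >= threshold,
       centroids = rbind(yes = c_yes, no = c_no),
       nd_assignment = nd_assignment)
}
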