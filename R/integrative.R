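#' PCA embedding of cells in expression space
#'
#' Column-centered principal component analysis of cells (rows = cells after
#' internal transposition of a genes x cells matrix). A deterministic sign
#' convention is applied: each component is flipped so that its
#' largest-magnitude score is positive.
#'
#' @param data A `normalized_matrix` or genes x cells numeric matrix.
#' @param n_components Number of components to return.
#' @return An `embedding` list: `scores` (cells x components),
#'   `explained_variance_fraction`, `rotation`.
#' @export
pca_embed <- function(data, n_components = 3L) {
  if (inherits(data, "normalized_matrix")) data <- data$values
  x <- t(data)
  if (anyNA(x)) stop_data("PCA input must have no missing values")
  max_comp <- min(dim(x))
  if (n_components > max_comp) {
    warning("n_components truncated to ", max_comp)
    n_components <- max_comp
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  n_avail <- min(n_components, ncol(fit$x))
  scores <- fit$x[, seq_len(n_avail), drop = FALSE]
  rotation <- fit$rotation[, seq_len(n_avail), drop = FALSE]
  for (j in seq_len(ncol(scores))) {
    i_max <- which.max(abs(scores[, j]))
    if (scores[i_max, j] < 0) {
      scores[, j] <- -scores[, j]
      rotation[, j] <- -rotation[, j]
    }
  }
  var_all <- fit$sdev^2
  structure(list(scores = scores,
                 explained_variance_fraction =
                   (var_all / sum(var_all))[seq_len(n_avail)],
                 rotation = rotation),
            class = "embedding")
}

#' t-SNE embedding of cells
#'
#' Two-dimensional t-distributed stochastic neighbor embedding of cells,
#' deterministic given the seed. Requires `perplexity < (n_cells - 1) / 3`.
#'
#' @param data A `normalized_matrix` or genes x cells matrix.
#' @param perplexity t-SNE perplexity.
#' @param seed Integer seed.
#' @param max_iter Gradient-descent iterations.
#' @return List: `coords` (cells x 2, rownames = cell ids), `parameters`.
#' @export
tsne_embed <- function(data, perplexity = 15, seed = 1, max_iter = 500L) {
  if (inherits(data, "normalized_matrix")) data <- data$values
  x <- t(data)
  n <- nrow(x)
  if (perplexity >= (n - 1) / 3) {
    stop_config("perplexity must be < (n_cells - 1)/3 = ", (n - 1) / 3)
  }
  coords <- with_seed_checked(seed, {
    Rtsne::Rtsne(x, dims = 2, perplexity = perplexity, max_iter = max_iter,
                 pca = FALSE, check_duplicates = FALSE, verbose = FALSE,
                 num_threads = 1L)$Y
  })
  rownames(coords) <- rownames(x)
  colnames(coords) <- c("tSNE1", "tSNE2")
  list(coords = coords,
       parameters = list(perplexity = perplexity, seed = seed,
                         max_iter = max_iter))
}

#' Robust Z-scores of OCR over respiring cells
#'
#' Centers at the median and scales by the MAD of the respiring (OCR > 0)
#' cells; appropriate because single-cell OCR distributions here are
#' zero-inflated and right-skewed. With zero MAD (constant OCR) all robust
#' Z-scores are 0.
#'
#' @param ocr Numeric OCR vector, fmol/min.
#' @return Numeric vector of robust Z-scores.
#' @keywords internal
robust_ocr_z <- function(ocr) {
  respiring <- ocr > 0
  if (!any(respiring)) {
    warning("all-zero OCR vector; robust Z-scores are all zero")
    return(rep(0, length(ocr)))
  }
  med <- stats::median(ocr[respiring])
  mad <- stats::mad(ocr[respiring])
  if (mad == 0) return(rep(0, length(ocr)))
  (ocr - med) / mad
}

#' Fuse OCR into a PCA embedding as a third axis
#'
#' Axes 1-2 are the first two expression principal components; axis 3 is
#' the robust Z-score (median/MAD over respiring cells) of the OCR. Cells
#' classified non-respiring are pinned at the minimum of axis 3, below
#' every respiring cell, mirroring the instrument's OCR = 0 reporting.
#'
#' @param pca_scores Cells x >=2 score matrix from [pca_embed()].
#' @param ocr OCR vector aligned with the score rows.
#' @param respirer_class Optional character vector (`"non-respiring"` pins
#'   the cell); default: cells with OCR of 0.
#' @return Cells x 3 matrix (`PC1`, `PC2`, `OCRz`).
#' @export
augment_with_ocr <- function(pca_scores, ocr, respirer_class = NULL) {
  if (nrow(pca_scores) != length(ocr)) {
    stop_data("ocr must align with the PCA score rows")
  }
  if (is.null(respirer_class)) {
    respirer_class <- ifelse(ocr > 0, "respiring", "non-respiring")
  }
  z <- robust_ocr_z(ocr)
  nonresp <- respirer_class == "non-respiring"
  if (any(nonresp) && any(!nonresp)) {
    z[nonresp] <- min(z[!nonresp]) - 1
  }
  out <- cbind(PC1 = pca_scores[, 1], PC2 = pca_scores[, 2], OCRz = z)
  rownames(out) <- rownames(pca_scores)
  out
}

#' Flag cells with aberrant combined phenotypes
#'
#' Two flag classes, operationalizing what neither readout detects alone:
#'
#' * `high-OCR-outlier`: the cell's respiration is extreme
#'   (`|robust OCR Z| > z_thresh`) while its transcriptome is ordinary -
#'   its distance to its own expression-cluster centroid is at or below the
#'   `q_thresh` quantile of within-cluster centroid distances (pooled over
#'   clusters). Expression-only clustering leaves such cells inside a
#'   normal cluster; only the OCR axis separates them.
#' * `non-respirer-cluster`: the cell is non-respiring and its expression
#'   profile is coherent with the other non-respirers (mean pairwise Pearson
#'   correlation over genes `> r_thresh`).
#'
#' @param normalized A `normalized_matrix` (or genes x cells matrix).
#' @param assignment A `cluster_assignment` over the same cells.
#' @param ocr_table Data frame with `cell_id`, `ocr_fmol_min`,
#'   `respirer_class`.
#' @param z_thresh Robust OCR Z threshold (default 2.5).
#' @param q_thresh Within-cluster distance quantile a flagged cell must not
#'   exceed (default 0.75).
#' @param r_thresh Mean pairwise correlation threshold for the non-respirer
#'   cluster flag (default 0.5).
#' @return Data frame: `cell_id`, `flag` (`"none"`, `"high-OCR-outlier"`,
#'   `"non-respirer-cluster"`), `ocr_z`, `centroid_distance`.
#' @export
flag_aberrant_cells <- function(normalized, assignment, ocr_table,
                                z_thresh = 2.5, q_thresh = 0.75,
                                r_thresh = 0.5) {
  values <- if (inherits(normalized, "normalized_matrix")) {
    normalized$values
  } else normalized
  cells <- colnames(values)
  labels <- assignment$labels
  if (!setequal(cells, names(labels)) ||
      !setequal(cells, ocr_table$cell_id)) {
    stop_data("cells of the matrix, clustering, and OCR table must match")
  }
  labels <- labels[cells]
  ord <- match(cells, ocr_table$cell_id)
  ocr <- ocr_table$ocr_fmol_min[ord]
  resp_class <- ocr_table$respirer_class[ord]

  z <- robust_ocr_z(ocr)

  # Distance of each cell to its own expression-cluster centroid.
  dist_to_centroid <- numeric(length(cells))
  for (k in unique(labels)) {
    members <- which(labels == k)
    centroid <- rowMeans(values[, members, drop = FALSE])
    dist_to_centroid[members] <-
      sqrt(colSums((values[, members, drop = FALSE] - centroid)^2))
  }
  q_cut <- stats::quantile(dist_to_centroid, q_thresh, names = FALSE)

  flags <- rep("none", length(cells))
  high <- abs(z) > z_thresh & dist_to_centroid <= q_cut &
    resp_class != "non-respiring"
  flags[high] <- "high-OCR-outlier"

  nonresp <- which(resp_class == "non-respiring")
  if (length(nonresp) < 2) {
    if (length(nonresp) == 1) {
      message("only one non-respirer; non-respirer-cluster flag skipped")
    }
  } else {
    cor_nr <- stats::cor(values[, nonresp, drop = FALSE])
    mean_cor <- (rowSums(cor_nr) - 1) / (length(nonresp) - 1)
    coherent <- nonresp[mean_cor > r_thresh]
    flags[coherent] <- "non-respirer-cluster"
  }

  data.frame(cell_id = cells, flag = flags, ocr_z = z,
             centroid_distance = dist_to_centroid,
             stringsAsFactors = FALSE)
}
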