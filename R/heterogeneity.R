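#' Normalize a single-cell expression matrix to per-gene Z-scores
#'
#' Two-step normalization of a genes x cells log-expression matrix with
#' non-detects: (1) subtract the global mean of all detected entries;
#' (2) Z-score each gene using the mean and sample SD (n - 1) of its
#' detected entries. Non-detects are first imputed at the gene's minimum
#' detected value (a qPCR-style limit-of-detection convention) and remain
#' flagged in the mask; the Z-scoring statistics are computed over detected
#' entries only, so detected values of every retained gene have mean 0 and
#' SD 1 after normalization. Genes detected in fewer than 3 cells are
#' dropped and reported.
#'
#' @param values Genes x cells numeric matrix, `NA` marking non-detects.
#' @param mask Optional logical non-detect matrix (default `is.na(values)`).
#' @return A `normalized_matrix` list: `values` (Z-scores, no `NA`),
#'   `mask`, `dropped_genes`, and `metadata` (global mean, per-gene
#'   means/SDs, conventions used).
#' @export
normalize_expression <- function(values, mask = NULL) {
  if (!is.matrix(values) || nrow(values) == 0 || ncol(values) == 0) {
    stop_data("values must be a non-empty genes x cells matrix")
  }
  if (is.null(mask)) mask <- is.na(values)
  storage.mode(values) <- "double"
  values[mask] <- NA_real_

  detected_per_gene <- rowSums(!mask)
  dropped <- rownames(values)[detected_per_gene < 3]
  keep <- detected_per_gene >= 3
  if (!any(keep)) stop_data("no gene is detected in at least 3 cells")
  values <- values[keep, , drop = FALSE]
  mask <- mask[keep, , drop = FALSE]

  # Impute non-detects at the per-gene minimum detected value.
  gene_min <- apply(values, 1, min, na.rm = TRUE)
  imputed <- values
  for (i in seq_len(nrow(values))) {
    imputed[i, mask[i, ]] <- gene_min[i]
  }

  global_mean <- mean(values[!mask])
  centered <- imputed - global_mean

  gene_mean <- rowMeans(ifelse(mask, NA, centered), na.rm = TRUE)
  gene_sd <- apply(ifelse(mask, NA, centered), 1, stats::sd, na.rm = TRUE)
  if (any(gene_sd == 0)) {
    # Constant detected values cannot be scaled; leave them centered.
    gene_sd[gene_sd == 0] <- 1
  }
  z <- (centered - gene_mean) / gene_sd

  structure(list(
    values = z, mask = mask, dropped_genes = dropped,
    metadata = list(global_mean = global_mean, gene_mean = gene_mean,
                    gene_sd = gene_sd, sd_convention = "sample (n-1)",
                    imputation = "per-gene minimum detected value")),
    class = "normalized_matrix")
}

#' Agglomerative hierarchical clustering of cells
#'
#' Builds an agglomerative tree over cells (columns of a matrix, or entries
#' of a numeric vector such as per-cell OCR) and cuts it to exactly `k`
#' clusters. Defaults are Ward linkage on Euclidean distance. The result is
#' deterministic given the input order.
#'
#' @param data A `normalized_matrix`, a genes x cells matrix (cells are
#'   clustered), or a named numeric vector (e.g. OCR per cell).
#' @param k Number of clusters, `<=` number of cells.
#' @param linkage Linkage method passed to [stats::hclust()]
#'   (`"ward.D2"` default).
#' @param metric Distance metric passed to [stats::dist()].
#' @return A `cluster_assignment` list: `labels` (named integer vector in
#'   1..k), `k`, `occupancy` (N_i), `p` (p_i = N_i / N_total), `tree`
#'   (the `hclust` object), `linkage_method`, `distance_metric`.
#' @export
hierarchical_cluster <- function(data, k = 10L, linkage = "ward.D2",
                                 metric = "euclidean") {
  if (inherits(data, "normalized_matrix")) data <- data$values
  if (is.matrix(data)) {
    x <- t(data)                       # cells as rows
  } else if (is.numeric(data)) {
    x <- matrix(data, ncol = 1, dimnames = list(names(data), NULL))
  } else {
    stop_config("data must be a matrix, normalized_matrix, or numeric vector")
  }
  if (anyNA(x)) stop_data("clustering input must have no missing values")
  n <- nrow(x)
  if (k > n) stop_config("k (", k, ") exceeds number of cells (", n, ")")
  d <- stats::dist(x, method = metric)
  tree <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(tree, k = k)
  occupancy <- tabulate(labels, nbins = k)
  structure(list(labels = labels, k = as.integer(k),
                 occupancy = occupancy, p = occupancy / n,
                 tree = tree, linkage_method = linkage,
                 distance_metric = metric),
            class = "cluster_assignment")
}

#' Cluster enrichment scores and total enrichment score (TES) per group
#'
#' For pooled clusters with occupancy probabilities `p_i = N_i / N_total`
#' and a grouping of cells (e.g. strain x cell type), computes each group's
#' per-cluster occupancy fraction `f_gi`, the enrichment ratio
#' `ES_gi = f_gi / p_i` (the observed probability of landing in cluster i
#' relative to chance), and the total enrichment score
#' `TES_g = sum_i f_gi * ES_gi = sum_i f_gi^2 / p_i`, the
#' occupancy-weighted mean enrichment. TES is bounded below by 1 (attained
#' exactly when the group's occupancy matches the pooled occupancy) and
#' above by `N_total / n_g` (attained when the group exclusively owns one
#' cluster). Higher TES = more concentrated = less variable.
#'
#' @param assignment A `cluster_assignment` from [hierarchical_cluster()].
#' @param groups Group label per cell, aligned with `assignment$labels`
#'   (or named by cell id).
#' @return An `enrichment_result` list: `f` (groups x clusters occupancy
#'   fractions), `es` (enrichment ratios), `tes` (named vector), `n_per_group`,
#'   `p` (pooled occupancy probabilities).
#' @export
enrichment_scores <- function(assignment, groups) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  labels <- assignment$labels
  if (!is.null(names(groups)) && !is.null(names(labels))) {
    if (!all(names(labels) %in% names(groups))) {
      stop_data("groups is missing cells present in the assignment")
    }
    groups <- groups[names(labels)]
  }
  if (length(groups) != length(labels)) {
    stop_data("groups must align one-to-one with clustered cells")
  }
  if (anyNA(groups)) stop_data("every cell needs a group label")
  groups <- as.character(groups)
  k <- assignment$k
  p <- assignment$p
  group_names <- unique(groups)
  n_g <- table(factor(groups, levels = group_names))
  if (any(n_g == 0)) stop_data("empty group")

  f <- matrix(0, length(group_names), k,
              dimnames = list(group_names, paste0("cluster", seq_len(k))))
  for (g in group_names) {
    in_g <- labels[groups == g]
    f[g, ] <- tabulate(in_g, nbins = k) / length(in_g)
  }
  es <- sweep(f, 2, p, "/")
  es[, p == 0] <- 0
  tes <- rowSums(f * es)
  structure(list(f = f, es = es, tes = tes,
                 n_per_group = as.integer(n_g), p = p),
            class = "enrichment_result")
}

#' Relative variability (RV) between a control and a hypoxia-resistant strain
#'
#' `RV = TES_control / TES_hypoxia` for one cell type. Because a higher TES
#' means lower variability, RV < 1 indicates that the hypoxia-resistant
#' strain is *less* transcriptionally variable than its control.
#'
#' @param tes_control TES of the control strain (> 0).
#' @param tes_hypoxia TES of the hypoxia-resistant strain (> 0).
#' @return List with `rv` (raw ratio) and `rv_rounded` (2 decimals).
#' @export
relative_variability <- function(tes_control, tes_hypoxia) {
  assert_scalar_number(tes_control, "tes_control", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(tes_hypoxia, "tes_hypoxia", lower = 0,
                       strict_lower = TRUE)
  rv <- tes_control / tes_hypoxia
  list(rv = rv, rv_rounded = round(rv, 2))
}

#' Compare control vs hypoxia-resistant OCR means per cell type
#'
#' For each cell type, tests the control strain's OCR values against the
#' hypoxia-resistant strain's with both a Welch (unequal-variance) t-test on
#' the means and a Mann-Whitney rank test, adjusting each family of p-values
#' across cell types with Benjamini-Hochberg. Degenerate pairs in which both
#' groups are identical and constant are reported with p = 1 and flagged.
#'
#' @param ocr_table Data frame with columns `cell_type`, `strain`
#'   (`"control"` / `"hypoxia"`), and `ocr_fmol_min`.
#' @return Data frame, one row per cell type: group sizes, means, raw and
#'   BH-adjusted p-values of both tests, and a `degenerate` flag.
#' @export
compare_groups <- function(ocr_table) {
  needed <- c("cell_type", "strain", "ocr_fmol_min")
  if (!all(needed %in% names(ocr_table))) {
    stop_data("ocr_table needs columns ", paste(needed, collapse = ", "))
  }
  types <- unique(ocr_table$cell_type)
  rows <- lapply(types, function(ct) {
    ctl <- ocr_table$ocr_fmol_min[ocr_table$cell_type == ct &
                                    ocr_table$strain == "control"]
    hyp <- ocr_table$ocr_fmol_min[ocr_table$cell_type == ct &
                                    ocr_table$strain == "hypoxia"]
    if (length(ctl) < 3 || length(hyp) < 3) {
      stop_data("each group needs n >= 3 (cell type ", ct, ")")
    }
    degenerate <- stats::var(ctl) == 0 && stats::var(hyp) == 0
    if (degenerate) {
      p_t <- if (identical(mean(ctl), mean(hyp))) 1 else 0
      p_w <- p_t
    } else {
      p_t <- stats::t.test(ctl, hyp, var.equal = FALSE)$p.value
      p_w <- suppressWarnings(stats::wilcox.test(ctl, hyp)$p.value)
    }
    data.frame(cell_type = ct, n_control = length(ctl),
               n_hypoxia = length(hyp),
               mean_control = mean(ctl), mean_hypoxia = mean(hyp),
               p_t = p_t, p_wilcox = p_w, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_t_adj <- stats::p.adjust(out$p_t, method = "BH")
  out$p_wilcox_adj <- stats::p.adjust(out$p_wilcox, method = "BH")
  out
}
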