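# Shared fixtures and independent oracles.

# Build a cluster_assignment directly from labels, bypassing the tree, so
# enrichment statistics can be tested against hand-constructed partitions.
make_assignment <- function(labels, k = max(labels)) {
  occupancy <- tabulate(labels, nbins = k)
  structure(list(labels = labels, k = as.integer(k), occupancy = occupancy,
                 p = occupancy / length(labels), tree = NULL,
                 linkage_method = "manual", distance_metric = "manual"),
            class = "cluster_assignment")
}

# Brute-force TES oracle: explicit loops over cells and clusters, no shared
# code with enrichment_scores().
brute_force_tes <- function(labels, groups, k) {
  n_total <- length(labels)
  p <- vapply(seq_len(k), function(i) sum(labels == i) / n_total, numeric(1))
  out <- c()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    tes <- 0
    for (i in seq_len(k)) {
      f_gi <- sum(labels[idx] == i) / length(idx)
      es_gi <- if (p[i] > 0) f_gi / p[i] else 0
      tes <- tes + f_gi * es_gi
    }
    out[g] <- tes
  }
  out
}

# Noiseless sensor/calibration pair sharing Stern-Volmer parameters.
noiseless_setup <- function(drift = 0) {
  sm <- sensor_model(noise_sd = 0, drift_per_min = drift)
  list(sensor = sm, cal = calibration_model(ksv = sm$ksv, i0 = sm$i0),
       geom = well_geometry())
}

# Trace whose concentration series is exactly C(t) = c0 + slope * t,
# built through the forward Stern-Volmer relation with constant reference.
trace_from_concentration <- function(times, conc, sm = sensor_model(noise_sd = 0),
                                     geom = well_geometry(), cell_id = "synth") {
  rho <- sm$i0 / (1 + sm$ksv * conc)
  sensor_trace(times, sensor = sm$ref_level * rho,
               reference = rep(sm$ref_level, length(times)),
               well = geom, cell_id = cell_id)
}

# Expression matrix with well-separated latent clusters; returns values plus
# the generating labels.
separated_clusters_matrix <- function(n_per = 20, n_genes = 40, n_clusters = 2,
                                      separation = 8, sd = 1, seed = 11) {
  withr::with_seed(seed, {
    centroids <- matrix(rnorm(n_clusters * n_genes, sd = separation),
                        n_clusters, n_genes)
    cells <- n_per * n_clusters
    labels <- rep(seq_len(n_clusters), each = n_per)
    values <- sapply(seq_len(cells), function(j) {
      centroids[labels[j], ] + rnorm(n_genes, sd = sd)
    })
    rownames(values) <- sprintf("g%02d", seq_len(n_genes))
    colnames(values) <- sprintf("cell%03d", seq_len(cells))
    list(values = values, labels = labels)
  })
}

# Synthetic study with two kinds of planted aberrant cells: one cell placed
# at its expression-cluster centroid but respiring an order of magnitude
# above the population, and a transcriptionally coherent zero-OCR subgroup.
planted_outlier_study <- function(seed = 18) {
  withr::with_seed(seed, {
    n_genes <- 60
    centroids <- matrix(rnorm(3 * n_genes, sd = 6), 3, n_genes)
    labels <- rep(1:3, each = 20)
    values <- sapply(seq_along(labels), function(j) {
      centroids[labels[j], ] + rnorm(n_genes)
    })
    rownames(values) <- sprintf("g%02d", seq_len(n_genes))
    colnames(values) <- sprintf("c%03d", seq_along(labels))
    ocr <- rlnorm(length(labels), log(2.5), 0.2)
    outlier <- 5L                        # expression-ordinary, OCR-extreme
    values[, outlier] <- centroids[labels[outlier], ] +
      rnorm(n_genes, sd = 0.3)
    ocr[outlier] <- 12 * median(ocr)
    # transcriptionally coherent zero-OCR subgroup spanning two "strains"
    nr_centroid <- rnorm(n_genes, sd = 6)
    nr_cells <- 55:60
    for (j in nr_cells) values[, j] <- nr_centroid + rnorm(n_genes, sd = 0.5)
    ocr[nr_cells] <- 0
    list(values = values, labels = labels, ocr = ocr,
         outlier = outlier, nr_cells = nr_cells)
  })
}

# Small study written to a temp dir for pipeline-level tests; cached per
# session because several tests reuse it.
study_dir_cached <- local({
  dir <- NULL
  function() {
    if (is.null(dir) || !dir.exists(dir)) {
      dir <<- tempfile("study")
      generate_study(seed = 2024, out_dir = dir)
    }
    dir
  }
})
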