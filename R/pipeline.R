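pipeline_config_fields <- c(
  "traces_dir", "manifest", "matrix", "out_dir",
  "volume_pl", "initial_o2_um", "ksv", "i0",
  "smooth", "smooth_window", "detection_floor",
  "k", "linkage", "metric",
  "perplexity", "tsne_max_iter",
  "z_thresh", "q_thresh", "r_thresh",
  "seed")

#' Validated end-to-end pipeline configuration
#'
#' Collects paths, well geometry, calibration, smoothing, clustering,
#' embedding and aberrance parameters, and the global seed. Unknown fields
#' are rejected.
#'
#' @param traces_dir Directory containing the per-well trace files.
#' @param manifest Path to the manifest JSON.
#' @param matrix Path to the expression matrix TSV.
#' @param out_dir Output directory.
#' @param volume_pl Well volume, pL.
#' @param initial_o2_um Dissolved oxygen at seal time, uM.
#' @param ksv,i0 Stern-Volmer calibration parameters.
#' @param smooth Apply the sliding average before regression.
#' @param smooth_window Odd smoothing window.
#' @param detection_floor Non-respirer threshold, fmol/min.
#' @param k,linkage,metric Hierarchical clustering parameters.
#' @param perplexity,tsne_max_iter t-SNE parameters.
#' @param z_thresh,q_thresh,r_thresh Aberrance thresholds; see
#'   [flag_aberrant_cells()].
#' @param seed Global seed.
#' @param ... Unknown fields; any produces a configuration error.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(traces_dir, manifest, matrix, out_dir,
                            volume_pl = 140, initial_o2_um = 200,
                            ksv = 0.005, i0 = 2,
                            smooth = TRUE, smooth_window = 5L,
                            detection_floor = 0.1,
                            k = 10L, linkage = "ward.D2",
                            metric = "euclidean",
                            perplexity = 15, tsne_max_iter = 500L,
                            z_thresh = 2.5, q_thresh = 0.75, r_thresh = 0.5,
                            seed = 1L, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop_config("unknown configuration field(s): ",
                paste(names(extra), collapse = ", "))
  }
  cfg <- list(traces_dir = traces_dir, manifest = manifest, matrix = matrix,
              out_dir = out_dir, volume_pl = volume_pl,
              initial_o2_um = initial_o2_um, ksv = ksv, i0 = i0,
              smooth = isTRUE(smooth), smooth_window = as.integer(smooth_window),
              detection_floor = detection_floor, k = as.integer(k),
              linkage = linkage, metric = metric, perplexity = perplexity,
              tsne_max_iter = as.integer(tsne_max_iter),
              z_thresh = z_thresh, q_thresh = q_thresh, r_thresh = r_thresh,
              seed = as.integer(seed))
  assert_scalar_number(cfg$volume_pl, "volume_pl", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(cfg$initial_o2_um, "initial_o2_um", lower = 0)
  assert_scalar_number(cfg$ksv, "ksv", lower = 0, strict_lower = TRUE)
  assert_scalar_number(cfg$i0, "i0", lower = 0, strict_lower = TRUE)
  assert_scalar_number(cfg$detection_floor, "detection_floor", lower = 0)
  assert_scalar_number(cfg$k, "k", lower = 1)
  assert_scalar_number(cfg$perplexity, "perplexity", lower = 1)
  if (cfg$smooth_window %% 2 == 0) {
    stop_config("smooth_window must be odd")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_data("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), pipeline_config_fields)
  if (length(unknown)) {
    stop_config("unknown configuration field(s): ",
                paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

write_sidecar <- function(path, parameters) {
  jsonlite::write_json(parameters, paste0(path, ".params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full same-cell analysis pipeline
#'
#' Orchestrates the three analysis stages over on-disk inputs:
#' OCR extraction from every trace, expression normalization with pooled
#' hierarchical clustering and enrichment statistics (TES per strain group,
#' RV per cell-type pair), and the integrated embeddings with aberrant-cell
#' flags. Every output file is accompanied by a parameter sidecar JSON;
#' re-running with an identical configuration and inputs reproduces the
#' numeric outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly; outputs: `ocr_table.tsv`,
#'   `cluster_assignment.tsv`, `enrichment.json`, `group_comparison.tsv`,
#'   `embedding.tsv`, `qc.json`, `run_log.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- read_manifest(config$manifest)
  if (config$k > nrow(manifest)) {
    stop_config("k (", config$k, ") exceeds the number of cells (",
                nrow(manifest), ")")
  }
  geom <- well_geometry(config$volume_pl, config$initial_o2_um)
  cal <- calibration_model(config$ksv, config$i0)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  # Stage 1: OCR extraction ---------------------------------------------
  loaded <- read_traces(config$traces_dir, manifest, well = geom)
  if (length(loaded$traces) == 0) {
    stop_data("stage extract-ocr: no readable traces under ",
              config$traces_dir)
  }
  ocr_table <- tryCatch(
    extract_ocr_batch(loaded$traces, manifest, cal,
                      smooth = config$smooth,
                      smooth_window = config$smooth_window,
                      detection_floor = config$detection_floor),
    error = function(e) stop_data("stage extract-ocr: ",
                                  conditionMessage(e)))
  utils::write.table(ocr_table, out("ocr_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_sidecar(out("ocr_table.tsv"),
                config[c("volume_pl", "initial_o2_um", "ksv", "i0", "smooth",
                         "smooth_window", "detection_floor", "seed")])

  # Stage 2: heterogeneity ----------------------------------------------
  expr <- read_expression_matrix(config$matrix)
  expr$values <- expr$values[, ocr_table$cell_id, drop = FALSE]
  normalized <- tryCatch(normalize_expression(expr$values),
                         error = function(e)
                           stop_data("stage heterogeneity: ",
                                     conditionMessage(e)))
  assignment <- hierarchical_cluster(normalized, k = config$k,
                                     linkage = config$linkage,
                                     metric = config$metric)
  groups <- paste0(ifelse(ocr_table$strain == "control", "c", "h"),
                   ocr_table$cell_type)
  names(groups) <- ocr_table$cell_id
  enrich <- enrichment_scores(assignment, groups)
  rv <- list()
  for (ct in unique(ocr_table$cell_type)) {
    c_g <- paste0("c", ct)
    h_g <- paste0("h", ct)
    if (all(c(c_g, h_g) %in% names(enrich$tes))) {
      rv[[ct]] <- relative_variability(enrich$tes[[c_g]],
                                       enrich$tes[[h_g]])
    }
  }
  utils::write.table(
    data.frame(cell_id = names(assignment$labels),
               cluster = unname(assignment$labels)),
    out("cluster_assignment.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    list(p = enrich$p, f = enrich$f, es = enrich$es,
         tes = as.list(enrich$tes),
         rv = lapply(rv, function(x) x[c("rv", "rv_rounded")])),
    out("enrichment.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE,
    matrix = "rowmajor")
  write_sidecar(out("enrichment.json"),
                config[c("k", "linkage", "metric", "seed")])
  comparison <- compare_groups(ocr_table)
  utils::write.table(comparison, out("group_comparison.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # Stage 3: integration -------------------------------------------------
  pca <- pca_embed(normalized, n_components = 3)
  tsne <- tsne_embed(normalized, perplexity = config$perplexity,
                     seed = config$seed, max_iter = config$tsne_max_iter)
  augmented <- augment_with_ocr(pca$scores, ocr_table$ocr_fmol_min,
                                ocr_table$respirer_class)
  flags <- flag_aberrant_cells(normalized, assignment, ocr_table,
                               z_thresh = config$z_thresh,
                               q_thresh = config$q_thresh,
                               r_thresh = config$r_thresh)
  embedding <- data.frame(
    cell_id = rownames(pca$scores),
    PC1 = pca$scores[, 1], PC2 = pca$scores[, 2],
    PC3 = pca$scores[, 3], OCRz = augmented[, "OCRz"],
    tSNE1 = tsne$coords[, 1], tSNE2 = tsne$coords[, 2],
    flag = flags$flag[match(rownames(pca$scores), flags$cell_id)],
    stringsAsFactors = FALSE)
  utils::write.table(embedding, out("embedding.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_sidecar(out("embedding.tsv"),
                config[c("perplexity", "tsne_max_iter", "z_thresh",
                         "q_thresh", "r_thresh", "seed")])

  jsonlite::write_json(
    list(trace_failures = loaded$qc,
         dropped_genes = normalized$dropped_genes,
         n_cells = nrow(ocr_table)),
    out("qc.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("picoresp")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = unclass(config)),
    out("run_log.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
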