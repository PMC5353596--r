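fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

#' Write a sensor trace to delimited text
#'
#' Columns `time_min`, `sensor_intensity`, `reference_intensity`,
#' tab-separated, Unix newlines. Output is byte-deterministic.
#'
#' @param trace A `sensor_trace`.
#' @param path Output file.
#' @export
write_trace <- function(trace, path) {
  lines <- c("time_min\tsensor_intensity\treference_intensity",
             paste(fmt_num(trace$times), fmt_num(trace$sensor),
                   fmt_num(trace$reference), sep = "\t"))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a sensor trace from delimited text
#'
#' @param path Trace file written by [write_trace()] (or an instrument
#'   export in the same dialect).
#' @param well A [well_geometry()] to attach.
#' @param cell_id Identifier; defaults to the file name without extension.
#' @return A validated `sensor_trace`.
#' @export
read_trace <- function(path, well = well_geometry(), cell_id = NULL) {
  if (!file.exists(path)) stop_data("trace file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  needed <- c("time_min", "sensor_intensity", "reference_intensity")
  if (!all(needed %in% names(tab))) {
    stop_data(path, " must have columns ", paste(needed, collapse = ", "))
  }
  if (is.null(cell_id)) cell_id <- sub("\\.[^.]*$", "", basename(path))
  sensor_trace(tab$time_min, tab$sensor_intensity, tab$reference_intensity,
               well = well, cell_id = cell_id)
}

#' Read all of a study's traces, collecting per-file failures
#'
#' Invalid or missing files do not abort the batch: each failure becomes an
#' entry of the returned QC report.
#'
#' @param dir Directory the manifest's `well_file` paths are relative to.
#' @param manifest Manifest data frame with `cell_id` and `well_file`.
#' @param well A [well_geometry()] attached to every trace.
#' @return List with `traces` (named list of `sensor_trace`) and `qc`
#'   (data frame of `cell_id`, `file`, `error` for each failed read).
#' @export
read_traces <- function(dir, manifest, well = well_geometry()) {
  if (nrow(manifest) == 0) {
    warning("empty manifest; no traces read")
    return(list(traces = list(),
                qc = data.frame(cell_id = character(), file = character(),
                                error = character())))
  }
  traces <- list()
  qc <- list()
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(dir, manifest$well_file[i])
    id <- manifest$cell_id[i]
    res <- tryCatch(read_trace(f, well = well, cell_id = id),
                    error = function(e) e)
    if (inherits(res, "error")) {
      qc[[length(qc) + 1L]] <- data.frame(
        cell_id = id, file = f, error = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      traces[[id]] <- res
    }
  }
  list(traces = traces,
       qc = if (length(qc)) do.call(rbind, qc) else
         data.frame(cell_id = character(), file = character(),
                    error = character()))
}

#' Write a genes x cells expression matrix as TSV
#'
#' Genes as rows, cells as columns, non-detects encoded as `NA`, first
#' column `gene_id`.
#'
#' @param values Numeric matrix with gene rownames and cell colnames.
#' @param path Output file.
#' @export
write_expression_matrix <- function(values, path) {
  header <- paste(c("gene_id", colnames(values)), collapse = "\t")
  body <- vapply(seq_len(nrow(values)), function(i) {
    paste(c(rownames(values)[i], fmt_num(values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path, sep = "\n")
  invisible(path)
}

#' Read a genes x cells expression matrix from TSV
#'
#' Validating reader: ragged rows and duplicated gene or cell identifiers
#' are parse errors reported with the offending line number; `NA` entries
#' become the non-detect mask.
#'
#' @param path TSV file as written by [write_expression_matrix()].
#' @return List with `values` (numeric matrix, `NA` at non-detects) and
#'   `mask` (logical matrix).
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop_data("matrix file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop_data(path, ": no data rows")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  cells <- header[-1]
  if (anyDuplicated(cells)) {
    stop_data(path, " line 1: duplicated cell id(s): ",
              paste(unique(cells[duplicated(cells)]), collapse = ", "))
  }
  n_col <- length(header)
  genes <- character(length(lines) - 1L)
  values <- matrix(NA_real_, length(lines) - 1L, length(cells))
  for (i in seq_along(genes)) {
    fields <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    if (length(fields) != n_col) {
      stop_data(path, " line ", i + 1L, ": expected ", n_col,
                " fields, found ", length(fields))
    }
    genes[i] <- fields[1]
    vals <- suppressWarnings(as.numeric(fields[-1]))
    bad <- which(is.na(vals) & fields[-1] != "NA")
    if (length(bad)) {
      stop_data(path, " line ", i + 1L, ": non-numeric value '",
                fields[-1][bad[1]], "'")
    }
    values[i, ] <- vals
  }
  if (anyDuplicated(genes)) {
    stop_data(path, ": duplicated gene id(s): ",
              paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  dimnames(values) <- list(genes, cells)
  list(values = values, mask = is.na(values))
}

#' Write a study manifest as JSON
#'
#' @param manifest Manifest data frame.
#' @param path Output file.
#' @export
write_manifest <- function(manifest, path) {
  json <- jsonlite::toJSON(manifest, dataframe = "rows", pretty = TRUE,
                           digits = NA)
  writeLines(json, path, sep = "\n")
  invisible(path)
}

#' Read a study manifest from JSON
#'
#' @param path Manifest file.
#' @return Data frame with one row per cell.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_data("manifest not found: ", path)
  m <- jsonlite::fromJSON(path)
  needed <- c("cell_id", "cell_type", "strain")
  if (!all(needed %in% names(m))) {
    stop_data("manifest needs fields ", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(m$cell_id)) stop_data("manifest has duplicated cell_id")
  bad <- setdiff(unique(m$strain), c("control", "hypoxia"))
  if (length(bad)) {
    stop_data("strain labels must be 'control' or 'hypoxia'; found: ",
              paste(bad, collapse = ", "))
  }
  m
}

#' Write all artifacts of a generated study to disk
#'
#' Emits `manifest.json`, one trace file per well under `traces/`, and
#' `expression_matrix.tsv`. Byte-deterministic given the study object.
#'
#' @param study Result of [generate_study()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(file.path(out_dir, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_data("cannot create output dir ", out_dir)
  write_manifest(study$manifest, file.path(out_dir, "manifest.json"))
  for (id in names(study$traces)) {
    write_trace(study$traces[[id]],
                file.path(out_dir, "traces", paste0(id, ".tsv")))
  }
  vals <- study$expression$values
  write_expression_matrix(vals, file.path(out_dir, "expression_matrix.tsv"))
  invisible(out_dir)
}
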