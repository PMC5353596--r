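#' Sealed-well geometry
#'
#' Geometry of one hermetically sealed measurement chamber. The study design
#' this package simulates uses 140 pL wells; the dissolved-oxygen
#' concentration at seal time defaults to 200 uM, air-saturated culture
#' medium near 37 C. At 140 pL that is 28 fmol of oxygen, enough for a
#' cell respiring at a few fmol/min to produce a measurable drawdown within
#' tens of minutes.
#'
#' @param volume Well volume in picoliters.
#' @param initial_o2 Dissolved oxygen concentration at seal time, in uM.
#' @return A `well_geometry` object.
#' @export
well_geometry <- function(volume = 140, initial_o2 = 200) {
  assert_scalar_number(volume, "volume", lower = 0, strict_lower = TRUE)
  assert_scalar_number(initial_o2, "initial_o2", lower = 0)
  structure(list(volume = volume, initial_o2 = initial_o2),
            class = "well_geometry")
}

#' Ratiometric oxygen sensor model
#'
#' Photophysics of the embedded luminescent oxygen sensor, modeled as ideal
#' Stern-Volmer quenching of the sensor/reference intensity ratio:
#' `ratio(C) = i0 / (1 + ksv * C)`, where `C` is dissolved oxygen in uM,
#' `i0` the unquenched (anoxic) ratio and `ksv` the quenching constant.
#' The sensor channel is self-referenced against an oxygen-insensitive
#' reference dye channel so the readout does not depend on deposited sensor
#' volume. Multiplicative intensity noise applies to both channels;
#' a linear drift term applies to the reference channel only.
#'
#' @param ksv Stern-Volmer quenching constant, per uM.
#' @param i0 Anoxic sensor/reference intensity ratio.
#' @param ref_level Mean reference-channel intensity (arbitrary units).
#' @param noise_sd Multiplicative intensity noise, as a fraction.
#' @param drift_per_min Linear reference-channel drift, fraction per minute.
#' @return A `sensor_model` object.
#' @export
sensor_model <- function(ksv = 0.005, i0 = 2, ref_level = 1000,
                         noise_sd = 0.01, drift_per_min = 0) {
  assert_scalar_number(ksv, "ksv", lower = 0, strict_lower = TRUE)
  assert_scalar_number(i0, "i0", lower = 0, strict_lower = TRUE)
  assert_scalar_number(ref_level, "ref_level", lower = 0, strict_lower = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(drift_per_min, "drift_per_min")
  structure(list(ksv = ksv, i0 = i0, ref_level = ref_level,
                 noise_sd = noise_sd, drift_per_min = drift_per_min),
            class = "sensor_model")
}

#' Zero-inflated lognormal OCR population model
#'
#' Single-cell oxygen consumption rates in this system are zero-inflated and
#' right-skewed: most strains contain an 18-35% fraction of non-respiring
#' cells (distinct from dead cells), and the respiring cells follow a
#' roughly lognormal distribution. Draws below `detection_floor` are
#' reported as 0, mirroring the instrument's detection limit.
#'
#' @param nonrespirer_fraction Probability a cell is a non-respirer.
#' @param log_mean Log of the median OCR of respiring cells (fmol/min).
#' @param log_sd Lognormal shape parameter.
#' @param detection_floor OCR below which a value is treated as zero
#'   (fmol/min).
#' @return An `ocr_population_model` object.
#' @export
ocr_population_model <- function(nonrespirer_fraction = 0.25,
                                 log_mean = log(2.5), log_sd = 0.6,
                                 detection_floor = 0.1) {
  assert_probability(nonrespirer_fraction, "nonrespirer_fraction")
  assert_scalar_number(log_mean, "log_mean")
  assert_scalar_number(log_sd, "log_sd", lower = 0)
  assert_scalar_number(detection_floor, "detection_floor", lower = 0)
  structure(list(nonrespirer_fraction = nonrespirer_fraction,
                 log_mean = log_mean, log_sd = log_sd,
                 detection_floor = detection_floor),
            class = "ocr_population_model")
}

#' Draw true single-cell OCR values from a population model
#'
#' @param model An [ocr_population_model()].
#' @param n Number of cells.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`, OCR in fmol/min (zeros for
#'   non-respirers).
#' @export
simulate_ocr_population <- function(model, n, seed) {
  stopifnot(inherits(model, "ocr_population_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop_config("n must be >= 1")
  }
  with_seed_checked(seed, {
    nonresp <- stats::runif(n) < model$nonrespirer_fraction
    ocr <- stats::rlnorm(n, meanlog = model$log_mean, sdlog = model$log_sd)
    ocr[nonresp] <- 0
    ocr[ocr < model$detection_floor] <- 0
    ocr
  })
}

#' Simulate one well's two-channel sensor drawdown trace
#'
#' Forward model of the sealed-well measurement. The oxygen amount in the
#' well is depleted at the cell's (constant) respiration rate and clamped at
#' zero; the sensor/reference ratio follows the Stern-Volmer relation, so the
#' sensor channel brightens as oxygen is consumed. An optional first-order
#' leak term relaxes the well toward an external oxygen concentration and is
#' used to emulate imperfectly sealed wells for seal QC.
#'
#' @param true_ocr True oxygen consumption rate, fmol/min.
#' @param geom A [well_geometry()].
#' @param sensor A [sensor_model()].
#' @param duration Trace duration in minutes.
#' @param dt Sampling interval in minutes.
#' @param seed Integer seed (noise draws).
#' @param cell_id Identifier attached to the trace.
#' @param leak_rate First-order leak constant, per minute (0 = hermetic).
#' @param external_o2 Oxygen concentration outside a leaky well, uM.
#' @return A `sensor_trace` object: `times` (min), `sensor`, `reference`
#'   intensity series, the geometry, and `cell_id`. The noiseless true
#'   concentration series is attached as attribute `"true_concentration"`.
#' @export
simulate_sensor_trace <- function(true_ocr, geom = well_geometry(),
                                  sensor = sensor_model(), duration = 30,
                                  dt = 0.5, seed = 1, cell_id = "cell",
                                  leak_rate = 0, external_o2 = NULL) {
  stopifnot(inherits(geom, "well_geometry"), inherits(sensor, "sensor_model"))
  assert_scalar_number(true_ocr, "true_ocr", lower = 0)
  assert_scalar_number(duration, "duration", lower = 0, strict_lower = TRUE)
  assert_scalar_number(dt, "dt", lower = 0, strict_lower = TRUE)
  assert_scalar_number(leak_rate, "leak_rate", lower = 0)
  if (is.null(external_o2)) external_o2 <- geom$initial_o2

  times <- seq(0, duration, by = dt)
  ku <- UM_PL_TO_FMOL
  cap <- geom$volume * ku   # fmol per uM of concentration
  if (leak_rate == 0) {
    amount <- pmax(0, geom$initial_o2 * cap - true_ocr * times)
  } else {
    # Euler integration with substeps; only needed for leaky wells.
    nsub <- 20L
    h <- dt / nsub
    a <- geom$initial_o2 * cap
    amount <- numeric(length(times))
    amount[1] <- a
    for (i in seq_along(times)[-1]) {
      for (s in seq_len(nsub)) {
        conc <- a / cap
        a <- a + (-true_ocr + leak_rate * (external_o2 - conc) * cap) * h
        a <- max(0, a)
      }
      amount[i] <- a
    }
  }
  conc <- amount / cap
  rho <- sensor$i0 / (1 + sensor$ksv * conc)

  with_seed_checked(seed, {
    n <- length(times)
    noise_s <- 1 + stats::rnorm(n, 0, sensor$noise_sd)
    noise_r <- 1 + stats::rnorm(n, 0, sensor$noise_sd)
    reference <- sensor$ref_level * (1 + sensor$drift_per_min * times) * noise_r
    sens <- sensor$ref_level * rho * noise_s
    structure(list(times = times, sensor = sens, reference = reference,
                   well = geom, cell_id = cell_id),
              class = "sensor_trace",
              true_concentration = conc)
  })
}

#' Design of the single-cell expression panel
#'
#' Describes a 96-gene qPCR-style expression panel with functional gene
#' categories, latent-cluster centroids on the log-expression scale,
#' within-cluster noise, and per-gene dropout (non-detect) probabilities.
#' Housekeeping genes (GAPDH-like, detected in nearly every cell) carry
#' near-zero dropout.
#'
#' @param cluster_centroids Numeric matrix, latent clusters x genes, of mean
#'   log-expression values. Column names are gene identifiers.
#' @param gene_categories Character vector mapping each gene to a functional
#'   group label; names must match the centroid columns.
#' @param within_cluster_sd Log-scale within-cluster noise SD.
#' @param dropout_prob_per_gene Per-gene non-detect probability (recycled to
#'   the gene count if scalar).
#' @param housekeeping_genes Genes forced to near-zero dropout.
#' @param housekeeping_dropout Dropout probability used for housekeepers.
#' @return An `expression_design` object.
#' @export
expression_design <- function(cluster_centroids, gene_categories = NULL,
                              within_cluster_sd = 1,
                              dropout_prob_per_gene = 0.15,
                              housekeeping_genes = character(),
                              housekeeping_dropout = 0.005) {
  if (!is.matrix(cluster_centroids) || is.null(colnames(cluster_centroids))) {
    stop_config("cluster_centroids must be a matrix with gene column names")
  }
  genes <- colnames(cluster_centroids)
  n_genes <- length(genes)
  dropout <- rep_len(dropout_prob_per_gene, n_genes)
  names(dropout) <- genes
  if (any(dropout < 0 | dropout > 1)) {
    stop_config("dropout probabilities must be in [0, 1]")
  }
  if (!all(housekeeping_genes %in% genes)) {
    stop_config("housekeeping_genes must be a subset of the gene panel")
  }
  dropout[housekeeping_genes] <- housekeeping_dropout
  if (is.null(gene_categories)) {
    gene_categories <- stats::setNames(rep("unannotated", n_genes), genes)
  }
  if (!all(genes %in% names(gene_categories))) {
    stop_config("gene_categories must cover every gene")
  }
  assert_scalar_number(within_cluster_sd, "within_cluster_sd", lower = 0)
  structure(list(n_genes = n_genes, genes = genes,
                 gene_categories = gene_categories[genes],
                 cluster_centroids = cluster_centroids,
                 within_cluster_sd = within_cluster_sd,
                 dropout_prob_per_gene = dropout,
                 housekeeping_genes = housekeeping_genes),
            class = "expression_design")
}

# The seven functional groups of the target-gene panel, hypoxia-response and
# energy-production categories first.
panel_functional_groups <- c(
  "blood vessel development/morphogenesis",
  "glycolysis/glucose metabolism",
  "positive regulation of chemotaxis",
  "phosphorylation and phosphorus metabolic process",
  "cell migration/motility",
  "phosphorylation regulation",
  "regulation of apoptosis"
)

#' Default 96-gene expression design
#'
#' Builds the default panel: six housekeeping genes plus ninety synthetic
#' target genes assigned cyclically to seven hypoxia-relevant functional
#' groups, with latent-cluster centroids drawn once from the given seed.
#'
#' @param n_latent Number of latent expression clusters.
#' @param separation Scale of centroid differences, in within-cluster SD
#'   units.
#' @param seed Integer seed for the centroid draw.
#' @param n_genes Panel size.
#' @param within_cluster_sd Within-cluster log-expression SD.
#' @param dropout_prob_per_gene Non-detect probability for target genes.
#' @return An [expression_design()].
#' @export
default_expression_design <- function(n_latent = 4, separation = 2, seed = 1,
                                      n_genes = 96, within_cluster_sd = 1,
                                      dropout_prob_per_gene = 0.15) {
  housekeepers <- c("GAPDH", "ACTB", "B2M", "GUSB", "HPRT1", "TBP")
  n_target <- n_genes - length(housekeepers)
  targets <- sprintf("G%03d", seq_len(n_target))
  genes <- c(housekeepers, targets)
  categories <- stats::setNames(
    c(rep("housekeeping", length(housekeepers)),
      rep_len(panel_functional_groups, n_target)),
    genes)
  centroids <- with_seed_checked(seed, {
    m <- matrix(stats::rnorm(n_latent * n_genes, mean = 0,
                             sd = separation * within_cluster_sd),
                nrow = n_latent, ncol = n_genes)
    # Housekeepers are highly and uniformly expressed across clusters.
    m[, seq_along(housekeepers)] <-
      matrix(rep(5 + stats::rnorm(length(housekeepers), 0, 0.2),
                 each = n_latent), nrow = n_latent)
    m
  })
  colnames(centroids) <- genes
  rownames(centroids) <- paste0("L", seq_len(n_latent))
  expression_design(centroids, gene_categories = categories,
                    within_cluster_sd = within_cluster_sd,
                    dropout_prob_per_gene = dropout_prob_per_gene,
                    housekeeping_genes = housekeepers)
}

#' Simulate a genes x cells expression matrix with non-detects
#'
#' Each cell's log-expression vector is its latent cluster's centroid plus
#' Gaussian within-cluster noise; entries are then masked as non-detects
#' with the per-gene dropout probability.
#'
#' @param design An [expression_design()].
#' @param manifest A study manifest data frame with columns `cell_id` and
#'   `latent_cluster`.
#' @param seed Integer seed.
#' @return List with `values` (genes x cells numeric matrix, `NA` at
#'   non-detects) and `mask` (logical matrix, `TRUE` = non-detect).
#' @export
simulate_expression_matrix <- function(design, manifest, seed) {
  stopifnot(inherits(design, "expression_design"))
  if (!all(c("cell_id", "latent_cluster") %in% names(manifest))) {
    stop_config("manifest needs cell_id and latent_cluster columns")
  }
  cl <- as.character(manifest$latent_cluster)
  known <- rownames(design$cluster_centroids)
  if (!all(cl %in% known)) {
    stop_config("latent cluster(s) without a centroid: ",
                paste(unique(setdiff(cl, known)), collapse = ", "))
  }
  n_genes <- design$n_genes
  n_cells <- nrow(manifest)
  with_seed_checked(seed, {
    values <- matrix(NA_real_, n_genes, n_cells,
                     dimnames = list(design$genes, manifest$cell_id))
    mask <- matrix(FALSE, n_genes, n_cells,
                   dimnames = dimnames(values))
    for (j in seq_len(n_cells)) {
      mu <- design$cluster_centroids[cl[j], ]
      values[, j] <- mu + stats::rnorm(n_genes, 0, design$within_cluster_sd)
      mask[, j] <- stats::runif(n_genes) < design$dropout_prob_per_gene
    }
    values[mask] <- NA_real_
    list(values = values, mask = mask)
  })
}

#' Configuration of the hypoxia bottleneck selection protocol
#'
#' The selection protocol this models: repeated episodes of acute hypoxia,
#' each killing all but a fixed fraction of the population (10% survival by
#' design), followed by re-expansion of the survivors to the original
#' population size under normal culture before the next episode. Six rounds
#' by default. `heritability` couples a latent survival trait to both who
#' survives and how faithfully offspring reproduce their parent's trait; it
#' is the knob that makes the recapitulation claim (selection at zero
#' heritability leaves the trait distribution unchanged) falsifiable.
#'
#' @param n_rounds Number of hypoxia episodes.
#' @param survival_fraction Fraction surviving each episode, in (0, 1].
#' @param heritability In [0, 1]; fraction of trait variance that is
#'   heritable.
#' @param expansion_size Population size restored between rounds (`NULL` =
#'   size of the input population).
#' @return A `selection_config` object.
#' @export
selection_config <- function(n_rounds = 6, survival_fraction = 0.10,
                             heritability = 0, expansion_size = NULL) {
  assert_scalar_number(n_rounds, "n_rounds", lower = 1)
  assert_scalar_number(survival_fraction, "survival_fraction",
                       lower = 0, upper = 1, strict_lower = TRUE)
  assert_probability(heritability, "heritability")
  if (!is.null(expansion_size)) {
    assert_scalar_number(expansion_size, "expansion_size", lower = 1)
  }
  structure(list(n_rounds = as.integer(n_rounds),
                 survival_fraction = survival_fraction,
                 heritability = heritability,
                 expansion_size = expansion_size),
            class = "selection_config")
}

#' Simulate repeated hypoxia bottleneck selection with re-expansion
#'
#' The latent survival trait is decomposed as `t = g + e` with heritable
#' variance `var(g) = h * var(t)` and environmental variance
#' `var(e) = (1 - h) * var(t)` (`h` = heritability). Each round keeps
#' `round(N * survival_fraction)` cells - a fraction `h` of the survivor
#' quota taken by trait rank, the rest uniformly at random - then re-expands
#' clonally: offspring inherit the parent's heritable component `g` exactly
#' and redraw the environmental component. Offspring therefore regress
#' toward the mean by factor `h` (`E[g | t] = h t`), so at `h = 0` the
#' trait distribution is invariant under any number of rounds and at
#' `h = 1` selection shifts it directionally.
#'
#' @param base_population Numeric trait vector, or a data frame with a
#'   `trait` column plus arbitrary columns inherited clonally (e.g. a
#'   latent expression-cluster label).
#' @param cfg A [selection_config()].
#' @param seed Integer seed.
#' @return Data frame with columns `trait`, `g`, and any extra columns of
#'   the input, one row per cell of the final expanded population.
#' @export
simulate_hypoxia_selection <- function(base_population, cfg = selection_config(),
                                       seed = 1) {
  stopifnot(inherits(cfg, "selection_config"))
  if (is.numeric(base_population)) {
    base_population <- data.frame(trait = base_population)
  }
  if (!is.data.frame(base_population) || !"trait" %in% names(base_population)) {
    stop_data("base_population must be a trait vector or data frame with a trait column")
  }
  pop <- base_population
  n0 <- nrow(pop)
  expansion <- if (is.null(cfg$expansion_size)) n0 else as.integer(cfg$expansion_size)
  if (round(n0 * cfg$survival_fraction) < 1) {
    stop_data("population size times survival_fraction must be >= 1")
  }
  h <- cfg$heritability
  sigma <- stats::sd(pop$trait)
  if (!is.finite(sigma)) sigma <- 0

  with_seed_checked(seed, {
    # Conditional draw of the heritable component given the observed trait:
    # E[g|t] = h*t, var(g|t) = h*(1-h)*sigma^2.
    mu <- mean(pop$trait)
    pop$g <- mu + h * (pop$trait - mu) +
      stats::rnorm(n0, 0, sqrt(h * (1 - h)) * sigma)
    e_sd <- sqrt(1 - h) * sigma

    for (round_i in seq_len(cfg$n_rounds)) {
      n <- nrow(pop)
      n_surv <- round(n * cfg$survival_fraction)
      if (n_surv < 1) stop_data("empty survivor set in round ", round_i)
      n_rank <- round(h * n_surv)
      by_rank <- order(pop$trait, decreasing = TRUE)
      ranked <- by_rank[seq_len(n_rank)]
      rest <- setdiff(seq_len(n), ranked)
      random_pick <- if (n_surv - n_rank > 0) {
        sample(rest, n_surv - n_rank)
      } else integer(0)
      survivors <- pop[c(ranked, random_pick), , drop = FALSE]

      parents <- survivors[sample.int(nrow(survivors), expansion,
                                      replace = TRUE), , drop = FALSE]
      parents$trait <- parents$g + stats::rnorm(expansion, 0, e_sd)
      pop <- parents
      rownames(pop) <- NULL
    }
    pop
  })
}

#' Full study configuration for the synthetic generator
#'
#' Defaults mirror the study design: four cell types (metaplastic CP-A and
#' dysplastic CP-B/C/D analogs), each with a control and a hypoxia-resistant
#' strain, 20-24 cells per strain, sealed 140 pL wells, a 96-gene panel,
#' and six 10%-survival hypoxia bottlenecks. Non-respirer fractions sit in
#' the observed 18-35% band for every strain except control CP-A, which has
#' none.
#'
#' @param cell_types Cell type labels.
#' @param cells_per_strain_range Inclusive range the per-strain cell count is
#'   drawn from.
#' @param nonrespirer_fractions Named vector, one entry per strain
#'   (`"<strain>.<cell type>"`), of non-respirer probabilities.
#' @param geom,sensor,design,selection Component configurations; see
#'   [well_geometry()], [sensor_model()], [expression_design()],
#'   [selection_config()].
#' @param log_mean,log_sd,detection_floor Shared lognormal OCR parameters.
#' @param duration,dt Trace duration and sampling interval, minutes.
#' @param base_cluster_prob Probability a cell's latent expression cluster is
#'   its cell type's modal cluster (residual mass spread uniformly).
#' @return A `study_config` object.
#' @export
study_config <- function(cell_types = c("CP-A", "CP-B", "CP-C", "CP-D"),
                         cells_per_strain_range = c(20L, 24L),
                         nonrespirer_fractions = c(
                           "control.CP-A" = 0.00, "hypoxia.CP-A" = 0.22,
                           "control.CP-B" = 0.18, "hypoxia.CP-B" = 0.30,
                           "control.CP-C" = 0.25, "hypoxia.CP-C" = 0.20,
                           "control.CP-D" = 0.35, "hypoxia.CP-D" = 0.28),
                         geom = well_geometry(), sensor = sensor_model(),
                         design = NULL, selection = selection_config(),
                         log_mean = log(2.5), log_sd = 0.6,
                         detection_floor = 0.1,
                         duration = 30, dt = 0.5,
                         base_cluster_prob = 0.7) {
  strains <- c("control", "hypoxia")
  needed <- as.vector(outer(strains, cell_types, paste, sep = "."))
  if (!all(needed %in% names(nonrespirer_fractions))) {
    stop_config("nonrespirer_fractions must name every strain.cell_type combination")
  }
  structure(list(cell_types = cell_types, strains = strains,
                 cells_per_strain_range = as.integer(cells_per_strain_range),
                 nonrespirer_fractions = nonrespirer_fractions,
                 geom = geom, sensor = sensor, design = design,
                 selection = selection, log_mean = log_mean, log_sd = log_sd,
                 detection_floor = detection_floor,
                 duration = duration, dt = dt,
                 base_cluster_prob = base_cluster_prob),
            class = "study_config")
}

#' Generate a complete synthetic same-cell study
#'
#' Forward-simulates the whole experiment: a cell manifest (8 strains of
#' 20-24 cells), true OCR values from per-strain zero-inflated lognormal
#' models, a sealed-well sensor trace per cell, and a 96-gene expression
#' matrix with dropout. Hypoxia-strain latent-cluster labels are drawn from
#' a [simulate_hypoxia_selection()] run seeded from the same stream, so at
#' the default heritability of 0 the hypoxia strains recapitulate their
#' controls' generative distribution exactly, as observed in the study this
#' emulates. Optionally writes all artifacts to disk in the package's
#' plain-text formats.
#'
#' @param config A [study_config()].
#' @param seed Integer seed; the run is fully deterministic given it.
#' @param out_dir Output directory (`NULL` = no files written).
#' @return List with `manifest` (data frame), `traces` (named list of
#'   `sensor_trace`), `expression` (list `values`/`mask`), and `config`.
#' @export
generate_study <- function(config = study_config(), seed = 1, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  design <- config$design
  if (is.null(design)) {
    design <- default_expression_design(n_latent = length(config$cell_types),
                                        seed = seed)
  }
  n_latent <- nrow(design$cluster_centroids)
  latent_names <- rownames(design$cluster_centroids)

  manifest <- with_seed_checked(seed, {
    rows <- list()
    for (ct_i in seq_along(config$cell_types)) {
      ct <- config$cell_types[ct_i]
      base_latent <- latent_names[(ct_i - 1L) %% n_latent + 1L]
      probs <- stats::setNames(
        rep((1 - config$base_cluster_prob) / (n_latent - 1), n_latent),
        latent_names)
      probs[base_latent] <- config$base_cluster_prob

      # Latent-cluster pool for the hypoxia strain: run the bottleneck
      # protocol on a base population carrying this cell type's cluster mix.
      base_pop <- data.frame(
        trait = stats::rnorm(1000),
        latent_cluster = sample(latent_names, 1000, replace = TRUE,
                                prob = probs))
      post <- simulate_hypoxia_selection(
        base_pop, config$selection,
        seed = sample.int(.Machine$integer.max, 1))

      for (strain in config$strains) {
        key <- paste(strain, ct, sep = ".")
        n_cells <- sample(seq(config$cells_per_strain_range[1],
                              config$cells_per_strain_range[2]), 1)
        model <- ocr_population_model(
          nonrespirer_fraction = config$nonrespirer_fractions[[key]],
          log_mean = config$log_mean, log_sd = config$log_sd,
          detection_floor = config$detection_floor)
        ocr <- simulate_ocr_population(
          model, n_cells, seed = sample.int(.Machine$integer.max, 1))
        latent <- if (strain == "control") {
          sample(latent_names, n_cells, replace = TRUE, prob = probs)
        } else {
          post$latent_cluster[sample.int(nrow(post), n_cells)]
        }
        prefix <- if (strain == "control") "c" else "h"
        ids <- sprintf("%s%s_%02d", prefix, gsub("-", "", ct),
                       seq_len(n_cells))
        rows[[key]] <- data.frame(
          cell_id = ids, cell_type = ct, strain = strain,
          well_file = paste0("traces/", ids, ".tsv"),
          true_ocr = ocr, latent_cluster = latent,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })

  trace_seeds <- with_seed_checked(seed + 1L,
    sample.int(.Machine$integer.max, nrow(manifest)))
  traces <- lapply(seq_len(nrow(manifest)), function(i) {
    simulate_sensor_trace(manifest$true_ocr[i], geom = config$geom,
                          sensor = config$sensor, duration = config$duration,
                          dt = config$dt, seed = trace_seeds[i],
                          cell_id = manifest$cell_id[i])
  })
  names(traces) <- manifest$cell_id

  expression <- simulate_expression_matrix(design, manifest, seed = seed + 2L)

  study <- list(manifest = manifest, traces = traces,
                expression = expression, config = config, design = design)
  if (!is.null(out_dir)) write_study(study, out_dir)
  invisible(study)
}
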