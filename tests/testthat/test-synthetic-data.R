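test_that("OCR population mixture honors its degenerate and sampling limits", {
  all_zero <- ocr_population_model(nonrespirer_fraction = 1)
  expect_identical(simulate_ocr_population(all_zero, 10, seed = 1), rep(0, 10))

  point_mass <- ocr_population_model(nonrespirer_fraction = 0, log_sd = 0)
  draws <- simulate_ocr_population(point_mass, 10000, seed = 2)
  expect_true(all(abs(draws - exp(point_mass$log_mean)) < 1e-12))

  mixed <- ocr_population_model(nonrespirer_fraction = 0.25)
  draws <- simulate_ocr_population(mixed, 10000, seed = 3)
  zero_frac <- mean(draws == 0)
  binom_sd <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(zero_frac - 0.25), 3 * binom_sd)
  expect_true(all(draws >= 0))

  expect_error(ocr_population_model(nonrespirer_fraction = 1.2),
               class = "picoresp_config_error")
})

test_that("sensor traces follow the closed-form depletion kinetics", {
  s <- noiseless_setup()

  quiet <- simulate_sensor_trace(0, s$geom, s$sensor, duration = 20,
                                 dt = 1, seed = 1)
  expect_equal(diff(range(quiet$sensor)), 0)
  expect_equal(diff(range(quiet$reference)), 0)

  tr <- simulate_sensor_trace(1, s$geom, s$sensor, duration = 20,
                              dt = 1, seed = 1)
  conc <- attr(tr, "true_concentration")
  # dC/dt = -ocr / (V * ku) = -1 / 0.14 uM/min until the floor
  expect_equal(diff(conc[1:2]), -1 / (140 * 1e-3))
  expect_equal(conc[1], 200)

  # Round trip through the Stern-Volmer inverse is exact at zero noise.
  recovered <- calibrate(ratiometric_normalize(tr), s$cal)
  expect_equal(as.numeric(recovered), conc, tolerance = 1e-12)
})

test_that("noiseless drawdowns deplete monotonically and brighten the ratio", {
  s <- noiseless_setup()
  for (ocr in c(0.2, 1, 3, 6)) {
    tr <- simulate_sensor_trace(ocr, s$geom, s$sensor, duration = 40,
                                dt = 0.5, seed = 1)
    conc <- attr(tr, "true_concentration")
    expect_true(all(diff(conc) <= 1e-12))
    expect_true(all(conc >= 0))
    expect_true(all(diff(ratiometric_normalize(tr)) >= -1e-12))
  }
})

test_that("expression simulator reproduces centroids and dropout contracts", {
  design <- default_expression_design(n_latent = 2, seed = 5,
                                      within_cluster_sd = 1)
  manifest <- data.frame(cell_id = c("a", "b", "c"),
                         latent_cluster = c("L1", "L2", "L1"))

  exact <- expression_design(design$cluster_centroids,
                             gene_categories = design$gene_categories,
                             within_cluster_sd = 0,
                             dropout_prob_per_gene = 0,
                             housekeeping_genes = character())
  sim <- simulate_expression_matrix(exact, manifest, seed = 1)
  expect_equal(sim$values[, "a"], design$cluster_centroids["L1", ])
  expect_equal(sim$values[, "b"], design$cluster_centroids["L2", ])
  expect_false(any(sim$mask))

  all_drop <- expression_design(design$cluster_centroids,
                                within_cluster_sd = 0,
                                dropout_prob_per_gene = 1,
                                housekeeping_genes = character())
  sim <- simulate_expression_matrix(all_drop, manifest, seed = 1)
  expect_true(all(sim$mask))
  expect_true(all(is.na(sim$values)))

  expect_error(
    simulate_expression_matrix(exact,
                               data.frame(cell_id = "x",
                                          latent_cluster = "L9"),
                               seed = 1),
    class = "picoresp_config_error")
})

test_that("well-separated latent clusters are recoverable from the simulation", {
  design <- default_expression_design(n_latent = 2, separation = 6, seed = 7,
                                      within_cluster_sd = 0.5,
                                      dropout_prob_per_gene = 0)
  manifest <- data.frame(
    cell_id = sprintf("c%02d", 1:30),
    latent_cluster = rep(c("L1", "L2"), each = 15))
  sim <- simulate_expression_matrix(design, manifest, seed = 9)
  cl <- hierarchical_cluster(sim$values, k = 2)
  tab <- table(cl$labels, manifest$latent_cluster)
  # column totals are 15/15, so a max-agreement sum of 30 means 0 errors
  expect_equal(sum(apply(tab, 1, max)), 30)
})

test_that("bottleneck selection conserves counts and responds to heritability", {
  base <- withr::with_seed(31, rnorm(1000))

  cfg <- selection_config(n_rounds = 3, survival_fraction = 0.10,
                          heritability = 0.5)
  post <- simulate_hypoxia_selection(base, cfg, seed = 4)
  expect_equal(nrow(post), 1000)

  # h = 1, trait = -OCR: strict directional response after 6 rounds.
  ocr <- withr::with_seed(32, rlnorm(1000, log(2.5), 0.6))
  pop <- data.frame(trait = -ocr, ocr = ocr)
  post <- simulate_hypoxia_selection(
    pop, selection_config(heritability = 1), seed = 5)
  expect_lt(mean(post$ocr), mean(ocr))
  expect_lt(mean(-post$trait), mean(ocr))

  # h = 0: latent-cluster proportions survive selection. Each 10% bottleneck
  # and re-expansion resamples the labels, so the null SD compounds over
  # rounds: var ~ n_rounds * p(1-p) * (1/n_surv + 1/N).
  pop <- data.frame(trait = base,
                    latent_cluster = rep(c("L1", "L2"), c(300, 700)))
  cfg0 <- selection_config(heritability = 0)
  post <- simulate_hypoxia_selection(pop, cfg0, seed = 6)
  prop <- mean(post$latent_cluster == "L1")
  drift_sd <- sqrt(cfg0$n_rounds * 0.3 * 0.7 * (1 / 100 + 1 / 1000))
  expect_lt(abs(prop - 0.3), 3 * drift_sd)

  expect_error(
    simulate_hypoxia_selection(rnorm(5),
                               selection_config(survival_fraction = 0.05),
                               seed = 1),
    class = "picoresp_data_error")
})

test_that("generated studies match the design bounds and are deterministic", {
  dir <- study_dir_cached()
  manifest <- read_manifest(file.path(dir, "manifest.json"))

  expect_false(anyDuplicated(manifest$cell_id) > 0)
  expect_gte(nrow(manifest), 160)
  expect_lte(nrow(manifest), 192)
  counts <- table(manifest$strain, manifest$cell_type)
  expect_true(all(counts >= 20 & counts <= 24))

  # Control CP-A mirrors the strain in which no non-respirers were seen.
  ccpa <- manifest[manifest$cell_type == "CP-A" &
                     manifest$strain == "control", ]
  expect_true(all(ccpa$true_ocr > 0))
  others <- manifest[!(manifest$cell_type == "CP-A" &
                         manifest$strain == "control"), ]
  expect_gt(sum(others$true_ocr == 0), 0)

  # Same seed twice: byte-identical artifacts.
  dir2 <- tempfile("study2")
  generate_study(seed = 2024, out_dir = dir2)
  files <- c("manifest.json", "expression_matrix.tsv",
             file.path("traces", paste0(manifest$cell_id[1:5], ".tsv")))
  for (f in files) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  }
  unlink(dir2, recursive = TRUE)
})
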