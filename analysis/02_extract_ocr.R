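#!/usr/bin/env Rscript
# Step 2: extract single-cell oxygen consumption rates from the sensor
# traces.
#
# Each well's two channels are self-reference normalized, inverted through
# the Stern-Volmer calibration, smoothed with the 5-point sliding average,
# and the pre-depletion concentration decline is fit by ordinary least
# squares; OCR = |slope| * V * ku. Cells below 0.1 fmol/min are classified
# non-respiring. Estimates are then compared against the simulator's truth.

library(picoresp)

study_dir <- "results/study"
manifest <- read_manifest(file.path(study_dir, "manifest.json"))
loaded <- read_traces(study_dir, manifest)
cat("read", length(loaded$traces), "traces,", nrow(loaded$qc), "failures\n")

sm <- sensor_model()
cal <- calibration_model(ksv = sm$ksv, i0 = sm$i0)
ocr <- extract_ocr_batch(loaded$traces, manifest, cal)

dir.create("results", showWarnings = FALSE)
write.table(ocr, "results/ocr_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- manifest$true_ocr[match(ocr$cell_id, manifest$cell_id)]
resp <- truth > 0
rel_err <- abs(ocr$ocr_fmol_min[resp] - truth[resp]) / truth[resp]
cat(sprintf("median relative OCR error over %d respiring cells: %.2f%%\n",
            sum(resp), 100 * median(rel_err)))
agreement <- mean((ocr$ocr_fmol_min == 0) == (truth == 0))
cat(sprintf("respirer classification agreement with truth: %.1f%%\n",
            100 * agreement))

cmp <- compare_groups(ocr)
write.table(cmp, "results/group_comparison.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\ncontrol vs hypoxia-resistant OCR means (Welch + rank tests, BH):\n")
print(cmp[, c("cell_type", "mean_control", "mean_hypoxia",
              "p_t_adj", "p_wilcox_adj")], digits = 3)
cat("as in the study this emulates, no pair differs significantly when the\n")
cat("strains share one generative distribution\n")
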