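#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Builds the three synthetic datasets the downstream stages consume:
#   (a) a patient-clustered 2-D embedding of tumor ductal cells
#       (10 patients x 100 cells, between_sd 5, within_sd 0.5),
#   (b) a single-cell expression matrix in which half the patients carry an
#       elevated glycolytic program (+3 on the log scale, 6 noise sd), and
#   (c) a bulk cohort of 300 samples whose tertile glycolytic group
#       multiplies an exponential survival hazard (High vs Low HR = 3),
#       administratively censored at 36 months.
# Everything is written as plain TSV under results/data/.

suppressPackageStartupMessages(library(glycostrat))

seed <- 20260927L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_patients = 10, cells_per_patient = 100, embed_dim = 2,
                  between_sd = 5, within_sd = 0.5, glyco_shift = 3,
                  n_genes = 200, noise_sd = 0.5, seed = seed)
sim <- gen_single_cell(cfg)

write_expression(sim$expr, "results/data/sc_expression.tsv")
write_table_tsv(sim$cells, "results/data/sc_cells.tsv")
write_table_tsv(data.frame(patient_id = names(sim$truth),
                           truth = unname(sim$truth)),
                "results/data/sc_truth.tsv")

co <- gen_cohort(cohort_sim_config(n_samples = 300,
                                   hazard_ratio_high_vs_low = 3,
                                   baseline_hazard = 0.03, censor_time = 36,
                                   seed = seed))
write_table_tsv(co, "results/data/cohort.tsv")

cat(sprintf("single-cell: %d genes x %d cells over %d patients (%d truth-high)\n",
            nrow(sim$expr), ncol(sim$expr), cfg$n_patients,
            sum(sim$truth == "high")))
cat(sprintf("cohort: %d samples, %d events before 36 months, groups %s\n",
            nrow(co), sum(co$event), paste(table(co$group), collapse = "/")))
cat("wrote results/data/{sc_expression,sc_cells,sc_truth,cohort}.tsv\n")
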