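#!/usr/bin/env Rscript

# Stage 0 of the synthetic study: generate every raw input the downstream
# analyses consume, with known ground truth.
#   - 8 two-channel micrographs (2 genotypes x 2 ages x 2 fields) as
#     plain-text PPM plus a ground-truth table
#   - one kinetic plate per genotype x age (3 inhibitor series + blanks,
#     3 technical replicates)
#   - a 540-protein label-free peptide table over the 2x2x5 design with a
#     Serpinb1a-like protein planted at 6-fold (3 months) and 7-fold
#     (7.5 months) in the dystrophic runs
# Everything is seeded; rerunning reproduces the files byte for byte.

suppressPackageStartupMessages(library(myoquant))

seed <- 20260918 %% 2147483647
data_dir <- file.path("results", "data")
for (d in c("images", "kinetics", "proteome"))
  dir.create(file.path(data_dir, d), recursive = TRUE, showWarnings = FALSE)

# --- micrographs -----------------------------------------------------------
# Dystrophic cultures differentiate poorly: fewer myotubes and fewer nuclei
# per myotube at 7.5 months than wild type.
scene_design <- expand.grid(field = 1:2,
                            genotype = c("WT", "Dys"),
                            age_group = c("3", "7.5"),
                            stringsAsFactors = FALSE)
scene_design$n_myotubes <- ifelse(scene_design$genotype == "WT", 4, 2)
scene_design$nuclei_per_myotube <- ifelse(scene_design$genotype == "WT", 4, 2)

truth_rows <- list()
for (i in seq_len(nrow(scene_design))) {
  sd_ <- scene_design[i, ]
  pars <- image_sim_params(n_nuclei = 40,
                           n_myotubes = sd_$n_myotubes,
                           nuclei_per_myotube = sd_$nuclei_per_myotube,
                           seed = seed + i)
  sc <- simulate_image(pars)
  name <- sprintf("scene_%s_%sm_f%d", sd_$genotype, sd_$age_group, sd_$field)
  write_image_pnm(sc$rgb, file.path(data_dir, "images",
                                    paste0(name, ".ppm")))
  tr <- sc$truth$true_indices
  truth_rows[[i]] <- data.frame(
    scene = name, genotype = sd_$genotype, age_group = sd_$age_group,
    field = sd_$field, seed = pars$seed,
    true_total_nuclei = tr$total_nuclei,
    true_differentiation_index = tr$differentiation_index,
    true_fusion_index = tr$fusion_index,
    true_myotube_count = tr$myotube_count,
    true_marker_area_px = tr$marker_area_px)
}
truth <- do.call(rbind, truth_rows)
write.csv(truth, file.path(data_dir, "images", "ground_truth.csv"),
          row.names = FALSE)
message(sprintf("wrote %d micrographs + ground truth under %s",
                nrow(truth), file.path(data_dir, "images")))

# --- kinetic plates --------------------------------------------------------
# Total protease activity and the elastase-attributable share both grow
# with disease progression: at 3 months the selective inhibitors remove
# little activity; at 7.5 months the dystrophic muscle loses the largest
# share to them. The broad cocktail always removes about half.
kin_design <- data.frame(
  condition = c("WT_3m", "Dys_3m", "WT_7.5m", "Dys_7.5m"),
  rate = c(1.5, 1.6, 2.0, 3.0),
  f_cocktail = 0.5,
  f_sivelestat = c(0.08, 0.10, 0.20, 0.35),
  f_elastatinal = c(0.08, 0.10, 0.18, 0.30))
for (i in seq_len(nrow(kin_design))) {
  kd <- kin_design[i, ]
  pars <- kinetic_sim_params(
    rate_uninhibited = kd$rate,
    inhibitors = c("cocktail", "sivelestat", "elastatinal"),
    inhibition_fraction = c(kd$f_cocktail, kd$f_sivelestat, kd$f_elastatinal),
    noise_sd = 2, condition = kd$condition, seed = seed + 100 + i)
  plate <- simulate_kinetics(pars)
  write.csv(plate, file.path(data_dir, "kinetics",
                             paste0("plate_", kd$condition, ".csv")),
            row.names = FALSE)
}
write.csv(kin_design, file.path(data_dir, "kinetics", "true_fractions.csv"),
          row.names = FALSE)
message(sprintf("wrote %d kinetic plates under %s",
                nrow(kin_design), file.path(data_dir, "kinetics")))

# --- peptide table ---------------------------------------------------------
serpin <- data.frame(protein = "P0001", age_group = c("3", "7.5"),
                     fold_change = c(6, 7))
sim <- simulate_peptide_table(proteome_sim_params(
  n_proteins = 540, differential_spec = serpin,
  run_scale_factors = NULL, seed = seed + 200))
write.csv(sim$peptides, file.path(data_dir, "proteome", "peptides.csv"),
          row.names = FALSE)
write.csv(sim$design, file.path(data_dir, "proteome", "run_design.csv"),
          row.names = FALSE)
write.csv(serpin, file.path(data_dir, "proteome", "true_differential.csv"),
          row.names = FALSE)
message(sprintf("wrote peptide table (%d rows, %d runs) under %s",
                nrow(sim$peptides), nrow(sim$design),
                file.path(data_dir, "proteome")))
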