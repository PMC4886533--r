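#!/usr/bin/env Rscript

# Stage 3: label-free differential abundance. Peptides outside charge
# 2+..7+ are discarded, runs are normalised by median log-ratio to the most
# complete run, proteins are quantified as the sum of their unique peptide
# abundances, replicate correlations are checked, and a per-age two-group
# ANOVA (WT vs Dys, log scale) with Bonferroni correction classifies each
# protein as non-significant, moderate (p < 0.05) or strong (q < 0.05).

suppressPackageStartupMessages(library(myoquant))

data_dir <- file.path("results", "data", "proteome")
peptides <- read.csv(file.path(data_dir, "peptides.csv"))
design <- read.csv(file.path(data_dir, "run_design.csv"),
                   colClasses = c(age_group = "character"))
planted <- read.csv(file.path(data_dir, "true_differential.csv"),
                    colClasses = c(age_group = "character"))

pep <- filter_peptides(peptides)
message(sprintf("charge filter: %d of %d peptide rows removed",
                attr(pep, "n_removed"), nrow(peptides)))
pep <- normalize_runs(pep, design)
message(sprintf("normalisation: reference %s, scale factors in [%.3f, %.3f]",
                attr(pep, "reference_run"),
                min(attr(pep, "scale_factors")),
                max(attr(pep, "scale_factors"))))
mat <- rollup_proteins(pep, design)
message(sprintf("rollup: %d proteins x %d runs (%d shared peptide rows excluded, %d proteins without unique peptides)",
                nrow(mat), ncol(mat), attr(mat, "n_shared_excluded"),
                length(attr(mat, "excluded_proteins"))))
write.csv(data.frame(protein = rownames(mat), mat, check.names = FALSE,
                     row.names = NULL),
          "results/protein_matrix.csv", row.names = FALSE)

qc <- replicate_correlation(mat, design)
write.csv(qc$pairs, "results/replicate_correlation.csv", row.names = FALSE)
message(sprintf("replicate QC: mean R^2 within groups %.3f, between genotypes %.3f",
                qc$within_group_mean_r2, qc$between_genotype_mean_r2))

res <- rbind(differential_test(mat, design, "3"),
             differential_test(mat, design, "7.5"))
write.csv(res, "results/differential_results.csv", row.names = FALSE)
summ <- significance_summary(res)
write.csv(summ, "results/significance_summary.csv", row.names = FALSE)

for (a in c("3", "7.5")) {
  ra <- res[res$age_group == a, ]
  ra <- ra[order(ra$q_value, ra$p_value), ]
  sa <- summ[summ$age_group == a, ]
  tf <- planted$fold_change[planted$age_group == a]
  message(sprintf("%s months: %d tested, %d at p<0.05, %d at q<0.05",
                  a, sa$n_tested, sa$n_moderate, sa$n_strong))
  message(sprintf("  top by q: %s, fold %.2f (planted %s at %.0f-fold), q = %.2e",
                  ra$protein[1], ra$fold_change[1], planted$protein[1], tf,
                  ra$q_value[1]))
}
message("wrote results/{protein_matrix,replicate_correlation,differential_results,significance_summary}.csv")
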