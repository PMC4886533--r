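#!/usr/bin/env Rscript

# Stage 2: the fluorogenic elastase assay analysis. Each plate is blank
# subtracted (sample minus buffer+substrate blank), technical replicates
# are averaged, and the inhibitor-sensitive fraction -- the product curve
# attributable to the inhibited enzyme -- is extracted from the averaged
# curves, together with least-squares rates and percent inhibition.

suppressPackageStartupMessages(library(myoquant))

data_dir <- file.path("results", "data", "kinetics")
plates <- list.files(data_dir, pattern = "^plate_.*\\.csv$", full.names = TRUE)
truth <- read.csv(file.path(data_dir, "true_fractions.csv"))

curves <- list()
sens <- list()
rates <- list()
for (f in plates) {
  res <- process_plate(read.csv(f))
  curves[[f]] <- res$curves
  sens[[f]] <- res$sensitive
  rates[[f]] <- res$rates
}
curves <- do.call(rbind, c(curves, make.row.names = FALSE))
sens <- do.call(rbind, c(sens, make.row.names = FALSE))
rates <- do.call(rbind, c(rates, make.row.names = FALSE))
write.csv(curves, "results/kinetics_curves.csv", row.names = FALSE)
write.csv(sens, "results/kinetics_sensitive_fraction.csv", row.names = FALSE)
write.csv(rates, "results/kinetics_rates.csv", row.names = FALSE)

message(sprintf("processed %d plates (%d activity curves)",
                length(plates), nrow(unique(curves[c("condition",
                                                     "inhibitor")]))))
message("percent inhibition (estimated vs generative):")
for (i in seq_len(nrow(rates))) {
  true_f <- truth[truth$condition == rates$condition[i],
                  paste0("f_", rates$inhibitor[i])]
  message(sprintf("  %-9s %-11s %.3f +/- %.3f (true %.2f)",
                  rates$condition[i], rates$inhibitor[i],
                  rates$percent_inhibition[i], rates$se[i], true_f))
}
# the elastase-attributable product at the end of the assay, per condition
end_sens <- sens[sens$time_min == max(sens$time_min) &
                   sens$inhibitor != "cocktail", ]
agg <- aggregate(sensitive_product ~ condition, end_sens, mean)
message("mean selective-inhibitor-sensitive product at 180 min:")
for (i in seq_len(nrow(agg)))
  message(sprintf("  %-9s %.1f AU", agg$condition[i],
                  agg$sensitive_product[i]))
message("wrote results/kinetics_{curves,sensitive_fraction,rates}.csv")
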