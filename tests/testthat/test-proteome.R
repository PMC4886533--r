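small_table <- function() {
  data.frame(
    peptide = c("A", "B", "C", "D", "E"),
    charge = c(1, 2, 7, 8, 3),
    accessions = c("P1", "P1", "P1", "P1", "P1;P2"),
    run_id = "r1",
    abundance = c(10, 100, 200, 10, 50))
}

test_that("charge filter keeps 2+..7+ and logs removals", {
  out <- filter_peptides(small_table())
  expect_setequal(out$peptide, c("B", "C", "E"))
  expect_identical(attr(out, "n_removed"), 2L)
  expect_error(filter_peptides(data.frame(x = 1)), "schema")
})

test_that("normalisation: identical runs give unit factors; a doubled run is halved", {
  base <- data.frame(peptide = sprintf("p%d", 1:20), charge = 2,
                     accessions = sprintf("P%d", 1:20))
  tab <- rbind(transform(base, run_id = "r1", abundance = 100 + 1:20),
               transform(base, run_id = "r2", abundance = 100 + 1:20),
               transform(base, run_id = "r3", abundance = 2 * (100 + 1:20)))
  out <- normalize_runs(tab)
  f <- attr(out, "scale_factors")
  expect_equal(unname(f[c("r1", "r2")]), c(1, 1))
  expect_equal(unname(f["r3"]), 0.5)
  # after normalisation all runs coincide
  expect_equal(out$abundance[out$run_id == "r3"],
               out$abundance[out$run_id == "r1"])
  expect_error(normalize_runs(tab[tab$run_id == "r1", ]), "at least 2 runs")
})

test_that("normalisation is idempotent and recovers planted run biases", {
  sim <- simulate_peptide_table(proteome_sim_params(
    n_proteins = 120, missing_rate = 0.1,
    run_scale_factors = rep(c(1, 2, 0.5, 1.5), 5), seed = 8))
  pep <- filter_peptides(sim$peptides)
  n1 <- normalize_runs(pep, sim$design)
  n2 <- normalize_runs(n1, sim$design)
  expect_equal(n1$abundance, n2$abundance, tolerance = 1e-12)
  # recovered factor inversely proportional to the planted bias
  f <- attr(n1, "scale_factors")
  planted <- sim$truth$run_scale_factors[names(f)]
  rel <- f * planted  # should be constant across runs
  expect_lte(diff(range(rel / mean(rel))), 0.1)  # within 5% of each other
})

test_that("unique-peptide rollup sums, excludes shared peptides, conserves totals", {
  tab <- data.frame(
    peptide = c("a", "b", "c", "s", "a", "b", "c"),
    charge = 2,
    accessions = c("P", "P", "P", "P;Q", "P", "P", "P"),
    run_id = c(rep("r1", 4), rep("r2", 3)),
    abundance = c(100, 200, 300, 999, 10, 20, 30))
  mat <- rollup_proteins(tab)
  expect_identical(dim(mat), c(1L, 2L))
  expect_equal(mat["P", "r1"], 600)
  expect_equal(mat["P", "r2"], 60)
  expect_identical(attr(mat, "n_shared_excluded"), 1L)
  expect_identical(attr(mat, "excluded_proteins"), "Q")
  # conservation: total matrix abundance = total unique retained abundance
  expect_equal(sum(mat), sum(tab$abundance[!grepl(";", tab$accessions)]))
  expect_error(rollup_proteins(tab[0, ]), "empty")
  expect_error(rollup_proteins(tab[tab$peptide == "s", ]), "no unique")
})

test_that("replicate correlation: self-pair R2 = 1, grouping logic, flags", {
  mat <- matrix(exp(rnorm(40, 10)), 10, 4,
                dimnames = list(sprintf("P%d", 1:10),
                                c("WT_3m_R1", "WT_3m_R2",
                                  "Dys_3m_R1", "Dys_3m_R2")))
  mat[, 2] <- mat[, 1]  # duplicate run
  design <- data.frame(run_id = colnames(mat),
                       genotype = c("WT", "WT", "Dys", "Dys"),
                       age_group = "3", replicate = c(1, 2, 1, 2))
  qc <- replicate_correlation(mat, design)
  pair12 <- qc$pairs[qc$pairs$run_a == "WT_3m_R1" &
                       qc$pairs$run_b == "WT_3m_R2", ]
  expect_equal(pair12$r_squared, 1)
  expect_identical(pair12$comparison, "within_group")
  expect_identical(
    qc$pairs$comparison[qc$pairs$run_a == "WT_3m_R1" &
                          qc$pairs$run_b == "Dys_3m_R1"],
    "between_genotype")
  # a pair sharing < 3 nonzero proteins is flagged
  mat2 <- mat
  mat2[3:10, 4] <- 0
  qc2 <- replicate_correlation(mat2, design)
  expect_true(any(qc2$pairs$flagged))
})

test_that("low-noise generator reproduces the printed QC behaviour", {
  ds <- data.frame(protein = sprintf("P%04d", 1:50), age_group = "3",
                   fold_change = 4)
  sim <- simulate_peptide_table(proteome_sim_params(
    n_proteins = 300, abundance_cv = 0.05, differential_spec = ds, seed = 31))
  mat <- rollup_proteins(filter_peptides(sim$peptides), sim$design)
  qc <- replicate_correlation(mat, sim$design)
  expect_gt(qc$within_group_mean_r2, 0.98)
  expect_lt(qc$between_genotype_mean_r2, qc$within_group_mean_r2)
})

test_that("two-group ANOVA: null identity, Bonferroni arithmetic, tiers", {
  mat <- matrix(rep(c(5, 5, 5, 5, 8, 8, 8, 8), 3), 3, 8, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), sprintf("r%d", 1:8)))
  design <- data.frame(run_id = sprintf("r%d", 1:8),
                       genotype = rep(c("WT", "Dys"), each = 4),
                       age_group = "3", replicate = rep(1:4, 2))
  # identical groups per protein -> F = 0 handled via equal means
  mat_eq <- matrix(rep(c(5, 6, 7, 8), 6), 3, 8, byrow = TRUE,
                   dimnames = dimnames(mat))
  res <- differential_test(mat_eq, design, "3")
  expect_equal(res$p_value, rep(1, 3))
  expect_equal(res$fold_change, rep(1, 3))
  expect_true(all(res$tier == "none"))
  # zero variance with unequal means: smallest representable p, flagged
  res2 <- differential_test(mat, design, "3")
  expect_true(all(res2$flag == "zero_variance"))
  expect_true(all(res2$p_value == .Machine$double.xmin))
  # Bonferroni arithmetic: p = 1e-4 with m = 540 -> q = 0.054, moderate
  expect_equal(min(1, 1e-4 * 540), 0.054)
  p <- c(1e-4, rep(0.5, 539))
  q <- pmin(1, p * 540)
  expect_equal(q[1], 0.054)
  tier <- ifelse(q < 0.05, "strong", ifelse(p < 0.05, "moderate", "none"))
  expect_identical(tier[1], "moderate")
})

test_that("ANOVA p matches the closed-form oracle and permutation ranking", {
  design <- data.frame(run_id = sprintf("r%d", 1:6),
                       genotype = rep(c("WT", "Dys"), each = 3),
                       age_group = "3", replicate = rep(1:3, 2))
  # printed-style worked groups (log-scale values)
  worked <- exp(c(1.0, 1.2, 0.9, 2.0, 2.2, 1.9))
  set.seed(12)
  mats <- c(list(worked), lapply(1:8, function(i) exp(rnorm(6, 1, 0.5))))
  p_pkg <- numeric(length(mats))
  p_oracle <- numeric(length(mats))
  p_perm <- numeric(length(mats))
  for (i in seq_along(mats)) {
    m <- matrix(mats[[i]], 1, 6, dimnames = list("P", design$run_id))
    res <- differential_test(m, design, "3")
    p_pkg[i] <- res$p_value
    p_oracle[i] <- oracle_anova_p(log(mats[[i]]), design$genotype)
    p_perm[i] <- oracle_permutation_p(log(mats[[i]]), design$genotype)
  }
  expect_equal(p_pkg, p_oracle, tolerance = 1e-10)
  # within a dataset, the permutation distribution of F ranks every label
  # assignment exactly as the parametric p does
  labs <- utils::combn(6, 3)
  fp <- apply(labs, 2, function(i) {
    g <- rep("b", 6)
    g[i] <- "a"
    a <- stats::anova(stats::lm(log(worked) ~ factor(g)))
    c(f = a[["F value"]][1], p = a[["Pr(>F)"]][1])
  })
  expect_true(all(diff(fp["p", order(-fp["f", ])]) >= -1e-12))
  # the well-separated worked groups sit at the permutation extreme (2/20:
  # the observed labelling and its mirror)
  expect_equal(p_perm[1], 2 / 20)
  expect_lt(p_pkg[1], 0.01)
})

test_that("significance summary counts tiers and directions", {
  res <- data.frame(protein = sprintf("P%d", 1:6), age_group = "3",
                    fold_change = c(6, 0.2, 3, 1.5, 0.9, 1.1),
                    p_value = c(1e-6, 1e-4, 0.01, 0.2, 0.9, 1),
                    q_value = c(6e-4, 0.06, 1, 1, 1, 1),
                    tier = c("strong", "moderate", "moderate",
                             "none", "none", "none"),
                    flag = NA_character_)
  s <- significance_summary(res)
  expect_identical(s$n_moderate, 3L)
  expect_identical(s$n_strong, 1L)
  expect_identical(s$n_increased, 2L)
  expect_identical(s$n_decreased, 1L)
  # all-null input: zero in both tiers
  res$p_value <- 1
  res$q_value <- 1
  s0 <- significance_summary(res)
  expect_identical(s0$n_moderate, 0L)
  expect_identical(s0$n_strong, 0L)
})

test_that("q >= p, q <= 1 and tier monotone in p on simulated data", {
  ds <- data.frame(protein = "P0001", age_group = "3", fold_change = 6)
  sim <- simulate_peptide_table(proteome_sim_params(
    n_proteins = 200, differential_spec = ds, seed = 77))
  mat <- rollup_proteins(normalize_runs(filter_peptides(sim$peptides),
                                        sim$design), sim$design)
  res <- differential_test(mat, sim$design, "3")
  expect_true(all(res$q_value >= res$p_value))
  expect_true(all(res$q_value <= 1))
  o <- order(res$p_value)
  lvl <- c(strong = 1, moderate = 2, none = 3)
  expect_true(all(diff(lvl[res$tier[o]]) >= 0))
})

test_that("two-way model option reports a genotype main effect", {
  ds <- data.frame(protein = "P0001", age_group = c("3", "7.5"),
                   fold_change = c(6, 7))
  sim <- simulate_peptide_table(proteome_sim_params(
    n_proteins = 40, differential_spec = ds, seed = 5))
  mat <- rollup_proteins(filter_peptides(sim$peptides), sim$design)
  res <- differential_test(mat, sim$design, "3", model = "two_way")
  expect_identical(res$protein[which.min(res$q_value)], "P0001")
  expect_true(all(res$q_value >= res$p_value))
})
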