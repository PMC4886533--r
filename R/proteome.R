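#' Retain peptide features by charge state
#'
#' Keeps peptide rows with charge in `charge_range` (default 2+..7+, the
#' retention rule of the label-free processing); removals are counted in
#' the `"n_removed"` attribute.
#'
#' @param peptides data.frame with a `charge` column.
#' @param charge_range inclusive `c(low, high)`.
#' @return filtered data.frame with attribute `n_removed`.
#' @export
filter_peptides <- function(peptides, charge_range = c(2, 7)) {
  if (!"charge" %in% names(peptides))
    stop("filter_peptides: schema error, no 'charge' column")
  keep <- peptides$charge >= charge_range[1] &
    peptides$charge <= charge_range[2]
  out <- peptides[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Median-log-ratio normalisation across runs
#'
#' Makes runs comparable by scaling each run so that its median log-ratio
#' to a reference run (the run with the most measured features) is zero,
#' computed over features present in both runs. Applying it twice is a
#' no-op (idempotent).
#'
#' @param peptides data.frame with `peptide`, `run_id`, `abundance`.
#' @param design optional design data.frame fixing the run order.
#' @return data.frame with scaled `abundance`; attributes `scale_factors`
#'   (named numeric) and `reference_run`.
#' @export
normalize_runs <- function(peptides, design = NULL) {
  need <- c("peptide", "run_id", "abundance")
  if (!all(need %in% names(peptides)))
    stop("normalize_runs: schema error, need columns ",
         paste(need, collapse = ", "))
  runs <- if (!is.null(design)) design$run_id else unique(peptides$run_id)
  if (length(runs) < 2) stop("normalize_runs: need at least 2 runs")
  peps <- unique(peptides$peptide)
  m <- matrix(NA_real_, length(peps), length(runs),
              dimnames = list(peps, runs))
  m[cbind(match(peptides$peptide, peps),
          match(peptides$run_id, runs))] <- peptides$abundance
  ref <- which.max(colSums(!is.na(m)))
  fac <- setNames(rep(1, length(runs)), runs)
  for (r in seq_along(runs)) {
    shared <- !is.na(m[, r]) & !is.na(m[, ref]) & m[, r] > 0 & m[, ref] > 0
    if (sum(shared) < 2)
      stop("normalize_runs: fewer than 2 features shared between run '",
           runs[r], "' and the reference")
    fac[r] <- exp(-median(log(m[shared, r] / m[shared, ref])))
  }
  out <- peptides
  out$abundance <- out$abundance * fac[match(out$run_id, runs)]
  attr(out, "scale_factors") <- fac
  attr(out, "reference_run") <- runs[ref]
  attr(out, "n_removed") <- attr(peptides, "n_removed")
  out
}

#' Unique-peptide protein rollup
#'
#' Protein abundance per run is the sum of the abundances of that protein's
#' *unique* peptides; peptides carrying more than one accession are excluded
#' from quantification entirely. Missing peptide measurements contribute 0
#' to the sum. Proteins mentioned only by shared peptides have no unique
#' peptides and are excluded (listed in the `"excluded_proteins"`
#' attribute).
#'
#' @param peptides normalised data.frame with `peptide`, `accessions`,
#'   `run_id`, `abundance`.
#' @param design optional design data.frame fixing the run (column) order.
#' @return numeric matrix proteins x runs with attributes
#'   `n_shared_excluded` and `excluded_proteins`.
#' @export
rollup_proteins <- function(peptides, design = NULL) {
  need <- c("peptide", "accessions", "run_id", "abundance")
  if (!all(need %in% names(peptides)))
    stop("rollup_proteins: schema error, need columns ",
         paste(need, collapse = ", "))
  if (nrow(peptides) == 0)
    stop("rollup_proteins: empty peptide table")
  shared <- grepl(";", peptides$accessions, fixed = TRUE)
  uniq <- peptides[!shared, , drop = FALSE]
  if (nrow(uniq) == 0)
    stop("rollup_proteins: no unique peptides for any protein")
  runs <- if (!is.null(design)) design$run_id else unique(peptides$run_id)
  prots <- sort(unique(uniq$accessions))
  mat <- matrix(0, length(prots), length(runs),
                dimnames = list(prots, runs))
  sums <- rowsum(uniq$abundance,
                 paste(uniq$accessions, uniq$run_id, sep = "\r"))
  key <- strsplit(rownames(sums), "\r", fixed = TRUE)
  pk <- vapply(key, `[`, "", 1)
  rk <- vapply(key, `[`, "", 2)
  ok <- rk %in% runs
  mat[cbind(match(pk[ok], prots), match(rk[ok], runs))] <- sums[ok, 1]
  mentioned <- unique(unlist(strsplit(peptides$accessions, ";", fixed = TRUE)))
  attr(mat, "n_shared_excluded") <- sum(shared)
  attr(mat, "excluded_proteins") <- setdiff(mentioned, prots)
  mat
}

#' Replicate-correlation quality control
#'
#' Squared Pearson correlations of log-transformed protein abundances for
#' every pair of runs (zeros excluded pairwise), summarised as the mean R^2
#' within groups (same genotype and age) and between genotypes within the
#' same age -- the reproducibility check reported for the study (within
#' groups above 0.98, between genotypes 0.95-0.96).
#'
#' @param mat protein x run abundance matrix.
#' @param design data.frame with `run_id`, `genotype`, `age_group`.
#' @return list: `pairs` data.frame (`run_a`, `run_b`, `r_squared`,
#'   `n_shared`, `comparison`, `flagged`), `within_group_mean_r2`,
#'   `between_genotype_mean_r2`.
#' @export
replicate_correlation <- function(mat, design) {
  runs <- colnames(mat)
  stopifnot(all(runs %in% design$run_id), length(runs) >= 2)
  d <- design[match(runs, design$run_id), ]
  lg <- log(mat)
  lg[!is.finite(lg)] <- NA
  out <- list()
  k <- 0
  for (i in seq_along(runs)[-length(runs)]) {
    for (j in (i + 1):length(runs)) {
      ok <- !is.na(lg[, i]) & !is.na(lg[, j])
      n <- sum(ok)
      r2 <- if (n >= 3) stats::cor(lg[ok, i], lg[ok, j])^2 else NA_real_
      cmp <- if (d$age_group[i] != d$age_group[j]) "between_age"
      else if (d$genotype[i] == d$genotype[j]) "within_group"
      else "between_genotype"
      k <- k + 1
      out[[k]] <- data.frame(run_a = runs[i], run_b = runs[j],
                             r_squared = r2, n_shared = n,
                             comparison = cmp, flagged = n < 3)
    }
  }
  pairs <- do.call(rbind, out)
  good <- !pairs$flagged
  list(pairs = pairs,
       within_group_mean_r2 =
         mean(pairs$r_squared[good & pairs$comparison == "within_group"]),
       between_genotype_mean_r2 =
         mean(pairs$r_squared[good & pairs$comparison == "between_genotype"]))
}

#' Per-age two-group differential abundance test
#'
#' Within one age group, a one-way two-group ANOVA (WT vs Dys, equivalent
#' to the pooled-variance F test) is applied per protein on log-transformed
#' abundances; zeros are replaced by half the smallest positive abundance
#' before the log. The Bonferroni q-value is `min(1, p * m)` with `m` the
#' number of proteins actually tested. Fold change is the ratio of
#' linear-scale group means (Dys/WT). Significance tiers follow the study:
#' moderate for p < 0.05, strong for q < 0.05.
#'
#' Proteins that are zero in every run of the age group are excluded
#' (listed in the `"excluded_proteins"` attribute). Zero within-group
#' variance with unequal means yields the smallest representable p,
#' flagged `"zero_variance"`.
#'
#' @param mat protein x run abundance matrix from [rollup_proteins()].
#' @param design data.frame with `run_id`, `genotype`, `age_group`.
#' @param age_group which age group to test (e.g. `"3"` or `"7.5"`).
#' @param model `"per_age"` (default) or `"two_way"` (genotype main effect
#'   from a two-way genotype x age ANOVA over all runs).
#' @return data.frame `protein`, `age_group`, `fold_change`, `p_value`,
#'   `q_value`, `tier`, `flag`; attribute `excluded_proteins`.
#' @export
differential_test <- function(mat, design, age_group,
                              model = c("per_age", "two_way")) {
  model <- match.arg(model)
  d <- design[match(colnames(mat), design$run_id), ]
  if (model == "two_way") return(differential_test_two_way(mat, d, age_group))
  keep <- d$age_group == age_group
  if (!any(keep)) stop("differential_test: no runs in age group ", age_group)
  X <- mat[, keep, drop = FALSE]
  g <- d$genotype[keep]
  n1 <- sum(g == "WT")
  n2 <- sum(g == "Dys")
  if (n1 < 2 || n2 < 2)
    stop("differential_test: need >= 2 replicates per genotype")
  allzero <- rowSums(X) == 0
  excluded <- rownames(X)[allzero]
  X <- X[!allzero, , drop = FALSE]
  if (nrow(X) == 0) stop("differential_test: no quantifiable proteins")
  pseudo <- min(X[X > 0]) / 2
  Xp <- X
  Xp[Xp == 0] <- pseudo
  L <- log(Xp)
  L1 <- L[, g == "WT", drop = FALSE]
  L2 <- L[, g == "Dys", drop = FALSE]
  m1 <- rowMeans(L1)
  m2 <- rowMeans(L2)
  ss <- rowSums((L1 - m1)^2) + rowSums((L2 - m2)^2)
  df2 <- n1 + n2 - 2
  sp2 <- ss / df2
  Fstat <- (m2 - m1)^2 / (sp2 * (1 / n1 + 1 / n2))
  p <- pf(Fstat, 1, df2, lower.tail = FALSE)
  flag <- rep(NA_character_, nrow(X))
  zv <- sp2 == 0
  p[zv & m1 == m2] <- 1
  if (any(zv & m1 != m2)) {
    p[zv & m1 != m2] <- .Machine$double.xmin
    flag[zv & m1 != m2] <- "zero_variance"
  }
  m <- nrow(X)
  q <- pmin(1, p * m)
  fold <- rowMeans(Xp[, g == "Dys", drop = FALSE]) /
    rowMeans(Xp[, g == "WT", drop = FALSE])
  tier <- ifelse(q < 0.05, "strong", ifelse(p < 0.05, "moderate", "none"))
  res <- data.frame(protein = rownames(X), age_group = age_group,
                    fold_change = unname(fold), p_value = unname(p),
                    q_value = unname(q), tier = tier, flag = flag,
                    row.names = NULL)
  attr(res, "excluded_proteins") <- excluded
  attr(res, "n_tested") <- m
  res
}

# genotype main effect from a two-way genotype x age ANOVA on all runs;
# fold change still reported within the requested age group
differential_test_two_way <- function(mat, d, age_group) {
  allzero <- rowSums(mat) == 0
  X <- mat[!allzero, , drop = FALSE]
  if (nrow(X) == 0) stop("differential_test: no quantifiable proteins")
  pseudo <- min(X[X > 0]) / 2
  Xp <- X
  Xp[Xp == 0] <- pseudo
  geno <- factor(d$genotype, levels = c("WT", "Dys"))
  age <- factor(d$age_group)
  p <- vapply(seq_len(nrow(Xp)), function(i) {
    a <- stats::anova(lm(log(Xp[i, ]) ~ geno * age))
    a["geno", "Pr(>F)"]
  }, numeric(1))
  m <- nrow(Xp)
  q <- pmin(1, p * m)
  in_age <- d$age_group == age_group
  fold <- rowMeans(Xp[, in_age & d$genotype == "Dys", drop = FALSE]) /
    rowMeans(Xp[, in_age & d$genotype == "WT", drop = FALSE])
  tier <- ifelse(q < 0.05, "strong", ifelse(p < 0.05, "moderate", "none"))
  res <- data.frame(protein = rownames(X), age_group = age_group,
                    fold_change = unname(fold), p_value = unname(p),
                    q_value = unname(q), tier = tier,
                    flag = NA_character_, row.names = NULL)
  attr(res, "excluded_proteins") <- rownames(mat)[allzero]
  attr(res, "n_tested") <- m
  res
}

#' Significance tier counts
#'
#' Counts of moderately (p < 0.05) and strongly (Bonferroni q < 0.05)
#' significant proteins per age group, with the increased/decreased
#' direction breakdown among the p < 0.05 set.
#'
#' @param results data.frame(s) from [differential_test()] (rbind-able).
#' @return data.frame per age group: `n_tested`, `n_moderate` (p < 0.05),
#'   `n_strong` (q < 0.05), `n_increased`, `n_decreased`.
#' @export
significance_summary <- function(results) {
  stopifnot(nrow(results) > 0)
  do.call(rbind, lapply(split(results, results$age_group), function(r) {
    sig <- r$p_value < 0.05
    data.frame(age_group = r$age_group[1],
               n_tested = nrow(r),
               n_moderate = sum(sig),
               n_strong = sum(r$q_value < 0.05),
               n_increased = sum(sig & r$fold_change > 1),
               n_decreased = sum(sig & r$fold_change < 1),
               row.names = NULL)
  }))
}
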