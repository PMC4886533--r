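#' Parameters for the synthetic label-free peptide table generator
#'
#' Emulates the peptide-level output of a label-free LC-MS experiment over
#' the 2x2 genotype (WT/Dys) by age (3/7.5 months) design with 4-5
#' biological replicates per cell. Peptide abundances are log-normal around
#' per-protein means (standard LC-MS error model); designated proteins are
#' scaled by a fold change in the Dys runs of one age group (e.g. a
#' Serpinb1a-like protein at ~6-fold and ~7-fold); a stated fraction of
#' peptides is shared between two proteins (flagged with both accessions,
#' so the unique-peptide rollup must drop them); charges are drawn from
#' 1..8 so the 2+..7+ retention filter is exercised; per-run multiplicative
#' biases exercise the normalisation.
#'
#' @param n_proteins number of proteins.
#' @param peptides_per_protein list `list(dist = "poisson", mean = 4)` or
#'   `list(dist = "fixed", n = k)`.
#' @param frac_shared_peptides fraction of peptides carrying a second
#'   protein accession.
#' @param n_replicates_per_group biological replicates per genotype x age.
#' @param genotypes,age_groups design factors.
#' @param differential_spec data.frame with columns `protein` (id such as
#'   "P0001"), `age_group`, `fold_change` (>0, Dys/WT).
#' @param abundance_cv coefficient of variation of replicate abundances.
#' @param missing_rate probability a peptide x run measurement is absent.
#' @param run_scale_factors optional named numeric of per-run multiplicative
#'   biases (default all 1).
#' @param seed integer RNG seed.
#' @return validated list of class `proteome_sim_params`.
#' @export
proteome_sim_params <- function(n_proteins = 540,
                                peptides_per_protein = list(dist = "poisson",
                                                            mean = 4),
                                frac_shared_peptides = 0.05,
                                n_replicates_per_group = 5,
                                genotypes = c("WT", "Dys"),
                                age_groups = c("3", "7.5"),
                                differential_spec = NULL,
                                abundance_cv = 0.2,
                                missing_rate = 0,
                                run_scale_factors = NULL,
                                seed = 1L) {
  if (is.null(differential_spec))
    differential_spec <- data.frame(protein = character(0),
                                    age_group = character(0),
                                    fold_change = numeric(0))
  p <- list(n_proteins = as.integer(n_proteins),
            peptides_per_protein = peptides_per_protein,
            frac_shared_peptides = frac_shared_peptides,
            n_replicates_per_group = as.integer(n_replicates_per_group),
            genotypes = genotypes, age_groups = age_groups,
            differential_spec = differential_spec,
            abundance_cv = abundance_cv, missing_rate = missing_rate,
            run_scale_factors = run_scale_factors,
            seed = as.integer(seed))
  stopifnot(p$n_proteins >= 1, p$n_replicates_per_group >= 2,
            p$frac_shared_peptides >= 0, p$frac_shared_peptides <= 1,
            p$abundance_cv >= 0, p$missing_rate >= 0, p$missing_rate <= 1,
            all(p$differential_spec$fold_change > 0))
  if (!all(p$differential_spec$age_group %in% p$age_groups))
    stop("proteome_sim_params: differential_spec age_group not in design")
  class(p) <- "proteome_sim_params"
  p
}

#' Simulate a label-free peptide abundance table
#'
#' @param params a `proteome_sim_params` object.
#' @return list with `peptides` (data.frame `peptide`, `charge`,
#'   `accessions` (";"-separated when shared), `run_id`, `abundance`),
#'   `design` (data.frame `run_id`, `genotype`, `age_group`, `replicate`),
#'   and `truth` (differential spec, per-protein log-means, peptide-protein
#'   assignment, run scale factors).
#' @export
simulate_peptide_table <- function(params = proteome_sim_params()) {
  stopifnot(inherits(params, "proteome_sim_params"))
  set.seed(params$seed)
  design <- expand.grid(replicate = seq_len(params$n_replicates_per_group),
                        genotype = params$genotypes,
                        age_group = params$age_groups,
                        stringsAsFactors = FALSE)
  design$run_id <- sprintf("%s_%sm_R%d", design$genotype, design$age_group,
                           design$replicate)
  design <- design[c("run_id", "genotype", "age_group", "replicate")]
  n_runs <- nrow(design)

  scale_f <- rep(1, n_runs)
  names(scale_f) <- design$run_id
  if (!is.null(params$run_scale_factors)) {
    rs <- params$run_scale_factors
    if (is.null(names(rs))) {
      scale_f[] <- rep_len(rs, n_runs)
    } else {
      scale_f[names(rs)] <- rs
    }
  }

  proteins <- sprintf("P%04d", seq_len(params$n_proteins))
  prot_meanlog <- rnorm(params$n_proteins, log(1e6), 1.5)

  ppp <- params$peptides_per_protein
  k <- switch(ppp$dist,
              fixed = rep(as.integer(ppp$n), params$n_proteins),
              poisson = pmax(1L, rpois(params$n_proteins, ppp$mean)),
              stop("peptides_per_protein: dist must be 'fixed' or 'poisson'"))
  n_pep <- sum(k)
  pep_protein <- rep(seq_len(params$n_proteins), k)
  pep_id <- sprintf("PEP%05d", seq_len(n_pep))
  pep_factor_log <- rnorm(n_pep, 0, 0.7)  # peptide ionisation efficiency
  charge <- sample(1:8, n_pep, replace = TRUE,
                   prob = c(.05, .40, .28, .15, .05, .03, .02, .02))
  accessions <- proteins[pep_protein]
  n_shared <- round(params$frac_shared_peptides * n_pep)
  shared_idx <- if (n_shared > 0) sample(n_pep, n_shared) else integer(0)
  if (length(shared_idx) > 0 && params$n_proteins > 1) {
    other <- vapply(pep_protein[shared_idx], function(pr)
      sample(setdiff(seq_len(params$n_proteins), pr), 1), integer(1))
    accessions[shared_idx] <- paste(accessions[shared_idx],
                                    proteins[other], sep = ";")
  }

  # per-protein, per-run fold multiplier (differential proteins in Dys runs
  # of the stated age group)
  log_fold <- matrix(0, params$n_proteins, n_runs)
  ds <- params$differential_spec
  for (i in seq_len(nrow(ds))) {
    pr <- match(ds$protein[i], proteins)
    if (is.na(pr)) stop("differential_spec: unknown protein ", ds$protein[i])
    cols <- design$genotype == "Dys" & design$age_group == ds$age_group[i]
    log_fold[pr, cols] <- log(ds$fold_change[i])
  }

  sdlog <- sqrt(log(1 + params$abundance_cv^2))
  pi_ <- rep(seq_len(n_pep), each = n_runs)
  ri <- rep(seq_len(n_runs), times = n_pep)
  logmu <- prot_meanlog[pep_protein[pi_]] + pep_factor_log[pi_] +
    log_fold[cbind(pep_protein[pi_], ri)] + log(scale_f[ri]) -
    sdlog^2 / 2  # mean-preserving log-normal noise
  abundance <- exp(logmu + rnorm(length(logmu), 0, sdlog))
  tab <- data.frame(peptide = pep_id[pi_], charge = charge[pi_],
                    accessions = accessions[pi_],
                    run_id = design$run_id[ri], abundance = abundance)
  if (params$missing_rate > 0)
    tab <- tab[runif(nrow(tab)) >= params$missing_rate, , drop = FALSE]
  rownames(tab) <- NULL

  list(peptides = tab, design = design,
       truth = list(differential_spec = ds,
                    protein_meanlog = setNames(prot_meanlog, proteins),
                    peptide_assignment = data.frame(peptide = pep_id,
                                                    protein = proteins[pep_protein],
                                                    charge = charge,
                                                    shared = seq_len(n_pep) %in%
                                                      shared_idx),
                    run_scale_factors = scale_f,
                    params = params))
}
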