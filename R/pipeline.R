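#' Pipeline configuration
#'
#' Bundles the per-stage parameter blocks of the synthetic study into one
#' validated configuration. Unknown keys (at the top level or inside a
#' stage block) are rejected by name; the resolved configuration is written
#' alongside every run's outputs.
#'
#' @param image list of overrides for [image_sim_params()] plus an optional
#'   `n_scenes` and a `quant` block of overrides for [image_config()].
#' @param kinetics list of overrides for [kinetic_sim_params()], optionally
#'   a `conditions` character vector (one simulated plate per condition).
#' @param proteome list of overrides for [proteome_sim_params()].
#' @param seed global integer seed, fanned out to stable per-stage seeds.
#' @param verbose print stage progress.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(image = list(), kinetics = list(),
                            proteome = list(), seed = 1L, verbose = FALSE) {
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad) > 0)
      stop("pipeline_config: unknown key(s) in ", where, ": ",
           paste(bad, collapse = ", "))
  }
  check_keys(image, c(names(formals(image_sim_params)), "n_scenes", "quant"),
             "image")
  check_keys(image$quant %||% list(), names(formals(image_config)),
             "image$quant")
  check_keys(kinetics, c(names(formals(kinetic_sim_params)), "conditions"),
             "kinetics")
  check_keys(proteome, names(formals(proteome_sim_params)), "proteome")
  structure(list(image = image, kinetics = kinetics, proteome = proteome,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable per-stage seed fan-out from the global seed (kept below 2^31)
stage_seed <- function(seed, stage) {
  offs <- c(image = 101L, kinetics = 211L, proteome = 307L)
  (as.integer(seed) * 7919L + offs[[stage]]) %% 2147483647L
}

#' Run the full synthetic study pipeline
#'
#' Simulates and analyses all three stages -- micrograph quantification,
#' elastase kinetics, and label-free differential abundance -- writing every
#' result as a UTF-8 CSV under `out_dir` together with the resolved
#' configuration and a manifest (file list with stage provenance and a
#' content hash). Identical configuration and seed produce byte-identical
#' output tables.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @return the manifest data.frame, invisibly; files written under
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message(...)
  files <- character(0)
  stages <- character(0)
  emit <- function(df, name, stage) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
    stages <<- c(stages, stage)
  }

  # --- stage 1: image quantification ------------------------------------
  say("stage image: simulating and quantifying scenes")
  img_over <- config$image
  n_scenes <- img_over$n_scenes %||% 5L
  quant_cfg <- do.call(image_config, img_over$quant %||% list())
  img_over$n_scenes <- NULL
  img_over$quant <- NULL
  img_rows <- lapply(seq_len(n_scenes), function(i) {
    pars <- do.call(image_sim_params, c(
      img_over, list(seed = stage_seed(config$seed, "image") + i)))
    sc <- simulate_image(pars)
    res <- quantify_image(sc$rgb, quant_cfg)
    tr <- sc$truth$true_indices
    data.frame(scene = i, seed = pars$seed,
               total_nuclei = res$total_nuclei,
               nuclei_in_marker = res$nuclei_in_marker,
               myotube_count = res$myotube_count,
               marker_area_px = res$marker_area_px,
               differentiation_index = res$differentiation_index,
               fusion_index = res$fusion_index,
               true_total_nuclei = tr$total_nuclei,
               true_differentiation_index = tr$differentiation_index,
               true_fusion_index = tr$fusion_index,
               threshold_nuclei = res$provenance$threshold_nuclei,
               threshold_marker = res$provenance$threshold_marker,
               n_large_removed = res$provenance$n_large_removed)
  })
  emit(do.call(rbind, img_rows), "image_quantification.csv", "image")

  # --- stage 2: elastase kinetics ---------------------------------------
  say("stage kinetics: simulating and processing plates")
  kin_over <- config$kinetics
  conds <- kin_over$conditions %||% "sample"
  kin_over$conditions <- NULL
  kin_curves <- list(); kin_sens <- list(); kin_rates <- list()
  for (ci in seq_along(conds)) {
    pars <- do.call(kinetic_sim_params, c(
      kin_over, list(condition = conds[ci],
                     seed = stage_seed(config$seed, "kinetics") + ci)))
    pl <- process_plate(simulate_kinetics(pars))
    kin_curves[[ci]] <- pl$curves
    kin_sens[[ci]] <- pl$sensitive
    kin_rates[[ci]] <- pl$rates
  }
  emit(do.call(rbind, kin_curves), "kinetics_curves.csv", "kinetics")
  if (!all(vapply(kin_sens, is.null, TRUE))) {
    emit(do.call(rbind, kin_sens), "kinetics_sensitive_fraction.csv",
         "kinetics")
    emit(do.call(rbind, kin_rates), "kinetics_rates.csv", "kinetics")
  }

  # --- stage 3: label-free proteomics -----------------------------------
  say("stage proteome: simulating and testing differential abundance")
  pars <- do.call(proteome_sim_params, c(
    config$proteome, list(seed = stage_seed(config$seed, "proteome"))))
  sim <- simulate_peptide_table(pars)
  pep <- filter_peptides(sim$peptides)
  pep <- normalize_runs(pep, sim$design)
  mat <- rollup_proteins(pep, sim$design)
  qc <- replicate_correlation(mat, sim$design)
  res <- do.call(rbind, lapply(pars$age_groups, function(a)
    differential_test(mat, sim$design, a)))
  emit(data.frame(protein = rownames(mat), mat, check.names = FALSE,
                  row.names = NULL), "protein_matrix.csv", "proteome")
  emit(qc$pairs, "replicate_correlation.csv", "proteome")
  emit(res, "differential_results.csv", "proteome")
  emit(significance_summary(res), "significance_summary.csv", "proteome")

  # --- resolved config + manifest ---------------------------------------
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  files <- c(files, "config.json")
  stages <- c(stages, "config")
  manifest <- data.frame(
    file = files, stage = stages,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    config_hash = digest_config(config))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# content hash of the resolved configuration (md5 of its serialised JSON)
digest_config <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}
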