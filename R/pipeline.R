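# End-to-end orchestration: synthetic study -> cohort FC -> per-cohort model
# inversion -> parameter contrasts -> feature-table statistics, with a
# manifest that ties outputs to the config and seeds. One base seed in the
# config drives every stage through fixed offsets.

#' Default pipeline configuration
#'
#' Returns the full configuration list understood by
#' [run_full_pipeline()]; override any element by passing a modified copy.
#' Seeds for the individual stages are derived from `seed` by fixed offsets.
#'
#' @param out_dir output directory.
#' @param seed base seed.
#' @return Named configuration list.
#' @export
default_pipeline_config <- function(out_dir = "rmfm_run", seed = 7) {
  list(
    out_dir = out_dir,
    seed = seed,
    connectome = list(n_regions = 40, n_networks = 4,
                      p_within = 0.6, p_between = 0.15, weight_scale = 2),
    truth = list(base_w = 0.9, base_I = 0.3, G = 0.115, sigma = 0.05),
    cohorts = list(n_subjects = 20, subject_noise_sd = 0.02,
                   duration_s = 550),
    fit = list(n_outer_iterations = 10, n_random_inits = 2,
               sim_duration_s = 500, jac_duration_s = 100,
               noise_realizations = 3, dt = 0.002,
               bounds = default_bounds()),
    features = list(effects = list(TLE = c(limbic = -1, somatomotor = -0.6),
                                   GE = c(default = -0.3)),
                    n_per_group = c(HC = 20, GE = 20, TLE = 20)),
    stats = list(terms = c("sex", "age"), n_perm = 1000)
  )
}

check_pipeline_config <- function(config) {
  need <- c("out_dir", "seed", "connectome", "truth", "cohorts", "fit",
            "features", "stats")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    stop("pipeline config missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$fit$bounds)) {
    stop("pipeline config missing field(s): fit$bounds", call. = FALSE)
  }
  invisible(config)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, in order: connectome and ground-truth synthesis, cohort FC
#' simulation, per-cohort model inversion, network-normalised parameter
#' contrasts (TLE vs GE and each vs HC), and feature-table group statistics
#' with permutation FWE control. All outputs are tab-separated or JSON files
#' under `config$out_dir`, listed in the returned manifest with md5 digests;
#' re-running with the same config reproduces them byte-identically.
#'
#' @param config configuration list from [default_pipeline_config()] (or a
#'   path to a JSON file holding one).
#' @param verbose print stage progress?
#' @return `run_manifest` list (also written to manifest.json).
#' @export
run_full_pipeline <- function(config = default_pipeline_config(),
                              verbose = TRUE) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  check_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed
  files <- character(0)

  # stage 1: connectome + ground truth -------------------------------------
  say("[synth] connectome (%d regions)", config$connectome$n_regions)
  syn <- make_synthetic_sc(n_regions = config$connectome$n_regions,
                           n_networks = config$connectome$n_networks,
                           p_within = config$connectome$p_within,
                           p_between = config$connectome$p_between,
                           weight_scale = config$connectome$weight_scale,
                           seed = seed)
  sc <- syn$sc; parc <- syn$parcellation
  specs <- default_cohorts(n_subjects = config$cohorts$n_subjects)
  specs <- lapply(specs, function(sp) {
    sp$w_shift <- sp$w_shift[names(sp$w_shift) %in% parc$network]
    sp$i_shift <- sp$i_shift[names(sp$i_shift) %in% parc$network]
    sp
  })
  truths <- lapply(specs, function(sp) {
    make_ground_truth(parc, sp, base_w = config$truth$base_w,
                      base_I = config$truth$base_I,
                      bounds = config$fit$bounds, seed = seed + 1)
  })
  write_parcellation(parc, out("parcellation.tsv"))
  write_matrix(sc, out("sc.tsv"))
  jsonlite::write_json(lapply(truths, function(tr) list(w = tr$w, I = tr$I)),
                       out("truth.json"), digits = NA, auto_unbox = TRUE)
  files <- c(files, "parcellation.tsv", "sc.tsv", "truth.json")

  # stage 2: cohort FC ------------------------------------------------------
  gstar <- mfm_global_params(G = config$truth$G, sigma = config$truth$sigma,
                             dt = config$fit$dt)
  group_fc <- list()
  for (grp in names(specs)) {
    say("[fc] cohort %s (%d subjects)", grp, specs[[grp]]$n_subjects)
    fcs <- generate_cohort_fc(sc, gstar, truths[[grp]],
                              n_subjects = specs[[grp]]$n_subjects,
                              subject_noise_sd = config$cohorts$subject_noise_sd,
                              seed = seed + 100 * match(grp, names(specs)),
                              duration_s = config$cohorts$duration_s)
    group_fc[[grp]] <- group_average_fc(fcs)
    write_matrix(group_fc[[grp]], out(paste0("fc_", grp, ".tsv")))
    files <- c(files, paste0("fc_", grp, ".tsv"))
  }

  # stage 3: model inversion per cohort -------------------------------------
  cfg <- standard_fit_config(base_seed = seed + 1000)
  for (fld in intersect(names(config$fit), names(cfg))) {
    cfg[[fld]] <- config$fit[[fld]]
  }
  fits <- list()
  for (grp in names(specs)) {
    say("[fit] cohort %s", grp)
    fits[[grp]] <- fit_rmfm(sc, group_fc[[grp]], cfg, verbose = verbose)
    jsonlite::write_json(
      list(group = grp, G = fits[[grp]]$params$G,
           sigma = fits[[grp]]$params$sigma, w = fits[[grp]]$params$w,
           I = fits[[grp]]$params$I,
           objective_trace = fits[[grp]]$objective_trace,
           best_similarity = fits[[grp]]$best_similarity,
           baseline = fits[[grp]]$baseline,
           converged = fits[[grp]]$converged),
      out(paste0("fit_", grp, ".json")), digits = NA, auto_unbox = TRUE)
    files <- c(files, paste0("fit_", grp, ".json"))
  }

  # stage 4: parameter contrasts --------------------------------------------
  pairs <- list(c("TLE", "GE"), c("TLE", "HC"), c("GE", "HC"))
  for (pr in pairs) {
    tab <- contrast_ready_params(fits[[pr[1]]], fits[[pr[2]]])
    tab$delta_w <- as.numeric(parameter_contrast(tab$w_a, tab$w_b,
                                                 tab$network))
    tab$delta_I <- as.numeric(parameter_contrast(tab$I_a, tab$I_b,
                                                 tab$network))
    fn <- paste0("params_", pr[1], "_vs_", pr[2], ".tsv")
    utils::write.table(tab, out(fn), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, fn)
  }

  # stage 5: feature-table statistics ---------------------------------------
  say("[stats] feature tables + permutation FWE")
  ft <- generate_feature_tables(parc, effects = config$features$effects,
                                n_per_group = config$features$n_per_group,
                                seed = seed + 2000)
  ft <- zscore_vs_controls(flip_to_ipsilateral(ft))
  for (pr in list(c("TLE", "GE"), c("TLE", "HC"), c("GE", "HC"))) {
    res <- permutation_fwe(ft, terms = config$stats$terms, contrast = pr,
                           n_perm = config$stats$n_perm, seed = seed + 3000)
    fn <- paste0("features_", pr[1], "_vs_", pr[2], ".tsv")
    utils::write.table(res, out(fn), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, fn)
  }

  # manifest -----------------------------------------------------------------
  cfg_path <- out("config.json")
  jsonlite::write_json(config, cfg_path, digits = NA, auto_unbox = TRUE)
  digests <- tools::md5sum(vapply(files, out, character(1)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("rmfm")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = setNames(unname(digests), files)
  )
  jsonlite::write_json(manifest, out("manifest.json"), digits = NA,
                       auto_unbox = TRUE)
  class(manifest) <- "run_manifest"
  manifest
}
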