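#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list) describing an end-to-end run:
#' simulation or input paths, QC thresholds, models, CV / MCMC / H-matrix
#' settings, winsorization percentile and the global seed. All violations
#' are collected and reported at once; defaults are filled in and echoed in
#' the returned object (and later into the run manifest).
#'
#' @param config path to a YAML file, or a named list.
#' @return A validated config list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      sp_stop(sprintf("config file not found: %s", config), "selfpred_io_error")
    config <- tryCatch(yaml::read_yaml(config), error = function(e)
      sp_stop(sprintf("cannot parse config: %s", conditionMessage(e)),
              "selfpred_parse_error"))
  }
  if (!is.list(config)) sp_stop("config must be a list", "selfpred_config_error")
  defaults <- list(
    outdir = "selfpred_run",
    seed = 1L,
    models = c("ablup", "gblup"),
    qc = list(maf_min = 0.05, callrate_min = 0.95, ind_missing_max = 0.95),
    cv = list(k = 10L, winsor_percentile = 0.05),
    mcmc = list(n_iter = 20000L, burn_in = 2000L, thin = 5L),
    relmat = list(blend = 0.05, tau = 1, omega = 1),
    ld = list(max_distance_bp = 1e6, bin_width_bp = 5e4, min_maf = 0.05),
    paternity = list(n_markers = 723L, error_rate = 0.05,
                     confidence_level = 0.80, n_replicates = 10000L),
    sim = list(),
    paths = list(),
    log_level = "info")
  cfg <- utils::modifyList(defaults, config)

  errors <- character(0)
  add <- function(msg) errors <<- c(errors, msg)
  valid_models <- c("ablup", "gblup", "gblup_ad", "hblup", "brr", "bayesa",
                    "bayesb", "bayesc", "bl")
  norm <- tryCatch(vapply(cfg$models, normalize_model_name, character(1)),
                   error = function(e) NULL)
  if (is.null(norm))
    add(sprintf("models: unknown name among [%s]; valid: %s",
                paste(cfg$models, collapse = ", "),
                paste(valid_models, collapse = ", ")))
  else cfg$models <- unname(norm)
  if (!is_count(cfg$cv$k)) add("cv.k: must be a count >= 1")
  if (!is.null(cfg$cv$winsor_percentile) &&
      !(cfg$cv$winsor_percentile > 0 && cfg$cv$winsor_percentile < 1))
    add("cv.winsor_percentile: must lie in (0, 1) or be null")
  if (!is_prob(cfg$qc$maf_min)) add("qc.maf_min: must be a probability")
  if (!is_prob(cfg$qc$callrate_min)) add("qc.callrate_min: must be a probability")
  if (!is_count(cfg$mcmc$n_iter)) add("mcmc.n_iter: must be a count >= 1")
  if (cfg$mcmc$burn_in >= cfg$mcmc$n_iter)
    add("mcmc.burn_in: must be smaller than mcmc.n_iter")
  if (!(cfg$relmat$blend >= 0 && cfg$relmat$blend <= 1))
    add("relmat.blend: must lie in [0, 1]")
  if (length(cfg$paths)) {
    for (nm in names(cfg$paths))
      if (!file.exists(cfg$paths[[nm]]))
        add(sprintf("paths.%s: file not found (%s)", nm, cfg$paths[[nm]]))
  }
  if (length(errors))
    sp_stop(paste0("invalid configuration:\n", paste("-", errors, collapse = "\n")),
            "selfpred_config_error")
  class(cfg) <- "run_config"
  cfg
}

#' Run the full genomic-selection pipeline
#'
#' Orchestrates simulate/load -> QC -> relationship matrices -> model fits ->
#' cross-validation -> comparison -> orchard GEBV ranking -> LD -> paternity,
#' writing every stage artifact plus a manifest (config echo, seed, package
#' version) into the run directory. Re-running with the same config
#' reproduces all outputs.
#'
#' @param config a `run_config` (or path / list accepted by
#'   [validate_config()]).
#' @return the run directory path, invisibly; stage results as the
#'   `"results"` attribute.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (!identical(cfg$log_level, "quiet"))
    message(sprintf(...))

  # --- inputs: bundled simulation or user-supplied files
  if (length(cfg$paths) && !is.null(cfg$paths$genotypes)) {
    g <- read_genotypes(cfg$paths$genotypes)
    ped <- if (!is.null(cfg$paths$pedigree)) read_pedigree(cfg$paths$pedigree) else NULL
    ph <- read_phenotypes(cfg$paths$phenotypes)
    truth <- NULL
    log_msg("loaded %d individuals x %d markers", nrow(g$dosage), ncol(g$dosage))
  } else {
    sim_args <- cfg$sim
    sim_args$seed <- sim_args$seed %||% derive_seed(cfg$seed, "simulate")
    pop <- simulate_population(do.call(sim_config, sim_args))
    g <- pop$genotypes; ped <- pop$pedigree; ph <- pop$phenotypes
    truth <- pop$truth
    write_genotypes(g, file.path(outdir, "genotypes.csv"))
    write_pedigree(ped, file.path(outdir, "pedigree.csv"))
    write_phenotypes(ph, file.path(outdir, "phenotypes.csv"))
    utils::write.csv(g$map, file.path(outdir, "marker_map.csv"),
                     row.names = FALSE, quote = FALSE)
    log_msg("simulated %d individuals x %d markers", nrow(g$dosage),
            ncol(g$dosage))
  }

  # --- QC
  qc <- qc_filter(g, cfg$qc$maf_min, cfg$qc$callrate_min, cfg$qc$ind_missing_max)
  jsonlite::write_json(unclass(qc$report), file.path(outdir, "qc_report.json"),
                       auto_unbox = TRUE)
  g <- qc$genotypes
  gi <- impute_mean(g)

  # --- relationship matrices
  G <- build_G(gi)
  A <- if (!is.null(ped)) build_A(ped) else NULL
  write_relmat <- function(K, name) {
    df <- data.frame(id = K$ids, K$values, check.names = FALSE)
    utils::write.csv(df, file.path(outdir, paste0(name, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  write_relmat(G, "G")
  if (!is.null(A)) write_relmat(A, "A")

  # --- cross-validation and comparison
  mcmc <- mcmc_settings(n_iter = cfg$mcmc$n_iter, burn_in = cfg$mcmc$burn_in,
                        thin = cfg$mcmc$thin, seed = derive_seed(cfg$seed, "mcmc"))
  cv <- kfold_cv(cfg$models, list(phenotypes = ph, genotypes = g,
                                  pedigree = ped),
                 k = cfg$cv$k, seed = cfg$seed,
                 winsor_percentile = cfg$cv$winsor_percentile, mcmc = mcmc,
                 blend = cfg$relmat$blend, tau = cfg$relmat$tau,
                 omega = cfg$relmat$omega)
  utils::write.csv(cv$per_fold, file.path(outdir, "cv_per_fold.csv"),
                   row.names = FALSE)
  comp <- comparison_report(cv)
  utils::write.csv(comp, file.path(outdir, "model_comparison.csv"),
                   row.names = FALSE)
  log_msg("best model by predictive capacity: %s (PC=%.3f)",
          comp$model[1], comp$pc_mean[1])

  # --- refit best model on all phenotypes; rank unphenotyped candidates
  best <- comp$model[1]
  fit <- gs_fit(stats::as.formula(paste(attr(ph, "trait") %||% "dbh_cm",
                                        "~ block")),
                data = ph, model = best, genotypes = g, pedigree = ped,
                mcmc = mcmc, blend = cfg$relmat$blend)
  ranking <- predict_unphenotyped(fit)
  utils::write.csv(ranking, file.path(outdir, "orchard_ranking.csv"),
                   row.names = FALSE)

  # --- LD decay
  pairs <- ld_pairs(g, max_distance_bp = cfg$ld$max_distance_bp,
                    min_maf = cfg$ld$min_maf)
  curve <- if (nrow(pairs)) ld_decay_curve(pairs, cfg$ld$bin_width_bp) else NULL
  if (!is.null(curve)) {
    utils::write.csv(curve, file.path(outdir, "ld_decay.csv"), row.names = FALSE)
    grDevices::png(file.path(outdir, "ld_decay.png"), width = 700, height = 500)
    plot_ld_decay(curve)
    grDevices::dev.off()
  }

  # --- paternity (needs a pedigree with known mothers)
  paternity <- NULL
  if (!is.null(ped)) {
    off <- ped[!is.na(ped$dam), ]
    cand <- unique(stats::na.omit(c(ped$dam, ped$sire)))
    have <- off$id %in% g$individual_ids & off$dam %in% g$individual_ids
    if (sum(have) > 0 && all(cand %in% g$individual_ids)) {
      sub <- select_informative_markers(
        gi, min(cfg$paternity$n_markers, length(gi$marker_ids)))
      thr <- delta_threshold(sub, cand,
                             confidence_level = cfg$paternity$confidence_level,
                             n_replicates = cfg$paternity$n_replicates,
                             error_rate = cfg$paternity$error_rate,
                             seed = cfg$seed)
      paternity <- assign_paternity(sub, off$id[have],
                                    setNames(off$dam, off$id)[off$id[have]],
                                    cand,
                                    error_rate = cfg$paternity$error_rate,
                                    delta_relaxed = thr$delta_critical)
      utils::write.csv(paternity, file.path(outdir, "paternity.csv"),
                       row.names = FALSE)
      summ <- classify_offspring(paternity)
      utils::write.csv(summ$per_family, file.path(outdir, "selfing_summary.csv"),
                       row.names = FALSE)
      grDevices::png(file.path(outdir, "selfing_summary.png"),
                     width = 800, height = 500)
      plot_selfing_summary(summ)
      grDevices::dev.off()
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("selfpred")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = unclass(cfg),
    config_hash = sum(utf8ToInt(paste(deparse(unclass(cfg)), collapse = ""))),
    created = "run manifest")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  out <- structure(outdir,
                   results = list(qc = qc$report, cv = cv, comparison = comp,
                                  ranking = ranking, paternity = paternity))
  invisible(out)
}
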