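# Pipeline orchestration: staged execution (simulate -> featurize ->
# cluster -> msm -> lump -> analyze -> report) driven by a validated
# config, with plain-text artifacts and a JSON report. Reruns with the
# same config and seed are byte-identical.

#' Default pipeline configuration
#'
#' The defaults reproduce the reference analysis parameters: 50/5000
#' high-resolution and 10/100 low-resolution cluster counts, the 5 A
#' regime split, a 6 ns lag with 300 ps minimum residence, the standard
#' density-level ladders, 100 bootstrap resamples, and 10 reported flux
#' pathways.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    paths = list(output_dir = "msmbind_out", trajectories = NULL),
    synth = list(scenario = "lao-like", n_traj = 65L, n_frames = 10000L,
                 seed = 1L),
    featurize = list(dt_ps = 20),
    discretize = list(threshold_A = 5, k_protein_high = 50L,
                      k_ligand_high = 5000L, k_protein_low = 10L,
                      k_ligand_low = 100L, seed_index = 1L),
    msm = list(lag_ns = 6, min_residence_ps = 300,
               lag_scan_ns = c(2, 4, 6, 8, 10)),
    lump = list(levels_high = density_levels()$levels_high,
                levels_low = density_levels()$levels_low),
    kinetics = list(source = "auto-unbound", target = "auto-bound",
                    n_boot = 100L, n_draw = NULL, n_paths = 10L,
                    temperature_K = 318, c0_molar = 0.0049, k_on = NULL,
                    seed = 1L)
  )
}

merge_config <- function(base, extra, path = "") {
  for (nm in names(extra)) {
    key <- if (nzchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(base))
      stopf("unknown config key '%s'", key)
    if (is.list(base[[nm]]) && !is.null(extra[[nm]])) {
      if (!is.list(extra[[nm]]))
        stopf("config key '%s' must be a block", key)
      base[[nm]] <- merge_config(base[[nm]], extra[[nm]], key)
    } else {
      base[nm] <- extra[nm]
    }
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' @param x path to a YAML file, a named list of overrides, or `NULL` for
#'   the defaults. Unknown keys are rejected.
#' @return validated config list (class `msmbind_config`).
#' @export
pipeline_config <- function(x = NULL) {
  cfg <- default_config()
  if (is.character(x)) x <- yaml::read_yaml(x)
  if (!is.null(x)) {
    if (inherits(x, "msmbind_config")) x <- unclass(x)
    cfg <- merge_config(cfg, x)
  }
  with(cfg$discretize, stopifnot(threshold_A > 0, k_protein_high >= 1,
                                 k_ligand_high >= 1, k_protein_low >= 1,
                                 k_ligand_low >= 1))
  stopifnot(cfg$msm$lag_ns > 0, cfg$msm$min_residence_ps >= 0,
            cfg$kinetics$n_boot >= 2, cfg$kinetics$n_paths >= 1)
  if (!cfg$synth$scenario %in% c("lao-like", "lao-like-3basin"))
    stopf("unknown synth scenario '%s'", cfg$synth$scenario)
  class(cfg) <- c("msmbind_config", "list")
  cfg
}

#' Serialize a configuration to YAML
#' @param config a [pipeline_config()].
#' @param path output file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

scenario_spec <- function(cfg) {
  lao_like_spec(seed = cfg$synth$seed,
                include_misbound = cfg$synth$scenario == "lao-like")
}

need_artifact <- function(path, stage_needed) {
  if (!all(file.exists(path)))
    stopf("missing artifact %s: run stage '%s' first", path[1], stage_needed)
  invisible(path)
}

write_coord_matrix <- function(m, path) {
  tri <- as_triplets(m)
  tri <- tri[order(tri$i, tri$j), , drop = FALSE]
  df <- data.frame(row = tri$i, col = tri$j, value = tri$x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_coord_matrix <- function(path, dims) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  Matrix::sparseMatrix(i = df$row, j = df$col, x = df$value, dims = dims)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order. Each stage reads the previous
#' stage's artifacts from the output directory and writes its own as plain
#' text (labels, delimited tables, coordinate-format matrices) plus a JSON
#' report; a manifest records the parameters each stage ran with. With a
#' fixed config the run is deterministic and reruns are byte-identical.
#'
#' Stages: `simulate` (synthetic trajectories with planted ground truth),
#' `featurize` (feature-table validation/ingest), `cluster` (two-regime
#' microstates), `msm` (transition model and implied timescales), `lump`
#' (macrostates), `analyze` (populations, MFPTs with bootstrap errors,
#' committor/flux/pathways, free energy), `report` (collated JSON).
#'
#' @param config a [pipeline_config()] (or `NULL` for defaults).
#' @param stages character vector of stages, or `"all"`.
#' @param outdir output directory (default from the config).
#' @return (invisibly) the report list if the `report` stage ran.
#' @export
run_pipeline <- function(config = NULL, stages = "all", outdir = NULL) {
  cfg <- pipeline_config(config)
  outdir <- outdir %||% cfg$paths$output_dir
  all_stages <- c("simulate", "featurize", "cluster", "msm", "lump",
                  "analyze", "report")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stage '%s'", bad[1])
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(outdir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list()
  log_stage <- function(stage, params) {
    manifest[[stage]] <<- params
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  report <- NULL

  for (stage in all_stages[all_stages %in% stages]) {
    message(sprintf("[msmbind] stage %s", stage))
    switch(stage,
      simulate = {
        spec <- scenario_spec(cfg)
        ds <- generate_dataset(spec, cfg$synth$n_traj, cfg$synth$n_frames)
        for (i in seq_along(ds$features)) {
          write_feature_trajectory(
            ds$features[[i]],
            file.path(outdir, sprintf("traj_%03d.tsv", i)))
          write_labels(ds$labels[[i]],
                       file.path(outdir, sprintf("truth_%03d.txt", i)))
        }
        writeLines(spec$state_names, file.path(outdir, "truth_states.txt"))
        log_stage("simulate", cfg$synth)
      },
      featurize = {
        files <- cfg$paths$trajectories %||%
          sort(list.files(outdir, "^traj_[0-9]+\\.tsv$", full.names = TRUE))
        if (!length(files))
          stopf("no feature trajectories found: run stage 'simulate' first or set paths$trajectories")
        for (f in files) read_feature_trajectory(f)  # validates
        writeLines(basename(files), file.path(outdir, "features_manifest.txt"))
        log_stage("featurize", list(n_traj = length(files)))
      },
      cluster = {
        fm <- need_artifact(file.path(outdir, "features_manifest.txt"),
                            "featurize")
        files <- file.path(outdir, readLines(fm))
        trajs <- lapply(files, read_feature_trajectory)
        dz <- cfg$discretize
        asg <- two_regime_assign(trajs, threshold_A = dz$threshold_A,
                                 k_protein_high = dz$k_protein_high,
                                 k_ligand_high = dz$k_ligand_high,
                                 k_protein_low = dz$k_protein_low,
                                 k_ligand_low = dz$k_ligand_low,
                                 seed_index = dz$seed_index)
        for (i in seq_along(asg$labels))
          write_labels(asg$labels[[i]],
                       file.path(outdir, sprintf("micro_%03d.txt", i)))
        utils::write.table(asg$provenance,
                           file.path(outdir, "micro_provenance.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeLines(asg$regime, file.path(outdir, "micro_regime.txt"))
        log_stage("cluster", c(dz, K = asg$K))
      },
      msm = {
        need_artifact(file.path(outdir, "micro_regime.txt"), "cluster")
        files <- sort(list.files(outdir, "^micro_[0-9]+\\.txt$",
                                 full.names = TRUE))
        labels <- lapply(files, read_labels)
        dt <- cfg$featurize$dt_ps
        lag_frames <- max(1L, as.integer(round(cfg$msm$lag_ns * 1000 / dt)))
        min_res <- max(1L,
                       as.integer(round(cfg$msm$min_residence_ps / dt)))
        K <- length(readLines(file.path(outdir, "micro_regime.txt")))
        tm <- transition_model(labels, lag_frames, min_res, dt_ps = dt,
                               K = K)
        write_coord_matrix(tm$counts, file.path(outdir, "micro_counts.tsv"))
        utils::write.table(
          data.frame(state = seq_along(tm$pi), pi = tm$pi,
                     pi_raw = tm$pi_raw),
          file.path(outdir, "micro_pi.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
        scan_frames <- unique(pmax(1L, as.integer(
          round(cfg$msm$lag_scan_ns * 1000 / dt))))
        its <- implied_timescales(labels, scan_frames, n_timescales = 3,
                                  min_residence_frames = min_res, dt_ps = dt)
        utils::write.table(
          cbind(lag_ns = its$lags_ns, its$timescales_ns),
          file.path(outdir, "implied_timescales.tsv"), sep = "\t",
          quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
          list(lag_frames = lag_frames, lag_ns = cfg$msm$lag_ns,
               min_residence_frames = min_res, dt_ps = dt, K = K),
          file.path(outdir, "msm_params.json"), auto_unbox = TRUE,
          digits = NA)
        log_stage("msm", cfg$msm)
      },
      lump = {
        need_artifact(file.path(outdir, "micro_counts.tsv"), "msm")
        K <- length(readLines(file.path(outdir, "micro_regime.txt")))
        counts <- read_coord_matrix(file.path(outdir, "micro_counts.tsv"),
                                    dims = c(K, K))
        regime <- readLines(file.path(outdir, "micro_regime.txt"))
        files <- sort(list.files(outdir, "^micro_[0-9]+\\.txt$",
                                 full.names = TRUE))
        labels <- lapply(files, read_labels)
        dens <- state_densities(labels, K = K)
        # connectivity for lumping is estimated at the frame interval, where
        # every visited state has coupling by construction; the kinetic
        # model itself uses the validated lag
        adj <- count_transitions(labels, 1L, 1L, K = K)
        mapping <- shc_lump(adj, regime,
                            levels = list(levels_high = cfg$lump$levels_high,
                                          levels_low = cfg$lump$levels_low),
                            densities = dens)
        utils::write.table(
          data.frame(micro = seq_len(K), macro = mapping$micro_to_macro),
          file.path(outdir, "macro_mapping.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
        write_coord_matrix(macro_counts(counts, mapping),
                           file.path(outdir, "macro_counts.tsv"))
        log_stage("lump", c(cfg$lump, M = mapping$M))
      },
      analyze = {
        need_artifact(file.path(outdir, "macro_mapping.tsv"), "lump")
        report <- analyze_stage(cfg, outdir)
        log_stage("analyze", cfg$kinetics)
      },
      report = {
        need_artifact(file.path(outdir, "analysis.json"), "analyze")
        report <- jsonlite::read_json(file.path(outdir, "analysis.json"))
        jsonlite::write_json(report, file.path(outdir, "report.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
        log_stage("report", list(keys = names(report)))
      })
  }
  invisible(report)
}

# The kinetic/thermodynamic analysis stage (macro-level readouts).
analyze_stage <- function(cfg, outdir) {
  dt <- cfg$featurize$dt_ps
  map_df <- utils::read.table(file.path(outdir, "macro_mapping.tsv"),
                              header = TRUE, sep = "\t")
  mm <- map_df$macro
  M <- max(mm)
  micro_files <- sort(list.files(outdir, "^micro_[0-9]+\\.txt$",
                                 full.names = TRUE))
  micro_labels <- lapply(micro_files, read_labels)
  macro_labels <- lapply(micro_labels, function(l) mm[l])
  prm <- jsonlite::read_json(file.path(outdir, "msm_params.json"))
  lag_frames <- prm$lag_frames
  min_res <- prm$min_residence_frames
  tm <- transition_model(macro_labels, lag_frames, min_res, dt_ps = dt,
                         K = M)
  Tmac <- as_dense(tm$T)
  pi <- tm$pi

  src_cfg <- cfg$kinetics$source
  tgt_cfg <- cfg$kinetics$target
  auto <- is.character(src_cfg) && grepl("^auto-", src_cfg[1])
  sets <- NULL
  if (auto) {
    truth_files <- sort(list.files(outdir, "^truth_[0-9]+\\.txt$",
                                   full.names = TRUE))
    need_artifact(truth_files[1] %||% "truth_001.txt", "simulate")
    truth <- lapply(truth_files, read_labels)
    states <- readLines(file.path(outdir, "truth_states.txt"))
    mapping <- list(micro_to_macro = mm, M = M)
    class(mapping) <- "macro_mapping"
    maj <- macro_majority_basin(truth, micro_labels, mapping)
    sets <- lapply(seq_along(states), function(b) which(maj == b))
    names(sets) <- states
    source_set <- sets[[sub("^auto-", "", src_cfg)]]
    target_set <- sets[[sub("^auto-", "", tgt_cfg)]]
  } else {
    source_set <- as.integer(src_cfg)
    target_set <- as.integer(tgt_cfg)
  }
  if (!length(source_set) || !length(target_set))
    stopf("empty source or target macrostate set")

  lag_ns <- lag_frames * dt / 1000
  mf <- mfpt(Tmac, lag_ns, source_set, target_set)
  n_draw <- cfg$kinetics$n_draw %||% length(macro_labels)
  boot <- bootstrap_statistic(
    macro_labels,
    function(tr) {
      tmb <- transition_model(tr, lag_frames, min_res, dt_ps = dt, K = M)
      mfpt(as_dense(tmb$T), lag_ns, source_set, target_set)$value
    },
    n_boot = cfg$kinetics$n_boot, n_draw = n_draw,
    seed = cfg$kinetics$seed)

  fl <- net_flux(Tmac, source_set, target_set, pi = pi)
  paths <- top_flux_paths(fl$flux, source_set, target_set,
                          n_paths = cfg$kinetics$n_paths,
                          total_flux = fl$total_flux)

  alpha_free <- sum(pi[source_set])
  dG <- if (alpha_free > 0 && alpha_free < 1)
    binding_free_energy(alpha_free, cfg$kinetics$c0_molar,
                        cfg$kinetics$temperature_K) else NA_real_
  tau <- if (!is.null(cfg$kinetics$k_on))
    association_timescale(cfg$kinetics$k_on, cfg$kinetics$c0_molar) else NULL

  report <- list(
    n_macrostates = M,
    macro_populations = as.numeric(pi),
    state_sets = if (!is.null(sets)) lapply(sets, as.integer) else NULL,
    mfpt = list(source = source_set, target = target_set,
                value_us = mf$value / 1000,
                bootstrap_mean_us = boot$mean / 1000,
                bootstrap_sd_us = boot$sd / 1000,
                lag_ns = lag_ns),
    binding = list(alpha_free = alpha_free, alpha_bound = 1 - alpha_free,
                   c0_molar = cfg$kinetics$c0_molar,
                   temperature_K = cfg$kinetics$temperature_K,
                   dG_kcal_mol = dG),
    association_timescale_s = tau,
    flux = list(total_flux = fl$total_flux,
                paths = paths$path, path_flux = paths$flux,
                path_fraction = paths$fraction))
  jsonlite::write_json(report, file.path(outdir, "analysis.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report
}
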