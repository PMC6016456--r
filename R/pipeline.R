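# Orchestration: plain-text run configuration and the end-to-end synthetic
# replay that exercises every stage against planted truth.

#' Default run configuration
#'
#' All tunable constants of the pipeline in one place: the 3 Å contact
#' cutoff and 10 Å interface cutoff, the per-ensemble pose count, the
#' localization and funnel thresholds, equilibration parameters and the
#' default fit model. Every value can be overridden and round-trips
#' losslessly through [write_run_config()]/[read_run_config()].
#'
#' @param ... Named overrides of individual fields.
#' @return Named list of class `iface_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    cutoff_contact = 3.0,      # Angstrom, residue-contact criterion
    cutoff_interface = 10.0,   # Angstrom, interface-residue definition
    n_poses = 30,              # poses per docking ensemble
    top_k = 20,                # residues entering domain localization
    localization_threshold = 0.8,
    funnel_low_fraction = 0.1,
    funnel_rho_min = 0.4,
    equil_window = 10,         # frames
    equil_band = 0.5,          # Angstrom
    fit_model = "single_site",
    seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")),
          class = "iface_config_error")
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "iface_config"
  cfg
}

#' Write / read a run configuration as plain-text key=value pairs
#'
#' @param cfg An `iface_config` list.
#' @param path File path.
#' @return `read_run_config()` returns an `iface_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(nm) {
    paste0(nm, "=", format(cfg[[nm]], scientific = FALSE))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- paste(p[-1], collapse = "=")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[`, "", 1)
  do.call(default_run_config, vals)
}

#' Run the full synthetic replay pipeline
#'
#' Generates a synthetic dimer + pose ensembles, trajectories, an MSA and
#' titration curves with planted truth, then runs every analysis stage in
#' dependency order: contact prevalence (per ensemble, averaged, folded over
#' the dimer symmetry), domain localization, composite-site fraction, funnel
#' analysis, RMSF with proximal/distant deltas, lineage-specific residue
#' calling and binding fits. Tabular results are written as TSV, fit results
#' as JSON, plus a run log with the configuration hash and seed.
#'
#' @param config An `iface_config` (default [default_run_config()]).
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param stages Character vector of stages to run, in any order (executed
#'   in dependency order). Empty vector is a no-op.
#' @return Named list of stage results, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         stages = c("prevalence", "funnel", "rmsf",
                                    "evolve", "fit")) {
  known <- c("prevalence", "funnel", "rmsf", "evolve", "fit")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")),
          class = "iface_config_error")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  res <- list()
  seed <- as.integer(config$seed)
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  if ("prevalence" %in% stages) {
    base <- make_dimer_complex(site_residues = c(5, 9, 13, 21), seed = seed)
    ens <- make_pose_ensemble(base, n_poses = config$n_poses,
                              target_freqs = c(1, 0.8, 0.5, 0.1), seed = seed)
    prof <- prevalence_profile(ens, receptor_chains = c("A", "B"),
                               ligand_chains = "L",
                               cutoff = config$cutoff_contact)
    folded <- fold_dimer_symmetry(prof, symmetry_map_chains(base, "A", "B"))
    part <- tibble(domain = c("kinase", "sulfurylase"),
                   chain = "A", start = c(1, 21), end = c(20, 40))
    loc <- domain_localization(folded, part, top_k = min(config$top_k,
                                                         nrow(folded)),
                               threshold = config$localization_threshold)
    comp <- composite_site_fraction(ens, receptor_chains = c("A", "B"),
                                    ligand_chains = "L",
                                    cutoff = config$cutoff_contact)
    res$prevalence <- list(profile = prof, folded = folded,
                           localization = loc, composite = comp)
    emit(as_tibble(prof), "prevalence")
    emit(as_tibble(folded), "prevalence_folded")
    emit(as_tibble(comp), "composite_site")
  }
  if ("funnel" %in% stages) {
    pts <- make_funnel_points(n = 200, seed = seed)
    res$funnel <- funnel_analysis(pts,
                                  low_fraction = config$funnel_low_fraction,
                                  rho_min = config$funnel_rho_min)
    emit(as_tibble(res$funnel), "funnel")
  }
  if ("rmsf" %in% stages) {
    base <- make_dimer_complex(site_residues = c(5, 9, 13), seed = seed)
    keys <- unique(residue_key(base$chain, base$resno, base$icode))
    sig <- setNames(ifelse(startsWith(keys, "A|"), 0.25, 0.5), keys)
    trj <- make_trajectory(base, sigma = sig, n_frames = 200, dt = 2,
                           seed = seed)
    prof <- rmsf(trj)
    trace <- rmsd_trace(trj)
    eq <- equilibration_time(trace, window = config$equil_window,
                             band = config$equil_band)
    smap <- symmetry_map_chains(base, "A", "B")
    iface <- tibble(chain = "A", resno = c(5, 9, 13), icode = "")
    delta <- rmsf_delta(prof, smap, iface)
    res$rmsf <- list(profile = prof, trace = trace, equilibration = eq,
                     delta = delta)
    emit(as_tibble(prof), "rmsf")
    emit(trace, "rmsd_trace")
    emit(delta, "rmsf_delta")
  }
  if ("evolve" %in% stages) {
    msa <- make_msa(specific_columns = c(12, 40), seed = seed)
    truth <- attr(msa, "truth")
    calls <- lineage_specific_residues(msa, clade = truth$clade_ids,
                                       interface_columns = seq_len(attr(msa, "width")))
    res$evolve <- list(msa = msa, calls = calls)
    emit(calls, "clade_calls")
  }
  if ("fit" %in% stages) {
    cur <- make_titration("single_site",
                          params = list(KD = 13.2, L = 1),
                          x_grid = c(0.5, 1, 2, 5, 10, 20, 35, 50, 75, 100,
                                     125, 150),
                          noise_sigma = 0, seed = seed)
    fit <- fit_single_site(cur)
    res$fit <- fit
    if (!is.null(out_dir)) {
      jsonlite::write_json(
        list(model = fit$model,
             estimate = as.list(fit$estimate),
             std_error = as.list(fit$std_error),
             rss = fit$rss),
        file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  if (!is.null(out_dir)) {
    log_lines <- c(
      paste0("config_hash=", rlang::hash(unclass(config))),
      paste0("seed=", seed),
      paste0("stages=", paste(stages, collapse = ",")),
      paste0("ifacetools_version=",
             as.character(utils::packageVersion("ifacetools"))),
      paste0("timestamp=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    )
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(res)
}
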