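# Config-driven orchestration: read one or more replicate trajectories,
# extract the triad distances and substrate torsion, build per-replicate
# and pooled free-energy landscapes, the kT-level population table, the
# torsion PMF, the conditional actionable report and (optionally) the
# pocket-volume series, and write everything as CSV.

#' Default run configuration
#'
#' All paper-gap parameters are surfaced here: hydrogen-bond cutoff,
#' distance and torsion bin widths, kT-level count, actionable tolerance,
#' and pocket-region geometry.
#'
#' @param replicates List of `list(topology =, frames =, id =)` entries.
#' @param output_dir Directory for the report bundle.
#' @return A validated `"run_config"` list.
#' @export
default_config <- function(replicates = list(), output_dir = "mdscape-out") {
  structure(list(
    replicates = replicates,
    output_dir = output_dir,
    ligand_residue = 1L,
    distance_bin_width = 0.1,
    dihedral_bin_width = 5,
    hbond_max_distance = 2.5,
    actionable_tolerance = 5,
    kT_levels = 10,
    empty_bin_value = 10,
    pmf_prefactor = 0.6,
    pocket = list(enabled = FALSE, center_atom = "C5", radius = 6,
                  grid_spacing = 1, probe_radius = 1.4,
                  occluders = "protein"),
    timestamps = FALSE,
    seed = 1L), class = "run_config")
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected; missing keys take the [default_config()]
#' values.
#'
#' @param path Path to a YAML file.
#' @return A `"run_config"` list.
#' @export
run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  bad <- setdiff(names(raw), names(cfg))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (k in names(raw)) {
    if (k == "pocket") {
      badp <- setdiff(names(raw$pocket), names(cfg$pocket))
      if (length(badp))
        stop("unknown pocket key(s): ", paste(badp, collapse = ", "),
             call. = FALSE)
      cfg$pocket[names(raw$pocket)] <- raw$pocket
    } else cfg[[k]] <- raw[[k]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!length(cfg$replicates))
    stop("config needs at least one replicate (topology + frames)",
         call. = FALSE)
  for (r in cfg$replicates) {
    if (is.null(r$topology) || is.null(r$frames))
      stop("each replicate needs 'topology' and 'frames' paths",
           call. = FALSE)
    for (p in c(r$topology, r$frames))
      if (!file.exists(p)) stop("replicate input not found: ", p,
                                call. = FALSE)
  }
  stopifnot(cfg$distance_bin_width > 0, cfg$dihedral_bin_width > 0,
            cfg$hbond_max_distance > 0, cfg$actionable_tolerance > 0,
            cfg$kT_levels >= 1)
  cfg
}

# hash of the scientific parameters only: where the report is written must
# not change its contents
config_hash <- function(cfg) {
  c2 <- unclass(cfg)
  c2$output_dir <- NULL
  rlang::hash(c2)
}

write_report_csv <- function(df, path, cfg, comment_fields = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mdscape config_hash=%s", config_hash(cfg)), con)
  if (isTRUE(cfg$timestamps))
    writeLines(sprintf("# written=%s", format(Sys.time())), con)
  for (cm in comment_fields) writeLines(paste0("# ", cm), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Generate an on-disk fixture from a named preset
#'
#' @param preset Preset name (see [preset_model()]).
#' @param n_frames Frames to simulate.
#' @param seed Integer seed (the fixture is byte-reproducible given it).
#' @param outdir Output directory.
#' @param frames_format `"dcd"` or `"pdb"`.
#' @param replicate_id Replicate label.
#' @return Invisible named list of file paths.
#' @export
generate_fixture <- function(preset, n_frames, seed, outdir,
                             frames_format = "dcd",
                             replicate_id = paste0(preset, "_rep1")) {
  model <- preset_model(preset)
  lt <- simulate_trajectory(model, n_frames, seed, replicate_id)
  write_fixture(lt, outdir, frames_format)
}

analyze_one <- function(traj, cfg) {
  specs <- tunnel_specs(cfg$ligand_residue)
  ser <- extract_series(traj, specs)
  d1 <- series_values(ser, specs$d1$label)
  d2 <- series_values(ser, specs$d2$label)
  chi <- series_values(ser, specs$chi$label)
  list(series = ser, d1 = d1, d2 = d2, chi = chi,
       hist = bin2d(d1, d2, cfg$distance_bin_width,
                    specs$d1$label, specs$d2$label))
}

#' Run the full analysis over one or more replicates
#'
#' Per replicate: observable extraction and a 2D distance histogram.
#' Pooled over replicates: the free-energy landscape, its minimum, the
#' kT-level population table, the torsion distribution/PMF and the
#' conditional actionable report; optionally the per-frame pocket volume.
#' Outputs are written as CSV files carrying the config hash in a header
#' comment; identical config and inputs give identical bytes (timestamps
#' are off by default).
#'
#' @param cfg A `"run_config"` (see [run_config()], [default_config()]).
#' @return Invisible list with the computed objects: `landscape` (fes),
#'   `minimum`, `levels`, `pmf`, `conditional`, `per_replicate`,
#'   `volumes` (or `NULL`), and `files`.
#' @export
analyze_run <- function(cfg) {
  cfg <- validate_config(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  per <- list(); failed <- character()
  for (r in cfg$replicates) {
    id <- if (is.null(r$id)) basename(r$frames) else r$id
    res <- tryCatch({
      traj <- read_trajectory(r$topology, r$frames, replicate_id = id)
      analyze_one(traj, cfg)
    }, error = function(e) {
      warning(sprintf("replicate '%s' failed: %s", id,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(res)) failed <- c(failed, id) else per[[id]] <- res
  }
  if (!length(per))
    stop("all replicates failed; nothing to pool", call. = FALSE)
  if (length(failed))
    warning("pooling over successful replicates only (failed: ",
            paste(failed, collapse = ", "), ")", call. = FALSE)

  pooled_hist <- pool_histograms(lapply(per, `[[`, "hist"))
  fes <- free_energy(pooled_hist, cfg$empty_bin_value)
  minimum <- fes_minimum(fes)
  levels <- level_populations(fes, cfg$kT_levels)
  chi <- unlist(lapply(per, `[[`, "chi"), use.names = FALSE)
  d1 <- unlist(lapply(per, `[[`, "d1"), use.names = FALSE)
  d2 <- unlist(lapply(per, `[[`, "d2"), use.names = FALSE)
  dist <- dihedral_distribution(chi, cfg$dihedral_bin_width)
  pmf <- dihedral_pmf(dist, cfg$pmf_prefactor)
  crit <- hbond_criterion(cfg$hbond_max_distance)
  cond <- conditional_actionable(chi, d1, d2, crit,
                                 cfg$actionable_tolerance)

  files <- list()
  for (id in names(per))
    files[[paste0("landscape_", id)]] <- write_report_csv(
      fes_table(free_energy(per[[id]]$hist, cfg$empty_bin_value)),
      file.path(cfg$output_dir, paste0("landscape_", id, ".csv")), cfg,
      sprintf("replicate=%s", id))
  files$landscape_pooled <- write_report_csv(
    fes_table(fes), file.path(cfg$output_dir, "landscape_pooled.csv"), cfg)
  files$levels <- write_report_csv(
    levels, file.path(cfg$output_dir, "level_populations.csv"), cfg)
  files$pmf <- write_report_csv(
    pmf_table(pmf), file.path(cfg$output_dir, "dihedral_pmf.csv"), cfg)
  files$conditional <- write_report_csv(
    conditional_table(cond),
    file.path(cfg$output_dir, "conditional_actionable.csv"), cfg,
    sprintf("hbond_max_distance_A=%g tolerance_deg=%g",
            cfg$hbond_max_distance, cfg$actionable_tolerance))

  volumes <- NULL
  if (isTRUE(cfg$pocket$enabled)) {
    region <- pocket_region(
      atom_spec(cfg$ligand_residue, cfg$pocket$center_atom),
      cfg$pocket$radius, cfg$pocket$grid_spacing, cfg$pocket$probe_radius,
      cfg$pocket$occluders)
    vols <- lapply(cfg$replicates, function(r) {
      id <- if (is.null(r$id)) basename(r$frames) else r$id
      if (!id %in% names(per)) return(NULL)
      traj <- read_trajectory(r$topology, r$frames, replicate_id = id)
      volume_series(traj, region)
    })
    volumes <- do.call(rbind, vols)
    files$volumes <- write_report_csv(
      volumes, file.path(cfg$output_dir, "pocket_volumes.csv"), cfg,
      sprintf("center=%s radius_A=%g spacing_A=%g probe_A=%g",
              cfg$pocket$center_atom, cfg$pocket$radius,
              cfg$pocket$grid_spacing, cfg$pocket$probe_radius))
  }
  invisible(list(landscape = fes, minimum = minimum, levels = levels,
                 pmf = pmf, conditional = cond, per_replicate = per,
                 volumes = volumes, files = files))
}
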