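# Pipeline orchestration: a single YAML config drives
# synthesize -> window -> leaflets -> densities -> contacts -> sites ->
# report, with reproducible seeds and a manifest of everything written.

CONFIG_KEYS <- c("synthetic", "input", "state", "window", "cutoff",
                 "bin_size_2d", "voxel_size_3d", "repeats", "sites",
                 "outdir", "seed")
SYNTH_KEYS <- c("nominal_per_leaflet", "box_a", "box_c", "n_steps", "step_dt",
                "write_every", "flipflop_rate", "sites")
SITE_KEYS <- c("name", "leaflet", "selectivity", "well_depth", "width",
               "radius", "angle_deg", "wedge", "available_in", "c5_replicate")

#' Validate a pipeline configuration
#'
#' Reads a YAML run configuration, rejects unknown keys (listing every
#' offending key), enforces that exactly one of `input` / `synthetic` is
#' present, checks referenced files exist, and fills defaults: cutoff 0.6 nm,
#' window last_fraction 0.5 with stride 10 ns, 2D bin 0.2 nm, 3D voxel
#' 0.1 nm, 1 repeat, seed 1.
#'
#' @param path YAML config file, or a named list with the same structure.
#' @return object of class `run_config`.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  bad <- setdiff(names(cfg), CONFIG_KEYS)
  if (!is.null(cfg$synthetic))
    bad <- c(bad, paste0("synthetic.", setdiff(names(cfg$synthetic), SYNTH_KEYS)))
  for (s in cfg$synthetic$sites %||% list())
    bad <- c(bad, paste0("synthetic.sites.", setdiff(names(s), SITE_KEYS)))
  bad <- bad[!grepl("\\.$", bad) | !bad %in% c("synthetic.")]
  bad <- setdiff(bad, c("synthetic.", "synthetic.sites."))
  if (length(bad))
    stopf("validation error: unknown config key(s): %s", paste(bad, collapse = ", "))
  has_in <- !is.null(cfg$input)
  has_syn <- !is.null(cfg$synthetic)
  if (has_in == has_syn)
    stopf("validation error: exactly one of 'input' or 'synthetic' must be given")
  if (has_in) {
    if (is.null(cfg$input$coordinates) || !file.exists(cfg$input$coordinates))
      stopf("validation error: input coordinate file missing or not found")
    if (!is.null(cfg$input$trajectory) && !file.exists(cfg$input$trajectory))
      stopf("validation error: input trajectory file not found: %s",
            cfg$input$trajectory)
  }
  state <- cfg$state %||% "inactive"
  if (!state %in% c("inactive", "active"))
    stopf("validation error: state must be 'inactive' or 'active'")
  win <- cfg$window %||% list()
  out <- structure(list(
    input = cfg$input,
    synthetic = if (has_syn) utils::modifyList(list(
      nominal_per_leaflet = 150, box_a = 12, box_c = 10, n_steps = 2000,
      step_dt = 0.2, write_every = 10, flipflop_rate = 1e-4, sites = list()),
      cfg$synthetic),
    state = state,
    window = list(last_fraction = win$last_fraction %||% 0.5,
                  stride_dt = win$stride_dt %||% 10),
    cutoff = cfg$cutoff %||% 0.6,
    bin_size_2d = cfg$bin_size_2d %||% 0.2,
    voxel_size_3d = cfg$voxel_size_3d %||% 0.1,
    repeats = cfg$repeats %||% 1,
    sites = cfg$sites %||% list(),
    outdir = cfg$outdir %||% "lipmap_out",
    seed = cfg$seed %||% 1),
    class = "run_config")
  stopifnot(out$cutoff > 0, out$bin_size_2d > 0, out$voxel_size_3d > 0)
  out
}

config_truth <- function(config) {
  sites <- lapply(config$synthetic$sites, function(s)
    planted_site(name = s$name, leaflet = s$leaflet, selectivity = s$selectivity,
                 well_depth = s$well_depth, width = s$width, radius = s$radius,
                 angle_deg = s$angle_deg %||% 0, wedge = s$wedge,
                 available_in = unlist(s$available_in %||% c("inactive", "active")),
                 c5_replicate = isTRUE(s$c5_replicate)))
  synthetic_truth(sites = sites, flipflop_rate = config$synthetic$flipflop_rate,
                  state = config$state)
}

#' Run the full analysis pipeline
#'
#' Executes every stage requested by the config and writes a report bundle to
#' the output directory: per-leaflet 2D density CSVs and their repeat
#' averages, 3D density OpenDX grids, the contact-duration table, lipid
#' hierarchy, C5 symmetry report, site reports and a JSON manifest
#' (package version, seed, config digest). Identical config + seed give
#' identical numeric outputs.
#'
#' @param config a [validate_config()] result (or a path to a YAML config).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- if (length(config$repeats) > 1) unlist(config$repeats) else
    config$seed + seq_len(config$repeats) - 1
  outputs <- character(0)
  say <- function(fmt, ...) message(sprintf(paste0("[lipmap] ", fmt), ...))

  runs <- list()
  for (i in seq_along(seeds)) {
    if (!is.null(config$synthetic)) {
      say("repeat %d/%d: synthesizing (seed %d)", i, length(seeds), seeds[i])
      sys <- build_membrane(
        neuronal_membrane_spec(nominal_per_leaflet = config$synthetic$nominal_per_leaflet),
        pentamer = build_pentamer(),
        box = hexagonal_box(config$synthetic$box_a, config$synthetic$box_c),
        seed = seeds[i])
      traj <- simulate_lipids(sys, config_truth(config),
                              n_steps = config$synthetic$n_steps,
                              step_dt = config$synthetic$step_dt,
                              write_every = config$synthetic$write_every,
                              seed = seeds[i])
      top <- sys$topology
    } else {
      say("reading input system")
      rs <- read_system(config$input$coordinates, config$input$trajectory)
      top <- rs$topology
      traj <- rs$trajectory
    }
    win <- analysis_window(config$window$last_fraction, config$window$stride_dt)
    wtraj <- tryCatch(select_window(traj, win), error = function(e) {
      say("window not applicable (%s); using all frames", conditionMessage(e))
      traj
    })
    runs[[i]] <- list(topology = top, trajectory = wtraj,
                      assignment = assign_leaflets(wtraj, top))
  }

  types <- sort(unique(runs[[1]]$topology$lipid_type[
    runs[[1]]$topology$mol_class == "lipid"]))

  say("computing 2D leaflet densities")
  grids2d <- list()
  for (ty in types) for (lf in LEAFLETS) {
    per_rep <- list()
    for (i in seq_along(runs)) {
      g <- tryCatch(density2d(runs[[i]]$trajectory, runs[[i]]$topology,
                              runs[[i]]$assignment, ty, lf,
                              bin_size = config$bin_size_2d),
                    error = function(e) NULL)
      if (!is.null(g)) per_rep[[length(per_rep) + 1L]] <- g
    }
    if (!length(per_rep)) next
    avg <- average_grids(per_rep)
    avg$metadata$state <- config$state
    key <- sprintf("%s_%s", ty, lf)
    grids2d[[key]] <- list(average = avg, per_repeat = per_rep)
    f <- file.path(config$outdir, sprintf("density2d_%s_%s.csv", ty, lf))
    export_density(avg, f)
    outputs <- c(outputs, f)
  }

  say("computing 3D densities")
  grids3d <- list()
  for (ty in types) {
    per_rep <- lapply(runs, function(r)
      density3d(r$trajectory, r$topology, ty, voxel_size = config$voxel_size_3d))
    avg <- average_grids(per_rep)
    avg$metadata$state <- config$state
    grids3d[[ty]] <- avg
    f <- file.path(config$outdir, sprintf("density3d_%s.dx", ty))
    export_density(avg, f)
    outputs <- c(outputs, f)
  }

  say("computing contact series (%d repeats)", length(runs))
  series <- lapply(runs, function(r)
    contact_series(r$trajectory, r$topology, cutoff = config$cutoff))
  tab <- contact_table(series, collapse_subunits = TRUE)
  f <- file.path(config$outdir, "contact_table.csv")
  write_contact_table(tab, f)
  outputs <- c(outputs, f)
  hier <- list(max = as.character(lipid_hierarchy(tab, "max")),
               mean_top20 = as.character(lipid_hierarchy(tab, "mean-top-20")))

  sym_key <- if ("CHOL_extracellular" %in% names(grids2d)) "CHOL_extracellular"
             else names(grids2d)[1]
  sym <- symmetry_report(grids2d[[sym_key]]$per_repeat)
  f <- file.path(config$outdir, "symmetry_report.csv")
  utils::write.csv(cbind(sym$per_repeat,
                         average_deviation = sym$average_deviation), f,
                   row.names = FALSE)
  outputs <- c(outputs, f)

  site_reports <- list()
  for (s in config$sites) {
    defs <- load_site_from_structure(s$pdb, s$ligand, radius = s$radius %||% 0.7)
    for (d in defs) {
      rep <- site_enrichment(grids3d[[s$lipid_type %||% "CHOL"]], d)
      site_reports[[d$name]] <- rep
    }
  }
  if (length(site_reports)) {
    f <- file.path(config$outdir, "site_reports.csv")
    utils::write.csv(do.call(rbind, lapply(site_reports, function(r)
      data.frame(site = r$site, lipid_type = r$lipid_type,
                 mean_site_density = r$mean_site_density,
                 bulk_density = r$bulk_density, enrichment = r$enrichment,
                 occupancy = r$occupancy))), f, row.names = FALSE)
    outputs <- c(outputs, f)
  }

  manifest <- list(
    package = "lipmap",
    version = as.character(utils::packageVersion("lipmap")),
    state = config$state,
    seed = config$seed,
    repeats = length(seeds),
    n_frames_analyzed = runs[[1]]$trajectory$n_frames,
    lipid_types = types,
    hierarchy = hier,
    symmetry = list(median_repeat_deviation = sym$median_repeat_deviation,
                    average_deviation = sym$average_deviation),
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: %d outputs in %s", length(outputs) + 1L, config$outdir)
  invisible(manifest)
}
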