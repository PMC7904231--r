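# Canonical synthetic study conditions: the reference configurations used by
# the validation suite (parameter recovery of the lipid hierarchy, and the
# state-dependent subunit-interface cholesterol site). Fixed here once so the
# same conditions drive the test-suite, the acceptance script and the
# documentation examples.

#' Planted truth for the lipid-hierarchy recovery study
#'
#' One C5-replicated surface site per lipid type over the outer (M4) helices
#' (radius 2.35 nm, width 0.3 nm), with well depths encoding the planted
#' hierarchy: CHOL 6 kT > PS 4 kT > PC = PE = SM 1 kT. Sites for
#' extracellular types sit in the extracellular leaflet, the PS and PE sites
#' in the intracellular leaflet.
#'
#' @param state receptor state label.
#' @return [synthetic_truth()].
#' @export
hierarchy_truth <- function(state = "active") {
  synthetic_truth(sites = list(
    planted_site("chol_surface", "extracellular", "CHOL", 6, 0.3, 2.35,
                 angle_deg = 0, c5_replicate = TRUE),
    planted_site("ps_surface", "intracellular", "DOPS", 4, 0.3, 2.35,
                 angle_deg = 0, c5_replicate = TRUE),
    planted_site("pc_surface", "extracellular", "POPC", 1, 0.3, 2.35,
                 angle_deg = 0, c5_replicate = TRUE),
    planted_site("pe_surface", "intracellular", "POPE", 1, 0.3, 2.35,
                 angle_deg = 0, c5_replicate = TRUE),
    planted_site("sm_surface", "extracellular", "SM", 1, 0.3, 2.35,
                 angle_deg = 0, c5_replicate = TRUE)),
    state = state)
}

#' Planted truth for the state-dependent interface site study
#'
#' A single cholesterol site in the extracellular leaflet, buried in the
#' subunit-interface wedges (radius 1.6 nm, inside the protein footprint),
#' available only in the active state - the synthetic analogue of a
#' modulator pocket that opens between subunits upon activation. Replicated
#' five-fold under C5.
#'
#' @param state receptor state label.
#' @param well_depth site depth (kT).
#' @return [synthetic_truth()].
#' @export
interface_truth <- function(state, well_depth = 6) {
  synthetic_truth(sites = list(
    planted_site("chol_interface", "extracellular", "CHOL", well_depth, 0.3,
                 1.6, wedge = 0, available_in = "active")),
    state = state)
}

#' Run a reference synthetic study
#'
#' Builds the default neuronal membrane (150 lipids per leaflet in a 12 nm
#' hexagonal cell) around the toy pentamer and simulates the toy lipid
#' dynamics under a given truth. The defaults (666 ns at 0.1 ns steps,
#' frames every 2 ns, ~300 lipids) give about 1e5 analyzed lipid-frames.
#'
#' @param truth [synthetic_truth()].
#' @param seed integer seed (controls both placement and dynamics).
#' @param n_steps,step_dt,write_every integration parameters.
#' @param nominal_per_leaflet lipids per leaflet.
#' @param box_a,box_c hexagonal cell dimensions (nm).
#' @return list with `system` ([build_membrane()] output) and `trajectory`.
#' @export
synthetic_reference_run <- function(truth, seed, n_steps = 6660, step_dt = 0.1,
                                    write_every = 20, nominal_per_leaflet = 150,
                                    box_a = 12, box_c = 10) {
  sys <- build_membrane(neuronal_membrane_spec(nominal_per_leaflet = nominal_per_leaflet),
                        pentamer = build_pentamer(),
                        box = hexagonal_box(box_a, box_c), seed = seed)
  traj <- simulate_lipids(sys, truth, n_steps = n_steps, step_dt = step_dt,
                          write_every = write_every, seed = seed)
  list(system = sys, trajectory = traj)
}

#' Lipid-hierarchy recovery study
#'
#' Runs the reference synthetic system under [hierarchy_truth()] and reports
#' the recovered lipid ordering by both hierarchy statistics, computed on the
#' per-subunit contact table.
#'
#' @param seed integer seed.
#' @param n_steps integration steps.
#' @return list with `hierarchy_max`, `hierarchy_top20` (character vectors,
#'   most persistent lipid first), `table` (the [contact_table()]), and
#'   `recovered` (TRUE iff both statistics rank CHOL first and DOPS second).
#' @export
hierarchy_study <- function(seed, n_steps = 13320) {
  r <- synthetic_reference_run(hierarchy_truth(), seed = seed, n_steps = n_steps)
  cs <- contact_series(r$trajectory, r$system$topology)
  tab <- contact_table(cs, collapse_subunits = FALSE)
  h1 <- lipid_hierarchy(tab, "max")
  h2 <- lipid_hierarchy(tab, "mean-top-20")
  ok <- function(h) h[1] == "CHOL" && h[2] == "DOPS"
  list(hierarchy_max = as.character(h1), hierarchy_top20 = as.character(h2),
       table = tab, recovered = ok(h1) && ok(h2))
}

#' State-dependent interface-site study
#'
#' Paired common-seed runs under [interface_truth()] in the active and
#' inactive state; reports the cholesterol enrichment of the
#' subunit-interface wedges (mean over the five wedges) and the mean
#' interface penetration depth per state. The penetration threshold is three
#' times the bulk density of the extracellular anchor layer.
#'
#' @param seed integer seed (shared by both states).
#' @param n_steps integration steps per run.
#' @param voxel_size 3D density voxel (nm).
#' @param wedge_half_width_deg wedge angular half-width (degrees).
#' @return list with per-state `enrichment`, `depth` (nm), the two density
#'   grids, and `difference` (the [state_difference()] summary).
#' @export
interface_state_study <- function(seed, n_steps = 13320, voxel_size = 0.25,
                                  wedge_half_width_deg = 15) {
  out <- list()
  for (state in c("active", "inactive")) {
    r <- synthetic_reference_run(interface_truth(state), seed = seed,
                                 n_steps = n_steps)
    g <- density3d(r$trajectory, r$system$topology, "CHOL", "hydroxyl",
                   voxel_size = voxel_size)
    g$metadata$state <- state
    fp <- r$system$pentamer$footprint_radius
    z_leaflet <- box_center(r$system$box)[3] +
      r$system$spec$leaflet_z[["extracellular"]]
    enr <- mean(vapply(0:4, function(w)
      site_enrichment(g, site_definition("interface",
                                         wedge = list(index = w,
                                                      half_width_deg = wedge_half_width_deg,
                                                      leaflet = "extracellular")),
                      footprint_radius = fp)$enrichment, 0))
    th <- 3 * bulk_layer_density(g, z_leaflet, z_half = 0.15)
    depth <- mean(interface_penetration(g, threshold = th,
                                        footprint_radius = fp)$depth_nm)
    out[[state]] <- list(enrichment = enr, depth = depth, grid = g)
  }
  out$difference <- state_difference(out$active$grid, out$inactive$grid)
  out
}
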