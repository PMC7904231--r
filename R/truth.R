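# Planted ground truth for the synthetic test-bed: binding sites of known
# position, lipid selectivity, depth and state availability, plus diffusion
# and flip-flop rates. Everything downstream (densities, contact durations,
# site enrichment) can be validated against these knowns.

#' Define a planted lipid binding site
#'
#' A site is an attractive 2D Gaussian well `U(x) = -depth * exp(-|x - x_s|^2
#' / (2 width^2))` (depth in kT) acting on lipids of one type in one leaflet.
#' Its centre is given either by an anchor (angle about the pore axis plus
#' radial distance) or by a subunit-interface wedge index 0-4, in which case
#' the site sits at the interface midline (36 degrees off the first subunit
#' axis) and is always replicated five-fold under the C5 symmetry of the
#' protein. Anchored sites can also be C5-replicated on request.
#'
#' @param name site label.
#' @param leaflet `"extracellular"` or `"intracellular"`.
#' @param selectivity lipid type the site attracts.
#' @param well_depth well depth in kT (>= 0).
#' @param width Gaussian width (nm, > 0).
#' @param radius radial distance of the site centre from the pore axis (nm).
#' @param angle_deg anchor angle about the pore axis (degrees); ignored for
#'   wedge sites.
#' @param wedge interface wedge index 0-4, or NULL for an anchored site.
#' @param available_in character subset of `c("inactive", "active")`: receptor
#'   states in which the site exists.
#' @param c5_replicate replicate an anchored site five-fold (wedge sites
#'   always are).
#' @return object of class `planted_site`.
#' @export
planted_site <- function(name, leaflet, selectivity, well_depth, width,
                         radius, angle_deg = 0, wedge = NULL,
                         available_in = c("inactive", "active"),
                         c5_replicate = FALSE) {
  stopifnot(leaflet %in% LEAFLETS, well_depth >= 0, width > 0, radius >= 0)
  if (!all(available_in %in% c("inactive", "active")))
    stopf("available_in must be a subset of {inactive, active}")
  if (!is.null(wedge)) {
    stopifnot(wedge %in% 0:4)
    c5_replicate <- TRUE
    angle_deg <- 36 + 72 * wedge
  }
  structure(list(name = name, leaflet = leaflet, selectivity = selectivity,
                 well_depth = well_depth, width = width, radius = radius,
                 angle_deg = angle_deg, wedge = wedge,
                 available_in = available_in, c5_replicate = c5_replicate),
            class = "planted_site")
}

#' Assemble synthetic ground truth
#'
#' @param sites list of [planted_site()] objects.
#' @param diffusion named numeric, lateral diffusion coefficient per lipid
#'   type (nm^2/ns). Types not named fall back to `default_diffusion`.
#' @param flipflop_rate cholesterol leaflet-exchange rate
#'   (events/ns per molecule); only CHOL may flip.
#' @param state receptor state label, `"inactive"` or `"active"`.
#' @param default_diffusion fallback diffusion coefficient (nm^2/ns).
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(sites = list(),
                            diffusion = c(POPC = 0.03, POPE = 0.03, DOPS = 0.03,
                                          SM = 0.03, CHOL = 0.05),
                            flipflop_rate = 1e-4,
                            state = "inactive",
                            default_diffusion = 0.03) {
  stopifnot(state %in% c("inactive", "active"))
  if (any(!vapply(sites, inherits, TRUE, "planted_site")))
    stopf("sites must be planted_site objects")
  if (any(!is.finite(diffusion)) || any(diffusion < 0))
    stopf("diffusion coefficients must be finite and >= 0")
  if (!is.finite(flipflop_rate) || flipflop_rate < 0)
    stopf("flipflop_rate must be finite and >= 0")
  structure(list(sites = sites, diffusion = diffusion,
                 flipflop_rate = flipflop_rate, state = state,
                 default_diffusion = default_diffusion),
            class = "synthetic_truth")
}

# Site centre(s) in absolute in-plane coordinates (k x 2 matrix), given the
# pore-axis point. Wedge or c5-replicated sites return five rows.
site_centers <- function(site, axis_xy) {
  base <- site$angle_deg * pi / 180
  angles <- if (site$c5_replicate) base + 2 * pi * (0:4) / 5 else base
  cbind(axis_xy[1] + site$radius * cos(angles),
        axis_xy[2] + site$radius * sin(angles))
}

# Sites acting in a given receptor state.
active_sites <- function(truth) {
  Filter(function(s) truth$state %in% s$available_in, truth$sites)
}

diffusion_of <- function(truth, types) {
  d <- truth$diffusion[types]
  d[is.na(d)] <- truth$default_diffusion
  as.numeric(d)
}

#' Serialize synthetic truth to YAML
#'
#' @param truth [synthetic_truth()] object.
#' @param path output file.
#' @export
write_truth_yaml <- function(truth, path) {
  yaml::write_yaml(list(
    state = truth$state,
    flipflop_rate_per_ns = truth$flipflop_rate,
    diffusion_nm2_per_ns = as.list(truth$diffusion),
    sites = lapply(truth$sites, function(s) s[c(
      "name", "leaflet", "selectivity", "well_depth", "width", "radius",
      "angle_deg", "wedge", "available_in", "c5_replicate")])), path)
  invisible(path)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: state '%s', %d site(s), CHOL flip-flop %.2g /ns\n",
              x$state, length(x$sites), x$flipflop_rate))
  for (s in x$sites)
    cat(sprintf("  %s: %s %s, depth %.1f kT, width %.2f nm, r %.2f nm%s, in {%s}\n",
                s$name, s$selectivity, s$leaflet, s$well_depth, s$width, s$radius,
                if (s$c5_replicate) " (x5 C5)" else "",
                paste(s$available_in, collapse = ",")))
  invisible(x)
}
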