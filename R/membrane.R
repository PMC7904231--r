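# Asymmetric neuronal model membrane: composition spec and lipid-count
# apportionment.

LIPID_TYPES <- c("POPC", "POPE", "DOPS", "SM", "CHOL")
LEAFLETS <- c("extracellular", "intracellular")

#' Membrane composition specification
#'
#' Describes an asymmetric bilayer by per-leaflet mole percents for each lipid
#' type, the nominal lipid count per leaflet, the signed z-offset of each
#' leaflet's headgroup plane from the bilayer midplane, and the Gaussian noise
#' applied to headgroup z positions when building coordinates.
#'
#' Percents in each leaflet must be non-negative and sum to 100 within +/- 0.2:
#' published one-decimal compositions can sum to slightly off 100 (the default
#' extracellular column sums to 100.1), and that imprecision is preserved
#' rather than renormalized away.
#'
#' @param per_leaflet_percent named list with elements `extracellular` and
#'   `intracellular`, each a named numeric vector of mole percents by lipid type.
#' @param nominal_per_leaflet nominal lipid count per leaflet.
#' @param leaflet_z named numeric: signed headgroup-plane offset from the
#'   midplane (nm); extracellular positive, intracellular negative.
#' @param headgroup_noise_sd standard deviation of headgroup z placement (nm).
#' @return object of class `membrane_spec`.
#' @seealso [neuronal_membrane_spec()] for the default five-lipid composition.
#' @export
membrane_spec <- function(per_leaflet_percent,
                          nominal_per_leaflet = 150,
                          leaflet_z = c(extracellular = 1.8, intracellular = -1.8),
                          headgroup_noise_sd = 0.1) {
  if (!setequal(names(per_leaflet_percent), LEAFLETS))
    stopf("per_leaflet_percent must have elements %s", paste(LEAFLETS, collapse = ", "))
  for (lf in LEAFLETS) {
    p <- per_leaflet_percent[[lf]]
    if (is.null(names(p)) || any(!nzchar(names(p))))
      stopf("percents for leaflet '%s' must be a named vector", lf)
    if (any(p < 0)) stopf("invalid membrane spec: negative percent in leaflet '%s'", lf)
    tot <- sum(p)
    if (abs(tot - 100) > 0.2)
      stopf("invalid membrane spec: leaflet '%s' percents sum to %.2f (must be 100 +/- 0.2)",
            lf, tot)
  }
  stopifnot(nominal_per_leaflet > 0, headgroup_noise_sd >= 0)
  if (!setequal(names(leaflet_z), LEAFLETS)) stopf("leaflet_z must name both leaflets")
  structure(list(per_leaflet_percent = lapply(per_leaflet_percent[LEAFLETS], function(p) p),
                 nominal_per_leaflet = as.integer(nominal_per_leaflet),
                 leaflet_z = leaflet_z[LEAFLETS],
                 headgroup_noise_sd = headgroup_noise_sd),
            class = "membrane_spec")
}

#' Default human neuronal model membrane composition
#'
#' Five-lipid asymmetric composition of a simplified human neuronal plasma
#' membrane (mole percents): POPC 24.4/13.7, POPE 11.1/21.5, DOPS 0/16.9,
#' SM 19.9/3.0 and cholesterol 44.7/44.9 for the extracellular/intracellular
#' leaflet. The anionic lipid DOPS is confined to the intracellular leaflet.
#'
#' @inheritParams membrane_spec
#' @return object of class `membrane_spec`.
#' @examples
#' spec <- neuronal_membrane_spec()
#' apportion_counts(spec$per_leaflet_percent$extracellular, 1000)
#' @export
neuronal_membrane_spec <- function(nominal_per_leaflet = 150,
                                   leaflet_z = c(extracellular = 1.8, intracellular = -1.8),
                                   headgroup_noise_sd = 0.1) {
  membrane_spec(
    per_leaflet_percent = list(
      extracellular = c(POPC = 24.4, POPE = 11.1, DOPS = 0, SM = 19.9, CHOL = 44.7),
      intracellular = c(POPC = 13.7, POPE = 21.5, DOPS = 16.9, SM = 3.0, CHOL = 44.9)),
    nominal_per_leaflet = nominal_per_leaflet,
    leaflet_z = leaflet_z,
    headgroup_noise_sd = headgroup_noise_sd)
}

#' Apportion lipid counts from mole percents
#'
#' Converts mole percents to integer molecule counts by independent
#' round-half-up of `percent * nominal_n / 100` per lipid type. The leaflet
#' total may deviate from `nominal_n` when the percents do not sum to exactly
#' 100; that is intentional, so that realized mole fractions reproduce the
#' specified one-decimal percents exactly (e.g. a column summing to 100.1
#' yields 1001 lipids for nominal 1000).
#'
#' @param percent_map named numeric vector of mole percents by lipid type.
#' @param nominal_n nominal leaflet lipid count.
#' @return named integer vector of counts, same names and order as `percent_map`.
#' @examples
#' apportion_counts(c(POPC = 24.4, POPE = 11.1, DOPS = 0, SM = 19.9, CHOL = 44.7), 1000)
#' @export
apportion_counts <- function(percent_map, nominal_n) {
  if (any(percent_map < 0)) stopf("invalid spec: negative mole percent")
  stopifnot(nominal_n > 0)
  counts <- round_half_up(percent_map * nominal_n / 100)
  names(counts) <- names(percent_map)
  counts
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat("Membrane composition spec (mole %):\n")
  m <- do.call(rbind, x$per_leaflet_percent)
  print(m)
  cat(sprintf("nominal lipids per leaflet: %d; leaflet z: %+.2f / %+.2f nm; headgroup noise sd %.3f nm\n",
              x$nominal_per_leaflet, x$leaflet_z[1], x$leaflet_z[2], x$headgroup_noise_sd))
  invisible(x)
}
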