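# Topology container: one row per coarse-grained bead, fully annotated with
# molecule class, lipid type, residue, subunit and bead role. Plain data.frame
# with class "topology" so standard data-frame tooling keeps working.

BEAD_ROLES <- c("cationic-headgroup", "phosphate", "hydroxyl", "tail",
                "backbone", "sidechain", "other")
MOL_CLASSES <- c("protein", "lipid", "solvent", "other")

#' Construct a bead topology
#'
#' @param beads data.frame with columns `bead_id`, `bead_name`, `mol_id`,
#'   `mol_class`, `lipid_type` (NA for non-lipids), `resid`, `resname`,
#'   `subunit` (NA for non-protein), `role`.
#' @return `topology` object (a validated data.frame).
#' @export
topology <- function(beads) {
  need <- c("bead_id", "bead_name", "mol_id", "mol_class", "lipid_type",
            "resid", "resname", "subunit", "role")
  miss <- setdiff(need, names(beads))
  if (length(miss)) stopf("topology missing columns: %s", paste(miss, collapse = ", "))
  beads <- as.data.frame(beads)[, need]
  if (anyDuplicated(beads$bead_id)) stopf("bead ids must be unique")
  if (!identical(sort(beads$bead_id), seq_len(nrow(beads))))
    stopf("bead ids must be dense 1..n")
  if (!all(beads$mol_class %in% MOL_CLASSES))
    stopf("unknown molecule class: %s",
          paste(setdiff(unique(beads$mol_class), MOL_CLASSES), collapse = ", "))
  if (!all(beads$role %in% BEAD_ROLES))
    stopf("unknown bead role: %s",
          paste(setdiff(unique(beads$role), BEAD_ROLES), collapse = ", "))
  lip <- beads$mol_class == "lipid"
  if (any(lip & is.na(beads$lipid_type)))
    stopf("every lipid bead must carry a lipid_type")
  pro <- beads$mol_class == "protein"
  if (any(pro & (is.na(beads$resid) | is.na(beads$subunit))))
    stopf("every protein bead must carry residue id and subunit id")
  class(beads) <- c("topology", "data.frame")
  beads
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("Topology: %d beads, %d molecules (%d protein beads, %d lipid beads)\n",
              nrow(x), length(unique(x$mol_id)),
              sum(x$mol_class == "protein"), sum(x$mol_class == "lipid")))
  lt <- table(x$lipid_type[x$mol_class == "lipid" & !duplicated(x$mol_id)])
  if (length(lt)) { cat("Lipid molecules by type:\n"); print(lt) }
  invisible(x)
}

#' Default residue/bead naming configuration
#'
#' Maps residue names to lipid types and bead names to roles. The defaults
#' cover the Martini names for the five membrane lipids used here
#' (POPC, POPE, DOPS, DPSM for sphingomyelin, CHOL) and their headgroup beads
#' (NC3 choline, NH3 ammonium, CNO serine, PO4 phosphate, ROH hydroxyl) plus
#' generic tail bead prefixes (C*, D*, R*, GL*). Protein beads use BB
#' (backbone) and SC* (sidechain). Editable: pass your own mapping or load one
#' from YAML with [read_naming_config()].
#'
#' @return list with elements `resname_to_lipid` (named character) and
#'   `bead_role_patterns` (data.frame of regex pattern -> role, first match wins).
#' @export
default_naming_config <- function() {
  list(
    resname_to_lipid = c(POPC = "POPC", POPE = "POPE", DOPS = "DOPS",
                         DPSM = "SM", SM = "SM", CHOL = "CHOL"),
    bead_role_patterns = data.frame(
      pattern = c("^NC3", "^NH3", "^PO4", "^ROH", "^BB", "^SC", "^GL",
                  "^C", "^D", "^R"),
      role = c("cationic-headgroup", "cationic-headgroup", "phosphate",
               "hydroxyl", "backbone", "sidechain", "tail", "tail", "tail",
               "tail"),
      stringsAsFactors = FALSE))
}

#' Read a naming configuration from YAML
#'
#' @param path YAML file with keys `resname_to_lipid` (map) and
#'   `bead_role_patterns` (list of `{pattern, role}`).
#' @return naming config list as in [default_naming_config()].
#' @export
read_naming_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_naming_config()
  if (!is.null(y$resname_to_lipid))
    cfg$resname_to_lipid <- unlist(y$resname_to_lipid)
  if (!is.null(y$bead_role_patterns))
    cfg$bead_role_patterns <- do.call(rbind, lapply(y$bead_role_patterns, function(e)
      data.frame(pattern = e$pattern, role = e$role, stringsAsFactors = FALSE)))
  cfg
}

bead_role_from_name <- function(bead_name, cfg) {
  role <- rep("other", length(bead_name))
  pending <- rep(TRUE, length(bead_name))
  for (i in seq_len(nrow(cfg$bead_role_patterns))) {
    hit <- pending & grepl(cfg$bead_role_patterns$pattern[i], bead_name)
    role[hit] <- cfg$bead_role_patterns$role[i]
    pending <- pending & !hit
  }
  role
}

# Anchor bead of each lipid molecule: phosphate for phospholipids, hydroxyl
# for cholesterol. Returns a data.frame (mol_id, lipid_type, bead_id) with one
# row per lipid molecule; errors if a lipid lacks its anchor.
lipid_anchors <- function(top) {
  lip <- top[top$mol_class == "lipid", ]
  want <- ifelse(lip$lipid_type == "CHOL", "hydroxyl", "phosphate")
  anch <- lip[lip$role == want, c("mol_id", "lipid_type", "bead_id")]
  mols <- unique(lip$mol_id)
  missing <- setdiff(mols, anch$mol_id)
  if (length(missing))
    stopf("lipid molecule(s) without an anchor bead: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  dup <- anch$mol_id[duplicated(anch$mol_id)]
  if (length(dup))
    stopf("lipid molecule(s) with multiple anchor beads: %s",
          paste(utils::head(dup, 5), collapse = ", "))
  anch[order(anch$mol_id), ]
}
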