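## Sidecar topology table: one row per atom, carrying everything the
## analyses need (species, subregion class, mass, vdW radius, H-bond roles).

TOPOLOGY_COLUMNS <- c(
  "atom_id", "atom_name", "residue_id", "species", "subregion", "element",
  "mass_amu", "vdw_radius_nm", "is_donor", "is_hydrogen", "is_acceptor",
  "donor_of", "leaflet_hint"
)

SUBREGION_LEVELS <- c("choline", "phosphate", "glycerol", "tails",
                      "sterol", "ligand", "other")

## Subregions counted as the lipid "headgroup" for SASA partitioning and
## density-based region boundaries; everything in "tails" is tail.
HEADGROUP_SUBREGIONS <- c("choline", "phosphate", "glycerol", "sterol")

#' Construct and validate a topology table
#'
#' A topology is a plain `data.frame` (class `c("topology", "data.frame")`)
#' with one row per atom and the columns `atom_id`, `atom_name`,
#' `residue_id`, `species`, `subregion`, `element`, `mass_amu`,
#' `vdw_radius_nm`, `is_donor`, `is_hydrogen`, `is_acceptor`, `donor_of`
#' (atom_id of the bonded donor heavy atom, `NA` for non-hydrogens) and
#' `leaflet_hint` (`"upper"`, `"lower"` or `NA`).
#'
#' @param df data.frame with the columns above.
#' @return validated `topology` object.
#' @export
as_topology <- function(df) {
  missing_cols <- setdiff(TOPOLOGY_COLUMNS, names(df))
  if (length(missing_cols))
    stop_input("topology is missing required column(s): %s",
               paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(df$subregion), SUBREGION_LEVELS)
  if (length(bad))
    stop_input("unknown subregion label(s): %s (must be one of %s)",
               paste(bad, collapse = ", "),
               paste(SUBREGION_LEVELS, collapse = ", "))
  if (anyDuplicated(df$atom_id))
    stop_input("duplicate atom_id in topology")
  if (any(!is.finite(df$mass_amu)) || any(df$mass_amu < 0))
    stop_input("mass_amu must be finite and non-negative")
  if (any(!is.finite(df$vdw_radius_nm)) || any(df$vdw_radius_nm <= 0))
    stop_input("vdw_radius_nm must be positive")
  hyd <- which(df$is_hydrogen)
  if (length(hyd)) {
    orphan <- hyd[is.na(df$donor_of[hyd]) |
                    !(df$donor_of[hyd] %in% df$atom_id)]
    if (length(orphan))
      stop_input("hydrogen atom(s) without a recorded donor parent: atom_id %s",
                 paste(df$atom_id[orphan], collapse = ", "))
  }
  class(df) <- c("topology", "data.frame")
  df
}

#' Read a topology TSV
#'
#' @param path path to a tab-separated topology file with the standard
#'   column header (see [as_topology()]).
#' @return a `topology` object.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop_input("topology file not found: %s", path)
  if (file.size(path) == 0) stop_input("topology file is empty: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  for (col in c("is_donor", "is_hydrogen", "is_acceptor"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  as_topology(df)
}

#' Write a topology TSV
#'
#' @param topology a `topology` object.
#' @param path output path.
#' @export
write_topology <- function(topology, path) {
  utils::write.table(topology[, TOPOLOGY_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

## Index helpers -----------------------------------------------------------

#' Atom indices by species / subregion / role
#'
#' @param topology a `topology` object.
#' @param species,subregion optional character vectors to filter by.
#' @param heavy_only drop hydrogens.
#' @return integer row indices into the topology.
#' @export
select_atoms <- function(topology, species = NULL, subregion = NULL,
                         heavy_only = FALSE) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(species)) keep <- keep & topology$species %in% species
  if (!is.null(subregion)) keep <- keep & topology$subregion %in% subregion
  if (heavy_only) keep <- keep & !topology$is_hydrogen
  which(keep)
}

## One headgroup reference atom per lipid residue: the phosphorus bead "P"
## for phospholipids, the hydroxyl oxygen "O3" for sterols.  Ligand and
## "other" residues have none.
reference_atom_indices <- function(topology) {
  idx <- which(topology$atom_name %in% c("P", "O3") &
                 !(topology$subregion %in% c("ligand", "other")))
  idx
}

## Residue table of lipid molecules with their reference atom row index.
lipid_reference_table <- function(topology) {
  ref <- reference_atom_indices(topology)
  lipid_res <- unique(topology$residue_id[!(topology$subregion %in%
                                              c("ligand", "other"))])
  m <- match(lipid_res, topology$residue_id[ref])
  if (anyNA(m)) {
    bad <- lipid_res[is.na(m)]
    stop_input("lipid residue(s) without a headgroup reference atom (P/O3): %s",
               paste(bad, collapse = ", "))
  }
  data.frame(residue_id = lipid_res,
             species = topology$species[ref][m],
             ref_atom = ref[m])
}
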