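# Chemical dictionary for ligand species: atom inventory, hydroxyl oxygens,
# ring membership (beta / epsilon terminal rings) and the end-to-end inversion
# pairing used to dock a conformer in the flipped orientation.
#
# Entries for real residues ship as JSON under extdata; synthetic species
# register their own entries at run time.

.tunneldock_registry <- new.env(parent = emptyenv())

load_shipped_dictionary <- function() {
  if (!is.null(.tunneldock_registry$.shipped)) return(.tunneldock_registry$.shipped)
  path <- system.file("extdata", "ligand_dictionary.json", package = "tunneldock")
  entries <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  .tunneldock_registry$.shipped <- entries
  entries
}

validate_dictionary_entry <- function(entry, name) {
  stopifnot(is.list(entry))
  req <- c("heavy_atoms", "hydroxyl", "rings", "inversion")
  miss <- setdiff(req, names(entry))
  if (length(miss) > 0)
    stop("dictionary entry '", name, "' lacks fields: ", paste(miss, collapse = ", "))
  if (length(entry$hydroxyl) != 2L)
    stop("dictionary entry '", name, "' must name exactly 2 hydroxyl oxygens")
  if (!all(c("beta", "epsilon") %in% names(entry$rings)))
    stop("dictionary entry '", name, "' must define 'beta' and 'epsilon' rings")
  inv <- entry$inversion
  pairs <- c(unlist(inv), names(inv))
  if (!all(pairs %in% entry$heavy_atoms))
    stop("dictionary entry '", name, "' inversion names atoms outside heavy_atoms")
  # complete the inversion to a symmetric map and check it is an involution
  full <- c(unlist(inv), names(inv))
  names(full) <- c(names(inv), unlist(inv))
  if (any(duplicated(names(full))) &&
      !identical(full[names(full)], full[names(full)]))
    stop("dictionary entry '", name, "' inversion is not one-to-one")
  entry$inversion_full <- full
  entry
}

#' Register a ligand species in the chemical dictionary
#'
#' Adds (or replaces) a run-time dictionary entry describing a two-ring diol
#' ligand species: its heavy-atom inventory, the two terminal hydroxyl
#' oxygens, membership of the beta and epsilon terminal rings, and the
#' atom-name pairing that exchanges the two ends of the molecule
#' ("inversion"). Synthetic generators call this automatically.
#'
#' @param residue_name Three-letter (or shorter) residue code.
#' @param heavy_atoms Character vector of all heavy-atom names, in canonical
#'   order.
#' @param hydroxyl Character vector of exactly two hydroxyl oxygen names.
#' @param rings Named list with components `beta` and `epsilon`, each a
#'   character vector of ring atom names.
#' @param inversion Named character vector mapping each atom of one half to
#'   its partner in the other half; completed symmetrically, and self-paired
#'   atoms may be omitted (they map to themselves).
#' @return The validated entry, invisibly.
#' @export
register_ligand_species <- function(residue_name, heavy_atoms, hydroxyl,
                                    rings, inversion) {
  entry <- validate_dictionary_entry(
    list(heavy_atoms = heavy_atoms, hydroxyl = hydroxyl,
         rings = rings, inversion = as.list(inversion)),
    residue_name)
  assign(residue_name, entry, envir = .tunneldock_registry)
  invisible(entry)
}

#' Look up a ligand species in the chemical dictionary
#'
#' Run-time registrations take precedence over the shipped JSON dictionary.
#'
#' @param residue_name Residue code to look up.
#' @return Dictionary entry (list) with a completed `inversion_full` map.
#' @export
ligand_dictionary <- function(residue_name) {
  if (exists(residue_name, envir = .tunneldock_registry, inherits = FALSE))
    return(get(residue_name, envir = .tunneldock_registry))
  shipped <- load_shipped_dictionary()
  if (!residue_name %in% names(shipped))
    stop("no dictionary entry for residue '", residue_name, "'")
  validate_dictionary_entry(shipped[[residue_name]], residue_name)
}
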