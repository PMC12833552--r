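#' Water-bridge inventory of a hydrogen-free crystallographic model
#'
#' Applies the bridge machinery to a single-model structure without
#' hydrogens (e.g. a crystal structure with crystallographic waters), using
#' the distance-only heavy-atom criterion: every N/O/S atom is both donor
#' and acceptor candidate and a link exists when two such atoms lie within
#' `heavy_cutoff`. The default cutoff of 3.5 Angstrom is the standard
#' crystallographic hydrogen-bond practice, wider than the 3.0 Angstrom
#' molecular-dynamics criterion because hydrogen positions are unknown.
#'
#' @param top an [topology()] of the structure.
#' @param coords n_atoms x 3 coordinate matrix (defaults to the topology's
#'   reference coordinates).
#' @param group1,group2 atom index sets of the two protein sides (e.g. from
#'   [select_atoms()]).
#' @param heavy_cutoff heavy-atom distance cutoff, Angstrom.
#' @param max_order maximum number of mediating waters (default 2).
#' @return data.frame of residue-level bridges: columns `pair`, `atom1`,
#'   `atom2`, `order`, `waters`. Empty (with a warning) when the structure
#'   has no waters.
#' @export
crystal_bridge_inventory <- function(top, coords = top$ref_coords,
                                     group1, group2,
                                     heavy_cutoff = 3.5, max_order = 2) {
  if (!any(top$atoms$is_water)) {
    warning("structure contains no waters; bridge inventory is empty")
    return(data.frame(frame = integer(0), atom1 = integer(0),
                      atom2 = integer(0), order = integer(0),
                      waters = character(0), pair = character(0)))
  }
  crit <- hbond_criteria(heavy_only = TRUE, heavy_cutoff = heavy_cutoff)
  da <- assign_donors_acceptors(top, heavy_only = TRUE)
  hb <- detect_hbonds(coords, da$donors, da$acceptors, crit)
  enumerate_water_bridges(hb, top, group1, group2, max_order = max_order)
}

#' Strip hydrogens from a topology/trajectory pair
#'
#' Utility for emulating crystallographic (hydrogen-free) structures from
#' synthetic systems: drops all hydrogen atoms and renumbers nothing else.
#' Stripped waters keep their single oxygen and remain flagged as waters.
#'
#' @param top an [topology()].
#' @param traj optional congruent [trajectory()].
#' @return list with `topology`, `trajectory` (NULL if not given) and `map`
#'   (old atom index for each kept atom).
#' @export
strip_hydrogens <- function(top, traj = NULL) {
  keep <- which(top$atoms$element != "H")
  atoms <- top$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  newtop <- structure(
    list(atoms = atoms, h_attach = list(),
         ref_coords = top$ref_coords[keep, , drop = FALSE]),
    class = "iw_topology")
  newtraj <- NULL
  if (!is.null(traj))
    newtraj <- trajectory(lapply(traj$coords, function(m)
      m[keep, , drop = FALSE]), box = traj$box)
  list(topology = newtop, trajectory = newtraj, map = keep)
}
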