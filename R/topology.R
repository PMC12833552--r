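#' @keywords internal
"_PACKAGE"

WATER_RESNAMES <- c("HOH", "WAT", "SOL", "TIP3", "TIP3P", "SPC")
BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Construct a molecular topology
#'
#' A topology holds the chemical identity of every atom in a system: serial
#' number, atom name, element, residue name, author residue number, chain id
#' and a water flag, together with a covalent hydrogen-attachment map
#' (heavy atom -> indices of its bonded hydrogens). Coordinates live in a
#' separate [trajectory()] object; the topology only carries a reference
#' coordinate set (typically the first frame) used for bond inference.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `chain`, `is_water` (one row per atom, file order).
#' @param h_attach list mapping heavy-atom row index (as character) to an
#'   integer vector of attached hydrogen row indices. Inferred from
#'   `ref_coords` when `NULL`.
#' @param ref_coords numeric matrix (n_atoms x 3, Angstrom) of reference
#'   coordinates used for covalent inference; may be `NULL` if `h_attach`
#'   is supplied.
#' @return An object of class `iw_topology`.
#' @export
topology <- function(atoms, h_attach = NULL, ref_coords = NULL) {
  req <- c("serial", "name", "element", "resname", "resno", "chain", "is_water")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0L)
    stop("atoms is missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$serial))
    stop("atom serial numbers must be unique")
  atoms <- atoms[, req]
  rownames(atoms) <- NULL
  if (is.null(h_attach)) {
    if (is.null(ref_coords))
      stop("either h_attach or ref_coords must be given")
    h_attach <- infer_h_attach(atoms, ref_coords)
  }
  top <- structure(
    list(atoms = atoms, h_attach = h_attach, ref_coords = ref_coords),
    class = "iw_topology")
  validate_topology(top)
  top
}

validate_topology <- function(top) {
  atoms <- top$atoms
  for (heavy in names(top$h_attach)) {
    hs <- top$h_attach[[heavy]]
    if (any(atoms$element[hs] != "H"))
      stop("hydrogen attachment map points at non-hydrogen atom(s) for heavy atom ",
           heavy)
  }
  wat <- atoms[atoms$is_water, , drop = FALSE]
  if (nrow(wat) > 0L) {
    grp <- split(wat$element, paste(wat$chain, wat$resno))
    # hydrated: 1 O + 2 H; crystallographic (hydrogen-free): bare O
    bad <- vapply(grp, function(e)
      sum(e == "O") != 1L || !sum(e == "H") %in% c(0L, 2L), logical(1))
    if (any(bad))
      stop("water group(s) without exactly 1 O and 0 or 2 H: ",
           paste(names(grp)[bad], collapse = ", "))
  }
  invisible(top)
}

#' @export
print.iw_topology <- function(x, ...) {
  a <- x$atoms
  cat("iw_topology:", nrow(a), "atoms,",
      length(unique(a$chain[!a$is_water])), "protein chain(s),",
      length(unique(paste(a$chain, a$resno)[a$is_water])), "water(s)\n")
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Construct a trajectory
#'
#' Ordered frames of Cartesian coordinates (Angstrom) congruent with a
#' topology. Frames are indexed from 1 in R; an optional per-frame
#' orthorhombic box (lengths in Angstrom) can be attached for minimum-image
#' handling in distance computations.
#'
#' @param coords list of numeric n_atoms x 3 matrices, one per frame.
#' @param box optional numeric matrix (n_frames x 3) of box edge lengths.
#' @return An object of class `iw_trajectory`.
#' @export
trajectory <- function(coords, box = NULL) {
  if (length(coords) < 1L) stop("trajectory needs at least one frame")
  na <- nrow(coords[[1]])
  ok <- vapply(coords, function(m) is.matrix(m) && nrow(m) == na &&
                 ncol(m) == 3L && all(is.finite(m)), logical(1))
  if (!all(ok))
    stop("all frames must be finite n_atoms x 3 matrices with equal atom count")
  if (!is.null(box)) {
    box <- rbind(box)
    if (nrow(box) == 1L) box <- box[rep(1L, length(coords)), , drop = FALSE]
    if (nrow(box) != length(coords) || ncol(box) != 3L)
      stop("box must be one row of 3 lengths or one row per frame")
  }
  structure(list(coords = coords, box = box), class = "iw_trajectory")
}

#' @export
print.iw_trajectory <- function(x, ...) {
  cat("iw_trajectory:", length(x$coords), "frame(s),",
      nrow(x$coords[[1]]), "atoms",
      if (!is.null(x$box)) "(boxed)" else "(no box)", "\n")
  invisible(x)
}

n_frames <- function(traj) length(traj$coords)

#' Number of frames / atoms in a trajectory
#'
#' @param traj an `iw_trajectory`.
#' @return Integer count.
#' @export
traj_n_frames <- function(traj) length(traj$coords)

#' @rdname traj_n_frames
#' @export
traj_n_atoms <- function(traj) nrow(traj$coords[[1]])

# Hydrogens are attached to the nearest heavy atom within 1.2 A in the
# reference frame, preferring a heavy atom of the same residue.
infer_h_attach <- function(atoms, coords, max_dist = 1.2) {
  h_idx <- which(atoms$element == "H")
  heavy_idx <- which(atoms$element != "H")
  out <- list()
  if (length(h_idx) == 0L || length(heavy_idx) == 0L) return(out)
  resid_key <- paste(atoms$chain, atoms$resno)
  for (h in h_idx) {
    d <- sqrt(colSums((t(coords[heavy_idx, , drop = FALSE]) - coords[h, ])^2))
    within <- heavy_idx[d <= max_dist]
    if (length(within) == 0L) next
    same <- within[resid_key[within] == resid_key[h]]
    pool <- if (length(same) > 0L) same else within
    dp <- d[match(pool, heavy_idx)]
    heavy <- pool[which.min(dp)]
    key <- as.character(heavy)
    out[[key]] <- c(out[[key]], h)
  }
  out
}

# Water molecule id for each atom row: integer id shared by the 3 atoms of a
# water group, NA for non-water atoms. Ids follow first appearance order.
water_ids <- function(top) {
  a <- top$atoms
  key <- ifelse(a$is_water, paste(a$chain, a$resno), NA)
  ids <- rep(NA_integer_, nrow(a))
  uk <- unique(key[!is.na(key)])
  ids[!is.na(key)] <- match(key[!is.na(key)], uk)
  ids
}

# Residue-level label in the field's naming style, e.g. "Lys48".
residue_label <- function(resname, resno) {
  nm <- paste0(substr(resname, 1, 1), tolower(substr(resname, 2, nchar(resname))))
  paste0(nm, resno)
}
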