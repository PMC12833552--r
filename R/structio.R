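#' Read a multi-model PDB file into a topology and trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one trajectory frame; a file without
#' `MODEL` records yields a single frame. Elements are taken from the element
#' column when present and otherwise inferred from the atom name. Covalent
#' hydrogen attachment is inferred from atom names and a 1.2 Angstrom distance
#' cutoff in the first frame. Author residue numbering is preserved untouched.
#'
#' @param path path to a fixed-column PDB file.
#' @return list with elements `topology` (an [topology()] object) and
#'   `trajectory` (an [trajectory()] object).
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # contract checks bio3d does not report in this form: per-model atom counts
  # and coordinate parseability, with model ids / line numbers in the message
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) > 0L) {
    model_of <- findInterval(which(is_atom), model_starts)
    counts <- tabulate(model_of, nbins = length(model_starts))
    if (length(unique(counts[counts > 0])) > 1L) {
      ref <- counts[1]
      bad <- which(counts != ref)[1]
      stop("inconsistent atom counts across models: MODEL ", bad,
           " has ", counts[bad], " atoms, expected ", ref)
    }
  }
  atom_lines <- which(is_atom)
  xyz_txt <- substr(lines[atom_lines], 31, 54)
  xs <- suppressWarnings(as.numeric(substr(xyz_txt, 1, 8)))
  ys <- suppressWarnings(as.numeric(substr(xyz_txt, 9, 16)))
  zs <- suppressWarnings(as.numeric(substr(xyz_txt, 17, 24)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad) > 0L)
    stop("unparseable ATOM record at line ", atom_lines[bad[1]], " of ", path)

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  need <- is.na(elem) | trimws(elem) == ""
  elem[need] <- infer_element(at$elety[need])
  elem <- trimws(elem)
  chain <- at$chain
  chain[is.na(chain)] <- " "
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = elem,
    resname = trimws(at$resid),
    resno = at$resno,
    chain = chain,
    is_water = trimws(at$resid) %in% WATER_RESNAMES,
    stringsAsFactors = FALSE)
  # serials may repeat across MODEL blocks in bio3d output for multi=TRUE;
  # the atom table is the first model's
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nfr <- nrow(xyz)
  na <- ncol(xyz) / 3
  if (na != nrow(atoms)) atoms <- atoms[seq_len(na), , drop = FALSE]
  coords <- lapply(seq_len(nfr), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  box <- NULL
  cryst <- lines[rec == "CRYST1"]
  if (length(cryst) > 0L) {
    abc <- suppressWarnings(as.numeric(c(substr(cryst[1], 7, 15),
                                         substr(cryst[1], 16, 24),
                                         substr(cryst[1], 25, 33))))
    if (all(is.finite(abc)) && all(abc > 1)) box <- matrix(abc, nrow = 1)
  }
  top <- topology(atoms, ref_coords = coords[[1]])
  list(topology = top, trajectory = trajectory(coords, box = box))
}

# Element from PDB atom name: strip digits/primes, first remaining letter,
# except 2-letter names starting with a digit (e.g. "1HG") which are hydrogens
# by convention, and names like "HW1"/"OW" where the leading letter rules.
infer_element <- function(name) {
  name <- trimws(name)
  stripped <- gsub("[0-9']", "", name)
  el <- toupper(substr(stripped, 1, 1))
  el[el == ""] <- "X"
  el
}

#' Write a topology and trajectory as a multi-model PDB file
#'
#' Fixed-column PDB output with one `MODEL`/`ENDMDL` block per frame
#' (`ATOM` records for protein, `HETATM` for waters). Coordinates are
#' written with 3 decimals, the format's precision.
#'
#' @param top an [topology()] object.
#' @param traj an [trajectory()] object congruent with `top`, or a single
#'   n_atoms x 3 coordinate matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(top, traj, path) {
  if (is.matrix(traj)) traj <- trajectory(list(traj))
  a <- top$atoms
  if (nrow(a) != nrow(traj$coords[[1]]))
    stop("topology and trajectory atom counts differ")
  rectype <- ifelse(a$is_water, "HETATM", "ATOM  ")
  # atom name starts in column 14 for 1-3 char names (column 13 is for
  # 4-char names or 2-char element symbols)
  nm <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
               sprintf(" %-3s", a$name))
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(traj$box)) {
    b <- traj$box[1, ]
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      b[1], b[2], b[3], 90, 90, 90), con)
  }
  multi <- n_frames(traj) > 1L
  for (f in seq_len(n_frames(traj))) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[[f]]
    writeLines(sprintf(
      "%s%5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rectype, a$serial %% 100000L, nm, substr(a$resname, 1, 4), a$chain,
      a$resno, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms by a small query grammar
#'
#' Clauses joined by `and`; supported clauses: `chain <id>`,
#' `resno <a>:<b>` or `resno <n> <n> ...`, `name <NAME> <NAME> ...`,
#' `water`, `not water` (synonym `protein`), `backbone` (atom names
#' N, CA, C, O on non-water residues). Matching is deterministic and
#' order-preserving: indices are returned in topology order.
#'
#' @param top an [topology()] object.
#' @param query selection string, e.g. `"chain A and backbone"`.
#' @return integer vector of atom row indices (possibly empty). An unknown
#'   chain or residue produces an empty result with a warning, not an error.
#' @export
select_atoms <- function(top, query) {
  if (!is.character(query) || length(query) != 1L || !nzchar(trimws(query)))
    stop("malformed selection query: expected a non-empty string")
  a <- top$atoms
  keep <- rep(TRUE, nrow(a))
  clauses <- strsplit(trimws(query), "\\s+and\\s+")[[1]]
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    head <- tolower(toks[1])
    if (head == "not" && length(toks) == 2L && tolower(toks[2]) == "water") {
      keep <- keep & !a$is_water
    } else if (head == "water") {
      keep <- keep & a$is_water
    } else if (head == "protein") {
      keep <- keep & !a$is_water
    } else if (head == "backbone") {
      keep <- keep & !a$is_water & a$name %in% BACKBONE_NAMES
    } else if (head == "chain") {
      if (length(toks) < 2L) stop("malformed selection clause: ", cl)
      if (!any(a$chain %in% toks[-1]))
        warning("no atoms in chain(s) ", paste(toks[-1], collapse = ","))
      keep <- keep & a$chain %in% toks[-1]
    } else if (head == "resno") {
      if (length(toks) < 2L) stop("malformed selection clause: ", cl)
      nums <- unlist(lapply(toks[-1], function(t) {
        if (grepl(":", t, fixed = TRUE)) {
          ab <- as.integer(strsplit(t, ":", fixed = TRUE)[[1]])
          if (length(ab) != 2L || anyNA(ab))
            stop("malformed residue range: ", t)
          seq(ab[1], ab[2])
        } else {
          v <- suppressWarnings(as.integer(t))
          if (is.na(v)) stop("malformed residue number: ", t)
          v
        }
      }))
      if (!any(a$resno %in% nums))
        warning("no atoms with residue number(s) in: ", cl)
      keep <- keep & a$resno %in% nums
    } else if (head == "name") {
      if (length(toks) < 2L) stop("malformed selection clause: ", cl)
      keep <- keep & a$name %in% toks[-1]
    } else {
      stop("malformed selection query, unknown clause: ", cl)
    }
  }
  which(keep)
}
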