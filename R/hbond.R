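#' Geometric hydrogen-bond criteria
#'
#' The criteria used throughout the package: a hydrogen bond exists between a
#' donor heavy atom D (carrying a hydrogen H) and an acceptor heavy atom A
#' when the D-A distance is at most `da_cutoff` and the D-H-A angle (vertex
#' at the hydrogen; 180 degrees = linear) is at least `dha_min_angle`. Both
#' boundaries are inclusive. `heavy_only` switches to a distance-only
#' criterion between polar heavy atoms (cutoff `heavy_cutoff`), for
#' structures without hydrogens such as crystallographic models.
#'
#' @param da_cutoff donor-acceptor distance cutoff in Angstrom (default 3.0).
#' @param dha_min_angle minimum D-H-A angle in degrees (default 120).
#' @param heavy_only logical; distance-only mode for hydrogen-free structures.
#' @param heavy_cutoff heavy-atom distance cutoff in Angstrom (default 3.5),
#'   used only when `heavy_only = TRUE`.
#' @return An object of class `iw_hbond_criteria`.
#' @export
hbond_criteria <- function(da_cutoff = 3.0, dha_min_angle = 120,
                           heavy_only = FALSE, heavy_cutoff = 3.5) {
  if (da_cutoff <= 0) stop("da_cutoff must be positive")
  if (dha_min_angle <= 0 || dha_min_angle > 180)
    stop("dha_min_angle must lie in (0, 180]")
  if (heavy_cutoff <= 0) stop("heavy_cutoff must be positive")
  structure(list(da_cutoff = da_cutoff, dha_min_angle = dha_min_angle,
                 heavy_only = isTRUE(heavy_only), heavy_cutoff = heavy_cutoff),
            class = "iw_hbond_criteria")
}

#' Assign hydrogen-bond donors and acceptors
#'
#' Donors are N, O or S heavy atoms with at least one covalently attached
#' hydrogen, one donor entry per attached hydrogen. Acceptors are all O and S
#' atoms, and N atoms that are not quaternary (heavy-atom bonds plus attached
#' hydrogens under four). A water oxygen is therefore both a double donor and
#' an acceptor. Carbon never donates or accepts. In `heavy_only` mode every
#' polar (N/O/S) atom is listed as a hydrogen-less donor and as an acceptor.
#'
#' @param top an [topology()] with reference coordinates (used to count
#'   heavy-atom neighbours of nitrogen within 1.7 Angstrom).
#' @param heavy_only logical, see [hbond_criteria()].
#' @return list with `donors` (data.frame `donor`, `hydrogen` atom indices;
#'   `hydrogen` is `NA` in heavy-only mode) and `acceptors` (integer atom
#'   indices).
#' @export
assign_donors_acceptors <- function(top, heavy_only = FALSE) {
  a <- top$atoms
  polar <- which(a$element %in% c("N", "O", "S"))
  if (heavy_only) {
    return(list(donors = data.frame(donor = polar, hydrogen = NA_integer_),
                acceptors = polar))
  }
  nh <- integer(nrow(a))
  hs <- top$h_attach
  for (k in names(hs)) nh[as.integer(k)] <- length(hs[[k]])

  don <- polar[nh[polar] > 0L]
  donors <- if (length(don) > 0L) {
    do.call(rbind, lapply(don, function(i)
      data.frame(donor = i, hydrogen = hs[[as.character(i)]])))
  } else data.frame(donor = integer(0), hydrogen = integer(0))

  acc_os <- polar[a$element[polar] %in% c("O", "S")]
  acc_n <- polar[a$element[polar] == "N"]
  if (length(acc_n) > 0L && !is.null(top$ref_coords)) {
    heavy <- which(a$element != "H")
    keep <- vapply(acc_n, function(i) {
      d <- sqrt(colSums((t(top$ref_coords[heavy, , drop = FALSE]) -
                           top$ref_coords[i, ])^2))
      nbond <- sum(d > 1e-6 & d <= 1.7)
      nbond + nh[i] < 4L
    }, logical(1))
    acc_n <- acc_n[keep]
  }
  list(donors = donors, acceptors = sort(c(acc_os, acc_n)))
}

# Pairwise displacement components with optional orthorhombic minimum image.
# `box_len` is a scalar (delta holds one coordinate component) or a length-3
# vector (delta is an n x 3 displacement matrix).
min_image <- function(delta, box_len) {
  if (is.null(box_len)) return(delta)
  if (length(box_len) == 1L)
    return(delta - box_len * round(delta / box_len))
  for (k in seq_along(box_len))
    delta[, k] <- delta[, k] - box_len[k] * round(delta[, k] / box_len[k])
  delta
}

#' Detect hydrogen bonds in one coordinate frame
#'
#' Returns exactly the donor-acceptor pairs satisfying the criteria
#' (inclusive boundaries). With hydrogens, the D-H-A angle has its vertex at
#' the hydrogen; in heavy-only mode only the heavy-atom distance is tested
#' and each unordered polar pair is reported once. Minimum-image convention
#' is applied only when a box is supplied.
#'
#' @param coords numeric n_atoms x 3 matrix (Angstrom).
#' @param donors,acceptors from [assign_donors_acceptors()].
#' @param criteria an [hbond_criteria()].
#' @param box optional orthorhombic box lengths (length-3 numeric).
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `distance`, `angle` (angle is `NA` in heavy-only mode).
#' @export
detect_hbonds <- function(coords, donors, acceptors,
                          criteria = hbond_criteria(), box = NULL) {
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0))
  if (nrow(donors) == 0L || length(acceptors) == 0L) return(empty)
  dn <- donors$donor
  hy <- donors$hydrogen
  nd <- length(dn); na <- length(acceptors)
  cutoff <- if (criteria$heavy_only) criteria$heavy_cutoff else criteria$da_cutoff

  dxyz <- coords[dn, , drop = FALSE]
  axyz <- coords[acceptors, , drop = FALSE]
  dd2 <- matrix(0, nd, na)
  deltas <- vector("list", 3)
  for (k in 1:3) {
    dk <- min_image(outer(dxyz[, k], axyz[, k], "-"),
                    if (is.null(box)) NULL else box[k])
    deltas[[k]] <- dk
    dd2 <- dd2 + dk^2
  }
  dist <- sqrt(dd2)
  same <- outer(dn, acceptors, "==")
  hit <- dist <= cutoff & !same

  if (!criteria$heavy_only && any(hit)) {
    idx <- which(hit, arr.ind = TRUE)
    h <- hy[idx[, 1]]
    dpos <- coords[dn[idx[, 1]], , drop = FALSE]
    apos <- coords[acceptors[idx[, 2]], , drop = FALSE]
    hpos <- coords[h, , drop = FALSE]
    hd <- min_image(dpos - hpos, if (is.null(box)) NULL else box)
    ha <- min_image(apos - hpos, if (is.null(box)) NULL else box)
    num <- rowSums(hd * ha)
    den <- sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2))
    ang <- acos(pmin(1, pmax(-1, num / den))) * 180 / pi
    keep <- ang >= criteria$dha_min_angle
    idx <- idx[keep, , drop = FALSE]
    if (nrow(idx) == 0L) return(empty)
    out <- data.frame(donor = dn[idx[, 1]], hydrogen = hy[idx[, 1]],
                      acceptor = acceptors[idx[, 2]],
                      distance = dist[idx],
                      angle = ang[keep])
  } else {
    if (!any(hit)) return(empty)
    idx <- which(hit, arr.ind = TRUE)
    out <- data.frame(donor = dn[idx[, 1]], hydrogen = NA_integer_,
                      acceptor = acceptors[idx[, 2]],
                      distance = dist[idx],
                      angle = NA_real_)
    # heavy-only: every polar atom appears on both sides; report each
    # unordered pair once, canonically ordered
    lo <- pmin(out$donor, out$acceptor)
    hi <- pmax(out$donor, out$acceptor)
    out$donor <- lo
    out$acceptor <- hi
    out <- out[!duplicated(paste(lo, hi)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Detect hydrogen bonds over all frames of a trajectory
#'
#' @param traj an [trajectory()].
#' @param top the congruent [topology()].
#' @param criteria an [hbond_criteria()].
#' @return data.frame as [detect_hbonds()] with an extra leading `frame`
#'   column (1-based).
#' @export
detect_hbonds_frames <- function(traj, top, criteria = hbond_criteria()) {
  da <- assign_donors_acceptors(top, heavy_only = criteria$heavy_only)
  out <- lapply(seq_len(n_frames(traj)), function(f) {
    hb <- detect_hbonds(traj$coords[[f]], da$donors, da$acceptors, criteria,
                        box = if (is.null(traj$box)) NULL else traj$box[f, ])
    if (nrow(hb) > 0L) cbind(frame = f, hb) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(frame = integer(0), donor = integer(0),
                      hydrogen = integer(0), acceptor = integer(0),
                      distance = numeric(0), angle = numeric(0)))
  do.call(rbind, out)
}

#' Export hydrogen-bond records as TSV
#'
#' @param hb data.frame from [detect_hbonds_frames()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hbonds_tsv <- function(hb, path) {
  utils::write.table(hb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
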