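#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation and translation mapping `mobile` onto `ref`,
#' restricted to proper rotations (determinant +1, no reflection), computed
#' by singular value decomposition of the covariance matrix.
#'
#' @param mobile,ref n x 3 coordinate matrices (n >= 3, non-collinear).
#' @return list with `R` (3 x 3 rotation), `t` (translation), and
#'   `transform(x)` applying them to an m x 3 matrix.
#' @export
kabsch <- function(mobile, ref) {
  if (nrow(mobile) != nrow(ref)) stop("coordinate sets differ in size")
  if (nrow(mobile) < 3L)
    stop("superposition needs at least 3 non-collinear atoms")
  mc <- colMeans(mobile); rc <- colMeans(ref)
  P <- sweep(mobile, 2, mc); Q <- sweep(ref, 2, rc)
  if (qr(P)$rank < 2L)
    stop("superposition needs at least 3 non-collinear atoms")
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_ <- rc - as.numeric(R %*% mc)
  list(R = R, t = t_,
       transform = function(x) sweep(x %*% t(R), 2, t_, "+"))
}

#' Superpose a trajectory onto a reference and compute the RMSD series
#'
#' Every frame is rigidly superposed (Kabsch, equal weights) onto the
#' reference frame over the alignment selection; the whole frame is moved by
#' the fitted transform, and the RMSD over the same selection is reported
#' after alignment.
#'
#' @param traj an [trajectory()].
#' @param align_sel integer atom indices used for fitting (and for RMSD).
#' @param reference reference frame index (default 1) or an n_sel x 3
#'   coordinate matrix.
#' @return list with `trajectory` (aligned) and `rmsd` (numeric, Angstrom,
#'   one value per frame).
#' @export
superpose_and_rmsd <- function(traj, align_sel, reference = 1L) {
  if (length(align_sel) < 3L)
    stop("superposition needs at least 3 non-collinear atoms in the selection")
  ref <- if (is.matrix(reference)) reference
         else traj$coords[[reference]][align_sel, , drop = FALSE]
  coords <- vector("list", n_frames(traj))
  rmsd <- numeric(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[[f]]
    fit <- kabsch(xyz[align_sel, , drop = FALSE], ref)
    moved <- fit$transform(xyz)
    coords[[f]] <- moved
    dd <- moved[align_sel, , drop = FALSE] - ref
    rmsd[f] <- sqrt(mean(rowSums(dd^2)))
  }
  list(trajectory = trajectory(coords, box = traj$box), rmsd = rmsd)
}

#' Per-atom and per-residue RMSF profile
#'
#' Root-mean-square fluctuation of each selected atom about its time-average
#' position, on a trajectory already aligned with [superpose_and_rmsd()].
#' The per-residue profile averages the per-atom RMSF over each residue's
#' selected atoms (typically the backbone).
#'
#' @param traj an aligned [trajectory()].
#' @param top the congruent [topology()].
#' @param sel integer atom indices to profile (default: all backbone atoms).
#' @return An object of class `iw_flex_profile`: list with `atom` (data.frame
#'   `atom`, `rmsf`) and `residue` (data.frame `chain`, `resno`, `resname`,
#'   `rmsf`).
#' @export
rmsf_profile <- function(traj, top, sel = select_atoms(top, "backbone")) {
  if (length(sel) == 0L) stop("empty RMSF selection")
  nf <- n_frames(traj)
  if (nf < 2L)
    warning("single-frame trajectory: RMSF is identically zero")
  X <- array(unlist(lapply(traj$coords, function(m) m[sel, , drop = FALSE])),
             dim = c(length(sel), 3, nf))
  mu <- apply(X, c(1, 2), mean)
  dev2 <- sweep(X, c(1, 2), mu)^2
  rmsf <- sqrt(apply(dev2, 1, mean) * 3)   # mean over frames of |dx|^2
  atom_df <- data.frame(atom = sel, rmsf = rmsf)
  a <- top$atoms[sel, , drop = FALSE]
  key <- paste(a$chain, a$resno)
  agg <- tapply(rmsf, key, mean)
  first <- !duplicated(key)
  res_df <- data.frame(chain = a$chain[first], resno = a$resno[first],
                       resname = a$resname[first],
                       rmsf = as.numeric(agg[key[first]]),
                       stringsAsFactors = FALSE)
  res_df <- res_df[order(res_df$chain, res_df$resno), ]
  rownames(res_df) <- NULL
  structure(list(atom = atom_df, residue = res_df,
                 selection = attr(sel, "query"), n_frames = nf),
            class = "iw_flex_profile")
}

#' @export
print.iw_flex_profile <- function(x, ...) {
  cat("iw_flex_profile:", nrow(x$atom), "atoms,", nrow(x$residue),
      "residues,", x$n_frames, "frames\n")
  invisible(x)
}

#' Minimum inter-chain atom distance per frame
#'
#' For each frame, the minimum distance over all cross-group atom pairs,
#' with its mean and standard deviation over frames. Minimum-image applied
#' when the trajectory carries a box.
#'
#' @param traj an [trajectory()].
#' @param group1,group2 non-empty disjoint atom index sets.
#' @return An object of class `iw_proximity`: list with `per_frame`
#'   (numeric), `mean`, `sd`.
#' @export
min_interchain_distance <- function(traj, group1, group2) {
  if (length(group1) == 0L || length(group2) == 0L)
    stop("groups must be non-empty")
  if (length(intersect(group1, group2)) > 0L)
    stop("groups must be disjoint")
  nf <- n_frames(traj)
  per_frame <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[[f]]
    g1 <- xyz[group1, , drop = FALSE]
    g2 <- xyz[group2, , drop = FALSE]
    box <- if (is.null(traj$box)) NULL else traj$box[f, ]
    d2 <- matrix(0, length(group1), length(group2))
    for (k in 1:3) {
      dk <- min_image(outer(g1[, k], g2[, k], "-"),
                      if (is.null(box)) NULL else box[k])
      d2 <- d2 + dk^2
    }
    per_frame[f] <- sqrt(min(d2))
  }
  structure(list(per_frame = per_frame, mean = mean(per_frame),
                 sd = stats::sd(per_frame)),
            class = "iw_proximity")
}

#' @export
print.iw_proximity <- function(x, ...) {
  cat(sprintf("iw_proximity: min inter-chain distance %.2f +/- %.2f A over %d frames\n",
              x$mean, ifelse(is.na(x$sd), 0, x$sd), length(x$per_frame)))
  invisible(x)
}

#' Export a flexibility profile / RMSD series as TSV
#'
#' @param profile an `iw_flex_profile`.
#' @param path output path for the per-residue profile.
#' @return `path`, invisibly.
#' @export
write_rmsf_tsv <- function(profile, path) {
  utils::write.table(profile$residue, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
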