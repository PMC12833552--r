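#' Enumerate water-mediated hydrogen-bond bridges between two protein groups
#'
#' Finds all simple water paths of order at most 2 connecting an atom of
#' `group1` to an atom of `group2` in each frame: order 1 is
#' protein--water--protein, order 2 is protein--water--water--protein with
#' the two waters themselves hydrogen-bonded. Every link of a path must be a
#' detected hydrogen bond in that frame; donor/acceptor direction along the
#' path is ignored by default (a water-mediated hydrogen bond names the
#' connected pair, not a directed chain). Each distinct combination of
#' endpoint atoms and water set is reported once per frame; an order-1 and an
#' order-2 path between the same endpoints are distinct bridges.
#'
#' @param hb hydrogen-bond records with a `frame` column
#'   ([detect_hbonds_frames()]), or a single-frame table from
#'   [detect_hbonds()].
#' @param top the [topology()].
#' @param group1,group2 disjoint non-water atom index sets (the two protein
#'   sides; `group1` is reported first in every pair).
#' @param max_order maximum number of mediating waters (1 or 2).
#' @param directional if `TRUE`, only paths whose links all run
#'   donor-to-acceptor from `group1` toward `group2` are kept (surfaced for
#'   sensitivity checks; the default, `FALSE`, is the convention used
#'   throughout).
#' @param ww_link how the two waters of an order-2 path must be connected:
#'   `"hbond"` (default) requires a detected water-water hydrogen bond;
#'   `"oo_distance"` only requires their oxygens within `oo_cutoff`
#'   (needs `traj`). Surfaced as a sensitivity option.
#' @param traj the [trajectory()]; required for `ww_link = "oo_distance"`.
#' @param oo_cutoff oxygen-oxygen distance cutoff (Angstrom) for
#'   `ww_link = "oo_distance"`.
#' @return data.frame with columns `frame`, `atom1`, `atom2`, `order`,
#'   `waters` (water ids joined by `+`, in path order from `group1`),
#'   `pair` (residue-level key, see [pair_key()]).
#' @export
enumerate_water_bridges <- function(hb, top, group1, group2, max_order = 2,
                                    directional = FALSE,
                                    ww_link = c("hbond", "oo_distance"),
                                    traj = NULL, oo_cutoff = 3.0) {
  ww_link <- match.arg(ww_link)
  if (ww_link == "oo_distance" && is.null(traj))
    stop("ww_link = \"oo_distance\" requires the trajectory")
  if (length(intersect(group1, group2)) > 0L)
    stop("group1 and group2 must be disjoint")
  a <- top$atoms
  if (any(a$is_water[c(group1, group2)]))
    stop("group1/group2 must not contain water atoms")
  if (!max_order %in% c(1, 2)) stop("max_order must be 1 or 2")
  if (!"frame" %in% names(hb))
    hb <- cbind(frame = if (nrow(hb)) 1L else integer(0), hb)

  wid <- water_ids(top)
  empty <- data.frame(frame = integer(0), atom1 = integer(0),
                      atom2 = integer(0), order = integer(0),
                      waters = character(0), pair = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(hb) == 0L) return(empty)

  # edges are collapsed to undirected heavy-atom pairs unless `directional`;
  # all frames are processed at once with merges keyed on (frame, water)
  d <- hb$donor; acc <- hb$acceptor; fr <- hb$frame
  dw <- wid[d]; aw <- wid[acc]

  pw <- function(group) {
    p1 <- d %in% group & !is.na(aw)     # protein donates to water
    p2 <- acc %in% group & !is.na(dw)   # water donates to protein
    df <- data.frame(frame = c(fr[p1], fr[p2]),
                     atom = c(d[p1], acc[p2]),
                     water = c(aw[p1], dw[p2]),
                     water_donates = c(rep(FALSE, sum(p1)),
                                       rep(TRUE, sum(p2))))
    if (directional) {
      want <- if (identical(group, group1)) !df$water_donates
              else df$water_donates
      df <- df[want, , drop = FALSE]
    }
    df[!duplicated(df[c("frame", "atom", "water")]), , drop = FALSE]
  }
  g1w <- pw(group1); g2w <- pw(group2)
  res <- NULL
  if (nrow(g1w) > 0L && nrow(g2w) > 0L) {
    m <- merge(g1w[c("frame", "atom", "water")],
               g2w[c("frame", "atom", "water")],
               by = c("frame", "water"), suffixes = c("1", "2"))
    if (nrow(m) > 0L)
      res <- data.frame(frame = m$frame, atom1 = m$atom1, atom2 = m$atom2,
                        order = 1L, waters = as.character(m$water),
                        stringsAsFactors = FALSE)
  }
  if (max_order >= 2 && nrow(g1w) > 0L && nrow(g2w) > 0L) {
    ww_directional <- directional
    if (ww_link == "hbond") {
      ww_sel <- !is.na(dw) & !is.na(aw) & dw != aw
      ww <- if (any(ww_sel))
        data.frame(frame = fr[ww_sel], w_from = dw[ww_sel],
                   w_to = aw[ww_sel]) else NULL
    } else {
      # proximity links: water oxygens within oo_cutoff, frames with any
      # candidate endpoints only; carries no direction
      ww_directional <- FALSE
      wo_idx <- which(!is.na(wid) & a$element == "O")
      wo_idx <- wo_idx[order(wid[wo_idx])]
      frames_cand <- intersect(unique(g1w$frame), unique(g2w$frame))
      ww <- NULL
      for (f in frames_cand) {
        xyz <- traj$coords[[f]][wo_idx, , drop = FALSE]
        dm <- as.matrix(stats::dist(xyz))
        close <- which(dm <= oo_cutoff & upper.tri(dm), arr.ind = TRUE)
        if (nrow(close) > 0L)
          ww <- rbind(ww, data.frame(frame = f, w_from = close[, 1],
                                     w_to = close[, 2]))
      }
    }
    if (!is.null(ww) && nrow(ww) > 0L) {
      if (!ww_directional)
        ww <- rbind(ww, data.frame(frame = ww$frame, w_from = ww$w_to,
                                   w_to = ww$w_from))
      ww <- ww[!duplicated(ww), , drop = FALSE]
      m <- merge(g1w[c("frame", "atom", "water")], ww,
                 by.x = c("frame", "water"), by.y = c("frame", "w_from"))
      m <- merge(m, g2w[c("frame", "atom", "water")],
                 by.x = c("frame", "w_to"), by.y = c("frame", "water"),
                 suffixes = c("1", "2"))
      m <- m[m$water != m$w_to, , drop = FALSE]   # simple paths only
      if (nrow(m) > 0L) {
        o2 <- data.frame(frame = m$frame, atom1 = m$atom1, atom2 = m$atom2,
                         order = 2L,
                         waters = paste(m$water, m$w_to, sep = "+"),
                         stringsAsFactors = FALSE)
        # distinct water *set*: a1-wA-wB-a2 and a1-wB-wA-a2 are one bridge
        wset <- paste(pmin(m$water, m$w_to), pmax(m$water, m$w_to))
        o2 <- o2[!duplicated(data.frame(o2$frame, o2$atom1, o2$atom2, wset)),
                 , drop = FALSE]
        res <- rbind(res, o2)
      }
    }
  }
  if (is.null(res) || nrow(res) == 0L) return(empty)
  res <- res[!duplicated(res), , drop = FALSE]
  res <- res[order(res$frame, res$order, res$atom1, res$atom2), , drop = FALSE]
  out <- res
  out$pair <- pair_key(top, out$atom1, out$atom2)
  rownames(out) <- NULL
  out
}

#' Residue-level pair key
#'
#' Canonical residue-pair label for bridge endpoints: the `group1` side
#' first, each side written as chain, residue name and author residue
#' number, e.g. `"Lys48-Tyr2105"` style labels `"Ser2-Ser2"` for forge
#' systems.
#'
#' @param top an [topology()].
#' @param atom1,atom2 atom indices (vectors of equal length).
#' @return character vector of pair keys.
#' @export
pair_key <- function(top, atom1, atom2) {
  a <- top$atoms
  paste(residue_label(a$resname[atom1], a$resno[atom1]),
        residue_label(a$resname[atom2], a$resno[atom2]), sep = "-")
}

#' Count direct inter-protein hydrogen bonds per frame
#'
#' Number of detected hydrogen bonds with one endpoint in each group (no
#' water involved), per frame.
#'
#' @inheritParams enumerate_water_bridges
#' @param n_frames total number of frames (so frames with zero direct bonds
#'   appear as zeros).
#' @return data.frame with columns `frame` and `n_direct`.
#' @export
count_direct_interface_hbonds <- function(hb, group1, group2, n_frames = NULL) {
  if (!"frame" %in% names(hb))
    hb <- cbind(frame = if (nrow(hb)) 1L else integer(0), hb)
  cross <- (hb$donor %in% group1 & hb$acceptor %in% group2) |
           (hb$donor %in% group2 & hb$acceptor %in% group1)
  hbc <- hb[cross, , drop = FALSE]
  if (is.null(n_frames))
    n_frames <- if (nrow(hb) > 0L) max(hb$frame) else 0L
  counts <- integer(n_frames)
  if (nrow(hbc) > 0L) {
    tab <- table(factor(hbc$frame, levels = seq_len(n_frames)))
    counts <- as.integer(tab)
  }
  data.frame(frame = seq_len(n_frames), n_direct = counts)
}

#' Export bridge records as TSV
#'
#' @param bridges data.frame from [enumerate_water_bridges()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bridges_tsv <- function(bridges, path) {
  utils::write.table(bridges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
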