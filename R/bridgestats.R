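#' Per-residue-pair bridge statistics
#'
#' Aggregates per-frame water bridges to residue-pair level. A "path" is a
#' distinct combination of water set and order connecting any atoms of the
#' two residues in a frame (an order-1 and an order-2 path through the same
#' first water are distinct). For each pair:
#' \itemize{
#'   \item occupancy: fraction of frames with at least one path;
#'   \item frequency of occurrence: mean number of distinct paths per frame.
#'     A frequency above one indicates that several water molecules bridge
#'     the same pair simultaneously;
#'   \item mean order: average number of mediating waters per path.
#' }
#' Frequency is always at least the occupancy.
#'
#' @param bridges data.frame from [enumerate_water_bridges()] (all frames).
#' @param n_frames total number of frames in the trajectory (>= 1).
#' @param condition optional label, e.g. `"apo"` or `"holo"`.
#' @param replica optional replica identifier.
#' @return data.frame of class `iw_pair_stats` with columns `pair`,
#'   `occupancy`, `frequency`, `mean_order`, `n_frames`, `condition`,
#'   `replica`, and an attribute `"frame_counts"` (pairs x frames path-count
#'   matrix) used by the contiguous persistence variant.
#' @export
pair_statistics <- function(bridges, n_frames, condition = NA, replica = NA) {
  if (is.null(n_frames) || n_frames < 1) stop("n_frames must be >= 1")
  n_frames <- as.integer(n_frames)
  if (nrow(bridges) == 0L) {
    out <- data.frame(pair = character(0), occupancy = numeric(0),
                      frequency = numeric(0), mean_order = numeric(0),
                      n_frames = integer(0), condition = character(0),
                      replica = character(0), stringsAsFactors = FALSE)
    attr(out, "frame_counts") <- matrix(0, 0, n_frames)
    class(out) <- c("iw_pair_stats", class(out))
    return(out)
  }
  if (max(bridges$frame) > n_frames)
    stop("bridges refer to frame ", max(bridges$frame),
         " beyond n_frames = ", n_frames)
  wset <- vapply(strsplit(bridges$waters, "+", fixed = TRUE), function(w)
    paste(sort(w), collapse = "+"), character(1))
  key <- paste(bridges$pair, bridges$frame, wset, bridges$order, sep = "\r")
  b <- bridges[!duplicated(key), , drop = FALSE]

  pairs <- sort(unique(b$pair))
  counts <- matrix(0L, length(pairs), n_frames,
                   dimnames = list(pairs, NULL))
  tab <- table(b$pair, factor(b$frame, levels = seq_len(n_frames)))
  counts[rownames(tab), ] <- as.integer(tab)
  ord_sum <- tapply(b$order, b$pair, sum)[pairs]
  npaths <- rowSums(counts)
  out <- data.frame(pair = pairs,
                    occupancy = rowMeans(counts >= 1),
                    frequency = npaths / n_frames,
                    mean_order = as.numeric(ord_sum) / npaths,
                    n_frames = n_frames,
                    condition = condition,
                    replica = replica,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "frame_counts") <- counts
  class(out) <- c("iw_pair_stats", class(out))
  out
}

#' Persistence filter on pair statistics
#'
#' Keeps pairs whose bridge lasted for at least a given fraction of the
#' simulation length. The default reading is total occupancy at or above the
#' threshold (inclusive); `mode = "contiguous"` instead requires the longest
#' unbroken run of bridged frames to reach the threshold (provided as a
#' sensitivity variant). The filter is idempotent.
#'
#' @param stats an `iw_pair_stats` data.frame from [pair_statistics()].
#' @param threshold fraction of frames in \[0, 1\] (default 0.20).
#' @param mode `"occupancy"` (default) or `"contiguous"`.
#' @return the filtered statistics, same class and attributes.
#' @export
apply_persistence_filter <- function(stats, threshold = 0.20,
                                     mode = c("occupancy", "contiguous")) {
  mode <- match.arg(mode)
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  if (mode == "occupancy") {
    keep <- stats$occupancy >= threshold
  } else {
    fc <- attr(stats, "frame_counts")
    if (is.null(fc))
      stop("contiguous mode needs the frame_counts attribute from ",
           "pair_statistics()")
    longest_run <- vapply(stats$pair, function(p) {
      r <- rle(fc[p, ] >= 1)
      runs <- r$lengths[r$values]
      if (length(runs) == 0L) 0L else max(runs)
    }, integer(1))
    keep <- longest_run / stats$n_frames >= threshold
  }
  out <- stats[keep, , drop = FALSE]
  fc <- attr(stats, "frame_counts")
  if (!is.null(fc)) attr(out, "frame_counts") <- fc[out$pair, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare apo and holo bridge statistics
#'
#' Outer join of apo and holo pair statistics per replica: pairs absent on
#' one side get zero occupancy/frequency there. Only pairs passing the
#' persistence filter in at least one condition (in any replica) are kept.
#' The per-replica frequency difference (holo minus apo) is reported, with
#' an across-replica mean and standard deviation per pair in the
#' `"summary"` attribute.
#'
#' @param stats_apo,stats_holo `iw_pair_stats` tables (may contain several
#'   replicas each; the `condition` column is overridden).
#' @param threshold persistence threshold handed to
#'   [apply_persistence_filter()].
#' @return data.frame with columns `pair`, `replica`, `freq_apo`,
#'   `freq_holo`, `occ_apo`, `occ_holo`, `pass_apo`, `pass_holo`,
#'   `delta_frequency`; attribute `"summary"` holds the per-pair
#'   across-replica mean and SD of frequencies and of the difference.
#' @export
compare_apo_holo <- function(stats_apo, stats_holo, threshold = 0.20) {
  warn_numbering_mismatch(stats_apo, stats_holo)
  pass_apo <- apply_persistence_filter(stats_apo, threshold)
  pass_holo <- apply_persistence_filter(stats_holo, threshold)
  keep_pairs <- union(pass_apo$pair, pass_holo$pair)

  reps <- sort(unique(c(stats_apo$replica, stats_holo$replica)),
               na.last = TRUE)
  if (length(reps) == 0L) reps <- NA
  rows <- list()
  for (r in reps) {
    sel <- function(s) if (all(is.na(reps))) s else
      s[!is.na(s$replica) & s$replica %in% r, , drop = FALSE]
    sa <- sel(stats_apo); sh <- sel(stats_holo)
    for (p in keep_pairs) {
      fa <- sa$frequency[sa$pair == p]; oa <- sa$occupancy[sa$pair == p]
      fh <- sh$frequency[sh$pair == p]; oh <- sh$occupancy[sh$pair == p]
      rows[[length(rows) + 1L]] <- data.frame(
        pair = p, replica = r,
        freq_apo = if (length(fa)) fa else 0,
        freq_holo = if (length(fh)) fh else 0,
        occ_apo = if (length(oa)) oa else 0,
        occ_holo = if (length(oh)) oh else 0,
        pass_apo = p %in% pass_apo$pair,
        pass_holo = p %in% pass_holo$pair,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair = character(0), replica = character(0),
               freq_apo = numeric(0), freq_holo = numeric(0),
               occ_apo = numeric(0), occ_holo = numeric(0),
               pass_apo = logical(0), pass_holo = logical(0))
  out$delta_frequency <- out$freq_holo - out$freq_apo
  summ <- NULL
  if (nrow(out) > 0L) {
    agg <- function(v, f) tapply(v, out$pair, f)
    pairs <- sort(unique(out$pair))
    summ <- data.frame(
      pair = pairs,
      mean_freq_apo = as.numeric(agg(out$freq_apo, mean)[pairs]),
      sd_freq_apo = as.numeric(agg(out$freq_apo, stats::sd)[pairs]),
      mean_freq_holo = as.numeric(agg(out$freq_holo, mean)[pairs]),
      sd_freq_holo = as.numeric(agg(out$freq_holo, stats::sd)[pairs]),
      mean_delta = as.numeric(agg(out$delta_frequency, mean)[pairs]),
      sd_delta = as.numeric(agg(out$delta_frequency, stats::sd)[pairs]),
      stringsAsFactors = FALSE)
  }
  attr(out, "summary") <- summ
  out
}

# Residue numbering sanity check: if the first-side residue numbers of the
# two tables occupy disjoint ranges, the inputs likely follow different
# author numbering conventions.
warn_numbering_mismatch <- function(a, b) {
  nums <- function(s) {
    side1 <- sub("-.*$", "", s$pair)
    as.integer(gsub("[^0-9]", "", side1))
  }
  na_ <- nums(a); nb <- nums(b)
  na_ <- na_[!is.na(na_)]; nb <- nb[!is.na(nb)]
  if (length(na_) > 0L && length(nb) > 0L &&
      (max(na_) < min(nb) || max(nb) < min(na_)))
    warning("residue numbering conventions may differ between the two ",
            "inputs: first-side residue ranges are disjoint (",
            min(na_), "-", max(na_), " vs ", min(nb), "-", max(nb), ")")
  invisible(NULL)
}

#' Export a comparison table as TSV
#'
#' @param cmp data.frame from [compare_apo_holo()].
#' @param path output path; the per-pair summary goes to
#'   `<path>.summary.tsv` when present.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(cmp, path) {
  utils::write.table(cmp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- attr(cmp, "summary")
  if (!is.null(summ))
    utils::write.table(summ, paste0(path, ".summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
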