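#' Bar chart of apo/holo bridge frequencies
#'
#' Per-pair mean frequency of occurrence in apo and holo conditions, with
#' across-replica SD error bars where available (layout mirroring the usual
#' paired-bar presentation of water-bridge frequencies).
#'
#' @param cmp comparison table from [compare_apo_holo()].
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot_pair_frequencies <- function(cmp, ...) {
  summ <- attr(cmp, "summary")
  if (is.null(summ) || nrow(summ) == 0L) {
    warning("nothing to plot: empty comparison")
    return(invisible(NULL))
  }
  h <- rbind(apo = summ$mean_freq_apo, holo = summ$mean_freq_holo)
  colnames(h) <- summ$pair
  mids <- graphics::barplot(h, beside = TRUE, las = 2,
                            ylab = "frequency of occurrence",
                            legend.text = rownames(h), ...)
  sds <- rbind(summ$sd_freq_apo, summ$sd_freq_holo)
  ok <- is.finite(sds) & sds > 0
  if (any(ok))
    graphics::arrows(mids[ok], h[ok] - sds[ok], mids[ok], h[ok] + sds[ok],
                     angle = 90, code = 3, length = 0.03)
  invisible(mids)
}

#' Plot a per-residue RMSF profile
#'
#' @param x an `iw_flex_profile` from [rmsf_profile()].
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.iw_flex_profile <- function(x, ...) {
  res <- x$residue
  chains <- unique(res$chain)
  graphics::plot(NULL, xlim = range(res$resno), ylim = range(0, res$rmsf),
                 xlab = "residue", ylab = "RMSF (A)", ...)
  for (i in seq_along(chains)) {
    r <- res[res$chain == chains[i], ]
    graphics::lines(r$resno, r$rmsf, col = i)
  }
  if (length(chains) > 1L)
    graphics::legend("topright", legend = paste("chain", chains),
                     col = seq_along(chains), lty = 1, bty = "n")
  invisible(x)
}
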