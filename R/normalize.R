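#' Default high-background RNAPIII locus used for no-tag correction
#'
#' The SCR1 locus gives a strong non-specific signal in both tagged and
#' untagged immunoprecipitations and therefore anchors the background ratio.
#' Coordinates are 1-based inclusive.
#'
#' @return A list with `chrom`, `start`, `end`.
#' @export
scr1_window <- function() list(chrom = "chrV", start = 442007L, end = 442458L)

#' No-tag background correction
#'
#' Estimates the tagged-over-untagged background ratio from a shared
#' high-background locus and subtracts the scaled no-tag track:
#' `corrected = flag - r * notag`, where `r` is the mean, over 10-nt bins of
#' the locus, of the per-bin FLAG/no-tag count ratio (bins with zero no-tag
#' counts are skipped).  Corrected values may be negative; downstream gene
#' filters handle them.
#'
#' @param flag_track Tagged-sample signal track.
#' @param notag_track No-tag control track on the same coordinate system.
#' @param window Background locus, as from [scr1_window()].
#' @param bin_width Bin size for the ratio estimate (default 10 nt).
#' @return The corrected signal track.
#' @export
notag_correct <- function(flag_track, notag_track, window = scr1_window(),
                          bin_width = 10) {
  r <- notag_ratio(flag_track, notag_track, window, bin_width)
  track_combine(flag_track, notag_track, coef = -r)
}

#' Mean FLAG/no-tag ratio over the background locus
#'
#' @inheritParams notag_correct
#' @return The scalar ratio `r`.
#' @export
notag_ratio <- function(flag_track, notag_track, window = scr1_window(),
                        bin_width = 10) {
  bin_sums <- function(track) {
    sub <- track[track$chrom == window$chrom & track$pos >= window$start &
                   track$pos <= window$end, ]
    bin <- (sub$pos - window$start) %/% bin_width
    n_bins <- (window$end - window$start) %/% bin_width + 1
    out <- numeric(n_bins)
    if (nrow(sub) > 0) {
      agg <- tapply(sub$score, bin, sum)
      out[as.integer(names(agg)) + 1] <- agg
    }
    out
  }
  f <- bin_sums(flag_track)
  n <- bin_sums(notag_track)
  usable <- n > 0
  if (!any(usable))
    stop("no-tag track has no signal in the background window; ",
         "ratio undefined", call. = FALSE)
  mean(f[usable] / n[usable])
}

#' Spike-in size factors by the median-of-ratios estimator
#'
#' For each spike-in gene with nonzero counts in every sample, the
#' geometric mean across samples is the reference; each sample's factor is
#' the median over those genes of count / reference.  Experimental tracks
#' are then calibrated by dividing by their sample's factor (see
#' [track_divide()]).
#'
#' @param spikein_counts Numeric matrix or data frame, genes x samples
#'   (a `gene_id` column, if present, is used for rownames).
#' @return Named numeric vector of per-sample size factors.
#' @export
#' @examples
#' spikein_size_factors(cbind(a = c(10, 100, 4), b = c(20, 200, 8)))
spikein_size_factors <- function(spikein_counts) {
  m <- spikein_counts
  if (is.data.frame(m)) {
    if ("gene_id" %in% names(m)) {
      ids <- m$gene_id
      m <- as.matrix(m[setdiff(names(m), "gene_id")])
      rownames(m) <- ids
    } else m <- as.matrix(m)
  }
  stopifnot(is.numeric(m), ncol(m) >= 1)
  full <- rowSums(m > 0) == ncol(m)
  if (!any(full))
    stop("no spike-in gene has nonzero counts in all samples", call. = FALSE)
  mm <- m[full, , drop = FALSE]
  geomean <- exp(rowMeans(log(mm)))
  apply(mm / geomean, 2, stats::median)
}
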