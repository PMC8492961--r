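#' Gene filters applied before NET-seq/TEF-seq metagenes
#'
#' Three filters, applied to background-corrected, calibrated tracks:
#' protein-coding genes longer than `min_length` nt are kept; genes with any
#' negative corrected value within the plotted window are discarded; and, to
#' avoid mis-annotated TSSs, genes whose upstream counts (-150 to 0 nt) are
#' more than `ratio_threshold` times their downstream counts (+1 to +150 nt)
#' are discarded (strict inequality: exactly 1.5x is retained).
#'
#' @param track Corrected, calibrated signal track.
#' @param annotation Gene annotation tibble.
#' @param window Plotted window (TSS-relative, +1 convention) used for the
#'   negative-value check.
#' @param min_length Minimum gene length in nt (genes must exceed it).
#' @param ratio_threshold Upstream/downstream ratio above which a gene is
#'   discarded.
#' @return The retained rows of `annotation`.
#' @export
filter_genes_for_metagene <- function(track, annotation,
                                      window = c(-250, 750),
                                      min_length = 750,
                                      ratio_threshold = 1.5) {
  keep <- annotation$biotype == "protein_coding" &
    gene_lengths(annotation) > min_length
  ann <- annotation[keep, , drop = FALSE]
  if (nrow(ann) == 0) return(ann)
  win <- extract_signal(track, ann, window = window, anchor = "TSS")
  no_negative <- apply(win, 1, function(x) all(x >= 0))
  up <- rowSums(extract_signal(track, ann, window = c(-150, 0),
                               anchor = "TSS"))
  down <- rowSums(extract_signal(track, ann, window = c(1, 150),
                                 anchor = "TSS"))
  ann[no_negative & !(up > ratio_threshold * down), , drop = FALSE]
}

#' Trimmed-mean metagene profile
#'
#' For each relative nt position, the mean across genes is computed after
#' excluding, at that position, the top and bottom `trim` fraction of
#' per-gene values (`ceiling(trim * n)` genes at each tail), which guards
#' against random sequencing spikes; the per-position means are then
#' averaged within `bin_width`-nt bins.  Alternatively `trim_mode =
#' "global"` removes whole values beyond global quantiles of all nonzero
#' window values before averaging.
#'
#' @param track Signal track.
#' @param annotation Genes to include (already filtered).
#' @param window `c(from, to)` relative window.
#' @param anchor `"TSS"`, `"PAS"`, or numeric per-gene anchor positions
#'   (see [extract_signal()]).
#' @param trim Tail fraction excluded per position (default 0.01).
#' @param bin_width Bin size in nt (default 10).
#' @param trim_mode `"per_position"` (default) or `"global"`.
#' @return A `metagene_result`: tibble with `rel_pos` (bin center), `bin`
#'   and `mean_signal`, with attributes `n_genes`, `anchor`, `window`.
#' @export
metagene <- function(track, annotation, anchor = "TSS",
                     window = c(-250, 750), trim = 0.01, bin_width = 10,
                     trim_mode = c("per_position", "global")) {
  trim_mode <- match.arg(trim_mode)
  n <- nrow(annotation)
  if (n < 3)
    stop("metagene needs at least 3 genes (trimming undefined below that)",
         call. = FALSE)
  mat <- extract_signal(track, annotation, window = window, anchor = anchor)
  if (trim_mode == "per_position") {
    k <- ceiling(trim * n)
    if (n - 2 * k < 1)
      stop("trim fraction removes all genes", call. = FALSE)
    means <- apply(mat, 2, function(x) {
      s <- sort(x)
      mean(s[(k + 1):(n - k)])
    })
  } else {
    vals <- mat[mat != 0]
    if (length(vals) == 0) {
      means <- colMeans(mat)
    } else {
      q <- stats::quantile(vals, c(trim, 1 - trim))
      capped <- mat
      capped[mat != 0 & (mat < q[1] | mat > q[2])] <- NA
      means <- colMeans(capped, na.rm = TRUE)
    }
  }
  rel <- as.integer(colnames(mat))
  bin <- (rel - rel[1]) %/% bin_width
  out <- tibble::tibble(rel_pos = as.numeric(tapply(rel, bin, mean)),
                        mean_signal = as.numeric(tapply(means, bin, mean)),
                        bin = sort(unique(bin)))[, c("rel_pos", "bin",
                                                     "mean_signal")]
  attr(out, "n_genes") <- n
  attr(out, "anchor") <- if (is.character(anchor)) anchor else "custom"
  attr(out, "window") <- window
  class(out) <- c("metagene_result", class(out))
  out
}

#' Plot a metagene profile
#'
#' @param x A `metagene_result` (or a list of them, named by condition).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_metagene <- function(x, ...) {
  df <- if (inherits(x, "metagene_result")) {
    dplyr::mutate(tibble::as_tibble(x), condition = "signal")
  } else {
    purrr::imap_dfr(x, ~ dplyr::mutate(tibble::as_tibble(.x),
                                       condition = .y))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_pos, y = .data$mean_signal,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position relative to anchor (nt)",
                  y = "mean signal") +
    ggplot2::theme_minimal()
}
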