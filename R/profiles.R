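#' Bin and normalise a per-nucleotide profile for fitting
#'
#' Counts over the first `n_positions` nt from the TSS are summed into
#' `bin_width`-nt bins and each bin is divided by the total count, so the
#' binned vector sums to 1.  This is the common representation in which
#' simulated occupancy and experimental NET-seq profiles are compared.
#'
#' @param counts Numeric vector of per-nt counts, position 1 = first
#'   transcribed nt.  Longer vectors are truncated to `n_positions`.
#' @param gene_id Optional identifier carried along.
#' @param bin_width Bin size in nt (default 10).
#' @param n_positions Number of nt from the TSS used (default 1000).
#' @return A `gene_profile`: list with `gene_id`, `bins` (normalised numeric
#'   vector), `bin_width`, `total` (raw count total).
#' @export
#' @examples
#' gp <- gene_profile(rpois(1000, 2))
#' sum(gp$bins)
gene_profile <- function(counts, gene_id = NA_character_, bin_width = 10,
                         n_positions = 1000) {
  counts <- as.numeric(counts)
  if (length(counts) < n_positions)
    counts <- c(counts, rep(0, n_positions - length(counts)))
  counts <- counts[seq_len(n_positions)]
  if (anyNA(counts) || any(counts < 0))
    stop("profile counts must be non-negative and non-missing", call. = FALSE)
  bins <- vapply(split(counts, (seq_len(n_positions) - 1) %/% bin_width),
                 sum, numeric(1))
  bins <- unname(bins)
  total <- sum(bins)
  if (total <= 0)
    stop("profile has zero total counts; cannot normalise", call. = FALSE)
  structure(list(gene_id = gene_id, bins = bins / total,
                 bin_width = bin_width, total = total),
            class = "gene_profile")
}

#' Normalised binned profile from a simulation result
#'
#' @param sim A `sim_result` from [simulate_population()].
#' @param ... Passed to [gene_profile()].
#' @return A `gene_profile`.
#' @export
sim_profile <- function(sim, ...) {
  stopifnot(inherits(sim, "sim_result"))
  gene_profile(sim$occupancy$count, ...)
}

profile_bins <- function(x) {
  if (inherits(x, "gene_profile")) x$bins
  else if (is.numeric(x)) x
  else stop("expected a gene_profile or numeric vector", call. = FALSE)
}

#' Kolmogorov-Smirnov distance between two binned profiles
#'
#' The maximum absolute difference between the cumulative distribution
#' functions of two binned, normalised profiles on the same bin grid.
#' Symmetric and contained in \[0, 1\].
#'
#' @param profile_a,profile_b `gene_profile` objects or normalised numeric
#'   vectors of equal length.
#' @return A single number in \[0, 1\].
#' @export
#' @examples
#' ks_distance(c(.5, .5, 0), c(0, .5, .5))
ks_distance <- function(profile_a, profile_b) {
  a <- profile_bins(profile_a)
  b <- profile_bins(profile_b)
  if (length(a) != length(b))
    stop("profiles must be binned on identical grids (got ", length(a),
         " vs ", length(b), " bins)", call. = FALSE)
  max(abs(cumsum(a) - cumsum(b)))
}
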