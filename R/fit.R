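#' Latin-hypercube sample of model parameter sets
#'
#' Draws `n_sets` parameter sets from the given per-dimension ranges so that,
#' in every dimension, the samples occupy the `n_sets` distinct
#' equal-probability strata of \[min, max\].  A degenerate range
#' (`min == max`) holds the dimension constant.
#'
#' @param ranges A tibble with columns `parameter`, `min`, `max`, as from
#'   [default_parameter_ranges()].
#' @param n_sets Number of parameter sets.
#' @param seed Integer seed for reproducibility.
#' @param constants Named list of fixed fields merged into every set (e.g.
#'   `gene_length`, `dt`); defaults of [model_params()] apply otherwise.
#' @return A tibble with `param_set` (1..n_sets) and one column per swept
#'   parameter; integer-valued dimensions (`window1_end`) are rounded.
#' @export
#' @examples
#' lhs_sample(default_parameter_ranges(), 4, seed = 1)
lhs_sample <- function(ranges, n_sets, seed = NULL, constants = list()) {
  stopifnot(is.data.frame(ranges),
            all(c("parameter", "min", "max") %in% names(ranges)))
  n_sets <- as.integer(n_sets)
  if (is.na(n_sets) || n_sets < 1) stop("`n_sets` must be >= 1")
  k <- nrow(ranges)
  draw <- function() lhs::randomLHS(n_sets, k)
  u <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  vals <- sweep(u, 2, ranges$max - ranges$min, `*`)
  vals <- sweep(vals, 2, ranges$min, `+`)
  colnames(vals) <- ranges$parameter
  out <- tibble::as_tibble(vals)
  if ("window1_end" %in% names(out))
    out$window1_end <- pmax(1, round(out$window1_end))
  for (nm in names(constants)) out[[nm]] <- constants[[nm]]
  dplyr::bind_cols(tibble::tibble(param_set = seq_len(n_sets)), out)
}

#' Simulate a library of parameter sets
#'
#' Runs [simulate_population()] for every row of a parameter-set tibble and
#' collects, per set, the normalised binned occupancy profile and the
#' measured metrics used downstream in fitting: the six per-gene metrics are
#' `init_elong_ratio` (initiation_rate / elongation_rate), `moving_ratio_w1`,
#' `window1_end`, `early_term_mean`, `moving_ratio_w2` and `processivity`.
#'
#' Each set gets its own reproducible RNG stream derived from `seed`.
#'
#' @param sets Tibble from [lhs_sample()] (or any tibble of parameter
#'   columns with a `param_set` id).
#' @param population Population size per simulation.
#' @param seed Integer seed.
#' @param bin_width,n_positions Binning of the stored profiles.
#' @param estimator Occupancy/metric estimator passed to
#'   [simulate_population()]; `"time_averaged"` makes small-population
#'   libraries far less noisy.
#' @return `sets` with added columns `moving_ratio_w1`, `moving_ratio_w2`,
#'   `processivity`, `init_elong_ratio` and a list-column `profile`
#'   (normalised bin vectors).
#' @export
simulate_library <- function(sets, population, seed = 1, bin_width = 10,
                             n_positions = 1000,
                             estimator = c("final", "time_averaged")) {
  estimator <- match.arg(estimator)
  stopifnot(is.data.frame(sets), nrow(sets) >= 1)
  if (!"param_set" %in% names(sets))
    sets <- dplyr::bind_cols(tibble::tibble(param_set = seq_len(nrow(sets))),
                             sets)
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1L, nrow(sets)))
  sims <- purrr::map(seq_len(nrow(sets)), function(i) {
    p <- as_model_params(sets[i, setdiff(names(sets), "param_set")])
    simulate_population(p, population, seed = seeds[i],
                        estimator = estimator)
  })
  sets$moving_ratio_w1 <- purrr::map_dbl(sims, ~ .x$metrics$moving_ratio_w1)
  sets$moving_ratio_w2 <- purrr::map_dbl(sims, ~ .x$metrics$moving_ratio_w2)
  sets$processivity <- purrr::map_dbl(sims, ~ .x$metrics$processivity)
  sets$init_elong_ratio <- sets$initiation_rate / sets$elongation_rate
  sets$profile <- purrr::map(sims, function(s) {
    gene_profile(s$occupancy$count, bin_width = bin_width,
                 n_positions = n_positions)$bins
  })
  sets
}

METRIC_COLS <- c("init_elong_ratio", "moving_ratio_w1", "window1_end",
                 "early_term_mean", "moving_ratio_w2", "processivity")

#' Fit one gene profile against a simulated library
#'
#' Computes the KS distance between the gene's binned profile and every
#' library profile, ranks the library ascending by distance, and summarises
#' the `k_best` best-fitting sets into the six per-gene metrics (mean over
#' the retained sets by default).
#'
#' @param profile A [gene_profile()] (or normalised bin vector).
#' @param library A tibble from [simulate_library()].
#' @param k_best Number of best-fitting sets retained (the headline fits use
#'   1 for profile display and 100 for metric comparisons).
#' @param aggregate Aggregator over the retained sets; the default is the
#'   mean over sets with a defined value (a set's moving ratio is undefined
#'   when its final snapshot has no stalled or backtracked polymerase in the
#'   window).
#' @return List with `ranks` (tibble `rank`, `param_set`, `ks`) and
#'   `metrics` (one-row tibble of the six metrics plus `best_ks`).
#' @export
fit_gene <- function(profile, library, k_best = 100,
                     aggregate = function(x) mean(x, na.rm = TRUE)) {
  if (!is.data.frame(library) || nrow(library) == 0)
    stop("`library` must be a non-empty simulated library", call. = FALSE)
  stopifnot(all(c("param_set", "profile", METRIC_COLS) %in% names(library)))
  bins <- profile_bins(profile)
  ks <- purrr::map_dbl(library$profile, ks_distance, profile_b = bins)
  ord <- order(ks)
  ranks <- tibble::tibble(rank = seq_along(ord),
                          param_set = library$param_set[ord],
                          ks = ks[ord])
  k_best <- min(k_best, nrow(library))
  top <- library[ord[seq_len(k_best)], ]
  metrics <- purrr::map(top[METRIC_COLS], aggregate) |> tibble::as_tibble()
  metrics$best_ks <- ranks$ks[1]
  list(ranks = ranks, metrics = metrics)
}

#' Fit many gene profiles against one simulated library
#'
#' @param profiles A named list of [gene_profile()] objects (names are gene
#'   ids), or a tibble with columns `gene_id` and list-column `profile`.
#' @inheritParams fit_gene
#' @return A `net_fit` object with `ranks` (per gene, all library ranks) and
#'   `metrics` (one row per gene: the six metrics plus `best_ks`); supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
fit_genes <- function(profiles, library, k_best = 100,
                      aggregate = function(x) mean(x, na.rm = TRUE)) {
  if (is.data.frame(profiles)) {
    ids <- profiles$gene_id
    profiles <- profiles$profile
  } else {
    ids <- names(profiles)
    if (is.null(ids)) ids <- paste0("gene_", seq_along(profiles))
  }
  fits <- purrr::map(profiles, fit_gene, library = library, k_best = k_best,
                     aggregate = aggregate)
  structure(list(
    ranks = purrr::map2_dfr(fits, ids, ~ dplyr::bind_cols(
      tibble::tibble(gene_id = .y), .x$ranks)),
    metrics = purrr::map2_dfr(fits, ids, ~ dplyr::bind_cols(
      tibble::tibble(gene_id = .y), .x$metrics)),
    k_best = min(k_best, nrow(library)),
    n_library = nrow(library)), class = "net_fit")
}

#' @export
print.net_fit <- function(x, ...) {
  cat(sprintf("<net_fit> %d genes against %d parameter sets (k_best = %d)\n",
              nrow(x$metrics), x$n_library, x$k_best))
  print(x$metrics)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-gene metrics of a fit
#' @param x A `net_fit`.
#' @param ... Unused.
#' @export
tidy.net_fit <- function(x, ...) x$metrics

#' One-row fit summary
#' @param x A `net_fit`.
#' @param ... Unused.
#' @export
glance.net_fit <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$metrics), n_library = x$n_library,
                 k_best = x$k_best, median_best_ks = stats::median(x$metrics$best_ks))
}

#' Select genes for model fitting
#'
#' Two-stage filter: keep genes longer than 1000 nt, then keep those whose
#' total counts in the first 1000 nt from the TSS are strictly greater than
#' the average of the totals over all initially selected genes.
#'
#' @param track A signal track tibble (see [signal_track()]).
#' @param annotation A gene annotation tibble (see [gene_annotation()]).
#' @return The selected rows of `annotation` with an added column
#'   `first_kb_count`.
#' @export
select_genes_for_fitting <- function(track, annotation) {
  if (nrow(annotation) == 0) {
    annotation$first_kb_count <- numeric(0)
    return(annotation)
  }
  long <- annotation[gene_lengths(annotation) > 1000, , drop = FALSE]
  if (nrow(long) == 0) {
    long$first_kb_count <- numeric(0)
    return(long)
  }
  mat <- extract_signal(track, long, window = c(1, 1000))
  long$first_kb_count <- unname(rowSums(mat))
  long[long$first_kb_count > mean(long$first_kb_count), , drop = FALSE]
}

#' Paired Cohen's d between two per-gene metric vectors
#'
#' Effect size of a paired condition comparison: the mean of the differences
#' `b - a` divided by the standard deviation of the differences, so positive
#' values indicate an increase in condition `b`.  The magnitude label follows
#' the conventional |d| thresholds: < 0.2 negligible, 0.2-0.5 small, 0.5-0.8
#' medium, > 0.8 large.  The p-value comes from a two-sided paired t-test.
#'
#' @param values_a,values_b Equal-length paired numeric vectors (one entry
#'   per gene), length >= 2.
#' @return A list with `d`, `magnitude`, `p_value`, `n`.
#' @export
#' @examples
#' cohens_d_paired(c(1, 2, 3, 4), c(2, 2, 5, 5))
cohens_d_paired <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length", call. = FALSE)
  ok <- stats::complete.cases(values_a, values_b)
  a <- values_a[ok]; b <- values_b[ok]
  if (length(a) < 2)
    stop("need at least 2 complete pairs", call. = FALSE)
  d <- b - a
  s <- stats::sd(d)
  m <- mean(d)
  if (s == 0) {
    if (m == 0)
      return(list(d = 0, magnitude = "negligible", p_value = NA_real_,
                  n = length(a)))
    stop("degenerate input: all paired differences identical and nonzero ",
         "(sd of differences is 0)", call. = FALSE)
  }
  dd <- m / s
  magnitude <- cut(abs(dd), c(-Inf, 0.2, 0.5, 0.8, Inf),
                   labels = c("negligible", "small", "medium", "large"))
  p <- stats::t.test(b, a, paired = TRUE)$p.value
  list(d = dd, magnitude = as.character(magnitude), p_value = p,
       n = length(a))
}

#' Compare per-gene metrics between two fitted conditions
#'
#' Joins two [fit_genes()] metric tables by gene and reports, per metric,
#' the paired Cohen's d (positive = increase in `fit_b`), its magnitude
#' label, and the two-sided paired t-test p-value.
#'
#' @param fit_a,fit_b `net_fit` objects or their `metrics` tibbles.
#' @param metrics Which metric columns to compare.
#' @return A tibble with `metric`, `cohens_d`, `magnitude`, `p_value`, `n`.
#' @export
compare_conditions <- function(fit_a, fit_b, metrics = METRIC_COLS) {
  ma <- if (inherits(fit_a, "net_fit")) fit_a$metrics else fit_a
  mb <- if (inherits(fit_b, "net_fit")) fit_b$metrics else fit_b
  joined <- dplyr::inner_join(ma, mb, by = "gene_id",
                              suffix = c("_a", "_b"))
  purrr::map_dfr(metrics, function(m) {
    r <- tryCatch(
      cohens_d_paired(joined[[paste0(m, "_a")]],
                      joined[[paste0(m, "_b")]]),
      error = function(e) list(d = NA_real_, magnitude = "degenerate",
                               p_value = NA_real_, n = nrow(joined)))
    tibble::tibble(metric = m, cohens_d = r$d, magnitude = r$magnitude,
                   p_value = r$p_value, n = r$n)
  })
}

#' Doubling time from an OD growth series
#'
#' Restricts the series to the exponential window (OD 0.2 to 0.7 by default)
#' and evaluates `log(2) * elapsed_time / (log(max OD) - log(min OD))`.
#'
#' @param time Time points (minutes).
#' @param od OD600 readings (blank-corrected).
#' @param window OD window defining the exponential phase.
#' @return Doubling time in the units of `time`.
#' @export
#' @examples
#' doubling_time(c(0, 90), c(0.2, 0.4))  # exact doubling: 90
doubling_time <- function(time, od, window = c(0.2, 0.7)) {
  stopifnot(length(time) == length(od))
  keep <- !is.na(od) & od >= window[1] & od <= window[2]
  t <- time[keep]; o <- od[keep]
  if (length(o) < 2 || max(o) <= min(o))
    stop("series has no growth within the exponential window (max OD <= ",
         "min OD)", call. = FALSE)
  elapsed <- max(t) - min(t)
  log(2) * elapsed / (log(max(o)) - log(min(o)))
}
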