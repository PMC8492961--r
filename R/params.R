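#' Parameterise one simulated transcription regime
#'
#' Collects the full rate and geometry parameterisation of the stochastic
#' RNAPII elongation model into a validated list.  Rates are continuous-time
#' rates converted internally to per-step Bernoulli probabilities
#' (`rate * dt`); elongation hops are Poisson with mean
#' `elongation_rate * 1000 * dt` nt per step.  Two kinetic windows along the
#' gene, split at `window1_end`, may carry different stalling, backtracking
#' and resumption rates.
#'
#' @param initiation_rate Initiation attempts per minute at position 1.
#' @param elongation_rate Elongation speed in kb per minute.
#' @param window1_end Last nt (from the TSS, 1-based) belonging to window 1.
#' @param stall_rate_w1,stall_rate_w2 Moving-to-stalled rate per minute.
#' @param backtrack_rate_w1,backtrack_rate_w2 Stalled-to-backtracked rate
#'   per minute.
#' @param resume_stall_w1,resume_stall_w2 Stalled-to-moving rate per minute.
#' @param resume_backtrack_w1,resume_backtrack_w2 Backtracked-to-moving rate
#'   per minute.
#' @param early_term_mean Mean (nt) of the Poisson-distributed early
#'   termination site.
#' @param early_term_prob Probability that an initiating polymerase is
#'   subject to early termination at all.
#' @param gene_length Length of the synthetic gene in nt.
#' @param footprint Polymerase footprint in nt; engaged active sites on one
#'   gene are always at least this far apart.
#' @param dt Time step in minutes.
#' @param total_time Total simulated time in minutes.
#'
#' @return An object of class `model_params` (a named list).
#' @export
#' @examples
#' p <- model_params(initiation_rate = 1, elongation_rate = 2)
#' p$gene_length
model_params <- function(initiation_rate = 1,
                         elongation_rate = 2,
                         window1_end = 250,
                         stall_rate_w1 = 2, stall_rate_w2 = 1,
                         backtrack_rate_w1 = 1, backtrack_rate_w2 = 0.5,
                         resume_stall_w1 = 4, resume_stall_w2 = 4,
                         resume_backtrack_w1 = 1, resume_backtrack_w2 = 1,
                         early_term_mean = 300,
                         early_term_prob = 0.1,
                         gene_length = 1000L,
                         footprint = 40L,
                         dt = 0.005,
                         total_time = 40) {
  p <- list(
    initiation_rate = initiation_rate, elongation_rate = elongation_rate,
    window1_end = as.integer(window1_end),
    stall_rate_w1 = stall_rate_w1, stall_rate_w2 = stall_rate_w2,
    backtrack_rate_w1 = backtrack_rate_w1,
    backtrack_rate_w2 = backtrack_rate_w2,
    resume_stall_w1 = resume_stall_w1, resume_stall_w2 = resume_stall_w2,
    resume_backtrack_w1 = resume_backtrack_w1,
    resume_backtrack_w2 = resume_backtrack_w2,
    early_term_mean = early_term_mean, early_term_prob = early_term_prob,
    gene_length = as.integer(gene_length), footprint = as.integer(footprint),
    dt = dt, total_time = total_time)
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  rates <- c("initiation_rate", "elongation_rate",
             "stall_rate_w1", "stall_rate_w2",
             "backtrack_rate_w1", "backtrack_rate_w2",
             "resume_stall_w1", "resume_stall_w2",
             "resume_backtrack_w1", "resume_backtrack_w2",
             "early_term_mean")
  for (r in rates) {
    if (!is.numeric(p[[r]]) || length(p[[r]]) != 1 || is.na(p[[r]]) ||
        p[[r]] < 0)
      stop("`", r, "` must be a single non-negative number", call. = FALSE)
  }
  if (p$early_term_prob < 0 || p$early_term_prob > 1)
    stop("`early_term_prob` must lie in [0, 1]", call. = FALSE)
  if (p$gene_length < 1) stop("`gene_length` must be >= 1", call. = FALSE)
  if (p$window1_end < 1 || p$window1_end > p$gene_length)
    stop("`window1_end` must lie in [1, gene_length]", call. = FALSE)
  if (p$footprint < 1) stop("`footprint` must be >= 1", call. = FALSE)
  if (p$dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (p$total_time <= 0) stop("`total_time` must be positive", call. = FALSE)
  # one transition per polymerase per step: per-step probabilities must be
  # valid after dt scaling
  for (w in c("w1", "w2")) {
    if (p[[paste0("stall_rate_", w)]] * p$dt > 1 ||
        p[[paste0("resume_backtrack_", w)]] * p$dt > 1 ||
        (p[[paste0("backtrack_rate_", w)]] +
           p[[paste0("resume_stall_", w)]]) * p$dt > 1)
      stop("per-step transition probability exceeds 1 after dt scaling; ",
           "use a smaller dt or smaller rates", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  initiation %.3g /min, elongation %.3g kb/min, window 1 ends at %d nt\n",
              x$initiation_rate, x$elongation_rate, x$window1_end))
  cat(sprintf("  stall %.3g/%.3g, backtrack %.3g/%.3g, resume(stall) %.3g/%.3g, resume(bt) %.3g/%.3g /min (w1/w2)\n",
              x$stall_rate_w1, x$stall_rate_w2, x$backtrack_rate_w1,
              x$backtrack_rate_w2, x$resume_stall_w1, x$resume_stall_w2,
              x$resume_backtrack_w1, x$resume_backtrack_w2))
  cat(sprintf("  early termination: prob %.3g, mean site %.3g nt\n",
              x$early_term_prob, x$early_term_mean))
  cat(sprintf("  gene %d nt, footprint %d nt, dt %.3g min, total %.3g min\n",
              x$gene_length, x$footprint, x$dt, x$total_time))
  invisible(x)
}

#' Convert a one-row parameter tibble to `model_params`
#'
#' @param df A data frame with one row and columns named after
#'   [model_params()] arguments (missing columns take the defaults).
#' @return A `model_params` object.
#' @export
as_model_params <- function(df) {
  stopifnot(is.data.frame(df), nrow(df) == 1)
  args <- as.list(df)[intersect(names(df), names(formals(model_params)))]
  do.call(model_params, args)
}

#' Default Latin-hypercube parameter ranges
#'
#' Biologically plausible sweep bounds for the swept model dimensions.
#' Every bound can be overridden via `...`, passed as `name = c(min, max)`;
#' a degenerate range (`min == max`) holds that dimension constant.
#'
#' @param ... Named `c(min, max)` overrides.
#' @return A tibble with columns `parameter`, `min`, `max`.
#' @export
#' @examples
#' default_parameter_ranges(initiation_rate = c(0.5, 2))
default_parameter_ranges <- function(...) {
  rng <- list(
    initiation_rate = c(0.1, 10),
    elongation_rate = c(0.5, 4),
    window1_end = c(50, 500),
    stall_rate_w1 = c(0, 20), stall_rate_w2 = c(0, 20),
    backtrack_rate_w1 = c(0, 20), backtrack_rate_w2 = c(0, 20),
    resume_stall_w1 = c(0, 20), resume_stall_w2 = c(0, 20),
    resume_backtrack_w1 = c(0, 20), resume_backtrack_w2 = c(0, 20),
    early_term_mean = c(50, 800),
    early_term_prob = c(0, 0.5))
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(rng)) stop("unknown parameter range: ", nm)
    stopifnot(length(dots[[nm]]) == 2)
    rng[[nm]] <- as.numeric(dots[[nm]])
  }
  out <- tibble::tibble(
    parameter = names(rng),
    min = vapply(rng, `[`, numeric(1), 1),
    max = vapply(rng, `[`, numeric(1), 2))
  bad <- out$min > out$max | !is.finite(out$min) | !is.finite(out$max) |
    out$min < 0
  if (any(bad))
    stop("parameter ranges must be finite, non-negative and min <= max")
  out
}
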