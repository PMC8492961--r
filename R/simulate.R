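STATE_LEVELS <- c("MOVING", "STALLED", "BACKTRACKED")

#' Create an empty polymerase ensemble
#'
#' An ensemble holds the engaged polymerases of a population of identical
#' synthetic genes, plus per-gene event tallies.  The invariants maintained
#' throughout stepping are (i) footprint exclusion: active sites on the same
#' gene differ by at least `footprint` nt, and (ii) conservation:
#' `initiated = engaged + completed + early_terminated + collision_terminated`.
#'
#' @param n_genes Number of population members (identical synthetic genes).
#' @return A `pol_ensemble` object: list with `polymerases` (tibble with
#'   columns `gene`, `position`, `state`, `early_term_site`) and `tallies`
#'   (one row per gene).
#' @export
new_ensemble <- function(n_genes) {
  n_genes <- as.integer(n_genes)
  stopifnot(n_genes >= 1)
  structure(list(
    polymerases = tibble::tibble(
      gene = integer(), position = integer(),
      state = character(), early_term_site = integer()),
    tallies = tibble::tibble(
      gene = seq_len(n_genes), initiated = 0L, completed = 0L,
      early_terminated = 0L, collision_terminated = 0L),
    n_genes = n_genes), class = "pol_ensemble")
}

ensemble_from_cpp <- function(res, n_genes) {
  e <- res$ensemble
  structure(list(
    polymerases = tibble::tibble(
      gene = e$gene, position = e$position,
      state = STATE_LEVELS[e$state + 1L],
      early_term_site = ifelse(e$early_term_site == 0L, NA_integer_,
                               e$early_term_site)),
    tallies = tibble::tibble(
      gene = seq_len(n_genes), initiated = e$initiated,
      completed = e$completed, early_terminated = e$early_terminated,
      collision_terminated = e$collision_terminated),
    n_genes = n_genes), class = "pol_ensemble")
}

step_ensemble <- function(ensemble, params, n_steps, do_advance, do_init,
                          check_invariants) {
  stopifnot(inherits(ensemble, "pol_ensemble"))
  validate_model_params(params)
  p <- ensemble$polymerases
  t <- ensemble$tallies
  res <- cpp_step_ensemble(
    as.integer(p$gene), as.integer(p$position),
    match(p$state, STATE_LEVELS) - 1L,
    as.integer(ifelse(is.na(p$early_term_site), 0L, p$early_term_site)),
    as.integer(t$initiated), as.integer(t$completed),
    as.integer(t$early_terminated), as.integer(t$collision_terminated),
    params, ensemble$n_genes, as.integer(n_steps),
    do_advance, do_init, check_invariants)
  ensemble_from_cpp(res, ensemble$n_genes)
}

#' Place a polymerase on a population member by hand
#'
#' Mainly for constructing small scenarios: adds an engaged polymerase and
#' counts it as initiated, so the conservation invariant keeps holding.
#'
#' @param ensemble A [new_ensemble()] object.
#' @param gene Population member index.
#' @param position Active-site position (1-based nt).
#' @param state `"MOVING"`, `"STALLED"` or `"BACKTRACKED"`.
#' @param early_term_site Optional early-termination site.
#' @return The updated `pol_ensemble`.
#' @export
place_polymerase <- function(ensemble, gene, position, state = "MOVING",
                             early_term_site = NA_integer_) {
  stopifnot(inherits(ensemble, "pol_ensemble"))
  state <- match.arg(state, STATE_LEVELS)
  ensemble$polymerases <- dplyr::bind_rows(
    ensemble$polymerases,
    tibble::tibble(gene = as.integer(gene), position = as.integer(position),
                   state = state,
                   early_term_site = as.integer(early_term_site)))
  i <- ensemble$tallies$gene == gene
  ensemble$tallies$initiated[i] <- ensemble$tallies$initiated[i] + 1L
  ensemble
}

#' Attempt initiation on every population member
#'
#' For each gene, with probability `min(initiation_rate * dt, 1)` a new
#' polymerase is placed at position 1 in the MOVING state, unless an engaged
#' polymerase's active site lies within `footprint` nt of position 1
#' (occlusion), in which case initiation is blocked for that step.  With
#' probability `early_term_prob` the newcomer receives an early-termination
#' site drawn from a Poisson distribution with mean `early_term_mean`
#' (redrawn while 0 or beyond the gene end).
#'
#' @param ensemble A [new_ensemble()] object.
#' @param params A [model_params()] object.
#' @param n_steps Number of initiation steps to apply (default 1).
#' @param check_invariants Assert footprint exclusion and conservation after
#'   every step.
#' @return The updated `pol_ensemble`.
#' @export
initiate <- function(ensemble, params, n_steps = 1, check_invariants = FALSE) {
  step_ensemble(ensemble, params, n_steps, do_advance = FALSE,
                do_init = TRUE, check_invariants = check_invariants)
}

#' Advance and transition every engaged polymerase
#'
#' One discrete time step of the elongation dynamics, applied most-downstream
#' polymerase first.  Rates come from window 1 at positions `<= window1_end`
#' and window 2 beyond.  A MOVING polymerase stalls with probability
#' `stall_rate * dt`, otherwise hops `n ~ Poisson(elongation_rate * 1000 * dt)`
#' nt, truncated so it stays at least `footprint` nt behind the nearest
#' engaged downstream polymerase; a truncated hop is a collision, resolved by
#' [resolve_collision()].  Reaching the early-termination site removes the
#' polymerase (tallied `early_terminated`); reaching the gene end removes it
#' (tallied `completed`).  STALLED polymerases backtrack with probability
#' `backtrack_rate * dt`, else resume with probability `resume_stall * dt`;
#' BACKTRACKED polymerases resume with probability `resume_backtrack * dt`.
#' Positions do not change while stalled or backtracked.
#'
#' @inheritParams initiate
#' @return The updated `pol_ensemble`.
#' @export
advance_and_transition <- function(ensemble, params, n_steps = 1,
                                   check_invariants = FALSE) {
  step_ensemble(ensemble, params, n_steps, do_advance = TRUE,
                do_init = FALSE, check_invariants = check_invariants)
}

#' Collision resolution rule table
#'
#' When a moving polymerase's hop is truncated by the footprint of the next
#' downstream polymerase, the outcome depends only on the downstream state:
#' the upstream polymerase always becomes STALLED; a STALLED downstream
#' polymerase is terminated (removed), while MOVING and BACKTRACKED
#' downstream polymerases are unchanged.
#'
#' @param upstream_state Must be `"MOVING"`; only moving polymerases collide.
#' @param downstream_state One of `"MOVING"`, `"STALLED"`, `"BACKTRACKED"`.
#' @return A list with `upstream` (new state) and `downstream` (`"unchanged"`
#'   or `"terminated"`).
#' @export
#' @examples
#' resolve_collision("MOVING", "STALLED")
resolve_collision <- function(upstream_state, downstream_state) {
  if (!identical(upstream_state, "MOVING"))
    stop("only a MOVING polymerase can collide (upstream_state must be ",
         "\"MOVING\")", call. = FALSE)
  downstream_state <- match.arg(downstream_state, STATE_LEVELS)
  list(
    upstream = "STALLED",
    downstream = if (downstream_state == "STALLED") "terminated"
                 else "unchanged")
}

#' Simulate a population of identical synthetic genes to steady state
#'
#' Runs `total_time / dt` discrete steps from an empty gene for every
#' population member and returns the final-snapshot occupancy (the summed
#' active-site locations of all engaged polymerases), per-gene event tallies,
#' and the measured summary metrics: `moving_ratio_w1` / `moving_ratio_w2`
#' (MOVING count divided by STALLED + BACKTRACKED count among engaged
#' polymerases in each window) and `processivity` (completed / initiated, in
#' percent).
#'
#' @param params A [model_params()] object.
#' @param population_size Number of identical genes to simulate.
#' @param seed Integer seed; fixed seed gives bit-identical results.
#' @param check_invariants Assert footprint exclusion and conservation at
#'   every step for every gene (slower; for validation runs).
#' @param estimator `"final"` takes the occupancy and moving ratios from the
#'   final snapshot (the headline convention); `"time_averaged"` averages
#'   occupancy and state counts over the second half of the run, which at
#'   small population sizes estimates the same steady-state quantities with
#'   far less Monte-Carlo noise (the desk-scale stand-in for a very large
#'   population).
#' @return A `sim_result`: list with `occupancy` (tibble `position`, `count`),
#'   `metrics` (one-row tibble), `tallies`, `params`, `population_size`.
#' @export
#' @examples
#' r <- simulate_population(model_params(total_time = 2), 20, seed = 1)
#' r$metrics
simulate_population <- function(params, population_size, seed = NULL,
                                check_invariants = FALSE,
                                estimator = c("final", "time_averaged")) {
  validate_model_params(params)
  estimator <- match.arg(estimator)
  population_size <- as.integer(population_size)
  if (is.na(population_size) || population_size < 1)
    stop("`population_size` must be at least 1", call. = FALSE)
  n_steps <- as.integer(round(params$total_time / params$dt))
  avg_from <- if (estimator == "time_averaged")
    as.integer(floor(n_steps / 2) + 1L) else 0L
  run <- function() cpp_simulate(params, population_size, n_steps,
                                 check_invariants, avg_from)
  res <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())

  ens <- ensemble_from_cpp(res, population_size)
  tot <- colSums(ens$tallies[, -1])
  cnt <- if (estimator == "final") res$snapshot_counts
         else res$averaged_counts
  ratio <- function(m, o) if (o > 0) m / o else NaN
  metrics <- tibble::tibble(
    moving_ratio_w1 = ratio(cnt[["moving_w1"]], cnt[["other_w1"]]),
    moving_ratio_w2 = ratio(cnt[["moving_w2"]], cnt[["other_w2"]]),
    processivity = if (tot[["initiated"]] > 0)
      100 * tot[["completed"]] / tot[["initiated"]] else NaN,
    initiated = tot[["initiated"]], completed = tot[["completed"]],
    early_terminated = tot[["early_terminated"]],
    collision_terminated = tot[["collision_terminated"]],
    engaged = nrow(ens$polymerases))
  structure(list(
    occupancy = tibble::tibble(
      position = seq_len(params$gene_length),
      count = as.numeric(if (estimator == "final") res$occupancy
                         else res$avg_occupancy)),
    metrics = metrics,
    tallies = ens$tallies,
    ensemble = ens,
    params = params,
    population_size = population_size), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> population %d, gene %d nt\n",
              x$population_size, x$params$gene_length))
  print(x$metrics[, 1:3])
  invisible(x)
}

#' Occupancy profile of a simulation as a ggplot
#'
#' @param x A `sim_result` from [simulate_population()].
#' @param binwidth Bin width in nt for display (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_occupancy <- function(x, binwidth = 10, ...) {
  stopifnot(inherits(x, "sim_result"))
  df <- x$occupancy |>
    dplyr::mutate(bin = (position - 1) %/% binwidth) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(position = mean(.data$position),
                     count = mean(.data$count), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position from TSS (nt)",
                  y = "engaged polymerases (final snapshot)") +
    ggplot2::theme_minimal()
}
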