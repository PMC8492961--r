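#' Default pipeline configuration
#'
#' Every numeric constant of the analysis surfaces here as a named,
#' defaulted key: the simulator geometry (footprint 40 nt, dt 0.005 min,
#' 40 min total, 1000-nt synthetic gene), the gene filters (fitting > 1000
#' nt and above-average counts; metagene > 750 nt, no negatives, 1.5x
#' upstream rule, 1% trimming; phasing >= 600 nt with 4 dyads in 600 nt),
#' the dyad flank windows (-60..-10 / +10..+60), and the sweep/scale knobs.
#'
#' @param ... Overrides merged over the defaults (nested lists merged
#'   shallowly).
#' @return A named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_genes = 60L,
    depth = 2000,
    n_sets = 64L,
    population = 500L,
    max_fit_genes = 8L,
    k_best = 10L,
    mutant = list(stall_rate_w1_factor = 4, spacing_delta = 10),
    stages = list(synth = TRUE, normalize = TRUE, metagene = TRUE,
                  fit = TRUE, compare = TRUE, dyads = TRUE),
    sim = list(footprint = 40L, dt = 0.005, total_time = 40,
               gene_length = 1000L),
    filters = list(fit_min_length = 1000, metagene_min_length = 750,
                   metagene_ratio = 1.5, trim = 0.01,
                   phasing_min_length = 600, phasing_n_dyads = 4),
    flanks = list(upstream = c(-60, -10), downstream = c(10, 60)),
    metagene_window = c(-250, 750))
  utils::modifyList(cfg, list(...))
}

cfg_error <- function(msg) rlang::abort(msg, class = "elongatr_config_error")
data_error <- function(msg) rlang::abort(msg, class = "elongatr_data_error")

write_tsv_q <- function(x, dir, name) {
  readr::write_tsv(x, file.path(dir, paste0(name, ".tsv")))
}

#' Run the full synthetic-data analysis pipeline
#'
#' Orchestrates the stages end to end on a generated wild-type/mutant
#' condition pair: synthesis, no-tag correction and spike-in calibration,
#' TSS metagenes, the Latin-hypercube fit with metric extraction, the
#' paired effect-size comparison, and the nucleosome position/spacing
#' analyses.  Deterministic given `config$seed`; results and a provenance
#' manifest are written to `out_dir`.
#'
#' @param config A list from [default_config()] (or a path to a JSON file
#'   holding one).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) cfg_error(paste("config file not found:", config))
    config <- utils::modifyList(default_config(),
                                jsonlite::read_json(config, simplifyVector = TRUE))
  }
  if (!is.list(config) || is.null(config$seed) ||
      !is.numeric(config$seed) || config$seed != as.integer(config$seed))
    cfg_error("config must be a list with an integer `seed`")
  st <- config$stages
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()

  if (isTRUE(st$synth)) {
    wt_params <- model_params(
      footprint = config$sim$footprint, dt = config$sim$dt,
      total_time = config$sim$total_time,
      gene_length = config$sim$gene_length)
    mut_params <- wt_params
    mut_params$stall_rate_w1 <-
      mut_params$stall_rate_w1 * config$mutant$stall_rate_w1_factor
    validate_model_params(mut_params)
    spec <- synthetic_spec(n_genes = config$n_genes, depth = config$depth,
                           params = wt_params, seed = config$seed)
    out$pair <- make_condition_pair(
      spec, mut_params = mut_params,
      mut_spacing_delta = config$mutant$spacing_delta)
    write_tsv_q(out$pair$annotation, out_dir, "annotation")
    write_tsv_q(out$pair$spike_counts, out_dir, "spike_counts")
    write_tsv_q(out$pair$wt$dyads, out_dir, "dyads_wt")
    write_tsv_q(out$pair$mut$dyads, out_dir, "dyads_mut")
  }

  if (isTRUE(st$normalize)) {
    if (is.null(out$pair)) data_error("normalize stage: missing input `pair` (synth stage off)")
    pair <- out$pair
    factors <- spikein_size_factors(
      pair$spike_counts[c("wt_net", "mut_net")])
    corr <- function(ds, f) {
      notag_correct(ds$tracks$net, ds$tracks$notag,
                    window = ds$scr1) |> track_divide(f)
    }
    out$factors <- factors
    out$net_wt <- corr(pair$wt, factors[["wt_net"]])
    out$net_mut <- corr(pair$mut, factors[["mut_net"]])
    write_tsv_q(tibble::tibble(sample = names(factors),
                               size_factor = unname(factors)),
                out_dir, "size_factors")
  }

  if (isTRUE(st$metagene)) {
    if (is.null(out$net_wt)) data_error("metagene stage: missing corrected tracks (normalize stage off)")
    genes <- filter_genes_for_metagene(
      out$net_wt, out$pair$annotation,
      window = config$metagene_window,
      min_length = config$filters$metagene_min_length,
      ratio_threshold = config$filters$metagene_ratio)
    out$metagene_genes <- genes
    mg <- dplyr::bind_rows(
      wt = metagene(out$net_wt, genes, window = config$metagene_window,
                    trim = config$filters$trim),
      mut = metagene(out$net_mut, genes, window = config$metagene_window,
                     trim = config$filters$trim),
      .id = "condition")
    out$metagene <- mg
    write_tsv_q(mg, out_dir, "metagene_tss")
  }

  if (isTRUE(st$fit)) {
    if (is.null(out$net_wt)) data_error("fit stage: missing corrected tracks (normalize stage off)")
    sets <- lhs_sample(default_parameter_ranges(), config$n_sets,
                       seed = config$seed,
                       constants = config$sim)
    out$library <- simulate_library(sets, config$population,
                                    seed = config$seed + 1L)
    prof_from <- function(track) {
      sel <- select_genes_for_fitting(track, out$pair$annotation)
      sel <- utils::head(sel, config$max_fit_genes)
      mat <- pmax(extract_signal(track, sel, window = c(1, 1000)), 0)
      list(sel = sel,
           profiles = purrr::map(seq_len(nrow(mat)),
                                 ~ gene_profile(mat[.x, ],
                                                gene_id = sel$gene_id[.x])) |>
             rlang::set_names(sel$gene_id))
    }
    pw <- prof_from(out$net_wt)
    pm <- prof_from(out$net_mut)
    shared <- intersect(names(pw$profiles), names(pm$profiles))
    out$fit_wt <- fit_genes(pw$profiles[shared], out$library,
                            k_best = config$k_best)
    out$fit_mut <- fit_genes(pm$profiles[shared], out$library,
                             k_best = config$k_best)
    write_tsv_q(out$fit_wt$metrics, out_dir, "fit_metrics_wt")
    write_tsv_q(out$fit_mut$metrics, out_dir, "fit_metrics_mut")
  }

  if (isTRUE(st$compare)) {
    if (is.null(out$fit_wt)) data_error("compare stage: missing fits (fit stage off)")
    out$comparison <- compare_conditions(out$fit_wt, out$fit_mut)
    write_tsv_q(out$comparison, out_dir, "metric_comparison")
  }

  if (isTRUE(st$dyads)) {
    if (is.null(out$pair)) data_error("dyads stage: missing input `pair` (synth stage off)")
    pos_wt <- nucleosome_positions(out$pair$wt$dyads, out$pair$annotation)
    pos_mut <- nucleosome_positions(out$pair$mut$dyads, out$pair$annotation)
    out$nucleosome_comparison <- compare_nucleosome_stats(pos_wt, pos_mut)
    write_tsv_q(out$nucleosome_comparison, out_dir, "nucleosome_comparison")
    density <- rowSums(extract_signal(out$pair$wt$tracks$net,
                                      out$pair$annotation,
                                      window = c(1, 500)))
    spacing <- pos_wt |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(spacing = stats::median(.data$sp_p1_p2),
                       .groups = "drop")
    df <- dplyr::inner_join(
      tibble::tibble(gene_id = out$pair$annotation$gene_id,
                     density = density),
      spacing, by = "gene_id")
    out$expression_spacing <- expression_group_spacing(
      df, n_groups = min(8, nrow(df)))
    write_tsv_q(out$expression_spacing, out_dir, "expression_spacing")
  }

  manifest <- list(
    package = "elongatr",
    version = as.character(utils::packageVersion("elongatr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = rlang::hash(config),
    stages_run = names(Filter(isTRUE, st)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
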