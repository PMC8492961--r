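#' Specification for a synthetic NET-seq/TEF-seq dataset
#'
#' Collects every knob of the ground-truth generator.  Per-gene NET-seq
#' expectations are the simulator's steady-state occupancy shape (extended
#' flat beyond 1000 nt) scaled by sequencing depth and a lognormal per-gene
#' expression factor; TEF-seq expectations multiply in a dyad-locked
#' sinusoidal occupancy modulation; all tracks receive a shared additive
#' Poisson background with an SCR1-like high-background locus that also
#' drives the no-tag control, so the printed background-correction formula
#' is exactly the right estimator in expectation.
#'
#' @param n_genes Number of genes.
#' @param gene_length_range Uniform range of gene lengths (nt); all genes
#'   exceed the 1000-nt fitting filter.
#' @param intergenic Intergenic gap (nt).
#' @param chrom Chromosome name of the synthetic genome.
#' @param params [model_params()] describing the condition's transcription
#'   regime (signal shape).
#' @param shape_population Population size for the shape simulation.
#' @param depth Mean reads per gene in the NET sample.
#' @param expr_sd sdlog of the lognormal per-gene expression factor.
#' @param spike_factors Named per-sample spike-in scale factors
#'   (samples `net` and `tef`).
#' @param n_spike_genes,spike_depth Spike-in species gene count and mean
#'   counts per spike gene.
#' @param background_rate Expected background counts per nt per strand in
#'   tagged samples (before spike scaling).
#' @param notag_scale Library scale of the no-tag control relative to the
#'   tagged background (the true correction ratio is
#'   `spike_factor / notag_scale`).
#' @param scr1_rate Background rate inside the SCR1-like locus.
#' @param nuc_spacing Mean dyad-to-dyad spacing (nt).
#' @param nuc_jitter_sd Per-replicate dyad jitter sd (nt).
#' @param ndr NDR length: distance between the -1 and +1 dyads (nt).
#' @param plus1_pos TSS-relative position of the +1 dyad (+1 convention).
#' @param n_nucleosomes Number of gene-body nucleosomes (+1 ... +n).
#' @param spacing_delta Added to every inter-dyad spacing from +1 to +2
#'   onward (the mutant's perturbation); NDR is untouched.
#' @param n_replicates Number of dyad-call replicates.
#' @param tef_amplitude,tef_phase Amplitude (must be < 1) and phase shift
#'   (nt) of the TEF/NET oscillation relative to the +1 dyad.
#' @param noise `TRUE` for Poisson sampling; `FALSE` writes the expectations
#'   directly (the infinite-depth limit).
#' @param seed Integer seed; fixed seed gives bit-identical datasets.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 200,
                           gene_length_range = c(1100, 1500),
                           intergenic = 500,
                           chrom = "chrSYN",
                           params = model_params(),
                           shape_population = 2000,
                           depth = 50,
                           expr_sd = 0.75,
                           spike_factors = c(net = 1, tef = 1),
                           n_spike_genes = 50,
                           spike_depth = 100,
                           background_rate = 0.001,
                           notag_scale = 0.7,
                           scr1_rate = 5,
                           nuc_spacing = 165,
                           nuc_jitter_sd = 4,
                           ndr = 170,
                           plus1_pos = 60,
                           n_nucleosomes = 6,
                           spacing_delta = 0,
                           n_replicates = 3,
                           tef_amplitude = 0.2,
                           tef_phase = 0,
                           noise = TRUE,
                           seed = 1) {
  spec <- as.list(environment())
  if (abs(tef_amplitude) >= 1)
    stop("`tef_amplitude` must have magnitude < 1 (expectations would go ",
         "negative)", call. = FALSE)
  if (depth <= 0 || background_rate < 0 || notag_scale <= 0 ||
      spike_depth <= 0 || any(spike_factors <= 0))
    stop("scales and depths must be positive", call. = FALSE)
  if (min(gene_length_range) < 1000 + 1)
    stop("gene lengths must exceed 1000 nt", call. = FALSE)
  structure(spec, class = "synthetic_spec")
}

make_layout <- function(spec, seed) {
  withr::with_seed(seed, {
    n <- spec$n_genes
    lens <- sample(seq(spec$gene_length_range[1], spec$gene_length_range[2]),
                   n, replace = TRUE)
    scr1_start <- 200L
    scr1 <- list(chrom = spec$chrom, start = scr1_start,
                 end = scr1_start + 451L)
    cursor <- scr1$end + 1000L
    strand <- rep(c("+", "-"), length.out = n)
    tss <- pas <- integer(n)
    for (i in seq_len(n)) {
      if (strand[i] == "+") {
        tss[i] <- cursor
        pas[i] <- cursor + lens[i] - 1L
      } else {
        tss[i] <- cursor + lens[i] - 1L
        pas[i] <- cursor
      }
      cursor <- cursor + lens[i] + spec$intergenic
    }
    expr <- stats::rlnorm(n, 0, spec$expr_sd)
    expr <- expr / mean(expr)
    list(
      annotation = gene_annotation(
        gene_id = sprintf("g%03d", seq_len(n)), chrom = spec$chrom,
        strand = strand, tss = tss, pas = pas),
      lengths = lens, expr = expr,
      chrom_len = cursor + 1000L, scr1 = scr1,
      spike_mu = spec$spike_depth * stats::runif(spec$n_spike_genes, 0.5, 2))
  })
}

# noise-free TSS-relative dyad ladder shared by all genes of one condition
dyad_ladder <- function(spec) {
  sp <- spec$nuc_spacing + spec$spacing_delta
  body <- spec$plus1_pos + c(0, cumsum(rep(sp, spec$n_nucleosomes - 1)))
  tibble::tibble(
    label = c("-1", paste0("+", seq_len(spec$n_nucleosomes))),
    rel_pos = c(spec$plus1_pos - spec$ndr, body))
}

sample_counts <- function(lambda, noise) {
  if (noise) stats::rpois(length(lambda), lambda) else lambda
}

# low uniform background over the genome plus the SCR1-like hot locus; in
# noiseless mode the expectations themselves are written, so tagged and
# no-tag backgrounds share one deterministic pattern and the correction
# cancels exactly
background_track <- function(layout, rate, scr1_rate, noise) {
  draws <- list()
  hot_pos <- seq(layout$scr1$start, layout$scr1$end)
  for (s in c("+", "-")) {
    if (noise) {
      n_bg <- stats::rpois(1, rate * layout$chrom_len)
      pos <- sample.int(layout$chrom_len, n_bg, replace = TRUE)
      n_hot <- stats::rpois(1, scr1_rate * length(hot_pos))
      hot <- sample(hot_pos, n_hot, replace = TRUE)
      tab <- table(c(pos, hot))
      draws[[s]] <- tibble::tibble(
        chrom = layout$scr1$chrom, pos = as.integer(names(tab)), strand = s,
        score = as.numeric(tab))
    } else {
      draws[[s]] <- tibble::tibble(
        chrom = layout$scr1$chrom,
        pos = c(seq_len(layout$chrom_len), hot_pos), strand = s,
        score = c(rep(rate, layout$chrom_len),
                  rep(scr1_rate, length(hot_pos))))
    }
  }
  dplyr::bind_rows(draws)
}

aggregate_track <- function(track) {
  track |>
    dplyr::filter(.data$score != 0) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$strand) |>
    dplyr::summarise(score = sum(.data$score), .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$strand, .data$pos)
}

#' Generate a complete synthetic dataset with known ground truth
#'
#' Produces everything the analysis pipeline consumes: gene annotation,
#' NET/TEF/no-tag signal tracks, spike-in species counts, replicated
#' nucleosome dyad calls, and a truth record of every generating value.
#'
#' @param spec A [synthetic_spec()].
#' @param layout Internal: a precomputed gene layout (used by
#'   [make_condition_pair()] to share the genome between conditions).
#' @return A list with `annotation`, `tracks` (named list `net`, `tef`,
#'   `notag`), `spike_counts` (tibble `gene_id`, `net`, `tef`), `dyads`
#'   (labeled tibble across replicates), `scr1` (background locus), and
#'   `truth`.
#' @export
generate_dataset <- function(spec, layout = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seeds <- withr::with_seed(as.integer(spec$seed),
                            sample.int(.Machine$integer.max - 1L, 4))
  if (is.null(layout)) layout <- make_layout(spec, seeds[1])
  ann <- layout$annotation

  shape_sim <- simulate_population(spec$params, spec$shape_population,
                                   seed = seeds[2])
  occ <- shape_sim$occupancy$count
  if (sum(occ) == 0)
    stop("shape simulation produced no engaged polymerases; check params",
         call. = FALSE)
  shape1k <- occ / sum(occ)
  tail_level <- mean(shape1k[901:1000])
  ladder <- dyad_ladder(spec)
  plus1 <- ladder$rel_pos[ladder$label == "+1"]

  res <- withr::with_seed(seeds[3], {
    net <- tef <- vector("list", nrow(ann))
    for (i in seq_len(nrow(ann))) {
      len <- layout$lengths[i]
      rel <- seq_len(len)
      shp <- c(shape1k, rep(tail_level, len - 1000))
      shp <- shp / sum(shp)
      lambda <- spec$depth * layout$expr[i] * shp
      mult <- 1 + spec$tef_amplitude *
        sin(2 * pi * (rel - plus1 - spec$tef_phase) / spec$nuc_spacing)
      gpos <- if (ann$strand[i] == "+") ann$tss[i] + rel - 1L
              else ann$tss[i] - rel + 1L
      net[[i]] <- tibble::tibble(
        chrom = ann$chrom[i], pos = gpos, strand = ann$strand[i],
        score = sample_counts(spec$spike_factors[["net"]] * lambda,
                              spec$noise))
      tef[[i]] <- tibble::tibble(
        chrom = ann$chrom[i], pos = gpos, strand = ann$strand[i],
        score = sample_counts(spec$spike_factors[["tef"]] * lambda * mult,
                              spec$noise))
    }
    bg_net <- background_track(layout, spec$background_rate * spec$spike_factors[["net"]],
                               spec$scr1_rate * spec$spike_factors[["net"]],
                               spec$noise)
    bg_tef <- background_track(layout, spec$background_rate * spec$spike_factors[["tef"]],
                               spec$scr1_rate * spec$spike_factors[["tef"]],
                               spec$noise)
    notag <- background_track(layout, spec$background_rate * spec$notag_scale,
                              spec$scr1_rate * spec$notag_scale, spec$noise)
    spike <- tibble::tibble(
      gene_id = sprintf("spike%03d", seq_along(layout$spike_mu)),
      net = sample_counts(layout$spike_mu * spec$spike_factors[["net"]], TRUE),
      tef = sample_counts(layout$spike_mu * spec$spike_factors[["tef"]], TRUE))
    list(net = aggregate_track(dplyr::bind_rows(c(net, list(bg_net)))),
         tef = aggregate_track(dplyr::bind_rows(c(tef, list(bg_tef)))),
         notag = aggregate_track(notag), spike = spike)
  })

  dyads <- withr::with_seed(seeds[4], {
    purrr::map_dfr(seq_len(spec$n_replicates), function(r) {
      purrr::map_dfr(seq_len(nrow(ann)), function(i) {
        jit <- round(stats::rnorm(nrow(ladder), 0, spec$nuc_jitter_sd))
        rel <- ladder$rel_pos + jit
        gpos <- if (ann$strand[i] == "+") ann$tss[i] + rel - 1L
                else ann$tss[i] - rel + 1L
        tibble::tibble(gene_id = ann$gene_id[i], label = ladder$label,
                       replicate = r, chrom = ann$chrom[i],
                       dyad = as.integer(gpos), rel_pos = as.integer(rel))
      })
    })
  })

  list(
    annotation = ann,
    tracks = list(net = res$net, tef = res$tef, notag = res$notag),
    spike_counts = res$spike,
    dyads = dyads,
    scr1 = layout$scr1,
    truth = list(
      spec = spec, shape = shape1k, expr = layout$expr,
      lengths = layout$lengths, spike_mu = layout$spike_mu,
      spike_factors = spec$spike_factors,
      notag_ratio = unname(spec$spike_factors[["net"]] / spec$notag_scale),
      dyad_ladder = ladder,
      shape_metrics = shape_sim$metrics))
}

#' Minimal dyad-flank dataset for calibrating the asymmetry test
#'
#' Generates isolated single-dyad "genes" with Poisson NET and TEF counts
#' over the dyad's +/-70 nt neighbourhood; `shift` multiplies the TEF
#' expectation on the downstream flank (+10..+60) only, so `shift = 0` is an
#' exactly symmetric null and `shift > 0` a known asymmetry.  Used for
#' Monte-Carlo size and power studies of [flank_asymmetry_test()] where the
#' full generator would be needlessly heavy.
#'
#' @param n_genes Number of genes.
#' @param shift Fractional TEF increase on the downstream flank.
#' @param rate Expected NET counts per nt.
#' @param seed Integer seed.
#' @return List with `net`, `tef` (tracks), `annotation`, `dyads`.
#' @export
synthetic_flank_data <- function(n_genes = 200, shift = 0, rate = 2,
                                 seed = 1) {
  withr::with_seed(as.integer(seed), {
    dyad <- 200L + 400L * (seq_len(n_genes) - 1L)
    rel <- -70:70
    rows_net <- rows_tef <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      lam_net <- rep(rate, length(rel))
      lam_tef <- lam_net * (1 + shift * (rel >= 10 & rel <= 60))
      gpos <- dyad[i] + rel
      rows_net[[i]] <- tibble::tibble(
        chrom = "chrF", pos = gpos, strand = "+",
        score = stats::rpois(length(rel), lam_net))
      rows_tef[[i]] <- tibble::tibble(
        chrom = "chrF", pos = gpos, strand = "+",
        score = stats::rpois(length(rel), lam_tef))
    }
    ann <- gene_annotation(
      gene_id = sprintf("f%03d", seq_len(n_genes)), chrom = "chrF",
      strand = "+", tss = dyad - 150L, pas = dyad + 150L)
    list(net = dplyr::bind_rows(rows_net), tef = dplyr::bind_rows(rows_tef),
         annotation = ann,
         dyads = tibble::tibble(gene_id = ann$gene_id, label = "+2",
                                replicate = 1L, chrom = "chrF",
                                dyad = dyad))
  })
}

#' Generate a paired wild-type/mutant synthetic dataset
#'
#' Both conditions share the genome layout, per-gene expression factors and
#' spike-in species; the mutant differs only by the declared parameter
#' deltas (its transcription regime, dyad spacing perturbation, and/or
#' spike-in factors), enabling end-to-end effect-size and spacing-recovery
#' tests against known truth.
#'
#' @param spec A [synthetic_spec()] describing the wild type.
#' @param mut_params [model_params()] for the mutant (default: same as WT).
#' @param mut_spacing_delta Added to the mutant's inter-dyad spacing from
#'   +1 to +2 onward (nt); NDR unchanged.
#' @param mut_spike_factors Optional spike factors for the mutant's samples.
#' @return List with `wt`, `mut` (each as [generate_dataset()]),
#'   `annotation`, and `spike_counts` (shared spike genes, columns
#'   `wt_net`, `wt_tef`, `mut_net`, `mut_tef`).
#' @export
make_condition_pair <- function(spec, mut_params = spec$params,
                                mut_spacing_delta = 0,
                                mut_spike_factors = spec$spike_factors) {
  seeds <- withr::with_seed(as.integer(spec$seed) ,
                            sample.int(.Machine$integer.max - 1L, 3) )
  layout <- make_layout(spec, seeds[1])
  wt_spec <- spec
  wt_spec$seed <- seeds[2]
  mut_spec <- spec
  mut_spec$params <- mut_params
  mut_spec$spacing_delta <- spec$spacing_delta + mut_spacing_delta
  mut_spec$spike_factors <- mut_spike_factors
  mut_spec$seed <- seeds[3]
  wt <- generate_dataset(wt_spec, layout = layout)
  mut <- generate_dataset(mut_spec, layout = layout)
  spike <- tibble::tibble(
    gene_id = wt$spike_counts$gene_id,
    wt_net = wt$spike_counts$net, wt_tef = wt$spike_counts$tef,
    mut_net = mut$spike_counts$net, mut_tef = mut$spike_counts$tef)
  list(wt = wt, mut = mut, annotation = layout$annotation,
       spike_counts = spike)
}
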