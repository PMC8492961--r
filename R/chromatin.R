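dyad_rel <- function(dyads, annotation) {
  ann <- annotation[match(dyads$gene_id, annotation$gene_id), ]
  ifelse(ann$strand == "+", dyads$dyad - ann$tss + 1L,
         ann$tss - dyads$dyad + 1L)
}

#' Label nucleosome dyads relative to the TSS
#'
#' Within each gene and replicate, the +1 nucleosome is the first dyad at or
#' downstream of the TSS (minus a configurable upstream tolerance), +2, +3,
#' ... follow in transcription order, and -1 is the last dyad upstream.
#'
#' @param dyads Tibble with `gene_id`, `replicate`, `chrom`, `dyad`
#'   (genomic dyad positions).
#' @param annotation Gene annotation tibble.
#' @param upstream_tol Dyads up to this many nt upstream of the TSS still
#'   count as +1 (default 0).
#' @return `dyads` with added columns `rel_pos` (TSS-relative, +1
#'   convention) and `label` (`"-1"`, `"+1"`, `"+2"`, ...).
#' @export
label_dyads <- function(dyads, annotation, upstream_tol = 0) {
  dyads$rel_pos <- dyad_rel(dyads, annotation)
  dyads |>
    dplyr::group_by(.data$gene_id, .data$replicate) |>
    dplyr::arrange(.data$rel_pos, .by_group = TRUE) |>
    dplyr::mutate(label = {
      down <- .data$rel_pos >= 1 - upstream_tol
      lab <- integer(dplyr::n())
      lab[down] <- seq_len(sum(down))
      lab[!down] <- -rev(seq_len(sum(!down)))
      ifelse(lab > 0, paste0("+", lab), as.character(lab))
    }) |>
    dplyr::ungroup()
}

#' Nucleosome positions, NDR length and spacing per gene
#'
#' TSS-relative dyad positions for the -1 and +1..+4 nucleosomes, the NDR
#' length (distance between the -1 and +1 dyads) and the spacing between
#' adjacent gene-body dyads, per gene and replicate.
#'
#' @param dyads Labeled dyad tibble (see [label_dyads()]; an unlabeled
#'   tibble is labeled automatically).
#' @param annotation Gene annotation tibble.
#' @return A tibble with one row per gene x replicate: `nuc_m1`, `nuc_p1` ..
#'   `nuc_p4` (TSS-relative dyad positions; NA where the labeled dyad is
#'   missing), `ndr`, `sp_p1_p2`, `sp_p2_p3`, `sp_p3_p4`.
#' @export
nucleosome_positions <- function(dyads, annotation) {
  if (!"label" %in% names(dyads)) dyads <- label_dyads(dyads, annotation)
  if (!"rel_pos" %in% names(dyads))
    dyads$rel_pos <- dyad_rel(dyads, annotation)
  wanted <- c("-1", "+1", "+2", "+3", "+4")
  cols <- c("nuc_m1", "nuc_p1", "nuc_p2", "nuc_p3", "nuc_p4")
  wide <- dyads |>
    dplyr::filter(.data$label %in% wanted) |>
    dplyr::mutate(label = cols[match(.data$label, wanted)]) |>
    dplyr::distinct(.data$gene_id, .data$replicate, .data$label,
                    .keep_all = TRUE) |>
    tidyr::pivot_wider(id_cols = c("gene_id", "replicate"),
                       names_from = "label", values_from = "rel_pos")
  for (cl in cols) if (!cl %in% names(wide)) wide[[cl]] <- NA_real_
  wide |>
    dplyr::mutate(
      ndr = .data$nuc_p1 - .data$nuc_m1,
      sp_p1_p2 = .data$nuc_p2 - .data$nuc_p1,
      sp_p2_p3 = .data$nuc_p3 - .data$nuc_p2,
      sp_p3_p4 = .data$nuc_p4 - .data$nuc_p3) |>
    dplyr::select(dplyr::all_of(c("gene_id", "replicate", cols, "ndr",
                                  "sp_p1_p2", "sp_p2_p3", "sp_p3_p4")))
}

#' Compare nucleosome statistics between two conditions
#'
#' For each statistic (dyad positions, NDR length, spacings), per-replicate
#' medians across genes are computed in each condition and compared by a
#' paired two-sided t-test across replicates; the overall medians (across
#' genes and replicates) and their difference are reported alongside.
#'
#' @param pos_a,pos_b Outputs of [nucleosome_positions()] for the two
#'   conditions, with matching replicate ids.
#' @param stats Which statistic columns to compare.
#' @return Tibble with `stat`, `median_a`, `median_b`, `difference`
#'   (b - a, from per-replicate medians), `p_value`, `n_replicates`.
#' @export
compare_nucleosome_stats <- function(pos_a, pos_b,
                                     stats = c("nuc_m1", "nuc_p1", "nuc_p2",
                                               "nuc_p3", "nuc_p4", "ndr",
                                               "sp_p1_p2", "sp_p2_p3",
                                               "sp_p3_p4")) {
  rep_medians <- function(df, col)
    tapply(df[[col]], df$replicate, stats::median, na.rm = TRUE)
  purrr::map_dfr(stats, function(cl) {
    ma <- rep_medians(pos_a, cl)
    mb <- rep_medians(pos_b, cl)
    reps <- intersect(names(ma), names(mb))
    ma <- ma[reps]; mb <- mb[reps]
    ok <- is.finite(ma) & is.finite(mb)
    ma <- ma[ok]; mb <- mb[ok]
    reps <- reps[ok]
    p <- if (length(reps) >= 2 && isTRUE(stats::sd(mb - ma) > 0))
      stats::t.test(mb, ma, paired = TRUE)$p.value else NA_real_
    tibble::tibble(
      stat = cl,
      median_a = stats::median(pos_a[[cl]], na.rm = TRUE),
      median_b = stats::median(pos_b[[cl]], na.rm = TRUE),
      difference = mean(mb - ma),
      p_value = p, n_replicates = length(reps))
  })
}

#' Gene filter for nucleosome phasing analyses
#'
#' Keeps protein-coding genes at least `min_length` nt long that have the
#' required number of dyad calls within the first 600 nt from the TSS (+1 to
#' +600) in every replicate, excluding genes with poorly phased nucleosomes.
#'
#' @param dyads Dyad tibble (labeled or not) covering all replicates.
#' @param annotation Gene annotation tibble.
#' @param n_required Number of dyads required in the window (default 4).
#' @param mode `"at_least"` (default) or `"exactly"`.
#' @param window TSS-relative window searched (default `c(1, 600)`).
#' @param min_length Minimum gene length in nt (default 600; shorter genes
#'   are discarded).
#' @return Character vector of retained gene ids.
#' @export
mnase_gene_filter <- function(dyads, annotation, n_required = 4,
                              mode = c("at_least", "exactly"),
                              window = c(1, 600), min_length = 600) {
  mode <- match.arg(mode)
  if (!"rel_pos" %in% names(dyads))
    dyads$rel_pos <- dyad_rel(dyads, annotation)
  eligible <- annotation$gene_id[annotation$biotype == "protein_coding" &
                                   gene_lengths(annotation) >= min_length]
  reps <- sort(unique(dyads$replicate))
  counts <- dyads |>
    dplyr::filter(.data$gene_id %in% eligible,
                  .data$rel_pos >= window[1], .data$rel_pos <= window[2]) |>
    dplyr::count(.data$gene_id, .data$replicate)
  ok <- counts |>
    dplyr::filter(if (mode == "at_least") .data$n >= n_required
                  else .data$n == n_required) |>
    dplyr::count(.data$gene_id, name = "n_reps") |>
    dplyr::filter(.data$n_reps == length(reps))
  ok$gene_id
}

#' Nucleosome spacing across expression groups
#'
#' Splits genes into equal-size quantile groups by expression (RNAPII
#' density over the first 500 nt by default) and reports, per group, the
#' median density and the median and standard deviation of nucleosome
#' spacing.  The same mechanics support grouping by any other per-gene value
#' (e.g. fixed-size groups by +1 nucleosome location) via `group_by_col`.
#'
#' @param genes Tibble with one row per gene containing the grouping value
#'   and the spacing value.
#' @param n_groups Number of equal-size groups (default 8).
#' @param group_by_col Column used for grouping (default `"density"`).
#' @param spacing_col Column holding the spacing value (default `"spacing"`).
#' @return Tibble with `group`, `n`, `median_density`, `median_spacing`,
#'   `sd_spacing` (the `median_density` column is named after
#'   `group_by_col` when grouping by something else).
#' @export
expression_group_spacing <- function(genes, n_groups = 8,
                                     group_by_col = "density",
                                     spacing_col = "spacing") {
  stopifnot(group_by_col %in% names(genes), spacing_col %in% names(genes))
  genes <- genes[stats::complete.cases(genes[[group_by_col]],
                                       genes[[spacing_col]]), ]
  if (nrow(genes) < n_groups)
    stop("fewer genes (", nrow(genes), ") than groups (", n_groups, ")",
         call. = FALSE)
  genes$group <- dplyr::ntile(genes[[group_by_col]], n_groups)
  genes |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_density = stats::median(.data[[group_by_col]]),
      median_spacing = stats::median(.data[[spacing_col]]),
      sd_spacing = stats::sd(.data[[spacing_col]]),
      .groups = "drop")
}

#' TEF/RNAPII ratio metagene anchored on nucleosome dyads
#'
#' Builds the trimmed-mean metagene of the TEF-seq and NET-seq tracks
#' (per [metagene()]) around per-gene anchor dyads and returns their
#' bin-wise ratio; bins where the NET-seq metagene is zero are masked (NA).
#'
#' @param tef_track,net_track Normalised signal tracks.
#' @param annotation Genes to include.
#' @param anchor_dyads Numeric vector of genomic dyad positions, one per
#'   annotation row (relative coordinate 0 = dyad).
#' @param window Relative window around the dyad (default `c(-250, 250)`).
#' @param trim,bin_width Passed to [metagene()].
#' @return A tibble with `rel_pos`, `bin`, `tef`, `net`, `ratio`.
#' @export
ratio_metagene <- function(tef_track, net_track, annotation, anchor_dyads,
                           window = c(-250, 250), trim = 0.01,
                           bin_width = 10) {
  mg_t <- metagene(tef_track, annotation, anchor = anchor_dyads,
                   window = window, trim = trim, bin_width = bin_width)
  mg_n <- metagene(net_track, annotation, anchor = anchor_dyads,
                   window = window, trim = trim, bin_width = bin_width)
  if (all(mg_n$mean_signal == 0))
    stop("NET-seq metagene is zero everywhere; ratio undefined",
         call. = FALSE)
  tibble::tibble(
    rel_pos = mg_t$rel_pos, bin = mg_t$bin,
    tef = mg_t$mean_signal, net = mg_n$mean_signal,
    ratio = ifelse(mg_n$mean_signal > 0,
                   mg_t$mean_signal / mg_n$mean_signal, NA_real_))
}

#' Flank asymmetry of factor occupancy around a nucleosome dyad
#'
#' For each gene, the TEF/RNAPII ratio is evaluated over the upstream flank
#' (-60 to -10 nt from the dyad) and the downstream flank (+10 to +60 nt;
#' the +/-10 nt core is excluded), and the per-gene paired values are tested
#' with a one-tailed paired t-test of upstream < downstream.
#'
#' @param tef_track,net_track Normalised signal tracks.
#' @param annotation Genes to include.
#' @param dyads Dyad tibble with `label` (see [label_dyads()]); when several
#'   replicates are present the per-gene median dyad is used.
#' @param nucleosome_label Which nucleosome (default `"+2"`).
#' @param upstream,downstream Flank windows relative to the dyad.
#' @return List with `per_gene` (tibble `gene_id`, `upstream`, `downstream`),
#'   `p_value`, `statistic`, `n`.
#' @export
flank_asymmetry_test <- function(tef_track, net_track, annotation, dyads,
                                 nucleosome_label = "+2",
                                 upstream = c(-60, -10),
                                 downstream = c(10, 60)) {
  if (!"label" %in% names(dyads)) dyads <- label_dyads(dyads, annotation)
  d <- dyads |>
    dplyr::filter(.data$label == nucleosome_label) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(dyad = stats::median(.data$dyad), .groups = "drop")
  ann <- annotation[match(d$gene_id, annotation$gene_id), ]
  ann <- ann[!is.na(ann$gene_id), ]
  d <- d[d$gene_id %in% ann$gene_id, ]
  flank_ratio <- function(win) {
    tef <- rowSums(extract_signal(tef_track, ann, window = win,
                                  anchor = d$dyad))
    net <- rowSums(extract_signal(net_track, ann, window = win,
                                  anchor = d$dyad))
    ifelse(net > 0, tef / net, NA_real_)
  }
  per_gene <- tibble::tibble(
    gene_id = ann$gene_id,
    upstream = flank_ratio(upstream),
    downstream = flank_ratio(downstream)) |>
    dplyr::filter(!is.na(.data$upstream), !is.na(.data$downstream))
  if (nrow(per_gene) < 2)
    stop("flank test needs at least 2 genes with signal in both flanks",
         call. = FALSE)
  tt <- stats::t.test(per_gene$upstream, per_gene$downstream, paired = TRUE,
                      alternative = "less")
  list(per_gene = per_gene, p_value = tt$p.value,
       statistic = unname(tt$statistic), n = nrow(per_gene))
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Z-score normalise a single gene profile
#'
#' Centers and scales a per-position profile to mean 0 and (population)
#' standard deviation 1 so that the shape of the RNAPII distribution can be
#' compared regardless of expression level.
#'
#' @param profile Numeric vector of per-position counts.
#' @return The z-scored vector.
#' @export
#' @examples
#' shape_normalize_gene(c(0, 0, 4, 0))
shape_normalize_gene <- function(profile) {
  s <- sd_pop(profile)
  if (is.na(s) || s == 0)
    stop("profile has zero standard deviation; gene excluded from ",
         "shape-normalised analyses", call. = FALSE)
  (profile - mean(profile)) / s
}

#' Z-score normalise a genes-by-positions matrix
#'
#' Rows (genes) with zero standard deviation are dropped; their ids are
#' recorded in the `"excluded"` attribute.
#'
#' @param mat Numeric matrix, genes in rows.
#' @return The matrix of z-scored rows.
#' @export
shape_normalize <- function(mat) {
  sds <- apply(mat, 1, sd_pop)
  keep <- !is.na(sds) & sds > 0
  out <- (mat[keep, , drop = FALSE] -
            rowMeans(mat[keep, , drop = FALSE])) / sds[keep]
  attr(out, "excluded") <- rownames(mat)[!keep]
  out
}
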