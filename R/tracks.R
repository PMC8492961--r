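#' Construct a strand-resolved single-nucleotide signal track
#'
#' A track is a sparse tibble of per-nucleotide counts (3'-end assigned):
#' one row per covered position, absent positions count 0.  Positions are
#' 1-based genomic coordinates.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions.
#' @param strand `"+"` or `"-"`.
#' @param score Non-negative (or, after background correction, possibly
#'   negative) finite counts.
#' @return A tibble with columns `chrom`, `pos`, `strand`, `score`.
#' @export
signal_track <- function(chrom = character(), pos = integer(),
                         strand = character(), score = numeric()) {
  out <- tibble::tibble(chrom = as.character(chrom), pos = as.integer(pos),
                        strand = as.character(strand),
                        score = as.numeric(score))
  validate_track(out)
  out
}

validate_track <- function(track) {
  stopifnot(is.data.frame(track),
            all(c("chrom", "pos", "strand", "score") %in% names(track)))
  if (nrow(track) > 0) {
    if (any(!track$strand %in% c("+", "-")))
      stop("track strand must be '+' or '-'", call. = FALSE)
    if (any(track$pos < 1) || anyNA(track$pos))
      stop("track positions must be 1-based positive integers", call. = FALSE)
    if (any(!is.finite(track$score)))
      stop("track scores must be finite", call. = FALSE)
  }
  invisible(track)
}

#' Construct a gene annotation table
#'
#' TSS and PAS are 1-based genomic coordinates of the first and last
#' transcribed nt; on the minus strand `tss > pas`.
#'
#' @param gene_id,chrom,strand,tss,pas,biotype Per-gene vectors.
#' @return A tibble with one row per gene.
#' @export
gene_annotation <- function(gene_id, chrom, strand, tss, pas,
                            biotype = "protein_coding") {
  out <- tibble::tibble(gene_id = as.character(gene_id),
                        chrom = as.character(chrom),
                        strand = as.character(strand),
                        tss = as.integer(tss), pas = as.integer(pas),
                        biotype = as.character(biotype))
  if (any(!out$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  if (any(out$tss == out$pas)) stop("TSS must differ from PAS", call. = FALSE)
  bad <- (out$strand == "+" & out$tss > out$pas) |
    (out$strand == "-" & out$tss < out$pas)
  if (any(bad))
    stop("TSS must be upstream of PAS in the transcription direction",
         call. = FALSE)
  out
}

gene_lengths <- function(annotation) abs(annotation$pas - annotation$tss) + 1L

#' Extract transcription-oriented signal windows for a set of genes
#'
#' Returns a genes-by-positions matrix of counts, oriented in the direction
#' of transcription (minus-strand genes are read from the minus-strand track
#' in reversed genomic order).  With `anchor = "TSS"` or `"PAS"`, relative
#' coordinates follow the `+1` convention (+1 is the anchor nt, 0 the nt
#' just upstream); with numeric per-gene `anchor` positions (e.g. nucleosome
#' dyads), relative coordinate 0 is the anchor itself.
#'
#' @param track A [signal_track()] tibble.
#' @param annotation A [gene_annotation()] tibble.
#' @param window `c(from, to)` in relative coordinates.
#' @param anchor `"TSS"`, `"PAS"`, or a numeric vector of genomic anchor
#'   positions, one per annotation row.
#' @return A numeric matrix, `nrow(annotation)` rows (rownames = gene ids),
#'   `window[2] - window[1] + 1` columns.
#' @export
extract_signal <- function(track, annotation, window, anchor = "TSS") {
  validate_track(track)
  stopifnot(length(window) == 2, window[1] <= window[2])
  rel <- seq.int(window[1], window[2])
  if (is.character(anchor)) {
    anchor <- match.arg(anchor, c("TSS", "PAS"))
    anchor_pos <- if (anchor == "TSS") annotation$tss else annotation$pas
    shift <- 1L   # +1 convention: r = +1 maps onto the anchor nt
  } else {
    anchor_pos <- as.numeric(anchor)
    stopifnot(length(anchor_pos) == nrow(annotation))
    shift <- 0L   # dyad convention: r = 0 is the anchor
  }
  # dense per (chrom, strand) lookup
  dense <- list()
  key <- paste(track$chrom, track$strand)
  for (k in unique(key)) {
    sub <- track[key == k, ]
    v <- numeric(max(sub$pos))
    v[sub$pos] <- sub$score
    dense[[k]] <- v
  }
  out <- matrix(0, nrow(annotation), length(rel),
                dimnames = list(annotation$gene_id, rel))
  for (i in seq_len(nrow(annotation))) {
    sgn <- if (annotation$strand[i] == "+") 1L else -1L
    gpos <- anchor_pos[i] + sgn * (rel - shift)
    v <- dense[[paste(annotation$chrom[i], annotation$strand[i])]]
    if (is.null(v)) next
    ok <- gpos >= 1 & gpos <= length(v)
    out[i, ok] <- v[gpos[ok]]
  }
  out
}

track_key <- function(track) paste(track$chrom, track$pos, track$strand)

#' Elementwise linear combination of two tracks
#'
#' Computes `a + coef * b` over the union of covered positions.
#'
#' @param a,b Signal tracks.
#' @param coef Coefficient applied to `b` (default -1, i.e. subtraction).
#' @return A signal track covering the union of positions.
#' @export
track_combine <- function(a, b, coef = -1) {
  validate_track(a)
  validate_track(b)
  m <- dplyr::full_join(a, b, by = c("chrom", "pos", "strand"),
                        suffix = c("_a", "_b"))
  m$score <- dplyr::coalesce(m$score_a, 0) + coef * dplyr::coalesce(m$score_b, 0)
  dplyr::arrange(m[, c("chrom", "pos", "strand", "score")],
                 .data$chrom, .data$strand, .data$pos)
}

#' Scale a track by a constant
#' @param track A signal track.
#' @param factor Divisor (e.g. a spike-in size factor).
#' @return The track with `score / factor`.
#' @export
track_divide <- function(track, factor) {
  validate_track(track)
  stopifnot(is.finite(factor), factor > 0)
  track$score <- track$score / factor
  track
}

# ---- genomic file IO (bedGraph / BED via rtracklayer) ----------------------

#' Read a pair of bedGraph files into one strand-resolved track
#'
#' bedGraph carries no strand, so strand-resolved data ship as one file per
#' strand.  Intervals are expanded to single-nt rows.
#'
#' @param plus_file,minus_file bedGraph paths (either may be `NULL`).
#' @return A [signal_track()] tibble.
#' @export
read_bedgraph_pair <- function(plus_file, minus_file = NULL) {
  one <- function(f, s) {
    if (is.null(f)) return(NULL)
    gr <- rtracklayer::import(f, format = "bedGraph")
    tibble::tibble(
      chrom = rep(as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::width(gr)),
      pos = unlist(purrr::map2(GenomicRanges::start(gr),
                               GenomicRanges::end(gr), seq.int)),
      strand = s,
      score = rep(gr$score, GenomicRanges::width(gr)))
  }
  out <- dplyr::bind_rows(one(plus_file, "+"), one(minus_file, "-"))
  validate_track(out)
  out
}

#' Write one strand of a track as bedGraph
#'
#' @param track A signal track.
#' @param file Output path.
#' @param strand Which strand to write.
#' @export
write_bedgraph <- function(track, file, strand = "+") {
  validate_track(track)
  sub <- track[track$strand == strand & track$score != 0, ]
  gr <- GenomicRanges::GRanges(
    sub$chrom, IRanges::IRanges(start = sub$pos, width = 1), score = sub$score)
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' Read gene annotation from BED6 (+ optional biotype column)
#'
#' BED blocks are taken as TSS-to-PAS extents; the strand decides which end
#' is the TSS.
#'
#' @param file BED path.
#' @return A [gene_annotation()] tibble.
#' @export
read_annotation_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED",
                            extraCols = c(biotype = "character"))
  plus <- as.character(GenomicRanges::strand(gr)) == "+"
  gene_annotation(
    gene_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = ifelse(plus, "+", "-"),
    tss = ifelse(plus, GenomicRanges::start(gr), GenomicRanges::end(gr)),
    pas = ifelse(plus, GenomicRanges::end(gr), GenomicRanges::start(gr)),
    biotype = if (!is.null(gr$biotype)) gr$biotype else "protein_coding")
}

#' Write gene annotation as BED6 + biotype
#' @param annotation A [gene_annotation()] tibble.
#' @param file Output path.
#' @export
write_annotation_bed <- function(annotation, file) {
  start <- pmin(annotation$tss, annotation$pas)
  end <- pmax(annotation$tss, annotation$pas)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s",
                   annotation$chrom, start - 1L, end, annotation$gene_id,
                   annotation$strand, annotation$biotype)
  writeLines(lines, file)
  invisible(file)
}

#' Read nucleosome dyad calls from BED
#'
#' One record per dyad; `name` is `gene:label` (label e.g. `-1`, `+1`),
#' `score` is the replicate id.
#'
#' @param file BED path.
#' @return Tibble with `gene_id`, `label`, `replicate`, `chrom`, `dyad`.
#' @export
read_dyad_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  parts <- strsplit(gr$name, ":", fixed = TRUE)
  tibble::tibble(
    gene_id = purrr::map_chr(parts, 1),
    label = purrr::map_chr(parts, 2),
    replicate = as.integer(gr$score),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    dyad = GenomicRanges::start(gr))
}

#' Write nucleosome dyad calls as BED
#' @param dyads Tibble with `gene_id`, `label`, `replicate`, `chrom`, `dyad`.
#' @param file Output path.
#' @export
write_dyad_bed <- function(dyads, file) {
  lines <- sprintf("%s\t%d\t%d\t%s:%s\t%d\t.",
                   dyads$chrom, dyads$dyad - 1L, dyads$dyad,
                   dyads$gene_id, dyads$label, dyads$replicate)
  writeLines(lines, file)
  invisible(file)
}
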