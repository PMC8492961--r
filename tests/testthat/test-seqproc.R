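# a small background window used instead of the genomic SCR1 default
toy_window <- list(chrom = "chrT", start = 1L, end = 30L)

test_that("no-tag correction reproduces the printed formula on a toy locus", {
  # SCR1-like bins: flag (10, 20, 30), notag (5, 5, 10) -> ratios (2, 4, 3)
  flag <- signal_track(chrom = rep("chrT", 4), pos = c(5L, 15L, 25L, 100L),
                       strand = "+", score = c(10, 20, 30, 9))
  notag <- signal_track(chrom = rep("chrT", 4), pos = c(5L, 15L, 25L, 100L),
                        strand = "+", score = c(5, 5, 10, 2))
  expect_equal(notag_ratio(flag, notag, toy_window), 3)
  corr <- notag_correct(flag, notag, toy_window)
  expect_equal(corr$score[corr$pos == 100], 9 - 3 * 2)
})

test_that("exact background correction cancels to zero", {
  pos <- c(5L, 15L, 25L, 200L, 300L)
  notag <- signal_track(chrom = rep("chrT", 5), pos = pos, strand = "+",
                        score = c(4, 6, 2, 1, 3))
  flag <- notag
  flag$score <- 2 * notag$score
  corr <- notag_correct(flag, notag, toy_window)
  expect_true(all(abs(corr$score) < 1e-12))
})

test_that("correction is the identity where the no-tag track is empty", {
  flag <- signal_track(chrom = rep("chrT", 3), pos = c(10L, 500L, 600L),
                       strand = "+", score = c(8, 7, 3))
  notag <- signal_track(chrom = "chrT", pos = 10L, strand = "+", score = 4)
  corr <- notag_correct(flag, notag, toy_window)
  expect_equal(corr$score[corr$pos %in% c(500, 600)], c(7, 3))
  # zero no-tag signal across the whole window is an error
  notag2 <- signal_track(chrom = "chrT", pos = 999L, strand = "+", score = 1)
  expect_error(notag_correct(flag, notag2, toy_window), "ratio undefined")
})

test_that("spike-in size factors implement median-of-ratios", {
  m <- cbind(a = c(10, 100, 4), b = c(20, 200, 8))
  f <- spikein_size_factors(m)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)))
  # identical columns -> unit factors
  expect_equal(unname(spikein_size_factors(cbind(x = c(3, 9), y = c(3, 9)))),
               c(1, 1))
  # scaling equivariance
  m2 <- m
  m2[, "b"] <- m[, "b"] * 3
  f2 <- spikein_size_factors(m2)
  expect_equal(f2[["b"]] / f2[["a"]], 3 * f[["b"]] / f[["a"]])
  # invariance under gene permutation
  expect_equal(spikein_size_factors(m[c(3, 1, 2), ]), f)
  expect_error(spikein_size_factors(cbind(c(0, 1), c(1, 0))), "nonzero")
})

test_that("size factors agree with the DESeq2 estimator on random tables", {
  skip_if_not_installed("DESeq2")
  withr::with_seed(8, {
    for (i in 1:5) {
      m <- matrix(rpois(63, 50), ncol = 3)  # odd gene count: medians exact
      m <- sweep(m, 2, c(1, 2, 0.5), `*`)
      expect_equal(unname(spikein_size_factors(m)),
                   unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                   tolerance = 1e-8)
    }
  })
})

test_that("metagene gene filters apply length, negativity and TSS rules", {
  mk <- function(upstream_total, downstream_total, len = 1000,
                 negative_at = NULL) {
    counts <- rep(downstream_total / 150, 150)
    counts <- c(counts, rep(1, len - 150))
    if (!is.null(negative_at)) counts[negative_at] <- -1
    toy_gene_track(counts, tss = 2000,
                   upstream = rep(upstream_total / 151, 151))
  }
  ok <- mk(30, 20)
  expect_equal(nrow(filter_genes_for_metagene(ok$track, ok$annotation)), 1)
  # strictly more than 1.5x upstream -> discarded
  bad <- mk(31, 20)
  expect_equal(nrow(filter_genes_for_metagene(bad$track, bad$annotation)), 0)
  # short gene -> discarded
  short <- mk(0, 20, len = 700)
  expect_equal(nrow(filter_genes_for_metagene(short$track,
                                              short$annotation)), 0)
  # any negative corrected value in the window -> discarded
  neg <- mk(0, 20, negative_at = 400)
  expect_equal(nrow(filter_genes_for_metagene(neg$track, neg$annotation)), 0)
  # non-coding genes are excluded up front
  nc <- mk(0, 20)
  nc$annotation$biotype <- "ncRNA"
  expect_equal(nrow(filter_genes_for_metagene(nc$track, nc$annotation)), 0)
})

test_that("metagene of identical genes equals the shared signal", {
  sig <- c(rep(5, 50), rep(2, 150))
  tracks <- list()
  anns <- list()
  for (i in 1:5) {
    tg <- toy_gene_track(sig, tss = 3000 * i, gene_id = paste0("g", i))
    tracks[[i]] <- tg$track
    anns[[i]] <- tg$annotation
  }
  track <- dplyr::bind_rows(tracks)
  ann <- dplyr::bind_rows(anns)
  mg <- metagene(track, ann, window = c(1, 200))
  expect_equal(mg$mean_signal, c(rep(5, 5), rep(2, 15)))
  expect_equal(nrow(mg), 20)
  expect_error(metagene(track, ann[1:2, ], window = c(1, 200)),
               "at least 3")
})

test_that("per-position trimming suppresses a single-gene spike", {
  sig <- rep(2, 200)
  tracks <- list(); anns <- list()
  for (i in 1:100) {
    s <- sig
    if (i == 1) s[50] <- 1e6
    tg <- toy_gene_track(s, tss = 3000 * i, gene_id = sprintf("g%03d", i))
    tracks[[i]] <- tg$track
    anns[[i]] <- tg$annotation
  }
  mg <- metagene(dplyr::bind_rows(tracks), dplyr::bind_rows(anns),
                 window = c(1, 200))
  expect_true(all(abs(mg$mean_signal - 2) < 1e-9))
})

test_that("minus-strand genes are read reversed from the minus track", {
  sig <- seq(1, 200)  # ramp: orientation is visible
  gs <- list(toy_gene_track(sig, strand = "+", tss = 1000, gene_id = "gp1"),
             toy_gene_track(sig, strand = "+", tss = 5000, gene_id = "gp2"),
             toy_gene_track(sig, strand = "-", tss = 9000, gene_id = "gm1"),
             toy_gene_track(sig, strand = "-", tss = 14000, gene_id = "gm2"))
  track <- dplyr::bind_rows(purrr::map(gs, "track"))
  ann <- dplyr::bind_rows(purrr::map(gs, "annotation"))
  mat <- extract_signal(track, ann, window = c(1, 200))
  expect_equal(unname(mat["gp1", ]), sig)
  expect_equal(unname(mat["gm1", ]), sig)   # identical once oriented
  # strand-symmetric dataset: metagene equals the shared oriented signal,
  # so it is invariant under flipping every gene
  mg_pair <- metagene(track, ann, window = c(1, 200), trim = 0,
                      bin_width = 1)
  expect_equal(mg_pair$mean_signal, as.numeric(sig))
})
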