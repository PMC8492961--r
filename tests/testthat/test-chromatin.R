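mk_dyads <- function(rel_list, tss = 1000, strand = "+", replicate = 1,
                     chrom = "chrT") {
  purrr::imap_dfr(rel_list, function(rels, gid) {
    gpos <- if (strand == "+") tss + rels - 1L else tss - rels + 1L
    tibble::tibble(gene_id = gid, replicate = replicate, chrom = chrom,
                   dyad = as.integer(gpos))
  })
}

test_that("dyad labeling assigns -1/+1.. relative to the TSS", {
  ann <- gene_annotation("g1", "chrT", "+", tss = 1000, pas = 2500)
  d <- mk_dyads(list(g1 = c(-110L, 60L, 225L, 390L)))
  lab <- label_dyads(d, ann)
  expect_equal(lab$label[order(lab$rel_pos)], c("-1", "+1", "+2", "+3"))
  expect_equal(sort(lab$rel_pos), c(-110, 60, 225, 390))
})

test_that("nucleosome positions, NDR and spacing follow their definitions", {
  ann <- gene_annotation("g1", "chrT", "+", tss = 1000, pas = 2500)
  d <- mk_dyads(list(g1 = c(-110L, 60L, 225L, 390L, 555L)))
  pos <- nucleosome_positions(d, ann)
  expect_equal(pos$ndr, 170)          # 60 - (-110)
  expect_equal(pos$sp_p1_p2, 165)
  expect_equal(pos$sp_p2_p3, 165)
  expect_equal(pos$nuc_p1, 60)
  # a missing labeled dyad propagates NA for the affected statistics only
  d2 <- mk_dyads(list(g1 = c(60L, 225L)))
  pos2 <- nucleosome_positions(d2, ann)
  expect_true(is.na(pos2$ndr))
  expect_equal(pos2$sp_p1_p2, 165)
})

test_that("nucleosome statistics are invariant under translation and strand flip", {
  ann_p <- gene_annotation("g1", "chrT", "+", tss = 1000, pas = 2500)
  rels <- c(-110L, 60L, 225L, 390L)
  d_p <- mk_dyads(list(g1 = rels))
  # translate the whole genome by +5000
  ann_t <- ann_p; ann_t$tss <- ann_t$tss + 5000L; ann_t$pas <- ann_t$pas + 5000L
  d_t <- d_p; d_t$dyad <- d_t$dyad + 5000L
  # flip to the minus strand at an arbitrary offset
  ann_m <- gene_annotation("g1", "chrT", "-", tss = 20000, pas = 18500)
  d_m <- mk_dyads(list(g1 = rels), tss = 20000, strand = "-")
  base <- nucleosome_positions(d_p, ann_p)
  expect_equal(nucleosome_positions(d_t, ann_t), base)
  expect_equal(nucleosome_positions(d_m, ann_m), base)
})

test_that("replicate-median comparison detects a spacing shift", {
  ann <- gene_annotation(paste0("g", 1:6), "chrT", "+",
                         tss = seq(1000, by = 3000, length.out = 6),
                         pas = seq(1000, by = 3000, length.out = 6) + 2500)
  mk_cond <- function(sp) {
    purrr::map_dfr(1:3, function(r) {
      d <- purrr::imap_dfr(rlang::set_names(ann$tss, ann$gene_id),
        function(tss, gid) {
          rels <- c(-110L, 60L, 60L + sp, 60L + 2L * sp)
          tibble::tibble(gene_id = gid, replicate = r, chrom = "chrT",
                         dyad = as.integer(tss + rels - 1L))
        })
      d
    })
  }
  cmp <- compare_nucleosome_stats(nucleosome_positions(mk_cond(165L), ann),
                                  nucleosome_positions(mk_cond(175L), ann))
  expect_equal(cmp$difference[cmp$stat == "sp_p1_p2"], 10)
  expect_equal(cmp$difference[cmp$stat == "ndr"], 0)
  expect_equal(cmp$difference[cmp$stat == "nuc_p1"], 0)
})

test_that("phasing gene filter enforces length and per-replicate dyad counts", {
  ann <- gene_annotation(c("ok", "short", "sparse"), "chrT", "+",
                         tss = c(1000, 10000, 20000),
                         pas = c(1000, 10000, 20000) + c(800, 499, 800))
  mk <- function(gid, tss, rels, r)
    tibble::tibble(gene_id = gid, replicate = r, chrom = "chrT",
                   dyad = as.integer(tss + rels - 1L))
  full <- c(80L, 245L, 410L, 575L)
  d <- dplyr::bind_rows(
    purrr::map_dfr(1:3, ~ mk("ok", 1000, full, .x)),
    purrr::map_dfr(1:3, ~ mk("short", 10000, full, .x)),
    mk("sparse", 20000, full, 1), mk("sparse", 20000, full, 2),
    mk("sparse", 20000, full[1:3], 3))   # only 3 dyads in replicate 3
  keep <- mnase_gene_filter(d, ann)
  expect_equal(keep, "ok")
  # 'exactly' mode rejects genes with a fifth dyad in the window
  d5 <- dplyr::bind_rows(d, purrr::map_dfr(1:3, ~ mk("ok", 1000, 590L, .x)))
  expect_equal(mnase_gene_filter(d5, ann, mode = "exactly"), character(0))
  expect_equal(mnase_gene_filter(d5, ann, mode = "at_least"), "ok")
})

test_that("expression-group spacing splits into equal quantile groups", {
  df <- tibble::tibble(gene_id = paste0("g", 1:16),
                       density = 2^(1:16),
                       spacing = 180 - 10 * log10(2^(1:16)))
  g <- expression_group_spacing(df, n_groups = 8)
  expect_equal(g$n, rep(2, 8))
  expect_true(all(diff(g$median_spacing) < 0))   # monotone decreasing
  expect_true(all(diff(g$median_density) > 0))
  expect_error(expression_group_spacing(df[1:4, ], n_groups = 8), "groups")
})

test_that("shape normalisation z-scores profiles", {
  z <- shape_normalize_gene(c(0, 0, 4, 0))
  expect_equal(z, c(-1, -1, 3, -1) / sqrt(3))
  expect_equal(mean(z), 0)
  expect_equal(sqrt(mean(z^2)), 1)   # unit population sd
  expect_equal(shape_normalize_gene(10 * c(0, 0, 4, 0)), z)  # scale invariant
  expect_error(shape_normalize_gene(rep(2, 5)), "zero standard deviation")
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 0, 1))
  zn <- shape_normalize(m)
  expect_equal(rownames(zn), c("a", "c"))
  expect_equal(attr(zn, "excluded"), "b")
  expect_true(all(abs(rowMeans(zn)) < 1e-12))
  expect_equal(unname(apply(zn, 1, function(x) sqrt(mean(x^2)))), c(1, 1))
})

test_that("ratio metagene recovers a dyad-locked oscillation", {
  d <- fixture("osc_dataset",
               generate_dataset(synthetic_spec(n_genes = 60, depth = 5000,
                                               nuc_jitter_sd = 0, seed = 21)))
  p1 <- dplyr::filter(d$dyads, label == "+1", replicate == 1)
  ann <- d$annotation[match(p1$gene_id, d$annotation$gene_id), ]
  rm <- ratio_metagene(d$tracks$tef, d$tracks$net, ann, p1$dyad,
                       window = c(-80, 320))
  ok <- !is.na(rm$ratio)
  X <- cbind(sin(2 * pi * rm$rel_pos[ok] / 165),
             cos(2 * pi * rm$rel_pos[ok] / 165))
  amp <- sqrt(sum(coef(lm(I(rm$ratio[ok] - 1) ~ 0 + X))^2))
  expect_lt(abs(amp - 0.2), 0.05)
  # TEF == NET gives a flat unit ratio
  rm1 <- ratio_metagene(d$tracks$net, d$tracks$net, ann, p1$dyad,
                        window = c(-80, 320))
  expect_true(all(abs(rm1$ratio[!is.na(rm1$ratio)] - 1) < 1e-12))
})

test_that("flank windows exclude the dyad core", {
  fd <- make_flank_data(n_genes = 30, shift = 0, seed = 3)
  base <- flank_asymmetry_test(fd$tef, fd$net, fd$annotation, fd$dyads)
  # a huge spike exactly at each dyad changes nothing
  spiked <- dplyr::bind_rows(
    fd$tef, tibble::tibble(chrom = "chrF", pos = fd$dyads$dyad,
                           strand = "+", score = 1e6))
  spiked <- dplyr::group_by(spiked, chrom, pos, strand) |>
    dplyr::summarise(score = sum(score), .groups = "drop")
  again <- flank_asymmetry_test(spiked, fd$net, fd$annotation, fd$dyads)
  expect_equal(again$per_gene, base$per_gene)
  expect_equal(again$p_value, base$p_value)
})

test_that("flank asymmetry p-value shrinks with a consistent downstream shift", {
  fd <- make_flank_data(100, shift = 0.15, seed = 6)
  p_shift <- flank_asymmetry_test(fd$tef, fd$net, fd$annotation, fd$dyads)
  expect_lt(p_shift$p_value, 1e-4)
  expect_equal(p_shift$n, 100)
  # too few genes is an error
  tiny <- make_flank_data(1, shift = 0, seed = 7)
  expect_error(flank_asymmetry_test(tiny$tef, tiny$net, tiny$annotation,
                                    tiny$dyads), "at least 2")
})
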