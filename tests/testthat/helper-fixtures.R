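# Shared in-code fixtures.  Everything is generated programmatically; the
# cache avoids re-simulating the same small objects across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# fast, low-traffic parameter set for short simulations
quick_params <- function(...) {
  model_params(initiation_rate = 0.5, elongation_rate = 2,
               stall_rate_w1 = 2, stall_rate_w2 = 1,
               backtrack_rate_w1 = 0.5, backtrack_rate_w2 = 0.5,
               resume_stall_w1 = 4, resume_stall_w2 = 4,
               resume_backtrack_w1 = 2, resume_backtrack_w2 = 2,
               early_term_prob = 0.1, early_term_mean = 300,
               total_time = 10, ...)
}

# a small cached synthetic dataset with enough depth for track analyses
small_dataset <- function() {
  fixture("small_dataset",
          generate_dataset(synthetic_spec(n_genes = 30, depth = 2000,
                                          seed = 42)))
}

# a tiny simulated library shared by fitting tests
small_library <- function() {
  fixture("small_library", {
    sets <- lhs_sample(default_parameter_ranges(), 12, seed = 7,
                       constants = list(total_time = 10))
    simulate_library(sets, 200, seed = 8)
  })
}

# a single-gene track: `counts[r]` at TSS-relative position r (+1 convention)
toy_gene_track <- function(counts, strand = "+", tss = 1000,
                           chrom = "chrT", gene_id = "g1",
                           upstream = numeric(0)) {
  rel_up <- if (length(upstream)) -(length(upstream):1) + 1L else integer(0)
  rel <- c(rel_up, seq_along(counts))
  score <- c(upstream, counts)
  gpos <- if (strand == "+") tss + rel - 1L else tss - rel + 1L
  list(
    track = signal_track(chrom = rep(chrom, length(gpos)), pos = gpos,
                         strand = rep(strand, length(gpos)), score = score),
    annotation = gene_annotation(
      gene_id = gene_id, chrom = chrom, strand = strand, tss = tss,
      pas = if (strand == "+") tss + length(counts) - 1L
            else tss - length(counts) + 1L))
}

make_flank_data <- function(n_genes = 200, shift = 0, rate = 2, seed = 1) {
  synthetic_flank_data(n_genes, shift, rate, seed)
}

# brute-force KS oracle: explicit scan over all CDF points
ks_bruteforce <- function(a, b) {
  best <- 0
  ca <- 0; cb <- 0
  for (i in seq_along(a)) {
    ca <- ca + a[i]
    cb <- cb + b[i]
    if (abs(ca - cb) > best) best <- abs(ca - cb)
  }
  best
}
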