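test_that("parameter validation enforces the model invariants", {
  expect_error(model_params(initiation_rate = -1), "non-negative")
  expect_error(model_params(early_term_prob = 1.5), "early_term_prob")
  expect_error(model_params(window1_end = 2000), "window1_end")
  expect_error(model_params(stall_rate_w1 = 300, dt = 0.005), "dt scaling")
  p <- model_params()
  expect_s3_class(p, "model_params")
  expect_identical(p$footprint, 40L)
  expect_identical(p$gene_length, 1000L)
  expect_equal(p$dt, 0.005)
})

test_that("zero initiation rate leaves the gene empty", {
  r <- simulate_population(model_params(initiation_rate = 0, total_time = 2),
                           20, seed = 1)
  expect_true(all(r$occupancy$count == 0))
  expect_equal(r$metrics$initiated, 0)
})

test_that("initiation is blocked while position 1 is occluded", {
  p <- model_params(initiation_rate = 1000)  # per-step probability capped at 1
  e <- place_polymerase(new_ensemble(1), 1, 30, "STALLED")
  e2 <- withr::with_seed(1, initiate(e, p))
  expect_equal(nrow(e2$polymerases), 1)  # blocked: active site within 40 nt
  e3 <- place_polymerase(new_ensemble(1), 1, 41, "STALLED")
  e4 <- withr::with_seed(1, initiate(e3, p))
  expect_equal(nrow(e4$polymerases), 2)  # exactly footprint apart: allowed
  expect_true(1 %in% e4$polymerases$position)
})

test_that("early-termination sites are Poisson around the stated mean", {
  p <- model_params(initiation_rate = 1000, early_term_prob = 1,
                    early_term_mean = 200)
  e <- withr::with_seed(11, initiate(new_ensemble(10000), p))
  sites <- e$polymerases$early_term_site
  expect_true(all(!is.na(sites)))
  expect_true(all(sites >= 1 & sites <= 1000))
  # oracle: direct Poisson sampling has mean 200, sd sqrt(200)
  se <- sqrt(200) / sqrt(length(sites))
  expect_lt(abs(mean(sites) - 200), 3 * se)
  expect_lt(abs(var(sites) - 200), 3 * 200 * sqrt(2 / length(sites)))
})

test_that("an unobstructed polymerase elongates as a Poisson hop process", {
  # 1000 independent single-polymerase genes, no stalling or termination
  p <- model_params(initiation_rate = 0, elongation_rate = 2,
                    stall_rate_w1 = 0, stall_rate_w2 = 0,
                    early_term_prob = 0)
  e <- new_ensemble(1000)
  for (g in 1:1000) e <- place_polymerase(e, g, 1)
  completed_at <- rep(NA_real_, 1000)
  for (s in 1:150) {
    e <- advance_and_transition(e, p, n_steps = 1)
    done <- e$tallies$gene[e$tallies$completed == 1]
    completed_at[done[is.na(completed_at[done])]] <- s * p$dt
    if (all(!is.na(completed_at))) break
  }
  expect_true(all(!is.na(completed_at)))
  # independent oracle: completion time of a cumulative Poisson(10)-hop walk
  oracle <- withr::with_seed(99, vapply(1:1000, function(i) {
    pos <- 1; steps <- 0
    while (pos < 1000) { pos <- pos + rpois(1, 10); steps <- steps + 1 }
    steps * 0.005
  }, numeric(1)))
  se <- sqrt(var(completed_at) / 1000 + var(oracle) / 1000)
  expect_lt(abs(mean(completed_at) - mean(oracle)), 3 * se)
  # ~0.5 min overall (the renewal overshoot adds ~half a hop)
  expect_lt(abs(mean(completed_at) - 0.5), 0.005)
})

test_that("stall/resume kinetics reach the two-state equilibrium", {
  # elongation off isolates the MOVING <-> STALLED chain
  p <- model_params(initiation_rate = 0, elongation_rate = 0,
                    stall_rate_w1 = 3, resume_stall_w1 = 6,
                    backtrack_rate_w1 = 0, early_term_prob = 0,
                    total_time = 20)
  e <- new_ensemble(800)
  for (g in 1:800) e <- place_polymerase(e, g, 100)
  e <- withr::with_seed(5, advance_and_transition(e, p, n_steps = 4000))
  frac <- mean(e$polymerases$state == "MOVING")
  expected <- 6 / (6 + 3)
  expect_lt(abs(frac - expected), 3 * sqrt(expected * (1 - expected) / 800))
})

test_that("footprint exclusion truncates hops and records collisions", {
  # MOVING polymerase exactly footprint behind a BACKTRACKED one: any hop is
  # truncated to zero displacement and resolved as a collision
  p <- model_params(initiation_rate = 0, elongation_rate = 2,
                    stall_rate_w1 = 0, stall_rate_w2 = 0,
                    resume_backtrack_w1 = 0, resume_backtrack_w2 = 0,
                    early_term_prob = 0)
  e <- place_polymerase(new_ensemble(1), 1, 140, "BACKTRACKED")
  e <- place_polymerase(e, 1, 100, "MOVING")
  e2 <- withr::with_seed(3, advance_and_transition(e, p))
  up <- e2$polymerases[e2$polymerases$position == 100, ]
  down <- e2$polymerases[e2$polymerases$position == 140, ]
  expect_equal(up$state, "STALLED")        # upstream stalls in place
  expect_equal(down$state, "BACKTRACKED")  # downstream unchanged
  expect_equal(e2$tallies$collision_terminated, 0)
})

test_that("colliding into a stalled polymerase terminates it", {
  p <- model_params(initiation_rate = 0, elongation_rate = 2,
                    stall_rate_w1 = 0, stall_rate_w2 = 0,
                    resume_stall_w1 = 0, resume_stall_w2 = 0,
                    early_term_prob = 0, backtrack_rate_w1 = 0,
                    backtrack_rate_w2 = 0)
  e <- place_polymerase(new_ensemble(1), 1, 100, "STALLED")
  e <- place_polymerase(e, 1, 60, "MOVING")
  e2 <- withr::with_seed(4, advance_and_transition(e, p,
                                                   check_invariants = TRUE))
  expect_equal(e2$tallies$collision_terminated, 1)
  expect_equal(nrow(e2$polymerases), 1)
  expect_equal(e2$polymerases$state, "STALLED")
  expect_equal(e2$polymerases$position, 60)
})

test_that("resolve_collision implements the rule table", {
  expect_equal(resolve_collision("MOVING", "MOVING"),
               list(upstream = "STALLED", downstream = "unchanged"))
  expect_equal(resolve_collision("MOVING", "STALLED"),
               list(upstream = "STALLED", downstream = "terminated"))
  expect_equal(resolve_collision("MOVING", "BACKTRACKED"),
               list(upstream = "STALLED", downstream = "unchanged"))
  expect_error(resolve_collision("STALLED", "MOVING"), "MOVING")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  p <- quick_params()
  a <- simulate_population(p, 50, seed = 123)
  b <- simulate_population(p, 50, seed = 123)
  expect_identical(a$occupancy, b$occupancy)
  expect_identical(a$metrics, b$metrics)
  c <- simulate_population(p, 50, seed = 124)
  expect_false(identical(a$occupancy, c$occupancy))
})

test_that("polymerase conservation holds after a full run", {
  r <- simulate_population(quick_params(), 100, seed = 17)
  engaged <- table(factor(r$ensemble$polymerases$gene, levels = 1:100))
  expect_equal(r$tallies$initiated,
               r$tallies$completed + r$tallies$early_terminated +
                 r$tallies$collision_terminated + as.vector(engaged))
})

test_that("without obstacles processivity is ~100%", {
  # low initiation: collisions essentially impossible
  p <- model_params(initiation_rate = 0.1, stall_rate_w1 = 0,
                    stall_rate_w2 = 0, early_term_prob = 0,
                    total_time = 40)
  r <- simulate_population(p, 200, seed = 2)
  expect_equal(r$metrics$early_terminated, 0)
  expect_equal(r$metrics$collision_terminated, 0)
  # only polymerases still in transit at the cutoff are missing
  expect_gt(r$metrics$processivity, 97)
})

test_that("early termination sets processivity to its binomial expectation", {
  # very low initiation: no collisions; 30% of polymerases carry a site
  p <- model_params(initiation_rate = 0.1, stall_rate_w1 = 0,
                    stall_rate_w2 = 0, early_term_prob = 0.3,
                    early_term_mean = 300, total_time = 30)
  r <- simulate_population(p, 1000, seed = 6)
  # oracle: tally of assigned sites = binomial(initiated, 0.3)
  n <- r$metrics$initiated
  se <- 100 * sqrt(0.3 * 0.7 / n)
  completed_frac <- r$metrics$processivity
  # polymerases still engaged at the end dilute the completed tally;
  # compare among finished ones only
  finished <- with(r$metrics, completed + early_terminated)
  expect_lt(abs(100 * r$metrics$early_terminated / finished - 30), 3 * se)
})

test_that("doubling the population leaves the normalised profile unchanged", {
  p <- quick_params()
  a <- sim_profile(simulate_population(p, 1000, seed = 31))
  b <- sim_profile(simulate_population(p, 2000, seed = 32))
  expect_lt(ks_distance(a, b), 0.15)
})

test_that("time-averaged moving ratios are available and finite", {
  r <- simulate_population(quick_params(), 100, seed = 9,
                           estimator = "time_averaged")
  expect_true(is.finite(r$metrics$moving_ratio_w1))
  expect_true(is.finite(r$metrics$moving_ratio_w2))
  expect_true(all(r$occupancy$count >= 0))
  # the averaged occupancy estimates the same shape as the snapshot
  f <- simulate_population(quick_params(), 100, seed = 9)
  expect_lt(ks_distance(sim_profile(r), sim_profile(f)), 0.25)
})

test_that("population size zero is rejected", {
  expect_error(simulate_population(quick_params(), 0), "population_size")
})
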