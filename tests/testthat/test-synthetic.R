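# the generator's contracts: determinism, anchor efficiency, exact recovery
# of true efficiencies, presence-mask calibration, and context links

test_that("generation is deterministic for a fixed spec and seed", {
  sp <- synthesis_spec(n_states = 5, seed = 42)
  g1 <- generate_panel(sp)
  g2 <- generate_panel(sp)
  expect_identical(g1$panel, g2$panel)
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$presence, g2$presence)
})

test_that("anchors are CRS-efficient within their own panel", {
  a <- generate_anchors(synthesis_spec(n_anchors = 4, seed = 5))
  th <- efficiency_scores(dea_frontier(a))
  expect_true(all(th >= 1 - 1e-7))

  # single anchor is trivially efficient
  a1 <- generate_anchors(synthesis_spec(n_anchors = 1, seed = 5))
  expect_equal(unname(efficiency_scores(dea_frontier(a1))), 1)
})

test_that("1-D geometry falls back on the dominant anchor subset", {
  sp <- synthesis_spec(n_anchors = 3, input_dims = "x", output_dims = "y",
                       seed = 9)
  expect_warning(a <- generate_anchors(sp, max_retries = 5), "dominant|kept")
  th <- ratio_efficiency_1d(a)
  expect_true(all(th >= 1 - 1e-9))
})

test_that("a point mass at 1 makes every unit efficient", {
  sp <- synthesis_spec(n_states = 4, theta_dist = list(kind = "point", value = 1),
                       seed = 3)
  g <- generate_panel(sp)
  th <- efficiency_scores(dea_frontier(g$panel))
  expect_true(all(th >= 1 - 1e-7))
})

test_that("estimated theta recovers the generating truth exactly", {
  sp <- synthesis_spec(n_states = 10, seed = 7)
  g <- generate_panel(sp)
  th <- efficiency_scores(dea_frontier(g$panel))
  err <- abs(th[names(g$truth)] - g$truth)
  expect_lt(max(err), 1e-6)
})

test_that("presence mask matches the requested probabilities", {
  probs <- c(1, 1, 1, 14 / 32, 25 / 32, 18 / 32)
  expected <- 32 * sum(probs)            # 153 DMUs in expectation
  counts <- vapply(1:60, function(sd) {
    g <- generate_panel(synthesis_spec(seed = sd))
    sum(g$presence)
  }, numeric(1))
  expect_equal(mean(counts), expected, tolerance = 0.02)
  # every draw within generous binomial bounds around 153
  p_var <- 32 * sum(probs * (1 - probs))
  expect_true(all(abs(counts - expected) <= 4 * sqrt(p_var)))
})

test_that("context GDP values are positive and links behave as declared", {
  states <- paste0("s", 1:32)
  ctx <- generate_context(states, "none", noise_sd = 0.4, seed = 1)
  expect_true(all(ctx$gdp_per_capita > 0))
  expect_equal(ctx$state, states)

  # noiseless monotone link is a perfect rank correlation
  eff <- setNames(seq(0.1, 0.9, length.out = 32), states)
  ctx_up <- generate_context(states, "monotone_increasing", noise_sd = 0,
                             seed = 1)
  r <- correlate_with_context(eff, ctx_up)
  expect_equal(r$spearman_rho, 1)
  ctx_dn <- generate_context(states, "monotone_decreasing", noise_sd = 0,
                             seed = 1)
  expect_equal(correlate_with_context(eff, ctx_dn)$spearman_rho, -1)

  expect_error(generate_context(states, noise_sd = -1), ">= 0")

  # positivity across many draws
  many <- unlist(lapply(1:50, function(sd) {
    generate_context(states, "none", seed = sd)$gdp_per_capita
  }))
  expect_true(all(many > 0))
})

test_that("null-link context is uncorrelated with efficiency across seeds", {
  states <- paste0("s", 1:32)
  eff <- setNames(seq(0.05, 0.95, length.out = 32), states)
  rhos <- vapply(1:100, function(sd) {
    correlate_with_context(eff, generate_context(states, "none",
                                                 seed = sd))$spearman_rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("integerized counts recover truth only approximately", {
  sp <- synthesis_spec(n_states = 6, integerize = TRUE, seed = 8,
                       output_scale_range = c(2, 8))
  g <- generate_panel(sp)
  th <- efficiency_scores(dea_frontier(g$panel))
  err <- abs(th[names(g$truth)] - g$truth)
  expect_lt(stats::median(err), 0.1)     # rounding noise only
})
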