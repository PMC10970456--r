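# stage 2/3: classification, matrix summaries, context correlation, annual
# variation

test_that("classification applies strict upper and inclusive lower bounds", {
  th <- dea_thresholds()
  expect_equal(as.character(classify_dmu(1, th)), "saturated")
  expect_equal(as.character(classify_dmu(0.82, th)), "intermediate")
  expect_equal(as.character(classify_dmu(0.22, th)), "untapped")
  expect_equal(as.character(classify_dmu(0.5, th)), "intermediate")
  expect_error(classify_dmu(1.2, th), "\\[0, 1\\]")
  expect_error(classify_dmu(-0.1, th), "\\[0, 1\\]")
})

test_that("classification partitions [0,1] and counts add up", {
  set.seed(31)
  x <- runif(500)
  cls <- classify_dmu(x, dea_thresholds())
  expect_equal(sum(table(cls)), 500)
  expect_false(anyNA(cls))
})

test_that("an all-ones matrix summarizes to the degenerate extreme", {
  M <- matrix(1, 3, 2, dimnames = list(c("s1", "s2", "s3"), c("A", "B")))
  s <- summarize_efficiency(efficiency_matrix(M))
  expect_true(all(s$institutional_means == 1))
  expect_true(all(s$state_means == 1))
  expect_equal(s$gap, 0)
  expect_equal(s$share_saturated, 100)
  expect_equal(s$share_untapped, 0)
  expect_equal(unname(s$counts_at_unity), c(3, 3))
})

test_that("summaries ignore absent cells and are permutation invariant", {
  M <- matrix(c(0.9, NA, 0.3,
                0.4, 0.2, NA), 3, 2,
              dimnames = list(c("s1", "s2", "s3"), c("A", "B")))
  s <- summarize_efficiency(efficiency_matrix(M))
  expect_equal(unname(s$institutional_means["A"]), 0.6)
  expect_equal(unname(s$state_means["s2"]), 0.2)
  expect_equal(s$n_present, 4)
  expect_equal(s$gap,
               max(s$institutional_means) - min(s$institutional_means))

  Mp <- M[c(3, 1, 2), c(2, 1)]
  sp <- summarize_efficiency(efficiency_matrix(Mp))
  expect_equal(sort(sp$institutional_means), sort(s$institutional_means))
  expect_equal(sp$national_mean_of_dmus, s$national_mean_of_dmus)
  expect_equal(sp$gap, s$gap)
})

test_that("empty institutions are dropped from means with a warning", {
  M <- matrix(c(0.5, 0.7, NA, NA), 2, 2,
              dimnames = list(c("s1", "s2"), c("A", "B")))
  expect_warning(s <- summarize_efficiency(efficiency_matrix(M)),
                 "no present cells")
  expect_equal(names(s$institutional_means), "A")
  expect_true(any(grepl("omitted", s$notes)))
})

test_that("perfect monotone context gives Spearman rho of 1", {
  eff <- setNames(seq(0.1, 1, length.out = 10), paste0("s", 1:10))
  ctx <- data.frame(state = paste0("s", 1:10),
                    gdp_per_capita = 1000 * (1:10))
  r <- correlate_with_context(eff, ctx)
  expect_equal(r$spearman_rho, 1)
  expect_equal(r$n, 10)
})

test_that("Spearman is invariant to monotone transforms of GDP", {
  set.seed(32)
  eff <- setNames(runif(12), paste0("s", 1:12))
  gdp <- runif(12, 2000, 30000)
  r1 <- correlate_with_context(eff, data.frame(state = names(eff),
                                               gdp_per_capita = gdp))
  r2 <- correlate_with_context(eff, data.frame(state = names(eff),
                                               gdp_per_capita = exp(log(gdp) * 2 - 5)))
  expect_equal(r1$spearman_rho, r2$spearman_rho, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(r1$pearson_r, r2$pearson_r)))
})

test_that("correlation requires at least three common states", {
  eff <- c(s1 = 0.5, s2 = 0.7)
  ctx <- data.frame(state = c("s1", "s2"), gdp_per_capita = c(1, 2) * 1e4)
  expect_error(correlate_with_context(eff, ctx), "at least 3")
})

test_that("quartile table groups lowest GDP into quartile 1", {
  eff <- setNames(c(0.9, 0.1, 0.5, 0.3, 0.7, 0.2, 0.6, 0.4),
                  paste0("s", 1:8))
  ctx <- data.frame(state = paste0("s", 1:8),
                    gdp_per_capita = c(1, 2, 3, 4, 5, 6, 7, 8) * 1000)
  r <- correlate_with_context(eff, ctx)
  expect_equal(nrow(r$quartile_table), 4)
  expect_equal(r$quartile_table$n, rep(2L, 4))
  expect_equal(r$quartile_table$eff_mean[1], mean(c(0.9, 0.1)))
  expect_true(grepl("s8", r$quartile_table$states[4]))
})

test_that("a high-GDP low-efficiency state lands in the upper quartile", {
  # Campeche ranks second lowest in state efficiency (0.280); rank it
  # highest in GDP and it must surface in quartile 4 of the profile
  s <- summarize_efficiency(mexico_efficiency_matrix())
  ord <- c(setdiff(names(s$state_means), "Campeche"), "Campeche")
  ctx <- generate_context(ord, "monotone_increasing", noise_sd = 0, seed = 2)
  r <- correlate_with_context(s$state_means, ctx)
  expect_true(grepl("Campeche", r$quartile_table$states[4]))
  expect_equal(round(unname(s$state_means["Campeche"]), 3), 0.280)
  expect_gte(r$quartile_table$eff_min[4], min(s$state_means))
})

test_that("annual variation handles constant, doubling and zero series", {
  mk <- function(x, y) {
    dea_panel(data.frame(institution = "A", state = "S", x = x, y = y),
              "x", "y")
  }
  av <- annual_variation(list(`2012` = mk(4, 10), `2013` = mk(4, 20),
                              `2014` = mk(4, 40)))
  xch <- subset(av$changes, dimension == "x")
  ych <- subset(av$changes, dimension == "y")
  expect_equal(xch$pct_change[-1], c(0, 0))
  expect_equal(subset(av$cv, dimension == "x")$cv, 0)
  expect_equal(ych$pct_change[-1], c(100, 100))

  # zero prior-year total -> undefined marker, not infinity
  av0 <- annual_variation(list(`2012` = mk(1, 0), `2013` = mk(1, 5)))
  y0 <- subset(av0$changes, dimension == "y")
  expect_true(is.na(y0$pct_change[2]))
})

test_that("lognormal year noise of 5% yields a CV near 0.05", {
  set.seed(33)
  mk <- function(y) {
    dea_panel(data.frame(institution = "A", state = "S", x = 10, y = y),
              "x", "y")
  }
  cvs <- replicate(200, {
    years <- as.character(2012:2018)
    panels <- lapply(setNames(years, years),
                     function(yy) mk(1000 * rlnorm(1, 0, 0.05)))
    subset(annual_variation(panels)$cv, dimension == "y")$cv
  })
  expect_equal(mean(cvs), 0.05, tolerance = 0.15)
})
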