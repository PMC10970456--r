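# independent verification routes: multiplier (dual) form, 1-D closed form,
# and the LP-free weight-grid lower bound

test_that("multiplier form reproduces known scores", {
  p <- toy_panel()
  expect_equal(dea_multiplier(p, "U02:S"), 0.5, tolerance = 1e-9)

  d <- data.frame(institution = "U", state = "S", x = 2, y = 9)
  expect_equal(dea_multiplier(dea_panel(d, "x", "y"), "U:S"), 1)
})

test_that("envelopment and multiplier forms agree by duality on random panels", {
  set.seed(21)
  worst <- 0
  for (rep in 1:100) {
    n <- sample(2:8, 1)
    m <- sample(1:3, 1)
    s <- sample(1:3, 1)
    p <- random_panel(n, m, s)
    for (id in panel_ids(p)) {
      gap <- abs(dea_solve(p, id)$theta - dea_multiplier(p, id))
      worst <- max(worst, gap)
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("1-D closed form matches its direct ratio definition", {
  p <- make_panel(matrix(c(1, 1, 4), 1), matrix(c(1, 2, 2), 1))
  expect_equal(unname(ratio_efficiency_1d(p)), c(0.5, 1, 0.25))

  p2 <- make_panel(matrix(c(2, 4, 6), 1), matrix(c(3, 6, 9), 1))
  expect_equal(unname(ratio_efficiency_1d(p2)), rep(1, 3))

  expect_error(ratio_efficiency_1d(random_panel(3, 2, 1)),
               "exactly one input")
})

test_that("LP solver agrees with the 1-D closed form on random panels", {
  set.seed(22)
  worst <- 0
  for (rep in 1:1000) {
    n <- sample(2:6, 1)
    p <- random_panel(n, 1, 1)
    cf <- ratio_efficiency_1d(p)
    th <- efficiency_scores(dea_frontier(p))
    worst <- max(worst, max(abs(th - cf)))
  }
  expect_lt(worst, 1e-9)
})

test_that("the coarse weight grid is a valid lower bound and tight in 1-D", {
  set.seed(23)
  for (rep in 1:10) {
    p <- random_panel(5, 2, 2)
    for (id in panel_ids(p)) {
      th <- dea_solve(p, id)$theta
      lb <- ratio_grid_bound(p, id, grid_points = 4)
      expect_lte(lb, th + 1e-9)
    }
  }
  # with one dimension each side the grid is exact
  p1 <- random_panel(4, 1, 1)
  for (id in panel_ids(p1)) {
    expect_equal(ratio_grid_bound(p1, id), dea_solve(p1, id)$theta,
                 tolerance = 1e-9)
  }
})

test_that("grid bound supports the six-institution national scores", {
  p <- mexico_obstetric_panel("full")
  th <- efficiency_scores(dea_frontier(p))
  for (id in panel_ids(p)) {
    lb <- ratio_grid_bound(p, id, grid_points = 6)
    expect_lte(lb, th[id] + 1e-9)
  }
  # the frontier institutions are certified efficient already at the grid level
  expect_gt(ratio_grid_bound(p, "A:National", grid_points = 6), 0.9)
})
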