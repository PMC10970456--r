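# the envelopment solver: closed-form cases, frontier structure, and the
# invariances a radial CRS measure must satisfy

test_that("1-in/1-out closed-form cases solve exactly", {
  p <- toy_panel()                       # U1 (x=1,y=2), U2 (x=2,y=2)
  r <- dea_solve(p, "U02:S")
  expect_equal(r$theta, 0.5, tolerance = 1e-9)
  expect_equal(r$status, "optimal")

  # a frontier unit alone is its own peer with unit weight and no slack
  d <- data.frame(institution = "U", state = "S", x = 3, y = 6)
  p1 <- dea_panel(d, "x", "y")
  r1 <- dea_solve(p1, "U:S")
  expect_equal(r1$theta, 1)
  expect_equal(unname(r1$lambdas["U:S"]), 1, tolerance = 1e-9)
  expect_equal(unname(r1$input_slacks), 0)
  expect_equal(unname(r1$output_slacks), 0)
})

test_that("a clone with doubled inputs scores half the efficient original", {
  X <- matrix(c(2, 5, 4, 10), 2)      # U2 = U1 with inputs doubled
  Y <- matrix(c(7, 3, 7, 3), 2)
  p <- make_panel(X, Y)
  fr <- efficiency_scores(dea_frontier(p))
  expect_equal(unname(fr["U01:S"]), 1)
  expect_equal(unname(fr["U02:S"]), 0.5, tolerance = 1e-9)
})

test_that("identical units all sit on the frontier", {
  p <- make_panel(matrix(3, 1, 5), matrix(8, 1, 5))
  expect_true(all(efficiency_scores(dea_frontier(p)) == 1))
})

test_that("theta is invariant to unit order and to per-dimension rescaling", {
  set.seed(11)
  p <- random_panel(7, 2, 2)
  th <- efficiency_scores(dea_frontier(p))

  perm <- c(4, 1, 7, 3, 6, 2, 5)
  d <- as.data.frame(p)[perm, ]
  p2 <- dea_panel(d, inputs = p$input_dims, outputs = p$output_dims)
  th2 <- efficiency_scores(dea_frontier(p2))
  expect_equal(th2[names(th)], th, tolerance = 1e-9)

  # multiply one input dimension and one output dimension by constants
  d3 <- as.data.frame(p)
  d3$in1 <- d3$in1 * 1000
  d3$out2 <- d3$out2 * 1e-3
  p3 <- dea_panel(d3, inputs = p$input_dims, outputs = p$output_dims)
  th3 <- efficiency_scores(dea_frontier(p3))
  expect_equal(th3[names(th)], th, tolerance = 1e-9)
})

test_that("CRS ray invariance: jointly scaling one unit leaves theta fixed", {
  set.seed(12)
  p <- random_panel(6, 2, 2)
  th <- efficiency_scores(dea_frontier(p))
  d <- as.data.frame(p)
  i <- 3
  d[i, c(p$input_dims, p$output_dims)] <-
    d[i, c(p$input_dims, p$output_dims)] * 7.3
  p2 <- dea_panel(d, p$input_dims, p$output_dims)
  th2 <- efficiency_scores(dea_frontier(p2))
  expect_equal(unname(th2[i]), unname(th[i]), tolerance = 1e-8)
})

test_that("adding a unit never increases any existing unit's theta", {
  set.seed(13)
  for (rep in 1:20) {
    p <- random_panel(5, 2, 1)
    th <- efficiency_scores(dea_frontier(p))
    d <- as.data.frame(p)
    extra <- data.frame(institution = "NEW", state = "S",
                        in1 = runif(1, 1, 100), in2 = runif(1, 1, 100),
                        out1 = runif(1, 1, 100))
    p2 <- dea_panel(rbind(d[, -1], extra), p$input_dims, p$output_dims)
    th2 <- efficiency_scores(dea_frontier(p2))
    expect_true(all(th2[names(th)] <= th + 1e-8))
  }
})

test_that("zero-output units get theta 0 with a degenerate status", {
  d <- data.frame(institution = c("A", "B"), state = "S",
                  x = c(1, 2), y = c(2, 0))
  p <- dea_panel(d, "x", "y")
  r <- dea_solve(p, "B:S")
  expect_equal(r$theta, 0)
  expect_equal(r$status, "degenerate_zero_output")
  # and a nonempty panel with positive outputs still has a frontier unit
  th <- efficiency_scores(dea_frontier(p))
  expect_equal(unname(th["A:S"]), 1)
})

test_that("variable returns to scale never scores below CRS", {
  set.seed(14)
  p <- random_panel(6, 2, 2)
  th_crs <- efficiency_scores(dea_frontier(p, dea_config("constant")))
  th_vrs <- efficiency_scores(dea_frontier(p, dea_config("variable")))
  expect_true(all(th_vrs >= th_crs - 1e-8))
  expect_true(any(th_vrs == 1))
})

test_that("unknown DMU ids raise an identifier error", {
  expect_error(dea_solve(toy_panel(), "nope"), "unknown DMU")
})

test_that("the six-institution national panel matches the independent solver", {
  # reference thetas computed with scipy.optimize.linprog (HiGHS) on the
  # identically scaled LP and frozen here at 9 decimals
  p <- mexico_obstetric_panel("full")
  th <- efficiency_scores(dea_frontier(p))
  expect_equal(unname(th), c(1, 1, 0.651238241, 1, 1, 0.62544333),
               tolerance = 1e-6)
  frontier <- names(th)[th >= 1 - 1e-6]
  expect_setequal(frontier, c("A:National", "B:National", "D:National",
                              "E:National"))

  pr <- mexico_obstetric_panel("reduced")
  thr <- efficiency_scores(dea_frontier(pr))
  expect_equal(unname(thr), c(1, 1, 0.542064899, 1, 1, 0.623560947),
               tolerance = 1e-6)
})

test_that("slacks are nonnegative and consistent with the radial projection", {
  set.seed(15)
  p <- random_panel(8, 3, 2)
  fr <- dea_frontier(p)
  for (r in fr$results) {
    expect_true(all(r$input_slacks >= -1e-9))
    expect_true(all(r$output_slacks >= -1e-9))
    expect_true(all(r$lambdas >= -1e-12))
    # projection identity: X lambda = theta x - s_in ; Y lambda = y + s_out
    i <- match(r$dmu_id, panel_ids(p))
    expect_equal(drop(p$X %*% r$lambdas),
                 r$theta * p$X[, i] - r$input_slacks, tolerance = 1e-6)
    expect_equal(drop(p$Y %*% r$lambdas),
                 p$Y[, i] + r$output_slacks, tolerance = 1e-6)
  }
})
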