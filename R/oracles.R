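# Independent verification oracles for the envelopment solver.

#' Multiplier-form (dual) CCR efficiency
#'
#' Solves the multiplier form of the input-oriented CCR model for one unit:
#' maximize the virtual-output score `u . y_i` over nonnegative output
#' weights `u` and input weights `v`, subject to the normalization
#' `v . x_i = 1` and `u . y_j - v . x_j <= 0` for every unit `j`. By LP
#' duality this equals the envelopment-form radial efficiency, which makes it
#' an independent check on [dea_solve()]: the two programs share no
#' formulation code.
#'
#' @inheritParams dea_solve
#' @return the efficiency score as a single number.
#' @examples
#' d <- data.frame(institution = c("U1", "U2"), state = "S",
#'                 x = c(1, 2), y = c(2, 2))
#' p <- dea_panel(d, inputs = "x", outputs = "y")
#' dea_multiplier(p, "U2:S")   # 0.5
#' @export
dea_multiplier <- function(panel, dmu_id, cfg = dea_config()) {
  stopifnot(inherits(panel, "dea_panel"))
  if (cfg$returns_to_scale != "constant") {
    stop("the multiplier oracle is implemented for constant returns only",
         call. = FALSE)
  }
  i <- .panel_index(panel, dmu_id)
  if (all(panel$Y[, i] <= 0)) return(0)
  sc <- .panel_scaled(panel)
  X <- sc$X
  Y <- sc$Y
  n <- ncol(X)
  m <- nrow(X)
  s <- nrow(Y)
  obj <- c(-Y[, i], rep(0, m))                 # maximize u . y_i
  A <- rbind(cbind(t(Y), -t(X)),               # u . y_j - v . x_j <= 0
             c(rep(0, s), X[, i]))             # v . x_i = 1
  dir <- c(rep("<=", n), "=")
  rhs <- c(rep(0, n), 1)
  r <- lp_solve(obj, A, dir, rhs, tol = min(cfg$solver_tolerance, 1e-9))
  if (r$status != "optimal") {
    stop("multiplier LP for ", dmu_id, " returned status ", r$status,
         call. = FALSE)
  }
  theta <- -r$objval
  if (theta > 1 - cfg$solver_tolerance) theta <- min(theta, 1)
  theta
}

#' Closed-form efficiency for one-input / one-output panels
#'
#' In the single-input single-output CRS case the frontier is the ray through
#' the unit with the best output/input ratio, so efficiency has the closed
#' form `theta_i = (y_i / x_i) / max_j (y_j / x_j)`. Used as a solver-free
#' oracle for [dea_solve()].
#'
#' @param panel a [dea_panel()] with exactly one input and one output
#'   dimension and strictly positive inputs.
#' @return named numeric vector of scores, one per unit.
#' @export
ratio_efficiency_1d <- function(panel) {
  stopifnot(inherits(panel, "dea_panel"))
  if (length(panel$input_dims) != 1L || length(panel$output_dims) != 1L) {
    stop("ratio_efficiency_1d needs exactly one input and one output dimension",
         call. = FALSE)
  }
  x <- drop(panel$X)
  y <- drop(panel$Y)
  if (any(x <= 0)) stop("all inputs must be positive", call. = FALSE)
  ratio <- y / x
  stats::setNames(ratio / max(ratio), panel_ids(panel))
}

#' Coarse weight-grid lower bound on CCR efficiency
#'
#' Evaluates the CCR ratio definition directly on a finite grid of weight
#' vectors: for each pair `(u, v)` of nonnegative weights summing to one, the
#' normalized score of unit `i` is
#' `(u . y_i / v . x_i) / max_j (u . y_j / v . x_j)`, and the CCR efficiency
#' is the supremum of that score over all weights. The grid maximum is
#' therefore a certified lower bound on the true score (tight as the grid is
#' refined), and it involves no linear programming at all — a useful sanity
#' check on both LP forms.
#'
#' @inheritParams dea_solve
#' @param grid_points number of grid levels per weight dimension.
#' @return a lower bound on the unit's efficiency.
#' @export
ratio_grid_bound <- function(panel, dmu_id, grid_points = 5L) {
  stopifnot(inherits(panel, "dea_panel"), grid_points >= 2L)
  i <- .panel_index(panel, dmu_id)
  sc <- .panel_scaled(panel)
  X <- sc$X
  Y <- sc$Y
  if (all(Y[, i] <= 0)) return(0)
  simplex_grid <- function(k, g) {
    # all nonnegative integer compositions of g into k parts, scaled to sum 1
    if (k == 1L) return(matrix(1, 1, 1))
    grid <- as.matrix(expand.grid(rep(list(0:g), k)))
    grid <- grid[rowSums(grid) == g, , drop = FALSE]
    grid / g
  }
  U <- simplex_grid(nrow(Y), grid_points)
  V <- simplex_grid(nrow(X), grid_points)
  num <- U %*% Y                                # |U| x n virtual outputs
  den <- V %*% X                                # |V| x n virtual inputs
  best <- 0
  for (a in seq_len(nrow(U))) {
    for (b in seq_len(nrow(V))) {
      ok <- den[b, ] > 0
      if (!ok[i]) next
      r <- num[a, ok] / den[b, ok]
      top <- max(r)
      if (top > 0) best <- max(best, (num[a, i] / den[b, i]) / top)
    }
  }
  min(best, 1)
}
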