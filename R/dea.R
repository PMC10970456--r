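# Input-oriented envelopment-form DEA with a second-phase slack maximization.
#
# For unit i with inputs x_i and outputs y_i, and technology matrices X, Y
# whose columns are all units, the Farrell input-oriented program under
# constant returns to scale is
#
#   theta_i = min { theta : Y lambda >= y_i,  theta x_i - X lambda >= 0,
#                   lambda >= 0 }
#
# Variable returns to scale adds sum(lambda) = 1. Slacks are recovered in a
# second phase that maximizes their sum at the fixed optimal theta, so the
# reported theta is always the purely radial measure.

.dea_envelopment <- function(sc, i, cfg) {
  X <- sc$X
  Y <- sc$Y
  n <- ncol(X)
  m <- nrow(X)
  s <- nrow(Y)
  obj <- c(1, rep(0, n))                       # variables: (theta, lambda)
  A <- rbind(cbind(rep(0, s), Y),              # Y lambda >= y_i
             cbind(X[, i], -X))                # theta x_i - X lambda >= 0
  dir <- rep(">=", s + m)
  rhs <- c(Y[, i], rep(0, m))
  if (cfg$returns_to_scale == "variable") {
    A <- rbind(A, c(0, rep(1, n)))
    dir <- c(dir, "=")
    rhs <- c(rhs, 1)
  }
  lp_solve(obj, A, dir, rhs, tol = min(cfg$solver_tolerance, 1e-9))
}

.dea_slack_phase <- function(sc, i, theta, cfg) {
  X <- sc$X
  Y <- sc$Y
  n <- ncol(X)
  m <- nrow(X)
  s <- nrow(Y)
  # variables: (lambda, s_in, s_out); maximize total slack at fixed theta
  obj <- c(rep(0, n), rep(-1, m + s))
  A <- rbind(cbind(X, diag(m), matrix(0, m, s)),    # X lambda + s_in = theta x_i
             cbind(Y, matrix(0, s, m), -diag(s)))   # Y lambda - s_out = y_i
  dir <- rep("=", m + s)
  rhs <- c(theta * X[, i], Y[, i])
  if (cfg$returns_to_scale == "variable") {
    A <- rbind(A, c(rep(1, n), rep(0, m + s)))
    dir <- c(dir, "=")
    rhs <- c(rhs, 1)
  }
  lp_solve(obj, A, dir, rhs, tol = min(cfg$solver_tolerance, 1e-9))
}

.dea_result <- function(dmu_id, theta, lambdas, input_slacks, output_slacks,
                        status, cfg) {
  structure(
    list(dmu_id = dmu_id,
         theta = theta,
         lambdas = lambdas,
         peers = names(lambdas)[lambdas > cfg$lambda_peer_cutoff],
         input_slacks = input_slacks,
         output_slacks = output_slacks,
         status = status),
    class = "dea_result"
  )
}

#' Input-oriented DEA efficiency of one DMU
#'
#' Solves the Farrell input-oriented envelopment program for `dmu_id` against
#' the technology spanned by all units of `panel`, then recovers slacks by a
#' second-phase maximization at the fixed optimal radial factor. Under
#' constant returns a unit with all outputs zero is assigned `theta = 0` with
#' status `"degenerate_zero_output"` rather than an error (such units do occur
#' in practice when an institution reports resources but no services).
#'
#' @param panel a [dea_panel()].
#' @param dmu_id identifier of the unit to evaluate.
#' @param cfg a [dea_config()].
#' @return an object of class `dea_result` with fields `dmu_id`, `theta`
#'   (radial technical efficiency in `[0, 1]`), `lambdas` (named intensity
#'   weights), `peers` (units with weight above the peer cutoff),
#'   `input_slacks`, `output_slacks` (in the original measurement units) and
#'   `status`. Alternative optimal weight vectors can exist, so `peers` is *a*
#'   supporting set, not necessarily the unique one.
#' @examples
#' d <- data.frame(institution = c("U1", "U2"), state = "S",
#'                 x = c(1, 2), y = c(2, 2))
#' p <- dea_panel(d, inputs = "x", outputs = "y")
#' dea_solve(p, "U2:S")$theta   # 0.5
#' @export
dea_solve <- function(panel, dmu_id, cfg = dea_config()) {
  stopifnot(inherits(panel, "dea_panel"), inherits(cfg, "dea_config"))
  i <- .panel_index(panel, dmu_id)
  ids <- panel_ids(panel)
  n <- length(ids)
  zero_lambda <- stats::setNames(numeric(n), ids)
  zero_in <- stats::setNames(numeric(length(panel$input_dims)),
                             panel$input_dims)
  zero_out <- stats::setNames(numeric(length(panel$output_dims)),
                              panel$output_dims)

  if (all(panel$Y[, i] <= 0) && cfg$returns_to_scale == "constant") {
    return(.dea_result(dmu_id, 0, zero_lambda, zero_in, zero_out,
                       "degenerate_zero_output", cfg))
  }

  sc <- .panel_scaled(panel)
  r1 <- .dea_envelopment(sc, i, cfg)
  if (r1$status != "optimal") {
    warning("envelopment LP for ", dmu_id, " returned status ", r1$status,
            call. = FALSE)
    return(.dea_result(dmu_id, NA_real_, zero_lambda, zero_in, zero_out,
                       "infeasible", cfg))
  }
  theta <- r1$objval
  if (theta > 1 - cfg$solver_tolerance) theta <- min(theta, 1)
  if (theta < 0 && theta > -cfg$solver_tolerance) theta <- 0

  r2 <- .dea_slack_phase(sc, i, r1$objval, cfg)
  if (r2$status == "optimal") {
    lambda <- stats::setNames(r2$x[seq_len(n)], ids)
    m <- length(panel$input_dims)
    s <- length(panel$output_dims)
    s_in <- r2$x[n + seq_len(m)] * sc$xscale
    s_out <- r2$x[n + m + seq_len(s)] * sc$yscale
  } else {
    # fall back on the phase-1 weights; slacks from the residuals
    lambda <- stats::setNames(r1$x[-1L], ids)
    s_in <- drop(r1$objval * sc$X[, i] - sc$X %*% lambda) * sc$xscale
    s_out <- drop(sc$Y %*% lambda - sc$Y[, i]) * sc$yscale
  }
  s_in[s_in < 0 & s_in > -cfg$solver_tolerance] <- 0
  s_out[s_out < 0 & s_out > -cfg$solver_tolerance] <- 0
  .dea_result(dmu_id, theta, lambda,
              stats::setNames(s_in, panel$input_dims),
              stats::setNames(s_out, panel$output_dims),
              "optimal", cfg)
}

#' @export
print.dea_result <- function(x, ...) {
  cat("<dea_result> ", x$dmu_id, ": theta = ",
      format(x$theta, digits = 6), " (", x$status, ")\n", sep = "")
  if (length(x$peers)) cat("  peers: ", paste(x$peers, collapse = ", "), "\n")
  invisible(x)
}

#' Efficiency scores of every unit in a panel
#'
#' Runs [dea_solve()] for each DMU. In any nonempty panel whose units all
#' produce some positive output, at least one unit attains `theta = 1` (the
#' frontier is spanned by observed units), and results do not depend on unit
#' ordering.
#'
#' @inheritParams dea_solve
#' @return an object of class `dea_frontier`: a list with `results` (one
#'   `dea_result` per unit, in panel order) and the originating `panel`.
#'   `as.data.frame()` gives a tidy table of id, institution, state, theta,
#'   status and peer count.
#' @export
dea_frontier <- function(panel, cfg = dea_config()) {
  stopifnot(inherits(panel, "dea_panel"))
  res <- lapply(panel_ids(panel), function(id) {
    tryCatch(dea_solve(panel, id, cfg),
             error = function(e) {
               stop("unit ", id, ": ", conditionMessage(e), call. = FALSE)
             })
  })
  names(res) <- panel_ids(panel)
  structure(list(results = res, panel = panel, cfg = cfg),
            class = "dea_frontier")
}

#' @export
as.data.frame.dea_frontier <- function(x, ...) {
  data.frame(
    x$panel$units,
    theta = vapply(x$results, function(r) r$theta, numeric(1)),
    status = vapply(x$results, function(r) r$status, character(1)),
    n_peers = vapply(x$results, function(r) length(r$peers), integer(1)),
    row.names = NULL
  )
}

#' @export
print.dea_frontier <- function(x, ...) {
  df <- as.data.frame(x)
  cat("<dea_frontier> ", nrow(df), " units; ",
      sum(df$theta >= 1 - x$cfg$solver_tolerance, na.rm = TRUE),
      " on the frontier\n", sep = "")
  print(utils::head(df, 10))
  if (nrow(df) > 10) cat("...\n")
  invisible(x)
}

#' Extract the theta scores of a frontier run
#' @param frontier a `dea_frontier`.
#' @return named numeric vector of efficiency scores.
#' @export
efficiency_scores <- function(frontier) {
  stopifnot(inherits(frontier, "dea_frontier"))
  vapply(frontier$results, function(r) r$theta, numeric(1))
}

#' Average per-year efficiency of each DMU
#'
#' The alternative to pooling quantities across years: solve one DEA per
#' yearly panel and average each unit's score over the years it appears in.
#'
#' @param panels_by_year named list of yearly [dea_panel()]s.
#' @param cfg a [dea_config()].
#' @return named numeric vector of mean scores, one per DMU id seen in any
#'   year.
#' @export
dea_per_year <- function(panels_by_year, cfg = dea_config()) {
  stopifnot(is.list(panels_by_year), length(panels_by_year) >= 1L)
  per <- lapply(panels_by_year, function(p) efficiency_scores(dea_frontier(p, cfg)))
  ids <- unique(unlist(lapply(per, names)))
  vapply(ids, function(id) {
    v <- unlist(lapply(per, function(th) th[id]))
    mean(v, na.rm = TRUE)
  }, numeric(1))
}
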