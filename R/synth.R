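# Synthetic fragmented-health-system panels with known ground truth.
#
# The generator emulates the structure the DEA pipeline assumes: a handful of
# anchor technologies spanning a common constant-returns frontier, and one
# DMU per (state, institution) pair present under a Bernoulli presence mask,
# built as a random convex combination of anchors scaled along a CRS ray and
# then radially inflated in inputs by 1/theta*. Because inefficiency is
# purely radial and the anchors are included in the panel, the envelopment
# solver must recover every theta* exactly (up to LP tolerance) - the
# module's core guarantee.

#' Specification for a synthetic fragmented-system panel
#'
#' Defaults mirror the study system the package ships reference data for:
#' 32 states and six federal institutions, three of them nationwide and three
#' with partial state presence (14/32, 25/32 and 18/32), so the expected DMU
#' count is 153. True efficiencies default to uniform(0.2, 1), spanning the
#' heavily right-spread score distributions typical of fragmented systems.
#'
#' @param n_states number of states.
#' @param institutions data.frame with columns `label` and `presence`
#'   (presence probability in (0, 1]).
#' @param n_anchors number of frontier anchor technologies (>= 1).
#' @param input_dims,output_dims dimension names.
#' @param theta_dist either `list(kind = "uniform", min =, max =)` on (0, 1]
#'   or `list(kind = "point", value = 1)`.
#' @param output_scale_range range of the CRS ray factor applied to each
#'   unit's frontier point (size heterogeneity across DMUs).
#' @param noise_sd sd of optional multiplicative lognormal measurement noise
#'   on all counts (0 = none; exact recovery only holds at 0).
#' @param integerize round all quantities to whole counts (recovery is then
#'   only approximate).
#' @param seed RNG seed; identical spec + seed gives identical output.
#' @return a validated list of class `synthesis_spec`.
#' @export
synthesis_spec <- function(n_states = 32L,
                           institutions = data.frame(
                             label = c("A", "B", "C", "D", "E", "F"),
                             presence = c(1, 1, 1, 14 / 32, 25 / 32, 18 / 32)),
                           n_anchors = 3L,
                           input_dims = c("gynecologists", "exam_rooms",
                                          "delivery_rooms", "operating_rooms"),
                           output_dims = c("prenatal_visits", "deliveries",
                                           "cesareans", "abortions"),
                           theta_dist = list(kind = "uniform",
                                             min = 0.2, max = 1),
                           output_scale_range = c(0.25, 4),
                           noise_sd = 0,
                           integerize = FALSE,
                           seed = 1L) {
  stopifnot(n_states >= 1L, is.data.frame(institutions),
            all(c("label", "presence") %in% names(institutions)),
            nrow(institutions) >= 1L,
            all(institutions$presence > 0 & institutions$presence <= 1),
            n_anchors >= 1L,
            length(input_dims) >= 1L, length(output_dims) >= 1L,
            length(output_scale_range) == 2L,
            all(output_scale_range > 0),
            output_scale_range[1] <= output_scale_range[2],
            noise_sd >= 0,
            theta_dist$kind %in% c("uniform", "point"))
  if (theta_dist$kind == "uniform") {
    stopifnot(theta_dist$min > 0, theta_dist$max <= 1,
              theta_dist$min <= theta_dist$max)
  } else {
    stopifnot(identical(theta_dist$value, 1))
  }
  structure(
    list(n_states = as.integer(n_states), institutions = institutions,
         n_anchors = as.integer(n_anchors),
         input_dims = input_dims, output_dims = output_dims,
         theta_dist = theta_dist, output_scale_range = output_scale_range,
         noise_sd = noise_sd, integerize = isTRUE(integerize),
         seed = as.integer(seed)),
    class = "synthesis_spec"
  )
}

.draw_theta <- function(dist, n) {
  if (dist$kind == "point") rep(1, n)
  else stats::runif(n, dist$min, dist$max)
}

# draws anchors from the current RNG stream; asserts CRS efficiency of each
# anchor within the anchor-only panel, regenerating dominated draws up to a
# retry budget and falling back on the dominant subset when the geometry
# cannot support the requested number (e.g. one input / one output, where
# only the best-ratio unit can be efficient)
.gen_anchors <- function(spec, max_retries = 50L) {
  m <- length(spec$input_dims)
  s <- length(spec$output_dims)
  k <- spec$n_anchors
  draw <- function(n) {
    list(X = matrix(stats::runif(m * n, 5, 50), m, n),
         Y = matrix(stats::runif(s * n, 50, 500), s, n))
  }
  a <- draw(k)
  mk_panel <- function(a) {
    d <- data.frame(institution = "ANCHOR",
                    state = sprintf("anchor%02d", seq_len(ncol(a$X))),
                    t(a$X), t(a$Y))
    names(d)[-(1:2)] <- c(spec$input_dims, spec$output_dims)
    dea_panel(d, inputs = spec$input_dims, outputs = spec$output_dims)
  }
  for (try in seq_len(max_retries)) {
    th <- efficiency_scores(dea_frontier(mk_panel(a)))
    bad <- which(th < 1 - 1e-7)
    if (!length(bad)) return(a)
    fresh <- draw(length(bad))
    a$X[, bad] <- fresh$X
    a$Y[, bad] <- fresh$Y
  }
  th <- efficiency_scores(dea_frontier(mk_panel(a)))
  keep <- which(th >= 1 - 1e-7)
  if (!length(keep)) {
    stop("anchor generation failed after ", max_retries,
         " retries (seed ", spec$seed, ")", call. = FALSE)
  }
  warning("kept ", length(keep), " of ", spec$n_anchors,
          " anchors (the mutually efficient subset); seed ", spec$seed,
          call. = FALSE)
  list(X = a$X[, keep, drop = FALSE], Y = a$Y[, keep, drop = FALSE])
}

#' Generate CRS-efficient anchor technologies
#'
#' Draws `n_anchors` strictly positive units and verifies by re-solving that
#' each is efficient within the anchor-only panel, regenerating dominated
#' draws within a bounded retry budget (falling back on the dominant subset,
#' with a warning, when the requested number cannot be mutually efficient).
#'
#' @param spec a [synthesis_spec()].
#' @param max_retries retry budget for regeneration.
#' @return a `dea_panel` of anchors (institution label `"ANCHOR"`), each with
#'   efficiency 1 in its own panel.
#' @export
generate_anchors <- function(spec, max_retries = 50L) {
  stopifnot(inherits(spec, "synthesis_spec"))
  set.seed(spec$seed)
  a <- .gen_anchors(spec, max_retries)
  d <- data.frame(institution = "ANCHOR",
                  state = sprintf("anchor%02d", seq_len(ncol(a$X))),
                  t(a$X), t(a$Y))
  names(d)[-(1:2)] <- c(spec$input_dims, spec$output_dims)
  dea_panel(d, inputs = spec$input_dims, outputs = spec$output_dims)
}

#' Generate a synthetic fragmented-system panel with known efficiencies
#'
#' For each (state, institution) pair present under its Bernoulli presence
#' probability, a frontier point is built as a random convex combination of
#' the anchors scaled by a CRS ray factor, and the unit's inputs are inflated
#' by `1 / theta*` with `theta*` drawn from the configured distribution. The
#' anchors themselves are appended to the panel (institution `"ANCHOR"`), so
#' the generating frontier is identified and [dea_solve()] recovers each
#' `theta*` exactly when no measurement noise is added.
#'
#' @param spec a [synthesis_spec()].
#' @return list with `panel` (a `dea_panel` of synthetic DMUs plus anchors),
#'   `truth` (named vector of true efficiencies; anchors have 1), and
#'   `presence` (logical states x institutions mask, anchors excluded).
#' @examples
#' g <- generate_panel(synthesis_spec(n_states = 4, seed = 7))
#' head(g$truth)
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "synthesis_spec"))
  set.seed(spec$seed)
  anchors <- .gen_anchors(spec)
  k <- ncol(anchors$X)
  states <- sprintf("S%02d", seq_len(spec$n_states))
  inst <- spec$institutions$label
  presence <- matrix(FALSE, spec$n_states, length(inst),
                     dimnames = list(states, inst))
  rows <- list()
  truth <- c()
  for (si in seq_along(states)) {
    for (ki in seq_along(inst)) {
      if (stats::runif(1) > spec$institutions$presence[ki]) next
      presence[si, ki] <- TRUE
      w <- stats::rexp(k)
      w <- w / sum(w)
      ray <- stats::runif(1, spec$output_scale_range[1],
                          spec$output_scale_range[2])
      x0 <- ray * drop(anchors$X %*% w)
      y0 <- ray * drop(anchors$Y %*% w)
      th <- .draw_theta(spec$theta_dist, 1L)
      x <- x0 / th
      y <- y0
      if (spec$noise_sd > 0) {
        x <- x * stats::rlnorm(length(x), 0, spec$noise_sd)
        y <- y * stats::rlnorm(length(y), 0, spec$noise_sd)
      }
      if (spec$integerize) {
        x <- round(x)
        y <- round(y)
        if (all(x == 0)) x[1] <- 1
      }
      id <- paste(inst[ki], states[si], sep = ":")
      rows[[id]] <- data.frame(institution = inst[ki], state = states[si],
                               t(x), t(y))
      truth[id] <- th
    }
  }
  if (!length(rows)) stop("presence draw produced no units (seed ",
                          spec$seed, ")", call. = FALSE)
  units <- do.call(rbind, rows)
  names(units)[-(1:2)] <- c(spec$input_dims, spec$output_dims)
  anc <- data.frame(institution = "ANCHOR",
                    state = sprintf("anchor%02d", seq_len(k)),
                    t(anchors$X), t(anchors$Y))
  names(anc)[-(1:2)] <- c(spec$input_dims, spec$output_dims)
  all_units <- rbind(units, anc)
  panel <- dea_panel(all_units, inputs = spec$input_dims,
                     outputs = spec$output_dims)
  truth <- c(truth,
             stats::setNames(rep(1, k),
                             paste("ANCHOR", anc$state, sep = ":")))
  list(panel = panel, truth = truth, presence = presence)
}

#' Generate synthetic state GDP-per-capita context
#'
#' Produces positive GDP-per-capita values for the given states, either
#' independent of any ordering (`link = "none"`) or rank-linked (with noise)
#' to the order in which `states` is supplied - pass states sorted by
#' efficiency to generate context with a known monotone association.
#'
#' @param states character vector of state labels; their order is the ranking
#'   the monotone links follow.
#' @param link `"none"`, `"monotone_increasing"` or `"monotone_decreasing"`.
#' @param noise_sd sd of lognormal scatter (>= 0). Under `link = "none"` this
#'   is the only source of variation, so it should be positive there.
#' @param seed RNG seed.
#' @param base_gdp median GDP per capita in USD (default near Mexico's
#'   national figure).
#' @return data.frame with columns `state` and `gdp_per_capita`.
#' @export
generate_context <- function(states,
                             link = c("none", "monotone_increasing",
                                      "monotone_decreasing"),
                             noise_sd = 0.4, seed = 1L, base_gdp = 9946) {
  link <- match.arg(link)
  stopifnot(length(states) >= 1L, base_gdp > 0)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  n <- length(states)
  idx <- (seq_len(n) - (n + 1) / 2) / max(n, 2)
  slope <- switch(link, none = 0, monotone_increasing = 1.5,
                  monotone_decreasing = -1.5)
  z <- slope * idx + stats::rnorm(n, 0, noise_sd)
  data.frame(state = as.character(states),
             gdp_per_capita = base_gdp * exp(z),
             stringsAsFactors = FALSE)
}
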