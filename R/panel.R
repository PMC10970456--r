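# Production panels: the set of decision-making units (DMUs) whose observed
# input/output mix defines the envelopment technology.

#' Build a DEA production panel
#'
#' A panel holds one row per decision-making unit (DMU) — here, one health
#' institution's operation within one state — together with its nonnegative
#' input and output quantities. Internally the panel stores the input matrix
#' `X` (input dimensions x units) and output matrix `Y` (output dimensions x
#' units) from which the envelopment technology is built.
#'
#' @param data a data.frame with one row per DMU, containing the identifier
#'   columns and one numeric column per input and output dimension.
#' @param inputs character vector of input column names (e.g. gynecologists,
#'   exam rooms, delivery rooms, operating rooms).
#' @param outputs character vector of output column names (e.g. prenatal
#'   visits, deliveries, cesareans, abortions).
#' @param institution,state names of the identifier columns.
#' @param id optional column of unique DMU identifiers; by default
#'   `"<institution>:<state>"`.
#' @return an object of class `dea_panel`.
#' @examples
#' d <- data.frame(institution = c("U1", "U2"), state = "S",
#'                 x = c(1, 2), y = c(2, 2))
#' dea_panel(d, inputs = "x", outputs = "y")
#' @export
dea_panel <- function(data, inputs, outputs,
                      institution = "institution", state = "state",
                      id = NULL) {
  stopifnot(is.data.frame(data))
  if (nrow(data) < 1L) stop("a panel needs at least one unit", call. = FALSE)
  need <- c(institution, state, inputs, outputs)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (length(intersect(inputs, outputs))) {
    stop("input and output dimensions must be disjoint", call. = FALSE)
  }
  ids <- if (is.null(id)) {
    paste(data[[institution]], data[[state]], sep = ":")
  } else {
    as.character(data[[id]])
  }
  if (anyDuplicated(ids)) {
    stop("duplicate DMU identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  X <- t(as.matrix(data[, inputs, drop = FALSE]))
  Y <- t(as.matrix(data[, outputs, drop = FALSE]))
  storage.mode(X) <- "double"
  storage.mode(Y) <- "double"
  if (anyNA(X) || anyNA(Y)) stop("missing quantity values", call. = FALSE)
  if (any(X < 0) || any(Y < 0)) {
    stop("input and output quantities must be nonnegative", call. = FALSE)
  }
  if (any(colSums(X) <= 0)) {
    bad <- ids[colSums(X) <= 0]
    stop("every unit needs at least one positive input; violated by: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dimnames(X) <- list(inputs, ids)
  dimnames(Y) <- list(outputs, ids)
  structure(
    list(
      units = data.frame(id = ids,
                         institution = as.character(data[[institution]]),
                         state = as.character(data[[state]]),
                         stringsAsFactors = FALSE),
      X = X, Y = Y,
      input_dims = inputs, output_dims = outputs
    ),
    class = "dea_panel"
  )
}

#' @export
print.dea_panel <- function(x, ...) {
  cat("<dea_panel> ", ncol(x$X), " units, ",
      length(x$input_dims), " inputs (", paste(x$input_dims, collapse = ", "),
      "), ", length(x$output_dims), " outputs (",
      paste(x$output_dims, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.dea_panel <- function(x, ...) {
  cbind(x$units,
        as.data.frame(t(x$X), check.names = FALSE),
        as.data.frame(t(x$Y), check.names = FALSE),
        row.names = NULL)
}

#' Number of units in a panel
#' @param panel a `dea_panel`.
#' @return integer count of DMUs.
#' @export
n_units <- function(panel) {
  stopifnot(inherits(panel, "dea_panel"))
  ncol(panel$X)
}

#' DMU identifiers of a panel
#' @param panel a `dea_panel`.
#' @return character vector of unit ids, in panel order.
#' @export
panel_ids <- function(panel) {
  stopifnot(inherits(panel, "dea_panel"))
  panel$units$id
}

#' Pool yearly panels into one period panel
#'
#' Sums every input and output quantity across years for each
#' (institution, state) pair, producing the single period-aggregated panel on
#' which a pooled DEA run is performed. All panels must share dimensions;
#' units absent in some years contribute only the years they appear in.
#'
#' @param panels a list of `dea_panel` objects (typically one per year).
#' @return a single `dea_panel` of period totals.
#' @export
pool_panels <- function(panels) {
  stopifnot(is.list(panels), length(panels) >= 1L)
  lapply(panels, function(p) stopifnot(inherits(p, "dea_panel")))
  ind <- panels[[1L]]$input_dims
  outd <- panels[[1L]]$output_dims
  for (p in panels) {
    if (!identical(p$input_dims, ind) || !identical(p$output_dims, outd)) {
      stop("all panels must share input and output dimensions", call. = FALSE)
    }
  }
  long <- do.call(rbind, lapply(panels, as.data.frame))
  agg <- stats::aggregate(long[, c(ind, outd), drop = FALSE],
                          by = list(institution = long$institution,
                                    state = long$state),
                          FUN = sum)
  dea_panel(agg, inputs = ind, outputs = outd)
}

.panel_index <- function(panel, dmu_id) {
  i <- match(dmu_id, panel$units$id)
  if (is.na(i)) stop("unknown DMU id: ", dmu_id, call. = FALSE)
  i
}

# Rescale each dimension by its maximum across units. Radial efficiency is
# invariant to per-dimension rescaling, and the raw obstetric quantities span
# five orders of magnitude (tens of delivery rooms vs tens of millions of
# prenatal visits), so this keeps the LP well conditioned. All-zero
# dimensions are left untouched.
.panel_scaled <- function(panel) {
  xs <- apply(panel$X, 1L, max)
  ys <- apply(panel$Y, 1L, max)
  xs[xs <= 0] <- 1
  ys[ys <= 0] <- 1
  list(X = panel$X / xs, Y = panel$Y / ys, xscale = xs, yscale = ys)
}
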