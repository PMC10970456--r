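# The state x institution efficiency grid. Absence (an institution that does
# not operate in a state) is encoded as NA and is distinct from a present
# score of 0: both occur in fragmented systems and they must never be
# conflated when averaging.

#' Construct a state-by-institution efficiency matrix
#'
#' @param cells numeric matrix of scores in `[0, 1]`, rows = states,
#'   columns = institutions, `NA` = institution absent from that state.
#' @return an object of class `efficiency_matrix` (a numeric matrix with
#'   dimnames).
#' @export
efficiency_matrix <- function(cells) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "double"
  if (is.null(rownames(cells)) || is.null(colnames(cells))) {
    stop("cells must carry state rownames and institution colnames",
         call. = FALSE)
  }
  present <- cells[!is.na(cells)]
  if (length(present) == 0L) stop("matrix has no present cells", call. = FALSE)
  if (any(present < 0 | present > 1)) {
    stop("efficiency scores must lie in [0, 1]", call. = FALSE)
  }
  structure(cells, class = c("efficiency_matrix", "matrix", "array"))
}

#' Arrange DEA scores into an efficiency matrix
#'
#' @param x a `dea_frontier` result, or a data.frame with columns `state`,
#'   `institution` and `theta`.
#' @param ... unused.
#' @return an [efficiency_matrix()] whose present cells are exactly the DMUs
#'   of `x`.
#' @export
as_efficiency_matrix <- function(x, ...) UseMethod("as_efficiency_matrix")

#' @export
as_efficiency_matrix.dea_frontier <- function(x, ...) {
  as_efficiency_matrix(as.data.frame(x))
}

#' @export
as_efficiency_matrix.data.frame <- function(x, ...) {
  stopifnot(all(c("state", "institution", "theta") %in% names(x)))
  states <- unique(x$state)
  inst <- unique(x$institution)
  M <- matrix(NA_real_, length(states), length(inst),
              dimnames = list(states, inst))
  M[cbind(match(x$state, states), match(x$institution, inst))] <- x$theta
  efficiency_matrix(M)
}

#' @export
print.efficiency_matrix <- function(x, ...) {
  cat("<efficiency_matrix> ", nrow(x), " states x ", ncol(x),
      " institutions; ", sum(!is.na(x)), " present cells\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Read a wide efficiency-matrix CSV
#'
#' Expects the first column to hold state labels and the remaining columns one
#' institution each; blank cells mean the institution is absent from that
#' state, while an explicit `0.000` is a present score of zero.
#'
#' @param path file path.
#' @return an [efficiency_matrix()].
#' @export
read_efficiency_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  if (ncol(df) < 2L || nrow(df) < 1L) {
    stop("matrix CSV needs a state column plus institution columns",
         call. = FALSE)
  }
  states <- df[[1L]]
  vals <- df[, -1L, drop = FALSE]
  M <- apply(vals, 2L, function(col) {
    col[col == ""] <- NA
    suppressWarnings(as.numeric(col))
  })
  M <- matrix(M, nrow = nrow(df),
              dimnames = list(states, names(vals)))
  bad <- !is.na(M) & (M < 0 | M > 1)
  if (any(bad)) {
    stop("scores outside [0, 1] at: ",
         paste(rownames(M)[row(M)[bad]], colnames(M)[col(M)[bad]],
               sep = "/", collapse = ", "),
         call. = FALSE)
  }
  parsed_na <- is.na(M) & !(as.matrix(vals) == "")
  if (any(parsed_na)) stop("non-numeric cells in matrix CSV", call. = FALSE)
  empty_cols <- colSums(!is.na(M)) == 0L
  if (any(empty_cols)) {
    warning("institutions with no presence in any state: ",
            paste(colnames(M)[empty_cols], collapse = ", "), call. = FALSE)
  }
  efficiency_matrix(M)
}

#' Write an efficiency matrix as wide CSV
#'
#' Absent cells are written blank (never 0). The written file round-trips
#' through [read_efficiency_matrix_csv()].
#'
#' @param mat an [efficiency_matrix()].
#' @param path destination file.
#' @param digits decimals to write, or `NA` for full precision.
#' @return `path`, invisibly.
#' @export
write_efficiency_matrix_csv <- function(mat, path, digits = NA) {
  stopifnot(inherits(mat, "efficiency_matrix"))
  M <- unclass(mat)
  fmt <- function(v) {
    out <- if (is.na(digits)) {
      vapply(v, function(z) format(z, digits = 15), character(1))
    } else {
      formatC(v, digits = digits, format = "f")
    }
    out[is.na(v)] <- ""
    out
  }
  df <- data.frame(state = rownames(M),
                   apply(M, 2L, fmt),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("state", colnames(M))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
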