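# Stage 2 and 3 of the benchmarking pipeline: threshold classification,
# institutional / state / national averaging, the efficiency gap, annual
# variation of quantities, and the correlation of state efficiency with GDP
# per capita.

#' Classify efficiency scores against capacity thresholds
#'
#' Scores strictly above the saturation threshold are `"saturated"`; scores
#' at or below the untapped threshold (inclusive) are `"untapped"`;
#' everything else is `"intermediate"`. The three categories partition
#' `[0, 1]`.
#'
#' @param theta numeric scores in `[0, 1]` (vectorized).
#' @param th a [dea_thresholds()].
#' @return factor with levels `untapped < intermediate < saturated`.
#' @examples
#' classify_dmu(c(1, 0.22, 0.5), dea_thresholds())
#' @export
classify_dmu <- function(theta, th = dea_thresholds()) {
  stopifnot(inherits(th, "dea_thresholds"))
  if (any(is.na(theta)) || any(theta < 0 | theta > 1)) {
    stop("theta must lie in [0, 1]", call. = FALSE)
  }
  out <- ifelse(theta > th$saturation, "saturated",
                ifelse(theta <= th$untapped, "untapped", "intermediate"))
  factor(out, levels = c("untapped", "intermediate", "saturated"),
         ordered = TRUE)
}

#' Aggregate an efficiency matrix into institutional and state summaries
#'
#' Institutional means average the present cells of each institution's
#' column; state means average each row; absent cells never enter any mean.
#' Three national averages are reported because they answer different
#' questions and genuinely differ in fragmented systems: the mean of the
#' institutional means, the mean of the state means, and the plain mean over
#' all DMUs. The efficiency gap is the spread of institutional means
#' (max minus min).
#'
#' @param mat an [efficiency_matrix()].
#' @param th a [dea_thresholds()] used for the saturated / untapped shares.
#' @param score_decimals decimals at which a cell counts as exactly 1 for the
#'   `counts_at_unity` tally (scores are conventionally reported at 3
#'   decimals).
#' @return an object of class `efficiency_summary`: a list with
#'   `institutional_means`, `state_means`, `national_mean_of_institutions`,
#'   `national_mean_of_states`, `national_mean_of_dmus`, `gap`,
#'   `share_saturated`, `share_untapped` (percentages of present cells),
#'   `counts_at_unity`, `class_counts`, `n_present` and `notes` (data-quality
#'   messages accumulated while summarizing).
#' @export
summarize_efficiency <- function(mat, th = dea_thresholds(),
                                 score_decimals = 3L) {
  stopifnot(inherits(mat, "efficiency_matrix"), inherits(th, "dea_thresholds"))
  M <- unclass(mat)
  notes <- character(0)

  empty_col <- colSums(!is.na(M)) == 0L
  empty_row <- rowSums(!is.na(M)) == 0L
  if (any(empty_col)) {
    msg <- paste0("institutions with no present cells omitted from means: ",
                  paste(colnames(M)[empty_col], collapse = ", "))
    warning(msg, call. = FALSE)
    notes <- c(notes, msg)
  }
  if (any(empty_row)) {
    msg <- paste0("states with no present cells omitted from means: ",
                  paste(rownames(M)[empty_row], collapse = ", "))
    warning(msg, call. = FALSE)
    notes <- c(notes, msg)
  }

  inst_means <- colMeans(M[, !empty_col, drop = FALSE], na.rm = TRUE)
  state_means <- rowMeans(M[!empty_row, , drop = FALSE], na.rm = TRUE)
  cells <- M[!is.na(M)]
  n_present <- length(cells)

  cls <- classify_dmu(cells, th)
  class_counts <- table(cls)
  share_sat <- 100 * sum(cls == "saturated") / n_present
  share_unt <- 100 * sum(cls == "untapped") / n_present

  at_unity <- vapply(colnames(M), function(j) {
    col <- M[, j]
    sum(round(col[!is.na(col)], score_decimals) == 1)
  }, integer(1))

  zero_cells <- sum(cells == 0)
  if (zero_cells > 0) {
    notes <- c(notes, paste0(zero_cells,
                             " present cell(s) with a zero score (recorded ",
                             "resources but no measured output)"))
  }

  structure(
    list(institutional_means = inst_means,
         state_means = state_means,
         national_mean_of_institutions = mean(inst_means),
         national_mean_of_states = mean(state_means),
         national_mean_of_dmus = mean(cells),
         gap = max(inst_means) - min(inst_means),
         share_saturated = share_sat,
         share_untapped = share_unt,
         counts_at_unity = at_unity,
         class_counts = class_counts,
         n_present = n_present,
         thresholds = th,
         notes = notes),
    class = "efficiency_summary"
  )
}

#' @export
print.efficiency_summary <- function(x, ...) {
  cat("<efficiency_summary> ", x$n_present, " DMUs\n", sep = "")
  cat("institutional means:\n")
  print(round(x$institutional_means, 3))
  cat(sprintf("national means: of institutions %.3f | of states %.3f | of DMUs %.3f\n",
              x$national_mean_of_institutions, x$national_mean_of_states,
              x$national_mean_of_dmus))
  cat(sprintf("efficiency gap (max - min institutional mean): %.3f\n", x$gap))
  cat(sprintf("saturated (> %.2f): %.1f%%; untapped (<= %.2f): %.1f%%\n",
              x$thresholds$saturation, x$share_saturated,
              x$thresholds$untapped, x$share_untapped))
  if (length(x$notes)) cat("notes:\n", paste(" -", x$notes, collapse = "\n"), "\n")
  invisible(x)
}

#' Correlate state efficiency with GDP per capita
#'
#' Computes Spearman's rank correlation (the primary statistic: monotone
#' association, robust to the skew of GDP) and Pearson's correlation
#' (secondary, reported alongside since linear correlation is what general
#' pairwise-correlation routines print), plus a GDP-quartile profile of
#' state efficiency. Quartile 1 holds the lowest-GDP states; breaks are at
#' rank n/4 splits with ties ranked by average.
#'
#' @param state_means named numeric vector of state efficiency scores.
#' @param context data.frame with columns `state` and `gdp_per_capita`
#'   (positive, USD).
#' @return an object of class `context_correlation`: list with
#'   `spearman_rho`, `spearman_p`, `pearson_r`, `pearson_p`, `n` and
#'   `quartile_table` (one row per GDP quartile with min / max / mean state
#'   efficiency and the member states).
#' @export
correlate_with_context <- function(state_means, context) {
  stopifnot(is.numeric(state_means), !is.null(names(state_means)),
            is.data.frame(context),
            all(c("state", "gdp_per_capita") %in% names(context)))
  if (any(context$gdp_per_capita <= 0)) {
    stop("gdp_per_capita must be positive", call. = FALSE)
  }
  common <- intersect(names(state_means), context$state)
  if (length(common) < 3L) {
    stop("need at least 3 states with both an efficiency score and GDP",
         call. = FALSE)
  }
  eff <- state_means[common]
  gdp <- context$gdp_per_capita[match(common, context$state)]

  sp <- suppressWarnings(stats::cor.test(gdp, eff, method = "spearman",
                                         exact = FALSE))
  pe <- stats::cor.test(gdp, eff, method = "pearson")

  n <- length(common)
  rk <- rank(gdp)                       # average ranks under ties
  q <- pmin(pmax(ceiling(4 * rk / n), 1L), 4L)
  qt <- do.call(rbind, lapply(sort(unique(q)), function(k) {
    e <- eff[q == k]
    data.frame(quartile = k, n = length(e),
               gdp_min = min(gdp[q == k]), gdp_max = max(gdp[q == k]),
               eff_min = min(e), eff_max = max(e), eff_mean = mean(e),
               states = paste(common[q == k], collapse = "; "),
               stringsAsFactors = FALSE)
  }))

  structure(
    list(spearman_rho = unname(sp$estimate),
         spearman_p = sp$p.value,
         pearson_r = unname(pe$estimate),
         pearson_p = pe$p.value,
         n = n,
         quartile_table = qt),
    class = "context_correlation"
  )
}

#' @export
print.context_correlation <- function(x, ...) {
  cat(sprintf("<context_correlation> n = %d states\n", x$n))
  cat(sprintf("  Spearman rho = %.3f (p = %.3f); Pearson r = %.3f (p = %.3f)\n",
              x$spearman_rho, x$spearman_p, x$pearson_r, x$pearson_p))
  print(x$quartile_table[, c("quartile", "n", "eff_min", "eff_max", "eff_mean")],
        row.names = FALSE)
  invisible(x)
}

#' Annual variation of inputs and outputs
#'
#' Descriptive check of temporal stability: for every institution and every
#' input/output dimension, the institution's national total per year, its
#' year-over-year percent changes, and the coefficient of variation (sd/mean)
#' of the yearly totals. A change following a zero prior-year total is
#' reported as `NA` (undefined), never as infinity.
#'
#' @param panels_by_year named list of yearly [dea_panel()]s sharing
#'   dimensions; names are the years.
#' @return an object of class `annual_variation`: list with `changes`
#'   (long data.frame: institution, dimension, year, value, pct_change) and
#'   `cv` (data.frame: institution, dimension, cv).
#' @export
annual_variation <- function(panels_by_year) {
  stopifnot(is.list(panels_by_year), length(panels_by_year) >= 2L,
            !is.null(names(panels_by_year)))
  years <- names(panels_by_year)
  p1 <- panels_by_year[[1L]]
  dims <- c(p1$input_dims, p1$output_dims)
  for (p in panels_by_year) {
    if (!identical(c(p$input_dims, p$output_dims), dims)) {
      stop("all yearly panels must share dimensions", call. = FALSE)
    }
  }
  insts <- sort(unique(unlist(lapply(panels_by_year,
                                     function(p) p$units$institution))))
  totals <- function(p, inst, dim) {
    sel <- p$units$institution == inst
    if (!any(sel)) return(0)
    Q <- rbind(p$X, p$Y)
    sum(Q[dim, sel])
  }
  changes <- list()
  cvs <- list()
  for (inst in insts) {
    for (dim in dims) {
      v <- vapply(panels_by_year, totals, numeric(1), inst = inst, dim = dim)
      pc <- c(NA_real_,
              ifelse(utils::head(v, -1) == 0, NA_real_,
                     100 * diff(v) / utils::head(v, -1)))
      changes[[length(changes) + 1L]] <-
        data.frame(institution = inst, dimension = dim, year = years,
                   value = unname(v), pct_change = pc,
                   stringsAsFactors = FALSE)
      cv <- if (stats::sd(v) == 0) 0 else stats::sd(v) / mean(v)
      cvs[[length(cvs) + 1L]] <-
        data.frame(institution = inst, dimension = dim, cv = cv,
                   stringsAsFactors = FALSE)
    }
  }
  structure(list(changes = do.call(rbind, changes),
                 cv = do.call(rbind, cvs)),
            class = "annual_variation")
}

#' @export
print.annual_variation <- function(x, ...) {
  cat("<annual_variation> ", length(unique(x$cv$institution)),
      " institutions x ", length(unique(x$cv$dimension)), " dimensions\n",
      sep = "")
  print(utils::head(x$cv, 12), row.names = FALSE)
  invisible(x)
}
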