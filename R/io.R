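# CSV readers/writers and the bundled reference tables.
#
# Panel CSVs are long format: one row per DMU (and optionally per year),
# identifier columns plus one numeric column per dimension. Thousands
# separators ("46,993,718") are accepted on read and never written.

.parse_count <- function(x, what, path) {
  v <- suppressWarnings(as.numeric(gsub("[ ,]", "", x)))
  bad <- which(is.na(v) & !(is.na(x) | x == ""))
  if (length(bad)) {
    stop("non-numeric ", what, " value in ", basename(path),
         " at data row ", bad[1L], ": '", x[bad[1L]], "'", call. = FALSE)
  }
  v
}

#' Variable sets for the obstetric-care production function
#'
#' Two input/output definitions are in circulation for this production
#' process and both are supported: the full operational set (four inputs -
#' gynecologists, exam rooms, delivery rooms, operating rooms - and four
#' outputs - prenatal visits, deliveries, cesareans, abortions) and a
#' reduced set (three inputs: gynecologists, exam rooms, delivery rooms; two
#' outputs: prenatal visits, deliveries).
#'
#' @param set `"full"` (4 x 4) or `"reduced"` (3 x 2).
#' @return list with `inputs` and `outputs` character vectors.
#' @export
obstetric_variables <- function(set = c("full", "reduced")) {
  set <- match.arg(set)
  if (set == "full") {
    list(inputs = c("gynecologists", "exam_rooms", "delivery_rooms",
                    "operating_rooms"),
         outputs = c("prenatal_visits", "deliveries", "cesareans",
                     "abortions"))
  } else {
    list(inputs = c("gynecologists", "exam_rooms", "delivery_rooms"),
         outputs = c("prenatal_visits", "deliveries"))
  }
}

#' Read a long-format panel CSV
#'
#' @param path file path.
#' @param inputs,outputs dimension column names expected in the header.
#' @param institution,state,year identifier column names (`year` is used only
#'   if present in the file).
#' @param per_year if the file carries a year column: `FALSE` (default) pools
#'   quantities across years into one period panel; `TRUE` returns a named
#'   list of yearly panels.
#' @return a [dea_panel()], or a named list of them in per-year mode.
#' @export
read_panel_csv <- function(path, inputs, outputs,
                           institution = "institution", state = "state",
                           year = "year", per_year = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  if (nrow(df) == 0L) stop("empty panel file: ", path, call. = FALSE)
  need <- c(institution, state, inputs, outputs)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("panel CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  has_year <- year %in% names(df)
  for (cn in c(inputs, outputs)) {
    df[[cn]] <- .parse_count(df[[cn]], cn, path)
    neg <- which(df[[cn]] < 0)
    if (length(neg)) {
      stop("negative ", cn, " in ", basename(path), " at data row ", neg[1L],
           call. = FALSE)
    }
  }
  key <- if (has_year) {
    paste(df[[institution]], df[[state]], df[[year]])
  } else {
    paste(df[[institution]], df[[state]])
  }
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate unit in ", basename(path), " at data row ", dup[1L],
         ": ", key[dup[1L]], call. = FALSE)
  }
  if (has_year && per_year) {
    out <- lapply(split(df, df[[year]]), function(d) {
      dea_panel(d, inputs = inputs, outputs = outputs,
                institution = institution, state = state)
    })
    return(out)
  }
  if (has_year) {
    agg <- stats::aggregate(df[, c(inputs, outputs), drop = FALSE],
                            by = list(institution = df[[institution]],
                                      state = df[[state]]),
                            FUN = sum)
    return(dea_panel(agg, inputs = inputs, outputs = outputs))
  }
  dea_panel(df, inputs = inputs, outputs = outputs,
            institution = institution, state = state)
}

#' Write a panel as long-format CSV
#'
#' @param panel a [dea_panel()].
#' @param path destination file.
#' @return `path`, invisibly. The file round-trips through
#'   [read_panel_csv()].
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "dea_panel"))
  df <- as.data.frame(panel)
  df$id <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Institution legend for the bundled Mexican tables
#'
#' The bundled tables anonymize the six federal institutions as A-F; the
#' public naming, in the order their national shares match, is adopted as:
#' A = SS (Ministry of Health), B = IMSS, C = ISSSTE, D = PEMEX, E = SEDENA,
#' F = SEMAR. The mapping affects labels only, never numbers.
#'
#' @return named character vector mapping column label to institution.
#' @export
mexico_institution_legend <- function() {
  c(A = "SS", B = "IMSS", C = "ISSSTE", D = "PEMEX", E = "SEDENA",
    F = "SEMAR")
}

#' Bundled national obstetric-care panel, Mexico 2012-2018
#'
#' Period totals of the obstetric inputs and outputs of Mexico's six federal
#' public health institutions (anonymized A-F; see
#' [mexico_institution_legend()]), transcribed from the published national
#' summary table for 2012-2018. One unit per institution at the national
#' level.
#'
#' @param variables `"full"` (4 inputs x 4 outputs) or `"reduced"`
#'   (3 x 2); see [obstetric_variables()].
#' @return a [dea_panel()] of six units.
#' @export
mexico_obstetric_panel <- function(variables = c("full", "reduced")) {
  v <- obstetric_variables(match.arg(variables))
  path <- system.file("extdata", "mexico_national_panel.csv",
                      package = "deacare", mustWork = TRUE)
  read_panel_csv(path, inputs = v$inputs, outputs = v$outputs)
}

#' Bundled state-by-institution efficiency matrix, Mexico 2012-2018
#'
#' The 153 technical-efficiency scores (32 states x 6 federal institutions,
#' blanks where an institution has no state presence) of Mexico's public
#' obstetric-care system over 2012-2018, transcribed at the published
#' 3-decimal precision. Institutions are anonymized A-F
#' ([mexico_institution_legend()]).
#'
#' @return an [efficiency_matrix()] with 153 present cells.
#' @export
mexico_efficiency_matrix <- function() {
  path <- system.file("extdata", "mexico_state_efficiency.csv",
                      package = "deacare", mustWork = TRUE)
  read_efficiency_matrix_csv(path)
}
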