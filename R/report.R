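#' Write the benchmarking report files
#'
#' Emits, under `outdir`: `efficiency_matrix.csv` (wide grid, blanks for
#' absence, when a matrix is supplied), `summary_marginals.csv` (the
#' institutional and state means plus national aggregates), and `report.md`,
#' a plain-markdown narrative with thresholds, gap, shares, correlation
#' results and every data-quality note accumulated during summarization.
#' Output is deterministic for fixed inputs (no timestamps).
#'
#' @param summary an [summarize_efficiency()] result.
#' @param corr optional [correlate_with_context()] result.
#' @param outdir output directory (created if needed).
#' @param matrix optional [efficiency_matrix()] to write alongside.
#' @param extra_notes optional character vector of additional notes for the
#'   narrative.
#' @return invisible character vector of the files written.
#' @export
write_report <- function(summary, corr = NULL, outdir, matrix = NULL,
                         extra_notes = character(0)) {
  stopifnot(inherits(summary, "efficiency_summary"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) {
      stop("cannot create output directory: ", outdir, call. = FALSE)
    }
  }
  files <- character(0)

  if (!is.null(matrix)) {
    f <- file.path(outdir, "efficiency_matrix.csv")
    write_efficiency_matrix_csv(matrix, f, digits = 3)
    files <- c(files, f)
  }

  marg <- rbind(
    data.frame(level = "institution",
               label = names(summary$institutional_means),
               mean_efficiency = round(unname(summary$institutional_means), 3)),
    data.frame(level = "state",
               label = names(summary$state_means),
               mean_efficiency = round(unname(summary$state_means), 3)),
    data.frame(level = "national",
               label = c("mean_of_institutions", "mean_of_states",
                         "mean_of_dmus"),
               mean_efficiency = round(c(summary$national_mean_of_institutions,
                                         summary$national_mean_of_states,
                                         summary$national_mean_of_dmus), 3))
  )
  f <- file.path(outdir, "summary_marginals.csv")
  utils::write.csv(marg, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  th <- summary$thresholds
  lines <- c(
    "# Technical-efficiency benchmarking report",
    "",
    sprintf("DMUs analysed: %d", summary$n_present),
    "",
    "## Institutional means",
    "",
    sprintf("- %s: %.3f", names(summary$institutional_means),
            summary$institutional_means),
    "",
    "## National aggregates",
    "",
    sprintf("- mean of institutional means: %.3f",
            summary$national_mean_of_institutions),
    sprintf("- mean of state means: %.3f", summary$national_mean_of_states),
    sprintf("- mean over all DMUs: %.3f", summary$national_mean_of_dmus),
    sprintf("- efficiency gap (max - min institutional mean): %.3f",
            summary$gap),
    "",
    "## Threshold classification",
    "",
    sprintf("- saturated (score > %.2f): %.1f%% of DMUs", th$saturation,
            summary$share_saturated),
    sprintf("- untapped capacity (score <= %.2f): %.1f%% of DMUs",
            th$untapped, summary$share_untapped),
    sprintf("- DMUs at unity per institution: %s",
            paste(sprintf("%s=%d", names(summary$counts_at_unity),
                          summary$counts_at_unity), collapse = ", "))
  )
  if (!is.null(corr)) {
    stopifnot(inherits(corr, "context_correlation"))
    lines <- c(lines, "",
               "## Efficiency vs GDP per capita",
               "",
               sprintf("- Spearman rho = %.3f (p = %.4f), n = %d",
                       corr$spearman_rho, corr$spearman_p, corr$n),
               sprintf("- Pearson r = %.3f (p = %.4f)",
                       corr$pearson_r, corr$pearson_p),
               "",
               "GDP-quartile profile of state efficiency (quartile 1 = lowest GDP):",
               "",
               sprintf("- Q%d (n=%d): min %.3f, max %.3f, mean %.3f",
                       corr$quartile_table$quartile, corr$quartile_table$n,
                       corr$quartile_table$eff_min, corr$quartile_table$eff_max,
                       corr$quartile_table$eff_mean))
  }
  notes <- c(summary$notes, extra_notes)
  if (length(notes)) {
    lines <- c(lines, "", "## Notes", "", paste0("- ", notes))
  }
  f <- file.path(outdir, "report.md")
  writeLines(lines, f)
  files <- c(files, f)
  invisible(files)
}
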