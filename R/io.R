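#' Read a cohort table from CSV
#'
#' One row per child, header with the schema column names (see
#' \link{cohort-schema}); dates ISO-8601, missing values empty. Dates
#' that fail to parse become \code{NA} and are reported.
#'
#' @param path CSV file path.
#' @return cohort data.frame.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"))
  for (nm in c("last_menses", "conception_date")) {
    if (!is.null(df[[nm]])) {
      raw <- df[[nm]]
      d <- as.Date(raw, format = "%Y-%m-%d")
      bad <- !is.na(raw) & is.na(d)
      if (any(bad))
        warning(sum(bad), " unparseable ", nm, " value(s) set to NA ",
                "(first at row ", which(bad)[1], ")")
      df[[nm]] <- d
    }
  }
  df
}

#' Write a cohort table to CSV
#'
#' @param records cohort data.frame.
#' @param path output path; dates are written ISO-8601, missing values
#'   empty.
#' @export
write_cohort <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
}

#' Write sectioned scan results to CSV
#'
#' One row per section with the cluster dates, n, c, E and RR (2 dp),
#' raw Monte Carlo p and the Holm-adjusted decision.
#'
#' @param x a \code{section_scan_set}.
#' @param path output path.
#' @return the written data.frame, invisibly.
#' @export
write_scan_results <- function(x, path) {
  stopifnot(inherits(x, "section_scan_set"))
  r <- x$results
  out <- data.frame(
    section = r$section,
    cluster_start = format(r$start), cluster_end = format(r$end),
    n = r$n, c = r$c, E = round(r$E, 2), RR = round(r$RR, 2),
    p = r$p, reject_holm = r$reject, reps = r$reps,
    N = r$N, C = r$C
  )
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(out)
}
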