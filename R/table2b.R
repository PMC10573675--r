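#' Published per-case median volumes for 50 stones and 3 observers
#'
#' A transcription of a published clinical reproducibility table: for each
#' of 50 renal-stone cases, the median (and Q1--Q3) of five repeated
#' density-window volume measurements by each of three observers of
#' different experience levels (junior urologist, senior urologist, expert
#' endourologist). Volumes in mm^3.
#'
#' Three typographic anomalies of the printed table are preserved verbatim
#' in the `raw` column but normalized in the numeric columns (decimal comma
#' and thousands separators); one printed interval does not bracket its
#' median and one median lies outside its interval -- they are kept as
#' printed, so analyses relying on the intervals should treat those rows
#' with care. The per-case medians themselves are the analysis substrate.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return A data.frame with columns `case_id`, `observer_id`,
#'   `median_mm3`, `q1_mm3`, `q3_mm3`, `raw`, plus `replicate` (all 1) and
#'   `volume_mm3` (copy of `median_mm3`) so the result is directly a valid
#'   measurement table for [agreement_study()] with
#'   `aggregation = "median"`.
#' @examples
#' tab <- read_table2b()
#' fit <- agreement_study(tab, aggregation = "median")
#' fit$overall$w
#' @export
read_table2b <- function(path = system.file("extdata", "table2b.csv",
                                            package = "stonevol")) {
  tab <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  tab$observer_id <- factor(tab$observer_id,
                            levels = c("junior", "senior", "expert"))
  tab$replicate <- 1L
  tab$volume_mm3 <- tab$median_mm3
  check_measurement_table(tab)
  tab
}
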