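#' Bundled reference cohort: treatment courses
#'
#' Course descriptors for a previously reported series of 17 non-small
#' cell lung cancer lesions followed with CT before every fraction: 5
#' patients on conventional fractionation (group L, 1.8-2.5 Gy weekday
#' fractions over 6-10 weeks) and 12 on hypofractionation (group S, 5 x 10
#' Gy in under two weeks). Columns give the total dose, the fraction
#' segments (`n1 x dose1_gy`, plus `n2 x dose2_gy` for the one
#' mixed-dose course), the BED at alpha/beta = 10, and the calendar days
#' to finish. Used as regression fixtures for the radiobiology utilities
#' and as templates for the synthetic-data generator.
#'
#' @return A data frame, one row per patient.
#' @export
reference_cohort <- function() {
  read.csv(system.file("extdata", "reference_courses.csv",
                       package = "rtkinetics"),
           stringsAsFactors = FALSE)
}

#' Bundled reference cohort: best-fit parameter summaries
#'
#' Best-fit model parameters and response types for the reference cohort
#' (see [reference_cohort()]). `rank` 1 marks the best-fitting model for
#' each patient; a few patients carry a rank-2 alternate that was not
#' significantly worse. Kill parameters `K`, `Kp`, `Kq` are percentages
#' per fraction; `Rini` is the initial resistant fraction and `Rind_pct`
#' the percent of sensitive survivors converted to resistant per fraction
#' (for rows fitted with both resistance variants, both are given);
#' `rec_start`/`rec_end` delimit the recruitment window in days after
#' treatment start (`NA` end = until the end of follow-up). `NA` in `Td`
#' or `D` means the parameter was not estimable from the data. Used as
#' regression fixtures for the classifier and as parameter points for the
#' synthetic archetypes.
#'
#' @return A data frame, one row per fitted model.
#' @export
reference_fits <- function() {
  read.csv(system.file("extdata", "reference_fits.csv",
                       package = "rtkinetics"),
           stringsAsFactors = FALSE)
}
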