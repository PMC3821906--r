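#' Treatment fraction schedule
#'
#' An ordered set of radiotherapy fractions, each a (day, dose) pair. Day 0
#' is by convention the first fraction; pretreatment observations carry
#' negative days.
#'
#' @param day integer vector of fraction days, strictly increasing.
#' @param dose_gy dose per fraction in Gy (scalar or vector), > 0.
#' @return An object of class `rt_schedule` (a data frame with columns
#'   `day`, `dose_gy`).
#' @examples
#' rt_schedule(c(0, 2, 4, 7, 9), 10)
#' @export
rt_schedule <- function(day, dose_gy) {
  stopifnot(is.numeric(day), length(day) >= 1, all(is.finite(day)))
  if (any(diff(day) <= 0)) stop("fraction days must be strictly increasing")
  if (any(day != round(day))) stop("fraction days must be integers")
  dose_gy <- rep_len(dose_gy, length(day))
  if (any(dose_gy <= 0)) stop("fraction doses must be > 0")
  structure(data.frame(day = as.integer(day), dose_gy = dose_gy),
            class = c("rt_schedule", "data.frame"))
}

#' @export
print.rt_schedule <- function(x, ...) {
  cat(sprintf("Schedule: %d fractions, %g Gy total, days %d-%d\n",
              nrow(x), sum(x$dose_gy), min(x$day), max(x$day)))
  invisible(x)
}

#' Build a typical treatment schedule for a fractionation group
#'
#' Generates the calendar of a conventional (`"L"`, long) or
#' hypofractionated (`"S"`, short) course:
#'
#' * group L: daily weekday fractions of 1.8-2.5 Gy. Day 0 is taken as a
#'   Monday; when the span offers more weekday slots than fractions, the
#'   fractions are spread evenly across the slots (mimicking holiday
#'   breaks in protracted courses).
#' * group S: 5 fractions of 10 Gy with 1-3 day gaps, spread evenly over
#'   the requested span. Hypofractionated courses must finish in under 14
#'   days.
#'
#' @param group `"L"` or `"S"`.
#' @param total_days calendar length of the course in days (first to last
#'   fraction inclusive).
#' @param dose_gy dose per fraction; defaults 2.5 (L) / 10 (S).
#' @param n_fractions number of fractions; defaults 30 (L) / 5 (S).
#' @return An [rt_schedule()].
#' @examples
#' make_schedule("S", 9)
#' make_schedule("L", 46)
#' @export
make_schedule <- function(group = c("L", "S"), total_days,
                          dose_gy = NULL, n_fractions = NULL) {
  group <- match.arg(group)
  stopifnot(is.numeric(total_days), length(total_days) == 1,
            total_days >= 1)
  if (group == "S") {
    if (is.null(dose_gy)) dose_gy <- 10
    if (is.null(n_fractions)) n_fractions <- 5
    if (total_days >= 14)
      stop("hypofractionated (group S) courses complete in less than 14 days")
    if (total_days < n_fractions)
      stop("span too short for ", n_fractions, " fractions")
    days <- unique(round(seq(0, total_days - 1, length.out = n_fractions)))
    if (length(days) < n_fractions)
      stop("span too short for ", n_fractions, " distinct fraction days")
  } else {
    if (is.null(dose_gy)) dose_gy <- 2.5
    if (is.null(n_fractions)) n_fractions <- 30
    slots <- seq(0, total_days - 1)
    slots <- slots[slots %% 7 < 5]  # day 0 is a Monday; treat weekdays only
    if (length(slots) < n_fractions)
      stop("only ", length(slots), " weekday slots in ", total_days,
           " days; cannot place ", n_fractions, " fractions")
    idx <- unique(round(seq(1, length(slots), length.out = n_fractions)))
    if (length(idx) < n_fractions)
      stop("cannot place ", n_fractions, " distinct fractions in ",
           total_days, " days")
    days <- slots[idx]
  }
  rt_schedule(days, dose_gy)
}
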