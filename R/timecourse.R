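#' Observed tumor volume time course
#'
#' Couples a series of (day, volume) observations with the treatment
#' schedule under which they were measured. Days are integers relative to
#' treatment start (day 0 = first fraction; pretreatment scans carry
#' negative days). Censored observations are measurements that fell below
#' the CT detection limit; by the conservative convention used throughout
#' the package they are recorded *at* the detection limit and fitted as
#' exact values there.
#'
#' @param observations data frame with columns `day`, `volume_cc`, and
#'   optionally `censored` (logical, default all `FALSE`).
#' @param schedule an [rt_schedule()].
#' @param detection_limit CT detection limit in cc, or `NA` if not
#'   applicable.
#' @param patient_id optional identifier.
#' @param group optional treatment group (`"L"` or `"S"`), used by response
#'   classification.
#' @return An object of class `timecourse`.
#' @export
timecourse <- function(observations, schedule, detection_limit = NA,
                       patient_id = NULL, group = NULL) {
  stopifnot(is.data.frame(observations),
            all(c("day", "volume_cc") %in% names(observations)),
            inherits(schedule, "rt_schedule"))
  obs <- observations
  if (is.null(obs$censored)) obs$censored <- FALSE
  obs <- obs[c("day", "volume_cc", "censored")]
  if (nrow(obs) == 0) stop("no observations")
  if (any(!is.finite(obs$day)) || any(obs$day != round(obs$day)))
    stop("observation days must be integers")
  if (is.unsorted(obs$day)) stop("observation days must be nondecreasing")
  if (any(!is.finite(obs$volume_cc)) || any(obs$volume_cc <= 0))
    stop("volumes must be positive")
  obs$censored <- as.logical(obs$censored)
  if (any(is.na(obs$censored))) stop("'censored' must be TRUE/FALSE")
  if (any(obs$censored)) {
    if (is.na(detection_limit))
      stop("censored observations require a detection limit")
    off <- obs$censored & abs(obs$volume_cc - detection_limit) >
      1e-9 * detection_limit
    if (any(off)) {
      warning(sum(off), " censored observation(s) reset to the detection ",
              "limit (", detection_limit, " cc)")
      obs$volume_cc[off] <- detection_limit
    }
  }
  structure(list(observations = obs, schedule = schedule,
                 detection_limit = detection_limit,
                 pretreatment_available = any(obs$day < min(schedule$day)),
                 patient_id = patient_id, group = group),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat("Tumor volume time course")
  if (!is.null(x$patient_id)) cat(" [", x$patient_id, "]", sep = "")
  cat(sprintf(": %d observations, days %d to %d\n",
              nrow(x$observations), min(x$observations$day),
              max(x$observations$day)))
  print(x$schedule)
  if (!x$pretreatment_available) cat("  (no pretreatment observation)\n")
  invisible(x)
}

#' Read tumor volume time courses from delimited text
#'
#' Reads an observation file (CSV with header columns `patient_id`, `day`,
#' `volume_cc`, `censored`) and a companion schedule file (`day`,
#' `dose_gy`, optionally `patient_id`). Days are integers relative to
#' treatment start. Malformed rows are reported by row number.
#'
#' @param path path to the observation CSV.
#' @param schedule_path path to the schedule CSV.
#' @param detection_limit detection limit in cc applied to censored rows.
#' @param group optional treatment group label, recycled over patients.
#' @return A single [timecourse()] if the file holds one patient, otherwise
#'   a named list of them.
#' @export
read_timecourse <- function(path, schedule_path, detection_limit = NA,
                            group = NULL) {
  obs <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "day", "volume_cc", "censored")
  if (!all(need %in% names(obs)))
    stop("observation file must have columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(obs$volume_cc) | obs$volume_cc <= 0)
  if (length(bad))
    stop("nonpositive or missing volume_cc at row(s) ",
         paste(bad, collapse = ", "), " of ", path)
  sch <- read.csv(schedule_path, stringsAsFactors = FALSE)
  if (!all(c("day", "dose_gy") %in% names(sch)))
    stop("schedule file must have columns: day, dose_gy")
  ids <- unique(obs$patient_id)
  out <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    o <- obs[obs$patient_id == id, ]
    if (is.unsorted(o$day))
      stop("days not sorted for patient ", id, " in ", path)
    s <- if ("patient_id" %in% names(sch)) sch[sch$patient_id == id, ] else sch
    if (nrow(s) == 0) stop("no schedule rows for patient ", id)
    timecourse(o[c("day", "volume_cc", "censored")],
               rt_schedule(s$day, s$dose_gy),
               detection_limit = detection_limit,
               patient_id = as.character(id),
               group = if (is.null(group)) NULL else rep_len(group, length(ids))[i])
  })
  names(out) <- as.character(ids)
  if (length(out) == 1) out[[1]] else out
}

#' Write time courses to the delimited format read by [read_timecourse()]
#'
#' @param tcs a [timecourse()] or list of them.
#' @param path observation CSV path.
#' @param schedule_path schedule CSV path.
#' @return Invisibly, the observation data frame written.
#' @export
write_timecourse <- function(tcs, path, schedule_path) {
  if (inherits(tcs, "timecourse")) tcs <- list(tcs)
  obs <- do.call(rbind, lapply(seq_along(tcs), function(i) {
    tc <- tcs[[i]]
    id <- tc$patient_id %||% names(tcs)[i] %||% paste0("P", i)
    cbind(patient_id = id, tc$observations)
  }))
  sch <- do.call(rbind, lapply(seq_along(tcs), function(i) {
    tc <- tcs[[i]]
    id <- tc$patient_id %||% names(tcs)[i] %||% paste0("P", i)
    cbind(patient_id = id, as.data.frame(tc$schedule))
  }))
  write.csv(obs, path, row.names = FALSE)
  write.csv(sch, schedule_path, row.names = FALSE)
  invisible(obs)
}
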