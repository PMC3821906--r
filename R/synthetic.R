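#' Synthetic-data scenario
#'
#' Everything needed to generate one noisy tumor-volume time course with
#' the statistical structure the fitting pipeline assumes: exponential
#' pretreatment growth, per-fraction kill with delayed loss, multiplicative
#' lognormal measurement noise, and a CT detection limit.
#'
#' The sampling calendar mimics image-guided radiotherapy practice: one
#' planning scan one to three weeks before treatment, a diagnostic CT
#' immediately before every fraction, and follow-up scans about one and two
#' months after the last fraction.
#'
#' @param group `"L"` or `"S"`.
#' @param growth a [growth_params()] object.
#' @param effect an [effect_model()].
#' @param V0 volume at treatment start, cc.
#' @param schedule an [rt_schedule()]; default: [make_schedule()] for the
#'   group (46-day conventional course / 9-day hypofractionated course).
#' @param planning_scan_day day of the pretreatment planning scan (< 0),
#'   or `NULL` to omit pretreatment data.
#' @param followup_days follow-up scan offsets after the last fraction
#'   (default one week, two weeks, one month, and two months — without
#'   the early follow-ups a short hypofractionated course yields too few
#'   observations to admit the recruitment model at all).
#' @param noise_cv coefficient of variation of the multiplicative
#'   measurement noise (default 0.07, the middle of the 5-10% range
#'   typical of CT volumetry).
#' @param detection_limit CT detection limit, cc.
#' @param seed integer seed making the generated series reproducible.
#' @param name optional scenario label.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(group = c("L", "S"), growth, effect, V0,
                          schedule = NULL, planning_scan_day = -14,
                          followup_days = c(7, 14, 30, 60), noise_cv = 0.07,
                          detection_limit = 0.1, seed = 1, name = NULL) {
  group <- match.arg(group)
  stopifnot(inherits(growth, "growth_params"), inherits(effect, "effect_model"),
            is.numeric(V0), V0 > 0, is.numeric(noise_cv), noise_cv >= 0,
            is.numeric(detection_limit), detection_limit > 0)
  if (V0 <= detection_limit)
    stop("'V0' must exceed the detection limit")
  if (is.null(schedule))
    schedule <- make_schedule(group, if (group == "L") 46 else 9)
  if (!is.null(planning_scan_day))
    stopifnot(planning_scan_day < 0)
  structure(list(group = group, growth = growth, effect = effect, V0 = V0,
                 schedule = schedule, planning_scan_day = planning_scan_day,
                 followup_days = followup_days, noise_cv = noise_cv,
                 detection_limit = detection_limit, seed = as.integer(seed),
                 name = name),
            class = "scenario_spec")
}

#' Generate a noisy tumor-volume time course from a scenario
#'
#' Simulates the noiseless model trajectory, samples it at the planning
#' scan, every pre-fraction day, and the follow-up days, multiplies each
#' volume by lognormal noise with the requested coefficient of variation
#' (median 1, so log volumes are Gaussian around the model, matching the
#' fitting likelihood), and censors values below the detection limit to
#' the limit. Fully deterministic given the scenario seed.
#'
#' @param spec a [scenario_spec()].
#' @return A list of class `synthetic_timecourse`: `tc` (the noisy
#'   [timecourse()]), `truth` (data frame of noiseless volumes), and
#'   `spec`.
#' @export
generate_timecourse <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  days <- sort(unique(c(spec$planning_scan_day, spec$schedule$day,
                        max(spec$schedule$day) + spec$followup_days)))
  truth <- simulate_course(spec$growth, spec$effect, spec$schedule,
                           V0 = spec$V0, sample_days = days)
  set.seed(spec$seed)
  sdlog <- sqrt(log1p(spec$noise_cv^2))
  noisy <- truth$volume_cc * exp(rnorm(nrow(truth), 0, sdlog))
  cens <- noisy < spec$detection_limit
  noisy[cens] <- spec$detection_limit
  tc <- timecourse(data.frame(day = truth$day, volume_cc = noisy,
                              censored = cens),
                   spec$schedule, detection_limit = spec$detection_limit,
                   patient_id = spec$name, group = spec$group)
  structure(list(tc = tc, truth = as.data.frame(truth), spec = spec),
            class = "synthetic_timecourse")
}

#' Standard battery of response-archetype scenarios
#'
#' One scenario per response type per group in which it occurs (types A-C
#' for conventional fractionation, A-D for hypofractionation; seven in
#' all), parameterized from representative best-fit rows of the bundled
#' reference cohort ([reference_fits()]) and using that patient's course
#' calendar. Intended as the standard end-to-end regression battery: each
#' scenario records the generating model tag and the response type it is
#' expected to produce after fitting and classification.
#'
#' @param seed base seed; scenario `i` uses `seed + i`.
#' @param noise_cv measurement noise CV passed to every scenario.
#' @return Named list of seven [scenario_spec()] objects, each with extra
#'   fields `expected_type` and `source_patient`.
#' @export
archetype_suite <- function(seed = 1, noise_cv = 0.07) {
  fits <- reference_fits()
  courses <- reference_cohort()
  pick <- c(L_A = "L5", L_B = "L3", L_C = "L2",
            S_A = "S1", S_B = "S12", S_C = "S5", S_D = "S3")
  # model used to generate each archetype (resistance rows use the
  # initial-resistance variant)
  tags <- c(L_A = "MResIni", L_B = "StRec", L_C = "M",
            S_A = "St", S_B = "StRec", S_C = "M", S_D = "M")
  out <- vector("list", length(pick))
  names(out) <- names(pick)
  for (i in seq_along(pick)) {
    id <- pick[i]
    row <- fits[fits$patient_id == id & fits$rank == 1, ]
    crs <- courses[courses$patient_id == id, ]
    tag <- tags[[names(pick)[i]]]
    grp <- row$group
    sched <- make_schedule(grp, crs$days_to_finish, dose_gy = crs$dose1_gy,
                           n_fractions = crs$n1)
    g <- if (startsWith(tag, "St"))
      growth_params(Td = row$Td, GF = row$GF,
                    Tc = tc_from_tpot(row$Td, row$GF, row$Tpot),
                    gamma = if (is.na(row$gamma)) 0 else row$gamma)
    else growth_params(Td = row$Td)
    e <- effect_model(tag, K = row$K, Kp = row$Kp, Kq = row$Kq, D = row$D,
                      gamma_rec = row$gamma_rec,
                      rec_window = if (grepl("Rec", tag))
                        c(row$rec_start,
                          if (is.na(row$rec_end)) Inf else row$rec_end),
                      Rini = if (grepl("ResIni", tag)) row$Rini else 0)
    sp <- scenario_spec(grp, g, e, V0 = row$V0_cc, schedule = sched,
                        noise_cv = noise_cv, seed = seed + i,
                        name = names(pick)[i])
    sp$expected_type <- row$response_type
    sp$source_patient <- id
    out[[i]] <- sp
  }
  out
}
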