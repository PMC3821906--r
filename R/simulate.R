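#' Simulate a tumor volume time course under a treatment schedule
#'
#' Steps the seven-compartment model forward in time (default step 1 day),
#' applying treatment fractions instantaneously at their scheduled days.
#' Observations are recorded immediately *before* any fraction delivered on
#' a sampling day, matching the pre-fraction CT convention of image-guided
#' radiotherapy.
#'
#' `V0` is the volume at day 0 (treatment start). When the simulation span
#' begins earlier (a pretreatment planning scan), the initial state is
#' placed on the untreated exponential trajectory through `V0`, which the
#' discrete update reproduces exactly.
#'
#' @param g a [growth_params()] object.
#' @param e an [effect_model()], or `NULL` for untreated growth.
#' @param schedule an [rt_schedule()], or `NULL` for untreated growth.
#' @param V0 tumor volume at treatment start, cc.
#' @param sample_days integer days at which to record the volume.
#' @param t_span optional `c(start, end)` days; defaults to the range of
#'   sample and fraction days (extended to include day 0).
#' @param dt time step in days; event days must fall on the step grid.
#' @param cells_per_cc volume-to-cell conversion (default `1e9`).
#' @param compartments if `TRUE`, attach the full per-step compartment
#'   trajectory as attribute `"daily"`.
#' @return A data frame with columns `day` and `volume_cc` (sorted by day),
#'   with attributes `state` (final `population_state`), `killed` and
#'   `lost` (cumulative cells sent to, and definitively lost from, the
#'   dying pipeline), and optionally `daily`.
#' @examples
#' g <- growth_params(Td = 250)
#' e <- effect_model("M", K = 8, D = 0.999)
#' simulate_course(g, e, rt_schedule(c(0, 2, 4, 7, 9), 10),
#'                 V0 = 2, sample_days = c(0, 5, 9, 30))
#' @export
simulate_course <- function(g, e = NULL, schedule = NULL, V0,
                            sample_days, t_span = NULL, dt = 1,
                            cells_per_cc = 1e9, compartments = FALSE) {
  stopifnot(inherits(g, "growth_params"), is.numeric(V0), length(V0) == 1,
            V0 > 0, is.numeric(sample_days), length(sample_days) >= 1)
  if (!is.null(e)) stopifnot(inherits(e, "effect_model"))
  if (!is.null(schedule)) stopifnot(inherits(schedule, "rt_schedule"))
  if (is.null(e) || is.null(schedule)) { e <- NULL; schedule <- NULL }
  sample_days <- sort(unique(round(sample_days)))
  fx_days <- if (is.null(schedule)) integer() else schedule$day
  if (is.null(t_span))
    t_span <- range(c(sample_days, fx_days, 0))
  t0 <- t_span[1]; t1 <- t_span[2]
  if (t0 > min(sample_days) || t1 < max(sample_days))
    stop("sample days outside simulation span")
  if (length(fx_days) && (min(fx_days) < t0 || max(fx_days) > t1))
    stop("treatment schedule outside simulation span")
  n_steps <- (t1 - t0) / dt
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("'dt' must divide the simulation span")
  n_steps <- as.integer(round(n_steps))
  to_idx <- function(day) {
    k <- (day - t0) / dt
    if (any(abs(k - round(k)) > 1e-9))
      stop("event days must fall on the dt step grid")
    as.integer(round(k))
  }

  d <- derive_rates(g, dt)
  N0 <- V0 * cells_per_cc * 2^(t0 / g$Td)
  Rini <- if (is.null(e)) 0 else e$Rini
  s0 <- init_state(N0, g, Rini = Rini, t = t0)

  if (is.null(e)) {
    kp <- 0; kq <- 0; rind <- 0; D <- 0
    grec <- 0; rs <- 1; re <- 0  # empty window
  } else {
    kp <- e$Kp / 100; kq <- e$Kq / 100; rind <- e$Rind
    D <- if (is.na(e$D)) 0 else e$D
    if (!is.null(e$rec_window)) {
      first_fx <- min(fx_days)
      grec <- e$gamma_rec
      rs <- first_fx + e$rec_window[1]
      re <- if (is.finite(e$rec_window[2])) first_fx + e$rec_window[2] else t1
    } else {
      grec <- 0; rs <- 1; re <- 0
    }
  }

  res <- .sim_kernel(unclass(s0)[1:7], t0, dt, n_steps,
                     to_idx(sample_days), to_idx(fx_days),
                     d$theta, d$u, d$mu_q, g$gamma, grec, rs, re,
                     d$dt_prime, D, kp, kq, rind, compartments)
  if (!res$ok)
    stop("negative compartment during simulation: inconsistent parameters")
  out <- data.frame(day = sample_days, volume_cc = res$volumes / cells_per_cc)
  attr(out, "state") <- as_state(res$state, t = t1)
  attr(out, "killed") <- res$killed
  attr(out, "lost") <- res$lost
  if (compartments) {
    daily <- res$daily
    colnames(daily) <- c("Np", "Nq", "Nrp", "Nrq", "Nd1", "Nd2", "Nd3")
    attr(out, "daily") <- cbind(day = seq(t0, t1, by = dt), daily)
  }
  out
}
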