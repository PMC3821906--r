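#' Tumor growth parameters
#'
#' Bundle the four independent proliferation parameters of the cell-kinetics
#' model: the population doubling time `Td`, the growth fraction `GF`
#' (fraction of cells actively cycling), the mean cell-cycle duration `Tc`,
#' and the rate `gamma` at which quiescent (G0) cells re-enter the cycle.
#' All dependent rates (see [derive_rates()]) follow from these four.
#'
#' Quiescent cells are, by definition, cells that rarely resume cycling: the
#' pretreatment re-entry rate is restricted to at most 0.01/day (1% of
#' quiescent cells per day). Elevated re-entry during a post-treatment
#' recruitment window is a property of the treatment model, not of the
#' baseline growth parameters (see [effect_model()]).
#'
#' @param Td doubling time of the untreated population, days (> 0).
#' @param GF growth fraction, in (0, 1].
#' @param Tc mean cell-cycle duration, days (> 0).
#' @param gamma quiescent-to-cycling re-entry rate, per day, in \[0, 0.01\].
#' @return An object of class `growth_params`.
#' @examples
#' growth_params(Td = 100, GF = 0.2, Tc = 3)
#' @export
growth_params <- function(Td, GF = 1, Tc = Td, gamma = 0) {
  stopifnot(is.numeric(Td), length(Td) == 1, is.finite(Td),
            is.numeric(GF), length(GF) == 1, is.finite(GF),
            is.numeric(Tc), length(Tc) == 1, is.finite(Tc),
            is.numeric(gamma), length(gamma) == 1, is.finite(gamma))
  if (Td <= 0) stop("'Td' must be > 0")
  if (GF <= 0 || GF > 1) stop("'GF' must be in (0, 1]")
  if (Tc <= 0) stop("'Tc' must be > 0")
  if (gamma < 0) stop("'gamma' must be >= 0")
  if (gamma > 0.01)
    stop("pretreatment 'gamma' must be <= 0.01 (quiescent cells re-enter ",
         "the cycle at no more than 1% per day); use a recruitment model ",
         "for transiently higher rates")
  structure(list(Td = Td, GF = GF, Tc = Tc, gamma = gamma),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Tumor growth parameters\n")
  cat(sprintf("  Td = %g d, GF = %g, Tc = %g d, gamma = %g /d\n",
              x$Td, x$GF, x$Tc, x$gamma))
  invisible(x)
}

#' Dependent kinetic rates of the growth model
#'
#' Compute the rates that drive the discrete-time update from the four
#' independent growth parameters and the step length `dt`:
#'
#' * `u`, the rate at which cycling cells complete the cycle:
#'   `u = log(2) / (Td * (exp(log(2) * Tc/Td) - 1))`.
#' * `dt_prime`, the effective step length
#'   `(exp(log(2) * dt/Td) - 1) / (log(2)/Td)` that makes the discrete
#'   update reproduce continuous exponential growth exactly at step `dt`
#'   (`dt_prime -> dt` as `dt/Td -> 0`).
#' * `Tpot`, the potential doubling time
#'   `Td * (exp(log(2) * Tc/Td) - 1) / GF`: the doubling time the
#'   population would show with no quiescent cell loss. Equals `Td` when
#'   `GF = 1` and `Tc = Td`, and is approximately `log(2) * Tc / GF` when
#'   `Tc << Td`.
#' * `mu_q`, the quiescent cell-loss rate
#'   `log(2) * (1/Tpot - 1/Td) / (1 - GF)` (0 when `GF = 1`).
#' * `theta`, the fraction of newborn cells that directly re-enter the
#'   cycle rather than becoming quiescent:
#'   `exp(x)/2 + gamma * (exp(x)/2 - 1) / (log(2)/Td + mu_q)` with
#'   `x = log(2) * Tc/Td`. This is exactly the value for which the
#'   discrete dynamics admit balanced exponential growth at rate
#'   `log(2)/Td` with a constant cycling fraction `GF`.
#'
#' Parameter combinations implying `Tpot > Td` (negative cell loss) or
#' `theta` outside \[0, 1\] are rejected as kinetically inconsistent;
#' `theta` values outside by less than 1e-9 are clamped with a warning.
#'
#' @param g a [growth_params()] object.
#' @param dt step length in days (default 1).
#' @return An object of class `derived_growth` with fields `u`, `dt_prime`,
#'   `Tpot`, `mu_q`, `theta` (plus `dt` and the input parameters).
#' @examples
#' derive_rates(growth_params(Td = 100, GF = 0.2, Tc = 3))
#' @export
derive_rates <- function(g, dt = 1) {
  stopifnot(inherits(g, "growth_params"), is.numeric(dt), length(dt) == 1,
            is.finite(dt), dt > 0)
  ln2 <- log(2)
  x <- ln2 * g$Tc / g$Td
  ex <- exp(x)
  u <- ln2 / (g$Td * (ex - 1))
  dt_prime <- (exp(ln2 * dt / g$Td) - 1) / (ln2 / g$Td)
  Tpot <- g$Td * (ex - 1) / g$GF
  if (g$GF == 1) {
    if (abs(Tpot - g$Td) > 1e-9 * g$Td)
      stop("GF = 1 requires Tc = Td (all cells cycling, no quiescent loss); ",
           "mu_q is ill-defined otherwise")
    mu_q <- 0
  } else {
    mu_q <- ln2 * (1 / Tpot - 1 / g$Td) / (1 - g$GF)
    if (mu_q < -1e-12)
      stop("inconsistent growth parameters: Tpot (", signif(Tpot, 4),
           " d) exceeds Td (", g$Td, " d), implying negative cell loss")
    mu_q <- max(mu_q, 0)
  }
  theta <- ex / 2 + g$gamma * (ex / 2 - 1) / (ln2 / g$Td + mu_q)
  if (theta < 0 || theta > 1) {
    if (theta > -1e-9 && theta < 1 + 1e-9) {
      warning("theta clamped into [0, 1] (numerical round-off)")
      theta <- min(max(theta, 0), 1)
    } else {
      stop("inconsistent growth parameters: theta = ", signif(theta, 4),
           " outside [0, 1]")
    }
  }
  structure(list(u = u, dt_prime = dt_prime, Tpot = Tpot, mu_q = mu_q,
                 theta = theta, dt = dt, params = g),
            class = "derived_growth")
}

#' @export
print.derived_growth <- function(x, ...) {
  cat("Derived growth rates (dt =", x$dt, "d)\n")
  cat(sprintf("  u = %.4g /d, dt' = %.6g d, Tpot = %.4g d, mu_q = %.4g /d, theta = %.4g\n",
              x$u, x$dt_prime, x$Tpot, x$mu_q, x$theta))
  invisible(x)
}

#' Cell-cycle duration implied by a potential doubling time
#'
#' Invert the `Tpot` relation of [derive_rates()] for `Tc`, given `Td` and
#' `GF`: `Tc = Td * log(1 + GF * Tpot / Td) / log(2)`. Useful when a fit or
#' a literature source reports `Tpot` rather than `Tc`.
#'
#' @param Td doubling time, days.
#' @param GF growth fraction, in (0, 1].
#' @param Tpot potential doubling time, days.
#' @return `Tc` in days.
#' @examples
#' tc_from_tpot(Td = 200, GF = 0.15, Tpot = 13.9)
#' @export
tc_from_tpot <- function(Td, GF, Tpot) {
  stopifnot(Td > 0, GF > 0, GF <= 1, Tpot > 0)
  Td * log1p(GF * Tpot / Td) / log(2)
}

#' Mean duration of the three-stage dying process
#'
#' Killed cells are not removed instantly: they traverse three dying stages,
#' advancing one stage per day with probability `D`. The time to definitive
#' loss is therefore a sum of three geometric waits (the discrete Erlang
#' analogue) with mean `3/D` days: 4 days at `D = 0.75`, 6 at `D = 0.5`,
#' 15 at `D = 0.2`, and exactly 3 at `D = 1`.
#'
#' @param D per-day stage-advance probability, in (0, 1].
#' @return Mean days from entering stage I to loss.
#' @examples
#' mean_dying_time(0.75)
#' @export
mean_dying_time <- function(D) {
  stopifnot(is.numeric(D), all(is.finite(D)))
  if (any(D <= 0) || any(D > 1)) stop("'D' must be in (0, 1]")
  3 / D
}
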