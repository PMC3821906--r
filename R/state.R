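#' Population state of the seven-compartment model
#'
#' The model tracks sensitive cycling (`Np`) and quiescent (`Nq`) cells,
#' their radioresistant counterparts (`Nrp`, `Nrq`), and three dying stages
#' (`Nd1`-`Nd3`). Counts are continuous nonnegative expected values, not
#' stochastic realizations.
#'
#' @param N0 total cell count at time `t` (> 0).
#' @param g a [growth_params()] object supplying the growth fraction used to
#'   split cells between cycling and quiescent compartments.
#' @param Rini fraction of cells resistant at time `t`, in \[0, 1).
#' @param t time in days attached to the state (default 0).
#' @return An object of class `population_state`: a named numeric state
#'   vector with a time attribute.
#' @examples
#' init_state(1000, growth_params(Td = 100, GF = 0.2, Tc = 3))
#' @export
init_state <- function(N0, g, Rini = 0, t = 0) {
  stopifnot(is.numeric(N0), length(N0) == 1, is.finite(N0),
            inherits(g, "growth_params"),
            is.numeric(Rini), length(Rini) == 1, Rini >= 0, Rini < 1)
  if (N0 <= 0) stop("'N0' must be > 0: cannot initialize an empty tumor")
  s <- c(Np = N0 * g$GF * (1 - Rini),
         Nq = N0 * (1 - g$GF) * (1 - Rini),
         Nrp = N0 * g$GF * Rini,
         Nrq = N0 * (1 - g$GF) * Rini,
         Nd1 = 0, Nd2 = 0, Nd3 = 0)
  structure(s, t = t, class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat("Population state at day", attr(x, "t"), "\n")
  print(unclass(x)[1:7])
  cat("  total:", format(total_cells(x)), "cells\n")
  invisible(x)
}

as_state <- function(x, t = 0) {
  # internal: accept a bare 7-vector in compartment order
  if (inherits(x, "population_state")) return(x)
  stopifnot(is.numeric(x), length(x) == 7)
  structure(setNames(x, c("Np", "Nq", "Nrp", "Nrq", "Nd1", "Nd2", "Nd3")),
            t = t, class = "population_state")
}

#' Advance the population state by one time step
#'
#' Pure-R reference implementation of the daily update. Cycling cells
#' complete the cycle at rate `u`; each division produces two newborns of
#' which a fraction `theta` stays in cycle and `1 - theta` becomes
#' quiescent; quiescent cells re-enter the cycle at rate `gamma` and are
#' lost at rate `mu_q`; all flows are scaled by the effective step length
#' `dt_prime`, which makes untreated balanced growth exactly exponential
#' with doubling time `Td` regardless of the step size. Resistant cells
#' follow the same equations. Dying cells advance one stage with per-day
#' probability `D`; exits from stage III are definitively lost.
#'
#' The compiled simulation path ([simulate_course()]) performs the same
#' update; this function is the single-step reference used for inspection
#' and cross-checking.
#'
#' @param s a `population_state` (or bare 7-vector in compartment order).
#' @param d a [derive_rates()] object.
#' @param D dying-stage advance probability per day, in \[0, 1\].
#' @param gamma overrides the quiescent re-entry rate for this step (e.g.
#'   the recruitment rate inside a recruitment window); default: the rate
#'   stored in `d`.
#' @return The advanced `population_state`, with attribute `lost` holding
#'   the cells definitively lost from stage III during the step.
#' @export
step_state <- function(s, d, D = 0, gamma = NULL) {
  stopifnot(inherits(d, "derived_growth"), is.numeric(D), length(D) == 1,
            D >= 0, D <= 1)
  s <- as_state(s, t = if (inherits(s, "population_state")) attr(s, "t") else 0)
  g <- if (is.null(gamma)) d$params$gamma else gamma
  dtp <- d$dt_prime
  u <- d$u; theta <- d$theta; mu_q <- d$mu_q

  rec_s <- g * s[["Nq"]] * dtp; die_s <- mu_q * s[["Nq"]] * dtp
  rec_r <- g * s[["Nrq"]] * dtp; die_r <- mu_q * s[["Nrq"]] * dtp
  if ((g + mu_q) * dtp > 1) {
    # outflow would overdrain the quiescent pool within one step: rescale
    rec_s <- s[["Nq"]] * g / (g + mu_q); die_s <- s[["Nq"]] * mu_q / (g + mu_q)
    rec_r <- s[["Nrq"]] * g / (g + mu_q); die_r <- s[["Nrq"]] * mu_q / (g + mu_q)
  }

  Np <- s[["Np"]] + theta * 2 * u * s[["Np"]] * dtp - u * s[["Np"]] * dtp + rec_s
  Nq <- s[["Nq"]] + (1 - theta) * 2 * u * s[["Np"]] * dtp - rec_s - die_s
  Nrp <- s[["Nrp"]] + theta * 2 * u * s[["Nrp"]] * dtp - u * s[["Nrp"]] * dtp + rec_r
  Nrq <- s[["Nrq"]] + (1 - theta) * 2 * u * s[["Nrp"]] * dtp - rec_r - die_r

  Nd1 <- (1 - D) * s[["Nd1"]]
  Nd2 <- (1 - D) * s[["Nd2"]] + D * s[["Nd1"]]
  Nd3 <- (1 - D) * s[["Nd3"]] + D * s[["Nd2"]]
  lost <- D * s[["Nd3"]]

  out <- c(Np = Np, Nq = Nq, Nrp = Nrp, Nrq = Nrq,
           Nd1 = Nd1, Nd2 = Nd2, Nd3 = Nd3)
  if (any(out < 0)) {
    if (all(out > -1e-9)) out <- pmax(out, 0)
    else stop("negative compartment after step: inconsistent parameters")
  }
  structure(out, t = attr(s, "t") + d$dt, lost = lost,
            class = "population_state")
}

#' Total cell count and volume of a population state
#'
#' The total is the sum of all seven compartments (live sensitive, live
#' resistant, and dying cells all contribute to the measured tumor mass).
#' Volume assumes a fixed packing density, by default `1e9` cells per cc;
#' results are invariant to this constant up to overall scale.
#'
#' @param s a `population_state` (or bare 7-vector).
#' @return `total_cells`: total cell count. `state_volume`: volume in cc.
#' @examples
#' s <- init_state(3.2e9, growth_params(Td = 25, GF = 0.06, Tc = 1))
#' total_cells(s)
#' state_volume(s)
#' @export
total_cells <- function(s) {
  s <- as_state(s)
  sum(unclass(s)[1:7])
}

#' @rdname total_cells
#' @param cells_per_cc packing density, cells per cm^3 (default `1e9`).
#' @export
state_volume <- function(s, cells_per_cc = 1e9) {
  stopifnot(cells_per_cc > 0)
  total_cells(s) / cells_per_cc
}
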