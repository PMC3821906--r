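#' Gaussian log-likelihood on log volumes
#'
#' The measurement model is multiplicative: log observed volumes are
#' Gaussian around log predicted volumes with standard deviation `sigma`
#' (a free scale parameter, profiled out during fitting). By default,
#' censored observations (below the CT detection limit, recorded at the
#' limit) contribute as exact values at the limit — the conservative
#' convention, which if anything underestimates the treatment effect.
#' Setting `censored = "integrate"` instead integrates the Gaussian tail
#' below the limit.
#'
#' @param tc a [timecourse()].
#' @param predicted model volumes at the observation days, cc (> 0).
#' @param sigma standard deviation of log-volume errors (> 0).
#' @param censored `"exact"` (default) or `"integrate"`.
#' @return The log-likelihood (a scalar).
#' @export
log_likelihood <- function(tc, predicted, sigma,
                           censored = c("exact", "integrate")) {
  censored <- match.arg(censored)
  stopifnot(inherits(tc, "timecourse"), sigma > 0,
            length(predicted) == nrow(tc$observations))
  if (any(!is.finite(predicted)) || any(predicted <= 0))
    stop("nonpositive predicted volume: model breakdown (e.g. total kill)")
  obs <- tc$observations
  ll <- dnorm(log(obs$volume_cc), log(predicted), sigma, log = TRUE)
  if (censored == "integrate" && any(obs$censored)) {
    i <- which(obs$censored)
    ll[i] <- stats::pnorm(log(obs$volume_cc[i]), log(predicted[i]), sigma,
                          log.p = TRUE)
  }
  sum(ll)
}

#' Average percent difference between data and fit
#'
#' The goodness-of-fit statistic reported for each fitted patient: the
#' arithmetic mean over observations of `100 * |V_obs - V_pred| / V_obs`.
#'
#' @param observed observed volumes (or a [timecourse()]).
#' @param predicted fitted volumes at the same days.
#' @return Mean percent difference (>= 0).
#' @examples
#' mean_delta_percent(c(10, 20), c(11, 22))  # 10
#' @export
mean_delta_percent <- function(observed, predicted) {
  if (inherits(observed, "timecourse"))
    observed <- observed$observations$volume_cc
  stopifnot(length(observed) == length(predicted), all(observed > 0))
  mean(100 * abs(observed - predicted) / observed)
}
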