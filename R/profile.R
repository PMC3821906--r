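#' Profile-likelihood confidence interval for one fitted parameter
#'
#' The interval endpoints are found by moving the parameter away from its
#' estimate, re-maximizing the likelihood over all other free parameters at
#' each value, until the profile log-likelihood has dropped by
#' `qchisq(level, 1) / 2` (about 1.9207 at the default 95% level); the
#' crossing is then located by root finding. Endpoints that run into the
#' parameter bounds are truncated there and flagged, which also covers
#' one-sided intervals for estimates sitting on a bound and effectively
#' unidentifiable parameters (interval spanning the whole box).
#'
#' @param fit an [fit_model()] result.
#' @param param name of a free parameter of the fit.
#' @param level confidence level (default 0.95).
#' @param tol relative tolerance on the endpoint location.
#' @return Numeric `c(low, high)` with logical attributes `truncated_low`
#'   and `truncated_high`.
#' @export
profile_ci <- function(fit, param, level = 0.95, tol = 5e-3) {
  stopifnot(inherits(fit, "rt_fit"), length(param) == 1,
            param %in% fit$free)
  if (!fit$converged)
    warning("profiling a non-converged fit; interval may be unreliable")
  drop <- qchisq(level, 1) / 2
  target <- fit$logL - drop
  free2 <- setdiff(fit$free, param)
  b <- fit$cfg$bounds[[param]]
  est <- fit$estimates[[param]]
  lo2 <- vapply(free2, function(nm) fit$cfg$bounds[[nm]][1], 0)
  hi2 <- vapply(free2, function(nm) fit$cfg$bounds[[nm]][2], 0)
  warm <- fit$estimates[free2]

  pl <- function(value) {
    fixed2 <- c(fit$fixed, setNames(value, param))
    obj <- make_objective(fit$tc, fit$model, free2, fixed2, fit$cfg,
                          fit$rec_window)
    if (length(free2) == 0) return(-obj(setNames(numeric(0), character(0))))
    run <- .optimize_from(obj, matrix(warm, nrow = 1,
                                      dimnames = list(NULL, free2)),
                          free2, lo2, hi2, maxit = 100)
    warm <<- run$par  # track the profile path for warm starts
    -run$value
  }

  log_scale <- param %in% .log_scale
  span <- if (log_scale) log(b[2] / b[1]) else b[2] - b[1]

  one_side <- function(dir) {
    warm <<- fit$estimates[free2]
    h <- span / 50
    prev <- est
    repeat {
      v <- if (log_scale) est * exp(dir * h) else est + dir * h
      hit_bound <- FALSE
      if (v <= b[1]) { v <- b[1]; hit_bound <- TRUE }
      if (v >= b[2]) { v <- b[2]; hit_bound <- TRUE }
      ll <- pl(v)
      if (ll < target) {
        root <- uniroot(function(z) pl(z) - target, sort(c(prev, v)),
                        tol = tol * max(abs(est), span / 100),
                        maxiter = 30, extendInt = "no")$root
        return(list(end = root, truncated = FALSE))
      }
      if (hit_bound) return(list(end = v, truncated = TRUE))
      prev <- v
      h <- 2 * h
    }
  }

  low <- if (est <= b[1] + 1e-12 * max(1, abs(b[1])))
    list(end = b[1], truncated = TRUE) else one_side(-1)
  high <- if (est >= b[2] - 1e-12 * max(1, abs(b[2])))
    list(end = b[2], truncated = TRUE) else one_side(1)
  structure(c(low = low$end, high = high$end),
            truncated_low = low$truncated, truncated_high = high$truncated)
}

#' Attach profile intervals for several parameters to a fit
#'
#' @param fit an [fit_model()] result.
#' @param params parameter names (default: all free parameters).
#' @param level confidence level.
#' @return The fit with `$ci` set to a matrix with columns `low`, `high`
#'   and attribute `truncated` (logical matrix).
#' @export
profile_cis <- function(fit, params = fit$free, level = 0.95) {
  ci <- matrix(NA_real_, length(params), 2,
               dimnames = list(params, c("low", "high")))
  trunc <- matrix(FALSE, length(params), 2,
                  dimnames = list(params, c("low", "high")))
  for (p in params) {
    iv <- profile_ci(fit, p, level = level)
    ci[p, ] <- iv
    trunc[p, ] <- c(attr(iv, "truncated_low"), attr(iv, "truncated_high"))
  }
  attr(ci, "truncated") <- trunc
  fit$ci <- ci
  fit
}
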