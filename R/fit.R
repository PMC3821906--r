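#' Fitting configuration
#'
#' Bounds, fixed parameters, and optimizer settings for maximum-likelihood
#' fitting. Default bounds follow the ranges reported for non-small cell
#' lung cancer kinetics: doubling times from tens of days to about 1000,
#' growth fractions around 0.2, potential doubling times of a few days to a
#' few weeks (expressed here through the cell-cycle duration `Tc`).
#'
#' @param bounds named list of `c(lo, hi)` pairs overriding the defaults
#'   (parameters: `V0`, `Td`, `GF`, `Tc`, `gamma`, `K`, `Kp`, `Kq`, `D`,
#'   `gamma_rec`, `Rini`, `Rind`).
#' @param fixed named list of fixed parameter values; by default `gamma` is
#'   fixed at 0 (higher baseline re-entry rates do not improve fits and the
#'   data cannot identify them).
#' @param n_starts number of multistart optimizations (Latin-hypercube
#'   draws within bounds plus one data-informed start).
#' @param seed seed for the multistart draws; recorded in the fit.
#' @param dt simulation step, days.
#' @param td_fallback the two fixed doubling times fitted when no
#'   pretreatment observation allows `Td` to be estimated.
#' @param rec_window default recruitment window (days relative to treatment
#'   start) for Rec models.
#' @param rec_window_grid candidate windows scanned during model selection:
#'   an early burst (days 1-3), a longer early window (1-13), and delayed
#'   recruitment from the 3rd or 4th week.
#' @param alpha significance level of the likelihood-ratio ladder (and the
#'   implied 95% profile intervals).
#' @param cells_per_cc volume-to-cell conversion.
#' @param censored_likelihood if `TRUE`, integrate the likelihood below the
#'   detection limit for censored points instead of treating them as exact.
#' @param maxit optimizer iteration cap per start.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(bounds = list(), fixed = list(gamma = 0),
                       n_starts = 20, seed = 0, dt = 1,
                       td_fallback = c(25, 150),
                       rec_window = c(1, 3),
                       rec_window_grid = list(c(1, 3), c(1, 13),
                                              c(15, Inf), c(22, Inf)),
                       alpha = 0.05, cells_per_cc = 1e9,
                       censored_likelihood = FALSE, maxit = 200) {
  default_bounds <- list(
    V0 = c(0.01, 1000), Td = c(10, 1000), GF = c(0.01, 0.95),
    Tc = c(0.5, 15), gamma = c(0, 0.01),
    K = c(0, 100), Kp = c(0, 100), Kq = c(0, 100), D = c(0.01, 1),
    gamma_rec = c(0.011, 1), Rini = c(0, 0.95), Rind = c(0, 0.3))
  b <- utils::modifyList(default_bounds, bounds)
  for (nm in names(b)) {
    if (length(b[[nm]]) != 2 || any(!is.finite(b[[nm]])) ||
        b[[nm]][1] >= b[[nm]][2])
      stop("bound for '", nm, "' must be a finite ordered pair")
  }
  structure(list(bounds = b, fixed = fixed, n_starts = n_starts,
                 seed = seed, dt = dt, td_fallback = td_fallback,
                 rec_window = rec_window, rec_window_grid = rec_window_grid,
                 alpha = alpha, cells_per_cc = cells_per_cc,
                 censored_likelihood = censored_likelihood, maxit = maxit),
            class = "fit_config")
}

# parameters optimized on the log scale
.log_scale <- c("V0", "Td", "Tc")

# named-vector lookup with default for absent entries
getp <- function(p, nm, default = NA_real_) {
  if (nm %in% names(p)) p[[nm]] else default
}

.transform <- function(p, names) ifelse(names %in% .log_scale, log(p), p)
.untransform <- function(p, names) ifelse(names %in% .log_scale, exp(p), p)

# Fast negative profiled log-likelihood closure for one model/data pairing.
# 'free' names the estimated parameters; 'fixed_vals' everything else.
# Returns a function of the natural-scale free-parameter vector.
make_objective <- function(tc, tag, free, fixed_vals, cfg,
                           rec_window = NULL, return_pred = FALSE) {
  obs <- tc$observations
  fam <- if (startsWith(tag, "St")) "St" else "M"
  has_rec <- grepl("Rec", tag)
  fx_days <- tc$schedule$day
  days <- obs$day
  t0 <- min(c(days, fx_days, 0L))
  t1 <- max(c(days, fx_days))
  dt <- cfg$dt
  n_steps <- as.integer(round((t1 - t0) / dt))
  sample_idx <- as.integer(round((days - t0) / dt))
  fx_idx <- as.integer(round((fx_days - t0) / dt))
  log_obs <- log(obs$volume_cc)
  n <- length(log_obs)
  cpc <- cfg$cells_per_cc
  ln2 <- log(2)
  cens <- which(obs$censored)
  use_cens <- cfg$censored_likelihood && length(cens) > 0
  if (has_rec && is.null(rec_window)) rec_window <- cfg$rec_window
  first_fx <- min(fx_days)

  function(par) {
    p <- c(par, fixed_vals)
    Td <- p[["Td"]]
    GF <- getp(p, "GF", 1)
    Tc <- getp(p, "Tc", Td)
    gamma <- getp(p, "gamma", 0)
    V0 <- p[["V0"]]

    x <- ln2 * Tc / Td
    ex <- exp(x)
    Tpot <- Td * (ex - 1) / GF
    # smooth penalty outside the kinetically consistent region
    viol <- max(0, Tpot / Td - 1)
    if (GF < 1) {
      mu_q <- ln2 * (1 / Tpot - 1 / Td) / (1 - GF)
      if (mu_q < 0) mu_q <- 0
    } else mu_q <- 0
    theta <- ex / 2 + gamma * (ex / 2 - 1) / (ln2 / Td + mu_q)
    viol <- viol + max(0, theta - 1) + max(0, -theta)
    if (viol > 0) return(1e6 * (1 + viol)^2)
    u <- ln2 / (Td * (ex - 1))
    dtp <- (exp(ln2 * dt / Td) - 1) / (ln2 / Td)

    if (fam == "M") { kp <- p[["K"]] / 100; kq <- kp }
    else { kp <- p[["Kp"]] / 100; kq <- p[["Kq"]] / 100 }
    D <- getp(p, "D", 0)
    rind <- getp(p, "Rind", 0)
    rini <- getp(p, "Rini", 0)
    if (has_rec) {
      grec <- p[["gamma_rec"]]
      rs <- first_fx + rec_window[1]
      re <- if (is.finite(rec_window[2])) first_fx + rec_window[2] else t1
    } else { grec <- 0; rs <- 1; re <- 0 }

    N0 <- V0 * cpc * 2^(t0 / Td)
    s0 <- c(N0 * GF * (1 - rini), N0 * (1 - GF) * (1 - rini),
            N0 * GF * rini, N0 * (1 - GF) * rini, 0, 0, 0)
    res <- .sim_kernel(s0, t0, dt, n_steps, sample_idx, fx_idx,
                       theta, u, mu_q, gamma, grec, rs, re,
                       dtp, D, kp, kq, rind, FALSE)
    if (!res$ok) return(1e8)
    pred <- res$volumes / cpc
    if (any(pred <= 0) || any(!is.finite(pred))) return(1e8)
    if (return_pred) return(pred)
    r <- log_obs - log(pred)
    if (use_cens) {
      # censored points: leave them out of the profiled scale, then add
      # their tail mass at that scale
      r2 <- r[-cens]
      sig2 <- max(mean(r2^2), 1e-16)
      nll <- 0.5 * length(r2) * (log(2 * pi * sig2) + 1) -
        sum(stats::pnorm(r[cens] / sqrt(sig2), log.p = TRUE))
    } else {
      sig2 <- max(mean(r^2), 1e-16)
      nll <- 0.5 * n * (log(2 * pi * sig2) + 1)
    }
    nll
  }
}

# Data-informed starts for the multistart: a central start plus a small
# grid over the qualitatively distinct treatment-response regimes
# (low/high kill x slow/fast dying, and for St fits low/high quiescent
# kill), which the likelihood surface separates into distinct basins.
heuristic_starts <- function(tc, free, cfg) {
  obs <- tc$observations
  v0 <- obs$volume_cc[which.min(abs(obs$day))]
  b <- cfg$bounds
  clamp <- function(v, nm) pmin(pmax(v, b[[nm]][1]), b[[nm]][2])
  base <- c(V0 = clamp(v0, "V0"), Td = 100, GF = 0.2, Tc = 2.5,
            gamma = 0.005, K = 20, Kp = 50, Kq = 5, D = 0.5,
            gamma_rec = 0.2, Rini = 0.2, Rind = 0.05)
  grid <- if ("Kp" %in% free)
    expand.grid(Kp = c(20, 90), Kq = c(1, 20), D = c(0.2, 0.9),
                GF = c(0.1, 0.5))
  else if ("K" %in% free)
    expand.grid(K = c(5, 30, 80), D = c(0.2, 0.9))
  else NULL
  starts <- matrix(base[free], nrow = 1, dimnames = list(NULL, free))
  if (!is.null(grid)) {
    extra <- matrix(rep(base[free], each = nrow(grid)), nrow = nrow(grid),
                    dimnames = list(NULL, free))
    for (nm in intersect(names(grid), free)) extra[, nm] <- grid[[nm]]
    starts <- rbind(starts, extra)
  }
  starts
}

# Clamp Tc so the implied Tpot stays below Td (keeps starts feasible).
feasible_tc <- function(Tc, Td, GF) {
  pmin(Tc, 0.95 * Td * log1p(0.9 * GF) / log(2))
}

#' Maximum-likelihood fit of a treatment-efficacy model
#'
#' Fits the chosen model variant to a tumor volume time course by
#' constrained maximization of the Gaussian log-likelihood of log volumes
#' (residual scale profiled out analytically). The optimizer is L-BFGS-B
#' from multiple starts: one data-informed start plus Latin-hypercube draws
#' within the parameter bounds, so results are deterministic given the
#' configuration seed.
#'
#' When the time course has no pretreatment observation the doubling time
#' cannot be estimated; the model is then fitted once at each fallback
#' value (default 25 and 150 days), the better fit is returned, and the
#' other is attached as `$alternate_td`.
#'
#' @param tc a [timecourse()].
#' @param model a model tag (see [effect_model()]) or an `effect_model`
#'   used as a template (its tag and recruitment window are taken).
#' @param cfg a [fit_config()].
#' @param Td_fixed fix the doubling time at this value (days) instead of
#'   estimating it.
#' @param gamma_free estimate the baseline quiescent re-entry rate instead
#'   of fixing it.
#' @param rec_window recruitment window for Rec models, days relative to
#'   treatment start (default: `cfg$rec_window`).
#' @param extra_starts optional extra multistart points: a named numeric
#'   vector or a list of them; entries for free parameters override the
#'   central start (used by [select_model()] to seed each larger model
#'   from the nested model's solution).
#' @return An object of class `rt_fit` with elements `model`, `estimates`
#'   (named vector, natural scale, including the derived `Tpot` for
#'   St-family fits), `sigma`, `logL`, `delta_percent`, `n_par`, `n_obs`,
#'   `converged`, `fitted` (data frame `day`, `observed`, `predicted`),
#'   `ci` (filled by [profile_ci()]), and the inputs needed to reproduce
#'   the fit.
#' @export
fit_model <- function(tc, model = "M", cfg = fit_config(), Td_fixed = NULL,
                      gamma_free = FALSE, rec_window = NULL,
                      extra_starts = NULL) {
  stopifnot(inherits(tc, "timecourse"), inherits(cfg, "fit_config"))
  tag <- if (inherits(model, "effect_model")) model$tag else model
  if (inherits(model, "effect_model") && is.null(rec_window))
    rec_window <- model$rec_window
  if (grepl("Rec", tag) && is.null(rec_window)) rec_window <- cfg$rec_window

  if (!tc$pretreatment_available && is.null(Td_fixed)) {
    fits <- lapply(cfg$td_fallback, function(td)
      fit_model(tc, tag, cfg, Td_fixed = td, gamma_free = gamma_free,
                rec_window = rec_window, extra_starts = extra_starts))
    best <- which.max(vapply(fits, function(f) f$logL, 0))
    out <- fits[[best]]
    out$alternate_td <- fits[-best][[1]]
    return(out)
  }

  pretreat <- is.null(Td_fixed)
  free <- free_params_for(tag, pretreatment = pretreat,
                          gamma_free = gamma_free)
  n <- nrow(tc$observations)
  if (length(free) >= n)
    stop("underdetermined: ", length(free), " free parameters for ", n,
         " observations")
  fixed_vals <- c(if (!pretreat) c(Td = Td_fixed),
                  if (!gamma_free) c(gamma = cfg$fixed$gamma %||% 0))
  obj <- make_objective(tc, tag, free, fixed_vals, cfg, rec_window)

  p <- length(free)
  lo <- vapply(free, function(nm) cfg$bounds[[nm]][1], 0)
  hi <- vapply(free, function(nm) cfg$bounds[[nm]][2], 0)
  set.seed(cfg$seed)
  starts <- heuristic_starts(tc, free, cfg)
  if (!is.null(extra_starts)) {
    if (!is.list(extra_starts)) extra_starts <- list(extra_starts)
    for (es in extra_starts) {
      row <- starts[1, ]
      ok <- intersect(names(es), free)
      row[ok] <- es[ok]
      starts <- rbind(starts, row)
    }
  }
  if (cfg$n_starts > 1) {
    lh <- lhs::randomLHS(cfg$n_starts - 1, p)
    # log-scale parameters drawn log-uniformly
    sc <- t(apply(lh, 1, function(q) {
      v <- ifelse(free %in% .log_scale,
                  exp(log(pmax(lo, 1e-12)) + q * (log(hi) - log(pmax(lo, 1e-12)))),
                  lo + q * (hi - lo))
      names(v) <- free
      v
    }))
    if (p == 1) sc <- matrix(sc, ncol = 1, dimnames = list(NULL, free))
    starts <- rbind(starts, sc)
  }
  if (all(c("Tc", "Td", "GF") %in% free))
    starts[, "Tc"] <- feasible_tc(starts[, "Tc"], starts[, "Td"],
                                  starts[, "GF"])

  run <- .optimize_from(obj, starts, free, lo, hi, cfg$maxit)
  est <- run$par
  pred_fn <- make_objective(tc, tag, free, fixed_vals, cfg, rec_window,
                            return_pred = TRUE)
  pred <- pred_fn(est)
  r <- log(tc$observations$volume_cc) - log(pred)
  sigma <- sqrt(max(mean(r^2), 1e-16))
  logL <- -run$value

  estimates <- est
  if ("GF" %in% free) {
    Td <- getp(estimates, "Td", Td_fixed)
    estimates <- c(estimates,
                   Tpot = Td * (exp(log(2) * estimates[["Tc"]] / Td) - 1) /
                     estimates[["GF"]])
  }
  structure(list(
    model = tag, estimates = estimates, sigma = sigma, logL = logL,
    delta_percent = mean_delta_percent(tc$observations$volume_cc, pred),
    n_par = p, n_obs = n,
    converged = run$convergence == 0,
    fitted = data.frame(day = tc$observations$day,
                        observed = tc$observations$volume_cc,
                        predicted = pred),
    ci = NULL, free = free, fixed = fixed_vals, rec_window = rec_window,
    gamma_free = gamma_free, Td_fixed = Td_fixed,
    tc = tc, cfg = cfg), class = "rt_fit")
}

# Run L-BFGS-B from the most promising starts (rows of 'starts', natural
# scale): screen all starts by a bare objective evaluation, optimize from
# the best ones, then polish the winner. Returns the solution on the
# natural scale.
.optimize_from <- function(obj, starts, free, lo, hi, maxit,
                           n_polish = NULL) {
  tlo <- .transform(lo, free); thi <- .transform(hi, free)
  # guard log(0) lower bounds
  tlo[!is.finite(tlo)] <- -30
  obj_t <- function(pt) {
    p <- .untransform(pt, free); names(p) <- free
    obj(p)
  }
  for (i in seq_len(nrow(starts)))
    starts[i, ] <- pmin(pmax(starts[i, ], lo), hi)
  if (nrow(starts) > 1) {
    vals <- apply(starts, 1, obj)
    keep <- order(vals)[seq_len(min(nrow(starts),
                                    n_polish %||% max(4L, nrow(starts) %/% 3L)))]
    starts <- starts[keep, , drop = FALSE]
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- .transform(starts[i, ], free)
    fit <- tryCatch(
      optim(st, obj_t, method = "L-BFGS-B", lower = tlo, upper = thi,
            control = list(maxit = maxit, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimization failed from every start")
  # polish the winner until a restart can no longer move it: L-BFGS-B's
  # own termination tests fire early on steep profiled-likelihood
  # surfaces, and its line search can end with a spurious error code at
  # the true optimum, so convergence is judged by stability alone
  converged <- FALSE
  for (round in 1:5) {
    polish <- tryCatch(
      optim(best$par, obj_t, method = "L-BFGS-B", lower = tlo, upper = thi,
            control = list(maxit = 3L * maxit, factr = 1e6)),
      error = function(e) NULL)
    if (is.null(polish)) break
    stable <- abs(best$value - polish$value) <=
      1e-7 * (1 + abs(best$value)) &&
      max(abs(polish$par - best$par)) <= 1e-5 * (1 + max(abs(best$par)))
    if (polish$value <= best$value) best <- polish
    if (stable) { converged <- TRUE; break }
  }
  par <- .untransform(best$par, free)
  names(par) <- free
  list(par = par, value = best$value, convergence = if (converged) 0L else 1L)
}

#' @export
print.rt_fit <- function(x, ...) {
  cat("Model", x$model, "fit:", x$n_obs, "observations,", x$n_par,
      "free parameters\n")
  cat("  logL =", format(x$logL, digits = 6),
      " sigma =", signif(x$sigma, 3),
      " mean Delta% =", signif(x$delta_percent, 3), "\n")
  est <- signif(x$estimates, 4)
  cat("  ", paste(names(est), est, sep = " = ", collapse = ", "), "\n")
  if (!is.null(x$Td_fixed))
    cat("  (Td fixed at", x$Td_fixed, "days: no pretreatment data)\n")
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

# Predicted volumes at arbitrary days for a fitted model.
predict_fit <- function(fit, days) {
  p <- c(fit$estimates[fit$free], fit$fixed)
  tag <- fit$model
  g <- growth_params(Td = p[["Td"]], GF = getp(p, "GF", 1),
                     Tc = getp(p, "Tc", p[["Td"]]),
                     gamma = getp(p, "gamma", 0))
  e <- fit_effect_model(fit)
  sim <- simulate_course(g, e, fit$tc$schedule, V0 = p[["V0"]],
                         sample_days = days, dt = fit$cfg$dt,
                         cells_per_cc = fit$cfg$cells_per_cc)
  sim$volume_cc
}

# Reconstruct the effect_model implied by a fit's estimates.
fit_effect_model <- function(fit) {
  p <- c(fit$estimates[fit$free], fit$fixed)
  tag <- fit$model
  effect_model(tag,
               K = if (!startsWith(tag, "St")) p[["K"]] else NA,
               Kp = if (startsWith(tag, "St")) p[["Kp"]] else NA,
               Kq = if (startsWith(tag, "St")) p[["Kq"]] else NA,
               D = getp(p, "D"),
               gamma_rec = if (grepl("Rec", tag)) p[["gamma_rec"]] else NA,
               rec_window = fit$rec_window %||% fit$cfg$rec_window,
               Rini = getp(p, "Rini", 0),
               Rind = getp(p, "Rind", 0))
}
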