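#' Likelihood-ratio test between nested model fits
#'
#' Compares two fits of the same time course, where the simpler model is a
#' constrained special case of the larger (M inside St via `Kp = Kq`;
#' either inside its Rec or Res extensions via a null recruitment or
#' resistance effect). The statistic `2 * (logL_larger - logL_nested)` is
#' referred to a chi-square distribution with degrees of freedom equal to
#' the difference in free-parameter counts; the profiled residual scale is
#' excluded from the count in both models.
#'
#' @param nested,larger `rt_fit` objects for the same data.
#' @return A list of class `rt_lrt` with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(nested, larger) {
  stopifnot(inherits(nested, "rt_fit"), inherits(larger, "rt_fit"))
  same_tag_more_free <- nested$model == larger$model &&
    all(nested$free %in% larger$free) && larger$n_par > nested$n_par
  if (!is_nested_tag(nested$model, larger$model) && !same_tag_more_free)
    stop("model ", nested$model, " is not nested in ", larger$model)
  if (nested$n_obs != larger$n_obs ||
      !isTRUE(all.equal(nested$tc$observations$volume_cc,
                        larger$tc$observations$volume_cc)))
    stop("fits must be to the same data")
  df <- larger$n_par - nested$n_par
  if (df < 1) stop("larger model must have more free parameters")
  stat <- max(0, 2 * (larger$logL - nested$logL))
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE)),
            class = "rt_lrt")
}

#' @export
print.rt_lrt <- function(x, ...) {
  cat(sprintf("LRT: 2*dlogL = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Parsimony-ladder model selection for one time course
#'
#' Implements the principle-of-parsimony ladder: fit the minimal model
#' first, adopt the standard model only if it improves the likelihood
#' significantly, then add recruitment and resistance variants to the
#' current base and adopt the best significant extension. For recruitment
#' models the window is chosen by scanning `cfg$rec_window_grid` and
#' keeping the best-likelihood window (the window is treated as a model
#' configuration, not a counted parameter). Extensions that are significant
#' but not significantly better than the adopted best fit are reported as
#' alternates.
#'
#' When the time course lacks a pretreatment observation the whole ladder
#' is run at each fallback doubling time and the better outcome returned,
#' with the other attached as `$alternate_td_selection`.
#'
#' @param tc a [timecourse()].
#' @param cfg a [fit_config()]; `cfg$alpha` is the ladder's significance
#'   level.
#' @param extensions which families of extensions to try after the base
#'   model (default recruitment and both resistance variants).
#' @param Td_fixed internal: fix the doubling time (used for the fallback
#'   ladder).
#' @return A list of class `rt_selection`: `best` (the adopted fit),
#'   `base`, `alternates` (list of fits not significantly worse than
#'   `best`), `candidates` (all fits tried), and `comparisons` (data frame
#'   of likelihood-ratio results).
#' @export
select_model <- function(tc, cfg = fit_config(),
                         extensions = c("Rec", "ResIni", "ResInd"),
                         Td_fixed = NULL) {
  stopifnot(inherits(tc, "timecourse"))

  if (!tc$pretreatment_available && is.null(Td_fixed)) {
    sels <- lapply(cfg$td_fallback, function(td)
      select_model(tc, cfg, extensions, Td_fixed = td))
    best <- which.max(vapply(sels, function(s) s$best$logL, 0))
    out <- sels[[best]]
    out$alternate_td_selection <- sels[-best][[1]]
    return(out)
  }

  n_obs <- nrow(tc$observations)
  try_fit <- function(tag, rec_window = NULL, extra_starts = NULL) {
    # require at least 2 residual degrees of freedom: a saturated model
    # absorbs noise and invalidates the likelihood-ratio comparison
    if (model_parameter_count(tag, pretreatment =
                                tc$pretreatment_available &&
                                is.null(Td_fixed)) > n_obs - 2)
      return(NULL)
    tryCatch(fit_model(tc, tag, cfg, Td_fixed = Td_fixed,
                       rec_window = rec_window,
                       extra_starts = extra_starts),
             error = function(e) NULL)
  }

  fitM <- try_fit("M")
  if (is.null(fitM)) stop("minimal model could not be fitted")
  # seed the standard model from the minimal solution (Kp = Kq = K)
  st_seed <- c(fitM$estimates,
               Kp = fitM$estimates[["K"]], Kq = fitM$estimates[["K"]])
  fitSt <- try_fit("St", extra_starts = st_seed)
  comparisons <- data.frame(model = character(), vs = character(),
                            statistic = numeric(), df = integer(),
                            p_value = numeric(), adopted = logical())
  note <- function(fit, parent, test, adopted) {
    comparisons <<- rbind(comparisons, data.frame(
      model = fit$model, vs = parent$model, statistic = test$statistic,
      df = test$df, p_value = test$p_value, adopted = adopted))
  }

  base <- fitM
  if (!is.null(fitSt)) {
    t_st <- lrt(fitM, fitSt)
    adopt <- t_st$p_value < cfg$alpha
    note(fitSt, fitM, t_st, adopt)
    if (adopt) base <- fitSt
  }

  candidates <- list(M = fitM)
  if (!is.null(fitSt)) candidates$St <- fitSt

  # seed each extension from the base solution plus weak/strong versions
  # of the added effect
  base_seed <- base$estimates
  ext_fits <- list()
  for (ext in extensions) {
    # recruitment acts on the quiescent pool, so its variant is always
    # built on the standard kill structure (when the base is minimal the
    # comparison is M vs StRec, df = 4)
    tag <- if (ext == "Rec") "StRec" else paste0(base$model, ext)
    rec_seed <- base_seed
    if (ext == "Rec" && "K" %in% names(base_seed))
      rec_seed <- c(base_seed, Kp = base_seed[["K"]], Kq = base_seed[["K"]])
    seeds <- switch(ext,
      Rec = list(c(rec_seed, gamma_rec = 0.05),
                 c(rec_seed, gamma_rec = 0.5)),
      ResIni = list(c(base_seed, Rini = 0.1), c(base_seed, Rini = 0.4)),
      ResInd = list(c(base_seed, Rind = 0.02), c(base_seed, Rind = 0.1)))
    f <- if (ext == "Rec") {
      ws <- lapply(cfg$rec_window_grid, function(w)
        try_fit(tag, w, extra_starts = seeds))
      ws <- Filter(Negate(is.null), ws)
      if (length(ws)) ws[[which.max(vapply(ws, function(x) x$logL, 0))]]
    } else try_fit(tag, extra_starts = seeds)
    if (is.null(f)) next
    ext_fits[[tag]] <- f
    candidates[[tag]] <- f
  }

  best <- base
  sig <- list()
  for (tag in names(ext_fits)) {
    t_ext <- lrt(base, ext_fits[[tag]])
    if (grepl("Rec", tag)) {
      # the window was chosen as the best of a scanned grid: correct the
      # test for that selection (Bonferroni over the grid)
      t_ext$p_value <- min(1, t_ext$p_value * length(cfg$rec_window_grid))
    }
    adopt <- t_ext$p_value < cfg$alpha
    note(ext_fits[[tag]], base, t_ext, adopt)
    if (adopt) sig[[tag]] <- ext_fits[[tag]]
  }
  if (length(sig))
    best <- sig[[which.max(vapply(sig, function(f) f$logL, 0))]]

  # alternates: other adopted-level fits not significantly worse than best
  thr <- qchisq(1 - cfg$alpha, 1) / 2
  alternates <- Filter(function(f)
    !identical(f, best) && f$logL >= best$logL - thr,
    c(sig, list(base = base)))

  structure(list(best = best, base = base, alternates = alternates,
                 candidates = candidates, comparisons = comparisons,
                 alpha = cfg$alpha),
            class = "rt_selection")
}

#' @export
print.rt_selection <- function(x, ...) {
  cat("Model selection (alpha =", x$alpha, ")\n")
  cat("Adopted:", x$best$model, "\n")
  if (nrow(x$comparisons)) {
    cat("Ladder:\n")
    print(x$comparisons, row.names = FALSE)
  }
  if (length(x$alternates))
    cat("Alternates (not significantly worse):",
        paste(vapply(x$alternates, function(f) f$model, ""),
              collapse = ", "), "\n")
  print(x$best)
  invisible(x)
}
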