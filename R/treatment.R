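#' Radiotherapy efficacy model
#'
#' Tagged description of how a treatment fraction acts on the population.
#' Eight variants are built from three orthogonal choices:
#'
#' * kill structure — `M` family: a single percentage `K` of all live
#'   sensitive cells is killed per fraction; `St` family: cycling and
#'   quiescent cells are killed with separate percentages `Kp` and `Kq`.
#' * recruitment (`Rec`): inside a window after treatment start the
#'   quiescent re-entry rate is replaced by `gamma_rec` (> 0.01/day,
#'   i.e. above anything a truly quiescent pool would show), modelling
#'   accelerated repopulation.
#' * resistance (`Res`): either a fraction `Rini` of cells is resistant
#'   from the outset (`Ini`), or a fraction `Rind` of the sensitive
#'   survivors converts to resistant at each fraction (`Ind`). Resistant
#'   cells grow like sensitive cells but are never killed.
#'
#' Valid tags: `"M"`, `"St"`, `"MRec"`, `"StRec"`, `"MResIni"`, `"MResInd"`,
#' `"StResIni"`, `"StResInd"`. Combined recruitment + resistance variants
#' can be built by supplying both sets of fields to a `Rec` tag, though none
#' was needed for the bundled reference cohort.
#'
#' @param tag model tag, see above.
#' @param K percent of all sensitive cells killed per fraction (M family).
#' @param Kp,Kq percent of cycling / quiescent sensitive cells killed per
#'   fraction (St family).
#' @param D dying-stage advance probability per day, in (0, 1\]; mean time
#'   from kill to loss is `3/D` days.
#' @param gamma_rec recruitment rate, per day (> 0.01; Rec tags only).
#' @param rec_window `c(start, end)` days relative to the first fraction
#'   during which `gamma_rec` applies; `end = Inf` means until the end of
#'   the simulation.
#' @param Rini initial resistant fraction, in \[0, 1) (ResIni tags).
#' @param Rind per-fraction induced-resistance fraction, in \[0, 1) (ResInd
#'   tags).
#' @return An object of class `effect_model`.
#' @examples
#' effect_model("St", Kp = 90, Kq = 5, D = 0.2)
#' effect_model("StRec", Kp = 76, Kq = 0.01, D = 0.75,
#'              gamma_rec = 0.74, rec_window = c(1, 3))
#' @export
effect_model <- function(tag, K = NA, Kp = NA, Kq = NA, D = NA,
                         gamma_rec = NA, rec_window = NULL,
                         Rini = 0, Rind = 0) {
  tags <- c("M", "St", "MRec", "StRec", "MResIni", "MResInd",
            "StResIni", "StResInd")
  if (!is.character(tag) || length(tag) != 1 || !tag %in% tags)
    stop("unknown model tag; expected one of: ", paste(tags, collapse = ", "))
  fam <- if (startsWith(tag, "St")) "St" else "M"
  if (fam == "M") {
    if (is.na(K)) stop("M-family models need 'K'")
    if (K < 0 || K > 100) stop("'K' must be in [0, 100] percent")
    Kp <- K; Kq <- K
  } else {
    if (is.na(Kp) || is.na(Kq)) stop("St-family models need 'Kp' and 'Kq'")
    if (Kp < 0 || Kp > 100 || Kq < 0 || Kq > 100)
      stop("'Kp'/'Kq' must be in [0, 100] percent")
    K <- NA_real_
  }
  any_kill <- max(Kp, Kq) > 0
  if (any_kill) {
    if (is.na(D)) stop("'D' is required when any cells are killed")
    if (D <= 0 || D > 1) stop("'D' must be in (0, 1]")
  }
  rec <- grepl("Rec", tag)
  if (rec) {
    if (is.na(gamma_rec)) stop("Rec models need 'gamma_rec'")
    if (gamma_rec <= 0.01)
      stop("'gamma_rec' must exceed 0.01/day (otherwise it is ordinary ",
           "quiescent re-entry, not recruitment)")
    if (is.null(rec_window)) stop("Rec models need 'rec_window'")
    stopifnot(length(rec_window) == 2, rec_window[1] <= rec_window[2])
  } else {
    gamma_rec <- NA_real_
  }
  res <- grepl("Res", tag)
  if (grepl("ResIni", tag)) {
    if (Rini < 0 || Rini >= 1) stop("'Rini' must be in [0, 1)")
    Rind <- 0
  } else if (grepl("ResInd", tag)) {
    if (Rind < 0 || Rind >= 1) stop("'Rind' must be in [0, 1)")
    Rini <- 0
  } else if (!rec) {
    Rini <- 0; Rind <- 0
  }
  structure(list(tag = tag, family = fam, K = K, Kp = Kp, Kq = Kq, D = D,
                 gamma_rec = gamma_rec,
                 rec_window = if (rec) rec_window else NULL,
                 Rini = Rini, Rind = Rind),
            class = "effect_model")
}

#' @export
print.effect_model <- function(x, ...) {
  cat("Treatment efficacy model:", x$tag, "\n")
  if (x$family == "M") cat(sprintf("  K = %g%%", x$K))
  else cat(sprintf("  Kp = %g%%, Kq = %g%%", x$Kp, x$Kq))
  cat(sprintf(", D = %g /d", x$D))
  if (!is.null(x$rec_window))
    cat(sprintf(", gamma_rec = %g /d on days [%g, %g]",
                x$gamma_rec, x$rec_window[1], x$rec_window[2]))
  if (x$Rini > 0) cat(sprintf(", Rini = %g", x$Rini))
  if (x$Rind > 0) cat(sprintf(", Rind = %g", x$Rind))
  cat("\n")
  invisible(x)
}

#' Apply one treatment fraction to a population state
#'
#' Instantaneous kill at a fraction time: cycling sensitive cells are
#' scaled by `1 - Kp/100`, quiescent sensitive cells by `1 - Kq/100` (for
#' the M family `Kp = Kq = K`); killed cells enter dying stage I. Under
#' induced resistance a fraction `Rind` of the sensitive survivors moves to
#' the resistant compartments. Resistant and dying cells are never hit.
#'
#' @param s a `population_state` (or bare 7-vector).
#' @param e an [effect_model()].
#' @return The post-fraction `population_state`, with attribute `killed`
#'   holding the number of cells sent to the dying pipeline.
#' @examples
#' g <- growth_params(Td = 100, GF = 0.1, Tc = 3)
#' apply_fraction(init_state(1000, g), effect_model("St", Kp = 90, Kq = 5, D = 0.5))
#' @export
apply_fraction <- function(s, e) {
  stopifnot(inherits(e, "effect_model"))
  s <- as_state(s, t = if (inherits(s, "population_state")) attr(s, "t") else 0)
  kp <- e$Kp / 100; kq <- e$Kq / 100
  knp <- kp * s[["Np"]]; knq <- kq * s[["Nq"]]
  Np <- s[["Np"]] - knp; Nq <- s[["Nq"]] - knq
  Nrp <- s[["Nrp"]]; Nrq <- s[["Nrq"]]
  if (e$Rind > 0) {
    Nrp <- Nrp + Np * e$Rind; Nrq <- Nrq + Nq * e$Rind
    Np <- Np * (1 - e$Rind); Nq <- Nq * (1 - e$Rind)
  }
  out <- c(Np = Np, Nq = Nq, Nrp = Nrp, Nrq = Nrq,
           Nd1 = s[["Nd1"]] + knp + knq, Nd2 = s[["Nd2"]], Nd3 = s[["Nd3"]])
  structure(out, t = attr(s, "t"), killed = knp + knq,
            class = "population_state")
}

#' Quiescent re-entry rate in force on a given day
#'
#' Returns the recruitment rate `gamma_rec` if the model carries one and
#' the day (relative to the first treatment fraction) falls inside the
#' recruitment window, and the pretreatment `gamma` otherwise.
#'
#' @param e an [effect_model()].
#' @param g a [growth_params()] object (supplies the pretreatment rate).
#' @param t day relative to treatment start.
#' @return Re-entry rate, per day.
#' @export
effective_gamma <- function(e, g, t) {
  stopifnot(inherits(e, "effect_model"), inherits(g, "growth_params"),
            is.numeric(t))
  if (is.null(e$rec_window)) return(rep(g$gamma, length(t)))
  ifelse(t >= e$rec_window[1] & t <= e$rec_window[2], e$gamma_rec, g$gamma)
}

# Free parameters of a fit configuration, by model tag.
# gamma is fixed (usually at 0) unless 'gamma_free'; Td is free only when
# pretreatment data allow its estimation. The quiescent-pool structure
# (GF, Tc) is estimated for St-family kills and for any recruitment
# variant — recruitment acts on quiescent cells, so even with a uniform
# kill the pool split must be a parameter.
free_params_for <- function(tag, pretreatment = TRUE, gamma_free = FALSE) {
  fam <- if (startsWith(tag, "St")) "St" else "M"
  quiescent <- fam == "St" || grepl("Rec", tag)
  p <- c("V0", if (pretreatment) "Td",
         if (quiescent) c("GF", "Tc"),
         if (gamma_free) "gamma",
         if (fam == "M") "K" else c("Kp", "Kq"),
         "D",
         if (grepl("Rec", tag)) "gamma_rec",
         if (grepl("ResIni", tag)) "Rini",
         if (grepl("ResInd", tag)) "Rind")
  p
}

#' Number of free parameters of a fit configuration
#'
#' Counts the independent parameters estimated when fitting a given model
#' variant: `V0` plus the growth parameters being estimated plus the kill
#' and dying-rate parameters, plus `gamma_rec` (Rec) or `Rini`/`Rind`
#' (Res). With `gamma` fixed and pretreatment data available, the minimal
#' model has 4 free parameters (`V0`, `Td`, `K`, `D`) and the standard
#' model 7; freeing `gamma` gives the standard model its full 8. The count
#' supplies the degrees of freedom of likelihood-ratio comparisons; the
#' residual scale `sigma` is profiled out in all models and never counted.
#'
#' @param e an [effect_model()] or a model tag string.
#' @param pretreatment `TRUE` when a pretreatment scan allows `Td` (and the
#'   other growth parameters) to be estimated.
#' @param gamma_free is the baseline re-entry rate estimated rather than
#'   fixed?
#' @return Integer count of free parameters.
#' @examples
#' model_parameter_count("St", gamma_free = TRUE)  # 8
#' model_parameter_count("M")                      # 4
#' @export
model_parameter_count <- function(e, pretreatment = TRUE, gamma_free = FALSE) {
  tag <- if (inherits(e, "effect_model")) e$tag else e
  length(free_params_for(tag, pretreatment, gamma_free))
}

# Nesting partial order used by the likelihood-ratio ladder.
is_nested_tag <- function(nested, larger) {
  if (nested == larger) return(FALSE)
  within <- list(
    M = c("St", "MRec", "StRec", "MResIni", "MResInd",
          "StResIni", "StResInd"),
    St = c("StRec", "StResIni", "StResInd"),
    MRec = "StRec",
    MResIni = "StResIni",
    MResInd = "StResInd")
  larger %in% (within[[nested]] %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
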