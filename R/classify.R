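#' Response-type classification from kill fraction and dying rate
#'
#' Fitted responses are typed on a 2x2 grid. Kill is "high" when the
#' per-fraction kill percentage (`K`, or `Kp` for compartment-specific
#' models) reaches the group-specific threshold — 5% for conventional
#' fractionation (group L), 35% for hypofractionation (group S) — and the
#' dying process is "fast" when `D >= 0.5`. Thresholds are inclusive. A
#' missing (not detectable) dying rate routes to the slow branch.
#'
#' * Type A: high kill, slow dying — delayed but sustained shrinkage.
#' * Type B: high kill, fast dying — rapid shrinkage.
#' * Type C: low kill, slow (or not detectable) dying — poor responder.
#' * Type D: low kill, fast dying — transient response, regrowth.
#'
#' @param group `"L"` (conventional) or `"S"` (hypofractionated, completed
#'   in under 14 days); vectorized.
#' @param kill per-fraction kill percentage from the best-fit model (`K` or
#'   `Kp`), in \[0, 100\]; vectorized.
#' @param D dying rate, in (0, 1\], or `NA` when not detectable;
#'   vectorized.
#' @return Character vector of labels `"A"`-`"D"`.
#' @examples
#' classify_response("S", kill = 90, D = 0.2)  # "A"
#' classify_response("L", kill = 1.8, D = 0.2) # "C"
#' @export
classify_response <- function(group, kill, D = NA) {
  n <- max(length(group), length(kill), length(D))
  group <- rep_len(group, n); kill <- rep_len(kill, n); D <- rep_len(D, n)
  if (!all(group %in% c("L", "S"))) stop("unknown group: expected 'L' or 'S'")
  if (any(!is.finite(kill)) || any(kill < 0) || any(kill > 100))
    stop("'kill' must be a percentage in [0, 100]")
  if (any(!is.na(D) & (D <= 0 | D > 1))) stop("'D' must be in (0, 1] or NA")
  thr <- unname(c(L = 5, S = 35)[group])
  high <- kill >= thr
  fast <- !is.na(D) & D >= 0.5
  unname(ifelse(high, ifelse(fast, "B", "A"), ifelse(fast, "D", "C")))
}

#' Tabulate response types across a cohort
#'
#' @param cohort data frame with columns `group`, `kill` (percent), and
#'   `D` (dying rate, `NA` when not detectable), one row per patient
#'   (the best-fit model's values).
#' @return An integer table with one row per group and columns `A`-`D`
#'   (all-zero rows/columns retained).
#' @export
classify_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort),
            all(c("group", "kill", "D") %in% names(cohort)))
  grp <- factor(cohort$group, levels = c("L", "S"))
  if (nrow(cohort) == 0)
    return(table(group = grp, type = factor(character(), levels = LETTERS[1:4])))
  type <- factor(classify_response(cohort$group, cohort$kill, cohort$D),
                 levels = LETTERS[1:4])
  table(group = grp, type = type)
}

# Kill percentage carried by a fit: K for M-family, Kp for St-family.
fit_kill <- function(fit) {
  if (startsWith(fit$model, "St")) fit$estimates[["Kp"]]
  else fit$estimates[["K"]]
}
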