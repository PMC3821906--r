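#' Fractionation course for radiobiological dose summaries
#'
#' A course is one or more segments of `n` fractions at `d` Gy per
#' fraction, with a tissue-specific alpha/beta ratio (default 10 Gy, the
#' conventional value for tumor response).
#'
#' @param n integer vector: fractions per segment (>= 1).
#' @param dose_gy dose per fraction for each segment, Gy (> 0).
#' @param alpha_beta alpha/beta ratio, Gy (> 0).
#' @return An object of class `fractionation_course`.
#' @examples
#' fractionation_course(5, 10)             # 5 x 10 Gy
#' fractionation_course(c(20, 15), c(2.5, 2))  # mixed course
#' @export
fractionation_course <- function(n, dose_gy, alpha_beta = 10) {
  stopifnot(length(n) == length(dose_gy), length(n) >= 1,
            all(n >= 1), all(n == round(n)), all(dose_gy > 0),
            length(alpha_beta) == 1, alpha_beta > 0)
  structure(list(n = as.integer(n), dose_gy = dose_gy,
                 alpha_beta = alpha_beta),
            class = "fractionation_course")
}

#' Biologically effective dose of a course
#'
#' Linear-quadratic BED: `sum(n * d * (1 + d / (alpha/beta)))` over the
#' segments of the course.
#'
#' @param course a [fractionation_course()].
#' @return BED in Gy.
#' @examples
#' bed(fractionation_course(5, 10))    # 100
#' bed(fractionation_course(30, 2.5))  # 93.75
#' @export
bed <- function(course) {
  stopifnot(inherits(course, "fractionation_course"))
  sum(course$n * course$dose_gy * (1 + course$dose_gy / course$alpha_beta))
}

#' Equivalent dose in 2-Gy fractions
#'
#' `EQD2 = sum(n * d * (d + alpha/beta) / (2 + alpha/beta))`; identically
#' `BED / (1 + 2 / (alpha/beta))`. A course already delivered in 2 Gy
#' fractions has EQD2 equal to its physical dose.
#'
#' @param course a [fractionation_course()].
#' @return EQD2 in Gy.
#' @examples
#' eqd2(fractionation_course(4, 10))  # 66.67
#' @export
eqd2 <- function(course) {
  stopifnot(inherits(course, "fractionation_course"))
  sum(course$n * course$dose_gy * (course$dose_gy + course$alpha_beta) /
        (2 + course$alpha_beta))
}

#' @export
print.fractionation_course <- function(x, ...) {
  seg <- paste(x$n, "x", x$dose_gy, "Gy", collapse = " + ")
  cat(sprintf("%s (alpha/beta = %g): BED = %.1f Gy, EQD2 = %.1f Gy\n",
              seg, x$alpha_beta, bed(x), eqd2(x)))
  invisible(x)
}
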