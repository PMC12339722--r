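# broom-style tidiers for the report and result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a locking report
#'
#' One row per unit and scope with the circular-shift locking statistics.
#'
#' @param x A `thetalock_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.thetalock_report <- function(x, ...) x$locking

#' One-row summary of a locking report
#'
#' @param x A `thetalock_report`.
#' @param ... Unused.
#' @return A tibble with overall unit counts and the binomial p versus the
#'   chance rate.
#' @export
glance.thetalock_report <- function(x, ...) {
  overall <- x$counts[x$counts$scope == "all", ]
  tibble::tibble(n_units = overall$n_units,
                 n_significant = overall$n_significant,
                 pct_significant = overall$pct,
                 binomial_p = overall$binomial_p,
                 alpha = x$alpha)
}

#' Tidy a phase-shift result
#'
#' @param x A `phase_shift_result`.
#' @param ... Unused.
#' @return The underlying per-unit tibble.
#' @export
tidy.phase_shift_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "phase_shift_result")
  out
}

#' One-row summary of a phase-shift result
#'
#' @param x A `phase_shift_result`.
#' @param ... Unused.
#' @return Counts of shifting units and the binomial p versus chance.
#' @export
glance.phase_shift_result <- function(x, ...) {
  tibble::tibble(n_tested = attr(x, "n_tested"),
                 n_shifting = attr(x, "n_shifting"),
                 pct_shifting = 100 * attr(x, "n_shifting") / attr(x, "n_tested"),
                 binomial_p = attr(x, "binomial_p"))
}
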