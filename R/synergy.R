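#' Additive expectation for two single-agent death fractions
#'
#' The null model for combination killing: the (capped) sum of the two
#' single-treatment death fractions. Bliss independence
#' (\code{1 - (1-a)(1-b)}) is available as an alternative null.
#'
#' @param d_a,d_b Single-treatment death fractions in [0, 1].
#' @param method \code{"sum"} (capped sum, default) or \code{"bliss"}.
#' @return Expected combination death fraction under additivity.
#' @export
additive_expectation <- function(d_a, d_b, method = c("sum", "bliss")) {
  method <- match.arg(method)
  if (any(c(d_a, d_b) < 0) || any(c(d_a, d_b) > 1)) {
    stop("death fractions must lie in [0, 1]")
  }
  switch(method,
         sum = min(1, d_a + d_b),
         bliss = 1 - (1 - d_a) * (1 - d_b))
}

#' Excess of combination killing over the additive expectation
#'
#' @param d_combo Combination death fraction in [0, 1].
#' @param d_a,d_b Single-treatment death fractions.
#' @param method Additivity null, see \code{\link{additive_expectation}}.
#' @return Excess as a percentage of the additive expectation:
#'   \code{100 * (d_combo - additive) / additive}. If the additive
#'   expectation is zero while the combination kills, \code{Inf} is
#'   returned (an "infinite synergy" flag, not a comparable number).
#' @export
synergy_excess <- function(d_combo, d_a, d_b, method = c("sum", "bliss")) {
  method <- match.arg(method)
  if (d_combo < 0 || d_combo > 1) stop("death fractions must lie in [0, 1]")
  add <- additive_expectation(d_a, d_b, method)
  if (add == 0) {
    return(if (d_combo > 0) Inf else 0)
  }
  100 * (d_combo - add) / add
}

#' Classify a combination as synergistic, additive or antagonistic
#'
#' @param excess Excess over additivity, in percent.
#' @param tolerance Dead band in percentage points (default 5, the scale of
#'   replicate noise in viability assays).
#' @return One of \code{"synergistic"}, \code{"additive"},
#'   \code{"antagonistic"}.
#' @export
classify_synergy <- function(excess, tolerance = 5) {
  stopifnot(is.numeric(excess), length(excess) == 1L, tolerance >= 0)
  if (is.infinite(excess) && excess > 0) return("synergistic")
  if (excess > tolerance) "synergistic"
  else if (excess < -tolerance) "antagonistic"
  else "additive"
}

#' Full synergy report for three death fractions
#'
#' @param death_ly30,death_trail,death_combo 24 h death fractions of the
#'   two single arms and the combination.
#' @param method Additivity null.
#' @param tolerance Classification dead band, percentage points.
#' @return A \code{synergy_report}: list with the inputs,
#'   \code{additive_expectation}, \code{excess_over_additive} (percent) and
#'   \code{classification}.
#' @export
synergy_report <- function(death_ly30, death_trail, death_combo,
                           method = c("sum", "bliss"), tolerance = 5) {
  method <- match.arg(method)
  add <- additive_expectation(death_ly30, death_trail, method)
  exc <- synergy_excess(death_combo, death_ly30, death_trail, method)
  structure(list(death_ly30 = death_ly30, death_trail = death_trail,
                 death_combo = death_combo, additive_expectation = add,
                 excess_over_additive = exc,
                 classification = classify_synergy(exc, tolerance),
                 method = method),
            class = "synergy_report")
}

#' @export
print.synergy_report <- function(x, ...) {
  cat("<synergy_report>\n",
      sprintf("  LY30 alone:  %.1f%% killed\n", 100 * x$death_ly30),
      sprintf("  TRAIL alone: %.1f%% killed\n", 100 * x$death_trail),
      sprintf("  combination: %.1f%% killed\n", 100 * x$death_combo),
      sprintf("  additive expectation (%s): %.1f%%\n", x$method,
              100 * x$additive_expectation),
      sprintf("  excess over additive: %.1f%% -> %s\n",
              x$excess_over_additive, x$classification), sep = "")
  invisible(x)
}
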