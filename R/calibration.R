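#' Define a calibration problem
#'
#' Fitting happens on the fold-change scale (all the assays this package
#' emulates are relative readouts, so absolute scale factors are not
#' identifiable). The loss is the weighted sum of squared residuals, with
#' each observation weighted by the inverse replicate standard error of its
#' (readout, time) group.
#'
#' @param predict_fn Function taking a named parameter vector (natural
#'   scale) and returning a data frame with columns \code{readout},
#'   \code{time}, \code{value}: the model prediction at every observed
#'   (readout, time) pair.
#' @param observations Data frame with columns \code{readout}, \code{time},
#'   \code{replicate}, \code{value} (an \code{observation_dataset} works).
#' @param bounds Named list of \code{c(lower, upper)} pairs, positive and
#'   finite, one per free parameter.
#' @return A \code{calibration_problem}.
#' @export
calibration_problem <- function(predict_fn, observations, bounds) {
  stopifnot(is.function(predict_fn), is.data.frame(observations),
            all(c("readout", "time", "replicate", "value") %in%
                  names(observations)),
            nrow(observations) >= 1L, is.list(bounds), length(bounds) >= 1L,
            !is.null(names(bounds)))
  for (p in names(bounds)) {
    b <- bounds[[p]]
    if (length(b) != 2L || any(b <= 0) || any(!is.finite(b)) || b[1] >= b[2]) {
      stop("bounds for '", p, "' must be positive, finite and ordered")
    }
  }
  key <- interaction(observations$readout, observations$time, drop = TRUE)
  grp_se <- stats::ave(observations$value, key, FUN = function(v) {
    if (length(v) < 2L) return(1)
    s <- stats::sd(v) / sqrt(length(v))
    if (s == 0) 1 else s
  })
  structure(list(predict_fn = predict_fn, observations = observations,
                 bounds = bounds, weights = 1 / grp_se),
            class = "calibration_problem")
}

#' Weighted residual vector of a parameter set
#'
#' @param parameters Named numeric vector (natural scale) of the free
#'   parameters.
#' @param problem A \code{\link{calibration_problem}}.
#' @return Numeric vector, one weighted residual
#'   (\code{(predicted - observed) / replicate SE}) per observation row.
#' @export
residuals_calibration <- function(parameters, problem) {
  stopifnot(inherits(problem, "calibration_problem"))
  pred <- problem$predict_fn(parameters)
  stopifnot(all(c("readout", "time", "value") %in% names(pred)))
  obs <- problem$observations
  idx <- match(paste(obs$readout, signif(obs$time, 12)),
               paste(pred$readout, signif(pred$time, 12)))
  if (anyNA(idx)) {
    stop("predict_fn did not cover all observed (readout, time) pairs")
  }
  (pred$value[idx] - obs$value) * problem$weights
}

#' Calibration loss (weighted sum of squares)
#'
#' @inheritParams residuals_calibration
#' @return Non-negative scalar; zero iff the model matches every
#'   observation exactly.
#' @export
calibration_loss <- function(parameters, problem) {
  sum(residuals_calibration(parameters, problem)^2)
}

#' Fit a calibration problem by multi-start bounded optimisation
#'
#' Parameters are optimised in log space (rates are positive and
#' scale-free). Starts are a maximin Latin-hypercube sample of the log
#' bounding box (plus the box centre), each refined with Nelder-Mead --
#' derivative-free by design, since timed-event discontinuities degrade
#' finite-difference gradients. Out-of-bounds proposals are folded back by
#' clamping with a quadratic penalty; fitted parameters that end up within
#' 0.1% of a bound are flagged.
#'
#' @param problem A \code{\link{calibration_problem}}.
#' @param n_starts Number of starts (default 10).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return A \code{calibration_result}: \code{best_parameters} (named,
#'   natural scale), \code{loss}, \code{at_boundary} (named logical),
#'   \code{trace} (per-start data frame), \code{converged}.
#' @export
fit_calibration <- function(problem, n_starts = 10, seed = 1) {
  stopifnot(inherits(problem, "calibration_problem"), n_starts >= 1)
  pnames <- names(problem$bounds)
  lo <- log(vapply(problem$bounds, `[`, numeric(1), 1L))
  hi <- log(vapply(problem$bounds, `[`, numeric(1), 2L))
  np <- length(pnames)
  objective <- function(theta) {
    clamped <- pmin(pmax(theta, lo), hi)
    penalty <- sum((theta - clamped)^2) * 1e4
    par <- stats::setNames(exp(clamped), pnames)
    val <- try(calibration_loss(par, problem), silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) return(1e12)
    val + penalty
  }
  set.seed(seed)
  unit <- if (n_starts > 1) {
    rbind(matrix(0.5, nrow = 1, ncol = np),
          lhs::maximinLHS(n_starts - 1L, np))
  } else matrix(0.5, nrow = 1, ncol = np)
  starts <- sweep(sweep(unit, 2L, hi - lo, `*`), 2L, lo, `+`)
  best <- NULL
  trace <- data.frame(start = integer(), loss = numeric(),
                      convergence = integer())
  for (i in seq_len(n_starts)) {
    fit <- try(
      if (np == 1L) {
        stats::optim(starts[i, ], objective, method = "Brent",
                     lower = lo, upper = hi)
      } else {
        stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-10))
      }, silent = TRUE)
    if (inherits(fit, "try-error")) next
    trace <- rbind(trace, data.frame(start = i, loss = fit$value,
                                     convergence = fit$convergence))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all ", n_starts, " starts failed to converge")
  theta <- pmin(pmax(best$par, lo), hi)
  par <- stats::setNames(exp(theta), pnames)
  tol <- 1e-3 * (hi - lo)
  structure(list(best_parameters = par, loss = calibration_loss(par, problem),
                 at_boundary = stats::setNames(
                   theta - lo < tol | hi - theta < tol, pnames),
                 trace = trace, converged = any(trace$convergence == 0),
                 n_starts = n_starts, seed = seed),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> loss ", format(x$loss, digits = 4), " from ",
      x$n_starts, " starts\n", sep = "")
  for (p in names(x$best_parameters)) {
    cat(sprintf("  %s = %.4g%s\n", p, x$best_parameters[[p]],
                if (x$at_boundary[[p]]) "  [at bound]" else ""))
  }
  invisible(x)
}

#' Profile the loss along one parameter
#'
#' At each grid value the named parameter is fixed and the remaining free
#' parameters are re-optimised; a flat profile flags non-identifiability.
#'
#' @param problem A \code{\link{calibration_problem}}.
#' @param parameter_name Parameter to profile.
#' @param grid Numeric vector of values (natural scale) for the profiled
#'   parameter.
#' @param n_starts Starts per grid point for the nuisance fit (default 3).
#' @param seed Integer seed.
#' @return Data frame with columns \code{value} and \code{loss}.
#' @export
profile_loss <- function(problem, parameter_name, grid, n_starts = 3,
                         seed = 1) {
  stopifnot(inherits(problem, "calibration_problem"),
            parameter_name %in% names(problem$bounds))
  others <- setdiff(names(problem$bounds), parameter_name)
  loss <- vapply(grid, function(v) {
    if (!length(others)) {
      return(calibration_loss(stats::setNames(v, parameter_name), problem))
    }
    sub <- calibration_problem(
      predict_fn = function(par) {
        problem$predict_fn(c(par, stats::setNames(v, parameter_name)))
      },
      observations = problem$observations,
      bounds = problem$bounds[others])
    fit_calibration(sub, n_starts = n_starts, seed = seed)$loss
  }, numeric(1))
  data.frame(value = grid, loss = loss)
}
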