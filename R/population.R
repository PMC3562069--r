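#' Population specification for Monte Carlo simulation
#'
#' Cell-to-cell variability is modelled as independent normal variation of
#' initial protein amounts: each varied species is drawn per cell from a
#' normal law with mean equal to the network initial amount and standard
#' deviation \code{cv} times the mean (coefficient of variation 0.4 by
#' default), resampled until non-negative. The study population size is
#' 10 000 cells.
#'
#' @param n_cells Number of cells (>= 1); default 10000.
#' @param cv Coefficient of variation of initial amounts; default 0.4.
#' @param seed Integer seed; fixed seed reproduces the population exactly.
#' @param varied_species Character vector of species to vary, or NULL for
#'   the default: every species with a nonzero initial amount.
#' @param p_direct_death Probability that a cell belongs to the small
#'   subpopulation susceptible to mitochondria-independent ROS-driven
#'   death (LY30-extended networks only).
#' @param k_ros_parp_flagged Direct-death channel rate constant applied in
#'   flagged cells.
#' @return A \code{population_spec}.
#' @export
population_spec <- function(n_cells = 10000, cv = 0.4, seed = 1,
                            varied_species = NULL,
                            p_direct_death = 0.12,
                            k_ros_parp_flagged = 1e-4) {
  stopifnot(n_cells >= 1, cv >= 0, p_direct_death >= 0, p_direct_death <= 1)
  if (cv >= 1) {
    warning("cv >= 1 implies heavy truncation bias in the resampled normals")
  }
  structure(list(n_cells = as.integer(n_cells), cv = cv,
                 seed = as.integer(seed), varied_species = varied_species,
                 p_direct_death = p_direct_death,
                 k_ros_parp_flagged = k_ros_parp_flagged),
            class = "population_spec")
}

#' Sample per-cell initial conditions
#'
#' @param network A \code{reaction_network}.
#' @param spec A \code{\link{population_spec}}.
#' @return Matrix (n_cells x species) of initial amounts; attribute
#'   \code{direct_death} holds the per-cell subpopulation flags.
#' @export
sample_initial_conditions <- function(network, spec) {
  stopifnot(inherits(spec, "population_spec"))
  init <- initial_state(network)
  varied <- spec$varied_species %||% names(init)[init > 0]
  bad <- setdiff(varied, names(init))
  if (length(bad)) stop("unknown varied species: ", paste(bad, collapse = ", "))
  set.seed(spec$seed)
  mat <- matrix(rep(init, each = spec$n_cells), nrow = spec$n_cells,
                dimnames = list(NULL, names(init)))
  for (s in varied) {
    m <- init[[s]]
    if (m == 0 || spec$cv == 0) next
    draws <- stats::rnorm(spec$n_cells, mean = m, sd = spec$cv * m)
    while (any(neg <- draws < 0)) {
      draws[neg] <- stats::rnorm(sum(neg), mean = m, sd = spec$cv * m)
    }
    mat[, s] <- draws
  }
  attr(mat, "direct_death") <-
    stats::runif(spec$n_cells) < spec$p_direct_death
  mat
}

#' Time of death of a single-cell trajectory
#'
#' A cell is scored dead at the first time its PARP pool is at least 50%
#' cleaved: cleaved/(intact + cleaved) >= 0.5, with linear interpolation
#' between grid points; \code{NA} if the threshold is never reached.
#'
#' @param trajectory A \code{trajectory} containing \code{PARP} and
#'   \code{cPARP} columns (names configurable).
#' @param parp Name of the intact-PARP species.
#' @param cparp Name of the cleaved-PARP species.
#' @param threshold Cleaved fraction defining death (default 0.5).
#' @return Death time in hours, or \code{NA_real_}.
#' @export
death_time <- function(trajectory, parp = "PARP", cparp = "cPARP",
                       threshold = 0.5) {
  p <- trace_of(trajectory, parp)
  cp <- trace_of(trajectory, cparp)
  tot <- p + cp
  if (any(tot <= .Machine$double.eps * 1e3)) {
    stop("total PARP is ~0; cleaved fraction undefined")
  }
  frac <- cp / tot
  t <- trajectory[, "time"]
  hit <- which(frac >= threshold)
  if (!length(hit)) return(NA_real_)
  i <- hit[1L]
  if (i == 1L || frac[i] == threshold) return(t[i])
  # linear interpolation on the cleaved fraction between grid points
  t[i - 1L] + (threshold - frac[i - 1L]) / (frac[i] - frac[i - 1L]) *
    (t[i] - t[i - 1L])
}

#' Run a Monte Carlo population simulation
#'
#' Integrates every sampled cell under the variant's treatment schedule and
#' aggregates: per-cell death times (>= 50% cleaved PARP), the
#' population-mean trajectory of every species (all cells, dying and
#' surviving, as in a lysate assay), and the cumulative death-fraction
#' curve. Cells whose integration fails are excluded and counted; more than
#' 1% failures aborts.
#'
#' @param variant A \code{\link{model_variant}}.
#' @param spec A \code{\link{population_spec}}.
#' @param times Output grid (hours); default 0 to 24 h by 0.1 h.
#' @return A \code{population_result}: list with \code{death_times},
#'   \code{averaged} (trajectory of population means),
#'   \code{death_fraction_curve} (data frame time/fraction), \code{n_cells},
#'   \code{n_failed}, \code{spec}, \code{variant_tag}.
#' @export
run_population <- function(variant, spec, times = seq(0, 24, 0.1)) {
  stopifnot(inherits(variant, "model_variant"),
            inherits(spec, "population_spec"))
  net <- variant$network
  events <- variant$schedule$events
  ics <- sample_initial_conditions(net, spec)
  flags <- attr(ics, "direct_death")
  has_ros_channel <- "k_ros_parp" %in% names(net$parameters)
  n <- spec$n_cells
  sums <- NULL
  deaths <- rep(NA_real_, n)
  failed <- 0L
  for (i in seq_len(n)) {
    cell <- set_initial(net, ics[i, ])
    if (has_ros_channel) {
      cell <- set_parameters(cell, c(
        k_ros_parp = if (flags[i]) spec$k_ros_parp_flagged else 0))
    }
    tr <- try(integrate_network(cell, events = events, times = times),
              silent = TRUE)
    if (inherits(tr, "try-error")) {
      failed <- failed + 1L
      if (failed > max(1, 0.01 * n)) {
        stop("more than 1% of cells failed to integrate (", failed, " of ",
             i, "); last error: ", attr(tr, "condition")$message)
      }
      next
    }
    deaths[i] <- death_time(tr)
    sums <- if (is.null(sums)) unclass(tr) else sums + unclass(tr)
  }
  if (failed > 0L) {
    message(failed, " of ", n, " cells excluded after integration failure")
  }
  ok <- n - failed
  avg <- structure(sums / ok, class = c("trajectory", "matrix"))
  avg[, "time"] <- times
  dcurve <- vapply(times, function(tt) {
    sum(deaths <= tt, na.rm = TRUE) / ok
  }, numeric(1))
  structure(list(death_times = deaths,
                 averaged = avg,
                 death_fraction_curve = data.frame(time = times,
                                                   fraction = dcurve),
                 n_cells = ok, n_failed = failed, spec = spec,
                 variant_tag = variant$variant_tag),
            class = "population_result")
}

#' @export
print.population_result <- function(x, ...) {
  cat("<population_result> ", x$variant_tag, ": ", x$n_cells, " cells, ",
      sprintf("%.1f%% dead at %g h", 100 * utils::tail(
        x$death_fraction_curve$fraction, 1),
        utils::tail(x$death_fraction_curve$time, 1)), "\n", sep = "")
  invisible(x)
}

#' Death fraction at a given time
#'
#' @param result A \code{population_result}.
#' @param t Time (hours); default 24.
#' @return Fraction of cells dead by \code{t}, in [0, 1].
#' @export
death_fraction <- function(result, t = 24) {
  stopifnot(inherits(result, "population_result"))
  sum(result$death_times <= t, na.rm = TRUE) / result$n_cells
}

#' Population viability
#'
#' @param result A \code{population_result}.
#' @param t Time (hours); default 24 (the crystal-violet endpoint).
#' @return Fraction of cells alive at \code{t}.
#' @export
viability <- function(result, t = 24) {
  1 - death_fraction(result, t)
}

#' Convert population-averaged caspase activity to measured-style fold-change
#'
#' Enzymatic caspase assays are not isoform-specific: the measured signal is
#' a weighted sum of active-caspase amounts plus a small positive
#' background, and results are reported as fold-change relative to the
#' untreated baseline (time 0), which is exactly 1.0 by construction.
#'
#' @param result A \code{population_result} (or a \code{trajectory}).
#' @param readout_tag \code{"caspase8_like"} or \code{"caspase3_like"};
#'   selects the default cross-talk weights.
#' @param weights Named non-negative weights over active-caspase species;
#'   overrides the tag defaults.
#' @param background Small positive constant added to the signal so the
#'   untreated baseline is nonzero; interpreted as assay background in
#'   active-caspase-equivalent copies.
#' @return A \code{fold_change_series}: data frame with time and
#'   fold_change, plus attributes \code{readout_tag} and \code{weights}.
#' @export
to_fold_change <- function(result, readout_tag = c("caspase8_like",
                                                   "caspase3_like"),
                           weights = NULL, background = 50) {
  readout_tag <- match.arg(readout_tag)
  traj <- if (inherits(result, "population_result")) result$averaged else result
  if (is.null(weights)) {
    weights <- switch(readout_tag,
                      caspase8_like = c(C8 = 1, C3 = 0.2),
                      caspase3_like = c(C3 = 1, C8 = 0.1, C9 = 0.05))
  }
  if (any(weights < 0)) stop("cross-talk weights must be non-negative")
  if (background <= 0) stop("background must be > 0 so the baseline signal is nonzero")
  present <- intersect(names(weights), colnames(traj))
  if (!length(present)) stop("none of the weighted species are in the trajectory")
  sig <- rep(background, nrow(traj))
  for (s in present) sig <- sig + weights[[s]] * trace_of(traj, s)
  if (sig[1L] <= 0) stop("baseline signal is zero")
  out <- data.frame(time = traj[, "time"], fold_change = sig / sig[1L])
  structure(out, class = c("fold_change_series", "data.frame"),
            readout_tag = readout_tag, weights = weights,
            background = background)
}
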