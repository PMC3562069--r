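#' Assemble the mass-action rate function of a network
#'
#' Compiles the network into a derivative function suitable for
#' \code{deSolve}: for each species the derivative is the stoichiometry-
#' weighted sum of reaction fluxes, where each flux is the rate constant
#' times the product of reactant and modifier amounts (modifiers carry zero
#' net stoichiometry), times any saturating inhibition factors.
#'
#' @param network A validated \code{reaction_network}.
#' @return A list with elements \code{func(t, y, parms)} (deSolve-style
#'   derivative), \code{stoich} (species x reaction stoichiometry matrix),
#'   and \code{flux(y, parms)} returning the per-reaction flux vector.
#' @export
assemble_rates <- function(network) {
  validate_network(network)
  sp <- network$species$name
  nsp <- length(sp)
  rxns <- network$reactions
  nr <- length(rxns)
  stoich <- matrix(0, nrow = nsp, ncol = nr,
                   dimnames = list(sp, names(rxns)))
  # factor index matrix: up to `maxord` multiplicative state factors per
  # reaction; index 1 is a dummy species pinned at 1
  ords <- vapply(rxns, function(r) length(r$reactants) + length(r$modifiers),
                 integer(1))
  maxord <- max(1L, ords)
  fidx <- matrix(1L, nrow = maxord, ncol = nr)
  kidx <- integer(nr)
  inh <- list()
  pnames <- names(network$parameters)
  for (j in seq_len(nr)) {
    r <- rxns[[j]]
    tab_r <- table(r$reactants)
    tab_p <- table(r$products)
    stoich[names(tab_r), j] <- stoich[names(tab_r), j] - as.integer(tab_r)
    stoich[names(tab_p), j] <- stoich[names(tab_p), j] + as.integer(tab_p)
    facs <- match(c(r$reactants, r$modifiers), sp)
    if (length(facs)) fidx[seq_along(facs), j] <- facs + 1L
    kidx[j] <- match(r$rate_param, pnames)
    if (!is.null(r$inhibitors)) {
      for (q in seq_len(nrow(r$inhibitors))) {
        inh[[length(inh) + 1L]] <- c(
          rxn = j,
          sp = match(r$inhibitors$species[q], sp),
          K = match(r$inhibitors$K_param[q], pnames))
      }
    }
  }
  flux_fn <- function(y, parms) {
    s <- c(1, pmax(y, 0))
    f <- parms[kidx]
    for (row in seq_len(maxord)) f <- f * s[fidx[row, ]]
    for (e in inh) f[e[["rxn"]]] <- f[e[["rxn"]]] /
        (1 + s[e[["sp"]] + 1L] / parms[e[["K"]]])
    f
  }
  func <- function(t, y, parms) {
    list(as.vector(stoich %*% flux_fn(y, parms)))
  }
  list(func = func, stoich = stoich, flux = flux_fn)
}

#' Timed events
#'
#' An event sets a species amount or a parameter value at a given time;
#' integration is stopped and restarted at each event time, so all
#' non-event species stay continuous across it.
#'
#' @param time Event time, hours (may be negative for pre-incubation).
#' @param target Species or parameter name.
#' @param value New value (non-negative).
#' @return One-row data frame.
#' @export
event <- function(time, target, value) {
  stopifnot(is.numeric(time), length(time) == 1L,
            is.character(target), length(target) == 1L,
            is.numeric(value), length(value) == 1L)
  if (value < 0) stop("event value must be non-negative")
  data.frame(time = time, target = target, value = value,
             stringsAsFactors = FALSE)
}

#' Integrate a reaction network
#'
#' Deterministic time-course integration with \code{deSolve::lsoda}
#' (stiff-capable), restarted at each event time. Relative tolerance 1e-6
#' and absolute tolerance 1e-8 molecules by default: copy numbers span
#' about six orders of magnitude, and the absolute tolerance must sit well
#' below the negative-undershoot abort threshold. Small negative
#' undershoots (above \code{-1e-6}) are clipped to zero in the returned
#' trajectory; larger undershoots abort with an error.
#'
#' @param network A \code{reaction_network}.
#' @param events Data frame of \code{\link{event}} rows (or NULL).
#' @param times Strictly increasing numeric grid of output times (hours).
#' @param rtol,atol Integrator tolerances.
#' @return A \code{trajectory}: matrix with a \code{time} column and one
#'   column per species.
#' @export
integrate_network <- function(network, events = NULL, times = seq(0, 24, 0.1),
                              rtol = 1e-6, atol = 1e-8) {
  stopifnot(is.numeric(times), length(times) >= 2L, !is.unsorted(times, strictly = TRUE))
  compiled <- assemble_rates(network)
  y <- initial_state(network)
  parms <- network$parameters
  spnames <- names(y)
  if (!is.null(events) && nrow(events) > 0L) {
    events <- events[order(events$time), , drop = FALSE]
    bad <- setdiff(events$target, c(spnames, names(parms)))
    if (length(bad)) {
      stop("event targets neither species nor parameter: ",
           paste(bad, collapse = ", "))
    }
    if (any(events$time > max(times))) {
      stop("event scheduled after the end of the time grid")
    }
  } else {
    events <- data.frame(time = numeric(), target = character(),
                         value = numeric())
  }
  apply_event <- function(i) {
    tg <- events$target[i]
    if (tg %in% spnames) y[tg] <<- events$value[i]
    else parms[tg] <<- events$value[i]
  }
  # events at or before the start of the grid are applied up-front
  pre <- events$time <= times[1]
  for (i in which(pre)) apply_event(i)
  events <- events[!pre, , drop = FALSE]
  breakpts <- unique(c(times[1], events$time, max(times)))
  out <- matrix(NA_real_, nrow = length(times), ncol = length(y) + 1L,
                dimnames = list(NULL, c("time", spnames)))
  out[, "time"] <- times
  fill <- function(seg) {
    idx <- match(round(seg[, 1], 12), round(times, 12))
    keep <- !is.na(idx)
    out[idx[keep], -1L] <<- seg[keep, -1L, drop = FALSE]
  }
  for (k in seq_len(length(breakpts) - 1L)) {
    t0 <- breakpts[k]; t1 <- breakpts[k + 1L]
    seg_times <- sort(unique(c(t0, times[times > t0 & times <= t1], t1)))
    seg_atol <- atol
    for (attempt in 1:3) {
      sol <- try(suppressWarnings(
        deSolve::lsoda(y = y, times = seg_times, func = compiled$func,
                       parms = parms, rtol = rtol, atol = seg_atol)),
        silent = TRUE)
      bad <- inherits(sol, "try-error") || nrow(sol) < length(seg_times) ||
        any(sol[, -1L] < -1e-6)
      if (!bad) break
      seg_atol <- seg_atol * 1e-3  # retry stiff segments at tighter tolerance
    }
    if (inherits(sol, "try-error") || nrow(sol) < length(seg_times)) {
      stop("integration failed in segment starting at t = ", t0, " h")
    }
    yend <- sol[nrow(sol), -1L]
    if (any(yend < -1e-6)) {
      stop("negative amounts (< -1e-6) at t = ", t1, " h: ",
           paste(spnames[yend < -1e-6], collapse = ", "))
    }
    fill(sol)
    y <- yend
    for (i in which(events$time == t1)) apply_event(i)
  }
  out[, -1L][out[, -1L] < 0] <- 0
  structure(out, class = c("trajectory", "matrix"))
}

#' Extract one species trace from a trajectory
#'
#' @param trajectory A \code{trajectory} matrix.
#' @param name Species name.
#' @return Numeric vector of amounts along the time grid.
#' @export
trace_of <- function(trajectory, name) {
  if (!name %in% colnames(trajectory)) stop("no species '", name, "' in trajectory")
  as.vector(trajectory[, name])
}

#' Tidy data-frame view of a trajectory
#'
#' @param x A \code{trajectory}.
#' @param ... Unused.
#' @return Long data frame with columns time, species, amount.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  sp <- setdiff(colnames(x), "time")
  data.frame(time = rep(x[, "time"], times = length(sp)),
             species = rep(sp, each = nrow(x)),
             amount = as.vector(x[, sp]),
             stringsAsFactors = FALSE)
}
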