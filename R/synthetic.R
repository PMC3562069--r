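#' Construct an observation dataset
#'
#' The tabular format shared by all synthetic (and real-format)
#' observations: one row per replicate measurement. Ground truth and noise
#' metadata ride along as attributes so parameter-recovery tests are
#' self-describing.
#'
#' @param rows Data frame with columns \code{readout}, \code{time},
#'   \code{replicate}, \code{value}.
#' @param ground_truth Named numeric vector of generating parameters (or
#'   NULL for real data).
#' @param noise Description of the noise model (list or character).
#' @param seed Integer seed used for generation.
#' @return An \code{observation_dataset} (data frame subclass).
#' @export
observation_dataset <- function(rows, ground_truth = NULL, noise = NULL,
                                seed = NULL) {
  stopifnot(is.data.frame(rows),
            all(c("readout", "time", "replicate", "value") %in% names(rows)))
  if (any(!is.finite(rows$value))) stop("non-finite observation values")
  structure(rows, class = c("observation_dataset", "data.frame"),
            ground_truth = ground_truth, noise = noise, seed = seed)
}

# mean-1 lognormal multiplier with a given coefficient of variation
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate synthetic caspase-activity fold-change observations
#'
#' Emulates enzymatic caspase activity time courses: the population
#' fold-change series of the given treatment arm, sampled at the
#' experimental grid (default 0, 30, 60, 120, 180, 240 min) and multiplied
#' by mean-1 lognormal replicate noise.
#'
#' @param variant A \code{\link{model_variant}}.
#' @param spec A \code{\link{population_spec}}.
#' @param times Observation times, hours.
#' @param noise_cv Replicate coefficient of variation (>= 0; default 0.1,
#'   an assumed assay noise scale, not a measured one).
#' @param n_reps Replicates per time point (>= 3 by convention).
#' @param seed Integer seed for the replicate noise.
#' @param readout_tag Passed to \code{\link{to_fold_change}}.
#' @param sim_times Simulation grid; must cover \code{times}.
#' @return An \code{observation_dataset}.
#' @export
generate_caspase_activity <- function(variant, spec,
                                      times = c(0, 30, 60, 120, 180, 240) / 60,
                                      noise_cv = 0.1, n_reps = 3, seed = 1,
                                      readout_tag = "caspase8_like",
                                      sim_times = NULL) {
  stopifnot(noise_cv >= 0, n_reps >= 1)
  if (is.null(sim_times)) sim_times <- seq(0, max(max(times), 1), 0.05)
  if (min(times) < min(sim_times) || max(times) > max(sim_times)) {
    stop("observation times fall outside the simulation window")
  }
  res <- run_population(variant, spec, times = sim_times)
  fc <- to_fold_change(res, readout_tag = readout_tag)
  truth <- stats::approx(fc$time, fc$fold_change, xout = times)$y
  set.seed(seed)
  rows <- data.frame(
    readout = readout_tag,
    time = rep(times, each = n_reps),
    replicate = rep(seq_len(n_reps), times = length(times)),
    value = rep(truth, each = n_reps) * rlnorm_cv(length(times) * n_reps,
                                                  noise_cv))
  observation_dataset(rows,
                      ground_truth = variant$network$parameters,
                      noise = list(model = "lognormal", cv = noise_cv),
                      seed = seed)
}

#' Generate synthetic cFLIP densitometry observations
#'
#' Emulates immunoblot densitometry of cFLIP after an LY30 input: the
#' deterministic ROS-cFLIP fold-change at the requested times, observed
#' through two noisy band intensities (target and loading control) that
#' share a common per-lane scale factor. The normalisation step divides the
#' two intensities, so the lane factor cancels exactly and only the two
#' measurement noises remain.
#'
#' @param network A \code{\link{build_ros_cflip_network}} network.
#' @param times Observation times, hours (default the blot sampling grid).
#' @param noise_cv Coefficient of variation of the normalised ratio.
#' @param n_reps Biological replicates (default 3).
#' @param seed Integer seed.
#' @param ly30_uM LY30 dose.
#' @param lane_cv Spread of the per-lane scale factor (cancelled by
#'   normalisation; nonzero by default to exercise the cancellation).
#' @return An \code{observation_dataset} with readout
#'   \code{"cflip_densitometry"}.
#' @export
generate_cflip_densitometry <- function(network,
                                        times = c(0, 0.5, 1, 2, 3, 4, 6),
                                        noise_cv = 0.1, n_reps = 3, seed = 1,
                                        ly30_uM = 25, lane_cv = 0.3) {
  stopifnot(noise_cv >= 0, n_reps >= 1)
  tr <- simulate_ros_cflip(network, ly30_uM = ly30_uM,
                           times = seq(0, max(max(times), 1), 0.01))
  truth <- cflip_fold_change(tr, times = times)$fold_change
  set.seed(seed)
  n <- length(times) * n_reps
  lane <- rlnorm_cv(n, lane_cv)
  cv_each <- sqrt(exp(log(1 + noise_cv^2) / 2) - 1) # split across two bands
  band_cflip <- rep(truth, each = n_reps) * lane * rlnorm_cv(n, cv_each)
  band_actin <- lane * rlnorm_cv(n, cv_each)
  rows <- data.frame(
    readout = "cflip_densitometry",
    time = rep(times, each = n_reps),
    replicate = rep(seq_len(n_reps), times = length(times)),
    value = band_cflip / band_actin)
  observation_dataset(rows, ground_truth = network$parameters,
                      noise = list(model = "lognormal-ratio", cv = noise_cv,
                                   lane_cv = lane_cv),
                      seed = seed)
}

#' Generate synthetic 24 h viability observations
#'
#' Emulates the crystal-violet endpoint: per treatment arm, the simulated
#' 24 h viability plus additive Gaussian noise truncated to [0, 1], then
#' normalised to the untreated replicate mean (so the untreated arm
#' averages exactly 1).
#'
#' @param results Named list of \code{population_result} objects, one per
#'   arm; include an element named \code{"untreated"} for normalisation.
#' @param noise_sd Additive noise standard deviation on the viability
#'   fraction scale.
#' @param n_reps Replicates per arm (default 3).
#' @param seed Integer seed.
#' @return An \code{observation_dataset} with readout \code{"viability"}
#'   and one row per (arm, replicate); arm names are carried in a
#'   \code{condition} column.
#' @export
generate_viability <- function(results, noise_sd = 0.05, n_reps = 3,
                               seed = 1) {
  stopifnot(is.list(results), !is.null(names(results)), noise_sd >= 0,
            n_reps >= 1)
  set.seed(seed)
  draw <- function(v) {
    x <- v + stats::rnorm(n_reps, 0, noise_sd)
    pmin(pmax(x, 0), 1)
  }
  raw <- lapply(results, function(r) draw(viability(r, t = 24)))
  norm <- if ("untreated" %in% names(results)) mean(raw$untreated) else 1
  if (norm == 0) stop("untreated replicate mean is zero; cannot normalise")
  rows <- do.call(rbind, lapply(names(raw), function(arm) {
    data.frame(readout = "viability", condition = arm, time = 24,
               replicate = seq_len(n_reps), value = raw[[arm]] / norm)
  }))
  observation_dataset(rows,
                      noise = list(model = "truncated-gaussian",
                                   sd = noise_sd),
                      seed = seed)
}

#' Write an observation dataset to CSV
#'
#' Byte-identical output for identical generation arguments (metadata is
#' embedded as comment-free extra columns are avoided; ground truth goes in
#' a sidecar if requested).
#'
#' @param dataset An \code{observation_dataset}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_observations_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' One-sample t-test per time point of an observation dataset
#'
#' Thin validation helper for synthetic data: tests, per (readout, time)
#' group, whether the replicate mean differs from a reference value
#' (fold-change 1), with Bonferroni correction across groups.
#'
#' @param dataset An \code{observation_dataset}.
#' @param mu Reference value (default 1).
#' @return Data frame with readout, time, mean, p_value, p_adjusted.
#' @export
observation_t_test <- function(dataset, mu = 1) {
  keys <- unique(data.frame(readout = dataset$readout, time = dataset$time))
  p <- mapply(function(r, tt) {
    v <- dataset$value[dataset$readout == r & dataset$time == tt]
    if (length(v) < 2L) return(NA_real_)
    stats::t.test(v, mu = mu)$p.value
  }, keys$readout, keys$time)
  m <- mapply(function(r, tt) {
    mean(dataset$value[dataset$readout == r & dataset$time == tt])
  }, keys$readout, keys$time)
  data.frame(readout = keys$readout, time = keys$time, mean = m,
             p_value = p,
             p_adjusted = stats::p.adjust(p, method = "bonferroni"),
             row.names = NULL)
}
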