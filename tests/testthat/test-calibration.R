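# predictor mapping free ROS-cFLIP parameters to densitometry fold-changes
cflip_predictor <- function(obs_times) {
  function(par) {
    net <- build_ros_cflip_network(overrides = par)
    tr <- simulate_ros_cflip(net, times = seq(0, max(obs_times) + 0.5, 0.05))
    data.frame(readout = "cflip_densitometry", time = obs_times,
               value = cflip_fold_change(tr, times = obs_times)$fold_change)
  }
}
obs_times <- c(0.5, 1, 2, 3, 4, 6)

test_that("residuals behave like weighted prediction errors", {
  obs <- data.frame(readout = "r", time = c(1, 2), replicate = 1,
                    value = c(2, 3))
  prob <- calibration_problem(
    predict_fn = function(par) data.frame(readout = "r", time = c(1, 2),
                                          value = c(2, 3) + par[["delta"]] - 1),
    observations = obs, bounds = list(delta = c(1e-3, 10)))
  expect_equal(residuals_calibration(c(delta = 1), prob), c(0, 0))
  # constant offset shows up as a constant residual (unit weights, n = 1 reps)
  expect_equal(residuals_calibration(c(delta = 1.5), prob), c(0.5, 0.5))
  expect_equal(calibration_loss(c(delta = 1.5), prob), 0.5)
})

test_that("the loss gradient direction matches a finite-difference check", {
  obs <- data.frame(readout = "r", time = 1:3, replicate = 1,
                    value = c(1, 4, 9))
  prob <- calibration_problem(
    predict_fn = function(par) data.frame(readout = "r", time = 1:3,
                                          value = par[["a"]] * (1:3)^2),
    observations = obs, bounds = list(a = c(0.01, 100)))
  # analytic: dL/da = 2 * sum(r * x^2) with r = (a - 1) x^2
  a0 <- 1.3
  analytic <- 2 * sum((a0 - 1) * (1:3)^2 * (1:3)^2)
  h <- 1e-6
  numeric_grad <- (calibration_loss(c(a = a0 + h), prob) -
                     calibration_loss(c(a = a0 - h), prob)) / (2 * h)
  expect_equal(numeric_grad, analytic, tolerance = 1e-4)
})

test_that("zero-noise synthetic data recovers the generating parameters", {
  truth <- c(k_cflip_deg = 1.5, k_h2o2_deg = 0.5)
  data <- generate_cflip_densitometry(build_ros_cflip_network(),
                                      times = obs_times, noise_cv = 0,
                                      lane_cv = 0, n_reps = 3, seed = 2)
  prob <- calibration_problem(cflip_predictor(obs_times), data,
                              bounds = list(k_cflip_deg = c(0.1, 20),
                                            k_h2o2_deg = c(0.05, 5)))
  fit <- fit_calibration(prob, n_starts = 6, seed = 3)
  expect_lte(calibration_loss(truth, prob), fit$loss + 1e-6)
  expect_lt(abs(fit$best_parameters[["k_cflip_deg"]] - 1.5) / 1.5, 0.2)
  expect_lt(abs(fit$best_parameters[["k_h2o2_deg"]] - 0.5) / 0.5, 0.2)
  expect_false(any(fit$at_boundary))
})

test_that("starting at the truth converges immediately to ~zero loss", {
  data <- generate_cflip_densitometry(build_ros_cflip_network(),
                                      times = obs_times, noise_cv = 0,
                                      lane_cv = 0, n_reps = 3, seed = 2)
  # bounds degenerate-narrow around the truth so the single start is the truth
  prob <- calibration_problem(cflip_predictor(obs_times), data,
                              bounds = list(k_cflip_deg = c(1.5 - 1e-9,
                                                            1.5 + 1e-9)))
  fit <- fit_calibration(prob, n_starts = 1, seed = 1)
  expect_lt(fit$loss, 1e-8)
})

test_that("bounds excluding the truth push the fit to the boundary, flagged", {
  data <- generate_cflip_densitometry(build_ros_cflip_network(),
                                      times = obs_times, noise_cv = 0,
                                      lane_cv = 0, n_reps = 3, seed = 2)
  prob <- calibration_problem(cflip_predictor(obs_times), data,
                              bounds = list(k_cflip_deg = c(3, 20)))
  fit <- fit_calibration(prob, n_starts = 3, seed = 1)
  expect_true(fit$at_boundary[["k_cflip_deg"]])
  expect_equal(fit$best_parameters[["k_cflip_deg"]], 3, tolerance = 0.01)
})

test_that("profiles reach their minimum at the truth and flag flat directions", {
  data <- generate_cflip_densitometry(build_ros_cflip_network(),
                                      times = obs_times, noise_cv = 0,
                                      lane_cv = 0, n_reps = 3, seed = 2)
  prob1 <- calibration_problem(cflip_predictor(obs_times), data,
                               bounds = list(k_cflip_deg = c(0.1, 20)))
  grid <- c(0.5, 1.0, 1.5, 2.5, 4)
  prof <- profile_loss(prob1, "k_cflip_deg", grid)
  expect_equal(grid[which.min(prof$loss)], 1.5)
  # monotone away from the minimum on both sides
  left <- prof$loss[grid <= 1.5]
  right <- prof$loss[grid >= 1.5]
  expect_true(all(diff(left) <= 0))
  expect_true(all(diff(right) >= 0))
  # a parameter the predictor ignores gives a flat profile
  prob2 <- calibration_problem(
    predict_fn = function(par) {
      data.frame(readout = "r", time = 1, value = 2)
    },
    observations = data.frame(readout = "r", time = 1, replicate = 1,
                              value = 2.5),
    bounds = list(ghost = c(0.1, 10)))
  flat <- profile_loss(prob2, "ghost", c(0.2, 1, 5))
  expect_equal(diff(range(flat$loss)), 0)
})
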