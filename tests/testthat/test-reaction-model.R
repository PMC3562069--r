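test_that("mass-action derivatives follow stoichiometry-weighted fluxes", {
  net <- reaction_network(
    list(species("A", 2), species("B", 3), species("C", 0)),
    list(reaction("abc", c("A", "B"), "C", rate_param = "k")),
    c(k = 1))
  f <- assemble_rates(net)
  d <- f$func(0, c(A = 2, B = 3, C = 0), net$parameters)[[1]]
  expect_equal(d, c(-6, -6, 6), ignore_attr = TRUE)
  # all-zero state with no zeroth-order input: zero derivative
  d0 <- f$func(0, c(A = 0, B = 0, C = 0), net$parameters)[[1]]
  expect_equal(d0, c(0, 0, 0), ignore_attr = TRUE)
})

test_that("catalysts enter the flux but carry zero net stoichiometry", {
  net <- reaction_network(
    list(species("S", 10), species("P", 0), species("E", 5)),
    list(reaction("cat", "S", "P", modifiers = "E", rate_param = "k")),
    c(k = 0.1))
  f <- assemble_rates(net)
  expect_equal(f$stoich["E", "cat"], 0)
  d <- f$func(0, c(S = 10, P = 0, E = 5), net$parameters)[[1]]
  expect_equal(d, c(-5, 5, 0), ignore_attr = TRUE)
})

test_that("fluxes are non-negative for non-negative states and rates", {
  net <- build_ly30_extension(build_trail_network())
  f <- assemble_rates(net)
  set.seed(4)
  for (i in 1:20) {
    y <- stats::runif(nrow(net$species), 0, 1e5)
    names(y) <- net$species$name
    expect_true(all(f$flux(y, net$parameters) >= 0))
  }
})

test_that("first-order decay matches the closed-form exponential", {
  net <- reaction_network(
    list(species("A", 100)),
    list(reaction("deg", "A", rate_param = "k",
                  kind = "first_order_degradation")),
    c(k = 0.1))
  tr <- integrate_network(net, times = seq(0, 24, 0.5),
                          rtol = 1e-10, atol = 1e-12)
  expected <- 100 * exp(-0.1 * tr[, "time"])
  expect_lt(max(abs(trace_of(tr, "A") - expected) / expected), 1e-6)
})

test_that("linear networks match the matrix-exponential closed form", {
  skip_if_not_installed("Matrix")
  net <- chain_network(kab = 0.7, kbc = 0.25, a0 = 5000)
  times <- seq(0, 12, 0.5)
  tr <- integrate_network(net, times = times, rtol = 1e-10, atol = 1e-12)
  A <- rbind(c(-0.7, 0, 0), c(0.7, -0.25, 0), c(0, 0.25, 0))
  y0 <- c(5000, 0, 0)
  for (i in seq_along(times)) {
    closed <- as.vector(Matrix::expm(A * times[i]) %*% y0)
    err <- abs(unclass(tr)[i, c("A", "B", "C")] - closed) / pmax(closed, 1)
    expect_lt(max(err), 1e-6)
  }
})

test_that("reversible binding relaxes to the analytic equilibrium", {
  net <- binding_network(kon = 1e-3, koff = 0.1)
  tr <- integrate_network(net, times = seq(0, 200, 1))
  fin <- unclass(tr)[nrow(tr), ]
  expect_equal(fin[["AB"]] / (fin[["A"]] * fin[["B"]]), 1e-3 / 0.1,
               tolerance = 1e-5)
})

test_that("conserved totals stay constant along trajectories", {
  net <- binding_network()
  tr <- integrate_network(net, times = seq(0, 50, 0.5))
  total_a <- trace_of(tr, "A") + trace_of(tr, "AB")
  total_b <- trace_of(tr, "B") + trace_of(tr, "AB")
  expect_lt(max(abs(total_a - total_a[1])) / total_a[1], 1e-8)
  expect_lt(max(abs(total_b - total_b[1])) / total_b[1], 1e-8)
})

test_that("events set amounts at their time and keep other species continuous", {
  net <- reaction_network(
    list(species("TRAIL", 0), species("X", 10)),
    list(reaction("dx", "X", rate_param = "k",
                  kind = "first_order_degradation")),
    c(k = 0.2))
  tr <- integrate_network(net, events = event(1, "TRAIL", 1200),
                          times = seq(0, 2, 0.1))
  expect_true(all(trace_of(tr, "TRAIL")[tr[, "time"] < 1] == 0))
  expect_equal(trace_of(tr, "TRAIL")[tr[, "time"] >= 1],
               rep(1200, sum(tr[, "time"] >= 1)))
  # X is continuous across the event: still the plain exponential
  expect_equal(trace_of(tr, "X"), 10 * exp(-0.2 * tr[, "time"]),
               tolerance = 1e-5)
})

test_that("empty event list with zero rates gives a constant trajectory", {
  net <- reaction_network(
    list(species("A", 7), species("B", 3)),
    list(reaction("ab", "A", "B", rate_param = "k")),
    c(k = 0))
  tr <- integrate_network(net, times = seq(0, 10, 1))
  expect_true(all(trace_of(tr, "A") == 7))
  expect_true(all(trace_of(tr, "B") == 3))
})

test_that("network definition errors are caught", {
  expect_error(reaction_network(
    list(species("A", 1)),
    list(reaction("r", "A", "Z", rate_param = "k")), c(k = 1)),
    "unknown species")
  expect_error(reaction_network(
    list(species("A", 1), species("A", 2)),
    list(reaction("r", "A", rate_param = "k",
                  kind = "first_order_degradation")), c(k = 1)),
    "duplicate species")
  expect_error(species("A", -1), "non-negative")
  expect_error(reaction("r", reactants = "A", rate_param = "k",
                        kind = "zeroth_order_synthesis"), "cannot have")
  expect_error(reaction("r", reactants = c("A", "B"), rate_param = "k",
                        kind = "first_order_degradation"), "exactly one")
  expect_error(event(0, "TRAIL", -5), "non-negative")
})

test_that("turnover balances synthesis against degradation at the target state", {
  net <- reaction_network(
    list(species("P", 10000)),
    list(), c(dummy = 0))
  net <- set_turnover(net, "P", c(P = 0.01))
  expect_equal(unname(net$parameters["k_syn_P"]), 100)
  tr <- integrate_network(net, times = seq(0, 48, 1))
  expect_lt(max(abs(trace_of(tr, "P") - 10000)) / 10000, 1e-6)
  # zero degradation constant cannot be balanced
  expect_error(set_turnover(net, "P", c(P = 0)), "positive")
})
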