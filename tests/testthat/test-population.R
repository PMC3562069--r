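test_that("initial-condition sampling has the specified moments and size", {
  net <- build_trail_network()
  spec <- population_spec(n_cells = 4000, cv = 0.4, seed = 3)
  ics <- sample_initial_conditions(net, spec)
  expect_equal(nrow(ics), 4000)
  expect_true(all(ics >= 0))
  init <- initial_state(net)
  for (s in c("flip", "XIAP", "PARP")) {
    m <- init[[s]]
    # mean within 3 SE of target, allowing a small truncation bias
    se <- 0.4 * m / sqrt(4000)
    bias_allowance <- 0.01 * m  # truncation at 0 for cv = 0.4 is tiny
    expect_lt(abs(mean(ics[, s]) - m), 3 * se + bias_allowance)
    expect_equal(stats::sd(ics[, s]) / m, 0.4, tolerance = 0.1)
  }
})

test_that("cv = 0 gives identical cells and a fixed seed reproduces draws", {
  net <- build_trail_network()
  ics0 <- sample_initial_conditions(net, population_spec(10, cv = 0, seed = 1))
  expect_true(all(apply(ics0, 2, function(col) all(col == col[1]))))
  a <- sample_initial_conditions(net, population_spec(50, cv = 0.4, seed = 9))
  b <- sample_initial_conditions(net, population_spec(50, cv = 0.4, seed = 9))
  expect_identical(a, b)
  expect_warning(population_spec(10, cv = 1.2), "truncation")
})

test_that("death time interpolates the 50% cleaved-PARP crossing", {
  # fraction 0.4 at t=6 and 0.6 at t=8: crossing at exactly 7 h
  tr <- fake_trajectory(time = c(0, 6, 8),
                        PARP = c(100, 60, 40), cPARP = c(0, 40, 60))
  expect_equal(death_time(tr), 7)
  # fraction exactly 0.5 at a grid point counts as dead ("at least 50%")
  tr2 <- fake_trajectory(time = c(0, 5, 10),
                         PARP = c(100, 50, 10), cPARP = c(0, 50, 90))
  expect_equal(death_time(tr2), 5)
  # capped below threshold: never dies
  tr3 <- fake_trajectory(time = c(0, 12, 24),
                         PARP = c(100, 60, 51), cPARP = c(0, 40, 49))
  expect_true(is.na(death_time(tr3)))
  # vanishing PARP pool is an error
  tr4 <- fake_trajectory(time = c(0, 1), PARP = c(0, 0), cPARP = c(0, 0))
  expect_error(death_time(tr4), "undefined")
})

test_that("fold-change conversion is exact on constructed trajectories", {
  tr <- fake_trajectory(time = c(0, 1), C8 = c(100, 100), C3 = c(50, 50))
  fc <- to_fold_change(tr, weights = c(C8 = 1, C3 = 0.3), background = 10)
  expect_equal(fc$fold_change, c(1, 1))
  tr2 <- fake_trajectory(time = c(0, 1), C8 = c(100, 200), C3 = c(50, 100))
  fc2 <- to_fold_change(tr2, weights = c(C8 = 1, C3 = 0.3), background = 1e-9)
  expect_equal(fc2$fold_change[2], 2, tolerance = 1e-7)
  # hand-computed ratio with background
  tr3 <- fake_trajectory(time = c(0, 2), C8 = c(0, 40), C3 = c(0, 100))
  fc3 <- to_fold_change(tr3, weights = c(C8 = 1, C3 = 0.3), background = 10)
  expect_equal(fc3$fold_change, c(1, (10 + 40 + 30) / 10))
  expect_error(to_fold_change(tr3, background = 0), "> 0")
  expect_error(to_fold_change(tr3, weights = c(C8 = -1), background = 1),
               "non-negative")
})

test_that("untreated populations neither die nor drift", {
  r <- cached_population("untreated", n = 4, cv = 0.4, seed = 5)
  expect_equal(death_fraction(r), 0)
  expect_equal(viability(r), 1)
  fc <- to_fold_change(r)
  expect_equal(max(abs(fc$fold_change - 1)), 0, tolerance = 1e-3)
})

test_that("population results are reproducible and internally consistent", {
  r1 <- cached_population("combination", n = 12, cv = 0.4, seed = 11)
  v <- model_variant("combination")
  r2 <- run_population(v, tiny_spec(n = 12, cv = 0.4, seed = 11),
                       times = seq(0, 24, 0.2))
  expect_identical(r1$death_times, r2$death_times)
  expect_equal(unclass(r1$averaged), unclass(r2$averaged))
  # death-fraction curve is a non-decreasing cumulative fraction in [0,1]
  d <- r1$death_fraction_curve$fraction
  expect_true(all(diff(d) >= 0))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(viability(r1, 24), 1 - d[length(d)])
})

test_that("identical cells (cv = 0) share one death time", {
  v <- model_variant("combination")
  r <- run_population(v, tiny_spec(n = 3, cv = 0, p_direct = 0),
                      times = seq(0, 24, 0.1))
  expect_true(all(!is.na(r$death_times)))
  expect_lt(diff(range(r$death_times)), 0.1)
})

test_that("single dying cells switch more sharply than the population average", {
  r <- cached_population("combination", n = 12, cv = 0.4, seed = 11)
  v <- model_variant("combination")
  spec <- tiny_spec(n = 12, cv = 0.4, seed = 11)
  ics <- sample_initial_conditions(v$network, spec)
  dying <- which(!is.na(r$death_times))[1]
  cell <- set_initial(v$network, ics[dying, ])
  tr <- integrate_network(cell, events = v$schedule$events,
                          times = seq(0, 24, 0.2))
  slope_cell <- max(diff(trace_of(tr, "C3")))
  slope_avg <- max(diff(trace_of(r$averaged, "C3")))
  expect_gt(slope_cell, slope_avg)
})

test_that("death-fraction estimates agree across population sizes within 3 SE", {
  v <- model_variant("combination")
  small <- run_population(v, tiny_spec(n = 30, cv = 0.4, seed = 2),
                          times = seq(0, 24, 0.25))
  large <- run_population(v, tiny_spec(n = 120, cv = 0.4, seed = 3),
                          times = seq(0, 24, 0.25))
  d1 <- death_fraction(small); d2 <- death_fraction(large)
  se <- sqrt(d1 * (1 - d1) / 30 + d2 * (1 - d2) / 120)
  expect_lt(abs(d1 - d2), 3 * se)
})

test_that("combination dominates single treatments at every time point", {
  rc <- cached_population("combination", n = 12, cv = 0.4, seed = 11)
  rt <- cached_population("trail_only", n = 12, cv = 0.4, seed = 11)
  rl <- cached_population("ly30_only", n = 12, cv = 0.4, seed = 11)
  expect_true(all(rc$death_fraction_curve$fraction >=
                    rt$death_fraction_curve$fraction))
  expect_true(all(rc$death_fraction_curve$fraction >=
                    rl$death_fraction_curve$fraction))
})
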