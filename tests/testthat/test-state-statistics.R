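make_ft <- function(E, id = "t", labels = NULL) {
  n <- length(E)
  ft <- fret_trace(E, valid_mask = rep(TRUE, n), bound_mask = rep(TRUE, n),
                   frame_dt = 0.1, id = id)
  ft
}

trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

test_that("a delta-distributed state gives a unit-area peak at its value", {
  ft <- make_ft(rep(0.8, 200))
  d <- composite_histogram(list(ft), list(rep(1L, 200)), state = 1)
  expect_equal(d$grid[which.max(d$density)], 0.8, tolerance = 0.005)
  expect_equal(trap(d$grid, d$density), 1, tolerance = 1e-3)
  # peak width is set by the kernel bandwidth
  half <- d$density > max(d$density) / 2
  # full width at half maximum, up to the grid spacing of 0.003
  expect_equal(diff(range(d$grid[half])), 2.355 * 0.04, tolerance = 0.08)
})

test_that("an unpopulated state yields an empty, flagged density", {
  ft <- make_ft(rep(0.8, 50))
  d <- composite_histogram(list(ft), list(rep(1L, 50)), state = 2)
  expect_true(d$empty)
  expect_equal(d$n_points, 0L)
})

test_that("per-state KDE peaks recover the true state means", {
  hm0 <- toy_hmm(means = c(0.6, 0.8), sds = c(0.05, 0.05))
  traces <- simulate(hm0, nsim = 30, seed = 3, nframes = 200)
  fit <- fret_hmm(traces, 2, seed = 3)
  paths <- predict(fit, traces)
  fts <- lapply(seq_along(traces), function(i) make_ft(traces[[i]],
                                                       id = paste0("t", i)))
  for (s in 1:2) {
    d <- composite_histogram(fts, paths, s)
    expect_equal(d$grid[which.max(d$density)], c(0.6, 0.8)[s],
                 tolerance = 0.01)
    expect_equal(trap(d$grid, d$density), 1, tolerance = 1e-3)
  }
})

test_that("state populations are frame-weighted fractions of bound frames", {
  p1 <- list(labels = c(rep(2L, 60), rep(1L, 40)))
  pops <- state_populations(list(p1), n_boot = 10)
  expect_equal(pops$fraction[pops$state == 2], 0.6)
  expect_equal(pops$fraction[pops$state == 1], 0.4)
  expect_equal(sum(pops$fraction), 1, tolerance = 1e-9)

  # permuting trace order changes nothing
  p2 <- list(labels = c(rep(1L, 10), rep(2L, 30)))
  a <- state_populations(list(p1, p2), n_boot = 10)
  b <- state_populations(list(p2, p1), n_boot = 10)
  expect_equal(a$fraction, b$fraction)

  # unbound frames (label 0) are excluded from the denominator
  p3 <- list(labels = c(rep(0L, 100), rep(1L, 30), rep(2L, 10)))
  pops3 <- state_populations(list(p3), n_boot = 10)
  expect_equal(pops3$fraction, c(0.75, 0.25))
})

test_that("populations recover a 2:1 stationary ratio with bootstrap error", {
  sch <- scheme_pn(k_pn = 1, k_np = 2)  # stationary P:N = 2:1
  sim <- simulate_dataset(sch, photophysics(bleach_rate = 0.03),
                          n_traces = 60, duration = 60, seed = 17)
  corr <- correct_traces(sim$traces)
  fit <- fret_hmm(corr$fret_traces, 2, seed = 17)
  paths <- predict(fit, corr$fret_traces)
  pops <- state_populations(paths, seed = 17)
  # state 2 is the higher-mean state P
  expect_lt(abs(pops$fraction[pops$state == 2] - 2 / 3), 0.03)
  expect_gt(pops$sd[1], 0)
})

test_that("TDP places mass at the dwell-median coordinates", {
  E <- rep(c(0.8, 0.6), each = 10, times = 10)
  lab <- rep(c(2L, 1L), each = 10, times = 10)
  ft <- make_ft(E)
  tdp <- transition_density(list(ft), list(lab))
  expect_equal(tdp$n_transitions, 19L)
  pk <- which(tdp$density == max(tdp$density), arr.ind = TRUE)
  peaks <- expand.grid(x = tdp$x[pk[, 1]], y = tdp$y[pk[, 2]])
  expect_true(all(abs(sort(unique(tdp$points$initial)) - c(0.6, 0.8)) < 1e-9))
  # forward and reverse cross peaks both present, nothing on the diagonal
  ix <- findInterval(0.8, tdp$x)
  iy <- findInterval(0.6, tdp$y)
  expect_gt(tdp$density[ix, iy], 0.1)
  expect_gt(tdp$density[iy, ix], 0.1)
  expect_lt(tdp$density[ix, ix] + 0.001, tdp$density[ix, iy])
  dx <- diff(tdp$x[1:2])
  expect_equal(sum(tdp$density) * dx * dx, 1, tolerance = 1e-3)
})

test_that("a transition-free path yields an empty TDP", {
  ft <- make_ft(rep(0.8, 30))
  tdp <- transition_density(list(ft), list(rep(1L, 30)))
  expect_equal(tdp$n_transitions, 0L)
  expect_true(all(tdp$density == 0))
})

test_that("binding events appear on the unbound sentinel axis", {
  # U -> P -> U ... with label 0 for unbound
  lab <- rep(c(0L, 1L), each = 8, times = 6)
  E <- ifelse(lab == 1L, 0.8, NA)
  n <- length(lab)
  ft <- fret_trace(E, valid_mask = lab == 1L, bound_mask = lab == 1L,
                   frame_dt = 0.1, id = "u", pre_bleach = rep(TRUE, n))
  tdp <- transition_density(list(ft), list(lab), unbound_states = 0L)
  bind <- tdp$points$initial < 0  # U -> P events
  expect_true(any(bind))
  expect_true(all(tdp$points$initial[bind] == -0.2))
  expect_equal(max(abs(tdp$points$final[bind] - 0.8)), 0, tolerance = 1e-9)
})

test_that("the exo-state correction reproduces the mutant comparison", {
  out <- exo_population_correction(0.74, 0.59)
  expect_equal(out$e_fraction, 0.15)
  expect_equal(out$n_corrected, 0.59)

  expect_equal(exo_population_correction(0.5, 0.5)$e_fraction, 0)
  out2 <- exo_population_correction(0.5, 0.3, 0.02, 0.02)
  expect_equal(out2$sd, sqrt(2) * 0.02, tolerance = 1e-6)
  expect_equal(round(out2$sd, 3), 0.028)
  expect_warning(exo_population_correction(0.3, 0.5, 0.01, 0.01),
                 "increased")
  # a small negative difference within noise is floored at zero
  out3 <- exo_population_correction(0.49, 0.5, 0.02, 0.02)
  expect_equal(out3$e_fraction, 0)
})
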