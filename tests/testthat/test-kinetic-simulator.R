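test_that("scheme validation enforces the physical invariants", {
  Q <- matrix(0, 2, 2)
  expect_error(kinetic_scheme(c("A", "B"), matrix(-1, 2, 2),
                              c(TRUE, TRUE), c(0.5, 0.6)),
               "rates")
  expect_error(kinetic_scheme(c("A", "B"), Q, c(FALSE, FALSE), c(0.5, 0.6)),
               "unbound")
  expect_error(kinetic_scheme(c("A", "B"), Q, c(TRUE, TRUE), c(1.5, 0.6)),
               "fret_means")
  expect_error(photophysics(leakage_alpha = 0.5), "leakage")
  expect_error(photophysics(total_intensity = 0), "total_intensity")
})

test_that("a scheme with no transitions stays in its start state", {
  sch <- kinetic_scheme(c("P", "N"), matrix(0, 2, 2), c(TRUE, TRUE),
                        c(0.8, 0.6))
  p <- simulate_state_path(sch, duration = 5, frame_dt = 0.1, seed = 1,
                           start = "P")
  expect_equal(length(p$labels), 50L)
  expect_true(all(p$labels == 1L))
  expect_error(simulate_state_path(sch, duration = 0, seed = 1), "duration")
})

test_that("symmetric two-state chain reaches 50/50 occupancy", {
  sch <- scheme_pn(k_pn = 1, k_np = 1)
  p <- simulate_state_path(sch, duration = 1e4, frame_dt = 0.1, seed = 42)
  occ <- mean(p$labels == 1L)
  expect_lt(abs(occ - 0.5), 0.02)
})

test_that("dwell times are exponential with the total exit rate", {
  # state P with exit rate 2/s (P->N at 2/s), returning at 2/s
  sch <- scheme_pn(k_pn = 2, k_np = 2)
  set.seed(99)
  p <- simulate_state_path(sch, duration = 10500, frame_dt = 0.5, seed = 99)
  ev <- p$events
  d <- diff(ev$time)
  dw_p <- d[ev$state[-nrow(ev)] == "P"]
  dw_p <- dw_p[-c(1, length(dw_p))]  # drop boundary dwells
  expect_gt(length(dw_p), 1e4)
  dw_p <- dw_p[seq_len(1e4)]
  expect_lt(abs(mean(dw_p) - 0.5) / 0.5, 0.02)
  ks <- suppressWarnings(ks.test(dw_p, "pexp", 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("fraction of bound frames matches the stationary distribution", {
  sch <- scheme_up(0.5, 0.5)
  pi <- stationary_distribution(sch)
  expect_equal(unname(pi), c(0.5, 0.5))
  p <- simulate_state_path(sch, duration = 1.2e4, frame_dt = 0.1, seed = 7)
  bound <- mean(p$labels == 2L)
  expect_lt(abs(bound - 0.5), 0.02)
})

test_that("stationary distribution solves pi Q = 0 for the default scheme", {
  sch <- scheme1_default()
  pi <- stationary_distribution(sch)
  Q <- sch$rate_matrix
  diag(Q) <- -rowSums(Q)
  expect_lt(max(abs(pi %*% Q)), 1e-12)
  expect_equal(sum(pi), 1)
  # flux balance gives U:P:N = 0.7 : 1 : 0.4 for the default rates
  expect_equal(unname(pi), c(0.7, 1, 0.4) / 2.1, tolerance = 1e-12)
})

test_that("noiseless rendering splits intensity by the state efficiency", {
  sch <- kinetic_scheme(c("U", "P"), matrix(c(0, 0, 0, 0), 2),
                        c(FALSE, TRUE), c(0.05, 0.8))
  phot <- photophysics(total_intensity = 1000, background_d = 0,
                       background_a = 0, noise_sd = 0, leakage_alpha = 0,
                       bleach_rate = 0)
  p <- simulate_state_path(sch, 1, 0.1, seed = 1, start = "P")
  tr <- render_trace(p, sch, phot, labeling_scheme = 1, seed = 1)
  expect_equal(tr$donor, rep(200, 10))
  expect_equal(tr$acceptor, rep(800, 10))

  # scheme 2, unbound: no signal at all
  p_u <- simulate_state_path(sch, 1, 0.1, seed = 1, start = "U")
  tr2 <- render_trace(p_u, sch, phot, labeling_scheme = 2, seed = 1)
  expect_equal(tr2$donor, rep(0, 10))
  expect_equal(tr2$acceptor, rep(0, 10))
  expect_error(render_trace(p, sch, phot, labeling_scheme = 3), "labeling")
})

test_that("noiseless rendering is exactly inverted by the FRET equation", {
  sch <- scheme_pn()
  phot <- photophysics(noise_sd = 0, background_d = 0, background_a = 0,
                       leakage_alpha = 0.08, bleach_rate = 0)
  p <- simulate_state_path(sch, 20, 0.1, seed = 3)
  tr <- render_trace(p, sch, phot, labeling_scheme = 1, seed = 3)
  ctr <- correct_leakage(tr, 0.08)
  E <- ctr$acceptor / (ctr$acceptor + ctr$donor)
  expect_equal(E, unname(sch$fret_means[p$labels]), tolerance = 1e-12)
})

test_that("dataset simulation is deterministic and validates inputs", {
  sch <- scheme_pn()
  a <- simulate_dataset(sch, photophysics(), n_traces = 3, duration = 10,
                        seed = 5)
  b <- simulate_dataset(sch, photophysics(), n_traces = 3, duration = 10,
                        seed = 5)
  expect_identical(a$traces, b$traces)
  expect_identical(lapply(a$truth$paths, `[[`, "labels"),
                   lapply(b$truth$paths, `[[`, "labels"))
  c <- simulate_dataset(sch, photophysics(), n_traces = 3, duration = 10,
                        seed = 6)
  expect_false(identical(a$traces, c$traces))
  expect_error(simulate_dataset(sch, photophysics(), n_traces = 0,
                                duration = 10, seed = 1), "n_traces")
})

test_that("ground-truth paths align frame-wise with rendered traces", {
  sch <- scheme1_default()
  sim <- simulate_dataset(sch, photophysics(), n_traces = 4, duration = 15,
                          seed = 9)
  for (i in seq_along(sim$traces$traces)) {
    expect_length(sim$truth$paths[[i]]$labels,
                  length(sim$traces$traces[[i]]$donor))
  }
})
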