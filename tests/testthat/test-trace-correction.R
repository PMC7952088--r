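noiseless_step_trace <- function(levels, lengths, id = "t") {
  total <- rep(levels, lengths)
  intensity_trace(donor = total / 2, acceptor = total / 2, id = id)
}

test_that("photobleach detection finds a single clean step", {
  tr <- noiseless_step_trace(c(1000, 10), c(500, 500))
  expect_equal(detect_photobleach(tr), 501L)
  const <- noiseless_step_trace(1000, 1000)
  expect_true(is.na(detect_photobleach(const)))
  expect_error(detect_photobleach(intensity_trace(1:5, 1:5)), "20 frames")
})

test_that("a two-step trace is flagged multi-step with the bleach at the final step", {
  tr <- noiseless_step_trace(c(1000, 500, 10), c(400, 300, 300))
  expect_equal(detect_photobleach(tr), 701L)
  qc <- qc_select(tr)
  expect_false(qc$single_bleach)
  expect_equal(qc$n_steps, 2L)
  expect_false(qc$accept)
})

test_that("background subtraction removes the post-bleach medians robustly", {
  d <- c(rep(1000, 100), rep(12, 100))
  a <- c(rep(500, 100), rep(7, 100))
  tr <- intensity_trace(d, a, bleach_frame = 101L)
  out <- subtract_background(tr)
  expect_equal(out$donor[1], 988)
  expect_equal(out$acceptor[1], 493)
  expect_equal(median(out$donor[101:200]), 0)

  # idempotent: a second application shifts by zero
  out2 <- subtract_background(out)
  expect_equal(out2$donor, out$donor)
  expect_equal(out2$acceptor, out$acceptor)

  # median is robust to a post-bleach outlier
  a_out <- c(rep(100, 100), c(9, 10, 11, 10, 200, rep(10, 95)))
  tr2 <- intensity_trace(rep(1, 200), a_out, bleach_frame = 101L)
  expect_equal(subtract_background(tr2)$acceptor[1], 90)

  expect_error(subtract_background(intensity_trace(1:30, 1:30,
                                                   bleach_frame = 25L)),
               "static background")
})

test_that("leakage correction subtracts alpha x donor and clips at zero", {
  tr <- intensity_trace(donor = c(100, 100, 100),
                        acceptor = c(58, 58, 5))
  out <- correct_leakage(tr, 0.08)
  expect_equal(out$acceptor, c(50, 50, 0))
  expect_equal(out$donor, tr$donor)
  expect_equal(correct_leakage(tr, 0)$acceptor, tr$acceptor)
  expect_error(correct_leakage(tr, 1), "alpha")
  expect_error(correct_leakage(tr, -0.1), "alpha")
})

test_that("FRET efficiency is the acceptor fraction of the total", {
  tr <- intensity_trace(donor = c(20, 50, 100),
                        acceptor = c(80, 50, 0))
  ft <- compute_fret(tr)
  expect_equal(ft$E, c(0.8, 0.5, 0))
  expect_true(all(ft$valid_mask))
  expect_error(compute_fret(intensity_trace(c(0, 0), c(0, 0))), "threshold")
})

test_that("scheme-2 bound detection requires sustained signal", {
  # signal present for frames 3..6 and a lone blip at 9
  tot <- c(0, 0, 300, 300, 300, 300, 0, 0, 300, 0)
  tr <- intensity_trace(donor = tot * 0.4, acceptor = tot * 0.6)
  ft <- compute_fret(tr, labeling_scheme = 2, signal_threshold = 100)
  expect_equal(which(ft$bound_mask), 3:6)
  expect_false(ft$bound_mask[9])  # single-frame blip is not a binding event
  expect_equal(ft$E[4], 0.6)
})

test_that("QC accepts good simulated traces and rejects constructed bad ones", {
  # noiseless scheme-1 trace with P<->N switching and one bleach step
  sch <- scheme_pn()
  phot <- photophysics(noise_sd = 0, background_d = 5, background_a = 5,
                       bleach_rate = 0)
  p <- simulate_state_path(sch, 30, 0.1, seed = 21)
  tr <- render_trace(p, sch, phot, 1, seed = 21)
  n <- length(tr$donor)
  tr$donor[(n - 49):n] <- 5
  tr$acceptor[(n - 49):n] <- 5
  qc <- qc_select(tr)
  expect_true(qc$anticorrelated)
  expect_true(qc$constant_total)
  expect_true(qc$single_bleach)
  expect_true(qc$accept)

  # both channels ramping together: correlated, not anticorrelated
  ramp <- seq(100, 1000, length.out = 300) + rep(c(0, 15), 150)
  tr_ramp <- intensity_trace(ramp, ramp)
  qc_ramp <- qc_select(tr_ramp)
  expect_false(qc_ramp$anticorrelated)
  expect_false(qc_ramp$accept)
})

test_that("QC acceptance on the default simulated dataset is at least 90%", {
  sch <- scheme1_default()
  sim <- simulate_dataset(sch, photophysics(), n_traces = 100, seed = 42)
  corr <- correct_traces(sim$traces)
  expect_gte(mean(corr$qc$accept), 0.9)
  # and the corrected traces have sane efficiencies
  allE <- unlist(lapply(corr$fret_traces, function(f) f$E[f$valid_mask]))
  expect_true(all(allE >= 0 & allE <= 1))
})

test_that("clipped efficiencies stay in [0, 1] while raw values are kept", {
  tr <- intensity_trace(donor = c(100, 100), acceptor = c(120, 4))
  ctr <- correct_leakage(tr, 0.08)
  ft <- compute_fret(ctr)
  expect_true(all(ft$E >= 0 & ft$E <= 1))
  expect_lt(ft$E_raw[2], 0)  # unclipped survives for diagnostics
})
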