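test_that("dwell extraction records runs, censoring and conservation", {
  # P,P,P,N,N,P at 0.1 s/frame
  dw <- extract_dwells(list(c(2L, 2L, 2L, 1L, 1L, 2L)), frame_dt = 0.1)
  expect_equal(nrow(dw), 3L)
  expect_equal(dw$duration, c(0.3, 0.2, 0.1))
  expect_equal(dw$state, c(2L, 1L, 2L))
  expect_equal(dw$left_censored, c(TRUE, FALSE, FALSE))
  expect_equal(dw$right_censored, c(FALSE, FALSE, TRUE))
  expect_equal(dw$prev_state, c(NA, 2L, 1L))
  expect_equal(dw$next_state, c(1L, 2L, NA))
  expect_equal(sum(dw$duration), 0.6)

  # single-state path: one fully censored dwell
  dw1 <- extract_dwells(list(rep(1L, 50)), frame_dt = 0.1)
  expect_equal(nrow(dw1), 1L)
  expect_true(dw1$left_censored && dw1$right_censored)
  expect_error(fit_dwell_rate(dw1, state = 1), "too few")

  # NA gaps split segments; boundary dwells at a gap are censored
  dw2 <- extract_dwells(list(c(1L, 1L, NA, 2L, 2L, 1L)), frame_dt = 0.1)
  expect_equal(nrow(dw2), 3L)
  expect_true(all(dw2$left_censored == c(TRUE, TRUE, FALSE)))
  expect_true(is.na(dw2$next_state[1]))  # no transition across the gap
  expect_equal(sum(dw2$duration), 0.5)
})

test_that("Freedman-Diaconis width follows 2 IQR N^(-1/3)", {
  # IQR 2, N = 8: w = 2 * 2 * 1/2 = 2
  x <- c(0, 1, 1, 2, 3, 3, 3, 100)
  x <- c(1, 2, 2, 2, 4, 4, 4, 5)  # quartiles 2 and 4 under type-7
  expect_equal(fd_bin_width(x), 2.0)
  expect_equal(fd_bin_width(1:8), 3.5)
  expect_equal(fd_bin_width(3 * (1:8)), 3 * 3.5)  # homogeneity
  expect_error(fd_bin_width(1:3), "at least 4")
  expect_warning(w <- fd_bin_width(c(5, 5, 5, 5, 5, 1)), "IQR")
  expect_equal(w, 4 / sqrt(6))
})

test_that("exponential dwell fits recover the generating rate", {
  set.seed(20)
  x <- rexp(5000, 2.0)
  f <- fit_dwell_rate(x)
  expect_lt(abs(f$k_obs - 2.0) / 2.0, 0.05)
  expect_lt(abs(f$k_mle - 2.0) / 2.0, 0.05)
  expect_lt(abs(f$k_obs - f$k_mle) / f$k_mle, 0.1)
  expect_gt(f$se, 0)

  # rescaling time by 2x halves the rate
  f2 <- fit_dwell_rate(2 * x)
  expect_equal(f2$k_obs, f$k_obs / 2, tolerance = 1e-6)
  expect_equal(f2$k_mle, f$k_mle / 2, tolerance = 1e-12)
})

test_that("transition frequencies count dwell adjacencies deterministically", {
  # every trace: P -> N -> P -> U (labels 2, 3, 2, 1)
  lab <- c(2L, 2L, 3L, 3L, 2L, 2L, 1L, 1L)
  paths <- rep(list(lab), 60)
  fr <- transition_frequencies(paths, sample_size = 50, n_boot = 20,
                               seed = 1)
  f_pn <- fr$mean[fr$from == 2 & fr$to == 3]
  f_np <- fr$mean[fr$from == 3 & fr$to == 2]
  f_pu <- fr$mean[fr$from == 2 & fr$to == 1]
  expect_equal(f_pn, f_pu)        # 1 : 1 by construction
  expect_equal(f_pn, f_np)
  expect_equal(fr$sd, rep(0, nrow(fr)))  # identical traces: no spread

  fr_b <- transition_frequencies(paths, sample_size = 50, n_boot = 20,
                                 seed = 1)
  expect_identical(fr, fr_b)      # same seed, same answer
})

test_that("branching frequencies reflect the 2:1 microscopic rate ratio", {
  sch <- scheme_pn()  # unused; build a branching chain instead
  Q <- matrix(0, 3, 3, dimnames = list(c("U", "P", "N"), c("U", "P", "N")))
  Q["P", "N"] <- 2; Q["P", "U"] <- 1; Q["U", "P"] <- 2; Q["N", "P"] <- 2
  sch <- kinetic_scheme(c("U", "P", "N"), Q, c(FALSE, TRUE, TRUE),
                        c(U = 0.05, P = 0.8, N = 0.6))
  paths <- lapply(1:80, function(i)
    simulate_state_path(sch, 60, 0.1, seed = 1000 + i)$labels)
  fr <- transition_frequencies(paths, seed = 2)
  ratio <- fr$mean[fr$from == 2 & fr$to == 3] /
    fr$mean[fr$from == 2 & fr$to == 1]
  sd_ratio <- ratio * sqrt((fr$sd[fr$from == 2 & fr$to == 3] /
                              fr$mean[fr$from == 2 & fr$to == 3])^2 +
                           (fr$sd[fr$from == 2 & fr$to == 1] /
                              fr$mean[fr$from == 2 & fr$to == 1])^2)
  expect_lt(abs(ratio - 2), 3 * sd_ratio + 0.2)
})

test_that("rate decomposition splits k_obs by frequency ratios exactly", {
  fr <- data.frame(from = c("P", "P"), to = c("N", "U"),
                   mean = c(3, 2), sd = c(0, 0))
  est <- decompose_rates(c(P = 10), fr)
  expect_equal(est$rate, c(6, 4))
  expect_equal(sum(est$rate), 10, tolerance = 1e-9)  # sum identity

  # invariant to rescaling all frequencies
  fr2 <- fr; fr2$mean <- fr2$mean * 37
  expect_equal(decompose_rates(c(P = 10), fr2)$rate, est$rate)

  # single exit channel: the microscopic rate is k_obs itself
  fr3 <- data.frame(from = "N", to = "P", mean = 12, sd = 1)
  expect_equal(decompose_rates(c(N = 4), fr3)$rate, 4)

  # uncertainty propagation in quadrature
  fr4 <- data.frame(from = c("P", "P"), to = c("N", "U"),
                    mean = c(3, 2), sd = c(0.3, 0.2))
  est4 <- decompose_rates(c(P = 10), fr4, k_obs_se = c(P = 0.5))
  expect_true(all(est4$sd > 0))
  num <- 10 * (0.3 * 2 / 25)  # |d k_PN / d f_PN| * sd
  expect_gt(est4$sd[1], num / 2)
  expect_error(decompose_rates(c(P = 1),
                               data.frame(from = "X", to = "Y",
                                          mean = 1, sd = 0)),
               "zero total")
})

test_that("excluding boundary-censored dwells is the less biased default", {
  # 12 s windows truncate a sizable share of the 1-s dwells
  sch <- scheme_pn(k_pn = 1, k_np = 1)
  paths <- lapply(1:250, function(i)
    simulate_state_path(sch, 12, 0.1, seed = 2000 + i)$labels)
  dw <- extract_dwells(paths, frame_dt = 0.1)
  f_ex <- fit_dwell_rate(dw, state = 1, frame_dt = 0.1)
  f_in <- fit_dwell_rate(dw, state = 1, include_censored = TRUE,
                         frame_dt = 0.1)
  expect_lt(abs(f_ex$k_mle - 1), abs(f_in$k_mle - 1))
})

test_that("fraction bound and Kd follow the binding relations", {
  p <- list(labels = c(rep(1L, 50), rep(0L, 50)))
  fb <- fraction_bound(list(p), sample_size = 1, n_boot = 5)
  expect_equal(fb$f_B, 0.5)
  p_all <- list(labels = rep(2L, 80))
  expect_equal(fraction_bound(list(p_all), sample_size = 1,
                              n_boot = 5)$f_B, 1)

  expect_equal(estimate_kd(0.5, pol_t = 5)$kd, 5)
  expect_equal(estimate_kd(1, pol_t = 5)$kd, 0)
  expect_equal(estimate_kd(0.2, pol_t = 5)$kd, 20)
  kd0 <- estimate_kd(0, 0.01, pol_t = 5)
  expect_false(kd0$finite)
  expect_equal(kd0$kd, Inf)
  # delta-method SD: pol_t * sd / f_B^2
  expect_equal(estimate_kd(0.5, 0.02, pol_t = 5)$kd_sd, 5 * 0.02 / 0.25)
  expect_error(estimate_kd(1.2), "f_B")
})

test_that("bound occupancy of a simulated binding equilibrium is recovered", {
  sch <- scheme_up(k_on = 2 / 3, k_off = 1)  # stationary bound = 0.4
  paths <- lapply(1:60, function(i)
    simulate_state_path(sch, 60, 0.1, seed = 3000 + i)$labels)
  # label 1 is U in this scheme
  fb <- fraction_bound(paths, unbound_states = 1L, seed = 4)
  expect_lt(abs(fb$f_B - 0.4), 0.03)
  expect_gt(fb$sd, 0)
})
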