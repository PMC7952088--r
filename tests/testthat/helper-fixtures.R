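# Shared fixtures. Expensive ones are computed lazily and cached for the
# whole test run.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

# Two-state P<->N scheme, both bound (k_PN = 1, k_NP = 2 by default).
scheme_pn <- function(k_pn = 1, k_np = 2, fret_sds = 0.07) {
  Q <- matrix(0, 2, 2, dimnames = list(c("P", "N"), c("P", "N")))
  Q["P", "N"] <- k_pn
  Q["N", "P"] <- k_np
  kinetic_scheme(c("P", "N"), Q, bound = c(TRUE, TRUE),
                 fret_means = c(P = 0.8, N = 0.6), fret_sds = fret_sds)
}

# Two-state binding scheme U<->P with stationary bound fraction
# k_on / (k_on + k_off).
scheme_up <- function(k_on = 0.5, k_off = 0.5) {
  Q <- matrix(0, 2, 2, dimnames = list(c("U", "P"), c("U", "P")))
  Q["U", "P"] <- k_on
  Q["P", "U"] <- k_off
  kinetic_scheme(c("U", "P"), Q, bound = c(FALSE, TRUE),
                 fret_means = c(U = 0.05, P = 0.8))
}

# hand-built fret_hmm object for simulation-based recovery tests
toy_hmm <- function(means = c(0.6, 0.8), sds = c(0.05, 0.05),
                    trans = matrix(c(0.9, 0.1, 0.1, 0.9), 2),
                    initial = NULL) {
  K <- length(means)
  if (is.null(initial)) initial <- rep(1 / K, K)
  structure(list(n_states = K, means = means, variances = sds^2,
                 transition = trans, initial = initial,
                 loglik = NA_real_, converged = TRUE, df = NA, n_obs = NA),
            class = "fret_hmm")
}

# Exhaustive-enumeration decoder used as the Viterbi oracle.
viterbi_brute <- function(obs, mu, sigma2, trans, init) {
  K <- length(mu)
  Tn <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  em <- sapply(seq_len(K), function(k)
    dnorm(obs, mu[k], sqrt(sigma2[k]), log = TRUE))
  em <- matrix(em, nrow = Tn)
  score <- log(init[paths[, 1]])
  for (t in seq_len(Tn)) score <- score + em[t, ][paths[, t]]
  if (Tn > 1) {
    lA <- log(trans)
    for (t in seq_len(Tn - 1))
      score <- score + lA[cbind(paths[, t], paths[, t + 1])]
  }
  best <- which.max(score)
  list(path = unname(paths[best, ]), logprob = score[best])
}

# Default-condition scheme-1 dataset run through the entire pipeline
# (200 traces, 60 s at 0.1 s/frame), used by the recovery checks.
crit_recovery <- function() fixture("crit_recovery", {
  cfg <- pipeline_config(
    simulation = list(scheme = "scheme1", n_traces = 200, duration = 60),
    hmm = list(n_states = 3),
    seed = 1)
  suppressWarnings(run_pipeline(cfg))
})

# map fitted HMM state labels onto scheme-1 state names by nearest mean
map_states_scheme1 <- function(model) {
  truth_means <- c(U = 0.0, N = 0.6, P = 0.8)
  names(truth_means)[apply(abs(outer(model$means, truth_means, "-")),
                           1, which.min)]
}
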