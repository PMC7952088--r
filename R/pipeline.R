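# 32-bit FNV-1a hash of a string, for config provenance stamps.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

pipeline_defaults <- function() {
  list(
    input = NULL,
    simulation = NULL,
    labeling_scheme = 1,
    correction = list(alpha = 0.08, anticorr_threshold = -0.2,
                      cv_threshold = 0.25, static_background = c(0, 0),
                      unbound_max_E = 0.2),
    hmm = list(n_states = "auto", candidates = 1:4, tol = 1e-4,
               max_iter = 500, n_restarts = 5),
    kde = list(bandwidth = 0.04, unbound_sentinel = -0.2),
    bootstrap = list(sample_size = 50, n_boot = 50, population_n_boot = 200),
    pol_t = 5,
    R0 = 52,
    min_dwells = 20,
    seed = 1,
    out_dir = NULL
  )
}

#' Build and validate a pipeline configuration
#'
#' Exactly one of `input` (a trace file readable by [read_traces()]) or
#' `simulation` (a list with `scheme` = `"scheme1"`/`"scheme2"`, optional
#' `rates`, `photophysics` overrides, `n_traces`, `duration`, `frame_dt`)
#' must be given. Unknown keys are rejected. The validated configuration
#' is serialized into the output directory on every run for provenance.
#'
#' @param ... Configuration entries overriding the defaults (see
#'   Details); nested lists (`correction`, `hmm`, `kde`, `bootstrap`) are
#'   merged element-wise.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  user <- list(...)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]]) && k != "simulation") {
      bad <- setdiff(names(user[[k]]), names(cfg[[k]]))
      if (length(bad))
        stop("unknown configuration key(s) under '", k, "': ",
             paste(bad, collapse = ", "))
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  if (!is.null(cfg$input) && !is.null(cfg$simulation))
    stop("give either an input trace file or a simulation spec, not both")
  if (is.null(cfg$input) && is.null(cfg$simulation))
    stop("one of 'input' or 'simulation' is required")
  if (!cfg$labeling_scheme %in% c(1, 2))
    stop("labeling_scheme must be 1 or 2")
  if (!is.null(cfg$simulation)) {
    sim_keys <- c("scheme", "rates", "photophysics", "n_traces",
                  "duration", "frame_dt")
    bad <- setdiff(names(cfg$simulation), sim_keys)
    if (length(bad))
      stop("unknown configuration key(s) under 'simulation': ",
           paste(bad, collapse = ", "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys match [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::yaml.load_file(path))
}

sim_from_config <- function(sim, labeling_scheme, seed) {
  scheme <- switch(as.character(sim$scheme %||% "scheme1"),
                   scheme1 = scheme1_default(rates = unlist(sim$rates)),
                   scheme2 = scheme2_default(),
                   stop("simulation$scheme must be 'scheme1' or 'scheme2'"))
  phot <- do.call(photophysics, as.list(sim$photophysics))
  simulate_dataset(scheme, phot,
                   n_traces = sim$n_traces %||% 100,
                   duration = sim$duration %||% 60,
                   frame_dt = sim$frame_dt %||% 0.1,
                   labeling_scheme = labeling_scheme, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full smFRET analysis pipeline
#'
#' Simulate (or load) traces, correct and quality-select them, fit the
#' global HMM, Viterbi-decode every accepted trace, compile state
#' statistics (populations, composite KDE histograms, transition density
#' plot), extract dwell kinetics (decay fits, bootstrap transition
#' frequencies, microscopic rates), and estimate the binding affinity and
#' state distances. Deterministic given the configuration: every random
#' draw uses a seed derived from `config$seed` by a fixed per-stage
#' offset. If `config$out_dir` is set, all tables, the serialized model
#' and configuration, a text report and a run log are written there.
#'
#' @param config A [pipeline_config()].
#' @return A `polfret_results` list (invisibly if written to disk).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- config$seed

  truth <- NULL
  ts <- stage("input", {
    if (!is.null(config$input)) {
      read_traces(config$input, compat = TRUE)
    } else {
      sim <- sim_from_config(config$simulation, config$labeling_scheme,
                             seed + 1L)
      truth <- sim$truth
      sim$traces
    }
  })
  note("input: %d traces at %.3g s/frame", length(ts$traces), ts$frame_dt)

  corr <- stage("correction", do.call(correct_traces, c(
    list(ts = ts, labeling_scheme = config$labeling_scheme),
    config$correction[c("alpha", "anticorr_threshold", "cv_threshold",
                        "static_background")])))
  note("correction: %d/%d traces accepted by QC",
       length(corr$fret_traces), length(ts$traces))
  if (!length(corr$fret_traces))
    stop("pipeline stage 'correction' failed: no trace passed QC")

  hm <- stage("hmm", {
    if (identical(config$hmm$n_states, "auto")) {
      sel <- select_n_states(corr$fret_traces,
                             candidates = config$hmm$candidates,
                             seed = seed + 2L, tol = config$hmm$tol,
                             max_iter = config$hmm$max_iter,
                             n_restarts = config$hmm$n_restarts)
      note("hmm: BIC selected %d states", sel$n_states)
      sel$models[[as.character(sel$n_states)]]
    } else {
      fret_hmm(corr$fret_traces, config$hmm$n_states,
               tol = config$hmm$tol, max_iter = config$hmm$max_iter,
               n_restarts = config$hmm$n_restarts, seed = seed + 2L)
    }
  })
  note("hmm: %d states, means %s, loglik %.1f", hm$n_states,
       paste(round(hm$means, 3), collapse = "/"), hm$loglik)

  paths <- stage("decoding", predict(hm, corr$fret_traces))

  # label bookkeeping: which HMM states represent unbound molecules
  unbound_labels <- if (config$labeling_scheme == 1)
    c(0L, which(hm$means < config$correction$unbound_max_E)) else 0L
  bound_labels <- setdiff(seq_len(hm$n_states), unbound_labels)

  pops <- stage("populations", state_populations(
    paths, states = bound_labels, unbound_states = unbound_labels,
    n_boot = config$bootstrap$population_n_boot, seed = seed + 3L))
  dens <- stage("histograms", lapply(bound_labels, function(s)
    composite_histogram(corr$fret_traces, paths, s,
                        bandwidth = config$kde$bandwidth)))
  tdp <- stage("tdp", transition_density(
    corr$fret_traces, paths, bandwidth = config$kde$bandwidth,
    unbound_sentinel = config$kde$unbound_sentinel,
    unbound_states = unbound_labels))

  dwells <- stage("dwells", extract_dwells(paths, frame_dt = ts$frame_dt))
  freq <- stage("frequencies", transition_frequencies(
    paths, sample_size = config$bootstrap$sample_size,
    n_boot = config$bootstrap$n_boot, seed = seed + 4L))

  rates <- stage("rates", {
    fit_states <- bound_labels[vapply(bound_labels, function(s) {
      d <- dwells[dwells$state == s & !dwells$left_censored &
                    !dwells$right_censored, ]
      nrow(d) >= config$min_dwells
    }, logical(1))]
    if (length(fit_states)) {
      fits <- lapply(fit_states, function(s) fit_dwell_rate(
        dwells, state = s, min_dwells = config$min_dwells,
        frame_dt = ts$frame_dt))
      k_obs <- stats::setNames(vapply(fits, `[[`, numeric(1), "k_obs"),
                               fit_states)
      k_se <- stats::setNames(vapply(fits, `[[`, numeric(1), "se"),
                              fit_states)
      list(fits = stats::setNames(fits, fit_states),
           estimates = decompose_rates(k_obs, freq, k_se))
    } else {
      note("rates: too few uncensored dwells; skipping decay fits")
      NULL
    }
  })

  binding <- stage("binding", {
    fb <- fraction_bound(paths, unbound_states = unbound_labels,
                         sample_size = config$bootstrap$sample_size,
                         n_boot = config$bootstrap$n_boot,
                         seed = seed + 5L)
    estimate_kd(fb$f_B, fb$sd, pol_t = config$pol_t)
  })

  ctx <- forster_context(config$R0)
  distances <- stage("distances", {
    ok <- hm$means > 0 & hm$means < 1
    data.frame(state = seq_len(hm$n_states)[ok],
               mean_E = hm$means[ok],
               distance_A = distance_from_fret(hm$means[ok], ctx))
  })

  results <- structure(
    list(config = config, qc = corr$qc, fret_traces = corr$fret_traces,
         model = hm, paths = paths, bound_labels = bound_labels,
         unbound_labels = unbound_labels, populations = pops,
         densities = dens, tdp = tdp, dwells = dwells,
         frequencies = freq, rates = rates, binding = binding,
         distances = distances, truth = truth,
         version = as.character(utils::packageVersion("polfret"))),
    class = "polfret_results")

  if (!is.null(config$out_dir)) {
    write_results(results, config$out_dir, log_lines)
    return(invisible(results))
  }
  results
}

config_as_yaml <- function(config) {
  yaml::as.yaml(unclass(rapply(config, function(x) x, how = "replace")))
}

write_results <- function(results, out_dir, log_lines = character(0)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  cfg_yaml <- config_as_yaml(results$config)
  writeLines(cfg_yaml, p("config.yaml"))
  utils::write.csv(results$qc, p("qc.csv"), row.names = FALSE)
  m <- results$model
  writeLines(yaml::as.yaml(list(
    n_states = m$n_states, means = m$means, variances = m$variances,
    transition = as.vector(t(m$transition)), initial = m$initial,
    loglik = m$loglik, converged = m$converged)), p("model.yaml"))
  export_idealized(results$fret_traces, results$paths, p("idealized.csv"))
  utils::write.csv(results$populations, p("populations.csv"),
                   row.names = FALSE)
  for (d in results$densities)
    utils::write.csv(data.frame(E = d$grid, density = d$density),
                     p(sprintf("density_state%d.csv", d$state)),
                     row.names = FALSE)
  utils::write.csv(results$tdp$points, p("tdp_points.csv"),
                   row.names = FALSE)
  utils::write.csv(results$dwells, p("dwells.csv"), row.names = FALSE)
  utils::write.csv(results$frequencies, p("frequencies.csv"),
                   row.names = FALSE)
  if (!is.null(results$rates))
    utils::write.csv(as.data.frame(unclass(results$rates$estimates)),
                     p("rates.csv"), row.names = FALSE)
  b <- results$binding
  utils::write.csv(data.frame(f_B = b$f_B, f_B_sd = b$f_B_sd,
                              pol_t_nM = b$pol_t, kd_nM = b$kd,
                              kd_sd_nM = b$kd_sd), p("binding.csv"),
                   row.names = FALSE)
  utils::write.csv(results$distances, p("distances.csv"), row.names = FALSE)
  writeLines(make_report(results), p("report.txt"))
  writeLines(c(sprintf("polfret %s", results$version),
               sprintf("config hash %s", fnv1a(cfg_yaml)),
               sprintf("written %s", format(Sys.time())),
               log_lines), p("run.log"))
  invisible(out_dir)
}

# round fractions to percentages (1 decimal) that sum to exactly 100
percentages_sum100 <- function(frac) {
  if (!length(frac)) return(numeric(0))
  raw <- frac / sum(frac) * 1000
  fl <- floor(raw)
  rem <- 1000 - sum(fl)
  ord <- order(raw - fl, decreasing = TRUE)
  if (rem > 0) fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  fl / 10
}

#' Render a human-readable results report
#'
#' Tables of state populations (as percentages summing to 100),
#' microscopic rate constants with uncertainties, the binding estimate,
#' and state distances. Regenerating the report from the same results
#' bundle is byte-identical.
#'
#' @param results A `polfret_results` bundle from [run_pipeline()].
#' @return Character vector of report lines.
#' @export
make_report <- function(results) {
  lines <- c("polfret analysis report",
             "=======================", "")
  if (is.null(results$model)) return(lines)
  m <- results$model
  lines <- c(lines, sprintf("Global HMM: %d states, log-likelihood %.2f",
                            m$n_states, m$loglik), "")
  pops <- results$populations
  if (!is.null(pops) && nrow(pops)) {
    pct <- percentages_sum100(pops$fraction)
    lines <- c(lines, "Bound-state populations:",
               sprintf("  state %s (E = %.2f): %.1f%% +/- %.1f%%",
                       pops$state, m$means[pops$state], pct,
                       100 * pops$sd),
               "")
  }
  r <- results$rates
  if (!is.null(r)) {
    est <- r$estimates
    lines <- c(lines, "Microscopic rate constants:",
               sprintf("  k_%s->%s = %.3g +/- %.2g /s",
                       est$from, est$to, est$rate, est$sd),
               "")
  }
  b <- results$binding
  if (!is.null(b)) {
    lines <- c(lines, if (b$finite)
      sprintf("Binding: f_B = %.3f +/- %.3f, Kd = %.3g +/- %.2g nM (at %g nM protein)",
              b$f_B, b$f_B_sd, b$kd, b$kd_sd, b$pol_t)
      else "Binding: no bound frames observed; Kd unbounded", "")
  }
  d <- results$distances
  if (!is.null(d) && nrow(d)) {
    lines <- c(lines, "Donor-acceptor distances (Forster relation):",
               sprintf("  state %d: E = %.2f -> r = %.1f A",
                       d$state, d$mean_E, d$distance_A))
  }
  lines
}

#' @export
print.polfret_results <- function(x, ...) {
  cat(make_report(x), sep = "\n")
  invisible(x)
}
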