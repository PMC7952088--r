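#' Simulate a state path from a kinetic scheme
#'
#' Draws a continuous-time Markov chain realization (Gillespie algorithm:
#' exponential dwell with the state's total exit rate, next state chosen
#' proportionally to the outgoing rates) and quantizes it to camera frames.
#' A frame is labeled with the state that occupies the majority of its
#' integration interval, mimicking CCD integration.
#'
#' @param scheme A [kinetic_scheme()].
#' @param duration Total simulated time (s).
#' @param frame_dt Frame integration time (s); default 0.1 s.
#' @param seed Integer seed.
#' @param start Starting state name, or `NULL` to draw from the stationary
#'   distribution (molecules are observed at equilibrium).
#' @return A `state_path` object: integer per-frame labels (indices into
#'   `scheme$state_names`), the continuous event record, and `frame_dt`.
#' @export
simulate_state_path <- function(scheme, duration, frame_dt = 0.1,
                                seed = NULL, start = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (duration <= 0) stop("duration must be > 0")
  if (frame_dt <= 0) stop("frame_dt must be > 0")
  if (!is.null(seed)) set.seed(seed)
  K <- length(scheme$state_names)
  Q <- scheme$rate_matrix
  exit <- rowSums(Q)
  if (is.null(start)) {
    if (all(exit == 0)) {
      s <- 1L
    } else {
      pi <- stationary_distribution(scheme)
      s <- sample.int(K, 1L, prob = pi)
    }
  } else {
    s <- match(start, scheme$state_names)
    if (is.na(s)) stop("unknown start state: ", start)
  }

  times <- numeric(0)
  states <- integer(0)
  t <- 0
  repeat {
    times <- c(times, t)
    states <- c(states, s)
    if (exit[s] == 0) break
    t <- t + stats::rexp(1L, exit[s])
    if (t >= duration) break
    s <- sample.int(K, 1L, prob = Q[s, ])
  }

  n_frames <- floor(duration / frame_dt + 1e-9)
  labels <- quantize_events(times, states, n_frames, frame_dt, K)
  structure(
    list(labels = labels, state_names = scheme$state_names,
         frame_dt = frame_dt,
         events = data.frame(time = times,
                             state = scheme$state_names[states])),
    class = "state_path"
  )
}

# Majority-occupancy frame quantization of a piecewise-constant path.
# times[i] is the entry time into states[i]; the last segment extends to
# the end of the observation window.
quantize_events <- function(times, states, n_frames, frame_dt, n_states) {
  occ <- matrix(0, n_frames, n_states)
  total <- n_frames * frame_dt
  ends <- c(times[-1], total)
  for (i in seq_along(times)) {
    t0 <- times[i]
    t1 <- min(ends[i], total)
    if (t1 <= t0) next
    s <- states[i]
    f0 <- floor(t0 / frame_dt + 1e-12) + 1L
    f1 <- ceiling(t1 / frame_dt - 1e-12)
    f1 <- min(f1, n_frames)
    if (f0 > n_frames || f1 < f0) next
    if (f0 == f1) {
      occ[f0, s] <- occ[f0, s] + (t1 - t0)
    } else {
      occ[f0, s] <- occ[f0, s] + f0 * frame_dt - t0
      occ[f1, s] <- occ[f1, s] + t1 - (f1 - 1L) * frame_dt
      if (f1 > f0 + 1L) {
        mid <- (f0 + 1L):(f1 - 1L)
        occ[mid, s] <- occ[mid, s] + frame_dt
      }
    }
  }
  max.col(occ, ties.method = "first")
}

#' @export
print.state_path <- function(x, ...) {
  cat(sprintf("State path: %d frames at %.3g s/frame (%d events)\n",
              length(x$labels), x$frame_dt, nrow(x$events)))
  tb <- table(factor(x$state_names[x$labels], levels = x$state_names))
  print(round(tb / length(x$labels), 3))
  invisible(x)
}

#' Render donor/acceptor intensities from a state path
#'
#' Converts a frame-quantized state path into a camera trace under a
#' photophysics model. For bound frames the signal splits as
#' `total * (1 - E, E)` between donor and acceptor, the acceptor channel
#' additionally receiving `alpha * donor_signal` leakage; both channels
#' get their background offset and Gaussian read noise. Unbound frames are
#' donor-only under labeling scheme 1 (donor dye on the DNA) and
#' background-only under scheme 2 (donor dye on the protein). A donor
#' bleach time is drawn from Exponential(`bleach_rate`); all later frames
#' are background plus noise in both channels.
#'
#' @param path A `state_path` from [simulate_state_path()].
#' @param scheme The [kinetic_scheme()] that generated it.
#' @param phot A [photophysics()] model.
#' @param labeling_scheme 1 (donor on DNA) or 2 (donor on protein).
#' @param seed Integer seed.
#' @return An `intensity_trace`: donor and acceptor vectors (a.u.),
#'   `frame_dt`, and the true bleach frame (first bleached frame index, or
#'   `NA` if the dye outlived the trace).
#' @export
render_trace <- function(path, scheme, phot, labeling_scheme = 1,
                         seed = NULL) {
  stopifnot(inherits(path, "state_path"), inherits(scheme, "kinetic_scheme"),
            inherits(phot, "photophysics"))
  if (!labeling_scheme %in% c(1, 2))
    stop("labeling_scheme must be 1 or 2")
  if (!is.null(seed)) set.seed(seed)
  n <- length(path$labels)
  E <- scheme$fret_means[path$labels]
  bound <- scheme$bound[path$labels]
  tot <- phot$total_intensity
  a <- phot$leakage_alpha

  donor_sig <- acceptor_sig <- numeric(n)
  if (labeling_scheme == 1) {
    donor_sig <- ifelse(bound, tot * (1 - E), tot)
    acceptor_sig <- ifelse(bound, tot * E, 0)
  } else {
    donor_sig <- ifelse(bound, tot * (1 - E), 0)
    acceptor_sig <- ifelse(bound, tot * E, 0)
  }
  acceptor_sig <- acceptor_sig + a * donor_sig

  bleach_time <- if (phot$bleach_rate > 0) stats::rexp(1L, phot$bleach_rate) else Inf
  bleach_frame <- if (bleach_time < n * path$frame_dt)
    floor(bleach_time / path$frame_dt) + 1L else NA_integer_
  if (!is.na(bleach_frame)) {
    donor_sig[bleach_frame:n] <- 0
    acceptor_sig[bleach_frame:n] <- 0
  }

  donor <- donor_sig + phot$background_d +
    stats::rnorm(n, 0, phot$noise_sd)
  acceptor <- acceptor_sig + phot$background_a +
    stats::rnorm(n, 0, phot$noise_sd)

  intensity_trace(donor = donor, acceptor = acceptor,
                  frame_dt = path$frame_dt,
                  bleach_frame = bleach_frame)
}

#' Simulate a full trace dataset with retained ground truth
#'
#' Draws `n_traces` independent molecules from the scheme, renders each
#' under the photophysics model, and keeps the true state paths for
#' parameter-recovery checks. Per-trace sub-seeds are drawn once from the
#' master seed (`set.seed(seed)` followed by a single `sample.int`), so a
#' dataset is reproducible from `(scheme, phot, seed)` alone.
#'
#' @inheritParams simulate_state_path
#' @inheritParams render_trace
#' @param n_traces Number of molecules (>= 1).
#' @return A list with `traces` (a [trace_set()]) and `truth` (list of true
#'   `state_path`s, the scheme, and the master seed).
#' @export
simulate_dataset <- function(scheme, phot = photophysics(), n_traces = 100,
                             duration = 120, frame_dt = 0.1,
                             labeling_scheme = 1, seed = 1) {
  if (n_traces < 1) stop("n_traces must be >= 1")
  set.seed(seed)
  sub <- matrix(sample.int(2147483646L, 2L * n_traces), ncol = 2L)
  paths <- vector("list", n_traces)
  traces <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    paths[[i]] <- simulate_state_path(scheme, duration, frame_dt,
                                      seed = sub[i, 1])
    tr <- render_trace(paths[[i]], scheme, phot, labeling_scheme,
                       seed = sub[i, 2])
    tr$id <- sprintf("trace%04d", i)
    traces[[i]] <- tr
  }
  ts <- trace_set(traces, frame_dt = frame_dt,
                  metadata = list(labeling_scheme = labeling_scheme,
                                  simulated = TRUE, seed = seed))
  list(traces = ts,
       truth = list(paths = paths, scheme = scheme, phot = phot,
                    labeling_scheme = labeling_scheme, seed = seed))
}
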