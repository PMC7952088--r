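#' Apparent FRET efficiency trace
#'
#' Per-frame apparent FRET efficiency with validity and bound masks.
#' `E` is clipped to \[0, 1\]; the unclipped values are kept in `E_raw`
#' for diagnostics.
#'
#' @param E Numeric vector of clipped efficiencies (`NA` where undefined).
#' @param valid_mask Logical: frame is pre-bleach and has defined E.
#' @param bound_mask Logical: protein signal present (always `TRUE` on
#'   valid frames for labeling scheme 1; detected from total intensity for
#'   scheme 2).
#' @param frame_dt Frame interval (s).
#' @param id Trace identifier.
#' @param E_raw Unclipped efficiencies.
#' @param pre_bleach Logical mask of frames before the photobleach
#'   (defaults to `valid_mask`); distinguishes unbound scheme-2 frames
#'   (pre-bleach, unbound) from bleached ones.
#' @return An object of class `fret_trace`.
#' @export
fret_trace <- function(E, valid_mask, bound_mask, frame_dt = 0.1,
                       id = "trace", E_raw = E, pre_bleach = valid_mask) {
  n <- length(E)
  if (length(valid_mask) != n || length(bound_mask) != n ||
      length(pre_bleach) != n)
    stop("masks must have the same length as E")
  if (any(valid_mask & !is.finite(E)))
    stop("E must be finite wherever valid_mask is TRUE")
  structure(list(id = id, E = E, E_raw = E_raw,
                 valid_mask = valid_mask, bound_mask = bound_mask,
                 pre_bleach = pre_bleach, frame_dt = frame_dt),
            class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("FRET trace '%s': %d frames, %d valid, %d bound\n", x$id,
              length(x$E), sum(x$valid_mask), sum(x$bound_mask & x$valid_mask)))
  invisible(x)
}

# Robust per-frame noise SD of a signal from its first differences.
noise_sd_estimate <- function(x) {
  if (length(x) < 3L) return(0)
  stats::mad(diff(x)) / sqrt(2)
}

# Rolling-median change-point analysis of the total intensity.
# Returns the first background frame (NA if the signal persists to the
# end) and the number of detected sustained downward steps.
bleach_analysis <- function(trace, window = 5L, nsigma = 3) {
  total <- trace$donor + trace$acceptor
  n <- length(total)
  if (n < 20L) stop("photobleach detection needs >= 20 frames")
  m <- stats::runmed(total, k = window, endrule = "median")
  sigma <- noise_sd_estimate(total)  # per-frame SD of the summed signal
  level_end <- stats::median(total[max(1L, n - 9L):n])
  level_ref <- max(stats::median(m[1:min(10L, n)]),
                   stats::quantile(m, 0.9, names = FALSE))

  bleached <- (level_ref - level_end) > max(2 * nsigma * sigma,
                                            0.3 * abs(level_ref), 1e-12)
  bleach_frame <- NA_integer_
  if (bleached) {
    thr <- level_end + nsigma * sigma
    above <- which(m > thr)
    if (length(above)) bleach_frame <- max(above) + 1L
    if (!is.na(bleach_frame) && bleach_frame > n) bleach_frame <- NA_integer_
  }

  # sustained downward steps of the rolling median, measured over a
  # 3-frame lag so a step falling mid-frame is still seen whole;
  # exceedances closer than one window count as one step
  step_thr <- max(5 * sigma, 0.25 * (level_ref - level_end), 1e-12)
  lag <- 3L
  d <- m[seq_len(n - lag)] - m[(lag + 1L):n]
  drops <- which(d > step_thr)
  gap <- window + lag
  n_steps <- if (length(drops)) sum(diff(c(-gap, drops)) > gap) else 0L

  list(bleach_frame = bleach_frame, n_steps = n_steps,
       noise_sd = sigma, level_end = level_end, level_ref = level_ref)
}

#' Detect single-step photobleaching
#'
#' Finds the last sustained drop of the total intensity (donor + acceptor)
#' into the background band, using a rolling median (window 5 frames) and
#' a threshold of background + 3 noise SD. Returns the index of the first
#' bleached frame (1-based), or `NA` if the signal persists to the end of
#' the trace.
#'
#' @param trace An [intensity_trace()] with at least 20 frames.
#' @param window Rolling-median window (frames).
#' @param nsigma Threshold multiple of the estimated noise SD.
#' @return Integer frame index or `NA`.
#' @export
detect_photobleach <- function(trace, window = 5L, nsigma = 3) {
  stopifnot(inherits(trace, "intensity_trace"))
  bleach_analysis(trace, window, nsigma)$bleach_frame
}

#' Subtract per-channel background using the post-bleach signal
#'
#' Each channel is shifted by its own median over the post-bleach frames,
#' the standard background estimate when the dye bleaches within the
#' observation window. The operation is idempotent: re-applying it shifts
#' by (numerically) zero.
#'
#' @param trace An [intensity_trace()].
#' @param bleach_frame First bleached frame; defaults to the trace's
#'   stored annotation.
#' @return The corrected trace, with the removed offsets in
#'   `$background`.
#' @export
subtract_background <- function(trace, bleach_frame = trace$bleach_frame) {
  stopifnot(inherits(trace, "intensity_trace"))
  n <- length(trace$donor)
  if (is.na(bleach_frame) || n - bleach_frame + 1L < 10L)
    stop("need a bleach event with >= 10 post-bleach frames; ",
         "use a configured static background instead")
  idx <- bleach_frame:n
  off_d <- stats::median(trace$donor[idx])
  off_a <- stats::median(trace$acceptor[idx])
  trace$donor <- trace$donor - off_d
  trace$acceptor <- trace$acceptor - off_a
  trace$bleach_frame <- bleach_frame
  trace$background <- c(donor = off_d, acceptor = off_a)
  trace
}

#' Correct the acceptor channel for donor leakage
#'
#' `acceptor' = acceptor - alpha * donor`, clipped at zero; the donor
#' channel is unchanged. Apply after background subtraction.
#'
#' @param trace An [intensity_trace()].
#' @param alpha Leakage coefficient in \[0, 1).
#' @return The corrected trace.
#' @export
correct_leakage <- function(trace, alpha = 0.08) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  unclipped <- trace$acceptor - alpha * trace$donor
  trace$acceptor <- pmax(unclipped, 0)
  # kept for model fitting: clipping at 0 puts a point mass at E = 0 that
  # a Gaussian emission model must not see
  trace$acceptor_unclipped <- unclipped
  trace
}

#' Compute the apparent FRET efficiency trajectory
#'
#' `E = I_A / (I_A + I_D)` per frame from corrected intensities. Frames at
#' or after the bleach are invalid; frames whose total intensity falls
#' below `signal_threshold` get an undefined E and, for labeling scheme 2,
#' a `FALSE` bound mask (no protein present). For scheme 2, bound periods
#' must additionally last at least `min_bound_run` consecutive frames.
#'
#' @param trace A corrected [intensity_trace()].
#' @param labeling_scheme 1 or 2.
#' @param signal_threshold Minimum total intensity for E to be defined
#'   (a.u.); typically background + 4 noise SD for scheme 2.
#' @param bleach_frame First bleached frame (`NA` = none).
#' @param min_bound_run Minimum consecutive above-threshold frames for a
#'   scheme-2 bound period.
#' @return A [fret_trace()].
#' @export
compute_fret <- function(trace, labeling_scheme = 1, signal_threshold = 0,
                         bleach_frame = trace$bleach_frame,
                         min_bound_run = 2L) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (!labeling_scheme %in% c(1, 2)) stop("labeling_scheme must be 1 or 2")
  n <- length(trace$donor)
  total <- trace$donor + trace$acceptor
  pre_bleach <- if (is.na(bleach_frame)) rep(TRUE, n)
                else seq_len(n) < bleach_frame
  has_signal <- total > signal_threshold

  acc_raw <- if (!is.null(trace$acceptor_unclipped))
    trace$acceptor_unclipped else trace$acceptor
  E_raw <- ifelse(has_signal, acc_raw / (trace$donor + acc_raw), NA_real_)
  valid <- pre_bleach & is.finite(E_raw)
  if (labeling_scheme == 2) {
    # bound only during sustained signal-present runs
    r <- rle(has_signal & pre_bleach)
    keep <- r$values & r$lengths >= min_bound_run
    bound <- inverse.rle(list(values = keep, lengths = r$lengths))
    valid <- valid & bound
  } else {
    bound <- valid
  }
  if (!any(valid))
    stop("trace '", trace$id, "': no frame above the signal threshold")

  E_raw[!valid] <- NA_real_
  E <- pmin(pmax(E_raw, 0), 1)
  fret_trace(E, valid_mask = valid, bound_mask = bound,
             frame_dt = trace$frame_dt, id = trace$id, E_raw = E_raw,
             pre_bleach = pre_bleach)
}

#' Quality-control report for one trace
#'
#' Implements the three selection criteria used for smFRET trajectories:
#' anti-correlated donor/acceptor fluctuations (Pearson correlation of the
#' frame-to-frame channel differences over pre-bleach frames below
#' `anticorr_threshold`), constant total intensity (coefficient of
#' variation of the pre-bleach total below `cv_threshold`), and a single
#' photobleaching step. A trace is accepted iff all three hold. For
#' labeling scheme 2 the first two statistics are computed over
#' signal-present frames only, since unbound periods legitimately carry no
#' signal.
#'
#' @param trace An [intensity_trace()].
#' @param labeling_scheme 1 or 2.
#' @param anticorr_threshold Maximum correlation (default -0.2).
#' @param cv_threshold Maximum total-intensity CV (default 0.25).
#' @param window,nsigma Passed to the bleach-step detector.
#' @return A one-row data frame: `id`, the three criterion booleans,
#'   `accept`, `bleach_frame`, `n_steps`, and a `reasons` string.
#' @export
qc_select <- function(trace, labeling_scheme = 1,
                      anticorr_threshold = -0.2, cv_threshold = 0.25,
                      window = 5L, nsigma = 3) {
  stopifnot(inherits(trace, "intensity_trace"))
  ba <- bleach_analysis(trace, window, nsigma)
  n <- length(trace$donor)
  pre <- if (is.na(ba$bleach_frame)) seq_len(n)
         else seq_len(max(ba$bleach_frame - 1L, 0L))
  total <- trace$donor + trace$acceptor
  if (labeling_scheme == 2 && length(pre)) {
    thr <- ba$level_end + 4 * ba$noise_sd
    pre <- pre[total[pre] > thr]
  }

  if (length(pre) >= 10L) {
    dd <- diff(trace$donor[pre])
    da <- diff(trace$acceptor[pre])
    anticorr <- isTRUE(stats::cor(dd, da) < anticorr_threshold)
    mu <- mean(total[pre])
    cv <- if (mu > 0) stats::sd(total[pre]) / mu else Inf
    const_total <- isTRUE(cv < cv_threshold)
  } else {
    anticorr <- FALSE
    const_total <- FALSE
  }
  single_bleach <- !is.na(ba$bleach_frame) && ba$n_steps == 1L

  reasons <- c(if (!anticorr) "not anticorrelated",
               if (!const_total) "total not constant",
               if (!single_bleach) "no single bleach step")
  data.frame(id = trace$id, anticorrelated = anticorr,
             constant_total = const_total, single_bleach = single_bleach,
             accept = anticorr && const_total && single_bleach,
             bleach_frame = if (is.na(ba$bleach_frame)) NA_integer_
                            else ba$bleach_frame,
             n_steps = ba$n_steps,
             reasons = paste(reasons, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Correct and select a whole trace set
#'
#' Runs the per-trace pipeline: photobleach detection and QC, background
#' subtraction (post-bleach medians, falling back to `static_background`
#' when too few post-bleach frames exist), leakage correction, and FRET
#' computation. Only QC-accepted traces yield FRET trajectories.
#'
#' @param ts A [trace_set()].
#' @param labeling_scheme 1 or 2; defaults to the set's metadata.
#' @param alpha Donor leakage coefficient.
#' @param static_background Fallback `c(donor, acceptor)` offsets (a.u.).
#' @param anticorr_threshold,cv_threshold,window,nsigma QC thresholds, see
#'   [qc_select()].
#' @return List with `fret_traces` (accepted traces only), `qc` (report
#'   for every trace) and `accepted_ids`.
#' @export
correct_traces <- function(ts, labeling_scheme = NULL, alpha = 0.08,
                           static_background = c(0, 0),
                           anticorr_threshold = -0.2, cv_threshold = 0.25,
                           window = 5L, nsigma = 3) {
  stopifnot(inherits(ts, "trace_set"))
  if (is.null(labeling_scheme))
    labeling_scheme <- ts$metadata$labeling_scheme
  if (is.null(labeling_scheme)) labeling_scheme <- 1
  qc <- do.call(rbind, lapply(ts$traces, qc_select,
                              labeling_scheme = labeling_scheme,
                              anticorr_threshold = anticorr_threshold,
                              cv_threshold = cv_threshold,
                              window = window, nsigma = nsigma))
  rownames(qc) <- NULL
  fret <- list()
  for (tr in ts$traces) {
    row <- qc[qc$id == tr$id, ]
    if (!row$accept) next
    bf <- row$bleach_frame
    ctr <- tryCatch(subtract_background(tr, bf), error = function(e) {
      tr$donor <- tr$donor - static_background[1]
      tr$acceptor <- tr$acceptor - static_background[2]
      tr$bleach_frame <- bf
      tr
    })
    ctr <- correct_leakage(ctr, alpha)
    thr <- if (labeling_scheme == 2)
      4 * noise_sd_estimate(ctr$donor + ctr$acceptor) else 0
    ft <- tryCatch(compute_fret(ctr, labeling_scheme, signal_threshold = thr,
                                bleach_frame = bf),
                   error = function(e) NULL)
    if (!is.null(ft)) fret[[tr$id]] <- ft
  }
  list(fret_traces = fret, qc = qc, accepted_ids = names(fret))
}
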