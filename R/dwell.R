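# Maximal runs of identical labels within contiguous non-NA segments.
# Returns a data frame: state, start, end, length, segment.
dwell_runs <- function(labels) {
  n <- length(labels)
  if (!n) return(data.frame(state = integer(0), start = integer(0),
                            end = integer(0), length = integer(0),
                            segment = integer(0)))
  ok <- !is.na(labels)
  if (!any(ok)) return(data.frame(state = integer(0), start = integer(0),
                                  end = integer(0), length = integer(0),
                                  segment = integer(0)))
  # segments = maximal non-NA stretches
  r <- rle(ok)
  seg_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  out <- list()
  seg_n <- 0L
  for (j in seq_along(r$lengths)) {
    if (!r$values[j]) next
    seg_n <- seg_n + 1L
    idx <- seg_start[j]:(seg_start[j] + r$lengths[j] - 1L)
    rr <- rle(labels[idx])
    ends <- idx[1] - 1L + cumsum(rr$lengths)
    starts <- ends - rr$lengths + 1L
    out[[seg_n]] <- data.frame(state = rr$values, start = starts,
                               end = ends, length = rr$lengths,
                               segment = seg_n)
  }
  do.call(rbind, out)
}

#' Extract dwell times from idealized paths
#'
#' One record per maximal run of a state along each decoded path;
#' durations are run length times the frame interval. Runs abutting the
#' start or end of the observed (pre-bleach) region are flagged as
#' censored, since their true duration is unknown; decay fits exclude
#' them by default. `prev_state`/`next_state` are `NA` at observation
#' boundaries, so transitions into the bleach are never counted.
#'
#' @param paths List of decoded `state_path`s (or integer label vectors).
#' @param frame_dt Frame interval (s); taken from the paths if present.
#' @return A `dwell_table` data frame: `trace`, `state`, `duration`,
#'   `prev_state`, `next_state`, `left_censored`, `right_censored`.
#' @export
extract_dwells <- function(paths, frame_dt = NULL) {
  if (!is.list(paths) ||
      (is.list(paths) && (inherits(paths, "state_path") ||
                          !is.null(paths$labels))))
    paths <- list(paths)
  rows <- list()
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    lab <- if (is.list(p)) p$labels else p
    dt <- frame_dt
    if (is.null(dt) && is.list(p) && !is.null(p$frame_dt) &&
        is.finite(p$frame_dt)) dt <- p$frame_dt
    if (is.null(dt)) stop("frame_dt is required")
    id <- if (is.list(p) && !is.null(p$id)) p$id else as.character(i)
    dw <- dwell_runs(lab)
    if (!nrow(dw)) next
    nseg <- ave(seq_len(nrow(dw)), dw$segment, FUN = length)
    pos <- ave(seq_len(nrow(dw)), dw$segment, FUN = seq_along)
    prev <- c(NA_integer_, dw$state[-nrow(dw)])
    nxt <- c(dw$state[-1], NA_integer_)
    prev[pos == 1L] <- NA_integer_
    nxt[pos == nseg] <- NA_integer_
    rows[[i]] <- data.frame(trace = id, state = dw$state,
                            duration = dw$length * dt,
                            prev_state = prev, next_state = nxt,
                            left_censored = pos == 1L,
                            right_censored = pos == nseg,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(trace = character(0), state = integer(0),
                      duration = numeric(0), prev_state = integer(0),
                      next_state = integer(0), left_censored = logical(0),
                      right_censored = logical(0))
  rownames(out) <- NULL
  class(out) <- c("dwell_table", "data.frame")
  out
}

#' Freedman-Diaconis histogram bin width
#'
#' `w = 2 IQR(x) N^(-1/3)`, with the interquartile range computed by
#' linear-interpolation quantiles (R's default type 7). A zero IQR falls
#' back to `range/sqrt(N)` with a warning.
#'
#' @param x Numeric vector of at least 4 values (e.g. dwell times).
#' @return The bin width.
#' @export
fd_bin_width <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) stop("need at least 4 values")
  iqr <- diff(stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7))
  if (iqr == 0) {
    warning("IQR is zero; falling back to range/sqrt(N)")
    w <- diff(range(x)) / sqrt(n)
    if (w == 0) stop("degenerate data: all values equal")
    return(w)
  }
  2 * iqr * n^(-1 / 3)
}

#' Fit a single-exponential decay to a dwell-time histogram
#'
#' Bins the (uncensored, by default) dwell times with the
#' Freedman-Diaconis width, density-normalizes the histogram, and fits
#' `A * exp(-k t)` by nonlinear least squares with both amplitude and
#' rate free. The standard error comes from the fit covariance. The
#' censoring-naive maximum-likelihood estimate `1/mean` is reported
#' alongside as a cross-check.
#'
#' Two refinements matter for idealized dwell times, which are discrete
#' multiples of the frame interval: bins are aligned to frame boundaries
#' (width rounded up to a whole number of frames, first break at half a
#' frame) so discrete durations never alias across bins, and the first
#' bin is excluded from the fit by default, because dwells at or below
#' the frame time are systematically under-detected by any idealizer and
#' would otherwise flatten the decay.
#'
#' @param dwells A `dwell_table` from [extract_dwells()], or a numeric
#'   vector of durations.
#' @param state If a table is given, which state's dwells to fit.
#' @param include_censored Include boundary-truncated dwells (default
#'   `FALSE`; including them biases the rate).
#' @param min_dwells Minimum number of dwells required.
#' @param frame_dt Frame interval for frame-aligned binning; `NULL` for
#'   continuous durations.
#' @param drop_first_bin Exclude the first histogram bin from the fit
#'   (default `TRUE`).
#' @return A `dwell_fit` list: `k_obs`, `se` (1/s), `A`, `k_mle`,
#'   `se_mle`, `n`, `bin_width`.
#' @export
fit_dwell_rate <- function(dwells, state = NULL, include_censored = FALSE,
                           min_dwells = 20L, frame_dt = NULL,
                           drop_first_bin = TRUE) {
  if (is.data.frame(dwells)) {
    d <- dwells
    if (!is.null(state)) d <- d[d$state == state, , drop = FALSE]
    if (!include_censored)
      d <- d[!d$left_censored & !d$right_censored, , drop = FALSE]
    x <- d$duration
  } else {
    x <- as.numeric(dwells)
  }
  x <- x[is.finite(x) & x > 0]
  n <- length(x)
  if (n < min_dwells)
    stop("too few dwells to fit (", n, " < ", min_dwells, ")")

  w <- fd_bin_width(x)
  if (!is.null(frame_dt)) {
    w <- max(round(w / frame_dt), 1) * frame_dt
    breaks <- seq(frame_dt / 2, max(x) + w, by = w)
  } else {
    breaks <- seq(0, max(x) + w, by = w)
  }
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  df <- data.frame(t = h$mids, y = h$density)
  if (drop_first_bin && nrow(df) > 3L) df <- df[-1L, ]
  k0 <- 1 / mean(x)
  fit <- minpack.lm::nlsLM(y ~ A * exp(-k * t), data = df,
                           start = list(A = k0, k = k0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- summary(fit)$coefficients
  if (!is.finite(co["k", "Estimate"]))
    stop("exponential fit did not converge")
  structure(list(k_obs = co["k", "Estimate"], se = co["k", "Std. Error"],
                 A = co["A", "Estimate"],
                 k_mle = k0, se_mle = k0 / sqrt(n),
                 n = n, bin_width = w, fit = fit),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf(
    "Dwell decay fit: k_obs = %.4g +/- %.2g /s (n = %d, bin width %.3g s)\n",
    x$k_obs, x$se, x$n, x$bin_width))
  cat(sprintf("  MLE cross-check: 1/mean = %.4g +/- %.2g /s\n",
              x$k_mle, x$se_mle))
  invisible(x)
}

# dwell-adjacency counts per trace as a named list of from->to counts
per_trace_transition_counts <- function(paths) {
  lapply(paths, function(p) {
    lab <- if (is.list(p)) p$labels else p
    dw <- dwell_runs(lab)
    if (nrow(dw) < 2L)
      return(data.frame(from = integer(0), to = integer(0),
                        n = integer(0)))
    adjacent <- dw$segment[-1] == dw$segment[-nrow(dw)]
    from <- dw$state[-nrow(dw)][adjacent]
    to <- dw$state[-1][adjacent]
    if (!length(from))
      return(data.frame(from = integer(0), to = integer(0), n = integer(0)))
    stats::aggregate(n ~ from + to,
                     data = data.frame(from = from, to = to, n = 1L), sum)
  })
}

#' Bootstrap transition frequencies
#'
#' Counts each dwell-to-dwell transition for a random sample of
#' `sample_size` traces (drawn with replacement), repeats `n_boot` times,
#' and reports the mean count and its SD per transition. These
#' frequencies set the branching ratios used to split observed decay
#' rates into microscopic rate constants.
#'
#' @param paths List of decoded paths.
#' @param sample_size Traces per bootstrap sample (default 50; reduced
#'   with a warning if fewer traces exist).
#' @param n_boot Bootstrap replicates (default 50).
#' @param seed Integer seed.
#' @return Data frame `from`, `to`, `mean` (count), `sd`.
#' @export
transition_frequencies <- function(paths, sample_size = 50L, n_boot = 50L,
                                   seed = 1L) {
  n <- length(paths)
  if (n < sample_size) {
    warning("only ", n, " traces available; reducing sample_size")
    sample_size <- n
  }
  counts <- per_trace_transition_counts(paths)
  pairs <- unique(do.call(rbind, lapply(counts, function(d) d[c("from", "to")])))
  if (is.null(pairs) || !nrow(pairs))
    return(data.frame(from = integer(0), to = integer(0),
                      mean = numeric(0), sd = numeric(0)))
  pairs <- pairs[order(pairs$from, pairs$to), , drop = FALSE]
  key <- paste(pairs$from, pairs$to)
  # per-trace count matrix for fast resampling
  M <- matrix(0L, n, nrow(pairs))
  for (i in seq_len(n)) {
    ci <- counts[[i]]
    if (nrow(ci))
      M[i, match(paste(ci$from, ci$to), key)] <- ci$n
  }
  set.seed(seed)
  reps <- matrix(0, n_boot, nrow(pairs))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, sample_size, replace = TRUE)
    reps[b, ] <- colSums(M[idx, , drop = FALSE])
  }
  data.frame(from = pairs$from, to = pairs$to,
             mean = colMeans(reps), sd = apply(reps, 2, stats::sd))
}

#' Decompose observed decay rates into microscopic rate constants
#'
#' The observed decay rate of a state is the sum of the microscopic rate
#' constants of all transitions leaving it; the ratios of those constants
#' equal the ratios of the observed transition frequencies. Hence
#' `k_{i->j} = k_obs_i * f_{i->j} / sum_j' f_{i->j'}`, which satisfies the
#' sum identity exactly by construction and is invariant to rescaling all
#' frequencies. Uncertainties are propagated to first order from the
#' decay-fit SE and the bootstrap frequency SDs, assuming independence.
#'
#' @param k_obs Named numeric vector of observed decay rates (1/s), one
#'   per state; names are state labels matching `frequencies$from`.
#' @param frequencies Data frame from [transition_frequencies()].
#' @param k_obs_se Named numeric vector of decay-rate SEs (default 0).
#' @return A `rate_estimates` data frame: `from`, `to`, `rate`, `sd`.
#' @export
decompose_rates <- function(k_obs, frequencies, k_obs_se = NULL) {
  if (is.null(names(k_obs))) stop("k_obs must be named by state")
  if (is.null(k_obs_se)) k_obs_se <- stats::setNames(rep(0, length(k_obs)),
                                                     names(k_obs))
  rows <- list()
  for (s in names(k_obs)) {
    fr <- frequencies[as.character(frequencies$from) == s, , drop = FALSE]
    Ftot <- sum(fr$mean)
    if (!nrow(fr) || Ftot <= 0)
      stop("zero total transition frequency out of state ", s)
    k <- k_obs[[s]]
    sek <- k_obs_se[[s]]
    for (r in seq_len(nrow(fr))) {
      f <- fr$mean[r]
      kij <- k * f / Ftot
      # d(kij)/df_r = k (Ftot - f)/Ftot^2 ; d(kij)/df_other = -k f/Ftot^2
      var <- (f / Ftot * sek)^2 +
        (k * (Ftot - f) / Ftot^2)^2 * fr$sd[r]^2 +
        sum(((k * f / Ftot^2)^2 * fr$sd[-r]^2))
      rows[[length(rows) + 1L]] <- data.frame(
        from = s, to = as.character(fr$to[r]), rate = kij, sd = sqrt(var),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "k_obs") <- k_obs
  class(out) <- c("rate_estimates", "data.frame")
  out
}

#' @export
print.rate_estimates <- function(x, ...) {
  cat("Microscopic rate constants (1/s):\n")
  df <- data.frame(transition = paste0(x$from, "->", x$to),
                   rate = signif(x$rate, 4), sd = signif(x$sd, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Fraction of frames in any bound state
#'
#' `f_B = bound frames / total valid frames`, pooled over traces, with a
#' trace-level bootstrap SD (sampling `sample_size` traces with
#' replacement, `n_boot` times).
#'
#' @param paths List of decoded paths.
#' @param unbound_states Labels counted as unbound (everything else
#'   non-`NA` is bound).
#' @param sample_size,n_boot,seed Bootstrap settings.
#' @return List with `f_B` and `sd`.
#' @export
fraction_bound <- function(paths, unbound_states = 0L, sample_size = 50L,
                           n_boot = 50L, seed = 1L) {
  n <- length(paths)
  if (n < sample_size) {
    warning("only ", n, " traces available; reducing sample_size")
    sample_size <- n
  }
  per <- t(vapply(paths, function(p) {
    lab <- if (is.list(p)) p$labels else p
    lab <- lab[!is.na(lab)]
    c(bound = sum(!lab %in% unbound_states), total = length(lab))
  }, numeric(2)))
  tot <- colSums(per)
  if (tot["total"] == 0) stop("no valid frames")
  f_B <- unname(tot["bound"] / tot["total"])
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, sample_size, replace = TRUE)
    s <- colSums(per[idx, , drop = FALSE])
    if (s["total"] > 0) s["bound"] / s["total"] else NA_real_
  }, numeric(1))
  list(f_B = f_B, sd = stats::sd(reps, na.rm = TRUE))
}

#' Equilibrium dissociation constant from the bound fraction
#'
#' `Kd = [Pol]_T / f_B - [Pol]_T`, valid when the protein is in large
#' excess over the immobilized DNA so its free concentration equals the
#' total concentration. The SD follows by the delta method.
#'
#' @param f_B Fraction of bound frames (0 < f_B <= 1; f_B = 0 yields an
#'   infinite Kd, flagged rather than raised).
#' @param sd SD of `f_B`.
#' @param pol_t Total protein concentration (nM); default 5 nM, the
#'   standard acquisition condition.
#' @return A `binding_estimate` list: `f_B`, `f_B_sd`, `pol_t`, `kd`,
#'   `kd_sd` (nM), `finite`.
#' @export
estimate_kd <- function(f_B, sd = 0, pol_t = 5) {
  if (f_B < 0 || f_B > 1) stop("f_B must lie in [0, 1]")
  if (f_B == 0) {
    return(structure(list(f_B = 0, f_B_sd = sd, pol_t = pol_t,
                          kd = Inf, kd_sd = NA_real_, finite = FALSE),
                     class = "binding_estimate"))
  }
  kd <- pol_t / f_B - pol_t
  kd_sd <- pol_t * sd / f_B^2
  structure(list(f_B = f_B, f_B_sd = sd, pol_t = pol_t,
                 kd = kd, kd_sd = kd_sd, finite = TRUE),
            class = "binding_estimate")
}

#' @export
print.binding_estimate <- function(x, ...) {
  if (!x$finite) {
    cat("Binding estimate: f_B = 0, Kd is unbounded (no binding observed)\n")
  } else {
    cat(sprintf(
      "Binding estimate: f_B = %.3f +/- %.3f, Kd = %.3g +/- %.2g nM at [Pol]_T = %g nM\n",
      x$f_B, x$f_B_sd, x$kd, x$kd_sd, x$pol_t))
  }
  invisible(x)
}
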