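# Pool E values assigned to one state across traces, following the
# idealized paths.
pooled_state_values <- function(fret_traces, paths, state) {
  vals <- numeric(0)
  n_contrib <- 0L
  for (i in seq_along(fret_traces)) {
    ft <- fret_traces[[i]]
    lab <- if (is.list(paths[[i]])) paths[[i]]$labels else paths[[i]]
    if (length(lab) != length(ft$E))
      stop("path/trace length mismatch for trace '", ft$id, "'")
    sel <- !is.na(lab) & lab == state & ft$valid_mask
    if (any(sel)) {
      vals <- c(vals, ft$E[sel])
      n_contrib <- n_contrib + 1L
    }
  }
  list(values = vals, n_traces = n_contrib)
}

#' Composite kernel-density FRET histogram for one state
#'
#' Pools every efficiency datapoint whose Viterbi label equals `state`
#' across all traces and evaluates a Gaussian kernel density estimate
#' (bandwidth 0.04 on the efficiency axis) on a fixed grid covering
#' \[-0.3, 1.2\]. The relative areas of these per-state densities give the
#' state populations directly.
#'
#' @param fret_traces List of [fret_trace()] objects.
#' @param paths List of decoded paths aligned to the traces.
#' @param state Integer state label to pool.
#' @param bandwidth Gaussian kernel SD (efficiency units).
#' @param grid_from,grid_to,grid_n Evaluation grid.
#' @return A `fret_density`: `grid`, `density` (integrates to 1), `state`,
#'   `n_points`, `n_traces`, `empty`.
#' @export
composite_histogram <- function(fret_traces, paths, state, bandwidth = 0.04,
                                grid_from = -0.3, grid_to = 1.2,
                                grid_n = 500L) {
  ps <- pooled_state_values(fret_traces, paths, state)
  if (length(ps$values) == 0L) {
    return(structure(list(grid = seq(grid_from, grid_to, length.out = grid_n),
                          density = rep(0, grid_n), state = state,
                          n_points = 0L, n_traces = 0L, empty = TRUE),
                     class = "fret_density"))
  }
  d <- stats::density(ps$values, bw = bandwidth, kernel = "gaussian",
                      from = grid_from, to = grid_to, n = grid_n)
  structure(list(grid = d$x, density = d$y, state = state,
                 n_points = length(ps$values), n_traces = ps$n_traces,
                 empty = FALSE),
            class = "fret_density")
}

#' @export
print.fret_density <- function(x, ...) {
  if (x$empty) {
    cat("Empty FRET density (state", x$state, "has no assigned frames)\n")
  } else {
    peak <- x$grid[which.max(x$density)]
    cat(sprintf(
      "FRET density for state %s: %d points from %d traces, peak at E = %.3f\n",
      format(x$state), x$n_points, x$n_traces, peak))
  }
  invisible(x)
}

#' @export
plot.fret_density <- function(x, ...) {
  graphics::plot(x$grid, x$density, type = "l",
                 xlab = "apparent FRET efficiency", ylab = "density", ...)
  invisible(x)
}

# frames per label over valid frames, one row per trace
label_frame_counts <- function(paths, labels_keep) {
  t(vapply(paths, function(p) {
    lab <- if (is.list(p)) p$labels else p
    vapply(labels_keep, function(s) sum(lab == s, na.rm = TRUE), numeric(1))
  }, numeric(length(labels_keep))))
}

#' Relative state populations with bootstrap uncertainties
#'
#' Fraction of frames assigned to each bound state, pooled across traces
#' (frame-weighted, i.e. every datapoint belonging to a state counts).
#' Unbound labels are excluded from both numerator and denominator, so
#' the bound-state fractions sum to 1. Uncertainties come from a
#' trace-level bootstrap (resampling traces with replacement).
#'
#' @param paths List of decoded paths.
#' @param states Integer labels of the (bound) states to report; defaults
#'   to all positive labels present.
#' @param unbound_states Labels treated as unbound and excluded.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return Data frame with `state`, `fraction`, `sd`, `n_frames`.
#' @export
state_populations <- function(paths, states = NULL, unbound_states = 0L,
                              n_boot = 200L, seed = 1L) {
  if (!length(paths)) stop("need at least one decoded path")
  all_lab <- unlist(lapply(paths, function(p)
    if (is.list(p)) p$labels else p))
  all_lab <- all_lab[!is.na(all_lab)]
  if (is.null(states))
    states <- setdiff(sort(unique(all_lab)), unbound_states)
  counts <- label_frame_counts(paths, states)
  tot <- sum(counts)
  if (tot == 0) stop("no frames in the requested states")
  frac <- colSums(counts) / tot

  set.seed(seed)
  n <- length(paths)
  boot <- matrix(NA_real_, n_boot, length(states))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    cb <- colSums(counts[idx, , drop = FALSE])
    if (sum(cb) > 0) boot[b, ] <- cb / sum(cb)
  }
  data.frame(state = states, fraction = frac,
             sd = apply(boot, 2, stats::sd, na.rm = TRUE),
             n_frames = colSums(counts))
}

#' Transition density plot (TDP)
#'
#' Each pair of adjacent dwells contributes one 2D point: the median
#' efficiency of the initial dwell against the median efficiency of the
#' final dwell. Dwells in an unbound (no-signal) state contribute a fixed
#' sentinel efficiency (-0.2 by convention), so binding and dissociation
#' events appear as peaks along the sentinel row/column. The point cloud
#' is smoothed with a 2D Gaussian kernel (SD `bandwidth` per axis) on a
#' grid covering \[-0.3, 1.2\] squared.
#'
#' @param fret_traces List of [fret_trace()] objects.
#' @param paths List of decoded paths.
#' @param bandwidth Gaussian kernel SD per axis.
#' @param unbound_sentinel Efficiency assigned to unbound dwells.
#' @param unbound_states Labels treated as unbound.
#' @param grid_n Grid points per axis.
#' @return A `tdp_grid`: `x`, `y`, `density` (matrix integrating to 1),
#'   `points` (the dwell-pair coordinates), `n_transitions`.
#' @export
transition_density <- function(fret_traces, paths, bandwidth = 0.04,
                               unbound_sentinel = -0.2,
                               unbound_states = 0L, grid_n = 151L) {
  pts_i <- numeric(0)
  pts_f <- numeric(0)
  for (i in seq_along(fret_traces)) {
    ft <- fret_traces[[i]]
    lab <- if (is.list(paths[[i]])) paths[[i]]$labels else paths[[i]]
    dw <- dwell_runs(lab)
    if (nrow(dw) < 2L) next
    med <- vapply(seq_len(nrow(dw)), function(j) {
      if (dw$state[j] %in% unbound_states) return(unbound_sentinel)
      stats::median(ft$E[dw$start[j]:dw$end[j]], na.rm = TRUE)
    }, numeric(1))
    # adjacent dwell pairs within the same contiguous segment
    adjacent <- dw$segment[-1] == dw$segment[-nrow(dw)]
    pts_i <- c(pts_i, med[-nrow(dw)][adjacent])
    pts_f <- c(pts_f, med[-1][adjacent])
  }
  n_tr <- length(pts_i)
  lims <- c(-0.3, 1.2, -0.3, 1.2)
  if (n_tr == 0L) {
    gx <- seq(lims[1], lims[2], length.out = grid_n)
    return(structure(list(x = gx, y = gx,
                          density = matrix(0, grid_n, grid_n),
                          points = data.frame(initial = numeric(0),
                                              final = numeric(0)),
                          n_transitions = 0L),
                     class = "tdp_grid"))
  }
  # MASS::kde2d divides the supplied bandwidth by 4 internally
  kd <- MASS::kde2d(pts_i, pts_f, h = 4 * bandwidth, n = grid_n, lims = lims)
  dx <- diff(kd$x[1:2])
  dy <- diff(kd$y[1:2])
  z <- kd$z / (sum(kd$z) * dx * dy)
  structure(list(x = kd$x, y = kd$y, density = z,
                 points = data.frame(initial = pts_i, final = pts_f),
                 n_transitions = n_tr),
            class = "tdp_grid")
}

#' @export
print.tdp_grid <- function(x, ...) {
  cat(sprintf("Transition density plot: %d transitions on a %dx%d grid\n",
              x$n_transitions, length(x$x), length(x$y)))
  invisible(x)
}

#' @export
plot.tdp_grid <- function(x, n_levels = 12, ...) {
  graphics::image(x$x, x$y, x$density,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "initial FRET efficiency",
                  ylab = "final FRET efficiency", ...)
  graphics::contour(x$x, x$y, x$density, nlevels = n_levels, add = TRUE)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Exonuclease-state population correction from a binding-site mutant
#'
#' The 0.6-efficiency state mixes DNA engaging the 5' nuclease domain
#' (state N) and the proofreading exonuclease domain (state E). Comparing
#' the 0.6-state population in the wild type against a mutant whose exo
#' site cannot bind DNA (L361A) isolates the two contributions: the drop
#' equals the E-state fraction, and the remainder is the corrected N
#' population.
#'
#' @param pop_wt Wild-type 0.6-state population (fraction).
#' @param pop_mut Mutant 0.6-state population (fraction).
#' @param sd_wt,sd_mut Their standard deviations.
#' @return List with `e_fraction` (floored at 0), `n_corrected`, and `sd`
#'   (quadrature of the two input SDs).
#' @export
exo_population_correction <- function(pop_wt, pop_mut, sd_wt = 0,
                                      sd_mut = 0) {
  stopifnot(pop_wt >= 0, pop_wt <= 1, pop_mut >= 0, pop_mut <= 1)
  diff <- pop_wt - pop_mut
  sd <- sqrt(sd_wt^2 + sd_mut^2)
  if (diff < -2 * sd)
    warning("mutation increased the population by more than 2 SD; ",
            "the exo-state interpretation does not apply")
  e_fraction <- max(diff, 0)
  list(e_fraction = e_fraction, n_corrected = pop_wt - e_fraction, sd = sd)
}
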