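#' @useDynLib polfret, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Split FRET traces into contiguous observation runs (valid & bound
# frames). Plain numeric vectors are accepted and split on NA.
# Returns pooled observations, run lengths, and the run->frame mapping.
obs_sequences <- function(fret_traces) {
  if (inherits(fret_traces, "fret_trace") || is.numeric(fret_traces))
    fret_traces <- list(fret_traces)
  obs <- numeric(0)
  lens <- integer(0)
  map <- list()
  for (i in seq_along(fret_traces)) {
    ft <- fret_traces[[i]]
    if (inherits(ft, "fret_trace")) {
      use <- ft$valid_mask & ft$bound_mask
      # fit/decode on the unclipped efficiencies: the Gaussian emission
      # model must not see the point mass that clipping puts at E = 0
      x <- if (!is.null(ft$E_raw)) ft$E_raw else ft$E
    } else {
      x <- as.numeric(ft)
      use <- is.finite(x)
    }
    r <- rle(use)
    stop_idx <- cumsum(r$lengths)
    start_idx <- stop_idx - r$lengths + 1L
    for (j in which(r$values)) {
      idx <- start_idx[j]:stop_idx[j]
      obs <- c(obs, x[idx])
      lens <- c(lens, length(idx))
      map[[length(map) + 1L]] <- list(trace = i, frames = idx)
    }
  }
  list(obs = obs, lens = lens, map = map)
}

# Number of free parameters of a K-state Gaussian HMM.
hmm_df <- function(K) (K - 1L) + K * (K - 1L) + 2L * K

em_run <- function(obs, lens, mu, sigma2, trans, init, tol, max_iter,
                   variance_floor) {
  K <- length(mu)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    es <- .hmm_estep(obs, lens, mu, sigma2, trans, init)
    ll_trace <- c(ll_trace, es$loglik)
    if (iter > 1L &&
        es$loglik - ll_trace[iter - 1L] < tol) {
      converged <- TRUE
      break
    }
    g <- es$gamma_sum
    degenerate <- g < 1
    g[g < 1e-12] <- 1e-12
    mu <- es$gamma_x / g
    sigma2 <- pmax(es$gamma_x2 / g - mu^2, variance_floor)
    if (any(degenerate)) sigma2[degenerate] <- pmax(sigma2[degenerate],
                                                    variance_floor)
    xs <- es$xi_sum
    rs <- rowSums(xs)
    for (i in seq_len(K))
      trans[i, ] <- if (rs[i] > 0) xs[i, ] / rs[i] else rep(1 / K, K)
    init <- es$init_sum / sum(es$init_sum)
  }
  final_ll <- .hmm_loglik(obs, lens, mu, sigma2, trans, init)
  list(mu = mu, sigma2 = sigma2, trans = trans, init = init,
       loglik = final_ll, ll_trace = ll_trace, converged = converged,
       n_iter = length(ll_trace), degenerate = any(es$gamma_sum < 1))
}

#' Fit a global Gaussian-emission hidden Markov model to FRET traces
#'
#' Trains one shared set of HMM parameters (state means and variances on
#' the FRET-efficiency axis, per-frame transition matrix, initial
#' probabilities) on all traces of a condition simultaneously, by
#' Baum-Welch expectation-maximization with scaled per-trace
#' forward-backward passes. Contiguous runs of valid, signal-present
#' frames are treated as independent observation sequences, so for
#' labeling scheme 2 the model operates only on bound segments.
#'
#' Initialization is k-means on the pooled efficiencies plus
#' `n_restarts` random restarts; the fit with the best final likelihood
#' wins. The returned model is canonicalized by sorting state means in
#' ascending order, so results do not depend on initialization order.
#'
#' @param fret_traces List of [fret_trace()] objects (or numeric vectors,
#'   split into sequences on `NA`).
#' @param n_states Number of hidden states (>= 1).
#' @param tol EM stops when the log-likelihood gain per iteration falls
#'   below this (nats).
#' @param max_iter Maximum EM iterations.
#' @param n_restarts Random restarts in addition to the k-means start.
#' @param seed Integer seed for initialization.
#' @param variance_floor Lower bound on state variances, guarding against
#'   state collapse onto single points.
#' @return An object of class `fret_hmm` with elements `n_states`,
#'   `means`, `variances`, `transition`, `initial`, `loglik`, `ll_trace`
#'   (per-iteration log-likelihoods of the winning start), `converged`,
#'   `n_iter`, `n_obs`, `n_seq`, `df`.
#' @seealso [viterbi_decode()], [select_n_states()]
#' @export
fret_hmm <- function(fret_traces, n_states, tol = 1e-4, max_iter = 500L,
                     n_restarts = 5L, seed = 1L, variance_floor = 1e-4) {
  if (n_states < 1L) stop("n_states must be >= 1")
  sq <- obs_sequences(fret_traces)
  if (length(sq$obs) < 10L)
    stop("need at least 10 valid frames to fit an HMM")
  if (max(sq$lens) < 2L && n_states > 1L)
    warning("all observation sequences have length 1; ",
            "transition probabilities are unidentifiable")
  set.seed(seed)
  K <- n_states
  x <- sq$obs

  starts <- list()
  # k-means initialization
  if (K == 1L) {
    starts[[1]] <- list(mu = mean(x), sigma2 = max(stats::var(x), variance_floor),
                        init = 1)
  } else {
    km <- suppressWarnings(stats::kmeans(x, centers = K, nstart = 5L))
    ord <- order(km$centers)
    starts[[1]] <- list(mu = as.vector(km$centers)[ord],
                        sigma2 = pmax(km$withinss[ord] /
                                        pmax(km$size[ord], 1),
                                      variance_floor),
                        init = km$size[ord] / length(x))
    for (r in seq_len(n_restarts)) {
      q <- sort(stats::runif(K, min(x), max(x)))
      starts[[r + 1L]] <- list(mu = q,
                               sigma2 = rep(max(stats::var(x) / K, variance_floor), K),
                               init = rep(1 / K, K))
    }
  }

  best <- NULL
  for (st in starts) {
    trans <- matrix((1 - 0.9) / max(K - 1L, 1L), K, K)
    diag(trans) <- if (K == 1L) 1 else 0.9
    fit <- em_run(sq$obs, sq$lens, st$mu, st$sigma2, trans,
                  st$init / sum(st$init), tol, max_iter, variance_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (best$degenerate)
    warning("one or more states have vanishing occupancy; variance floor applied")

  ord <- order(best$mu)
  model <- structure(
    list(n_states = K,
         means = best$mu[ord],
         variances = best$sigma2[ord],
         transition = best$trans[ord, ord, drop = FALSE],
         initial = best$init[ord],
         loglik = best$loglik,
         ll_trace = best$ll_trace,
         converged = best$converged,
         n_iter = best$n_iter,
         n_obs = length(sq$obs),
         n_seq = length(sq$lens),
         df = hmm_df(K),
         tol = tol, variance_floor = variance_floor,
         call = match.call()),
    class = "fret_hmm")
  if (!best$converged)
    warning("EM did not converge in ", max_iter, " iterations")
  model
}

#' @export
print.fret_hmm <- function(x, digits = 3, ...) {
  cat(sprintf("Global FRET HMM: %d states, %d observations in %d sequences\n",
              x$n_states, x$n_obs, x$n_seq))
  cat(sprintf("log-likelihood %.2f (%s after %d iterations)\n", x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  df <- data.frame(state = seq_len(x$n_states),
                   mean_E = round(x$means, digits),
                   sd_E = round(sqrt(x$variances), digits),
                   initial = round(x$initial, digits))
  print(df, row.names = FALSE)
  cat("Per-frame transition probabilities:\n")
  print(round(x$transition, digits))
  invisible(x)
}

#' @export
summary.fret_hmm <- function(object, ...) {
  dwell_frames <- 1 / pmax(1 - diag(object$transition), 1e-12)
  out <- list(model = object,
              bic = -2 * object$loglik + object$df * log(object$n_obs),
              mean_dwell_frames = dwell_frames)
  class(out) <- "summary.fret_hmm"
  out
}

#' @export
print.summary.fret_hmm <- function(x, ...) {
  print(x$model)
  cat(sprintf("BIC %.2f\n", x$bic))
  cat("Mean dwell (frames) by state:",
      paste(round(x$mean_dwell_frames, 1), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.fret_hmm <- function(object, ...) {
  list(means = object$means, variances = object$variances,
       transition = object$transition, initial = object$initial)
}

#' @export
logLik.fret_hmm <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n_obs,
            class = "logLik")
}

#' Viterbi idealization of a FRET trace
#'
#' Computes the exact maximum a-posteriori joint state sequence for each
#' contiguous run of valid, signal-present frames under a trained
#' [fret_hmm()]. Ties are broken toward the lower state index. Zero
#' probabilities are floored in log space, so the decoder never returns
#' `NaN`.
#'
#' @param model A fitted [fret_hmm()].
#' @param fret_trace A [fret_trace()] or numeric vector of efficiencies.
#' @return A `state_path`: `$labels` is an integer vector aligned to the
#'   trace frames with values 1..K for decoded states, 0 for pre-bleach
#'   unbound (no-signal) frames, and `NA` for invalid frames;
#'   `$state_means` carries the model's state means.
#' @export
viterbi_decode <- function(model, fret_trace) {
  stopifnot(inherits(model, "fret_hmm"))
  sq <- obs_sequences(list(fret_trace))
  if (inherits(fret_trace, "fret_trace")) {
    n <- length(fret_trace$E)
    labels <- rep(NA_integer_, n)
    labels[fret_trace$pre_bleach & !fret_trace$bound_mask] <- 0L
    frame_dt <- fret_trace$frame_dt
    id <- fret_trace$id
  } else {
    n <- length(fret_trace)
    labels <- rep(NA_integer_, n)
    frame_dt <- NA_real_
    id <- "trace"
  }
  logprob <- 0
  off <- 0L
  for (j in seq_along(sq$lens)) {
    run <- sq$obs[(off + 1L):(off + sq$lens[j])]
    vit <- .hmm_viterbi(run, model$means, model$variances,
                        model$transition, model$initial)
    labels[sq$map[[j]]$frames] <- vit$path
    logprob <- logprob + vit$logprob
    off <- off + sq$lens[j]
  }
  structure(list(labels = labels, state_means = model$means,
                 frame_dt = frame_dt, id = id, logprob = logprob),
            class = "state_path")
}

#' @export
#' @rdname viterbi_decode
#' @param object,newdata,... For the `predict` method: the model, a list
#'   of FRET traces, and ignored extra arguments.
predict.fret_hmm <- function(object, newdata, ...) {
  if (inherits(newdata, "fret_trace") || is.numeric(newdata))
    newdata <- list(newdata)
  lapply(newdata, function(ft) viterbi_decode(object, ft))
}

#' @export
residuals.fret_hmm <- function(object, fret_traces, ...) {
  paths <- predict(object, fret_traces)
  if (inherits(fret_traces, "fret_trace") || is.numeric(fret_traces))
    fret_traces <- list(fret_traces)
  mapply(function(ft, p) {
    x <- if (inherits(ft, "fret_trace")) ft$E else as.numeric(ft)
    r <- rep(NA_real_, length(x))
    dec <- !is.na(p$labels) & p$labels > 0L
    r[dec] <- x[dec] - object$means[p$labels[dec]]
    r
  }, fret_traces, paths, SIMPLIFY = FALSE)
}

#' Simulate FRET-efficiency traces from a fitted HMM
#'
#' Draws state sequences from the model's Markov chain and Gaussian
#' emissions around the state means. This simulates on the efficiency
#' axis directly (no photophysics); use [simulate_dataset()] for full
#' intensity traces.
#'
#' @param object A [fret_hmm()].
#' @param nsim Number of traces.
#' @param seed Integer seed.
#' @param nframes Frames per trace.
#' @param ... Unused.
#' @return List of numeric E vectors, with the true label vectors in
#'   `attr(, "paths")`.
#' @export
simulate.fret_hmm <- function(object, nsim = 1, seed = NULL,
                              nframes = 100L, ...) {
  if (!is.null(seed)) set.seed(seed)
  K <- object$n_states
  out <- vector("list", nsim)
  paths <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    s <- integer(nframes)
    s[1] <- sample.int(K, 1L, prob = object$initial)
    for (t in seq_len(nframes - 1L))
      s[t + 1L] <- sample.int(K, 1L, prob = object$transition[s[t], ])
    paths[[i]] <- s
    out[[i]] <- stats::rnorm(nframes, object$means[s],
                             sqrt(object$variances[s]))
  }
  attr(out, "paths") <- paths
  out
}

#' @export
plot.fret_hmm <- function(x, fret_traces = NULL, ...) {
  grid <- seq(-0.3, 1.2, length.out = 400L)
  # stationary state weights of the fitted chain
  ev <- eigen(t(x$transition))
  w <- abs(Re(ev$vectors[, which.min(abs(ev$values - 1))]))
  w <- w / sum(w)
  comp <- sapply(seq_len(x$n_states), function(k)
    w[k] * stats::dnorm(grid, x$means[k], sqrt(x$variances[k])))
  mix <- rowSums(comp)
  if (!is.null(fret_traces)) {
    sq <- obs_sequences(fret_traces)
    d <- stats::density(sq$obs, bw = 0.04, from = -0.3, to = 1.2)
    graphics::plot(d, main = "FRET efficiency density and HMM components",
                   xlab = "apparent FRET efficiency", ...)
    ylim_max <- max(d$y)
  } else {
    graphics::plot(grid, mix, type = "l",
                   main = "HMM emission mixture",
                   xlab = "apparent FRET efficiency", ylab = "density", ...)
  }
  for (k in seq_len(x$n_states))
    graphics::lines(grid, comp[, k], lty = 2, col = k + 1L)
  graphics::lines(grid, mix, col = 1, lwd = 2)
  invisible(x)
}

#' Choose the number of HMM states by BIC
#'
#' Fits each candidate state count and reports the Bayesian information
#' criterion; the chosen model is the smallest state count within 10 BIC
#' units of the minimum (an automated stand-in for choosing the minimum
#' number of states that adequately fits the traces by inspection). The
#' full table is returned so a human can override.
#'
#' @param fret_traces As in [fret_hmm()].
#' @param candidates Integer vector of state counts to try.
#' @param seed Seed forwarded to each fit.
#' @param ... Further arguments to [fret_hmm()].
#' @return List with `n_states` (chosen), `table` (candidate, loglik, df,
#'   bic), and `models` (the fitted models, named by state count).
#' @export
select_n_states <- function(fret_traces, candidates = 1:4, seed = 1L, ...) {
  if (!length(candidates)) stop("candidates must be non-empty")
  candidates <- sort(unique(as.integer(candidates)))
  models <- list()
  rows <- list()
  for (K in candidates) {
    m <- suppressWarnings(fret_hmm(fret_traces, K, seed = seed, ...))
    models[[as.character(K)]] <- m
    rows[[as.character(K)]] <- data.frame(
      n_states = K, loglik = m$loglik, df = m$df,
      bic = -2 * m$loglik + m$df * log(m$n_obs))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  chosen <- min(tab$n_states[tab$bic <= min(tab$bic) + 10])
  list(n_states = chosen, table = tab, models = models)
}
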