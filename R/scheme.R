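#' Kinetic scheme for a Pol I-DNA complex
#'
#' A continuous-time Markov chain over complex configurations. States are a
#' subset of the configurations observed for Pol I on flap/gapped DNA
#' substrates: unbound DNA (`U`), primer engaging the polymerase domain
#' (`P`), the 5' nuclease domain (`N`), the proofreading exonuclease domain
#' (`E`), and the polymerase-engaged complex with the 5' nuclease domain
#' extended away (`P'`). Each state carries a mean apparent FRET efficiency
#' (for the labeling scheme the object describes), an emission SD, and a
#' flag saying whether the protein is DNA-bound in that state.
#'
#' @param state_names Character vector of state labels.
#' @param rate_matrix Square numeric matrix of transition rates
#'   \eqn{k_{i \to j}} in 1/s; the diagonal is ignored. All off-diagonal
#'   entries must be non-negative.
#' @param bound Logical vector: is the protein bound to the DNA in each
#'   state? Exactly one state must be unbound.
#' @param fret_means Numeric vector of mean apparent FRET efficiencies per
#'   state, each in \[-0.2, 1.2\].
#' @param fret_sds Numeric vector (or scalar, recycled) of per-state FRET
#'   emission SDs.
#'
#' @return An object of class `kinetic_scheme`.
#' @seealso [scheme1_default()], [scheme2_default()], [simulate_state_path()]
#' @export
kinetic_scheme <- function(state_names, rate_matrix, bound, fret_means,
                           fret_sds = 0.07) {
  state_names <- as.character(state_names)
  K <- length(state_names)
  if (K < 1L) stop("at least one state is required")
  if (anyDuplicated(state_names)) stop("state names must be unique")
  rate_matrix <- as.matrix(rate_matrix)
  if (!all(dim(rate_matrix) == K))
    stop("rate_matrix must be ", K, " x ", K)
  diag(rate_matrix) <- 0
  if (any(rate_matrix < 0)) stop("all rates must be >= 0")
  bound <- as.logical(bound)
  if (length(bound) != K) stop("bound must have one flag per state")
  if (sum(!bound) > 1L)
    stop("at most one state may be unbound")
  fret_means <- as.numeric(fret_means)
  if (length(fret_means) != K) stop("fret_means must have one value per state")
  if (any(fret_means < -0.2 | fret_means > 1.2))
    stop("fret_means must lie in [-0.2, 1.2]")
  fret_sds <- rep_len(as.numeric(fret_sds), K)
  if (any(fret_sds < 0)) stop("fret_sds must be >= 0")
  dimnames(rate_matrix) <- list(state_names, state_names)
  structure(
    list(state_names = state_names, rate_matrix = rate_matrix,
         bound = stats::setNames(bound, state_names),
         fret_means = stats::setNames(fret_means, state_names),
         fret_sds = stats::setNames(fret_sds, state_names)),
    class = "kinetic_scheme"
  )
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme with", length(x$state_names), "states\n")
  df <- data.frame(state = x$state_names, bound = unname(x$bound),
                   fret_mean = unname(x$fret_means),
                   fret_sd = unname(x$fret_sds),
                   exit_rate = rowSums(x$rate_matrix))
  print(df, row.names = FALSE)
  cat("Transition rates (1/s):\n")
  print(x$rate_matrix)
  invisible(x)
}

#' Default labeling-scheme-1 kinetic scheme (donor on the DNA)
#'
#' Three-state scheme U (unbound), P (pol-domain engaged, E ~ 0.8) and
#' N (5' nuclease engaged, E ~ 0.6). With the donor on the upstream primer
#' the unbound state still emits donor signal, giving a near-zero apparent
#' FRET efficiency (default 0.05 after leakage correction).
#'
#' Default rates (1/s): `k_P->N` = 1.0, `k_N->P` = 2.0, `k_P->U` = 0.5,
#' `k_N->U` = 0.5, `k_U->P` = 1.0 — the regime of reversible pol/5'nuc
#' domain switching punctuated by dissociation that the flap substrates
#' show at 5 nM protein.
#'
#' @param rates Optional named numeric vector overriding individual rates;
#'   names like `"P->N"`.
#' @param fret_means Named state means (default U 0.05, P 0.8, N 0.6).
#' @param fret_sds Per-state emission SD (default 0.07).
#' @return A [kinetic_scheme()].
#' @export
scheme1_default <- function(rates = NULL,
                            fret_means = c(U = 0.05, P = 0.8, N = 0.6),
                            fret_sds = 0.07) {
  states <- c("U", "P", "N")
  Q <- matrix(0, 3, 3, dimnames = list(states, states))
  Q["U", "P"] <- 1.0
  Q["P", "N"] <- 1.0
  Q["N", "P"] <- 2.0
  Q["P", "U"] <- 0.5
  Q["N", "U"] <- 0.5
  if (!is.null(rates)) {
    for (nm in names(rates)) {
      ij <- strsplit(nm, "->", fixed = TRUE)[[1]]
      if (length(ij) != 2L || !all(ij %in% states))
        stop("bad rate name: ", nm)
      Q[ij[1], ij[2]] <- rates[[nm]]
    }
  }
  kinetic_scheme(states, Q, bound = c(FALSE, TRUE, TRUE),
                 fret_means = fret_means[states], fret_sds = fret_sds)
}

#' Default labeling-scheme-2 kinetic scheme (donor on the protein)
#'
#' With the donor on the 5' nuclease domain and the acceptor on the
#' downstream template, unbound periods carry no signal at all; bound
#' states have E ~ 0.6 (P) and ~ 0.8 (N). A primer/template-only species
#' P' (5' nuclease domain extended away, E ~ 0.3) can be added via
#' `include_pprime`.
#'
#' @param include_pprime Add the P' state (default `FALSE`).
#' @param fret_sds Per-state emission SD (default 0.07).
#' @return A [kinetic_scheme()].
#' @export
scheme2_default <- function(include_pprime = FALSE, fret_sds = 0.07) {
  if (include_pprime) {
    states <- c("U", "P'", "P", "N")
    Q <- matrix(0, 4, 4, dimnames = list(states, states))
    Q["U", "P'"] <- 1.0
    Q["P'", "U"] <- 0.5
    Q["P'", "P"] <- 0.05   # P' <-> P interconversion is rare (few TDP cross peaks)
    Q["P", "P'"] <- 0.05
    Q["P", "N"] <- 1.0
    Q["N", "P"] <- 2.0
    Q["P", "U"] <- 0.5
    Q["N", "U"] <- 0.5
    means <- c(U = 0, "P'" = 0.3, P = 0.6, N = 0.8)
    kinetic_scheme(states, Q, bound = c(FALSE, TRUE, TRUE, TRUE),
                   fret_means = means[states], fret_sds = fret_sds)
  } else {
    states <- c("U", "P", "N")
    Q <- matrix(0, 3, 3, dimnames = list(states, states))
    Q["U", "P"] <- 1.0
    Q["P", "N"] <- 1.0
    Q["N", "P"] <- 2.0
    Q["P", "U"] <- 0.5
    Q["N", "U"] <- 0.5
    kinetic_scheme(states, Q, bound = c(FALSE, TRUE, TRUE),
                   fret_means = c(U = 0, P = 0.6, N = 0.8)[states],
                   fret_sds = fret_sds)
  }
}

#' Stationary distribution of a kinetic scheme
#'
#' Solves \eqn{\pi Q = 0}, \eqn{\sum \pi = 1} for the CTMC generator built
#' from the off-diagonal rates.
#'
#' @param scheme A [kinetic_scheme()].
#' @return Named numeric vector of stationary state probabilities.
#' @export
stationary_distribution <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  Q <- scheme$rate_matrix
  diag(Q) <- -rowSums(Q)
  K <- nrow(Q)
  # solve pi Q = 0 with the normalization replacing one equation
  A <- rbind(t(Q), rep(1, K))
  b <- c(rep(0, K), 1)
  pi <- stats::setNames(as.vector(qr.solve(A, b)), scheme$state_names)
  pi[pi < 0 & pi > -1e-12] <- 0
  pi / sum(pi)
}

#' Photophysics / detection model for trace rendering
#'
#' Describes how a state path turns into camera intensities: total summed
#' signal when bound, additive channel backgrounds, per-channel Gaussian
#' read noise, donor-to-acceptor spectral leakage, and a single-step donor
#' photobleaching rate.
#'
#' Defaults: `total_intensity` 350 a.u. (the single-molecule acceptor
#' level seen by direct excitation), backgrounds 10 a.u., `noise_sd` 30
#' a.u. (giving an apparent-FRET spread of roughly 0.07 at 350 a.u.
#' total), `leakage_alpha` 0.08, and `bleach_rate` 0.05/s (mean dye
#' survival 20 s, so nearly every molecule shows its bleach step within a
#' 120 s observation window).
#'
#' @param total_intensity Mean donor+acceptor signal when bound (a.u.).
#' @param background_d,background_a Additive channel offsets (a.u.).
#' @param noise_sd Gaussian per-channel SD (a.u.).
#' @param leakage_alpha Fraction of donor signal bleeding into the
#'   acceptor channel, in \[0, 0.3\].
#' @param bleach_rate Donor photobleaching rate (1/s); single exponential.
#' @return An object of class `photophysics`.
#' @export
photophysics <- function(total_intensity = 350, background_d = 10,
                         background_a = 10, noise_sd = 30,
                         leakage_alpha = 0.08, bleach_rate = 0.05) {
  if (total_intensity <= 0) stop("total_intensity must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (leakage_alpha < 0 || leakage_alpha > 0.3)
    stop("leakage_alpha must lie in [0, 0.3]")
  if (bleach_rate < 0) stop("bleach_rate must be >= 0")
  structure(
    list(total_intensity = total_intensity, background_d = background_d,
         background_a = background_a, noise_sd = noise_sd,
         leakage_alpha = leakage_alpha, bleach_rate = bleach_rate),
    class = "photophysics"
  )
}

#' @export
print.photophysics <- function(x, ...) {
  cat("Photophysics model:\n")
  cat(sprintf("  total intensity %.4g a.u., background (D, A) = (%.4g, %.4g) a.u.\n",
              x$total_intensity, x$background_d, x$background_a))
  cat(sprintf("  noise SD %.4g a.u., leakage alpha %.3g, bleach rate %.3g /s\n",
              x$noise_sd, x$leakage_alpha, x$bleach_rate))
  invisible(x)
}
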