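#' Förster context
#'
#' Holds the Förster radius R0 (the donor-acceptor distance at which the
#' transfer efficiency is 0.5). The default of 52 Angstrom is the value
#' (to the nearest Angstrom) jointly consistent with the distances the
#' two labeling schemes report for efficiencies 0.8, 0.6 and 0.3; set it
#' per dye pair as needed.
#'
#' @param R0 Förster radius in Angstrom (> 0).
#' @return An object of class `forster_context`.
#' @export
forster_context <- function(R0 = 52) {
  if (R0 <= 0) stop("R0 must be > 0")
  structure(list(R0 = R0), class = "forster_context")
}

#' Donor-acceptor distance from FRET efficiency
#'
#' `r = R0 (1/E - 1)^(1/6)` under the Förster relation.
#'
#' @param E Apparent FRET efficiency, strictly between 0 and 1.
#' @param ctx A [forster_context()].
#' @return Distance in Angstrom.
#' @export
distance_from_fret <- function(E, ctx = forster_context()) {
  if (any(E <= 0 | E >= 1))
    stop("E must lie strictly between 0 and 1")
  ctx$R0 * (1 / E - 1)^(1 / 6)
}

#' FRET efficiency from donor-acceptor distance
#'
#' `E = 1 / (1 + (r/R0)^6)`; the exact inverse of
#' [distance_from_fret()].
#'
#' @param r Distance in Angstrom (> 0).
#' @param ctx A [forster_context()].
#' @return Efficiency in (0, 1).
#' @export
fret_from_distance <- function(r, ctx = forster_context()) {
  if (any(r <= 0)) stop("r must be > 0")
  1 / (1 + (r / ctx$R0)^6)
}

#' Distance change between two FRET states
#'
#' `distance_change(E1, E2)` is positive when the second state is more
#' extended (lower efficiency) than the first; it is antisymmetric in its
#' arguments.
#'
#' @param E1,E2 Efficiencies strictly between 0 and 1.
#' @param ctx A [forster_context()].
#' @return `r(E2) - r(E1)` in Angstrom.
#' @export
distance_change <- function(E1, E2, ctx = forster_context()) {
  distance_from_fret(E2, ctx) - distance_from_fret(E1, ctx)
}
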