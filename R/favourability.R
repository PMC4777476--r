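#' The favourability transformation
#'
#' Converts the probability output of a presence/absence logistic model into
#' favourability, a prevalence-corrected suitability index:
#'
#' \deqn{F = \frac{P/(1-P)}{n_1/n_0 + P/(1-P)}}
#'
#' where `P` is the modelled probability in a cell, `n1` the number of
#' presences and `n0` the number of absences in the modelling dataset.
#' Favourability removes the effect of species prevalence: F = 0.5 marks
#' conditions exactly as good as the species' average (P equal to the
#' prevalence), so favourability values are comparable across species with
#' different presence/absence ratios.
#'
#' Computation uses the equivalent logit-shift identity
#' `F = plogis(qlogis(P) - log(n1/n0))`, which is numerically stable near
#' P = 0 and P = 1; the limits F(0) = 0 and F(1) = 1 are returned exactly.
#'
#' @param p probability value(s) in \[0, 1\].
#' @param n1 number of presences (>= 1).
#' @param n0 number of absences (>= 1).
#' @return favourability value(s) in \[0, 1\].
#' @examples
#' favourability(250 / 4532, n1 = 250, n0 = 4282)  # prevalence -> exactly 0.5
#' @export
favourability <- function(p, n1, n0) {
  if (n1 < 1 || n0 < 1) stop("n1 and n0 must both be >= 1")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  out <- stats::plogis(stats::qlogis(p) - log(n1 / n0))
  out[p == 0] <- 0
  out[p == 1] <- 1
  out
}

#' Invert the favourability transformation
#'
#' Exact algebraic inverse of [favourability()]: recovers the probability
#' whose favourability equals `f` for a dataset with `n1` presences and `n0`
#' absences. Useful to express the neutral favourability threshold F = 0.5 on
#' the probability scale (it maps back to the prevalence).
#'
#' @param f favourability value(s) in \[0, 1\].
#' @inheritParams favourability
#' @return probability value(s) in \[0, 1\].
#' @export
probability_from_favourability <- function(f, n1, n0) {
  if (n1 < 1 || n0 < 1) stop("n1 and n0 must both be >= 1")
  if (anyNA(f) || any(f < 0 | f > 1)) stop("favourability must lie in [0, 1]")
  out <- stats::plogis(stats::qlogis(f) + log(n1 / n0))
  out[f == 0] <- 0
  out[f == 1] <- 1
  out
}

#' Classify favourability values into low / medium / high
#'
#' Three-way banding used for presentation maps: `low` below `low_cut`,
#' `high` at or above `high_cut` (the upper boundary is inclusive on the high
#' side), `medium` otherwise.
#'
#' @param f favourability value(s) in \[0, 1\].
#' @param low_cut,high_cut band boundaries, 0 < low_cut < high_cut < 1;
#'   defaults 0.2 and 0.8, the customary favourability bands.
#' @return factor with levels `low`, `medium`, `high`.
#' @export
classify_favourability <- function(f, low_cut = 0.2, high_cut = 0.8) {
  if (!(low_cut > 0 && low_cut < high_cut && high_cut < 1))
    stop("cuts must satisfy 0 < low_cut < high_cut < 1")
  out <- ifelse(f < low_cut, "low", ifelse(f >= high_cut, "high", "medium"))
  factor(out, levels = c("low", "medium", "high"))
}
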