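#' Construct an in-silico cell-line response profile
#'
#' The viability oracle models each drug's single-agent effect as a Hill
#' curve (parameters \code{ec50} in ng/mL, slope \code{hill}, maximal kill
#' fraction \code{emax} in [0, 1]) and combines drugs under Bliss
#' independence with an optional pairwise additive deviation (a
#' "Bliss excess" surface): a symmetric coefficient \eqn{\gamma_{ij}} per
#' drug pair, 0 meaning exactly Bliss-independent, negative synergy (extra
#' kill), positive antagonism. See [predict_survival()] for the scaling of
#' \eqn{\gamma}.
#'
#' @param ec50 named positive vector, one entry per drug (ng/mL).
#' @param hill named positive vector of Hill slopes.
#' @param emax named vector of maximal kill fractions in [0, 1].
#' @param interaction symmetric matrix of pairwise gamma in [-1, 1]
#'   (drugs x drugs, diagonal ignored), or NULL for no interactions.
#' @param noise_sd Gaussian measurement noise, percent survival, >= 0.
#' @param name optional cell-line identifier.
#' @return An object of class \code{cell_line_profile}.
#' @export
cell_line_profile <- function(ec50, hill, emax, interaction = NULL,
                              noise_sd = 3, name = "line") {
  drugs <- names(ec50)
  if (is.null(drugs)) stop("ec50 must be named by drug")
  stopifnot(all(ec50 > 0), all(hill[drugs] > 0),
            all(emax[drugs] >= 0), all(emax[drugs] <= 1), noise_sd >= 0)
  if (is.null(interaction)) {
    interaction <- matrix(0, length(drugs), length(drugs),
                          dimnames = list(drugs, drugs))
  }
  interaction <- as.matrix(interaction)[drugs, drugs]
  if (any(abs(interaction) > 1)) stop("|interaction gamma| must be <= 1")
  if (any(interaction != t(interaction))) stop("interaction must be symmetric")
  structure(
    list(drugs = drugs, ec50 = ec50, hill = hill[drugs], emax = emax[drugs],
         interaction = interaction, noise_sd = noise_sd, name = name),
    class = "cell_line_profile"
  )
}

#' Draw a cell-line profile from a resistance archetype
#'
#' Archetypes mirror the spread seen across bladder-cancer panels:
#' \code{sensitive} lines have EC50s well inside the tested dose ladder,
#' \code{resistant} lines sit at least an order of magnitude higher,
#' \code{moderate} in between, and \code{benign} (the normal-epithelium
#' stand-in) has uniformly high EC50s and a reduced attainable kill.
#' EC50s are drawn log-uniformly from archetype bands expressed as
#' multiples of each drug's geometric-mid ladder dose.
#'
#' @param panel a [drug_panel()] supplying drugs and dose ladders.
#' @param archetype one of \code{"sensitive"}, \code{"moderate"},
#'   \code{"resistant"}, \code{"benign"}.
#' @param noise_sd measurement noise (percent survival), default 3.
#' @param name optional cell-line identifier.
#' @return A [cell_line_profile()]. Uses R's RNG stream; seed outside.
#' @export
sample_profile <- function(panel, archetype = c("sensitive", "moderate",
                                                "resistant", "benign"),
                           noise_sd = 3, name = NULL) {
  stopifnot(inherits(panel, "drug_panel"))
  archetype <- match.arg(archetype)
  band <- switch(archetype,
    sensitive = c(0.05, 0.5),
    moderate  = c(0.5, 5),
    resistant = c(5, 50),
    benign    = c(20, 200)
  )
  emax_band <- switch(archetype,
    sensitive = c(0.90, 1.00),
    moderate  = c(0.80, 0.95),
    resistant = c(0.70, 0.90),
    benign    = c(0.50, 0.75)
  )
  drugs <- panel$drugs
  mid <- vapply(panel$dose_levels, function(lv) exp(mean(log(lv))), numeric(1))
  ec50 <- mid * 10^stats::runif(length(drugs), log10(band[1]), log10(band[2]))
  names(ec50) <- drugs
  hill <- stats::setNames(stats::runif(length(drugs), 0.8, 2), drugs)
  emax <- stats::setNames(stats::runif(length(drugs), emax_band[1],
                                       emax_band[2]), drugs)
  cell_line_profile(ec50, hill, emax, noise_sd = noise_sd,
                    name = name %||% paste0(archetype, "-line"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Noise-free predicted survival for combinations
#'
#' Per-drug kill \eqn{k_i = e_i d_i^{h_i} / (ec50_i^{h_i} + d_i^{h_i})};
#' Bliss baseline survival fraction \eqn{\prod_i (1 - k_i)}; pairwise
#' Bliss-excess deviation added on the survival-fraction scale,
#' \deqn{S = 100 \, \mathrm{clamp}\Big(\prod_i (1 - k_i) +
#'       3 \sum_{i<j} \gamma_{ij} k_i k_j,\; 0,\; 1\Big).}
#' With all \eqn{\gamma = 0} this is exact Bliss independence and survival
#' is monotone non-increasing in every dose. The factor 3 calibrates the
#' deviation so that a moderate \eqn{|\gamma| = 0.5} interaction exceeds
#' the Bliss product's own positive cross term \eqn{+k_i k_j} and is
#' therefore readable off a fitted second-order response surface; a purely
#' multiplicative deviation of the same magnitude never changes the sign
#' of that surface's bilinear term.
#'
#' @param profile a [cell_line_profile()].
#' @param combos data frame of doses (ng/mL), one column per drug, or a
#'   single named dose vector.
#' @return Numeric vector of survival percentages, one per combination.
#' @export
predict_survival <- function(profile, combos) {
  stopifnot(inherits(profile, "cell_line_profile"))
  if (!is.data.frame(combos)) combos <- as.data.frame(as.list(combos))
  d <- as.matrix(combos[profile$drugs])
  if (any(d < 0)) stop("negative dose")
  k <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  for (j in seq_along(profile$drugs)) {
    dj <- d[, j]
    e <- profile$ec50[j]; h <- profile$hill[j]
    k[, j] <- profile$emax[j] * dj^h / (e^h + dj^h)
  }
  s <- apply(1 - k, 1, prod)
  gam <- profile$interaction
  idx <- which(upper.tri(gam) & gam != 0, arr.ind = TRUE)
  if (nrow(idx)) {
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      s <- s + 3 * gam[i, j] * k[, i] * k[, j]
    }
  }
  unname(100 * pmin(pmax(s, 0), 1))
}

#' Simulate a plate screen over a cell-line panel
#'
#' For every (combination, cell line) the reported survival is the mean of
#' \code{replicates} independent draws of noise-free prediction plus
#' Gaussian noise (the profile's \code{noise_sd}), with the final entry
#' truncated to [0, 120] (the tolerance band of plate readers that report
#' slightly-above-control wells).
#'
#' @param profiles list of [cell_line_profile()]; names (or profile names)
#'   become the cell-line columns.
#' @param combos data frame of doses, one row per combination.
#' @param replicates assay replicates averaged per well (default 3,
#'   triplicate).
#' @param round_id,divisor,label passed to [viability_table()]; divisor
#'   defaults to the number of cell lines.
#' @return A [viability_table()]. Uses R's RNG stream; seed outside.
#' @export
simulate_panel <- function(profiles, combos, replicates = 3,
                           round_id = "simulated",
                           divisor = length(profiles), label = NULL) {
  if (inherits(profiles, "cell_line_profile")) profiles <- list(profiles)
  nm <- names(profiles) %||% vapply(profiles, `[[`, character(1), "name")
  if (is.null(names(profiles))) names(profiles) <- nm
  combos <- as.data.frame(combos)
  surv <- vapply(profiles, function(p) {
    truth <- predict_survival(p, combos)
    draws <- replicate(replicates,
                       truth + stats::rnorm(length(truth), 0, p$noise_sd))
    draws <- matrix(draws, nrow = length(truth))
    pmin(pmax(rowMeans(draws), 0), 120)
  }, numeric(nrow(combos)))
  surv <- matrix(surv, nrow = nrow(combos),
                 dimnames = list(NULL, names(profiles)))
  suppressWarnings(
    viability_table(combos, surv, round_id = round_id, divisor = divisor,
                    label = label)
  )
}

#' A deterministic or stochastic viability oracle from profiles
#'
#' Wraps a profile list as the oracle interface consumed by
#' [run_fsc_loop()]: a function taking a data frame of dose combinations
#' and returning the survival matrix (combinations x cell lines), averaging
#' \code{replicates} noisy draws per well (noise-free when every profile
#' has \code{noise_sd = 0}).
#'
#' @inheritParams simulate_panel
#' @return A function \code{f(combos) -> matrix}.
#' @export
panel_oracle <- function(profiles, replicates = 3) {
  if (inherits(profiles, "cell_line_profile")) profiles <- list(profiles)
  force(replicates)
  function(combos) {
    simulate_panel(profiles, combos, replicates = replicates)$survival
  }
}
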