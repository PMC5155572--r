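#' The nine pathway reporters
#'
#' Default pathway list of the dual-luciferase reporter stage. Kept
#' configurable: every function below takes the pathway set from its
#' input's names.
#' @export
PATHWAYS <- c("DNA Damage", "Hypoxia", "ER Stress", "Heat Shock", "Wnt",
              "Notch", "Cell Cycle", "Myc/Max", "MAPK/ERK")

#' Normalize a dual-luciferase reporter reading
#'
#' Pathway activity = background-subtracted firefly signal over the
#' constitutive Renilla signal: \code{max(firefly - background, 0) /
#' renilla}. A firefly signal below its promoter-less negative control is
#' clamped to zero activity with a warning. Vectorized.
#'
#' @param firefly inducible firefly luciferase signal (>= 0).
#' @param renilla constitutive Renilla signal (> 0).
#' @param background firefly signal of the matched negative control.
#' @return Normalized activity (dimensionless, >= 0).
#' @export
normalize_reporter <- function(firefly, renilla, background = 0) {
  if (any(renilla <= 0)) stop("Renilla signal must be positive")
  if (any(firefly < 0) || any(background < 0)) {
    stop("luciferase signals must be non-negative")
  }
  net <- firefly - background
  if (any(net < 0)) {
    warning(sum(net < 0),
            " firefly reading(s) below background clamped to 0")
    net <- pmax(net, 0)
  }
  net / renilla
}

#' Per-condition pathway activities from replicate reporter readings
#'
#' Normalizes each replicate with [normalize_reporter()] and averages the
#' normalized activities per (pathway, cell line, treatment).
#'
#' @param readings data frame with columns \code{pathway},
#'   \code{cell_line}, \code{treatment}, \code{replicate}, \code{firefly},
#'   \code{renilla}, \code{firefly_negctrl}.
#' @return Data frame \code{pathway}, \code{cell_line}, \code{treatment},
#'   \code{activity}.
#' @export
reporter_activity <- function(readings) {
  need <- c("pathway", "cell_line", "treatment", "firefly", "renilla",
            "firefly_negctrl")
  missing_cols <- setdiff(need, names(readings))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  readings$activity <- normalize_reporter(readings$firefly,
                                          readings$renilla,
                                          readings$firefly_negctrl)
  out <- stats::aggregate(activity ~ pathway + cell_line + treatment,
                          data = readings, FUN = mean)
  out[order(out$cell_line, out$treatment, out$pathway), , drop = FALSE]
}

#' Fold-change of pathway activities against a reference profile
#'
#' For basal comparisons the reference is the most chemo-sensitive line's
#' basal profile; for drug-response comparisons, the same line's no-drug
#' profile. The reference's fold against itself is exactly 1.
#'
#' @param activity named numeric vector of activities (names = pathways).
#' @param reference named numeric vector over the same pathways, all > 0.
#' @return Named fold-change vector.
#' @export
relative_activity <- function(activity, reference) {
  if (is.null(names(activity)) || is.null(names(reference))) {
    stop("activity vectors must be named by pathway")
  }
  missing_pw <- setdiff(names(activity), names(reference))
  if (length(missing_pw)) {
    stop("reference lacks pathway(s): ", paste(missing_pw, collapse = ", "))
  }
  ref <- reference[names(activity)]
  if (any(ref <= 0)) stop("reference activity must be positive")
  activity / ref
}

#' Digitize fold-changes to ternary pathway states
#'
#' State 1 (activated) iff fold strictly above the \code{up} threshold,
#' -1 (repressed) iff strictly below \code{down}, else 0. Comparisons are
#' strict: a fold exactly at a threshold is null.
#'
#' @param fold named non-negative fold-change vector.
#' @param up activation threshold (default 1.5).
#' @param down repression threshold (default 0.5).
#' @return Named integer vector with values in \{-1, 0, 1\}.
#' @export
digitize_states <- function(fold, up = 1.5, down = 0.5) {
  if (any(fold < 0)) stop("fold-changes must be non-negative")
  stopifnot(down < up)
  state <- integer(length(fold))
  state[fold > up] <- 1L
  state[fold < down] <- -1L
  names(state) <- names(fold)
  state
}

#' Pearson correlation of two digitized state vectors
#'
#' Sample Pearson correlation of two ternary profiles of equal length.
#' A zero-variance (constant) vector makes the correlation undefined and
#' raises an explicit error rather than returning a silent 0 or 1.
#'
#' @param a,b state vectors (same length; typically from
#'   [digitize_states()]).
#' @return Correlation in [-1, 1].
#' @export
state_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("state vectors differ in length")
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("undefined correlation: a state vector has zero variance")
  }
  stats::cor(a, b)
}

#' Pairwise correlation matrix over digitized profiles
#'
#' @param states matrix with one column per profile (rows = pathways), or
#'   a named list of state vectors.
#' @return Symmetric correlation matrix with unit diagonal; pairs
#'   involving a zero-variance profile are \code{NA} with a warning.
#' @export
state_correlation_matrix <- function(states) {
  if (is.list(states)) states <- do.call(cbind, states)
  n <- ncol(states)
  out <- diag(1, n)
  dimnames(out) <- list(colnames(states), colnames(states))
  flat <- apply(states, 2, stats::var) == 0
  if (any(flat)) {
    warning("zero-variance profile(s): ",
            paste(colnames(states)[flat], collapse = ", "),
            "; their correlations are NA")
  }
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      out[i, j] <- out[j, i] <-
        if (flat[i] || flat[j]) NA_real_ else stats::cor(states[, i],
                                                         states[, j])
    }
  }
  out
}

#' Classify pathway-response concordance
#'
#' Two treatments are called "same" (concordant pathway response) when
#' their state-vector correlation reaches the cutoff; the boundary is
#' inclusive.
#'
#' @param r correlation value(s).
#' @param cutoff concordance cutoff (default 0.917).
#' @return Character vector, \code{"same"} or \code{"different"}.
#' @export
flag_concordance <- function(r, cutoff = 0.917) {
  if (anyNA(r)) stop("concordance undefined for NA correlation")
  ifelse(r >= cutoff, "same", "different")
}

#' Simulate a synthetic dual-luciferase reporter screen
#'
#' Generates replicate firefly/Renilla/background readings for a panel of
#' cell lines under a set of treatments, from planted per-condition
#' activity levels plus log-normal signal noise. Used to exercise the
#' digitization/correlation stage end to end; it emulates signal scales
#' and replicate scatter of reporter plates, not any real pathway biology.
#'
#' @param cell_lines character vector.
#' @param treatments character vector (first is taken as the untreated
#'   reference when computing folds downstream).
#' @param pathways pathway names (default [PATHWAYS]).
#' @param replicates readings per condition (default 3).
#' @param cv log-normal coefficient of variation of the signals.
#' @param combo_mimics optional named character vector, one entry per cell
#'   line, naming the treatment whose planted response pattern the LAST
#'   treatment copies in that line. Emulates a combination regimen whose
#'   pathway response matches a dominant component drug, so downstream
#'   concordance calls have planted positives.
#' @return Data frame in the [reporter_activity()] input layout, plus a
#'   \code{true_activity} column with the planted values. Uses R's RNG;
#'   seed outside.
#' @export
simulate_reporter_panel <- function(cell_lines, treatments,
                                    pathways = PATHWAYS, replicates = 3,
                                    cv = 0.1, combo_mimics = NULL) {
  grid <- expand.grid(pathway = pathways, cell_line = cell_lines,
                      treatment = treatments, stringsAsFactors = FALSE)
  # planted activity: per (line, pathway) basal level, treatment-specific
  # multiplicative shifts drawn from {repressed, flat, activated}
  basal_tab <- stats::runif(length(pathways) * length(cell_lines), 0.5, 4)
  dim(basal_tab) <- c(length(pathways), length(cell_lines))
  basal <- basal_tab[cbind(match(grid$pathway, pathways),
                           match(grid$cell_line, cell_lines))]
  shift <- sample(c(0.25, 1, 2.5), nrow(grid), replace = TRUE,
                  prob = c(0.25, 0.4, 0.35))
  shift[grid$treatment == treatments[1]] <- 1
  if (!is.null(combo_mimics)) {
    last <- treatments[length(treatments)]
    for (cl in names(combo_mimics)) {
      src <- shift[grid$cell_line == cl &
                     grid$treatment == combo_mimics[[cl]]]
      shift[grid$cell_line == cl & grid$treatment == last] <- src
    }
  }
  grid$true_activity <- basal * shift
  grid <- grid[rep(seq_len(nrow(grid)), each = replicates), ]
  grid$replicate <- rep(seq_len(replicates),
                        times = nrow(grid) / replicates)
  renilla <- 10^stats::runif(nrow(grid), 4, 5)
  background <- 10^stats::runif(nrow(grid), 2, 3)
  noise <- exp(stats::rnorm(nrow(grid), 0, sqrt(log(1 + cv^2))))
  grid$renilla <- renilla
  grid$firefly_negctrl <- background
  grid$firefly <- background + grid$true_activity * renilla * noise
  rownames(grid) <- NULL
  grid
}
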