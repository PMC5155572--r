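#' Round half away from zero
#'
#' Plate-report rounding: ties go up (23.025 -> 23.03), unlike base R's
#' round-half-even. A small epsilon absorbs binary representation error so
#' that decimal ties are recognized as ties.
#'
#' @param x numeric vector (non-negative in this pipeline).
#' @param digits decimal places (default 2, the reporting precision).
#' @return \code{x} rounded half-up to \code{digits} places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  out <- sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
  # re-parse so results are bit-identical to typed decimal literals
  as.numeric(sprintf("%.*f", digits, out))
}

#' Average cumulative survival (ACS) of one combination
#'
#' The search objective: the sum of the present per-cell-line survival
#' percentages divided by a fixed panel divisor. The divisor is explicit
#' and may exceed the number of present values (screens divide by the
#' intended panel size even when a line went unmeasured).
#'
#' @param survivals numeric vector of survival percentages; \code{NA} =
#'   unmeasured.
#' @param divisor positive denominator.
#' @return ACS in percent (unrounded; round for display with
#'   [round_half_up()]).
#' @export
average_cumulative_survival <- function(survivals, divisor) {
  if (!is.numeric(divisor) || length(divisor) != 1 || is.na(divisor) ||
      divisor < 1) {
    stop("divisor must be a positive number")
  }
  if (all(is.na(survivals))) stop("all survival values missing")
  sum(survivals, na.rm = TRUE) / divisor
}

#' Classify a combination as effective
#'
#' Strict comparison: a combination is effective iff its ACS is below the
#' threshold; an ACS exactly at the threshold is not effective.
#'
#' @param acs ACS in percent.
#' @param threshold effectiveness cutoff in percent (default 30).
#' @return Logical vector.
#' @export
classify_effective <- function(acs, threshold = 30) {
  acs < threshold
}

#' Score every combination of a viability table
#'
#' @param table a [viability_table()].
#' @param divisor ACS denominator (default: the table's own).
#' @param threshold effectiveness cutoff in percent.
#' @return A data frame with one row per combination: \code{label},
#'   \code{n_present}, \code{acs} (unrounded), \code{acs_display}
#'   (half-up, 2 decimals), \code{divisor}, \code{effective}.
#' @export
score_table <- function(table, divisor = table$divisor, threshold = 30) {
  stopifnot(inherits(table, "viability_table"))
  acs <- apply(table$survival, 1, average_cumulative_survival,
               divisor = divisor)
  data.frame(
    label = table$label,
    n_present = rowSums(!is.na(table$survival)),
    acs = acs,
    acs_display = round_half_up(acs, 2),
    divisor = divisor,
    effective = classify_effective(acs, threshold),
    stringsAsFactors = FALSE
  )
}

#' Therapeutic window of a regimen
#'
#' Selectivity metrics contrasting cancer-panel kill with toxicity to a
#' benign reference line: with \code{normal_kill = 100 - normal_survival},
#' \deqn{TW = normal\_kill - ACS_{cancer}, \quad
#'       TW_{index} = TW - ACS_{cancer}.}
#' A larger TW index means more cancer kill per unit of benign-cell kill.
#'
#' @param acs_cancer cancer-panel ACS in percent, in [0, 150].
#' @param normal_survival survival percent of the benign line, in [0, 150].
#' @return A list of class \code{therapeutic_window}: \code{acs_cancer},
#'   \code{normal_survival}, \code{normal_kill}, \code{tw}, \code{tw_index}.
#' @export
therapeutic_window <- function(acs_cancer, normal_survival) {
  stopifnot(acs_cancer >= 0, acs_cancer <= 150,
            normal_survival >= 0, normal_survival <= 150)
  normal_kill <- 100 - normal_survival
  tw <- normal_kill - acs_cancer
  structure(
    list(
      acs_cancer = acs_cancer,
      normal_survival = normal_survival,
      normal_kill = normal_kill,
      tw = tw,
      tw_index = tw - acs_cancer
    ),
    class = "therapeutic_window"
  )
}

#' @export
print.therapeutic_window <- function(x, ...) {
  cat(sprintf(
    "Therapeutic window: TW = %.2f%%, TW index = %.2f%% (cancer ACS %.2f%%, benign kill %.2f%%)\n",
    x$tw, x$tw_index, x$acs_cancer, x$normal_kill))
  invisible(x)
}
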