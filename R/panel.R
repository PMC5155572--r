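#' Define a drug panel with a discrete dose grid
#'
#' A drug panel is the design space of the combination search: an ordered set
#' of drugs, each with an ordered ladder of allowed non-zero doses (ng/mL).
#' The size of the search space is \code{prod(levels + zero_allowed)}; for the
#' canonical six-drug, five-level panel without a zero option this is
#' \eqn{5^6 = 15625}.
#'
#' @param dose_levels named list; one strictly increasing positive numeric
#'   vector of allowed doses (ng/mL) per drug. Names are the drug codes.
#' @param zero_allowed logical; may a combination set a drug to dose 0?
#'   This is a property of a search round, not of the chemistry, and can be
#'   overridden per call in [validate_combination()] and the search loop.
#' @return An object of class \code{drug_panel}.
#' @seealso [default_drug_panel()], [validate_combination()]
#' @export
drug_panel <- function(dose_levels, zero_allowed = FALSE) {
  if (!is.list(dose_levels) || is.null(names(dose_levels)) ||
      any(!nzchar(names(dose_levels)))) {
    stop("`dose_levels` must be a named list of dose vectors, one per drug")
  }
  for (drug in names(dose_levels)) {
    lv <- dose_levels[[drug]]
    if (!is.numeric(lv) || length(lv) < 2) {
      stop("drug ", drug, ": at least 2 dose levels required")
    }
    if (any(lv <= 0) || any(diff(lv) <= 0)) {
      stop("drug ", drug, ": dose levels must be positive and strictly increasing")
    }
  }
  structure(
    list(
      drugs = names(dose_levels),
      dose_levels = lapply(dose_levels, as.numeric),
      zero_allowed = isTRUE(zero_allowed)
    ),
    class = "drug_panel"
  )
}

#' The default six-drug bladder-cancer panel
#'
#' Six clinical anti-bladder-cancer agents (pirarubicin Pi, paclitaxel Pa,
#' epirubicin hydrochloride EH, cisplatin Ci, gemcitabine Ge, mitomycin Mi),
#' each on a five-point, five-fold dilution ladder (ng/mL). The four upper
#' levels per drug are the ones observed in the published screening rounds;
#' the fifth extends each ladder one five-fold step downward, since only four
#' distinct non-zero doses per drug appear in print.
#'
#' @param zero_allowed logical, passed to [drug_panel()].
#' @return A \code{drug_panel} with \code{5^6 = 15625} zero-free combinations.
#' @export
default_drug_panel <- function(zero_allowed = FALSE) {
  drug_panel(
    dose_levels = list(
      Pi = c(0.064, 0.32, 1.6, 8, 40),
      Pa = c(0.256, 1.28, 6.4, 32, 160),
      EH = c(0.4, 2, 10, 50, 250),
      Ci = c(2.4, 12, 60, 300, 1500),
      Ge = c(0.008, 0.04, 0.2, 1, 5),
      Mi = c(1.6, 8, 40, 200, 1000)
    ),
    zero_allowed = zero_allowed
  )
}

#' @export
print.drug_panel <- function(x, ...) {
  cat("Drug panel:", length(x$drugs), "drugs, search space",
      format(search_space_size(x), big.mark = ","),
      if (x$zero_allowed) "(zero dose allowed)\n" else "(no zero dose)\n")
  for (drug in x$drugs) {
    cat(sprintf("  %-3s %s ng/mL\n", drug,
                paste(format(x$dose_levels[[drug]], trim = TRUE), collapse = ", ")))
  }
  invisible(x)
}

#' Size of the discrete combination design space
#'
#' @param panel a [drug_panel()].
#' @param zero_allowed optionally override the panel's zero-dose flag.
#' @return \code{prod(levels + zero_allowed)} over the panel's drugs.
#' @export
search_space_size <- function(panel, zero_allowed = panel$zero_allowed) {
  stopifnot(inherits(panel, "drug_panel"))
  prod(vapply(panel$dose_levels, length, integer(1)) + as.integer(zero_allowed))
}

#' Construct combinations (points on the dose grid)
#'
#' A combination assigns one dose (ng/mL) to every drug of the panel. They are
#' represented throughout as rows of a data frame with one numeric column per
#' drug, which keeps plate tables, design matrices and search populations in
#' the same shape.
#'
#' @param ... named doses, one per drug (ng/mL), or a single named list/vector.
#' @param panel the [drug_panel()] naming and ordering the drugs.
#' @return A one-row data frame with the panel's drug columns.
#' @export
combination <- function(..., panel = default_drug_panel()) {
  doses <- list(...)
  if (length(doses) == 1L && is.null(names(doses)) && !is.null(names(doses[[1]]))) {
    doses <- as.list(doses[[1]])
  }
  missing_drugs <- setdiff(panel$drugs, names(doses))
  if (length(missing_drugs)) {
    stop("missing dose for drug(s): ", paste(missing_drugs, collapse = ", "))
  }
  as.data.frame(doses)[panel$drugs]
}

#' Check combinations against a panel's dose grid
#'
#' Violations are data, not errors: the return value is a character vector of
#' human-readable problems (empty when the combination is valid). A dose is
#' valid when it is one of that drug's allowed levels, or exactly 0 where the
#' zero option is in force.
#'
#' @param combo a one-row data frame (or coercible named vector) of doses.
#' @param panel a [drug_panel()].
#' @param zero_allowed optionally override the panel's zero-dose flag.
#' @return Character vector of violations; \code{character(0)} if valid.
#' @export
validate_combination <- function(combo, panel,
                                 zero_allowed = panel$zero_allowed) {
  stopifnot(inherits(panel, "drug_panel"))
  if (!is.data.frame(combo)) combo <- as.data.frame(as.list(combo))
  violations <- character(0)
  absent <- setdiff(panel$drugs, names(combo))
  if (length(absent)) {
    return(paste0("missing dose for drug ", absent))
  }
  for (drug in panel$drugs) {
    d <- combo[[drug]][1]
    if (is.na(d)) {
      violations <- c(violations, paste0(drug, ": dose is missing"))
    } else if (d == 0) {
      if (!zero_allowed) {
        violations <- c(violations,
                        paste0(drug, ": zero dose not allowed in this round"))
      }
    } else if (!any(abs(panel$dose_levels[[drug]] - d) < 1e-9)) {
      violations <- c(violations,
                      paste0(drug, ": dose ", format(d, trim = TRUE),
                             " ng/mL is not an allowed level"))
    }
  }
  violations
}

# dose level index (0 = zero dose, 1..L = ladder position) <-> ng/mL
level_to_dose <- function(idx, panel) {
  stopifnot(length(idx) == length(panel$drugs))
  vapply(seq_along(idx), function(j) {
    if (idx[j] == 0) 0 else panel$dose_levels[[j]][idx[j]]
  }, numeric(1))
}

dose_to_level <- function(doses, panel) {
  stopifnot(length(doses) == length(panel$drugs))
  vapply(seq_along(doses), function(j) {
    if (doses[j] == 0) return(0L)
    hit <- which(abs(panel$dose_levels[[j]] - doses[j]) < 1e-9)
    if (!length(hit)) stop("dose off grid for drug ", panel$drugs[j])
    hit[1]
  }, integer(1))
}
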