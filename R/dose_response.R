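#' Estimate an IC50 from a dose-survival series
#'
#' IC50 is read as the dose at which survival equals 50\% of the untreated
#' control. Two estimators are provided:
#' \describe{
#'   \item{\code{"4pl"}}{Four-parameter logistic on log10 dose,
#'     \eqn{s(d) = b + (t - b) / (1 + 10^{h (\log_{10} d - m)})}, fitted by
#'     bounded Levenberg-Marquardt least squares with the top and bottom
#'     asymptotes constrained to [0, 100] and slope \eqn{h > 0}. The IC50 is
#'     the analytic dose at which the fitted curve crosses 50.}
#'   \item{\code{"interpolation"}}{Assumption-free log-linear interpolation
#'     between the two adjacent tested doses bracketing the 50\% crossing;
#'     deterministic, used as a fallback and as an independent check.}
#' }
#'
#' @param doses strictly increasing positive doses (ng/mL), at least 4.
#' @param survival survival percentages, same length.
#' @param method \code{"4pl"} (default) or \code{"interpolation"}.
#' @return A list of class \code{dose_response_fit}: \code{ic50} (ng/mL),
#'   \code{method}, \code{rmse} (of the 4PL fit; \code{NA} for
#'   interpolation), \code{extrapolated} (TRUE when the observed series
#'   never brackets 50\%), and \code{coefficients} (4PL only).
#' @export
fit_dose_response <- function(doses, survival,
                              method = c("4pl", "interpolation")) {
  method <- match.arg(method)
  if (length(doses) != length(survival)) stop("doses/survival length mismatch")
  if (length(doses) < 4) stop("at least 4 dose points required")
  if (any(doses <= 0)) stop("doses must be positive")
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  if (length(unique(survival)) == 1) {
    stop("degenerate series: survival is constant, IC50 not estimable")
  }
  bracketed <- min(survival) <= 50 && max(survival) >= 50
  if (method == "interpolation") {
    fit <- ic50_interpolate(doses, survival)
    return(structure(
      list(ic50 = fit, method = method, rmse = NA_real_,
           extrapolated = !bracketed, coefficients = NULL),
      class = "dose_response_fit"))
  }
  ld <- log10(doses)
  # starting values: asymptotes from the data, midpoint from interpolation;
  # a couple of perturbed restarts guard against local convergence failures
  start <- list(
    top = min(100, max(survival)),
    bottom = max(0, min(survival)),
    mid = log10(ic50_interpolate(doses, survival)),
    hill = 1
  )
  starts <- list(
    start,
    utils::modifyList(start, list(hill = 1.5)),
    utils::modifyList(start, list(mid = start$mid + 0.3, hill = 0.8)),
    utils::modifyList(start, list(mid = mean(ld), hill = 1,
                                  top = 100, bottom = 0))
  )
  lower <- c(top = 0, bottom = 0, mid = min(ld) - 3, hill = 0.05)
  upper <- c(top = 100, bottom = 100, mid = max(ld) + 3, hill = 10)
  fit <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      stats::nls(
        survival ~ bottom + (top - bottom) / (1 + 10^(hill * (ld - mid))),
        start = s0, algorithm = "port", lower = lower, upper = upper,
        control = stats::nls.control(maxiter = 1000, tol = 1e-12,
                                     scaleOffset = 1)),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          survival ~ bottom + (top - bottom) / (1 + 10^(hill * (ld - mid))),
          start = s0, lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL)
    }
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("4PL fit did not converge; try method = 'interpolation'")
  # derivative-free polish sharpens near-exact fits the bounded solver
  # leaves a hair off (parameters clamped into the box)
  cf <- stats::coef(fit)[c("top", "bottom", "mid", "hill")]
  rss_of <- function(p) {
    p <- pmin(pmax(p, lower), upper)
    pred <- p[2] + (p[1] - p[2]) / (1 + 10^(p[4] * (ld - p[3])))
    sum((survival - pred)^2)
  }
  pol <- tryCatch(
    stats::optim(cf, rss_of, method = "L-BFGS-B", lower = lower,
                 upper = upper,
                 control = list(factr = 10, maxit = 2000,
                                ndeps = rep(1e-8, 4))),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value <= rss_of(cf)) {
    cf[] <- pmin(pmax(pol$par, lower), upper)
  }
  rmse <- sqrt(rss_of(cf) / length(survival))
  if (cf[["top"]] <= 50 || cf[["bottom"]] >= 50) {
    stop("fitted curve never crosses 50% survival; IC50 undefined")
  }
  # solve s(d) = 50 for d on the fitted curve
  ic50 <- 10^(cf[["mid"]] +
                log10((cf[["top"]] - 50) / (50 - cf[["bottom"]])) / cf[["hill"]])
  structure(
    list(ic50 = ic50, method = method,
         rmse = rmse,
         extrapolated = !bracketed,
         coefficients = cf),
    class = "dose_response_fit"
  )
}

# log-linear interpolation at the first adjacent pair bracketing 50%;
# boundary estimate (nearest end dose) when no crossing exists
ic50_interpolate <- function(doses, survival) {
  ld <- log10(doses)
  cross <- which((survival[-length(survival)] - 50) *
                   (survival[-1] - 50) <= 0)
  if (!length(cross)) {
    return(if (survival[length(survival)] > 50) doses[length(doses)]
           else doses[1])
  }
  i <- cross[1]
  if (survival[i] == survival[i + 1]) return(10^mean(ld[i:(i + 1)]))
  10^(ld[i] + (survival[i] - 50) / (survival[i] - survival[i + 1]) *
        (ld[i + 1] - ld[i]))
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("IC50 = %.4g ng/mL (%s%s)\n", x$ic50, x$method,
              if (x$extrapolated) ", extrapolated" else ""))
  invisible(x)
}

#' Relative-IC50 matrix across a cell-line panel
#'
#' Normalizes each drug's IC50 column by its minimum across cell lines, so
#' the most sensitive line scores exactly 1 for every drug and every other
#' entry is a resistance fold.
#'
#' @param ic50 numeric matrix, cell lines (rows) x drugs (columns), all
#'   entries positive and present.
#' @return A list of class \code{chemoresistance_report}:
#'   \code{relative_ic50} (same shape, column minima exactly 1) and
#'   \code{index} (per-row mean over all drugs).
#' @export
relative_ic50_matrix <- function(ic50) {
  ic50 <- as.matrix(ic50)
  if (anyNA(ic50)) {
    bad <- which(is.na(ic50), arr.ind = TRUE)
    stop("missing IC50 for (cell line, drug): ",
         paste(sprintf("(%s, %s)", rownames(ic50)[bad[, 1]],
                       colnames(ic50)[bad[, 2]]), collapse = ", "))
  }
  if (any(ic50 <= 0)) stop("IC50 values must be positive")
  rel <- sweep(ic50, 2, apply(ic50, 2, min), "/")
  structure(
    list(relative_ic50 = rel, index = rowMeans(rel)),
    class = "chemoresistance_report"
  )
}

#' Chemoresistance index of one cell line
#'
#' The arithmetic mean of a cell line's relative IC50 over a drug subset;
#' higher means more broadly resistant. Computed over all drugs it is the
#' panel-wide resistance rank; dropping an outlier drug (a line extremely
#' resistant to a single agent) gives the subset index quoted alongside.
#'
#' @param report a [relative_ic50_matrix()] result, or a relative-IC50
#'   matrix.
#' @param cell_line row identifier.
#' @param drugs drug subset (default: all columns).
#' @return Positive scalar.
#' @export
chemoresistance_index <- function(report, cell_line,
                                  drugs = NULL) {
  rel <- if (inherits(report, "chemoresistance_report")) {
    report$relative_ic50
  } else {
    as.matrix(report)
  }
  if (is.null(drugs)) drugs <- colnames(rel)
  if (!length(drugs)) stop("drug subset must be non-empty")
  if (!all(drugs %in% colnames(rel))) {
    stop("unknown drug(s): ",
         paste(setdiff(drugs, colnames(rel)), collapse = ", "))
  }
  if (!cell_line %in% rownames(rel)) stop("unknown cell line: ", cell_line)
  mean(rel[cell_line, drugs])
}

#' @export
print.chemoresistance_report <- function(x, ...) {
  cat("Chemoresistance report:", nrow(x$relative_ic50), "cell lines x",
      ncol(x$relative_ic50), "drugs\n")
  ord <- order(x$index, decreasing = TRUE)
  for (i in ord) {
    cat(sprintf("  %-10s index %8.2f\n", rownames(x$relative_ic50)[i],
                x$index[i]))
  }
  invisible(x)
}
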