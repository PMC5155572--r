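#' Second-order design matrix over drug doses
#'
#' Builds the full quadratic response-surface design in the raw ng/mL
#' scale: intercept, k linear dose terms, k pure quadratic terms and
#' k(k-1)/2 bilinear (pairwise interaction) terms, 1 + 2k + k(k-1)/2
#' columns in total (28 for six drugs). Column order is deterministic:
#' intercept, linear in panel order, quadratics, then bilinears i < j.
#'
#' @param combos data frame of doses (ng/mL), one column per drug.
#' @return A list of class \code{design_matrix}: \code{X} (numeric matrix
#'   including the intercept column), \code{terms} (data frame with
#'   \code{label}, \code{type} in intercept/linear/quadratic/bilinear,
#'   \code{var1}, \code{var2}), \code{drugs}.
#' @export
build_design_matrix <- function(combos) {
  combos <- as.data.frame(combos)
  if (!nrow(combos)) stop("at least one combination required")
  drugs <- names(combos)
  k <- length(drugs)
  D <- as.matrix(combos)
  cols <- list(`(Intercept)` = rep(1, nrow(D)))
  terms <- data.frame(label = "(Intercept)", type = "intercept",
                      var1 = NA_character_, var2 = NA_character_,
                      stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    cols[[drugs[j]]] <- D[, j]
    terms <- rbind(terms, data.frame(label = drugs[j], type = "linear",
                                     var1 = drugs[j], var2 = NA))
  }
  for (j in seq_len(k)) {
    lab <- paste0(drugs[j], "^2")
    cols[[lab]] <- D[, j]^2
    terms <- rbind(terms, data.frame(label = lab, type = "quadratic",
                                     var1 = drugs[j], var2 = NA))
  }
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      lab <- paste0(drugs[i], ":", drugs[j])
      cols[[lab]] <- D[, i] * D[, j]
      terms <- rbind(terms, data.frame(label = lab, type = "bilinear",
                                       var1 = drugs[i], var2 = drugs[j]))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(list(X = X, terms = terms, drugs = drugs),
            class = "design_matrix")
}

# least-squares fit on a column subset of a design, computed on scaled
# columns for conditioning (dose ladders span five orders of magnitude)
# and back-transformed to the raw scale for reporting
ls_fit <- function(X, y, labels) {
  Xs <- X[, labels, drop = FALSE]
  scale_by <- apply(Xs, 2, function(col) {
    s <- max(abs(col))
    if (s == 0) 1 else s
  })
  fit <- stats::lm.fit(sweep(Xs, 2, scale_by, "/"), y)
  dropped <- labels[is.na(fit$coefficients)]
  beta <- fit$coefficients / scale_by
  rss <- sum(fit$residuals^2)
  list(beta = beta[!is.na(beta)], dropped = dropped, rss = rss,
       rank = fit$rank, residuals = fit$residuals, fitted = fit$fitted.values)
}

#' Fit the full second-order polynomial surface
#'
#' Ordinary least squares of survival on the full quadratic design.
#' Internally the columns are scaled for conditioning and the coefficients
#' back-transformed, so reported coefficients are on the raw ng/mL scale.
#' Rank-deficient columns are dropped with a warning. The overall fit is
#' summarized by \eqn{R^2 = 1 - RSS/TSS} and the F-test against the
#' intercept-only model.
#'
#' @param design a [build_design_matrix()] result, or a dose data frame.
#' @param y response per combination (survival or ACS, percent; lower =
#'   more kill).
#' @param response label for reporting (e.g. the cell line).
#' @return An object of class \code{polynomial_model}: \code{coefficients}
#'   (named, raw scale), \code{retained} (term labels), \code{r_squared},
#'   \code{p_value}, \code{n}, \code{df_residual}, \code{response},
#'   \code{design}, \code{y}.
#' @export
fit_polynomial <- function(design, y, response = "survival") {
  if (!inherits(design, "design_matrix")) {
    design <- build_design_matrix(design)
  }
  y <- as.numeric(y)
  if (length(y) != nrow(design$X)) stop("response length mismatch")
  if (anyNA(y) || any(!is.finite(y))) stop("response must be finite")
  if (stats::var(y) == 0) stop("degenerate response: survival is constant")
  fit_model(design, y, design$terms$label, response)
}

fit_model <- function(design, y, labels, response) {
  X <- design$X
  n <- length(y)
  p_all <- length(labels)
  if (n <= sum(labels != "(Intercept)") + 1) {
    stop("n (", n, ") too small for ", p_all,
         " terms; simplify the term set first (fewer drugs or rounds)")
  }
  fit <- ls_fit(X, y, labels)
  if (length(fit$dropped)) {
    warning("rank-deficient design; dropped term(s): ",
            paste(fit$dropped, collapse = ", "))
  }
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - fit$rss / tss
  df1 <- fit$rank - 1
  df2 <- n - fit$rank
  p_value <- if (df1 > 0 && df2 > 0) {
    f <- (tss - fit$rss) / df1 / (fit$rss / df2)
    stats::pf(f, df1, df2, lower.tail = FALSE)
  } else {
    NA_real_
  }
  structure(
    list(coefficients = fit$beta,
         retained = setdiff(names(fit$beta), "(Intercept)"),
         r_squared = r2, p_value = p_value, n = n, df_residual = df2,
         rss = fit$rss, response = response, design = design, y = y),
    class = "polynomial_model"
  )
}

#' @export
print.polynomial_model <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Second-order surface for %s: n = %d, %d retained term(s)\n",
    x$response, x$n, length(x$retained)))
  cat(sprintf("  R-squared %.4f, overall F-test p = %.4g\n",
              x$r_squared, x$p_value))
  print(signif(x$coefficients, digits))
  invisible(x)
}

# term hierarchy: parents that must be present for a label to enter,
# children whose presence forbids dropping it
term_parents <- function(terms, label) {
  row <- terms[terms$label == label, ]
  switch(row$type,
         quadratic = row$var1,
         bilinear = c(row$var1, row$var2),
         character(0))
}

term_children <- function(terms, label) {
  terms$label[(terms$type == "quadratic" & terms$var1 == label) |
                (terms$type == "bilinear" &
                   (terms$var1 %in% label | terms$var2 %in% label))]
}

model_criterion <- function(rss, n, npar, penalty, floor = 0) {
  # floor keeps the log-likelihood term finite on (near-)interpolating
  # fits so the parameter penalty can still discriminate among them
  n * log(max(rss, floor) / n) + penalty * npar
}

#' Stepwise simplification of a fitted surface
#'
#' Bidirectional greedy term elimination/addition minimizing an
#' information criterion (AIC by default, BIC or any penalty-per-parameter
#' via \code{penalty}; an infinite penalty collapses to the intercept-only
#' model). With \code{hierarchy = TRUE} (default) a quadratic or bilinear
#' term can only be present together with its linear parent(s): drops of a
#' linear term are blocked while a child is retained, and additions
#' require the parents first.
#'
#' @param model a [fit_polynomial()] result (fit on the full term set).
#' @param criterion \code{"AIC"} or \code{"BIC"}.
#' @param penalty optional explicit penalty per parameter, overriding
#'   \code{criterion} (2 = AIC, \code{log(n)} = BIC).
#' @param hierarchy enforce term hierarchy (default TRUE).
#' @return A \code{polynomial_model} on the selected term subset, with
#'   R-squared and p-value recomputed for that subset.
#' @export
simplify_model <- function(model, criterion = c("AIC", "BIC"),
                           penalty = NULL, hierarchy = TRUE) {
  stopifnot(inherits(model, "polynomial_model"))
  criterion <- match.arg(criterion)
  n <- model$n
  pen <- penalty %||% switch(criterion, AIC = 2, BIC = log(n))
  if (!is.finite(pen)) pen <- 1e12  # "infinite" penalty: parsimony dominates
  design <- model$design
  terms <- design$terms
  all_labels <- terms$label[terms$label != "(Intercept)"]
  current <- model$retained
  rss_floor <- sum((model$y - mean(model$y))^2) * 1e-12
  crit_of <- function(labels) {
    fit <- ls_fit(design$X, model$y, c("(Intercept)", labels))
    model_criterion(fit$rss, n, fit$rank, pen, floor = rss_floor)
  }
  best <- crit_of(current)
  repeat {
    moves <- list()
    for (lab in current) {
      if (hierarchy &&
          any(term_children(terms, lab) %in% setdiff(current, lab))) next
      moves[[length(moves) + 1]] <- list(action = "drop", label = lab,
                                         set = setdiff(current, lab))
    }
    for (lab in setdiff(all_labels, current)) {
      if (hierarchy && !all(term_parents(terms, lab) %in% current)) next
      moves[[length(moves) + 1]] <- list(action = "add", label = lab,
                                         set = c(current, lab))
    }
    if (!length(moves)) break
    crits <- vapply(moves, function(m) crit_of(m$set), numeric(1))
    if (min(crits) < best - 1e-10) {
      pick <- which.min(crits)
      current <- moves[[pick]]$set
      best <- crits[pick]
    } else {
      break
    }
  }
  # keep deterministic column order
  current <- all_labels[all_labels %in% current]
  fit_model(design, model$y, c("(Intercept)", current), model$response)
}

#' Interpret interaction structure of a fitted surface
#'
#' Because the response is survival (lower = more kill), a retained
#' negative bilinear coefficient means the pair kills more together than
#' Bliss-style addition predicts (synergy) and a positive one antagonism;
#' an absent term is a "none" call. A drug shows diminishing returns when
#' its linear coefficient is negative but it owns the largest positive
#' quadratic coefficient (dose increases stop paying off); such a drug is
#' recommended for elimination when it additionally owns the largest
#' positive bilinear coefficient. Quadratic ties are broken toward the
#' drug with the larger total absolute bilinear involvement.
#'
#' @param model a (possibly simplified) [fit_polynomial()] result.
#' @return A list of class \code{interaction_report}: \code{pairs} (data
#'   frame drug_a, drug_b, coefficient, call), \code{diminishing_returns}
#'   (named logical per drug), \code{eliminate} (character vector of drug
#'   recommendations).
#' @export
interpret_interactions <- function(model) {
  stopifnot(inherits(model, "polynomial_model"))
  terms <- model$design$terms
  drugs <- model$design$drugs
  beta <- model$coefficients
  bil <- terms[terms$type == "bilinear", ]
  pair_coef <- ifelse(bil$label %in% names(beta), beta[bil$label], NA_real_)
  call <- ifelse(is.na(pair_coef) | pair_coef == 0, "none",
                 ifelse(pair_coef < 0, "synergistic", "antagonistic"))
  pairs <- data.frame(drug_a = bil$var1, drug_b = bil$var2,
                      coefficient = unname(pair_coef), call = call,
                      stringsAsFactors = FALSE)

  quad_coef <- vapply(drugs, function(d) {
    lab <- paste0(d, "^2")
    if (lab %in% names(beta)) beta[[lab]] else NA_real_
  }, numeric(1))
  lin_coef <- vapply(drugs, function(d) {
    if (d %in% names(beta)) beta[[d]] else NA_real_
  }, numeric(1))
  bil_abs_sum <- vapply(drugs, function(d) {
    sum(abs(pairs$coefficient[(pairs$drug_a == d | pairs$drug_b == d) &
                                !is.na(pairs$coefficient)]))
  }, numeric(1))

  pos_quad <- which(!is.na(quad_coef) & quad_coef > 0)
  largest_quad <- character(0)
  if (length(pos_quad)) {
    top <- pos_quad[quad_coef[pos_quad] == max(quad_coef[pos_quad])]
    if (length(top) > 1) top <- top[which.max(bil_abs_sum[top])]
    largest_quad <- drugs[top]
  }
  diminishing <- !is.na(lin_coef) & lin_coef < 0 & drugs %in% largest_quad
  names(diminishing) <- drugs

  eliminate <- character(0)
  pos_pairs <- pairs[!is.na(pairs$coefficient) & pairs$coefficient > 0, ]
  if (nrow(pos_pairs)) {
    top_pair <- pos_pairs[which.max(pos_pairs$coefficient), ]
    owners <- c(top_pair$drug_a, top_pair$drug_b)
    eliminate <- drugs[diminishing & drugs %in% owners]
  }
  structure(
    list(pairs = pairs, diminishing_returns = diminishing,
         eliminate = eliminate),
    class = "interaction_report"
  )
}

#' @export
print.interaction_report <- function(x, ...) {
  act <- x$pairs[x$pairs$call != "none", ]
  if (nrow(act)) {
    for (i in seq_len(nrow(act))) {
      cat(sprintf("  %s x %s: %s (beta = %.3g)\n", act$drug_a[i],
                  act$drug_b[i], act$call[i], act$coefficient[i]))
    }
  } else {
    cat("  no retained pairwise interactions\n")
  }
  dim_drugs <- names(x$diminishing_returns)[x$diminishing_returns]
  if (length(dim_drugs)) {
    cat("  diminishing returns:", paste(dim_drugs, collapse = ", "), "\n")
  }
  if (length(x$eliminate)) {
    cat("  elimination recommended:", paste(x$eliminate, collapse = ", "), "\n")
  }
  invisible(x)
}
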