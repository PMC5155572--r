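#' Configuration for the feedback search loop
#'
#' Control parameters for differential evolution over the integer
#' dose-level grid. Mutation and crossover operate on level indices, not
#' ng/mL, so step sizes are scale-free across drugs whose ladders span five
#' orders of magnitude. Defaults follow the canonical DE/rand/1/bin setting
#' (F = 0.8, CR = 0.9) with a batch of 20 per round, matching the published
#' per-round screen size, and four rounds: the random round 1 plus three DE
#' rounds, the last of which doubles the batch, for a 100-evaluation budget
#' on the 15,625-point default grid (0.64\% coverage).
#'
#' @param np population size (>= 4; DE mutation needs 4 distinct members).
#' @param F differential weight in [0, 2].
#' @param cr crossover rate in [0, 1].
#' @param rounds total screening rounds including the random first round.
#' @param batch_multiplier integer multiplier per DE round (length
#'   \code{rounds - 1}); each parent faces that many successive trials.
#' @param zero_from_round first round in which the zero-dose option opens
#'   (Inf = never); the published search opened it in round 3 to push
#'   six-drug combinations down to four or five drugs.
#' @param divisor ACS denominator (default: number of oracle cell lines).
#' @param threshold effectiveness cutoff in percent, for reporting.
#' @param replicates oracle draws averaged per combination.
#' @param patience stop early after this many rounds without improvement
#'   of the best ACS (default Inf: run all rounds).
#' @param max_evaluations cap on distinct oracle evaluations (default Inf:
#'   bounded by \code{np * (1 + sum(batch_multiplier))} anyway). Because
#'   repeated combinations are served from the cache for free, a budgeted
#'   run can iterate many rounds: trials beyond the budget are left
#'   unevaluated and their parents kept.
#' @param stall_repair probability of nudging a trial that rounding has
#'   collapsed onto its parent by one dose level in the forced coordinate.
#'   Keeps a discrete population from stalling permanently once diversity
#'   is lost; 0 restores the unrepaired canonical scheme.
#' @return A list of class \code{de_config}.
#' @export
de_config <- function(np = 20, F = 0.8, cr = 0.9, rounds = 4,
                      batch_multiplier = c(rep(1, max(rounds - 2, 0)),
                                           if (rounds > 1) 2),
                      zero_from_round = 3, divisor = NULL, threshold = 30,
                      replicates = 3, patience = Inf,
                      max_evaluations = Inf, stall_repair = 0.15) {
  stopifnot(np >= 4, F >= 0, F <= 2, cr >= 0, cr <= 1, rounds >= 1,
            max_evaluations >= np, stall_repair >= 0, stall_repair <= 1)
  batch_multiplier <- as.integer(batch_multiplier %||% integer(0))
  if (length(batch_multiplier) != rounds - 1) {
    stop("batch_multiplier must have one entry per DE round (rounds - 1)")
  }
  structure(
    list(np = as.integer(np), F = F, cr = cr, rounds = as.integer(rounds),
         batch_multiplier = batch_multiplier,
         zero_from_round = zero_from_round, divisor = divisor,
         threshold = threshold, replicates = replicates,
         patience = patience, max_evaluations = max_evaluations,
         stall_repair = stall_repair),
    class = "de_config"
  )
}

#' Random initial population on the dose grid
#'
#' Draws \code{np} combinations uniformly and independently over each
#' drug's level grid (the zero level included only when allowed).
#'
#' @param panel a [drug_panel()].
#' @param config a [de_config()].
#' @param zero_allowed does round 1 admit the zero dose? Default: only if
#'   \code{config$zero_from_round <= 1}.
#' @return Integer matrix \code{np x n_drugs} of level indices
#'   (0 = zero dose, 1..L = ladder position). Uses R's RNG; seed outside.
#' @export
init_population <- function(panel, config,
                            zero_allowed = config$zero_from_round <= 1) {
  stopifnot(inherits(panel, "drug_panel"), inherits(config, "de_config"))
  lo <- if (zero_allowed) 0L else 1L
  nl <- vapply(panel$dose_levels, length, integer(1))
  pop <- vapply(nl, function(L) {
    sample(seq.int(lo, L), config$np, replace = TRUE)
  }, integer(config$np))
  pop <- matrix(as.integer(pop), nrow = config$np,
                dimnames = list(NULL, panel$drugs))
  pop
}

#' DE/rand/1/bin trial generation on the level grid
#'
#' For each parent i, a mutant \eqn{v = x_{r1} + F (x_{r2} - x_{r3})} is
#' built from three distinct random members other than i, then binomial
#' crossover with rate CR and one forced coordinate mixes it with the
#' parent. Components are rounded to the nearest integer level and clamped
#' to the valid index range (0 included only when the zero dose is open).
#'
#' @param pop integer level-index matrix (np x drugs).
#' @param panel a [drug_panel()].
#' @param config a [de_config()].
#' @param zero_allowed is the zero level admissible for the trials?
#' @return Integer matrix of np trial members. Uses R's RNG; seed outside.
#' @export
propose_candidates <- function(pop, panel, config, zero_allowed = FALSE) {
  np <- nrow(pop)
  if (np < 4) stop("population too small for DE mutation (need np >= 4)")
  k <- ncol(pop)
  lo <- if (zero_allowed) 0L else 1L
  hi <- vapply(panel$dose_levels, length, integer(1))
  trials <- pop
  for (i in seq_len(np)) {
    donors <- sample(setdiff(seq_len(np), i), 3)
    v <- pop[donors[1], ] + config$F * (pop[donors[2], ] - pop[donors[3], ])
    jrand <- sample.int(k, 1)
    take <- stats::runif(k) < config$cr
    take[jrand] <- TRUE
    u <- ifelse(take, v, pop[i, ])
    u <- pmin(pmax(as.integer(round(u)), lo), hi)
    if (all(u == pop[i, ]) && stats::runif(1) < config$stall_repair) {
      # rounding collapsed the trial onto its parent (diversity lost in the
      # mutated coordinates); occasionally nudge the forced coordinate one
      # level, or the discrete population can stall permanently
      step <- if (stats::runif(1) < 0.5) -1L else 1L
      u[jrand] <- pop[i, jrand] + step
      if (u[jrand] < lo || u[jrand] > hi[jrand]) {
        u[jrand] <- pop[i, jrand] - step
      }
    }
    trials[i, ] <- u
  }
  trials
}

#' Greedy member-wise selection
#'
#' A trial replaces its parent iff its score (ACS; lower is better) is
#' strictly smaller; ties keep the parent, so the population is stable
#' under re-scoring.
#'
#' @param pop parent matrix; \code{scores} their ACS values.
#' @param trials trial matrix (same shape); \code{trial_scores} their ACS.
#' @return List with the surviving \code{pop} and \code{scores}.
#' @export
select_survivors <- function(pop, scores, trials, trial_scores) {
  if (nrow(pop) != nrow(trials) || length(scores) != nrow(pop) ||
      length(trial_scores) != nrow(trials)) {
    stop("parents/trials size mismatch")
  }
  if (anyNA(scores) || anyNA(trial_scores)) stop("unscored members")
  win <- trial_scores < scores
  pop[win, ] <- trials[win, ]
  scores[win] <- trial_scores[win]
  list(pop = pop, scores = scores)
}

#' Run the closed feedback search loop
#'
#' Iterates propose -> evaluate -> select against a viability oracle:
#' round 1 is random initialization; each later round proposes trials by
#' [propose_candidates()] (repeated per its batch multiplier), scores them
#' through the oracle, and keeps winners by [select_survivors()]. Every
#' distinct combination is evaluated once and cached, so the oracle-call
#' budget is at most \code{np * (1 + sum(batch_multiplier))} and typically
#' less. The best ACS is monotone non-increasing across rounds.
#'
#' @param oracle function mapping a dose data frame (rows = combinations)
#'   to a survival matrix (rows x cell lines), e.g. [panel_oracle()] or a
#'   lookup into a measured [viability_table()].
#' @param panel a [drug_panel()].
#' @param config a [de_config()].
#' @param seed integer seed; all loop and oracle randomness flows from it.
#' @return An object of class \code{fsc_trajectory}: \code{$rounds} (data
#'   frame with per-round best ACS, evaluation counts, design-space
#'   fraction, effective count), \code{$evaluated} (all distinct evaluated
#'   combinations with survival and ACS), \code{$best} (doses, survival,
#'   ACS of the optimum found), \code{$population}, \code{$config},
#'   \code{$seed}.
#' @export
run_fsc_loop <- function(oracle, panel, config = de_config(), seed = 1) {
  stopifnot(inherits(panel, "drug_panel"), inherits(config, "de_config"))
  set.seed(seed)
  drugs <- panel$drugs
  cache <- new.env(parent = emptyenv())
  n_lines <- NULL
  divisor <- config$divisor

  evaluate <- function(level_mat) {
    doses <- t(apply(level_mat, 1, level_to_dose, panel = panel))
    colnames(doses) <- drugs
    keys <- apply(doses, 1, paste, collapse = "|")
    new <- !vapply(keys, exists, logical(1), envir = cache)
    uniq <- which(!duplicated(keys) & new)
    remaining <- config$max_evaluations - length(ls(cache))
    if (length(uniq) > remaining) uniq <- uniq[seq_len(remaining)]
    if (length(uniq)) {
      surv <- oracle(as.data.frame(doses[uniq, , drop = FALSE]))
      if (is.null(dim(surv))) surv <- matrix(surv, nrow = length(uniq))
      if (anyNA(surv)) {
        bad <- which(apply(is.na(surv), 1, any))[1]
        stop("oracle returned missing survival for combination [",
             paste(doses[uniq[bad], ], collapse = ", "), "]")
      }
      if (is.null(n_lines)) n_lines <<- ncol(surv)
      for (r in seq_along(uniq)) {
        assign(keys[uniq[r]], surv[r, ], envir = cache)
      }
    }
    # combinations beyond the evaluation budget stay unscored (NA rows)
    t(vapply(keys, function(k) {
      if (exists(k, envir = cache)) get(k, envir = cache)
      else rep(NA_real_, n_lines)
    }, numeric(n_lines))) -> res
    if (n_lines == 1) matrix(as.vector(res), ncol = 1) else res
  }

  score <- function(surv_mat) {
    div <- divisor %||% ncol(surv_mat)
    apply(surv_mat, 1, function(s) {
      if (all(is.na(s))) Inf  # beyond-budget trial: never beats a parent
      else average_cumulative_survival(s, div)
    })
  }

  zero_open <- function(round) round >= config$zero_from_round
  pop <- init_population(panel, config, zero_allowed = zero_open(1))
  surv <- evaluate(pop)
  scores <- score(surv)

  traj <- data.frame(round = 1L, best_acs = min(scores),
                     n_evaluated = length(ls(cache)),
                     frac_space = length(ls(cache)) / search_space_size(panel),
                     n_effective = sum(classify_effective(scores,
                                                          config$threshold)))
  stall <- 0L
  for (round in seq_len(config$rounds - 1) + 1L) {
    za <- zero_open(round)
    for (b in seq_len(config$batch_multiplier[round - 1L])) {
      trials <- propose_candidates(pop, panel, config, zero_allowed = za)
      trial_scores <- score(evaluate(trials))
      kept <- select_survivors(pop, scores, trials, trial_scores)
      pop <- kept$pop
      scores <- kept$scores
    }
    improved <- min(scores) < traj$best_acs[nrow(traj)] - 1e-12
    traj <- rbind(traj, data.frame(
      round = round, best_acs = min(scores),
      n_evaluated = length(ls(cache)),
      frac_space = length(ls(cache)) / search_space_size(panel),
      n_effective = sum(classify_effective(scores, config$threshold))))
    stall <- if (improved) 0L else stall + 1L
    if (stall >= config$patience) break
  }

  keys <- ls(cache)
  eval_doses <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  eval_doses <- matrix(as.numeric(eval_doses), ncol = length(drugs),
                       dimnames = list(NULL, drugs))
  eval_surv <- vapply(keys, get, numeric(n_lines), envir = cache)
  eval_surv <- if (n_lines == 1) matrix(eval_surv, ncol = 1) else t(eval_surv)
  eval_acs <- score(eval_surv)
  ord <- order(eval_acs)
  evaluated <- data.frame(eval_doses, check.names = FALSE)
  colnames(eval_surv) <- paste0("surv_", colnames(eval_surv) %||%
                                  seq_len(ncol(eval_surv)))
  evaluated <- cbind(evaluated, eval_surv,
                     acs = eval_acs)[ord, , drop = FALSE]
  rownames(evaluated) <- NULL

  best_i <- which.min(scores)
  structure(
    list(
      rounds = traj,
      evaluated = evaluated,
      best = list(doses = stats::setNames(level_to_dose(pop[best_i, ], panel),
                                          drugs),
                  acs = unname(scores[best_i])),
      population = pop,
      scores = scores,
      config = config,
      seed = seed
    ),
    class = "fsc_trajectory"
  )
}

#' @export
print.fsc_trajectory <- function(x, ...) {
  cat(sprintf(
    "Feedback search: %d rounds, %d combinations evaluated (%.2f%% of space)\n",
    nrow(x$rounds), max(x$rounds$n_evaluated),
    100 * max(x$rounds$frac_space)))
  cat(sprintf("  best ACS %.2f%% at [%s] ng/mL\n", x$best$acs,
              paste(names(x$best$doses), format(x$best$doses, trim = TRUE),
                    sep = "=", collapse = ", ")))
  print(x$rounds, row.names = FALSE)
  invisible(x)
}
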