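# shared fixtures for the suite: noiseless profiles and random grid screens

panel6 <- default_drug_panel()

# a noiseless single-line profile with mid-grid potency
noiseless_profile <- function(seed = 1, archetype = "moderate") {
  set.seed(seed)
  sample_profile(panel6, archetype, noise_sd = 0)
}

# random combinations drawn uniformly from the panel's dose ladders
random_combos <- function(n, panel = panel6) {
  as.data.frame(lapply(panel$dose_levels, function(lv) sample(lv, n, TRUE)))
}

# a weak-kill profile with EC50 pinned above the ladder top: survival stays
# off the 0% floor over the whole grid, so interaction structure is visible
# to a fitted response surface
subpotent_profile <- function(interaction = NULL, noise_sd = 3,
                              panel = panel6) {
  tops <- vapply(panel$dose_levels, max, numeric(1))
  cell_line_profile(
    ec50 = tops * 2,
    hill = stats::setNames(stats::runif(length(tops), 1.0, 1.4), panel$drugs),
    emax = stats::setNames(rep(0.9, length(tops)), panel$drugs),
    interaction = interaction, noise_sd = noise_sd, name = "subpotent"
  )
}

# pairwise interaction matrix with a single non-zero entry
pair_gamma <- function(a, b, gamma, panel = panel6) {
  g <- matrix(0, length(panel$drugs), length(panel$drugs),
              dimnames = list(panel$drugs, panel$drugs))
  g[a, b] <- g[b, a] <- gamma
  g
}
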