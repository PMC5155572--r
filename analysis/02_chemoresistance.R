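#!/usr/bin/env Rscript
# Chemoresistance profiling on a simulated nine-line panel: per-drug
# dose-response series, IC50 estimation (4PL with an interpolation
# cross-check), relative IC50s and per-line chemoresistance indices.

suppressMessages(library(fscombo))
dir.create("results", showWarnings = FALSE)
set.seed(20)

panel <- default_drug_panel()
archetypes <- c(`5637` = "sensitive", Biu87 = "moderate", T24 = "moderate",
                EJ = "moderate", `J-82` = "moderate", `UM-UC-3` = "resistant",
                `H-bc` = "resistant", SCaBER = "resistant",
                `SV-HUC-1` = "benign")
profiles <- lapply(archetypes, function(a) sample_profile(panel, a,
                                                          noise_sd = 3))

# 9-point dilution series per (drug, line), triplicate means
doses_for <- function(drug) panel$dose_levels[[drug]][3] *
  5^seq(-3, 3, length.out = 9)

fits <- expand.grid(cell_line = names(profiles), drug = panel$drugs,
                    stringsAsFactors = FALSE)
fits$ic50 <- NA_real_
fits$ic50_interp <- NA_real_
for (i in seq_len(nrow(fits))) {
  prof <- profiles[[fits$cell_line[i]]]
  d <- doses_for(fits$drug[i])
  combos <- as.data.frame(stats::setNames(rep(list(0), 6), panel$drugs))
  combos <- combos[rep(1, 9), ]
  combos[[fits$drug[i]]] <- d
  truth <- predict_survival(prof, combos)
  s <- pmax(0, pmin(120, rowMeans(replicate(3, truth + rnorm(9, 0, 3)))))
  # 4PL when the curve crosses 50%; otherwise the interpolation boundary
  # estimate stands in (sub-potent drug on a resistant or benign line)
  fits$ic50_interp[i] <- fit_dose_response(d, s,
                                           method = "interpolation")$ic50
  fits$ic50[i] <- tryCatch(fit_dose_response(d, s)$ic50,
                           error = function(e) fits$ic50_interp[i])
}
write.csv(fits, "results/ic50_fits.csv", row.names = FALSE)

ic50_mat <- matrix(fits$ic50, nrow = length(profiles),
                   dimnames = list(names(profiles), panel$drugs))
report <- relative_ic50_matrix(ic50_mat)
write.csv(report$relative_ic50, "results/relative_ic50.csv")
idx <- sort(report$index, decreasing = TRUE)
write.csv(data.frame(cell_line = names(idx), chemoresistance_index = idx),
          "results/chemoresistance_index.csv", row.names = FALSE)

cat("Chemoresistance ranking (mean relative IC50 over six drugs):\n")
print(round(idx, 2))
agree <- with(fits[!is.na(fits$ic50) & !is.na(fits$ic50_interp), ],
              median(abs(log10(ic50 / ic50_interp))))
cat(sprintf("4PL vs interpolation IC50s: median |log10 ratio| %.3f\n", agree))
cat("Published-value arithmetic: removing the one extreme drug from the",
    "most resistant line's 6-drug index (678.68, relative IC50 3976.1)",
    sprintf("leaves %.1f over the other five drugs\n",
            (678.68 * 6 - 3976.1) / 5))
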