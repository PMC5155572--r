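# Published screening-round tables, inlined as literals and exposed as
# viability_table objects. The printed per-combination statistics (ACS and,
# for the fourth round, the three-line cumulative ACCS) are carried in
# $extra as acs_printed / accs_printed so the scoring code can be checked
# against every printed cell. Assembled from the transcribed tables; the
# published layout (one column per combination) is transposed to one row
# per combination.

ref_table_data <- local({
  table1_Pi <- c(1.6, 8, 8, 1.6, 8, 0.32, 40, 0.32, 0.32, 8, 1.6, 8, 40, 40, 0.32, 40, 40, 8, 1.6, 8)
  table1_Pa <- c(32, 6.4, 32, 1.28, 32, 160, 1.28, 6.4, 6.4, 160, 1.28, 160, 1.28, 1.28, 1.28, 1.28, 32, 6.4, 6.4, 1.28)
  table1_EH <- c(10, 2, 50, 10, 50, 10, 50, 250, 10, 10, 50, 50, 250, 250, 10, 50, 50, 50, 250, 2)
  table1_Ci <- c(300, 300, 300, 12, 60, 1500, 60, 1500, 300, 12, 60, 1500, 300, 60, 1500, 12, 1500, 1500, 1500, 300)
  table1_Ge <- c(5, 1, 0.04, 5, 5, 0.2, 0.2, 1, 0.2, 0.2, 0.04, 5, 5, 0.04, 1, 1, 5, 5, 0.2, 0.04)
  table1_Mi <- c(8, 8, 8, 8, 40, 1000, 200, 1000, 1000, 200, 8, 40, 40, 8, 40, 200, 200, 8, 200, 40)
  table1_x5637 <- c(24.58, 43.82, 45.43, 65.40, 42.03, 1.23, 26.47, 0.51, 11.57, 16.17, 62.93, 13.59, 26.19, 47.21, 30.10, 25.27, 6.62, 23.94, 1.99, 48.26)
  table1_H_bc <- c(52.57, 56.01, 52.30, 59.60, 58.01, 18.96, 48.40, 3.40, 42.60, 51.76, 57.78, 26.84, 30.01, 33.02, 33.64, 44.03, 15.80, 29.12, 5.48, 58.13)
  table1_J_82 <- c(43.69, 55.27, 50.62, 72.9, 46.08, 6.07, 23.75, 6.62, 11.53, 26.82, 65.16, 13.4, 18.67, 31, 24.3, 24.77, 7.63, 16.23, 8.26, 56.8)
  table1_T24 <- c(36.41, 44.71, 45.20, 62.06, 39.05, 7.97, 32.91, 11.67, 20.07, 29.74, 61.60, 14.80, 17.25, 24.05, 22.03, 34.08, 11.21, 15.78, 8.73, 39.38)
  table1_EJ <- c(46.55, 51.31, 40.41, 69.1, 41.61, 30.67, 37.67, 21.79, 35.01, 36.4, 56.02, 36.62, 22.28, 28.35, 45.2, 34.79, 31.27, 37.86, 23.63, 53.67)
  table1_Biu87 <- c(21.67, 49.15, 51.1, 26.78, 31.5, 7.64, 48.37, 16.09, 20.32, 37.65, 72.26, 8.56, 17.59, 33.22, 14.02, 45.38, 12.87, 14.05, 13.3, 65.93)
  table1_ACS <- c(37.58, 50.04, 47.51, 59.31, 43.05, 12.09, 36.26, 10.01, 23.52, 33.09, 62.63, 18.97, 22.00, 32.81, 28.21, 34.72, 14.23, 22.83, 10.23, 53.70)

  table2_Pi <- c(40, 8, 8, 40, 0, 0, 1.6, 0, 0, 40, 1.6, 1.6, 1.6, 1.6, 1.6, 8, 8, 0.32, 8, 8, 0, 40, 8, 40, 40, 0, 0, 40, 40, 40, 0, 0, 0, 8, 8, 1.6, 40, 0, 8, 0.32)
  table2_Pa <- c(160, 6.4, 0, 1.28, 160, 1.28, 0, 0, 0, 160, 160, 0, 6.4, 0, 0, 6.4, 6.4, 32, 160, 0, 32, 0, 160, 0, 0, 32, 0, 0, 160, 32, 160, 6.4, 0, 0, 0, 160, 0, 32, 0, 0)
  table2_EH <- c(250, 250, 50, 50, 250, 50, 50, 50, 250, 0, 2, 2, 2, 2, 50, 2, 50, 50, 0, 0, 2, 50, 0, 250, 250, 50, 10, 50, 50, 0, 10, 0, 10, 50, 0, 2, 50, 250, 50, 250)
  table2_Ci <- c(1500, 12, 60, 300, 1500, 60, 1500, 60, 1500, 1500, 300, 1500, 1500, 0, 0, 60, 60, 300, 1500, 300, 300, 12, 0, 300, 60, 0, 1500, 0, 300, 12, 1500, 1500, 0, 1500, 1500, 0, 1500, 1500, 1500, 1500)
  table2_Ge <- c(0, 0, 1, 0.2, 0, 0, 5, 5, 0.2, 5, 0.04, 1, 1, 0.2, 5, 0.2, 5, 0.2, 5, 0.2, 5, 0, 0.2, 5, 0, 5, 1, 1, 5, 0, 0.2, 1, 5, 0.2, 5, 0.2, 5, 0.2, 5, 0)
  table2_Mi <- c(1000, 200, 200, 1000, 1000, 8, 8, 8, 8, 0, 8, 0, 40, 200, 8, 1000, 200, 0, 0, 1000, 0, 200, 200, 40, 0, 1000, 0, 200, 200, 1000, 0, 1000, 1000, 1000, 40, 1000, 1000, 1000, 40, 200)
  table2_Biu87 <- c(1.06, 13.15, 10.83, 3.44, 1.76, 67.33, 2.49, 19.33, 4.74, 2.33, 19.08, 3.03, 3.98, 11.15, 16.07, 4.11, 4.84, 32.59, 2.01, 2.97, 11.37, 13.41, 13.91, 5.62, 19.78, 2.76, 4.77, 12.09, 5.70, 6.88, 2.83, 1.70, 2.42, 1.41, 2.23, 3.39, 1.73, 2.01, 3.74, 2.17)
  table2_J_82 <- c(1.09, 16.03, 24.08, 3.20, 1.55, 81.67, 10.85, 83.10, 11.47, 9.01, 46.99, 17.53, 13.42, 22.31, 83.37, 5.41, 15.91, 55.90, 11.47, 3.26, 69.36, 21.93, 24.21, 25.25, 65.75, 8.46, 20.82, 28.68, 19.46, 9.93, 15.54, 2.21, 9.93, 1.86, 12.82, 8.68, 1.71, 1.61, 12.36, 7.14)
  table2_EJ <- c(10.47, 33.23, 44.31, 20.32, 13.79, 95.23, 49.72, 89.61, 48.27, 39.92, 65.19, 59.73, 51.97, 42.01, 86.61, 23.16, 37.99, 73.87, 49.02, 18.98, 77.62, 36.29, 36.91, 44.56, 66.58, 25.51, 63.19, 37.58, 39.91, 20.74, 40.61, 15.55, 26.85, 16.89, 47.02, 21.00, 13.66, 15.55, 48.61, 28.13)
  table2_ACCS <- c(4.21, 20.80, 26.41, 8.99, 5.70, 81.41, 21.02, 64.01, 21.49, 17.09, 43.75, 26.76, 23.12, 25.16, 62.02, 10.89, 19.58, 54.12, 20.83, 8.40, 52.78, 23.88, 25.01, 25.14, 50.70, 12.25, 29.60, 26.11, 21.69, 12.51, 19.66, 6.49, 13.06, 6.72, 20.69, 11.02, 5.70, 6.39, 21.57, 12.48)
  table2_x5637 <- c(12.67, NA, NA, 49.82, 31.48, NA, 58.46, NA, 54.30, 54.91, NA, NA, NA, NA, NA, 58.89, 63.70, NA, 59.90, 58.19, NA, NA, NA, NA, NA, 55.04, NA, NA, NA, 55.21, 56.03, 41.74, 67.91, 38.98, 72.15, 53.50, 47.58, 48.65, 74.74, 39.77)
  table2_T24 <- c(6.71, NA, NA, 6.07, 6.53, NA, 67.09, NA, 60.35, 64.83, NA, NA, NA, NA, NA, 14.88, 32.74, NA, 62.31, 11.91, NA, NA, NA, NA, NA, 8.76, NA, NA, NA, 10.50, 63.41, 4.91, 8.76, 6.51, 56.17, 8.21, 5.96, 5.54, 58.66, 5.62)
  table2_UM_UC_3 <- c(4.66, NA, NA, 19.97, 11.74, NA, 39.16, NA, 35.24, 25.80, NA, NA, NA, NA, NA, 19.74, 31.35, NA, 34.55, 44.89, NA, NA, NA, NA, NA, 11.12, NA, NA, NA, 22.07, 36.00, 20.91, 12.29, 27.58, 22.86, 18.08, 25.76, 21.01, 25.44, 21.67)
  table2_H_bc <- c(0.08, NA, NA, 69.34, 1.83, NA, 79.74, NA, 73.68, 72.95, NA, NA, NA, NA, NA, 76.52, 77.57, NA, 69.74, 72.60, NA, NA, NA, NA, NA, 72.55, NA, NA, NA, 73.72, 73.03, 35.05, 81.70, 36.08, 78.21, 75.08, 15.01, 3.23, 76.61, 4.30)
  table2_ACS <- c(4.59, NA, NA, 21.52, 8.58, NA, 38.44, NA, 36.01, 33.72, NA, NA, NA, NA, NA, 25.34, 33.01, NA, 36.13, 26.60, NA, NA, NA, NA, NA, 23.03, NA, NA, NA, 24.88, 35.93, 15.26, 26.23, 16.16, 36.43, 23.49, 13.93, 12.20, 37.52, 13.60)

  table3_Pi <- c(0, 0, 0, 40, 0, 0, 0, 8, 0, 0, 0, 0, 40, 0, 0, 0, 0, 0, 0, 0, 0, 40, 0, 40, 40, 40, 8, 0, 0, 0, 8, 0, 0, 40)
  table3_Pa <- c(0, 0, 160, 0, 0, 0, 32, 0, 0, 0, 0, 160, 0, 0, 0, 0, 160, 0, 0, 0, 160, 0, 0, 32, 0, 0, 0, 32, 0, 32, 0, 0, 0, 32)
  table3_EH <- c(0, 250, 0, 0, 0, 50, 0, 0, 0, 0, 250, 0, 0, 0, 0, 250, 0, 0, 0, 250, 0, 0, 0, 0, 50, 0, 0, 0, 50, 250, 250, 250, 250, 50)
  table3_Ci <- c(1500, 1500, 1500, 1500, 1500, 1500, 1500, 1500, 1500, 1500, 1500, 1500, 1500, 1500, 300, 300, 300, 300, 300, 300, 300, 300, 300, 300, 300, 300, 300, 300, 300, 300, 300, 300, 300, 1500)
  table3_Ge <- c(0, 0, 0, 0, 5, 0, 0, 0, 1, 0, 0, 0, 0, 5, 0, 0, 0, 5, 0, 0, 0, 0, 5, 0, 0, 1, 5, 5, 5, 0, 0, 1, 5, 5)
  table3_Mi <- c(1000, 1000, 1000, 1000, 1000, 1000, 1000, 1000, 1000, 200, 200, 200, 200, 200, 1000, 1000, 1000, 1000, 200, 200, 200, 200, 200, 200, 200, 200, 200, 200, 200, 200, 200, 200, 200, 200)
  table3_Biu87 <- c(4.5, 2, 1.3, 3.5, 5.7, 4.3, 1.9, 1.7, 3.5, 5.3, 0.6, 1.9, 2.8, 3.7, 13.4, 9.9, 10.7, 13.3, 6.8, 36.4, 21.7, 27.2, 30.7, 8.4, 30.4, 29.3, 24.2, 14.9, 12.5, 14.5, 28.1, 27.3, 22.7, 13.2)
  table3_EJ <- c(17, 15.4, 10.4, 16.7, 20, 22.4, 14.3, 20, 19.4, 27.7, 16.7, 25.1, 22.5, 25.7, 30.9, 29.8, 23.5, 31.8, 27, 52.8, 40.9, 38.7, 55.9, 39.3, 38.1, 47.8, 48.4, 46.5, 37.5, 44.9, 40.5, 45.1, 49.9, 40.4)
  table3_H_bc <- c(29.5, 4.79, 19.82, 5.84, 7.57, 5.11, 42.68, 8.5, 29.95, 41.03, 12.43, 13.56, 17.24, 32.23, 57.1, 29.7, 44, 49.9, 50.3, 73.2, 48.4, 55.9, 49.9, 64.2, 55, 58.3, 70.9, 63, 63.1, 58.6, 47.8, 33.1, 45.4, 51.9)
  table3_T24 <- c(3.6, 1.6, 3.7, 1.6, 4.8, 3.2, 3.9, 3.8, 4.5, 5.6, 6.5, 1.6, 3.5, 8.9, 7.09, 29.5, 7.69, 12.76, 71.7, 8.87, 45.97, 55.81, 46.27, 50.98, 40.97, 34.88, 46.03, 51.52, 47.05, 53.67, 33.09, 31.25, 39.53, 33.27)
  table3_UM_UC_3 <- c(3, 2.9, 3, 3.6, 3.5, 2.7, 3, 3.6, 3.1, 4.6, 3.6, 4.2, 4.1, 4.1, 32, 14.1, 19.4, 25.5, 34.6, 64.5, 30.1, 32.3, 22.1, 49.6, 37.1, 30.9, 43.4, 58.7, 41.1, 49.7, 19.7, 17.1, 22.4, 21.2)
  table3_ACS <- c(11.52, 5.34, 7.64, 6.25, 8.31, 7.54, 13.16, 7.52, 12.09, 16.85, 7.97, 9.27, 10.03, 14.93, 28.10, 22.60, 21.06, 26.65, 38.08, 47.15, 37.41, 41.98, 40.97, 42.50, 40.31, 40.24, 46.59, 46.92, 40.25, 44.27, 33.84, 30.77, 35.99, 31.99)

  list(
    table1 = list(
      combos = data.frame(Pi = table1_Pi, Pa = table1_Pa, EH = table1_EH,
                          Ci = table1_Ci, Ge = table1_Ge, Mi = table1_Mi),
      survival = cbind(`5637` = table1_x5637, `H-bc` = table1_H_bc,
                       `J-82` = table1_J_82, T24 = table1_T24,
                       EJ = table1_EJ, Biu87 = table1_Biu87),
      divisor = 6L,
      extra = data.frame(acs_printed = table1_ACS)
    ),
    table2 = list(
      combos = data.frame(Pi = table2_Pi, Pa = table2_Pa, EH = table2_EH,
                          Ci = table2_Ci, Ge = table2_Ge, Mi = table2_Mi),
      survival = cbind(Biu87 = table2_Biu87, `J-82` = table2_J_82,
                       EJ = table2_EJ, `5637` = table2_x5637,
                       T24 = table2_T24, `UM-UC-3` = table2_UM_UC_3,
                       `H-bc` = table2_H_bc),
      divisor = 8L,
      extra = data.frame(accs_printed = table2_ACCS,
                         acs_printed = table2_ACS)
    ),
    table3 = list(
      combos = data.frame(Pi = table3_Pi, Pa = table3_Pa, EH = table3_EH,
                          Ci = table3_Ci, Ge = table3_Ge, Mi = table3_Mi),
      survival = cbind(Biu87 = table3_Biu87, EJ = table3_EJ,
                       `H-bc` = table3_H_bc, T24 = table3_T24,
                       `UM-UC-3` = table3_UM_UC_3),
      divisor = 5L,
      extra = data.frame(acs_printed = table3_ACS)
    )
  )
})

#' Published screening-round viability tables
#'
#' The three in-print screening tables of the bladder-cancer combination
#' screen, as [viability_table()] objects:
#' \describe{
#'   \item{\code{"round1"}}{First random round: 20 six-drug combinations
#'     over 6 TCC cell lines, ACS divisor 6.}
#'   \item{\code{"round4"}}{Fourth (final search) round: 40 combinations.
#'     Three lines (Biu87, J-82, EJ) were measured for every combination
#'     (their cumulative score, divisor 3, is in \code{$extra$accs_printed});
#'     four further lines only for a subset, with the full-panel ACS using
#'     divisor 8 over the 7 present values (\code{$extra$acs_printed}).}
#'   \item{\code{"refinement"}}{Tri-drug refinement screen: 34 combinations
#'     around fixed cisplatin/mitomycin doses over 5 lines, divisor 5.}
#' }
#' The \code{$extra} columns hold the statistics as printed (2 decimals),
#' for cross-checking the scoring functions; they are not used in any
#' computation.
#'
#' @param which one of \code{"round1"}, \code{"round4"}, \code{"refinement"}.
#' @return A [viability_table()].
#' @export
reference_viability_table <- function(which = c("round1", "round4",
                                                "refinement")) {
  which <- match.arg(which)
  key <- switch(which, round1 = "table1", round4 = "table2",
                refinement = "table3")
  d <- ref_table_data[[key]]
  suppressWarnings(  # round4 holds no >100 values, others neither; keep quiet
    viability_table(d$combos, d$survival, round_id = which,
                    divisor = d$divisor, extra = d$extra)
  )
}

#' Write the reference screening tables as delimited-text fixtures
#'
#' Emits the three published rounds in the package's table dialect
#' (see [write_viability_table()]). Deterministic: re-emitting produces
#' byte-identical files.
#'
#' @param outdir directory to write into (created if needed).
#' @return Character vector of the three file paths, invisibly.
#' @export
emit_reference_tables <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(c("round1", "round4", "refinement"), function(w) {
    p <- file.path(outdir, paste0(w, ".csv"))
    write_viability_table(reference_viability_table(w), p)
    p
  }, character(1))
  invisible(paths)
}
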