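#' Construct a viability table
#'
#' The central data container of the pipeline: per-combination, per-cell-line
#' cell survival percentages from a plate screen (or from the simulator), plus
#' the round's ACS divisor. Survival entries may be missing (unmeasured
#' wells); present entries must lie in [0, 150], with values above 100
#' tolerated under a warning (over-100 readings occur in practice from
#' assay normalization).
#'
#' @param combos data frame of doses, one column per drug (ng/mL), one row per
#'   combination.
#' @param survival numeric matrix, combinations x cell lines, in percent.
#'   Column names are the cell-line identifiers. \code{NA} marks missing.
#' @param round_id character label for the screening round.
#' @param divisor positive integer used as the ACS denominator for this table.
#'   It is an explicit design parameter, never inferred from the number of
#'   present values: published screens divide by the intended panel size even
#'   when one line went unmeasured.
#' @param label optional character vector of combination labels.
#' @param extra optional data frame of additional per-combination columns
#'   (e.g. printed reference statistics); preserved on round-trip.
#' @return An object of class \code{viability_table}.
#' @export
viability_table <- function(combos, survival, round_id = "round",
                            divisor = ncol(survival), label = NULL,
                            extra = NULL) {
  combos <- as.data.frame(combos)
  survival <- as.matrix(survival)
  storage.mode(survival) <- "double"
  if (nrow(combos) != nrow(survival)) {
    stop("combos and survival must have one row per combination")
  }
  if (is.null(colnames(survival)) || any(!nzchar(colnames(survival)))) {
    stop("survival matrix must have cell-line column names")
  }
  if (!is.numeric(divisor) || length(divisor) != 1 || divisor < 1) {
    stop("divisor must be a positive integer")
  }
  bad <- which(!is.na(survival) & (survival < 0 | survival > 150), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "survival outside [0, 150] at combination %d, cell line %s (%.2f)",
      bad[1, 1], colnames(survival)[bad[1, 2]], survival[bad[1, , drop = FALSE]]))
  }
  high <- which(!is.na(survival) & survival > 100, arr.ind = TRUE)
  if (nrow(high)) {
    warning(sprintf("%d survival value(s) above 100%% retained", nrow(high)))
  }
  if (is.null(label)) label <- as.character(seq_len(nrow(combos)))
  if (!is.null(extra)) {
    extra <- as.data.frame(extra)
    stopifnot(nrow(extra) == nrow(combos))
  }
  structure(
    list(
      combos = combos,
      survival = survival,
      cell_lines = colnames(survival),
      round_id = as.character(round_id),
      divisor = as.integer(divisor),
      label = as.character(label),
      extra = extra
    ),
    class = "viability_table"
  )
}

#' @export
print.viability_table <- function(x, ...) {
  cat(sprintf(
    "Viability table '%s': %d combinations x %d cell lines (ACS divisor %d)\n",
    x$round_id, nrow(x$combos), length(x$cell_lines), x$divisor))
  cat("  drugs:     ", paste(names(x$combos), collapse = ", "), "\n")
  cat("  cell lines:", paste(x$cell_lines, collapse = ", "), "\n")
  n_missing <- sum(is.na(x$survival))
  if (n_missing) cat("  missing survival entries:", n_missing, "\n")
  invisible(x)
}

#' Restrict a viability table to a subset of cell lines
#'
#' Used when one screening round carries two statistics over different
#' cell-line blocks (e.g. a three-line cumulative score next to a
#' full-panel one). The divisor must be restated because it does not follow
#' from the subset size.
#'
#' @param table a [viability_table()].
#' @param cell_lines character vector of lines to keep.
#' @param divisor ACS divisor for the subset (default: number of kept lines).
#' @return A new \code{viability_table}.
#' @export
subset_cell_lines <- function(table, cell_lines,
                              divisor = length(cell_lines)) {
  stopifnot(inherits(table, "viability_table"))
  missing_lines <- setdiff(cell_lines, table$cell_lines)
  if (length(missing_lines)) {
    stop("unknown cell line(s): ", paste(missing_lines, collapse = ", "))
  }
  viability_table(
    combos = table$combos,
    survival = table$survival[, cell_lines, drop = FALSE],
    round_id = table$round_id,
    divisor = divisor,
    label = table$label,
    extra = table$extra
  )
}

#' Read a viability table from delimited text
#'
#' Dialect: UTF-8 comma- or tab-separated (auto-detected from the header
#' line), one combination per row. Columns: optional \code{label}, dose
#' columns prefixed \code{dose_}, cell-line survival columns prefixed
#' \code{surv_}; any remaining columns are carried along in \code{$extra}.
#' Missing survival is an empty cell or an em-dash. Two comment
#' lines \code{# round_id:} and \code{# divisor:} carry the table metadata.
#'
#' @param path file to read.
#' @param dialect \code{"auto"} (default), \code{"csv"} or \code{"tsv"}.
#' @return A [viability_table()].
#' @export
read_viability_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines)))) {
    stop("malformed viability table: file is empty")
  }
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (!length(body)) stop("malformed viability table: no header line")
  sep <- switch(dialect,
    csv = ",",
    tsv = "\t",
    auto = if (grepl("\t", body[1])) "\t" else ","
  )
  df <- utils::read.table(
    text = body, header = TRUE, sep = sep, quote = "\"",
    stringsAsFactors = FALSE, check.names = FALSE,
    na.strings = c("", "NA", "—"), encoding = "UTF-8",
    colClasses = NA
  )
  dose_cols <- grep("^dose_", names(df), value = TRUE)
  surv_cols <- grep("^surv_", names(df), value = TRUE)
  if (!length(dose_cols) || !length(surv_cols)) {
    stop("malformed viability table header: need dose_* then surv_* columns")
  }
  meta_value <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), meta, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", hit[1]))
  }
  combos <- df[dose_cols]
  names(combos) <- sub("^dose_", "", dose_cols)
  for (cl in names(combos)) {
    if (!is.numeric(combos[[cl]])) stop("non-numeric dose column: ", cl)
    if (anyNA(combos[[cl]])) stop("missing dose in column ", cl)
    combos[[cl]] <- as.numeric(combos[[cl]])
  }
  survival <- as.matrix(df[surv_cols])
  if (!is.numeric(survival)) stop("non-numeric survival column")
  colnames(survival) <- sub("^surv_", "", surv_cols)
  bad <- which(!is.na(survival) & (survival < 0 | survival > 150), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("survival outside [0, 150] at row %d, column surv_%s",
                 bad[1, 1], colnames(survival)[bad[1, 2]]))
  }
  other <- setdiff(names(df), c("label", dose_cols, surv_cols))
  viability_table(
    combos = combos,
    survival = survival,
    round_id = meta_value("round_id", sub("\\.[^.]*$", "", basename(path))),
    divisor = as.integer(meta_value("divisor", ncol(survival))),
    label = if ("label" %in% names(df)) df$label else NULL,
    extra = if (length(other)) df[other] else NULL
  )
}

#' Write a viability table as delimited text
#'
#' Inverse of [read_viability_table()]: emits the metadata comment lines, a
#' header and one row per combination. Survival is serialized with two
#' decimals (the reporting precision of the plate tables); missing cells are
#' written empty. \code{read(write(t))} reproduces \code{t} field for field.
#'
#' @param table a [viability_table()].
#' @param path output file.
#' @param dialect \code{"csv"} (default) or \code{"tsv"}.
#' @return Invisibly, \code{path}.
#' @export
write_viability_table <- function(table, path, dialect = c("csv", "tsv")) {
  stopifnot(inherits(table, "viability_table"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  num <- function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "" else format(v, trim = TRUE, scientific = FALSE, digits = 15)
    }, character(1))
    out
  }
  surv_chr <- apply(table$survival, 2, function(col) {
    ifelse(is.na(col), "", formatC(col, format = "f", digits = 2))
  })
  surv_chr <- matrix(surv_chr, nrow = nrow(table$survival),
                     dimnames = list(NULL, paste0("surv_", table$cell_lines)))
  cols <- c(
    list(label = table$label),
    stats::setNames(lapply(table$combos, num),
                    paste0("dose_", names(table$combos))),
    as.data.frame(surv_chr, stringsAsFactors = FALSE)
  )
  if (!is.null(table$extra)) {
    cols <- c(cols, lapply(as.list(table$extra), function(col) {
      if (is.numeric(col)) {
        ifelse(is.na(col), "", formatC(col, format = "f", digits = 2))
      } else {
        ifelse(is.na(col), "", as.character(col))
      }
    }))
  }
  df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# round_id: ", table$round_id),
    paste0("# divisor: ", table$divisor)
  ), con)
  utils::write.table(df, con, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
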