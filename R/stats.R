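# Post-processing of interaction-energy component tables: Spearman rank
# correlations among the five components, delocalization/electrostatic
# covalency ratios, and the component-table CSV dialect.

.COMPONENTS <- c("e_hl", "e_el_10", "e_ex_hl", "e_del_hf", "e_hf")
.CSV_COLUMNS <- c(e_hl = "DE_HL", e_el_10 = "e_el_10", e_ex_hl = "DE_ex_HL",
                  e_del_hf = "DE_del_HF", e_hf = "DE_HF")

#' Read an interaction-energy component table
#'
#' CSV dialect: columns `label, DE_HL, e_el_10, DE_ex_HL, DE_del_HF, DE_HF`
#' in kcal/mol.  Per-row additivity (`e_el_10 + e_ex_hl + e_del_hf = e_hf`
#' and `e_el_10 + e_ex_hl = e_hl`) is validated on ingest; published tables
#' are rounded to ~2 decimals, so the default tolerance admits accumulated
#' print rounding.
#'
#' @param path CSV file.
#' @param additivity_tol Largest admissible per-row additivity residual
#'   (kcal/mol) for ingested, printed tables.
#' @return A `component_table` data frame with columns
#'   `label, e_hl, e_el_10, e_ex_hl, e_del_hf, e_hf`.
#' @export
read_component_table <- function(path, additivity_tol = 0.05) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("label", .CSV_COLUMNS), names(raw))
  if (length(missing) > 0) {
    stop("component CSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  df <- data.frame(label = raw$label, stringsAsFactors = FALSE)
  for (k in names(.CSV_COLUMNS)) df[[k]] <- as.numeric(raw[[.CSV_COLUMNS[k]]])
  validate_component_table(df, additivity_tol)
  class(df) <- c("component_table", "data.frame")
  df
}

#' Write a component table in the CSV dialect
#'
#' @param table A `component_table` (e.g. from [eda_result_table()]).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_component_table <- function(table, path) {
  out <- data.frame(label = table$label)
  for (k in names(.CSV_COLUMNS)) out[[.CSV_COLUMNS[[k]]]] <- table[[k]]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate per-row additivity of a component table
#'
#' @param table A component table.
#' @param tol Largest admissible residual (kcal/mol).
#' @return Invisibly, a data frame of per-row residuals for both identities.
#' @export
validate_component_table <- function(table, tol = 0.05) {
  if (anyDuplicated(table$label)) stop("component-table labels must be unique")
  res_hf <- table$e_el_10 + table$e_ex_hl + table$e_del_hf - table$e_hf
  res_hl <- table$e_el_10 + table$e_ex_hl - table$e_hl
  bad <- abs(res_hf) > tol | abs(res_hl) > tol
  if (any(bad)) {
    stop("component additivity violated beyond ", tol, " kcal/mol for: ",
         paste(table$label[bad], collapse = ", "))
  }
  invisible(data.frame(label = table$label, residual_hf = res_hf,
                       residual_hl = res_hl))
}

#' Spearman rank correlation by the rank-difference formula
#'
#' `rho = 1 - 6 * sum(d_i^2) / (n (n^2 - 1))`, with `d_i` the difference of
#' the ascending ranks of `x_i` and `y_i` and no tie correction.  Ties get
#' average ranks and raise a warning (energies are continuous; ties are
#' pathological).
#'
#' @param x,y Numeric vectors of equal length `n >= 2`.
#' @return The correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least 2 paired observations")
  if (anyDuplicated(x) || anyDuplicated(y)) {
    warning("ties present; the rank-difference formula has no tie correction")
  }
  d <- rank(x, ties.method = "average") - rank(y, ties.method = "average")
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

#' Spearman correlations among all component pairs
#'
#' @param table A `component_table`.
#' @param exclude Labels dropped before correlating (default: the ligand
#'   sub-fragment rows, so the default row set is the amino-acid complexes).
#' @return An object of class `correlation_matrix`: a symmetric 5 x 5
#'   matrix of rho values over
#'   `dE^HL, e_el^(10), dE_ex^HL, dE_del^HF, dE^HF`, with the row count as
#'   attribute `n`.
#' @export
correlation_table <- function(table, exclude = c("ADP", "NICO")) {
  rows <- table[!table$label %in% exclude, , drop = FALSE]
  if (nrow(rows) < 2) stop("need at least 2 rows after filtering")
  m <- diag(1, length(.COMPONENTS))
  dimnames(m) <- list(.COMPONENTS, .COMPONENTS)
  for (i in seq_along(.COMPONENTS)) {
    for (j in seq_along(.COMPONENTS)) {
      if (i < j) {
        m[i, j] <- m[j, i] <-
          spearman_rho(rows[[.COMPONENTS[i]]], rows[[.COMPONENTS[j]]])
      }
    }
  }
  structure(m, n = nrow(rows), class = c("correlation_matrix", "matrix"))
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("Spearman rank correlations (n = %d complexes)\n", attr(x, "n")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Covalency ratio of a hydrogen-bonded complex
#'
#' The ratio of the delocalization to the first-order electrostatic
#' component.  Ratios above the threshold flag hydrogen bonds with partially
#' covalent character (charge-transfer dominated); the comparison is a
#' strict inequality.
#'
#' @param e_del_hf,e_el_10 Components in kcal/mol; `e_el_10` must be
#'   nonzero.
#' @return Dimensionless ratio.
#' @export
covalency_ratio <- function(e_del_hf, e_el_10) {
  if (any(e_el_10 == 0)) {
    stop("covalency ratio undefined: zero electrostatic component")
  }
  e_del_hf / e_el_10
}

#' @rdname covalency_ratio
#' @param ratio Ratio from `covalency_ratio()`.
#' @param threshold Classification threshold (default 0.45).
#' @return `"partially-covalent"` or `"electrostatic"` per element.
#' @export
classify_covalency <- function(ratio, threshold = 0.45) {
  ifelse(ratio > threshold, "partially-covalent", "electrostatic")
}

#' Covalency report for selected complexes
#'
#' @param table A `component_table`.
#' @param labels Rows to report (default: all).
#' @param distances Optional named numeric vector of hydrogen-bond lengths
#'   (angstrom) merged into the report.
#' @param threshold Classification threshold.
#' @return A `covalency_report` data frame with label, distance, `e_hf`,
#'   ratio and classification; ratios are reported at full precision with a
#'   2-decimal display column.
#' @export
covalency_report <- function(table, labels = NULL, distances = NULL,
                             threshold = 0.45) {
  rows <- if (is.null(labels)) table else table[match(labels, table$label), ]
  if (anyNA(rows$label)) {
    stop("labels not in table: ",
         paste(setdiff(labels, table$label), collapse = ", "))
  }
  ratio <- covalency_ratio(rows$e_del_hf, rows$e_el_10)
  out <- data.frame(
    label = rows$label,
    hbond_distance = if (is.null(distances)) NA_real_ else
      as.numeric(distances[rows$label]),
    e_hf = rows$e_hf,
    ratio = ratio,
    ratio_2dp = round(ratio, 2),
    classification = classify_covalency(ratio, threshold),
    stringsAsFactors = FALSE)
  class(out) <- c("covalency_report", "data.frame")
  out
}
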