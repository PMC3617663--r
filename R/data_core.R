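#' Published coumarin antioxidant activity fixture
#'
#' Returns the embedded reference table of 45 coumarin derivatives assayed for
#' DPPH radical-scavenging activity: observed pIC50 (IC50 on the molar scale),
#' the activity calculated (training set) or predicted (test set) by the
#' published five-term GFA spline model, and the training/test membership used
#' throughout the original analysis (32 train, 13 test; test compounds
#' 1, 3, 5, 7, 14, 15, 18, 28, 31, 32, 33, 36, 39).
#'
#' Values are stored exactly as printed (three decimals); IC50 values were
#' never published so activities are not re-derived.
#'
#' @return A data.frame with columns `compound` (integer id 1-45), `observed`
#'   (pIC50), `predicted` (pIC50 from the published model), and `set`
#'   (`"train"` or `"test"`).
#' @export
#' @examples
#' act <- coumarin_activity()
#' table(act$set)
coumarin_activity <- function() {
  observed <- c(
    2.890, 4.239, 4.117, 2.871, 2.794, 4.978, 3.067, 3.502, 4.436, 5.161,
    4.478, 4.790, 2.618, 1.012, 1.112, 1.069, 1.860, 1.833, 2.232, 2.128,
    2.144, 2.156, 2.620, 5.000, 2.664, 2.424, 1.118, 1.197, 1.815, 2.943,
    1.604, 1.491, 1.314, 1.425, 1.572, 1.672, 3.740, 3.697, 3.694, 3.886,
    4.010, 3.792, 3.802, 3.780, 3.906
  )
  predicted <- c(
    2.412, 3.439, 3.834, 3.181, 3.602, 5.268, 3.323, 3.793, 4.418, 4.921,
    4.461, 4.932, 2.196, 1.488, 1.035, 1.055, 2.012, 2.008, 2.715, 2.726,
    2.163, 2.334, 2.326, 4.818, 2.156, 2.369, 1.754, 1.860, 1.765, 3.005,
    1.915, 2.013, 1.394, 1.495, 1.430, 2.195, 3.346, 3.626, 3.915, 4.011,
    3.765, 3.752, 3.998, 4.148, 3.478
  )
  test_ids <- c(1L, 3L, 5L, 7L, 14L, 15L, 18L, 28L, 31L, 32L, 33L, 36L, 39L)
  data.frame(
    compound = seq_along(observed),
    observed = observed,
    predicted = predicted,
    set = ifelse(seq_along(observed) %in% test_ids, "test", "train"),
    stringsAsFactors = FALSE
  )
}

#' Published GFA spline model fixture
#'
#' The five-term GFA spline model selected in the original descriptor-based
#' analysis:
#' pIC50 = -0.123 + 1.243 Atype_O57 + 0.010 JursPPSA_1 - 0.806 Atype_C25
#'         + 0.085 Kappa2 + 67.5 <Density - 1.18046>,
#' where `<x - a>` is the truncated-power spline max(0, x - a). The knot
#' 1.18046 is stored exactly as printed.
#'
#' @return A [linear_model()] object with intercept -0.123 and five terms.
#' @export
gfa_spline_model <- function() {
  linear_model(
    intercept = -0.123,
    terms = list(
      basis_term("Atype_O57"),
      basis_term("JursPPSA_1"),
      basis_term("Atype_C25"),
      basis_term("Kappa2"),
      basis_term("Density", form = "spline", knot = 1.18046,
                 orientation = "x_minus_knot")
    ),
    coefficients = c(1.243, 0.010, -0.806, 0.085, 67.5)
  )
}

#' Construct a descriptor table
#'
#' A descriptor table pairs an n x d numeric matrix of named molecular
#' descriptors with a pIC50 activity vector of length n.
#'
#' @param values Numeric matrix (compounds x descriptors) with unique column
#'   names.
#' @param activity Numeric pIC50 vector, length `nrow(values)`.
#' @param compound_ids Optional character/integer ids; defaults to row
#'   numbers.
#' @return An object of class `descriptor_table`.
#' @export
descriptor_table <- function(values, activity, compound_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("descriptor values must be numeric")
  if (nrow(values) < 2L) stop("a descriptor table needs at least 2 compounds")
  if (anyNA(values) || any(!is.finite(values)))
    stop("descriptor table contains missing or non-finite values")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("descriptor columns must have unique names")
  activity <- as.numeric(activity)
  if (length(activity) != nrow(values))
    stop("activity length does not match the number of compounds")
  if (anyNA(activity) || any(!is.finite(activity)))
    stop("activity contains missing or non-finite values")
  if (is.null(compound_ids)) compound_ids <- as.character(seq_len(nrow(values)))
  compound_ids <- as.character(compound_ids)
  if (anyDuplicated(compound_ids)) stop("duplicate compound ids")
  structure(
    list(compound_ids = compound_ids,
         descriptor_names = colnames(values),
         values = values,
         activity = activity),
    class = "descriptor_table"
  )
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("descriptor_table: %d compounds x %d descriptors\n",
              nrow(x$values), ncol(x$values)))
  cat("activity range:", sprintf("%.3f", range(x$activity)), "\n")
  invisible(x)
}

#' Read a descriptor table from CSV
#'
#' Expects a header row, a first column of compound ids, an `activity` column,
#' and numeric descriptor columns (comma separator, "." decimal, UTF-8).
#'
#' @param path CSV file path.
#' @return A [descriptor_table()].
#' @export
read_descriptor_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("descriptor CSV needs an id column, an activity column, and at least one descriptor")
  ids <- as.character(df[[1L]])
  if (!"activity" %in% names(df)) stop("descriptor CSV lacks an 'activity' column")
  activity <- df[["activity"]]
  desc <- df[, setdiff(names(df)[-1L], "activity"), drop = FALSE]
  for (j in seq_along(desc)) {
    col <- desc[[j]]
    if (is.character(col)) col <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(col))
    if (length(bad))
      stop(sprintf("non-numeric or missing cell at row %d, column '%s'",
                   bad[1L], names(desc)[j]))
    desc[[j]] <- col
  }
  descriptor_table(as.matrix(desc), activity, compound_ids = ids)
}

#' Write a descriptor table to CSV
#'
#' Inverse of [read_descriptor_table()]; round-trips are lossless at 15
#' significant digits.
#'
#' @param table A [descriptor_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(table, path) {
  stopifnot(inherits(table, "descriptor_table"))
  df <- data.frame(compound = table$compound_ids,
                   activity = table$activity,
                   check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.data.frame(table$values)
  names(vals) <- table$descriptor_names
  df <- cbind(df, vals)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a metric report to JSON
#'
#' Serializes the full validation panel (see [metric_report()]) to a
#' machine-readable JSON file; unavailable metrics become JSON nulls.
#'
#' @param report A named list of metrics (class `metric_report` or plain list).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  clean <- lapply(report, function(v) {
    if (is.null(v) || (length(v) == 1L && is.na(v))) NULL else v
  })
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a metric report from JSON
#'
#' @param path JSON file written by [write_metric_report()].
#' @return A named list; JSON nulls become `NA`.
#' @export
read_metric_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(rep, function(v) if (is.null(v)) NA_real_ else v)
}
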