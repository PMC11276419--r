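# CSV ingestion and TSV report rendering.
#
# Reports are tab-separated with '#'-prefixed metadata header lines
# (seed, sample size, replicate counts, adjustment flag): greppable,
# spreadsheet-safe and easy to diff. Re-read them with
# read.delim(..., comment.char = "#").

#' Read a regression dataset from CSV
#'
#' Reads a header-rowed CSV and extracts the named outcome and covariate
#' columns into a [bmf_data] object. Parsing is locale-independent (dot
#' decimal separator). Missing values and non-numeric cells are rejected
#' with the offending location; no imputation is performed.
#'
#' @param path Path to the CSV file.
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of covariate column names (may be
#'   empty for an intercept-only problem).
#'
#' @return A [bmf_data] object with rows in file order.
#' @export
read_dataset <- function(path, outcome, covariates = character(0)) {
  if (!file.exists(path))
    stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  wanted <- c(outcome, covariates)
  missing_cols <- setdiff(wanted, names(raw))
  if (length(missing_cols))
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  parse_col <- function(nm) {
    txt <- raw[[nm]]
    bad <- which(is.na(txt) | txt == "" | toupper(txt) == "NA")
    if (length(bad))
      stop("missing value in column '", nm, "', row ", bad[1])
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(val))
    if (length(bad))
      stop("non-numeric value '", txt[bad[1]], "' in column '", nm,
           "', row ", bad[1])
    val
  }
  y <- parse_col(outcome)
  X <- if (length(covariates)) {
    vapply(covariates, parse_col, numeric(nrow(raw)))
  } else NULL
  bmf_data(y, X, covariates)
}

write_tsv_with_header <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    v <- meta[[nm]]
    writeLines(paste0("# ", nm, ": ", if (is.null(v)) "NA" else v), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a model-frequency report
#'
#' Renders one row per candidate model with 0/1 mask indicators for each
#' covariate, the Akaike weight on the original sample, and the bootstrap
#' selection count and frequency. An optional second frequency run (for
#' example the unadjusted companion of an adjusted run on the same seed) is
#' written as an extra column.
#'
#' @param result A `"bmf_result"` from [bmf()].
#' @param weights A `"criterion_table"` from [akaike_weights()] computed on
#'   the same candidate ordering.
#' @param path Output path (tab-separated).
#' @param extra Optional second `"bmf_result"` on the same candidate set;
#'   its frequencies appear as column `frequency_2`.
#'
#' @return The path, invisibly.
#' @export
write_frequency_report <- function(result, weights, path, extra = NULL) {
  stopifnot(inherits(result, "bmf_result"),
            inherits(weights, "criterion_table"))
  m <- nrow(result$table)
  if (nrow(weights) != m)
    stop("weights table has ", nrow(weights), " rows, expected ", m)
  df <- data.frame(result$masks, check.names = FALSE)
  out <- cbind(model = result$table$model, df,
               weight = weights$weight,
               count = result$table$count,
               frequency = result$table$frequency)
  if (!is.null(extra)) {
    stopifnot(inherits(extra, "bmf_result"))
    if (nrow(extra$table) != m)
      stop("extra frequency table has ", nrow(extra$table),
           " rows, expected ", m)
    out$frequency_2 <- extra$table$frequency
  }
  meta <- list(report = "bootstrap model frequencies",
               n = result$n, B = result$B,
               adjusted = result$adjusted,
               seed = if (is.null(result$seed)) "NA" else result$seed,
               redraws = result$redraws)
  if (!is.null(extra))
    meta$frequency_2 <- paste0(if (extra$adjusted) "adjusted" else "unadjusted",
                               " run, seed ",
                               if (is.null(extra$seed)) "NA" else extra$seed)
  write_tsv_with_header(out, path, meta)
}

#' Write a smoothed-coefficient report
#'
#' Renders one row per coefficient with the smoothed estimate, smoothed
#' standard error, confidence bounds and interval length.
#'
#' @param result A `"smoothed_result"` from [smooth_coefficients()] or
#'   [smoothed_ci()].
#' @param path Output path (tab-separated).
#' @param seed Optional seed to record in the header.
#'
#' @return The path, invisibly.
#' @export
write_smoothed_report <- function(result, path, seed = NULL) {
  stopifnot(inherits(result, "smoothed_result"))
  out <- data.frame(variable = result$variable,
                    estimate = result$estimate,
                    se = result$se,
                    ci_low = result$ci_low,
                    ci_high = result$ci_high,
                    ci_length = result$ci_high - result$ci_low,
                    stringsAsFactors = FALSE)
  meta <- list(report = "bootstrap-smoothed coefficients",
               B = if (is.null(attr(result, "B"))) "NA" else attr(result, "B"),
               z = attr(result, "z"),
               seed = if (is.null(seed)) "NA" else seed)
  write_tsv_with_header(out, path, meta)
}
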