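#' Column order of the long-format mobility result table
#' @keywords internal
result_table_columns <- function() {
  c("sample_id", "run", "age_draw", "slice_time", "origin_x", "origin_y",
    "dx", "dy", "length_km", "direction_deg", "tie")
}

#' Validate a long-format mobility result table
#'
#' One row per (sample, resampling run); every pair must be unique.
#'
#' @param table A `data.frame` with the columns of
#'   [result_table_columns()].
#' @return The table, invisibly, if valid.
#' @export
validate_result_table <- function(table) {
  stopifnot(is.data.frame(table))
  missing <- setdiff(result_table_columns(), names(table))
  if (length(missing) > 0) {
    stop("result table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  key <- paste(table$sample_id, table$run)
  if (anyDuplicated(key)) {
    stop("duplicated (sample_id, run) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  invisible(table)
}

#' Write a mobility result table to TSV
#'
#' Deterministic column order, `NA` for missing values, `.` decimal point;
#' `write(read(write(x)))` is byte-identical to `write(x)`.
#'
#' @param table A valid result table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  validate_result_table(table)
  out <- table[, result_table_columns(), drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(format(out, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  invisible(path)
}

#' Read a mobility result table written by [write_results()]
#'
#' @param path Path to a TSV result table.
#' @return A validated result `data.frame`.
#' @export
read_results <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA")
  tab$sample_id <- as.character(tab$sample_id)
  tab$tie <- as.logical(tab$tie)
  validate_result_table(tab)
  tab
}
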