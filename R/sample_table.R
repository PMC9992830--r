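#' Read a per-sample metadata table
#'
#' Reads a TSV/CSV of ancient-DNA sample metadata into a validated sample
#' table. One row per sample with burial coordinates, a calibrated age
#' (median and 2-sigma bounds on the calBC/AD axis, negative = BC) and the
#' quality fields used by the filtering steps. Unknown columns are kept
#' untouched so provenance metadata survives a round trip.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Named character vector mapping the canonical column names
#'   (`id`, `lon`, `lat`, `age_median`, `age_lo`, `age_hi`, and optionally
#'   `n_autosomal_snps`, `molecular_sex`, `x_contamination`, `region_tag`)
#'   to the names used in the file. Defaults to the identity mapping.
#' @param sep Field separator; `"\t"` by default, use `","` for CSV.
#'
#' @return A `data.frame` with canonical column names, one row per sample.
#'   `x`/`y` planar columns are initialised to `NA` (fill them with
#'   [project_coordinates()]). Extra columns from the file are preserved.
#' @export
read_sample_table <- function(path, dialect = NULL, sep = "\t") {
  if (!file.exists(path)) stop("sample table not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""),
                           check.names = FALSE, quote = "", comment.char = "")
  canonical <- c("id", "lon", "lat", "age_median", "age_lo", "age_hi")
  optional <- c("n_autosomal_snps", "molecular_sex", "x_contamination",
                "region_tag")
  map <- stats::setNames(c(canonical, optional), c(canonical, optional))
  if (!is.null(dialect)) map[names(dialect)] <- dialect

  for (col in canonical) {
    if (!map[[col]] %in% names(raw)) {
      stop("sample table is missing required column '", map[[col]], "'")
    }
  }
  out <- data.frame(sample_id = as.character(raw[[map[["id"]]]]),
                    stringsAsFactors = FALSE)
  out$lon <- as.numeric(raw[[map[["lon"]]]])
  out$lat <- as.numeric(raw[[map[["lat"]]]])
  out$x <- NA_real_
  out$y <- NA_real_
  out$age_median <- as.numeric(raw[[map[["age_median"]]]])
  out$age_lo <- as.numeric(raw[[map[["age_lo"]]]])
  out$age_hi <- as.numeric(raw[[map[["age_hi"]]]])
  out$n_autosomal_snps <-
    if (map[["n_autosomal_snps"]] %in% names(raw)) {
      as.numeric(raw[[map[["n_autosomal_snps"]]]])
    } else NA_real_
  out$molecular_sex <-
    if (map[["molecular_sex"]] %in% names(raw)) {
      as.character(raw[[map[["molecular_sex"]]]])
    } else NA_character_
  out$x_contamination <-
    if (map[["x_contamination"]] %in% names(raw)) {
      as.numeric(raw[[map[["x_contamination"]]]])
    } else NA_real_
  out$region_tag <-
    if (map[["region_tag"]] %in% names(raw)) {
      as.character(raw[[map[["region_tag"]]]])
    } else NA_character_

  extras <- setdiff(names(raw), unname(map))
  for (col in extras) out[[col]] <- raw[[col]]

  validate_sample_table(out)
  out
}

#' Validate a sample table against the sample-record invariants
#'
#' Checks `age_lo <= age_median <= age_hi`, coordinate ranges and the
#' molecular-sex vocabulary. Violations raise an error naming the offending
#' sample ids.
#'
#' @param samples A sample table as returned by [read_sample_table()].
#' @return The table, invisibly, if valid.
#' @export
validate_sample_table <- function(samples) {
  stopifnot(is.data.frame(samples))
  needed <- c("sample_id", "lon", "lat", "age_median", "age_lo", "age_hi")
  missing <- setdiff(needed, names(samples))
  if (length(missing) > 0) {
    stop("sample table is missing required column '", missing[[1]], "'")
  }
  bad_order <- which(samples$age_lo > samples$age_median |
                       samples$age_median > samples$age_hi)
  if (length(bad_order) > 0) {
    stop("age bounds violated (need age_lo <= age_median <= age_hi) for ",
         "sample(s): ", paste(samples$sample_id[bad_order], collapse = ", "))
  }
  bad_lon <- which(!is.na(samples$lon) & abs(samples$lon) > 180)
  bad_lat <- which(!is.na(samples$lat) & abs(samples$lat) > 90)
  if (length(c(bad_lon, bad_lat)) > 0) {
    stop("coordinates out of range for sample(s): ",
         paste(unique(samples$sample_id[c(bad_lon, bad_lat)]),
               collapse = ", "))
  }
  if ("molecular_sex" %in% names(samples)) {
    sex <- samples$molecular_sex
    ok <- is.na(sex) | sex %in% c("male", "female", "undetermined")
    if (!all(ok)) {
      stop("molecular_sex must be one of male/female/undetermined for ",
           "sample(s): ", paste(samples$sample_id[!ok], collapse = ", "))
    }
  }
  if ("age_pmf" %in% names(samples)) {
    for (i in seq_len(nrow(samples))) {
      pmf <- samples$age_pmf[[i]]
      if (is.null(pmf) || (length(pmf) == 1 && is.na(pmf[1]))) next
      if (any(pmf$probability < 0) ||
          abs(sum(pmf$probability) - 1) > 1e-9) {
        stop("age_pmf for sample ", samples$sample_id[i],
             " must be non-negative and sum to 1")
      }
    }
  }
  invisible(samples)
}

#' Write a sample table to TSV
#'
#' Canonical columns first, extras after, `NA` for missing, `.` decimal.
#' `read_sample_table(write_sample_table(x))` round-trips the table.
#'
#' @param samples A validated sample table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  validate_sample_table(samples)
  out <- samples
  names(out)[names(out) == "sample_id"] <- "id"
  out$age_pmf <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
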