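#' Sample quality-control filter
#'
#' Keeps samples with at least `snp_min` recovered autosomal SNPs,
#' determinable molecular sex and — for males only — an X-chromosome
#' contamination estimate strictly below `contam_max`. A male with no
#' contamination estimate cannot pass the contamination condition and is
#' rejected; the contamination filter does not apply to females.
#'
#' @param samples A sample table with `n_autosomal_snps`, `molecular_sex`
#'   and `x_contamination` columns.
#' @param snp_min Minimum autosomal SNP count (default 25000).
#' @param contam_max Maximum male X-contamination fraction (default 0.1).
#' @return List with `kept` (the surviving sub-table) and `rejected`
#'   (`data.frame` of `sample_id` and semicolon-joined `reason` strings
#'   drawn from `snp_count`, `undetermined_sex`, `contamination`).
#' @export
qc_filter <- function(samples, snp_min = 25000, contam_max = 0.1) {
  validate_sample_table(samples)
  snp_ok <- !is.na(samples$n_autosomal_snps) &
    samples$n_autosomal_snps >= snp_min
  sex_ok <- !is.na(samples$molecular_sex) &
    samples$molecular_sex %in% c("male", "female")
  contam_ok <- samples$molecular_sex %in% "female" |
    (!is.na(samples$x_contamination) & samples$x_contamination < contam_max)
  keep <- snp_ok & sex_ok & contam_ok
  reasons <- vapply(seq_len(nrow(samples)), function(i) {
    r <- c(if (!snp_ok[i]) "snp_count",
           if (!sex_ok[i]) "undetermined_sex",
           if (sex_ok[i] && !contam_ok[i]) "contamination")
    paste(r, collapse = ";")
  }, character(1))
  list(kept = samples[keep, , drop = FALSE],
       rejected = data.frame(sample_id = samples$sample_id[!keep],
                             reason = reasons[!keep],
                             stringsAsFactors = FALSE))
}

#' Relatedness filter on an IBS distance matrix
#'
#' Builds a graph connecting samples whose pairwise distance falls below
#' `threshold` (close relatives or duplicate libraries of one individual)
#' and keeps, from each connected group, only the best-preserved sample —
#' the one with the highest autosomal SNP count, ties broken by the
#' lexicographically smallest sample id.
#'
#' @param D An [ibs_distance_matrix()] result.
#' @param quality Named numeric vector mapping every sample id in `D` to
#'   its autosomal SNP count.
#' @param threshold Distance below which a pair counts as related
#'   (default 0.245).
#' @return Character vector of kept sample ids, in input order.
#' @export
relatedness_filter <- function(D, quality, threshold = 0.245) {
  stopifnot(inherits(D, "ibs_dist"))
  ids <- D$sample_ids
  missing <- setdiff(ids, names(quality))
  if (length(missing) > 0) {
    stop("no SNP count for sample(s): ", paste(missing, collapse = ", "))
  }
  adj <- !is.na(D$d) & D$d < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  kept <- vapply(split(ids, comp), function(members) {
    q <- quality[members]
    best <- members[q == max(q)]
    sort(best)[1]
  }, character(1))
  ids[ids %in% kept]
}

#' Remove loci falling in configured high-LD regions
#'
#' Long-range linkage-disequilibrium regions distort distance-based
#' dimension reduction; their coordinates are supplied as configuration
#' (BED-like: chromosome, 1-based inclusive start, exclusive end).
#'
#' @param loci `data.frame` with `chrom` and `pos` columns (1-based).
#' @param regions `data.frame` with `chrom`, `start`, `end` columns;
#'   half-open intervals `[start, end)`. Empty or `NULL` keeps every locus.
#' @return Logical vector, `TRUE` for loci to keep.
#' @export
ld_region_mask <- function(loci, regions) {
  keep <- rep(TRUE, nrow(loci))
  if (is.null(regions) || nrow(regions) == 0) return(keep)
  if (any(regions$start >= regions$end)) {
    stop("malformed LD region (start >= end) at row ",
         which(regions$start >= regions$end)[1])
  }
  for (i in seq_len(nrow(regions))) {
    hit <- loci$chrom == regions$chrom[i] &
      loci$pos >= regions$start[i] & loci$pos < regions$end[i]
    keep[hit] <- FALSE
  }
  keep
}
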