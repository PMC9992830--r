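#' Pairwise identity-by-state distance matrix
#'
#' Computes, for every pair of samples, `1 - mean per-locus IBS share` over
#' the loci where both genotypes are observed. The diploid per-locus share
#' is `1 - |g_i - g_j| / 2`, so opposite homozygotes (0 vs 2) share nothing,
#' a het against either homozygote shares one allele (0.5), and identical
#' calls share fully. This is the allele-sharing convention behind
#' "1 - proportion of alleles identical by state".
#'
#' @param G A [genotype_matrix()] with dosage calls 0/1/2/`NA`.
#' @return An object of class `ibs_dist`: list with `sample_ids`, the
#'   symmetric distance matrix `d` in `[0, 1]` (zero diagonal; `NA` where a
#'   pair shares no observed locus, with a warning), and the matrix
#'   `n_overlap` of pairwise observed-locus counts.
#' @export
ibs_distance_matrix <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  calls <- G$calls
  obs <- !is.na(calls)
  mode(obs) <- "numeric"
  n_overlap <- crossprod(obs)
  # sum over shared loci of |g_i - g_j| via dosage-level indicator matrices:
  # |u - v| summed over value pairs (u, v) in {0,1,2}^2
  ind <- lapply(0:2, function(v) {
    m <- !is.na(calls) & calls == v
    mode(m) <- "numeric"
    m
  })
  absdiff <- matrix(0, ncol(calls), ncol(calls))
  for (u in 0:2) {
    for (v in 0:2) {
      if (u == v) next
      absdiff <- absdiff + abs(u - v) * crossprod(ind[[u + 1]], ind[[v + 1]])
    }
  }
  d <- absdiff / (2 * n_overlap)
  d[n_overlap == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(G$sample_ids, G$sample_ids)
  dimnames(n_overlap) <- dimnames(d)
  if (anyNA(d)) {
    idx <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    pairs <- apply(idx, 1, function(ij) {
      paste(G$sample_ids[ij[1]], G$sample_ids[ij[2]], sep = "/")
    })
    warning("no overlapping loci for pair(s): ",
            paste(pairs, collapse = ", "))
  }
  structure(list(sample_ids = G$sample_ids, d = d, n_overlap = n_overlap),
            class = "ibs_dist")
}

#' @export
print.ibs_dist <- function(x, ...) {
  cat("<ibs_dist> ", length(x$sample_ids), " samples, distance range [",
      format(min(x$d, na.rm = TRUE), digits = 4), ", ",
      format(max(x$d, na.rm = TRUE), digits = 4), "]\n", sep = "")
  invisible(x)
}
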