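#' Classical multidimensional scaling of a genetic distance matrix
#'
#' Torgerson scaling: square the distances, double-centre
#' (`B = -1/2 J D^2 J`), eigendecompose, and scale the top-`k`
#' positive-eigenvalue eigenvectors by the square root of their eigenvalues.
#' The resulting columns are the "ancestry components" used as dependent
#' variables of the spatiotemporal interpolation — orthogonal axes of
#' genetic distance, not admixture proportions. Signs are fixed so each
#' component's largest-magnitude loading is positive, making the embedding
#' reproducible across platforms.
#'
#' @param D An [ibs_distance_matrix()] result, or any symmetric numeric
#'   distance matrix with zero diagonal. Must be complete: pairs without
#'   overlap must be resolved upstream (relatedness / overlap filters)
#'   before embedding.
#' @param k Number of components (default 2).
#' @return An object of class `ancestry_coords`: list with `sample_ids`,
#'   the `n x k` matrix `coords` (columns `C1..Ck`, centred), and the `k`
#'   retained `eigenvalues` in descending order.
#' @export
classical_mds <- function(D, k = 2) {
  if (inherits(D, "ibs_dist")) {
    ids <- D$sample_ids
    d <- D$d
  } else {
    d <- as.matrix(D)
    ids <- rownames(d)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(d)))
  }
  if (anyNA(d)) {
    stop("distance matrix has missing entries; resolve zero-overlap pairs ",
         "(relatedness / minimum-overlap filtering) before MDS")
  }
  n <- nrow(d)
  if (k < 1 || k > n - 1) stop("k must be between 1 and n - 1")
  d2 <- d^2
  # double centering: B = -1/2 * J d2 J with J = I - 11'/n
  rm_ <- rowMeans(d2)
  B <- -0.5 * (d2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) +
                 mean(d2))
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-12 & eig$values > 0
  if (sum(pos) < k) {
    stop("only ", sum(pos), " positive eigenvalue(s); cannot extract k = ",
         k, " components")
  }
  vals <- eig$values[seq_len(k)]
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals), nrow = k)
  # deterministic sign: largest-magnitude entry of each column positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(ids, paste0("C", seq_len(k)))
  structure(list(sample_ids = ids, coords = coords, eigenvalues = vals),
            class = "ancestry_coords")
}

#' @export
print.ancestry_coords <- function(x, ...) {
  cat("<ancestry_coords> ", length(x$sample_ids), " samples x ",
      ncol(x$coords), " components; eigenvalues: ",
      paste(format(x$eigenvalues, digits = 4), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Export ancestry coordinates as TSV
#'
#' @param ac An [classical_mds()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ancestry_coords <- function(ac, path) {
  stopifnot(inherits(ac, "ancestry_coords"))
  out <- data.frame(sample_id = ac$sample_ids, ac$coords,
                    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read ancestry coordinates written by [write_ancestry_coords()]
#'
#' @param path Path to the TSV.
#' @return An `ancestry_coords` object (eigenvalues unavailable, `NA`).
#' @export
read_ancestry_coords <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  coords <- as.matrix(tab[, grep("^C[0-9]+$", names(tab)), drop = FALSE])
  rownames(coords) <- tab$sample_id
  structure(list(sample_ids = as.character(tab$sample_id), coords = coords,
                 eigenvalues = rep(NA_real_, ncol(coords))),
            class = "ancestry_coords")
}
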