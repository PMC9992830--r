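#' Genotype matrix constructor
#'
#' Container for a biallelic genotype matrix in alternate-allele dosage
#' coding (0/1/2, `NA` = missing), with loci in rows and samples in columns
#' as in the EIGENSTRAT `.geno` layout.
#'
#' @param calls Integer matrix, loci x samples, values in `{0, 1, 2, NA}`.
#' @param sample_ids Character vector, one per column of `calls`.
#' @param loci `data.frame` with columns `id`, `chrom`, `pos` (1-based),
#'   one row per row of `calls`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sample_ids, loci) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != length(sample_ids)) {
    stop("calls has ", ncol(calls), " columns but ", length(sample_ids),
         " sample ids were given")
  }
  if (nrow(calls) != nrow(loci)) {
    stop("calls has ", nrow(calls), " rows but ", nrow(loci),
         " loci were given")
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) > 0 && !all(bad %in% 0:2)) {
    stop("genotype calls must be 0, 1, 2 or missing")
  }
  structure(list(calls = calls,
                 sample_ids = as.character(sample_ids),
                 loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$calls), " loci x ",
      length(x$sample_ids), " samples, ",
      sum(is.na(x$calls)), " missing calls\n", sep = "")
  invisible(x)
}

#' Read an EIGENSTRAT genotype triple
#'
#' Reads `.geno` (one line per SNP, one character per sample: `0`, `1`, `2`
#' or `9` for missing), `.snp` (locus id, chromosome, genetic position,
#' physical position, alleles) and `.ind` (sample id, sex, group) files
#' sharing a path prefix, and checks their mutual consistency.
#'
#' @param prefix Path stem; `<prefix>.geno`, `<prefix>.snp`, `<prefix>.ind`
#'   must all exist.
#' @return A [genotype_matrix()] with `9` mapped to `NA`.
#' @export
read_eigenstrat <- function(prefix) {
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  for (p in paths) if (!file.exists(p)) stop("missing EIGENSTRAT file: ", p)

  ind <- utils::read.table(paths[3], header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("id", "sex", "group"))
  snp_raw <- utils::read.table(paths[2], header = FALSE,
                               stringsAsFactors = FALSE)
  if (ncol(snp_raw) < 4) stop("malformed .snp file: expected >= 4 columns")
  loci <- data.frame(id = as.character(snp_raw[[1]]),
                     chrom = as.character(snp_raw[[2]]),
                     pos = as.integer(snp_raw[[4]]),
                     stringsAsFactors = FALSE)

  lines <- readLines(paths[1])
  if (length(lines) != nrow(loci)) {
    stop(".geno has ", length(lines), " lines but .snp lists ",
         nrow(loci), " loci")
  }
  n_samp <- nrow(ind)
  calls <- matrix(NA_integer_, nrow = length(lines), ncol = n_samp)
  for (i in seq_along(lines)) {
    if (nchar(lines[i]) != n_samp) {
      stop(".geno line ", i, " has ", nchar(lines[i]),
           " characters but .ind lists ", n_samp, " samples")
    }
    chars <- strsplit(lines[i], "", fixed = TRUE)[[1]]
    bad <- !chars %in% c("0", "1", "2", "9")
    if (any(bad)) {
      stop(".geno line ", i, " contains illegal character '",
           chars[which(bad)[1]], "'")
    }
    vals <- match(chars, c("0", "1", "2")) - 1L
    calls[i, ] <- vals
  }
  genotype_matrix(calls, ind$id, loci)
}

#' Write an EIGENSTRAT genotype triple
#'
#' Inverse of [read_eigenstrat()]: `NA` is written as `9`. The `.snp` file
#' gets a zero genetic position and `A`/`T` placeholder alleles when the
#' object carries none; `.ind` sex and group default to `U` and `ancient`.
#'
#' @param G A [genotype_matrix()].
#' @param prefix Output path stem.
#' @return `prefix`, invisibly.
#' @export
write_eigenstrat <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  chr <- matrix("9", nrow = nrow(G$calls), ncol = ncol(G$calls))
  for (v in 0:2) chr[!is.na(G$calls) & G$calls == v] <- as.character(v)
  writeLines(apply(chr, 1, paste, collapse = ""), paste0(prefix, ".geno"))
  snp <- data.frame(id = G$loci$id, chrom = G$loci$chrom, gen = 0,
                    pos = G$loci$pos, ref = "A", alt = "T")
  utils::write.table(snp, paste0(prefix, ".snp"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ind <- data.frame(id = G$sample_ids, sex = "U", group = "ancient")
  utils::write.table(ind, paste0(prefix, ".ind"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
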