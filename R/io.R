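#' Write genotypes as PLINK .ped/.map text files
#'
#' Alleles are coded A (reference) / B (counted); missing genotypes as "0 0".
#' The .map file carries one dummy chromosome with SNPs at 1 kb spacing.
#'
#' @param gm \code{genotype_matrix} or 0/1/2 matrix with NA for missing.
#' @param prefix path prefix; \code{<prefix>.ped} and \code{<prefix>.map} are
#'   written.
#' @return invisibly, the two file paths.
#' @export
write_plink <- function(gm, prefix) {
  M <- if (inherits(gm, "genotype_matrix")) gm$geno else as.matrix(gm)
  ids <- rownames(M) %||% sprintf("A%04d", seq_len(nrow(M)))
  snps <- colnames(M) %||% sprintf("SNP%05d", seq_len(ncol(M)))
  a1 <- matrix("A", nrow(M), ncol(M)); a2 <- a1
  a1[M >= 1] <- "B"; a2[M == 2] <- "B"
  a1[is.na(M)] <- "0"; a2[is.na(M)] <- "0"
  gen <- matrix("", nrow(M), 2 * ncol(M))
  gen[, seq(1, 2 * ncol(M), 2)] <- a1
  gen[, seq(2, 2 * ncol(M), 2)] <- a2
  ped <- cbind("FAM1", ids, "0", "0", "0", "-9", gen)
  write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  map <- data.frame(chr = 1L, snp = snps, cm = 0, bp = seq_len(ncol(M)) * 1000L)
  write.table(map, paste0(prefix, ".map"), quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}

#' Read PLINK .ped/.map text files into a 0/1/2 genotype matrix
#'
#' The counted allele per SNP is the "B" allele written by [write_plink()];
#' for generic files it is the second distinct allele observed. "0 0" is
#' treated as missing.
#'
#' @param prefix path prefix of the .ped/.map pair.
#' @return \code{genotype_matrix} object.
#' @export
read_plink <- function(prefix) {
  ped <- read.table(paste0(prefix, ".ped"), colClasses = "character")
  map <- read.table(paste0(prefix, ".map"), colClasses = "character")
  n_snps <- nrow(map)
  stopifnot(ncol(ped) == 6 + 2 * n_snps)
  ids <- ped[[2]]
  M <- matrix(NA_integer_, nrow(ped), n_snps,
              dimnames = list(ids, map[[2]]))
  for (j in seq_len(n_snps)) {
    A1 <- ped[[6 + 2 * j - 1]]
    A2 <- ped[[6 + 2 * j]]
    alleles <- setdiff(sort(unique(c(A1, A2))), "0")
    # A/B is this package's own dialect (B = counted), so a SNP showing only
    # "A" is monomorphic reference; generic files count the last allele seen
    counted <- if (any(c("A", "B") %in% alleles)) "B" else alleles[length(alleles)]
    g <- (A1 == counted) + (A2 == counted)
    g[A1 == "0" | A2 == "0"] <- NA_integer_
    M[, j] <- g
  }
  structure(list(geno = M, sire = rep(NA_integer_, nrow(M)),
                 maf = pmin(colMeans(M, na.rm = TRUE) / 2,
                            1 - colMeans(M, na.rm = TRUE) / 2)),
            class = "genotype_matrix")
}

#' Write / read the plain 0/1/2 genotype text dialect
#'
#' Tab-separated matrix with animal ids in the first column, SNP ids in the
#' header, and "NA" for missing calls.
#' @param gm genotype matrix (or \code{genotype_matrix} object).
#' @param path file path.
#' @return \code{read_geno_matrix} returns a \code{genotype_matrix} object.
#' @export
write_geno_matrix <- function(gm, path) {
  M <- if (inherits(gm, "genotype_matrix")) gm$geno else as.matrix(gm)
  df <- data.frame(animal_id = rownames(M), M, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geno_matrix
#' @export
read_geno_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "integer"
  rownames(M) <- df[[1]]
  structure(list(geno = M, sire = rep(NA_integer_, nrow(M)),
                 maf = pmin(colMeans(M, na.rm = TRUE) / 2,
                            1 - colMeans(M, na.rm = TRUE) / 2)),
            class = "genotype_matrix")
}

#' Write a genomic relationship matrix as text
#'
#' @param grm [vanraden_grm()] object.
#' @param path_dense dense symmetric matrix with an id header; NULL to skip.
#' @param path_triplet long (i, j, value) triplets of the lower triangle;
#'   NULL to skip.
#' @export
write_grm <- function(grm, path_dense = NULL, path_triplet = NULL) {
  stopifnot(inherits(grm, "grm"))
  if (!is.null(path_dense)) {
    df <- data.frame(animal_id = rownames(grm$G), grm$G, check.names = FALSE)
    write.table(df, path_dense, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_triplet)) {
    idx <- which(lower.tri(grm$G, diag = TRUE), arr.ind = TRUE)
    trip <- data.frame(i = rownames(grm$G)[idx[, 1]],
                       j = colnames(grm$G)[idx[, 2]],
                       value = grm$G[idx])
    write.table(trip, path_triplet, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

#' Write / read long-format phenotype and climate tables as CSV
#' @param x data frame.
#' @param path file path.
#' @export
write_phenotypes <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if ("date" %in% names(x)) x$date <- as.Date(x$date)
  class(x) <- c("phenotype_table", "data.frame")
  x
}

#' @rdname write_phenotypes
#' @export
write_climate <- function(x, path) {
  x$timestamp <- format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_climate <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  x$timestamp <- as.POSIXct(x$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  class(x) <- c("climate_series", "data.frame")
  x
}
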