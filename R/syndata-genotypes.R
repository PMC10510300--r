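#' Simulate SNP genotypes
#'
#' Draws per-SNP allele frequencies uniformly within \code{maf_range} and
#' samples allele counts. Two population structures are available:
#' \itemize{
#'   \item unrelated animals (default): each genotype is an independent
#'     Binomial(2, p) draw, i.e. Hardy-Weinberg proportions;
#'   \item paternal half-sib families (\code{n_sires > 0}): sire and dam
#'     genotypes are drawn binomially at the same frequencies and each
#'     offspring receives one gamete from its sire and one from its own dam
#'     (gene dropping), giving the sire-family relatedness typical of a
#'     commercial sow herd.
#' }
#' A configurable fraction of deliberately QC-failing SNPs and animals can be
#' injected to exercise the quality-control stage: low-MAF SNPs, low-call-rate
#' SNPs/animals, and SNPs with excess heterozygosity.
#'
#' @param n_animals number of animals (>= 2).
#' @param n_snps number of SNPs (>= 1).
#' @param maf_range length-2 numeric in [0, 0.5]; allele frequencies are drawn
#'   uniformly in this interval.
#' @param missing_rate probability in [0, 1) that any genotype call is missing
#'   (missing completely at random).
#' @param seed integer seed for the genotype stream.
#' @param n_sires number of sires for the half-sib structure; 0 (default)
#'   simulates unrelated animals.
#' @param frac_low_maf,frac_low_call,frac_excess_het fractions of SNPs made to
#'   fail the MAF rule (frequency ~ 0.003), the call-rate rule (55% called),
#'   and the heterozygosity rule (all heterozygous), respectively.
#' @param frac_bad_animals fraction of animals given a low call rate (55%).
#' @return object of class \code{genotype_matrix}: a list with \code{geno}
#'   (n_animals x n_snps integer matrix of 0/1/2 with NA for missing, animal
#'   ids as rownames, SNP ids as colnames), \code{sire} (integer vector of
#'   sire codes, NA when unrelated) and \code{maf} (the simulated allele
#'   frequencies).
#' @export
simulate_genotypes <- function(n_animals, n_snps, maf_range = c(0.05, 0.5),
                               missing_rate = 0, seed = 1, n_sires = 0,
                               frac_low_maf = 0, frac_low_call = 0,
                               frac_excess_het = 0, frac_bad_animals = 0) {
  stopifnot(n_animals >= 2, n_snps >= 1)
  if (length(maf_range) != 2 || any(maf_range < 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("simulate_genotypes: maf_range must be increasing within [0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("simulate_genotypes: missing_rate must be in [0, 1)")
  set.seed(seed)
  p <- runif(n_snps, maf_range[1], maf_range[2])
  sire <- rep(NA_integer_, n_animals)
  if (n_sires > 0) {
    sire <- rep(seq_len(n_sires), length.out = n_animals)
    # gene dropping: two sire alleles per SNP, one transmitted per offspring
    sire_al <- array(rbinom(n_sires * n_snps * 2, 1, rep(p, each = n_sires)),
                     dim = c(n_sires, n_snps, 2))
    pick <- rbinom(n_animals * n_snps, 1, 0.5) + 1L
    sire_row <- rep(sire, times = n_snps)
    snp_col <- rep(seq_len(n_snps), each = n_animals)
    pat <- integer(n_animals * n_snps)
    for (k in 1:2) {
      sel <- which(pick == k)
      pat[sel] <- sire_al[, , k][cbind(sire_row[sel], snp_col[sel])]
    }
    pat <- matrix(pat, n_animals, n_snps)
    mat <- matrix(rbinom(n_animals * n_snps, 1, rep(p, each = n_animals)),
                  n_animals, n_snps)  # maternal gamete, dams unrelated/unique
    geno <- pat + mat
  } else {
    geno <- matrix(rbinom(n_animals * n_snps, 2, rep(p, each = n_animals)),
                   n_animals, n_snps)
  }
  storage.mode(geno) <- "integer"

  n_bad_maf <- round(frac_low_maf * n_snps)
  n_bad_call <- round(frac_low_call * n_snps)
  n_bad_het <- round(frac_excess_het * n_snps)
  bad <- sample.int(n_snps, min(n_snps, n_bad_maf + n_bad_call + n_bad_het))
  idx_maf <- bad[seq_len(n_bad_maf)]
  idx_call <- bad[n_bad_maf + seq_len(n_bad_call)]
  idx_het <- bad[n_bad_maf + n_bad_call + seq_len(n_bad_het)]
  if (length(idx_maf)) {
    geno[, idx_maf] <- matrix(rbinom(n_animals * length(idx_maf), 2, 0.003),
                              n_animals, length(idx_maf))
    p[idx_maf] <- 0.003
  }
  if (length(idx_het)) geno[, idx_het] <- 1L

  if (missing_rate > 0) {
    drop <- matrix(runif(n_animals * n_snps) < missing_rate, n_animals, n_snps)
    geno[drop] <- NA_integer_
  }
  if (length(idx_call)) {
    drop <- matrix(runif(n_animals * length(idx_call)) < 0.45,
                   n_animals, length(idx_call))
    geno[, idx_call][drop] <- NA_integer_
  }
  n_bad_an <- round(frac_bad_animals * n_animals)
  if (n_bad_an > 0) {
    rows <- sample.int(n_animals, n_bad_an)
    drop <- matrix(runif(n_bad_an * n_snps) < 0.45, n_bad_an, n_snps)
    geno[rows, ][drop] <- NA_integer_
  }

  rownames(geno) <- sprintf("A%04d", seq_len(n_animals))
  colnames(geno) <- sprintf("SNP%05d", seq_len(n_snps))
  structure(list(geno = geno, sire = sire, maf = p),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "animals x", ncol(x$geno), "SNPs;",
      sprintf("%.2f%% missing\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}
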