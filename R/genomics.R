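#' Genotype quality control
#'
#' Applies the standard chip QC rules in two steps: first animals with a call
#' rate below \code{call_rate_min} are removed, then SNPs with a call rate
#' below \code{call_rate_min}, a minor allele frequency below \code{maf_min},
#' or an absolute difference between observed and expected (2p(1-p))
#' heterozygote frequencies above \code{het_dev_max}.
#'
#' @param gm \code{genotype_matrix} object or 0/1/2 matrix with NA for missing.
#' @param call_rate_min minimum call rate (default 0.90).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param het_dev_max maximum |observed het - expected het| (default 0.15).
#' @return list of class \code{genotype_qc}: \code{geno} (filtered matrix),
#'   \code{report} (data frame of counts removed per rule), \code{removed}
#'   (ids of dropped animals and SNPs).
#' @export
qc_genotypes <- function(gm, call_rate_min = 0.90, maf_min = 0.01,
                         het_dev_max = 0.15) {
  M <- if (inherits(gm, "genotype_matrix")) gm$geno else as.matrix(gm)
  stopifnot(nrow(M) > 0, ncol(M) > 0,
            call_rate_min >= 0, call_rate_min <= 1,
            maf_min >= 0, maf_min <= 1, het_dev_max >= 0, het_dev_max <= 1)
  cr_animal <- rowMeans(!is.na(M))
  bad_animals <- cr_animal < call_rate_min
  M2 <- M[!bad_animals, , drop = FALSE]
  if (nrow(M2) == 0)
    stop("qc_genotypes: all animals removed by the call-rate rule")

  cr_snp <- colMeans(!is.na(M2))
  p <- colMeans(M2, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  het_obs <- colMeans(M2 == 1, na.rm = TRUE)
  het_exp <- 2 * p * (1 - p)
  bad_cr <- cr_snp < call_rate_min
  bad_maf <- !bad_cr & maf < maf_min
  bad_het <- !bad_cr & !bad_maf & abs(het_obs - het_exp) > het_dev_max
  keep <- !(bad_cr | bad_maf | bad_het)
  keep[is.na(keep)] <- FALSE
  if (!any(keep))
    stop("qc_genotypes: all SNPs removed by QC")

  report <- data.frame(
    rule = c("animal_call_rate", "snp_call_rate", "snp_maf", "snp_het_dev"),
    threshold = c(call_rate_min, call_rate_min, maf_min, het_dev_max),
    removed = c(sum(bad_animals), sum(bad_cr), sum(bad_maf), sum(bad_het)),
    stringsAsFactors = FALSE)
  structure(list(geno = M2[, keep, drop = FALSE], report = report,
                 removed = list(animals = rownames(M)[bad_animals],
                                snps = colnames(M2)[!keep])),
            class = "genotype_qc")
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Missing codes are imputed to the SNP mean 2p; columns are centered by 2p
#' with p the observed post-QC allele frequencies; then
#' \deqn{G = ZZ' / (2 \sum_j p_j (1 - p_j)).}
#' The returned matrix is blended with the identity,
#' \code{(1 - w) G + w I}, to guarantee invertibility for the sampler.
#' Genomic inbreeding is taken from the unblended diagonal,
#' \code{F_i = diag(G) - 1}.
#'
#' @param gm \code{genotype_qc}, \code{genotype_matrix} or 0/1/2 matrix.
#' @param blend_weight identity blending weight w in [0, 1) (default 0.05).
#' @return object of class \code{grm}: \code{G} (blended matrix), \code{G_raw}
#'   (unblended), \code{F_i} (per-animal genomic inbreeding), \code{p}
#'   (allele frequencies used), \code{blend_weight}.
#' @export
vanraden_grm <- function(gm, blend_weight = 0.05) {
  M <- if (inherits(gm, c("genotype_qc", "genotype_matrix"))) gm$geno else as.matrix(gm)
  stopifnot(blend_weight >= 0, blend_weight < 1)
  p <- colMeans(M, na.rm = TRUE) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("vanraden_grm: no polymorphic SNPs (zero denominator)")
  Z <- sweep(M, 2, 2 * p)
  Z[is.na(Z)] <- 0  # missing imputed to the SNP mean 2p, hence 0 after centering
  G_raw <- tcrossprod(Z) / denom
  G_raw <- (G_raw + t(G_raw)) / 2
  G <- (1 - blend_weight) * G_raw + blend_weight * diag(nrow(G_raw))
  dimnames(G) <- dimnames(G_raw) <- list(rownames(M), rownames(M))
  structure(list(G = G, G_raw = G_raw, F_i = diag(G_raw) - 1, p = p,
                 blend_weight = blend_weight),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$G), "animals; blend weight", x$blend_weight,
      sprintf("; mean diagonal %.3f\n", mean(diag(x$G_raw))))
  invisible(x)
}
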