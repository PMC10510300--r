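test_that("QC removes SNPs and animals by the three rules", {
  set.seed(1)
  n <- 60
  M <- matrix(rbinom(n * 30, 2, 0.3), n, 30,
              dimnames = list(sprintf("A%02d", 1:n), sprintf("S%02d", 1:30)))
  M[, 1] <- rbinom(n, 2, 0.005)            # MAF ~ 0.005
  M[, 2] <- 1L                             # all heterozygous: dev 0.5 > 0.15
  M[1, sample(30, 9)] <- NA                # animal call rate 0.70
  M[-1, 3][sample(n - 1, 20)] <- NA        # SNP call rate ~ 0.66
  qc <- qc_genotypes(M)
  expect_true("A01" %in% qc$removed$animals)
  expect_true(all(c("S01", "S02", "S03") %in% qc$removed$snps))
  rep <- qc$report
  expect_equal(rep$removed[rep$rule == "animal_call_rate"], 1)
  expect_gte(rep$removed[rep$rule == "snp_maf"], 1)
  expect_gte(rep$removed[rep$rule == "snp_het_dev"], 1)
})

test_that("QC fails loudly when everything is removed", {
  M <- matrix(1L, 10, 5)  # every SNP fails the heterozygosity rule
  expect_error(qc_genotypes(M), "all SNPs")
})

test_that("QC default thresholds keep clean simulated data", {
  gm <- simulate_genotypes(100, 300, maf_range = c(0.1, 0.5), seed = 2)
  qc <- qc_genotypes(gm)
  expect_equal(nrow(qc$geno), 100)
  expect_gt(ncol(qc$geno), 290)
  gm2 <- simulate_genotypes(100, 300, maf_range = c(0.1, 0.5), seed = 3,
                            frac_low_maf = 0.1, frac_excess_het = 0.1,
                            frac_low_call = 0.1, frac_bad_animals = 0.05)
  qc2 <- qc_genotypes(gm2)
  expect_equal(sum(qc2$report$removed[-1]), 90, tolerance = 10)
  expect_equal(length(qc2$removed$animals), 5)
})

test_that("VanRaden G reproduces the 3-animal / 2-SNP worked instance", {
  M <- rbind(A = c(0, 2), B = c(1, 1), C = c(2, 0))
  G <- vanraden_grm(M, blend_weight = 0)$G
  want <- matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3,
                 dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(G, want)
})

test_that("VanRaden G matches a brute-force oracle, with missing codes", {
  set.seed(4)
  M <- matrix(rbinom(8 * 20, 2, runif(20, 0.1, 0.5)), 8, 20, byrow = TRUE,
              dimnames = list(sprintf("A%d", 1:8), sprintf("S%d", 1:20)))
  M[sample(length(M), 15)] <- NA
  expect_equal(unname(vanraden_grm(M, blend_weight = 0)$G), brute_grm(M),
               tolerance = 1e-12)
})

test_that("identical animals have identical G rows; diag equals off-diag", {
  M <- rbind(A = c(0, 1, 2, 1), B = c(0, 1, 2, 1), C = c(2, 1, 0, 1))
  G <- vanraden_grm(M, blend_weight = 0)$G
  expect_equal(G["A", ], G["B", ])
  expect_equal(G["A", "B"], G["A", "A"])
})

test_that("G is invariant to SNP and animal permutations and SNP duplication", {
  gm <- simulate_genotypes(30, 80, seed = 5)
  M <- gm$geno
  G <- vanraden_grm(M, blend_weight = 0)$G
  set.seed(6)
  js <- sample(ncol(M))
  expect_equal(vanraden_grm(M[, js], blend_weight = 0)$G, G)
  is <- sample(nrow(M))
  expect_equal(vanraden_grm(M[is, ], blend_weight = 0)$G[rownames(M), rownames(M)], G)
  expect_equal(vanraden_grm(cbind(M, M), blend_weight = 0)$G, G)
})

test_that("under HWE the mean diagonal is near 1 and blending gives PD", {
  gm <- simulate_genotypes(300, 3000, maf_range = c(0.05, 0.5), seed = 7)
  g <- vanraden_grm(gm)
  expect_equal(mean(diag(g$G_raw)), 1, tolerance = 0.02)
  expect_gt(min(eigen(g$G, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(g$F_i, diag(g$G_raw) - 1)
  # blending is a numerical device: inbreeding uses the unblended diagonal
  expect_false(isTRUE(all.equal(g$F_i, diag(g$G) - 1)))
})

test_that("monomorphic-only input fails with a zero denominator", {
  M <- matrix(2L, 10, 4)
  expect_error(vanraden_grm(M), "polymorphic")
})

test_that("PLINK and matrix-dialect round trips preserve genotypes", {
  gm <- simulate_genotypes(15, 25, missing_rate = 0.1, seed = 8)
  pre <- file.path(tempdir(), "geno_test")
  write_plink(gm, pre)
  back <- read_plink(pre)
  expect_identical(back$geno, gm$geno)
  p2 <- file.path(tempdir(), "geno_test.tsv")
  write_geno_matrix(gm, p2)
  expect_identical(read_geno_matrix(p2)$geno, gm$geno)
})
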