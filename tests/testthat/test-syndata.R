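test_that("genotype simulation respects missingness and MAF settings", {
  gm <- simulate_genotypes(100, 1000, missing_rate = 0, seed = 1)
  expect_false(anyNA(gm$geno))
  emp_maf <- pmin(colMeans(gm$geno) / 2, 1 - colMeans(gm$geno) / 2)
  expect_true(all(emp_maf <= 0.5 + 1e-9))
  expect_gt(cor(emp_maf, pmin(gm$maf, 1 - gm$maf)), 0.9)

  gm2 <- simulate_genotypes(200, 500, missing_rate = 0.5, seed = 2)
  expect_equal(mean(is.na(gm2$geno)), 0.5, tolerance = 0.01)
})

test_that("unrelated genotypes are in Hardy-Weinberg proportions", {
  gm <- simulate_genotypes(300, 2000, maf_range = c(0.05, 0.5), seed = 3)
  p <- colMeans(gm$geno) / 2
  exp_het <- mean(2 * p * (1 - p))
  obs_het <- mean(gm$geno == 1)
  expect_equal(obs_het, exp_het, tolerance = 0.01)
})

test_that("half-sib families carry the expected genomic relationship", {
  gm <- simulate_genotypes(200, 2000, seed = 4, n_sires = 8)
  G <- vanraden_grm(gm)$G_raw
  same_sire <- outer(gm$sire, gm$sire, "==") & upper.tri(G)
  diff_sire <- (!outer(gm$sire, gm$sire, "==")) & upper.tri(G)
  # centering on observed frequencies shifts the whole matrix, so the
  # half-sib signal shows up as the contrast between the two pair classes
  expect_lt(abs(mean(G[same_sire]) - mean(G[diff_sire]) - 0.25), 0.03)
  expect_lt(abs(mean(G[diff_sire])), 0.06)
})

test_that("genotype simulation is seed-reproducible", {
  a <- simulate_genotypes(50, 100, missing_rate = 0.1, seed = 7)
  b <- simulate_genotypes(50, 100, missing_rate = 0.1, seed = 7)
  c <- simulate_genotypes(50, 100, missing_rate = 0.1, seed = 8)
  expect_identical(a$geno, b$geno)
  expect_false(identical(a$geno, c$geno))
})

test_that("genotype simulation rejects invalid arguments", {
  expect_error(simulate_genotypes(1, 10), "n_animals")
  expect_error(simulate_genotypes(10, 10, maf_range = c(0.2, 0.7)), "maf_range")
  expect_error(simulate_genotypes(10, 10, missing_rate = 1), "missing_rate")
})

test_that("climate simulation has the right shape and diurnal peak", {
  cp <- climate_params(daily_mean_c = 28, amplitude_c = 0, noise_sd_c = 0)
  clim <- simulate_climate(2, 2, cp, seed = 1)
  expect_equal(nrow(clim), 2 * 2 * 288)
  expect_true(all(clim$dbt_c == 28))

  clim4 <- simulate_climate(4, 4, climate_params(), seed = 2)
  expect_equal(nrow(clim4), 4 * 4 * 288)

  # noiseless sinusoid: with 5-min ticks at :00..:55 the 16:00 bin sits
  # closest to the peak, so its hourly mean is the analytic maximum
  cp2 <- climate_params(amplitude_c = 5, phase_h = 16, noise_sd_c = 0)
  h <- hourly_average(simulate_climate(3, 4, cp2, seed = 3))
  agg <- tapply(h$avgtemp_c, h$hour, mean)
  expect_equal(as.integer(names(which.max(agg))), 16)
  expect_true(all(clim4$rh_pct > 0 & clim4$rh_pct <= 100))
})

test_that("breeding values follow the requested covariance structure", {
  expect_equal(simulate_breeding_values(diag(5), matrix(0, 1, 1), seed = 1),
               matrix(0, 5, 1), ignore_attr = TRUE)
  bv <- simulate_breeding_values(diag(10000), matrix(1), seed = 2)
  expect_equal(var(bv[, 1]), 1, tolerance = 0.03)
  # two traits, genetic correlation 0.9
  S <- matrix(c(1, 0.9, 0.9, 1), 2)
  bv2 <- simulate_breeding_values(diag(5000), S, seed = 3)
  expect_equal(cor(bv2)[1, 2], 0.9, tolerance = 0.03)
  expect_error(simulate_breeding_values(diag(3), matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
})

test_that("phenotypes equal their systematic means when all variances are 0", {
  gm <- simulate_genotypes(20, 50, seed = 5)
  grm <- vanraden_grm(gm)
  bv <- matrix(0, 20, 1, dimnames = list(rownames(grm$G), "trait1"))
  params <- true_params(sigma_a = c(trait1 = 0), sigma_e = c(trait1 = 0),
                        mean_value = c(trait1 = 10),
                        parity_effects = c(0, 1, 2, 3, 4, 5))
  layout <- study_layout(rownames(grm$G), n_days = 2, seed = 6)
  ph1 <- simulate_phenotypes(layout, bv, params, seed = 7)
  ph2 <- simulate_phenotypes(layout, bv, params, seed = 99)
  expect_identical(ph1$value, ph2$value)  # no randomness left
  expect_equal(ph1$value, 10 + (ph1$parity - 2))
})

test_that("simulated variance decomposition matches the truth (intraclass)", {
  sim <- simulate_recovery_dataset(2000, 4, sigma_a = 0.3, sigma_pe = 0.3,
                                   sigma_e = 0.4, n_snps = 200,
                                   daughters_per_sire = 0, seed = 11)
  d <- sim$pheno
  res <- resid(lm(value ~ factor(parity), data = d))
  expect_lt(abs(brute_icc(res, d$animal_id) - 0.6), 0.03)
})

test_that("ordinal traits follow the latent-threshold category frequencies", {
  n <- 4000
  gm <- simulate_genotypes(n, 50, seed = 12)
  grm_d <- diag(n)
  rownames(grm_d) <- colnames(grm_d) <- rownames(gm$geno)
  bv <- matrix(0, n, 1, dimnames = list(rownames(gm$geno), "PS"))
  params <- true_params(sigma_a = c(PS = 0), sigma_e = c(PS = 1),
                        parity_effects = 0,
                        thresholds = list(PS = c(-0.5, 0.5)))
  layout <- study_layout(rownames(gm$geno), n_days = 1, hours = 8, seed = 13)
  ph <- simulate_phenotypes(layout, bv, params, seed = 14)
  freq <- as.numeric(table(factor(ph$value, levels = 0:2)) / n)
  want <- c(pnorm(-0.5), pnorm(0.5) - pnorm(-0.5), pnorm(-0.5))
  expect_equal(freq, want, tolerance = 3 * sqrt(0.25 / n) + 0.02)
  expect_error(true_params(sigma_a = c(PS = 0.1), sigma_e = c(PS = 1),
                           thresholds = list(PS = c(0.5, -0.5))),
               "increasing")
})

test_that("phenotype simulation is seed-deterministic", {
  sim1 <- simulate_recovery_dataset(50, 4, sigma_a = 0.3, sigma_pe = 0.2,
                                    sigma_e = 0.5, n_snps = 100, seed = 21)
  sim2 <- simulate_recovery_dataset(50, 4, sigma_a = 0.3, sigma_pe = 0.2,
                                    sigma_e = 0.5, n_snps = 100, seed = 21)
  sim3 <- simulate_recovery_dataset(50, 4, sigma_a = 0.3, sigma_pe = 0.2,
                                    sigma_e = 0.5, n_snps = 100, seed = 22)
  expect_identical(sim1$pheno$value, sim2$pheno$value)
  expect_false(identical(sim1$pheno$value, sim3$pheno$value))
})

test_that("layout referencing unknown animals is rejected", {
  gm <- simulate_genotypes(10, 20, seed = 31)
  grm <- vanraden_grm(gm)
  bv <- simulate_breeding_values(grm, matrix(0.5), seed = 32)
  colnames(bv) <- "trait1"
  params <- true_params(sigma_a = c(trait1 = 0.5), sigma_e = c(trait1 = 0.5))
  layout <- study_layout(c(rownames(grm$G), "GHOST"), n_days = 1, seed = 33)
  expect_error(simulate_phenotypes(layout, bv, params), "GHOST")
})
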