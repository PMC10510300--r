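test_that("backward elimination matches a brute-force RSS oracle", {
  set.seed(1)
  d <- data.frame(value = rnorm(12),
                  f1 = rep(c("a", "b"), 6),
                  f2 = rep(c("x", "y", "z"), 4))
  d$value <- d$value + ifelse(d$f1 == "b", 2, 0)
  # alpha = 1 keeps both factors, exposing the full-model marginal F table
  be <- backward_eliminate(d, c("f1", "f2"), alpha = 1)
  expect_setequal(be$retained, c("f1", "f2"))
  for (f in c("f1", "f2")) {
    oracle <- brute_partial_f(d, c("f1", "f2"), f)
    row <- be$anova[be$anova$factor == f, ]
    expect_equal(row$F, oracle$F, tolerance = 1e-10)
    expect_equal(row$P, oracle$P, tolerance = 1e-10)
  }
})

test_that("elimination keeps strong factors and drops null ones", {
  strong_kept <- 0
  null_dropped <- 0
  for (r in 1:20) {
    set.seed(100 + r)
    n <- 2000
    d <- data.frame(f_strong = sample(c("a", "b"), n, TRUE),
                    f_null = sample(c("u", "v", "w"), n, TRUE))
    d$value <- rnorm(n) + ifelse(d$f_strong == "b", 1, 0)
    be <- backward_eliminate(d, c("f_strong", "f_null"))
    strong_kept <- strong_kept + ("f_strong" %in% be$retained)
    null_dropped <- null_dropped + !("f_null" %in% be$retained)
  }
  expect_equal(strong_kept, 20)
  expect_gte(null_dropped, 16)  # nominal rate 95%
})

test_that("gibbs chain is reproducible and seed-sensitive", {
  sim <- simulate_recovery_dataset(60, 4, sigma_a = 0.3, sigma_pe = 0.2,
                                   sigma_e = 0.5, n_snps = 150, seed = 5)
  cfg <- gibbs_config(600, 100, 5, seed = 42)
  f1 <- gibbs_fit(sim$pheno, model_spec("trait1"), sim$grm, cfg)
  f2 <- gibbs_fit(sim$pheno, model_spec("trait1"), sim$grm, cfg)
  expect_identical(f1$draws, f2$draws)
  cfg$seed <- 43L
  f3 <- gibbs_fit(sim$pheno, model_spec("trait1"), sim$grm, cfg)
  expect_false(identical(f1$draws, f3$draws))
  expect_equal(nrow(f1$draws), (600 - 100) %/% 5)
  expect_true(all(f1$draws$sigma_a > 0) && all(f1$draws$sigma_e > 0))
})

test_that("residual-variance draws match the conjugate closed form (KS)", {
  set.seed(7)
  n <- 120
  d <- data.frame(animal_id = sprintf("A%03d", 1:n), trait = "y",
                  value = rnorm(n, 10, 2),
                  parity = sample(2:7, n, TRUE))
  G <- diag(n); dimnames(G) <- list(d$animal_id, d$animal_id)
  grm <- structure(list(G = G, G_raw = G, F_i = rep(0, n), p = numeric(),
                        blend_weight = 0), class = "grm")
  spec <- model_spec("y", fixed = "parity", additive = FALSE)
  fit <- gibbs_fit(d, spec, grm, gibbs_config(10500, 500, 1, seed = 9))
  X <- model.matrix(~factor(parity), d)
  rss <- sum(resid(lm(d$value ~ X - 1))^2)
  df <- n - ncol(X) - 2  # flat prior: scaled inverse chi-square posterior
  set.seed(10)
  ref <- rss / rchisq(10000, df)
  ks <- suppressWarnings(ks.test(fit$draws$sigma_e, ref))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("posterior mode agrees with an independent REML oracle", {
  sim <- simulate_recovery_dataset(200, 1, sigma_a = 0.5, sigma_e = 0.5,
                                   n_snps = 600, seed = 11)
  d <- sim$pheno[order(sim$pheno$animal_id), ]
  ids <- sort(unique(d$animal_id))
  reml <- reml_animal_model(d$value, model.matrix(~factor(parity), d),
                            sim$grm$G[ids, ids])
  fit <- gibbs_fit(sim$pheno, model_spec("trait1", fixed = "parity"),
                   sim$grm, gibbs_config(12000, 2000, 2, seed = 12))
  mode_of <- function(x) {
    dd <- density(x, n = 1024)
    dd$x[which.max(dd$y)]
  }
  tot_mode <- mode_of(fit$draws$sigma_a + fit$draws$sigma_e)
  h2_mode <- mode_of(fit$draws$sigma_a / (fit$draws$sigma_a + fit$draws$sigma_e))
  expect_lt(abs(h2_mode - reml$h2), 0.06)
  expect_lt(abs(tot_mode - (reml$sigma_a + reml$sigma_e)) /
              (reml$sigma_a + reml$sigma_e), 0.10)
})

test_that("null additive variance is recovered as near-zero heritability", {
  sim <- simulate_recovery_dataset(400, 4, sigma_a = 1e-6, sigma_pe = 0.3,
                                   sigma_e = 0.7, n_snps = 300, seed = 13)
  fit <- gibbs_fit(sim$pheno, model_spec("trait1"), sim$grm,
                   gibbs_config(6000, 1000, 5, seed = 14))
  h2 <- fit$draws$sigma_a /
    (fit$draws$sigma_a + fit$draws$sigma_pe + fit$draws$sigma_e)
  expect_lt(mean(h2), 0.05)
  expect_lt(quantile(h2, 0.05), 0.02)  # credible interval reaches near 0
})

test_that("bivariate fit is label-symmetric and finds a null correlation", {
  sim <- simulate_recovery_dataset(150, 4, sigma_a = c(0.4, 0.4),
                                   sigma_pe = c(0.2, 0.2),
                                   sigma_e = c(0.4, 0.4), rg = 0,
                                   n_snps = 400, seed = 15)
  cfg <- gibbs_config(4000, 1000, 5, seed = 16)
  fab <- gibbs_fit(sim$pheno, model_spec(c("trait1", "trait2")), sim$grm, cfg)
  fba <- gibbs_fit(sim$pheno, model_spec(c("trait2", "trait1")), sim$grm, cfg)
  rg_ab <- mean(genetic_correlation(fab$draws$cov_a12, fab$draws$sigma_a1,
                                    fab$draws$sigma_a2))
  rg_ba <- mean(genetic_correlation(fba$draws$cov_a12, fba$draws$sigma_a1,
                                    fba$draws$sigma_a2))
  sdv <- sd(genetic_correlation(fab$draws$cov_a12, fab$draws$sigma_a1,
                                fab$draws$sigma_a2))
  expect_lt(abs(rg_ab), 2 * sdv)          # null recovery
  expect_lt(abs(rg_ab - rg_ba), 3 * sdv / sqrt(nrow(fab$draws) / 10))
})

test_that("DIC is deviance for a degenerate chain and penalizes extra noise", {
  fake <- list(draws = data.frame(deviance = rep(123.4, 50)),
               deviance_at_mean = 123.4)
  d <- compute_dic(fake)
  expect_equal(d$pd, 0)
  expect_equal(d$dic, 123.4)
  expect_error(compute_dic(list(draws = data.frame(deviance = 1),
                                deviance_at_mean = 1)), "fewer than 2")
})

test_that("DIC prefers the model with the generating climate covariate", {
  cs <- sim_climate_trait(n_animals = 120, seed = 21, slope = 0.1)
  cfg <- gibbs_config(3000, 500, 5, seed = 22)
  with_cov <- gibbs_fit(cs$pheno,
                        model_spec("trait1", covariate = "avgtemp"),
                        cs$grm, cfg)
  without <- gibbs_fit(cs$pheno, model_spec("trait1"), cs$grm, cfg)
  expect_lt(compute_dic(with_cov)$dic, compute_dic(without)$dic)
})

test_that("raftery-lewis behaves as documented on iid and AR(1) chains", {
  set.seed(31)
  rl <- raftery_lewis(rnorm(50000))
  expect_gt(rl$dependence_factor, 0.7)
  expect_lt(rl$dependence_factor, 1.5)
  ar <- as.numeric(arima.sim(list(ar = 0.95), 50000))
  rl_ar <- raftery_lewis(ar)
  expect_gt(rl_ar$dependence_factor, 5)
  short <- raftery_lewis(rnorm(100))
  expect_true(isTRUE(short$insufficient))
  const <- raftery_lewis(rep(1, 5000))
  expect_true(isTRUE(const$constant))
})

test_that("raftery-lewis agrees with the coda reference implementation", {
  set.seed(32)
  for (x in list(rnorm(20000), as.numeric(arima.sim(list(ar = 0.8), 20000)))) {
    ours <- raftery_lewis(x)
    ref <- coda::raftery.diag(coda::mcmc(x), q = 0.025, r = 0.005, s = 0.95)
    resmat <- ref$resmatrix
    expect_equal(ours$burnin, unname(resmat[, "M"]))
    # coda's N column is burn-in plus the required kept iterations
    expect_equal(ours$burnin + ours$n, unname(resmat[, "N"]))
    expect_equal(signif(ours$dependence_factor, 3), unname(resmat[, "I"]))
  }
})
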