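# Independent oracles used to check the package's estimators.

# REML for the single-record animal model y = Xb + a + e, a ~ N(0, G sa),
# via the eigendecomposition of G and direct optimisation of the restricted
# log-likelihood. Independent of the Gibbs sampler's code path.
reml_animal_model <- function(y, X, G) {
  eg <- eigen(G, symmetric = TRUE)
  lam <- eg$values
  ys <- crossprod(eg$vectors, y)
  Xs <- crossprod(eg$vectors, X)
  nll <- function(par) {
    sa <- exp(par[1]); se <- exp(par[2])
    v <- sa * lam + se
    W <- Xs / v
    XtVX <- crossprod(Xs, W)
    b <- solve(XtVX, crossprod(W, ys))
    r <- ys - Xs %*% b
    0.5 * (sum(log(v)) + determinant(XtVX)$modulus[1] + sum(r^2 / v))
  }
  o <- optim(c(log(var(y) / 2), log(var(y) / 2)), nll)
  list(sigma_a = exp(o$par[1]), sigma_e = exp(o$par[2]),
       h2 = exp(o$par[1]) / sum(exp(o$par)))
}

# Brute-force VanRaden method-1 G: explicit loops, mean imputation of
# missing, no shared code with vanraden_grm().
brute_grm <- function(M) {
  n <- nrow(M); m <- ncol(M)
  p <- numeric(m)
  for (j in 1:m) p[j] <- mean(M[, j], na.rm = TRUE) / 2
  Z <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) {
    g <- M[i, j]
    if (is.na(g)) g <- 2 * p[j]
    Z[i, j] <- g - 2 * p[j]
  }
  den <- 0
  for (j in 1:m) den <- den + 2 * p[j] * (1 - p[j])
  G <- matrix(0, n, n)
  for (i in 1:n) for (k in 1:n) G[i, k] <- sum(Z[i, ] * Z[k, ]) / den
  G
}

# Rank-then-Pearson Spearman correlation with average ranks for ties.
brute_spearman <- function(a, b) {
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Partial (marginal) F statistic for dropping `drop_fac` from the model with
# `factors`, by explicit residual-sum-of-squares comparison.
brute_partial_f <- function(d, factors, drop_fac) {
  fml <- function(fs) as.formula(paste("value ~", paste(fs, collapse = "+")))
  full <- lm(fml(factors), data = d)
  red <- lm(fml(setdiff(factors, drop_fac)), data = d)
  rss_f <- sum(resid(full)^2)
  rss_r <- sum(resid(red)^2)
  df1 <- red$df.residual - full$df.residual
  f <- ((rss_r - rss_f) / df1) / (rss_f / full$df.residual)
  list(F = f, P = pf(f, df1, full$df.residual, lower.tail = FALSE))
}

# Balanced one-way intraclass correlation (between-animal variance fraction).
brute_icc <- function(values, groups) {
  gm <- tapply(values, groups, mean)
  m <- length(values) / length(gm)
  msb <- m * var(gm)
  msw <- mean(tapply(values, groups, var))
  (msb - msw) / (msb + (m - 1) * msw)
}

# Small simulated dataset with an hourly-average-temperature effect, for
# covariate-selection checks: returns the phenotype table with avgtemp /
# avg_rh / avg_dp attached, plus the GRM.
sim_climate_trait <- function(n_animals = 150, n_days = 4, seed = 1,
                              slope = 0.08, sigma_a = 0.1, sigma_pe = 0.1,
                              sigma_e = 0.2, n_snps = 400) {
  gm <- simulate_genotypes(n_animals, n_snps, seed = seed, n_sires = max(2, n_animals %/% 25))
  grm <- vanraden_grm(gm)
  bv <- simulate_breeding_values(grm, matrix(sigma_a, 1), seed = seed + 1)
  colnames(bv) <- "trait1"
  cp <- climate_params(daily_mean_c = 28, amplitude_c = 4, phase_h = 16,
                       noise_sd_c = 0.3)
  clim <- simulate_climate(n_days, n_loggers = 4, params = cp,
                           seed = seed + 2, n_rooms = 2)
  params <- true_params(sigma_a = c(trait1 = sigma_a),
                        sigma_pe = c(trait1 = sigma_pe),
                        sigma_e = c(trait1 = sigma_e),
                        mean_value = c(trait1 = 39.5),
                        climate_slope = c(trait1 = slope), climate = cp)
  layout <- study_layout(rownames(grm$G), n_days = n_days, seed = seed + 3)
  pheno <- simulate_phenotypes(layout, bv, params, climate = clim,
                               seed = seed + 4)
  pheno <- attach_climate_all(pheno, hourly_average(clim))
  list(pheno = pheno, grm = grm, truth = list(sigma_a = sigma_a,
       sigma_pe = sigma_pe, sigma_e = sigma_e, slope = slope))
}
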