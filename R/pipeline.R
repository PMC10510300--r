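#' Attach all three hourly climate covariates to a phenotype table
#'
#' Adds \code{avgtemp}, \code{avg_rh} and \code{avg_dp} columns (the hourly
#' room aggregates of the record's measurement hour).
#'
#' @param pheno phenotype table with \code{location}, \code{date}, \code{time}.
#' @param hourly output of [hourly_average()].
#' @return \code{pheno} with the three covariate columns.
#' @export
attach_climate_all <- function(pheno, hourly) {
  for (w in c(avgtemp = "avgtemp_c", avg_rh = "avg_rh_pct", avg_dp = "avg_dp_c")) {
    pheno <- attach_climate(pheno, hourly, w)
    names(pheno)[names(pheno) == "climate"] <-
      names(which(c(avgtemp = "avgtemp_c", avg_rh = "avg_rh_pct",
                    avg_dp = "avg_dp_c") == w))
  }
  pheno
}

#' Single-trait analysis: factor selection, DIC covariate comparison, final fit
#'
#' Runs the full single-trait workflow: backward elimination of candidate
#' fixed factors (P < alpha), one Gibbs fit per candidate climate covariate
#' (plus an optional quadratic average-temperature variant), selection of the
#' lowest-DIC model, and the genetic-parameter report from the selected fit.
#'
#' @param pheno phenotype table containing the trait's records and any
#'   covariate columns (see [attach_climate_all()]).
#' @param trait trait name.
#' @param grm [vanraden_grm()] covering the recorded animals.
#' @param fixed candidate fixed-factor column names.
#' @param covariates candidate climate covariate columns; \code{character(0)}
#'   skips the DIC comparison (traits without a climate term).
#' @param quadratic also try a quadratic term for \code{"avgtemp"}.
#' @param cfg [gibbs_config()].
#' @param alpha backward-elimination significance level.
#' @param pe fit a permanent-environment term (NULL = iff repeated records).
#' @param verbose print stage progress.
#' @return list of class \code{single_trait_run}: \code{params}
#'   ([genetic_parameters()] of the selected model), \code{fit},
#'   \code{elimination}, \code{model_comparison} (covariate, degree, DIC,
#'   h2), \code{selected} (covariate name or "none").
#' @export
run_single_trait <- function(pheno, trait, grm, fixed = character(),
                             covariates = character(), quadratic = FALSE,
                             cfg = gibbs_config(), alpha = 0.05, pe = NULL,
                             verbose = FALSE) {
  d <- pheno[pheno$trait == trait & !is.na(pheno$value), , drop = FALSE]
  if (nrow(d) == 0) stop("run_single_trait: no records for trait ", trait)
  elim <- NULL
  retained <- character()
  if (length(fixed)) {
    usable <- fixed[vapply(fixed, function(f)
      length(unique(d[[f]])) >= 2, TRUE)]
    if (length(usable)) {
      elim <- backward_eliminate(d, usable, alpha = alpha,
                                 covariate = if (length(covariates))
                                   covariates[1] else NULL)
      retained <- elim$retained
    }
  }
  cand <- data.frame(covariate = c(covariates,
                                   if (quadratic && "avgtemp" %in% covariates)
                                     "avgtemp"),
                     degree = c(rep(1L, length(covariates)),
                                if (quadratic && "avgtemp" %in% covariates) 2L),
                     stringsAsFactors = FALSE)
  if (nrow(cand) == 0) cand <- data.frame(covariate = NA_character_, degree = 1L)
  fits <- vector("list", nrow(cand))
  comp <- cand
  comp$dic <- NA_real_
  comp$h2 <- NA_real_
  for (i in seq_len(nrow(cand))) {
    cv <- if (is.na(cand$covariate[i])) NULL else cand$covariate[i]
    spec <- model_spec(trait, fixed = retained, covariate = cv,
                       degree = cand$degree[i], pe = pe)
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i - 1L
    if (verbose) message("fitting ", trait, " | covariate ",
                         cv %||% "none", " degree ", cand$degree[i])
    fits[[i]] <- gibbs_fit(d, spec, grm, cfg_i)
    comp$dic[i] <- compute_dic(fits[[i]])$dic
    gp <- genetic_parameters(fits[[i]], grm)
    comp$h2[i] <- gp$summary$h2[1]
  }
  best <- which.min(comp$dic)
  comp$covariate[is.na(comp$covariate)] <- "none"
  structure(list(params = genetic_parameters(fits[[best]], grm),
                 fit = fits[[best]], elimination = elim,
                 model_comparison = comp,
                 selected = comp$covariate[best],
                 selected_degree = comp$degree[best]),
            class = "single_trait_run")
}

#' @export
print.single_trait_run <- function(x, ...) {
  cat("selected covariate:", x$selected,
      if (x$selected_degree > 1) "(quadratic)" else "", "\n")
  print(x$model_comparison, row.names = FALSE, digits = 6)
  print(x$params)
  invisible(x)
}

#' Bivariate analysis: genetic correlation between two traits
#'
#' Fits the two-trait model with each trait's own fixed/random structure
#' (residual covariance is estimated when the two record sets are paired and
#' fixed at zero otherwise) and reports r_g with its posterior SD.
#'
#' @param pheno phenotype table containing both traits' records.
#' @param trait_a,trait_b trait names.
#' @param grm [vanraden_grm()].
#' @param fixed_a,fixed_b per-trait fixed factors (from the single-trait
#'   runs).
#' @param covariate_a,covariate_b per-trait covariate columns (or NULL).
#' @param degree_a,degree_b covariate degrees.
#' @param pe_a,pe_b permanent-environment flags (NULL = auto).
#' @param cfg [gibbs_config()].
#' @return list of class \code{bivariate_run}: \code{params}
#'   ([genetic_parameters()], including \code{rg}), \code{fit}.
#' @export
run_bivariate <- function(pheno, trait_a, trait_b, grm,
                          fixed_a = character(), fixed_b = fixed_a,
                          covariate_a = NULL, covariate_b = covariate_a,
                          degree_a = 1, degree_b = degree_a,
                          pe_a = NULL, pe_b = NULL,
                          cfg = gibbs_config()) {
  spec <- model_spec(c(trait_a, trait_b),
                     fixed = list(fixed_a, fixed_b),
                     covariate = list(covariate_a, covariate_b),
                     degree = list(degree_a, degree_b),
                     pe = list(pe_a, pe_b))
  fit <- gibbs_fit(pheno, spec, grm, cfg)
  structure(list(params = genetic_parameters(fit, grm), fit = fit),
            class = "bivariate_run")
}

#' @export
print.bivariate_run <- function(x, ...) {
  print(x$params)
  invisible(x)
}

#' Simulate a complete recovery dataset for one or two traits
#'
#' Convenience wrapper tying the generators together for variance-component
#' recovery experiments: simulates genotypes (paternal half-sib families by
#' default, the structure of a commercial sow herd), builds the blended
#' VanRaden G, draws additive values from it, and generates balanced
#' repeated records with parity as a fixed effect.
#'
#' @param n_animals number of animals.
#' @param n_records records per animal per trait (1 = single-record trait).
#' @param sigma_a,sigma_pe,sigma_e per-trait variance components (length 1
#'   or 2).
#' @param rg genetic correlation between the two traits (ignored for one
#'   trait).
#' @param n_snps SNPs for the genomic relationship matrix.
#' @param daughters_per_sire half-sib family size (0 = unrelated animals).
#' @param seed integer seed (drives genotypes, breeding values and records).
#' @param mean_value trait intercept(s).
#' @return list: \code{pheno} (phenotype table), \code{grm}, \code{bv} (true
#'   additive values), \code{truth} (list of true parameters incl. h2, re).
#' @export
simulate_recovery_dataset <- function(n_animals, n_records, sigma_a,
                                      sigma_pe = 0 * sigma_a, sigma_e,
                                      rg = 0, n_snps = 1000,
                                      daughters_per_sire = 25, seed = 1,
                                      mean_value = 39.5) {
  k <- length(sigma_a)
  stopifnot(k %in% 1:2, length(sigma_e) == k)
  n_sires <- if (daughters_per_sire > 0)
    max(2L, ceiling(n_animals / daughters_per_sire)) else 0L
  gm <- simulate_genotypes(n_animals, n_snps, seed = seed, n_sires = n_sires)
  grm <- vanraden_grm(gm)
  traits <- paste0("trait", seq_len(k))
  Sigma_a <- if (k == 2) {
    cv <- rg * sqrt(sigma_a[1] * sigma_a[2])
    matrix(c(sigma_a[1], cv, cv, sigma_a[2]), 2)
  } else matrix(sigma_a, 1)
  bv <- simulate_breeding_values(grm, Sigma_a, seed = seed + 1)
  colnames(bv) <- traits
  params <- true_params(sigma_a = setNames(sigma_a, traits),
                        sigma_pe = setNames(sigma_pe, traits),
                        sigma_e = setNames(sigma_e, traits),
                        Sigma_a = Sigma_a,
                        mean_value = setNames(rep(mean_value, k), traits))
  hours <- c(8, 12, 16, 20)
  n_days <- max(1L, ceiling(n_records / length(hours)))
  layout <- study_layout(rownames(grm$G), n_days = n_days,
                         hours = hours, seed = seed + 2)
  layout$occ <- ave(seq_len(nrow(layout)), layout$animal_id, FUN = seq_along)
  layout <- layout[layout$occ <= n_records, names(layout) != "occ"]
  pheno <- simulate_phenotypes(layout, bv, params, seed = seed + 3)
  tot <- sigma_a + sigma_pe + sigma_e
  list(pheno = pheno, grm = grm, bv = bv,
       truth = list(sigma_a = sigma_a, sigma_pe = sigma_pe,
                    sigma_e = sigma_e, h2 = sigma_a / tot,
                    re = (sigma_a + sigma_pe) / tot, rg = if (k == 2) rg))
}
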