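#' Heritability from variance components
#'
#' \deqn{h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{pe} + \sigma^2_e).}
#' Vectorized over posterior draws; summaries are taken as the mean and SD of
#' the per-draw ratios.
#'
#' @param sa2 additive genetic variance (scalar or per-draw vector).
#' @param spe2 permanent-environment variance (0 for single-record traits).
#' @param se2 residual variance.
#' @return h^2, same length as the inputs.
#' @export
heritability <- function(sa2, spe2 = 0, se2) {
  tot <- sa2 + spe2 + se2
  if (any(sa2 < 0) || any(spe2 < 0) || any(se2 < 0))
    stop("heritability: variances must be >= 0")
  if (any(tot <= 0)) stop("heritability: zero total variance")
  sa2 / tot
}

#' Repeatability from variance components
#'
#' \deqn{r_e = (\sigma^2_a + \sigma^2_{pe}) / (\sigma^2_a + \sigma^2_{pe} +
#' \sigma^2_e).} Equals h^2 when \code{spe2 = 0}.
#'
#' @inheritParams heritability
#' @return r_e, same length as the inputs.
#' @export
repeatability <- function(sa2, spe2 = 0, se2) {
  tot <- sa2 + spe2 + se2
  if (any(sa2 < 0) || any(spe2 < 0) || any(se2 < 0))
    stop("repeatability: variances must be >= 0")
  if (any(tot <= 0)) stop("repeatability: zero total variance")
  (sa2 + spe2) / tot
}

#' Genetic correlation from an additive covariance and two additive variances
#'
#' \deqn{r_g = cov_{12} / \sqrt{\sigma^2_{a1} \sigma^2_{a2}}.}
#' Values exceeding [-1, 1] by less than 1e-8 (floating-point noise) are
#' clipped; larger excursions are an error.
#'
#' @param cov12 additive genetic covariance (scalar or per-draw vector).
#' @param sa2_1,sa2_2 additive genetic variances of the two traits (> 0).
#' @return r_g, same length as the inputs.
#' @export
genetic_correlation <- function(cov12, sa2_1, sa2_2) {
  if (any(sa2_1 <= 0) || any(sa2_2 <= 0))
    stop("genetic_correlation: additive variances must be > 0")
  rg <- cov12 / sqrt(sa2_1 * sa2_2)
  out <- abs(rg) - 1
  if (any(out > 1e-8))
    stop("genetic_correlation: |r_g| exceeds 1 beyond numerical tolerance")
  pmin(pmax(rg, -1), 1)
}

#' Theoretical accuracy of a genomic breeding value
#'
#' \deqn{Accuracy_i = \sqrt{1 - \widehat{SD}_i^2 /
#'   ((1 + F_i)\,\hat\sigma^2_a)},}
#' with \eqn{\widehat{SD}_i} the posterior SD of animal i's sampled additive
#' effect and \eqn{F_i} its genomic inbreeding (unblended GRM diagonal minus
#' one). Ratios exceeding 1 through Monte-Carlo noise give accuracy 0 and are
#' flagged.
#'
#' @param posterior_sd_gebv per-animal posterior SD of the additive effect.
#' @param F_i per-animal genomic inbreeding coefficient (> -1).
#' @param sa2 estimated additive genetic variance (> 0).
#' @return data frame: \code{accuracy}, \code{clamped} (logical flag).
#' @export
theoretical_accuracy <- function(posterior_sd_gebv, F_i, sa2) {
  if (any(sa2 <= 0)) stop("theoretical_accuracy: sa2 must be > 0")
  if (any(F_i <= -1)) stop("theoretical_accuracy: F_i must be > -1")
  ratio <- posterior_sd_gebv^2 / ((1 + F_i) * sa2)
  clamped <- ratio > 1
  data.frame(accuracy = sqrt(pmax(1 - ratio, 0)), clamped = clamped)
}

#' Spearman rank correlation between two traits' GEBVs
#'
#' Rank correlation (average ranks for ties) over the animals shared by the
#' two vectors.
#'
#' @param gebv_a,gebv_b named numeric vectors of per-animal GEBV posterior
#'   means; names are animal ids.
#' @return the Spearman correlation.
#' @export
gebv_spearman <- function(gebv_a, gebv_b) {
  shared <- intersect(names(gebv_a), names(gebv_b))
  if (length(shared) < 3)
    stop("gebv_spearman: fewer than 3 shared animals")
  cor(gebv_a[shared], gebv_b[shared], method = "spearman")
}

#' Posterior summaries of genetic parameters from a Gibbs fit
#'
#' Applies [heritability()], [repeatability()] and (bivariate fits)
#' [genetic_correlation()] per stored draw, then summarizes each by its
#' posterior mean and SD; GEBV accuracies use [theoretical_accuracy()] with
#' the posterior-mean additive variance. Ratios are averaged per draw
#' (posterior mean of the ratio), not taken of posterior means.
#'
#' @param fit a [gibbs_fit()] object.
#' @param grm the [vanraden_grm()] used in the fit (for genomic inbreeding).
#' @return object of class \code{genetic_parameters}: \code{summary} (per
#'   trait: sigma_a, h2, re with posterior means and SDs, mean accuracy),
#'   \code{rg} (bivariate fits: posterior mean and SD), \code{accuracy}
#'   (per-animal table), \code{draws} (per-draw h2/re/rg).
#' @export
genetic_parameters <- function(fit, grm) {
  stopifnot(inherits(fit, "gibbs_fit"), inherits(grm, "grm"))
  d <- fit$draws
  k <- length(fit$spec$traits)
  Fi <- grm$F_i[fit$animals]
  out_sum <- list()
  out_acc <- list()
  draws <- list()
  for (t in seq_len(k)) {
    tr <- fit$spec$traits[t]
    sa <- if (k == 1) d$sigma_a else d[[paste0("sigma_a", t)]]
    spe_name <- if (k == 1) "sigma_pe" else paste0("sigma_pe", t)
    spe <- if (fit$use_pe[t]) d[[spe_name]] else 0
    se <- if (k == 1) d$sigma_e else d[[paste0("sigma_e", t)]]
    h2 <- heritability(sa, spe, se)
    re <- repeatability(sa, spe, se)
    acc <- theoretical_accuracy(fit$gebv$sd[, t], Fi, mean(sa))
    out_sum[[t]] <- data.frame(
      trait = tr, repeated = fit$use_pe[t],
      sigma_a = mean(sa), sigma_a_sd = sd(sa),
      h2 = mean(h2), h2_sd = sd(h2),
      re = if (fit$use_pe[t]) mean(re) else NA_real_,
      re_sd = if (fit$use_pe[t]) sd(re) else NA_real_,
      accuracy = mean(acc$accuracy), accuracy_sd = sd(acc$accuracy),
      stringsAsFactors = FALSE)
    out_acc[[t]] <- data.frame(
      trait = tr, animal_id = fit$animals,
      gebv = fit$gebv$mean[, t], gebv_sd = fit$gebv$sd[, t],
      F_i = Fi, accuracy = acc$accuracy, clamped = acc$clamped,
      stringsAsFactors = FALSE)
    draws[[paste0("h2_", tr)]] <- h2
    draws[[paste0("re_", tr)]] <- re
  }
  rg <- NULL
  if (k == 2) {
    rg_draws <- genetic_correlation(d$cov_a12, d$sigma_a1, d$sigma_a2)
    rg <- data.frame(trait_1 = fit$spec$traits[1],
                     trait_2 = fit$spec$traits[2],
                     rg = mean(rg_draws), rg_sd = sd(rg_draws),
                     stringsAsFactors = FALSE)
    draws$rg <- rg_draws
  }
  structure(list(summary = do.call(rbind, out_sum), rg = rg,
                 accuracy = do.call(rbind, out_acc),
                 draws = as.data.frame(draws)),
            class = "genetic_parameters")
}

#' @export
print.genetic_parameters <- function(x, ...) {
  print(x$summary, row.names = FALSE, digits = 3)
  if (!is.null(x$rg)) print(x$rg, row.names = FALSE, digits = 3)
  invisible(x)
}
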