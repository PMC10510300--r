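#' Variance components from an additive variance, heritability and repeatability
#'
#' Inverts the usual ratios: total phenotypic variance = sigma_a / h2,
#' permanent-environment variance = re * total - sigma_a (0 for single-record
#' traits, re = h2), residual = total - sigma_a - sigma_pe.
#'
#' @param sigma_a additive genetic variance (> 0).
#' @param h2 heritability in (0, 1).
#' @param re repeatability in [h2, 1); defaults to \code{h2} (single-record
#'   trait, no permanent-environment variance).
#' @return list with \code{sigma_a}, \code{sigma_pe}, \code{sigma_e}.
#' @export
trait_variances <- function(sigma_a, h2, re = h2) {
  stopifnot(sigma_a > 0, h2 > 0, h2 < 1, re >= h2, re < 1)
  total <- sigma_a / h2
  sigma_pe <- re * total - sigma_a
  list(sigma_a = sigma_a, sigma_pe = sigma_pe,
       sigma_e = total - sigma_a - sigma_pe)
}

#' True simulation parameters
#'
#' Collects per-trait variance components, the genetic covariance matrix
#' across traits, fixed-effect level values, a climate regression coefficient
#' and ordinal thresholds into one validated object used by the phenotype
#' generator.
#'
#' @param sigma_a,sigma_pe,sigma_e named numeric vectors (one entry per trait)
#'   of additive, permanent-environment and residual variances.
#' @param Sigma_a genetic covariance matrix across the traits (symmetric PSD,
#'   diagonal equal to \code{sigma_a}); defaults to \code{diag(sigma_a)}.
#' @param mean_value named numeric, trait intercepts.
#' @param parity_effects numeric vector of fixed parity-class deviations
#'   (parities 2-7); recycled across traits.
#' @param location_effects,recorder_effects,time_effects optional fixed-level
#'   deviations for location, recorder and time-of-day.
#' @param climate_slope named numeric, trait units per degC of the hourly
#'   climate covariate (0 = no covariate); \code{climate_quad} optional
#'   quadratic coefficient.
#' @param thresholds optional named list of strictly increasing cut points for
#'   ordinal traits (latent-scale thresholds).
#' @param climate [climate_params()] for the barn sinusoid.
#' @return list of class \code{true_params}.
#' @export
true_params <- function(sigma_a, sigma_pe = 0 * sigma_a, sigma_e,
                        Sigma_a = NULL, mean_value = 0 * sigma_a,
                        parity_effects = c(0, 0.05, 0.08, 0.08, 0.05, 0),
                        location_effects = 0, recorder_effects = 0,
                        time_effects = 0,
                        climate_slope = 0 * sigma_a, climate_quad = 0 * sigma_a,
                        thresholds = NULL, climate = climate_params()) {
  traits <- names(sigma_a)
  if (is.null(traits)) {
    traits <- paste0("trait", seq_along(sigma_a))
    names(sigma_a) <- traits
  }
  fill <- function(x) {
    if (is.null(names(x))) x <- setNames(rep_len(x, length(traits)), traits)
    x[traits]
  }
  sigma_pe <- fill(sigma_pe); sigma_e <- fill(sigma_e)
  mean_value <- fill(mean_value)
  climate_slope <- fill(climate_slope); climate_quad <- fill(climate_quad)
  if (any(sigma_a < 0) || any(sigma_pe < 0) || any(sigma_e < 0))
    stop("true_params: variances must be >= 0")
  if (is.null(Sigma_a)) Sigma_a <- diag(sigma_a, nrow = length(sigma_a))
  Sigma_a <- as.matrix(Sigma_a)
  dimnames(Sigma_a) <- list(traits, traits)
  if (!isSymmetric(unname(Sigma_a), tol = 1e-10))
    stop("true_params: Sigma_a must be symmetric")
  if (min(eigen(Sigma_a, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("true_params: Sigma_a must be positive semi-definite")
  if (!is.null(thresholds))
    for (th in thresholds)
      if (is.unsorted(th, strictly = TRUE))
        stop("true_params: ordinal thresholds must be strictly increasing")
  structure(list(traits = traits, sigma_a = sigma_a, sigma_pe = sigma_pe,
                 sigma_e = sigma_e, Sigma_a = Sigma_a,
                 mean_value = mean_value, parity_effects = parity_effects,
                 location_effects = location_effects,
                 recorder_effects = recorder_effects,
                 time_effects = time_effects,
                 climate_slope = climate_slope, climate_quad = climate_quad,
                 thresholds = thresholds, climate = climate),
            class = "true_params")
}

#' Simulate additive genetic values from a genomic relationship matrix
#'
#' Draws a matrix-normal sample with row covariance G and column covariance
#' \code{Sigma_a} via factorization of both matrices, i.e.
#' \code{vec(A) ~ N(0, Sigma_a \%x\% G)}.
#'
#' @param grm a [vanraden_grm()] object or a PSD matrix (the blended G is used
#'   when a \code{grm} object is supplied).
#' @param Sigma_a genetic covariance matrix (k x k, PSD); a scalar is taken as
#'   a single-trait variance.
#' @param seed integer seed.
#' @return n_animals x k matrix of additive genetic values, animal ids as
#'   rownames.
#' @export
simulate_breeding_values <- function(grm, Sigma_a, seed = 1) {
  G <- if (inherits(grm, "grm")) grm$G else as.matrix(grm)
  Sigma_a <- as.matrix(Sigma_a)
  k <- ncol(Sigma_a)
  n <- nrow(G)
  eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(eg$values))
    stop("simulate_breeding_values: G is not positive semi-definite")
  es <- eigen(Sigma_a, symmetric = TRUE)
  if (min(es$values) < -1e-12 * max(abs(es$values), 1))
    stop("simulate_breeding_values: Sigma_a is not positive semi-definite")
  set.seed(seed)
  Lg <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  Ls <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  A <- Lg %*% matrix(rnorm(n * k), n, k) %*% Ls
  rownames(A) <- rownames(G)
  colnames(A) <- colnames(Sigma_a)
  A
}

#' Build a balanced repeated-record measurement layout
#'
#' Records are laid out over consecutive days at the stated measurement hours
#' (the in-barn protocol: a 4-day window with records at 8:00, 12:00, 16:00
#' and 20:00 h), with parity, location and recorder assigned per animal.
#'
#' @param animal_ids character vector of animal ids.
#' @param n_days days of collection.
#' @param hours integer clock hours measured within each day.
#' @param n_locations,n_recorders number of levels to assign round-robin.
#' @param start first collection date.
#' @param seed seed for the parity assignment.
#' @return data frame with one row per planned record: \code{animal_id},
#'   \code{week}, \code{day}, \code{date}, \code{time}, \code{recorder},
#'   \code{parity}, \code{days_in_lactation}, \code{location}.
#' @export
study_layout <- function(animal_ids, n_days = 4, hours = c(8, 12, 16, 20),
                         n_locations = 2, n_recorders = 2,
                         start = as.Date("2021-06-09"), seed = 1) {
  set.seed(seed)
  n <- length(animal_ids)
  per <- data.frame(animal_id = animal_ids,
                    parity = sample(2:7, n, replace = TRUE),
                    location = sprintf("R%02d", ((seq_len(n) - 1) %% n_locations) + 1),
                    recorder = sprintf("REC%d", ((seq_len(n) - 1) %% n_recorders) + 1),
                    days_in_lactation = sample(5:20, n, replace = TRUE),
                    stringsAsFactors = FALSE)
  grid <- expand.grid(day = seq_len(n_days), time = hours,
                      animal_id = animal_ids, stringsAsFactors = FALSE)
  out <- merge(grid, per, by = "animal_id")
  out$date <- start + out$day - 1
  out$week <- 1L + (out$day - 1L) %/% 7L
  out[order(out$animal_id, out$day, out$time), ]
}

#' Simulate phenotype records
#'
#' Generates each record as the sum of its systematic means (intercept,
#' parity, location, recorder and time-of-day deviations), the hourly climate
#' covariate term, the animal's additive genetic value, a permanent-
#' environment effect drawn once per animal (repeated traits only) and an iid
#' residual. Ordinal traits are produced by cutting the continuous latent
#' record at the trait's thresholds.
#'
#' @param design layout data frame from [study_layout()] (or the same columns).
#' @param bv matrix of additive genetic values from
#'   [simulate_breeding_values()], rownames = animal ids, one column per trait.
#' @param params [true_params()].
#' @param climate optional [simulate_climate()] series; when supplied and a
#'   trait has a non-zero \code{climate_slope}, the hourly average temperature
#'   of the record's room-hour enters the record (centered at the daily mean).
#' @param seed integer seed for pe and residual draws.
#' @return long-format phenotype table of class \code{phenotype_table}: the
#'   design columns plus \code{trait} and \code{value}.
#' @export
simulate_phenotypes <- function(design, bv, params, climate = NULL, seed = 1) {
  stopifnot(inherits(params, "true_params"))
  miss <- setdiff(unique(design$animal_id), rownames(bv))
  if (length(miss))
    stop("simulate_phenotypes: layout references animals without breeding values: ",
         paste(head(miss, 3), collapse = ", "))
  set.seed(seed)
  hourly <- if (!is.null(climate)) hourly_average(climate) else NULL
  out <- vector("list", length(params$traits))
  animals <- rownames(bv)
  for (it in seq_along(params$traits)) {
    tr <- params$traits[it]
    d <- design
    d$trait <- tr
    # systematic part
    mu <- params$mean_value[tr] +
      idx_effect(d$parity - 1L, params$parity_effects) +
      idx_effect(match(d$location, sort(unique(d$location))), params$location_effects) +
      idx_effect(match(d$recorder, sort(unique(d$recorder))), params$recorder_effects) +
      idx_effect(match(d$time, sort(unique(d$time))), params$time_effects)
    if (params$climate_slope[tr] != 0 || params$climate_quad[tr] != 0) {
      if (is.null(hourly))
        stop("simulate_phenotypes: trait ", tr,
             " has a climate coefficient but no climate series was given")
      d2 <- attach_climate(d, hourly, "avgtemp_c")
      cov_c <- d2$climate - params$climate$daily_mean_c
      cov_c[is.na(cov_c)] <- 0
      mu <- mu + params$climate_slope[tr] * cov_c +
        params$climate_quad[tr] * cov_c^2
    }
    ai <- match(d$animal_id, animals)
    pe <- if (params$sigma_pe[tr] > 0)
      rnorm(length(animals), 0, sqrt(params$sigma_pe[tr])) else
      numeric(length(animals))
    val <- mu + bv[ai, it] + pe[ai] +
      rnorm(nrow(d), 0, sqrt(params$sigma_e[tr]))
    if (!is.null(params$thresholds[[tr]])) {
      val <- as.numeric(cut(val, c(-Inf, params$thresholds[[tr]], Inf),
                            labels = FALSE)) - 1
    }
    d$value <- val
    out[[it]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("phenotype_table", "data.frame")
  res
}

#' Restrict a true-parameter object to a subset of traits
#'
#' @param params [true_params()].
#' @param traits trait names to keep.
#' @return a \code{true_params} object over the selected traits.
#' @export
params_subset <- function(params, traits) {
  stopifnot(inherits(params, "true_params"), all(traits %in% params$traits))
  out <- params
  out$traits <- traits
  for (f in c("sigma_a", "sigma_pe", "sigma_e", "mean_value",
              "climate_slope", "climate_quad"))
    out[[f]] <- params[[f]][traits]
  out$Sigma_a <- params$Sigma_a[traits, traits, drop = FALSE]
  out$thresholds <- params$thresholds[traits]
  out
}

# pick effect values by level index, recycling and tolerating short vectors
idx_effect <- function(idx, effects) {
  if (length(effects) == 0 || all(effects == 0)) return(numeric(length(idx)))
  effects[((idx - 1L) %% length(effects)) + 1L]
}
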